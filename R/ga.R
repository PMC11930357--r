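#' @include profile-analysis.R
NULL

#' Genetic-algorithm configuration for sub-ensemble selection
#'
#' @param K sub-ensemble size (>= 1, default 20).
#' @param populationSize chromosomes per generation (default 100).
#' @param generations number of generations (default 200).
#' @param mutationRate per-gene mutation probability (default 0.02).
#' @param crossoverRate crossover probability (default 0.8).
#' @param elitism chromosomes copied unchanged (default 2).
#' @param seed RNG seed.
#' @return A `gaConfig` list.
#' @export
gaConfig <- function(K = 20L, populationSize = 100L, generations = 200L,
                     mutationRate = 0.02, crossoverRate = 0.8,
                     elitism = 2L, seed = 1L) {
  stopifnot(K >= 1L, populationSize >= 2L, generations >= 1L,
            mutationRate >= 0, mutationRate <= 1,
            crossoverRate >= 0, crossoverRate <= 1,
            elitism >= 0L, elitism < populationSize)
  structure(list(K = as.integer(K), populationSize = as.integer(populationSize),
                 generations = as.integer(generations),
                 mutationRate = mutationRate, crossoverRate = crossoverRate,
                 elitism = as.integer(elitism), seed = as.integer(seed)),
            class = "gaConfig")
}

#' Select a sub-ensemble by genetic algorithm
#'
#' Chromosomes are multisets of `K` pool indices (repetition allowed, as in
#' ensemble-optimization practice); fitness is the chi2 of the scale-fitted
#' uniform average of the `K` member profiles against the target. Tournament
#' selection, single-point crossover, per-gene mutation to a random pool
#' index, and elitism. Deterministic under a fixed seed.
#'
#' @param poolProfiles list of [ScatteringProfile-class] on the target
#'   q-grid (or an N x M intensity matrix).
#' @param target [ScatteringProfile-class] with positive errors.
#' @param config a [gaConfig()].
#' @return list with `selected` (sorted index multiset), `chi2`, `trace`
#'   (best fitness per generation) and `config`.
#' @export
gaSelect <- function(poolProfiles, target, config = gaConfig()) {
  y <- intensities(target); sig <- sigmas(target)
  if (any(is.na(sig))) stop("target profile must carry errors")
  M <- length(y)
  Imat <- .asIMatrix(poolProfiles, M)
  N <- nrow(Imat)
  if (N < 1L) stop("empty pool")
  if (N < config$K) stop("pool smaller than the sub-ensemble size K")
  K <- config$K
  fitness <- function(chrom) {
    Iavg <- colMeans(Imat[chrom, , drop = FALSE])
    sc <- .fitScale(Iavg, y, sig)
    .chi2(Iavg, y, sig, sc[["scale"]])
  }
  .withSeed(config$seed, function() {
    P <- config$populationSize
    pop <- matrix(sample.int(N, P * K, replace = TRUE), nrow = P)
    fit <- apply(pop, 1L, fitness)
    trace <- numeric(config$generations)
    for (g in seq_len(config$generations)) {
      ord <- order(fit)
      newPop <- matrix(0L, P, K)
      nE <- config$elitism
      if (nE > 0L) newPop[seq_len(nE), ] <- pop[ord[seq_len(nE)], ]
      for (i in seq.int(nE + 1L, P)) {
        pick <- function() {
          cand <- sample.int(P, 2L)
          cand[which.min(fit[cand])]
        }
        p1 <- pop[pick(), ]; p2 <- pop[pick(), ]
        child <- if (stats::runif(1) < config$crossoverRate && K > 1L) {
          cut <- sample.int(K - 1L, 1L)
          c(p1[seq_len(cut)], p2[seq.int(cut + 1L, K)])
        } else p1
        mut <- stats::runif(K) < config$mutationRate
        if (any(mut)) child[mut] <- sample.int(N, sum(mut), replace = TRUE)
        newPop[i, ] <- child
      }
      pop <- newPop
      fit <- apply(pop, 1L, fitness)
      trace[g] <- min(fit)
    }
    best <- which.min(fit)
    ## elitism guarantees the trace is non-increasing
    list(selected = sort(pop[best, ]), chi2 = fit[best],
         trace = cummin(trace), config = config)
  })
}

#' Maximum dimension of a conformer
#'
#' Largest bead-bead distance (Angstrom).
#' @param conformer a [Conformer-class].
#' @return Dmax in Angstrom.
#' @export
conformerDmax <- function(conformer) {
  max(stats::dist(beadCoords(conformer)))
}

#' Pool-versus-selected size distributions
#'
#' Normalized histograms of a size metric (Dmax or Rg) for the full pool
#' ("before", uniform) and a selected sub-ensemble multiset ("after"), on a
#' shared grid -- the standard way of reading ensemble-optimization output.
#'
#' @param pool an [Ensemble-class] (or numeric metric vector).
#' @param selected integer index multiset into the pool.
#' @param metric `"Dmax"` or `"Rg"` (ignored when `pool` is numeric).
#' @param nBreaks number of histogram bins.
#' @return A `distributionPair` list: `mids`, `breaks`, `before`, `after`,
#'   `metric`.
#' @export
distributionReport <- function(pool, selected, metric = c("Dmax", "Rg"),
                               nBreaks = 20L) {
  metric <- match.arg(metric)
  vals <- if (is.numeric(pool)) pool
  else vapply(conformers(pool), function(cf)
    if (metric == "Dmax") conformerDmax(cf) else radiusOfGyration(cf), 0)
  if (any(selected < 1L | selected > length(vals)))
    stop("selected indices out of range")
  rng <- range(vals)
  breaks <- seq(rng[1L] - 1e-9, rng[2L] + 1e-9, length.out = nBreaks + 1L)
  cnt <- function(v) {
    h <- findInterval(v, breaks, rightmost.closed = TRUE)
    tab <- tabulate(h, nbins = nBreaks)
    tab / sum(tab)
  }
  structure(list(mids = (breaks[-1L] + breaks[-(nBreaks + 1L)]) / 2,
                 breaks = breaks, before = cnt(vals),
                 after = cnt(vals[selected]), metric = metric),
            class = "distributionPair")
}
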