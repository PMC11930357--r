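# Shared fixtures, memoized so expensive synthetic ensembles are built once
# per test run.

.fixtureEnv <- new.env(parent = emptyenv())

fixture <- function(name, make) {
  if (!exists(name, envir = .fixtureEnv)) assign(name, make(), envir = .fixtureEnv)
  get(name, envir = .fixtureEnv)
}

# Small single-chain topology: rigid core 10-24, phosphosites 3-6, one basic
# (30-34) and one acidic (15-18) segment. Fast to sample, yet exercises the
# phospho/basic compaction machinery.
toyTopology <- function() {
  fixture("toyTopology", function() {
    seg <- data.frame(name = c("phosS", "bX", "aX"),
                      start = c(3, 30, 15), end = c(6, 34, 18),
                      charge = c(0, 1, -1))
    topologySpec(c(A = 40L),
                 rigidBodies = list(data.frame(chain = "A", start = 10,
                                               end = 24)),
                 phosphoSites = 3:6, segments = seg)
  })
}

toyMixture <- function() {
  fixture("toyMixture", function()
    makeMixtureEnsemble(mixtureSpec(c(0.5, 0.5), kappas = c(5, 0), N = 60L,
                                    topology = toyTopology(), seed = 11L)))
}

randomConformer <- function(n, seed, spread = 10) {
  set.seed(seed)
  Conformer(matrix(stats::rnorm(3 * n, 0, spread), ncol = 3))
}

# independent brute-force of the weighted GROMOS rule, written as plain
# loops over the stated procedure
gromosOracle <- function(D, w, cutoff) {
  N <- nrow(D)
  labels <- rep(NA_integer_, N)
  centers <- integer(); cw <- numeric()
  k <- 0L
  while (anyNA(labels)) {
    scores <- rep(-Inf, N)
    for (j in seq_len(N)) {
      if (!is.na(labels[j])) next
      s <- 0
      for (m in seq_len(N))
        if (is.na(labels[m]) && D[j, m] <= cutoff) s <- s + w[m]
      scores[j] <- s
    }
    best <- which(scores >= max(scores) - 1e-9)[1L]
    k <- k + 1L
    mem <- which(is.na(labels) & D[best, ] <= cutoff)
    labels[mem] <- k
    centers[k] <- best
    cw[k] <- sum(w[mem])
  }
  ord <- order(-round(cw, 9), seq_along(cw))
  relabel <- integer(k); relabel[ord] <- seq_len(k)
  list(labels = relabel[labels], centers = centers[ord], weights = cw[ord])
}

# all compositions of total into N non-negative parts (simplex grid)
simplexGrid <- function(N, step) {
  total <- round(1 / step)
  if (N == 1L) return(matrix(1, 1, 1))
  counts <- seq.int(0L, total)
  grid <- as.matrix(counts)
  for (k in (if (N > 2L) seq.int(2L, N - 1L) else integer())) {
    rows <- lapply(seq_len(nrow(grid)), function(i) {
      left <- total - sum(grid[i, ])
      cbind(matrix(grid[i, ], nrow = left + 1L, ncol = k - 1L,
                   byrow = TRUE), seq.int(0L, left))
    })
    grid <- do.call(rbind, rows)
  }
  grid <- cbind(grid, total - rowSums(grid))
  grid / total
}

# L(w) of the stated reweighting objective (no scale factor), evaluated for
# every row of a weight matrix W (rows on the simplex)
bmeObjective <- function(W, Imat, y, sig, theta, w0) {
  Iavg <- W %*% Imat
  chi2 <- rowSums(sweep(sweep(Iavg, 2L, y), 2L, sig, "/")^2)
  lr <- log(pmax(W, 1e-300) / matrix(w0, nrow(W), ncol(W), byrow = TRUE))
  S <- -rowSums(W * lr)
  chi2 / 2 - theta * S
}
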