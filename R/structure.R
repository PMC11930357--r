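#' @include ga.R
NULL

#' Weighted residue-residue contact probability map
#'
#' A residue pair is in contact when their beads are within `cutoff`
#' (default 11 Angstrom, the coarse-grained bead interaction criterion).
#' The map is the weighted fraction of conformers in which the pair is in
#' contact: `P[a,b] = sum_j w_j 1[d_ab(j) <= cutoff]`. `mode = "intra"`
#' restricts to same-chain pairs (averaged over chains for multimers);
#' `mode = "inter"` to cross-chain pairs, combining both subunit pairings
#' symmetrized.
#'
#' @param ensemble an [Ensemble-class]; chains must share one residue
#'   numbering.
#' @param weights simplex weights (default: ensemble weights).
#' @param cutoff contact distance in Angstrom (default 11).
#' @param mode `"intra"` or `"inter"`.
#' @return A [ContactMap-class].
#' @export
contactProbability <- function(ensemble, weights = NULL, cutoff = 11,
                               mode = c("intra", "inter")) {
  mode <- match.arg(mode)
  if (is.null(weights)) weights <- ensembleWeights(ensemble)
  if (abs(sum(weights) - 1) > 1e-9 || min(weights) < 0)
    stop("weights must lie on the simplex")
  ref <- conformers(ensemble)[[1L]]
  chains <- unique(chainIds(ref))
  if (mode == "inter" && length(chains) < 2L)
    stop("inter-chain map requested for a single-chain system")
  resByChain <- lapply(chains, function(ch)
    residueIds(ref)[chainIds(ref) == ch])
  res <- resByChain[[1L]]
  for (r in resByChain)
    if (!identical(r, res))
      stop("chains must share one residue numbering")
  nr <- length(res)
  acc <- matrix(0, nr, nr)
  for (j in seq_len(nConformers(ensemble))) {
    cf <- conformers(ensemble)[[j]]
    x <- beadCoords(cf)
    cid <- chainIds(cf)
    idx <- lapply(chains, function(ch) which(cid == ch))
    ind <- matrix(0, nr, nr)
    npairs <- 0L
    if (mode == "intra") {
      for (ii in idx) {
        d <- as.matrix(stats::dist(x[ii, , drop = FALSE]))
        ind <- ind + (d <= cutoff)
        npairs <- npairs + 1L
      }
    } else {
      combos <- utils::combn(length(chains), 2L)
      for (k in seq_len(ncol(combos))) {
        i1 <- idx[[combos[1L, k]]]; i2 <- idx[[combos[2L, k]]]
        A <- x[i1, , drop = FALSE]; B <- x[i2, , drop = FALSE]
        d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
        hit <- d2 <= cutoff^2
        ind <- ind + (hit + t(hit)) / 2
        npairs <- npairs + 1L
      }
    }
    acc <- acc + weights[j] * ind / npairs
  }
  acc <- (acc + t(acc)) / 2
  acc[acc > 1] <- 1
  dimnames(acc) <- NULL
  new("ContactMap", probs = acc, residues = as.integer(res),
      mode = mode, cutoff = cutoff)
}

#' Pairwise subset-RMSD matrix of an ensemble
#'
#' @inheritParams subsetRMSD
#' @param ensemble an [Ensemble-class].
#' @return symmetric N x N matrix (Angstrom).
#' @export
rmsdMatrix <- function(ensemble, superposeSel = NULL, rmsdSel = superposeSel,
                       chainSwap = FALSE) {
  confs <- conformers(ensemble)
  N <- length(confs)
  D <- matrix(0, N, N)
  for (i in seq_len(N - 1L)) for (j in seq.int(i + 1L, N)) {
    D[i, j] <- D[j, i] <- subsetRMSD(confs[[i]], confs[[j]],
                                     superposeSel, rmsdSel, chainSwap)
  }
  D
}

#' Weight-modified GROMOS clustering
#'
#' Leader-style conformational clustering in which the neighbour *count* of
#' the classic GROMOS algorithm is replaced by the *sum of the weights* of
#' the neighbours: iteratively, the unassigned conformer whose
#' within-cutoff unassigned neighbourhood (itself included) carries the
#' largest summed weight becomes a cluster center, its neighbours join the
#' cluster and are removed, until everything is assigned. Ties go to the
#' lowest index; clusters are ordered by descending weight. With uniform
#' weights this reduces exactly to classic GROMOS.
#'
#' @param ensemble an [Ensemble-class].
#' @param superposeSel,rmsdSel selections for the RMSD distance measure
#'   (see [subsetRMSD()]).
#' @param cutoff neighbourhood RMSD cutoff in Angstrom.
#' @param chainSwap minimize RMSD over subunit relabeling first.
#' @param weights simplex weights (default: ensemble weights).
#' @param distMatrix optional precomputed [rmsdMatrix()].
#' @return A [ClusterAssignment-class].
#' @export
gromosClusterWeighted <- function(ensemble, superposeSel = NULL,
                                  rmsdSel = superposeSel, cutoff,
                                  chainSwap = FALSE, weights = NULL,
                                  distMatrix = NULL) {
  stopifnot(cutoff > 0)
  if (is.null(weights)) weights <- ensembleWeights(ensemble)
  N <- nConformers(ensemble)
  if (N < 1L) stop("empty ensemble")
  if (abs(sum(weights) - 1) > 1e-9 || min(weights) < 0)
    stop("weights must lie on the simplex")
  if (is.null(distMatrix))
    distMatrix <- rmsdMatrix(ensemble, superposeSel, rmsdSel, chainSwap)
  nb <- distMatrix <= cutoff          # self included: diag is 0 <= cutoff
  labels <- integer(N)
  centers <- integer()
  cw <- numeric()
  unassigned <- rep(TRUE, N)
  k <- 0L
  while (any(unassigned)) {
    score <- as.numeric(nb[, unassigned, drop = FALSE] %*%
                          weights[unassigned])
    score[!unassigned] <- -Inf
    ## ties (within numerical noise) go to the lowest index
    center <- which(score >= max(score) - 1e-9)[1L]
    members <- which(unassigned & nb[center, ])
    k <- k + 1L
    labels[members] <- k
    centers[k] <- center
    cw[k] <- sum(weights[members])
    unassigned[members] <- FALSE
  }
  ord <- order(-round(cw, 9), seq_along(cw))
  relabel <- integer(k)
  relabel[ord] <- seq_len(k)
  new("ClusterAssignment", labels = relabel[labels],
      centers = centers[ord], clusterWeights = cw[ord], cutoff = cutoff)
}

#' Representative structures of the heaviest clusters
#'
#' @param assignment a [ClusterAssignment-class].
#' @param ensemble the clustered [Ensemble-class].
#' @param topK number of clusters to report (default 6).
#' @return list with `conformers` (cluster centers) and `summary`
#'   (data.frame: cluster, center, weight, size).
#' @export
representativeStructures <- function(assignment, ensemble, topK = 6L) {
  k <- length(clusterCenters(assignment))
  if (topK > k) {
    warning(sprintf("only %d cluster(s) available; returning all", k))
    topK <- k
  }
  sel <- seq_len(topK)
  ctr <- clusterCenters(assignment)[sel]
  list(conformers = conformers(ensemble)[ctr],
       summary = data.frame(
         cluster = sel,
         center = ctr,
         weight = clusterWeights(assignment)[sel],
         size = as.integer(table(factor(clusterLabels(assignment),
                                        levels = seq_len(k)))[sel])))
}
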