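#' @import methods
NULL

#' Conformer: a one-bead-per-residue structure
#'
#' A `Conformer` stores one coarse-grained structural model with exactly one
#' bead per residue. Beads carry a 3D position (in Angstrom), a residue
#' number, a chain (subunit/molecule) label, a forward scattering factor
#' \eqn{f_i(0)} and a net charge. Dimers and two-molecule systems are
#' represented with two chains sharing a common residue numbering.
#'
#' @slot coords numeric matrix (n x 3) of bead positions in Angstrom.
#' @slot residueIds integer vector of residue numbers, strictly increasing
#'   within each chain.
#' @slot chainIds character vector of chain labels, one per bead.
#' @slot scatterWeight numeric vector of per-bead forward scattering factors
#'   \eqn{f_i(0)}; non-negative.
#' @slot charge numeric vector of per-bead net charges (e); phosphoserine
#'   beads typically carry -2.
#'
#' @seealso [Conformer()], [radiusOfGyration()], [debyeProfile()]
#' @exportClass Conformer
setClass("Conformer",
  representation(
    coords = "matrix",
    residueIds = "integer",
    chainIds = "character",
    scatterWeight = "numeric",
    charge = "numeric"
  )
)

setValidity("Conformer", function(object) {
  n <- nrow(object@coords)
  msg <- character()
  if (ncol(object@coords) != 3L)
    msg <- c(msg, "coords must have 3 columns")
  if (n < 1L)
    msg <- c(msg, "conformer must contain at least one bead")
  if (!all(is.finite(object@coords)))
    msg <- c(msg, "coordinates must be finite")
  if (length(object@residueIds) != n || length(object@chainIds) != n ||
      length(object@scatterWeight) != n || length(object@charge) != n)
    msg <- c(msg, "per-bead vectors must match the number of beads")
  else {
    for (ch in unique(object@chainIds)) {
      rid <- object@residueIds[object@chainIds == ch]
      if (length(rid) == 0L)
        msg <- c(msg, sprintf("chain '%s' is empty", ch))
      if (any(diff(rid) <= 0L))
        msg <- c(msg, sprintf(
          "residue ids must be strictly increasing within chain '%s'", ch))
    }
    if (any(object@scatterWeight < 0))
      msg <- c(msg, "scatter weights must be non-negative")
    if (!all(is.finite(object@charge)))
      msg <- c(msg, "charges must be finite")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a Conformer
#'
#' @param coords numeric matrix (n x 3), Angstrom.
#' @param residueIds integer residue numbers (default `1:n` in one chain).
#' @param chainIds character chain labels (default `"A"`).
#' @param scatterWeight per-bead \eqn{f_i(0)} (default 1).
#' @param charge per-bead net charge (default 0).
#' @return A [Conformer-class] object.
#' @examples
#' conf <- Conformer(matrix(rnorm(30), ncol = 3))
#' radiusOfGyration(conf)
#' @export
Conformer <- function(coords, residueIds = NULL, chainIds = NULL,
                      scatterWeight = NULL, charge = NULL) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  n <- nrow(coords)
  if (is.null(residueIds)) residueIds <- seq_len(n)
  if (is.null(chainIds)) chainIds <- rep("A", n)
  if (length(chainIds) == 1L) chainIds <- rep(chainIds, n)
  if (is.null(scatterWeight)) scatterWeight <- rep(1, n)
  if (is.null(charge)) charge <- rep(0, n)
  new("Conformer", coords = coords, residueIds = as.integer(residueIds),
      chainIds = as.character(chainIds),
      scatterWeight = as.numeric(scatterWeight), charge = as.numeric(charge))
}

#' Ensemble: a weighted collection of conformers
#'
#' An `Ensemble` holds an ordered list of topologically identical
#' [Conformer-class] objects together with a weight vector `w` on the
#' probability simplex and the initial (prior) weights `w0` used as the
#' reference for reweighting.
#'
#' @slot conformers list of [Conformer-class] objects sharing one topology.
#' @slot weights numeric simplex vector (current weights).
#' @slot initialWeights numeric simplex vector (prior weights `w0`).
#' @slot source character free-text provenance.
#' @exportClass Ensemble
setClass("Ensemble",
  representation(
    conformers = "list",
    weights = "numeric",
    initialWeights = "numeric",
    source = "character"
  )
)

setValidity("Ensemble", function(object) {
  msg <- character()
  N <- length(object@conformers)
  if (N < 1L) msg <- c(msg, "ensemble must contain at least one conformer")
  if (length(object@weights) != N || length(object@initialWeights) != N)
    msg <- c(msg, "weight vectors must have one entry per conformer")
  for (wname in c("weights", "initialWeights")) {
    w <- slot(object, wname)
    if (length(w) == N && N > 0L) {
      if (abs(sum(w) - 1) >= 1e-9)
        msg <- c(msg, sprintf("%s must sum to 1", wname))
      if (min(w) < 0)
        msg <- c(msg, sprintf("%s must be non-negative", wname))
    }
  }
  if (N > 1L) {
    ref <- object@conformers[[1L]]
    for (j in seq.int(2L, N)) {
      cj <- object@conformers[[j]]
      if (!identical(cj@residueIds, ref@residueIds) ||
          !identical(cj@chainIds, ref@chainIds)) {
        msg <- c(msg, sprintf("conformer %d has a different topology", j))
        break
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct an Ensemble
#'
#' @param conformers list of [Conformer-class] objects (identical topology).
#' @param weights simplex weights (default uniform).
#' @param initialWeights prior weights `w0` (default same as `weights`).
#' @param source provenance string.
#' @return An [Ensemble-class] object.
#' @export
Ensemble <- function(conformers, weights = NULL, initialWeights = NULL,
                     source = "unspecified") {
  N <- length(conformers)
  if (is.null(weights)) weights <- rep(1 / N, N)
  if (is.null(initialWeights)) initialWeights <- weights
  new("Ensemble", conformers = conformers, weights = as.numeric(weights),
      initialWeights = as.numeric(initialWeights), source = source)
}

#' ScatteringProfile: a 1D SAXS profile
#'
#' Scattering vector magnitudes `q` (1/Angstrom, strictly increasing,
#' non-negative), intensities `I` and optional per-point errors `sigma`
#' (`NA` where unknown; fitting requires positive errors).
#'
#' @slot q numeric, 1/Angstrom.
#' @slot I numeric intensities (arbitrary units).
#' @slot sigma numeric per-point errors; `NA` marks absent errors.
#' @exportClass ScatteringProfile
setClass("ScatteringProfile",
  representation(q = "numeric", I = "numeric", sigma = "numeric")
)

setValidity("ScatteringProfile", function(object) {
  msg <- character()
  if (length(object@q) != length(object@I) ||
      length(object@q) != length(object@sigma))
    msg <- c(msg, "q, I and sigma must have equal length")
  if (length(object@q)) {
    if (any(object@q < 0)) msg <- c(msg, "q must be non-negative")
    if (any(diff(object@q) <= 0)) msg <- c(msg, "q must be strictly increasing")
    s <- object@sigma[!is.na(object@sigma)]
    if (any(s <= 0)) msg <- c(msg, "sigma must be positive where given")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a ScatteringProfile
#'
#' @param q scattering vector, 1/Angstrom, strictly increasing.
#' @param I intensities.
#' @param sigma optional per-point errors (`NULL` = absent).
#' @return A [ScatteringProfile-class] object.
#' @export
ScatteringProfile <- function(q, I, sigma = NULL) {
  if (is.null(sigma)) sigma <- rep(NA_real_, length(q))
  new("ScatteringProfile", q = as.numeric(q), I = as.numeric(I),
      sigma = as.numeric(sigma))
}

#' ReweightResult: output of Bayesian maximum-entropy reweighting
#'
#' @slot weights optimized simplex weights.
#' @slot lambda Lagrange multipliers of the dual route (length M).
#' @slot chi2 chi-square of the reweighted average against the target.
#' @slot entropy relative entropy S(w) (<= 0).
#' @slot L objective L(w) = chi2/2 - theta * S(w).
#' @slot theta regularization parameter.
#' @slot phiEff effective ensemble fraction exp(S(w)).
#' @slot scale fitted global scale factor.
#' @slot c1 form-factor excluded-volume parameter in effect.
#' @slot c2 form-factor hydration parameter in effect.
#' @slot log list with iteration/protocol history.
#' @exportClass ReweightResult
setClass("ReweightResult",
  representation(
    weights = "numeric", lambda = "numeric", chi2 = "numeric",
    entropy = "numeric", L = "numeric", theta = "numeric",
    phiEff = "numeric", scale = "numeric", c1 = "numeric", c2 = "numeric",
    log = "list"
  )
)

setValidity("ReweightResult", function(object) {
  msg <- character()
  w <- object@weights
  if (abs(sum(w) - 1) > 1e-6) msg <- c(msg, "weights must sum to 1")
  if (min(w) < -1e-12) msg <- c(msg, "weights must be non-negative")
  if (object@phiEff > 1 + 1e-9 || object@phiEff <= 0)
    msg <- c(msg, "phiEff must lie in (0, 1]")
  if (object@entropy > 1e-9) msg <- c(msg, "entropy must be <= 0")
  if (length(msg)) msg else TRUE
})

#' ContactMap: weighted residue-pair interaction probabilities
#'
#' @slot probs numeric matrix of probabilities in \[0, 1\], rows/cols indexed
#'   by residue number.
#' @slot residues integer residue numbers labelling rows/columns.
#' @slot mode `"intra"` (same chain) or `"inter"` (across chains).
#' @slot cutoff contact cutoff in Angstrom.
#' @exportClass ContactMap
setClass("ContactMap",
  representation(probs = "matrix", residues = "integer",
                 mode = "character", cutoff = "numeric")
)

setValidity("ContactMap", function(object) {
  msg <- character()
  p <- object@probs
  if (any(p < -1e-12) || any(p > 1 + 1e-12))
    msg <- c(msg, "probabilities must lie in [0, 1]")
  if (max(abs(p - t(p))) > 1e-9)
    msg <- c(msg, "contact map must be symmetric")
  if (!object@mode %in% c("intra", "inter"))
    msg <- c(msg, "mode must be 'intra' or 'inter'")
  if (length(msg)) msg else TRUE
})

#' ClusterAssignment: weighted GROMOS clustering result
#'
#' @slot labels integer cluster label per conformer (1 = heaviest cluster).
#' @slot centers integer index of the representative (center) per cluster.
#' @slot clusterWeights numeric summed member weights per cluster.
#' @slot cutoff RMSD cutoff in Angstrom.
#' @exportClass ClusterAssignment
setClass("ClusterAssignment",
  representation(labels = "integer", centers = "integer",
                 clusterWeights = "numeric", cutoff = "numeric")
)

setValidity("ClusterAssignment", function(object) {
  msg <- character()
  k <- length(object@centers)
  if (length(object@clusterWeights) != k)
    msg <- c(msg, "one weight per cluster required")
  if (length(object@labels) && !all(object@labels %in% seq_len(k)))
    msg <- c(msg, "labels must reference existing clusters")
  if (abs(sum(object@clusterWeights) - 1) > 1e-6)
    msg <- c(msg, "cluster weights must sum to 1")
  if (length(msg)) msg else TRUE
})
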