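#' @include topology.R
NULL

.BOND <- 3.8      # Calpha virtual bond, Angstrom
.EXCL <- 4.0      # excluded-volume distance between non-bonded beads
.CONTACT_BIAS <- 8.0  # phospho/basic contact distance for the growth bias

.randUnit <- function(n = 1L) {
  z <- matrix(stats::rnorm(3L * n), ncol = 3L)
  z / sqrt(rowSums(z^2))
}

.randRotation <- function() {
  ## QR of a Gaussian matrix, sign-fixed to a proper rotation
  qr_ <- qr(matrix(stats::rnorm(9L), 3L))
  R <- qr.Q(qr_)
  d <- diag(qr.R(qr_))
  R <- R %*% diag(sign(d))
  if (det(R) < 0) R[, 1L] <- -R[, 1L]
  R
}

.minDistToSet <- function(p, set) {
  if (is.null(set) || nrow(set) == 0L) return(Inf)
  sqrt(min(rowSums(sweep(set, 2L, p)^2)))
}

## squared cross-distances between two coordinate sets (rows)
.crossDist2 <- function(A, B) {
  pmax(outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B), 0)
}

## per-row minimum distance from A to B
.rowMinDist <- function(A, B) {
  if (is.null(B) || nrow(B) == 0L) return(rep(Inf, nrow(A)))
  sqrt(apply(.crossDist2(A, B), 1L, min))
}

#' Generate a compact rigid-domain template
#'
#' Grows a 3.8-Angstrom-bond self-avoiding chain inside a confining sphere
#' and accepts the result only if every non-bonded bead pair is at least
#' 4.0 Angstrom apart and the radius of gyration does not exceed
#' `0.9 * (3.8 * nRes^0.33)` -- a compact-globule scaling standing in for an
#' elastic-network domain core. Deterministic in `seed`.
#'
#' @param nRes number of residues (>= 3).
#' @param seed RNG seed.
#' @param maxAttempts regrowth attempts before failing.
#' @return numeric matrix (nRes x 3), centered at the origin.
#' @export
makeRigidDomain <- function(nRes, seed = 1L, maxAttempts = 200L) {
  stopifnot(nRes >= 3L)
  rgMax <- 0.9 * (.BOND * nRes^0.33)
  rSph <- max(rgMax / sqrt(3 / 5), .BOND * 1.2)
  .withSeed(seed, function() {
    for (attempt in seq_len(maxAttempts)) {
      xyz <- matrix(NA_real_, nRes, 3L)
      xyz[1L, ] <- c(stats::runif(1, -1, 1), stats::runif(1, -1, 1),
                     stats::runif(1, -1, 1))
      ok <- TRUE
      for (i in seq.int(2L, nRes)) {
        placed <- FALSE
        for (round in 1:6) {
          u <- .randUnit(30L)
          cand <- sweep(u * .BOND, 2L, xyz[i - 1L, ], FUN = "+")
          inside <- sqrt(rowSums(cand^2)) <= rSph
          if (i > 2L) {
            prev <- xyz[seq_len(i - 2L), , drop = FALSE]
            far <- .rowMinDist(cand, prev) >= .EXCL
          } else far <- rep(TRUE, nrow(cand))
          feas <- which(inside & far)
          if (length(feas)) {
            ## prefer candidates nearer the origin: compact packing
            r2 <- rowSums(cand[feas, , drop = FALSE]^2)
            wts <- exp(-3 * r2 / rSph^2)
            pick <- feas[sample.int(length(feas), 1L, prob = wts)]
            xyz[i, ] <- cand[pick, ]
            placed <- TRUE
            break
          }
        }
        if (!placed) { ok <- FALSE; break }
      }
      if (!ok) next
      conf <- Conformer(xyz)
      if (radiusOfGyration(conf) > rgMax) next
      d <- as.matrix(stats::dist(xyz))
      nb <- abs(row(d) - col(d)) > 1L
      if (min(d[nb]) < .EXCL) next
      return(sweep(xyz, 2L, colMeans(xyz)))
    }
    stop(sprintf(
      "rigid-domain generation failed after %d attempts (nRes = %d, Rg cap %.2f A)",
      maxAttempts, nRes, rgMax))
  })
}

## Soft phospho/basic contact score of candidate bead positions: a
## long-tailed (Cauchy) smoothing of the 8-Angstrom contact indicator, so
## the growth bias funnels tails toward oppositely signed segments even
## before hard contacts form. Zero when the bead has no partners.
.contactGain <- function(cand, beadPhospho, beadBasic, coords, phospho, basic) {
  if (beadPhospho && any(basic)) {
    set <- coords[basic, , drop = FALSE]
  } else if (beadBasic && any(phospho)) {
    set <- coords[phospho, , drop = FALSE]
  } else return(rep(0, nrow(cand)))
  score <- numeric(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    d2 <- rowSums(sweep(set, 2L, cand[k, ])^2)
    score[k] <- sum(1 / (1 + d2 / .CONTACT_BIAS^2))
  }
  score
}

## Grow one molecule of the topology. Returns coords in bead-table order
## (rows of top$beads restricted to the molecule).
.growMolecule <- function(top, molBeads, kappa, maxRestarts = 60L) {
  n <- nrow(molBeads)
  bodies <- sort(unique(molBeads$rigid[!is.na(molBeads$rigid)]))
  key <- paste(molBeads$chain, molBeads$resid)
  for (restart in seq_len(maxRestarts)) {
    coords <- matrix(NA_real_, n, 3L)
    placed <- rep(FALSE, n)
    placeBody <- function(b, anchorIdx = NULL, anchorFrom = NULL) {
      mem <- which(molBeads$rigid %in% b)
      tmpl <- top$templates[[b]]
      for (try in 1:300) {
        R <- .randRotation()
        Tr <- tmpl %*% R
        if (is.null(anchorIdx)) {
          shift <- c(0, 0, 0)
        } else {
          a <- match(anchorIdx, mem)
          u <- .randUnit(1L)[1L, ]
          shift <- coords[anchorFrom, ] + .BOND * u - Tr[a, ]
        }
        cand <- sweep(Tr, 2L, shift, FUN = "+")
        if (any(placed)) {
          prev <- coords[placed, , drop = FALSE]
          dmin <- .rowMinDist(cand, prev)
          ## the anchor bead is bonded to `anchorFrom` (bond < excluded
          ## volume); check it against everything else only
          if (!is.null(anchorIdx)) {
            a <- match(anchorIdx, mem)
            others <- setdiff(which(placed), anchorFrom)
            dmin[a] <- .minDistToSet(cand[a, ],
                                     coords[others, , drop = FALSE])
          }
          if (min(dmin) < .EXCL) next
        }
        coords[mem, ] <<- cand
        placed[mem] <<- TRUE
        return(TRUE)
      }
      FALSE
    }
    growBead <- function(i, from) {
      phosphoHere <- molBeads$phospho[i]
      basicHere <- molBeads$charge[i] > 0
      for (round in 1:8) {
        u <- .randUnit(24L)
        cand <- sweep(u * .BOND, 2L, coords[from, ], FUN = "+")
        prevIdx <- which(placed)
        prevIdx <- prevIdx[prevIdx != from]
        if (length(prevIdx)) {
          prev <- coords[prevIdx, , drop = FALSE]
          feas <- which(.rowMinDist(cand, prev) >= .EXCL)
        } else feas <- seq_len(nrow(cand))
        if (!length(feas)) next
        candF <- cand[feas, , drop = FALSE]
        if (kappa > 0 && (phosphoHere || basicHere)) {
          gain <- .contactGain(candF, phosphoHere, basicHere, coords,
                               molBeads$phospho & placed,
                               molBeads$charge > 0 & placed)
          wts <- exp(kappa * gain)
        } else wts <- rep(1, nrow(candF))
        pick <- feas[sample.int(length(feas), 1L, prob = wts)]
        coords[i, ] <<- cand[pick, ]
        placed[i] <<- TRUE
        return(TRUE)
      }
      FALSE
    }
    ## seed the molecule: largest rigid body, or the first bead
    ok <- TRUE
    if (length(bodies)) {
      sizes <- vapply(bodies, function(b) sum(molBeads$rigid %in% b), 0L)
      primary <- bodies[which.max(sizes)]
      R <- .randRotation()
      mem <- which(molBeads$rigid %in% primary)
      coords[mem, ] <- top$templates[[primary]] %*% R
      placed[mem] <- TRUE
      restBodies <- setdiff(bodies, primary)
    } else {
      coords[1L, ] <- c(0, 0, 0)
      placed[1L] <- TRUE
      restBodies <- integer()
    }
    ## frontier growth until everything is placed
    while (ok && !all(placed)) {
      frontier <- NULL
      for (i in which(!placed)) {
        nb <- which(molBeads$chain == molBeads$chain[i] &
                      abs(molBeads$resid - molBeads$resid[i]) == 1L)
        nb <- nb[placed[nb]]
        if (length(nb)) { frontier <- c(i, nb[1L]); break }
      }
      if (is.null(frontier)) {
        ok <- FALSE  # disconnected within a molecule: should not happen
        break
      }
      i <- frontier[1L]; from <- frontier[2L]
      if (!is.na(molBeads$rigid[i]) && molBeads$rigid[i] %in% restBodies) {
        if (!placeBody(molBeads$rigid[i], anchorIdx = i, anchorFrom = from)) {
          ok <- FALSE; break
        }
        restBodies <- setdiff(restBodies, molBeads$rigid[i])
      } else {
        if (!growBead(i, from)) { ok <- FALSE; break }
      }
    }
    if (ok) return(coords)
  }
  stop("unsatisfiable excluded volume while growing a molecule; ",
       "increase maxRestarts or loosen the topology")
}

.rodrigues <- function(ax, ang) {
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
              3L, byrow = TRUE)
  diag(3) + sin(ang) * K + (1 - cos(ang)) * K %*% K
}

## total soft phospho/basic contact score of one molecule
.softContactEnergy <- function(coords, phospho, basic) {
  if (!any(phospho) || !any(basic)) return(0)
  A <- coords[phospho, , drop = FALSE]
  B <- coords[basic, , drop = FALSE]
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  sum(1 / (1 + d2 / .CONTACT_BIAS^2))
}

## Metropolis pivot refinement: rotate tail segments about flexible beads,
## accepting moves with probability min(1, exp(kappa * dScore)) under the
## soft contact score; rigid bodies move as wholes and are never broken.
.mcRefine <- function(coords, molBeads, kappa, nMoves = 150L) {
  flex <- which(is.na(molBeads$rigid))
  if (!length(flex)) return(coords)
  phospho <- molBeads$phospho
  basic <- molBeads$charge > 0
  n <- nrow(coords)
  E <- .softContactEnergy(coords, phospho, basic)
  for (mv in seq_len(nMoves)) {
    i <- flex[sample.int(length(flex), 1L)]
    dir <- if (stats::runif(1) < 0.5) -1L else 1L
    ch <- molBeads$chain[i]; r <- molBeads$resid[i]
    seg <- if (dir < 0L) which(molBeads$chain == ch & molBeads$resid < r)
           else which(molBeads$chain == ch & molBeads$resid > r)
    if (!length(seg)) next
    segBodies <- unique(molBeads$rigid[seg])
    segBodies <- segBodies[!is.na(segBodies)]
    broken <- FALSE
    for (b in segBodies)
      if (!all(which(molBeads$rigid %in% b) %in% seg)) broken <- TRUE
    if (broken) next
    R <- .rodrigues(.randUnit(1L)[1L, ], stats::rnorm(1, 0, 1.2))
    pivot <- coords[i, ]
    moved <- sweep(sweep(coords[seg, , drop = FALSE], 2L, pivot) %*% R,
                   2L, pivot, FUN = "+")
    static <- setdiff(seq_len(n), seg)
    S <- coords[static, , drop = FALSE]
    d2 <- outer(rowSums(moved^2), rowSums(S^2), "+") - 2 * moved %*% t(S)
    ## the pivot bead i is static and bonded to the first moved bead
    bonded <- which(molBeads$chain[seg] == ch &
                      abs(molBeads$resid[seg] - r) == 1L)
    if (length(bonded)) d2[bonded, match(i, static)] <- Inf
    if (min(d2) < .EXCL^2) next
    cand <- coords
    cand[seg, ] <- moved
    Ecand <- .softContactEnergy(cand, phospho, basic)
    if (Ecand >= E || stats::runif(1) < exp(kappa * (Ecand - E))) {
      coords <- cand; E <- Ecand
    }
  }
  coords
}

.interContacts <- function(c1, b1, c2, b2) {
  ## contacts between phospho beads of one molecule and basic of the other
  cnt <- 0L
  for (pair in list(list(c1[b1$phospho, , drop = FALSE],
                         c2[b2$charge > 0, , drop = FALSE]),
                    list(c2[b2$phospho, , drop = FALSE],
                         c1[b1$charge > 0, , drop = FALSE]))) {
    A <- pair[[1L]]; B <- pair[[2L]]
    if (nrow(A) && nrow(B)) {
      d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
      cnt <- cnt + sum(d2 <= .CONTACT_BIAS^2)
    }
  }
  cnt
}

#' Sample one conformer from a topology
#'
#' Rigid domains are placed as internally fixed bodies; tails and linkers
#' are grown as 3.8-Angstrom excluded-volume random walks. A compactness
#' bias `kappa > 0` favours growth steps that create phosphoserine/basic
#' -segment contacts (< 8 Angstrom) with Boltzmann weight
#' `exp(kappa * contacts)`, emulating phosphorylation-driven tail
#' compaction; `kappa = 0` is the unbiased walk. For two-molecule systems
#' the second molecule starts at a centroid separation > 60 Angstrom and is
#' then relaxed by rigid-body Monte Carlo moves under the same contact
#' energy.
#'
#' @param topology a `topologySpec`.
#' @param kappa compactness bias (>= 0).
#' @param seed RNG seed; same `(topology, kappa, seed)` gives an identical
#'   conformer.
#' @return A [Conformer-class].
#' @export
sampleConformer <- function(topology, kappa = 0, seed = 1L) {
  stopifnot(inherits(topology, "topologySpec"), kappa >= 0)
  beads <- topology$beads
  .withSeed(seed, function() {
    mols <- sort(unique(beads$molecule))
    coordsAll <- matrix(NA_real_, nrow(beads), 3L)
    prevTabs <- list()
    for (m in mols) {
      idx <- which(beads$molecule == m)
      mb <- beads[idx, , drop = FALSE]
      xyz <- .growMolecule(topology, mb, kappa)
      if (kappa > 0) xyz <- .mcRefine(xyz, mb, kappa)
      xyz <- sweep(xyz, 2L, colMeans(xyz))
      if (m > mols[1L]) {
        ## place beyond 60 A centroid separation, then rigid-body relaxation
        placedMat <- coordsAll[beads$molecule < m, , drop = FALSE]
        placedTab <- beads[beads$molecule < m, , drop = FALSE]
        for (try in 1:200) {
          d <- 60 + 5 * try / 10 + stats::runif(1, 0, 10)
          ctr <- .randUnit(1L)[1L, ] * d
          cand <- sweep(xyz %*% .randRotation(), 2L, ctr, FUN = "+")
          if (min(.crossDist2(cand, placedMat)) >= .EXCL^2) {
            xyz <- cand; break
          }
          if (try == 200L) stop("failed to place molecule without clashes")
        }
        ## Metropolis relaxation toward inter-molecular contacts
        E <- -kappa * .interContacts(placedMat, placedTab, xyz, mb)
        for (step in 1:200) {
          prop <- xyz
          ctr <- colMeans(prop)
          ax <- .randUnit(1L)[1L, ]
          ang <- stats::rnorm(1, 0, 0.15)
          K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1],
                        -ax[2], ax[1], 0), 3L, byrow = TRUE)
          R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * K %*% K
          prop <- sweep(sweep(prop, 2L, ctr) %*% R, 2L,
                        ctr + stats::rnorm(3, 0, 2.5), FUN = "+")
          if (min(.crossDist2(prop, placedMat)) < .EXCL^2) next
          Eprop <- -kappa * .interContacts(placedMat, placedTab, prop, mb)
          if (Eprop <= E || stats::runif(1) < exp(E - Eprop)) {
            xyz <- prop; E <- Eprop
          }
        }
      }
      coordsAll[idx, ] <- xyz
    }
    Conformer(coordsAll, residueIds = beads$resid, chainIds = beads$chain,
              scatterWeight = beads$scatter, charge = beads$charge)
  })
}

#' Mixture specification for synthetic ensembles
#'
#' @param fractions named numeric ground-truth fractions (simplex).
#' @param kappas compactness bias per subpopulation (same length).
#' @param N ensemble size (>= number of subpopulations).
#' @param topology a `topologySpec`.
#' @param seed base RNG seed.
#' @return A `mixtureSpec` list.
#' @export
mixtureSpec <- function(fractions, kappas, N, topology, seed = 1L) {
  stopifnot(length(fractions) == length(kappas),
            abs(sum(fractions) - 1) < 1e-9, all(fractions >= 0), N >= 2L)
  if (N < length(fractions))
    stop("N must be at least the number of subpopulations")
  out <- list(fractions = fractions, kappas = kappas, N = as.integer(N),
              topology = topology, seed = as.integer(seed))
  class(out) <- "mixtureSpec"
  out
}

## Largest-remainder allocation; remainder goes to the largest fractional
## part, ties to the lowest index.
.allocateCounts <- function(N, fractions) {
  base <- floor(N * fractions)
  rem <- N - sum(base)
  if (rem > 0) {
    fr <- N * fractions - base
    ord <- order(-fr, seq_along(fr))
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1L
  }
  as.integer(base)
}

#' Build a mixture ensemble with known ground truth
#'
#' Draws `N` conformers from the subpopulations of a [mixtureSpec()] in
#' ground-truth proportions (largest-remainder allocation) with uniform
#' initial weights `w0 = 1/N`, recording the subpopulation label of every
#' member.
#'
#' @param spec a `mixtureSpec`.
#' @return A list with `ensemble` ([Ensemble-class]), `labels` (integer
#'   subpopulation per conformer) and `counts`.
#' @export
makeMixtureEnsemble <- function(spec) {
  stopifnot(inherits(spec, "mixtureSpec"))
  counts <- .allocateCounts(spec$N, spec$fractions)
  labels <- rep(seq_along(counts), counts)
  confs <- vector("list", spec$N)
  for (j in seq_len(spec$N)) {
    confs[[j]] <- sampleConformer(spec$topology,
                                  kappa = spec$kappas[labels[j]],
                                  seed = spec$seed * 1000L + j)
  }
  ens <- Ensemble(confs, source = sprintf(
    "synthetic mixture (N=%d, fractions=%s, kappas=%s, seed=%d)",
    spec$N, paste(spec$fractions, collapse = "/"),
    paste(spec$kappas, collapse = "/"), spec$seed))
  list(ensemble = ens, labels = labels, counts = counts)
}

#' Synthesize a noisy target SAXS profile from an ensemble
#'
#' Computes `I_true(q)` as the `trueWeights`-weighted average of per-conformer
#' Debye profiles, assigns errors
#' `sigma(q) = noiseFrac * I_true(q) * (1 + q/q_max)` and adds Gaussian noise
#' of that magnitude. With `noiseFrac = 0` the returned intensities equal the
#' weighted sum exactly and a nominal error of `1e-6 * I_true` is stored so
#' the profile remains usable in fits.
#'
#' @param ensemble an [Ensemble-class] (or a list of per-conformer
#'   [ScatteringProfile-class]s sharing a q-grid).
#' @param trueWeights simplex weights used for the ground-truth average.
#' @param qGrid q values (default [defaultQGrid()]).
#' @param noiseFrac relative noise level (default 0.02).
#' @param seed RNG seed.
#' @param params form-factor parameters for the Debye calculation.
#' @return A [ScatteringProfile-class] with errors.
#' @export
makeTargetProfile <- function(ensemble, trueWeights, qGrid = defaultQGrid(),
                              noiseFrac = 0.02, seed = 1L,
                              params = formFactorParams()) {
  stopifnot(noiseFrac >= 0, abs(sum(trueWeights) - 1) < 1e-9,
            all(trueWeights >= 0))
  profiles <- if (is(ensemble, "Ensemble")) {
    lapply(conformers(ensemble), debyeProfile, qGrid = qGrid, params = params)
  } else ensemble
  Imat <- vapply(profiles, intensities, numeric(length(qGrid)))
  Itrue <- as.numeric(Imat %*% trueWeights)
  if (noiseFrac == 0)
    return(ScatteringProfile(qGrid, Itrue, 1e-6 * Itrue))
  sig <- noiseFrac * Itrue * (1 + qGrid / max(qGrid))
  .withSeed(seed, function() {
    ScatteringProfile(qGrid, Itrue + stats::rnorm(length(qGrid), 0, sig), sig)
  })
}

#' Default scattering-vector grid
#'
#' 60 logarithmically spaced points on 0.01-0.30 1/Angstrom, a typical
#' usable SEC-SAXS range for a flexible two-domain protein.
#'
#' @param n number of points.
#' @param qmin,qmax range in 1/Angstrom.
#' @return numeric vector.
#' @export
defaultQGrid <- function(n = 60L, qmin = 0.01, qmax = 0.30) {
  exp(seq(log(qmin), log(qmax), length.out = n))
}
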