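#' @include geometry.R
NULL

## Run expr with a temporary RNG state seeded at `seed`; restores the caller's
## stream so generators behave as pure functions of (spec, seed).
.withSeed <- function(seed, fun) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1L)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed %% 2147483647))
  fun()
}

#' Charged-segment table of an HP1alpha-like chain
#'
#' Alternating acidic (a1-a7, charge -1) and basic (b1-b7, charge +1)
#' segments along a 191-residue chain with an N-tail (1-18), chromodomain
#' (CD, 19-74), hinge region (HR, 75-112), chromo shadow domain
#' (CSD, 113-173) and C-tail (174-191). The four N-tail serines (11-14)
#' carry -2 each when phosphorylated. Segment positions anchored by the
#' field's HP1alpha landmarks (b4 = 68-72 at the CD end, b6 = 89-92 and
#' b7 = 102-105 in HR) are exact; the remaining ranges are plausible
#' placements used by the synthetic emulator.
#'
#' @return `data.frame` with columns `name`, `start`, `end`, `charge`.
#' @export
hp1SegmentTable <- function() {
  data.frame(
    name  = c("Ntail", "CD", "HR", "CSD", "Ctail",
              "b1", "phosS", "a1", "b2", "b3", "a2", "a3", "b4",
              "a4", "b5", "b6", "a5", "b7", "a6", "a7"),
    start = c(1, 19, 75, 113, 174,
              3, 11, 15, 31, 40, 45, 52, 68,
              76, 83, 89, 95, 102, 120, 150),
    end   = c(18, 74, 112, 173, 191,
              6, 14, 18, 34, 43, 47, 56, 72,
              81, 86, 92, 99, 105, 126, 156),
    charge = c(0, 0, 0, 0, 0,
               1, 0, -1, 1, 1, -1, -1, 1,
               -1, 1, 1, -1, 1, -1, -1),
    stringsAsFactors = FALSE
  )
}

#' Segment annotation (named residue ranges)
#'
#' @param table data.frame with columns `name`, `start`, `end` (and
#'   optionally `charge`). Defaults to [hp1SegmentTable()].
#' @param nRes sequence length for bounds checking (default: max end).
#' @return A `segmentAnnotation` object (data.frame).
#' @export
segmentAnnotation <- function(table = hp1SegmentTable(), nRes = NULL) {
  stopifnot(all(c("name", "start", "end") %in% names(table)))
  if (is.null(nRes)) nRes <- max(table$end)
  if (any(table$start < 1L) || any(table$end > nRes))
    stop("segment ranges exceed sequence bounds")
  if (any(table$end < table$start)) stop("segment end before start")
  class(table) <- c("segmentAnnotation", "data.frame")
  attr(table, "nRes") <- nRes
  table
}

.perResidueCharge <- function(nRes, segments, phospho) {
  charge <- rep(0, nRes)
  if (!is.null(segments$charge)) {
    for (k in seq_len(nrow(segments))) {
      if (segments$charge[k] != 0 && segments$start[k] <= nRes) {
        idx <- segments$start[k]:min(segments$end[k], nRes)
        charge[idx] <- segments$charge[k]
      }
    }
  }
  charge[phospho[phospho <= nRes]] <- -2
  charge
}

#' Topology specification for the synthetic conformer generator
#'
#' Defines per-chain residue counts, rigid-domain ranges (kept internally
#' fixed during sampling), phosphosite residues and per-residue charges from
#' a charged-segment table. Rigid bodies spanning several chains (a CSD
#' dimer) link those chains into one molecule. Rigid-body template
#' coordinates are generated once here (deterministic in `rigidSeed`) so
#' every sampled conformer shares identical internal domain geometry.
#'
#' @param chainLengths named integer vector, residues per chain.
#' @param rigidBodies list; each element a data.frame with columns `chain`,
#'   `start`, `end` describing one rigid body (possibly several rows/chains).
#' @param phosphoSites integer residues carrying phosphoserine (per chain).
#' @param phosphorylated logical; if `FALSE` the phosphosites are plain
#'   serines (charge 0) and the compaction bias has no anchors.
#' @param segments segment table with charges (default [hp1SegmentTable()]).
#' @param rigidSeed seed for the rigid-domain templates.
#' @return A `topologySpec` list.
#' @export
topologySpec <- function(chainLengths, rigidBodies = list(),
                         phosphoSites = 11:14, phosphorylated = TRUE,
                         segments = hp1SegmentTable(), rigidSeed = 1L) {
  chains <- names(chainLengths)
  if (is.null(chains)) chains <- LETTERS[seq_along(chainLengths)]
  beads <- do.call(rbind, lapply(seq_along(chainLengths), function(i) {
    n <- chainLengths[[i]]
    data.frame(chain = chains[i], resid = seq_len(n),
               charge = .perResidueCharge(
                 n, segments, if (phosphorylated) phosphoSites else integer()),
               phospho = if (phosphorylated)
                 seq_len(n) %in% phosphoSites else FALSE,
               scatter = 1, rigid = NA_integer_,
               stringsAsFactors = FALSE)
  }))
  for (b in seq_along(rigidBodies)) {
    rb <- rigidBodies[[b]]
    for (k in seq_len(nrow(rb))) {
      hit <- beads$chain == rb$chain[k] &
        beads$resid >= rb$start[k] & beads$resid <= rb$end[k]
      if (any(!is.na(beads$rigid[hit])))
        stop("rigid bodies must not overlap")
      beads$rigid[hit] <- b
    }
  }
  ## molecules: chains connected through shared rigid bodies
  mol <- seq_along(chains)
  names(mol) <- chains
  for (b in seq_along(rigidBodies)) {
    ch <- unique(rigidBodies[[b]]$chain)
    if (length(ch) > 1L) mol[ch] <- min(mol[ch])
  }
  beads$molecule <- as.integer(factor(mol[beads$chain], levels = unique(mol)))
  templates <- lapply(seq_along(rigidBodies), function(b) {
    m <- sum(beads$rigid %in% b)
    makeRigidDomain(m, seed = rigidSeed + b)
  })
  nRes <- max(beads$resid)
  segClip <- segments[segments$start <= nRes, , drop = FALSE]
  segClip$end <- pmin(segClip$end, nRes)
  out <- list(beads = beads, rigidBodies = rigidBodies,
              templates = templates, chains = chains,
              phosphorylated = phosphorylated,
              segments = segmentAnnotation(segClip, nRes = nRes))
  class(out) <- "topologySpec"
  out
}

#' HP1alpha-like dimer topology
#'
#' Two 191-residue chains; one rigid CD (19-74) per chain and a single
#' rigid CSD dimer body (113-173 of both chains) bridging the subunits,
#' emulating the elastic-network cores of a coarse-grained HP1alpha dimer.
#'
#' @param phosphorylated phosphorylate the N-tail serines 11-14.
#' @param rigidSeed seed for rigid-domain templates.
#' @return A `topologySpec`.
#' @export
hp1DimerTopology <- function(phosphorylated = TRUE, rigidSeed = 1L) {
  topologySpec(
    chainLengths = c(A = 191L, B = 191L),
    rigidBodies = list(
      data.frame(chain = "A", start = 19, end = 74),
      data.frame(chain = "B", start = 19, end = 74),
      data.frame(chain = c("A", "B"), start = c(113, 113),
                 end = c(173, 173))
    ),
    phosphorylated = phosphorylated, rigidSeed = rigidSeed
  )
}

#' CSD-deletion (monomeric) HP1alpha-like topology
#'
#' 120-residue chain(s): N-tail (1-18), rigid CD (19-74) and a flexible
#' hinge tail (75-120). `nMolecules = 2` builds the two-molecule system used
#' to probe dynamic dimerization.
#'
#' @param nMolecules 1 or 2 independent molecules.
#' @param phosphorylated phosphorylate the N-tail serines 11-14.
#' @param rigidSeed seed for rigid-domain templates.
#' @return A `topologySpec`.
#' @export
deltaCSDTopology <- function(nMolecules = 1L, phosphorylated = TRUE,
                             rigidSeed = 1L) {
  stopifnot(nMolecules %in% c(1L, 2L))
  lens <- stats::setNames(rep(120L, nMolecules),
                          LETTERS[seq_len(nMolecules)])
  topologySpec(
    chainLengths = lens,
    rigidBodies = lapply(LETTERS[seq_len(nMolecules)], function(ch)
      data.frame(chain = ch, start = 19, end = 74)),
    phosphorylated = phosphorylated, rigidSeed = rigidSeed
  )
}
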