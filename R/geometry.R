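#' @include methods.R
NULL

#' Bead selections by residue range
#'
#' A selection is a data frame of inclusive residue ranges, one row per
#' `(chain, start, end)` triple, with a role tag (`"superpose"`, `"rmsd"` or
#' `"contact"`). `chain = NA` applies a range to every chain. Residue
#' numbering is 1-based and follows the input topology.
#'
#' @param start,end integer vectors of inclusive range bounds (recycled).
#' @param chain chain labels, or `NA` for all chains.
#' @param role role tag.
#' @return A `data.frame` with class `"beadSelection"`.
#' @examples
#' csd <- beadSelection(113, 173)            # CSD of every chain
#' serines <- beadSelection(11, 14, role = "rmsd")
#' @export
beadSelection <- function(start, end, chain = NA_character_, role = "rmsd") {
  sel <- data.frame(chain = as.character(chain), start = as.integer(start),
                    end = as.integer(end), stringsAsFactors = FALSE)
  if (any(sel$end < sel$start)) stop("selection ranges must have end >= start")
  sel$role <- role
  class(sel) <- c("beadSelection", "data.frame")
  sel
}

#' Combine selections
#' @param ... beadSelection objects.
#' @return A combined `beadSelection`.
#' @export
combineSelections <- function(...) {
  sel <- do.call(rbind, lapply(list(...), as.data.frame))
  class(sel) <- c("beadSelection", "data.frame")
  sel
}

#' Map a selection to bead indices of a conformer
#'
#' @param conformer a [Conformer-class].
#' @param selection a [beadSelection()] (or `NULL` for all beads).
#' @return Sorted integer bead indices.
#' @export
selectionIndices <- function(conformer, selection) {
  if (is.null(selection)) return(seq_len(nBeads(conformer)))
  rid <- residueIds(conformer)
  cid <- chainIds(conformer)
  keep <- rep(FALSE, length(rid))
  for (k in seq_len(nrow(selection))) {
    inRange <- rid >= selection$start[k] & rid <= selection$end[k]
    if (!is.na(selection$chain[k]))
      inRange <- inRange & cid == selection$chain[k]
    keep <- keep | inRange
  }
  idx <- which(keep)
  if (!length(idx)) stop("selection matches no beads in this topology")
  idx
}

#' @rdname radiusOfGyration
setMethod("radiusOfGyration", "Conformer", function(object, massWeights = NULL) {
  x <- object@coords
  n <- nrow(x)
  if (n < 1L) stop("empty conformer")
  if (is.null(massWeights)) massWeights <- rep(1, n)
  if (length(massWeights) != n) stop("one weight per bead required")
  if (any(massWeights < 0)) stop("mass weights must be non-negative")
  W <- sum(massWeights)
  if (W <= 0) stop("mass weights must not all be zero")
  ctr <- colSums(x * massWeights) / W
  d2 <- rowSums(sweep(x, 2L, ctr)^2)
  sqrt(sum(massWeights * d2) / W)
})

## Kabsch rotation: returns 3x3 R with det +1 such that Xc %*% R ~ Yc
.kabsch <- function(Xc, Yc) {
  H <- crossprod(Xc, Yc)
  sv <- svd(H)
  d <- sign(det(sv$u) * det(sv$v))
  if (d == 0) d <- 1
  sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
}

.checkSuperposable <- function(P) {
  if (nrow(P) < 3L) stop("superposition needs at least 3 beads")
  Pc <- sweep(P, 2L, colMeans(P))
  s <- svd(Pc, nu = 0, nv = 0)$d
  if (s[2L] < 1e-8 * max(s[1L], 1e-12))
    stop("degenerate (collinear) geometry in superposition selection")
  invisible(TRUE)
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Rotates and translates `mobile` onto `reference` minimizing the RMSD over
#' the selected beads. The rotation is proper (determinant +1, never a
#' reflection).
#'
#' @param mobile,reference [Conformer-class] objects with identical topology
#'   over the selection.
#' @param selection a [beadSelection()] (default: all beads).
#' @return A list with `conformer` (transformed mobile), `rotation` (3x3),
#'   `translation` (length 3) and `rmsd` (Angstrom, over the selection).
#' @export
superposeConformers <- function(mobile, reference, selection = NULL) {
  im <- selectionIndices(mobile, selection)
  ir <- selectionIndices(reference, selection)
  if (length(im) != length(ir))
    stop("selection maps to different bead counts in mobile and reference")
  X <- beadCoords(mobile)[im, , drop = FALSE]
  Y <- beadCoords(reference)[ir, , drop = FALSE]
  .checkSuperposable(X)
  .checkSuperposable(Y)
  cX <- colMeans(X); cY <- colMeans(Y)
  R <- .kabsch(sweep(X, 2L, cX), sweep(Y, 2L, cY))
  allX <- sweep(beadCoords(mobile), 2L, cX) %*% R
  newCoords <- sweep(allX, 2L, cY, FUN = "+")
  fitted <- sweep(sweep(X, 2L, cX) %*% R, 2L, cY, FUN = "+")
  out <- mobile
  out@coords <- newCoords
  list(conformer = out, rotation = R, translation = cY - cX %*% R,
       rmsd = sqrt(mean(rowSums((fitted - Y)^2))))
}

.swapTwoChains <- function(conformer) {
  ch <- unique(chainIds(conformer))
  if (length(ch) != 2L)
    stop("chain swap is defined for exactly 2 chains")
  cid <- chainIds(conformer)
  ## relabel and reorder so bead order (chain, residue) matches the original
  i1 <- which(cid == ch[1L]); i2 <- which(cid == ch[2L])
  if (length(i1) != length(i2) ||
      !identical(residueIds(conformer)[i1], residueIds(conformer)[i2]))
    stop("chain swap requires identical per-chain topologies")
  perm <- integer(nBeads(conformer))
  perm[i1] <- i2
  perm[i2] <- i1
  out <- conformer
  out@coords <- beadCoords(conformer)[perm, , drop = FALSE]
  out
}

#' Subset RMSD after superposition
#'
#' Superposes `b` onto `a` using `superposeSel`, then reports the RMSD over
#' `rmsdSel`. With `chainSwap = TRUE` (two-chain systems only) both subunit
#' label assignments are evaluated and the minimum returned; this makes the
#' distance invariant to the arbitrary labelling of identical subunits.
#'
#' @param a,b [Conformer-class] objects with identical topology.
#' @param superposeSel selection used for superposition (default all beads).
#' @param rmsdSel selection over which the RMSD is measured
#'   (default: same as `superposeSel`).
#' @param chainSwap evaluate both chain labelings and return the minimum.
#' @return RMSD in Angstrom.
#' @export
subsetRMSD <- function(a, b, superposeSel = NULL, rmsdSel = superposeSel,
                       chainSwap = FALSE) {
  if (!identical(residueIds(a), residueIds(b)) ||
      !identical(chainIds(a), chainIds(b)))
    stop("conformers have mismatched topology")
  one <- function(bb) {
    sup <- superposeConformers(bb, a, superposeSel)
    ia <- selectionIndices(a, rmsdSel)
    X <- beadCoords(sup$conformer)[ia, , drop = FALSE]
    Y <- beadCoords(a)[ia, , drop = FALSE]
    sqrt(mean(rowSums((X - Y)^2)))
  }
  r <- one(b)
  if (chainSwap) {
    if (length(unique(chainIds(a))) > 2L)
      stop("chainSwap supports at most 2 chains")
    if (length(unique(chainIds(a))) == 2L)
      r <- min(r, one(.swapTwoChains(b)))
  }
  r
}
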