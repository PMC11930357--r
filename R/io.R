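#' @include csp.R
NULL

## fixed-column PDB ATOM record for a CA bead
.pdbAtomLine <- function(serial, chain, resid, xyz) {
  sprintf("ATOM  %5d  CA  ALA %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
          serial, substr(chain, 1L, 1L), resid, xyz[1L], xyz[2L], xyz[3L])
}

#' Write an ensemble as a multi-MODEL PDB (CA beads)
#'
#' One MODEL per conformer, one CA ATOM per bead, fixed PDB columns
#' (coordinates to 3 decimals).
#'
#' @param ensemble an [Ensemble-class] (or a single [Conformer-class]).
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
writeEnsemblePDB <- function(ensemble, path) {
  confs <- if (is(ensemble, "Conformer")) list(ensemble)
           else conformers(ensemble)
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_along(confs)) {
    cf <- confs[[m]]
    writeLines(sprintf("MODEL     %4d", m), con)
    x <- beadCoords(cf); rid <- residueIds(cf); cid <- chainIds(cf)
    for (i in seq_len(nBeads(cf)))
      writeLines(.pdbAtomLine(i, cid[i], rid[i], x[i, ]), con)
    writeLines(c("TER", "ENDMDL"), con)
  }
  writeLines("END", con)
  invisible(path)
}

## pre-scan model blocks: list of data.frames (chain, resid) per model
.scanPDBModels <- function(lines) {
  atom <- grepl("^ATOM  ", lines)
  modelStarts <- grep("^MODEL", lines)
  if (!length(modelStarts)) {
    return(list(which(atom)))
  }
  modelEnds <- grep("^ENDMDL", lines)
  if (length(modelEnds) != length(modelStarts))
    stop("unbalanced MODEL/ENDMDL records")
  lapply(seq_along(modelStarts), function(m)
    which(atom & seq_along(lines) > modelStarts[m] &
            seq_along(lines) < modelEnds[m]))
}

#' Read a multi-MODEL CA-bead PDB into an Ensemble
#'
#' Parses CA records via \pkg{bio3d} after verifying that every MODEL
#' carries the same (chain, residue) topology; a mismatch names the
#' offending model. Scattering weights default to 1 and charges to 0 unless
#' a `beadTable` supplies them.
#'
#' @param path PDB file with CA-only ATOM records.
#' @param beadTable optional data.frame with columns `chain`, `resid` and
#'   any of `scatter`, `charge` to attach per-bead properties.
#' @return An [Ensemble-class] with uniform weights.
#' @export
readEnsemblePDB <- function(path, beadTable = NULL) {
  lines <- readLines(path)
  blocks <- .scanPDBModels(lines)
  sig <- lapply(blocks, function(idx)
    paste(substr(lines[idx], 22L, 22L), trimws(substr(lines[idx], 23L, 26L))))
  for (m in seq_along(sig))
    if (!identical(sig[[m]], sig[[1L]]))
      stop(sprintf("model %d has a different topology than model 1", m))
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  ca <- which(pdb$atom$elety == "CA")
  cid <- pdb$atom$chain[ca]
  rid <- pdb$atom$resno[ca]
  nModels <- nrow(pdb$xyz)
  scatter <- rep(1, length(ca)); charge <- rep(0, length(ca))
  if (!is.null(beadTable)) {
    key <- paste(cid, rid)
    hit <- match(key, paste(beadTable$chain, beadTable$resid))
    if ("scatter" %in% names(beadTable))
      scatter[!is.na(hit)] <- beadTable$scatter[hit[!is.na(hit)]]
    if ("charge" %in% names(beadTable))
      charge[!is.na(hit)] <- beadTable$charge[hit[!is.na(hit)]]
  }
  confs <- lapply(seq_len(nModels), function(m) {
    xyz <- matrix(pdb$xyz[m, ], ncol = 3L, byrow = TRUE)[ca, , drop = FALSE]
    Conformer(xyz, residueIds = rid, chainIds = cid,
              scatterWeight = scatter, charge = charge)
  })
  Ensemble(confs, source = path)
}

#' Write a scattering profile as 3-column ASCII (.dat)
#'
#' Columns `q I sigma` (sigma omitted when absent), `#` header, q in
#' 1/Angstrom.
#'
#' @param profile a [ScatteringProfile-class].
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
writeProfileDat <- function(profile, path) {
  sig <- sigmas(profile)
  hasSig <- !all(is.na(sig))
  hdr <- if (hasSig) "# q[1/A] I sigma" else "# q[1/A] I"
  body <- if (hasSig)
    sprintf("%.8e %.8e %.8e", qValues(profile), intensities(profile), sig)
  else sprintf("%.8e %.8e", qValues(profile), intensities(profile))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a 3-column ASCII scattering profile
#'
#' Tolerates `#` comment lines anywhere; 2-column files are accepted with
#' errors marked absent (fitting then refuses until errors are supplied).
#' q must be strictly increasing.
#'
#' @param path .dat file.
#' @return A [ScatteringProfile-class].
#' @export
readProfileDat <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) < 2L) stop("profile file needs at least 2 numeric rows")
  fields <- strsplit(lines, "[ \t,]+")
  ncols <- unique(lengths(fields))
  if (length(ncols) != 1L || !ncols %in% c(2L, 3L))
    stop("profile file must have a consistent 2 or 3 columns")
  num <- matrix(as.numeric(unlist(fields)), ncol = ncols, byrow = TRUE)
  if (any(is.na(num))) stop("non-numeric data in profile file")
  if (any(diff(num[, 1L]) <= 0))
    stop("q must be strictly increasing")
  ScatteringProfile(num[, 1L], num[, 2L],
                    if (ncols == 3L) num[, 3L] else NULL)
}

#' Write a P(r) curve as 2-column ASCII
#' @param pr a `prCurve`.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
writePrCurve <- function(pr, path) {
  writeLines(c(sprintf("# P(r): Dmax = %.3f A, alpha = %g", pr$Dmax,
                       pr$alpha),
               "# r[A] P", sprintf("%.6e %.6e", pr$r, pr$P)), path)
  invisible(path)
}
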