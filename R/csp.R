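#' @include structure.R
NULL

#' Amide peak list
#'
#' @param residue integer residue numbers (unique).
#' @param dH amide 1H chemical shifts (ppm).
#' @param dN amide 15N chemical shifts (ppm).
#' @param condition free-text condition label.
#' @return A `peakList` data.frame.
#' @export
peakList <- function(residue, dH, dN, condition = "") {
  if (anyDuplicated(residue)) stop("residue ids must be unique")
  if (!all(is.finite(dH)) || !all(is.finite(dN)))
    stop("chemical shifts must be finite")
  out <- data.frame(residue = as.integer(residue), dH = as.numeric(dH),
                    dN = as.numeric(dN))
  attr(out, "condition") <- condition
  class(out) <- c("peakList", "data.frame")
  out
}

#' Read a peak list from CSV
#'
#' Expects columns `residue`, `dH`, `dN` (extra columns ignored).
#' @param path CSV file.
#' @param condition condition label.
#' @return A [peakList()].
#' @export
readPeakListCSV <- function(path, condition = basename(path)) {
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("residue", "dH", "dN")
  if (!all(need %in% names(df)))
    stop("peak list CSV needs columns: ", paste(need, collapse = ", "))
  peakList(df$residue, df$dH, df$dN, condition)
}

#' Chemical shift perturbation between two conditions
#'
#' For residues present in both lists,
#' `ddelta = sqrt(ddeltaH^2 + (ddeltaN/5)^2)` -- the combined amide
#' perturbation with the nitrogen difference scaled by 1/5. Residues
#' missing from either list (e.g. exchange-broadened peaks) are reported as
#' absent, never as zero.
#'
#' @param listA,listB [peakList()] objects.
#' @return A `cspTable` data.frame (`residue`, `dDeltaH`, `dDeltaN`,
#'   `dDelta`) with attributes `absentA`/`absentB` (residues only in the
#'   other list).
#' @export
chemicalShiftPerturbation <- function(listA, listB) {
  if (!nrow(listA) || !nrow(listB)) stop("peak lists must be nonempty")
  common <- intersect(listA$residue, listB$residue)
  if (!length(common)) stop("no common residues between the peak lists")
  common <- sort(common)
  a <- listA[match(common, listA$residue), ]
  b <- listB[match(common, listB$residue), ]
  dH <- a$dH - b$dH
  dN <- a$dN - b$dN
  out <- data.frame(residue = common, dDeltaH = dH, dDeltaN = dN,
                    dDelta = sqrt(dH^2 + (dN / 5)^2))
  attr(out, "absentA") <- setdiff(listB$residue, listA$residue)
  attr(out, "absentB") <- setdiff(listA$residue, listB$residue)
  class(out) <- c("cspTable", "data.frame")
  out
}

#' Per-segment summary of chemical shift perturbations
#'
#' Mean and maximum perturbation per annotated segment, plus flagged
#' residues whose perturbation exceeds `mean + k * SD` of all residues.
#'
#' @param cspTable a [chemicalShiftPerturbation()] table.
#' @param segments a [segmentAnnotation()].
#' @param k flagging threshold in SD units (default 1).
#' @return list with `summary` (segment, n, mean, max) and `flagged`
#'   (residues above threshold, with their segments).
#' @export
segmentSummary <- function(cspTable, segments, k = 1) {
  thr <- mean(cspTable$dDelta) + k * stats::sd(cspTable$dDelta)
  rows <- lapply(seq_len(nrow(segments)), function(i) {
    hit <- cspTable$residue >= segments$start[i] &
      cspTable$residue <= segments$end[i]
    if (!any(hit)) {
      warning(sprintf("segment '%s' contains no measured residues",
                      segments$name[i]))
      return(data.frame(segment = segments$name[i], n = 0L,
                        mean = NA_real_, max = NA_real_))
    }
    data.frame(segment = segments$name[i], n = sum(hit),
               mean = mean(cspTable$dDelta[hit]),
               max = max(cspTable$dDelta[hit]))
  })
  flaggedRes <- cspTable$residue[cspTable$dDelta > thr]
  segOf <- vapply(flaggedRes, function(r) {
    hit <- which(segments$start <= r & segments$end >= r)
    if (length(hit)) paste(segments$name[hit], collapse = ",")
    else NA_character_
  }, "")
  list(summary = do.call(rbind, rows), threshold = thr,
       flagged = data.frame(residue = flaggedRes,
                            dDelta = cspTable$dDelta[cspTable$dDelta > thr],
                            segment = segOf))
}
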