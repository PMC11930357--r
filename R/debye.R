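#' @include synthetic.R
NULL

#' Adjustable two-parameter form-factor model
#'
#' Bead form factors are
#' `f_i(q) = f_i(0) * exp(-(q*sigmaB*c1)^2/2) + c2 * h_i * exp(-(q*sigmaW)^2/2)`
#' where `h_i` is a solvent-exposure proxy (1 minus the capped 7-Angstrom
#' neighbour count over 12). `c1` plays the role of an effective
#' excluded-volume adjustment through the bead width, `c2` the amplitude of a
#' hydration-layer term on exposed beads; the bounds follow the common
#' convention for such parameters.
#'
#' @param c1 excluded-volume adjustment, in \[0.95, 1.05\].
#' @param c2 hydration-layer amplitude, in \[-2, 4\].
#' @param sigmaB bead form width (Angstrom).
#' @param sigmaW hydration width (Angstrom).
#' @return A `formFactorParams` list.
#' @export
formFactorParams <- function(c1 = 1, c2 = 0, sigmaB = 3.0, sigmaW = 3.0) {
  if (c1 < 0.95 || c1 > 1.05) stop("c1 must lie in [0.95, 1.05]")
  if (c2 < -2 || c2 > 4) stop("c2 must lie in [-2, 4]")
  if (sigmaB <= 0 || sigmaW <= 0) stop("form widths must be positive")
  structure(list(c1 = c1, c2 = c2, sigmaB = sigmaB, sigmaW = sigmaW),
            class = "formFactorParams")
}

.EXPOSURE_CUTOFF <- 7.0
.MAX_NEIGHBORS <- 12L

#' Exposure proxy per bead
#'
#' `h_i = 1 - min(n_i, 12)/12` with `n_i` the number of other beads within
#' 7 Angstrom: a cheap deterministic stand-in for solvent accessibility.
#'
#' @param conformer a [Conformer-class].
#' @return numeric vector in \[0, 1\].
#' @export
exposureProxy <- function(conformer) {
  d <- as.matrix(stats::dist(beadCoords(conformer)))
  n <- rowSums(d <= .EXPOSURE_CUTOFF) - 1L
  1 - pmin(n, .MAX_NEIGHBORS) / .MAX_NEIGHBORS
}

#' Precompute the (c1, c2)-independent Debye basis of a conformer
#'
#' The Debye intensity with the two-parameter form factor decomposes as
#' `I(q) = g1(q)^2 A(q) + c2 g1(q) g2(q) B(q) + c2^2 g2(q)^2 C(q)` with
#' `g1 = exp(-(q sigmaB c1)^2/2)`, `g2 = exp(-(q sigmaW)^2/2)` and basis sums
#' `A = sum f0_i f0_j sinc(q r_ij)`, `B = sum (f0_i h_j + h_i f0_j) sinc`,
#' `C = sum h_i h_j sinc`. Computing `A`, `B`, `C` once makes profile
#' evaluation at any `(c1, c2)` O(M).
#'
#' @param conformer a [Conformer-class].
#' @param qGrid non-negative, strictly increasing q values (1/Angstrom).
#' @return A `debyeBasis` list (`q`, `A`, `B`, `C`).
#' @export
debyeBasis <- function(conformer, qGrid) {
  if (any(qGrid < 0)) stop("negative q is not allowed")
  f0 <- scatterWeights(conformer)
  h <- exposureProxy(conformer)
  x <- beadCoords(conformer)
  n <- nrow(x)
  A0 <- sum(f0^2); B0 <- 2 * sum(f0 * h); C0 <- sum(h^2)
  if (n > 1L) {
    dv <- as.numeric(stats::dist(x))       # unique pairs i<j
    ij <- utils::combn(n, 2L)
    wA <- 2 * f0[ij[1L, ]] * f0[ij[2L, ]]
    wB <- 2 * (f0[ij[1L, ]] * h[ij[2L, ]] + h[ij[1L, ]] * f0[ij[2L, ]])
    wC <- 2 * h[ij[1L, ]] * h[ij[2L, ]]
    qd <- outer(qGrid, dv)
    S <- ifelse(qd == 0, 1, sin(qd) / ifelse(qd == 0, 1, qd))
    A <- as.numeric(S %*% wA) + A0
    B <- as.numeric(S %*% wB) + B0
    C <- as.numeric(S %*% wC) + C0
  } else {
    A <- rep(A0, length(qGrid)); B <- rep(B0, length(qGrid))
    C <- rep(C0, length(qGrid))
  }
  structure(list(q = qGrid, A = A, B = B, C = C), class = "debyeBasis")
}

#' Evaluate a Debye profile from a precomputed basis
#'
#' @param basis a [debyeBasis()].
#' @param params [formFactorParams()].
#' @return A [ScatteringProfile-class] (no errors).
#' @export
profileFromBasis <- function(basis, params = formFactorParams()) {
  q <- basis$q
  g1 <- exp(-(q * params$sigmaB * params$c1)^2 / 2)
  g2 <- exp(-(q * params$sigmaW)^2 / 2)
  I <- g1^2 * basis$A + params$c2 * g1 * g2 * basis$B +
    params$c2^2 * g2^2 * basis$C
  ScatteringProfile(q, I)
}

#' Theoretical SAXS profile of a bead conformer (Debye formula)
#'
#' `I(q) = sum_i sum_j f_i(q) f_j(q) sinc(q r_ij)` with `sinc(0) = 1` and the
#' two-parameter form factors of [formFactorParams()].
#'
#' @param conformer a [Conformer-class].
#' @param qGrid non-negative q values (1/Angstrom).
#' @param params [formFactorParams()].
#' @return A [ScatteringProfile-class] (errors unset).
#' @examples
#' conf <- Conformer(matrix(c(0, 0, 0, 10, 0, 0), 2, 3, byrow = TRUE))
#' debyeProfile(conf, c(0, 0.05, 0.1))
#' @export
debyeProfile <- function(conformer, qGrid, params = formFactorParams()) {
  profileFromBasis(debyeBasis(conformer, qGrid), params)
}

#' Weighted ensemble-average profile
#'
#' @param profiles list of [ScatteringProfile-class] on a common q-grid.
#' @param weights simplex weights.
#' @return A [ScatteringProfile-class] with `I_i = sum_j w_j I_j,i`.
#' @export
ensembleAverageProfile <- function(profiles, weights) {
  stopifnot(length(profiles) == length(weights))
  if (abs(sum(weights) - 1) > 1e-9 || min(weights) < 0)
    stop("weights must lie on the simplex")
  q <- qValues(profiles[[1L]])
  for (p in profiles)
    if (!isTRUE(all.equal(qValues(p), q, tolerance = 1e-12)))
      stop("profiles must share one q-grid")
  Imat <- vapply(profiles, intensities, numeric(length(q)))
  ScatteringProfile(q, as.numeric(Imat %*% weights))
}

## weighted least-squares scale (and optional offset) of calc onto data
.fitScale <- function(Icalc, Idata, sigma, offset = FALSE) {
  w <- 1 / sigma^2
  if (!offset) {
    s <- sum(w * Icalc * Idata) / sum(w * Icalc^2)
    c(scale = s, offset = 0)
  } else {
    Sxx <- sum(w * Icalc^2); Sx <- sum(w * Icalc); S0 <- sum(w)
    Sxy <- sum(w * Icalc * Idata); Sy <- sum(w * Idata)
    den <- Sxx * S0 - Sx^2
    c(scale = (Sxy * S0 - Sx * Sy) / den,
      offset = (Sxx * Sy - Sx * Sxy) / den)
  }
}

.chi2 <- function(Icalc, Idata, sigma, scale = 1, offset = 0) {
  sum(((scale * Icalc + offset - Idata) / sigma)^2)
}

## interpolate a calculated profile onto data q (no extrapolation)
.interpCalc <- function(calc, qData) {
  qc <- qValues(calc)
  if (min(qData) < min(qc) - 1e-12 || max(qData) > max(qc) + 1e-12)
    stop("data q-range extends beyond the calculated profile; ",
         "extrapolation is not allowed")
  stats::approx(qc, intensities(calc), xout = qData)$y
}

#' Fit a calculated profile to data
#'
#' Closed-form weighted least-squares scale (optionally with a constant
#' offset) minimizing `chi2 = sum_i ((scale*I_calc,i + offset - I_data,i) /
#' sigma_i)^2`. With `fitCParams = TRUE` the form-factor parameters
#' `(c1, c2)` are additionally optimized by a coarse grid followed by
#' coordinate-wise golden-section refinement within their bounds; this
#' requires the conformer's [debyeBasis()] so that profiles can be
#' recomputed.
#'
#' @param calc calculated [ScatteringProfile-class] (ignored when a basis is
#'   given and `fitCParams = TRUE`).
#' @param data measured [ScatteringProfile-class]; must carry positive
#'   errors.
#' @param fitCParams also fit `(c1, c2)`.
#' @param basis [debyeBasis()] evaluated on a q-grid covering the data.
#' @param params starting [formFactorParams()].
#' @param offset fit a constant offset too (default `FALSE`).
#' @return A `fitResult` list: `scale`, `offset`, `c1`, `c2`, `chi2`,
#'   `chi2Reduced`, `n`.
#' @export
fitProfile <- function(calc, data, fitCParams = FALSE, basis = NULL,
                       params = formFactorParams(), offset = FALSE) {
  sig <- sigmas(data)
  if (any(is.na(sig)))
    stop("data profile carries no errors; provide sigma before fitting")
  y <- intensities(data); qd <- qValues(data)
  if (length(y) < 2L) stop("need at least 2 usable points")
  evalChi2 <- function(c1, c2) {
    p <- formFactorParams(c1, c2, params$sigmaB, params$sigmaW)
    Ic <- .interpCalc(profileFromBasis(basis, p), qd)
    sc <- .fitScale(Ic, y, sig, offset)
    list(chi2 = .chi2(Ic, y, sig, sc["scale"], sc["offset"]), sc = sc,
         c1 = c1, c2 = c2)
  }
  if (!fitCParams) {
    Ic <- if (!is.null(basis)) .interpCalc(profileFromBasis(basis, params), qd)
          else .interpCalc(calc, qd)
    sc <- .fitScale(Ic, y, sig, offset)
    chi2 <- .chi2(Ic, y, sig, sc["scale"], sc["offset"])
    best <- list(chi2 = chi2, sc = sc, c1 = params$c1, c2 = params$c2)
  } else {
    if (is.null(basis))
      stop("fitCParams = TRUE requires the conformer's debyeBasis")
    grid1 <- seq(0.95, 1.05, length.out = 6L)
    grid2 <- seq(-2, 4, length.out = 9L)
    best <- NULL
    for (c1 in grid1) for (c2 in grid2) {
      cur <- evalChi2(c1, c2)
      if (is.null(best) || cur$chi2 < best$chi2) best <- cur
    }
    golden <- function(f, lo, hi, iter = 25L) {
      gr <- (sqrt(5) - 1) / 2
      a <- lo; b <- hi
      x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
      f1 <- f(x1); f2 <- f(x2)
      for (i in seq_len(iter)) {
        if (f1 < f2) { b <- x2; x2 <- x1; f2 <- f1
          x1 <- b - gr * (b - a); f1 <- f(x1)
        } else { a <- x1; x1 <- x2; f1 <- f2
          x2 <- a + gr * (b - a); f2 <- f(x2) }
      }
      if (f1 < f2) x1 else x2
    }
    for (pass in 1:2) {
      st1 <- diff(grid1[1:2]); st2 <- diff(grid2[1:2])
      c1 <- golden(function(v) evalChi2(v, best$c2)$chi2,
                   max(0.95, best$c1 - st1), min(1.05, best$c1 + st1))
      cur <- evalChi2(c1, best$c2)
      if (cur$chi2 < best$chi2) best <- cur
      c2 <- golden(function(v) evalChi2(best$c1, v)$chi2,
                   max(-2, best$c2 - st2), min(4, best$c2 + st2))
      cur <- evalChi2(best$c1, c2)
      if (cur$chi2 < best$chi2) best <- cur
    }
  }
  structure(list(scale = unname(best$sc["scale"]),
                 offset = unname(best$sc["offset"]),
                 c1 = best$c1, c2 = best$c2, chi2 = best$chi2,
                 chi2Reduced = best$chi2 / length(y), n = length(y)),
            class = "fitResult")
}
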