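#' @include bme.R
NULL

#' Guinier analysis of a scattering profile
#'
#' Linear fit of `ln I` versus `q^2` over the largest low-q window
#' satisfying `qmax * Rg <= qRgLimit`, found iteratively: fit over the
#' current window, trim points violating the limit with the fitted Rg,
#' refit, until the window is stable. `Rg = sqrt(-3 * slope)`,
#' `I0 = exp(intercept)`.
#'
#' @param profile a [ScatteringProfile-class].
#' @param qRgLimit Guinier validity limit (default 1.3).
#' @param minPoints minimum number of points in the window (default 5).
#' @return A `guinierResult` list: `Rg`, `I0`, `qRange`, `qmaxRg`, `r2`,
#'   `nPoints`.
#' @export
guinierFit <- function(profile, qRgLimit = 1.3, minPoints = 5L) {
  q <- qValues(profile); I <- intensities(profile)
  usable <- which(I > 0)
  if (length(usable) && usable[1L] == 1L) {
    m <- which(diff(usable) > 1L)
    mEnd <- if (length(m)) usable[m[1L]] else usable[length(usable)]
  } else stop("non-positive intensities at low q; no Guinier regime")
  m <- mEnd
  if (m < minPoints) stop("fewer than minPoints usable low-q points")
  fitWindow <- function(m) {
    x <- q[1:m]^2; y <- log(I[1:m])
    fit <- stats::lm.fit(cbind(1, x), y)
    slope <- fit$coefficients[2L]
    list(slope = slope, intercept = fit$coefficients[1L],
         r2 = 1 - sum(fit$residuals^2) / sum((y - mean(y))^2))
  }
  for (iter in 1:100) {
    f <- fitWindow(m)
    if (!is.finite(f$slope) || f$slope >= 0)
      stop("non-negative Guinier slope; profile has no valid Guinier regime")
    Rg <- sqrt(-3 * f$slope)
    mNew <- max(which(q * Rg <= qRgLimit))
    mNew <- min(mNew, mEnd)
    if (mNew < minPoints)
      stop("no convergent Guinier window with >= minPoints points")
    if (mNew == m) break
    m <- mNew
  }
  f <- fitWindow(m)
  Rg <- sqrt(-3 * f$slope)
  structure(list(Rg = unname(Rg), I0 = unname(exp(f$intercept)),
                 qRange = c(q[1L], q[m]), qmaxRg = unname(q[m] * Rg),
                 r2 = f$r2, nPoints = m),
            class = "guinierResult")
}

#' Pair-distance distribution from coordinates
#'
#' Weighted histogram of all scattering-weighted (`f_i f_j`) pair distances
#' of a conformer, or the weight-mixed histogram of an ensemble. `Dmax` is
#' the maximum pair distance. The curve is normalized to unit area. This is
#' the real-space oracle route for [prFromProfile()].
#'
#' @param x a [Conformer-class] or [Ensemble-class].
#' @param rBin bin width in Angstrom (default 2).
#' @param weights ensemble weights (default: the ensemble's weights).
#' @return A `prCurve` list: `r` (bin centers), `P`, `Dmax`, `alpha = NA`.
#' @export
prFromCoordinates <- function(x, rBin = 2, weights = NULL) {
  stopifnot(rBin > 0)
  confs <- if (is(x, "Conformer")) list(x) else conformers(x)
  if (is.null(weights))
    weights <- if (is(x, "Conformer")) 1 else ensembleWeights(x)
  dmaxAll <- 0
  pairData <- lapply(confs, function(cf) {
    d <- as.numeric(stats::dist(beadCoords(cf)))
    f0 <- scatterWeights(cf)
    n <- nBeads(cf)
    ij <- utils::combn(n, 2L)
    list(d = d, w = f0[ij[1L, ]] * f0[ij[2L, ]])
  })
  dmaxAll <- max(vapply(pairData, function(p) max(p$d), 0))
  breaks <- seq(0, dmaxAll + rBin, by = rBin)
  P <- numeric(length(breaks) - 1L)
  for (j in seq_along(pairData)) {
    idx <- findInterval(pairData[[j]]$d, breaks, rightmost.closed = TRUE)
    Pj <- numeric(length(P))
    agg <- tapply(pairData[[j]]$w, idx, sum)
    Pj[as.integer(names(agg))] <- agg
    P <- P + weights[j] * Pj
  }
  P <- P / (sum(P) * rBin)
  structure(list(r = (breaks[-1L] + breaks[-length(breaks)]) / 2, P = P,
                 Dmax = dmaxAll, alpha = NA_real_),
            class = "prCurve")
}

#' Radius of gyration from a P(r) curve
#'
#' `Rg = sqrt( sum r^2 P / (2 sum P) )`: the pairwise identity applied to
#' the distance distribution.
#'
#' @param pr a `prCurve`.
#' @return Rg in Angstrom.
#' @export
prRg <- function(pr) {
  sqrt(sum(pr$r^2 * pr$P) / (2 * sum(pr$P)))
}

.prDesign <- function(q, rNodes, dr) {
  ## I(q) = 4*pi * sum_r P(r) sinc(q r) dr
  qr <- outer(q, rNodes)
  S <- ifelse(qr == 0, 1, sin(qr) / ifelse(qr == 0, 1, qr))
  4 * pi * S * dr
}

#' Indirect Fourier transform: P(r) from a profile
#'
#' Regularized non-negative least squares on a P(r) node basis linked to the
#' profile by `I(q) = 4 pi sum_r P(r) sinc(q r) dr`, with a second-difference
#' smoothness penalty `alpha` and the endpoint nodes pinned to zero. With
#' `alpha = NULL` a 10-point logarithmic scan minimizing the generalized
#' cross-validation score of the unconstrained ridge path picks alpha.
#'
#' @param profile a [ScatteringProfile-class] (errors used as weights when
#'   present).
#' @param Dmax assumed maximum dimension (Angstrom, > 0).
#' @param alpha smoothness penalty (>= 0), or `NULL` for GCV selection.
#' @param nBins number of r nodes on \[0, Dmax\] (default 101).
#' @return A `prCurve` with fields `r`, `P`, `Dmax`, `alpha`, `chi2`.
#' @export
prFromProfile <- function(profile, Dmax, alpha = NULL, nBins = 101L) {
  stopifnot(Dmax > 0, is.null(alpha) || alpha >= 0)
  q <- qValues(profile); y <- intensities(profile)
  sig <- sigmas(profile)
  if (any(is.na(sig))) sig <- rep(stats::sd(y) * 0.01 + 1e-12, length(y))
  rNodes <- seq(0, Dmax, length.out = nBins)
  dr <- rNodes[2L] - rNodes[1L]
  free <- 2:(nBins - 1L)              # endpoints pinned to zero
  A <- .prDesign(q, rNodes[free], dr)
  Aw <- A / sig
  yw <- y / sig
  nf <- length(free)
  D2 <- diff(diag(nf), differences = 2L)
  AtA <- crossprod(Aw); DtD <- crossprod(D2)
  if (!is.null(alpha) && alpha == 0) {
    if (kappa(AtA, exact = FALSE) > 1e10)
      stop("system is ill-conditioned at alpha = 0; use alpha > 0")
  }
  if (is.null(alpha)) {
    ref <- sum(diag(AtA)) / sum(diag(DtD))
    alphas <- ref * 10^seq(-6, 3, length.out = 10L)
    gcv <- vapply(alphas, function(a) {
      G <- AtA + a * DtD
      xa <- tryCatch(solve(G, crossprod(Aw, yw)),
                     error = function(e) NULL)
      if (is.null(xa)) return(Inf)
      H <- Aw %*% solve(G, t(Aw))
      resid <- yw - Aw %*% xa
      M <- length(yw)
      M * sum(resid^2) / (M - sum(diag(H)))^2
    }, 0)
    alpha <- alphas[which.min(gcv)]
  }
  obj <- function(x) {
    r <- Aw %*% x - yw
    sum(r^2) + alpha * sum((D2 %*% x)^2)
  }
  grad <- function(x) {
    as.numeric(2 * (AtA %*% x - crossprod(Aw, yw)) + 2 * alpha * DtD %*% x)
  }
  x0 <- pmax(solve(AtA + alpha * DtD + diag(1e-10 * mean(diag(AtA)), nf),
                   crossprod(Aw, yw)), 0)
  fit <- stats::optim(as.numeric(x0), obj, grad, method = "L-BFGS-B",
                      lower = 0,
                      control = list(maxit = 500L, factr = 1e3))
  P <- numeric(nBins)
  P[free] <- fit$par
  chi2 <- sum((as.numeric(A %*% fit$par) - y)^2 / sig^2)
  structure(list(r = rNodes, P = P, Dmax = Dmax, alpha = alpha,
                 chi2 = chi2),
            class = "prCurve")
}

#' Scan candidate Dmax values
#'
#' Runs [prFromProfile()] over candidate maximum dimensions and scores each
#' by fit chi2 plus a penalty proportional to the P(r) mass stranded in the
#' last 5% of bins (a too-small Dmax fits poorly; a too-large one piles
#' mass at the boundary). The score drops steeply while Dmax is too small
#' and plateaus beyond the true dimension, so the estimate is the smallest
#' candidate whose score is within `plateauTol` of the plateau minimum.
#'
#' @param profile a [ScatteringProfile-class].
#' @param candidates increasing candidate Dmax values (Angstrom).
#' @param alpha smoothness penalty passed to [prFromProfile()].
#' @param nBins number of r nodes.
#' @param plateauTol relative score tolerance for the plateau-onset rule.
#' @return list with `Dmax` (selected candidate) and `table`
#'   (candidate, chi2, tailFraction, score).
#' @export
dmaxScan <- function(profile, candidates, alpha = NULL, nBins = 101L,
                     plateauTol = 0.05) {
  stopifnot(length(candidates) >= 1L, all(candidates > 0))
  M <- length(qValues(profile))
  rows <- lapply(candidates, function(dm) {
    pr <- prFromProfile(profile, dm, alpha = alpha, nBins = nBins)
    tailIdx <- pr$r > 0.95 * dm
    tailFrac <- sum(pr$P[tailIdx]) / max(sum(pr$P), 1e-300)
    data.frame(candidate = dm, chi2 = pr$chi2, tailFraction = tailFrac,
               score = pr$chi2 + M * tailFrac)
  })
  tab <- do.call(rbind, rows)
  ok <- tab$score <= (1 + plateauTol) * min(tab$score)
  list(Dmax = min(tab$candidate[ok]), table = tab)
}
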