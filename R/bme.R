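#' @include debye.R
NULL

#' Effective ensemble fraction
#'
#' `phi_eff = exp(S(w))` with the relative entropy
#' `S(w) = -sum_j w_j log(w_j / w0_j)` (and `0 log 0 = 0`): the fraction of
#' the prior ensemble that still contributes substantially after
#' reweighting. Equals 1 iff `w = w0`.
#'
#' @param w simplex weight vector.
#' @param w0 prior weights (default uniform).
#' @return `phi_eff` in (0, 1\].
#' @export
effectiveFraction <- function(w, w0 = NULL) {
  exp(relativeEntropy(w, w0))
}

#' Relative entropy of weights against a prior
#' @rdname effectiveFraction
#' @export
relativeEntropy <- function(w, w0 = NULL) {
  if (is.null(w0)) w0 <- rep(1 / length(w), length(w))
  if (abs(sum(w) - 1) > 1e-9 || min(w) < 0)
    stop("w must lie on the simplex")
  pos <- w > 0
  -sum(w[pos] * log(w[pos] / w0[pos]))
}

## intensity matrix (snapshots x points) from a list of profiles or a matrix
.asIMatrix <- function(IMatrix, M) {
  if (is.list(IMatrix))
    IMatrix <- t(vapply(IMatrix, intensities, numeric(M)))
  if (!is.matrix(IMatrix)) IMatrix <- matrix(IMatrix, nrow = 1L)
  IMatrix
}

## Dual BME solve at fixed scale. F is (N x M) scaled/normalized intensities,
## yp the normalized target. Returns lambda, weights and diagnostics.
.bmeDual <- function(F, yp, w0, theta, lambda0 = NULL) {
  M <- ncol(F)
  logw0 <- log(w0)
  wOf <- function(lambda) {
    e <- logw0 - as.numeric(F %*% lambda)
    e <- e - max(e)
    w <- exp(e)
    w / sum(w)
  }
  ## theta-normalized dual: G(lambda)/theta, whose gradient is
  ## -<F>_w + y' + theta*lambda -- well-scaled at any theta
  Gfun <- function(lambda) {
    e <- logw0 - as.numeric(F %*% lambda)
    m <- max(e)
    (m + log(sum(exp(e - m)))) + sum(lambda * yp) +
      theta / 2 * sum(lambda^2)
  }
  Ggrad <- function(lambda) {
    w <- wOf(lambda)
    avgF <- as.numeric(crossprod(F, w))
    -avgF + yp + theta * lambda
  }
  lambda <- if (is.null(lambda0)) rep(0, M) else lambda0
  opt <- stats::optim(lambda, Gfun, Ggrad, method = "BFGS",
                      control = list(maxit = 2000L, reltol = 1e-15))
  lambda <- opt$par
  ## Newton polish: Hessian = Cov_w(F) + theta I, convex
  for (it in 1:30) {
    w <- wOf(lambda)
    g <- Ggrad(lambda)
    if (sqrt(sum(g^2)) < 1e-10) break
    avgF <- as.numeric(crossprod(F, w))
    Fc <- sweep(F, 2L, avgF)
    H <- crossprod(Fc * sqrt(w)) + diag(theta, M)
    step <- tryCatch(solve(H, g), error = function(e) g / max(diag(H)))
    ## backtracking line search on the convex dual
    t <- 1; G0 <- Gfun(lambda)
    repeat {
      cand <- lambda - t * step
      if (Gfun(cand) <= G0 + 1e-12 || t < 1e-8) break
      t <- t / 2
    }
    lambda <- lambda - t * step
  }
  w <- wOf(lambda)
  list(lambda = lambda, w = w, gradNorm = sqrt(sum(Ggrad(lambda)^2)),
       iterations = opt$counts[["function"]])
}

#' Bayesian maximum-entropy reweighting against a SAXS profile
#'
#' Finds simplex weights minimizing `L(w) = chi2(w)/2 - theta * S(w)` with
#' `chi2(w) = sum_i ((scale * sum_j w_j I_j,i - I_exp,i)/sigma_i)^2` and the
#' relative entropy `S(w) = -sum_j w_j log(w_j/w0_j)`. The optimization uses
#' the convex dual over one Lagrange multiplier per data point (cheap for
#' many snapshots and few points), solved by BFGS with Newton polishing,
#' starting from `lambda = 0` (`w = w0`) -- fully deterministic. A global
#' multiplicative scale factor is refit to the weighted average after each
#' solve and the two steps alternate to convergence (`fitScale = FALSE`
#' keeps `scale` fixed).
#'
#' @param IMatrix per-snapshot intensities: an N x M matrix or a list of
#'   [ScatteringProfile-class] on the target's q-grid.
#' @param target [ScatteringProfile-class] with positive errors.
#' @param theta entropy regularization parameter (> 0).
#' @param w0 prior weights (default uniform).
#' @param fitScale alternate a global scale refit (default `TRUE`).
#' @param scale fixed scale used when `fitScale = FALSE`.
#' @return A [ReweightResult-class].
#' @export
bmeWeights <- function(IMatrix, target, theta, w0 = NULL, fitScale = TRUE,
                       scale = 1) {
  stopifnot(theta > 0)
  y <- intensities(target)
  sig <- sigmas(target)
  M <- length(y)
  if (M < 1L) stop("target must contain at least one point")
  if (any(is.na(sig)) || any(sig <= 0))
    stop("target profile must carry positive errors")
  Imat <- .asIMatrix(IMatrix, M)
  if (ncol(Imat) != M) stop("IMatrix and target have mismatched lengths")
  N <- nrow(Imat)
  if (is.null(w0)) w0 <- rep(1 / N, N)
  if (length(w0) != N || abs(sum(w0) - 1) > 1e-9 || min(w0) < 0)
    stop("w0 must be a simplex vector of length N")
  finish <- function(w, lambda, s, iters) {
    Iavg <- as.numeric(crossprod(Imat, w))
    chi2 <- .chi2(Iavg, y, sig, s)
    S <- relativeEntropy(w, w0)
    new("ReweightResult", weights = w, lambda = lambda, chi2 = chi2,
        entropy = S, L = chi2 / 2 - theta * S, theta = theta,
        phiEff = exp(S), scale = s, c1 = NA_real_, c2 = NA_real_,
        log = list(iterations = iters, fitScale = fitScale))
  }
  if (N == 1L)
    return(finish(1, rep(0, M),
                  if (fitScale)
                    .fitScale(Imat[1L, ], y, sig)[["scale"]] else scale,
                  0L))
  yp <- y / sig
  s <- if (fitScale)
    .fitScale(as.numeric(crossprod(Imat, w0)), y, sig)[["scale"]] else scale
  lambda <- NULL
  w <- w0
  iters <- 0L
  Lprev <- Inf
  solveAt <- function(sCur, lambda0) {
    F <- t(t(Imat) / sig) * sCur
    .bmeDual(F, yp, w0, theta, lambda0 = lambda0)
  }
  primalL <- function(w, sCur) {
    .chi2(as.numeric(crossprod(Imat, w)), y, sig, sCur) / 2 -
      theta * relativeEntropy(w, w0)
  }
  converged <- FALSE
  for (outer in 1:60) {
    sol <- solveAt(s, lambda)
    lambda <- sol$lambda
    w <- sol$w
    iters <- iters + 1L
    if (!fitScale) { converged <- TRUE; break }
    sNew <- .fitScale(as.numeric(crossprod(Imat, w)), y, sig)[["scale"]]
    Lnow <- primalL(w, sNew)
    conv <- abs(sNew - s) <= 1e-10 * max(1, abs(s)) ||
      abs(Lnow - Lprev) <= 1e-12 * (1 + abs(Lnow))
    s <- sNew
    Lprev <- Lnow
    if (conv) { converged <- TRUE; break }
  }
  if (!converged) {
    ## the alternation crawls along a flat scale/weight valley in weakly
    ## regularized regimes; minimize the scale-profiled objective directly
    lamState <- lambda
    profL <- function(t) {
      solT <- solveAt(exp(t), lamState)
      lamState <<- solT$lambda
      primalL(solT$w, exp(t))
    }
    opt <- stats::optimize(profL, interval = log(s) + c(-1, 1), tol = 1e-12)
    s <- exp(opt$minimum)
    sol <- solveAt(s, lamState)
    lambda <- sol$lambda
    w <- sol$w
    iters <- iters + 1L
  }
  if (sol$gradNorm > 1e-6)
    stop(sprintf("BME dual failed to converge (gradient norm %.3g)",
                 sol$gradNorm))
  finish(w, lambda, s, iters)
}

#' Scan the entropy-regularization parameter theta
#'
#' Runs [bmeWeights()] over a grid of theta values and tabulates
#' `(theta, chi2, S, phi_eff)` for L-curve inspection. Solver failures at
#' individual theta values are flagged and the scan continues.
#'
#' @inheritParams bmeWeights
#' @param thetaGrid positive increasing theta values.
#' @return A `thetaScan` object: data.frame with attribute `results`
#'   (the per-theta [ReweightResult-class]s).
#' @export
thetaScan <- function(IMatrix, target, thetaGrid, w0 = NULL,
                      fitScale = TRUE) {
  stopifnot(all(thetaGrid > 0), !is.unsorted(thetaGrid, strictly = TRUE))
  results <- vector("list", length(thetaGrid))
  tab <- data.frame(theta = thetaGrid, chi2 = NA_real_,
                    chi2Reduced = NA_real_, entropy = NA_real_,
                    phiEff = NA_real_, ok = FALSE)
  for (k in seq_along(thetaGrid)) {
    res <- tryCatch(bmeWeights(IMatrix, target, thetaGrid[k], w0 = w0,
                               fitScale = fitScale),
                    error = function(e) e)
    if (inherits(res, "error")) {
      warning(sprintf("theta = %g failed: %s", thetaGrid[k],
                      conditionMessage(res)))
      next
    }
    results[[k]] <- res
    tab$chi2[k] <- res@chi2
    tab$chi2Reduced[k] <- res@chi2 / length(intensities(target))
    tab$entropy[k] <- res@entropy
    tab$phiEff[k] <- res@phiEff
    tab$ok[k] <- TRUE
  }
  attr(tab, "results") <- results
  class(tab) <- c("thetaScan", "data.frame")
  tab
}

#' Select theta from a scan
#'
#' `method = "curvature"` picks the elbow of the `phi_eff`--`chi2` L-curve
#' as the point of maximum discrete (Menger) curvature on normalized
#' log-log axes. `method = "phiEff"` picks the smallest theta whose
#' effective fraction exceeds `phiMin` (the manual criterion of keeping a
#' substantial part of the prior ensemble).
#'
#' @param scan a [thetaScan()] result.
#' @param method `"curvature"` or `"phiEff"`.
#' @param phiMin threshold for `method = "phiEff"` (default 0.7).
#' @return Selected theta (numeric scalar).
#' @export
selectTheta <- function(scan, method = c("curvature", "phiEff"),
                        phiMin = 0.7) {
  method <- match.arg(method)
  ok <- scan$ok
  th <- scan$theta[ok]
  if (length(th) < 3L) stop("need at least 3 successful theta values")
  if (method == "phiEff") {
    hit <- which(scan$phiEff[ok] > phiMin)
    if (!length(hit)) stop("no theta reaches the phi_eff threshold")
    return(th[min(hit)])
  }
  x <- log10(scan$chi2[ok]); y <- log10(scan$phiEff[ok])
  rx <- max(x) - min(x); ry <- max(y) - min(y)
  x <- (x - min(x)) / ifelse(rx > 0, rx, 1)
  y <- (y - min(y)) / ifelse(ry > 0, ry, 1)
  n <- length(x)
  curv <- rep(-Inf, n)
  for (k in 2:(n - 1L)) {
    a <- c(x[k - 1L], y[k - 1L]); b <- c(x[k], y[k]); cc <- c(x[k + 1L], y[k + 1L])
    ab <- sqrt(sum((a - b)^2)); bc <- sqrt(sum((b - cc)^2))
    ca <- sqrt(sum((cc - a)^2))
    area2 <- abs((b[1] - a[1]) * (cc[2] - a[2]) -
                   (cc[1] - a[1]) * (b[2] - a[2]))
    if (ab * bc * ca > 0) curv[k] <- 2 * area2 / (ab * bc * ca)
  }
  th[which.max(curv)]
}

#' Iterative BME with form-factor averaging
#'
#' The two-round reweighting protocol: (1) fit `(c1, c2)` and profiles per
#' snapshot against the target; (2) reweight by BME; (3) average the fitted
#' `(c1, c2)` with the BME weights; (4) recompute all snapshot profiles at
#' the fixed averaged parameters; (5) reweight again. Both rounds are
#' logged.
#'
#' @param ensemble an [Ensemble-class].
#' @param target [ScatteringProfile-class] with errors.
#' @param theta entropy regularization parameter.
#' @param maxRounds number of BME rounds (default 2 = the full protocol).
#' @param params base [formFactorParams()] (widths are kept fixed).
#' @param bases optional precomputed list of [debyeBasis()] on the target
#'   q-grid, to avoid recomputation.
#' @return A [ReweightResult-class] whose `log` carries the per-snapshot
#'   fits, the weighted-average `(c1, c2)` and the per-round results.
#' @export
iterativeBME <- function(ensemble, target, theta, maxRounds = 2L,
                         params = formFactorParams(), bases = NULL) {
  qd <- qValues(target)
  if (is.null(bases))
    bases <- lapply(conformers(ensemble), debyeBasis, qGrid = qd)
  N <- length(bases)
  fits <- lapply(bases, function(b)
    fitProfile(NULL, target, fitCParams = TRUE, basis = b, params = params))
  c1s <- vapply(fits, `[[`, 0, "c1")
  c2s <- vapply(fits, `[[`, 0, "c2")
  Imat <- t(vapply(seq_len(N), function(j)
    intensities(profileFromBasis(bases[[j]], formFactorParams(
      c1s[j], c2s[j], params$sigmaB, params$sigmaW))), numeric(length(qd))))
  w0 <- initialWeights(ensemble)
  rounds <- list()
  res <- bmeWeights(Imat, target, theta, w0 = w0)
  res@c1 <- NA_real_; res@c2 <- NA_real_
  rounds[[1L]] <- res
  cbar <- c(c1 = sum(res@weights * c1s), c2 = sum(res@weights * c2s))
  if (maxRounds >= 2L) {
    pbar <- formFactorParams(min(max(cbar["c1"], 0.95), 1.05),
                             min(max(cbar["c2"], -2), 4),
                             params$sigmaB, params$sigmaW)
    Imat2 <- t(vapply(bases, function(b)
      intensities(profileFromBasis(b, pbar)), numeric(length(qd))))
    res <- bmeWeights(Imat2, target, theta, w0 = w0)
    res@c1 <- pbar$c1; res@c2 <- pbar$c2
    rounds[[2L]] <- res
  } else {
    res@c1 <- cbar[["c1"]]; res@c2 <- cbar[["c2"]]
  }
  res@log <- c(res@log, list(
    perSnapshot = data.frame(c1 = c1s, c2 = c2s,
                             scale = vapply(fits, `[[`, 0, "scale"),
                             chi2 = vapply(fits, `[[`, 0, "chi2")),
    cbar = cbar, rounds = rounds))
  res
}
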