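test_that("Debye profiles match closed forms and a brute-force double sum", {
  q <- defaultQGrid(40, 0.005, 0.4)

  # single bead: pure form-factor envelope
  one <- Conformer(matrix(0, 1, 3), scatterWeight = 1.7)
  p1 <- debyeProfile(one, q, formFactorParams(c1 = 1.03, c2 = 0))
  expect_equal(intensities(p1), 1.7^2 * exp(-(q * 3 * 1.03)^2),
               tolerance = 1e-12)

  # two identical beads: I(q)/f^2 = 2(1 + sin(qd)/(qd)); I(0)/f(0)^2 = 4
  d <- 23.1
  two <- Conformer(matrix(c(0, 0, 0, d, 0, 0), 2, 3, byrow = TRUE))
  p2 <- debyeProfile(two, c(0, q), formFactorParams(c2 = 0))
  fq <- exp(-(c(0, q) * 3)^2 / 2)
  ref <- 2 * fq^2 * (1 + c(1, sin(q * d) / (q * d)))
  expect_lt(max(abs(intensities(p2) - ref)), 1e-10 * max(ref))
  expect_equal(intensities(p2)[1], 4)

  # 50-bead conformer against an independent double loop
  cf <- randomConformer(50, seed = 10)
  cf@scatterWeight <- runif(50, 0.5, 2)
  pars <- formFactorParams(c1 = 0.98, c2 = 1.2)
  p <- debyeProfile(cf, q, pars)
  f0 <- scatterWeights(cf); h <- exposureProxy(cf)
  x <- beadCoords(cf)
  oracle <- vapply(q, function(qq) {
    f <- f0 * exp(-(qq * 3 * 0.98)^2 / 2) + 1.2 * h * exp(-(qq * 3)^2 / 2)
    s <- 0
    for (i in 1:50) for (j in 1:50) {
      r <- sqrt(sum((x[i, ] - x[j, ])^2))
      s <- s + f[i] * f[j] * (if (qq * r == 0) 1 else sin(qq * r) / (qq * r))
    }
    s
  }, 0)
  expect_lt(max(abs(intensities(p) - oracle)), 1e-10 * max(oracle))

  expect_error(debyeProfile(cf, c(-0.1, 0.1)), "negative q")
})

test_that("I(0) identity and rigid-transform invariance hold", {
  cf <- randomConformer(30, seed = 11)
  pars <- formFactorParams(c2 = 2)
  p <- debyeProfile(cf, c(0, 0.1), pars)
  f0 <- scatterWeights(cf); h <- exposureProxy(cf)
  expect_equal(intensities(p)[1], (sum(f0) + 2 * sum(h))^2)

  R <- diag(3)[c(2, 3, 1), ]                  # a proper rotation
  moved <- Conformer(sweep(beadCoords(cf) %*% R, 2, c(3, 4, 5), "+"))
  pm <- debyeProfile(moved, c(0, 0.1), pars)
  expect_equal(intensities(p), intensities(pm), tolerance = 1e-12)
})

test_that("small-q expansion reproduces the coordinate Rg", {
  dom <- makeRigidDomain(40, seed = 12)
  cf <- Conformer(dom)
  rg <- radiusOfGyration(cf)
  q <- seq(0.002, 0.5 / rg, length.out = 25)
  p <- debyeProfile(cf, q, formFactorParams(c2 = 0, sigmaB = 1e-4))
  gu <- guinierFit(p, qRgLimit = 0.5)
  expect_lt(abs(gu$Rg - rg) / rg, 0.01)
})

test_that("ensemble averaging is the weighted sum and validates grids", {
  q <- defaultQGrid(20)
  profs <- lapply(1:5, function(s) debyeProfile(randomConformer(15, s), q))
  w <- c(0.1, 0.2, 0.3, 0.25, 0.15)
  avg <- ensembleAverageProfile(profs, w)
  Imat <- vapply(profs, intensities, numeric(20))
  expect_equal(intensities(avg), as.numeric(Imat %*% w))

  oneHot <- ensembleAverageProfile(profs, c(0, 0, 1, 0, 0))
  expect_identical(intensities(oneHot), intensities(profs[[3]]))

  same <- ensembleAverageProfile(profs[c(1, 1, 1)], rep(1 / 3, 3))
  expect_equal(intensities(same), intensities(profs[[1]]))

  qOther <- defaultQGrid(20, 0.02, 0.25)
  profs2 <- c(profs[1:4], list(debyeProfile(randomConformer(15, 9), qOther)))
  expect_error(ensembleAverageProfile(profs2, w), "q-grid")
  expect_error(ensembleAverageProfile(profs, w * 2), "simplex")
})

test_that("profile fitting recovers scale and matches a numeric optimizer", {
  q <- defaultQGrid(60)
  cf <- randomConformer(20, seed = 13)
  calc <- debyeProfile(cf, q)
  data <- ScatteringProfile(q, 2.5 * intensities(calc),
                            0.01 * intensities(calc) + 1e-9)
  fit <- fitProfile(calc, data)
  expect_equal(fit$scale, 2.5, tolerance = 1e-12)
  expect_lt(fit$chi2, 1e-16)

  # closed-form scale equals 1-D numeric minimization
  set.seed(14)
  noisy <- ScatteringProfile(q, intensities(calc) *
                               (1 + rnorm(60, 0, 0.05)),
                             0.05 * intensities(calc))
  fitN <- fitProfile(calc, noisy)
  num <- optimize(function(s)
    sum(((s * intensities(calc) - intensities(noisy)) / sigmas(noisy))^2),
    interval = c(0.1, 10), tol = 1e-12)
  expect_lt(abs(fitN$scale - num$minimum), 1e-8)

  # pure-noise residuals give a sane reduced chi2
  red <- vapply(1:100, function(s) {
    set.seed(200 + s)
    sig <- 0.03 * intensities(calc)
    dat <- ScatteringProfile(q, intensities(calc) + rnorm(60, 0, sig), sig)
    fitProfile(calc, dat)$chi2Reduced
  }, 0)
  expect_true(all(red > 0.5 & red < 2))

  noSigma <- ScatteringProfile(q, intensities(calc))
  expect_error(fitProfile(calc, noSigma), "no errors")
})

test_that("(c1, c2) fitting recovers injected form-factor parameters", {
  cf <- randomConformer(25, seed = 15)
  q <- defaultQGrid(50)
  basis <- debyeBasis(cf, q)
  truthPars <- formFactorParams(c1 = 1.02, c2 = 1.4)
  truth <- profileFromBasis(basis, truthPars)
  data <- ScatteringProfile(q, 3 * intensities(truth),
                            0.002 * intensities(truth))
  fit <- fitProfile(NULL, data, fitCParams = TRUE, basis = basis)
  # (c1, c2, scale) are strongly correlated at one-bead resolution; the
  # parameters land near the injected values and the fit is excellent
  expect_lt(abs(fit$c1 - 1.02), 0.03)
  expect_lt(abs(fit$c2 - 1.4), 0.3)
  expect_equal(fit$scale, 3, tolerance = 0.15)
  expect_lt(fit$chi2Reduced, 1)
  expect_error(fitProfile(NULL, data, fitCParams = TRUE), "debyeBasis")
})
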