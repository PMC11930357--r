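test_that("effective fraction follows the entropy formula", {
  expect_equal(effectiveFraction(rep(0.25, 4)), 1.0)
  expect_equal(effectiveFraction(c(1, 0, 0, 0)), 0.25)

  set.seed(30)
  w <- rgamma(10, 1); w <- w / sum(w)
  w0 <- rgamma(10, 2); w0 <- w0 / sum(w0)
  direct <- exp(-sum(w * log(w / w0)))
  expect_equal(effectiveFraction(w, w0), direct, tolerance = 1e-12)

  expect_lte(relativeEntropy(w), 1e-12)     # S(w) <= 0 against uniform
  expect_error(effectiveFraction(c(0.5, 0.6)), "simplex")
})

test_that("BME solves degenerate and limiting cases", {
  q <- c(0.1, 0.2, 0.3)
  target <- ScatteringProfile(q, c(5, 4, 3), c(0.2, 0.2, 0.2))

  # single snapshot: forced weights, zero entropy
  one <- bmeWeights(matrix(c(6, 5, 4), 1), target, theta = 3)
  expect_identical(one@weights, 1)
  expect_identical(one@phiEff, 1)
  expect_identical(one@entropy, 0)

  set.seed(31)
  Imat <- matrix(runif(5 * 3, 1, 10), 5)
  big <- bmeWeights(Imat, target, theta = 1e9)
  expect_lt(max(abs(big@weights - 0.2)), 1e-4)

  res <- bmeWeights(Imat, target, theta = 5)
  expect_lt(abs(sum(res@weights) - 1), 1e-9)
  expect_gte(min(res@weights), 0)
  expect_gt(res@phiEff, 0); expect_lte(res@phiEff, 1 + 1e-12)
  # the solution is no worse than the prior
  L0 <- bmeObjective(matrix(0.2, 1, 5), Imat * res@scale,
                     intensities(target), sigmas(target), 5, rep(0.2, 5))
  expect_lte(res@L, L0 + 1e-9)

  expect_error(bmeWeights(Imat, target, theta = 5, w0 = c(1, 1, 1, 1, 1)),
               "simplex")
  bad <- ScatteringProfile(q, c(5, 4, 3))
  expect_error(bmeWeights(Imat, bad, theta = 5), "positive errors")
})

test_that("the dual solver matches a simplex-grid oracle on a printed toy", {
  Imat <- matrix(c(10, 2,
                   5, 5,
                   1, 9), 3, byrow = TRUE)
  target <- ScatteringProfile(c(0.1, 0.2), c(6, 4), c(0.5, 0.5))
  theta <- 2
  res <- bmeWeights(Imat, target, theta, fitScale = FALSE)
  W <- simplexGrid(3, 1e-3)
  Lgrid <- bmeObjective(W, Imat, c(6, 4), c(0.5, 0.5), theta, rep(1 / 3, 3))
  # polish the grid argmin with an independent simplex optimizer: the raw
  # 1e-3 grid sits slightly above the continuous minimum
  softmax <- function(z) { e <- exp(z - max(z)); e / sum(e) }
  pol <- optim(log(pmax(W[which.min(Lgrid), ], 1e-8)), function(z)
    bmeObjective(matrix(softmax(z), 1), Imat, c(6, 4), c(0.5, 0.5), theta,
                 rep(1 / 3, 3)),
    method = "Nelder-Mead", control = list(maxit = 5000, reltol = 1e-14))
  expect_lt(abs(res@L - min(min(Lgrid), pol$value)), 1e-6)
})

test_that("theta scans trace a monotone trade-off frontier", {
  set.seed(32)
  Imat <- matrix(runif(8 * 4, 1, 10), 8)
  q <- c(0.05, 0.1, 0.2, 0.3)
  truth <- as.numeric(crossprod(Imat, c(0.4, 0.3, 0.1, 0.1, 0.05, 0.05, 0, 0)))
  target <- ScatteringProfile(q, truth * (1 + rnorm(4, 0, 0.02)),
                              0.02 * truth)
  grid <- 10^seq(-2, 7, length.out = 12)
  scan <- thetaScan(Imat, target, grid)
  expect_true(all(scan$ok))
  expect_true(all(diff(scan$chi2) >= -1e-6))
  expect_true(all(diff(scan$phiEff) >= -1e-6))
  expect_gt(scan$phiEff[12], 0.99)

  th <- selectTheta(scan)
  expect_true(th %in% grid)
  thPhi <- selectTheta(scan, method = "phiEff", phiMin = 0.7)
  expect_gte(scan$phiEff[match(thPhi, scan$theta)], 0.7)
})

test_that("iterative reweighting averages and reapplies form factors", {
  mix <- toyMixture()
  ens <- mix$ensemble
  q <- defaultQGrid(40, 0.01, 0.3)

  # identical snapshots: weights stay uniform, cbar equals the single fit
  same <- Ensemble(rep(conformers(ens)[1], 4))
  tgt1 <- makeTargetProfile(same, rep(0.25, 4), qGrid = q, noiseFrac = 0.01,
                            seed = 7)
  resSame <- iterativeBME(same, tgt1, theta = 10)
  expect_lt(max(abs(ensembleWeights(resSame) - 0.25)), 1e-9)
  expect_equal(unname(resSame@log$cbar["c1"]),
               resSame@log$perSnapshot$c1[1], tolerance = 1e-12)
  expect_equal(unname(resSame@log$cbar["c2"]),
               resSame@log$perSnapshot$c2[1], tolerance = 1e-12)

  # one-hot weighted average returns that snapshot's parameters exactly
  cs <- data.frame(c1 = c(0.97, 1.01, 1.04), c2 = c(-1, 0.5, 2))
  wOne <- c(0, 1, 0)
  expect_identical(sum(wOne * cs$c1), cs$c1[2])
  expect_identical(sum(wOne * cs$c2), cs$c2[2])

  # the second round does not degrade the fit
  tgt <- makeTargetProfile(ens, initialWeights(ens), qGrid = q,
                           noiseFrac = 0.01, seed = 3)
  res <- iterativeBME(ens, tgt, theta = 5)
  r1 <- res@log$rounds[[1]]@chi2
  r2 <- res@log$rounds[[2]]@chi2
  expect_lte(r2, r1 * 1.05)
  expect_equal(length(res@log$rounds), 2L)
  expect_equal(nrow(res@log$perSnapshot), nConformers(ens))
})
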