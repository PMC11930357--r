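test_that("Guinier analysis is exact on a Gaussian profile", {
  q <- seq(0.004, 0.05, length.out = 40)
  p <- ScatteringProfile(q, 250 * exp(-q^2 * 30^2 / 3))
  g <- guinierFit(p)
  expect_lt(abs(g$Rg - 30), 0.1)
  expect_lt(abs(g$I0 - 250) / 250, 0.001)
  expect_lte(g$qmaxRg, 1.3)
  expect_gte(g$nPoints, 5)

  # scale invariance: I0 scales, Rg unchanged
  g2 <- guinierFit(ScatteringProfile(q, 7 * intensities(p)))
  expect_equal(g2$Rg, g$Rg)
  expect_equal(g2$I0, 7 * g$I0, tolerance = 1e-9)

  expect_error(guinierFit(ScatteringProfile(q, exp(40 * q))),
               "no valid Guinier regime")
  expect_error(guinierFit(ScatteringProfile(q, rep(-1, 40))),
               "non-positive")
})

test_that("Guinier Rg agrees with the coordinate-route oracle", {
  cf <- Conformer(makeRigidDomain(35, seed = 20))
  rg <- radiusOfGyration(cf)
  q <- seq(0.003, 0.8 / rg, length.out = 30)
  p <- debyeProfile(cf, q, formFactorParams(c2 = 0, sigmaB = 1e-4))
  g <- guinierFit(p, qRgLimit = 0.8)
  expect_lt(abs(g$Rg - rg) / rg, 0.02)
})

test_that("coordinate-route P(r) has the stated structure", {
  d <- 20
  two <- Conformer(matrix(c(0, 0, 0, 0, 0, d), 2, 3, byrow = TRUE))
  pr <- prFromCoordinates(two, rBin = 2)
  expect_equal(pr$Dmax, d)
  expect_equal(sum(pr$P > 0), 1L)
  expect_true(pr$r[pr$P > 0] > d - 2 && pr$r[pr$P > 0] < d + 2)

  cf <- randomConformer(30, seed = 21)
  pr <- prFromCoordinates(cf, rBin = 1)
  expect_equal(pr$Dmax, max(dist(beadCoords(cf))))

  # rigid rotation leaves P(r) unchanged
  R <- diag(3)[c(3, 1, 2), ]
  rot <- Conformer(beadCoords(cf) %*% R)
  expect_equal(prFromCoordinates(rot, rBin = 1)$P, pr$P, tolerance = 1e-12)

  # ensemble mixing is linear in the weights
  cf2 <- randomConformer(30, seed = 22)
  ens <- Ensemble(list(cf, cf2), weights = c(0.3, 0.7))
  prE <- prFromCoordinates(ens, rBin = 1)
  expect_gte(min(prE$P), 0)
  expect_equal(sum(prE$P) * 1, 1, tolerance = 1e-9)  # unit area, rBin = 1
})

test_that("indirect Fourier transform inverts the forward model", {
  # known smooth P(r) -> exact profile -> recovery
  Dmax <- 60
  r <- seq(0, Dmax, length.out = 101)
  Ptrue <- r^2 * (Dmax - r)^2
  Ptrue <- Ptrue / (sum(Ptrue) * diff(r)[1])
  q <- defaultQGrid(60, 0.01, 0.35)
  qr <- outer(q, r)
  S <- ifelse(qr == 0, 1, sin(qr) / ifelse(qr == 0, 1, qr))
  I <- as.numeric(4 * pi * S %*% Ptrue * diff(r)[1])
  prof <- ScatteringProfile(q, I, 1e-4 * I[1] + 0 * I)
  rec <- prFromProfile(prof, Dmax, alpha = 1e-8)
  expect_gte(min(rec$P), 0)
  expect_gt(cor(rec$P, Ptrue), 0.99)

  # Rg from P(r) consistent with Guinier on a synthetic globule
  cf <- Conformer(makeRigidDomain(45, seed = 23))
  rg <- radiusOfGyration(cf)
  qf <- defaultQGrid(60, 0.005, 0.3)
  pf <- debyeProfile(cf, qf, formFactorParams(c2 = 0, sigmaB = 1e-4))
  tgt <- makeTargetProfile(list(pf), 1, qGrid = qf, noiseFrac = 0.01,
                           seed = 5)
  prP <- prFromProfile(tgt, Dmax = conformerDmax(cf) * 1.05)
  gu <- guinierFit(tgt)
  expect_lt(abs(prRg(prP) - gu$Rg) / gu$Rg, 0.05)
})

test_that("profile-route P(r) matches the coordinate route at 2% noise", {
  cf <- Conformer(makeRigidDomain(60, seed = 9))
  q <- defaultQGrid(60, 0.01, 0.35)
  pf <- debyeProfile(cf, q, formFactorParams(c2 = 0, sigmaB = 1e-4))
  tgt <- makeTargetProfile(list(pf), 1, qGrid = q, noiseFrac = 0.02,
                           seed = 4)
  prC <- prFromCoordinates(cf, rBin = 2)
  prP <- prFromProfile(tgt, Dmax = prC$Dmax * 1.05)
  onGrid <- approx(prC$r, prC$P, xout = prP$r, rule = 2)$y
  expect_gt(cor(onGrid, prP$P), 0.98)
})

test_that("Dmax scan recovers the true dimension within one step", {
  cf <- Conformer(makeRigidDomain(60, seed = 9))
  truth <- conformerDmax(cf)
  q <- defaultQGrid(60, 0.01, 0.35)
  pf <- debyeProfile(cf, q, formFactorParams(c2 = 0, sigmaB = 1e-4))
  tgt <- makeTargetProfile(list(pf), 1, qGrid = q, noiseFrac = 0.02,
                           seed = 2)
  cands <- seq(12, 48, by = 4)
  scan <- dmaxScan(tgt, cands)
  expect_equal(nrow(scan$table), length(cands))
  expect_lte(abs(scan$Dmax - truth), 4 + min(abs(cands - truth)))

  # chi2 drops steeply below the truth, then plateaus
  below <- scan$table$chi2[scan$table$candidate <= truth - 4]
  expect_true(all(diff(below) < 0))
  above <- scan$table$chi2[scan$table$candidate >= truth]
  expect_lt(max(above) / min(above), 1.2)
})

test_that("ill-conditioned unregularized inversion is refused", {
  q <- defaultQGrid(20, 0.01, 0.05)   # few low-q points, many bins
  I <- exp(-q^2 * 300)
  prof <- ScatteringProfile(q, I, 0.01 * I)
  expect_error(prFromProfile(prof, 100, alpha = 0), "alpha > 0")
})
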