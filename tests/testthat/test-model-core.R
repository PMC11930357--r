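test_that("radius of gyration matches closed forms and the pairwise identity", {
  one <- Conformer(matrix(c(1, 2, 3), 1, 3))
  expect_equal(radiusOfGyration(one), 0)

  d <- 7.4
  two <- Conformer(matrix(c(0, 0, 0, d, 0, 0), 2, 3, byrow = TRUE))
  expect_equal(radiusOfGyration(two), d / 2)

  cf <- randomConformer(100, seed = 1)
  dmat <- as.matrix(dist(beadCoords(cf)))
  pairwise <- sqrt(sum(dmat^2) / (2 * 100^2))
  expect_lt(abs(radiusOfGyration(cf) - pairwise), 1e-10)

  # weighted centroid definition
  w <- runif(100, 0.1, 2)
  ctr <- colSums(beadCoords(cf) * w) / sum(w)
  byHand <- sqrt(sum(w * rowSums(sweep(beadCoords(cf), 2, ctr)^2)) / sum(w))
  expect_equal(radiusOfGyration(cf, w), byHand)

  expect_error(radiusOfGyration(cf, rep(0, 100)), "zero")
  expect_error(radiusOfGyration(cf, rep(-1, 100)), "non-negative")
})

test_that("Rg is invariant under rigid transforms", {
  cf <- randomConformer(40, seed = 2)
  th <- 0.83
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3,
              byrow = TRUE)
  moved <- Conformer(sweep(beadCoords(cf) %*% R, 2, c(5, -3, 11), "+"))
  expect_lt(abs(radiusOfGyration(cf) - radiusOfGyration(moved)), 1e-9)
})

test_that("Kabsch superposition recovers rotations and is optimal", {
  cf <- randomConformer(25, seed = 3)
  sup <- superposeConformers(cf, cf)
  expect_lt(sup$rmsd, 1e-12)
  expect_equal(sup$rotation, diag(3), tolerance = 1e-9)

  th <- pi / 2
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3,
              byrow = TRUE)
  rotated <- Conformer(beadCoords(cf) %*% R)
  sup <- superposeConformers(rotated, cf)
  expect_lt(sup$rmsd, 1e-9)
  expect_equal(sup$rotation %*% R, diag(3), tolerance = 1e-9)

  # optimality: no random rigid transform does better
  a <- randomConformer(20, seed = 4)
  b <- randomConformer(20, seed = 5)
  best <- superposeConformers(b, a)$rmsd
  set.seed(6)
  for (k in 1:1000) {
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
    ang <- runif(1, 0, 2 * pi)
    K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3,
                byrow = TRUE)
    Rr <- diag(3) + sin(ang) * K + (1 - cos(ang)) * K %*% K
    X <- sweep(beadCoords(b) %*% Rr, 2, rnorm(3, 0, 5), "+")
    # optimal translation for this rotation: match centroids
    X <- sweep(X, 2, colMeans(X) - colMeans(beadCoords(a)), "-")
    rmsd <- sqrt(mean(rowSums((X - beadCoords(a))^2)))
    expect_gte(rmsd, best - 1e-9)
  }
})

test_that("superposition is proper and rejects degenerate selections", {
  a <- randomConformer(10, seed = 7)
  b <- randomConformer(10, seed = 8)
  expect_equal(det(superposeConformers(b, a)$rotation), 1, tolerance = 1e-9)

  tiny <- Conformer(matrix(rnorm(6), 2, 3))
  expect_error(superposeConformers(tiny, tiny), "at least 3")
  line <- Conformer(cbind(1:5 * 3.8, 0, 0))
  expect_error(superposeConformers(line, line), "degenerate")
})

test_that("subset RMSD handles selections, symmetry and chain swapping", {
  set.seed(9)
  n <- 10
  xyz <- matrix(rnorm(2 * n * 3, 0, 8), 2 * n, 3)
  mk <- function(x) Conformer(x, residueIds = rep(1:n, 2),
                              chainIds = rep(c("A", "B"), each = n))
  a <- mk(xyz)
  expect_equal(subsetRMSD(a, a), 0)

  # relabeled subunits recovered by chain swap
  swapped <- mk(xyz[c((n + 1):(2 * n), 1:n), ])
  expect_gt(subsetRMSD(a, swapped, chainSwap = FALSE), 0.1)
  expect_lt(subsetRMSD(a, swapped, chainSwap = TRUE), 1e-9)

  # uniform displacement on the rmsd selection only
  sel5 <- beadSelection(1, 5, chain = "A")
  supSel <- beadSelection(6, 10, chain = "A")
  shifted <- xyz
  shifted[1:5, 1] <- shifted[1:5, 1] + 1
  b <- mk(shifted)
  expect_equal(subsetRMSD(a, b, superposeSel = supSel, rmsdSel = sel5), 1.0,
               tolerance = 1e-9)

  # symmetry
  c1 <- mk(matrix(rnorm(2 * n * 3, 0, 8), 2 * n, 3))
  expect_equal(subsetRMSD(a, c1), subsetRMSD(c1, a), tolerance = 1e-9)
  # swap result never exceeds the unswapped distance
  expect_lte(subsetRMSD(a, c1, chainSwap = TRUE), subsetRMSD(a, c1) + 1e-12)

  bad <- Conformer(xyz, residueIds = rep(1:n, 2),
                   chainIds = rep(c("A", "C"), each = n))
  expect_error(subsetRMSD(a, bad), "topology")
})

test_that("selections map residue ranges to bead indices", {
  cf <- Conformer(matrix(0, 6, 3), residueIds = c(1:3, 1:3),
                  chainIds = rep(c("A", "B"), each = 3))
  expect_equal(selectionIndices(cf, beadSelection(2, 3)), c(2, 3, 5, 6))
  expect_equal(selectionIndices(cf, beadSelection(2, 3, chain = "B")), 5:6)
  expect_error(selectionIndices(cf, beadSelection(7, 9)), "no beads")
  expect_error(beadSelection(5, 3), "end >= start")
})

test_that("class validity enforces the stated invariants", {
  expect_error(Conformer(matrix(c(0, 0, NA), 1, 3)), "finite")
  expect_error(Conformer(matrix(0, 2, 3), residueIds = c(2, 1)),
               "strictly increasing")
  expect_error(Conformer(matrix(0, 2, 3), scatterWeight = c(-1, 1)),
               "non-negative")
  cfs <- list(randomConformer(5, 1), randomConformer(5, 2))
  expect_error(Ensemble(cfs, weights = c(0.6, 0.6)), "sum to 1")
  expect_error(Ensemble(cfs, weights = c(1.5, -0.5)), "non-negative")
  expect_error(ScatteringProfile(c(0.2, 0.1), c(1, 1)),
               "strictly increasing")
  expect_error(ScatteringProfile(c(0.1, 0.2), c(1, 1), c(0, 1)), "positive")
})
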