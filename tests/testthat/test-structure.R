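mkTwoChain <- function(xyz, n) {
  Conformer(xyz, residueIds = rep(seq_len(n), 2),
            chainIds = rep(c("A", "B"), each = n))
}

test_that("contact probabilities are weighted indicator means", {
  # pair fixed at 5 A in every conformer -> P = 1
  n <- 4
  base <- cbind(c(0, 5, 20, 40), 0, 0)
  ens1 <- Ensemble(lapply(1:3, function(s) {
    set.seed(s)
    Conformer(base + cbind(0, 0, rnorm(4, 0, 0.1)))
  }))
  cm <- contactProbability(ens1, cutoff = 11, mode = "intra")
  expect_equal(contactProbs(cm)[1, 2], 1)

  # pair at 12 A in half the conformers, 5 A in the other half -> 0.5
  near <- Conformer(cbind(c(0, 5), 0, 0))
  far <- Conformer(cbind(c(0, 12), 0, 0))
  ens2 <- Ensemble(list(near, far), weights = c(0.5, 0.5))
  cm2 <- contactProbability(ens2, cutoff = 11, mode = "intra")
  expect_equal(contactProbs(cm2)[1, 2], 0.5)

  # random ensemble against a per-pair brute-force loop
  set.seed(50)
  n <- 6
  confs <- lapply(1:5, function(s) {
    set.seed(s * 7)
    mkTwoChain(matrix(rnorm(2 * n * 3, 0, 8), 2 * n, 3), n)
  })
  w <- c(0.3, 0.25, 0.2, 0.15, 0.1)
  ens <- Ensemble(confs, weights = w)
  for (mode in c("intra", "inter")) {
    cm <- contactProbability(ens, cutoff = 11, mode = mode)
    P <- contactProbs(cm)
    expect_true(all(P >= 0 & P <= 1))
    expect_equal(P, t(P))
    ref <- matrix(0, n, n)
    for (j in 1:5) {
      x <- beadCoords(confs[[j]])
      for (a in 1:n) for (b in 1:n) {
        if (mode == "intra") {
          hit <- (sqrt(sum((x[a, ] - x[b, ])^2)) <= 11) +
                 (sqrt(sum((x[n + a, ] - x[n + b, ])^2)) <= 11)
          ref[a, b] <- ref[a, b] + w[j] * hit / 2
        } else {
          hit <- (sqrt(sum((x[a, ] - x[n + b, ])^2)) <= 11) +
                 (sqrt(sum((x[b, ] - x[n + a, ])^2)) <= 11)
          ref[a, b] <- ref[a, b] + w[j] * hit / 2
        }
      }
    }
    expect_equal(P, ref, tolerance = 1e-12)
  }

  # uniform weights equal the plain frequency map
  ensU <- Ensemble(confs)
  cmU <- contactProbability(ensU, cutoff = 11, mode = "intra")
  cmF <- contactProbability(ensU, weights = rep(0.2, 5), cutoff = 11,
                            mode = "intra")
  expect_identical(contactProbs(cmU), contactProbs(cmF))

  single <- Ensemble(list(Conformer(cbind(c(0, 5), 0, 0))))
  expect_error(contactProbability(single, mode = "inter"), "single-chain")
})

test_that("reweighting toward the compact subpopulation raises the engineered contact", {
  mix <- toyMixture()
  ens <- mix$ensemble
  wUp <- ifelse(mix$labels == 1, 2, 0.5)
  wUp <- wUp / sum(wUp)
  pu <- contactProbs(contactProbability(ens, mode = "intra"))
  pc <- contactProbs(contactProbability(ens, weights = wUp, mode = "intra"))
  # phosphosites 3-6 against the basic segment 30-34 of the toy topology
  expect_gt(mean(pc[3:6, 30:34]), mean(pu[3:6, 30:34]))
})

test_that("weighted GROMOS clustering follows the stated rule", {
  # identical conformers: one cluster holding all weight
  same <- Ensemble(rep(list(randomConformer(8, 1)), 4))
  cl <- gromosClusterWeighted(same, cutoff = 1)
  expect_equal(length(clusterCenters(cl)), 1L)
  expect_equal(clusterWeights(cl), 1)
  expect_equal(clusterCenters(cl), 1L)

  # two shape-distinct rigid groups with weights 0.6 / 0.4; the cutoff
  # sits between the jitter scale and the inter-shape RMSD
  gA <- makeRigidDomain(8, seed = 2)
  gB <- beadCoords(randomConformer(8, seed = 99, spread = 6))
  jitter <- function(x, s) { set.seed(s); x + matrix(rnorm(24, 0, 0.05), 8) }
  ens <- Ensemble(c(lapply(1:3, function(s) Conformer(jitter(gA, s))),
                    lapply(4:5, function(s) Conformer(jitter(gB, s)))),
                  weights = c(0.25, 0.2, 0.15, 0.25, 0.15))
  stopifnot(subsetRMSD(Conformer(gA), Conformer(gB)) > 2)
  cl2 <- gromosClusterWeighted(ens, cutoff = 1)
  expect_equal(length(clusterCenters(cl2)), 2L)
  expect_equal(clusterWeights(cl2), c(0.6, 0.4))
  expect_equal(clusterLabels(cl2), c(1L, 1L, 1L, 2L, 2L))
})

test_that("clustering matches an independent brute-force oracle", {
  set.seed(51)
  for (inst in 1:100) {
    N <- sample(3:8, 1)
    confs <- lapply(seq_len(N), function(s)
      randomConformer(6, seed = inst * 100 + s, spread = 4))
    w <- rgamma(N, 1); w <- w / sum(w)
    ens <- Ensemble(confs, weights = w)
    cutoff <- runif(1, 4, 12)
    D <- rmsdMatrix(ens)
    got <- gromosClusterWeighted(ens, cutoff = cutoff, distMatrix = D)
    ref <- gromosOracle(D, w, cutoff)
    expect_identical(clusterLabels(got), ref$labels)
    expect_identical(clusterCenters(got), ref$centers)
    expect_equal(clusterWeights(got), ref$weights, tolerance = 1e-12)

    # uniform weights reduce to classic neighbour counting
    gotU <- gromosClusterWeighted(ens, cutoff = cutoff, distMatrix = D,
                                  weights = rep(1 / N, N))
    refU <- gromosOracle(D, rep(1 / N, N), cutoff)
    expect_identical(clusterLabels(gotU), refU$labels)
  }
})

test_that("representatives come from the heaviest clusters", {
  same <- Ensemble(rep(list(randomConformer(8, 1)), 3))
  cl <- gromosClusterWeighted(same, cutoff = 1)
  expect_warning(reps <- representativeStructures(cl, same, topK = 6),
                 "returning all")
  expect_length(reps$conformers, 1L)

  shapes <- lapply(c(101, 102, 103), function(s) randomConformer(8, s, 6))
  ens <- Ensemble(shapes, weights = c(0.5, 0.3, 0.2))
  cl3 <- gromosClusterWeighted(ens, cutoff = 0.5)
  reps3 <- representativeStructures(cl3, ens, topK = 2)
  expect_equal(reps3$summary$weight, c(0.5, 0.3))
  expect_lte(sum(reps3$summary$weight), 1)
  # centers are members of their own cluster
  expect_equal(clusterLabels(cl3)[reps3$summary$center],
               reps3$summary$cluster)
})
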