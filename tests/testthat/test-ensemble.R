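# build a ResVAEModel shell around hand-set decoder weights so the
# extraction arithmetic can be checked against brute-force path sums
toyDecoderModel <- function(Wd1, Wd2, u = 1L, clusterIds = NULL,
                            featureIds = NULL) {
  K <- nrow(Wd1) / u
  if (is.null(clusterIds)) clusterIds <- paste0("c", seq_len(K))
  if (is.null(featureIds)) featureIds <- paste0("g", seq_len(ncol(Wd2)))
  cfg <- modelConfig(epochs = 1L, latentUnitsPerCluster = as.integer(u),
                     encoderUnits = 2L, decoderUnits = nrow(Wd2))
  new("ResVAEModel", config = cfg,
      params = list(We = matrix(0, 2, 2), be = numeric(2),
                    Wmu = matrix(0, 2, 2), bmu = numeric(2),
                    Wls = matrix(0, 2, 2), bls = numeric(2),
                    Wd1 = Wd1, bd1 = numeric(ncol(Wd1)),
                    Wd2 = Wd2, bd2 = numeric(ncol(Wd2))),
      lossHistory = 0, featureIds = featureIds, clusterIds = clusterIds,
      normalization = list(method = "none"))
}

bruteForcePaths <- function(Wd1, Wd2, u, K) {
  out <- matrix(0, K, ncol(Wd2))
  for (c in seq_len(K))
    for (g in seq_len(ncol(Wd2)))
      for (i in ((c - 1) * u + 1):(c * u))
        for (h in seq_len(ncol(Wd1)))
          out[c, g] <- out[c, g] + abs(Wd1[i, h]) * abs(Wd2[h, g])
  out
}

test_that("weight mapping equals brute-force absolute path enumeration", {
  W1 <- rbind(c(1, 0), c(0, 2))      # 2 latent (u=1, 2 clusters), 2 hidden
  W2 <- rbind(c(3, 0), c(0, 4))      # 2 hidden, 2 genes
  wm <- extractWeightMapping(toyDecoderModel(W1, W2))
  expect_equal(unname(mappingScores(wm)), rbind(c(3, 0), c(0, 8)))

  set.seed(9)
  for (i in 1:10) {
    u <- sample(1:3, 1); K <- sample(2:4, 1); H <- sample(2:6, 1)
    G <- sample(2:7, 1)
    W1 <- matrix(rnorm(K * u * H), K * u, H)
    W2 <- matrix(rnorm(H * G), H, G)
    wm <- extractWeightMapping(toyDecoderModel(W1, W2, u = u))
    expect_equal(unname(mappingScores(wm)),
                 bruteForcePaths(W1, W2, u, K))
  }
})

test_that("mapping is invariant to weight sign and equivariant to feature permutation", {
  set.seed(2)
  W1 <- matrix(rnorm(8), 4, 2)
  W2 <- matrix(rnorm(10), 2, 5)
  base <- mappingScores(extractWeightMapping(toyDecoderModel(W1, W2, u = 2)))
  W1n <- W1; W1n[2, 1] <- -W1n[2, 1]
  W2n <- W2; W2n[1, 4] <- -W2n[1, 4]
  expect_equal(mappingScores(extractWeightMapping(
    toyDecoderModel(W1n, W2n, u = 2))), base)
  perm <- c(3, 1, 5, 2, 4)
  permed <- mappingScores(extractWeightMapping(toyDecoderModel(
    W1, W2[, perm], u = 2, featureIds = paste0("g", perm))))
  expect_equal(unname(permed), unname(base[, perm]))
})

test_that("extraction refuses all-zero (untrained-like) and non-finite decoders", {
  W <- matrix(0, 2, 2)
  wm <- extractWeightMapping(toyDecoderModel(W, W))
  expect_true(all(mappingScores(wm) == 0))
  # NaN parameters are already rejected by the class validity contract
  expect_error(toyDecoderModel(matrix(c(1, NA, 0, 1), 2, 2),
                               matrix(1, 2, 2)), "finite")
})

test_that("ensemble produces one deterministic mapping per model in grid order", {
  sim <- tinySim()
  ens <- ensembleConfig(tinyConfig(epochs = 4L),
                        grid = list(list(alpha = 1), list(alpha = 2)),
                        replicatesPerSetting = 2L)
  maps <- runEnsemble(sim$counts, sim$hard, ens)
  expect_length(maps, 4L)
  expect_identical(names(maps), c("g1r1", "g1r2", "g2r1", "g2r2"))
  maps2 <- runEnsemble(sim$counts, sim$hard, ens)
  expect_equal(maps, maps2)
  # identical settings with identical seeds give identical mappings
  expect_error(
    ensembleConfig(tinyConfig(epochs = 4L),
                   grid = list(list(alpha = 1), list(alpha = 1)),
                   replicatesPerSetting = 1L, seeds = c(3L, 3L)),
    "unique")
  ensSame <- ensembleConfig(tinyConfig(epochs = 4L),
                            grid = list(list(alpha = 1), list(alpha = 1)),
                            replicatesPerSetting = 1L, seeds = c(5L, 6L))
  m <- runEnsemble(sim$counts, sim$hard, ensSame)
  expect_false(identical(mappingScores(m[[1]]), mappingScores(m[[2]])))
})

test_that("ensemble requires at least two requested and surviving models", {
  sim <- tinySim()
  ens1 <- ensembleConfig(tinyConfig(), grid = list(list(alpha = 1)),
                         replicatesPerSetting = 1L)
  expect_error(runEnsemble(sim$counts, sim$hard, ens1), "at least 2")
})

test_that("true branch TFs outscore housekeeping genes in their clusters", {
  sim <- tinySim()
  ens <- ensembleConfig(tinyConfig(epochs = 20L),
                        grid = list(list(alpha = 1, beta = 1),
                                    list(alpha = 2, beta = 1)),
                        replicatesPerSetting = 2L)
  maps <- runEnsemble(sim$counts, sim$hard, ens)
  hk <- housekeepingIds(sim$truth)
  for (cl in c("sEndC", "sEndD")) {
    tfs <- trueTfs(sim$truth, cl)
    medTf <- median(vapply(maps, function(m)
      median(mappingScores(m)[cl, tfs]), numeric(1)))
    medHk <- median(vapply(maps, function(m)
      median(mappingScores(m)[cl, hk]), numeric(1)))
    expect_gt(medTf, medHk)
  }
  # (the across-model rank-dispersion contrast of true TFs versus
  # housekeeping genes needs full-size models; it is asserted in the
  # acceptance suite's end-to-end block)
})
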