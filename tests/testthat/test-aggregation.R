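test_that("rra rho reproduces closed forms", {
  r <- rraRho(0.3, m = 1)
  expect_equal(r$rho, 0.3)                      # Beta(1,1) CDF = identity
  expect_equal(r$corrected, 0.3)
  r2 <- rraRho(c(0.1, 0.2))
  expect_equal(r2$rho, 0.04)                    # min(1-(1-.1)^2, .2^2)
  expect_equal(r2$corrected, 0.08)
  rAbs <- rraRho(c(1, 1, 1))
  expect_equal(rAbs$rho, 1)
  expect_equal(rAbs$corrected, 1)
  # padding with r = 1 for missing lists
  expect_equal(rraRho(0.1, m = 3)$rho, rraRho(c(0.1, 1, 1))$rho)
  expect_error(rraRho(c(0, 0.5)), "\\(0, 1]")
  expect_error(rraRho(c(0.5, 1.2)), "\\(0, 1]")
  expect_error(rraRho(c(0.1, 0.2, 0.3), m = 2), "more ranks")
})

test_that("rra agrees with the order-statistic oracle to 1e-9", {
  set.seed(77)
  maxErr <- 0
  for (i in 1:100) {
    m <- sample(1:6, 1)
    k <- sample(1:m, 1)
    ranks <- sort(runif(k))
    got <- rraRho(ranks, m = m)$rho
    want <- rraOracle(ranks, m = m)
    maxErr <- max(maxErr, abs(got - want))
  }
  expect_lt(maxErr, 1e-9)
})

test_that("rho is monotone in each rank", {
  set.seed(5)
  for (i in 1:40) {
    m <- sample(2:6, 1)
    r <- runif(m)
    j <- sample(m, 1)
    better <- r
    better[j] <- r[j] * runif(1)
    expect_lte(rraRho(better, m)$rho, rraRho(r, m)$rho)
  }
})

test_that("cluster aggregation scores, orders and pads correctly", {
  mkList <- function(features) data.frame(feature = features,
                                          rank = seq_along(features))
  # top-ranked everywhere: Beta(m, 1) CDF = r^m dominates
  lists <- replicate(10, mkList(c("hit", paste0("f", 1:4))),
                     simplify = FALSE)
  cons <- aggregateCluster(lists, n = 100)
  tb <- consensusTable(cons)
  expect_identical(tb$feature[1], "hit")
  expect_equal(tb$rho[1], 1e-20, tolerance = 1e-6)
  expect_equal(tb$corrected[1], 1e-19, tolerance = 1e-6)
  expect_equal(tb$confidence[1], 1)

  # aggregation of identical lists preserves their order
  ids <- letters[1:8]
  same <- replicate(4, mkList(ids), simplify = FALSE)
  expect_identical(consensusTable(aggregateCluster(same, n = 8))$feature,
                   ids)

  # exactly reversed pair: mirror-rank features get identical rho
  l1 <- mkList(letters[1:6])
  l2 <- mkList(rev(letters[1:6]))
  tb2 <- consensusTable(aggregateCluster(list(l1, l2), n = 6))
  rho <- setNames(tb2$rho, tb2$feature)
  expect_equal(rho[["a"]], rho[["f"]])
  expect_equal(rho[["b"]], rho[["e"]])

  # truncation: below-cutoff items are treated as absent (r = 1)
  l3 <- mkList(c("x", "y", "z"))
  tb3 <- consensusTable(aggregateCluster(list(l3, l3), n = 10, cutoff = 1L))
  rho3 <- setNames(tb3$rho, tb3$feature)
  expect_equal(rho3[["y"]], 1)
  expect_equal(rho3[["x"]], rraRho(c(0.1, 0.1))$rho)

  expect_error(aggregateCluster(list(l1), n = 6), "at least 2")
  expect_error(aggregateCluster(list(l1, l2), n = 3), "universe")
})

test_that("corrected scores are conservative under the uniform null", {
  # scaled-down Monte-Carlo of the Bonferroni bound (the acceptance
  # suite runs the full 2000-replicate version)
  set.seed(123)
  m <- 5; n <- 50; reps <- 400
  hits <- 0
  for (i in seq_len(reps)) {
    ranks <- vapply(seq_len(m), function(j) which(sample.int(n) == 1L),
                    integer(1))
    if (rraRho(ranks / n, m)$corrected <= 0.05) hits <- hits + 1
  }
  expect_lte(hits / reps, 0.08)
})

test_that("feature confidence counts models above the cut-off", {
  lists <- list(data.frame(feature = c("a", "b"), rank = 1:2),
                data.frame(feature = c("b", "a"), rank = 1:2))
  expect_equal(featureConfidence("a", lists, cutoff = 2), 1)
  expect_equal(featureConfidence("a", lists, cutoff = 1), 0.5)
  expect_equal(featureConfidence("zz", lists, cutoff = 2), 0)
})

test_that("maic aggregation is monotone, category-additive and guarded", {
  s1 <- maicAggregate(list(letters[1:5]))
  expect_identical(names(s1)[1], "a")
  expect_true(all(diff(s1[letters[1:5]]) < 0))
  oneCat <- maicAggregate(list(letters[1:4], letters[1:4]),
                          categories = c("x", "x"))
  twoCat <- maicAggregate(list(letters[1:4], letters[1:4]),
                          categories = c("x", "y"))
  expect_true(all(twoCat[letters[1:4]] >= oneCat[letters[1:4]]))
  # unranked lists contribute flat weights
  flat <- maicAggregate(list(letters[1:4]), ranked = FALSE)
  expect_true(length(unique(round(flat, 10))) == 1L)
  expect_error(maicAggregate(list()), "empty")
  expect_error(maicAggregate(list(character(0))), "empty")
})

test_that("consensus of an ensemble is deterministic and structured", {
  sim <- tinySim()
  ens <- ensembleConfig(tinyConfig(epochs = 6L),
                        grid = list(list(alpha = 1), list(alpha = 2)),
                        replicatesPerSetting = 1L)
  maps <- runEnsemble(sim$counts, sim$hard, ens)
  cons <- resvaeConsensus(maps)
  expect_identical(names(cons), clusterIds(maps[[1]]))
  for (cl in names(cons)) {
    tb <- consensusTable(cons[[cl]])
    expect_false(is.unsorted(tb$rho))
    expect_true(all(tb$corrected >= tb$rho))
    expect_true(all(tb$confidence >= 0 & tb$confidence <= 1))
    expect_equal(tb$score, -log10(tb$corrected))
  }
  cons2 <- resvaeConsensus(runEnsemble(sim$counts, sim$hard, ens))
  expect_equal(consensusTable(cons[[1]]), consensusTable(cons2[[1]]))
})
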