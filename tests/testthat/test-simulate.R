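test_that("bifurcation generator matches the declared design counts", {
  sim <- tinySim()
  ft <- sim$truth$featureType
  expect_equal(sum(ft == "tf"), 35L)
  expect_equal(sum(ft == "target"), 500L)
  expect_equal(sum(ft == "housekeeping"), 20L)
  expect_equal(ncol(sim$counts), 555L)
  expect_equal(ncol(clusterWeights(sim$hard)), 7L)
  expect_setequal(clusterIds(sim$hard),
                  c("sA", "sB", "sBmid", "sC", "sD", "sEndC", "sEndD"))
  expect_equal(nrow(sim$counts), 7L * 40L)
  expect_equal(sum(resvae:::bifurcationModules()), 35L)
})

test_that("ground truth wiring respects the regulatory constraints", {
  sim <- tinySim()
  hk <- housekeepingIds(sim$truth)
  expect_length(hk, 20L)
  expect_false(any(sim$truth$edges$target %in% hk))
  expect_false(any(sim$truth$edges$tf %in% hk))
  # every edge source is a TF, every edge target a target gene
  expect_true(all(sim$truth$featureType[sim$truth$edges$tf] == "tf"))
  expect_true(all(sim$truth$featureType[sim$truth$edges$target] == "target"))
  # branch-exclusive modules are never co-active in terminal populations
  act <- sim$truth$activeModules
  branchOf <- sim$truth$branchOf
  expect_false(any(branchOf[act$sEndC] == "D"))
  expect_false(any(branchOf[act$sEndD] == "C"))
  # sA initialisation uses exactly the burn-in plus B4/B5 modules
  expect_setequal(act$sA, c("Burn1", "Burn2", "Burn3", "Burn4", "B4", "B5"))
})

test_that("branch antagonism zeroes foreign module activity in terminal cells", {
  # a cell deep on the C branch receives no activity from D-branch modules
  A <- resvae:::moduleActivities(t = c(4.5, 4.5), branch = c("C", "D"))
  dMods <- names(which(tinySim()$truth$branchOf == "D"))
  cMods <- names(which(tinySim()$truth$branchOf == "C"))
  expect_true(all(A[1, dMods] == 0))
  expect_true(all(A[2, cMods] == 0))
  expect_gt(sum(A[1, cMods]), 0)
})

test_that("counts are non-negative integers with super-Poisson dispersion", {
  sim <- tinySim()
  expect_true(all(sim$counts >= 0))
  expect_true(all(sim$counts == round(sim$counts)))
  v <- apply(sim$counts, 2, var)
  m <- colMeans(sim$counts)
  keep <- m > 1
  expect_gt(mean(v[keep] - m[keep]), 0)
  expect_gt(mean(v[keep] / m[keep]), 1.5)
})

test_that("soft assignments are proper and agree with hard labels off-boundary", {
  sim <- tinySim()
  w <- clusterWeights(sim$soft)
  expect_equal(unname(rowSums(w)), rep(1, nrow(w)), tolerance = 1e-12)
  expect_true(all(w >= 0 & w <= 1))
  hardLab <- clusterIds(sim$hard)[max.col(clusterWeights(sim$hard))]
  softLab <- colnames(w)[max.col(w)]
  centers <- resvae:::populationCenters()
  offBoundary <- abs(sim$pseudotime - centers[hardLab]) < 0.25
  agree <- mean(hardLab[offBoundary] == softLab[offBoundary])
  expect_gte(agree, 0.95)
})

test_that("generator is reproducible and validates its config", {
  s1 <- simulateBifurcation(simulationConfig(nCellsPerPopulation = 10L,
                                             seed = 9L))
  s2 <- simulateBifurcation(simulationConfig(nCellsPerPopulation = 10L,
                                             seed = 9L))
  expect_identical(s1$counts, s2$counts)
  expect_error(simulationConfig(nCellsPerPopulation = 0L), "positive")
  expect_error(simulationConfig(nTargets = -5L), "positive")
  expect_error(simulationConfig(dispersion = 0), "dispersion")
})

test_that("myeloid model encodes the fate-regulator ground truth", {
  sim <- simulateMyeloid(simulationConfig(nCellsPerPopulation = 40L,
                                          seed = 2L))
  regs <- names(sim$truth$featureType)[sim$truth$featureType == "tf"]
  expect_length(regs, 11L)
  expect_setequal(regs, c("EKLF", "Fli-1", "GATA-1", "GATA-2", "PU.1",
                          "cJun", "EgrNab", "C/EBPa", "Gfi-1", "SCL",
                          "FOG-1"))
  pops <- clusterIds(sim$assignment)
  expect_length(pops, 5L)
  expect_setequal(pops, c("Prog", "Ery", "Mk", "Granu", "Mono"))
  assoc <- sim$truth$activeModules
  expect_true("EKLF" %in% assoc$Ery)
  expect_true("Fli-1" %in% assoc$Mk)
  expect_true(all(c("Ery", "Mk") %in%
                    names(Filter(function(a) "GATA-1" %in% a, assoc))))
  expect_setequal(assoc$Mono, c("PU.1", "cJun", "EgrNab", "C/EBPa"))
  expect_true("Gfi-1" %in% assoc$Granu)
  # expression backs the table: Ery mean of EKLF far above its Gfi-1 mean
  lab <- clusterIds(sim$assignment)[max.col(clusterWeights(sim$assignment))]
  ery <- lab == "Ery"
  expect_gt(mean(sim$counts[ery, "EKLF"]), mean(sim$counts[ery, "Gfi-1"]))
  expect_error(simulateMyeloid(simulationConfig(nCellsPerPopulation = 5L)),
               "at least 10")
})

test_that("cluster splitting halves every cluster reproducibly", {
  labels <- rep(paste0("cl", 1:15), each = 4)
  a <- hardAssignment(labels)
  sp <- splitClusterPartitions(a, seed = 4L)
  expect_length(clusterIds(sp), 30L)
  expect_true(all(table(clusterIds(sp)[max.col(clusterWeights(sp))]) == 2))

  odd <- hardAssignment(rep("x", 11))
  spOdd <- splitClusterPartitions(odd, seed = 1L)
  sizes <- table(clusterIds(spOdd)[max.col(clusterWeights(spOdd))])
  expect_setequal(as.integer(sizes), c(6L, 5L))

  expect_identical(clusterWeights(splitClusterPartitions(a, seed = 4L)),
                   clusterWeights(sp))
  expect_error(splitClusterPartitions(hardAssignment(c("a", "b", "b")), 1L),
               "< 2 cells")
  soft <- clusterAssignment(matrix(0.5, 2, 2,
                                   dimnames = list(NULL, c("a", "b"))))
  expect_error(splitClusterPartitions(soft, 1L), "hard")
})
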