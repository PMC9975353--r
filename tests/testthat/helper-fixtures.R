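# shared small fixtures, built once per test run and cached

.fixtures <- new.env(parent = emptyenv())

tinySim <- function() {
  if (is.null(.fixtures$sim))
    .fixtures$sim <- simulateBifurcation(
      simulationConfig(nCellsPerPopulation = 40L, seed = 5L))
  .fixtures$sim
}

tinyConfig <- function(...) {
  args <- utils::modifyList(
    list(encoderUnits = 32L, decoderUnits = 32L,
         latentUnitsPerCluster = 2L, epochs = 15L, batchSize = 64L,
         seed = 3L),
    list(...))
  do.call(modelConfig, args)
}

tinyModel <- function() {
  if (is.null(.fixtures$model)) {
    sim <- tinySim()
    .fixtures$model <- trainResVAE(sim$counts, sim$hard, tinyConfig())
  }
  .fixtures$model
}

# ground-truth TFs of a population's active modules
trueTfs <- function(truth, cluster) {
  mods <- truth$activeModules[[cluster]]
  names(truth$moduleOf)[truth$moduleOf %in% mods]
}

housekeepingIds <- function(truth)
  names(truth$featureType)[truth$featureType == "housekeeping"]

# independent geometric oracle for the bin-and-rotate cut-off: normalize
# the bin, rotate all its points by -theta with an explicit rotation
# matrix, return rotated y
rotateBinOracle <- function(yBin, from, to) {
  b <- length(yBin)
  x <- (seq_len(b) - 1) / (b - 1)
  rng <- range(yBin)
  yn <- if (diff(rng) > 0) (yBin - rng[1]) / diff(rng) else rep(0, b)
  theta <- atan2(yn[to] - yn[from], x[to] - x[from])
  R <- matrix(c(cos(-theta), sin(-theta), -sin(-theta), cos(-theta)), 2, 2)
  (R %*% rbind(x, yn))[2, ]
}

# independent oracle for the CDF of the k-th order statistic of m
# uniforms, via the binomial-sum identity (no pbeta)
orderStatCdfOracle <- function(x, k, m) {
  j <- k:m
  sum(choose(m, j) * x^j * (1 - x)^(m - j))
}

rraOracle <- function(ranks, m) {
  r <- sort(c(ranks, rep(1, m - length(ranks))))
  min(vapply(seq_len(m), function(k) orderStatCdfOracle(r[k], k, m),
             numeric(1)))
}
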