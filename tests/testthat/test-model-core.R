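test_that("mish matches its closed form and asymptotics", {
  expect_identical(mish(0), 0)
  expect_equal(mish(1), 0.8650984, tolerance = 1e-6)
  v <- mish(-40)
  expect_true(v > -1e-10 && v < 0)
  # numerically stable far into both tails
  expect_true(all(is.finite(mish(c(-50, -30, 30, 50)))))
  expect_equal(mish(50), 50, tolerance = 1e-12)
  expect_error(mish(Inf), "non-finite")
  expect_error(mish(NaN), "non-finite")
})

test_that("mish is monotone for x >= 0 and bounded below near -0.31", {
  grid <- seq(-20, 20, by = 0.01)
  vals <- mish(grid)
  pos <- vals[grid >= 0]
  expect_true(all(diff(pos) > 0))
  expect_gt(min(vals), -0.31)
})

test_that("label smoothing mixes one-hot rows towards uniform", {
  a <- hardAssignment(c("a", "b"))
  expect_equal(clusterWeights(smoothLabels(a, 0))[1, ], c(a = 1, b = 0))
  sm <- clusterWeights(smoothLabels(a, 0.1))
  expect_equal(sm[1, ], c(a = 0.95, b = 0.05))
  expect_equal(unname(rowSums(sm)), c(1, 1))
  # a uniform soft row is a fixed point: soft assignments pass through
  w <- matrix(0.5, 2, 2, dimnames = list(NULL, c("a", "b")))
  soft <- clusterAssignment(w)
  expect_equal(clusterWeights(smoothLabels(soft, 0.3)), w)
  expect_error(smoothLabels(a, 1), "eps")
  expect_error(smoothLabels(a, -0.1), "eps")
})

test_that("latent restriction gates per-cluster blocks", {
  expect_equal(restrictLatent(rep(1, 4), c(1, 0), 2), c(1, 1, 0, 0))
  expect_equal(restrictLatent(rep(1, 4), c(0.5, 0.5), 2), rep(0.5, 4))
  z <- rnorm(6)
  expect_equal(restrictLatent(z, c(1, 1, 1), 2), z)
  expect_error(restrictLatent(rep(1, 4), c(1, 0, 0), 2), "length")
  # matrix form gates row-wise
  zm <- matrix(1, 2, 4)
  am <- rbind(c(1, 0), c(0, 1))
  expect_equal(restrictLatent(zm, am, 2),
               rbind(c(1, 1, 0, 0), c(0, 0, 1, 1)))
})

test_that("vae loss reproduces hand-computed values and identities", {
  expect_equal(vaeLoss(c(1), c(1), c(0), c(0), s = 0), 0)
  expect_equal(vaeLoss(c(1), c(0), c(0), c(0), s = 0, alpha = 2, beta = 1), 2)
  # linearity in alpha with beta = 0
  l1 <- vaeLoss(1:3, c(0, 0, 0), c(0.2), c(0.1), alpha = 1, beta = 0)
  l2 <- vaeLoss(1:3, c(0, 0, 0), c(0.2), c(0.1), alpha = 2, beta = 0)
  expect_equal(l2, 2 * l1)
  expect_error(vaeLoss(c(NaN), c(0), c(0), c(0)), "NaN|non-finite")
})

test_that("alpha = beta = 1 equals an independent reference VAE objective", {
  set.seed(42)
  for (i in 1:20) {
    n <- sample(2:8, 1)
    x <- rnorm(n); xr <- rnorm(n)
    mu <- rnorm(3); ls <- rnorm(3, sd = 0.5); s <- rnorm(1)
    ref <- sum((x - xr)^2) +
      sum(exp(ls) + (s - mu)^2 - 1 - ls) / 2   # term-by-term reference
    expect_equal(vaeLoss(x, xr, mu, ls, s = s, alpha = 1, beta = 1), ref)
    expect_gte(vaeLoss(x, x, mu, ls, s = s), 0)
  }
})

test_that("kernel init pairing follows the activation", {
  set.seed(1)
  he <- replicate(30, max(abs(resvae:::initKernel(10, 100, "relu"))))
  gl <- replicate(30, max(abs(resvae:::initKernel(10, 100, "mish"))))
  heLimit <- sqrt(6 / 10)           # He uniform: fan-in only
  glLimit <- sqrt(6 / 110)          # Glorot uniform: fan-in + fan-out
  expect_true(all(he <= heLimit) && any(he > glLimit))
  expect_true(all(gl <= glLimit))
})

test_that("training is reproducible and reduces the loss", {
  sim <- tinySim()
  m1 <- tinyModel()
  m2 <- trainResVAE(sim$counts, sim$hard, tinyConfig())
  expect_identical(m1@params, m2@params)
  expect_identical(lossHistory(m1), lossHistory(m2))
  lh <- lossHistory(m1)
  expect_lt(tail(lh, 1), lh[1])
  nTail <- ceiling(length(lh) / 10)
  expect_lte(mean(tail(lh, nTail)), mean(head(lh, nTail)))
  expect_true(all(vapply(m1@params, function(p) all(is.finite(p)),
                         logical(1))))
})

test_that("training accepts soft assignments", {
  sim <- tinySim()
  fit <- trainResVAE(sim$counts, sim$soft, tinyConfig(epochs = 3L))
  expect_s4_class(fit, "ResVAEModel")
  expect_equal(length(lossHistory(fit)), 3L)
})

test_that("training rejects degenerate inputs", {
  sim <- tinySim()
  cfg <- tinyConfig()
  expect_error(trainResVAE(sim$counts[0, , drop = FALSE],
                           sim$hard, cfg), "empty|cell count")
  zero <- sim$counts * 0
  expect_error(trainResVAE(zero, sim$hard, cfg), "zero")
  expect_error(trainResVAE(sim$counts[1:10, ], sim$hard, cfg),
               "cell count")
  expect_error(tinyConfig(epochs = 0L), "epochs")
  neg <- sim$counts; neg[1, 1] <- -1
  expect_error(trainResVAE(neg, sim$hard, cfg), "negative")
})

test_that("an all-zero assignment row decodes like the zero latent vector", {
  fit <- tinyModel()
  L <- length(clusterIds(fit)) * modelConfigOf(fit)@latentUnitsPerCluster
  z <- rnorm(L)
  gated <- restrictLatent(z, rep(0, length(clusterIds(fit))), 2)
  expect_equal(decodeLatent(fit, gated), decodeLatent(fit, rep(0, L)))
})

test_that("latent means have the restricted block structure", {
  sim <- tinySim()
  fit <- tinyModel()
  mu <- latentMeans(fit, sim$counts, sim$hard)
  expect_equal(dim(mu), c(nrow(sim$counts), 7 * 2))
  # with eps = 0.1 smoothing, a cell's own block carries most mass
  w <- clusterWeights(sim$hard)
  cell <- 1L
  own <- which(w[cell, ] == 1)
  blocks <- matrix(abs(mu[cell, ]), nrow = 2)
  expect_equal(unname(which.max(colSums(blocks))), unname(own))
})
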