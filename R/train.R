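#' Train a restricted-latent VAE
#'
#' Fits a single resVAE model: a dense encoder maps each cell's (optionally
#' library-size-normalized, log1p-transformed) expression profile to the
#' mean and log-variance of a Gaussian latent posterior whose units are
#' partitioned into contiguous per-cluster blocks; the sampled latent
#' vector is gated by the cell's (label-smoothed) cluster assignment row
#' (see \code{\link{restrictLatent}}) before a dense decoder reconstructs
#' the profile. The objective is \code{\link{vaeLoss}} averaged over
#' minibatches, minimized with Rectified Adam wrapped in Lookahead
#' (sync period 6, slow-weights step 0.5). All randomness (weight init,
#' shuffling, latent sampling) derives from \code{config@seed}, so a run
#' is bit-for-bit reproducible on one machine.
#'
#' @param counts cells x features non-negative matrix with feature ids as
#'   colnames, or a \code{SummarizedExperiment} (features x cells; the
#'   first assay is used and transposed).
#' @param assignment a \linkS4class{ClusterAssignment} row-aligned with
#'   the cells.
#' @param config a \linkS4class{ModelConfig}.
#' @return A \linkS4class{ResVAEModel}.
#' @seealso \code{\link{extractWeightMapping}}, \code{\link{runEnsemble}}
#' @examples
#' sim <- simulateBifurcation(simulationConfig(nCellsPerPopulation = 30))
#' cfg <- modelConfig(epochs = 2, encoderUnits = 16L, decoderUnits = 16L,
#'                    latentUnitsPerCluster = 2L, seed = 1L)
#' fit <- trainResVAE(sim$counts, sim$hard, cfg)
#' @export
trainResVAE <- function(counts, assignment, config) {
  stopifnot(is(assignment, "ClusterAssignment"), is(config, "ModelConfig"))
  X <- asCellByFeature(counts)
  if (nrow(X) == 0L || ncol(X) == 0L) stop("trainResVAE: empty matrix")
  if (any(X < 0)) stop("trainResVAE: negative expression values")
  if (all(colSums(X) == 0)) stop("trainResVAE: all feature columns are zero")
  if (nrow(X) != nrow(assignment@weights))
    stop("trainResVAE: cell count differs between matrix and assignment")

  pre <- applyNormalization(X, config@normalize)
  X <- pre$X
  norm <- pre$norm
  if (config@centerFeatures) {
    norm$featureMeans <- colMeans(X)
    X <- sweep(X, 2, norm$featureMeans)
  }

  A <- clusterWeights(smoothLabels(assignment, config@labelSmoothingEps))
  K <- ncol(A)
  u <- config@latentUnitsPerCluster
  L <- K * u
  G <- ncol(X)
  E <- config@encoderUnits
  D <- config@decoderUnits
  n <- nrow(X)
  act <- activationFun(config@activation)
  actg <- activationGrad(config@activation)

  set.seed(config@seed)
  params <- list(
    We  = initKernel(G, E, config@activation), be  = numeric(E),
    Wmu = initKernel(E, L, config@activation), bmu = numeric(L),
    Wls = initKernel(E, L, config@activation) * 0.01, bls = numeric(L),
    Wd1 = initKernel(L, D, config@activation), bd1 = numeric(D),
    Wd2 = initKernel(D, G, config@activation), bd2 = numeric(G))

  opt <- radamLookaheadInit(params, lr = config@learningRate,
                            maxGradNorm = config@maxGradNorm,
                            weightDecay = config@weightDecay)
  maskCols <- rep(seq_len(K), each = u)
  s <- config@latentOffset
  alpha <- config@alpha
  beta <- config@beta
  lossHist <- numeric(config@epochs)
  # stochastic tail averaging: accumulate end-of-epoch parameters over the
  # final tailAverage fraction of epochs
  tailFrom <- config@epochs - ceiling(config@tailAverage * config@epochs)
  if (config@tailAverage == 0) tailFrom <- config@epochs + 1L
  tailSum <- lapply(params, `*`, 0)
  tailN <- 0L

  for (epoch in seq_len(config@epochs)) {
    # linear learning-rate anneal to 10% of the base rate: late-training
    # gradient noise otherwise keeps unsupported weights at an
    # lr-proportional random-walk equilibrium that pollutes the mappings
    if (config@annealLearningRate)
      opt$lr <- config@learningRate *
        (1 - 0.9 * (epoch - 1) / max(1L, config@epochs - 1L))
    perm <- sample.int(n)
    starts <- seq(1L, n, by = config@batchSize)
    epochLoss <- 0
    for (st in starts) {
      idx <- perm[st:min(st + config@batchSize - 1L, n)]
      B <- length(idx)
      xb <- X[idx, , drop = FALSE]
      ab <- A[idx, , drop = FALSE]
      mask <- ab[, maskCols, drop = FALSE]

      # forward
      pre1 <- sweep(xb %*% params$We, 2, params$be, "+")
      h1 <- act(pre1)
      mu <- sweep(h1 %*% params$Wmu, 2, params$bmu, "+")
      lv <- sweep(h1 %*% params$Wls, 2, params$bls, "+")
      lv <- pmin(pmax(lv, -8), 8)            # keep exp(lv) in range
      epsz <- matrix(rnorm(B * L), B, L)
      sd <- exp(lv / 2)
      z <- mu + sd * epsz
      zm <- z * mask
      pre2 <- sweep(zm %*% params$Wd1, 2, params$bd1, "+")
      h2 <- act(pre2)
      xrec <- sweep(h2 %*% params$Wd2, 2, params$bd2, "+")

      diff <- xrec - xb
      rec <- rowSums(diff * diff)
      kl <- 0.5 * rowSums(exp(lv) + (s - mu)^2 - 1 - lv)
      loss <- mean(alpha * rec + beta * kl)
      epochLoss <- epochLoss + loss * B

      # backward (objective = batch mean)
      dxrec <- (2 * alpha / B) * diff
      g <- list()
      g$Wd2 <- crossprod(h2, dxrec)
      g$bd2 <- colSums(dxrec)
      dh2 <- tcrossprod(dxrec, params$Wd2) * actg(pre2)
      g$Wd1 <- crossprod(zm, dh2)
      g$bd1 <- colSums(dh2)
      dzm <- tcrossprod(dh2, params$Wd1)
      dz <- dzm * mask
      dmu <- dz + (beta / B) * (mu - s)
      dlv <- dz * (0.5 * sd * epsz) + (beta / B) * 0.5 * (exp(lv) - 1)
      g$Wmu <- crossprod(h1, dmu)
      g$bmu <- colSums(dmu)
      g$Wls <- crossprod(h1, dlv)
      g$bls <- colSums(dlv)
      dh1 <- (tcrossprod(dmu, params$Wmu) + tcrossprod(dlv, params$Wls)) *
        actg(pre1)
      g$We <- crossprod(xb, dh1)
      g$be <- colSums(dh1)

      upd <- radamLookaheadStep(opt, params, g)
      opt <- upd$opt
      params <- upd$params
    }
    lossHist[epoch] <- epochLoss / n
    if (epoch > tailFrom) {
      tailSum <- Map(`+`, tailSum, params)
      tailN <- tailN + 1L
    }
  }
  if (tailN > 0L) params <- lapply(tailSum, `/`, tailN)

  new("ResVAEModel", config = config, params = params,
      lossHistory = lossHist, featureIds = colnames(X),
      clusterIds = colnames(A), normalization = norm)
}

# ---- optimizer: RAdam wrapped in Lookahead ------------------------------

radamLookaheadInit <- function(params, lr, beta1 = 0.9, beta2 = 0.999,
                               eps = 1e-8, syncPeriod = 6L, slowStep = 0.5,
                               maxGradNorm = Inf, weightDecay = 0) {
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0L,
       syncPeriod = as.integer(syncPeriod), slowStep = slowStep,
       maxGradNorm = maxGradNorm, weightDecay = weightDecay,
       m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       slow = params)
}

radamLookaheadStep <- function(opt, params, grads) {
  if (is.finite(opt$maxGradNorm)) {
    gnorm <- sqrt(sum(vapply(grads, function(g) sum(g * g), numeric(1))))
    if (gnorm > opt$maxGradNorm)
      grads <- lapply(grads, function(g) g * (opt$maxGradNorm / gnorm))
  }
  opt$t <- opt$t + 1L
  t <- opt$t
  b1 <- opt$beta1; b2 <- opt$beta2
  rhoInf <- 2 / (1 - b2) - 1
  b2t <- b2^t
  rhoT <- rhoInf - 2 * t * b2t / (1 - b2t)
  useRect <- rhoT > 4
  if (useRect)
    rT <- sqrt(((rhoT - 4) * (rhoT - 2) * rhoInf) /
               ((rhoInf - 4) * (rhoInf - 2) * rhoT))
  for (nm in names(params)) {
    # decoupled weight decay on the weight matrices (not the biases)
    if (opt$weightDecay > 0 && startsWith(nm, "W"))
      params[[nm]] <- params[[nm]] * (1 - opt$lr * opt$weightDecay)
    gpar <- grads[[nm]]
    opt$m[[nm]] <- b1 * opt$m[[nm]] + (1 - b1) * gpar
    opt$v[[nm]] <- b2 * opt$v[[nm]] + (1 - b2) * gpar * gpar
    mhat <- opt$m[[nm]] / (1 - b1^t)
    if (useRect) {
      vhat <- sqrt(opt$v[[nm]] / (1 - b2t))
      params[[nm]] <- params[[nm]] - opt$lr * rT * mhat / (vhat + opt$eps)
    } else {
      params[[nm]] <- params[[nm]] - opt$lr * mhat
    }
  }
  if (opt$t %% opt$syncPeriod == 0L) {
    for (nm in names(params)) {
      opt$slow[[nm]] <- opt$slow[[nm]] +
        opt$slowStep * (params[[nm]] - opt$slow[[nm]])
      params[[nm]] <- opt$slow[[nm]]
    }
  }
  list(opt = opt, params = params)
}

# ---- shared input coercion ----------------------------------------------

applyNormalization <- function(X, mode) {
  if (mode == "log1p") {
    list(X = log1p(X), norm = list(method = "log1p"))
  } else if (mode == "library") {
    tot <- rowSums(X)
    med <- stats::median(tot[tot > 0])
    sf <- tot / med
    sf[sf <= 0] <- 1
    list(X = log1p(X / sf),
         norm = list(method = "library", medianTotal = med))
  } else {
    list(X = X, norm = list(method = "none"))
  }
}

# accept cells x features matrix, Matrix, or SummarizedExperiment
# (features x cells, transposed here)
asCellByFeature <- function(counts) {
  if (is(counts, "SummarizedExperiment")) {
    X <- t(as.matrix(SummarizedExperiment::assay(counts, 1L)))
  } else if (is(counts, "Matrix")) {
    X <- as.matrix(counts)
  } else {
    X <- as.matrix(counts)
  }
  storage.mode(X) <- "double"
  if (is.null(colnames(X)))
    colnames(X) <- paste0("feature", seq_len(ncol(X)))
  if (anyDuplicated(colnames(X))) stop("duplicate feature ids")
  X
}

#' Restricted latent means for each cell
#'
#' Encodes cells with a trained model and gates the posterior means by the
#' assignment (the default embedding used by \code{\link{clusteringMetrics}}
#' and \code{\link{optimalKScan}}).
#'
#' @param model a \linkS4class{ResVAEModel}.
#' @param counts the expression input used for training (same features).
#' @param assignment the \linkS4class{ClusterAssignment}; omit for
#'   unrestricted means.
#' @return cells x latent matrix of (gated) posterior means.
#' @export
latentMeans <- function(model, counts, assignment = NULL) {
  X <- asCellByFeature(counts)
  if (!identical(colnames(X), model@featureIds))
    stop("latentMeans: feature ids differ from the training features")
  mode <- model@normalization$method
  if (mode == "library") {
    tot <- rowSums(X)
    sf <- tot / model@normalization$medianTotal
    sf[sf <= 0] <- 1
    X <- log1p(X / sf)
  } else if (mode == "log1p") {
    X <- log1p(X)
  }
  if (!is.null(model@normalization$featureMeans))
    X <- sweep(X, 2, model@normalization$featureMeans)
  act <- activationFun(model@config@activation)
  h1 <- act(sweep(X %*% model@params$We, 2, model@params$be, "+"))
  mu <- sweep(h1 %*% model@params$Wmu, 2, model@params$bmu, "+")
  if (!is.null(assignment)) {
    A <- clusterWeights(smoothLabels(assignment,
                                     model@config@labelSmoothingEps))
    mu <- restrictLatent(mu, A, model@config@latentUnitsPerCluster)
  }
  mu
}

#' Decode a latent matrix with a trained model
#'
#' @param model a \linkS4class{ResVAEModel}.
#' @param z cells x latent matrix (already gated if desired).
#' @return cells x features reconstruction on the model's working scale.
#' @export
decodeLatent <- function(model, z) {
  z <- if (is.matrix(z)) z else matrix(z, nrow = 1)
  act <- activationFun(model@config@activation)
  h2 <- act(sweep(z %*% model@params$Wd1, 2, model@params$bd1, "+"))
  sweep(h2 %*% model@params$Wd2, 2, model@params$bd2, "+")
}
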