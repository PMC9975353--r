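#' Extract the per-cluster decoder weight mapping
#'
#' Reads cluster-to-feature relevance from a trained decoder as absolute
#' linear path weights: score(c, g) sums |W1[i, h]| * |W2[h, g]| over every
#' latent unit i in cluster c's block and every hidden unit h. With deeper
#' decoders the absolute matrices are chained. Nonlinearities and bias
#' terms are ignored (biases are feature-global, not cluster-specific), so
#' the score is a reproducible, architecture-agnostic linear-path
#' surrogate of how strongly a cluster's latent block drives each feature.
#'
#' @param model a \linkS4class{ResVAEModel}.
#' @param modelId identifier stored with the mapping.
#' @return A \linkS4class{WeightMapping} (clusters x features).
#' @examples
#' sim <- simulateBifurcation(simulationConfig(nCellsPerPopulation = 30))
#' cfg <- modelConfig(epochs = 2, encoderUnits = 8L, decoderUnits = 8L,
#'                    latentUnitsPerCluster = 2L, seed = 1L)
#' wm <- extractWeightMapping(trainResVAE(sim$counts, sim$hard, cfg))
#' @export
extractWeightMapping <- function(model, modelId = "model") {
  stopifnot(is(model, "ResVAEModel"))
  W1 <- model@params$Wd1
  W2 <- model@params$Wd2
  if (any(!is.finite(W1)) || any(!is.finite(W2)))
    stop("extractWeightMapping: non-finite decoder parameters")
  paths <- abs(W1) %*% abs(W2)                      # latent x features
  u <- model@config@latentUnitsPerCluster
  K <- length(model@clusterIds)
  grp <- rep(seq_len(K), each = u)
  scores <- rowsum(paths, grp, reorder = TRUE)
  dimnames(scores) <- list(model@clusterIds, model@featureIds)
  new("WeightMapping", scores = scores, modelId = as.character(modelId))
}

#' Ensemble configuration
#'
#' Defines the hyperparameter grid of a resVAE ensemble. Each grid entry
#' is a list of \code{\link{modelConfig}} argument overrides applied to
#' the base configuration; each setting is trained
#' \code{replicatesPerSetting} times with distinct seeds. The default grid
#' crosses alpha in {1, 2} and beta in {1, 2} with the mish activation and
#' 4 replicates (16 models).
#'
#' @param base a \linkS4class{ModelConfig} giving defaults.
#' @param grid list of named override lists (e.g.
#'   \code{list(list(alpha = 2, beta = 1))}).
#' @param replicatesPerSetting models trained per grid entry.
#' @param seeds optional integer vector of unique seeds, length
#'   \code{length(grid) * replicatesPerSetting} (derived from
#'   \code{base@seed} when NULL).
#' @return A list with class \code{"EnsembleConfig"}.
#' @export
ensembleConfig <- function(base = modelConfig(),
                           grid = defaultGrid(),
                           replicatesPerSetting = 4L,
                           seeds = NULL) {
  replicatesPerSetting <- as.integer(replicatesPerSetting)
  stopifnot(length(grid) >= 1L, replicatesPerSetting >= 1L)
  nModels <- length(grid) * replicatesPerSetting
  if (is.null(seeds)) seeds <- base@seed + seq_len(nModels) - 1L
  seeds <- as.integer(seeds)
  if (length(seeds) != nModels) stop("need one seed per model")
  if (anyDuplicated(seeds)) stop("seeds must be unique")
  structure(list(base = base, grid = grid,
                 replicatesPerSetting = replicatesPerSetting,
                 seeds = seeds),
            class = "EnsembleConfig")
}

#' @rdname ensembleConfig
#' @export
defaultGrid <- function() {
  list(list(alpha = 1, beta = 1, activation = "mish"),
       list(alpha = 1, beta = 2, activation = "mish"),
       list(alpha = 2, beta = 1, activation = "mish"),
       list(alpha = 2, beta = 2, activation = "mish"))
}

# rebuild a ModelConfig with a named override list applied
applyOverrides <- function(base, overrides, seed) {
  args <- lapply(setNames(nm = slotNames("ModelConfig")),
                 function(s) slot(base, s))
  args$seed <- seed
  args <- modifyList(args, overrides)
  do.call(modelConfig, args)
}

#' Train a resVAE ensemble and extract all weight mappings
#'
#' Trains one model per (grid setting, replicate) pair — grid-major,
#' replicate-minor order, each with its own seed — and returns the decoder
#' weight mapping of every model. A model whose training fails is logged
#' and skipped; at least two surviving models are required.
#'
#' @param counts cells x features matrix or SummarizedExperiment.
#' @param assignment a \linkS4class{ClusterAssignment}.
#' @param ens an \code{\link{ensembleConfig}}.
#' @param verbose print per-model progress.
#' @return List of \linkS4class{WeightMapping}, named by model id
#'   \code{"g<setting>r<replicate>"}.
#' @examples
#' sim <- simulateBifurcation(simulationConfig(nCellsPerPopulation = 30))
#' ens <- ensembleConfig(modelConfig(epochs = 2, encoderUnits = 8L,
#'                                   decoderUnits = 8L,
#'                                   latentUnitsPerCluster = 2L),
#'                       grid = defaultGrid()[1:2],
#'                       replicatesPerSetting = 1L)
#' maps <- runEnsemble(sim$counts, sim$hard, ens)
#' @export
runEnsemble <- function(counts, assignment, ens, verbose = FALSE) {
  stopifnot(inherits(ens, "EnsembleConfig"))
  nModels <- length(ens$grid) * ens$replicatesPerSetting
  if (nModels < 2L) stop("runEnsemble: at least 2 models are required")
  mappings <- list()
  i <- 0L
  for (gi in seq_along(ens$grid)) {
    for (ri in seq_len(ens$replicatesPerSetting)) {
      i <- i + 1L
      id <- sprintf("g%dr%d", gi, ri)
      cfg <- applyOverrides(ens$base, ens$grid[[gi]], ens$seeds[i])
      fit <- tryCatch(trainResVAE(counts, assignment, cfg),
                      error = function(e) {
                        warning(sprintf("model %s failed: %s", id,
                                        conditionMessage(e)), call. = FALSE)
                        NULL
                      })
      if (is.null(fit)) next
      mappings[[id]] <- extractWeightMapping(fit, modelId = id)
      if (verbose)
        message(sprintf("model %s: final loss %.4f", id,
                        tail(fit@lossHistory, 1)))
    }
  }
  if (length(mappings) < 2L)
    stop("runEnsemble: fewer than 2 models trained successfully")
  mappings
}
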