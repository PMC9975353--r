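#' @import methods
#' @importFrom stats median pbeta phyper kmeans prcomp rnbinom runif rnorm setNames
#' @importFrom utils head tail read.csv write.csv read.delim read.table
#'   write.table modifyList
#' @importFrom tools file_ext
NULL

#' Model configuration for a restricted-latent VAE
#'
#' Holds every hyperparameter of a single resVAE model: the loss weights
#' \code{alpha} (reconstruction) and \code{beta} (KL divergence), the latent
#' prior offset \code{s}, the activation function, layer widths, the number
#' of latent units reserved for each cluster, the label-smoothing epsilon,
#' and the optimisation schedule.
#'
#' @slot alpha numeric(1), reconstruction weight, > 0.
#' @slot beta numeric(1), KL weight, >= 0.
#' @slot latentOffset numeric(1), prior centre s of the latent Gaussian.
#' @slot activation character(1), one of \code{"mish"} or \code{"relu"}.
#' @slot encoderUnits integer(1), hidden units in the encoder (default 256).
#' @slot decoderUnits integer(1), hidden units in the decoder (default 512).
#' @slot latentUnitsPerCluster integer(1), latent units per cluster block.
#' @slot labelSmoothingEps numeric(1) in [0, 1), epsilon of label smoothing.
#' @slot epochs integer(1), training epochs, >= 1.
#' @slot batchSize integer(1), minibatch size.
#' @slot learningRate numeric(1), base learning rate of RAdam.
#' @slot seed integer(1), global seed for init, shuffling and sampling.
#' @slot normalize character(1), working scale of the reconstruction:
#'   \code{"log1p"} (default), \code{"library"} (library-size normalized
#'   then log1p) or \code{"none"} (raw values).
#' @slot maxGradNorm numeric(1), global gradient-norm clip (Inf disables).
#' @slot weightDecay numeric(1), decoupled weight decay on the weight
#'   matrices (0 disables).
#' @slot annealLearningRate logical(1), linearly anneal the learning rate
#'   to 10\% of its base value over the epochs.
#' @slot tailAverage numeric(1) in [0, 1), fraction of final epochs whose
#'   end-of-epoch parameters are averaged into the returned model (0
#'   returns the last iterate).
#' @slot centerFeatures logical(1), centre each feature (subtract its
#'   global mean on the working scale) before reconstruction.
#'
#' @exportClass ModelConfig
setClass("ModelConfig",
  representation(
    alpha = "numeric", beta = "numeric", latentOffset = "numeric",
    activation = "character", encoderUnits = "integer",
    decoderUnits = "integer", latentUnitsPerCluster = "integer",
    labelSmoothingEps = "numeric", epochs = "integer",
    batchSize = "integer", learningRate = "numeric", seed = "integer",
    normalize = "character", maxGradNorm = "numeric",
    weightDecay = "numeric", annealLearningRate = "logical",
    tailAverage = "numeric", centerFeatures = "logical"
  )
)

setValidity("ModelConfig", function(object) {
  msg <- character()
  scalars <- c("alpha", "beta", "latentOffset", "labelSmoothingEps",
               "learningRate")
  for (s in scalars) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v))
      msg <- c(msg, sprintf("'%s' must be a finite scalar", s))
  }
  if (length(msg) == 0L) {
    if (object@alpha <= 0) msg <- c(msg, "'alpha' must be > 0")
    if (object@beta < 0) msg <- c(msg, "'beta' must be >= 0")
    if (object@labelSmoothingEps < 0 || object@labelSmoothingEps >= 1)
      msg <- c(msg, "'labelSmoothingEps' must be in [0, 1)")
    if (object@learningRate <= 0) msg <- c(msg, "'learningRate' must be > 0")
  }
  if (!object@activation %in% c("mish", "relu"))
    msg <- c(msg, "'activation' must be \"mish\" or \"relu\"")
  if (!object@normalize %in% c("log1p", "library", "none"))
    msg <- c(msg, "'normalize' must be \"log1p\", \"library\" or \"none\"")
  if (length(object@maxGradNorm) != 1L || is.na(object@maxGradNorm) ||
      object@maxGradNorm <= 0)
    msg <- c(msg, "'maxGradNorm' must be a positive number (Inf to disable)")
  if (length(object@weightDecay) != 1L || !is.finite(object@weightDecay) ||
      object@weightDecay < 0)
    msg <- c(msg, "'weightDecay' must be a finite non-negative number")
  if (length(object@tailAverage) != 1L || !is.finite(object@tailAverage) ||
      object@tailAverage < 0 || object@tailAverage >= 1)
    msg <- c(msg, "'tailAverage' must lie in [0, 1)")
  if (object@encoderUnits < 1L) msg <- c(msg, "'encoderUnits' must be >= 1")
  if (object@decoderUnits < 1L) msg <- c(msg, "'decoderUnits' must be >= 1")
  if (object@latentUnitsPerCluster < 1L)
    msg <- c(msg, "'latentUnitsPerCluster' must be >= 1")
  if (object@epochs < 1L) msg <- c(msg, "'epochs' must be >= 1")
  if (object@batchSize < 1L) msg <- c(msg, "'batchSize' must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct a ModelConfig
#'
#' @param alpha reconstruction weight (> 0).
#' @param beta KL weight (>= 0).
#' @param latentOffset latent prior offset s.
#' @param activation \code{"mish"} (default) or \code{"relu"}.
#' @param encoderUnits encoder hidden width.
#' @param decoderUnits decoder hidden width.
#' @param latentUnitsPerCluster latent units per cluster block.
#' @param labelSmoothingEps label-smoothing epsilon in [0, 1).
#' @param epochs training epochs.
#' @param batchSize minibatch size.
#' @param learningRate base learning rate.
#' @param seed integer seed controlling weight init, shuffling and latent
#'   sampling.
#' @param normalize working scale of the reconstruction target:
#'   \code{"log1p"} (default; the counts are only log1p-transformed,
#'   minimal processing), \code{"library"} (library-size normalized to
#'   the median total, then log1p) or \code{"none"} (raw values).
#' @param maxGradNorm clip the global gradient norm at this value each
#'   step (default 10; \code{Inf} disables clipping).
#' @param weightDecay decoupled weight decay applied to the weight
#'   matrices each step (default 8; 0 disables). Strong decay prunes
#'   weight paths lacking consistent gradient support, so each cluster
#'   block keeps only the features it genuinely drives; this is what
#'   makes the per-cluster weight mappings mutually exclusive rather
#'   than dominated by globally high-variance features.
#' @param annealLearningRate linearly anneal the learning rate to 10\%
#'   of its base value over training (default TRUE).
#' @param tailAverage average the end-of-epoch parameters over this
#'   fraction of final epochs (default 0.2). Weights kept alive only by
#'   gradient noise flip sign between epochs and average towards zero,
#'   while consistently supported weights survive, sharpening the decoder
#'   weight mappings; 0 disables.
#' @param centerFeatures centre each feature on the working scale before
#'   reconstruction (default TRUE). The decoder then models per-cluster
#'   deviations from the global mean profile, so features that are flat
#'   across clusters (e.g. housekeeping genes) need no decoder weights at
#'   all and drop out of the weight mappings.
#' @return A validated \linkS4class{ModelConfig}.
#' @examples
#' cfg <- modelConfig(alpha = 1, beta = 1, epochs = 10, seed = 1L)
#' @export
modelConfig <- function(alpha = 1, beta = 1, latentOffset = 0,
                        activation = c("mish", "relu"),
                        encoderUnits = 256L, decoderUnits = 512L,
                        latentUnitsPerCluster = 8L,
                        labelSmoothingEps = 0.1, epochs = 50L,
                        batchSize = 128L, learningRate = 5e-3,
                        seed = 0L, normalize = c("log1p", "library", "none"),
                        maxGradNorm = 10, weightDecay = 8,
                        annealLearningRate = TRUE, tailAverage = 0.2,
                        centerFeatures = TRUE) {
  activation <- match.arg(activation)
  normalize <- match.arg(normalize)
  new("ModelConfig",
      alpha = as.numeric(alpha), beta = as.numeric(beta),
      latentOffset = as.numeric(latentOffset), activation = activation,
      encoderUnits = as.integer(encoderUnits),
      decoderUnits = as.integer(decoderUnits),
      latentUnitsPerCluster = as.integer(latentUnitsPerCluster),
      labelSmoothingEps = as.numeric(labelSmoothingEps),
      epochs = as.integer(epochs), batchSize = as.integer(batchSize),
      learningRate = as.numeric(learningRate), seed = as.integer(seed),
      normalize = normalize, maxGradNorm = as.numeric(maxGradNorm),
      weightDecay = as.numeric(weightDecay),
      annealLearningRate = isTRUE(annealLearningRate),
      tailAverage = as.numeric(tailAverage),
      centerFeatures = isTRUE(centerFeatures))
}

#' Cluster assignment of cells
#'
#' A cells x clusters weight matrix in [0, 1]. One-hot rows encode a hard
#' clustering; rows mixing several clusters encode soft or partial
#' identities (e.g. transitional states along a trajectory), and must sum
#' to 1.
#'
#' @slot weights numeric matrix, cells x clusters, entries in [0, 1], rows
#'   summing to 1; rownames are cell ids, colnames cluster ids.
#' @slot isHard logical(1), TRUE when every row is one-hot.
#'
#' @exportClass ClusterAssignment
setClass("ClusterAssignment",
  representation(weights = "matrix", isHard = "logical"))

setValidity("ClusterAssignment", function(object) {
  w <- object@weights
  if (!is.numeric(w)) return("'weights' must be numeric")
  if (is.null(colnames(w))) return("'weights' must have cluster ids as colnames")
  if (anyDuplicated(colnames(w))) return("duplicate cluster ids")
  if (any(!is.finite(w))) return("non-finite assignment weights")
  if (any(w < -1e-12) || any(w > 1 + 1e-12))
    return("assignment weights must lie in [0, 1]")
  rs <- rowSums(w)
  if (any(abs(rs - 1) > 1e-6))
    return("assignment rows must sum to 1 (tolerance 1e-6)")
  if (object@isHard) {
    oneHot <- rowSums(w == 1) == 1L & rowSums(w == 0) == ncol(w) - 1L
    if (!all(oneHot)) return("isHard = TRUE but some rows are not one-hot")
  }
  TRUE
})

#' Construct a ClusterAssignment from a weight matrix
#'
#' @param weights cells x clusters numeric matrix with cluster ids as
#'   colnames (cell ids as rownames recommended). Rows must sum to 1.
#' @return A \linkS4class{ClusterAssignment}; \code{isHard} is detected
#'   from the rows.
#' @examples
#' w <- rbind(c(1, 0), c(0.5, 0.5))
#' colnames(w) <- c("a", "b")
#' clusterAssignment(w)
#' @export
clusterAssignment <- function(weights) {
  weights <- as.matrix(weights)
  storage.mode(weights) <- "double"
  hard <- all(rowSums(weights == 1) == 1L) &&
    all(rowSums(weights == 0) == ncol(weights) - 1L)
  new("ClusterAssignment", weights = weights, isHard = hard)
}

#' Construct a hard ClusterAssignment from labels
#'
#' @param labels character or factor vector of cluster labels, one per cell.
#' @param cellIds optional cell identifiers (defaults to names of
#'   \code{labels} or seq_along).
#' @return A one-hot \linkS4class{ClusterAssignment}.
#' @examples
#' hardAssignment(c("a", "a", "b"))
#' @export
hardAssignment <- function(labels, cellIds = NULL) {
  labels <- as.character(labels)
  if (is.null(cellIds)) cellIds <- names(labels)
  if (is.null(cellIds)) cellIds <- paste0("cell", seq_along(labels))
  ids <- sort(unique(labels))
  w <- matrix(0, length(labels), length(ids),
              dimnames = list(cellIds, ids))
  w[cbind(seq_along(labels), match(labels, ids))] <- 1
  new("ClusterAssignment", weights = w, isHard = TRUE)
}

#' A trained restricted-latent VAE
#'
#' Parameters of one trained model plus its training trace. The latent
#' space has \code{length(clusterIds) * latentUnitsPerCluster} units,
#' partitioned into contiguous per-cluster blocks in \code{clusterIds}
#' order.
#'
#' @slot config the \linkS4class{ModelConfig} used for training.
#' @slot params named list of parameter matrices/vectors (We, be, Wmu, bmu,
#'   Wls, bls, Wd1, bd1, Wd2, bd2).
#' @slot lossHistory numeric vector, mean training loss per epoch.
#' @slot featureIds character, feature universe (decoder output order).
#' @slot clusterIds character, cluster block order.
#' @slot normalization list with the library-size/log1p parameters applied
#'   to the inputs (empty when \code{normalize = FALSE}).
#'
#' @exportClass ResVAEModel
setClass("ResVAEModel",
  representation(config = "ModelConfig", params = "list",
                 lossHistory = "numeric", featureIds = "character",
                 clusterIds = "character", normalization = "list"))

setValidity("ResVAEModel", function(object) {
  if (length(object@lossHistory) != object@config@epochs)
    return("loss history length must equal epochs")
  fin <- vapply(object@params, function(p) all(is.finite(p)), logical(1))
  if (!all(fin)) return("non-finite model parameters")
  TRUE
})

#' Per-cluster feature relevance extracted from one decoder
#'
#' Non-negative clusters x features matrix of absolute decoder weight-path
#' sums: entry (c, g) totals |W| products along every linear path from
#' cluster c's latent block to output feature g.
#'
#' @slot scores numeric matrix, clusters x features, >= 0; dimnames are
#'   cluster and feature ids.
#' @slot modelId character(1), identifier of the source model.
#'
#' @exportClass WeightMapping
setClass("WeightMapping",
  representation(scores = "matrix", modelId = "character"))

setValidity("WeightMapping", function(object) {
  s <- object@scores
  if (any(!is.finite(s))) return("non-finite scores")
  if (any(s < 0)) return("negative scores")
  if (is.null(rownames(s)) || is.null(colnames(s)))
    return("scores must carry cluster (rows) and feature (cols) ids")
  TRUE
})

#' Consensus per-cluster feature ranking from an ensemble
#'
#' Output of Robust Rank Aggregation over one cluster's truncated ranked
#' lists. Features are ordered by the RRA rho score (ascending; smaller =
#' more consistently top-ranked than expected under a uniform null), with
#' a Bonferroni-corrected score, a display score -log10(corrected), and the
#' ensemble confidence (fraction of models ranking the feature above the
#' cluster's cut-off).
#'
#' @slot clusterId character(1).
#' @slot table data.frame with columns feature, rho, corrected, score,
#'   confidence, nModels.
#' @slot m integer(1), number of aggregated lists.
#' @slot n integer(1), feature universe size used for rank normalization.
#' @slot cutoff integer(1), the cluster's median cut-off index (NA when no
#'   truncation was applied).
#'
#' @exportClass ConsensusRanking
setClass("ConsensusRanking",
  representation(clusterId = "character", table = "data.frame",
                 m = "integer", n = "integer", cutoff = "integer"))

setValidity("ConsensusRanking", function(object) {
  tb <- object@table
  need <- c("feature", "rho", "corrected", "score", "confidence", "nModels")
  if (!all(need %in% names(tb)))
    return(paste("table must have columns:", paste(need, collapse = ", ")))
  if (nrow(tb)) {
    if (any(tb$rho <= 0 | tb$rho > 1)) return("rho must lie in (0, 1]")
    if (any(tb$corrected < tb$rho - 1e-12))
      return("corrected score must be >= rho")
    if (is.unsorted(tb$rho)) return("table must be ordered by rho ascending")
  }
  TRUE
})
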