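#' Accessors for resvae classes
#'
#' @param object an object of the documented classes.
#' @return \code{clusterWeights}: the cells x clusters weight matrix.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("clusterWeights", function(object) standardGeneric("clusterWeights"))

#' @rdname accessors
#' @export
setGeneric("clusterIds", function(object) standardGeneric("clusterIds"))

#' @rdname accessors
#' @export
setGeneric("isHard", function(object) standardGeneric("isHard"))

#' @rdname accessors
#' @export
setGeneric("mappingScores", function(object) standardGeneric("mappingScores"))

#' @rdname accessors
#' @export
setGeneric("featureIds", function(object) standardGeneric("featureIds"))

#' @rdname accessors
#' @export
setGeneric("lossHistory", function(object) standardGeneric("lossHistory"))

#' @rdname accessors
#' @export
setGeneric("modelConfigOf", function(object) standardGeneric("modelConfigOf"))

#' @rdname accessors
#' @export
setGeneric("consensusTable", function(object) standardGeneric("consensusTable"))

#' @rdname accessors
#' @export
setMethod("clusterWeights", "ClusterAssignment", function(object) object@weights)

#' @rdname accessors
#' @export
setMethod("clusterIds", "ClusterAssignment",
          function(object) colnames(object@weights))

#' @rdname accessors
#' @export
setMethod("clusterIds", "ResVAEModel", function(object) object@clusterIds)

#' @rdname accessors
#' @export
setMethod("clusterIds", "WeightMapping",
          function(object) rownames(object@scores))

#' @rdname accessors
#' @export
setMethod("isHard", "ClusterAssignment", function(object) object@isHard)

#' @rdname accessors
#' @export
setMethod("mappingScores", "WeightMapping", function(object) object@scores)

#' @rdname accessors
#' @export
setMethod("featureIds", "ResVAEModel", function(object) object@featureIds)

#' @rdname accessors
#' @export
setMethod("featureIds", "WeightMapping",
          function(object) colnames(object@scores))

#' @rdname accessors
#' @export
setMethod("lossHistory", "ResVAEModel", function(object) object@lossHistory)

#' @rdname accessors
#' @export
setMethod("modelConfigOf", "ResVAEModel", function(object) object@config)

#' @rdname accessors
#' @export
setMethod("consensusTable", "ConsensusRanking", function(object) object@table)

setMethod("show", "ModelConfig", function(object) {
  cat("ModelConfig: alpha=", object@alpha, " beta=", object@beta,
      " s=", object@latentOffset, " activation=", object@activation, "\n",
      "  encoder ", object@encoderUnits, " | decoder ", object@decoderUnits,
      " | ", object@latentUnitsPerCluster, " latent units/cluster\n",
      "  eps=", object@labelSmoothingEps, " epochs=", object@epochs,
      " batch=", object@batchSize, " lr=", object@learningRate,
      " seed=", object@seed, "\n", sep = "")
})

setMethod("show", "ClusterAssignment", function(object) {
  cat("ClusterAssignment: ", nrow(object@weights), " cells x ",
      ncol(object@weights), " clusters (",
      if (object@isHard) "hard" else "soft", ")\n", sep = "")
  cat("  clusters:", paste(head(colnames(object@weights), 8), collapse = ", "),
      if (ncol(object@weights) > 8) "..." else "", "\n")
})

setMethod("show", "ResVAEModel", function(object) {
  L <- length(object@clusterIds) * object@config@latentUnitsPerCluster
  cat("ResVAEModel: ", length(object@featureIds), " features, ",
      length(object@clusterIds), " clusters, latent dim ", L, "\n", sep = "")
  cat("  final epoch loss: ",
      format(utils::tail(object@lossHistory, 1), digits = 6), "\n", sep = "")
})

setMethod("show", "WeightMapping", function(object) {
  cat("WeightMapping [", object@modelId, "]: ", nrow(object@scores),
      " clusters x ", ncol(object@scores), " features\n", sep = "")
})

setMethod("show", "ConsensusRanking", function(object) {
  cat("ConsensusRanking for cluster '", object@clusterId, "': ",
      nrow(object@table), " features from m=", object@m,
      " lists (universe n=", object@n, ", cut-off ",
      ifelse(is.na(object@cutoff), "none", object@cutoff), ")\n", sep = "")
  print(head(object@table, 5))
})
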