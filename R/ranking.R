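#' Rank features of one cluster by decoder weight
#'
#' @param mapping a \linkS4class{WeightMapping}.
#' @param clusterId cluster to rank.
#' @return data.frame with columns \code{feature}, \code{score},
#'   \code{rank}; scores descending, ties broken lexicographically by
#'   feature id.
#' @examples
#' s <- matrix(c(2, 5, 5), 1, dimnames = list("c1", c("a", "b", "c")))
#' rankFeatures(new("WeightMapping", scores = s, modelId = "m"), "c1")
#' @export
rankFeatures <- function(mapping, clusterId) {
  stopifnot(is(mapping, "WeightMapping"))
  if (!clusterId %in% rownames(mapping@scores))
    stop("rankFeatures: unknown cluster '", clusterId, "'")
  sc <- setNames(as.vector(mapping@scores[clusterId, , drop = FALSE]),
                 colnames(mapping@scores))
  ord <- order(-sc, names(sc), method = "radix")
  data.frame(feature = names(sc)[ord], score = unname(sc[ord]),
             rank = seq_along(sc), stringsAsFactors = FALSE)
}

# shared bin-and-rotate machinery: normalize a bin's points, rotate by the
# chord angle, return rotated y values
rotatedY <- function(yBin, chordFrom, chordTo) {
  b <- length(yBin)
  x <- if (b > 1) (seq_len(b) - 1) / (b - 1) else 0
  rng <- range(yBin)
  yn <- if (diff(rng) > 0) (yBin - rng[1]) / diff(rng) else rep(0, b)
  theta <- atan2(yn[chordTo] - yn[chordFrom], x[chordTo] - x[chordFrom])
  # rotate points by -theta; the chord becomes horizontal
  -x * sin(theta) + yn * cos(theta)
}

#' Knee point of a descending weight curve
#'
#' Splits the ranked curve into \code{nBins} bins of equal size and looks
#' for the pronounced drop expected in the first bin: x is normalized to
#' [0, 1] over the bin, y over its own range, the chord from the bin's
#' first data point to its median data point (the point at index
#' ceiling(binSize / 2)) gives a rotation angle theta, the bin is rotated
#' by -theta so the chord lies parallel to the x-axis, and the knee is the
#' index (1-based in the full list) where the rotated y is maximal. When
#' several points tie, the last of them — the final point before the drop
#' — is returned; when the whole rotated bin is flat (e.g. a strictly
#' linear decline) the bin's first index is returned, and when the raw y
#' is constant over the bin there is no drop and the result is \code{NA}.
#'
#' @param y numeric vector sorted non-increasing (a ranked weight curve).
#' @param nBins number of equal-size bins (>= 2); the bin size is
#'   \code{floor(length(y) / nBins)}.
#' @return Integer knee index within the first bin, or \code{NA_integer_}.
#' @examples
#' findKnee(c(1, 1, 1, 0, 0, 0, 0, 0, 0, 0), nBins = 2)  # 3
#' @export
findKnee <- function(y, nBins = 10L) {
  checkCurve(y, nBins)
  b <- length(y) %/% as.integer(nBins)
  yBin <- y[seq_len(b)]
  if (diff(range(yBin)) == 0) return(NA_integer_)
  ry <- rotatedY(yBin, chordFrom = 1L, chordTo = as.integer(ceiling(b / 2)))
  if (diff(range(ry)) <= 1e-12 * max(1, max(abs(ry))))
    return(1L)                       # flat rotated curve: no interior point
  ties <- which(ry >= max(ry) - 1e-12 * max(1, max(abs(ry))))
  as.integer(ties[length(ties)])
}

#' Elbow point of a descending weight curve
#'
#' Mirror of \code{\link{findKnee}} on the last bin: the chord runs from
#' the bin's median data point to its last data point, and the elbow is
#' the full-list index where the rotated y is minimal (the first tied
#' point — the last point of the low tail before any rise; a flat rotated
#' bin returns the bin's last index, a constant bin \code{NA}).
#'
#' @inheritParams findKnee
#' @return Integer elbow index within the last bin, or \code{NA_integer_}.
#' @export
findElbow <- function(y, nBins = 10L) {
  checkCurve(y, nBins)
  n <- length(y)
  b <- n %/% as.integer(nBins)
  start <- n - b + 1L
  yBin <- y[start:n]
  if (diff(range(yBin)) == 0) return(NA_integer_)
  ry <- rotatedY(yBin, chordFrom = as.integer(ceiling(b / 2)), chordTo = b)
  if (diff(range(ry)) <= 1e-12 * max(1, max(abs(ry))))
    return(as.integer(n))            # flat rotated curve
  ties <- which(ry <= min(ry) + 1e-12 * max(1, max(abs(ry))))
  as.integer(start - 1L + ties[1])
}

checkCurve <- function(y, nBins) {
  nBins <- as.integer(nBins)
  if (nBins < 2L) stop("nBins must be >= 2")
  if (length(y) < 2L * nBins)
    stop("curve must have at least 2 * nBins points")
  if (any(!is.finite(y))) stop("non-finite values in curve")
  if (is.unsorted(-y)) stop("curve must be sorted non-increasing")
  invisible(TRUE)
}

#' Median cut-off across an ensemble
#'
#' The consensus truncation index: the median of the per-model cut-offs
#' (models whose knee search returned \code{NA} are excluded before
#' calling this). An even count rounds the half-integer median up so the
#' result stays a valid index.
#'
#' @param cutoffs integer vector of per-model cut-off indices (>= 1).
#' @return Integer median cut-off.
#' @examples
#' medianCutoff(c(10, 12))  # 11
#' @export
medianCutoff <- function(cutoffs) {
  cutoffs <- cutoffs[!is.na(cutoffs)]
  if (length(cutoffs) == 0L)
    stop("medianCutoff: no usable cut-offs; inspect the weight curves ",
         "(every model returned NA — the ranked curves may be constant)")
  if (any(cutoffs < 1)) stop("medianCutoff: cut-offs must be >= 1")
  as.integer(floor(stats::median(cutoffs) + 0.5))
}

#' Per-cluster cut-off table for an ensemble of weight mappings
#'
#' Ranks every (model, cluster) weight curve, finds its knee (and elbow),
#' and reduces the knees to one shared median cut-off per cluster.
#'
#' @param mappings list of \linkS4class{WeightMapping} (one per model).
#' @param nBins bins for \code{\link{findKnee}}.
#' @return List with \code{perModel} (data.frame model, cluster, knee,
#'   elbow) and \code{perCluster} (named integer vector of median knees).
#' @export
computeCutoffs <- function(mappings, nBins = 10L) {
  stopifnot(length(mappings) >= 1L)
  clusters <- rownames(mappings[[1]]@scores)
  rows <- list()
  for (mi in seq_along(mappings)) {
    mid <- mappings[[mi]]@modelId
    for (cl in clusters) {
      y <- rankFeatures(mappings[[mi]], cl)$score
      rows[[length(rows) + 1L]] <- data.frame(
        model = mid, cluster = cl,
        knee = findKnee(y, nBins), elbow = findElbow(y, nBins),
        stringsAsFactors = FALSE)
    }
  }
  perModel <- do.call(rbind, rows)
  perCluster <- vapply(clusters, function(cl)
    medianCutoff(perModel$knee[perModel$cluster == cl]), integer(1))
  list(perModel = perModel, perCluster = perCluster)
}
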