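#' Hypergeometric overlap test between two feature sets
#'
#' Upper-tail probability P(X >= |A intersect B|) of drawing the observed
#' overlap when |B| features are sampled without replacement from a
#' universe of \code{universeN} containing |A| marked features. An empty
#' set (or zero overlap) gives p = 1.
#'
#' @param setA,setB character vectors of feature ids (subsets of the
#'   universe).
#' @param universeN universe size (>= |A union B|).
#' @return p-value in (0, 1].
#' @examples
#' hypergeomOverlap(letters[1:3], letters[1:3], 10)  # 1/120
#' @export
hypergeomOverlap <- function(setA, setB, universeN) {
  setA <- unique(setA); setB <- unique(setB)
  universeN <- as.integer(universeN)
  if (universeN < length(union(setA, setB)))
    stop("hypergeomOverlap: universe smaller than the union of the sets")
  k <- length(intersect(setA, setB))
  if (k == 0L || length(setA) == 0L || length(setB) == 0L) return(1)
  phyper(k - 1, length(setA), universeN - length(setA), length(setB),
         lower.tail = FALSE)
}

#' Pairwise overlap significance matrix
#'
#' Clusters x clusters matrix of -log10 hypergeometric overlap p-values
#' between identified feature sets (the heatmap diagnostic for cluster
#' partitions).
#'
#' @param sets named list of feature-id character vectors, one per
#'   cluster.
#' @param universeN universe size.
#' @return Symmetric numeric matrix of -log10(p).
#' @export
overlapMatrix <- function(sets, universeN) {
  ids <- names(sets)
  M <- matrix(0, length(sets), length(sets), dimnames = list(ids, ids))
  for (i in seq_along(sets))
    for (j in seq_len(i)) {
      p <- hypergeomOverlap(sets[[i]], sets[[j]], universeN)
      M[i, j] <- M[j, i] <- -log10(p)
    }
  M
}

#' Clustering-quality metrics
#'
#' Silhouette coefficient (via \pkg{cluster}), Calinski-Harabasz index
#' (between/within dispersion ratio scaled by degrees of freedom) and
#' Davies-Bouldin index (mean over clusters of the worst within-to-
#' between scatter ratio), computed on any embedding — by default the
#' restricted latent means of a trained model (see
#' \code{\link{latentMeans}}), or a PCA of the data.
#'
#' @param embedding cells x dimensions numeric matrix.
#' @param labels cluster label per cell (>= 2 distinct values).
#' @return Named list: \code{silhouette}, \code{calinskiHarabasz},
#'   \code{daviesBouldin}.
#' @examples
#' x <- rbind(matrix(rnorm(40), 20), matrix(rnorm(40, 6), 20))
#' clusteringMetrics(x, rep(c("a", "b"), each = 20))
#' @export
clusteringMetrics <- function(embedding, labels) {
  embedding <- as.matrix(embedding)
  labels <- as.character(labels)
  ids <- unique(labels)
  if (length(ids) < 2L)
    stop("clusteringMetrics: at least 2 clusters are required")
  sil <- cluster::silhouette(as.integer(factor(labels)),
                             stats::dist(embedding))
  silMean <- mean(sil[, "sil_width"])

  centroids <- t(vapply(ids, function(cl)
    colMeans(embedding[labels == cl, , drop = FALSE]),
    numeric(ncol(embedding))))
  grand <- colMeans(embedding)
  nk <- table(labels)[ids]
  k <- length(ids); n <- nrow(embedding)
  ssb <- sum(nk * rowSums(sweep(centroids, 2, grand)^2))
  ssw <- sum(vapply(ids, function(cl) {
    sub <- embedding[labels == cl, , drop = FALSE]
    sum(sweep(sub, 2, colMeans(sub))^2)
  }, numeric(1)))
  ch <- if (ssw == 0) Inf else (ssb / (k - 1)) / (ssw / (n - k))

  scatter <- vapply(ids, function(cl) {
    sub <- embedding[labels == cl, , drop = FALSE]
    mean(sqrt(rowSums(sweep(sub, 2, colMeans(sub))^2)))
  }, numeric(1))
  db <- mean(vapply(seq_len(k), function(i) {
    max(vapply(setdiff(seq_len(k), i), function(j) {
      d <- sqrt(sum((centroids[i, ] - centroids[j, ])^2))
      (scatter[i] + scatter[j]) / d
    }, numeric(1)))
  }, numeric(1)))

  list(silhouette = silMean, calinskiHarabasz = ch, daviesBouldin = db)
}

#' Scan candidate cluster numbers
#'
#' k-means clustering for each k in \code{kRange} — on the restricted
#' latent means of a trained model when one is supplied, otherwise on a
#' PCA of the data — scoring each k with the three clustering metrics.
#'
#' @param data cells x features matrix (or an embedding when
#'   \code{embed = "none"}).
#' @param kRange integer vector of cluster numbers within
#'   [2, nrow(data) - 1].
#' @param embed \code{"pca"} (default, top \code{nPcs} components),
#'   or \code{"none"} to use \code{data} as the embedding directly (e.g.
#'   latent means from \code{\link{latentMeans}}).
#' @param nPcs number of principal components for \code{embed = "pca"}.
#' @param seed seed for the k-means starts.
#' @return data.frame with k and the three metrics, plus attribute
#'   \code{"best"}: the per-metric argbest k (max silhouette, max CH, min
#'   DB).
#' @export
optimalKScan <- function(data, kRange = 2:8, embed = c("pca", "none"),
                         nPcs = 10L, seed = 0L) {
  embed <- match.arg(embed)
  data <- as.matrix(data)
  kRange <- as.integer(kRange)
  if (length(kRange) == 0L) stop("optimalKScan: empty k range")
  if (any(kRange < 2L) || any(kRange > nrow(data) - 1L))
    stop("optimalKScan: k must lie in [2, nCells - 1]")
  emb <- if (embed == "pca") {
    p <- prcomp(data, center = TRUE, scale. = FALSE)
    p$x[, seq_len(min(nPcs, ncol(p$x))), drop = FALSE]
  } else data
  set.seed(as.integer(seed))
  rows <- lapply(kRange, function(k) {
    km <- kmeans(emb, centers = k, nstart = 5, iter.max = 50)
    m <- clusteringMetrics(emb, km$cluster)
    data.frame(k = k, silhouette = m$silhouette,
               calinskiHarabasz = m$calinskiHarabasz,
               daviesBouldin = m$daviesBouldin)
  })
  out <- do.call(rbind, rows)
  attr(out, "best") <- c(
    silhouette = out$k[which.max(out$silhouette)],
    calinskiHarabasz = out$k[which.max(out$calinskiHarabasz)],
    daviesBouldin = out$k[which.min(out$daviesBouldin)])
  out
}

#' Ground-truth recovery of a consensus
#'
#' Per cluster, the fraction of the ground truth's active-module
#' transcription factors appearing above the cluster's cut-off in the
#' consensus ranking; macro-averaged over the requested clusters.
#'
#' @param consensus named list of \linkS4class{ConsensusRanking} (from
#'   \code{\link{resvaeConsensus}}).
#' @param truth a ground-truth list from the simulators.
#' @param clusters clusters to score (default: all in \code{consensus}).
#' @return List with \code{perCluster} (named fractions) and \code{macro}
#'   (their mean, in [0, 1]).
#' @export
recoveryScore <- function(consensus, truth, clusters = names(consensus)) {
  missing <- setdiff(clusters, names(truth$activeModules))
  if (length(missing))
    stop("recoveryScore: cluster(s) missing from the ground truth: ",
         paste(missing, collapse = ", "))
  per <- vapply(clusters, function(cl) {
    mods <- truth$activeModules[[cl]]
    tfs <- names(truth$moduleOf)[truth$moduleOf %in% mods]
    cr <- consensus[[cl]]
    cut <- cr@cutoff
    top <- if (is.na(cut)) cr@table$feature
           else head(cr@table$feature, cut)
    if (length(tfs) == 0L) return(NA_real_)
    mean(tfs %in% top)
  }, numeric(1))
  list(perCluster = per, macro = mean(per, na.rm = TRUE))
}
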