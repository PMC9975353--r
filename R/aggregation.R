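#' Robust Rank Aggregation rho score for one item
#'
#' Given an item's normalized ranks r = rank / n across m lists (r = 1 for
#' lists where the item is absent or below the cut-off), the ranks are
#' sorted ascending and compared against the order statistics of m uniform
#' draws: beta_k = BetaCDF(r_(k); k, m - k + 1) is the probability that
#' the k-th smallest of m uniforms is <= r_(k). The rho score is
#' min_k beta_k, and the Bonferroni-corrected score is min(rho * m, 1).
#'
#' @param normalizedRanks numeric vector of ranks in (0, 1]; padded with
#'   1s to length \code{m} if shorter.
#' @param m number of aggregated lists (defaults to the vector length).
#' @return List with \code{rho} and \code{corrected}.
#' @examples
#' rraRho(c(0.1, 0.2))  # rho 0.04, corrected 0.08
#' @export
rraRho <- function(normalizedRanks, m = length(normalizedRanks)) {
  r <- as.numeric(normalizedRanks)
  if (any(!is.finite(r)) || any(r <= 0) || any(r > 1))
    stop("rraRho: normalized ranks must lie in (0, 1]")
  m <- as.integer(m)
  if (length(r) > m) stop("rraRho: more ranks than lists")
  if (length(r) < m) r <- c(r, rep(1, m - length(r)))
  r <- sort(r)
  k <- seq_len(m)
  rho <- min(pbeta(r, k, m - k + 1))
  list(rho = rho, corrected = min(rho * m, 1))
}

#' Aggregate truncated ranked lists into a consensus ranking
#'
#' Robust Rank Aggregation over one cluster's ensemble of ranked feature
#' lists. Each list is truncated at \code{cutoff} (evidence of absence:
#' features below it get normalized rank 1), ranks above the cut-off are
#' normalized by the full universe size n, and every feature of the
#' universe is scored with \code{\link{rraRho}}. The output is ordered by
#' rho ascending (ties broken by feature id) and carries the Bonferroni
#' corrected score, a display score -log10(corrected), and the ensemble
#' confidence — the fraction of lists ranking the feature above the
#' cut-off.
#'
#' @param rankedLists list (length >= 2) of data.frames with columns
#'   \code{feature} and \code{rank} (as from \code{\link{rankFeatures}}).
#' @param n universe size used to normalize ranks (>= every observed
#'   rank); typically the number of features in the weight mapping.
#' @param clusterId label stored in the result.
#' @param cutoff 1-based inclusive truncation index (NA = no truncation).
#' @return A \linkS4class{ConsensusRanking}.
#' @examples
#' l1 <- data.frame(feature = c("a", "b"), rank = 1:2)
#' l2 <- data.frame(feature = c("a", "b"), rank = 1:2)
#' aggregateCluster(list(l1, l2), n = 10)
#' @export
aggregateCluster <- function(rankedLists, n, clusterId = "cluster",
                             cutoff = NA_integer_) {
  if (length(rankedLists) < 2L)
    stop("aggregateCluster: need at least 2 lists")
  n <- as.integer(n)
  m <- length(rankedLists)
  maxRank <- max(vapply(rankedLists, function(l) max(l$rank), numeric(1)))
  if (n < maxRank)
    stop("aggregateCluster: universe size n smaller than an observed rank")
  universe <- sort(unique(unlist(lapply(rankedLists, `[[`, "feature"))))
  R <- matrix(1, length(universe), m, dimnames = list(universe, NULL))
  for (j in seq_len(m)) {
    l <- rankedLists[[j]]
    keep <- if (is.na(cutoff)) rep(TRUE, nrow(l)) else l$rank <= cutoff
    R[l$feature[keep], j] <- l$rank[keep] / n
  }
  k <- seq_len(m)
  rho <- apply(R, 1, function(r) min(pbeta(sort(r), k, m - k + 1)))
  corrected <- pmin(rho * m, 1)
  confidence <- rowMeans(R < 1)
  ord <- order(rho, universe, method = "radix")
  tb <- data.frame(feature = universe[ord], rho = unname(rho[ord]),
                   corrected = unname(corrected[ord]),
                   score = -log10(unname(corrected[ord])),
                   confidence = unname(confidence[ord]),
                   nModels = m, stringsAsFactors = FALSE)
  new("ConsensusRanking", clusterId = as.character(clusterId), table = tb,
      m = as.integer(m), n = n, cutoff = as.integer(cutoff))
}

#' Ensemble confidence of a feature in a cluster
#'
#' Fraction of ensemble models ranking the feature above the cluster's
#' cut-off. A feature unknown to every list has confidence 0 by contract.
#'
#' @param feature feature id.
#' @param rankedLists list of per-model ranked data.frames for one cluster.
#' @param cutoff the cluster's cut-off index.
#' @return numeric in [0, 1].
#' @export
featureConfidence <- function(feature, rankedLists, cutoff) {
  hits <- vapply(rankedLists, function(l) {
    i <- match(feature, l$feature)
    !is.na(i) && l$rank[i] <= cutoff
  }, logical(1))
  mean(hits)
}

#' Consensus rankings for every cluster of an ensemble
#'
#' The aggregation stage of the pipeline: per cluster, ranks every model's
#' weight curve, finds the bin-and-rotate knee per model, truncates each
#' model's list at the cluster's median knee, and reduces the ensemble to
#' one \linkS4class{ConsensusRanking} by Robust Rank Aggregation.
#'
#' @param mappings list of \linkS4class{WeightMapping} from
#'   \code{\link{runEnsemble}}.
#' @param nBins bins for the knee search (default 10).
#' @return Named list of \linkS4class{ConsensusRanking}, one per cluster,
#'   with the cut-off table attached as attribute \code{"cutoffs"}.
#' @export
resvaeConsensus <- function(mappings, nBins = 10L) {
  stopifnot(length(mappings) >= 2L)
  cuts <- computeCutoffs(mappings, nBins = nBins)
  clusters <- rownames(mappings[[1]]@scores)
  n <- ncol(mappings[[1]]@scores)
  out <- lapply(clusters, function(cl) {
    lists <- lapply(mappings, rankFeatures, clusterId = cl)
    aggregateCluster(lists, n = n, clusterId = cl,
                     cutoff = cuts$perCluster[[cl]])
  })
  names(out) <- clusters
  attr(out, "cutoffs") <- cuts
  out
}

#' Meta-analysis by information content (MAIC) aggregation
#'
#' Iterative aggregation accommodating ranked and unranked lists grouped
#' into categories. Each list carries a weight (root-mean of its member
#' features' scores); each feature's score sums, over categories, the
#' maximum weighted contribution of any list in that category containing
#' it. Ranked lists contribute a linearly rank-weighted factor
#' 2 (n - rank + 1) / (n + 1) (mean 1 over the list); unranked lists
#' contribute 1. Iterated to convergence (max score change < 1e-6) or 100
#' iterations (warning, last iterate returned). Deterministic given the
#' input order.
#'
#' @param lists list of character vectors of feature ids (ordered when
#'   ranked).
#' @param categories character vector, one category per list (default:
#'   each list its own category).
#' @param ranked logical vector, one flag per list (default all TRUE).
#' @return Named numeric vector of feature scores, decreasing.
#' @export
maicAggregate <- function(lists, categories = NULL, ranked = NULL) {
  if (length(lists) == 0L || any(lengths(lists) == 0L))
    stop("maicAggregate: empty list input")
  m <- length(lists)
  if (is.null(categories)) categories <- paste0("cat", seq_len(m))
  if (is.null(ranked)) ranked <- rep(TRUE, m)
  stopifnot(length(categories) == m, length(ranked) == m)
  universe <- sort(unique(unlist(lists)))
  # per-list rank-weighting of each universe feature (0 = absent)
  D <- matrix(0, length(universe), m, dimnames = list(universe, NULL))
  for (j in seq_len(m)) {
    l <- lists[[j]]
    nl <- length(l)
    D[l, j] <- if (ranked[j]) 2 * (nl - seq_len(nl) + 1) / (nl + 1) else 1
  }
  catOf <- as.character(categories)
  w <- rep(1, m)
  s <- rep(1, length(universe))
  names(s) <- universe
  converged <- FALSE
  for (it in seq_len(100L)) {
    contrib <- sweep(D, 2, w, "*")
    sNew <- setNames(numeric(length(universe)), universe)
    for (ct in unique(catOf)) {
      cols <- which(catOf == ct)
      sNew <- sNew + apply(contrib[, cols, drop = FALSE], 1, max)
    }
    wNew <- vapply(seq_len(m), function(j)
      sqrt(mean(sNew[lists[[j]]])), numeric(1))
    if (max(abs(sNew - s)) < 1e-6) {
      s <- sNew; w <- wNew; converged <- TRUE; break
    }
    s <- sNew; w <- wNew
  }
  if (!converged)
    warning("maicAggregate: no convergence in 100 iterations; ",
            "returning the last iterate")
  sort(s, decreasing = TRUE)
}
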