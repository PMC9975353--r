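#' Mish activation
#'
#' The smooth self-regularizing activation x * tanh(softplus(x)), with
#' softplus evaluated in a numerically stable form so large |x| neither
#' overflows nor underflows.
#'
#' @param x numeric vector or matrix of finite values.
#' @return x * tanh(log(1 + exp(x))), same shape as \code{x}.
#' @examples
#' mish(0)      # 0
#' mish(1)      # 0.8650984
#' @export
mish <- function(x) {
  if (any(!is.finite(x))) stop("mish: non-finite input")
  x * tanh(softplus(x))
}

# stable softplus: log1p(exp(-|x|)) + max(x, 0)
softplus <- function(x) {
  pmax(x, 0) + log1p(exp(-abs(x)))
}

# derivative of mish wrt x: tanh(sp) + x * sech^2(sp) * sigmoid(x)
mishGrad <- function(x) {
  sp <- softplus(x)
  t <- tanh(sp)
  sig <- 1 / (1 + exp(-x))
  t + x * (1 - t * t) * sig
}

reluFun <- function(x) pmax(x, 0)
reluGrad <- function(x) (x > 0) * 1

activationFun <- function(name) switch(name, mish = mish, relu = reluFun)
activationGrad <- function(name) switch(name, mish = mishGrad, relu = reluGrad)

#' Smooth one-hot cluster labels
#'
#' Replaces each hard one-hot row y by (1 - eps) * y + eps / K, keeping row
#' sums at 1, so the latent gating never fully silences the other cluster
#' blocks and the model cannot become over-confident. Soft rows (partial
#' identities) already encode uncertainty and are left untouched.
#'
#' @param assignment a \linkS4class{ClusterAssignment}.
#' @param eps smoothing epsilon in [0, 1).
#' @return A \linkS4class{ClusterAssignment} with smoothed weights (soft,
#'   unless eps = 0 or there is a single cluster).
#' @examples
#' a <- hardAssignment(c("a", "b"))
#' clusterWeights(smoothLabels(a, 0.1))
#' @export
smoothLabels <- function(assignment, eps) {
  stopifnot(is(assignment, "ClusterAssignment"))
  if (!is.numeric(eps) || length(eps) != 1L || eps < 0 || eps >= 1)
    stop("smoothLabels: 'eps' must lie in [0, 1)")
  if (!assignment@isHard || eps == 0) return(assignment)
  w <- assignment@weights
  K <- ncol(w)
  w <- (1 - eps) * w + eps / K
  clusterAssignment(w)
}

#' Gate a latent vector by a cluster assignment row
#'
#' The latent space is partitioned into contiguous per-cluster blocks of
#' equal size u; block c of the sampled latent vector is multiplied by the
#' cell's (smoothed) assignment weight for cluster c. A hard assignment
#' therefore zeroes every block but the cell's own, giving each label its
#' own label-specific latent space; soft assignments open several blocks
#' in proportion to the partial identities.
#'
#' @param z numeric latent vector of length K * u (or a cells x (K * u)
#'   matrix, gated row-wise).
#' @param assignRow numeric vector of K assignment weights (or a matrix of
#'   rows aligned with \code{z}).
#' @param unitsPerCluster block size u.
#' @return The gated latent vector/matrix, same shape as \code{z}.
#' @examples
#' restrictLatent(rep(1, 4), c(1, 0), 2)   # 1 1 0 0
#' @export
restrictLatent <- function(z, assignRow, unitsPerCluster) {
  u <- as.integer(unitsPerCluster)
  if (is.matrix(z)) {
    if (!is.matrix(assignRow) || nrow(assignRow) != nrow(z))
      stop("restrictLatent: matrix z needs a row-aligned assignment matrix")
    if (ncol(assignRow) * u != ncol(z))
      stop("restrictLatent: latent length must equal n_clusters * u")
    mask <- assignRow[, rep(seq_len(ncol(assignRow)), each = u), drop = FALSE]
    return(z * mask)
  }
  if (length(assignRow) * u != length(z))
    stop("restrictLatent: latent length must equal n_clusters * u")
  z * rep(assignRow, each = u)
}

# block index map: list of latent index vectors, one per cluster
latentBlocks <- function(nClusters, unitsPerCluster) {
  lapply(seq_len(nClusters), function(c)
    ((c - 1L) * unitsPerCluster + 1L):(c * unitsPerCluster))
}

#' Restricted-VAE loss
#'
#' alpha * sum((x_in - x_rec)^2) + beta * KL, where KL is the Gaussian
#' divergence of the latent posterior N(mu, exp(logSigma)) from the prior
#' N(s, 1), with logSigma the log-variance:
#' KL = 1/2 * sum(exp(logSigma) + (s - mu)^2 - 1 - logSigma) >= 0.
#' With alpha = beta = 1 this is the standard VAE objective.
#'
#' @param xIn,xRec input and reconstruction vectors (same length).
#' @param mu,logSigma latent posterior mean and log-variance (same length).
#' @param s latent prior offset (scalar).
#' @param alpha reconstruction weight (> 0).
#' @param beta KL weight (>= 0).
#' @return Non-negative scalar loss.
#' @examples
#' vaeLoss(c(1), c(0), c(0), c(0), s = 0, alpha = 2, beta = 1)  # 2
#' @export
vaeLoss <- function(xIn, xRec, mu, logSigma, s = 0, alpha = 1, beta = 1) {
  if (length(xIn) != length(xRec))
    stop("vaeLoss: xIn and xRec lengths differ")
  if (length(mu) != length(logSigma))
    stop("vaeLoss: mu and logSigma lengths differ")
  vals <- c(xIn, xRec, mu, logSigma, s, alpha, beta)
  if (any(is.na(vals)) || any(!is.finite(vals)))
    stop("vaeLoss: NaN or non-finite input")
  if (alpha <= 0) stop("vaeLoss: alpha must be > 0")
  if (beta < 0) stop("vaeLoss: beta must be >= 0")
  rec <- sum((xIn - xRec)^2)
  kl <- 0.5 * sum(exp(logSigma) + (s - mu)^2 - 1 - logSigma)
  alpha * rec + beta * kl
}

# kernel init paired to the activation: He uniform for relu,
# Glorot (Xavier) uniform for the tanh-based mish
initKernel <- function(fanIn, fanOut, activation) {
  limit <- if (activation == "relu") sqrt(6 / fanIn)
           else sqrt(6 / (fanIn + fanOut))
  matrix(runif(fanIn * fanOut, -limit, limit), fanIn, fanOut)
}
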