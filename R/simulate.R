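#' Configuration of the synthetic regulatory-trajectory generators
#'
#' The bifurcation generator emulates a stochastic gene-regulatory
#' trajectory simulation: 7 cell populations (sA, sB, sBmid, sC, sD,
#' sEndC, sEndD) along a trunk that forks into two antagonistic branches,
#' 35 transcription factors grouped into named modules (Burn1-4, the
#' A-group, B1-B14 and D6) regulating 500 target genes, plus 20
#' unregulated housekeeping genes. Module activities are smooth truncated
#' Gaussian windows of pseudotime, branch-exclusive after the fork, and
#' counts are drawn negative-binomially.
#'
#' @param nCellsPerPopulation cells simulated per population (default 200,
#'   i.e. 1400 cells over the 7 bifurcation populations).
#' @param nTargets regulated target genes (default 500).
#' @param nHousekeeping unregulated constant-mean genes (default 20).
#' @param dispersion negative-binomial dispersion phi (> 0); the count
#'   variance is mu + phi * mu^2.
#' @param softBandwidth Gaussian kernel bandwidth (pseudotime units) of
#'   the soft archetype assignment.
#' @param nNoiseFeatures unregulated features added by
#'   \code{\link{simulateMyeloid}} beside its 11 regulators.
#' @param seed integer seed.
#' @return List of class \code{"SimulationConfig"}.
#' @export
simulationConfig <- function(nCellsPerPopulation = 200L, nTargets = 500L,
                             nHousekeeping = 20L, dispersion = 0.4,
                             softBandwidth = 0.45, nNoiseFeatures = 30L,
                             seed = 1L) {
  cfg <- list(nCellsPerPopulation = as.integer(nCellsPerPopulation),
              nTargets = as.integer(nTargets),
              nHousekeeping = as.integer(nHousekeeping),
              dispersion = as.numeric(dispersion),
              softBandwidth = as.numeric(softBandwidth),
              nNoiseFeatures = as.integer(nNoiseFeatures),
              seed = as.integer(seed))
  if (cfg$nCellsPerPopulation <= 0L || cfg$nTargets <= 0L ||
      cfg$nHousekeeping <= 0L)
    stop("simulationConfig: cell/feature counts must be positive")
  if (cfg$dispersion <= 0) stop("simulationConfig: dispersion must be > 0")
  if (cfg$softBandwidth <= 0) stop("simulationConfig: bandwidth must be > 0")
  structure(cfg, class = "SimulationConfig")
}

# module inventory: 35 TFs total
# Burn1-4 x2, A x3, B1-B9 x2, B10-B14 x1, D6 x1 = 8 + 3 + 18 + 5 + 1
bifurcationModules <- function() {
  sizes <- c(Burn1 = 2L, Burn2 = 2L, Burn3 = 2L, Burn4 = 2L, A = 3L,
             B1 = 2L, B2 = 2L, B3 = 2L, B4 = 2L, B5 = 2L, B6 = 2L,
             B7 = 2L, B8 = 2L, B9 = 2L, B10 = 1L, B11 = 1L, B12 = 1L,
             B13 = 1L, B14 = 1L, D6 = 1L)
  stopifnot(sum(sizes) == 35L)
  sizes
}

bifurcationPopulations <- function()
  c("sA", "sB", "sBmid", "sC", "sD", "sEndC", "sEndD")

# module x population activity amplitudes; >= 1 counts as "active" in the
# ground truth. C-branch modules (B2,B6,B9,B10,B11) and D-branch modules
# (B3,B7,B12,B13,B14,D6) are mutually exclusive after the fork; B8 is
# shared; terminal populations emphasise their modules more strongly than
# the pre-terminal ones.
bifurcationActivity <- function() {
  pops <- bifurcationPopulations()
  mods <- names(bifurcationModules())
  act <- matrix(0, length(mods), length(pops),
                dimnames = list(mods, pops))
  act[c("Burn1", "Burn2", "Burn3", "Burn4"), "sA"] <- 3
  act[c("Burn1", "Burn2", "Burn3", "Burn4"), "sB"] <- 0.8
  act[c("B4", "B5"), c("sA", "sB", "sBmid")] <- rep(c(2.5, 2, 0.5),
                                                    each = 2)
  act["A", c("sB", "sBmid")] <- c(3, 2.5)
  act["B1", c("sB", "sBmid")] <- c(2, 2.5)
  cMods <- c("B2", "B6", "B9", "B10", "B11")
  dMods <- c("B3", "B7", "B12", "B13", "B14")
  act[cMods, "sC"] <- 2;  act[cMods, "sEndC"] <- 3
  act[dMods, "sD"] <- 2;  act[dMods, "sEndD"] <- 3
  act["B8", c("sC", "sD")] <- 2
  act["B8", c("sEndC", "sEndD")] <- 2.5
  act["D6", c("sBmid", "sD", "sEndD")] <- c(0.6, 2, 2.5)
  act
}

# branch membership of each population: trunk populations are visible to
# every cell, branch populations only to cells on that branch
populationBranch <- function()
  c(sA = "trunk", sB = "trunk", sBmid = "trunk",
    sC = "C", sEndC = "C", sD = "D", sEndD = "D")

populationCenters <- function()
  c(sA = 0.5, sB = 1.5, sBmid = 2.5, sC = 3.5, sEndC = 4.5,
    sD = 3.5, sEndD = 4.5)

# truncated Gaussian pseudotime window (zero beyond 1.5 time units, so
# branch-terminal cells receive exactly zero trunk-module leakage)
activityWindow <- function(t, center, sigma = 0.45, cut = 1.5) {
  d <- abs(t - center)
  ifelse(d <= cut, exp(-d^2 / (2 * sigma^2)), 0)
}

# per-cell module activities given pseudotime and branch
moduleActivities <- function(t, branch) {
  act <- bifurcationActivity()
  centers <- populationCenters()
  popBranch <- populationBranch()
  n <- length(t)
  A <- matrix(0, n, nrow(act), dimnames = list(NULL, rownames(act)))
  for (pop in colnames(act)) {
    visible <- popBranch[pop] == "trunk" | branch == popBranch[pop]
    w <- activityWindow(t, centers[pop]) * visible
    A <- A + outer(w, act[, pop])
  }
  A
}

#' Simulate the bifurcating regulatory trajectory
#'
#' Places cells on pseudotime along sA -> sB -> sBmid, forking into
#' (sC -> sEndC) or (sD -> sEndD); computes smooth, branch-antagonistic
#' module activities; sets each transcription factor's mean from its
#' module's activity and each target gene's mean from a weighted sum of
#' its 1-3 regulators; draws negative-binomial counts; and returns hard
#' labels (by pseudotime segment), soft labels (normalized Gaussian
#' kernel similarity to the 7 population archetype centroids in
#' pseudotime x branch space) and the full regulatory ground truth.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @return List with \code{counts} (cells x features integer matrix),
#'   \code{hard} and \code{soft} (\linkS4class{ClusterAssignment}),
#'   \code{truth} (ground-truth list: featureType, activeModules,
#'   moduleOf, branchOf, edges), \code{pseudotime} and \code{branch}.
#' @examples
#' sim <- simulateBifurcation(simulationConfig(nCellsPerPopulation = 20))
#' dim(sim$counts)  # 140 x 555
#' @export
simulateBifurcation <- function(config = simulationConfig()) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  pops <- bifurcationPopulations()
  sizes <- bifurcationModules()
  nCells <- config$nCellsPerPopulation
  centers <- populationCenters()
  popBranch <- populationBranch()

  popLab <- rep(pops, each = nCells)
  t <- runif(length(popLab), centers[popLab] - 0.5, centers[popLab] + 0.5)
  branch <- unname(popBranch[popLab])
  branch[branch == "trunk"] <- "none"

  tfIds <- unlist(lapply(names(sizes), function(m)
    paste0("TF_", m, "_", seq_len(sizes[[m]]))))
  moduleOf <- rep(names(sizes), sizes)
  names(moduleOf) <- tfIds
  targetIds <- sprintf("target%03d", seq_len(config$nTargets))
  hkIds <- sprintf("hk%02d", seq_len(config$nHousekeeping))

  A <- moduleActivities(t, branch)                  # cells x modules
  tfScale <- 12
  tfMu <- tfScale * A[, moduleOf, drop = FALSE] + 0.2
  colnames(tfMu) <- tfIds

  # each target belongs to one regulatory module (mirroring the modular
  # TF -> target wiring of regulatory-network simulators) and is
  # regulated by 1-3 of that module's TFs with normalized positive
  # weights, so targets inherit the branch specificity of their module
  nReg <- sample(1:3, config$nTargets, replace = TRUE)
  targetModule <- sample(names(sizes), config$nTargets, replace = TRUE)
  edgeList <- vector("list", config$nTargets)
  targetScale <- 6
  tgMu <- matrix(0.2, length(t), config$nTargets,
                 dimnames = list(NULL, targetIds))
  tfActivity <- A[, moduleOf, drop = FALSE]         # activity of each TF
  for (j in seq_len(config$nTargets)) {
    modTfs <- tfIds[moduleOf == targetModule[j]]
    regs <- sample(modTfs, min(nReg[j], length(modTfs)))
    w <- runif(length(regs), 0.5, 1.5)
    w <- w / sum(w)
    tgMu[, j] <- tgMu[, j] +
      targetScale * as.vector(tfActivity[, match(regs, tfIds), drop = FALSE] %*% w)
    edgeList[[j]] <- data.frame(tf = regs, target = targetIds[j],
                                weight = w)
  }
  edges <- do.call(rbind, edgeList)

  hkMu <- matrix(rep(runif(config$nHousekeeping, 5, 15), each = length(t)),
                 length(t), config$nHousekeeping,
                 dimnames = list(NULL, hkIds))

  mu <- cbind(tfMu, tgMu, hkMu)
  phi <- config$dispersion
  counts <- matrix(rnbinom(length(mu), mu = as.vector(mu), size = 1 / phi),
                   nrow(mu), ncol(mu))
  dimnames(counts) <- list(sprintf("cell%04d", seq_len(nrow(mu))),
                           colnames(mu))

  hard <- hardAssignment(popLab, cellIds = rownames(counts))
  soft <- softArchetypeAssignment(t, branch, config$softBandwidth,
                                  rownames(counts))

  activity <- bifurcationActivity()
  activeModules <- lapply(pops, function(p)
    rownames(activity)[activity[, p] >= 1])
  names(activeModules) <- pops
  truth <- structure(list(
    featureType = setNames(rep(c("tf", "target", "housekeeping"),
                               c(length(tfIds), length(targetIds),
                                 length(hkIds))),
                           c(tfIds, targetIds, hkIds)),
    activeModules = activeModules,
    moduleOf = moduleOf,
    branchOf = c(Burn1 = "trunk", Burn2 = "trunk", Burn3 = "trunk",
                 Burn4 = "trunk", A = "trunk", B1 = "trunk", B4 = "trunk",
                 B5 = "trunk", B2 = "C", B6 = "C", B9 = "C", B10 = "C",
                 B11 = "C", B3 = "D", B7 = "D", B12 = "D", B13 = "D",
                 B14 = "D", D6 = "D", B8 = "shared"),
    edges = edges), class = "RegulatoryGroundTruth")

  list(counts = counts, hard = hard, soft = soft, truth = truth,
       pseudotime = t, branch = branch)
}

# soft assignment: Gaussian kernel similarity to the 7 archetype
# centroids in (pseudotime, branch-coordinate) space, rows normalized.
# The branch coordinate is 0 on the trunk and grows to +/-(t - 3) past
# the fork, so early branch cells stay close to the sBmid archetype.
softArchetypeAssignment <- function(t, branch, bandwidth, cellIds) {
  pops <- bifurcationPopulations()
  centers <- populationCenters()
  popBranch <- populationBranch()
  bcOf <- function(tt, br)
    ifelse(br == "C", pmax(tt - 3, 0), ifelse(br == "D", -pmax(tt - 3, 0), 0))
  cellBc <- bcOf(t, branch)
  centBc <- bcOf(centers, ifelse(popBranch == "trunk", "none", popBranch))
  W <- vapply(pops, function(p)
    exp(-((t - centers[p])^2 + (cellBc - centBc[p])^2) /
          (2 * bandwidth^2)), numeric(length(t)))
  W <- W / rowSums(W)
  rownames(W) <- cellIds
  clusterAssignment(W)
}

#' Simulate the myeloid-differentiation model
#'
#' A progenitor population (Prog) branching into four terminal fates --
#' megakaryocytes (Mk), erythrocytes (Ery), granulocytes (Granu) and
#' monocytes (Mono) -- expressed over the 11 regulatory features of the
#' classical myeloid gene-regulatory network (EKLF, Fli-1, GATA-1,
#' GATA-2, PU.1, cJun, EgrNab, C/EBPa, Gfi-1, SCL, FOG-1) plus unregulated
#' noise features. The fate-to-regulator ground truth encodes EKLF with
#' Ery, Fli-1 with Mk, GATA-1 with both Ery and Mk, PU.1/cJun/EgrNab/
#' C/EBPa with Mono, Gfi-1 with Granu, and the progenitor factors
#' GATA-2/SCL/FOG-1 with Prog (SCL and FOG-1 also with Ery).
#'
#' @param config a \code{\link{simulationConfig}};
#'   \code{nCellsPerPopulation} and \code{nNoiseFeatures} apply.
#' @return List with \code{counts}, \code{assignment} (hard
#'   \linkS4class{ClusterAssignment}) and \code{truth}.
#' @examples
#' sim <- simulateMyeloid(simulationConfig(nCellsPerPopulation = 30))
#' @export
simulateMyeloid <- function(config = simulationConfig()) {
  stopifnot(inherits(config, "SimulationConfig"))
  if (config$nCellsPerPopulation < 10L)
    stop("simulateMyeloid: need at least 10 cells per fate")
  set.seed(config$seed + 1L)
  regulators <- c("EKLF", "Fli-1", "GATA-1", "GATA-2", "PU.1", "cJun",
                  "EgrNab", "C/EBPa", "Gfi-1", "SCL", "FOG-1")
  fates <- c("Prog", "Ery", "Mk", "Granu", "Mono")
  assoc <- list(
    Prog = c("GATA-2", "SCL", "FOG-1"),
    Ery = c("EKLF", "GATA-1", "SCL", "FOG-1"),
    Mk = c("Fli-1", "GATA-1"),
    Granu = c("Gfi-1"),
    Mono = c("PU.1", "cJun", "EgrNab", "C/EBPa"))

  nCells <- config$nCellsPerPopulation
  popLab <- rep(fates, each = nCells)
  mu <- matrix(2, length(popLab), length(regulators),
               dimnames = list(NULL, regulators))
  for (f in fates)
    mu[popLab == f, assoc[[f]]] <- 25
  if (config$nNoiseFeatures > 0L) {
    noiseIds <- sprintf("noise%02d", seq_len(config$nNoiseFeatures))
    noiseMu <- matrix(rep(runif(config$nNoiseFeatures, 3, 10),
                          each = length(popLab)),
                      length(popLab), config$nNoiseFeatures,
                      dimnames = list(NULL, noiseIds))
    mu <- cbind(mu, noiseMu)
  }
  counts <- matrix(rnbinom(length(mu), mu = as.vector(mu),
                           size = 1 / config$dispersion),
                   nrow(mu), ncol(mu))
  dimnames(counts) <- list(sprintf("cell%04d", seq_len(nrow(mu))),
                           colnames(mu))
  assignment <- hardAssignment(popLab, cellIds = rownames(counts))
  truth <- structure(list(
    featureType = setNames(
      rep(c("tf", "housekeeping"),
          c(length(regulators), ncol(mu) - length(regulators))),
      colnames(mu)),
    activeModules = assoc,
    moduleOf = setNames(regulators, regulators),
    branchOf = NULL,
    edges = data.frame(tf = character(0), target = character(0),
                       weight = numeric(0))),
    class = "RegulatoryGroundTruth")
  list(counts = counts, assignment = assignment, truth = truth)
}

#' Split every cluster into two random partitions
#'
#' Diagnostic used to test identification consistency: each cluster's
#' cells are randomly halved into \code{<id>_1} and \code{<id>_2}
#' (sizes differing by at most 1), doubling the cluster count. Partitions
#' of a homogeneous cluster should later yield strongly overlapping
#' identified feature sets, while dissimilar clusters should not.
#'
#' @param assignment a hard \linkS4class{ClusterAssignment}.
#' @param seed integer seed making the halving reproducible.
#' @return A hard \linkS4class{ClusterAssignment} with doubled clusters.
#' @examples
#' a <- hardAssignment(rep(c("x", "y"), each = 4))
#' clusterIds(splitClusterPartitions(a, seed = 1))
#' @export
splitClusterPartitions <- function(assignment, seed = 0L) {
  stopifnot(is(assignment, "ClusterAssignment"))
  if (!assignment@isHard)
    stop("splitClusterPartitions: a hard assignment is required")
  set.seed(as.integer(seed))
  w <- assignment@weights
  labels <- colnames(w)[max.col(w)]
  out <- character(nrow(w))
  for (cl in colnames(w)) {
    idx <- which(labels == cl)
    if (length(idx) < 2L)
      stop("splitClusterPartitions: cluster '", cl, "' has < 2 cells")
    half <- sample(idx, ceiling(length(idx) / 2))
    out[half] <- paste0(cl, "_1")
    out[setdiff(idx, half)] <- paste0(cl, "_2")
  }
  hardAssignment(out, cellIds = rownames(w))
}
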