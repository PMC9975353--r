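#' Read a cells x features expression matrix
#'
#' Supports MatrixMarket MTX (with sibling \code{features.tsv} and
#' \code{barcodes.tsv} files, the usual genes-major layout transposed to
#' cells x features) and dense CSV/TSV (cells in rows, feature ids in the
#' header, cell ids in the first column).
#'
#' @param path file path (.mtx, .csv or .tsv/.txt).
#' @param format \code{"auto"} (by extension), \code{"mtx"} or
#'   \code{"csv"}.
#' @param featuresMajor for MTX: TRUE (default, 10x convention) when rows
#'   of the MTX are features; the result is transposed to cells x
#'   features.
#' @param dropZeroFeatures drop all-zero feature columns (with a message).
#' @return Numeric matrix, cells x features, with cell ids as rownames
#'   and unique feature ids as colnames (duplicates suffixed
#'   deterministically with .1, .2, ...).
#' @export
readMatrix <- function(path, format = c("auto", "mtx", "csv"),
                       featuresMajor = TRUE, dropZeroFeatures = FALSE) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "mtx") "mtx" else "csv"
  }
  if (format == "mtx") {
    m <- as.matrix(Matrix::readMM(path))
    dir <- dirname(path)
    fFile <- file.path(dir, "features.tsv")
    bFile <- file.path(dir, "barcodes.tsv")
    if (!file.exists(fFile) || !file.exists(bFile))
      stop("readMatrix: features.tsv / barcodes.tsv not found next to ", path)
    feats <- read.delim(fFile, header = FALSE)[[1]]
    cells <- read.delim(bFile, header = FALSE)[[1]]
    if (featuresMajor) m <- t(m)
    if (length(feats) != ncol(m))
      stop("readMatrix: feature id count (", length(feats),
           ") does not match matrix columns (", ncol(m), ")")
    if (length(cells) != nrow(m))
      stop("readMatrix: barcode count (", length(cells),
           ") does not match matrix rows (", nrow(m), ")")
    dimnames(m) <- list(cells, feats)
  } else {
    sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
    df <- read.table(path, header = TRUE, sep = sep, row.names = 1,
                     check.names = FALSE)
    m <- as.matrix(df)
    storage.mode(m) <- "double"
  }
  if (any(m < 0)) stop("readMatrix: negative expression values")
  colnames(m) <- make.unique(colnames(m), sep = ".")
  if (dropZeroFeatures) {
    zero <- colSums(m) == 0
    if (any(zero)) {
      message("readMatrix: dropping ", sum(zero), " all-zero features")
      m <- m[, !zero, drop = FALSE]
    }
  }
  m
}

#' Read cluster assignments
#'
#' Hard mode reads a two-column (cell, cluster) table into a one-hot
#' \linkS4class{ClusterAssignment}; soft mode reads a cell x cluster
#' numeric table (cell ids in the first column) and renormalizes each row
#' to sum 1, warning when any row deviates by more than 1e-3. When
#' \code{cellIds} is given, rows are re-ordered to match it and missing
#' cells are an error.
#'
#' @param path CSV/TSV path.
#' @param mode \code{"hard"} or \code{"soft"}.
#' @param cellIds optional cell ids (e.g. rownames of the expression
#'   matrix) used to align and validate the assignment.
#' @return A \linkS4class{ClusterAssignment}.
#' @export
readAssignments <- function(path, mode = c("hard", "soft"),
                            cellIds = NULL) {
  mode <- match.arg(mode)
  sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  if (mode == "hard") {
    df <- read.table(path, header = TRUE, sep = sep,
                     stringsAsFactors = FALSE)
    a <- hardAssignment(as.character(df[[2]]),
                        cellIds = as.character(df[[1]]))
  } else {
    df <- read.table(path, header = TRUE, sep = sep, row.names = 1,
                     check.names = FALSE)
    w <- as.matrix(df)
    storage.mode(w) <- "double"
    rs <- rowSums(w)
    if (any(abs(rs - 1) > 1e-3))
      warning("readAssignments: ", sum(abs(rs - 1) > 1e-3),
              " row sums deviate from 1 by > 1e-3; renormalizing")
    a <- clusterAssignment(w / rs)
  }
  if (!is.null(cellIds)) {
    w <- clusterWeights(a)
    missing <- setdiff(cellIds, rownames(w))
    if (length(missing))
      stop("readAssignments: cells missing from the assignment: ",
           paste(head(missing, 10), collapse = ", "),
           if (length(missing) > 10) " ...")
    a <- clusterAssignment(w[cellIds, , drop = FALSE])
  }
  a
}

#' Write a simulation (or any counts + labels) to disk
#'
#' Writes the counts as MatrixMarket MTX (features major, with
#' features.tsv and barcodes.tsv), the hard labels as a two-column CSV
#' and any soft weights as a cell x cluster CSV.
#'
#' @param counts cells x features matrix.
#' @param dir output directory (created).
#' @param hard optional hard \linkS4class{ClusterAssignment}.
#' @param soft optional soft \linkS4class{ClusterAssignment}.
#' @return Invisibly, the directory.
#' @export
writeCounts <- function(counts, dir, hard = NULL, soft = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- asCellByFeature(counts)
  Matrix::writeMM(Matrix::Matrix(t(m), sparse = TRUE),
                  file.path(dir, "matrix.mtx"))
  write.table(colnames(m), file.path(dir, "features.tsv"),
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  write.table(rownames(m), file.path(dir, "barcodes.tsv"),
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  if (!is.null(hard)) {
    w <- clusterWeights(hard)
    df <- data.frame(cell = rownames(w),
                     cluster = colnames(w)[max.col(w)])
    write.csv(df, file.path(dir, "labels.csv"), row.names = FALSE,
              quote = FALSE)
  }
  if (!is.null(soft)) {
    w <- clusterWeights(soft)
    write.csv(data.frame(cell = rownames(w), w, check.names = FALSE),
              file.path(dir, "soft_labels.csv"), row.names = FALSE,
              quote = FALSE)
  }
  invisible(dir)
}

#' Write consensus rankings to TSV files
#'
#' One TSV per cluster with columns feature, rho, corrected, score,
#' confidence, nModels, plus a cut-off table TSV when available.
#'
#' @param consensus named list of \linkS4class{ConsensusRanking}.
#' @param dir output directory (created).
#' @return Invisibly, the directory.
#' @export
writeConsensus <- function(consensus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (cl in names(consensus)) {
    fn <- file.path(dir, paste0("consensus_", gsub("[^A-Za-z0-9_.-]", "_", cl),
                                ".tsv"))
    write.table(consensusTable(consensus[[cl]]), fn, sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  cuts <- attr(consensus, "cutoffs")
  if (!is.null(cuts))
    write.table(cuts$perModel, file.path(dir, "cutoffs.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  invisible(dir)
}
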