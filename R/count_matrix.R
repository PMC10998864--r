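#' Construct a cell-by-feature count matrix
#'
#' The basic container used throughout the package: a sparse, non-negative
#' cell x feature matrix of raw counts tagged with its modality, plus
#' optional per-cell labels and, for chromatin (ATAC) data, genomic
#' intervals parsed from the feature names.
#'
#' @param values numeric matrix or \code{Matrix::sparseMatrix}, cells in
#'   rows, features in columns; entries must be non-negative.
#' @param cell_ids character vector of length \code{nrow(values)}.
#' @param feature_ids character vector of length \code{ncol(values)}.
#' @param modality one of \code{"rna"}, \code{"atac"}, \code{"adt"}.
#' @param cell_labels optional per-cell type labels (length = cells).
#' @param batch_labels optional per-cell batch labels (length = cells).
#'
#' @return An object of class \code{count_matrix}: a list with the fields
#'   above plus \code{feature_intervals} (a data frame with columns
#'   \code{chrom}, \code{start}, \code{end}, one row per feature, NA where
#'   the feature id does not look like a genomic interval; only populated
#'   for ATAC data).
#' @export
count_matrix <- function(values, cell_ids = NULL, feature_ids = NULL,
                         modality = c("rna", "atac", "adt"),
                         cell_labels = NULL, batch_labels = NULL) {
  modality <- match.arg(modality)
  values <- methods::as(methods::as(Matrix::Matrix(values, sparse = TRUE), "generalMatrix"), "CsparseMatrix")
  if (any(values@x < 0)) stop("count_matrix: negative entries are not allowed")
  n <- nrow(values); p <- ncol(values)
  if (is.null(cell_ids)) cell_ids <- rownames(values)
  if (is.null(cell_ids)) cell_ids <- paste0("cell_", seq_len(n))
  if (is.null(feature_ids)) feature_ids <- colnames(values)
  if (is.null(feature_ids)) feature_ids <- paste0("feature_", seq_len(p))
  if (length(cell_ids) != n)
    stop("count_matrix: ", length(cell_ids), " cell ids for ", n, " rows")
  if (length(feature_ids) != p)
    stop("count_matrix: ", length(feature_ids), " feature ids for ", p, " columns")
  for (lab in list(cell_labels = cell_labels, batch_labels = batch_labels)) NULL
  if (!is.null(cell_labels) && length(cell_labels) != n)
    stop("count_matrix: cell_labels must have length ", n)
  if (!is.null(batch_labels) && length(batch_labels) != n)
    stop("count_matrix: batch_labels must have length ", n)
  dimnames(values) <- NULL
  intervals <- NULL
  if (modality == "atac") intervals <- parse_feature_intervals(feature_ids)
  structure(list(values = values,
                 cell_ids = as.character(cell_ids),
                 feature_ids = as.character(feature_ids),
                 modality = modality,
                 cell_labels = if (is.null(cell_labels)) NULL else as.character(cell_labels),
                 batch_labels = if (is.null(batch_labels)) NULL else as.character(batch_labels),
                 feature_intervals = intervals),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d cells x %d features, modality = %s\n",
              nrow(x$values), ncol(x$values), x$modality))
  if (!is.null(x$cell_labels))
    cat("  cell labels:", paste(utils::head(unique(x$cell_labels), 6), collapse = ", "),
        if (length(unique(x$cell_labels)) > 6) "..." else "", "\n")
  nz <- length(x$values@x)
  cat(sprintf("  nonzero entries: %d (%.1f%%)\n", nz,
              100 * nz / prod(dim(x$values))))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$values)

# Parse "chr1:100-200" / "chr1-100-200" style feature ids into a chrom/start/end
# data frame; rows that do not match either dialect are left NA. Coordinates
# are kept verbatim (no 0/1-based adjustment).
parse_feature_intervals <- function(feature_ids) {
  out <- data.frame(chrom = NA_character_, start = NA_real_, end = NA_real_,
                    stringsAsFactors = FALSE)[rep(1, length(feature_ids)), , drop = FALSE]
  rownames(out) <- NULL
  m <- regmatches(feature_ids,
                  regexec("^([A-Za-z0-9_.]+)[:-]([0-9]+)-([0-9]+)$", feature_ids))
  hit <- vapply(m, length, integer(1)) == 4L
  if (any(hit)) {
    parts <- do.call(rbind, m[hit])
    out$chrom[hit] <- parts[, 2]
    out$start[hit] <- as.numeric(parts[, 3])
    out$end[hit] <- as.numeric(parts[, 4])
  }
  out
}

#' Read a count matrix from disk
#'
#' Supported layouts: \code{"mtx_dir"}, a directory holding
#' \code{matrix.mtx} plus \code{features.tsv} and \code{barcodes.tsv}
#' (features-by-cells orientation, the common sparse triplet convention;
#' a cells-by-features matrix is detected and handled via the id lengths);
#' \code{"csv"}, cells in rows with a header of feature names and the cell
#' id in the first column; and \code{"h5ad"}, converted through the
#' \code{python} \code{anndata} module on the PATH (an error is raised when
#' that is unavailable).
#'
#' @param path file (csv, h5ad) or directory (mtx_dir).
#' @param fmt one of \code{"mtx_dir"}, \code{"h5ad"}, \code{"csv"}.
#' @param modality modality tag for the returned object.
#' @inheritParams count_matrix
#' @return A [count_matrix()].
#' @export
load_count_matrix <- function(path, fmt = c("mtx_dir", "h5ad", "csv"),
                              modality = c("rna", "atac", "adt")) {
  fmt <- match.arg(fmt)
  modality <- match.arg(modality)
  if (!file.exists(path)) stop("load_count_matrix: path does not exist: ", path)
  switch(fmt,
    mtx_dir = read_mtx_dir(path, modality),
    csv = read_count_csv(path, modality),
    h5ad = read_h5ad(path, modality))
}

read_mtx_dir <- function(path, modality) {
  mtx <- file.path(path, "matrix.mtx")
  feat <- file.path(path, "features.tsv")
  barc <- file.path(path, "barcodes.tsv")
  for (f in c(mtx, feat, barc))
    if (!file.exists(f)) stop("load_count_matrix: missing file ", f)
  m <- tryCatch(Matrix::readMM(mtx),
                error = function(e) stop("load_count_matrix: malformed MTX file ",
                                         mtx, ": ", conditionMessage(e)))
  features <- readLines(feat)
  features <- vapply(strsplit(features, "\t"), `[`, character(1), 1L)
  barcodes <- readLines(barc)
  if (nrow(m) == length(features) && ncol(m) == length(barcodes)) {
    m <- Matrix::t(m)                       # features x cells -> cells x features
  } else if (nrow(m) == length(barcodes) && ncol(m) == length(features)) {
    # already cells x features
  } else {
    stop(sprintf(paste0("load_count_matrix: matrix is %d x %d but there are ",
                        "%d features and %d barcodes"),
                 nrow(m), ncol(m), length(features), length(barcodes)))
  }
  count_matrix(m, cell_ids = barcodes, feature_ids = features, modality = modality)
}

read_count_csv <- function(path, modality) {
  lines <- readLines(path)
  if (length(lines) < 2) stop("load_count_matrix: csv has no data rows")
  header <- strsplit(lines[1], ",")[[1]]
  feats <- header[-1]
  rows <- strsplit(lines[-1], ",")
  n <- length(rows)
  vals <- matrix(0, n, length(feats))
  ids <- character(n)
  for (i in seq_len(n)) {
    r <- rows[[i]]
    if (length(r) != length(feats) + 1L)
      stop("load_count_matrix: line ", i + 1L, " has ", length(r),
           " fields, expected ", length(feats) + 1L)
    ids[i] <- r[1]
    v <- suppressWarnings(as.numeric(r[-1]))
    if (anyNA(v))
      stop("load_count_matrix: non-numeric value on line ", i + 1L, ": '",
           r[-1][which(is.na(v))[1]], "'")
    vals[i, ] <- v
  }
  count_matrix(vals, cell_ids = ids, feature_ids = feats, modality = modality)
}

read_h5ad <- function(path, modality) {
  py <- Sys.which("python")
  if (!nzchar(py))
    stop("load_count_matrix: reading h5ad requires a 'python' with the anndata ",
         "module on the PATH; convert the file to an MTX directory instead")
  tmp <- tempfile("h5ad2mtx_")
  dir.create(tmp)
  script <- paste(
    "import sys, anndata, scipy.io, scipy.sparse, numpy as np",
    "ad = anndata.read_h5ad(sys.argv[1])",
    "X = scipy.sparse.csr_matrix(ad.X)",
    "scipy.io.mmwrite(sys.argv[2] + '/matrix.mtx', X.T)",
    "open(sys.argv[2] + '/features.tsv', 'w').write('\\n'.join(map(str, ad.var_names)) + '\\n')",
    "open(sys.argv[2] + '/barcodes.tsv', 'w').write('\\n'.join(map(str, ad.obs_names)) + '\\n')",
    sep = "; ")
  status <- system2(py, c("-c", shQuote(script), shQuote(path), shQuote(tmp)),
                    stdout = TRUE, stderr = TRUE)
  if (!is.null(attr(status, "status")))
    stop("load_count_matrix: h5ad conversion failed: ",
         paste(status, collapse = "\n"))
  out <- read_mtx_dir(tmp, modality)
  unlink(tmp, recursive = TRUE)
  out
}

#' Write a count matrix as an MTX triplet directory
#'
#' Writes \code{matrix.mtx} (features x cells), \code{features.tsv} and
#' \code{barcodes.tsv}, the layout [load_count_matrix()] reads back.
#'
#' @param x a [count_matrix()].
#' @param path directory to create.
#' @return \code{path}, invisibly.
#' @export
write_count_matrix <- function(x, path) {
  stopifnot(inherits(x, "count_matrix"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::t(x$values), file.path(path, "matrix.mtx"))
  writeLines(x$feature_ids, file.path(path, "features.tsv"))
  writeLines(x$cell_ids, file.path(path, "barcodes.tsv"))
  if (!is.null(x$cell_labels))
    writeLines(x$cell_labels, file.path(path, "cell_labels.tsv"))
  invisible(path)
}
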