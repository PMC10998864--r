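#' Pre-process RNA counts: depth normalisation, log1p, HVG selection
#'
#' Scales every cell's counts so its total equals the median of the
#' pre-normalisation totals, applies \code{log(1 + x)}, and keeps the
#' \code{n_hvg} most highly variable genes, ranked by mean-binned
#' normalised dispersion on the logged matrix (the standard
#' highly-variable-gene procedure: genes are binned into 20
#' equal-frequency bins by mean expression and dispersions are z-scored
#' within each bin).
#'
#' @param raw a [count_matrix()] with \code{modality = "rna"}.
#' @param n_hvg number of highly variable genes to keep (default 3000,
#'   capped at the number of genes).
#' @return An object of class \code{processed_matrix}: list with
#'   \code{values} (dense cells x genes), \code{modality},
#'   \code{transform_log}, \code{selected_features} (column indices into
#'   the raw matrix), \code{feature_ids}, \code{cell_ids}, \code{cell_labels}.
#' @export
preprocess_rna <- function(raw, n_hvg = 3000) {
  stopifnot(inherits(raw, "count_matrix"))
  if (raw$modality != "rna") stop("preprocess_rna: modality is ", raw$modality)
  x <- as.matrix(raw$values)
  totals <- rowSums(x)
  if (any(totals == 0))
    stop("preprocess_rna: cells with zero total count (filter them first): ",
         paste(raw$cell_ids[totals == 0], collapse = ", "))
  if (n_hvg < 1) stop("preprocess_rna: n_hvg must be positive")
  n_hvg <- min(n_hvg, ncol(x))
  med <- stats::median(totals)
  xn <- x * (med / totals)
  xl <- log1p(xn)
  keep <- sort(rank_hvg(xl)[seq_len(n_hvg)])
  structure(list(values = xl[, keep, drop = FALSE],
                 modality = "rna",
                 transform_log = list(
                   list(step = "normalize_total", target = med),
                   list(step = "log1p"),
                   list(step = "select_hvg", n_hvg = n_hvg,
                        method = "binned_normalized_dispersion", n_bins = 20L)),
                 selected_features = keep,
                 feature_ids = raw$feature_ids[keep],
                 cell_ids = raw$cell_ids,
                 cell_labels = raw$cell_labels),
            class = "processed_matrix")
}

# Gene order by decreasing normalized dispersion (ties by column order).
# Dispersion = var/mean of the logged values; z-scored within 20
# equal-frequency mean bins (degenerate bins score 0).
rank_hvg <- function(xl) {
  mu <- colMeans(xl)
  v <- apply(xl, 2, stats::var)
  disp <- ifelse(mu > 0, v / mu, 0)
  nb <- min(20L, length(unique(mu)))
  bins <- if (nb < 2) rep(1L, length(mu)) else
    cut(rank(mu, ties.method = "first"), breaks = nb, labels = FALSE)
  norm_disp <- disp
  for (b in unique(bins)) {
    idx <- which(bins == b)
    s <- stats::sd(disp[idx])
    m <- mean(disp[idx])
    norm_disp[idx] <- if (is.na(s) || s == 0) 0 else (disp[idx] - m) / s
  }
  # ties in the normalised score (degenerate bins) fall back to raw dispersion
  order(norm_disp, disp, decreasing = TRUE)
}

#' Pre-process ATAC counts: binarise, filter rare peaks, TF-IDF, scale
#'
#' Counts are binarised (any positive entry becomes 1), peaks open in
#' strictly fewer than \code{min_cell_frac} of cells are removed, and the
#' remaining matrix is TF-IDF transformed: \code{TF[i,j] = bin[i,j] /
#' rowsum_i}, \code{IDF[j] = log(1 + n / colsum_j)} (natural log). The
#' TF-IDF product is divided by its global maximum \code{S} so values lie
#' in [0, 1]. The returned \code{tfidf_model} retains everything needed to
#' invert the transform with [recover_atac_counts()].
#'
#' @param raw a [count_matrix()] with \code{modality = "atac"}.
#' @param min_cell_frac rare-peak threshold as a fraction of cells
#'   (default 0.005, i.e. peaks active in < 0.5\% of cells are dropped).
#' @return list with \code{processed} (a \code{processed_matrix}) and
#'   \code{tfidf} (a \code{tfidf_model}: \code{idf}, \code{scale_S},
#'   \code{cell_totals}, \code{kept_features}).
#' @export
preprocess_atac <- function(raw, min_cell_frac = 0.005) {
  stopifnot(inherits(raw, "count_matrix"))
  if (raw$modality != "atac") stop("preprocess_atac: modality is ", raw$modality)
  xb <- as.matrix(raw$values > 0) * 1
  n <- nrow(xb)
  active <- colSums(xb)
  keep <- which(active >= min_cell_frac * n & active > 0)
  if (length(keep) == 0) stop("preprocess_atac: no peaks pass the filter")
  xb <- xb[, keep, drop = FALSE]
  totals <- rowSums(xb)
  if (any(totals == 0))
    stop("preprocess_atac: cells with no open peaks after filtering: ",
         paste(raw$cell_ids[totals == 0], collapse = ", "))
  idf <- log(1 + n / colSums(xb))
  tfidf <- (xb / totals) * rep(idf, each = n)
  S <- max(tfidf)
  structure(list(
    processed = structure(list(values = tfidf / S,
                               modality = "atac",
                               transform_log = list(
                                 list(step = "binarize"),
                                 list(step = "filter_peaks", min_cell_frac = min_cell_frac),
                                 list(step = "tfidf", scale_S = S)),
                               selected_features = keep,
                               feature_ids = raw$feature_ids[keep],
                               cell_ids = raw$cell_ids,
                               cell_labels = raw$cell_labels),
                          class = "processed_matrix"),
    tfidf = structure(list(idf = idf, scale_S = S, cell_totals = totals,
                           kept_features = keep),
                      class = "tfidf_model")),
    class = "atac_preprocessing")
}

#' Pre-process ADT counts with the centered log-ratio transform
#'
#' Per cell, with \code{x' = x + pseudocount}, returns
#' \code{log(x'_j / geometric_mean(x'))}; each row then sums to zero.
#'
#' @param raw a [count_matrix()] with \code{modality = "adt"}.
#' @param pseudocount positive offset added to the counts before the
#'   transform (default 1; the raw transform is undefined at zero counts).
#' @return a \code{processed_matrix}.
#' @export
preprocess_adt <- function(raw, pseudocount = 1) {
  stopifnot(inherits(raw, "count_matrix"))
  if (raw$modality != "adt") stop("preprocess_adt: modality is ", raw$modality)
  if (pseudocount <= 0) stop("preprocess_adt: pseudocount must be positive")
  x <- as.matrix(raw$values) + pseudocount
  lx <- log(x)
  clr <- lx - rowMeans(lx)
  structure(list(values = clr,
                 modality = "adt",
                 transform_log = list(list(step = "clr", pseudocount = pseudocount)),
                 selected_features = seq_len(ncol(x)),
                 feature_ids = raw$feature_ids,
                 cell_ids = raw$cell_ids,
                 cell_labels = raw$cell_labels),
            class = "processed_matrix")
}

#' @export
print.processed_matrix <- function(x, ...) {
  steps <- vapply(x$transform_log, function(s) s$step, character(1))
  cat(sprintf("<processed_matrix> %d cells x %d features (%s); transforms: %s\n",
              nrow(x$values), ncol(x$values), x$modality,
              paste(steps, collapse = " -> ")))
  invisible(x)
}

#' Group ATAC peaks by chromosome
#'
#' Parses peak names of the form \code{"chr1:100-200"} (or with dashes
#' throughout) and groups feature indices by chromosome in order of first
#' appearance. Peaks whose names match neither dialect are collected in a
#' catch-all group. The grouping drives the per-chromosome blocks of the
#' ATAC encoder/decoder, which carry no cross-chromosome weights.
#'
#' @param feature_ids character vector of peak names (post-filtering).
#' @param allow_single_group if all names are unparseable, fall back to a
#'   single group containing every peak instead of raising an error.
#' @return An object of class \code{chromosome_index}: list with
#'   \code{groups} (named list of integer index vectors) and
#'   \code{catch_all} (integer vector, possibly empty).
#' @export
group_peaks_by_chromosome <- function(feature_ids, allow_single_group = FALSE) {
  iv <- parse_feature_intervals(feature_ids)
  parseable <- !is.na(iv$chrom)
  if (!any(parseable)) {
    if (allow_single_group)
      return(structure(list(groups = list(all = seq_along(feature_ids)),
                            catch_all = integer(0)),
                       class = "chromosome_index"))
    stop("group_peaks_by_chromosome: no feature name parses as 'chrom:start-end'; ",
         "use allow_single_group = TRUE to treat all peaks as one group")
  }
  chroms <- unique(iv$chrom[parseable])
  groups <- lapply(chroms, function(ch) which(!is.na(iv$chrom) & iv$chrom == ch))
  names(groups) <- chroms
  structure(list(groups = groups, catch_all = which(!parseable)),
            class = "chromosome_index")
}

# All feature groups of a chromosome index, catch-all included, as the
# encoder/decoder consume them.
chrom_index_groups <- function(ci) {
  g <- ci$groups
  if (length(ci$catch_all) > 0) g <- c(g, list(.catch_all = ci$catch_all))
  g
}
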