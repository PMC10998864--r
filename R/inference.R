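#' Translate a whole dataset with a trained model
#'
#' Deterministic forward pass (no masking, no dropout, mean latent path)
#' over mini-batches; batching does not change the result. Predicted RNA
#' and ATAC values below 1e-4 are set to zero to mirror the sparsity of
#' real profiles; ADT predictions are left untouched (CLR values are
#' signed).
#'
#' @param model a \code{dualvae_model}.
#' @param values cells x features matrix of processed source-modality data.
#' @param direction \code{"x2y"} or \code{"y2x"}.
#' @param batch_size forward batch size (purely a memory knob).
#' @param threshold sparsity threshold (default 1e-4); applied only to
#'   RNA/ATAC targets.
#' @return An object of class \code{predicted_matrix}: list with
#'   \code{values}, \code{direction}, \code{thresholded},
#'   \code{target_type}, \code{feature_ids}.
#' @export
translate_dataset <- function(model, values, direction = c("x2y", "y2x"),
                              batch_size = 512, threshold = 1e-4) {
  direction <- match.arg(direction)
  values <- as.matrix(values)
  src <- if (direction == "x2y") "x" else "y"
  tgt <- if (direction == "x2y") "y" else "x"
  if (ncol(values) != model$sides[[src]]$dim)
    stop("translate_dataset: input has ", ncol(values),
         " features but the ", src, " side expects ", model$sides[[src]]$dim)
  n <- nrow(values)
  out <- matrix(0, n, model$sides[[tgt]]$dim)
  starts <- seq(1, n, by = batch_size)
  for (s in starts) {
    idx <- s:min(s + batch_size - 1, n)
    out[idx, ] <- vae_translate(model, values[idx, , drop = FALSE], src, tgt)
  }
  tgt_type <- model$sides[[tgt]]$type
  thresholded <- tgt_type %in% c("rna", "atac")
  if (thresholded) out[out < threshold] <- 0
  structure(list(values = out, direction = direction, thresholded = thresholded,
                 target_type = tgt_type,
                 feature_ids = model$sides[[tgt]]$feature_ids),
            class = "predicted_matrix")
}

#' @export
print.predicted_matrix <- function(x, ...) {
  cat(sprintf("<predicted_matrix> %d cells x %d features (%s, %s)%s\n",
              nrow(x$values), ncol(x$values), x$direction, x$target_type,
              if (x$thresholded) ", sparsity-thresholded" else ""))
  invisible(x)
}

#' Recover a binarised ATAC count matrix from a prediction
#'
#' Inverts the TF-IDF pre-processing:
#' \code{count[i, j] = pred[i, j] * S / idf[j] * total_i}, where the
#' per-cell totals are the binarised row sums from the test cells' own raw
#' ATAC when available; for translated cells with no measured ATAC the
#' median of the training totals is used for every cell (flagged in the
#' result). The count matrix is then binarised: an entry becomes 1 iff it
#' strictly exceeds both its row mean and its column mean of the recovered
#' counts.
#'
#' @param pred a \code{predicted_matrix} whose target is ATAC (or a plain
#'   matrix of scaled TF-IDF values).
#' @param tfidf the \code{tfidf_model} from [preprocess_atac()].
#' @param cell_totals optional per-cell binarised peak totals for the
#'   predicted cells; default NULL falls back to the scalar median of
#'   \code{tfidf$cell_totals}.
#' @param binarize return the thresholded binary matrix (default TRUE);
#'   FALSE returns the raw recovered counts.
#' @return matrix; attribute \code{totals_source} records whether measured
#'   totals or the training median were used.
#' @export
recover_atac_counts <- function(pred, tfidf, cell_totals = NULL, binarize = TRUE) {
  stopifnot(inherits(tfidf, "tfidf_model"))
  v <- if (inherits(pred, "predicted_matrix")) pred$values else as.matrix(pred)
  if (ncol(v) != length(tfidf$idf))
    stop("recover_atac_counts: prediction has ", ncol(v),
         " features but the TF-IDF model keeps ", length(tfidf$idf))
  totals_source <- "supplied"
  if (is.null(cell_totals)) {
    if (length(tfidf$cell_totals) == nrow(v)) {
      cell_totals <- tfidf$cell_totals
      totals_source <- "measured"
    } else {
      cell_totals <- rep(stats::median(tfidf$cell_totals), nrow(v))
      totals_source <- "training_median"
    }
  }
  stopifnot(length(cell_totals) == nrow(v))
  counts <- v * tfidf$scale_S / rep(tfidf$idf, each = nrow(v)) * cell_totals
  if (!binarize) {
    attr(counts, "totals_source") <- totals_source
    return(counts)
  }
  rm_ <- rowMeans(counts); cm_ <- colMeans(counts)
  out <- (counts > rm_ & counts > rep(cm_, each = nrow(counts))) * 1
  attr(out, "totals_source") <- totals_source
  out
}

#' Chain two trained translators
#'
#' Runs \code{model_1} then \code{model_2} (e.g. ATAC -> RNA -> ADT),
#' checking that the intermediate feature list of the first model matches
#' the source features of the second.
#'
#' @param model_1,model_2 trained \code{dualvae_model}s.
#' @param values processed source data for \code{model_1}.
#' @param directions character vector of length 2, each \code{"x2y"} or
#'   \code{"y2x"}.
#' @return a \code{predicted_matrix} from the second stage, with the
#'   intermediate stage attached as attribute \code{intermediate}.
#' @export
chain_translate <- function(model_1, model_2, values,
                            directions = c("x2y", "x2y")) {
  stopifnot(length(directions) == 2)
  mid <- translate_dataset(model_1, values, directions[1])
  src2 <- if (directions[2] == "x2y") "x" else "y"
  f1 <- mid$feature_ids
  f2 <- model_2$sides[[src2]]$feature_ids
  if (!is.null(f1) && !is.null(f2) && !identical(f1, f2)) {
    missing <- setdiff(f2, f1)
    stop("chain_translate: stage-2 source features do not match stage-1 output",
         if (length(missing)) paste0("; missing: ",
                                     paste(utils::head(missing, 5), collapse = ", "),
                                     if (length(missing) > 5) ", ..." else "") else "")
  }
  if (ncol(mid$values) != model_2$sides[[src2]]$dim)
    stop("chain_translate: stage-1 output width ", ncol(mid$values),
         " does not match stage-2 source dimension ", model_2$sides[[src2]]$dim)
  out <- translate_dataset(model_2, mid$values, directions[2])
  attr(out, "intermediate") <- mid
  out
}
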