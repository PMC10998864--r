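#' Fit a dual-VAE cross-modality translator
#'
#' The one-stop fitting interface: pre-processes the two modalities,
#' optionally augments the training pairs by cell type or by derived
#' clusters, pretrains each modality's autoencoder stack, and runs the
#' integrative adversarial training phase.
#'
#' @param x,y paired [count_matrix()] objects over the same cells (any of
#'   rna/atac/adt, or rna/rna for control vs stimulated), or
#'   already-processed \code{processed_matrix} objects.
#' @param augment training-set augmentation: \code{"none"} (originals
#'   only), \code{"type"} (two rounds of within-cell-type shuffling,
#'   tripling the training set; needs cell labels), or \code{"cluster"}
#'   (same, with labels from [derive_cluster_labels()]).
#' @param cell_types per-cell labels for \code{augment = "type"}
#'   (default: the labels carried by \code{x}).
#' @param pairs optional pre-built [paired_dataset()] (e.g. from
#'   [pair_unpaired_by_type()] or [ot_pair_perturbation()]); overrides
#'   \code{augment}.
#' @param config a [dualvae_config()].
#' @param n_hvg,min_cell_frac pre-processing parameters passed to
#'   [preprocess_rna()] / [preprocess_atac()].
#' @param seed integer seed controlling every stochastic step.
#' @param pretrain_epochs,train_epochs optional caps overriding the
#'   config (useful for quick runs).
#' @return An object of class \code{dualvae}: list with \code{model},
#'   \code{processed} (both sides plus the ATAC TF-IDF state),
#'   \code{pairs}, \code{logs}, \code{seed}, \code{call}.
#' @examples
#' sim <- simulate_paired_multiome(n_cells = 120, n_genes = 60, n_peaks = 90,
#'                                 n_types = 3, seed = 1)
#' fit <- dualvae(sim$rna, sim$atac, augment = "type",
#'                config = dualvae_config(batch_size = 32),
#'                seed = 1, pretrain_epochs = 3, train_epochs = 3)
#' pred <- predict(fit, direction = "x2y")
#' @export
dualvae <- function(x, y, augment = c("none", "type", "cluster"),
                    cell_types = NULL, pairs = NULL,
                    config = dualvae_config(), n_hvg = 3000,
                    min_cell_frac = 0.005, seed = 1,
                    pretrain_epochs = NULL, train_epochs = NULL) {
  augment <- match.arg(augment)
  cl <- match.call()
  set.seed(seed)
  px <- prepare_side_data(x, n_hvg, min_cell_frac)
  py <- prepare_side_data(y, n_hvg, min_cell_frac)
  n <- nrow(px$processed$values)
  if (nrow(py$processed$values) != n && is.null(pairs))
    stop("dualvae: x and y have different cell counts and no explicit pairs")

  if (is.null(pairs)) {
    if (augment == "none") {
      pairs <- paired_dataset(seq_len(n), seq_len(n))
    } else {
      labels <- if (augment == "cluster") {
        derive_cluster_labels(px$processed, py$processed)
      } else {
        if (is.null(cell_types)) cell_types <- px$processed$cell_labels
        if (is.null(cell_types))
          stop("dualvae: augment = 'type' needs cell_types (or labels on x)")
        cell_types
      }
      pairs <- augment_by_label(n, labels)
    }
  }

  side_x <- build_side_from_processed(px$processed)
  side_y <- build_side_from_processed(py$processed)
  idx1 <- pairs$pairs$idx1; idx2 <- pairs$pairs$idx2

  pre_x <- pretrain_modality(px$processed$values[idx1, , drop = FALSE], side_x,
                             config, seed = NULL, epochs = pretrain_epochs)
  pre_y <- pretrain_modality(py$processed$values[idx2, , drop = FALSE], side_y,
                             config, seed = NULL, epochs = pretrain_epochs)
  model <- assemble_model(pre_x, pre_y, side_x, side_y, config)
  tr <- train_integrative(model, px$processed$values, py$processed$values,
                          pairs = pairs, seed = NULL, epochs = train_epochs)
  structure(list(model = tr$model,
                 processed = list(x = px$processed, y = py$processed,
                                  tfidf_x = px$tfidf, tfidf_y = py$tfidf),
                 pairs = pairs,
                 logs = list(pretrain_x = pre_x$log, pretrain_y = pre_y$log,
                             integrative = tr$log),
                 augment = augment, seed = seed, call = cl),
            class = "dualvae")
}

prepare_side_data <- function(d, n_hvg, min_cell_frac) {
  if (inherits(d, "processed_matrix")) return(list(processed = d, tfidf = NULL))
  if (!inherits(d, "count_matrix"))
    stop("dualvae: inputs must be count_matrix or processed_matrix objects")
  switch(d$modality,
         rna = list(processed = preprocess_rna(d, n_hvg = min(n_hvg, ncol(d$values))),
                    tfidf = NULL),
         atac = {
           pa <- preprocess_atac(d, min_cell_frac = min_cell_frac)
           list(processed = pa$processed, tfidf = pa$tfidf)
         },
         adt = list(processed = preprocess_adt(d), tfidf = NULL))
}

build_side_from_processed <- function(p) {
  if (p$modality == "atac") {
    ci <- group_peaks_by_chromosome(p$feature_ids, allow_single_group = TRUE)
    modality_side("atac", ncol(p$values), ci, p$feature_ids)
  } else {
    modality_side(p$modality, ncol(p$values), feature_ids = p$feature_ids)
  }
}

#' @export
print.dualvae <- function(x, ...) {
  sx <- x$model$sides$x; sy <- x$model$sides$y
  cat(sprintf("Dual-VAE cross-modality translator (%s <-> %s)\n", sx$type, sy$type))
  cat(sprintf("  features: %d (%s) / %d (%s); latent dim %d\n",
              sx$dim, sx$type, sy$dim, sy$type, x$model$config$latent_dim))
  cat(sprintf("  training pairs: %d (augmentation: %s)\n",
              nrow(x$pairs$pairs), x$augment))
  il <- x$logs$integrative
  cat(sprintf("  integrative training: %d epochs (best %d), final val loss %.4g\n",
              nrow(il$history), il$best_epoch,
              il$history$val_loss[nrow(il$history)]))
  invisible(x)
}

#' @export
summary.dualvae <- function(object, ...) {
  comps <- object$model$components
  np <- vapply(comps, n_parameters, numeric(1))
  out <- list(sides = lapply(object$model$sides, function(s) s[c("type", "dim")]),
              n_parameters = np,
              total_parameters = sum(np),
              n_pairs = nrow(object$pairs$pairs),
              augment = object$augment,
              logs = object$logs,
              seed = object$seed)
  class(out) <- "summary.dualvae"
  out
}

#' @export
print.summary.dualvae <- function(x, ...) {
  cat("Dual-VAE translator summary\n")
  cat(sprintf("  sides: %s (%d features) <-> %s (%d features)\n",
              x$sides$x$type, x$sides$x$dim, x$sides$y$type, x$sides$y$dim))
  cat(sprintf("  parameters: %s total\n", format(x$total_parameters, big.mark = ",")))
  for (nm in names(x$n_parameters))
    cat(sprintf("    %-16s %s\n", nm, format(x$n_parameters[[nm]], big.mark = ",")))
  cat(sprintf("  training pairs: %d (augmentation: %s), seed %s\n",
              x$n_pairs, x$augment, format(x$seed)))
  invisible(x)
}

#' Predict translated profiles from a fitted translator
#'
#' @param object a fitted [dualvae()] object.
#' @param newdata optional [count_matrix()] of source-modality cells; the
#'   training-time transforms (stored normalisation target, HVG list,
#'   IDF/scale, CLR) are applied to it. Default NULL translates the
#'   training cells (the data-enhancement mode).
#' @param direction \code{"x2y"} or \code{"y2x"}.
#' @param type \code{"processed"} returns profiles on the processed scale
#'   (thresholded below 1e-4 for RNA/ATAC); \code{"counts"} additionally
#'   inverts the TF-IDF transform for an ATAC target and returns the
#'   binarised count matrix.
#' @param ... unused.
#' @return a \code{predicted_matrix}, or a binary count matrix for
#'   \code{type = "counts"}.
#' @export
predict.dualvae <- function(object, newdata = NULL,
                            direction = c("x2y", "y2x"),
                            type = c("processed", "counts"), ...) {
  direction <- match.arg(direction)
  type <- match.arg(type)
  src <- if (direction == "x2y") "x" else "y"
  tgt <- if (direction == "x2y") "y" else "x"
  values <- if (is.null(newdata)) {
    object$processed[[src]]$values
  } else {
    apply_stored_preprocess(newdata, object$processed[[src]],
                            object$processed[[paste0("tfidf_", src)]])
  }
  pred <- translate_dataset(object$model, values, direction)
  if (type == "processed") return(pred)
  if (object$model$sides[[tgt]]$type != "atac")
    stop("predict: type = 'counts' is only defined for an ATAC target")
  tfidf <- object$processed[[paste0("tfidf_", tgt)]]
  totals <- if (is.null(newdata)) tfidf$cell_totals else NULL
  recover_atac_counts(pred, tfidf, cell_totals = totals)
}

# Re-apply the transforms learned at training time to new raw data.
apply_stored_preprocess <- function(raw, trained, tfidf) {
  stopifnot(inherits(raw, "count_matrix"))
  if (raw$modality != trained$modality)
    stop("predict: newdata modality ", raw$modality,
         " does not match the model side (", trained$modality, ")")
  x <- as.matrix(raw$values)
  if (trained$modality == "rna") {
    totals <- rowSums(x)
    if (any(totals == 0)) stop("predict: newdata has zero-count cells")
    med <- trained$transform_log[[1]]$target
    log1p(x * (med / totals))[, trained$selected_features, drop = FALSE]
  } else if (trained$modality == "atac") {
    xb <- (x > 0) * 1
    xb <- xb[, tfidf$kept_features, drop = FALSE]
    totals <- rowSums(xb)
    if (any(totals == 0)) stop("predict: newdata cells with no open kept peaks")
    (xb / totals) * rep(tfidf$idf, each = nrow(xb)) / tfidf$scale_S
  } else {
    pc <- trained$transform_log[[1]]$pseudocount
    lx <- log(x + pc)
    lx - rowMeans(lx)
  }
}

#' @export
coef.dualvae <- function(object, component = NULL, ...) {
  ps <- lapply(object$model$components, net_params)
  if (is.null(component)) ps else ps[[component]]
}

#' @export
plot.dualvae <- function(x, ...) {
  h <- x$logs$integrative$history
  graphics::plot(h$epoch, h$val_loss, type = "l", col = "firebrick",
                 xlab = "epoch", ylab = "loss",
                 main = "integrative training", ...)
  if ("total" %in% names(h))
    graphics::lines(h$epoch, h$total, col = "steelblue")
  graphics::legend("topright", legend = c("validation", "training"),
                   col = c("firebrick", "steelblue"), lty = 1, bty = "n")
  invisible(x)
}

#' @export
residuals.dualvae <- function(object, direction = c("x2y", "y2x"), ...) {
  direction <- match.arg(direction)
  tgt <- if (direction == "x2y") "y" else "x"
  pred <- predict(object, direction = direction)
  object$processed[[tgt]]$values - pred$values
}

#' Draw synthetic cells from a fitted side's generative model
#'
#' Samples latent vectors from the standard-normal prior and decodes them
#' through the target side's output block and decoder.
#'
#' @param object a fitted [dualvae()] object.
#' @param nsim number of cells to draw.
#' @param seed optional seed.
#' @param side target side, \code{"x"} or \code{"y"}.
#' @param ... unused.
#' @return nsim x features matrix.
#' @export
simulate.dualvae <- function(object, nsim = 1, seed = NULL, side = "y", ...) {
  if (!is.null(seed)) set.seed(seed)
  d <- object$model$config$latent_dim
  z <- matrix(stats::rnorm(nsim * d), nsim, d)
  slope <- object$model$config$leaky_slope
  e <- net_forward(object$model$components[[paste0("tr_out_", side)]], z,
                   FALSE, slope)$y
  vae_decode(object$model, e, side, training = FALSE)
}
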