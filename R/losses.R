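# Loss functions. Reduction convention throughout: sum over features,
# mean over cells; scalar outputs.

#' Reconstruction and regularisation losses
#'
#' \code{loss_mse} is the mean (over cells) squared Euclidean distance
#' between predicted and target profiles. \code{loss_bce} is the mean
#' (over cells) of the per-cell feature-summed binary cross-entropy, with
#' predictions clamped to [1e-7, 1 - 1e-7] for numerical safety.
#' \code{loss_kl} is the mean (over cells) Kullback-Leibler divergence
#' between N(mean, exp(logvar)) and the standard normal prior,
#' \code{-0.5 * sum(1 + logvar - mean^2 - exp(logvar))} per cell.
#'
#' @param pred,target numeric matrices, cells x features.
#' @param mean_,logvar numeric matrices, cells x latent dims.
#' @return scalar loss value.
#' @export
loss_mse <- function(pred, target) {
  pred <- as.matrix(pred); target <- as.matrix(target)
  stopifnot(all(dim(pred) == dim(target)))
  sum((pred - target)^2) / nrow(pred)
}

#' @rdname loss_mse
#' @export
loss_bce <- function(pred, target) {
  pred <- as.matrix(pred); target <- as.matrix(target)
  stopifnot(all(dim(pred) == dim(target)))
  p <- pmin(pmax(pred, 1e-7), 1 - 1e-7)
  -sum(target * log(p) + (1 - target) * log(1 - p)) / nrow(pred)
}

#' @rdname loss_mse
#' @export
loss_kl <- function(mean_, logvar) {
  mean_ <- as.matrix(mean_); logvar <- as.matrix(logvar)
  stopifnot(all(dim(mean_) == dim(logvar)))
  -0.5 * sum(1 + logvar - mean_^2 - exp(logvar)) / nrow(mean_)
}

# Per-sample soft labels: positive ~ U[lo_pos, hi_pos], negative ~ U[lo_neg, hi_neg].
draw_soft_labels <- function(n, range_) stats::runif(n, range_[1], range_[2])

#' Adversarial discriminator loss with soft labels
#'
#' Sum of four binary cross-entropy terms: each discriminator scores the
#' other modality's translated embeddings against soft negative labels
#' (drawn per sample from U[0, 0.2]) and its own native embeddings
#' against soft positive labels (U[0.8, 1]). Each term is averaged over
#' its batch.
#'
#' @param model a \code{dualvae_model} (its discriminators are used).
#' @param native_x,native_y encoder outputs for each modality.
#' @param trans_x,trans_y translator outputs toward each modality.
#' @param labels optional list with elements \code{pos_x, neg_x, pos_y,
#'   neg_y} (per-sample label vectors); drawn fresh when NULL.
#' @return scalar loss (attributes carry the labels used, for reuse).
#' @export
loss_discriminator <- function(model, native_x, trans_x, native_y, trans_y,
                               labels = NULL) {
  cfg <- model$config
  if (is.null(labels)) {
    labels <- list(pos_x = draw_soft_labels(nrow(native_x), cfg$soft_label_pos),
                   neg_x = draw_soft_labels(nrow(trans_x), cfg$soft_label_neg),
                   pos_y = draw_soft_labels(nrow(native_y), cfg$soft_label_pos),
                   neg_y = draw_soft_labels(nrow(trans_y), cfg$soft_label_neg))
  }
  p_tx <- discriminate(model, trans_x, "x")
  p_nx <- discriminate(model, native_x, "x")
  p_ty <- discriminate(model, trans_y, "y")
  p_ny <- discriminate(model, native_y, "y")
  val <- bce_vec(p_ty, labels$neg_y) + bce_vec(p_ny, labels$pos_y) +
    bce_vec(p_tx, labels$neg_x) + bce_vec(p_nx, labels$pos_x)
  attr(val, "labels") <- labels
  val
}

# BCE of a column of probabilities against a label vector, mean over batch.
bce_vec <- function(p, l) {
  p <- pmin(pmax(as.numeric(p), 1e-7), 1 - 1e-7)
  -mean(l * log(p) + (1 - l) * log(1 - p))
}
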