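# End-to-end benchmark pipelines on synthetic data with known ground truth.
# These are the package's own full-pipeline checks: simulate, train, translate,
# evaluate. Problem sizes and epoch caps are chosen so a run completes in
# minutes on one CPU while still recovering the planted structure; see the
# methods vignette.

#' Paired-multiome translation benchmark
#'
#' Simulates a paired RNA + ATAC dataset with planted cell types, fits the
#' translator (optionally with cell-type augmentation), translates in both
#' directions in data-enhancement mode, and scores clustering agreement of
#' the translated profiles against the true types.
#'
#' @param seed integer seed for the generator and the fit.
#' @param augment \code{"none"} or \code{"type"}.
#' @param n_cells,n_genes,n_peaks,n_types,n_chroms fixture dimensions.
#' @param pretrain_epochs,train_epochs epoch caps for the two phases.
#' @param batch_size mini-batch size.
#' @return named list: \code{ari_rna2atac}, \code{ari_atac2rna} (plus the
#'   full \code{eval_x2y} / \code{eval_y2x} reports and the fitted object).
#' @export
translation_benchmark <- function(seed, augment = "none", n_cells = 500,
                                  n_genes = 300, n_peaks = 400, n_types = 5,
                                  n_chroms = 3, pretrain_epochs = 40,
                                  train_epochs = 60, batch_size = 64) {
  sim <- simulate_paired_multiome(n_cells = n_cells, n_genes = n_genes,
                                  n_peaks = n_peaks, n_types = n_types,
                                  n_chroms = n_chroms, seed = seed)
  fit <- dualvae(sim$rna, sim$atac, augment = augment, seed = seed,
                 config = dualvae_config(batch_size = batch_size),
                 n_hvg = n_genes,
                 pretrain_epochs = pretrain_epochs, train_epochs = train_epochs)
  pred_atac <- predict(fit, direction = "x2y")
  pred_rna <- predict(fit, direction = "y2x")
  set.seed(seed)
  ev_xy <- clustering_heterogeneity_eval(pred_atac, sim$atac$cell_labels)
  ev_yx <- clustering_heterogeneity_eval(pred_rna, sim$rna$cell_labels)
  list(ari_rna2atac = unname(ev_xy$metrics["ari"]),
       ari_atac2rna = unname(ev_yx$metrics["ari"]),
       eval_x2y = ev_xy, eval_y2x = ev_yx, fit = fit)
}

#' Perturbation-response prediction benchmark
#'
#' Simulates control and stimulated cells with planted DEGs, holds one cell
#' type out, pairs the remaining types by exact optimal transport, trains a
#' control-to-stimulated translator, predicts the held-out type's response,
#' and scores DEG recovery plus bootstrap R-squared on the held-out cells.
#'
#' @param seed integer seed.
#' @param n_cells cells per condition.
#' @param n_genes,n_types fixture dimensions.
#' @param n_degs,lfc planted differential-expression structure.
#' @param holdout_type type id (1..n_types) excluded from training pairs.
#' @param pretrain_epochs,train_epochs epoch caps.
#' @param n_top DEG list size for the evaluation (defaults to n_degs).
#' @return named list: \code{common_degs} (overlap of top-\code{n_top}
#'   predicted DEGs with the planted set), \code{common_degs_real_vs_pred}
#'   (overlap of predicted with empirically ranked real DEGs),
#'   \code{r2_mean}, \code{r2_sd}, plus the \code{eval_report}.
#' @export
perturbation_benchmark <- function(seed, n_cells = 600, n_genes = 300,
                                   n_types = 7, n_degs = 40, lfc = 2,
                                   holdout_type = 1, pretrain_epochs = 30,
                                   train_epochs = 40, n_top = n_degs) {
  sim <- simulate_perturbation(n_cells = n_cells, n_genes = n_genes,
                               n_types = n_types, n_degs = n_degs, lfc = lfc,
                               holdout_type = holdout_type, seed = seed)
  pc <- preprocess_rna(sim$ctrl, n_hvg = n_genes)
  ps <- preprocess_rna(sim$stim, n_hvg = n_genes)
  hold <- paste0("type_", holdout_type)
  train_c <- which(pc$cell_labels != hold)
  train_s <- which(ps$cell_labels != hold)
  set.seed(seed)
  ot <- ot_pair_perturbation(pc$values[train_c, , drop = FALSE],
                             ps$values[train_s, , drop = FALSE],
                             pc$cell_labels[train_c], ps$cell_labels[train_s])
  # re-index the pair table into the full matrices
  pairs <- ot$pairs
  pairs$pairs$idx1 <- train_c[pairs$pairs$idx1]
  pairs$pairs$idx2 <- train_s[pairs$pairs$idx2]
  side <- modality_side("rna", n_genes)
  cfg <- dualvae_config()
  pre_c <- pretrain_modality(pc$values[pairs$pairs$idx1, , drop = FALSE], side,
                             cfg, epochs = pretrain_epochs)
  pre_s <- pretrain_modality(ps$values[pairs$pairs$idx2, , drop = FALSE], side,
                             cfg, epochs = pretrain_epochs)
  model <- assemble_model(pre_c, pre_s, side, side, cfg)
  tr <- train_integrative(model, pc$values, ps$values, pairs = pairs,
                          epochs = train_epochs)
  test_c <- which(pc$cell_labels == hold)
  test_s <- which(ps$cell_labels == hold)
  pred_stim <- translate_dataset(tr$model, pc$values[test_c, , drop = FALSE],
                                 "x2y")
  ev <- perturbation_metrics(pc$values[test_c, , drop = FALSE],
                             ps$values[test_s, , drop = FALSE],
                             pred_stim$values, n_top = n_top)
  pred_ord <- rank_sum_deg(pc$values[test_c, , drop = FALSE], pred_stim$values)
  common_planted <- length(intersect(pred_ord[seq_len(n_top)], sim$truth$deg_idx))
  list(common_degs = common_planted,
       common_degs_real_vs_pred = unname(ev$metrics["common_degs"]),
       r2_mean = unname(ev$metrics["r2_mean"]),
       r2_sd = unname(ev$metrics["r2_sd"]),
       eval = ev, truth = sim$truth)
}
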