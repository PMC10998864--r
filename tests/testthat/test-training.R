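# Training uses deliberately small fixtures and epoch caps: enough steps for
# the losses to move, cheap enough to run everywhere.

small_rna_side <- function(p) dualvae:::modality_side("rna", p)

test_that("pretraining reduces the validation loss on a synthetic RNA fixture", {
  sim <- make_small_multiome(seed = 11, n_cells = 200)
  px <- preprocess_rna(sim$rna, 60)
  cfg <- dualvae_config(batch_size = 32)
  res <- pretrain_modality(px$values, small_rna_side(60), cfg, seed = 1,
                           epochs = 15)
  h <- res$log$history
  expect_lt(h$val_loss[nrow(h)], h$val_loss[1])
  expect_lt(h$train_loss[nrow(h)], h$train_loss[1])
  expect_equal(res$log$phase, "pretrain")
})

test_that("pretraining is bit-reproducible under a fixed seed", {
  sim <- make_small_multiome(seed = 12, n_cells = 80)
  px <- preprocess_rna(sim$rna, 60)
  cfg <- dualvae_config(batch_size = 32)
  r1 <- pretrain_modality(px$values, small_rna_side(60), cfg, seed = 5, epochs = 4)
  r2 <- pretrain_modality(px$values, small_rna_side(60), cfg, seed = 5, epochs = 4)
  expect_identical(r1$log$history, r2$log$history)
  expect_identical(r1$components, r2$components)
})

test_that("early stopping respects the patience window", {
  sim <- make_small_multiome(seed = 13, n_cells = 60)
  px <- preprocess_rna(sim$rna, 60)
  cfg <- dualvae_config(batch_size = 32, patience = 3)
  res <- pretrain_modality(px$values, small_rna_side(60), cfg, seed = 2,
                           epochs = 60)
  expect_lte(res$log$stopped_epoch - res$log$best_epoch, 3)
  expect_gte(res$log$best_epoch, res$log$stopped_epoch - 3)
  # degenerate inputs are rejected
  expect_error(pretrain_modality(px$values[1, , drop = FALSE],
                                 small_rna_side(60), cfg), "2 cells")
})

fit_small_integrative <- function(epochs = 4, seed = 3, ...) {
  sim <- make_small_multiome(seed = 14, n_cells = 90)
  px <- preprocess_rna(sim$rna, 60)
  pa <- preprocess_atac(sim$atac)
  sx <- dualvae:::build_side_from_processed(px)
  sy <- dualvae:::build_side_from_processed(pa$processed)
  cfg <- dualvae_config(batch_size = 32, ...)
  set.seed(seed)
  pre_x <- pretrain_modality(px$values, sx, cfg, epochs = 3)
  pre_y <- pretrain_modality(pa$processed$values, sy, cfg, epochs = 3)
  model <- assemble_model(pre_x, pre_y, sx, sy, cfg)
  list(res = train_integrative(model, px$values, pa$processed$values,
                               epochs = epochs),
       x = px$values, y = pa$processed$values, cfg = cfg)
}

test_that("integrative training improves the validation loss and logs every
           loss component", {
  out <- fit_small_integrative(epochs = 10)
  h <- out$res$log$history
  expect_lt(h$val_loss[nrow(h)], h$val_loss[1])
  expect_true(all(c("recon_xx", "recon_yx", "recon_yy", "recon_xy",
                    "kl_x", "kl_y", "disc", "total", "val_loss") %in% names(h)))
})

test_that("the logged total is the stated weighted combination of its terms", {
  out <- fit_small_integrative(epochs = 3)
  h <- out$res$log$history
  cfg <- out$cfg
  klw <- dualvae:::integrative_kl_weights(out$res$model)
  recombined <- cfg$w_x * (h$recon_xx + h$recon_yx) +
    cfg$w_y * (h$recon_yy + h$recon_xy) +
    klw["x"] * h$kl_x + klw["y"] * h$kl_y - cfg$w_dis * h$disc
  expect_equal(h$total, recombined, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("integrative training is bit-reproducible under a fixed seed", {
  o1 <- fit_small_integrative(epochs = 3, seed = 9)
  o2 <- fit_small_integrative(epochs = 3, seed = 9)
  expect_identical(o1$res$log$history, o2$res$log$history)
  expect_identical(o1$res$model$components, o2$res$model$components)
})

test_that("generator and discriminator updates are isolated", {
  # the generator backward emits no discriminator gradients, and the
  # discriminator step leaves generator parameters untouched
  out <- fit_small_integrative(epochs = 1)
  grads_names <- names(dualvae:::integrative_gen_backward(
    out$res$model,
    dualvae:::full_forward(out$res$model, out$x[1:8, ], out$y[1:8, ],
                           training = FALSE, sample = FALSE),
    out$x[1:8, ], out$y[1:8, ],
    list(pos_x = rep(0.9, 8), neg_x = rep(0.1, 8),
         pos_y = rep(0.9, 8), neg_y = rep(0.1, 8)),
    dualvae:::integrative_kl_weights(out$res$model)))
  expect_false(any(c("dis_x", "dis_y") %in% grads_names))
  expect_setequal(grads_names,
                  c(dualvae:::gen_component_names("x"),
                    dualvae:::gen_component_names("y")))
})

test_that("with w_dis = 0 the model reduces to paired VAE cross-reconstruction
           with finite losses", {
  out <- fit_small_integrative(epochs = 3, w_dis = 0)
  h <- out$res$log$history
  expect_true(all(is.finite(as.matrix(h[, sapply(h, is.numeric)]))))
  expect_equal(h$total,
               h$total - 0 * h$disc)  # disc term carries zero weight
})

test_that("mismatched data dimensions are a configuration error", {
  out <- fit_small_integrative(epochs = 1)
  expect_error(train_integrative(out$res$model, out$x[, 1:10], out$y),
               "dimensions")
})
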