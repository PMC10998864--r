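trained_tiny_fit <- local({
  value <- NULL
  function() {
    if (is.null(value)) {
      sim <- make_small_multiome(seed = 41, n_cells = 100)
      value <<- dualvae(sim$rna, sim$atac, augment = "none", seed = 2,
                        config = dualvae_config(batch_size = 32),
                        pretrain_epochs = 4, train_epochs = 4)
    }
    value
  }
})

test_that("translation is deterministic and invariant to batching", {
  fit <- trained_tiny_fit()
  v <- fit$processed$x$values
  p_full <- translate_dataset(fit$model, v, "x2y", batch_size = nrow(v))
  p_one <- translate_dataset(fit$model, v, "x2y", batch_size = 1)
  p_again <- translate_dataset(fit$model, v, "x2y", batch_size = 7)
  # batching only regroups BLAS products; results agree to rounding noise
  expect_equal(p_full$values, p_one$values, tolerance = 1e-12)
  expect_equal(p_full$values, p_again$values, tolerance = 1e-12)
})

test_that("sparsity thresholding leaves no value in (0, 1e-4)", {
  fit <- trained_tiny_fit()
  p <- translate_dataset(fit$model, fit$processed$x$values, "x2y")
  expect_true(p$thresholded)
  expect_false(any(p$values > 0 & p$values < 1e-4))
  expect_error(translate_dataset(fit$model, fit$processed$x$values[, 1:5], "x2y"),
               "features")
})

test_that("TF-IDF inversion reproduces a random binary matrix exactly", {
  set.seed(6)
  xb <- matrix(rbinom(30 * 20, 1, 0.4), 30, 20)
  xb[rowSums(xb) == 0, 1] <- 1
  xb[, colSums(xb) == 0] <- 1
  pa <- preprocess_atac(count_matrix(xb, modality = "atac"), min_cell_frac = 0)
  recovered <- recover_atac_counts(pa$processed$values, pa$tfidf,
                                   binarize = FALSE)
  expect_equal(recovered, xb, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(attr(recovered, "totals_source"), "measured")
})

test_that("the 2x3 worked toy round-trips through scaling and inversion", {
  xb <- rbind(c(1, 0, 1), c(1, 1, 0))
  pa <- preprocess_atac(count_matrix(xb, modality = "atac"), 0)
  rec <- recover_atac_counts(pa$processed$values, pa$tfidf, binarize = FALSE)
  expect_equal(rec, xb, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("binarisation thresholds on strict row and column means", {
  # constant recovered counts can never strictly exceed their own means
  pa <- preprocess_atac(count_matrix(matrix(1, 3, 4), modality = "atac"), 0)
  out <- recover_atac_counts(pa$processed$values, pa$tfidf)
  expect_equal(out, matrix(0, 3, 4), ignore_attr = TRUE)
  # general case: output is exactly {0,1}-valued
  set.seed(7)
  xb <- matrix(rbinom(60, 1, 0.5), 10, 6)
  xb[rowSums(xb) == 0, 1] <- 1; xb[, colSums(xb) == 0] <- 1
  pa2 <- preprocess_atac(count_matrix(xb, modality = "atac"), 0)
  out2 <- recover_atac_counts(pa2$processed$values, pa2$tfidf)
  expect_true(all(out2 %in% c(0, 1)))
})

test_that("unknown cell totals fall back to the training median with a flag", {
  set.seed(8)
  xb <- matrix(rbinom(40, 1, 0.6), 8, 5)
  xb[rowSums(xb) == 0, 1] <- 1; xb[, colSums(xb) == 0] <- 1
  pa <- preprocess_atac(count_matrix(xb, modality = "atac"), 0)
  pred <- pa$processed$values[1:3, , drop = FALSE]   # different cell count
  rec <- recover_atac_counts(pred, pa$tfidf, binarize = FALSE)
  expect_equal(attr(rec, "totals_source"), "training_median")
})

test_that("chained translation checks features and propagates shapes", {
  fit <- trained_tiny_fit()
  # identity-style second stage: same model applied y2x after x2y
  out <- chain_translate(fit$model, fit$model, fit$processed$x$values,
                         directions = c("x2y", "y2x"))
  expect_equal(ncol(out$values), fit$model$sides$x$dim)
  expect_equal(ncol(attr(out, "intermediate")$values), fit$model$sides$y$dim)
  # mismatched feature lists produce an explicit error
  m2 <- fit$model
  m2$sides$y$feature_ids <- paste0("other_", seq_len(m2$sides$y$dim))
  expect_error(chain_translate(fit$model, m2, fit$processed$x$values,
                               directions = c("x2y", "y2x")), "features")
})

test_that("a reconstruction-trained second stage approximates the single
           translation", {
  fit <- trained_tiny_fit()
  v <- fit$processed$x$values
  single <- translate_dataset(fit$model, v, "x2y")
  # stage 2 = the model's own y -> y mapping (its reconstruction pathway)
  chained_raw <- vae_translate(fit$model,
                               translate_dataset(fit$model, v, "x2y")$values,
                               "y", "y")
  recon_err <- sqrt(mean((vae_translate(fit$model, fit$processed$y$values,
                                        "y", "y") -
                            fit$processed$y$values)^2))
  expect_lt(sqrt(mean((chained_raw - single$values)^2)), 3 * recon_err + 0.05)
})

test_that("data-enhancement mode: training data translates through predict()", {
  fit <- trained_tiny_fit()
  p1 <- predict(fit, direction = "x2y")
  expect_s3_class(p1, "predicted_matrix")
  expect_equal(nrow(p1$values), 100)
  counts <- predict(fit, direction = "x2y", type = "counts")
  expect_true(all(counts %in% c(0, 1)))
  expect_equal(attr(counts, "totals_source"), "supplied")
})
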