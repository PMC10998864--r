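# Two-phase optimisation: per-modality pretraining of encoder/translator/
# decoder stacks, then integrative adversarial training of the full model.
# All gradients are computed by the hand-written backward passes in nn.R.

gen_component_names <- function(side) {
  c(paste0("en_", side), paste0("tr_in_", side, "_mean"),
    paste0("tr_in_", side, "_logvar"), paste0("tr_out_", side),
    paste0("de_", side))
}

comps_params <- function(model, names) {
  out <- lapply(model$components[names], net_params)
  names(out) <- names
  out
}

comps_set_params <- function(model, params) {
  for (nm in names(params)) {
    model$components[[nm]] <- net_set_params(model$components[[nm]], params[[nm]])
  }
  model
}

# Gradient of the reconstruction loss at the decoder output (MSE, identity
# output) or at the output pre-activation (BCE, sigmoid output, fused).
recon_out_grad <- function(pred, target, loss, weight) {
  n <- nrow(pred)
  if (loss == "mse") list(dy = weight * 2 * (pred - target) / n, preact = FALSE)
  else list(dy = weight * (pred - target) / n, preact = TRUE)
}

recon_loss_value <- function(pred, target, loss) {
  if (loss == "mse") loss_mse(pred, target) else loss_bce(pred, target)
}

# One stochastic forward pass of a single-side stack (encoder, same-side
# translator blocks, decoder); returns caches for the backward pass.
side_stack_forward <- function(comps, side_spec, x, cfg, training, sample) {
  slope <- cfg$leaky_slope
  xin <- if (training) apply_input_mask(x, side_mask_rate(side_spec, cfg)) else x
  en <- net_forward(comps$en, xin, training, slope)
  tm <- net_forward(comps$tr_in_mean, en$y, FALSE, slope)
  tv <- net_forward(comps$tr_in_logvar, en$y, FALSE, slope)
  eps <- NULL
  z <- tm$y
  if (sample) {
    eps <- matrix(stats::rnorm(length(z)), nrow(z), ncol(z))
    z <- tm$y + exp(tv$y / 2) * eps
  }
  to <- net_forward(comps$tr_out, z, FALSE, slope)
  de <- net_forward(comps$de, to$y, training, slope)
  list(en = en, tm = tm, tv = tv, eps = eps, z = z, to = to, de = de, x = x)
}

# Backward through the single-side stack given gradient at the decoder
# output (or output pre-activation) and the KL weight; returns per-component
# gradients.
side_stack_backward <- function(comps, fw, dout, preact, kl_weight, cfg) {
  slope <- cfg$leaky_slope
  n <- nrow(fw$tm$y)
  de_bw <- net_backward(comps$de, fw$de$caches, dout, slope, last_is_preact = preact)
  to_bw <- net_backward(comps$tr_out, fw$to$caches, de_bw$dx, slope)
  dz <- to_bw$dx
  dmean <- dz + kl_weight * fw$tm$y / n
  dlogvar <- kl_weight * (exp(fw$tv$y) - 1) / (2 * n)
  if (!is.null(fw$eps)) dlogvar <- dlogvar + dz * 0.5 * exp(fw$tv$y / 2) * fw$eps
  tm_bw <- net_backward(comps$tr_in_mean, fw$tm$caches, dmean, slope)
  tv_bw <- net_backward(comps$tr_in_logvar, fw$tv$caches, dlogvar, slope)
  en_bw <- net_backward(comps$en, fw$en$caches, tm_bw$dx + tv_bw$dx, slope)
  list(en = en_bw$grads, tr_in_mean = tm_bw$grads, tr_in_logvar = tv_bw$grads,
       tr_out = to_bw$grads, de = de_bw$grads)
}

#' Pretrain one modality's encoder/translator/decoder stack
#'
#' Trains the side's encoder, its same-modality translator blocks and its
#' decoder on a reconstruction objective (MSE for RNA/ADT, feature-summed
#' BCE for ATAC) plus the KL term weighted 20/I (1/150 for ADT), with Adam
#' at \code{cfg$lr_main}, up to \code{cfg$pretrain_epochs} epochs and
#' early stopping with patience \code{cfg$patience} on the loss of a
#' held-out 20\% validation split; the best-epoch weights are restored.
#'
#' @param values numeric matrix, cells x features, already pre-processed.
#' @param side a [modality_side()] descriptor matching \code{values}.
#' @param cfg a [dualvae_config()].
#' @param seed integer seed for the split, initial weights, masking,
#'   dropout and latent sampling; \code{NULL} uses the current RNG state.
#' @param epochs optional cap overriding \code{cfg$pretrain_epochs}.
#' @return list with \code{components} (parameterised nets: \code{en},
#'   \code{tr_in_mean}, \code{tr_in_logvar}, \code{tr_out}, \code{de}) and
#'   \code{log} (a \code{training_log}).
#' @export
pretrain_modality <- function(values, side, cfg = dualvae_config(), seed = NULL,
                              epochs = NULL) {
  values <- as.matrix(values)
  if (nrow(values) < 2) stop("pretrain_modality: need at least 2 cells")
  if (ncol(values) != side$dim)
    stop("pretrain_modality: data has ", ncol(values), " features, side expects ", side$dim)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(epochs)) epochs <- cfg$pretrain_epochs
  comps <- list(en = build_encoder(side, cfg),
                tr_in_mean = list(nn_dense(cfg$latent_dim, cfg$latent_dim, "leaky", 0)),
                tr_in_logvar = list(nn_dense(cfg$latent_dim, cfg$latent_dim, "leaky", 0)),
                tr_out = list(nn_dense(cfg$latent_dim, cfg$latent_dim, "leaky", 0)),
                de = build_decoder(side, cfg))
  n <- nrow(values)
  n_val <- max(1L, floor(cfg$val_frac * n))
  val_idx <- sample.int(n, n_val)
  train_idx <- setdiff(seq_len(n), val_idx)
  kl_w <- side_kl_weight(side, cfg)
  params <- lapply(comps, net_params)
  opt <- adam_init(params)
  eval_val <- function() {
    fw <- side_stack_forward(comps, side, values[val_idx, , drop = FALSE], cfg,
                             training = FALSE, sample = FALSE)
    recon_loss_value(fw$de$y, fw$x, side$loss) + kl_w * loss_kl(fw$tm$y, fw$tv$y)
  }
  log_rows <- list()
  best <- list(val = Inf, epoch = 0L, params = params)
  stopped <- epochs
  for (ep in seq_len(epochs)) {
    ord <- sample(train_idx)
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
    tr_loss <- 0
    for (b in batches) {
      xb <- values[b, , drop = FALSE]
      fw <- side_stack_forward(comps, side, xb, cfg, training = TRUE, sample = TRUE)
      rg <- recon_out_grad(fw$de$y, xb, side$loss, 1)
      grads <- side_stack_backward(comps, fw, rg$dy, rg$preact, kl_w, cfg)
      st <- adam_step(params, grads, opt, lr = cfg$lr_main)
      params <- st$params; opt <- st$state
      for (nm in names(comps)) comps[[nm]] <- net_set_params(comps[[nm]], params[[nm]])
      tr_loss <- tr_loss + (recon_loss_value(fw$de$y, xb, side$loss) +
                              kl_w * loss_kl(fw$tm$y, fw$tv$y)) * length(b)
    }
    vl <- eval_val()
    log_rows[[ep]] <- data.frame(epoch = ep, train_loss = tr_loss / length(ord),
                                 val_loss = vl)
    if (vl < best$val) best <- list(val = vl, epoch = ep, params = params)
    if (ep - best$epoch >= cfg$patience) { stopped <- ep; break }
  }
  for (nm in names(comps)) comps[[nm]] <- net_set_params(comps[[nm]], best$params[[nm]])
  log <- structure(list(history = do.call(rbind, log_rows),
                        best_epoch = best$epoch, stopped_epoch = stopped,
                        phase = "pretrain", seed = seed),
                   class = "training_log")
  list(components = comps, log = log)
}

#' Assemble a full model from two pretrained stacks
#'
#' @param pre_x,pre_y results of [pretrain_modality()] for each side.
#' @param side_x,side_y the matching [modality_side()] descriptors.
#' @param cfg a [dualvae_config()]; fresh discriminators are initialised
#'   from the current RNG state.
#' @return a \code{dualvae_model}.
#' @export
assemble_model <- function(pre_x, pre_y, side_x, side_y, cfg = dualvae_config()) {
  model <- init_model_state(side_x, side_y, cfg)
  model$components$en_x <- pre_x$components$en
  model$components$tr_in_x_mean <- pre_x$components$tr_in_mean
  model$components$tr_in_x_logvar <- pre_x$components$tr_in_logvar
  model$components$tr_out_x <- pre_x$components$tr_out
  model$components$de_x <- pre_x$components$de
  model$components$en_y <- pre_y$components$en
  model$components$tr_in_y_mean <- pre_y$components$tr_in_mean
  model$components$tr_in_y_logvar <- pre_y$components$tr_in_logvar
  model$components$tr_out_y <- pre_y$components$tr_out
  model$components$de_y <- pre_y$components$de
  model
}

# Integrative KL weights per side: both sides share 20/I_x + 20/I_y, except
# that an ADT side's KL keeps its constant 1/150 weight.
integrative_kl_weights <- function(model) {
  cfg <- model$config
  sx <- model$sides$x; sy <- model$sides$y
  if (sx$type != "adt" && sy$type != "adt") {
    w <- side_kl_weight(sx, cfg) + side_kl_weight(sy, cfg)
    c(x = w, y = w)
  } else {
    c(x = side_kl_weight(sx, cfg), y = side_kl_weight(sy, cfg))
  }
}

# Forward all four reconstruction/translation paths for a paired batch.
full_forward <- function(model, xb, yb, training, sample) {
  cfg <- model$config
  cm <- model$components
  cx <- list(en = cm$en_x, tr_in_mean = cm$tr_in_x_mean,
             tr_in_logvar = cm$tr_in_x_logvar, tr_out = cm$tr_out_x, de = cm$de_x)
  cy <- list(en = cm$en_y, tr_in_mean = cm$tr_in_y_mean,
             tr_in_logvar = cm$tr_in_y_logvar, tr_out = cm$tr_out_y, de = cm$de_y)
  slope <- cfg$leaky_slope
  fx <- side_stack_forward(cx, model$sides$x, xb, cfg, training, sample)
  fy <- side_stack_forward(cy, model$sides$y, yb, cfg, training, sample)
  # cross paths: z of one side through the other side's output block/decoder
  to_xy <- net_forward(cm$tr_out_y, fx$z, FALSE, slope)   # x -> y embedding
  to_yx <- net_forward(cm$tr_out_x, fy$z, FALSE, slope)   # y -> x embedding
  de_xy <- net_forward(cm$de_y, to_xy$y, training, slope)
  de_yx <- net_forward(cm$de_x, to_yx$y, training, slope)
  list(fx = fx, fy = fy, to_xy = to_xy, to_yx = to_yx,
       de_xy = de_xy, de_yx = de_yx)
}

full_losses <- function(model, fw, xb, yb, labels = NULL) {
  lx <- model$sides$x$loss; ly <- model$sides$y$loss
  ld <- loss_discriminator(model, fw$fx$en$y, fw$to_yx$y, fw$fy$en$y, fw$to_xy$y,
                           labels = labels)
  list(recon_xx = recon_loss_value(fw$fx$de$y, xb, lx),
       recon_yx = recon_loss_value(fw$de_yx$y, xb, lx),
       recon_yy = recon_loss_value(fw$fy$de$y, yb, ly),
       recon_xy = recon_loss_value(fw$de_xy$y, yb, ly),
       kl_x = loss_kl(fw$fx$tm$y, fw$fx$tv$y),
       kl_y = loss_kl(fw$fy$tm$y, fw$fy$tv$y),
       disc = as.numeric(ld),
       labels = attr(ld, "labels"))
}

combine_losses <- function(losses, cfg, klw) {
  cfg$w_x * (losses$recon_xx + losses$recon_yx) +
    cfg$w_y * (losses$recon_yy + losses$recon_xy) +
    klw["x"] * losses$kl_x + klw["y"] * losses$kl_y -
    cfg$w_dis * losses$disc
}

# Discriminator-side gradients for one BCE term; returns dx at the
# discriminator input and the parameter gradients.
disc_term_backward <- function(net, emb, labels, coeff, slope) {
  fw <- net_forward(net, emb, FALSE, slope)
  n <- nrow(emb)
  ds <- matrix(coeff * (as.numeric(fw$y) - labels) / n, n, 1)
  net_backward(net, fw$caches, ds, slope, last_is_preact = TRUE)
}

#' Integrative adversarial training of the full model
#'
#' Per mini-batch: (1) the two discriminators take one plain SGD step at
#' \code{cfg$lr_disc} minimising the four-term soft-label adversarial
#' loss on detached embeddings; (2) the adversarial loss is recomputed
#' with the updated discriminators; (3) the encoders, translator and
#' decoders take one Adam step at \code{cfg$lr_main} minimising the
#' combination of the four reconstruction/translation losses, the two KL
#' terms and minus \code{w_dis} times the recomputed adversarial loss.
#' Runs up to \code{cfg$train_epochs} epochs with early stopping
#' (patience \code{cfg$patience}) on a deterministic total loss over a
#' held-out 20\% of the pairs; best-epoch weights are restored.
#'
#' @param model a \code{dualvae_model}, typically from [assemble_model()].
#' @param x_values,y_values processed matrices for the two modalities
#'   (rows indexed by the pair table).
#' @param pairs a \code{paired_dataset} from [augment_by_label()] and
#'   friends, or NULL for identity pairing (row i with row i).
#' @param seed integer seed; NULL uses the current RNG state.
#' @param epochs optional cap overriding \code{cfg$train_epochs}.
#' @return list with \code{model} (trained) and \code{log} (a
#'   \code{training_log} whose history carries all loss components).
#' @export
train_integrative <- function(model, x_values, y_values, pairs = NULL,
                              seed = NULL, epochs = NULL) {
  stopifnot(inherits(model, "dualvae_model"))
  cfg <- model$config
  x_values <- as.matrix(x_values); y_values <- as.matrix(y_values)
  if (ncol(x_values) != model$sides$x$dim || ncol(y_values) != model$sides$y$dim)
    stop("train_integrative: data dimensions do not match the model sides")
  if (is.null(pairs)) {
    stopifnot(nrow(x_values) == nrow(y_values))
    pairs <- paired_dataset(seq_len(nrow(x_values)), seq_len(nrow(x_values)),
                            origin = "original")
  }
  if (!is.null(seed)) set.seed(seed)
  if (is.null(epochs)) epochs <- cfg$train_epochs
  idx1 <- pairs$pairs$idx1; idx2 <- pairs$pairs$idx2
  np <- length(idx1)
  n_val <- max(1L, floor(cfg$val_frac * np))
  val_sel <- sample.int(np, n_val)
  train_sel <- setdiff(seq_len(np), val_sel)
  klw <- integrative_kl_weights(model)

  gen_names <- c(gen_component_names("x"), gen_component_names("y"))
  gen_params <- comps_params(model, gen_names)
  gen_opt <- adam_init(gen_params)
  dis_params <- comps_params(model, c("dis_x", "dis_y"))
  slope <- cfg$leaky_slope

  mid_labels_for <- function(n) list(
    pos_x = rep(mean(cfg$soft_label_pos), n), neg_x = rep(mean(cfg$soft_label_neg), n),
    pos_y = rep(mean(cfg$soft_label_pos), n), neg_y = rep(mean(cfg$soft_label_neg), n))

  eval_val <- function() {
    xb <- x_values[idx1[val_sel], , drop = FALSE]
    yb <- y_values[idx2[val_sel], , drop = FALSE]
    fw <- full_forward(model, xb, yb, training = FALSE, sample = FALSE)
    ls <- full_losses(model, fw, xb, yb, labels = mid_labels_for(length(val_sel)))
    combine_losses(ls, cfg, klw)
  }

  log_rows <- list()
  best <- list(val = Inf, epoch = 0L, gen = gen_params, dis = dis_params)
  stopped <- epochs
  for (ep in seq_len(epochs)) {
    ord <- sample(train_sel)
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
    ep_losses <- NULL
    for (b in batches) {
      xb <- x_values[idx1[b], , drop = FALSE]
      yb <- y_values[idx2[b], , drop = FALSE]
      nb <- length(b)
      fw <- full_forward(model, xb, yb, training = TRUE, sample = TRUE)
      labels <- list(pos_x = draw_soft_labels(nb, cfg$soft_label_pos),
                     neg_x = draw_soft_labels(nb, cfg$soft_label_neg),
                     pos_y = draw_soft_labels(nb, cfg$soft_label_pos),
                     neg_y = draw_soft_labels(nb, cfg$soft_label_neg))
      # (1) discriminator SGD step on detached embeddings
      h_x <- fw$fx$en$y; h_y <- fw$fy$en$y
      e_yx <- fw$to_yx$y; e_xy <- fw$to_xy$y
      gx1 <- disc_term_backward(model$components$dis_x, e_yx, labels$neg_x, 1, slope)
      gx2 <- disc_term_backward(model$components$dis_x, h_x, labels$pos_x, 1, slope)
      gy1 <- disc_term_backward(model$components$dis_y, e_xy, labels$neg_y, 1, slope)
      gy2 <- disc_term_backward(model$components$dis_y, h_y, labels$pos_y, 1, slope)
      dis_grads <- list(dis_x = tree_add(gx1$grads, gx2$grads),
                        dis_y = tree_add(gy1$grads, gy2$grads))
      dis_params <- sgd_step(dis_params, dis_grads, lr = cfg$lr_disc)
      model <- comps_set_params(model, dis_params)
      # (2)+(3) recompute adversarial loss with updated discriminators and
      # take the generator Adam step
      gen_grads <- integrative_gen_backward(model, fw, xb, yb, labels, klw)
      st <- adam_step(gen_params, gen_grads, gen_opt, lr = cfg$lr_main)
      gen_params <- st$params; gen_opt <- st$state
      model <- comps_set_params(model, gen_params)
      ls <- full_losses(model, fw, xb, yb, labels = labels)
      ls$labels <- NULL
      ls <- as.data.frame(ls)
      ls$total <- combine_losses(ls, cfg, klw)
      ls$n <- nb
      ep_losses <- rbind(ep_losses, ls)
    }
    w <- ep_losses$n / sum(ep_losses$n)
    tr <- colSums(ep_losses[, setdiff(names(ep_losses), "n")] * w)
    vl <- eval_val()
    log_rows[[ep]] <- data.frame(epoch = ep, t(tr), val_loss = vl)
    if (vl < best$val) best <- list(val = vl, epoch = ep, gen = gen_params,
                                    dis = dis_params)
    if (ep - best$epoch >= cfg$patience) { stopped <- ep; break }
  }
  model <- comps_set_params(model, best$gen)
  model <- comps_set_params(model, best$dis)
  log <- structure(list(history = do.call(rbind, log_rows),
                        best_epoch = best$epoch, stopped_epoch = stopped,
                        phase = "integrative", seed = seed),
                   class = "training_log")
  list(model = model, log = log)
}

# Backward pass for the generator objective (reconstruction + translation +
# KL - w_dis * adversarial), using the updated discriminators. Gradients
# flowing into the discriminators are computed (they carry the chain into
# the embeddings) but their parameter gradients are discarded.
integrative_gen_backward <- function(model, fw, xb, yb, labels, klw) {
  cfg <- model$config
  cm <- model$components
  slope <- cfg$leaky_slope
  lx <- model$sides$x$loss; ly <- model$sides$y$loss
  n <- nrow(xb)

  # adversarial contributions at the embeddings, scaled by -w_dis
  bx1 <- disc_term_backward(cm$dis_x, fw$to_yx$y, labels$neg_x, -cfg$w_dis, slope)
  bx2 <- disc_term_backward(cm$dis_x, fw$fx$en$y, labels$pos_x, -cfg$w_dis, slope)
  by1 <- disc_term_backward(cm$dis_y, fw$to_xy$y, labels$neg_y, -cfg$w_dis, slope)
  by2 <- disc_term_backward(cm$dis_y, fw$fy$en$y, labels$pos_y, -cfg$w_dis, slope)

  grads <- list()
  # same-side stacks: decoder grads from own reconstruction
  cx <- list(en = cm$en_x, tr_in_mean = cm$tr_in_x_mean,
             tr_in_logvar = cm$tr_in_x_logvar, tr_out = cm$tr_out_x, de = cm$de_x)
  cy <- list(en = cm$en_y, tr_in_mean = cm$tr_in_y_mean,
             tr_in_logvar = cm$tr_in_y_logvar, tr_out = cm$tr_out_y, de = cm$de_y)

  # cross-path backward: de_y(to_xy(z_x)) vs yb, de_x(to_yx(z_y)) vs xb
  rg_xy <- recon_out_grad(fw$de_xy$y, yb, ly, cfg$w_y)
  de_xy_bw <- net_backward(cm$de_y, fw$de_xy$caches, rg_xy$dy, slope, rg_xy$preact)
  to_xy_bw <- net_backward(cm$tr_out_y, fw$to_xy$caches, de_xy_bw$dx + by1$dx, slope)

  rg_yx <- recon_out_grad(fw$de_yx$y, xb, lx, cfg$w_x)
  de_yx_bw <- net_backward(cm$de_x, fw$de_yx$caches, rg_yx$dy, slope, rg_yx$preact)
  to_yx_bw <- net_backward(cm$tr_out_x, fw$to_yx$caches, de_yx_bw$dx + bx1$dx, slope)

  # own-side reconstruction gradients at decoder outputs
  rg_xx <- recon_out_grad(fw$fx$de$y, xb, lx, cfg$w_x)
  rg_yy <- recon_out_grad(fw$fy$de$y, yb, ly, cfg$w_y)

  side_bw <- function(comps, f, rg, klwt, dz_cross, dh_disc) {
    de_bw <- net_backward(comps$de, f$de$caches, rg$dy, slope, rg$preact)
    to_bw <- net_backward(comps$tr_out, f$to$caches, de_bw$dx, slope)
    dz <- to_bw$dx + dz_cross
    dmean <- dz + klwt * f$tm$y / n
    dlogvar <- klwt * (exp(f$tv$y) - 1) / (2 * n)
    if (!is.null(f$eps)) dlogvar <- dlogvar + dz * 0.5 * exp(f$tv$y / 2) * f$eps
    tm_bw <- net_backward(comps$tr_in_mean, f$tm$caches, dmean, slope)
    tv_bw <- net_backward(comps$tr_in_logvar, f$tv$caches, dlogvar, slope)
    en_bw <- net_backward(comps$en, f$en$caches, tm_bw$dx + tv_bw$dx + dh_disc, slope)
    list(en = en_bw$grads, tr_in_mean = tm_bw$grads, tr_in_logvar = tv_bw$grads,
         tr_out = to_bw$grads, de = de_bw$grads)
  }

  bx <- side_bw(cx, fw$fx, rg_xx, klw["x"], to_xy_bw$dx, bx2$dx)
  by <- side_bw(cy, fw$fy, rg_yy, klw["y"], to_yx_bw$dx, by2$dx)

  list(
    en_x = bx$en,
    tr_in_x_mean = bx$tr_in_mean, tr_in_x_logvar = bx$tr_in_logvar,
    tr_out_x = tree_add(bx$tr_out, to_yx_bw$grads),
    de_x = tree_add(bx$de, de_yx_bw$grads),
    en_y = by$en,
    tr_in_y_mean = by$tr_in_mean, tr_in_y_logvar = by$tr_in_logvar,
    tr_out_y = tree_add(by$tr_out, to_xy_bw$grads),
    de_y = tree_add(by$de, de_xy_bw$grads))
}

#' @export
print.training_log <- function(x, ...) {
  h <- x$history
  cat(sprintf("<training_log> phase = %s, %d epochs (best %d, stopped %d)\n",
              x$phase, nrow(h), x$best_epoch, x$stopped_epoch))
  cat(sprintf("  final val loss %.5g (best %.5g)\n",
              h$val_loss[nrow(h)], min(h$val_loss)))
  invisible(x)
}
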