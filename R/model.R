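#' Model hyperparameter configuration
#'
#' Collects every architectural and optimisation hyperparameter of the
#' dual-VAE translator. Defaults follow the reference training recipe:
#' a 256-unit RNA hidden layer, 128-dimensional latent space,
#' 32-dimensional per-chromosome ATAC blocks, LeakyReLU slope 0.01,
#' dropout 0.1 on latent layers, input-masking rates 0.5 (RNA), 0.3
#' (ATAC) and 0 (ADT), reconstruction weights 1 (RNA side) and 2
#' (second side), adversarial weight 1, KL weight 20/I per modality
#' (constant 1/150 for an ADT side), Adam at 0.001 for the
#' encoders/translator/decoders and plain SGD at 0.005 for the
#' discriminators, 100 pretraining and 200 integrative epochs with
#' early-stopping patience 50, batch size 64, and soft adversarial labels
#' drawn from U[0.8, 1] (positive) and U[0, 0.2] (negative).
#'
#' @param ... named overrides of any default listed above.
#' @return list of class \code{dualvae_config}.
#' @export
dualvae_config <- function(...) {
  cfg <- list(
    rna_hidden = 256L,
    latent_dim = 128L,
    atac_per_chrom_dim = 32L,
    adt_hidden = 128L,
    dropout_rate = 0.1,
    leaky_slope = 0.01,
    mask_rate_rna = 0.5,
    mask_rate_atac = 0.3,
    mask_rate_adt = 0.0,
    w_x = 1,
    w_y = 2,
    w_dis = 1,
    kl_weight_adt = 1 / 150,
    lr_main = 0.001,
    lr_disc = 0.005,
    pretrain_epochs = 100L,
    train_epochs = 200L,
    patience = 50L,
    batch_size = 64L,
    val_frac = 0.2,
    soft_label_pos = c(0.8, 1),
    soft_label_neg = c(0, 0.2))
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("dualvae_config: unknown option(s): ", paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  stopifnot(cfg$dropout_rate >= 0, cfg$dropout_rate < 1,
            cfg$mask_rate_rna >= 0, cfg$mask_rate_rna <= 1,
            cfg$mask_rate_atac >= 0, cfg$mask_rate_atac <= 1,
            cfg$latent_dim > 0, cfg$w_x >= 0, cfg$w_y >= 0, cfg$w_dis >= 0)
  class(cfg) <- "dualvae_config"
  cfg
}

#' Describe one modality slot of the model
#'
#' A "side" bundles what the model needs to know about one modality: its
#' data type (which decides the encoder/decoder architecture, the
#' reconstruction loss, the masking rate and the KL weight), its feature
#' dimension, and — for ATAC — the chromosome grouping of its peaks.
#'
#' @param type \code{"rna"}, \code{"atac"} or \code{"adt"}.
#' @param dim number of features.
#' @param chrom_index a [group_peaks_by_chromosome()] result (ATAC only).
#' @param feature_ids optional feature names, carried into predictions.
#' @return list describing the side, consumed by [init_model_state()] and
#'   [pretrain_modality()].
#' @export
modality_side <- function(type = c("rna", "atac", "adt"), dim,
                          chrom_index = NULL, feature_ids = NULL) {
  type <- match.arg(type)
  if (type == "atac") {
    if (is.null(chrom_index)) stop("modality_side: atac side needs a chromosome index")
    stopifnot(inherits(chrom_index, "chromosome_index"))
  }
  list(type = type, dim = as.integer(dim), chrom_index = chrom_index,
       feature_ids = feature_ids,
       loss = if (type == "atac") "bce" else "mse")
}

side_mask_rate <- function(side, cfg) {
  switch(side$type, rna = cfg$mask_rate_rna, atac = cfg$mask_rate_atac,
         adt = cfg$mask_rate_adt)
}

side_kl_weight <- function(side, cfg) {
  if (side$type == "adt") cfg$kl_weight_adt else 20 / side$dim
}

build_encoder <- function(side, cfg) {
  d <- cfg$latent_dim
  p <- cfg$dropout_rate
  switch(side$type,
    rna = list(nn_dense(side$dim, cfg$rna_hidden, "leaky", p),
               nn_dense(cfg$rna_hidden, d, "leaky", p)),
    adt = list(nn_dense(side$dim, cfg$adt_hidden, "leaky", p),
               nn_dense(cfg$adt_hidden, d, "leaky", p)),
    atac = {
      groups <- chrom_index_groups(side$chrom_index)
      k <- cfg$atac_per_chrom_dim
      out_groups <- split(seq_len(k * length(groups)),
                          rep(seq_along(groups), each = k))
      list(nn_blocked(groups, out_groups, "leaky", p),
           nn_dense(k * length(groups), d, "leaky", p))
    })
}

build_decoder <- function(side, cfg) {
  d <- cfg$latent_dim
  p <- cfg$dropout_rate
  switch(side$type,
    rna = list(nn_dense(d, cfg$rna_hidden, "leaky", p),
               nn_dense(cfg$rna_hidden, side$dim, "identity", 0)),
    adt = list(nn_dense(d, cfg$adt_hidden, "leaky", p),
               nn_dense(cfg$adt_hidden, side$dim, "identity", 0)),
    atac = {
      groups <- chrom_index_groups(side$chrom_index)
      k <- cfg$atac_per_chrom_dim
      in_groups <- split(seq_len(k * length(groups)),
                         rep(seq_along(groups), each = k))
      list(nn_dense(d, k * length(groups), "leaky", p),
           nn_blocked(in_groups, groups, "sigmoid", 0))
    })
}

#' Initialise the parameters of all seven model components
#'
#' Builds the two encoders, the latent translator (a mean and a
#' log-variance input block per source modality, and one output block per
#' target modality, shared across sources), the two discriminators and the
#' two decoders, with fresh uniform initial weights drawn from the current
#' RNG state.
#'
#' @param side_x,side_y side descriptors from [modality_side()].
#' @param cfg a [dualvae_config()].
#' @return list of class \code{dualvae_model} holding \code{config},
#'   \code{sides} and \code{components}.
#' @export
init_model_state <- function(side_x, side_y, cfg = dualvae_config()) {
  d <- cfg$latent_dim
  comps <- list(
    en_x = build_encoder(side_x, cfg),
    en_y = build_encoder(side_y, cfg),
    tr_in_x_mean = list(nn_dense(d, d, "leaky", 0)),
    tr_in_x_logvar = list(nn_dense(d, d, "leaky", 0)),
    tr_in_y_mean = list(nn_dense(d, d, "leaky", 0)),
    tr_in_y_logvar = list(nn_dense(d, d, "leaky", 0)),
    tr_out_x = list(nn_dense(d, d, "leaky", 0)),
    tr_out_y = list(nn_dense(d, d, "leaky", 0)),
    dis_x = list(nn_dense(d, d, "leaky", 0), nn_dense(d, 1L, "sigmoid", 0)),
    dis_y = list(nn_dense(d, d, "leaky", 0), nn_dense(d, 1L, "sigmoid", 0)),
    de_x = build_decoder(side_x, cfg),
    de_y = build_decoder(side_y, cfg))
  structure(list(config = cfg, sides = list(x = side_x, y = side_y),
                 components = comps),
            class = "dualvae_model")
}

check_side <- function(model, side) {
  if (!side %in% c("x", "y")) stop("side must be 'x' or 'y'")
  side
}

#' Encode a batch of cells into the latent space
#'
#' Forward pass through one encoder. During training a fresh Bernoulli
#' mask zeroes a modality-specific fraction of the input entries (without
#' rescaling the survivors) and dropout is active on latent layers; at
#' inference the pass is deterministic.
#'
#' @param model a \code{dualvae_model}.
#' @param x numeric matrix, cells x features of the side's modality.
#' @param side \code{"x"} or \code{"y"}.
#' @param training logical; enables input masking and dropout.
#' @return cells x latent_dim embedding matrix.
#' @export
vae_encode <- function(model, x, side = "x", training = FALSE) {
  side <- check_side(model, side)
  sd <- model$sides[[side]]
  x <- as.matrix(x)
  if (ncol(x) != sd$dim)
    stop("vae_encode: input has ", ncol(x), " features, encoder expects ", sd$dim)
  if (training) x <- apply_input_mask(x, side_mask_rate(sd, model$config))
  net_forward(model$components[[paste0("en_", side)]], x, training,
              model$config$leaky_slope)$y
}

#' Translate a latent embedding between modalities
#'
#' Applies the source side's mean/log-variance input blocks, optionally
#' draws \code{z = mean + exp(logvar / 2) * eps} with \code{eps ~ N(0, I)}
#' (the reparameterisation step), and maps the result through the target
#' side's output block. The output block is shared across source
#' modalities, which ties the two translation directions together.
#'
#' @param model a \code{dualvae_model}.
#' @param emb cells x latent_dim matrix from [vae_encode()].
#' @param source,target \code{"x"} or \code{"y"}.
#' @param sample draw a stochastic latent sample; if \code{FALSE} the mean
#'   path is used and the result is deterministic.
#' @return list with \code{embedding} (after the target output block),
#'   \code{mean}, \code{logvar}, \code{z} (the latent draw) and
#'   \code{sampled}.
#' @export
translate_latent <- function(model, emb, source = "x", target = "y",
                             sample = FALSE) {
  source <- check_side(model, source); target <- check_side(model, target)
  slope <- model$config$leaky_slope
  cm <- model$components
  mean_ <- net_forward(cm[[paste0("tr_in_", source, "_mean")]], emb, FALSE, slope)$y
  logvar <- net_forward(cm[[paste0("tr_in_", source, "_logvar")]], emb, FALSE, slope)$y
  z <- if (sample) {
    mean_ + exp(logvar / 2) * matrix(stats::rnorm(length(mean_)),
                                     nrow(mean_), ncol(mean_))
  } else mean_
  out <- net_forward(cm[[paste0("tr_out_", target)]], z, FALSE, slope)$y
  list(embedding = out, mean = mean_, logvar = logvar, z = z, sampled = sample)
}

#' Decode a latent embedding back to profile space
#'
#' @inheritParams vae_encode
#' @param emb cells x latent_dim matrix (a translated or mapped embedding).
#' @return cells x features reconstruction; values lie in (0, 1) for an
#'   ATAC side (sigmoid output) and are unbounded for RNA/ADT (linear
#'   output over log-space data).
#' @export
vae_decode <- function(model, emb, side = "x", training = FALSE) {
  side <- check_side(model, side)
  net_forward(model$components[[paste0("de_", side)]], as.matrix(emb), training,
              model$config$leaky_slope)$y
}

#' Discriminator forward pass
#'
#' Scores embeddings with the side's adversarial discriminator; outputs in
#' (0, 1), trained toward 1 for native encoder embeddings and 0 for
#' translated ones.
#'
#' @inheritParams vae_decode
#' @return cells x 1 matrix of probabilities.
#' @export
discriminate <- function(model, emb, side = "x") {
  side <- check_side(model, side)
  net_forward(model$components[[paste0("dis_", side)]], as.matrix(emb), FALSE,
              model$config$leaky_slope)$y
}

#' Full deterministic translation of a batch
#'
#' encode -> translate (mean path) -> decode, with no masking, dropout or
#' sampling; used at inference time.
#'
#' @inheritParams vae_encode
#' @param source,target \code{"x"} or \code{"y"}.
#' @return cells x target-features matrix.
#' @export
vae_translate <- function(model, x, source = "x", target = "y") {
  emb <- vae_encode(model, x, source, training = FALSE)
  tl <- translate_latent(model, emb, source, target, sample = FALSE)
  vae_decode(model, tl$embedding, target, training = FALSE)
}

n_parameters <- function(net) {
  sum(vapply(net, function(l) {
    if (l$kind == "dense") length(l$W) + length(l$b)
    else sum(vapply(l$Ws, length, numeric(1))) + sum(vapply(l$bs, length, numeric(1)))
  }, numeric(1)))
}

# --- serialization -----------------------------------------------------------
# Tensors are stored as base64-encoded little-endian doubles with their dims,
# giving a bit-exact round trip; the config travels as plain JSON.

encode_tensor <- function(x) {
  list(dims = if (is.matrix(x)) dim(x) else length(x),
       data = jsonlite::base64_enc(writeBin(as.numeric(x), raw(),
                                            size = 8, endian = "little")))
}

decode_tensor <- function(t) {
  v <- readBin(jsonlite::base64_dec(t$data), "numeric",
               n = prod(unlist(t$dims)), size = 8, endian = "little")
  if (length(t$dims) == 2) matrix(v, t$dims[[1]], t$dims[[2]]) else v
}

serialize_tree <- function(x) {
  if (is.numeric(x)) c(list(.tensor = TRUE), encode_tensor(x))
  else if (is.list(x)) lapply(x, serialize_tree)
  else x
}

deserialize_tree <- function(x) {
  if (is.list(x) && isTRUE(x$.tensor)) decode_tensor(x)
  else if (is.list(x)) lapply(x, deserialize_tree)
  else x
}

#' Save / load a model to a single JSON container
#'
#' Weights are stored as base64-encoded doubles so the round trip is
#' bit-exact; the configuration and side descriptors are stored as plain
#' JSON alongside.
#'
#' @param model a \code{dualvae_model}.
#' @param path file to write / read.
#' @return \code{write_model_state}: \code{path}, invisibly;
#'   \code{read_model_state}: the restored \code{dualvae_model}.
#' @export
write_model_state <- function(model, path) {
  stopifnot(inherits(model, "dualvae_model"))
  payload <- list(
    config = unclass(model$config),
    sides = lapply(model$sides, function(s) {
      s$chrom_index <- if (is.null(s$chrom_index)) NULL else unclass(s$chrom_index)
      s
    }),
    components = serialize_tree(model$components))
  writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, null = "null"),
             path)
  invisible(path)
}

#' @rdname write_model_state
#' @export
read_model_state <- function(path) {
  payload <- jsonlite::fromJSON(readLines(path), simplifyVector = FALSE)
  cfg <- payload$config
  cfg$soft_label_pos <- as.numeric(unlist(cfg$soft_label_pos))
  cfg$soft_label_neg <- as.numeric(unlist(cfg$soft_label_neg))
  cfg <- do.call(dualvae_config, cfg)
  sides <- lapply(payload$sides, function(s) {
    ci <- NULL
    if (!is.null(s$chrom_index)) {
      ci <- structure(list(groups = lapply(s$chrom_index$groups,
                                           function(g) as.integer(unlist(g))),
                           catch_all = as.integer(unlist(s$chrom_index$catch_all))),
                      class = "chromosome_index")
    }
    modality_side(s$type, as.integer(s$dim), ci,
                  if (is.null(s$feature_ids)) NULL else as.character(unlist(s$feature_ids)))
  })
  comps <- deserialize_tree(payload$components)
  comps <- restore_layer_fields(comps)
  structure(list(config = cfg, sides = sides, components = comps),
            class = "dualvae_model")
}

# fromJSON turns layer index-group vectors into lists; coerce back.
restore_layer_fields <- function(comps) {
  lapply(comps, function(net) {
    lapply(net, function(layer) {
      layer$act <- as.character(layer$act)
      layer$kind <- as.character(layer$kind)
      layer$dropout <- as.numeric(layer$dropout)
      if (layer$kind == "blocked") {
        layer$in_groups <- lapply(layer$in_groups, function(g) as.integer(unlist(g)))
        layer$out_groups <- lapply(layer$out_groups, function(g) as.integer(unlist(g)))
      } else {
        layer$b <- as.numeric(layer$b)
      }
      layer
    })
  })
}
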