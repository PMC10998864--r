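# Minimal dense / block-structured feed-forward machinery with hand-written
# backpropagation. Layers are plain lists; a network is a list of layers.
# Shapes follow the x %*% W convention: W is (in x out), b length out.

leaky_slope_default <- 0.01

nn_act <- function(s, act, slope) {
  switch(act,
         # LeakyReLU written as a single abs() pass for speed
         leaky = 0.5 * ((1 + slope) * s + (1 - slope) * abs(s)),
         sigmoid = 1 / (1 + exp(-s)),
         identity = s)
}

nn_act_grad <- function(s, y, act, slope) {
  switch(act,
         leaky = 0.5 * ((1 + slope) + (1 - slope) * sign(s)),
         sigmoid = y * (1 - y),
         identity = 1)
}

# Uniform(-1/sqrt(in), 1/sqrt(in)) initialisation for a dense layer.
nn_dense <- function(n_in, n_out, act = "leaky", dropout = 0) {
  lim <- 1 / sqrt(n_in)
  list(kind = "dense",
       W = matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out),
       b = stats::runif(n_out, -lim, lim),
       act = act, dropout = dropout)
}

# Block-diagonal layer: block g maps input columns in_groups[[g]] to output
# columns out_groups[[g]]; there are no cross-block weights.
nn_blocked <- function(in_groups, out_groups, act = "leaky", dropout = 0) {
  stopifnot(length(in_groups) == length(out_groups))
  Ws <- vector("list", length(in_groups))
  bs <- vector("list", length(in_groups))
  for (g in seq_along(in_groups)) {
    n_in <- length(in_groups[[g]]); n_out <- length(out_groups[[g]])
    lim <- 1 / sqrt(n_in)
    Ws[[g]] <- matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
    bs[[g]] <- stats::runif(n_out, -lim, lim)
  }
  list(kind = "blocked", in_groups = in_groups, out_groups = out_groups,
       Ws = Ws, bs = bs, act = act, dropout = dropout)
}

layer_forward <- function(layer, x, training, slope) {
  n <- nrow(x)
  if (layer$kind == "dense") {
    s <- x %*% layer$W + rep(layer$b, each = n)
  } else {
    width <- max(unlist(layer$out_groups))
    s <- matrix(0, n, width)
    for (g in seq_along(layer$Ws)) {
      s[, layer$out_groups[[g]]] <- x[, layer$in_groups[[g]], drop = FALSE] %*%
        layer$Ws[[g]] + rep(layer$bs[[g]], each = n)
    }
  }
  y_pre <- nn_act(s, layer$act, slope)
  y <- y_pre
  drop_mask <- NULL
  if (training && layer$dropout > 0) {
    # inverted dropout: surviving activations rescaled so expectations match
    drop_mask <- matrix(stats::rbinom(length(y), 1, 1 - layer$dropout),
                        nrow(y), ncol(y)) / (1 - layer$dropout)
    y <- y_pre * drop_mask
  }
  list(y = y, cache = list(x = x, s = s, y_pre_drop = y_pre,
                           drop_mask = drop_mask))
}

layer_backward <- function(layer, cache, dy, slope) {
  if (!is.null(cache$drop_mask)) dy <- dy * cache$drop_mask
  ds <- dy * nn_act_grad(cache$s, cache$y_pre_drop, layer$act, slope)
  if (layer$kind == "dense") {
    gW <- crossprod(cache$x, ds)
    gb <- colSums(ds)
    dx <- tcrossprod(ds, layer$W)
    list(dx = dx, grads = list(W = gW, b = gb))
  } else {
    dx <- matrix(0, nrow(cache$x), ncol(cache$x))
    gWs <- vector("list", length(layer$Ws))
    gbs <- vector("list", length(layer$Ws))
    for (g in seq_along(layer$Ws)) {
      dsg <- ds[, layer$out_groups[[g]], drop = FALSE]
      xg <- cache$x[, layer$in_groups[[g]], drop = FALSE]
      gWs[[g]] <- crossprod(xg, dsg)
      gbs[[g]] <- colSums(dsg)
      dx[, layer$in_groups[[g]]] <- dx[, layer$in_groups[[g]], drop = FALSE] +
        tcrossprod(dsg, layer$Ws[[g]])
    }
    list(dx = dx, grads = list(Ws = gWs, bs = gbs))
  }
}

net_forward <- function(net, x, training = FALSE, slope = leaky_slope_default) {
  caches <- vector("list", length(net))
  for (i in seq_along(net)) {
    fw <- layer_forward(net[[i]], x, training, slope)
    x <- fw$y
    caches[[i]] <- fw$cache
  }
  list(y = x, caches = caches)
}

# `last_is_preact = TRUE` means `dy` is already the gradient at the last
# layer's pre-activation (used to fuse sigmoid outputs with cross-entropy
# losses for numerical stability).
net_backward <- function(net, caches, dy, slope = leaky_slope_default,
                         last_is_preact = FALSE) {
  grads <- vector("list", length(net))
  for (i in rev(seq_along(net))) {
    if (last_is_preact && i == length(net)) {
      bw <- layer_backward_preact(net[[i]], caches[[i]], dy)
    } else {
      bw <- layer_backward(net[[i]], caches[[i]], dy, slope)
    }
    grads[[i]] <- bw$grads
    dy <- bw$dx
  }
  list(dx = dy, grads = grads)
}

layer_backward_preact <- function(layer, cache, ds) {
  if (layer$kind == "dense") {
    list(dx = tcrossprod(ds, layer$W),
         grads = list(W = crossprod(cache$x, ds), b = colSums(ds)))
  } else {
    dx <- matrix(0, nrow(cache$x), ncol(cache$x))
    gWs <- vector("list", length(layer$Ws))
    gbs <- vector("list", length(layer$Ws))
    for (g in seq_along(layer$Ws)) {
      dsg <- ds[, layer$out_groups[[g]], drop = FALSE]
      xg <- cache$x[, layer$in_groups[[g]], drop = FALSE]
      gWs[[g]] <- crossprod(xg, dsg)
      gbs[[g]] <- colSums(dsg)
      dx[, layer$in_groups[[g]]] <- dx[, layer$in_groups[[g]], drop = FALSE] +
        tcrossprod(dsg, layer$Ws[[g]])
    }
    list(dx = dx, grads = list(Ws = gWs, bs = gbs))
  }
}

# --- parameter trees ---------------------------------------------------------
# Parameters live in nested lists of numeric arrays; these helpers walk two
# trees of identical shape (params + grads, or params + optimizer state).

tree_map2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- a
    for (i in seq_along(a)) out[[i]] <- tree_map2(a[[i]], b[[i]], f)
    out
  } else if (is.numeric(a)) f(a, b) else a
}

tree_map <- function(a, f) {
  if (is.list(a)) {
    out <- a
    for (i in seq_along(a)) out[[i]] <- tree_map(a[[i]], f)
    out
  } else if (is.numeric(a)) f(a) else a
}

tree_zeros_like <- function(a) tree_map(a, function(x) x * 0)

tree_add <- function(a, b) tree_map2(a, b, `+`)
tree_scale <- function(a, k) tree_map(a, function(x) x * k)

net_params <- function(net) {
  lapply(net, function(l) {
    if (l$kind == "dense") list(W = l$W, b = l$b) else list(Ws = l$Ws, bs = l$bs)
  })
}

net_set_params <- function(net, params) {
  for (i in seq_along(net)) {
    if (net[[i]]$kind == "dense") {
      net[[i]]$W <- params[[i]]$W; net[[i]]$b <- params[[i]]$b
    } else {
      net[[i]]$Ws <- params[[i]]$Ws; net[[i]]$bs <- params[[i]]$bs
    }
  }
  net
}

# --- optimizers --------------------------------------------------------------

adam_init <- function(params) {
  list(m = tree_zeros_like(params), v = tree_zeros_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr = 0.001,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- tree_map2(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  scale_ <- lr / (1 - beta1^state$t)
  c2 <- sqrt(1 - beta2^state$t)
  step_ <- tree_map2(state$m, state$v,
                     function(m, v) scale_ * m / (sqrt(v) / c2 + eps))
  params <- tree_map2(params, step_, `-`)
  list(params = params, state = state)
}

sgd_step <- function(params, grads, lr = 0.005) {
  tree_map2(params, grads, function(p, g) p - lr * g)
}

# Random Bernoulli input mask: zeroes `rate` of the entries, no rescaling of
# the survivors (masked-autoencoder style corruption, not dropout).
apply_input_mask <- function(x, rate) {
  if (rate <= 0) return(x)
  x * matrix(stats::rbinom(length(x), 1, 1 - rate), nrow(x), ncol(x))
}
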