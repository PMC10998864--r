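# Independent straight-line re-implementations used as oracles. These are
# deliberately naive (explicit loops, textbook formulas) and share no code
# with the package internals they check.

oracle_mse <- function(pred, target) {
  total <- 0
  for (i in seq_len(nrow(pred))) {
    total <- total + sum((pred[i, ] - target[i, ])^2)
  }
  total / nrow(pred)
}

oracle_bce <- function(pred, target) {
  total <- 0
  for (i in seq_len(nrow(pred))) {
    for (j in seq_len(ncol(pred))) {
      p <- min(max(pred[i, j], 1e-7), 1 - 1e-7)
      total <- total - (target[i, j] * log(p) + (1 - target[i, j]) * log(1 - p))
    }
  }
  total / nrow(pred)
}

oracle_kl <- function(mean_, logvar) {
  total <- 0
  for (i in seq_len(nrow(mean_))) {
    for (j in seq_len(ncol(mean_))) {
      total <- total - 0.5 * (1 + logvar[i, j] - mean_[i, j]^2 - exp(logvar[i, j]))
    }
  }
  total / nrow(mean_)
}

# Clustering metrics from first principles (contingency-table formulas).
oracle_cluster_metrics <- function(truth, clusters) {
  tab <- table(truth, clusters)
  n <- sum(tab)
  a <- rowSums(tab); b <- colSums(tab)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab)); sa <- sum(comb2(a)); sb <- sum(comb2(b))
  expd <- sa * sb / comb2(n)
  ari <- (sij - expd) / ((sa + sb) / 2 - expd)
  H <- function(cnt) { p <- cnt[cnt > 0] / sum(cnt); -sum(p * log(p)) }
  mi <- 0
  for (i in seq_along(a)) for (j in seq_along(b)) {
    if (tab[i, j] > 0)
      mi <- mi + tab[i, j] / n * log(tab[i, j] * n / (a[i] * b[j]))
  }
  nmi <- mi / ((H(a) + H(b)) / 2)
  # exact expected MI under the permutation model
  emi <- 0
  for (ai in a) for (bj in b) {
    for (nij in max(1, ai + bj - n):min(ai, bj)) {
      if (nij < 1) next
      lp <- lchoose(bj, nij) + lchoose(n - bj, ai - nij) - lchoose(n, ai)
      emi <- emi + exp(lp) * nij / n * log(nij * n / (ai * bj))
    }
  }
  ami <- (mi - emi) / ((H(a) + H(b)) / 2 - emi)
  hcond <- 0
  for (j in seq_along(b)) for (i in seq_along(a)) {
    if (tab[i, j] > 0) hcond <- hcond - tab[i, j] / n * log(tab[i, j] / b[j])
  }
  hom <- if (H(a) == 0) 1 else 1 - hcond / H(a)
  c(ari = unname(ari), ami = unname(ami), nmi = unname(nmi), hom = unname(hom))
}

# Minimum transport cost of a square instance with uniform marginals by
# brute force over permutations (Birkhoff: some permutation matrix / n is
# optimal).
oracle_emd_square <- function(cost) {
  n <- nrow(cost)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  best <- Inf
  for (p in perms(seq_len(n))) {
    val <- sum(cost[cbind(seq_len(n), p)]) / n
    if (val < best) best <- val
  }
  best
}

# LP solution of a (possibly rectangular) transport instance through an
# external solver (scipy.optimize.linprog); objective value only. Returns
# NULL when python is unavailable.
oracle_emd_lp <- function(cost, a, b) {
  py <- Sys.which("python")
  if (!nzchar(py)) return(NULL)
  script <- paste(
    "import sys, json, numpy as np",
    "from scipy.optimize import linprog",
    "spec = json.loads(sys.stdin.read())",
    "C = np.array(spec['cost']); a = np.array(spec['a']); b = np.array(spec['b'])",
    "n, m = C.shape",
    "Aeq = []",
    "for i in range(n): Aeq.append([1.0 if k // m == i else 0.0 for k in range(n * m)])",
    "for j in range(m): Aeq.append([1.0 if k % m == j else 0.0 for k in range(n * m)])",
    "res = linprog(C.ravel(), A_eq=np.array(Aeq), b_eq=np.concatenate([a, b]),",
    "              bounds=(0, None), method='highs')",
    "print(json.dumps(res.fun))", sep = "\n")
  payload <- jsonlite::toJSON(list(cost = cost, a = a, b = b), digits = NA)
  out <- system2(py, c("-c", shQuote(script)), input = as.character(payload),
                 stdout = TRUE, stderr = FALSE)
  if (is.null(attr(out, "status"))) jsonlite::fromJSON(out) else NULL
}

# sklearn cross-check (pre-installed python); returns NULL if unavailable.
sklearn_cluster_metrics <- function(truth, clusters) {
  py <- Sys.which("python")
  if (!nzchar(py)) return(NULL)
  script <- paste(
    "import sys, json",
    "from sklearn import metrics",
    "t = sys.argv[1].split(','); c = sys.argv[2].split(',')",
    "print(json.dumps({'ari': metrics.adjusted_rand_score(t, c),",
    " 'ami': metrics.adjusted_mutual_info_score(t, c),",
    " 'nmi': metrics.normalized_mutual_info_score(t, c),",
    " 'hom': metrics.homogeneity_score(t, c)}))",
    sep = "\n")
  out <- suppressWarnings(system2(py, c("-c", shQuote(script),
                                        shQuote(paste(truth, collapse = ",")),
                                        shQuote(paste(clusters, collapse = ","))),
                                  stdout = TRUE, stderr = FALSE))
  if (is.null(attr(out, "status"))) unlist(jsonlite::fromJSON(out)) else NULL
}

# Small paired fixture shared by several training tests.
make_small_multiome <- function(seed = 11, n_cells = 150) {
  simulate_paired_multiome(n_cells = n_cells, n_genes = 60, n_peaks = 90,
                           n_types = 3, n_chroms = 3, seed = seed)
}

# Zero all weights/biases of a network without touching its structure fields.
zero_net <- function(net) {
  dualvae:::net_set_params(net, dualvae:::tree_zeros_like(dualvae:::net_params(net)))
}
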