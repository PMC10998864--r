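# Evaluation protocols: clustering-agreement metrics on a PCA + Leiden
# pipeline, classification metrics, perturbation DEG overlap / bootstrap R^2,
# and per-cell correlation summaries for protein predictions.

entropy_counts <- function(n) {
  p <- n[n > 0] / sum(n)
  -sum(p * log(p))
}

#' Clustering agreement metrics from a contingency table
#'
#' Computes the adjusted Rand index (ARI), adjusted and normalised mutual
#' information (AMI, NMI; both normalised by the arithmetic mean of the
#' label entropies, with AMI additionally corrected by the exact expected
#' mutual information under the permutation model) and homogeneity (HOM,
#' one minus the conditional entropy of the true labels given the
#' clusters over the true-label entropy).
#'
#' @param true_labels,cluster_labels label vectors of equal length.
#' @return named numeric vector with \code{ari}, \code{ami}, \code{nmi},
#'   \code{hom}.
#' @export
cluster_agreement <- function(true_labels, cluster_labels) {
  stopifnot(length(true_labels) == length(cluster_labels))
  tab <- table(true_labels, cluster_labels)
  n <- sum(tab)
  a <- rowSums(tab); b <- colSums(tab)
  # ARI
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(a, 2)); sum_b <- sum(choose(b, 2))
  exp_idx <- sum_a * sum_b / choose(n, 2)
  max_idx <- (sum_a + sum_b) / 2
  ari <- if (max_idx == exp_idx) 1 else (sum_ij - exp_idx) / (max_idx - exp_idx)
  # MI and entropies
  p <- tab / n
  pa <- a / n; pb <- b / n
  nzi <- which(p > 0, arr.ind = TRUE)
  mi <- sum(p[nzi] * log(p[nzi] / (pa[nzi[, 1]] * pb[nzi[, 2]])))
  ha <- entropy_counts(a); hb <- entropy_counts(b)
  mean_h <- (ha + hb) / 2
  nmi <- if (mean_h == 0) 1 else mi / mean_h
  emi <- expected_mutual_information(a, b, n)
  denom <- mean_h - emi
  ami <- if (abs(denom) < 1e-12) 1 else (mi - emi) / denom
  # homogeneity
  h_cond <- 0
  for (j in seq_along(b)) {
    cj <- tab[, j]
    nz <- cj[cj > 0]
    h_cond <- h_cond - sum(nz / n * log(nz / b[j]))
  }
  hom <- if (ha == 0) 1 else 1 - h_cond / ha
  c(ari = ari, ami = ami, nmi = nmi, hom = hom)
}

# Exact expected mutual information under the hypergeometric permutation
# model (the standard correction used by the AMI).
expected_mutual_information <- function(a, b, n) {
  emi <- 0
  lgn <- lgamma(n + 1)
  for (ai in a) {
    for (bj in b) {
      lo <- max(1, ai + bj - n)
      hi <- min(ai, bj)
      if (hi < lo) next
      nij <- lo:hi
      lp <- lgamma(ai + 1) + lgamma(bj + 1) + lgamma(n - ai + 1) + lgamma(n - bj + 1) -
        lgn - lgamma(nij + 1) - lgamma(ai - nij + 1) - lgamma(bj - nij + 1) -
        lgamma(pmax(n - ai - bj + nij, 0) + 1)
      term <- nij / n * log(nij * n / (ai * bj))
      emi <- emi + sum(exp(lp) * term)
    }
  }
  emi
}

#' Leiden clustering of an embedding
#'
#' Builds a k-nearest-neighbour graph (Euclidean, undirected union of
#' neighbourhoods) and runs the Leiden community-detection algorithm with
#' the modularity objective.
#'
#' @param emb cells x dims embedding matrix.
#' @param resolution Leiden resolution parameter.
#' @param k_neighbors neighbourhood size (default 15).
#' @param n_iterations Leiden refinement iterations.
#' @return integer membership vector.
#' @export
leiden_cluster <- function(emb, resolution = 1, k_neighbors = 15,
                           n_iterations = 5) {
  emb <- as.matrix(emb)
  n <- nrow(emb)
  k <- min(k_neighbors, n - 1)
  d <- as.matrix(stats::dist(emb))
  edges <- NULL
  for (i in seq_len(n)) {
    nb <- order(d[i, ])[2:(k + 1)]
    edges <- rbind(edges, cbind(i, nb))
  }
  edges <- t(apply(edges, 1, sort))
  edges <- unique(edges)
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  cl <- igraph::cluster_leiden(g, objective_function = "modularity",
                               resolution = resolution,
                               n_iterations = n_iterations)
  igraph::membership(cl)
}

#' Clustering-based heterogeneity evaluation of a profile matrix
#'
#' The protocol used to judge how much cell heterogeneity a (translated)
#' profile matrix preserves: PCA to \code{n_pcs} dimensions (reduced with
#' a warning when there are fewer cells), a 15-nearest-neighbour graph,
#' Leiden clustering at resolution 1, and the four agreement metrics of
#' [cluster_agreement()] against the true cell-type labels.
#'
#' @param values cells x features matrix (predicted or raw profiles), or a
#'   \code{predicted_matrix} / \code{processed_matrix}.
#' @param true_labels per-cell type labels.
#' @param n_pcs PCA dimensionality (default 50).
#' @param resolution Leiden resolution (default 1).
#' @param k_neighbors neighbourhood size (default 15).
#' @return list of class \code{eval_report} with \code{metrics} (ari, ami,
#'   nmi, hom), \code{cluster_labels} and the protocol parameters.
#' @export
clustering_heterogeneity_eval <- function(values, true_labels, n_pcs = 50,
                                          resolution = 1, k_neighbors = 15) {
  v <- if (is.list(values) && !is.null(values$values)) values$values else as.matrix(values)
  stopifnot(length(true_labels) == nrow(v))
  if (nrow(v) <= n_pcs) {
    warning("clustering_heterogeneity_eval: fewer cells than requested PCs; ",
            "reducing to n - 1")
    n_pcs <- nrow(v) - 1
  }
  emb <- pca_embed(v, n_pcs)
  cl <- leiden_cluster(emb, resolution = resolution, k_neighbors = k_neighbors)
  structure(list(metrics = cluster_agreement(true_labels, cl),
                 cluster_labels = as.integer(cl),
                 params = list(n_pcs = n_pcs, resolution = resolution,
                               k_neighbors = k_neighbors)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>\n")
  print(round(x$metrics, 4))
  invisible(x)
}

#' Classification metrics for cell-type annotation
#'
#' Accuracy, Cohen's kappa (chance agreement from the marginals), and the
#' macro- and support-weighted averages of the per-class F1 scores.
#' When the truth contains a single class, kappa is undefined and reported
#' as 0 with \code{kappa_defined = FALSE}.
#'
#' @param pred_labels,true_labels label vectors of equal length.
#' @return list of class \code{eval_report} with \code{metrics} (acc,
#'   kappa, f1_macro, f1_weighted) and \code{kappa_defined}.
#' @export
annotation_metrics <- function(pred_labels, true_labels) {
  stopifnot(length(pred_labels) == length(true_labels))
  pred_labels <- as.character(pred_labels); true_labels <- as.character(true_labels)
  classes <- sort(unique(c(pred_labels, true_labels)))
  tab <- table(factor(true_labels, classes), factor(pred_labels, classes))
  n <- sum(tab)
  acc <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  kappa_defined <- pe < 1
  kappa <- if (kappa_defined) (acc - pe) / (1 - pe) else 0
  f1 <- numeric(length(classes)); support <- numeric(length(classes))
  for (ci in seq_along(classes)) {
    tp <- tab[ci, ci]
    fp <- sum(tab[-ci, ci]); fn <- sum(tab[ci, -ci])
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1[ci] <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    support[ci] <- sum(tab[ci, ])
  }
  present <- support > 0   # macro/weighted averages over classes present in truth
  structure(list(metrics = c(acc = acc, kappa = kappa,
                             f1_macro = mean(f1[present]),
                             f1_weighted = sum(f1[present] * support[present]) /
                               sum(support[present])),
                 kappa_defined = kappa_defined),
            class = "eval_report")
}

#' One-sided rank-sum differential-expression ranking
#'
#' Ranks genes by a one-sided Wilcoxon rank-sum z-score (ties mid-ranked,
#' tie-corrected variance, alternative: greater in the second group).
#'
#' @param x,y cells x genes matrices for the two groups (same genes).
#' @return integer vector of gene indices ordered from most to least
#'   significantly up in \code{y}; attribute \code{z} carries the scores.
#' @export
rank_sum_deg <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  stopifnot(ncol(x) == ncol(y))
  n1 <- nrow(x); n2 <- nrow(y); n <- n1 + n2
  z <- numeric(ncol(x))
  for (j in seq_len(ncol(x))) {
    v <- c(x[, j], y[, j])
    r <- rank(v)
    w <- sum(r[(n1 + 1):n])          # rank sum of group y
    mu <- n2 * (n + 1) / 2
    ties <- table(v)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z[j] <- if (sigma2 > 0) (w - mu) / sqrt(sigma2) else 0
  }
  ord <- order(z, decreasing = TRUE)
  attr(ord, "z") <- z
  ord
}

#' Perturbation-response prediction metrics
#'
#' Two summaries of how well predicted stimulated profiles reproduce the
#' real response: (1) the number of genes shared between the top
#' \code{n_top} real DEGs (control vs real stimulated, one-sided rank-sum
#' ranking) and the top \code{n_top} predicted DEGs (control vs predicted
#' stimulated); (2) over \code{n_boot} resamples drawing \code{frac} of
#' the test cells with replacement, the squared Pearson correlation of the
#' mean expression of the top-\code{n_top} real DEGs between predicted and
#' real stimulated cells, reported as mean and sd.
#'
#' @param ctrl,real_stim,pred_stim cells x genes expression matrices. When
#'   \code{pred_stim} has the same number of rows as \code{real_stim} the
#'   two are treated as row-aligned and each bootstrap draws the same cells
#'   from both; otherwise they are resampled independently.
#' @param n_top number of top DEGs (default 100).
#' @param n_boot bootstrap replicates (default 100).
#' @param frac resample fraction (default 0.8).
#' @return list of class \code{eval_report}: \code{metrics} holds
#'   \code{common_degs}, \code{r2_mean}, \code{r2_sd}; \code{real_degs}
#'   and \code{pred_degs} hold the rankings.
#' @export
perturbation_metrics <- function(ctrl, real_stim, pred_stim, n_top = 100,
                                 n_boot = 100, frac = 0.8) {
  ctrl <- as.matrix(ctrl); real_stim <- as.matrix(real_stim)
  pred_stim <- as.matrix(pred_stim)
  n_top <- min(n_top, ncol(ctrl))
  real_ord <- rank_sum_deg(ctrl, real_stim)
  pred_ord <- rank_sum_deg(ctrl, pred_stim)
  top_real <- real_ord[seq_len(n_top)]
  top_pred <- pred_ord[seq_len(n_top)]
  common <- length(intersect(top_real, top_pred))
  aligned <- nrow(pred_stim) == nrow(real_stim)
  r2 <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    ir <- sample.int(nrow(real_stim), ceiling(frac * nrow(real_stim)), replace = TRUE)
    # row-aligned matrices resample the same cells; otherwise independently
    ip <- if (aligned) ir else
      sample.int(nrow(pred_stim), ceiling(frac * nrow(pred_stim)), replace = TRUE)
    mr <- colMeans(real_stim[ir, top_real, drop = FALSE])
    mp <- colMeans(pred_stim[ip, top_real, drop = FALSE])
    r2[b] <- stats::cor(mr, mp)^2
  }
  structure(list(metrics = c(common_degs = common, r2_mean = mean(r2),
                             r2_sd = stats::sd(r2)),
                 real_degs = top_real, pred_degs = top_pred, r2 = r2,
                 params = list(n_top = n_top, n_boot = n_boot, frac = frac)),
            class = "eval_report")
}

#' Per-cell correlation between real and predicted protein profiles
#'
#' Pearson and Spearman correlation of each cell's real vs predicted
#' protein vector, summarised as mean and median.
#'
#' @param real,pred cells x proteins matrices (CLR scale), row-aligned.
#' @return list of class \code{eval_report}: \code{metrics} holds
#'   \code{pearson_mean/median}, \code{spearman_mean/median};
#'   \code{per_cell} holds both full vectors.
#' @export
adt_correlations <- function(real, pred) {
  real <- as.matrix(real); pred <- as.matrix(pred)
  stopifnot(all(dim(real) == dim(pred)))
  pear <- vapply(seq_len(nrow(real)),
                 function(i) stats::cor(real[i, ], pred[i, ]), numeric(1))
  spear <- vapply(seq_len(nrow(real)),
                  function(i) stats::cor(real[i, ], pred[i, ], method = "spearman"),
                  numeric(1))
  structure(list(metrics = c(pearson_mean = mean(pear),
                             pearson_median = stats::median(pear),
                             spearman_mean = mean(spear),
                             spearman_median = stats::median(spear)),
                 per_cell = list(pearson = pear, spearman = spear)),
            class = "eval_report")
}
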