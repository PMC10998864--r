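#' Construct a paired dataset
#'
#' A pair table linking rows of the modality-1 matrix with rows of the
#' modality-2 matrix, with an origin tag per pair (\code{original},
#' \code{shuffled_round_1}, \code{shuffled_round_2},
#' \code{unpaired_sampled}, \code{ot_matched}) and an optional group label.
#'
#' @param idx1,idx2 integer indices into the two matrices.
#' @param origin character vector (recycled) of origin tags.
#' @param group optional per-pair group label.
#' @return list of class \code{paired_dataset} with a data frame
#'   \code{pairs}.
#' @export
paired_dataset <- function(idx1, idx2, origin = "original", group = NA_character_) {
  stopifnot(length(idx1) == length(idx2))
  structure(list(pairs = data.frame(idx1 = as.integer(idx1),
                                    idx2 = as.integer(idx2),
                                    origin = rep_len(as.character(origin), length(idx1)),
                                    group = rep_len(as.character(group), length(idx1)),
                                    stringsAsFactors = FALSE)),
            class = "paired_dataset")
}

#' @export
print.paired_dataset <- function(x, ...) {
  cat(sprintf("<paired_dataset> %d pairs\n", nrow(x$pairs)))
  print(table(x$pairs$origin))
  invisible(x)
}

#' Cell-type (or cluster) based training-set augmentation
#'
#' Starts from the n original pairs (cell i with itself) and, for each
#' shuffling round and each label group, adds pairs matching modality 1 of
#' cell i with modality 2 of a uniformly chosen within-group permutation
#' of the same cells. With the default two rounds the output holds
#' exactly 3n pairs: n originals plus 2n synthetic ones.
#'
#' @param n_cells number of paired cells.
#' @param labels per-cell group labels (cell type or cluster), length
#'   \code{n_cells}.
#' @param rounds number of shuffling rounds (default 2).
#' @return a [paired_dataset()] with \code{(rounds + 1) * n_cells} pairs.
#' @export
augment_by_label <- function(n_cells, labels, rounds = 2) {
  if (rounds < 0) stop("augment_by_label: rounds must be >= 0")
  labels <- as.character(labels)
  if (length(labels) != n_cells)
    stop("augment_by_label: labels must have length ", n_cells)
  idx1 <- seq_len(n_cells)
  out <- list(data.frame(idx1 = idx1, idx2 = idx1, origin = "original",
                         group = labels, stringsAsFactors = FALSE))
  groups <- split(seq_len(n_cells), labels)
  for (r in seq_len(rounds)) {
    idx2 <- integer(n_cells)
    for (g in groups) idx2[g] <- if (length(g) == 1) g else sample(g)
    out[[r + 1L]] <- data.frame(idx1 = idx1, idx2 = idx2,
                                origin = paste0("shuffled_round_", r),
                                group = labels, stringsAsFactors = FALSE)
  }
  structure(list(pairs = do.call(rbind, out)), class = "paired_dataset")
}

#' Derive cluster labels from a joint embedding for label-free augmentation
#'
#' When no cell-type annotation is available, the augmentation groups come
#' from unsupervised clustering: a joint embedding of the paired cells is
#' clustered with the Leiden algorithm at a deliberately high resolution
#' (default 3) so clusters are small and pure. The default embedding
#' provider computes a 50-component PCA per modality, z-scores each, and
#' concatenates them; any function \code{(rna_values, second_values) ->
#' embedding matrix} can be plugged in instead, and a pre-computed label
#' vector (e.g. from an external joint model) is passed through verbatim.
#'
#' @param rna,second \code{processed_matrix} objects (or plain matrices)
#'   over the same cells, row-aligned.
#' @param resolution Leiden resolution (default 3).
#' @param provider joint-embedding function, or a character/factor vector
#'   of pre-computed labels (returned as-is), or NULL for the built-in
#'   PCA-concatenation provider.
#' @param n_pcs components per modality for the default provider.
#' @param k_neighbors neighbourhood size of the clustering graph.
#' @return integer cluster labels, one per cell.
#' @export
derive_cluster_labels <- function(rna, second, resolution = 3, provider = NULL,
                                  n_pcs = 50, k_neighbors = 15) {
  if (is.character(provider) || is.factor(provider)) return(as.character(provider))
  vx <- if (inherits(rna, "processed_matrix")) rna$values else as.matrix(rna)
  vy <- if (inherits(second, "processed_matrix")) second$values else as.matrix(second)
  if (nrow(vx) != nrow(vy))
    stop("derive_cluster_labels: matrices must be row-aligned (same cells)")
  emb <- if (is.function(provider)) {
    provider(vx, vy)
  } else {
    # scale each modality's PCA block as a whole so neither dominates while
    # the within-modality variance ordering of the components is preserved
    block_scale <- function(m) {
      m <- sweep(m, 2, colMeans(m))
      s <- stats::sd(as.numeric(m))
      if (s > 0) m / s else m
    }
    cbind(block_scale(pca_embed(vx, n_pcs)), block_scale(pca_embed(vy, n_pcs)))
  }
  leiden_cluster(emb, resolution = resolution, k_neighbors = k_neighbors)
}

#' Proportion-matched pairing of unpaired datasets
#'
#' For two datasets measured on different cells, pairs are sampled within
#' the cell types present in both: type i receives sampling proportion
#' \code{s_i = (s_i^1 + s_i^2) / sum_k (s_k^1 + s_k^2)} (the normalised
#' average of its per-dataset proportions) and contributes
#' \code{round(s_i * (n_1 + n_2) / 2)} pairs (round-half-to-even), each
#' drawn by independently sampling one cell of that type from each dataset
#' (with replacement whenever a pool is smaller than its quota).
#' Cell types not shared between the datasets are excluded from pairing.
#'
#' @param labels1,labels2 per-cell type labels of the two datasets.
#' @return a [paired_dataset()] with origin \code{unpaired_sampled};
#'   attribute \code{proportions} carries the s_i used.
#' @export
pair_unpaired_by_type <- function(labels1, labels2) {
  labels1 <- as.character(labels1); labels2 <- as.character(labels2)
  shared <- intersect(unique(labels1), unique(labels2))
  if (length(shared) == 0) stop("pair_unpaired_by_type: no shared cell types")
  n1 <- length(labels1); n2 <- length(labels2)
  s1 <- table(factor(labels1, levels = shared)) / n1
  s2 <- table(factor(labels2, levels = shared)) / n2
  s <- (as.numeric(s1) + as.numeric(s2))
  s <- s / sum(s)
  names(s) <- shared
  out <- NULL
  for (i in seq_along(shared)) {
    quota <- round(s[i] * (n1 + n2) / 2)
    if (quota == 0) next
    pool1 <- which(labels1 == shared[i])
    pool2 <- which(labels2 == shared[i])
    i1 <- pool1[sample.int(length(pool1), quota, replace = quota > length(pool1))]
    i2 <- pool2[sample.int(length(pool2), quota, replace = quota > length(pool2))]
    out <- rbind(out, data.frame(idx1 = i1, idx2 = i2, origin = "unpaired_sampled",
                                 group = shared[i], stringsAsFactors = FALSE))
  }
  res <- structure(list(pairs = out), class = "paired_dataset")
  attr(res, "proportions") <- s
  res
}
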