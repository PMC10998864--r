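# Synthetic paired multi-omics generators with known ground truth. Cells of
# the same index share one latent type factor across modalities, so a
# translator can in principle recover the cross-modality mapping exactly.
# Counts are Poisson (RNA), Bernoulli (ATAC peaks) and negative binomial
# with additive background (ADT), deliberately simple mechanistic stand-ins
# for real assays.

simulate_latents <- function(n_cells, n_types, n_factors, type_scale, cell_noise,
                             type_probs = NULL) {
  if (n_types > n_cells) stop("simulate: n_types > n_cells")
  if (is.null(type_probs)) type_probs <- rep(1 / n_types, n_types)
  types <- sample.int(n_types, n_cells, replace = TRUE, prob = type_probs)
  # guarantee every type appears
  types[seq_len(n_types)] <- seq_len(n_types)
  mu <- matrix(stats::rnorm(n_types * n_factors, 0, type_scale), n_types, n_factors)
  z <- mu[types, , drop = FALSE] +
    matrix(stats::rnorm(n_cells * n_factors, 0, cell_noise), n_cells, n_factors)
  list(types = types, mu = mu, z = z)
}

#' Simulate a paired RNA + ATAC multiome dataset
#'
#' Each cell draws a type and a shared latent factor vector z; RNA counts
#' are Poisson with log-rate \code{offset_g + (A z)_g + size_i} (plus an
#' optional per-gene batch shift), ATAC peaks are Bernoulli with logit
#' \code{atac_offset + (B z)_j}. Peaks are assigned round-robin to
#' \code{n_chroms} chromosomes with interval-style names so every
#' per-chromosome encoder block is exercised even at small peak counts.
#' The same cell index carries the same z in both modalities.
#'
#' @param n_cells,n_genes,n_peaks,n_types,n_chroms dataset dimensions.
#' @param batch_effect scalar >= 0; a per-gene/peak shift of this scale
#'   separates two batches (0 disables batch structure).
#' @param n_factors latent dimensionality of the type factors.
#' @param type_scale sd of the type centroids in latent space.
#' @param cell_noise within-type latent sd.
#' @param atac_offset baseline peak-openness logit (more negative =
#'   sparser; sparsity is monotone in this offset).
#' @param seed integer seed (NULL: current RNG state).
#' @return list with \code{rna}, \code{atac} ([count_matrix()]s carrying
#'   cell/batch labels) and \code{truth} (types, latent factors, loadings,
#'   seed).
#' @export
simulate_paired_multiome <- function(n_cells = 500, n_genes = 300, n_peaks = 400,
                                     n_types = 5, n_chroms = 3, batch_effect = 0,
                                     n_factors = 10, type_scale = 1.5,
                                     cell_noise = 0.3, atac_offset = -2,
                                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lat <- simulate_latents(n_cells, n_types, n_factors, type_scale, cell_noise)
  A <- matrix(stats::rnorm(n_genes * n_factors), n_genes, n_factors) / sqrt(n_factors)
  B <- matrix(stats::rnorm(n_peaks * n_factors), n_peaks, n_factors) / sqrt(n_factors)
  gene_offset <- stats::rnorm(n_genes, 0.3, 0.3)
  size_f <- stats::rnorm(n_cells, 0, 0.2)
  batches <- rep_len(c("b1", "b2"), n_cells)
  rna_lograte <- tcrossprod(lat$z, A) +
    rep(gene_offset, each = n_cells) + size_f
  atac_logit <- tcrossprod(lat$z, B) + atac_offset
  if (batch_effect > 0) {
    shift_r <- matrix(stats::rnorm(2 * n_genes, 0, batch_effect), 2, n_genes)
    shift_a <- matrix(stats::rnorm(2 * n_peaks, 0, batch_effect), 2, n_peaks)
    bidx <- as.integer(factor(batches))
    rna_lograte <- rna_lograte + shift_r[bidx, , drop = FALSE]
    atac_logit <- atac_logit + shift_a[bidx, , drop = FALSE]
  }
  rna_counts <- matrix(stats::rpois(n_cells * n_genes, exp(rna_lograte)),
                       n_cells, n_genes)
  atac_counts <- matrix(stats::rbinom(n_cells * n_peaks, 1, stats::plogis(atac_logit)),
                        n_cells, n_peaks)
  chrom <- rep_len(paste0("chr", seq_len(n_chroms)), n_peaks)
  start <- 1000 * seq_len(n_peaks)
  peak_ids <- paste0(chrom, ":", start, "-", start + 500)
  types <- paste0("type_", lat$types)
  list(
    rna = count_matrix(rna_counts, feature_ids = paste0("gene_", seq_len(n_genes)),
                       modality = "rna", cell_labels = types, batch_labels = batches),
    atac = count_matrix(atac_counts, feature_ids = peak_ids, modality = "atac",
                        cell_labels = types, batch_labels = batches),
    truth = list(types = types, z = lat$z, type_means = lat$mu,
                 rna_loadings = A, atac_loadings = B, chrom = chrom, seed = seed))
}

#' Simulate a paired RNA + surface-protein (CITE-style) dataset
#'
#' RNA as in [simulate_paired_multiome()]; protein counts are negative
#' binomial with mean \code{exp(offset_p + (C z)_p)} plus an additive
#' Poisson background per protein, emulating the ambient antibody signal
#' of real surface-proteome panels.
#'
#' @inheritParams simulate_paired_multiome
#' @param n_proteins size of the antibody panel (e.g. 25 or 134).
#' @param dispersion negative-binomial size parameter.
#' @param background mean of the per-protein additive background counts
#'   (0 disables background).
#' @return list with \code{rna}, \code{adt} and \code{truth}.
#' @export
simulate_cite <- function(n_cells = 500, n_genes = 300, n_proteins = 25,
                          n_types = 5, n_factors = 10, type_scale = 1.5,
                          cell_noise = 0.3, dispersion = 10, background = 5,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lat <- simulate_latents(n_cells, n_types, n_factors, type_scale, cell_noise)
  A <- matrix(stats::rnorm(n_genes * n_factors), n_genes, n_factors) / sqrt(n_factors)
  C <- matrix(stats::rnorm(n_proteins * n_factors), n_proteins, n_factors) / sqrt(n_factors)
  gene_offset <- stats::rnorm(n_genes, 0.3, 0.3)
  prot_offset <- stats::rnorm(n_proteins, 3, 0.5)
  size_f <- stats::rnorm(n_cells, 0, 0.2)
  rna_counts <- matrix(stats::rpois(n_cells * n_genes,
                                    exp(tcrossprod(lat$z, A) +
                                          rep(gene_offset, each = n_cells) + size_f)),
                       n_cells, n_genes)
  adt_mu <- exp(tcrossprod(lat$z, C) + rep(prot_offset, each = n_cells))
  adt_counts <- matrix(stats::rnbinom(n_cells * n_proteins, mu = adt_mu,
                                      size = dispersion),
                       n_cells, n_proteins)
  if (background > 0) {
    bg_rate <- stats::runif(n_proteins, 0, 2 * background)
    adt_counts <- adt_counts +
      matrix(stats::rpois(n_cells * n_proteins, rep(bg_rate, each = n_cells)),
             n_cells, n_proteins)
  }
  types <- paste0("type_", lat$types)
  list(
    rna = count_matrix(rna_counts, feature_ids = paste0("gene_", seq_len(n_genes)),
                       modality = "rna", cell_labels = types),
    adt = count_matrix(adt_counts, feature_ids = paste0("prot_", seq_len(n_proteins)),
                       modality = "adt", cell_labels = types),
    truth = list(types = types, z = lat$z, adt_loadings = C, adt_mu = adt_mu,
                 seed = seed))
}

#' Simulate a control / stimulated perturbation dataset
#'
#' Control cells follow the RNA model of [simulate_paired_multiome()];
#' stimulated cells are drawn independently from the same type structure
#' with \code{lfc} added to the log-rates of \code{n_degs} randomly chosen
#' genes, uniformly across types. One type can be marked as the held-out
#' test type for out-of-sample prediction. The default of seven types
#' mirrors the seven-cell-type control/stimulated PBMC design this
#' generator emulates.
#'
#' @inheritParams simulate_paired_multiome
#' @param n_degs number of planted differentially expressed genes.
#' @param lfc log-fold-change added to the planted genes on stimulation.
#' @param holdout_type type id (integer in 1..n_types) marked as test
#'   type, or NULL.
#' @return list with \code{ctrl}, \code{stim} ([count_matrix()]s, each
#'   \code{n_cells} cells) and \code{truth} (including \code{deg_idx}).
#' @export
simulate_perturbation <- function(n_cells = 600, n_genes = 300, n_types = 7,
                                  n_degs = 40, lfc = 2, holdout_type = NULL,
                                  n_factors = 10, type_scale = 1.5,
                                  cell_noise = 0.3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_degs < 1) stop("simulate_perturbation: n_degs must be >= 1")
  lat_mu <- matrix(stats::rnorm(n_types * n_factors, 0, type_scale), n_types, n_factors)
  A <- matrix(stats::rnorm(n_genes * n_factors), n_genes, n_factors) / sqrt(n_factors)
  gene_offset <- stats::rnorm(n_genes, 0.3, 0.3)
  deg_idx <- sort(sample.int(n_genes, n_degs))
  draw_condition <- function(add_lfc) {
    types <- sample.int(n_types, n_cells, replace = TRUE)
    types[seq_len(n_types)] <- seq_len(n_types)
    z <- lat_mu[types, , drop = FALSE] +
      matrix(stats::rnorm(n_cells * n_factors, 0, cell_noise), n_cells, n_factors)
    lr <- tcrossprod(z, A) + rep(gene_offset, each = n_cells) +
      stats::rnorm(n_cells, 0, 0.2)
    if (add_lfc) lr[, deg_idx] <- lr[, deg_idx] + lfc
    counts <- matrix(stats::rpois(n_cells * n_genes, exp(lr)), n_cells, n_genes)
    list(counts = counts, types = paste0("type_", types))
  }
  ctrl <- draw_condition(FALSE)
  stim <- draw_condition(TRUE)
  gene_ids <- paste0("gene_", seq_len(n_genes))
  list(
    ctrl = count_matrix(ctrl$counts, feature_ids = gene_ids, modality = "rna",
                        cell_labels = ctrl$types),
    stim = count_matrix(stim$counts, feature_ids = gene_ids, modality = "rna",
                        cell_labels = stim$types),
    truth = list(deg_idx = deg_idx, lfc = lfc,
                 holdout_type = if (is.null(holdout_type)) NULL
                 else paste0("type_", holdout_type),
                 seed = seed))
}
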