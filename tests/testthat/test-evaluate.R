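# Clustering agreement metrics ------------------------------------------------

test_that("perfect clustering scores 1 on every agreement metric", {
  labs <- rep(c("a", "b", "c"), each = 8)
  m <- cluster_agreement(labs, labs)
  expect_equal(unname(m), rep(1, 4))
})

test_that("the 6-cell hand case matches direct formula evaluation", {
  truth <- c("x", "x", "x", "y", "y", "y")
  clusters <- c("a", "a", "b", "b", "b", "a")
  m <- cluster_agreement(truth, clusters)
  expect_equal(unname(m["ari"]), -1 / 9, tolerance = 1e-12)
  expect_equal(unname(m["ami"]), -0.1111111, tolerance = 1e-6)
  expect_equal(unname(m["nmi"]), 0.0817042, tolerance = 1e-6)
  expect_equal(unname(m["hom"]), 0.0817042, tolerance = 1e-6)
  expect_equal(m, oracle_cluster_metrics(truth, clusters), tolerance = 1e-10)
})

test_that("metrics match the straight-line oracle on random label vectors", {
  set.seed(1)
  for (i in 1:100) {
    n <- sample(8:50, 1)
    truth <- sample(letters[1:sample(2:5, 1)], n, replace = TRUE)
    clus <- sample(letters[1:sample(2:5, 1)], n, replace = TRUE)
    if (length(unique(truth)) < 2 || length(unique(clus)) < 2) next
    expect_equal(cluster_agreement(truth, clus),
                 oracle_cluster_metrics(truth, clus), tolerance = 1e-8)
  }
})

test_that("metrics agree with the external reference implementations", {
  set.seed(2)
  truth <- sample(c("a", "b", "c"), 40, replace = TRUE)
  clus <- sample(c("p", "q", "r", "s"), 40, replace = TRUE)
  m <- cluster_agreement(truth, clus)
  expect_equal(unname(m["ari"]), mclust::adjustedRandIndex(truth, clus),
               tolerance = 1e-10)
  sk <- sklearn_cluster_metrics(truth, clus)
  if (!is.null(sk)) expect_equal(unname(m), unname(sk[c("ari", "ami", "nmi", "hom")]),
                                 tolerance = 1e-7)
})

test_that("ARI is invariant to label permutation; AMI/NMI are symmetric", {
  set.seed(3)
  truth <- sample(c("a", "b", "c"), 30, replace = TRUE)
  clus <- sample(c("p", "q"), 30, replace = TRUE)
  relab <- c(a = "z1", b = "z2", c = "z3")[truth]
  expect_equal(cluster_agreement(truth, clus)["ari"],
               cluster_agreement(relab, clus)["ari"])
  expect_equal(cluster_agreement(truth, clus)[c("ami", "nmi")],
               cluster_agreement(clus, truth)[c("ami", "nmi")],
               tolerance = 1e-10)
})

test_that("random balanced clusterings score near zero ARI", {
  set.seed(4)
  n <- 400
  truth <- rep(c("a", "b", "c", "d"), each = n / 4)
  aris <- replicate(10, cluster_agreement(truth, sample(truth))["ari"])
  expect_lt(max(abs(aris)), 0.05)
})

test_that("the PCA + Leiden protocol recovers planted structure", {
  sim <- make_small_multiome(seed = 31, n_cells = 120)
  px <- preprocess_rna(sim$rna, 60)
  set.seed(5)
  ev <- clustering_heterogeneity_eval(px$values, sim$rna$cell_labels)
  expect_gte(ev$metrics["ari"], 0.9)
  expect_warning(clustering_heterogeneity_eval(px$values[1:30, ],
                                               sim$rna$cell_labels[1:30]),
                 "fewer cells")
})

# Annotation metrics ----------------------------------------------------------

test_that("annotation metrics: perfect, hand case, degenerate truth", {
  labs <- rep(c("A", "B"), 5)
  perfect <- annotation_metrics(labs, labs)
  expect_equal(unname(perfect$metrics), rep(1, 4))
  # confusion [[1,1],[0,2]]: Acc 0.75, Kappa 0.5, F1-macro 0.7333
  truth <- c("A", "A", "B", "B")
  pred <- c("A", "B", "B", "B")
  m <- annotation_metrics(pred, truth)
  expect_equal(unname(m$metrics["acc"]), 0.75)
  expect_equal(unname(m$metrics["kappa"]), 0.5)
  expect_equal(unname(m$metrics["f1_macro"]), 0.7333, tolerance = 1e-4)
  expect_equal(unname(m$metrics["f1_macro"]), (2 / 3 + 4 / 5) / 2, tolerance = 1e-12)
  # single-class truth: kappa undefined -> 0 with flag
  deg <- annotation_metrics(rep("A", 4), rep("A", 4))
  expect_equal(unname(deg$metrics["kappa"]), 0)
  expect_false(deg$kappa_defined)
})

test_that("kappa agrees with an independent implementation on random cases", {
  set.seed(6)
  for (i in 1:20) {
    truth <- sample(c("a", "b", "c"), 30, replace = TRUE)
    pred <- sample(c("a", "b", "c"), 30, replace = TRUE)
    expect_equal(unname(annotation_metrics(pred, truth)$metrics["kappa"]),
                 e1071::classAgreement(table(truth, pred))$kappa,
                 tolerance = 1e-10)
  }
})

# Differential-expression ranking and perturbation metrics --------------------

test_that("rank-sum z-scores match wilcox.test up to the tie-corrected
           normal approximation", {
  set.seed(7)
  x <- matrix(rpois(60, 4), 20, 3)
  y <- matrix(rpois(45, 6), 15, 3)
  ord <- rank_sum_deg(x, y)
  z <- attr(ord, "z")
  for (j in 1:3) {
    w <- wilcox.test(y[, j], x[, j], alternative = "greater",
                     exact = FALSE, correct = FALSE)
    # convert the W statistic's normal deviate to our z
    n1 <- nrow(x); n2 <- nrow(y)
    v <- c(x[, j], y[, j])
    ties <- table(v)
    sigma2 <- n1 * n2 / 12 * ((n1 + n2 + 1) - sum(ties^3 - ties) /
                                ((n1 + n2) * (n1 + n2 - 1)))
    zj <- (w$statistic - n1 * n2 / 2) / sqrt(sigma2)
    expect_equal(unname(z[j]), unname(zj), tolerance = 1e-10)
  }
})

test_that("identical predictions recover all DEGs with unit R^2", {
  set.seed(8)
  ctrl <- matrix(rnorm(40 * 30), 40, 30)
  stim <- matrix(rnorm(40 * 30, 0.5), 40, 30)
  res <- perturbation_metrics(ctrl, stim, stim, n_top = 10, n_boot = 20)
  expect_equal(unname(res$metrics["common_degs"]), 10)
  expect_equal(unname(res$metrics["r2_mean"]), 1, tolerance = 1e-10)
})

test_that("an uninformative prediction overlaps roughly at the hypergeometric
           chance level", {
  set.seed(9)
  n_genes <- 400; n_top <- 20
  overlaps <- replicate(5, {
    ctrl <- matrix(rpois(50 * n_genes, 3), 50, n_genes)
    stim <- matrix(rpois(50 * n_genes, 3), 50, n_genes)
    # prediction carries no signal at all: it *is* the control matrix, so
    # its DEG ranking is pure tie-breaking noise
    perturbation_metrics(ctrl, stim, ctrl, n_top = n_top,
                         n_boot = 2)$metrics["common_degs"]
  })
  expected <- n_top^2 / n_genes   # 1 gene
  expect_lt(mean(overlaps), expected + 4)
})

test_that("R^2 on matching means is exactly 1 even for two genes", {
  ctrl <- matrix(0, 4, 2)
  stim <- rbind(c(1, 5), c(2, 6), c(1, 5), c(2, 6))
  res <- perturbation_metrics(ctrl, stim, stim, n_top = 2, n_boot = 5)
  expect_equal(unname(res$metrics["r2_mean"]), 1, tolerance = 1e-12)
})

# Protein correlation metrics -------------------------------------------------

test_that("per-cell correlations behave at the fixed points and match the
           textbook formula", {
  set.seed(10)
  real <- matrix(rnorm(5 * 8), 5, 8)
  same <- adt_correlations(real, real)
  expect_equal(unname(same$metrics["pearson_mean"]), 1)
  expect_equal(unname(same$metrics["spearman_mean"]), 1)
  anti <- adt_correlations(real, -real)
  expect_equal(unname(anti$metrics["pearson_mean"]), -1)
  # 4-protein hand case
  r <- c(1, 2, 3, 4); p <- c(2, 1, 4, 10)
  res <- adt_correlations(rbind(r), rbind(p))
  num <- sum((r - mean(r)) * (p - mean(p)))
  den <- sqrt(sum((r - mean(r))^2) * sum((p - mean(p))^2))
  expect_equal(unname(res$metrics["pearson_mean"]), num / den, tolerance = 1e-12)
  expect_equal(unname(res$metrics["spearman_mean"]),
               cor(rank(r), rank(p)), tolerance = 1e-12)
})
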