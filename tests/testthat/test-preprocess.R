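# RNA pre-processing ---------------------------------------------------------

test_that("median depth normalisation equalises cell totals at the median", {
  m <- rbind(c(5, 5), c(10, 10), c(20, 20))   # totals 10, 20, 40 -> median 20
  cm <- count_matrix(m, modality = "rna")
  p <- preprocess_rna(cm, n_hvg = 2)
  expect_equal(rowSums(expm1(p$values)), rep(20, 3))
})

test_that("n_hvg covering all genes keeps everything, values = log1p(normalised)", {
  m <- matrix(3, 4, 5)
  p <- preprocess_rna(count_matrix(m, modality = "rna"), n_hvg = 5)
  expect_equal(sort(p$selected_features), 1:5)
  expect_equal(p$values, matrix(log1p(3), 4, 5), ignore_attr = TRUE)
  expect_gt(length(p$transform_log), 0)
})

test_that("HVG selection picks the genes a brute-force dispersion ranking picks", {
  set.seed(3)
  n <- 60
  base <- matrix(rpois(n * 5, 20), n, 5)
  # genes 1 and 3 get strong bimodal structure -> largest dispersion
  base[1:30, 1] <- rpois(30, 200)
  base[31:60, 3] <- rpois(30, 220)
  cm <- count_matrix(base, modality = "rna")
  p <- preprocess_rna(cm, n_hvg = 2)
  # brute-force oracle: dispersion of the logged, normalised matrix
  x <- as.matrix(base)
  xl <- log1p(x * (median(rowSums(x)) / rowSums(x)))
  disp <- apply(xl, 2, var) / colMeans(xl)
  expect_setequal(p$selected_features, order(disp, decreasing = TRUE)[1:2])
  expect_setequal(p$selected_features, c(1, 3))
})

test_that("feature selection is idempotent on the selected submatrix", {
  set.seed(4)
  cm <- count_matrix(matrix(rpois(200, 5), 20, 10), modality = "rna")
  p1 <- preprocess_rna(cm, n_hvg = 6)
  sub <- count_matrix(cm$values[, p1$selected_features], modality = "rna")
  p2 <- preprocess_rna(sub, n_hvg = 6)
  expect_equal(sort(p2$selected_features), 1:6)
})

test_that("cells with zero totals are an error naming the cells", {
  m <- rbind(c(1, 2), c(0, 0))
  cm <- count_matrix(m, cell_ids = c("good", "empty"), modality = "rna")
  expect_error(preprocess_rna(cm, 2), "empty")
})

# ATAC pre-processing --------------------------------------------------------

test_that("TF-IDF matches hand evaluation on the 2x3 toy", {
  xb <- rbind(c(1, 0, 1), c(1, 1, 0))
  cm <- count_matrix(xb, modality = "atac",
                     feature_ids = paste0("chr1:", 1:3 * 10, "-", 1:3 * 10 + 5))
  pa <- preprocess_atac(cm, min_cell_frac = 0)
  # IDF = log(1 + 2/colsum) = (log 2, log 3, log 3); TF rows = (1/2, 1/2)
  expected <- rbind(c(log(2) / 2, 0, log(3) / 2),
                    c(log(2) / 2, log(3) / 2, 0))
  expect_equal(pa$tfidf$scale_S, log(3) / 2, tolerance = 1e-12)
  expect_equal(pa$tfidf$scale_S, 0.5493, tolerance = 1e-4)
  expect_equal(pa$processed$values, expected / (log(3) / 2), ignore_attr = TRUE)
  expect_equal(max(pa$processed$values), 1)
  expect_equal(pa$tfidf$idf, c(log(2), log(3), log(3)), ignore_attr = TRUE)
  expect_equal(pa$tfidf$cell_totals, c(2, 2), ignore_attr = TRUE)
})

test_that("an all-ones matrix scales to all ones", {
  pa <- preprocess_atac(count_matrix(matrix(1, 2, 2), modality = "atac"), 0)
  expect_equal(pa$processed$values, matrix(1, 2, 2), ignore_attr = TRUE)
})

test_that("peaks open in fewer than 0.5% of cells are removed (strictly)", {
  set.seed(5)
  n <- 1000
  m <- matrix(1, n, 3)                        # peak 1 open everywhere
  m[, 2] <- 0; m[sample(n, 4), 2] <- 1        # 4/1000 = 0.4% < 0.5% -> dropped
  m[, 3] <- 0; m[sample(n, 5), 3] <- 1        # exactly 0.5% -> kept
  pa <- preprocess_atac(count_matrix(m, modality = "atac"), min_cell_frac = 0.005)
  expect_equal(pa$tfidf$kept_features, c(1L, 3L))
})

test_that("a retained cell with zero open peaks is an error", {
  m <- rbind(c(1, 1), c(0, 0))
  cm <- count_matrix(m, cell_ids = c("ok", "closed"), modality = "atac")
  expect_error(preprocess_atac(cm, 0), "closed")
})

# ADT pre-processing ---------------------------------------------------------

test_that("CLR matches hand evaluation and its identities", {
  # counts (0, 3, 15) + pseudocount 1 -> (1, 4, 16), geometric mean 4
  cm <- count_matrix(rbind(c(0, 3, 15)), modality = "adt")
  p <- preprocess_adt(cm)
  expect_equal(as.numeric(p$values), c(-log(4), 0, log(4)), tolerance = 1e-12)
  expect_equal(as.numeric(p$values), c(-1.3863, 0, 1.3863), tolerance = 1e-4)
  # constant rows map to zero; all rows sum to zero
  pc <- preprocess_adt(count_matrix(matrix(7, 2, 3), modality = "adt"))
  expect_equal(pc$values, matrix(0, 2, 3), ignore_attr = TRUE)
  set.seed(6)
  pr <- preprocess_adt(count_matrix(matrix(rpois(40, 30), 5, 8), modality = "adt"))
  expect_lt(max(abs(rowSums(pr$values))), 1e-9)
})

test_that("CLR is invariant to per-cell scaling of counts + pseudocount", {
  x <- c(2, 9, 39)   # x + 1 = (3, 10, 40)
  p1 <- preprocess_adt(count_matrix(rbind(x), modality = "adt"))
  # scale (x + 1) by 5: equivalent counts are 5 * (x + 1) - 1
  p2 <- preprocess_adt(count_matrix(rbind(5 * (x + 1) - 1), modality = "adt"))
  expect_equal(p1$values, p2$values, tolerance = 1e-12)
})

# chromosome grouping --------------------------------------------------------

test_that("peaks group by chromosome in first-appearance order", {
  ci <- group_peaks_by_chromosome(c("chr1:1-2", "chr2:3-4", "chr1:5-6"))
  expect_equal(ci$groups, list(chr1 = c(1L, 3L), chr2 = 2L))
  expect_length(ci$catch_all, 0)
  one <- group_peaks_by_chromosome(c("chrX:1-2", "chrX:3-4"))
  expect_equal(one$groups, list(chrX = c(1L, 2L)))
})

test_that("unparseable names land in the catch-all; all-unparseable errors", {
  ci <- group_peaks_by_chromosome(c("chr1:1-2", "peak_17", "chr1:9-10"))
  expect_equal(ci$catch_all, 2L)
  expect_error(group_peaks_by_chromosome(c("p1", "p2")), "single")
  ok <- group_peaks_by_chromosome(c("p1", "p2"), allow_single_group = TRUE)
  expect_equal(ok$groups[[1]], 1:2)
})
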