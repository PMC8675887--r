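test_that("z-score normalization yields unit-variance centered columns", {
  set.seed(501)
  X <- matrix(rnorm(60, 5, 3), 20, 3)
  Z <- normalize_matrix(X)
  expect_equal(colMeans(Z), rep(0, 3), tolerance = 1e-10)
  expect_equal(apply(Z, 2, sd), rep(1, 3), tolerance = 1e-10)
  expect_equal(normalize_matrix(X, method = "none"), X, ignore_attr = TRUE)
})

test_that("zero-variance columns and incomplete rows are reported", {
  X <- cbind(a = rnorm(10), b = rep(2, 10))
  expect_warning(Z <- normalize_matrix(X), "zero-variance")
  expect_equal(ncol(Z), 1)
  expect_error(suppressWarnings(normalize_matrix(cbind(rep(1, 5)))),
               "zero variance")
  X2 <- cbind(a = rnorm(6), b = rnorm(6))
  rownames(X2) <- paste0("s", 1:6)
  X2[3, 1] <- NA
  expect_message(Z2 <- normalize_matrix(X2), "s3")
  expect_equal(nrow(Z2), 5)
})

test_that("PCoA on Euclidean distances reproduces PCA scores of the centered matrix", {
  set.seed(502)
  X <- matrix(rnorm(100), 20, 5)
  pc <- pcoa(dist(X))
  pca <- prcomp(X, center = TRUE, scale. = FALSE)
  k <- ncol(pc$scores)
  for (j in seq_len(k))
    expect_equal(abs(cor(pc$scores[, j], pca$x[, j])), 1, tolerance = 1e-8)
  # eigenvalues equal (n-1) * PCA variances
  expect_equal(pc$eigenvalues[seq_len(k)], (pca$sdev^2 * 19)[seq_len(k)],
               tolerance = 1e-8)
})

test_that("degenerate clouds have the expected PCoA spectrum", {
  D0 <- matrix(0, 5, 5)
  pc0 <- pcoa(D0)
  expect_true(all(abs(pc0$eigenvalues) < 1e-9))
  expect_equal(ncol(pc0$vectors), 0)

  X2 <- rbind(c(0, 0), c(3, 4))
  pc2 <- pcoa(dist(X2))
  expect_equal(sum(pc2$eigenvalues > 1e-9), 1)
})

test_that("invalid distance matrices are rejected", {
  D <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(pcoa(D), "symmetric")
  D2 <- matrix(c(1, 1, 1, 1), 2, 2)
  expect_error(pcoa(D2), "diagonal")
})

test_that("well-separated clusters are perfectly allocated with small permutation p", {
  set.seed(503)
  X <- rbind(matrix(rnorm(10 * 4), 10, 4),
             cbind(rnorm(10, 6), matrix(rnorm(10 * 3), 10, 3)))
  rownames(X) <- paste0("s", 1:20)
  g <- rep(c("lo", "hi"), each = 10)
  res <- cap_fit(X, g, cap_config(n_permutations = 999, seed = 42))
  expect_equal(res$n_correct, 20)
  expect_lte(res$p_perm, 0.01)
  expect_true(all(res$canonical_sq_corr >= 0 & res$canonical_sq_corr <= 1))
})

test_that("identical seeds give identical results and the trace respects its bound", {
  set.seed(504)
  X <- matrix(rnorm(30 * 4), 30, 4); rownames(X) <- paste0("s", 1:30)
  g <- rep(c("a", "b", "c"), each = 10)
  r1 <- cap_fit(X, g, cap_config(n_permutations = 99, seed = 7))
  r2 <- cap_fit(X, g, cap_config(n_permutations = 99, seed = 7))
  expect_identical(r1$p_perm, r2$p_perm)
  expect_identical(r1$canonical_scores, r2$canonical_scores)
  expect_identical(r1$m_used, r2$m_used)
  expect_lte(r1$trace_statistic, min(r1$m_used, 2) + 1e-12)
  expect_gte(r1$p_perm, 1 / 100)
})

test_that("allocation is invariant to sample order and group relabeling", {
  set.seed(505)
  X <- rbind(matrix(rnorm(8 * 3), 8, 3),
             cbind(rnorm(8, 4), matrix(rnorm(8 * 2), 8, 2)))
  rownames(X) <- paste0("s", 1:16)
  g <- rep(c("a", "b"), each = 8)
  r1 <- cap_fit(X, g, cap_config(n_permutations = 49, seed = 1))
  perm <- sample(16)
  r2 <- cap_fit(X[perm, ], g[perm], cap_config(n_permutations = 49, seed = 1))
  expect_equal(r2$n_correct, r1$n_correct)
  g3 <- ifelse(g == "a", "north", "south")
  r3 <- cap_fit(X, g3, cap_config(n_permutations = 49, seed = 1))
  expect_equal(r3$n_correct, r1$n_correct)
  expect_equal(r3$m_used, r1$m_used)
})

test_that("group size and axis-count preconditions are enforced", {
  X <- matrix(rnorm(12), 6, 2); rownames(X) <- paste0("s", 1:6)
  expect_error(cap_fit(X, c("a", "a", "a", "a", "a", "b")), "at least 2 samples")
  expect_error(cap_fit(X, rep(c("a", "b"), 3), cap_config(m = 10)),
               "n - 2")
})

test_that("fixed m uses the cheap fixed-m permutation path deterministically", {
  set.seed(506)
  X <- matrix(rnorm(20 * 3), 20, 3); rownames(X) <- paste0("s", 1:20)
  g <- rep(c("a", "b"), each = 10)
  r <- cap_fit(X, g, cap_config(m = 2, n_permutations = 199, seed = 3))
  expect_equal(r$m_used, 2)
  expect_true(r$p_perm >= 1 / 200 && r$p_perm <= 1)
})

test_that("ordination plots are written, with a 1-D fallback for one axis", {
  set.seed(507)
  X <- rbind(matrix(rnorm(8 * 3), 8, 3),
             cbind(rnorm(8, 5), matrix(rnorm(8 * 2), 8, 2)))
  rownames(X) <- paste0("s", 1:16)
  g <- rep(c("a", "b"), each = 8)   # 2 groups -> single canonical axis
  res <- cap_fit(X, g, cap_config(n_permutations = 49, seed = 1))
  expect_equal(ncol(res$canonical_scores), 1)
  path <- withr::local_tempfile(fileext = ".png")
  plot_cap(res, path)
  expect_true(file.exists(path) && file.size(path) > 0)

  md <- data.frame(sample_id = paste0("s", 1:15))  # s16 missing
  expect_error(plot_cap(res, path, metadata = md), "s16")
})
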