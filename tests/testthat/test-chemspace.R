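test_that("duplicate and constant descriptors are always removed", {
  set.seed(3)
  x <- matrix(rnorm(100 * 6), 100, 6)
  colnames(x) <- paste0("d", 1:6)
  x <- cbind(x, dup = x[, "d2"], const = 7)
  f <- filter_descriptors(x)
  expect_true("const" %in% attr(f, "removed_low_diversity"))
  expect_equal(sum(c("d2", "dup") %in% colnames(f)), 1)  # one of the pair
})

test_that("retained descriptors satisfy the pairwise r2 bound", {
  set.seed(14)
  base <- matrix(rnorm(150 * 8), 150, 8)
  x <- cbind(base,
             base[, 1] + rnorm(150, 0, 0.1),   # strongly correlated
             base[, 2] * -1 + rnorm(150, 0, 0.05))
  colnames(x) <- paste0("d", seq_len(ncol(x)))
  f <- filter_descriptors(x)
  r2 <- cor(f)^2
  expect_true(all(r2[upper.tri(r2)] <= 0.8))   # brute-force scan
})

test_that("independent descriptors are retained and filtering is idempotent", {
  set.seed(8)
  x <- matrix(rnorm(200 * 20), 200, 20)
  colnames(x) <- paste0("d", 1:20)
  f1 <- filter_descriptors(x)
  expect_equal(ncol(f1), 20)
  f2 <- filter_descriptors(f1)
  expect_equal(colnames(f2), colnames(f1))
  expect_equal(length(attr(f2, "removed_correlated")), 0)
})

test_that("PCA keeps exactly the components the variance target needs", {
  set.seed(4)
  basis <- matrix(rnorm(50 * 2), 50, 2)
  load <- matrix(rnorm(2 * 6), 2, 6)
  x <- basis %*% load + matrix(rnorm(50 * 6, 0, 1e-8), 50, 6)
  colnames(x) <- paste0("d", 1:6)
  e <- reduce_embed(x, chemspace_config(pca_variance_target = 0.99,
                                        tsne_perplexity = 10))
  expect_equal(attr(e, "provenance")$components, 2)
  expect_equal(nrow(e), 50)
})

test_that("the embedding is deterministic under a fixed seed", {
  set.seed(5)
  x <- matrix(rnorm(60 * 5), 60, 5)
  colnames(x) <- paste0("d", 1:5)
  cfg <- chemspace_config(tsne_perplexity = 15, tsne_seed = 99)
  expect_identical(reduce_embed(x, cfg), reduce_embed(x, cfg))
})

test_that("well-separated clusters stay separated in two dimensions", {
  set.seed(6)
  x <- rbind(matrix(rnorm(30 * 5, 0), 30, 5),
             matrix(rnorm(30 * 5, 8), 30, 5))
  colnames(x) <- paste0("d", 1:5)
  e <- reduce_embed(x, chemspace_config(tsne_perplexity = 10))
  lab <- rep(1:2, each = 30)
  d <- as.matrix(dist(cbind(e$x, e$y))); diag(d) <- Inf
  purity <- mean(lab[apply(d, 1, which.min)] == lab)
  expect_gt(purity, 0.9)
})

test_that("degenerate inputs are refused", {
  x <- matrix(1, 10, 3)
  colnames(x) <- paste0("d", 1:3)
  expect_error(filter_descriptors(x), "diversity")
  y <- matrix(rnorm(4), 2, 2)
  colnames(y) <- c("a", "b")
  expect_error(reduce_embed(y), "at least 3")
})
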