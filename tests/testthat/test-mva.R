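test_that("PCA by SVD matches an independent eigendecomposition oracle", {
  set.seed(42)
  m <- matrix(rnorm(24), 6, 4,
              dimnames = list(1:6, paste0("v", 1:4, "@0")))
  pca <- fit_pca(m, n_components = 4)
  ms <- scale(m)
  eig <- eigen(cov(ms))                  # brute-force covariance eigen-oracle
  for (j in 1:3) {
    expect_equal(abs(pca$all_loadings[, j]), abs(eig$vectors[, j]),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
  ev <- eig$values / sum(eig$values)
  expect_equal(pca$explained[1:3], ev[1:3], tolerance = 1e-8)
  # orthonormal loadings, non-increasing variance, score identity
  G <- crossprod(pca$all_loadings)
  expect_equal(G, diag(ncol(G)), tolerance = 1e-8, ignore_attr = TRUE)
  expect_true(all(diff(pca$explained) <= 1e-12))
  expect_equal(unclass(ms) %*% pca$all_loadings, pca$all_scores,
               tolerance = 1e-8, ignore_attr = TRUE)
  # deterministic sign: dominant loading entry positive
  for (j in seq_len(ncol(pca$all_loadings))) {
    expect_gt(pca$all_loadings[which.max(abs(pca$all_loadings[, j])), j], 0)
  }
})

test_that("PCA handles rank-1 structure and reconstructs its input", {
  u <- c(1, 2, 3, 4, 5); v <- c(2, -1, 3)
  m <- tcrossprod(u, v) + 0             # rank-1 outer product
  colnames(m) <- paste0("v", 1:3); rownames(m) <- 1:5
  pca <- fit_pca(m, n_components = 1)
  expect_equal(pca$explained[1], 1, tolerance = 1e-10)
  set.seed(1)
  m2 <- matrix(rnorm(40), 8, 5, dimnames = list(1:8, paste0("v", 1:5)))
  pca2 <- fit_pca(m2, n_components = 5)
  rec <- tcrossprod(pca2$all_scores, pca2$all_loadings)
  expect_equal(rec, unclass(scale(m2)), tolerance = 1e-8, ignore_attr = TRUE)
  expect_warning(fit_pca(m2[1:3, ], n_components = 5), "rank")
})

test_that("Hotelling T2 flags a displaced run and spares homogeneous data", {
  set.seed(7)
  m <- matrix(rnorm(20 * 6, sd = 1), 20, 6,
              dimnames = list(1:20, paste0("v", 1:6)))
  base <- matrix(rep(colMeans(m), each = 20), 20) + 0.01 * m
  rownames(base) <- 1:20; colnames(base) <- paste0("v", 1:6)
  flags <- detect_outliers(fit_pca(base, n_components = 2))
  expect_false(any(flags$outlier))

  shifted <- base
  pca0 <- fit_pca(base, n_components = 2)
  shifted[3, ] <- shifted[3, ] + 10 * apply(base, 2, sd)
  flags2 <- detect_outliers(fit_pca(shifted, n_components = 2))
  expect_true(flags2$outlier[flags2$run_id == "3"])
  expect_error(detect_outliers(fit_pca(base[1:4, ], n_components = 1)),
               "at least 5")
})

test_that("k-means recovers separated blobs and matches the stats oracle", {
  set.seed(13)
  centers <- rbind(c(0, 0), c(10, 0), c(0, 10))
  x <- do.call(rbind, lapply(1:3, function(k)
    sweep(matrix(rnorm(30, sd = 0.5), 15, 2), 2, centers[k, ], "+")))
  rownames(x) <- seq_len(nrow(x))
  truth <- rep(1:3, each = 15)

  cl <- cluster_scores(x, k = 3, seed = 5)
  # perfect recovery up to label permutation
  expect_equal(length(unique(paste(truth, cl$assignments))), 3)
  expect_equal(sort(cl$sizes), c(15, 15, 15))

  ref <- stats::kmeans(x, centers = 3, nstart = 20)
  expect_equal(length(unique(paste(ref$cluster, cl$assignments))), 3)
  expect_equal(cl$inertia, ref$tot.withinss, tolerance = 1e-8)

  # k = 1: inertia equals the total sum of squares around the mean
  c1 <- cluster_scores(x, k = 1, seed = 5)
  expect_equal(c1$inertia, sum(scale(x, scale = FALSE)^2), tolerance = 1e-8)

  # determinism under a fixed seed; best-of-restarts no worse than one restart
  expect_identical(cluster_scores(x, k = 3, seed = 5)$assignments,
                   cl$assignments)
  one <- cluster_scores(x, k = 3, seed = 5, n_init = 1)
  expect_lte(cl$inertia, one$inertia + 1e-12)
  expect_error(cluster_scores(x[1:2, ], k = 3, seed = 1), "smaller")
})

test_that("classification trees split separable labels and resist noise", {
  runs <- expand_design(default_design(), 3)
  labels <- ifelse(runs$mu_set == 0.35, "hi", "lo")
  names(labels) <- runs$run_id
  tree <- characterize_clusters(labels, runs, min_leaf = 5)
  expect_equal(cart_depth(tree), 1L)
  expect_equal(tree$root$split$var, "mu_set")
  pred <- predict(tree, design_factors(runs))
  expect_equal(mean(pred == labels), 1)

  # label permutation invariance of tree accuracy
  relabeled <- c(hi = "A", lo = "B")[labels]
  names(relabeled) <- runs$run_id
  tree2 <- characterize_clusters(relabeled, runs, min_leaf = 5)
  expect_equal(mean(predict(tree2, design_factors(runs)) == relabeled), 1)

  # labels independent of the design: under the n/3 leaf constraint the
  # tree stays a stump for the vast majority of seeded permutations
  set.seed(202)
  depths <- vapply(1:20, function(i) {
    noise <- sample(labels)
    names(noise) <- runs$run_id
    cart_depth(characterize_clusters(noise, runs, min_leaf = 16))
  }, integer(1))
  expect_gte(sum(depths == 0L), 16L)
})

test_that("the exact CART split matches brute-force and rpart oracles", {
  set.seed(21)
  x <- data.frame(num = rep(c(1, 2, 3, 4), each = 6),
                  cat = factor(rep(c("a", "b", "c"), 8)))
  y <- ifelse(x$num <= 2, 10, 20) + rnorm(24, sd = 0.1)
  fit <- cart_fit(x, y, type = "regression", min_leaf = 6, cp = 0.01)

  # brute-force search over every admissible split
  best <- -Inf; best_desc <- NULL
  sse <- function(v) sum((v - mean(v))^2)
  for (thr in c(1.5, 2.5, 3.5)) {
    l <- x$num <= thr
    if (min(sum(l), sum(!l)) >= 6) {
      gain <- sse(y) - sse(y[l]) - sse(y[!l])
      if (gain > best) { best <- gain; best_desc <- c("num", thr) }
    }
  }
  for (lv in list("a", "b", "c", c("a", "b"), c("a", "c"), c("b", "c"))) {
    l <- x$cat %in% lv
    if (min(sum(l), sum(!l)) >= 6) {
      gain <- sse(y) - sse(y[l]) - sse(y[!l])
      if (gain > best) { best <- gain; best_desc <- c("cat", paste(lv, collapse = "")) }
    }
  }
  expect_equal(fit$root$split$var, best_desc[1])
  expect_equal(fit$root$split$threshold, as.numeric(best_desc[2]))

  skip_if_not_installed("rpart")
  ref <- rpart::rpart(y ~ num + cat, data = cbind(x, y),
                      control = rpart::rpart.control(minbucket = 6,
                                                     minsplit = 12, cp = 0.01,
                                                     xval = 0))
  expect_equal(unname(predict(fit, x)), unname(predict(ref, x)),
               tolerance = 1e-9)
})
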