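#' K-means clustering of PCA score space
#'
#' Lloyd iterations with greedy furthest-point seeding: the first centroid is
#' a seeded random run, each further centroid the run furthest from its
#' nearest chosen centroid. The best of `n_init` seeded restarts (by inertia)
#' is returned, so results are deterministic under a fixed seed without
#' depending on any library-specific initialization.
#'
#' @param model a `pca_model` (clustered on its retained components) or a
#'   plain numeric matrix of coordinates
#' @param k number of clusters (default 3; must be < number of rows)
#' @param seed integer seed
#' @param n_init number of seeded restarts
#' @param max_iter Lloyd iteration cap per restart
#' @return a `cluster_result`: `assignments` (named integer vector),
#'   `centroids` (k x d), `inertia`, `k`, `seed`, `sizes`
#' @export
cluster_scores <- function(model, k = 3, seed = 1, n_init = 50,
                           max_iter = 100) {
  x <- if (inherits(model, "pca_model")) model$scores else as.matrix(model)
  n <- nrow(x)
  if (k >= n) stop("k must be smaller than the number of runs", call. = FALSE)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  old <- .Random.seed_exists()
  set.seed(seed)
  on.exit(.Random.seed_restore(old), add = TRUE)

  best <- NULL
  starts <- sample.int(n, n_init, replace = TRUE)
  for (s in starts) {
    fit <- .kmeans_once(x, k, first = s, max_iter = max_iter)
    if (is.null(fit)) next            # empty cluster: restart consumed
    if (is.null(best) || fit$inertia < best$inertia - 1e-12) best <- fit
  }
  if (is.null(best)) stop("k-means failed to produce k non-empty clusters",
                          call. = FALSE)
  assignments <- best$cluster
  names(assignments) <- rownames(x)
  structure(list(assignments = assignments, centroids = best$centers,
                 inertia = best$inertia, k = k, seed = seed,
                 sizes = tabulate(assignments, k)),
            class = "cluster_result")
}

.kmeans_once <- function(x, k, first, max_iter) {
  n <- nrow(x)
  centers_idx <- first
  d2 <- rowSums(sweep(x, 2, x[first, ], "-")^2)
  while (length(centers_idx) < k) {    # greedy furthest-point seeding
    nxt <- which.max(d2)
    centers_idx <- c(centers_idx, nxt)
    d2 <- pmin(d2, rowSums(sweep(x, 2, x[nxt, ], "-")^2))
  }
  centers <- x[centers_idx, , drop = FALSE]
  cluster <- integer(n)
  for (it in seq_len(max_iter)) {
    dist2 <- sapply(seq_len(k), function(j)
      rowSums(sweep(x, 2, centers[j, ], "-")^2))
    if (k == 1) dist2 <- matrix(dist2, ncol = 1)
    new_cluster <- max.col(-dist2, ties.method = "first")
    if (length(unique(new_cluster)) < k) return(NULL)
    if (identical(new_cluster, cluster)) break
    cluster <- new_cluster
    for (j in seq_len(k)) {
      centers[j, ] <- colMeans(x[cluster == j, , drop = FALSE])
    }
  }
  dist2 <- sapply(seq_len(k), function(j)
    rowSums(sweep(x, 2, centers[j, ], "-")^2))
  if (k == 1) dist2 <- matrix(dist2, ncol = 1)
  list(cluster = cluster, centers = centers,
       inertia = sum(dist2[cbind(seq_len(n), cluster)]))
}
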