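#' Principal component analysis of a batch-wise-unfolded matrix
#'
#' PCA by singular value decomposition of the autoscaled matrix. The number of
#' retained components defaults to the smallest number explaining at least 80%
#' of variance, capped at 5. Component signs follow a deterministic
#' convention: the largest-magnitude loading element of each component is made
#' positive.
#'
#' @param m an `unfolded_matrix` (autoscaled internally if not already)
#' @param n_components number of components to retain (`NULL` for the
#'   variance rule); truncated with a warning if it exceeds the matrix rank
#' @param var_target retained-variance target for the automatic rule
#' @param cap maximum automatically retained components
#' @return a `pca_model`: `scores` (runs x k), `loadings` (columns x k),
#'   `explained` (variance fractions, all components), `n_components`,
#'   `center`, `scale`, `col_meta`
#' @export
fit_pca <- function(m, n_components = NULL, var_target = 0.8, cap = 5) {
  if (!isTRUE(attr(m, "scaled"))) m <- autoscale(m)
  n <- nrow(m)
  if (!is.null(n_components) && n_components < 1) {
    stop("n_components must be >= 1", call. = FALSE)
  }
  sv <- svd(m)
  pos <- sv$d > max(sv$d) * 1e-10
  rank <- sum(pos)
  ev <- sv$d^2 / sum(sv$d^2)
  if (is.null(n_components)) {
    k <- min(which(cumsum(ev[seq_len(rank)]) >= var_target - 1e-12), cap, rank)
  } else {
    if (n_components > rank) {
      warning("n_components exceeds matrix rank (", rank, "); truncated")
    }
    k <- min(n_components, rank)
  }
  loadings <- sv$v[, seq_len(rank), drop = FALSE]
  scores <- sv$u[, seq_len(rank), drop = FALSE] %*% diag(sv$d[seq_len(rank)],
                                                         nrow = rank)
  for (j in seq_len(rank)) {           # deterministic sign convention
    jmax <- which.max(abs(loadings[, j]))
    if (loadings[jmax, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  rownames(scores) <- rownames(m)
  rownames(loadings) <- colnames(m)
  structure(list(
    scores = scores[, seq_len(k), drop = FALSE],
    loadings = loadings[, seq_len(k), drop = FALSE],
    all_scores = scores, all_loadings = loadings,
    explained = ev[seq_len(rank)], n_components = k, n = n,
    center = attr(m, "center"), scale = attr(m, "scale"),
    col_meta = attr(m, "col_meta")
  ), class = "pca_model")
}

#' Hotelling T-squared outlier detection on PCA scores
#'
#' Computes T^2 of each run on the retained components and flags runs above
#' the F-distribution control limit
#' `k (n-1) / (n-k) * F(1 - alpha; k, n - k)`.
#'
#' @param model a `pca_model`
#' @param alpha significance level (default 0.01)
#' @return `data.frame` `run_id`, `T2`, `limit`, `outlier`
#' @export
detect_outliers <- function(model, alpha = 0.01) {
  if (model$n < 5) stop("need at least 5 runs for outlier limits", call. = FALSE)
  k <- model$n_components
  n <- model$n
  lam <- apply(model$scores, 2, stats::var)
  if (any(lam < 1e-12)) stop("degenerate component variance", call. = FALSE)
  T2 <- rowSums(sweep(model$scores^2, 2, lam, "/"))
  lim <- k * (n - 1) / (n - k) * stats::qf(1 - alpha, k, n - k)
  data.frame(run_id = rownames(model$scores), T2 = T2, limit = lim,
             outlier = T2 > lim, row.names = NULL)
}
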