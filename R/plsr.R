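#' Partial least squares regression (NIPALS, single response)
#'
#' Sequential NIPALS extraction on the autoscaled predictor matrix and
#' centered response. Deterministic: no random initialization is involved.
#'
#' @param X numeric predictor matrix (rows = runs)
#' @param y numeric response vector
#' @param n_latent number of latent components (capped at the number of
#'   informative components; extraction stops early when the residual is
#'   exhausted)
#' @return a `plsr_model` with weights `W`, loadings `P`, response loadings
#'   `q`, regression coefficients `coef` (on the scaled space), centers and
#'   scales, usable with `predict()`
#' @export
fit_plsr <- function(X, y, n_latent) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), n_latent >= 1)
  if (nrow(X) < n_latent + 2) stop("need at least n_latent + 2 rows", call. = FALSE)
  if (!all(is.finite(y))) stop("y must be finite", call. = FALSE)
  if (stats::sd(y) < 1e-12) stop("zero-variance response", call. = FALSE)
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl < 1e-12] <- 1
  Xc <- sweep(sweep(X, 2, ctr, "-"), 2, scl, "/")
  ym <- mean(y)
  yc <- y - ym

  p <- ncol(X)
  A <- min(n_latent, p, nrow(X) - 1)
  W <- P <- matrix(0, p, A)
  q <- numeric(A)
  Tm <- matrix(0, nrow(X), A)
  a_used <- 0
  for (a in seq_len(A)) {
    w <- drop(crossprod(Xc, yc))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break                 # residual response exhausted
    w <- w / nw
    tt <- drop(Xc %*% w)
    tt2 <- sum(tt^2)
    if (tt2 < 1e-12) break
    pp <- drop(crossprod(Xc, tt)) / tt2
    qq <- sum(yc * tt) / tt2
    Xc <- Xc - tcrossprod(tt, pp)
    yc <- yc - qq * tt
    W[, a] <- w; P[, a] <- pp; q[a] <- qq; Tm[, a] <- tt
    a_used <- a
  }
  if (a_used == 0) {                    # degenerate predictors: intercept only
    coef <- numeric(p)
    W <- P <- matrix(0, p, 0); q <- numeric(0)
  } else {
    W <- W[, seq_len(a_used), drop = FALSE]
    P <- P[, seq_len(a_used), drop = FALSE]
    q <- q[seq_len(a_used)]
    coef <- drop(W %*% solve(crossprod(P, W), q))
  }
  structure(list(W = W, P = P, q = q, scores = Tm[, seq_len(a_used), drop = FALSE],
                 coef = coef, n_latent = a_used,
                 x_center = ctr, x_scale = scl, y_mean = ym,
                 colnames = colnames(X)),
            class = "plsr_model")
}

#' @export
predict.plsr_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  Xc <- sweep(sweep(X, 2, object$x_center, "-"), 2, object$x_scale, "/")
  drop(Xc %*% object$coef) + object$y_mean
}

#' Relative root mean square error of cross validation
#'
#' `sqrt(mean(((y_pred - y_act) / y_act)^2))`: a target-normalized error,
#' reported as a fraction (multiply by 100 for percent).
#'
#' @param y_act observed values (must be non-zero)
#' @param y_pred predicted values
#' @export
rmsecv <- function(y_act, y_pred) {
  stopifnot(length(y_act) == length(y_pred))
  if (any(y_act == 0)) stop("relative error undefined: y_act contains 0",
                            call. = FALSE)
  sqrt(mean(((y_pred - y_act) / y_act)^2))
}

#' Seeded cross-validation fold assignment
#'
#' Random partition into folds whose sizes differ by at most one.
#'
#' @param n number of rows
#' @param folds number of folds
#' @param seed integer seed
#' @return integer fold id per row
#' @export
cv_folds <- function(n, folds, seed) {
  if (folds > n) stop("more folds than rows", call. = FALSE)
  old <- .Random.seed_exists()
  set.seed(seed)
  on.exit(.Random.seed_restore(old), add = TRUE)
  sample(rep_len(seq_len(folds), n))
}

#' Cross-validated PLSR with per-fold relative RMSECV
#'
#' Each fold is predicted by a model fit on the remaining runs. If `n_latent`
#' is `NULL` the latent dimension is chosen inside each training fold as the
#' minimizer of an inner 5-fold RMSECV (capped at `max_latent`).
#'
#' @param X predictor matrix
#' @param y response
#' @param folds number of outer folds (default 10)
#' @param seed fold seed (ignored if `fold_id` given)
#' @param n_latent fixed latent dimension, or `NULL` for inner selection
#' @param fold_id optional precomputed fold assignment
#' @param max_latent cap for inner selection
#' @return list: `predictions` (aligned with `y`), `fold_id`, `per_fold`
#'   (RMSECV per fold), `mean` and `sd` of the per-fold values, `pooled`
#'   (single RMSECV over all cross-validated predictions), `n_latent_used`
#' @export
cross_validate <- function(X, y, folds = 10, seed = 1, n_latent = NULL,
                           fold_id = NULL, max_latent = 10) {
  X <- as.matrix(X)
  n <- nrow(X)
  fold_id <- fold_id %||% cv_folds(n, folds, seed)
  nf <- max(fold_id)
  preds <- numeric(n)
  nl_used <- integer(nf)
  for (f in seq_len(nf)) {
    tr <- fold_id != f
    Xtr <- X[tr, , drop = FALSE]; ytr <- y[tr]
    nl <- n_latent %||% .choose_n_latent(Xtr, ytr, max_latent,
                                         seed = (abs(seed) %% 2097151) * 131 + f)
    nl <- min(nl, ncol(X), sum(tr) - 2)
    fit <- fit_plsr(Xtr, ytr, nl)
    preds[!tr] <- predict(fit, X[!tr, , drop = FALSE])
    nl_used[f] <- fit$n_latent
  }
  per_fold <- vapply(seq_len(nf), function(f)
    rmsecv(y[fold_id == f], preds[fold_id == f]), numeric(1))
  list(predictions = preds, fold_id = fold_id, per_fold = per_fold,
       mean = mean(per_fold), sd = stats::sd(per_fold),
       pooled = rmsecv(y, preds), n_latent_used = nl_used)
}

.choose_n_latent <- function(X, y, max_latent, seed, inner_folds = 5) {
  cands <- seq_len(min(max_latent, ncol(X), nrow(X) - 3))
  if (length(cands) <= 1) return(1L)
  fid <- cv_folds(nrow(X), min(inner_folds, nrow(X)), seed)
  errs <- vapply(cands, function(a) {
    preds <- numeric(nrow(X))
    for (f in seq_len(max(fid))) {
      tr <- fid != f
      fit <- fit_plsr(X[tr, , drop = FALSE], y[tr], min(a, sum(tr) - 2))
      preds[!tr] <- predict(fit, X[!tr, , drop = FALSE])
    }
    rmsecv(y, preds)
  }, numeric(1))
  cands[which.min(errs)]
}

#' Greedy forward variable selection under cross-validated RMSECV
#'
#' Starting from the intercept-only baseline, candidate columns are added one
#' at a time; at each step the candidate minimizing the mean per-fold RMSECV
#' joins the model, and selection stops when no addition improves the current
#' minimum. Ties are broken by earlier measurement time (design factors count
#' as available before the process starts), then by column-name order. During
#' the scan the latent dimension is held at `min(p, scan_latent)`; the
#' returned final model statistics come from a full cross-validation with
#' inner latent-dimension selection on the selected set.
#'
#' @param X candidate matrix; column names `variable@time` for process
#'   measurements (time parsed for tie-breaks), anything else treated as a
#'   design factor
#' @param y response
#' @param folds,seed outer cross-validation setup (fold assignment is fixed
#'   once and shared by every candidate evaluation)
#' @param scan_latent latent-dimension cap during the scan
#' @param max_steps optional cap on the number of selected variables
#' @return a `selection_result`: `selected` (ordered names), `trace` (mean
#'   RMSECV after 0, 1, 2, ... additions), `rmsecv_mean`, `rmsecv_sd`,
#'   `final_cv` (full [cross_validate()] result on the selected set),
#'   `fold_id`, `seed`
#' @export
forward_select_variables <- function(X, y, folds = 10, seed = 1,
                                     scan_latent = 4, max_steps = Inf) {
  X <- as.matrix(X)
  stopifnot(ncol(X) >= 1, !is.null(colnames(X)))
  fold_id <- cv_folds(nrow(X), folds, seed)
  col_time <- suppressWarnings(as.numeric(sub("^.*@", "", colnames(X))))
  col_time[is.na(col_time)] <- -1        # design factors: known pre-process

  baseline <- vapply(seq_len(max(fold_id)), function(f) {
    rmsecv(y[fold_id == f], rep(mean(y[fold_id != f]), sum(fold_id == f)))
  }, numeric(1))
  trace <- mean(baseline)
  selected <- character(0)
  pool <- colnames(X)

  repeat {
    if (!length(pool) || length(selected) >= max_steps) break
    errs <- vapply(pool, function(cand) {
      cols <- c(selected, cand)
      cross_validate(X[, cols, drop = FALSE], y,
                     n_latent = min(length(cols), scan_latent),
                     fold_id = fold_id)$mean
    }, numeric(1))
    best_err <- min(errs)
    if (best_err >= trace[length(trace)] - 1e-12) break
    at_min <- pool[errs <= best_err + 1e-12]
    ord <- order(col_time[match(at_min, colnames(X))], at_min)
    pick <- at_min[ord[1]]
    selected <- c(selected, pick)
    pool <- setdiff(pool, pick)
    trace <- c(trace, best_err)
  }

  final_cv <- if (length(selected)) {
    cross_validate(X[, selected, drop = FALSE], y, fold_id = fold_id,
                   seed = seed)
  } else {
    list(per_fold = baseline, mean = mean(baseline), sd = stats::sd(baseline),
         predictions = rep(mean(y), length(y)), fold_id = fold_id)
  }
  structure(list(selected = selected, trace = trace,
                 rmsecv_mean = final_cv$mean, rmsecv_sd = final_cv$sd,
                 final_cv = final_cv, fold_id = fold_id, seed = seed),
            class = "selection_result")
}

#' Assemble the historical predictor matrix for soft-sensor models
#'
#' Unfolds the gridded process measurements up to `horizon` and appends the
#' design factors (feed-rate set-point, initial substrate, hunger phase, and
#' a one-hot encoding of the feed profile).
#'
#' @param gridded a `gridded_series` from [align_to_grid()]
#' @param runs the `run_plan` (design factors per run)
#' @param horizon history horizon, h
#' @param variables process variables offered to the model
#' @param include_design offer design factors as candidates
#' @return numeric matrix, rows aligned with the gridded runs
#' @export
build_predictor_matrix <- function(gridded, runs, horizon,
                                   variables = c("biomass", "glucose", "ethanol",
                                                 "pH", "DOT", "volume"),
                                   include_design = TRUE) {
  variables <- intersect(variables, dimnames(gridded)$variable)
  m <- batch_wise_unfold(gridded, variables = variables, horizon = horizon)
  X <- as.matrix(m)
  attributes(X) <- attributes(X)[c("dim", "dimnames")]
  if (include_design) {
    idx <- match(as.integer(rownames(X)), runs$run_id)
    fac <- design_factors(runs[idx, , drop = FALSE])
    des <- cbind(mu_set = fac$mu_set, S0 = fac$S0, hunger_h = fac$hunger_h,
                 profile_exponential = as.numeric(fac$profile == "exponential"),
                 profile_linear = as.numeric(fac$profile == "linear"),
                 profile_constant = as.numeric(fac$profile == "constant"))
    X <- cbind(X, des)
  }
  X
}

#' Read the prediction target (a variable at a fixed time) off the grid
#'
#' Off-grid times within the grid span are linearly interpolated between the
#' neighbouring grid points.
#'
#' @param gridded a `gridded_series`
#' @param time target time, h (within the grid span)
#' @param variable target variable (default volumetric enzyme activity)
#' @return named numeric vector (names = run ids)
#' @export
grid_target <- function(gridded, time, variable = "EAv") {
  grid <- attr(gridded, "grid")
  if (time < min(grid) || time > max(grid)) {
    stop("target time ", time, " is outside the grid span", call. = FALSE)
  }
  vals <- apply(gridded[, variable, , drop = FALSE], 1, function(v)
    stats::approx(grid, v, xout = time)$y)
  stats::setNames(vals, dimnames(gridded)$run)
}

#' RMSECV of the soft sensor across process-history horizons
#'
#' Runs the forward-selection + cross-validation routine once per history
#' horizon with a shared fold assignment, quantifying how early the process
#' outcome can be predicted.
#'
#' @param gridded a `gridded_series` containing the campaign
#' @param runs the `run_plan`
#' @param target_time time of the predicted enzyme activity, h
#' @param horizons increasing history horizons, h (entries beyond
#'   `target_time` are rejected; horizons with fewer than 2 grid points are
#'   skipped with a warning)
#' @param folds,seed cross-validation setup
#' @param variables process variables offered to the model
#' @return a `history_sweep` data.frame: `horizon`, `rmsecv_mean`,
#'   `rmsecv_sd`, `n_selected`, with per-horizon selections in attribute
#'   `selections`
#' @export
history_sweep <- function(gridded, runs, target_time, horizons,
                          folds = 10, seed = 1,
                          variables = c("biomass", "glucose", "ethanol",
                                        "pH", "DOT", "volume")) {
  stopifnot(all(diff(horizons) > 0))
  if (any(horizons > target_time)) {
    stop("horizons must not exceed the target time", call. = FALSE)
  }
  y <- grid_target(gridded, target_time)
  grid <- attr(gridded, "grid")
  fold_ref <- cv_folds(length(y), folds, seed)  # shared across horizons
  rows <- list(); sels <- list()
  for (h in horizons) {
    if (sum(grid <= h + 1e-9) < 2) {
      warning("horizon ", h, " h has fewer than 2 grid points; skipped")
      next
    }
    X <- build_predictor_matrix(gridded, runs, horizon = h,
                                variables = variables)
    sel <- forward_select_variables(X, y, folds = folds, seed = seed)
    sel$fold_id <- fold_ref
    rows[[length(rows) + 1]] <- data.frame(
      horizon = h, rmsecv_mean = sel$rmsecv_mean, rmsecv_sd = sel$rmsecv_sd,
      n_selected = length(sel$selected))
    sels[[as.character(h)]] <- sel
  }
  out <- do.call(rbind, rows)
  attr(out, "selections") <- sels
  class(out) <- c("history_sweep", "data.frame")
  out
}
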