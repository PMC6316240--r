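#' Classification and regression trees over design factors
#'
#' A small exact CART: greedy binary splits, Gini impurity for classification
#' and variance (sum-of-squares) reduction for regression. Numeric predictors
#' split at midpoint thresholds; categorical predictors by the best binary
#' partition of their observed levels, found exhaustively (the design factors
#' have at most 3 levels, so the exhaustive search is exact). A split is
#' accepted only if both children hold at least `min_leaf` rows and the
#' impurity reduction exceeds `cp` times the root impurity. Ties are broken
#' deterministically by predictor order, then threshold.
#'
#' @param x `data.frame` of predictors (numeric or factor columns)
#' @param y response: factor (classification) or numeric (regression)
#' @param type `"classification"` or `"regression"` (default: from `y`)
#' @param min_leaf minimum rows per leaf
#' @param cp complexity threshold as a fraction of root impurity
#' @return a `cart_model`: recursive node list plus fit metadata; leaves carry
#'   `n` and either class counts or mean/sd
#' @export
cart_fit <- function(x, y, type = NULL,
                     min_leaf = max(1L, floor(nrow(x) / 10)), cp = 0.01) {
  stopifnot(is.data.frame(x), nrow(x) == length(y), nrow(x) >= 1)
  type <- type %||% if (is.factor(y) || is.character(y) || is.logical(y))
    "classification" else "regression"
  type <- match.arg(type, c("classification", "regression"))
  if (type == "classification") y <- factor(y)
  root_imp <- .cart_impurity(y, type)
  node <- .cart_grow(x, y, type, min_leaf, cp * max(root_imp, 1e-300), depth = 0)
  structure(list(root = node, type = type, min_leaf = min_leaf, cp = cp,
                 vars = names(x), n = nrow(x),
                 levels = if (type == "classification") levels(y) else NULL,
                 xlevels = lapply(x, function(col)
                   if (is.factor(col)) levels(col) else NULL)),
            class = "cart_model")
}

.cart_impurity <- function(y, type) {
  n <- length(y)
  if (n == 0) return(0)
  if (type == "classification") {
    p <- tabulate(y, nbins = nlevels(y)) / n
    n * (1 - sum(p^2))
  } else {
    sum((y - mean(y))^2)
  }
}

.cart_leaf <- function(y, type, depth) {
  if (type == "classification") {
    counts <- table(y)
    list(leaf = TRUE, depth = depth, n = length(y),
         class = names(counts)[which.max(counts)], counts = counts)
  } else {
    list(leaf = TRUE, depth = depth, n = length(y), mean = mean(y),
         sd = if (length(y) > 1) stats::sd(y) else 0)
  }
}

.cart_grow <- function(x, y, type, min_leaf, min_gain, depth) {
  n <- length(y)
  imp <- .cart_impurity(y, type)
  pure <- if (type == "classification") length(unique(y)) == 1 else imp < 1e-12
  if (n < 2 * min_leaf || pure) return(.cart_leaf(y, type, depth))

  best <- NULL
  for (v in names(x)) {
    col <- x[[v]]
    cands <- if (is.factor(col)) .cart_factor_splits(col) else .cart_numeric_splits(col)
    for (cand in cands) {
      left <- if (cand$type == "numeric") col <= cand$threshold
              else col %in% cand$levels_left
      nl <- sum(left)
      if (nl < min_leaf || n - nl < min_leaf) next
      gain <- imp - .cart_impurity(y[left], type) - .cart_impurity(y[!left], type)
      if (is.null(best) || gain > best$gain + 1e-12) {
        best <- c(cand, list(var = v, gain = gain, left = left))
      }
    }
  }
  if (is.null(best) || best$gain <= min_gain) return(.cart_leaf(y, type, depth))

  li <- best$left
  node <- .cart_leaf(y, type, depth)        # carry stats on internal nodes too
  node$leaf <- FALSE
  node$split <- best[intersect(names(best), c("var", "type", "threshold", "levels_left"))]
  node$children <- list(
    left = .cart_grow(x[li, , drop = FALSE], y[li], type, min_leaf, min_gain, depth + 1),
    right = .cart_grow(x[!li, , drop = FALSE], y[!li], type, min_leaf, min_gain, depth + 1)
  )
  node
}

.cart_numeric_splits <- function(col) {
  u <- sort(unique(col))
  if (length(u) < 2) return(list())
  thr <- (u[-1] + u[-length(u)]) / 2
  lapply(thr, function(tt) list(type = "numeric", threshold = tt))
}

.cart_factor_splits <- function(col) {
  lev <- levels(droplevels(col))
  L <- length(lev)
  if (L < 2) return(list())
  out <- list()
  for (mask in seq_len(2^(L - 1) - 1)) {   # non-trivial halves, no mirror duplicates
    left <- lev[bitwAnd(mask, 2^(seq_len(L) - 1)) > 0]
    out[[length(out) + 1]] <- list(type = "factor", levels_left = left)
  }
  out
}

#' Predict from a fitted CART
#'
#' @param object a `cart_model`
#' @param newdata `data.frame` with the training predictor columns
#' @param ... unused
#' @return class labels (classification) or leaf means (regression)
#' @export
predict.cart_model <- function(object, newdata, ...) {
  walk <- function(node, row) {
    while (!node$leaf) {
      s <- node$split
      go_left <- if (s$type == "numeric") row[[s$var]] <= s$threshold
                 else as.character(row[[s$var]]) %in% s$levels_left
      node <- if (go_left) node$children$left else node$children$right
    }
    if (object$type == "classification") node$class else node$mean
  }
  out <- vapply(seq_len(nrow(newdata)), function(i)
    walk(object$root, newdata[i, , drop = FALSE]),
    if (object$type == "classification") character(1) else numeric(1))
  if (object$type == "classification") factor(out, levels = object$levels) else out
}

#' Maximum depth of a fitted CART
#' @param tree a `cart_model`
#' @export
cart_depth <- function(tree) {
  rec <- function(node) {
    if (node$leaf) return(0L)
    1L + max(rec(node$children$left), rec(node$children$right))
  }
  rec(tree$root)
}

#' Enumerate root-to-leaf paths of a CART as factor constraints
#'
#' Each leaf becomes one path: per predictor the interval (numeric) or level
#' set (categorical) implied by the splits on the way down; predictors not
#' split on the path are unconstrained ("any").
#'
#' @param tree a `cart_model`
#' @return list of paths; each path has `constraints` (named list with `lo`,
#'   `hi` for numeric or `levels` for factors; absent = any), `n`, and leaf
#'   stats (`mean`, `sd` or `class`, `counts`)
#' @export
cart_paths <- function(tree) {
  paths <- list()
  rec <- function(node, cons) {
    if (node$leaf) {
      p <- list(constraints = cons, n = node$n)
      if (tree$type == "regression") {
        p$mean <- node$mean; p$sd <- node$sd
      } else {
        p$class <- node$class; p$counts <- node$counts
      }
      paths[[length(paths) + 1]] <<- p
      return(invisible())
    }
    s <- node$split
    cl <- cons; cr <- cons
    if (s$type == "numeric") {
      cur <- cons[[s$var]] %||% list(lo = -Inf, hi = Inf)
      cl[[s$var]] <- list(lo = cur$lo, hi = min(cur$hi, s$threshold))
      cr[[s$var]] <- list(lo = max(cur$lo, s$threshold), hi = cur$hi)
    } else {
      all_lev <- tree$xlevels[[s$var]]
      cur <- cons[[s$var]]$levels %||% all_lev
      cl[[s$var]] <- list(levels = intersect(cur, s$levels_left))
      cr[[s$var]] <- list(levels = setdiff(cur, s$levels_left))
    }
    rec(node$children$left, cl)
    rec(node$children$right, cr)
  }
  rec(tree$root, stats::setNames(list(), character(0)))
  paths
}

#' @export
print.cart_model <- function(x, digits = 4, ...) {
  cat(sprintf("CART (%s), n = %d, min_leaf = %d\n", x$type, x$n, x$min_leaf))
  rec <- function(node, prefix, label) {
    stat <- if (x$type == "regression") {
      sprintf("mean = %s, sd = %s", format(node$mean, digits = digits),
              format(node$sd, digits = digits))
    } else {
      sprintf("class = %s", node$class)
    }
    cat(sprintf("%s%s n = %d, %s\n", prefix, label, node$n, stat))
    if (!node$leaf) {
      s <- node$split
      desc <- if (s$type == "numeric") {
        c(sprintf("IF %s <= %s:", s$var, format(s$threshold, digits = digits)),
          sprintf("IF %s >  %s:", s$var, format(s$threshold, digits = digits)))
      } else {
        c(sprintf("IF %s in {%s}:", s$var, paste(s$levels_left, collapse = ", ")),
          sprintf("IF %s not in {%s}:", s$var, paste(s$levels_left, collapse = ", ")))
      }
      rec(node$children$left, paste0(prefix, "  "), desc[1])
      rec(node$children$right, paste0(prefix, "  "), desc[2])
    }
  }
  rec(x$root, "", "root:")
  invisible(x)
}

#' Characterize score-space clusters by the experimental design
#'
#' Fits a classification tree mapping the design factors (profile, feed-rate
#' set-point, initial substrate, hunger phase) to cluster labels, revealing
#' which manipulated variables drive the separation of process behaviors.
#'
#' @param assignments named cluster labels (names = run ids), e.g. from
#'   [cluster_scores()]
#' @param runs a `run_plan` (or data.frame with `run_id`, `profile`, `mu_set`,
#'   `S0`, `hunger_h`)
#' @param min_leaf,cp passed to [cart_fit()]; the conservative default `cp`
#'   suppresses splits on design factors whose association with the clusters
#'   is not strong (no post-pruning is implemented)
#' @return a `cart_model` (classification)
#' @export
characterize_clusters <- function(assignments, runs,
                                  min_leaf = max(2L, floor(length(assignments) / 8)),
                                  cp = 0.1) {
  idx <- match(as.integer(names(assignments)), runs$run_id)
  if (anyNA(idx)) stop("assignments contain run ids absent from the plan",
                       call. = FALSE)
  feats <- design_factors(runs[idx, , drop = FALSE])
  cart_fit(feats, factor(assignments), type = "classification",
           min_leaf = min_leaf, cp = cp)
}

#' Design-factor frame used by trees and as PLSR candidates
#' @param runs a `run_plan` or design table slice
#' @return `data.frame` with `mu_set`, `profile` (factor), `S0`, `hunger_h`
#' @export
design_factors <- function(runs) {
  data.frame(mu_set = runs$mu_set,
             profile = factor(as.character(runs$profile),
                              levels = c("exponential", "linear", "constant")),
             S0 = runs$S0, hunger_h = runs$hunger_h)
}
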