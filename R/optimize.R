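#' Regression tree of a process outcome over the design factors
#'
#' CART with variance-reduction splitting on feed-rate set-point, feed
#' profile, initial substrate and hunger phase. The default minimum leaf size
#' of 6 equals two conditions' worth of triplicates, so no reported "optimal
#' condition" rests on fewer than two design points.
#'
#' @param runs a `run_plan` (or data.frame with the design-factor columns)
#' @param target numeric outcome per run, aligned with `runs` rows
#' @param min_leaf minimum runs per leaf
#' @param cp complexity threshold (fraction of root variance); with no
#'   post-pruning implemented, this is the guard against noise splits
#' @return a `cart_model` (regression)
#' @export
fit_regression_tree <- function(runs, target, min_leaf = 6, cp = 0.1) {
  stopifnot(nrow(runs) == length(target), nrow(runs) >= 2 * min_leaf)
  cart_fit(design_factors(runs), target, type = "regression",
           min_leaf = min_leaf, cp = cp)
}

#' Extract near-optimal decision paths from a regression tree
#'
#' Returns every leaf whose mean lies within `slack` times the range of leaf
#' means of the best leaf (the single best leaf for `slack = 0`), converted to
#' root-to-leaf factor constraints. Unconstrained factors are reported as
#' "any".
#'
#' @param tree a regression `cart_model`
#' @param direction optimize direction: `"minimize"` (e.g. ethanol) or
#'   `"maximize"` (e.g. product activity)
#' @param slack near-optimality tolerance as a fraction of the leaf-mean range
#' @return list of `optimal_path`s: `constraints` (as in [cart_paths()]),
#'   `n`, `mean`, `sd`, `direction`
#' @export
extract_optimal_paths <- function(tree, direction = c("minimize", "maximize"),
                                  slack = 0.15) {
  direction <- match.arg(direction)
  stopifnot(tree$type == "regression", slack >= 0)
  paths <- cart_paths(tree)
  means <- vapply(paths, `[[`, numeric(1), "mean")
  rng <- diff(range(means))
  keep <- if (direction == "minimize") {
    means <= min(means) + slack * rng + 1e-12
  } else {
    means >= max(means) - slack * rng - 1e-12
  }
  out <- lapply(paths[keep], function(p) {
    p$direction <- direction
    class(p) <- "optimal_path"
    p
  })
  out[order(vapply(out, `[[`, numeric(1), "mean"),
            decreasing = (direction == "maximize"))]
}

#' Design conditions matched by a path's constraints
#'
#' @param path an `optimal_path` (or anything with a `constraints` field)
#' @param design a `design_table`
#' @return integer vector of matched `condition_id`s
#' @export
match_conditions <- function(path, design) {
  feats <- design_factors(design)
  ok <- rep(TRUE, nrow(design))
  for (v in names(path$constraints)) {
    cc <- path$constraints[[v]]
    ok <- ok & if (!is.null(cc$levels)) {
      as.character(feats[[v]]) %in% cc$levels
    } else {
      feats[[v]] > cc$lo & feats[[v]] <= cc$hi
    }
  }
  design$condition_id[ok]
}

#' Superimpose near-optimal paths across several targets
#'
#' Maps every path of every target to its matched design-condition set, takes
#' the per-target union, and intersects across targets to find the conditions
#' recurring in all of them, together with the factor levels those conditions
#' share. If the intersection is empty, pairwise overlap diagnostics are
#' reported instead.
#'
#' @param paths_per_target named list (one entry per target) of
#'   [extract_optimal_paths()] results
#' @param design the `design_table`
#' @return a `superposition_report`: `per_target` (condition-id sets),
#'   `intersection`, `common_levels` (factor levels shared by all intersection
#'   members; factors without a shared level are dropped), `pairwise` overlap
#'   counts (on empty intersection)
#' @export
superimpose_targets <- function(paths_per_target, design) {
  stopifnot(length(paths_per_target) >= 1)
  if (any(!lengths(paths_per_target))) {
    stop("every target needs at least one optimal path", call. = FALSE)
  }
  per_target <- lapply(paths_per_target, function(paths) {
    sort(unique(unlist(lapply(paths, match_conditions, design = design))))
  })
  inter <- Reduce(intersect, per_target)
  common <- list()
  if (length(inter)) {
    feats <- design_factors(design[design$condition_id %in% inter, , drop = FALSE])
    for (v in names(feats)) {
      u <- unique(feats[[v]])
      if (length(u) == 1) common[[v]] <- as.character(u)
    }
  }
  pairwise <- NULL
  if (!length(inter) && length(per_target) > 1) {
    nm <- names(per_target)
    pairwise <- expand.grid(a = nm, b = nm, stringsAsFactors = FALSE)
    pairwise <- pairwise[pairwise$a < pairwise$b, ]
    pairwise$overlap <- mapply(function(a, b)
      length(intersect(per_target[[a]], per_target[[b]])),
      pairwise$a, pairwise$b)
    rownames(pairwise) <- NULL
  }
  structure(list(per_target = per_target, intersection = inter,
                 common_levels = common, pairwise = pairwise),
            class = "superposition_report")
}

#' Four-target design-space optimization of a campaign
#'
#' Fits independent regression trees for ethanol (minimized) and volumetric
#' enzyme activity (maximized) at two evaluation times, extracts near-optimal
#' decision paths from each, and superimposes them to report the recurring
#' optimal conditions.
#'
#' @param gridded a `gridded_series` containing `ethanol` and `EAv`
#' @param runs the `run_plan` (rows aligned with the gridded runs)
#' @param design the `design_table`
#' @param times the two evaluation times, h (grid points)
#' @param min_leaf,slack see [fit_regression_tree()], [extract_optimal_paths()]
#' @return an `optimization_report`: `trees`, `paths`, `superposition`,
#'   `table` (Table-3-style data.frame of all near-optimal paths)
#' @export
optimize_conditions <- function(gridded, runs, design, times = c(22, 35),
                                min_leaf = 6, slack = 0.15) {
  idx <- match(as.integer(dimnames(gridded)$run), runs$run_id)
  rr <- runs[idx, , drop = FALSE]
  targets <- list()
  for (tt in times) {
    targets[[paste0("ethanol_", tt, "h")]] <-
      list(y = grid_target(gridded, tt, "ethanol"), direction = "minimize")
    targets[[paste0("EAv_", tt, "h")]] <-
      list(y = grid_target(gridded, tt, "EAv"), direction = "maximize")
  }
  trees <- lapply(targets, function(tg)
    fit_regression_tree(rr, tg$y, min_leaf = min_leaf))
  paths <- mapply(function(tree, tg)
    extract_optimal_paths(tree, tg$direction, slack = slack),
    trees, targets, SIMPLIFY = FALSE)
  structure(list(trees = trees, paths = paths,
                 superposition = superimpose_targets(paths, design),
                 table = optimal_paths_table(paths, design)),
            class = "optimization_report")
}

#' Tabulate near-optimal paths in the campaign's reporting format
#'
#' One row per path: constrained factor levels (`-` for "any value"), number
#' of matched runs in the tree's training set, and the leaf mean and sd of the
#' target.
#'
#' @param paths_per_target named list of [extract_optimal_paths()] results
#' @param design the `design_table`
#' @export
optimal_paths_table <- function(paths_per_target, design) {
  fmt <- function(path, v) {
    cc <- path$constraints[[v]]
    if (is.null(cc)) return("-")
    if (!is.null(cc$levels)) {
      lv <- intersect(unique(as.character(design_factors(design)[[v]])), cc$levels)
      if (length(lv) == length(unique(design_factors(design)[[v]]))) return("-")
      return(paste(lv, collapse = "/"))
    }
    u <- sort(unique(design_factors(design)[[v]]))
    inside <- u[u > cc$lo & u <= cc$hi]
    if (length(inside) == length(u)) return("-")
    paste(inside, collapse = "/")
  }
  rows <- list()
  for (nm in names(paths_per_target)) {
    for (p in paths_per_target[[nm]]) {
      rows[[length(rows) + 1]] <- data.frame(
        target = nm,
        feed_rate = fmt(p, "mu_set"), profile = fmt(p, "profile"),
        S0 = fmt(p, "S0"), hunger = fmt(p, "hunger_h"),
        n_runs = p$n, mean = p$mean, sd = p$sd)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
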