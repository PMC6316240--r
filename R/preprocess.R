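#' Volume-normalized biomass
#'
#' Feeding, base addition and evaporation change the culture volume, so raw
#' biomass concentrations of different runs are not comparable. Biomass is
#' re-expressed relative to the common start volume, `X_N = X * V / V0`; all
#' other variables are left unnormalized.
#'
#' @param raw measurement rows for one or more runs with `variable == "biomass"`
#'   (other variables are ignored)
#' @param volume_history `data.frame` with `run_id`, `time_h`, `value` giving
#'   the known volume history per run (e.g. the `volume` rows of a measurement
#'   table, or a trajectory's volume)
#' @param V0 reference start volume, L
#' @return `data.frame` `run_id`, `time_h`, `X_N`, `X`, `V`
#' @export
normalize_biomass <- function(raw, volume_history, V0 = 0.010) {
  b <- raw[raw$variable == "biomass", , drop = FALSE]
  out <- lapply(split(b, b$run_id), function(bb) {
    id <- bb$run_id[1]
    vh <- volume_history[volume_history$run_id == id, , drop = FALSE]
    if (!nrow(vh)) stop("no volume history for run ", id, call. = FALSE)
    lo <- min(vh$time_h); hi <- max(vh$time_h)
    miss <- bb$time_h < lo - 1e-9 | bb$time_h > hi + 1e-9
    if (any(miss)) {
      stop("volume unknown at biomass times (run ", id, "): ",
           paste(round(bb$time_h[miss], 2), collapse = ", "), call. = FALSE)
    }
    V <- stats::approx(vh$time_h, vh$value, xout = bb$time_h, ties = mean)$y
    data.frame(run_id = id, time_h = bb$time_h, X_N = bb$value * V / V0,
               X = bb$value, V = V)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Finite-difference specific rates between consecutive samples
#'
#' For consecutive sample pairs (t1, t2): specific growth rate
#' `mu = (ln X_N2 - ln X_N1) / (t2 - t1)`; substrate consumption rate
#' `qS = (S1 - S2) / ((t2 - t1) * (X1 + X2)/2)` (consumption positive);
#' specific product formation rate
#' `qP = (EAv2 - EAv1) * 1000 / ((t2 - t1) * (X1 + X2)/2)` converting
#' U mL^-1 to U g^-1 h^-1 with the arithmetic-mean biomass.
#'
#' @param series per-run `data.frame` with `time_h` and any of `X_N`, `X`,
#'   `S`, `EAv`; rows sorted or sortable by time, at least 2 rows
#' @return `data.frame` with `t1`, `t2`, `t_mid` and available rates `mu`,
#'   `qS`, `qP`; non-positive biomass yields `NA` (flagged, not dropped)
#' @export
specific_rates <- function(series) {
  s <- series[order(series$time_h), , drop = FALSE]
  if (nrow(s) < 2) stop("need at least 2 samples", call. = FALSE)
  i1 <- seq_len(nrow(s) - 1); i2 <- i1 + 1
  dt <- s$time_h[i2] - s$time_h[i1]
  if (any(dt <= 0)) stop("non-increasing sample times", call. = FALSE)
  out <- data.frame(t1 = s$time_h[i1], t2 = s$time_h[i2],
                    t_mid = (s$time_h[i1] + s$time_h[i2]) / 2)
  if (!is.null(s$X_N)) {
    ok <- s$X_N[i1] > 0 & s$X_N[i2] > 0
    mu <- rep(NA_real_, length(i1))
    mu[ok] <- (log(s$X_N[i2][ok]) - log(s$X_N[i1][ok])) / dt[ok]
    out$mu <- mu
  }
  xbar <- if (!is.null(s$X)) (s$X[i1] + s$X[i2]) / 2 else NULL
  if (!is.null(s$S) && !is.null(xbar)) {
    out$qS <- (s$S[i1] - s$S[i2]) / (dt * xbar)
  }
  if (!is.null(s$EAv) && !is.null(xbar)) {
    out$qP <- (s$EAv[i2] - s$EAv[i1]) * 1000 / (dt * xbar)
  }
  out
}

#' Align staggered measurements onto a common time grid
#'
#' Duplicate determinations at one time are averaged first, then each
#' run/variable series is linearly interpolated onto the grid
#' `0, grid_step, ..., horizon`. No extrapolation: values beyond the first or
#' last sample are held at the boundary value.
#'
#' @param meas long measurement `data.frame` (`run_id`, `time_h`, `variable`,
#'   `value`)
#' @param grid_step grid spacing, h (default 2, the per-reactor sampling period)
#' @param horizon last grid time, h
#' @param variables variables to align (default: all present)
#' @return a 3-d array runs x variables x grid times (class `gridded_series`),
#'   with dimnames and attribute `grid`
#' @export
align_to_grid <- function(meas, grid_step = 2, horizon,
                          variables = sort(unique(meas$variable))) {
  grid <- seq(0, horizon, by = grid_step)
  run_ids <- sort(unique(meas$run_id))
  arr <- array(NA_real_,
               dim = c(length(run_ids), length(variables), length(grid)),
               dimnames = list(run = as.character(run_ids),
                               variable = variables,
                               time = as.character(grid)))
  for (id in run_ids) {
    mm <- meas[meas$run_id == id, , drop = FALSE]
    for (v in variables) {
      sub <- mm[mm$variable == v, , drop = FALSE]
      if (nrow(sub) == 0) {
        stop("variable `", v, "` absent for run ", id, call. = FALSE)
      }
      agg <- stats::aggregate(value ~ time_h, data = sub, FUN = mean)
      if (sum(agg$time_h <= horizon + grid_step) < 2) {
        stop("run ", id, " has < 2 samples of `", v, "` within the horizon",
             call. = FALSE)
      }
      arr[as.character(id), v, ] <-
        stats::approx(agg$time_h, agg$value, xout = grid, rule = 2)$y
    }
  }
  structure(arr, grid = grid, class = c("gridded_series", "array"))
}

#' Batch-wise unfolding of a gridded campaign
#'
#' Reshapes the runs x variables x times array into a runs x (variable, time)
#' matrix: one row per run, columns ordered variable-major, time-minor
#' (`v1@t1, v1@t2, ..., v2@t1, ...`), restricted to grid times `<= horizon`.
#'
#' @param gridded a `gridded_series` from [align_to_grid()]
#' @param variables variables to include, in order (default: all)
#' @param horizon history horizon, h (default: full grid)
#' @return an `unfolded_matrix`: numeric matrix with attributes `col_meta`
#'   (`data.frame` of variable and time per column), `grid`, `scaled`
#' @export
batch_wise_unfold <- function(gridded, variables = dimnames(gridded)$variable,
                              horizon = Inf) {
  grid <- attr(gridded, "grid")
  keep <- grid <= horizon + 1e-9
  grid <- grid[keep]
  blocks <- lapply(variables, function(v) {
    m <- gridded[, v, keep, drop = FALSE]
    dim(m) <- dim(m)[c(1, 3)]
    colnames(m) <- paste0(v, "@", grid)
    m
  })
  out <- do.call(cbind, blocks)
  rownames(out) <- dimnames(gridded)$run
  structure(out,
            col_meta = data.frame(
              variable = rep(variables, each = length(grid)),
              time = rep(grid, times = length(variables))),
            grid = grid, scaled = FALSE,
            class = c("unfolded_matrix", "matrix", "array"))
}

#' Refold an unfolded matrix back into a runs x variables x times array
#'
#' Inverse of [batch_wise_unfold()] (exact round trip on unscaled matrices).
#'
#' @param m an `unfolded_matrix`
#' @export
refold <- function(m) {
  meta <- attr(m, "col_meta")
  grid <- attr(m, "grid")
  vars <- unique(meta$variable)
  arr <- array(NA_real_, dim = c(nrow(m), length(vars), length(grid)),
               dimnames = list(run = rownames(m), variable = vars,
                               time = as.character(grid)))
  for (v in vars) arr[, v, ] <- m[, meta$variable == v, drop = FALSE]
  structure(arr, grid = grid, class = c("gridded_series", "array"))
}

#' Autoscale an unfolded matrix
#'
#' Centers every column and scales it to unit variance (n-1 denominator).
#' Constant columns are set to zero and flagged rather than producing NaN.
#'
#' @param m an `unfolded_matrix` (or plain matrix) with at least 2 rows
#' @return the scaled matrix with attributes `center`, `scale`,
#'   `constant_cols` (logical) and `scaled = TRUE`
#' @export
autoscale <- function(m) {
  if (nrow(m) < 2) stop("autoscaling needs at least 2 rows", call. = FALSE)
  ctr <- colMeans(m)
  sds <- apply(m, 2, stats::sd)
  const <- sds < 1e-12
  sds[const] <- 1
  out <- sweep(sweep(m, 2, ctr, "-"), 2, sds, "/")
  out[, const] <- 0
  attributes(out) <- c(attributes(out)[c("dim", "dimnames")],
                       attributes(m)[c("col_meta", "grid")])
  structure(out, center = ctr, scale = sds, constant_cols = const,
            scaled = TRUE,
            class = c("unfolded_matrix", "matrix", "array"))
}
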