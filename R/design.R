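#' The packaged 16-condition fractional-factorial design
#'
#' Loads the default experimental design of the 48-run campaign: 16 conditions
#' crossing feed profile (exponential / linear / constant), feed rate set-point
#' (0.0875, 0.175, 0.35 h^-1), initial glucose concentration S0 (20 or
#' 30 g L^-1) and an optional 2-h hunger phase after batch end.
#'
#' @param path CSV file with header
#'   `condition_id,profile,feed_rate_1_per_h,S0_g_per_L,hunger_h`; defaults to
#'   the packaged table.
#' @return a `data.frame` of class `design_table` with columns `condition_id`,
#'   `profile` (factor), `mu_set`, `S0`, `hunger_h`
#' @export
read_design <- function(path = system.file("extdata", "design_table1.csv",
                                           package = "mbrcampaign")) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("condition_id", "profile", "feed_rate_1_per_h", "S0_g_per_L", "hunger_h")
  if (!identical(names(raw), need)) {
    stop("design table must have header ", paste(need, collapse = ","),
         " but found ", paste(names(raw), collapse = ","), call. = FALSE)
  }
  d <- data.frame(
    condition_id = as.integer(raw$condition_id),
    profile = factor(tolower(raw$profile),
                     levels = c("exponential", "linear", "constant")),
    mu_set = as.numeric(raw$feed_rate_1_per_h),
    S0 = as.numeric(raw$S0_g_per_L),
    hunger_h = as.numeric(raw$hunger_h)
  )
  if (anyNA(d$profile)) stop("unknown feed profile in design table", call. = FALSE)
  if (any(d$mu_set <= 0)) stop("mu_set must be > 0", call. = FALSE)
  if (any(d$S0 <= 0)) stop("S0 must be > 0", call. = FALSE)
  if (any(d$hunger_h < 0)) stop("hunger_h must be >= 0", call. = FALSE)
  dup <- d$condition_id[duplicated(d$condition_id)]
  if (length(dup)) {
    stop("duplicate condition_ids in design: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  class(d) <- c("design_table", "data.frame")
  d
}

#' @rdname read_design
#' @export
default_design <- function() read_design()

#' Expand a design into replicated run plans with plate positions
#'
#' Each condition is replicated and laid out on the 8-row x 6-column reactor
#' block. Runs are ordered replicate-block-wise (all 16 conditions of
#' replicate 1, then replicate 2, ...) and positions assigned column-major, so
#' the replicates of one condition land in different columns — matching
#' column-wise sampling by an 8-channel pipette.
#'
#' @param design a `design_table` (see [read_design()])
#' @param replicates replicates per condition (default 3)
#' @param V0 start volume per reactor, L
#' @param Y_XS biomass yield assumed in feed-rate calculation, g g^-1
#' @return a `data.frame` of class `run_plan`, one row per run, with plate
#'   position (`row`, `col`), feed-stock concentration `S_in` (500 g L^-1 for
#'   the highest rate to limit volume increase, else 100 g L^-1) and empty
#'   slots (`t_batch_end`, `t_feed_start`, `X0_feedstart`, `F0`) filled in by
#'   [plan_campaign_feeding()] or [generate_campaign()].
#' @export
expand_design <- function(design, replicates = 3, V0 = 0.010, Y_XS = 0.5) {
  stopifnot(nrow(design) >= 1, replicates >= 1)
  dup <- design$condition_id[duplicated(design$condition_id)]
  if (length(dup)) {
    stop("duplicate condition_ids: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  nc <- nrow(design)
  idx <- rep(seq_len(nc), times = replicates)
  runs <- design[idx, , drop = FALSE]
  n <- nrow(runs)
  runs$replicate <- rep(seq_len(replicates), each = nc)
  runs$run_id <- seq_len(n)
  pos <- seq_len(n)                      # column-major over an 8 x 6 block
  runs$row <- ((pos - 1L) %% 8L) + 1L
  runs$col <- ((pos - 1L) %/% 8L) + 1L
  runs$V0 <- V0
  runs$Y_XS <- Y_XS
  runs$S_in <- ifelse(runs$mu_set >= 0.35, 500, 100)
  runs$X0_feedstart <- NA_real_
  runs$t_batch_end <- NA_real_
  runs$t_feed_start <- NA_real_
  runs$F0 <- NA_real_
  rownames(runs) <- NULL
  class(runs) <- c("run_plan", "data.frame")
  runs
}

#' Initial feed rate from the set-point growth rate
#'
#' `F0 = mu_set / (S_in * Y_XS) * X0 * V0`: the flow that would support growth
#' at `mu_set` given the biomass present at feed start and the assumed yield.
#'
#' @param mu_set set-point specific growth rate, h^-1
#' @param S_in feed-stock glucose concentration, g L^-1
#' @param Y_XS biomass yield on glucose, g g^-1
#' @param X0 biomass concentration at feed start, g L^-1
#' @param V0 culture volume at feed start, L
#' @return initial feed rate, L h^-1
#' @export
initial_feed_rate <- function(mu_set, S_in, Y_XS, X0, V0) {
  check_positive(mu_set = mu_set, S_in = S_in, Y_XS = Y_XS, X0 = X0, V0 = V0)
  mu_set / (S_in * Y_XS) * X0 * V0
}

#' Construct a two-phase feed plan
#'
#' Phase 1 lasts `T` hours and is exponential, linear or constant; the linear
#' slope and constant level are anchored so that all three shapes deliver the
#' same phase-1 glucose total as the exponential profile
#' (`F0 * (exp(mu_set*T) - 1) / mu_set`). The linear profile is anchored at
#' `F0`; the constant profile is the phase-1 time average of the exponential.
#' Phase 2 is the common constant rate `F0 * exp(mu_set*T)` shared by all
#' shapes of one feed-rate group (continuity of the exponential profile at the
#' switch).
#'
#' @param profile one of `"exponential"`, `"linear"`, `"constant"`
#' @param F0 initial feed rate, L h^-1
#' @param mu_set set-point rate, h^-1
#' @param T_phase1 phase-1 duration, h (default 12)
#' @return a `feed_plan` list with fields `profile`, `F0`, `mu_set`, `T`,
#'   `slope` (linear), `level` (constant), `phase2_rate`
#' @export
feed_plan <- function(profile, F0, mu_set, T_phase1 = 12) {
  profile <- match.arg(profile, c("exponential", "linear", "constant"))
  check_positive(mu_set = mu_set, T_phase1 = T_phase1)
  if (!is.numeric(F0) || !is.finite(F0) || F0 < 0) {
    stop_domain("F0", "must be a non-negative finite number")
  }
  total <- F0 * expm1(mu_set * T_phase1) / mu_set  # phase-1 glucose-equivalent volume
  plan <- list(
    profile = profile, F0 = F0, mu_set = mu_set, T = T_phase1,
    slope = 2 * (total - F0 * T_phase1) / T_phase1^2,
    level = total / T_phase1,
    phase2_rate = phase2_rate(mu_set, F0, T_phase1)
  )
  class(plan) <- "feed_plan"
  plan
}

#' Constant feed rate of the second fed-batch phase
#'
#' All profiles of one feed-rate group switch to the same constant rate after
#' phase 1; the level is the exponential end value `F0 * exp(mu_set * T)`
#' (continuous limit `F0` as `mu_set -> 0`).
#'
#' @inheritParams feed_plan
#' @param T phase-1 duration, h
#' @export
phase2_rate <- function(mu_set, F0, T = 12) {
  stopifnot(T > 0, F0 >= 0, mu_set >= 0)
  F0 * exp(mu_set * T)
}

#' Evaluate a feed plan at time since feed start
#'
#' @param plan a [feed_plan()]
#' @param t hours since feed start (vectorised, `t >= 0`)
#' @return feed rate, L h^-1
#' @export
feed_profile_value <- function(plan, t) {
  if (any(t < 0)) stop_domain("t", "must be >= 0 (time since feed start)")
  p1 <- switch(plan$profile,
    exponential = plan$F0 * exp(plan$mu_set * t),
    linear = plan$F0 + plan$slope * t,
    constant = rep(plan$level, length(t))
  )
  ifelse(t < plan$T, p1, plan$phase2_rate)
}

# Closed-form integral of the feed plan over [t1, t2] (times since feed start).
feed_integral <- function(plan, t1, t2) {
  stopifnot(all(t2 >= t1), all(t1 >= 0))
  piece <- function(a, b) {            # integral within phase 1 only
    switch(plan$profile,
      exponential = plan$F0 / plan$mu_set * (exp(plan$mu_set * b) - exp(plan$mu_set * a)),
      linear = plan$F0 * (b - a) + plan$slope / 2 * (b^2 - a^2),
      constant = plan$level * (b - a)
    )
  }
  a1 <- pmin(t1, plan$T); b1 <- pmin(t2, plan$T)
  a2 <- pmax(t1, plan$T); b2 <- pmax(t2, plan$T)
  out <- numeric(length(t1))
  in1 <- b1 > a1
  if (any(in1)) out[in1] <- piece(a1[in1], b1[in1])
  in2 <- b2 > a2
  out[in2] <- out[in2] + plan$phase2_rate * (b2[in2] - a2[in2])
  out
}

#' Discretize a feed plan into 5-min bolus pulses
#'
#' Pulse times lie on the global 5-min grid (multiples of `dt` from time 0);
#' the first pulse is the first grid point at or after `t_feed_start`, so
#' hunger phases are pulse-free by construction. The pulse at grid time `t`
#' delivers the continuous-profile integral over `[t, t+dt]`, clipped at
#' `v_max_pulse` (30 uL by default, the dispensing limit of the liquid
#' handler); clipped excess is discarded, not carried over, which shortens the
#' effective first feed phase of fast-fed runs.
#'
#' @param plan a [feed_plan()]
#' @param t_feed_start feed start, h (absolute campaign time)
#' @param t_end end of feeding, h
#' @param v_max_pulse maximum pulse volume, L (default 30e-6)
#' @param dt pulse spacing, h (default 1/12 = 5 min)
#' @return a `data.frame` of class `bolus_schedule` with `time_h`, `volume_L`,
#'   `clipped`, and attributes `saturation_time` (first clipped pulse or `NA`)
#'   and `t_feed_start`
#' @export
discretize_bolus <- function(plan, t_feed_start, t_end,
                             v_max_pulse = 30e-6, dt = 1 / 12) {
  stopifnot(t_end > t_feed_start, dt > 0, v_max_pulse > 0)
  if (abs(plan$T / dt - round(plan$T / dt)) > 1e-9) {
    warning("phase-1 duration is not a multiple of the pulse spacing; ",
            "pulse integrals are split across the phase switch")
  }
  first <- ceiling(t_feed_start / dt - 1e-9) * dt
  times <- seq(first, t_end - dt + 1e-12, by = dt)
  if (length(times) == 0 || plan$F0 <= 0) {
    sched <- data.frame(time_h = numeric(0), volume_L = numeric(0),
                        clipped = logical(0))
  } else {
    raw <- feed_integral(plan, times - first, times - first + dt)
    clipped <- raw > v_max_pulse + 1e-18
    sched <- data.frame(time_h = times, volume_L = pmin(raw, v_max_pulse),
                        clipped = clipped)
  }
  attr(sched, "saturation_time") <-
    if (any(sched$clipped)) sched$time_h[which(sched$clipped)[1]] else NA_real_
  attr(sched, "t_feed_start") <- t_feed_start
  attr(sched, "dt") <- dt
  class(sched) <- c("bolus_schedule", "data.frame")
  sched
}

#' Build bolus schedules for every run of a campaign
#'
#' @param runs a `run_plan` with `t_feed_start`, `X0_feedstart` filled in
#' @param t_end end of feeding, h
#' @param v_max_pulse,dt see [discretize_bolus()]
#' @param T_phase1 phase-1 duration, h
#' @return named list (`run_id`) of `bolus_schedule`s
#' @export
build_campaign_schedule <- function(runs, t_end = 48, v_max_pulse = 30e-6,
                                    dt = 1 / 12, T_phase1 = 12) {
  if (anyNA(runs$t_feed_start)) {
    stop("t_feed_start missing for runs: ",
         paste(runs$run_id[is.na(runs$t_feed_start)], collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(runs$F0)) {
    stop("F0 missing for runs: ",
         paste(runs$run_id[is.na(runs$F0)], collapse = ", "), call. = FALSE)
  }
  out <- lapply(seq_len(nrow(runs)), function(i) {
    plan <- feed_plan(as.character(runs$profile[i]), runs$F0[i],
                      runs$mu_set[i], T_phase1)
    discretize_bolus(plan, runs$t_feed_start[i], t_end, v_max_pulse, dt)
  })
  names(out) <- as.character(runs$run_id)
  out
}

#' Export a campaign schedule to CSV
#'
#' Long format `run_id,time_h,pulse_volume_uL,clipped` on the 5-min grid.
#'
#' @param schedules list of `bolus_schedule`s from [build_campaign_schedule()]
#' @param path output CSV path
#' @export
write_schedule_csv <- function(schedules, path) {
  rows <- do.call(rbind, lapply(names(schedules), function(id) {
    s <- schedules[[id]]
    data.frame(run_id = as.integer(id), time_h = s$time_h,
               pulse_volume_uL = s$volume_L * 1e6, clipped = s$clipped)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
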