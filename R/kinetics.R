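#' Kinetic and observation parameters of the campaign emulator
#'
#' Defaults describe a Crabtree-positive *S. cerevisiae* production strain with
#' a respiratory bottleneck: glucose uptake up to `qS_crit` is respired
#' (yield `Y_XS_ox`, after a maintenance draw `m_S`), excess flux overflows to
#' ethanol (biomass yield `Y_XS_ferm`, ethanol yield `Y_ES`); ethanol is
#' re-assimilated under glucose derepression. Product (secreted
#' endopolygalacturonase) formation peaks at a low specific growth rate and
#' decays late in the process; a sigmoidal stagnation factor arrests uptake
#' after `t_stagnation`. The defaults are calibrated once so that the
#' noiseless batch phase reproduces the observed campaign's printed
#' batch-phase growth rate, substrate uptake rate and feed-start biomass when
#' read back through the finite-difference rate estimators.
#'
#' @param ... overrides of any default listed below
#' @return a named list of class `kinetic_params`
#' @export
kinetic_params <- function(...) {
  p <- list(
    # substrate uptake / overflow split
    qS_max = 1.6,       # g g-1 h-1 maximum specific glucose uptake
    K_S = 0.1,          # g L-1 glucose affinity
    qS_crit = 0.2,      # g g-1 h-1 respiratory (oxidative) capacity bound
    m_S = 0.065,       # g g-1 h-1 maintenance glucose draw on the oxidative route
    Y_XS_ox = 0.5,      # g g-1 biomass yield, oxidative route
    Y_XS_ferm = 0.05,   # g g-1 biomass yield, fermentative route
    Y_ES = 0.45,        # g g-1 ethanol per overflowed glucose
    # ethanol re-assimilation
    qE_max = 0.30,      # g g-1 h-1
    K_E = 0.5,          # g L-1
    K_I_S = 0.1,       # g L-1 glucose repression of ethanol uptake
    Y_XE = 0.3,         # g g-1 biomass yield on ethanol
    # product formation (volumetric enzyme activity, U mL-1)
    qP_max = 270,       # U g-1 h-1
    mu_opt_P = 0.028,    # h-1 growth optimum of production
    t_decline = 23,     # h onset of late productivity decay
    k_decline = 0.08,   # h-1 decay constant
    # growth arrest
    t_stagnation = 35,  # h sigmoid midpoint of uptake shutdown
    tau_stagnation = 3, # h sigmoid width
    # oxygen / pH / base observation models
    kLa = 100,          # h-1
    cO2_sat = 0.0074,   # g L-1 dissolved oxygen at air saturation, 30 C
    y_OS = 0.4,         # g O2 per g glucose respired
    y_OE = 1.0,         # g O2 per g ethanol respired
    pH_drift = 0.01,    # pH rise per (g L-1 overflowed glucose)
    pH_set = 6.0, pH_max = 7.5,
    base_mol_per_gX = 0.007,  # mol NH3 titrated per g new biomass
    base_conc = 3.5,    # mol L-1 titrant
    evap_rate = 5e-6,   # L h-1 per reactor
    # inoculation and batch end
    OD0 = 0.3, g_per_OD = 0.6,    # OD600 inoculum and conversion, g L-1 per OD
    S_batch_end = 0.05,           # g L-1 glucose threshold defining batch end
    sample_volume = 250e-6,       # L withdrawn per sample
    ethanol_lod = 1.0,            # g L-1 at-line detection limit (left-censored)
    # multiplicative measurement noise (relative sd)
    noise = c(biomass = 0.05, glucose = 0.07, ethanol = 0.08, EAv = 0.10,
              pH = 0.003, DOT = 0.02, volume = 0.005, base = 0.02)
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown)) stop("unknown kinetic parameter(s): ",
                            paste(unknown, collapse = ", "), call. = FALSE)
  p[names(dots)] <- dots
  num <- p[setdiff(names(p), "noise")]
  if (any(!vapply(num, function(v) is.numeric(v) && all(v >= 0), TRUE))) {
    stop("kinetic parameters must be non-negative numerics", call. = FALSE)
  }
  if (p$Y_XS_ferm >= p$Y_XS_ox) {
    stop("Y_XS_ferm must be smaller than Y_XS_ox", call. = FALSE)
  }
  class(p) <- "kinetic_params"
  p
}

#' Remove measurement noise from a parameter set
#' @param params a [kinetic_params()]
#' @export
noise_free <- function(params) {
  params$noise[] <- 0
  params
}

#' Simulate one fed-batch run
#'
#' Explicit Euler integration on amounts (biomass, glucose, ethanol, product
#' units, volume) with impulse glucose additions at bolus pulse times and
#' 250-uL withdrawals at sample times. Uptake is availability-limited within
#' each step, so states stay non-negative by construction; a hard check guards
#' against residual negative state.
#'
#' @param plan one row of a `run_plan` (data.frame or list) with `S0`,
#'   `mu_set`, `V0`, and (for fed runs) `S_in`
#' @param schedule a `bolus_schedule` or `NULL` for a batch-only simulation
#' @param params a [kinetic_params()]
#' @param dt integration step, h; must divide the 5-min pulse spacing
#' @param t_end simulation end, h
#' @param sample_times times of 250-uL sample withdrawals, h
#' @return a `run_trajectory`: list with `time` and aligned vectors `X`, `S`,
#'   `E`, `V`, `EAv`, `DOT`, `pH`, `base` (cumulative titrant, L), plus
#'   `events` (feed start, phase switch, sample times) and `t_batch_end`
#'   (first time glucose falls below the batch-end threshold)
#' @export
simulate_run <- function(plan, schedule = NULL, params = kinetic_params(),
                         dt = 1 / 240, t_end = 48, sample_times = NULL) {
  p <- params
  if (!is.null(schedule) && nrow(schedule)) {
    pulse_dt <- attr(schedule, "dt") %||% (1 / 12)
    if (abs(pulse_dt / dt - round(pulse_dt / dt)) > 1e-9) {
      stop("dt must divide the pulse spacing", call. = FALSE)
    }
  }
  n <- round(t_end / dt)
  time <- seq(0, by = dt, length.out = n + 1)
  # map impulse events onto step indices
  pulse_vol <- numeric(n + 1)
  if (!is.null(schedule) && nrow(schedule)) {
    idx <- round(schedule$time_h / dt) + 1L
    keep <- idx >= 1L & idx <= n + 1L
    pulse_vol[idx[keep]] <- schedule$volume_L[keep]
  }
  S_in <- if (!is.null(plan$S_in) && !is.na(plan$S_in)) plan$S_in else 0
  sample_flag <- logical(n + 1)
  if (length(sample_times)) {
    bad <- sample_times < 0 | sample_times > t_end
    if (any(bad)) stop("sample times outside simulation span: ",
                       paste(round(sample_times[bad], 2), collapse = ", "),
                       call. = FALSE)
    sample_flag[round(sample_times / dt) + 1L] <- TRUE
  }

  V <- plan$V0
  mX <- p$OD0 * p$g_per_OD * V
  mS <- plan$S0 * V
  mE <- 0; U <- 0; baseV <- 0; pH <- p$pH_set

  X_out <- S_out <- E_out <- V_out <- EA_out <- DOT_out <- pH_out <- base_out <-
    cons_out <- numeric(n + 1)
  t_batch_end <- NA_real_
  consumed <- 0; fed <- 0; withdrawn_S <- 0

  for (i in seq_len(n + 1)) {
    t <- time[i]
    if (pulse_vol[i] > 0) {            # bolus glucose addition
      V <- V + pulse_vol[i]
      mS <- mS + pulse_vol[i] * S_in
      fed <- fed + pulse_vol[i] * S_in
    }
    if (sample_flag[i] && V > 4 * p$sample_volume) {  # skip near-empty reactors
      frac <- max(0, (V - p$sample_volume) / V)
      withdrawn_S <- withdrawn_S + mS * (1 - frac)
      mX <- mX * frac; mS <- mS * frac; mE <- mE * frac; U <- U * frac
      V <- V * frac
    }
    X <- mX / V; S <- mS / V; E <- mE / V
    if (is.na(t_batch_end) && S < p$S_batch_end) t_batch_end <- t

    f_stag <- 1 / (1 + exp((t - p$t_stagnation) / p$tau_stagnation))
    qS <- p$qS_max * S / (p$K_S + S) * f_stag
    if (mX > 0) qS <- min(qS, mS / (mX * dt))        # availability limit
    qS_ox <- min(qS, p$qS_crit)
    qS_of <- qS - qS_ox
    qE <- p$qE_max * E / (p$K_E + E) * p$K_I_S / (p$K_I_S + S) * f_stag
    if (mX > 0) qE <- min(qE, mE / (mX * dt))
    mu <- p$Y_XS_ox * max(qS_ox - p$m_S, 0) + p$Y_XS_ferm * qS_of + p$Y_XE * qE
    qP <- if (p$mu_opt_P > 0 && mu > 0) {
      p$qP_max * (mu / p$mu_opt_P) * exp(1 - mu / p$mu_opt_P) *
        exp(-p$k_decline * max(0, t - p$t_decline))
    } else 0

    OUR <- (p$y_OS * qS_ox + p$y_OE * qE) * X
    DOT_out[i] <- clamp(100 * (1 - OUR / (p$kLa * p$cO2_sat)), 0, 100)
    X_out[i] <- X; S_out[i] <- S; E_out[i] <- E; V_out[i] <- V
    EA_out[i] <- U / (V * 1000)        # U mL-1
    pH_out[i] <- pH; base_out[i] <- baseV; cons_out[i] <- consumed

    if (i <= n) {                      # Euler update
      dmX <- mu * mX * dt
      mX <- mX + dmX
      consumed <- consumed + qS * mX0_step(mX, dmX) * dt
      mS <- max(0, mS - qS * mX0_step(mX, dmX) * dt)
      mE <- max(0, mE + (p$Y_ES * qS_of - qE) * mX0_step(mX, dmX) * dt)
      U <- U + qP * mX0_step(mX, dmX) * dt
      dBase <- p$base_mol_per_gX * max(dmX, 0) / p$base_conc
      baseV <- baseV + dBase
      V <- V + dBase - p$evap_rate * dt
      pH <- min(p$pH_max, pH + p$pH_drift * qS_of * X * dt)
      if (min(mX, mS, mE, U, V) < -1e-9) {
        stop("negative state at t = ", round(t, 3), " h despite rate limiting",
             call. = FALSE)
      }
    }
  }

  structure(list(
    run_id = plan$run_id %||% NA_integer_,
    time = time, X = X_out, S = S_out, E = E_out, V = V_out,
    EAv = EA_out, DOT = DOT_out, pH = pH_out, base = base_out,
    cum_S_consumed = cons_out, S_fed = fed, S_withdrawn = withdrawn_S,
    t_batch_end = t_batch_end,
    events = list(
      feed_start = if (!is.null(schedule) && nrow(schedule)) schedule$time_h[1] else NA_real_,
      phase_switch = if (!is.null(schedule) && nrow(schedule)) schedule$time_h[1] + 12 else NA_real_,
      samples = time[sample_flag]
    ),
    dt = dt
  ), class = "run_trajectory")
}

# uptake/production fluxes are evaluated at the pre-step biomass
mX0_step <- function(mX_new, dmX) mX_new - dmX

#' Interpolate trajectory variables at arbitrary times
#'
#' @param traj a `run_trajectory`
#' @param var one of `"X"`, `"S"`, `"E"`, `"V"`, `"EAv"`, `"DOT"`, `"pH"`, `"base"`
#' @param times times, h (within the trajectory span)
#' @export
trajectory_value <- function(traj, var, times) {
  v <- traj[[var]]
  if (is.null(v)) stop("unknown trajectory variable: ", var, call. = FALSE)
  bad <- times < traj$time[1] - 1e-9 | times > traj$time[length(traj$time)] + 1e-9
  if (any(bad)) stop("times outside trajectory span: ",
                     paste(round(times[bad], 2), collapse = ", "), call. = FALSE)
  stats::approx(traj$time, v, xout = times, rule = 2)$y
}

#' Plan per-run feeding from simulated batch phases
#'
#' Simulates the batch phase of every run (no feed), defines batch end as the
#' first time glucose drops below the configured threshold, sets
#' `t_feed_start = t_batch_end + hunger_h`, reads the simulated biomass
#' concentration at feed start, and computes the initial feed rate from it.
#'
#' @param runs a `run_plan` from [expand_design()]
#' @param params a [kinetic_params()]
#' @param dt integration step, h
#' @param t_max latest allowed feed start, h
#' @return `runs` with `t_batch_end`, `t_feed_start`, `X0_feedstart`, `F0` filled
#' @export
plan_campaign_feeding <- function(runs, params = kinetic_params(),
                                  dt = 1 / 240, t_max = 30) {
  for (i in seq_len(nrow(runs))) {
    traj <- simulate_run(runs[i, ], schedule = NULL, params = params,
                         dt = dt, t_end = t_max)
    if (is.na(traj$t_batch_end)) {
      stop("batch phase of run ", runs$run_id[i], " did not finish by ",
           t_max, " h", call. = FALSE)
    }
    runs$t_batch_end[i] <- traj$t_batch_end
    runs$t_feed_start[i] <- traj$t_batch_end + runs$hunger_h[i]
    runs$X0_feedstart[i] <- trajectory_value(traj, "X", runs$t_feed_start[i])
    runs$F0[i] <- initial_feed_rate(runs$mu_set[i], runs$S_in[i], runs$Y_XS[i],
                                    runs$X0_feedstart[i], runs$V0[i])
  }
  runs
}

#' Column-staggered sampling schedule for the reactor block
#'
#' The 8-channel pipette samples one 8-reactor column at a time. During the
#' batch phase columns are visited with a short fixed offset between columns;
#' once feeding has begun, columns are visited back-to-back at
#' `fedbatch_column_interval` so every reactor is sampled with period
#' `n_columns * fedbatch_column_interval` (2 h for 6 columns at 20 min).
#'
#' @param runs a `run_plan` with plate positions
#' @param t_feed_switch campaign time at which fed-batch sampling mode starts, h
#' @param batch_column_offset_min offset between columns during batch, min
#' @param fedbatch_column_interval_min column interval during fed-batch, min
#' @param batch_period_h per-column sampling period during batch, h
#' @param t_end end of sampling, h
#' @param n_columns width of the reactor block (6; the fed-batch period is
#'   `n_columns * fedbatch_column_interval` regardless of how many columns are
#'   actually occupied)
#' @return named list (`run_id`) of sample-time vectors, h
#' @export
sampling_schedule <- function(runs, t_feed_switch,
                              batch_column_offset_min = 5,
                              fedbatch_column_interval_min = 20,
                              batch_period_h = 2, t_end = 48,
                              n_columns = 6) {
  n_col <- n_columns
  out <- lapply(seq_len(nrow(runs)), function(i) {
    cc <- runs$col[i] - 1L
    batch <- seq(cc * batch_column_offset_min / 60, t_feed_switch - 1e-9,
                 by = batch_period_h)
    if (t_end <= t_feed_switch) return(batch[batch <= t_end])
    fed <- seq(t_feed_switch + cc * fedbatch_column_interval_min / 60, t_end,
               by = n_col * fedbatch_column_interval_min / 60)
    c(batch, fed)
  })
  names(out) <- as.character(runs$run_id)
  out
}

#' Draw noisy at-line measurements from a trajectory
#'
#' Multiplicative Gaussian noise per variable; in fed-batch sampling mode
#' biomass and glucose are measured in duplicate and enzyme activity in
#' triplicate (single determination during batch). Ethanol readings below the
#' detection limit are reported left-censored at the limit.
#'
#' @param traj a `run_trajectory`
#' @param times sample times, h
#' @param params a [kinetic_params()] (noise levels, detection limit)
#' @param seed integer seed for this run's measurement stream
#' @param fedbatch_from campaign time from which duplicate determination
#'   applies, h (defaults to the run's feed start; `Inf` for none)
#' @return long `data.frame`: `run_id`, `time_h`, `variable`, `value`,
#'   `replicate`, `censored`
#' @export
sample_measurements <- function(traj, times, params = kinetic_params(),
                                seed = 1, fedbatch_from = NULL) {
  fedbatch_from <- fedbatch_from %||% traj$events$feed_start %||% Inf
  if (is.na(fedbatch_from)) fedbatch_from <- Inf
  vars <- c(biomass = "X", glucose = "S", ethanol = "E", EAv = "EAv",
            pH = "pH", DOT = "DOT", volume = "V", base = "base")
  n_rep <- function(v, fed) {
    if (!fed) return(1L)
    switch(v, biomass = 2L, glucose = 2L, EAv = 3L, 1L)
  }
  rows <- vector("list", length(times) * length(vars))
  k <- 0
  old <- .Random.seed_exists()
  set.seed(seed)
  on.exit(.Random.seed_restore(old), add = TRUE)
  for (tt in times) {
    fed <- tt >= fedbatch_from
    for (v in names(vars)) {
      truth <- trajectory_value(traj, vars[[v]], tt)
      reps <- n_rep(v, fed)
      sd_rel <- unname(params$noise[[v]])
      val <- truth * (1 + sd_rel * stats::rnorm(reps))
      val <- pmax(val, 0)
      cens <- rep(FALSE, reps)
      if (v == "ethanol") {
        cens <- val < params$ethanol_lod
        val[cens] <- params$ethanol_lod
      }
      k <- k + 1
      rows[[k]] <- data.frame(run_id = traj$run_id, time_h = tt, variable = v,
                              value = val, replicate = seq_len(reps),
                              censored = cens)
    }
  }
  out <- do.call(rbind, rows[seq_len(k)])
  rownames(out) <- NULL
  out
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Inject a pH/DOT sensor failure into a trajectory
#'
#' Emulates a run whose pH and DOT sensors fail early, leading to incorrect
#' culture handling: after `onset` the pH signal drifts downward and the DOT
#' signal sticks (both with seeded jitter), base dosing freezes, and the
#' culture itself degrades (biomass, ethanol and product are damped by an
#' exponential degradation factor while residual glucose relaxes toward the
#' unconsumed level), so the run is multivariately abnormal from early times.
#'
#' @param traj a `run_trajectory`
#' @param mode failure mode; only `"pH_DOT_failure"` is defined
#' @param onset failure onset, h
#' @param seed seed for the sensor jitter
#' @param k_fail degradation rate of the culture, h^-1
#' @return the perturbed `run_trajectory` (unchanged if `onset` is beyond the span)
#' @export
inject_sensor_failure <- function(traj, mode = "pH_DOT_failure", onset = 0.5,
                                  seed = 1, k_fail = 0.03) {
  mode <- match.arg(mode, "pH_DOT_failure")
  tmax <- traj$time[length(traj$time)]
  if (onset > tmax) return(traj)
  old <- .Random.seed_exists()
  set.seed(seed)
  on.exit(.Random.seed_restore(old), add = TRUE)
  after <- traj$time > onset
  g <- exp(-k_fail * (traj$time[after] - onset))
  S0 <- traj$S[1]
  traj$X[after] <- traj$X[after] * g
  traj$E[after] <- traj$E[after] * g
  traj$EAv[after] <- traj$EAv[after] * g
  w <- 0.5 * (1 - g)                    # unconsumed glucose lingers
  traj$S[after] <- traj$S[after] * (1 - w) + pmax(traj$S[after], S0 * 0.3) * w
  i0 <- which(after)[1]
  traj$pH[after] <- pmax(4.8, traj$pH[i0] - 0.08 * (traj$time[after] - onset)) +
    stats::rnorm(sum(after), sd = 0.02)
  traj$DOT[after] <- clamp(traj$DOT[i0] + stats::rnorm(sum(after), sd = 0.5), 0, 100)
  traj$base[after] <- traj$base[i0]
  traj$events$failure_onset <- onset
  traj
}

#' Generate a full synthetic campaign
#'
#' Expands the design, plans per-run feeding from simulated batch phases,
#' builds bolus schedules, simulates every run with staggered column-wise
#' sample withdrawals, injects one sensor-failure run (run 46 by default) and
#' draws noisy at-line measurements. All randomness derives from `seed` via
#' named substreams. Ground-truth trajectories are retained.
#'
#' @param design a `design_table` (default: the packaged 16-condition table)
#' @param params a [kinetic_params()]
#' @param seed master integer seed
#' @param replicates replicates per condition
#' @param t_end campaign duration, h
#' @param failure_run run id receiving the sensor failure (`NA` for none)
#' @param failure_onset failure onset, h
#' @param dt integration step, h
#' @return a `campaign` list: `runs` (filled `run_plan`), `schedules`,
#'   `sampling`, `trajectories`, `measurements` (long data.frame), `params`,
#'   `seed`, `failure_run`, `t_end`
#' @export
generate_campaign <- function(design = default_design(),
                              params = kinetic_params(), seed = 1,
                              replicates = 3, t_end = 48,
                              failure_run = 46, failure_onset = 0.5,
                              dt = 1 / 240) {
  runs <- expand_design(design, replicates = replicates)
  if (!is.na(failure_run) && !failure_run %in% runs$run_id) failure_run <- NA
  runs <- plan_campaign_feeding(runs, params, dt = dt)
  schedules <- build_campaign_schedule(runs, t_end = t_end)
  t_switch <- min(runs$t_feed_start)
  sampling <- sampling_schedule(runs, t_feed_switch = t_switch, t_end = t_end)

  trajectories <- vector("list", nrow(runs))
  names(trajectories) <- as.character(runs$run_id)
  meas <- vector("list", nrow(runs))
  for (i in seq_len(nrow(runs))) {
    id <- as.character(runs$run_id[i])
    st <- sampling[[id]]
    traj <- simulate_run(runs[i, ], schedules[[id]], params, dt = dt,
                         t_end = t_end, sample_times = st)
    if (!is.na(failure_run) && runs$run_id[i] == failure_run) {
      traj <- inject_sensor_failure(traj, onset = failure_onset,
                                    seed = substream_seed(seed, paste0("fail_", id)))
    }
    trajectories[[id]] <- traj
    meas[[i]] <- sample_measurements(traj, st, params,
                                     seed = substream_seed(seed, paste0("meas_", id)),
                                     fedbatch_from = t_switch)
  }
  structure(list(
    runs = runs, schedules = schedules, sampling = sampling,
    trajectories = trajectories,
    measurements = do.call(rbind, meas),
    params = params, seed = seed, failure_run = failure_run, t_end = t_end
  ), class = "campaign")
}
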