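#' Batch-phase calibration readout of the campaign emulator
#'
#' Simulates the noiseless batch phase of one design condition (no feeding, no
#' sample withdrawals), samples it on the routine 2-h period, and reads the
#' batch-phase physiology back through the finite-difference estimators of the
#' preprocessing module: the specific growth rate from the log-difference of
#' volume-normalized biomass, the specific substrate uptake rate from the
#' glucose differences over mean biomass, and the biomass concentration at
#' feed start. Mid-batch sample pairs (from 2 h to 2 h before batch end) are
#' averaged so that inoculation transients and the terminal glucose depletion
#' do not enter the estimate.
#'
#' @param params a [kinetic_params()] (noise is ignored; the readout is
#'   noiseless by construction)
#' @param condition_id row of the packaged design used for the batch
#'   (default 5: exponential 0.0875 h^-1, S0 = 20 g L^-1, no hunger)
#' @param sample_period_h sampling period of the readout, h
#' @param dt integration step, h
#' @return list with `mu` (h^-1), `qS` (g g^-1 h^-1), `X_feedstart` (g L^-1),
#'   `t_batch_end` (h), `n_pairs` (sample pairs averaged)
#' @export
batch_calibration <- function(params = kinetic_params(), condition_id = 5,
                              sample_period_h = 2, dt = 1 / 240) {
  design <- default_design()
  runs <- expand_design(design[design$condition_id == condition_id, ,
                               drop = FALSE], replicates = 1)
  traj <- simulate_run(runs[1, ], schedule = NULL, params = noise_free(params),
                       dt = dt, t_end = 30)
  if (is.na(traj$t_batch_end)) stop("batch did not finish by 30 h", call. = FALSE)
  tbe <- traj$t_batch_end
  t_fs <- tbe + runs$hunger_h[1]
  ts <- seq(sample_period_h, floor(tbe) - sample_period_h,
            by = sample_period_h)
  series <- data.frame(
    time_h = ts,
    X = trajectory_value(traj, "X", ts),
    X_N = trajectory_value(traj, "X", ts) *
      trajectory_value(traj, "V", ts) / runs$V0[1],
    S = trajectory_value(traj, "S", ts)
  )
  rates <- specific_rates(series)
  list(mu = mean(rates$mu), qS = mean(rates$qS),
       X_feedstart = trajectory_value(traj, "X", t_fs),
       t_batch_end = tbe, n_pairs = nrow(rates))
}
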