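params0 <- noise_free(kinetic_params())

test_that("a zero-feed batch passes through the expected metabolic regimes", {
  plan <- list(run_id = 1L, S0 = 20, mu_set = 0.0875, V0 = 0.010, S_in = NA)
  traj <- simulate_run(plan, NULL, params0, t_end = 30)
  # glucose decreases monotonically to exhaustion
  expect_true(all(diff(traj$S) <= 1e-9))
  expect_lt(min(traj$S), 0.01)
  # ethanol rises while glucose lasts, is consumed afterwards
  i_be <- which(traj$time >= traj$t_batch_end)[1]
  expect_gt(traj$E[i_be], 5)
  expect_true(all(diff(traj$E[1:(i_be - 10)]) >= -1e-9))
  expect_lt(traj$E[length(traj$E)], traj$E[i_be])
  expect_true(all(traj$X >= 0 & traj$S >= -1e-12 & traj$E >= -1e-12))
  expect_true(all(traj$DOT >= 0 & traj$DOT <= 100))
})

test_that("glucose mass balance closes for fed runs", {
  camp <- mini_campaign()
  for (i in seq_len(nrow(camp$runs))) {
    tr <- camp$trajectories[[i]]
    n <- length(tr$time)
    glucose_in <- camp$runs$S0[i] * camp$runs$V0[i] + tr$S_fed
    glucose_out <- tr$cum_S_consumed[n] + tr$S[n] * tr$V[n] + tr$S_withdrawn
    expect_lt(abs(glucose_in - glucose_out) / glucose_in, 0.005)
  }
})

test_that("volume balance is exact at event resolution", {
  runs <- planned_run()
  sch <- build_campaign_schedule(runs, t_end = 30)[[1]]
  st <- c(5, 10, 20, 25)
  traj <- simulate_run(runs[1, ], sch, params0, t_end = 30, sample_times = st)
  n <- length(traj$time)
  v_expect <- runs$V0[1] +
    sum(sch$volume_L[sch$time_h < traj$time[n]]) +
    traj$base[n] - params0$evap_rate * traj$time[n] -
    length(st) * params0$sample_volume
  # withdrawal is proportional, capped at the available volume, so the
  # event-resolution balance holds to within one part in 1e6
  expect_equal(traj$V[n], v_expect, tolerance = 1e-6)
})

test_that("ethanol is produced exactly when uptake exceeds the respiratory bound", {
  camp <- mini_campaign()
  runs <- camp$runs
  # condition 3 (0.35 h-1) accumulates ethanol beyond condition 1 everywhere
  e1 <- camp$trajectories[[which(runs$condition_id == 1)]]$E
  e3 <- camp$trajectories[[which(runs$condition_id == 3)]]$E
  expect_true(all(e3 >= e1 - 1e-6))
  expect_gt(e3[length(e3)], e1[length(e1)] + 5)
  # condition 1: feed-limited below qS_crit, ethanol falls below the 1 g/L
  # reporting limit during fed-batch
  tr1 <- camp$trajectories[[which(runs$condition_id == 1)]]
  fed <- tr1$time > runs$t_feed_start[runs$condition_id == 1]
  expect_lt(min(tr1$E[fed]), 1.0)
  # time-averaged fed-batch ethanol is monotone in the feed-rate set-point
  avg_e <- vapply(seq_len(nrow(runs)), function(i) {
    tr <- camp$trajectories[[i]]
    mean(tr$E[tr$time > runs$t_feed_start[i]])
  }, numeric(1))
  expect_true(all(diff(avg_e[order(runs$mu_set)]) > 0))
})

test_that("column-staggered sampling gives every reactor a 2-h fed-batch period", {
  runs <- expand_design(default_design(), 3)
  sched <- sampling_schedule(runs, t_feed_switch = 16, t_end = 48)
  for (id in names(sched)) {
    fed <- sched[[id]][sched[[id]] >= 16]
    expect_equal(unique(round(diff(fed), 9)), 2)
  }
  # columns offset by 20 min in fed-batch, 5 min in batch
  first_fed <- vapply(sched, function(s) min(s[s >= 16]), numeric(1))
  expect_equal(sort(unique(first_fed)), 16 + (0:5) * 20 / 60)
  first_batch <- vapply(sched, function(s) min(s), numeric(1))
  expect_equal(sort(unique(first_batch)), (0:5) * 5 / 60)

  # single-column block: fed-batch period degenerates to the column interval
  one_col <- expand_design(default_design()[1:8, ], 1)
  s1 <- sampling_schedule(one_col, t_feed_switch = 16, t_end = 20,
                          n_columns = 1)
  expect_equal(unique(round(diff(s1[[1]][s1[[1]] >= 16]), 9)), 20 / 60)

  # enumeration oracle for the total sample count
  count_expected <- function(col, t_switch, t_end, n_col = 6) {
    batch <- seq((col - 1) * 5 / 60, t_switch - 1e-9, by = 2)
    fed <- seq(t_switch + (col - 1) * 20 / 60, t_end, by = n_col * 20 / 60)
    length(batch) + length(fed)
  }
  for (id in c("1", "20", "48")) {
    i <- match(as.integer(id), runs$run_id)
    expect_length(sched[[id]], count_expected(runs$col[i], 16, 48))
  }
})

test_that("measurement sampling is noiseless-faithful, censored and seeded", {
  runs <- planned_run()
  sch <- build_campaign_schedule(runs, t_end = 30)[[1]]
  traj <- simulate_run(runs[1, ], sch, params0, t_end = 30)
  times <- c(4, 10, 20, 26)

  m0 <- sample_measurements(traj, times, params0, seed = 5,
                            fedbatch_from = runs$t_feed_start[1])
  for (i in seq_len(nrow(m0))) {
    v <- c(biomass = "X", glucose = "S", ethanol = "E", EAv = "EAv",
           pH = "pH", DOT = "DOT", volume = "V", base = "base")[[m0$variable[i]]]
    truth <- trajectory_value(traj, v, m0$time_h[i])
    if (m0$variable[i] == "ethanol" && truth < 1.0) {
      expect_equal(m0$value[i], 1.0)
      expect_true(m0$censored[i])
    } else {
      expect_equal(m0$value[i], truth)
    }
  }
  # duplicate determination only in fed-batch mode
  reps <- with(m0[m0$variable == "biomass", ], tapply(replicate, time_h, max))
  expect_equal(as.vector(reps[c("4", "10")]), c(1L, 1L))
  expect_equal(as.vector(reps[c("20", "26")]), c(2L, 2L))
  expect_equal(max(m0$replicate[m0$variable == "EAv" & m0$time_h == 26]), 3)

  noisy <- kinetic_params()
  m1 <- sample_measurements(traj, times, noisy, seed = 5)
  m2 <- sample_measurements(traj, times, noisy, seed = 5)
  expect_identical(m1, m2)
  m3 <- sample_measurements(traj, times, noisy, seed = 6)
  expect_false(identical(m1$value, m3$value))

  expect_error(sample_measurements(traj, c(4, 99), params0, seed = 1),
               "outside trajectory span.*99")
})

test_that("measurement noise matches its nominal relative sd", {
  runs <- planned_run()
  traj <- simulate_run(runs[1, ], NULL, params0, t_end = 10)
  m <- sample_measurements(traj, rep(8, 1e4), kinetic_params(), seed = 2,
                           fedbatch_from = Inf)
  b <- m$value[m$variable == "biomass"]
  rel_sd <- sd(b) / trajectory_value(traj, "X", 8)
  expect_gt(rel_sd / 0.05, 0.95)
  expect_lt(rel_sd / 0.05, 1.05)
})

test_that("sensor-failure injection degrades the culture after onset only", {
  runs <- planned_run()
  traj <- simulate_run(runs[1, ], NULL, params0, t_end = 20)
  f1 <- inject_sensor_failure(traj, onset = 5, seed = 1)
  before <- traj$time <= 5
  expect_identical(f1$X[before], traj$X[before])
  after <- traj$time > 10
  expect_true(all(f1$X[after] < traj$X[after]))
  expect_true(all(diff(f1$base[traj$time > 5]) == 0))
  expect_lt(min(f1$pH), 5.9)

  # beyond the span: unchanged
  expect_identical(inject_sensor_failure(traj, onset = 25, seed = 1), traj)
  expect_error(inject_sensor_failure(traj, mode = "nonsense", onset = 5),
               "arg")

  # different seeds: same deterministic degradation, different sensor jitter
  f2 <- inject_sensor_failure(traj, onset = 5, seed = 2)
  expect_identical(f1$X, f2$X)
  expect_false(identical(f1$pH, f2$pH))
})

test_that("campaign generation is reproducible byte-for-byte under a seed", {
  d <- default_design()[5, , drop = FALSE]
  c1 <- generate_campaign(d, kinetic_params(), seed = 3, replicates = 1,
                          t_end = 24, failure_run = NA)
  c2 <- generate_campaign(d, kinetic_params(), seed = 3, replicates = 1,
                          t_end = 24, failure_run = NA)
  expect_equal(nrow(c1$runs), 1)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_measurements(c1$measurements, f1)
  write_measurements(c2$measurements, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  c3 <- generate_campaign(d, kinetic_params(), seed = 4, replicates = 1,
                          t_end = 24, failure_run = NA)
  expect_false(identical(c1$measurements$value, c3$measurements$value))
})
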