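test_that("design expansion replicates conditions with deterministic plate layout", {
  d <- default_design()
  expect_equal(nrow(d), 16)
  expect_equal(levels(d$profile), c("exponential", "linear", "constant"))
  expect_setequal(unique(d$mu_set), c(0.0875, 0.175, 0.35))

  runs <- expand_design(d, replicates = 3)
  expect_equal(nrow(runs), 48)
  expect_equal(runs$run_id, 1:48)
  expect_equal(as.vector(table(runs$condition_id)), rep(3L, 16))
  # replicates of one condition sit in different columns
  for (cid in d$condition_id) {
    expect_equal(anyDuplicated(runs$col[runs$condition_id == cid]), 0L)
  }
  expect_true(all(runs$row %in% 1:8), all(runs$col %in% 1:6))

  one <- expand_design(d[1, , drop = FALSE], replicates = 1)
  expect_equal(nrow(one), 1)
  expect_equal(c(one$row, one$col), c(1L, 1L))

  # brute-force count over a 2 x 2 expansion
  four <- expand_design(d[1:2, ], replicates = 2)
  expect_equal(nrow(four), 4)
  counts <- vapply(1:2, function(cid) sum(four$condition_id == cid), integer(1))
  expect_equal(counts, c(2L, 2L))

  dup <- rbind(d[1:2, ], d[2, ])
  expect_error(expand_design(dup, 1), "duplicate condition_ids.*2")
})

test_that("initial feed rate follows the set-point relation and rejects bad input", {
  expect_equal(initial_feed_rate(0.0875, 100, 0.5, 1.70, 0.010), 2.975e-5)
  expect_equal(initial_feed_rate(0.35, 500, 0.5, 1.70, 0.010), 2.38e-5)
  # linear in X0: shrinking X0 shrinks F0 proportionally
  expect_equal(initial_feed_rate(0.175, 100, 0.5, 1e-9, 0.010) /
                 initial_feed_rate(0.175, 100, 0.5, 1, 0.010), 1e-9)
  expect_error(initial_feed_rate(0.175, -100, 0.5, 1.7, 0.01), "S_in")
  expect_error(initial_feed_rate(0, 100, 0.5, 1.7, 0.01), "mu_set")
})

test_that("feed profiles anchor at F0 and meet their closed forms", {
  pe <- feed_plan("exponential", 1, 0.175, 12)
  expect_equal(feed_profile_value(pe, 11.999999), exp(2.1), tolerance = 1e-5)
  expect_equal(feed_profile_value(pe, 12), exp(2.1))   # continuous switch
  pc <- feed_plan("constant", 1, 0.175, 12)
  expect_equal(feed_profile_value(pc, 3), expm1(2.1) / 2.1)
  expect_equal(unique(feed_profile_value(pc, c(0, 5, 11.9))),
               expm1(2.1) / 2.1)
  pl <- feed_plan("linear", 1, 0.175, 12)
  expect_equal(feed_profile_value(pl, 0), 1)
  expect_equal(feed_profile_value(pe, 0), 1)
  expect_error(feed_profile_value(pe, -0.1), "t")
})

test_that("phase-2 rate is the exponential end value, shared across profiles", {
  expect_equal(phase2_rate(0.175, 1, 12), exp(2.1))
  expect_equal(phase2_rate(0.0875, 1, 12), exp(1.05))
  expect_equal(phase2_rate(1e-12, 1, 12), 1, tolerance = 1e-9)
  rates <- vapply(c("exponential", "linear", "constant"), function(p)
    feed_plan(p, 1, 0.175, 12)$phase2_rate, numeric(1))
  expect_equal(unname(diff(range(rates))), 0)
})

test_that("all three profile shapes deliver the same phase-1 glucose total", {
  for (mu in c(0.0875, 0.175, 0.35)) {
    totals <- vapply(c("exponential", "linear", "constant"), function(p) {
      mbrcampaign:::feed_integral(feed_plan(p, 3.1e-5, mu, 12), 0, 12)
    }, numeric(1))
    expect_lt(diff(range(totals)) / mean(totals), 1e-9)
    # and so do the discretized schedules, pulse sums vs continuous integral
    for (p in c("exponential", "linear", "constant")) {
      plan <- feed_plan(p, 3.1e-5, mu, 12)
      sch <- discretize_bolus(plan, 0, 12, v_max_pulse = Inf)
      expect_lt(abs(sum(sch$volume_L) - totals[[1]]) / totals[[1]], 1e-9)
    }
  }
})

test_that("bolus discretization clips at the pulse cap and reports saturation", {
  plan <- feed_plan("constant", 1, 1e-6, 12)      # level ~ F0 in the mu -> 0 limit
  plan$level <- 3e-4                              # 300 uL/h
  plan$phase2_rate <- 3e-4
  sch <- discretize_bolus(plan, 0, 12)
  expect_equal(unique(round(sch$volume_L * 1e6, 9)), 25)
  expect_false(any(sch$clipped))
  expect_true(is.na(attr(sch, "saturation_time")))

  plan$level <- 4e-4; plan$phase2_rate <- 4e-4
  sch2 <- discretize_bolus(plan, 0, 12)
  expect_true(all(sch2$clipped))
  expect_equal(unique(sch2$volume_L), 30e-6)
  expect_equal(attr(sch2, "saturation_time"), sch2$time_h[1])

  empty <- discretize_bolus(feed_plan("exponential", 0, 0.175), 0, 12)
  expect_equal(nrow(empty), 0)
})

test_that("clipping is monotone in the pulse cap and bounded by the integral", {
  plan <- feed_plan("exponential", 5e-5, 0.35, 12)
  caps <- c(10e-6, 20e-6, 30e-6, 60e-6, Inf)
  delivered <- vapply(caps, function(vm)
    sum(discretize_bolus(plan, 0, 20, v_max_pulse = vm)$volume_L), numeric(1))
  expect_true(all(diff(delivered) >= 0))
  total <- mbrcampaign:::feed_integral(plan, 0, 20)
  expect_true(all(delivered <= total * (1 + 1e-12)))
  sch <- discretize_bolus(plan, 0, 20, v_max_pulse = 30e-6)
  expect_lt(sum(sch$volume_L), total)             # clipped => strict loss
  expect_equal(sum(discretize_bolus(plan, 0, 20, v_max_pulse = Inf)$volume_L),
               total, tolerance = 1e-9)
})

test_that("campaign schedules share the 5-min grid and honor hunger phases", {
  runs <- expand_design(default_design(), 1)
  runs$t_batch_end <- 16.55
  runs$t_feed_start <- 16.55 + runs$hunger_h
  runs$X0_feedstart <- 1.70
  runs$F0 <- with(runs, mu_set / (S_in * Y_XS) * X0_feedstart * V0)
  sch <- build_campaign_schedule(runs, t_end = 30)
  expect_length(sch, 16)
  for (i in seq_len(nrow(runs))) {
    s <- sch[[as.character(runs$run_id[i])]]
    # global 5-min grid
    expect_equal(s$time_h * 12, round(s$time_h * 12), tolerance = 1e-9)
    expect_true(all(s$time_h >= runs$t_feed_start[i]))
  }
  hunger <- runs$hunger_h > 0
  first_pulse <- vapply(sch, function(s) s$time_h[1], numeric(1))
  expect_true(all(first_pulse[hunger] >= 18.55))
  expect_true(all(first_pulse[!hunger] >= 16.55 & first_pulse[!hunger] < 16.7))

  # determinism: byte-identical schedules for identical inputs
  expect_identical(sch, build_campaign_schedule(runs, t_end = 30))

  runs$t_feed_start[3] <- NA
  expect_error(build_campaign_schedule(runs), "t_feed_start missing.*3")
})
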