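# Shared fixtures, built once per test session and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# The full default campaign (seed 1): the study conditions of the acceptance
# suite. Expensive (~1 min), so built lazily and shared.
default_campaign <- function() {
  cached("default_campaign", function() generate_campaign(seed = 1))
}

default_gridded <- function() {
  cached("default_gridded", function() {
    camp <- default_campaign()
    meas <- camp$measurements
    norm <- normalize_biomass(meas, meas[meas$variable == "volume", ])
    key <- paste(meas$run_id, meas$time_h)
    nk <- paste(norm$run_id, norm$time_h)
    bio <- meas$variable == "biomass"
    meas$value[bio] <- meas$value[bio] *
      (norm$X_N / norm$X)[match(key[bio], nk)]
    align_to_grid(meas, grid_step = 2, horizon = 46)
  })
}

pca_variables <- c("biomass", "glucose", "ethanol", "pH", "DOT", "base", "volume")

default_outliers <- function() {
  cached("default_outliers", function() {
    m <- batch_wise_unfold(default_gridded(), variables = pca_variables,
                           horizon = 22)
    detect_outliers(fit_pca(m))
  })
}

# gridded series restricted to the non-flagged runs
filtered_gridded <- function() {
  cached("filtered_gridded", function() {
    gr <- default_gridded()
    keep <- !default_outliers()$outlier
    structure(gr[keep, , , drop = FALSE], grid = attr(gr, "grid"),
              class = class(gr))
  })
}

# A small noiseless mini-campaign: conditions 1-3 (exponential at the three
# feed rates, S0 = 30), one replicate each. Used for regime-ordering and
# balance checks.
mini_campaign <- function() {
  cached("mini_campaign", function() {
    d <- default_design()
    generate_campaign(d[d$condition_id %in% 1:3, ],
                      params = noise_free(kinetic_params()),
                      seed = 9, replicates = 1, t_end = 48,
                      failure_run = NA)
  })
}

# one planned batch run (condition 5) reused by simulator tests
planned_run <- function() {
  cached("planned_run", function() {
    d <- default_design()
    runs <- expand_design(d[d$condition_id == 5, , drop = FALSE], 1)
    plan_campaign_feeding(runs, noise_free(kinetic_params()))
  })
}
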