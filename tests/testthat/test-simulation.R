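short_cfg <- function(...) {
  default_config("SOAR", years = 4, burn_in = 0, tick_days = 30, ...)
}

test_that("simulations are reproducible from the seed", {
  cfg <- short_cfg(response = "cessation")
  a <- simulate_population(cfg, seed = 42)
  b <- simulate_population(cfg, seed = 42)
  expect_identical(a$trajectory, b$trajectory)
  expect_identical(a$lifehistory, b$lifehistory)
  c <- simulate_population(cfg, seed = 43)
  expect_false(identical(a$trajectory$N, c$trajectory$N))
})

test_that("the initial population matches the configuration", {
  cfg <- default_config("AUTEC")
  set.seed(1)
  init <- sonarPCoD:::init_population(cfg)
  expect_equal(nrow(init), 40)
  expect_true(all(init$age >= cfg$params$Tw))
  expect_true(all(init$area %in% 0:4))
  # reserves start at the target condition
  S <- structural_mass(structural_length(init$age, cfg$params), cfg$params)
  expect_equal(body_condition(init$F, S), rep(cfg$params$rho_f, 40))
})

test_that("trajectory bookkeeping is internally consistent", {
  cfg <- short_cfg(response = "both")
  sim <- simulate_population(cfg, seed = 7)
  tr <- sim$trajectory
  expect_true(all(tr$N == tr$calves + tr$males + tr$resting + tr$waiting +
                    tr$pregnant + tr$lactating))
  expect_true(all(tr$on_range <= tr$N))
  expect_true(all(tr$disturbed <= tr$N))
  expect_true(all(tr$R >= 0 & tr$R <= cfg$prey$R_max + 1e-9))
  expect_equal(tr$N[1], cfg$N0)
  expect_equal(tr$t, seq(0, (cfg$years) * 365.25, by = 30))
})

test_that("vital statistics reconcile with the population trajectory", {
  cfg <- short_cfg(response = "none")
  sim <- simulate_population(cfg, seed = 3)
  v <- sim$vitals
  expect_equal(sim$final_N, cfg$N0 + sum(v$births) - sum(v$deaths))
  expect_true(all(v$female_starvation_deaths <= v$female_deaths))
  expect_true(all(v$female_deaths <= v$deaths))
})

test_that("no whale is ever disturbed when the response is none", {
  sim <- simulate_population(short_cfg(response = "none"), seed = 5)
  expect_true(all(sim$trajectory$disturbed == 0))
})

test_that("cessation produces disturbed whales while sonar is active, none after it stops", {
  cfg <- default_config("SOAR", response = "cessation", years = 6, burn_in = 0,
                        sonar_off_year = 3, tick_days = 10)
  sim <- simulate_population(cfg, seed = 11)
  tr <- sim$trajectory
  during <- tr$disturbed[tr$t < 3 * 365.25]
  after <- tr$disturbed[tr$t > 3 * 365.25 + 10]
  expect_gt(sum(during), 0)
  expect_equal(sum(after), 0)
})

test_that("displacement shifts whales off range while sonar is active", {
  cfg <- default_config("SOAR", years = 30, burn_in = 0, tick_days = 30)
  cfg_d <- cfg; cfg_d$response <- "displacement"
  base <- simulate_population(cfg, seed = 13)
  disp <- simulate_population(cfg_d, seed = 13)
  on_base <- mean(base$trajectory$on_range / base$trajectory$N, na.rm = TRUE)
  on_disp <- mean(disp$trajectory$on_range / disp$trajectory$N, na.rm = TRUE)
  expect_lt(on_disp, on_base)
})

test_that("undisturbed area occupancy converges to the stationary distribution", {
  cfg <- default_config("SOAR", response = "none", years = 30, burn_in = 0)
  sim <- simulate_population(cfg, seed = 17)
  tr <- sim$trajectory
  on_frac <- sum(tr$on_range) / sum(tr$N)
  target <- fraction_on_range(stationary_distribution(soar_Q()), soar_areas())
  expect_equal(on_frac, target, tolerance = 0.08)
})

test_that("a population without prey starves to extinction", {
  cfg <- short_cfg(response = "none", R_max = 1e-6)
  cfg$prey$R_max <- 1e-6
  sim <- simulate_population(cfg, seed = 19)
  expect_lt(sim$final_N, cfg$N0 / 2)
  lh <- sim$lifehistory
  expect_gt(sum(lh$starved[lh$death_t >= 0]), 0)
})

test_that("an engine run and the reference allocation rules agree statistically", {
  # one-event comparison: the engine's cessation allocation and the R
  # reference implementation disturb the same expected fraction
  set.seed(23)
  ar <- soar_areas()
  z <- 0.4
  n_rep <- 200
  fracs <- replicate(n_rep, {
    pop <- data.frame(id = 1:50, area = "western range", weaned = TRUE,
                      mother_id = NA_integer_, disturbed_until = -Inf)
    out <- apply_event(pop, list(t = 0, z = c("western range" = z)), ar,
                       mode = "cessation")
    mean(out$disturbed_until > 0)
  })
  expect_equal(mean(fracs), 1 - z, tolerance = 0.02)
  # engine side: a quarter-day after the onset of a z = 0.4 event almost no
  # Erlang durations have expired and almost no whales have moved, so the
  # disturbed count is close to (1 - z) times the on-range count at onset
  cfg <- default_config("SOAR", response = "cessation", years = 0.1,
                        burn_in = 0, tick_days = 0.25)
  ev <- data.frame(start_day = 0, duration_hours = 24 * 40,
                   z_west = z, z_east = z)
  attr(ev, "span_days") <- 40
  cfg$sonar_series <- ev
  ratios <- replicate(30, {
    sim <- simulate_population(cfg, seed = sample.int(1e6, 1))
    tr <- sim$trajectory
    tr$disturbed[2] / tr$on_range[1]
  })
  expect_equal(mean(ratios), 1 - z, tolerance = 0.08)
})

test_that("replicate runs share the sonar series but differ demographically", {
  cfg <- default_config("SOAR", response = "cessation", years = 3,
                        burn_in = 0)
  reps <- run_replicates(cfg, n_reps = 3, seed = 31)
  expect_length(reps$runs, 3)
  expect_identical(reps$runs[[1]]$config$sonar_series,
                   reps$runs[[2]]$config$sonar_series)
  expect_false(identical(reps$runs[[1]]$trajectory$N,
                         reps$runs[[2]]$trajectory$N))
  agg <- reps$aggregate
  expect_equal(nrow(agg), nrow(reps$runs[[1]]$trajectory))
  Ns <- sapply(reps$runs, function(r) r$trajectory$N)
  expect_equal(agg$N_mean, rowMeans(Ns))
})

test_that("mean_abundance averages the post-burn-in window", {
  cfg <- short_cfg(response = "none")
  sim <- simulate_population(cfg, seed = 37)
  expect_equal(mean_abundance(sim, 0, 4), mean(sim$trajectory$N))
  m2 <- mean_abundance(sim, 2, 4)
  sel <- sim$trajectory$t >= 2 * 365.25
  expect_equal(m2, mean(sim$trajectory$N[sel]))
})

test_that("calibration errors when the target is not bracketed", {
  cfg <- short_cfg(response = "none")
  expect_error(
    calibrate_rmax(cfg, target = 1e5, interval = c(0.05, 0.1), n_reps = 1,
                   years = 1, seed = 1, max_iter = 1),
    "not bracketed")
})
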