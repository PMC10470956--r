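test_that("stochastic rounding is unbiased and nearest rounding is deterministic", {
  expect_equal(round_count(c(3, 0, 7.5, 2.4), "nearest"), c(3L, 0L, 8L, 2L))
  expect_equal(round_count(-1, "nearest"), 0L)     # counts cannot be negative
  set.seed(5)
  draws <- replicate(20000, round_count(3.3))
  expect_true(all(draws %in% c(3L, 4L)))
  se <- sqrt(0.3 * 0.7 / 20000)
  expect_lt(abs(mean(draws) - 3.3), 4 * se)
})

test_that("cessation and displacement targets follow their defining formulas", {
  # brute-force oracle over all small populations and tabulated z values
  for (N in 0:20) for (z in c(0, 0.25, 0.5, 0.75, 1)) {
    expect_equal(n_cessation(N, z, "nearest"), as.integer(floor((1 - z) * N + 0.5)))
    for (M in c(0, 5.5, 12)) {
      expect_equal(n_displacement(N, M, z, "nearest"),
                   as.integer(floor(max(N - M * z, 0) + 0.5)))
    }
  }
  expect_error(n_cessation(5, 1.2))
  expect_error(n_displacement(-1, 3, 0.5))
})

test_that("disturbance durations are Erlang with mean 1.5 and sd 1.06 days", {
  k <- 2; mu <- 0.75
  expect_equal(k * mu, 1.5)
  expect_equal(sqrt(k) * mu, 1.06, tolerance = 0.01)
  set.seed(99)
  n <- 1e5
  d <- sample_duration(n)
  se_mean <- sqrt(k) * mu / sqrt(n)
  expect_lt(abs(mean(d) - 1.5), 3 * se_mean)
  expect_equal(stats::sd(d), 1.06, tolerance = 0.02)
  expect_true(all(d > 0))
  expect_error(sample_duration(10, k = 1.5))
})

make_pop <- function(n_per_area, areas, t0 = -Inf) {
  data.frame(id = seq_len(sum(n_per_area)),
             area = rep(areas$name, n_per_area),
             weaned = TRUE, mother_id = NA_integer_,
             disturbed_until = t0)
}

test_that("cessation disturbs the (1-z) fraction in each on-range area only", {
  set.seed(21)
  ar <- soar_areas()
  pop <- make_pop(c(40, 50, 10), ar)
  ev <- list(t = 100, z = c("western range" = 0.4, "eastern range" = 0.8))
  out <- apply_event(pop, ev, ar, mode = "cessation", rounding = "nearest")
  dist <- tapply(out$disturbed_until > 100, out$area, sum)
  expect_equal(unname(dist[["western range"]]), round((1 - 0.4) * 50))
  expect_equal(unname(dist[["eastern range"]]), round((1 - 0.8) * 10))
  expect_equal(unname(dist[["off range"]]), 0)   # off-range whales never disturbed
  expect_equal(out$area, pop$area)               # cessation does not relocate
})

test_that("already-disturbed whales count towards the cessation target", {
  set.seed(22)
  ar <- soar_areas()
  pop <- make_pop(c(0, 20, 0), ar)
  pop$disturbed_until[1:10] <- 150            # ten still disturbed at t = 100
  ev <- list(t = 100, z = c("western range" = 0.5))
  out <- apply_event(pop, ev, ar, mode = "cessation", rounding = "nearest")
  # target (1-0.5)*20 = 10 is already met: no new whales selected
  expect_equal(sum(out$disturbed_until > 100), 10)
  expect_equal(out$disturbed_until[1:10], rep(150, 10))
})

test_that("re-disturbance extends but never shortens a suppression clock", {
  set.seed(23)
  ar <- soar_areas()
  pop <- make_pop(c(0, 5, 0), ar)
  pop$disturbed_until <- 1e6                  # far-future clocks
  ev <- list(t = 100, z = c("western range" = 0))
  out <- apply_event(pop, ev, ar, mode = "both", p_stable = c(1, 0, 0))
  expect_true(all(out$disturbed_until >= 1e6))
})

test_that("displacement moves max(N - Mz, 0) whales to the designated area", {
  set.seed(24)
  ar <- autec_areas()
  p_st <- as.numeric(stationary_distribution(autec_Q()))
  n0 <- c(10, 30, 20, 15, 25)
  pop <- make_pop(n0, ar)
  ev <- list(t = 0, z = c("western range" = 0.5, "eastern range" = 0.9))
  out <- apply_event(pop, ev, ar, mode = "displacement", p_stable = p_st,
                     rounding = "nearest")
  Ntot <- nrow(pop)
  exp_w <- round(max(30 - p_st[2] * Ntot * 0.5, 0))
  exp_e <- round(max(25 - p_st[5] * Ntot * 0.9, 0))
  tab <- table(factor(out$area, levels = ar$name))
  expect_equal(unname(tab[["western range"]]), 30 - exp_w)
  expect_equal(unname(tab[["eastern range"]]), 25 - exp_e)
  # AUTEC displacement goes to the off-range area directly north
  expect_equal(unname(tab[["northwest"]]), 20 + exp_w)
  expect_equal(unname(tab[["northeast"]]), 15 + exp_e)
  # displacement alone does not suppress foraging
  expect_true(all(out$disturbed_until == -Inf))
})

test_that("dependent calves are relocated with their mothers and are not counted", {
  set.seed(25)
  ar <- soar_areas()
  mothers <- data.frame(id = 1:6, area = "western range", weaned = TRUE,
                        mother_id = NA_integer_, disturbed_until = -Inf)
  calves <- data.frame(id = 7:12, area = "western range", weaned = FALSE,
                       mother_id = 1:6, disturbed_until = -Inf)
  pop <- rbind(mothers, calves)
  # z = 0 displaces all weaned whales regardless of the stable distribution
  ev <- list(t = 0, z = c("western range" = 0, "eastern range" = 0))
  out <- apply_event(pop, ev, ar, mode = "displacement",
                     p_stable = c(1, 0, 0), rounding = "nearest")
  expect_true(all(out$area == "off range"))
})

test_that("whales in areas with z = 1 are untouched", {
  set.seed(26)
  ar <- soar_areas()
  pop <- make_pop(c(10, 10, 10), ar)
  ev <- list(t = 0, z = c("western range" = 1, "eastern range" = 1))
  for (m in c("cessation", "displacement", "both")) {
    out <- apply_event(pop, ev, ar, mode = m, p_stable = c(1, 0, 0))
    expect_identical(out, pop)
  }
})

test_that("realized cessation fraction converges to 1 - z", {
  set.seed(27)
  ar <- soar_areas()
  z <- 0.3
  N <- 2000
  pop <- make_pop(c(0, N, 0), ar)
  out <- apply_event(pop, list(t = 0, z = c("western range" = z)), ar,
                     mode = "cessation")
  frac <- mean(out$disturbed_until > 0)
  expect_equal(frac, 1 - z, tolerance = 3 * sqrt(z * (1 - z) / N) / (1 - z))
})
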