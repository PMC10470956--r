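p <- energetics_params()

test_that("structural growth follows the von Bertalanffy curve", {
  expect_equal(structural_length(0, p), p$L0)
  a <- c(0, 500, 5000, 2e4)
  L <- structural_length(a, p)
  expect_true(all(diff(L) > 0))
  expect_lt(max(L), p$Linf)
  expect_equal(structural_length(1e7, p), p$Linf, tolerance = 1e-6)
  # closed form at an arbitrary age
  expect_equal(structural_length(1234, p),
               p$Linf - (p$Linf - p$L0) * exp(-p$k * 1234))
  # fetal ages allowed down to -Tg, clamped at zero length
  expect_gte(structural_length(-p$Tg, p), 0)
  expect_error(structural_length(-p$Tg - 1, p))
})

test_that("structural mass is allometric in length and growth is its chain-rule derivative", {
  L <- structural_length(3000, p)
  expect_equal(structural_mass(L, p), p$omega1 * L^p$omega2)
  # central-difference oracle for dS/da
  h <- 0.01
  num <- (structural_mass(structural_length(3000 + h, p), p) -
            structural_mass(structural_length(3000 - h, p), p)) / (2 * h)
  expect_equal(structural_mass_growth(3000, p), num, tolerance = 1e-6)
})

test_that("feeding level is a decreasing sigmoid with half-point at target condition", {
  expect_equal(feeding_level(p$rho_f, p), 0.5)
  expect_equal(feeding_level(0, p), 1)
  rho <- seq(0.05, 0.6, by = 0.05)
  expect_true(all(diff(feeding_level(rho, p)) < 0))
  # closed form
  expect_equal(feeding_level(0.25, p), 1 / (1 + (0.25 / p$rho_f)^p$eta))
})

test_that("prey intake follows a type II response scaled by area quality and age", {
  adult <- list(age = 25 * 365, F = 400)
  i1 <- prey_intake_rate(adult, R = 0.2, phi = 1, p)
  i2 <- prey_intake_rate(adult, R = 0.4, phi = 1, p)
  i_hi <- prey_intake_rate(adult, R = 0.2, phi = 13.3, p)
  expect_gt(i2, i1)           # increasing in prey density
  expect_lt(i2, 2 * i1)       # saturating
  expect_gt(i_hi, i1)         # high-quality habitat multiplies the attack rate
  # phi*R enters the response as effective density
  expect_equal(i_hi, prey_intake_rate(adult, R = 0.2 * 13.3, phi = 1, p))
  # closed form of the saturation ratio
  L <- structural_length(adult$age, p)
  S <- structural_mass(L, p)
  f <- feeding_level(body_condition(adult$F, S), p)
  expect_equal(i1, f * p$Imax_coef * L^2 * 0.2 / (0.2 + p$R_half) * p$assim)
  expect_equal(prey_intake_rate(list(age = 0, F = 10), 0.3, 1, p), 0)
  ramp_mid <- prey_intake_rate(list(age = p$Tw / 2, F = 50), 0.3, 1, p)
  expect_gt(ramp_mid, 0)
  expect_equal(prey_intake_rate(c(adult, disturbed = TRUE), 0.3, 1, p), 0)
  expect_error(prey_intake_rate(adult, -0.1, 1, p), ">= 0")
})

test_that("milk intake scales with calf surface area and stops at weaning", {
  mother <- list(age = 25 * 365, F = 500)
  young <- list(age = 50, F = 20)
  old <- list(age = p$Tw, F = 80)
  expect_gt(milk_intake_rate(young, mother, p), 0)
  expect_equal(milk_intake_rate(old, mother, p), 0)
  # milk declines with calf age between Tn and Tw
  mid <- list(age = (p$Tn + p$Tw) / 2, F = 50)
  m_young <- milk_intake_rate(list(age = p$Tn, F = 50), mother, p)
  expect_lt(milk_intake_rate(mid, mother, p), m_young)
  # a starving mother provides no milk
  poor <- list(age = 25 * 365, F = 0.05 / 0.95 *
                 structural_mass(structural_length(25 * 365, p), p))
  expect_equal(milk_intake_rate(young, poor, p), 0)
})

test_that("field metabolic rate scales with the 3/4 power of maintenance mass", {
  w <- list(age = 20 * 365, F = 300)
  L <- structural_length(w$age, p); S <- structural_mass(L, p)
  expect_equal(field_metabolic_rate(w, p),
               p$sigma_M * (S + p$theta_F * w$F)^0.75)
  # a pregnant female pays for the fetus
  wp <- c(w, fetal_age = -30)
  expect_gt(field_metabolic_rate(wp, p), field_metabolic_rate(w, p))
})

test_that("reserve dynamics respect the anabolic/catabolic efficiency asymmetry", {
  w <- list(age = 20 * 365, F = 300)
  out <- field_metabolic_rate(w, p) +
    p$sigma_G * structural_mass_growth(w$age, p)
  surplus <- energy_balance(w, out + 10, p)
  deficit <- energy_balance(w, out - 10, p)
  expect_equal(surplus, p$eps_plus * 10 / p$rho_E)
  expect_equal(deficit, -10 / (p$eps_minus * p$rho_E))
  # storing then mobilising the same energy loses mass: eps+ * eps- < 1
  expect_lt(surplus, -deficit)
  expect_equal(energy_balance(w, out, p), 0, tolerance = 1e-12)
})

test_that("lactation and gestation costs reduce the mother's energy balance", {
  w <- list(age = 20 * 365, F = 300)
  base <- energy_balance(w, 200, p)
  expect_lt(energy_balance(w, 200, p, lactation_cost = 50), base)
  expect_lt(energy_balance(c(w, fetal_age = -10), 200, p), base)
})

test_that("the Siler hazard is U-shaped in age and males have constant adult hazard", {
  h <- sapply(c(0, 2, 10, 30, 50) * 365.25, function(a)
    background_hazard(list(age = a, sex = "f"), p))
  expect_gt(h[1], h[3])         # juvenile decline
  expect_gt(h[5], h[3])         # senescent increase
  hm1 <- background_hazard(list(age = 10 * 365, sex = "m"), p)
  hm2 <- background_hazard(list(age = 40 * 365, sex = "m"), p)
  expect_equal(hm1, hm2)
  expect_equal(hm1, p$male_hazard)
  # unweaned males follow the Siler curve like calves of either sex
  expect_equal(background_hazard(list(age = 100, sex = "m", weaned = FALSE), p),
               background_hazard(list(age = 100, sex = "f", weaned = FALSE), p))
})

test_that("starvation hazard is zero above the threshold and rises hyperbolically below", {
  expect_equal(starvation_hazard(p$rho_f, p), 0)
  expect_equal(starvation_hazard(p$rho_s, p), 0)
  rho <- p$rho_s / 2
  expect_equal(starvation_hazard(rho, p), p$mu_s * (p$rho_s / rho - 1))
  expect_true(all(diff(starvation_hazard(seq(0.01, p$rho_s, by = 0.01), p)) < 1e-12))
})

test_that("the reproductive state machine cycles resting -> waiting -> pregnant -> lactating", {
  set.seed(7)
  f <- list(state = "resting", F = p$F_preg + 50, preg_clock = 0)
  f <- reproduction_step(f, 1, p)$female
  expect_equal(f$state, "waiting")
  # poor condition reverts receptivity
  f2 <- reproduction_step(list(state = "waiting", F = p$F_preg - 1,
                               preg_clock = 0), 1, p)$female
  expect_equal(f2$state, "resting")
  # conception happens eventually at rate nu
  while (f$state == "waiting") f <- reproduction_step(f, 1, p)$female
  expect_equal(f$state, "pregnant")
  # gestation runs Tg days and ends in a birth that debits the mother
  F_before <- f$F
  calf <- NULL
  for (i in seq_len(ceiling(p$Tg) + 1)) {
    res <- reproduction_step(f, 1, p)
    f <- res$female
    if (!is.null(res$calf)) calf <- res$calf
  }
  expect_equal(f$state, "lactating")
  expect_false(is.null(calf))
  expect_equal(calf$age, 0)
  S0 <- structural_mass(p$L0, p)
  expect_equal(calf$F, p$rho_birth / (1 - p$rho_birth) * S0)
  expect_equal(f$F, F_before - calf$F)
  # weaning returns the mother to resting
  f3 <- f; f3$calf_age <- p$Tw
  expect_equal(reproduction_step(f3, 1, p)$female$state, "resting")
})

test_that("conception waiting times are exponential with the configured rate", {
  set.seed(11)
  n <- 2000
  waits <- replicate(n, {
    f <- list(state = "waiting", F = p$F_preg + 100, preg_clock = 0)
    d <- 0
    while (f$state == "waiting") { f <- reproduction_step(f, 0.5, p)$female
      d <- d + 0.5 }
    d
  })
  # discrete-hazard mean: dt / p with p = 1 - exp(-nu dt), minus no offset
  p_step <- 1 - exp(-p$nu_conception * 0.5)
  expect_equal(mean(waits), 0.5 / p_step, tolerance = 0.05)
})

test_that("parameter validation rejects unknown names and inconsistent thresholds", {
  expect_error(energetics_params(not_a_param = 1), "unknown")
  expect_error(energetics_params(rho_s = 0.5, rho_f = 0.3))
  expect_error(energetics_params(L0 = 700))
})

test_that("a single foraging whale approaches its equilibrium condition", {
  # independent ODE oracle: integrate dF/dt at fixed prey density and compare
  # with the root of the net-energy function
  R <- 0.25; phi <- 1
  age0 <- 25 * 365
  rate <- function(t, y, parms) {
    w <- list(age = age0 + t, F = y[1])
    list(energy_balance(w, prey_intake_rate(w, R, phi, p), p))
  }
  L <- structural_length(age0, p); S <- structural_mass(L, p)
  sol <- deSolve::ode(y = c(F = 0.15 * S), times = seq(0, 4000, by = 50),
                      func = rate, parms = NULL)
  F_end <- sol[nrow(sol), "F"]
  # equilibrium: net energy zero
  net <- function(F) {
    w <- list(age = age0 + 4000, F = F)
    energy_balance(w, prey_intake_rate(w, R, phi, p), p)
  }
  F_star <- stats::uniroot(net, c(1, 5 * S))$root
  expect_equal(unname(F_end), F_star, tolerance = 0.02)
})
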