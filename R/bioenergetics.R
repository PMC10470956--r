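#' Energy-budget parameter sets
#'
#' Whale life history is governed by a dynamic energy budget: structural
#' growth is deterministic (von Bertalanffy in length, allometric in mass)
#' while reserve mass responds to the balance of assimilated energy (prey
#' and, for calves, milk) against field metabolic rate, growth, gestation and
#' lactation costs. Body condition \eqn{\rho = F/(S+F)} (reserves over total
#' mass) feeds back on intake through a decreasing sigmoidal "feeding level"
#' and, below a starvation threshold \eqn{\rho_s}, adds a mortality hazard.
#'
#' Parameter values are read from flat YAML files shipped with the package,
#' one per species-location scenario (\code{params_zc_soar.yaml},
#' \code{params_md_autec.yaml}); each numeric entry is annotated in the file
#' with its unit and provenance. \code{energetics_params()} validates a named
#' list of values and fills unspecified entries from the Cuvier's defaults.
#'
#' @param ... named parameter overrides, see the YAML files for the full set.
#' @param base optional list of values to start from.
#' @return A named list of class \code{"energetics_params"}.
#' @export
energetics_params <- function(..., base = NULL) {
  if (is.null(base)) base <- species_config("zc_soar")$energetics
  over <- list(...)
  unknown <- setdiff(names(over), names(base))
  if (length(unknown)) stop("unknown parameters: ", paste(unknown, collapse = ", "))
  base[names(over)] <- over
  p <- lapply(base, as.numeric)
  with(p, {
    stopifnot(all(unlist(p) >= 0), L0 < Linf, k > 0,
              eps_plus <= 1, eps_minus <= 1,
              rho_s < rho_f, rho_f < 1, Tn < Tw, rho_milk_full > rho_s)
  })
  structure(p, class = "energetics_params")
}

#' Read a species-location configuration file
#'
#' @param which \code{"zc_soar"} (Cuvier's beaked whale, SOAR) or
#'   \code{"md_autec"} (Blainville's beaked whale, AUTEC), or a path to a
#'   YAML file with the same layout.
#' @return Named list with elements \code{species}, \code{location},
#'   \code{energetics}, \code{prey}, \code{phi_high}, \code{dose_response},
#'   \code{target_abundance}, \code{sonar}.
#' @export
species_config <- function(which = c("zc_soar", "md_autec")) {
  path <- if (file.exists(which[1])) which[1] else {
    which <- match.arg(which)
    system.file("extdata", paste0("params_", which, ".yaml"),
                package = "sonarPCoD", mustWork = TRUE)
  }
  cfg <- yaml::read_yaml(path)
  cfg$energetics <- energetics_params(base = cfg$energetics)
  cfg
}

check_params <- function(params) {
  if (!inherits(params, "energetics_params"))
    params <- energetics_params(base = params)
  params
}

#' Deterministic structural growth
#'
#' Structural length follows a von Bertalanffy curve in age,
#' \eqn{L(a) = L_\infty - (L_\infty - L_0) e^{-ka}}; fetal ages (down to
#' \eqn{-T_g}) are allowed and clamped at zero length. Structural mass is
#' \eqn{S = \omega_1 L^{\omega_2}}. Growth is independent of food conditions.
#'
#' @param a age in days (may be negative for a fetus).
#' @param L structural length in cm.
#' @param params an [energetics_params()] set.
#' @return Length in cm, mass in kg, or mass growth rate in kg/day.
#' @export
structural_length <- function(a, params) {
  params <- check_params(params)
  stopifnot(all(a >= -params$Tg))
  .eb_length(as.numeric(a), params)
}

#' @rdname structural_length
#' @export
structural_mass <- function(L, params) {
  .eb_smass(as.numeric(L), check_params(params))
}

#' @rdname structural_length
#' @export
structural_mass_growth <- function(a, params) {
  .eb_smass_growth(as.numeric(a), check_params(params))
}

#' Body condition
#'
#' @param F reserve mass (kg).
#' @param S structural mass (kg).
#' @return \eqn{\rho = F/(S+F)}.
#' @export
body_condition <- function(F, S) ifelse(S + F > 0, F / (S + F), 0)

#' Feeding level as a function of body condition
#'
#' Hill-form decreasing sigmoid \eqn{f(\rho) = 1/(1+(\rho/\rho_f)^\eta)}:
#' close to 1 for animals in poor condition, 0.5 at the target condition
#' \eqn{\rho_f}, and approaching 0 as condition saturates.
#'
#' @param rho body condition in \[0, 1).
#' @inheritParams structural_length
#' @return Scalar multiplier on intake in \[0, 1\].
#' @export
feeding_level <- function(rho, params) {
  .eb_feeding_level(as.numeric(rho), check_params(params))
}

#' Assimilated prey-intake rate of a whale
#'
#' Prey feeding follows a type II functional response in the shared prey
#' density with an area-specific attack-rate multiplier \eqn{\phi_i}, a
#' maximum consumption rate proportional to structural surface area
#' (\eqn{L^2}), the condition-dependent feeding level, and an age ramp for
#' solid food (0 at birth, 1 at weaning age). Intake is zero while a whale's
#' foraging is suppressed by disturbance.
#'
#' @param whale a list with at least \code{age} (days), \code{F} (kg) and
#'   optionally \code{disturbed} (logical).
#' @param R shared prey density (non-negative).
#' @param phi attack-rate multiplier of the whale's area.
#' @inheritParams structural_length
#' @return Assimilated energy rate, MJ/day.
#' @export
prey_intake_rate <- function(whale, R, phi, params) {
  params <- check_params(params)
  if (any(R < 0)) stop("prey density must be >= 0")
  if (isTRUE(whale$disturbed)) return(0)
  L <- structural_length(whale$age, params)
  S <- structural_mass(L, params)
  rho <- body_condition(whale$F, S)
  .eb_intake(rho, L, whale$age, R, phi, params)
}

#' Assimilated milk-intake rate of a calf
#'
#' Milk intake is proportional to calf structural surface area, declines
#' with calf age from the milk-decline age to zero at weaning, is modulated
#' by the calf's feeding level, and by the mother's provisioning willingness,
#' which drops to zero when her condition falls to the starvation threshold.
#'
#' @param calf,mother lists with \code{age} (days) and \code{F} (kg).
#' @inheritParams structural_length
#' @return Assimilated energy rate, MJ/day.
#' @export
milk_intake_rate <- function(calf, mother, params) {
  params <- check_params(params)
  Lc <- structural_length(calf$age, params)
  Sc <- structural_mass(Lc, params)
  Lm <- structural_length(mother$age, params)
  Sm <- structural_mass(Lm, params)
  .eb_milk_intake(body_condition(calf$F, Sc), Lc, calf$age,
                  body_condition(mother$F, Sm), params)
}

#' Field metabolic rate
#'
#' Three-quarter-power function of maintenance body mass
#' \eqn{S + \theta_F F + S_{fetus}}; reserves contribute at the discounted
#' weight \eqn{\theta_F < 1} and the fetus's structural mass is included for
#' pregnant females.
#'
#' @param whale list with \code{age}, \code{F}, and for pregnant females
#'   \code{fetal_age} (days, in \[-Tg, 0\]).
#' @inheritParams structural_length
#' @return Energy rate, MJ/day.
#' @export
field_metabolic_rate <- function(whale, params) {
  params <- check_params(params)
  L <- structural_length(whale$age, params)
  S <- structural_mass(L, params)
  S_fet <- if (!is.null(whale$fetal_age))
    structural_mass(structural_length(whale$fetal_age, params), params) else 0
  .eb_fmr(S, whale$F, S_fet, params)
}

#' Reserve-mass dynamics from the energy balance
#'
#' Net energy is assimilated intake minus expenditure (field metabolic rate,
#' growth cost \eqn{\sigma_G \dot S}, gestation cost proportional to fetal
#' structural growth, and lactation cost, the calf's milk energy divided by
#' the lactation efficiency). A positive net is stored at anabolic efficiency
#' \eqn{\epsilon_+}; a deficit is met by mobilising reserves at catabolic
#' efficiency \eqn{\epsilon_-}, both through the reserve energy density
#' \eqn{\rho_E}.
#'
#' @param whale list with \code{age}, \code{F}, optional \code{fetal_age}.
#' @param intake total assimilated energy intake, MJ/day.
#' @param lactation_cost MJ/day spent on milk production (already divided by
#'   the lactation efficiency), default 0.
#' @inheritParams structural_length
#' @return dF/dt in kg/day.
#' @export
energy_balance <- function(whale, intake, params, lactation_cost = 0) {
  params <- check_params(params)
  gest <- if (!is.null(whale$fetal_age))
    params$sigma_G * structural_mass_growth(whale$fetal_age, params) else 0
  out <- field_metabolic_rate(whale, params) +
    params$sigma_G * structural_mass_growth(whale$age, params) +
    gest + lactation_cost
  .eb_reserves_rate(intake - out, params)
}

#' Mortality hazards
#'
#' Calves and weaned females follow a five-parameter Siler hazard
#' \eqn{\alpha_1 e^{-\beta_1 a} + \alpha_2 + \alpha_3 e^{\beta_3 a}}; weaned
#' males have a constant hazard. Whales below the starvation condition
#' threshold incur an additional hazard \eqn{\mu_s(\rho_s/\rho - 1)},
#' continuous at the threshold and increasing as condition declines.
#'
#' @param whale list with \code{age}, \code{sex} (\code{"f"}/\code{"m"}), and
#'   \code{weaned} (logical, default TRUE).
#' @inheritParams structural_length
#' @return Hazard rate, 1/day.
#' @export
background_hazard <- function(whale, params) {
  params <- check_params(params)
  weaned <- if (is.null(whale$weaned)) TRUE else isTRUE(whale$weaned)
  .eb_background_hazard(whale$age, identical(whale$sex, "m"), weaned, params)
}

#' @rdname background_hazard
#' @param rho body condition.
#' @export
starvation_hazard <- function(rho, params) {
  .eb_starvation_hazard(as.numeric(rho), check_params(params))
}

#' Advance the reproductive state machine of a female
#'
#' Resting females whose absolute reserve mass exceeds the pregnancy
#' threshold become receptive ("waiting"); receptive females conceive at a
#' constant rate; pregnancy lasts the gestation period and ends with the
#' birth of a calf of neonate length and random sex (equal ratio), after
#' which the mother lactates until the calf reaches weaning age or dies.
#'
#' Uses R's RNG stream (seed with [set.seed()]).
#'
#' @param female list with \code{state} (one of \code{"resting"},
#'   \code{"waiting"}, \code{"pregnant"}, \code{"lactating"}), \code{F},
#'   \code{preg_clock} (days) and, when lactating, \code{calf_age}.
#' @param dt time step in days.
#' @inheritParams structural_length
#' @return List with updated \code{female} and \code{calf} (a list with
#'   \code{sex}, \code{age = 0}, \code{F}, or NULL when no birth occurred).
#' @export
reproduction_step <- function(female, dt, params) {
  params <- check_params(params)
  calf <- NULL
  st <- female$state
  if (st == "resting" && female$F > params$F_preg) st <- "waiting"
  else if (st == "waiting" && female$F <= params$F_preg) st <- "resting"
  if (st == "waiting" && stats::runif(1) < 1 - exp(-params$nu_conception * dt)) {
    st <- "pregnant"
    female$preg_clock <- 0
  } else if (st == "pregnant") {
    female$preg_clock <- female$preg_clock + dt
    if (female$preg_clock >= params$Tg) {
      S0 <- structural_mass(params$L0, params)
      F0 <- params$rho_birth / (1 - params$rho_birth) * S0
      calf <- list(sex = if (stats::runif(1) < 0.5) "m" else "f",
                   age = 0, F = F0)
      female$F <- max(female$F - F0, 0)
      st <- "lactating"
      female$preg_clock <- 0
    }
  } else if (st == "lactating" &&
             !is.null(female$calf_age) && female$calf_age >= params$Tw) {
    st <- "resting"
  }
  female$state <- st
  list(female = female, calf = calf)
}
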