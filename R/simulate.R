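`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assemble a ready-to-run simulation configuration
#'
#' Combines the area layout, telemetry-derived movement generator, species
#' energetics, prey parameters, dose-response curve and sonar-schedule
#' statistics for one of the two modelled populations into a single
#' configuration object. All components can be overridden to set up
#' sensitivity experiments.
#'
#' @param location \code{"SOAR"} (Cuvier's beaked whale) or \code{"AUTEC"}
#'   (Blainville's beaked whale).
#' @param response behavioral response to sonar: \code{"none"},
#'   \code{"cessation"} (of foraging), \code{"displacement"}, or
#'   \code{"both"}.
#' @param years length of the exposure period (years) simulated after the
#'   burn-in.
#' @param burn_in years simulated before sonar starts, to reach the
#'   undisturbed stationary state.
#' @param sonar_off_year optional year (counted from the start of exposure)
#'   at which sonar stops, for recovery experiments.
#' @param phi_high attack-rate ratio override (\code{NULL} = location
#'   default; 1 removes habitat-quality differences).
#' @param adjust_Q if TRUE, use the 10-fold adjusted movement generator
#'   (more residency on range).
#' @param R_max prey productivity ceiling override.
#' @param mean_disturbance_days mean duration of foraging cessation; the
#'   Erlang scale is \code{mean/2} at shape 2.
#' @param sonar_from generate the sonar series with the schedule statistics
#'   and dose-response of this location (defaults to \code{location}; set to
#'   the other range for the series-swap experiment).
#' @param sonar_series optionally, a precomputed event table from
#'   [sonar_series_from_schedule()] (shared across replicates by
#'   [run_replicates()]).
#' @param N0 initial population size (defaults to the location's target
#'   abundance).
#' @param dt integration step (days).
#' @param tick_days trajectory output cadence (days).
#' @param rounding rounding rule for disturbance targets.
#' @return List of class \code{"pcod_config"}.
#' @export
default_config <- function(location = c("SOAR", "AUTEC"),
                           response = c("none", "cessation", "displacement",
                                        "both"),
                           years = 100, burn_in = 100, sonar_off_year = NULL,
                           phi_high = NULL, adjust_Q = FALSE, R_max = NULL,
                           mean_disturbance_days = 1.5, sonar_from = NULL,
                           sonar_series = NULL, N0 = NULL, dt = 0.25,
                           tick_days = 30,
                           rounding = c("stochastic", "nearest")) {
  location <- match.arg(location)
  response <- match.arg(response)
  rounding <- match.arg(rounding)
  sc <- species_config(if (location == "SOAR") "zc_soar" else "md_autec")
  phi_high <- phi_high %||% sc$phi_high
  areas <- if (location == "SOAR") soar_areas(phi_high) else
    autec_areas(phi_high)
  Q <- if (location == "SOAR") soar_Q() else autec_Q()
  if (adjust_Q) Q <- adjust_generator(Q, areas, 10)
  sonar_from <- sonar_from %||% location
  sf <- if (sonar_from == location) sc else
    species_config(if (sonar_from == "SOAR") "zc_soar" else "md_autec")
  spec <- sonar_schedule_spec(fraction = sf$sonar$fraction,
                              mean_area = sf$sonar$mean_area,
                              mean_area_east = sf$sonar$mean_area_east,
                              correlation = sf$sonar$correlation)
  structure(list(
    species = sc$species, location = location, response = response,
    areas = areas, Q = Q,
    params = sc$energetics,
    prey = list(R_max = R_max %||% sc$prey$R_max, delta = sc$prey$delta,
                kappa = sc$prey$kappa),
    dose = dose_response(z_min = sf$dose_response$z_min),
    sonar_spec = spec, record_hours = sf$sonar$record_hours,
    sonar_series = sonar_series,
    erlang_k = 2, erlang_mu = mean_disturbance_days / 2,
    rounding = rounding,
    years = years, burn_in = burn_in, sonar_off_year = sonar_off_year,
    N0 = N0 %||% sc$target_abundance,
    target_abundance = sc$target_abundance,
    dt = dt, tick_days = tick_days
  ), class = "pcod_config")
}

#' @export
print.pcod_config <- function(x, ...) {
  cat("PCoD simulation config:", x$species, "at", x$location,
      "| response:", x$response, "\n",
      " areas:", nrow(x$areas), "| phi:", paste(round(x$areas$phi, 2),
                                                collapse = "/"),
      "| R_max:", x$prey$R_max, "| N0:", x$N0, "\n",
      " burn-in:", x$burn_in, "y + exposure:", x$years, "y\n")
  invisible(x)
}

# initial population: weaned whales with ages drawn from the Siler
# survivorship curve, 50/50 sex ratio, areas from the stationary
# distribution of the movement generator, reserves at the target condition
init_population <- function(config) {
  p <- config$params
  ages <- seq(p$Tw, 55 * 365.25, by = 30)
  surv <- exp(-(p$siler_a1 / p$siler_b1 * (1 - exp(-p$siler_b1 * ages)) +
                  p$siler_a2 * ages +
                  p$siler_a3 / p$siler_b3 * (exp(p$siler_b3 * ages) - 1)))
  n <- config$N0
  age <- sample(ages, n, replace = TRUE, prob = surv)
  sex <- stats::rbinom(n, 1, 0.5)
  pi <- stationary_distribution(config$Q)
  area <- sample(seq_len(nrow(config$areas)) - 1L, n, replace = TRUE,
                 prob = pi)
  S <- structural_mass(structural_length(age, p), p)
  F <- p$rho_f / (1 - p$rho_f) * S
  data.frame(age = age, sex = sex, area = area, F = F)
}

build_sonar_series <- function(config) {
  if (!is.null(config$sonar_series)) return(config$sonar_series)
  s <- gen_sonar_schedule(config$sonar_spec, config$record_hours)
  sonar_series_from_schedule(s, config$dose)
}

#' Run one replicate simulation
#'
#' Simulates an initial population through a burn-in to its undisturbed
#' stationary state, then applies the configured sonar regime. The
#' continuous dynamics (shared prey density, per-whale reserves) are
#' integrated with fixed-step RK4; movement, disturbance, and demographic
#' events are resolved on the integration grid. All randomness derives from
#' the seed, so identical calls are bit-reproducible.
#'
#' @param config a [default_config()] object.
#' @param seed integer seed for this replicate.
#' @return Object of class \code{"pcod_sim"}: list with data frames
#'   \code{trajectory} (every \code{tick_days}: abundance by class, prey
#'   density, disturbed and on-range head counts), \code{vitals} (yearly
#'   births, deaths, female starvation deaths) and \code{lifehistory} (one
#'   row per female dead by the end of the run), plus \code{final_N},
#'   \code{final_R}, and the \code{config} and \code{seed} used.
#' @export
simulate_population <- function(config, seed = 1) {
  stopifnot(inherits(config, "pcod_config"))
  set.seed(seed)
  series <- build_sonar_series(config)
  init <- init_population(config)
  n_areas <- nrow(config$areas)
  zmat <- matrix(1, nrow = nrow(series), ncol = n_areas)
  zmat[, match("western range", config$areas$name)] <- series$z_west
  zmat[, match("eastern range", config$areas$name)] <- series$z_east
  mode <- match(config$response, c("none", "cessation", "displacement",
                                   "both")) - 1L
  burn_days <- config$burn_in * 365.25
  end_day <- if (is.null(config$sonar_off_year)) Inf else
    burn_days + config$sonar_off_year * 365.25
  cfg <- list(
    params = config$params,
    areas = list(phi = config$areas$phi,
                 on_range = as.integer(config$areas$on_range),
                 disp_target = match(config$areas$displacement_target,
                                     config$areas$name) - 1L),
    p_stable = as.numeric(stationary_distribution(config$Q)),
    Q = unclass(config$Q),
    prey = list(R_max = config$prey$R_max, delta = config$prey$delta,
                kappa = config$prey$kappa, R0 = config$prey$R_max),
    sonar = list(onset = series$start_day, z = zmat,
                 loop_days = max(attr(series, "span_days") %||%
                                   (max(series$start_day) + 1), 1),
                 start = burn_days, end = end_day,
                 scenario = mode, erlang_k = config$erlang_k,
                 erlang_mu = config$erlang_mu,
                 rounding = match(config$rounding,
                                  c("stochastic", "nearest")) - 1L),
    control = list(dt = config$dt, tick_days = config$tick_days,
                   total_days = (config$burn_in + config$years) * 365.25),
    init = init
  )
  cfg$areas$disp_target[is.na(cfg$areas$disp_target)] <- -1L
  res <- .sim_engine(cfg)
  out <- list(trajectory = as.data.frame(res$trajectory),
              vitals = data.frame(year = seq_len(nrow(res$vitals)) - 1L,
                                  as.data.frame(res$vitals)),
              lifehistory = as.data.frame(res$lifehistory),
              final_N = res$final_N, final_R = res$final_R,
              config = config, seed = seed)
  class(out) <- "pcod_sim"
  out
}

#' @export
print.pcod_sim <- function(x, ...) {
  cat("PCoD replicate:", x$config$species, "at", x$config$location,
      "| response:", x$config$response, "| seed", x$seed, "\n",
      " final N:", x$final_N, "| ticks:", nrow(x$trajectory), "\n")
  invisible(x)
}

#' Run replicate simulations and aggregate abundance
#'
#' Runs independent replicates that share a single realized sonar series
#' (as when one recorded series is looped in every replicate) but use
#' replicate-specific seeds for all demographic and behavioral randomness.
#'
#' @param config a [default_config()].
#' @param n_reps number of replicates.
#' @param seed root seed; replicate seeds are derived from it.
#' @return Object of class \code{"pcod_replicates"}: \code{runs} (list of
#'   [simulate_population()] results), \code{aggregate} (per-tick mean and
#'   sd of total abundance and prey density) and the shared \code{config}.
#' @export
run_replicates <- function(config, n_reps = 8, seed = 1) {
  stopifnot(n_reps >= 1)
  set.seed(seed)
  config$sonar_series <- build_sonar_series(config)
  seeds <- seed + 7919L * seq_len(n_reps)
  runs <- lapply(seeds, function(s) simulate_population(config, seed = s))
  N <- sapply(runs, function(r) r$trajectory$N)
  R <- sapply(runs, function(r) r$trajectory$R)
  if (is.null(dim(N))) N <- matrix(N, ncol = n_reps)
  if (is.null(dim(R))) R <- matrix(R, ncol = n_reps)
  sd0 <- function(m) if (ncol(m) > 1) apply(m, 1, stats::sd) else 0
  agg <- data.frame(t = runs[[1]]$trajectory$t,
                    N_mean = rowMeans(N), N_sd = sd0(N),
                    R_mean = rowMeans(R), R_sd = sd0(R))
  structure(list(runs = runs, aggregate = agg, config = config,
                 seed = seed), class = "pcod_replicates")
}

#' Time-averaged mean abundance over a window
#'
#' @param x a \code{pcod_sim} or \code{pcod_replicates} object.
#' @param from,to window bounds in years on the simulation clock (burn-in
#'   included); defaults cover the post-burn-in period.
#' @return Mean of total abundance over ticks in the window (averaged over
#'   replicates for \code{pcod_replicates}).
#' @export
mean_abundance <- function(x, from = NULL, to = NULL) {
  traj <- if (inherits(x, "pcod_replicates")) {
    data.frame(t = x$aggregate$t, N = x$aggregate$N_mean)
  } else x$trajectory[, c("t", "N")]
  cfg <- x$config
  from <- from %||% cfg$burn_in
  to <- to %||% (cfg$burn_in + cfg$years)
  sel <- traj$t >= from * 365.25 & traj$t <= to * 365.25
  mean(traj$N[sel])
}

#' Calibrate prey productivity to a target abundance
#'
#' Adjusts the maximum prey density \code{R_max} by bisection until the
#' time-averaged undisturbed stationary abundance matches a target. Mean
#' stationary abundance is monotone non-decreasing in \code{R_max} because
#' whale density is limited by prey productivity.
#'
#' @param config a [default_config()] (the response is forced to
#'   \code{"none"}).
#' @param target target mean abundance (defaults to the location's).
#' @param tol acceptable absolute deviation in whales.
#' @param interval search interval for \code{R_max}.
#' @param n_reps,years replication and run length per evaluation.
#' @param seed root seed.
#' @param max_iter bisection iteration cap.
#' @return List with \code{R_max}, the achieved \code{abundance}, and the
#'   evaluation \code{history}.
#' @export
calibrate_rmax <- function(config, target = NULL, tol = 5,
                           interval = c(0.1, 1.5), n_reps = 2, years = 60,
                           seed = 1, max_iter = 12) {
  target <- target %||% config$target_abundance
  config$response <- "none"
  config$years <- years
  ev <- function(rmax) {
    cfg <- config
    cfg$prey$R_max <- rmax
    mean_abundance(run_replicates(cfg, n_reps = n_reps, seed = seed))
  }
  lo <- interval[1]; hi <- interval[2]
  flo <- ev(lo); fhi <- ev(hi)
  hist <- data.frame(R_max = c(lo, hi), abundance = c(flo, fhi))
  if (flo > target || fhi < target)
    stop("target abundance ", target, " not bracketed: endpoints give ",
         round(flo, 1), " and ", round(fhi, 1))
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    fm <- ev(mid)
    hist <- rbind(hist, data.frame(R_max = mid, abundance = fm))
    if (abs(fm - target) <= tol) {
      return(list(R_max = mid, abundance = fm, history = hist))
    }
    if (fm < target) lo <- mid else hi <- mid
  }
  list(R_max = mid, abundance = fm, history = hist)
}

#' Run a grid of sensitivity experiments
#'
#' Evaluates time-averaged mean abundance across combinations of attack-rate
#' ratio, movement generator and behavioral response, optionally with a
#' per-cell prey-productivity override.
#'
#' @param location \code{"SOAR"} or \code{"AUTEC"}.
#' @param phi_high vector of attack-rate ratios.
#' @param adjust_Q logical vector: baseline and/or adjusted generator.
#' @param responses character vector of responses.
#' @param R_max optional named list \code{[[phi]][[Q]]} of calibrated values.
#' @param n_reps,years,burn_in,seed passed to the runner.
#' @param ... further overrides for [default_config()].
#' @return Data frame with one row per grid cell: \code{phi_high},
#'   \code{adjust_Q}, \code{response}, \code{R_max}, \code{abundance},
#'   \code{abundance_sd}.
#' @export
experiment_matrix <- function(location, phi_high, adjust_Q = FALSE,
                              responses = c("none", "cessation",
                                            "displacement", "both"),
                              R_max = NULL, n_reps = 8, years = 100,
                              burn_in = 60, seed = 1, ...) {
  grid <- expand.grid(phi_high = phi_high, adjust_Q = adjust_Q,
                      response = responses, stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    rm <- if (is.null(R_max)) NULL else
      R_max[[as.character(g$phi_high)]][[as.character(g$adjust_Q)]]
    cfg <- default_config(location, response = g$response, years = years,
                          burn_in = burn_in, phi_high = g$phi_high,
                          adjust_Q = g$adjust_Q, R_max = rm, ...)
    reps <- run_replicates(cfg, n_reps = n_reps, seed = seed)
    sel <- reps$aggregate$t >= cfg$burn_in * 365.25
    data.frame(g, R_max = cfg$prey$R_max,
               abundance = mean(reps$aggregate$N_mean[sel]),
               abundance_sd = mean(reps$aggregate$N_sd[sel]))
  })
  do.call(rbind, res)
}
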