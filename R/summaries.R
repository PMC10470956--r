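#' Yearly vital rates from a simulation
#'
#' Births and deaths per year, and the yearly proportion of females that
#' died from starvation. A female is classified as starving if her body
#' condition at death was below the starvation threshold, regardless of
#' which hazard fired. Years with no female deaths have an undefined
#' (missing) starvation fraction, not zero.
#'
#' @param sim a [simulate_population()] result.
#' @return Data frame with columns \code{year}, \code{births}, \code{deaths},
#'   \code{starvation_fraction}.
#' @export
vital_rates <- function(sim) {
  v <- sim$vitals
  data.frame(year = v$year, births = v$births, deaths = v$deaths,
             starvation_fraction = ifelse(v$female_deaths > 0,
                                          v$female_starvation_deaths /
                                            v$female_deaths, NA_real_))
}

#' Recovery time and annualized growth rate of a mean trajectory
#'
#' Recovery time is the first output tick, after a given onset, at which
#' mean abundance re-enters 1 percent of an undisturbed reference level.
#' The growth rate is the geometric mean annual rate over a window.
#'
#' @param traj data frame with columns \code{t} (days) and \code{N}
#'   (e.g. the \code{aggregate} of [run_replicates()] with \code{N_mean}
#'   renamed, or a single replicate's trajectory).
#' @param reference undisturbed stationary abundance.
#' @param onset time (days) from which to search.
#' @param tol relative band defining recovery (default 1 percent).
#' @return \code{recovery_time}: years from onset to recovery (NA if the
#'   trajectory never recovers within the data).
#' @export
recovery_time <- function(traj, reference, onset = 0, tol = 0.01) {
  sel <- traj$t >= onset
  hit <- which(traj$N[sel] >= (1 - tol) * reference)
  if (!length(hit)) return(NA_real_)
  (traj$t[sel][hit[1]] - onset) / 365.25
}

#' @rdname recovery_time
#' @param from,to window bounds in days for the growth-rate computation.
#' @return \code{annual_growth_rate}: proportional growth per year (0.0113
#'   means +1.13 percent per year).
#' @export
annual_growth_rate <- function(traj, from, to) {
  N0 <- traj$N[which.min(abs(traj$t - from))]
  N1 <- traj$N[which.min(abs(traj$t - to))]
  yrs <- (to - from) / 365.25
  if (N0 <= 0 || yrs <= 0) return(NA_real_)
  (N1 / N0)^(1 / yrs) - 1
}

#' Life-history statistics of completed female lives
#'
#' Pools the life-history records of females that were born during the
#' simulation and died before its end: lifetime calves born and weaned,
#' ages at first receptivity, first reproduction and first weaning, the
#' starvation classification at death, and mean adult body condition.
#' In a stationary population the mean lifetime number of calves born per
#' female is 2 (each female, on average, exactly replaces herself with one
#' daughter, and the sex ratio at birth is even).
#'
#' @param x a \code{pcod_sim} or \code{pcod_replicates} object.
#' @param min_birth_year only count females born on or after this year of
#'   the simulation clock (to exclude transient cohorts).
#' @param max_birth_year only count females born on or before this year.
#'   Life-history records exist only for females dead by the end of the run,
#'   so pooling cohorts born too close to the end over-represents short
#'   (right-censored) lives; restrict to cohorts born at least a maximum
#'   lifespan before the end to obtain unbiased lifetime statistics.
#' @return List with the pooled \code{records} data frame and summary
#'   statistics \code{mean_calves_born}, \code{mean_calves_weaned},
#'   \code{mean_age_first_reproduction} (years), \code{n_females}.
#' @export
lifetime_statistics <- function(x, min_birth_year = 0, max_birth_year = Inf) {
  runs <- if (inherits(x, "pcod_replicates")) x$runs else list(x)
  rec <- do.call(rbind, lapply(runs, function(r) r$lifehistory))
  rec <- rec[rec$born_in_sim == 1 & rec$born_t >= min_birth_year * 365.25 &
               rec$born_t <= max_birth_year * 365.25, , drop = FALSE]
  list(records = rec,
       mean_calves_born = mean(rec$calves_born),
       mean_calves_weaned = mean(rec$calves_weaned),
       mean_age_first_reproduction =
         mean(rec$age_first_reproduction[rec$age_first_reproduction >= 0]) /
         365.25,
       n_females = nrow(rec))
}

# deterministic 32-bit FNV-1a digest of a configuration's deparsed text,
# excluding the (potentially large) realized sonar series
config_digest <- function(cfg) {
  txt <- paste(deparse(cfg[setdiff(names(cfg), "sonar_series")],
                       control = "all"), collapse = "")
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Write simulation outputs as CSV files with a manifest
#'
#' Writes \code{trajectory.csv}, \code{vitals.csv} and \code{lifehistory.csv}
#' to a directory, together with \code{manifest.json} recording the seed,
#' package version and a digest of the configuration, so a run can be
#' identified and reproduced.
#'
#' @param sim a [simulate_population()] result.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_outputs <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(sim$trajectory, file.path(dir, "trajectory.csv"),
                   row.names = FALSE)
  utils::write.csv(vital_rates(sim), file.path(dir, "vitals.csv"),
                   row.names = FALSE)
  utils::write.csv(sim$lifehistory, file.path(dir, "lifehistory.csv"),
                   row.names = FALSE)
  cfg <- sim$config
  manifest <- c(
    sprintf('{"package": "sonarPCoD %s",',
            as.character(utils::packageVersion("sonarPCoD"))),
    sprintf(' "seed": %d,', sim$seed),
    sprintf(' "species": "%s", "location": "%s", "response": "%s",',
            cfg$species, cfg$location, cfg$response),
    sprintf(' "config_hash": "%s"}', config_digest(cfg)))
  writeLines(manifest, file.path(dir, "manifest.json"))
  invisible(dir)
}
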