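#' Specification of a synthetic sonar schedule
#'
#' Emulates the temporal statistics of recorded mid-frequency active sonar
#' use on an instrumented range: sonar occurs in episodic events whose
#' inter-event gaps are heavy-tailed (lognormal), the fraction of hours with
#' sonar matches a configured value, and the western and eastern spatial
#' units share event timing with correlated hourly intensities.
#'
#' @param fraction target fraction of hours with sonar present (0-1).
#' @param mean_area mean standardized sonar area of sonar hours, western unit.
#' @param mean_area_east same for the eastern unit (defaults to
#'   \code{mean_area}).
#' @param correlation target correlation between hourly western and eastern
#'   intensities within events.
#' @param mean_event_hours mean sonar-event duration (hours).
#' @param gap_sdlog lognormal sdlog of inter-event gaps (right-skewed).
#' @param concentration beta concentration of hourly intensities.
#' @return List of class \code{"sonar_schedule_spec"}.
#' @export
sonar_schedule_spec <- function(fraction, mean_area, mean_area_east = mean_area,
                                correlation = 0.85, mean_event_hours = 6,
                                gap_sdlog = 1, concentration = 4) {
  stopifnot(fraction > 0, fraction < 1, mean_area > 0, mean_area <= 1,
            mean_area_east > 0, mean_area_east <= 1,
            abs(correlation) < 1, mean_event_hours >= 1)
  structure(list(fraction = fraction, mean_area = mean_area,
                 mean_area_east = mean_area_east, correlation = correlation,
                 mean_event_hours = mean_event_hours, gap_sdlog = gap_sdlog,
                 concentration = concentration),
            class = "sonar_schedule_spec")
}

# mean gap (hours between event ends and next starts) implied by the target
# sonar-hour fraction; moment-matched lognormal meanlog
gap_meanlog <- function(spec) {
  mean_gap <- spec$mean_event_hours * (1 - spec$fraction) / spec$fraction
  log(mean_gap) - spec$gap_sdlog^2 / 2
}

#' Generate an hourly standardized-sonar-area record
#'
#' Draws sonar events with lognormal inter-event gaps and geometric-tailed
#' durations, then hourly intensities for the western and eastern units from
#' beta distributions coupled through a Gaussian copula. Uses R's RNG
#' stream; seed with [set.seed()] for reproducibility.
#'
#' @param spec a [sonar_schedule_spec()].
#' @param hours record length in hours.
#' @return Matrix \code{hours x 2} with columns \code{west} and \code{east};
#'   0 when no sonar is present in the hour.
#' @export
gen_sonar_schedule <- function(spec, hours) {
  stopifnot(inherits(spec, "sonar_schedule_spec"), hours >= 1)
  s <- matrix(0, nrow = hours, ncol = 2,
              dimnames = list(NULL, c("west", "east")))
  mlog <- gap_meanlog(spec)
  shape_w <- c(spec$mean_area, 1 - spec$mean_area) * spec$concentration
  shape_e <- c(spec$mean_area_east, 1 - spec$mean_area_east) *
    spec$concentration
  r <- spec$correlation
  h <- 1 + round(stats::rlnorm(1, mlog, spec$gap_sdlog))
  while (h <= hours) {
    dur <- 1 + stats::rgeom(1, 1 / spec$mean_event_hours)
    idx <- h:min(h + dur - 1, hours)
    zw <- stats::rnorm(length(idx))
    ze <- r * zw + sqrt(1 - r^2) * stats::rnorm(length(idx))
    s[idx, 1] <- stats::qbeta(stats::pnorm(zw), shape_w[1], shape_w[2])
    s[idx, 2] <- stats::qbeta(stats::pnorm(ze), shape_e[1], shape_e[2])
    h <- h + dur + 1 + round(stats::rlnorm(1, mlog, spec$gap_sdlog))
  }
  s
}

#' Simulate hourly dive-start counts under a known dose-response
#'
#' Counts are Poisson with mean \code{area * baseline * z(s)}: used to test
#' recovery of a dose-response curve from synthetic passive-acoustic data.
#'
#' @param s hourly standardized sonar area.
#' @param curve the true [dose_response()] curve.
#' @param baseline dive starts per hour per km^2 in the absence of sonar.
#' @param area spatial-unit size (km^2).
#' @return Integer vector of counts.
#' @export
gen_dive_counts <- function(s, curve, baseline, area) {
  stopifnot(baseline >= 0, area > 0)
  stats::rpois(length(s), area * baseline * dose_response_z(s, curve))
}

#' Convert an hourly schedule into the simulator's sonar-event table
#'
#' Maps each unit's hourly standardized sonar area to foraging activity z
#' through the location's dose-response curve, then run-length encodes the
#' joint hourly (z_west, z_east) series: consecutive hours with identical
#' values form one event, and hours with no effect in either unit are
#' dropped.
#'
#' @param s matrix from [gen_sonar_schedule()] (columns west, east).
#' @param curve a [dose_response()] curve.
#' @return Data frame with columns \code{start_day}, \code{duration_hours},
#'   \code{z_west}, \code{z_east}, plus attribute \code{span_days} (record
#'   length), ready for [simulate_population()].
#' @export
sonar_series_from_schedule <- function(s, curve) {
  zw <- dose_response_z(s[, 1], curve)
  ze <- dose_response_z(s[, 2], curve)
  key <- paste(zw, ze)
  r <- rle(key)
  start <- cumsum(c(0, r$lengths))[seq_along(r$lengths)]
  first <- start + 1
  keep <- zw[first] < 1 | ze[first] < 1
  out <- data.frame(start_day = start[keep] / 24,
                    duration_hours = r$lengths[keep],
                    z_west = zw[first][keep], z_east = ze[first][keep])
  attr(out, "span_days") <- nrow(s) / 24
  out
}
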