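#' Standardized sonar area from hourly hydrophone detections
#'
#' Within each spatial unit, the tessellated areas of the hydrophones on
#' which sonar was detected in an hour are summed and scaled by the maximum
#' summed detection area observed anywhere in the location's record, giving a
#' 0-1 measure of how much of the unit was ensonified.
#'
#' @param hourly data frame with columns \code{hour} (integer hour index),
#'   \code{hydrophone} (id) and \code{sonar} (0/1 detection flag).
#' @param grid data frame with columns \code{hydrophone}, \code{unit}
#'   (spatial-unit name) and \code{area} (tessellated area, km^2).
#' @return Data frame with columns \code{hour}, \code{unit} and \code{s}
#'   (standardized sonar area), one row per hour and unit.
#' @export
standardized_sonar_area <- function(hourly, grid) {
  stopifnot(all(c("hour", "hydrophone", "sonar") %in% names(hourly)),
            all(c("hydrophone", "unit", "area") %in% names(grid)),
            all(grid$area > 0), !anyDuplicated(grid$hydrophone))
  m <- match(hourly$hydrophone, grid$hydrophone)
  if (anyNA(m)) stop("hydrophones present in 'hourly' but not in 'grid'")
  hours <- sort(unique(hourly$hour))
  units <- unique(grid$unit)
  hit_area <- hourly$sonar * grid$area[m]
  # per-hour, per-unit summed detection area
  sums <- tapply(hit_area,
                 list(factor(hourly$hour, levels = hours),
                      factor(grid$unit[m], levels = units)),
                 sum, default = 0)
  loc_max <- max(rowSums(sums, na.rm = TRUE))
  if (loc_max <= 0)
    stop("no sonar detected anywhere in the record: ",
         "the standardizing maximum area is undefined")
  out <- expand.grid(hour = hours, unit = units, KEEP.OUT.ATTRS = FALSE,
                     stringsAsFactors = FALSE)
  out$s <- as.vector(sums) / loc_max
  out
}

#' Dose-response curve from standardized sonar area to foraging activity
#'
#' Maps standardized sonar area \eqn{s \in [0,1]} to the relative foraging
#' activity \eqn{z \in [0,1]} (1 = no reduction, 0 = complete cessation of
#' foraging). The default is piecewise linear through (0, 1) and
#' (1, \code{z_min}); a tabulated curve may be supplied instead and is
#' interpolated linearly.
#'
#' @param z_min foraging activity at the maximal recorded sonar use.
#' @param table optional data frame with columns \code{s} and \code{z}
#'   tabulating the curve; must have \code{z = 1} at \code{s = 0}.
#' @return An object of class \code{"dose_response"}.
#' @export
dose_response <- function(z_min = 0.47, table = NULL) {
  if (is.null(table)) {
    stopifnot(z_min >= 0, z_min <= 1)
    table <- data.frame(s = c(0, 1), z = c(1, z_min))
  }
  stopifnot(all(c("s", "z") %in% names(table)),
            abs(table$z[which.min(table$s)] - 1) < 1e-9,
            all(table$z >= 0 & table$z <= 1))
  structure(list(table = table[order(table$s), ]), class = "dose_response")
}

#' @rdname dose_response
#' @param s standardized sonar area values in \[0, 1\].
#' @param curve a \code{dose_response} object.
#' @return \code{dose_response_z} returns z values in \[0, 1\].
#' @export
dose_response_z <- function(s, curve) {
  stopifnot(inherits(curve, "dose_response"), all(s >= 0), all(s <= 1))
  stats::approx(curve$table$s, curve$table$z, xout = s, rule = 2)$y
}

#' Run-length encode an hourly foraging-activity series into sonar events
#'
#' Consecutive hours with identical z-values are merged into a single event;
#' runs with \eqn{z = 1} (no sonar effect) are dropped. Decoding an encoded
#' series recovers the input exactly.
#'
#' @param z hourly z-values (vector).
#' @param unit spatial-unit label stored with the events.
#' @param t0 model time (days) of the first hour.
#' @return Data frame with columns \code{unit}, \code{start_day}, \code{z},
#'   \code{duration_hours}.
#' @export
rle_encode <- function(z, unit = "western range", t0 = 0) {
  stopifnot(all(z >= 0 & z <= 1))
  r <- rle(z)
  start_hour <- cumsum(c(0, r$lengths))[seq_along(r$lengths)]
  keep <- r$values < 1
  data.frame(unit = rep_len(unit, sum(keep)),
             start_day = t0 + start_hour[keep] / 24,
             z = r$values[keep], duration_hours = r$lengths[keep],
             stringsAsFactors = FALSE)
}

#' @rdname rle_encode
#' @param events a data frame produced by \code{rle_encode}.
#' @param n_hours length of the series to reconstruct.
#' @export
rle_decode <- function(events, n_hours, t0 = 0) {
  z <- rep(1, n_hours)
  for (i in seq_len(nrow(events))) {
    h0 <- round((events$start_day[i] - t0) * 24) + 1
    z[seq(h0, length.out = events$duration_hours[i])] <- events$z[i]
  }
  z
}

#' Fit a dose-response curve from hourly dive counts
#'
#' A Poisson regression with log link of hourly beaked whale dive-start
#' counts on a polynomial in standardized sonar area, with the log of the
#' spatial-unit size as an offset. The back-transformed prediction is
#' rescaled so that \eqn{z(0) = 1}, giving the relative change in foraging
#' activity attributable to sonar. This is a parsimonious stand-in for a
#' full smooth-additive analysis: the simulator only consumes the mean
#' \eqn{s \to z} mapping.
#'
#' @param counts hourly dive-start counts (non-negative integers).
#' @param s hourly standardized sonar area.
#' @param area spatial-unit size(s) used as offset (recycled).
#' @param degree polynomial degree (default 2).
#' @return A [dose_response()] object tabulated on a fine grid of s.
#' @export
fit_dose_response <- function(counts, s, area, degree = 2) {
  stopifnot(length(counts) == length(s), all(counts >= 0), all(s >= 0 & s <= 1))
  area <- rep_len(area, length(counts))
  if (max(s) - min(s) < 1e-12) {
    if (max(s) > 0) stop("degenerate design: sonar area does not vary")
    return(dose_response(table = data.frame(s = c(0, 1), z = c(1, 1))))
  }
  fit <- stats::glm(counts ~ poly(s, degree, raw = TRUE),
                    family = stats::poisson(), offset = log(area))
  grid <- seq(0, 1, by = 0.01)
  eta <- stats::predict(fit, newdata = data.frame(s = grid, area = 1),
                        type = "link") - log(1)
  z <- exp(eta - eta[1])
  z <- pmin(pmax(z, 0), 1)
  z[1] <- 1
  dose_response(table = data.frame(s = grid, z = z))
}
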