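#' Integer rounding of fractional whale counts
#'
#' Disturbance targets like \eqn{(1-z)N} are rarely integers. The default
#' stochastic rule (floor plus a Bernoulli draw on the fractional part) is
#' unbiased in expectation even for small populations; \code{"nearest"}
#' rounds deterministically to the nearest integer.
#'
#' @param x non-negative fractional count(s).
#' @param method \code{"stochastic"} or \code{"nearest"}.
#' @return Integer vector.
#' @export
round_count <- function(x, method = c("stochastic", "nearest")) {
  method <- match.arg(method)
  x <- pmax(x, 0)
  if (method == "nearest") return(as.integer(floor(x + 0.5)))
  fl <- floor(x)
  as.integer(fl + (stats::runif(length(x)) < (x - fl)))
}

#' Number of whales disturbed by a sonar event
#'
#' Under cessation of foraging, the target number of disturbed whales in an
#' on-range area is \eqn{N_{i,d} = (1-z_i) N_i}, counting whales already
#' disturbed by an earlier event, so the disturbed fraction matches the
#' observed reduction in foraging activity. Under displacement, the number
#' displaced is \eqn{N_{i,d} = \max(N_i - M_i z_i, 0)}, where
#' \eqn{M_i = p_i N_{tot}} is the expected head count in area \eqn{i} under
#' the stable distribution \eqn{p} of baseline movement.
#'
#' @param N whale count present in the area at the event onset.
#' @param z relative foraging activity of the event in the area (0-1).
#' @param M expected whale count in the area under the stable distribution.
#' @inheritParams round_count
#' @return Integer target count of disturbed whales.
#' @export
n_cessation <- function(N, z, method = c("stochastic", "nearest")) {
  stopifnot(all(N >= 0), all(z >= 0 & z <= 1))
  round_count((1 - z) * N, method)
}

#' @rdname n_cessation
#' @export
n_displacement <- function(N, M, z, method = c("stochastic", "nearest")) {
  stopifnot(all(N >= 0), all(M >= 0), all(z >= 0 & z <= 1))
  round_count(pmax(N - M * z, 0), method)
}

#' Sample disturbance durations
#'
#' Disturbance durations follow an Erlang distribution (the sum of
#' \code{k} independent exponentials with scale \code{mu} days); the default
#' shape 2 and scale 0.75 give mean 1.5 days and standard deviation
#' \eqn{\sqrt{2}\times0.75 \approx 1.06} days.
#'
#' @param n number of draws.
#' @param k integer shape parameter.
#' @param mu scale parameter (days).
#' @return Durations in days.
#' @export
sample_duration <- function(n, k = 2, mu = 0.75) {
  stopifnot(k == as.integer(k), k >= 1, mu > 0)
  stats::rgamma(n, shape = k, scale = mu)
}

#' Apply a sonar event to a population table
#'
#' Reference implementation of the disturbance-allocation rules on a plain
#' data frame of whales (the simulation engine applies the same rules
#' internally). At the onset of a sonar event, only whales present in an
#' on-range area can be disturbed. Under \code{"cessation"} the target
#' \eqn{(1-z)N} includes already-disturbed whales, and only the shortfall is
#' newly selected, uniformly at random, from the undisturbed whales in the
#' area; selected whales stop foraging until \code{t} plus an Erlang draw.
#' Under \code{"displacement"}, \eqn{\max(N - M z, 0)} whales are selected
#' and instantly relocated to the area's displacement target (dependent
#' calves move with their mothers and are not counted); their movement
#' regime is unchanged. \code{"both"} relocates and additionally suppresses
#' foraging. Re-disturbance can only extend, never shorten, an existing
#' foraging-suppression clock.
#'
#' @param pop data frame with columns \code{area} (area name), \code{weaned}
#'   (logical) and \code{disturbed_until} (days; \code{-Inf} when never
#'   disturbed).
#' @param event list with \code{t} (onset time, days) and \code{z}, a named
#'   vector of z-values for the on-range areas.
#' @param areas the [area_set()].
#' @param mode \code{"cessation"}, \code{"displacement"} or \code{"both"}.
#' @param p_stable stationary distribution used for the displacement rule.
#' @param k,mu Erlang duration parameters.
#' @param rounding rounding rule for fractional targets.
#' @return The updated population data frame.
#' @export
apply_event <- function(pop, event, areas, mode = c("cessation", "displacement",
                                                    "both"),
                        p_stable = NULL, k = 2, mu = 0.75,
                        rounding = c("stochastic", "nearest")) {
  mode <- match.arg(mode)
  rounding <- match.arg(rounding)
  stopifnot(inherits(areas, "area_set"),
            all(c("area", "weaned", "disturbed_until") %in% names(pop)))
  t <- event$t
  N_tot <- sum(pop$weaned)
  for (a in areas$name[areas$on_range]) {
    z <- unname(event$z[a])
    if (length(z) != 1 || is.na(z) || z >= 1) next
    members <- which(pop$area == a & pop$weaned)
    N <- length(members)
    if (N == 0) next
    if (mode == "cessation") {
      target <- n_cessation(N, z, rounding)
      cur <- sum(pop$disturbed_until[members] > t)
      undist <- members[pop$disturbed_until[members] <= t]
      need <- min(max(0, target - cur), length(undist))
      sel <- if (need > 0) sample(undist, need) else integer(0)
      pop$disturbed_until[sel] <- t + sample_duration(length(sel), k, mu)
    } else {
      tgt_area <- areas$displacement_target[match(a, areas$name)]
      if (is.na(tgt_area)) stop("no displacement target for area '", a, "'")
      M <- p_stable[[match(a, areas$name)]] * N_tot
      target <- min(n_displacement(N, M, z, rounding), N)
      sel <- if (target > 0) sample(members, target) else integer(0)
      if (length(sel)) {
        pop$area[sel] <- tgt_area
        if (!is.null(pop$mother_id) && !is.null(pop$id)) {
          dep <- which(!pop$weaned & pop$mother_id %in% pop$id[sel])
          pop$area[dep] <- tgt_area
        }
        if (mode == "both")
          pop$disturbed_until[sel] <- pmax(pop$disturbed_until[sel],
                                           t + sample_duration(length(sel), k, mu))
      }
    }
  }
  pop
}
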