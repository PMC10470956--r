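#' Define a set of discrete habitat areas
#'
#' An area set describes the discrete spatial units among which simulated
#' whales move: whether each unit lies on the instrumented Navy range (and can
#' therefore receive sonar), its habitat quality, the prey encounter-rate
#' (attack-rate) multiplier implied by that quality, and the off-range area to
#' which whales are displaced when a sonar response involves displacement.
#'
#' Habitat quality enters the model only through the attack-rate multiplier
#' \eqn{\phi_i}: low-quality areas have \eqn{\phi_i = 1} by convention and
#' high-quality areas have \eqn{\phi_i = \phi_{high}}, the ratio of foraging
#' effort needed in low- versus high-quality habitat.
#'
#' @param name character vector of unique area names.
#' @param on_range logical; is the area part of the instrumented range?
#' @param quality character, \code{"high"} or \code{"low"}.
#' @param displacement_target name of the off-range area that whales displaced
#'   from this area are moved to; \code{NA} for off-range areas.
#' @param phi_high attack-rate multiplier applied to high-quality areas.
#' @return A data frame of class \code{"area_set"} with columns \code{name},
#'   \code{on_range}, \code{quality}, \code{phi}, \code{displacement_target}.
#' @examples
#' soar_areas()
#' @export
area_set <- function(name, on_range, quality, displacement_target = NA_character_,
                     phi_high = 1) {
  stopifnot(is.character(name), !anyDuplicated(name),
            length(on_range) == length(name),
            all(quality %in% c("high", "low")),
            is.numeric(phi_high), length(phi_high) == 1, phi_high > 0)
  displacement_target <- rep_len(as.character(displacement_target), length(name))
  out <- data.frame(name = name, on_range = as.logical(on_range),
                    quality = quality,
                    phi = ifelse(quality == "high", phi_high, 1),
                    displacement_target = displacement_target,
                    stringsAsFactors = FALSE)
  for (i in which(out$on_range)) {
    tgt <- out$displacement_target[i]
    if (is.na(tgt) || !tgt %in% out$name || out$on_range[match(tgt, out$name)])
      stop("on-range area '", out$name[i],
           "' must have an off-range displacement_target")
  }
  class(out) <- c("area_set", "data.frame")
  out
}

#' Area layouts for the two modelled Navy ranges
#'
#' \code{soar_areas()} returns the three-area layout used for Cuvier's beaked
#' whales around the Southern California range (SOAR): a single low-quality
#' off-range area plus a high-quality western and low-quality eastern range
#' area, both displacing to the off-range area. \code{autec_areas()} returns
#' the five-area layout for Blainville's beaked whales around AUTEC (Bahamas):
#' a low-quality southern off-range area, high-quality western range,
#' high-quality northwest and low-quality northeast off-range areas, and a
#' low-quality eastern range area. Each on-range AUTEC area displaces to the
#' off-range area directly to its north, which shares its habitat quality.
#'
#' @param phi_high attack-rate ratio between high- and low-quality habitat.
#'   Defaults are the ratios of foraging-dive requirements in low- versus
#'   high-quality habitat: 20/1.5 = 13.3 at SOAR and 6.0/1.2 = 5.0 at AUTEC.
#' @return An [area_set()].
#' @export
soar_areas <- function(phi_high = 20 / 1.5) {
  area_set(name = c("off range", "western range", "eastern range"),
           on_range = c(FALSE, TRUE, TRUE),
           quality = c("low", "high", "low"),
           displacement_target = c(NA, "off range", "off range"),
           phi_high = phi_high)
}

#' @rdname soar_areas
#' @export
autec_areas <- function(phi_high = 6.0 / 1.2) {
  area_set(name = c("south", "western range", "northwest", "northeast",
                    "eastern range"),
           on_range = c(FALSE, TRUE, FALSE, FALSE, TRUE),
           quality = c("low", "high", "high", "low", "low"),
           displacement_target = c(NA, "northwest", NA, NA, "northeast"),
           phi_high = phi_high)
}
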