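#' Construct a continuous-time Markov generator matrix
#'
#' Movement among habitat areas is modelled as a discrete-space,
#' continuous-time Markov chain. The generator (transition-rate) matrix
#' \eqn{Q} has off-diagonal entries \eqn{q_{ij} \ge 0} giving the per-day rate
#' of moving from area \eqn{i} to area \eqn{j}; each diagonal entry is set to
#' minus the sum of the off-diagonal entries in its row, so rows sum to zero.
#'
#' @param rates square numeric matrix of per-day transition rates. Off-diagonal
#'   entries must be non-negative; the diagonal is recomputed and need not be
#'   supplied.
#' @param areas character vector of area names (defaults to the rownames of
#'   \code{rates}).
#' @return A matrix of class \code{"generator_matrix"} with area names as
#'   dimnames and rows summing to zero.
#' @examples
#' Q <- generator_matrix(matrix(c(0, 1, 1, 0), 2, 2), areas = c("a", "b"))
#' stationary_distribution(Q)
#' @export
generator_matrix <- function(rates, areas = rownames(rates)) {
  rates <- as.matrix(rates)
  n <- nrow(rates)
  if (n != ncol(rates)) stop("'rates' must be square")
  if (is.null(areas)) areas <- paste0("area", seq_len(n))
  stopifnot(length(areas) == n)
  off <- rates
  diag(off) <- 0
  if (any(off < 0)) stop("off-diagonal transition rates must be >= 0")
  Q <- off
  diag(Q) <- -rowSums(off)
  dimnames(Q) <- list(areas, areas)
  stopifnot(all(abs(rowSums(Q)) < 1e-9))
  class(Q) <- c("generator_matrix", class(Q))
  Q
}

#' @export
print.generator_matrix <- function(x, ...) {
  cat("Continuous-time movement generator (", nrow(x), " areas, rates per day)\n",
      sep = "")
  print(unclass(x), ...)
  invisible(x)
}

area_index <- function(Q, area) {
  if (is.character(area)) {
    i <- match(area, rownames(Q))
    if (is.na(i)) stop("unknown area '", area, "'")
    i
  } else as.integer(area)
}

# strong connectivity of the directed graph of positive rates
is_irreducible <- function(Q) {
  n <- nrow(Q)
  A <- (Q > 0)
  diag(A) <- TRUE
  reach <- A
  for (k in seq_len(n)) reach <- (reach %*% A) > 0 | reach
  all(reach) && all(t(reach))
}

#' Stationary distribution of a movement generator
#'
#' Solves \eqn{\pi Q = 0}, \eqn{\sum_i \pi_i = 1} as a linear system (one
#' balance equation is replaced by the normalisation constraint). This is the
#' long-run ("stable") distribution of whales over areas under baseline
#' movement.
#'
#' @param Q a [generator_matrix()]; must be irreducible.
#' @return Named probability vector over areas.
#' @export
stationary_distribution <- function(Q) {
  if (!inherits(Q, "generator_matrix")) Q <- generator_matrix(Q)
  if (!is_irreducible(Q))
    stop("generator is reducible: stationary distribution is not unique")
  n <- nrow(Q)
  A <- t(unclass(Q))
  A[n, ] <- 1
  pi <- solve(A, c(rep(0, n - 1), 1))
  if (any(pi < -1e-9)) stop("stationary solve produced negative probabilities")
  pi <- pmax(pi, 0)
  pi <- pi / sum(pi)
  names(pi) <- rownames(Q)
  pi
}

#' Mean residency time in an area
#'
#' The holding time in area \eqn{i} of a continuous-time Markov chain is
#' exponential with rate \eqn{-q_{ii}}, so the mean residency is
#' \eqn{-1/q_{ii}} days.
#'
#' @param Q a [generator_matrix()].
#' @param area area name or index.
#' @return Mean residency time in days.
#' @export
mean_residency <- function(Q, area) {
  i <- area_index(Q, area)
  qii <- Q[i, i]
  if (qii >= 0) stop("area '", rownames(Q)[i], "' is absorbing (q_ii = 0)")
  -1 / qii
}

#' Reduce movement off the range by scaling on-range rows of the generator
#'
#' To explore sensitivity to baseline movement, all transition rates out of
#' on-range areas can be divided by \code{factor}, increasing on-range
#' residency. The default (\code{rows = "full"}) divides every off-diagonal
#' entry of each on-range row, matching the tabulated adjusted matrices; the
#' alternative \code{rows = "offrange_only"} divides only the rates into
#' off-range areas, leaving range-to-range rates untouched.
#'
#' @param Q a [generator_matrix()].
#' @param areas the matching [area_set()] (supplies the on-range flags).
#' @param factor positive scalar divisor (10 for the default adjustment).
#' @param rows which entries of on-range rows to scale; see Details.
#' @return The adjusted [generator_matrix()] with recomputed diagonal.
#' @export
adjust_generator <- function(Q, areas, factor, rows = c("full", "offrange_only")) {
  rows <- match.arg(rows)
  stopifnot(inherits(areas, "area_set"), nrow(Q) == nrow(areas),
            is.numeric(factor), length(factor) == 1, factor > 0)
  off <- unclass(Q)
  diag(off) <- 0
  on <- which(areas$on_range[match(rownames(Q), areas$name)])
  for (i in on) {
    cols <- if (rows == "full") seq_len(ncol(off)) else
      which(!areas$on_range[match(colnames(Q), areas$name)])
    off[i, cols] <- off[i, cols] / factor
  }
  generator_matrix(off, areas = rownames(Q))
}

#' Fraction of the population on the range
#'
#' @param pi probability vector over areas (e.g. from
#'   [stationary_distribution()]).
#' @param areas the matching [area_set()].
#' @return Sum of \code{pi} over on-range areas.
#' @export
fraction_on_range <- function(pi, areas) {
  stopifnot(inherits(areas, "area_set"), length(pi) == nrow(areas),
            abs(sum(pi) - 1) < 1e-6)
  nm <- names(pi)
  idx <- if (is.null(nm)) seq_along(pi) else match(nm, areas$name)
  sum(pi[areas$on_range[idx]])
}

#' Sample the next movement of a whale
#'
#' Implements the competing-exponentials formulation used in the simulation:
#' for each destination \eqn{j \ne i} a candidate time is drawn from an
#' exponential distribution with rate \eqn{q_{ij}} (infinite when
#' \eqn{q_{ij} = 0}), and the whale moves to the area with the earliest
#' candidate time. This is distributionally equivalent to drawing a holding
#' time Exponential(\eqn{-q_{ii}}) and then a destination with probabilities
#' \eqn{q_{ij}/(-q_{ii})}.
#'
#' Uses R's global random number stream; seed with [set.seed()].
#'
#' @param Q a [generator_matrix()].
#' @param current_area area name or index the whale currently occupies.
#' @return List with \code{time} (waiting time, days) and \code{destination}
#'   (area name).
#' @export
sample_move <- function(Q, current_area) {
  i <- area_index(Q, current_area)
  rates <- unclass(Q)[i, ]
  rates[i] <- 0
  t <- rep(Inf, length(rates))
  pos <- rates > 0
  t[pos] <- stats::rexp(sum(pos), rate = rates[pos])
  j <- which.min(t)
  list(time = t[j], destination = rownames(Q)[j])
}

#' Read and write generator matrices as CSV
#'
#' The on-disk format is a square table with a header row and a leading
#' column of area names.
#'
#' @param path file path.
#' @return \code{read_generator_csv} returns a [generator_matrix()].
#' @export
read_generator_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, row.names = 1)
  generator_matrix(as.matrix(df), areas = rownames(df))
}

#' @rdname read_generator_csv
#' @param Q a [generator_matrix()] to write.
#' @export
write_generator_csv <- function(Q, path) {
  df <- as.data.frame(unclass(Q))
  utils::write.csv(df, path, row.names = TRUE)
  invisible(path)
}

#' Telemetry-derived movement generators for the two ranges
#'
#' Transition-rate matrices (per day) among the SOAR and AUTEC area layouts,
#' estimated from satellite telemetry of Cuvier's and Blainville's beaked
#' whales respectively. Shipped as CSV fixtures under \code{inst/extdata}.
#'
#' @return A [generator_matrix()] (3 areas for SOAR, 5 for AUTEC).
#' @export
soar_Q <- function() {
  read_generator_csv(system.file("extdata", "Q_zc_soar.csv",
                                 package = "sonarPCoD", mustWork = TRUE))
}

#' @rdname soar_Q
#' @export
autec_Q <- function() {
  read_generator_csv(system.file("extdata", "Q_md_autec.csv",
                                 package = "sonarPCoD", mustWork = TRUE))
}
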