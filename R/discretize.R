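#' Build a discretization grid for survival times
#'
#' Discrete-time survival models need continuous follow-up times cut into a
#' grid of `m` intervals. Two schemes are supported: `equidistant` intervals
#' of equal width on `[0, max duration]`, and `km_quantile`, which places
#' boundaries where the training Kaplan-Meier curve crosses `m` equally
#' spaced marginal survival probabilities (so intervals carry comparable
#' event mass).
#'
#' @param durations Nonnegative follow-up times (training set).
#' @param events Event indicators (1 = event, 0 = right-censored); required
#'   for `km_quantile`.
#' @param m Number of intervals (>= 2).
#' @param scheme `"equidistant"` or `"km_quantile"`.
#' @return A `time_grid`: list with `cuts` (m+1 strictly increasing
#'   boundaries starting at 0) and `scheme`.
#' @export
make_grid <- function(durations, events = NULL, m = 20L,
                      scheme = c("equidistant", "km_quantile")) {
  scheme <- match.arg(scheme)
  stopifnot(m >= 2L)
  if (any(durations < 0)) stop("negative durations are not allowed")
  tmax <- max(durations)
  if (tmax <= 0) stop("degenerate durations: maximum follow-up is zero")
  if (scheme == "equidistant") {
    cuts <- seq(0, tmax, length.out = m + 1L)
  } else {
    if (is.null(events) || sum(events) == 0) {
      stop("km_quantile grid needs at least one event")
    }
    km <- kaplan_meier(durations, events)
    s_end <- min(km$values)
    levels <- seq(1, s_end, length.out = m + 1L)[-1]
    # smallest time at which the KM curve falls to or below each level
    bnd <- vapply(levels, function(lv) {
      hit <- which(km$values <= lv + 1e-12)
      if (length(hit)) km$times[hit[1]] else tmax
    }, numeric(1))
    bnd[length(bnd)] <- tmax
    cuts <- c(0, bnd[!duplicated(bnd)])  # keep leftmost boundary on ties
    cuts <- cuts[c(TRUE, diff(cuts) > 0)]
    if (length(cuts) < m + 1L) {
      warning(sprintf("km_quantile grid shrunk to %d intervals (ties in KM curve)",
                      length(cuts) - 1L))
    }
  }
  structure(list(cuts = cuts, scheme = scheme), class = "time_grid")
}

#' Number of intervals in a time grid
#' @param grid A `time_grid`.
#' @export
n_intervals <- function(grid) length(grid$cuts) - 1L

#' Map continuous survival records onto a discrete grid
#'
#' Each duration is assigned the half-open interval `(cuts[j], cuts[j+1]]`
#' containing it (interval indices `kappa` run 0..m-1; duration 0 falls in
#' interval 0). Durations beyond the last boundary are clamped to the final
#' interval and relabeled as censored there: nothing is known about events
#' past the observed training range.
#'
#' @param durations Nonnegative follow-up times.
#' @param events Event indicators.
#' @param grid A `time_grid`.
#' @return Data frame with columns `kappa` (0-based interval index) and
#'   `event`.
#' @export
discretize <- function(durations, events, grid) {
  if (any(durations < 0)) stop("negative durations are not allowed")
  cuts <- grid$cuts
  m <- length(cuts) - 1L
  kappa <- findInterval(durations, cuts, left.open = TRUE) - 1L
  kappa[kappa < 0L] <- 0L
  events <- as.integer(events)
  beyond <- kappa > m - 1L
  if (any(beyond)) {
    kappa[beyond] <- m - 1L
    events[beyond] <- 0L
  }
  data.frame(kappa = kappa, event = events)
}

#' Interpolate discrete survival predictions to arbitrary times
#'
#' Discrete predictions place survival values at the right endpoints of the
#' grid intervals (with survival 1 at time 0). Between knots,
#' `const_density` assumes a piecewise-constant event density (linear
#' interpolation of S) and `const_hazard` a piecewise-constant hazard rate
#' (linear interpolation of log S). Queries beyond the last knot hold the
#' final value.
#'
#' @param S Matrix of survival probabilities, patients x intervals,
#'   non-increasing along rows (a single curve may be given as a vector).
#' @param grid A `time_grid` whose interval right-endpoints are the knots.
#' @param times Query times.
#' @param mode `"const_density"` (default) or `"const_hazard"`.
#' @return Matrix patients x length(times) of interpolated survival values.
#' @export
interpolate_survival <- function(S, grid, times,
                                 mode = c("const_density", "const_hazard")) {
  mode <- match.arg(mode)
  if (is.null(dim(S))) S <- matrix(S, nrow = 1L)
  knots <- c(0, grid$cuts[-1])
  if (ncol(S) != length(knots) - 1L) {
    stop("S must have one column per grid interval")
  }
  eps <- 1e-12
  out <- matrix(NA_real_, nrow(S), length(times))
  for (i in seq_len(nrow(S))) {
    yi <- c(1, S[i, ])
    if (mode == "const_density") {
      out[i, ] <- stats::approx(knots, yi, xout = times, rule = 2)$y
    } else {
      ly <- log(pmax(yi, eps))
      out[i, ] <- exp(stats::approx(knots, ly, xout = times, rule = 2)$y)
    }
  }
  out
}

#' Serialize a time grid as a single-line JSON array of cut points
#' @param grid A `time_grid`.
#' @param path Output file.
#' @export
write_time_grid <- function(grid, path) {
  jsonlite::write_json(grid$cuts, path, digits = NA)
  invisible(path)
}

#' Read a time grid written by [write_time_grid()]
#' @param path File with a JSON array of cut points.
#' @param scheme Scheme label to attach.
#' @export
read_time_grid <- function(path, scheme = "equidistant") {
  cuts <- as.numeric(jsonlite::read_json(path, simplifyVector = TRUE))
  structure(list(cuts = cuts, scheme = scheme), class = "time_grid")
}
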