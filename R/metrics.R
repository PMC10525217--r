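#' Kaplan-Meier product-limit estimator
#'
#' Estimates either the event survival distribution or, with
#' `target = "censoring"`, the censoring survival distribution G (the
#' indicator is flipped). Ties between events and censorings at the same
#' time are handled events-first: censored patients at t remain in the risk
#' set for events at t, and weights that need the value just before an
#' event time use the left limit via `sf_eval(..., left = TRUE)`.
#'
#' @param durations Follow-up times.
#' @param events Event indicators (1 = event, 0 = censored).
#' @param target `"event"` (default) or `"censoring"`.
#' @return A `step_function`: list with `times` (distinct observed times,
#'   increasing), `values` (estimate just after each time), `n_risk`,
#'   `n_event` bookkeeping vectors. Value before the first time is 1.
#' @export
kaplan_meier <- function(durations, events, target = c("event", "censoring")) {
  target <- match.arg(target)
  stopifnot(length(durations) > 0, length(durations) == length(events))
  ind <- if (target == "event") as.integer(events) else 1L - as.integer(events)
  ord <- order(durations)
  tt <- durations[ord]
  ii <- ind[ord]
  times <- unique(tt)
  n <- length(tt)
  n_risk <- n - findInterval(times, tt, left.open = TRUE)  # #{T >= t}
  n_event <- vapply(times, function(t0) sum(ii[tt == t0]), integer(1))
  surv <- cumprod(1 - n_event / n_risk)
  structure(list(times = times, values = surv, n_risk = n_risk,
                 n_event = n_event, target = target),
            class = "step_function")
}

#' Evaluate a right-continuous step function
#'
#' Value at `t` is the value attached to the last time `<= t`, and 1 before
#' the first time. With `left = TRUE` the left limit is returned (last time
#' strictly `< t`), as needed for Graf-style weights at event times.
#'
#' @param sf A `step_function`.
#' @param t Query times (vectorized).
#' @param left Return the left limit.
#' @export
sf_eval <- function(sf, t, left = FALSE) {
  idx <- findInterval(t, sf$times, left.open = left)
  c(1, sf$values)[idx + 1L]
}

#' @export
print.step_function <- function(x, ...) {
  cat(sprintf("<step_function> (%s) %d steps, final value %.4f\n",
              x$target %||% "", length(x$times), x$values[length(x$values)]))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' IPCW Brier score at one time point
#'
#' Graf's inverse-probability-of-censoring weighted squared error of
#' survival predictions at time `t`: patients with an observed event by `t`
#' contribute `S_i(t)^2 / G(T_i^-)`, patients still under observation
#' contribute `(1 - S_i(t))^2 / G(t)`, and patients censored by `t`
#' contribute nothing (their status at `t` is unknown). Terms whose
#' censoring weight is zero are dropped with a message.
#'
#' @param S_at_t Predicted survival probability at `t`, one per patient.
#' @param t Evaluation time.
#' @param durations,events Observed follow-up of the same patients.
#' @param G Censoring distribution `step_function` from
#'   [kaplan_meier()] with `target = "censoring"`.
#' @return Scalar score (mean over the cohort).
#' @export
brier_score <- function(S_at_t, t, durations, events, G) {
  n <- length(durations)
  stopifnot(length(S_at_t) == n)
  contrib <- numeric(n)
  had_event <- durations <= t & events == 1
  at_risk <- durations > t
  dropped <- 0L
  if (any(had_event)) {
    w <- sf_eval(G, durations[had_event], left = TRUE)
    ok <- w > 0
    dropped <- dropped + sum(!ok)
    contrib[had_event][ok] <- (S_at_t[had_event][ok])^2 / w[ok]
  }
  if (any(at_risk)) {
    gt <- sf_eval(G, t)
    if (gt > 0) {
      contrib[at_risk] <- (1 - S_at_t[at_risk])^2 / gt
    } else {
      dropped <- dropped + sum(at_risk)
    }
  }
  if (dropped > 0) {
    message(sprintf("brier_score: %d term(s) dropped (zero censoring weight)",
                    dropped))
  }
  sum(contrib) / n
}

#' Integrated Brier score over an equidistant time grid
#'
#' Evaluates the IPCW Brier score on `n_points` equidistant times spanning
#' the observed range, integrates the curve by the trapezoidal rule and
#' normalizes by the span. The time range is taken from
#' `range_durations` (by default the durations being scored; pass the
#' validation-set durations to freeze the range from the validation split).
#'
#' @param S Discrete survival predictions, patients x grid intervals.
#' @param grid The `time_grid` the predictions live on.
#' @param durations,events Observed follow-up of the scored patients.
#' @param n_points Number of evaluation times (default 100).
#' @param range_durations Durations defining `[min, max]` of the evaluation
#'   range (default `durations`).
#' @param interpolation Passed to [interpolate_survival()].
#' @return List with `ibs` and `brier_curve` (data frame `time`, `brier`).
#' @export
integrated_brier <- function(S, grid, durations, events, n_points = 100L,
                             range_durations = durations,
                             interpolation = "const_density") {
  stopifnot(n_points >= 2L)
  lo <- min(range_durations)
  hi <- max(range_durations)
  if (hi <= lo) stop("degenerate time range for integrated Brier score")
  times <- seq(lo, hi, length.out = n_points)
  G <- kaplan_meier(durations, events, target = "censoring")
  Sq <- interpolate_survival(S, grid, times, mode = interpolation)
  bs <- vapply(seq_along(times), function(k) {
    brier_score(Sq[, k], times[k], durations, events, G)
  }, numeric(1))
  ibs <- trapezoid(times, bs) / (hi - lo)
  list(ibs = ibs, brier_curve = data.frame(time = times, brier = bs))
}

trapezoid <- function(x, y) sum(diff(x) * (y[-length(y)] + y[-1]) / 2)

#' Time-dependent concordance index (Antolini)
#'
#' Over ordered pairs (i, j) with `T_i < T_j` and an observed event for i,
#' the pair is concordant when the predicted survival of i at its own event
#' time is lower than that of j at the same time, `S_i(T_i) < S_j(T_i)`;
#' tied predictions count 1/2. Returns concordant weight / comparable
#' pairs.
#'
#' @param S Discrete survival predictions, patients x grid intervals.
#' @param grid The `time_grid` the predictions live on.
#' @param durations,events Observed follow-up.
#' @param interpolation Passed to [interpolate_survival()].
#' @return Concordance in \[0, 1\].
#' @export
ctd <- function(S, grid, durations, events, interpolation = "const_density") {
  n <- length(durations)
  ev_idx <- which(events == 1)
  if (length(ev_idx) == 0L) stop("no comparable pairs: no events observed")
  ev_times <- durations[ev_idx]
  # survival of every patient at every event time (columns = event times)
  Sq <- interpolate_survival(S, grid, ev_times, mode = interpolation)
  conc <- 0
  pairs <- 0
  for (a in seq_along(ev_idx)) {
    i <- ev_idx[a]
    later <- which(durations > ev_times[a])
    if (!length(later)) next
    si <- Sq[i, a]
    sj <- Sq[later, a]
    conc <- conc + sum(si < sj) + 0.5 * sum(si == sj)
    pairs <- pairs + length(later)
  }
  if (pairs == 0) stop("no comparable pairs among the supplied records")
  conc / pairs
}
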