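## Discrete-time survival likelihoods and the transforms between network
## outputs (logits), hazards, probability mass and survival curves.

sigmoid <- function(x) 1 / (1 + exp(-x))

row_softmax <- function(x) {
  x <- x - apply(x, 1L, max)
  ex <- exp(x)
  ex / rowSums(ex)
}

.clamp_log <- function(p, eps = 1e-7) log(pmax(p, eps))

# Build the (event one-hot, survived-interval mask) pair shared by the
# logistic-hazard likelihood and its gradient.
.lh_masks <- function(kappa, event, m, censor_inclusive) {
  n <- length(kappa)
  cols <- matrix(seq_len(m) - 1L, n, m, byrow = TRUE)
  Y <- (cols == kappa) * event
  # intervals known to be survived: l < kappa for events, l <= kappa for
  # censored (inclusive convention) or l < kappa (exclusive)
  lim <- ifelse(event == 1, kappa - 1L,
                if (censor_inclusive) kappa else kappa - 1L)
  M <- (cols <= lim) * 1
  list(Y = Y, M = M)
}

#' Logistic-Hazard (Nnet-survival) loss
#'
#' Negative mean log-likelihood of right-censored discrete survival data
#' under per-interval hazards `h = sigmoid(logits)`. A patient with an event
#' in interval `kappa` contributes `-log h_kappa - sum_{l<kappa} log(1-h_l)`;
#' a patient censored in interval `kappa` contributes survival through that
#' interval, `-sum_{l<=kappa} log(1-h_l)` (set `censor_inclusive = FALSE`
#' for the exclusive convention that stops at `l < kappa`).
#'
#' @param logits Numeric matrix, patients x intervals.
#' @param labels Data frame with columns `kappa` (0-based) and `event`, as
#'   produced by [discretize()].
#' @param censor_inclusive Censored patients count their own interval as
#'   survived (default TRUE).
#' @param eps Clamp for log arguments.
#' @return Scalar mean loss.
#' @export
logistic_hazard_loss <- function(logits, labels, censor_inclusive = TRUE,
                                 eps = 1e-7) {
  h <- sigmoid(logits)
  mk <- .lh_masks(labels$kappa, labels$event, ncol(logits), censor_inclusive)
  ll <- mk$Y * .clamp_log(h, eps) + mk$M * .clamp_log(1 - h, eps)
  -sum(ll) / nrow(logits)
}

#' @rdname logistic_hazard_loss
#' @return `logistic_hazard_grad`: gradient of the mean loss with respect to
#'   the logits (same shape as `logits`).
#' @export
logistic_hazard_grad <- function(logits, labels, censor_inclusive = TRUE) {
  h <- sigmoid(logits)
  mk <- .lh_masks(labels$kappa, labels$event, ncol(logits), censor_inclusive)
  (mk$Y * (h - 1) + mk$M * h) / nrow(logits)
}

# Tail indicator for censored PMF contributions: intervals strictly after
# kappa, except in the final interval, where the bin absorbs all tail mass
# and "survived into it" means the event falls there or beyond.
.pmf_tail_indicator <- function(kappa, m) {
  n <- length(kappa)
  cols <- matrix(seq_len(m) - 1L, n, m, byrow = TRUE)
  lower <- ifelse(kappa == m - 1L, kappa, kappa + 1L)
  (cols >= lower) * 1
}

#' PMF survival loss
#'
#' Negative mean log-likelihood under a probability mass function over the
#' `m` grid intervals, `pi = softmax(logits)` per patient. An event in
#' interval `kappa` contributes `-log pi_kappa`; a censored patient
#' contributes the tail mass, `-log sum_{l>kappa} pi_l`. The final grid
#' interval absorbs all mass beyond the training horizon, so a patient
#' censored in the final interval contributes that interval's own mass
#' `pi_{m-1}` (the event is known to fall there or beyond) rather than an
#' empty tail.
#'
#' @inheritParams logistic_hazard_loss
#' @return Scalar mean loss.
#' @export
pmf_loss <- function(logits, labels, eps = 1e-7) {
  m <- ncol(logits)
  pi <- row_softmax(logits)
  n <- nrow(logits)
  contrib <- numeric(n)
  ev <- labels$event == 1
  contrib[ev] <- .clamp_log(pi[cbind(which(ev), labels$kappa[ev] + 1L)], eps)
  if (any(!ev)) {
    tail_ind <- .pmf_tail_indicator(labels$kappa, m)
    tail_mass <- rowSums(pi * tail_ind)
    contrib[!ev] <- .clamp_log(tail_mass[!ev], eps)
  }
  -mean(contrib)
}

#' @rdname pmf_loss
#' @return `pmf_grad`: gradient of the mean loss with respect to the logits.
#' @export
pmf_grad <- function(logits, labels, eps = 1e-7) {
  m <- ncol(logits)
  pi <- row_softmax(logits)
  n <- nrow(logits)
  G <- pi
  ev <- labels$event == 1
  # events: softmax cross-entropy, pi - onehot(kappa)
  G[cbind(which(ev), labels$kappa[ev] + 1L)] <-
    G[cbind(which(ev), labels$kappa[ev] + 1L)] - 1
  if (any(!ev)) {
    tail_ind <- .pmf_tail_indicator(labels$kappa, m)
    s <- rowSums(pi * tail_ind)
    cen <- which(!ev)
    G[cen, ] <- pi[cen, , drop = FALSE] -
      (pi[cen, , drop = FALSE] * tail_ind[cen, , drop = FALSE]) /
      pmax(s[cen], eps)
  }
  G / n
}

#' Convert discrete hazards to survival curves
#'
#' Uses the discrete-time identity \eqn{S(\kappa) = \prod_{l \le \kappa}
#' (1 - h_l)}.
#'
#' @param h Matrix of hazards in (0, 1), patients x intervals.
#' @return Matrix of survival probabilities, non-increasing along rows.
#' @export
hazard_to_survival <- function(h) {
  if (is.null(dim(h))) h <- matrix(h, nrow = 1L)
  S <- exp(t(apply(log1p(-h), 1L, cumsum)))
  if (ncol(h) == 1L) S <- matrix(S, ncol = 1L)
  S
}

#' Convert a probability mass function to survival curves
#'
#' \eqn{S(\kappa) = 1 - \sum_{l \le \kappa} \pi_l}.
#'
#' @param pi Matrix of interval probabilities, rows summing to ~1.
#' @return Matrix of survival probabilities.
#' @export
pmf_to_survival <- function(pi) {
  if (is.null(dim(pi))) pi <- matrix(pi, nrow = 1L)
  S <- 1 - t(apply(pi, 1L, cumsum))
  if (ncol(pi) == 1L) S <- matrix(S, ncol = 1L)
  pmin(pmax(S, 0), 1)
}

#' Survival curves from network logits
#'
#' @param logits Matrix patients x intervals.
#' @param survival_model `"logistic_hazard"` or `"pmf"`.
#' @return Matrix of survival probabilities over the grid intervals.
#' @export
logits_to_survival <- function(logits,
                               survival_model = c("logistic_hazard", "pmf")) {
  survival_model <- match.arg(survival_model)
  if (survival_model == "logistic_hazard") {
    hazard_to_survival(sigmoid(logits))
  } else {
    pmf_to_survival(row_softmax(logits))
  }
}

#' Evaluate a survival loss by name
#' @inheritParams logits_to_survival
#' @param labels Output of [discretize()].
#' @export
survival_loss <- function(logits, labels,
                          survival_model = c("logistic_hazard", "pmf"), ...) {
  survival_model <- match.arg(survival_model)
  if (survival_model == "logistic_hazard") {
    logistic_hazard_loss(logits, labels, ...)
  } else {
    pmf_loss(logits, labels, ...)
  }
}

survival_loss_grad <- function(logits, labels, survival_model) {
  if (survival_model == "logistic_hazard") {
    logistic_hazard_grad(logits, labels)
  } else {
    pmf_grad(logits, labels)
  }
}
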