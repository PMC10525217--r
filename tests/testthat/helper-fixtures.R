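# Small programmatic fixtures shared across test files.

# random feature matrix with a continuous and optional binary block
rand_features <- function(n, p, p_bin = 0, seed = 1) {
  set.seed(seed)
  cont <- matrix(rnorm(n * p), n, p)
  if (p_bin > 0) {
    bin <- matrix(rbinom(n * p_bin, 1, 0.4), n, p_bin)
    feature_matrix(cbind(cont, bin),
                   feature_kind = c(rep("continuous", p), rep("binary", p_bin)))
  } else {
    feature_matrix(cont)
  }
}

# random right-censored cohort records
rand_records <- function(n, seed = 1, cens = 0.4) {
  set.seed(seed)
  t_event <- rexp(n, 1 / 300)
  t_cens <- if (cens > 0) rexp(n, cens / (1 - cens) / 300) else rep(Inf, n)
  data.frame(duration = pmin(t_event, t_cens),
             event = as.integer(t_event <= t_cens))
}

# random discrete labels for loss tests
rand_labels <- function(n, m, seed = 1) {
  set.seed(seed)
  data.frame(kappa = sample(0:(m - 1), n, replace = TRUE),
             event = rbinom(n, 1, 0.6))
}

# brute-force product-limit estimator via an explicit risk-set loop
km_oracle <- function(durations, events) {
  times <- sort(unique(durations))
  s <- 1
  vals <- numeric(length(times))
  for (k in seq_along(times)) {
    at_risk <- sum(durations >= times[k])
    d <- sum(durations == times[k] & events == 1)
    s <- s * (1 - d / at_risk)
    vals[k] <- s
  }
  list(times = times, values = vals)
}

# exhaustive Antolini pair loop on already-interpolated survival values
ctd_oracle <- function(S, grid, durations, events) {
  n <- length(durations)
  conc <- 0; pairs <- 0
  for (i in seq_len(n)) {
    if (events[i] != 1) next
    si <- gnnsurv::interpolate_survival(S[i, , drop = FALSE], grid,
                                        durations[i])[1, 1]
    for (j in seq_len(n)) {
      if (durations[j] <= durations[i]) next
      sj <- gnnsurv::interpolate_survival(S[j, , drop = FALSE], grid,
                                          durations[i])[1, 1]
      pairs <- pairs + 1
      if (si < sj) conc <- conc + 1
      else if (si == sj) conc <- conc + 0.5
    }
  }
  conc / pairs
}
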