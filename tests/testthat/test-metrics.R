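test_that("Kaplan-Meier matches the textbook product limit and survfit", {
  km <- kaplan_meier(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$values, c(2 / 3, 1 / 3, 0))
  expect_equal(sf_eval(km, c(0.5, 1, 2.5, 10)), c(1, 2 / 3, 1 / 3, 0))
  expect_equal(sf_eval(km, 1, left = TRUE), 1)

  # no events: survival identically one
  km0 <- kaplan_meier(c(5, 8, 9), c(0, 0, 0))
  expect_true(all(km0$values == 1))

  rec <- rand_records(60, seed = 4)
  km1 <- kaplan_meier(rec$duration, rec$event)
  orc <- km_oracle(rec$duration, rec$event)
  expect_equal(km1$times, orc$times)
  expect_equal(km1$values, orc$values)
  # independent reference: survival::survfit on the same records
  fit <- survival::survfit(survival::Surv(rec$duration, rec$event) ~ 1)
  expect_equal(sf_eval(km1, fit$time), fit$surv, tolerance = 1e-12)
  # censoring distribution = product limit with flipped indicator
  kmc <- kaplan_meier(rec$duration, rec$event, target = "censoring")
  orc2 <- km_oracle(rec$duration, 1 - rec$event)
  expect_equal(kmc$values, orc2$values)
})

test_that("event and censoring KM risk sets are consistent with the cohort size", {
  rec <- rand_records(50, seed = 6)
  ke <- kaplan_meier(rec$duration, rec$event)
  kc <- kaplan_meier(rec$duration, rec$event, target = "censoring")
  expect_equal(ke$times, kc$times)
  expect_equal(ke$n_risk, kc$n_risk)
  expect_equal(sum(ke$n_event) + sum(kc$n_event), 50)
  expect_equal(ke$n_risk[1], 50)
})

test_that("Brier score matches closed forms and a term-by-term expansion", {
  dur <- c(10, 20, 30, 40)
  ev <- c(1, 1, 1, 1)
  G <- kaplan_meier(dur, ev, target = "censoring")  # no censoring: G == 1
  expect_equal(brier_score(rep(1, 4), 5, dur, ev, G), 0)
  expect_equal(brier_score(rep(0.5, 4), 25, dur, ev, G), 0.25)

  # mixed cohort, hand expansion with IPCW weights
  dur2 <- c(5, 12, 15, 22, 30)
  ev2 <- c(1, 0, 1, 0, 1)
  G2 <- kaplan_meier(dur2, ev2, target = "censoring")
  S2 <- c(0.9, 0.8, 0.4, 0.7, 0.6)
  t0 <- 16
  manual <- (S2[1]^2 / sf_eval(G2, 5, left = TRUE) +      # event by t
             0 +                                          # censored by t
             S2[3]^2 / sf_eval(G2, 15, left = TRUE) +     # event by t
             (1 - S2[4])^2 / sf_eval(G2, t0) +            # still at risk
             (1 - S2[5])^2 / sf_eval(G2, t0)) / 5
  expect_equal(brier_score(S2, t0, dur2, ev2, G2), manual)
})

test_that("with zero censoring the Brier score is the unweighted MSE of indicators", {
  set.seed(12)
  n <- 40
  dur <- rexp(n, 1 / 50)
  ev <- rep(1, n)
  G <- kaplan_meier(dur, ev, target = "censoring")
  S <- runif(n)
  for (t0 in quantile(dur, c(0.2, 0.5, 0.8))) {
    alive <- as.numeric(dur > t0)
    expect_equal(brier_score(S, t0, dur, ev, G), mean((alive - S)^2))
  }
})

test_that("integrated Brier normalizes correctly and refines stably", {
  # constant predictions, no censoring: flat curve integrates to itself
  # (the range starts at the first knot; before it, interpolation correctly
  # ramps down from S(0) = 1)
  set.seed(14)
  n <- 30
  dur <- runif(n, 10, 100)
  ev <- rep(1, n)
  grid <- make_grid(dur, ev, m = 5)
  S <- matrix(0.5, n, 5)
  ib <- integrated_brier(S, grid, dur, ev,
                         range_durations = c(grid$cuts[2], max(dur)))
  expect_true(all(abs(ib$brier_curve$brier - 0.25) < 1e-12))
  expect_equal(ib$ibs, 0.25, tolerance = 1e-12)
  expect_equal(nrow(ib$brier_curve), 100L)

  # trapezoid rule integrates a linear curve exactly
  x <- seq(0, 1, length.out = 11)
  expect_equal(gnnsurv:::trapezoid(x, 2 * x) / 1, 1)

  # refinement oracle: 100-point integral within 1% of a 10,000-point one
  rec <- rand_records(50, seed = 16)
  g2 <- make_grid(rec$duration, rec$event, m = 8)
  set.seed(17)
  S2 <- t(apply(matrix(runif(50 * 8), 50, 8), 1,
                function(r) rev(sort(r))))
  ib100 <- integrated_brier(S2, g2, rec$duration, rec$event, n_points = 100)
  ib10k <- integrated_brier(S2, g2, rec$duration, rec$event,
                            n_points = 10000)
  expect_equal(ib100$ibs, ib10k$ibs, tolerance = 0.01)
})

test_that("time-dependent concordance matches closed forms and the pair-loop oracle", {
  grid <- structure(list(cuts = c(0, 10, 20, 30), scheme = "equidistant"),
                    class = "time_grid")
  # shorter-lived patient with uniformly lower curve: perfect concordance
  S <- rbind(c(0.3, 0.2, 0.1), c(0.9, 0.8, 0.7))
  expect_equal(ctd(S, grid, c(5, 15), c(1, 1)), 1)
  # identical curves: all ties
  S2 <- rbind(c(0.8, 0.5, 0.2), c(0.8, 0.5, 0.2), c(0.8, 0.5, 0.2))
  expect_equal(ctd(S2, grid, c(5, 12, 25), c(1, 1, 1)), 0.5)
  expect_error(ctd(S, grid, c(5, 15), c(0, 0)), "comparable")

  rec <- rand_records(35, seed = 18)
  g2 <- make_grid(rec$duration, rec$event, m = 6)
  set.seed(19)
  S3 <- t(apply(matrix(runif(35 * 6), 35, 6), 1, function(r) rev(sort(r))))
  expect_equal(ctd(S3, g2, rec$duration, rec$event),
               ctd_oracle(S3, g2, rec$duration, rec$event))
})

test_that("complementing the ranking maps Ctd to 1 - Ctd on tie-free instances", {
  set.seed(20)
  n <- 25
  rec <- rand_records(n, seed = 20)
  g <- make_grid(rec$duration, rec$event, m = 5)
  r <- rnorm(n)  # per-patient risk scalars, non-crossing curves
  base <- seq(0.95, 0.5, length.out = 5)
  S <- t(vapply(r, function(ri) base^exp(ri), numeric(5)))
  c1 <- ctd(S, g, rec$duration, rec$event)
  Sc <- t(vapply(-r, function(ri) base^exp(ri), numeric(5)))
  c2 <- ctd(Sc, g, rec$duration, rec$event)
  expect_equal(c1 + c2, 1)
})

test_that("Antolini equals Harrell's concordance under non-crossing curves", {
  set.seed(22)
  n <- 40
  rec <- rand_records(n, seed = 22)
  g <- make_grid(rec$duration, rec$event, m = 6)
  r <- rnorm(n)
  base <- seq(0.97, 0.4, length.out = 6)
  S <- t(vapply(r, function(ri) base^exp(ri), numeric(6)))
  # Harrell's C on the risk scalars, exhaustive pair loop
  conc <- 0; pairs <- 0
  for (i in seq_len(n)) {
    if (rec$event[i] != 1) next
    for (j in seq_len(n)) {
      if (rec$duration[j] <= rec$duration[i]) next
      pairs <- pairs + 1
      if (r[i] > r[j]) conc <- conc + 1
      else if (r[i] == r[j]) conc <- conc + 0.5
    }
  }
  expect_equal(ctd(S, g, rec$duration, rec$event), conc / pairs)
})
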