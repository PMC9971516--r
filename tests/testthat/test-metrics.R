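# hand-stepped Aalen-Johansen table for the 6-subject fixture, frozen before
# implementation: times 1..6, statuses event/competing/censored/event/
# censored/event.
#   t=1: risk 6, event    -> CIF1 = 1/6,            S = 5/6
#   t=2: risk 5, compete  -> CIF2 = 1/6,            S = 2/3
#   t=4: risk 3, event    -> CIF1 = 1/6 + 2/9 = 7/18
#   t=6: risk 1, event    -> CIF1 = 7/18 + 4/9 = 5/6
aj_fixture <- list(time = 1:6, status = c(1, 2, 0, 1, 0, 1))

test_that("Aalen-Johansen matches the hand-stepped fixture table", {
  f <- aj_fixture
  expect_equal(cumulative_incidence(f$time, f$status, horizon = 4.5)$estimate,
               7 / 18, tolerance = 1e-12)
  expect_equal(cumulative_incidence(f$time, f$status, horizon = 10)$estimate,
               5 / 6, tolerance = 1e-12)
})

test_that("Aalen-Johansen agrees with an independent competing-risks implementation", {
  skip_if_not_installed("cmprsk")
  set.seed(42)
  n <- 400
  time <- rexp(n, 0.08)
  status <- sample(0:2, n, TRUE, prob = c(0.3, 0.4, 0.3))
  ours <- cumulative_incidence(time, status, horizon = 8)
  ci <- cmprsk::cuminc(time, status, cencode = 0)
  ref <- cmprsk::timepoints(ci, times = 8)
  expect_equal(ours$estimate, unname(ref$est["1 1", 1]), tolerance = 1e-8)
  expect_equal(ours$variance, unname(ref$var["1 1", 1]), tolerance = 0.15)
})

test_that("without censoring or competing events the estimator reduces to a proportion, and to 1-KM", {
  time <- c(runif(20, 0, 9), runif(80, 11, 15))
  status <- c(rep(1, 20), rep(0, 80))
  expect_equal(cumulative_incidence(time, status, 10)$estimate, 0.20,
               tolerance = 1e-12)
  expect_equal(cumulative_incidence(rep(5, 10), rep(0, 10), 10)$estimate, 0)
  # with zero competing events AJ equals 1 - Kaplan-Meier exactly
  set.seed(9)
  t2 <- rexp(300, 0.1); s2 <- rbinom(300, 1, 0.6)
  km <- survival::survfit(survival::Surv(t2, s2) ~ 1)
  km10 <- summary(km, times = 7, extend = TRUE)$surv
  expect_equal(cumulative_incidence(t2, s2, 7)$estimate, 1 - km10,
               tolerance = 1e-12)
})

test_that("state occupation probabilities sum to one and CVD CIF is bounded by all-cause incidence", {
  set.seed(31)
  n <- 500
  time <- rexp(n, 0.12)
  status <- sample(0:2, n, TRUE, prob = c(0.35, 0.4, 0.25))
  f <- factor(status, levels = 0:2, labels = c("censor", "cvd", "death"))
  fit <- survival::survfit(survival::Surv(time, f) ~ 1)
  for (h in c(2, 5, 9)) {
    sm <- summary(fit, times = h, extend = TRUE)
    expect_equal(sum(sm$pstate[1, ]), 1, tolerance = 1e-10)
    cvd <- cumulative_incidence(time, status, h)$estimate
    allcause <- cumulative_incidence(time, pmin(status, 1), h)$estimate
    expect_lte(cvd, allcause + 1e-10)
  }
})

test_that("OE ratio: identity case, uncensored exactness, and the published-count arithmetic", {
  f <- aj_fixture
  o <- cumulative_incidence(f$time, f$status, 10)$estimate
  r <- oe_ratio(f$time, f$status, rep(o, 6), horizon = 10)
  expect_equal(r$oe_ratio, 1, tolerance = 1e-12)
  expect_true(r$ci[1] <= 1 && 1 <= r$ci[2])
  # uncensored cohort where O reduces to a count share and E to a mean:
  # the observed-versus-expected event totals force the ratio
  n <- 10000; o_events <- 6966; e_sum <- 5495
  time <- c(runif(o_events, 0, 10), runif(n - o_events, 10.5, 14))
  status <- c(rep(1, o_events), rep(0, n - o_events))
  pred <- rep(e_sum / n, n)
  r2 <- oe_ratio(time, status, pred)
  expect_equal(r2$oe_ratio, 6966 / 5495, tolerance = 1e-12)
  expect_equal(r2$oe_ratio, 1.268, tolerance = 1e-3)
  expect_error(oe_ratio(f$time, f$status, rep(0, 6)), "positive")
})

test_that("decile curve partitions the sample with non-decreasing bin means", {
  set.seed(13)
  n <- 4000
  p <- runif(n, 0.01, 0.25)
  lam <- -log(1 - p) / 10
  t_ev <- rexp(n, lam)
  time <- pmin(t_ev, 12)
  status <- as.integer(t_ev <= 12)
  cc <- calibration_curve(time, status, p, horizon = 10)
  expect_equal(sum(cc$bins$n), n)
  expect_true(all(diff(cc$bins$mean_predicted) > 0))
  # perfectly calibrated by construction: points near the identity line
  expect_true(all(cc$bins$ci_lo <= cc$bins$mean_predicted + 0.02 &
                    cc$bins$mean_predicted - 0.02 <= cc$bins$ci_hi))
  expect_warning(calibration_curve(time, status, rep(0.1, n)), "merging")
})

test_that("a designed 1.9-fold miscalibration shows up in the curve slope", {
  g <- generate_cohort(synthetic_cohort_config(
    n_men = 12000, n_women = 0, multipliers = 1.9, seed = 77,
    missing = c(sbp = 0, tchol = 0, hdl = 0, smoking = 0, ses = 0)))
  d <- build_analysis_cohort(g$cohort)$data
  p <- predict(score2_test_model(), d, region = "low")
  cc <- calibration_curve(d$time, d$status, p, horizon = 10)
  slope <- stats::coef(stats::lm(observed ~ 0 + mean_predicted,
                                 data = cc$bins, weights = cc$bins$n))
  expect_equal(unname(slope), 1.9, tolerance = 0.2 / 1.9)
  expect_true(all(cc$bins$observed > cc$bins$mean_predicted))
})

test_that("Harrell's C equals a brute-force all-pairs oracle", {
  set.seed(5)
  n <- 300
  time <- rexp(n, 0.1)
  status <- sample(0:2, n, TRUE, prob = c(0.3, 0.45, 0.25))
  pred <- runif(n)
  pred[sample(n, 30)] <- 0.5  # some prediction ties
  brute <- function(time, status, pred) {
    ev <- status == 1
    conc <- comp <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      a <- i; b <- j
      if (time[b] < time[a]) { a <- j; b <- i }
      if (!ev[a] || time[a] == time[b]) next  # earlier subject must be an event
      comp <- comp + 1
      if (pred[a] > pred[b]) conc <- conc + 1
      else if (pred[a] == pred[b]) conc <- conc + 0.5
    }
    list(c = conc / comp, comp = comp)
  }
  ours <- harrells_c(time, status, pred, truncate_at = Inf)
  ref <- brute(time, status, pred)
  expect_equal(ours$c_statistic, ref$c, tolerance = 1e-12)
  expect_equal(ours$comparable_pairs, ref$comp)
  # truncation: events after the horizon become censored at the horizon
  ours10 <- harrells_c(time, status, pred, truncate_at = 10)
  ref10 <- brute(pmin(time, 10),
                 ifelse(status == 1 & time <= 10, 1, 0), pred)
  expect_equal(ours10$c_statistic, ref10$c, tolerance = 1e-12)
})

test_that("concordance is invariant under monotone transforms; degenerate predictions behave", {
  set.seed(6)
  n <- 200
  time <- rexp(n, 0.1)
  status <- rbinom(n, 1, 0.5)
  pred <- runif(n)
  c1 <- harrells_c(time, status, pred)$c_statistic
  expect_equal(harrells_c(time, status, qlogis(pred))$c_statistic, c1,
               tolerance = 1e-12)
  expect_equal(harrells_c(time, status, pred^3)$c_statistic, c1,
               tolerance = 1e-12)
  expect_equal(harrells_c(time, status, rep(0.2, n))$c_statistic, 0.5)
  # uncensored and perfectly ranked: highest risk fails first
  t3 <- sort(rexp(50), decreasing = TRUE)
  expect_equal(harrells_c(t3, rep(1, 50), seq_len(50),
                          truncate_at = Inf)$c_statistic, 1)
})

test_that("minimum-events gate uses the 200-event boundary", {
  s <- c(rep(1, 199), rep(0, 500))
  expect_false(min_events_gate(s))
  expect_true(min_events_gate(c(s, 1)))
  expect_false(min_events_gate(integer(0)))
})
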