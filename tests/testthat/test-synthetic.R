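test_that("two-cause hazard inversion: closed forms and a quadrature oracle", {
  z <- invert_two_cause_hazards(0, 0, 10)
  expect_equal(z$lambda_event, 0)
  expect_equal(z$lambda_competing, 0)
  one <- invert_two_cause_hazards(0.07, 0, 10)
  expect_equal(one$lambda_event, -log(1 - 0.07) / 10, tolerance = 1e-12)
  expect_equal(one$lambda_competing, 0, tolerance = 1e-12)
  # CIF_1(h) = integral_0^h lambda1 exp(-Lambda t) dt, checked by quadrature
  h <- invert_two_cause_hazards(0.05, 0.03, 10)
  cif1 <- stats::integrate(function(t)
    h$lambda_event * exp(-(h$lambda_event + h$lambda_competing) * t),
    0, 10, rel.tol = 1e-12)$value
  cif2 <- stats::integrate(function(t)
    h$lambda_competing * exp(-(h$lambda_event + h$lambda_competing) * t),
    0, 10, rel.tol = 1e-12)$value
  expect_equal(cif1, 0.05, tolerance = 1e-10)
  expect_equal(cif2, 0.03, tolerance = 1e-10)
  expect_error(invert_two_cause_hazards(0.6, 0.4, 10), "infeasible")
})

test_that("per-person CIF under the fitted hazards equals the designed probability", {
  g <- generate_cohort(synthetic_cohort_config(n_men = 600, n_women = 600,
                                               multipliers = 1.3, seed = 21))
  tr <- g$truth
  i <- sample(nrow(tr), 100)
  cif <- with(tr[i, ], lambda_event / (lambda_event + lambda_competing) *
                (1 - exp(-(lambda_event + lambda_competing) * 10)))
  expect_equal(cif, tr$p_true[i], tolerance = 1e-9)
  expect_equal(tr$p_true, pmin(tr$multiplier * tr$p_low, 0.95 + 1e-12),
               tolerance = 1e-12)
})

test_that("default covariate marginals match the design table on the truth record", {
  g <- generate_cohort(synthetic_scenario("table1_default", seed = 17,
                                          n_men = 30000, n_women = 30000))
  tr <- g$truth
  men <- tr$sex == "male"; women <- !men
  se <- function(x) sd(x) / sqrt(length(x))
  expect_lt(abs(mean(tr$age[men]) - 48.1), 2 * se(tr$age[men]) + 0.02)
  expect_lt(abs(mean(tr$age[women]) - 48.3), 2 * se(tr$age[women]) + 0.02)
  expect_lt(abs(mean(tr$sbp[men]) - 138), 3 * se(tr$sbp[men]) + 0.2)
  expect_lt(abs(mean(tr$sbp[women]) - 134), 3 * se(tr$sbp[women]) + 0.2)
  expect_lt(abs(mean(tr$tchol) - 5.5), 0.05)
  expect_lt(abs(mean(tr$hdl[men]) - 1.2), 0.02)
  expect_lt(abs(mean(tr$hdl[women]) - 1.5), 0.02)
  expect_lt(abs(mean(tr$smoking[men]) - 0.334), 0.01)
  expect_lt(abs(mean(tr$smoking[women]) - 0.321), 0.01)
  eth <- prop.table(table(tr$ethnicity[men]))
  expect_equal(unname(eth["dutch"]), 0.640, tolerance = 0.02)
  expect_equal(unname(eth["surinamese"]), 0.055, tolerance = 0.1)
  # analysed smoking prevalence survives the missing-source structure
  b <- build_analysis_cohort(g$cohort)$data
  expect_lt(abs(mean(b$smoking[b$sex == "male"]) - 0.334), 0.012)
})

test_that("masking hits the configured marginal rates and is MAR in age", {
  g <- generate_cohort(synthetic_scenario("table1_default", seed = 23,
                                          n_men = 25000, n_women = 25000))
  co <- g$cohort
  expect_equal(mean(is.na(co$sbp)), 0.31, tolerance = 0.02)
  expect_equal(mean(is.na(co$tchol)), 0.35, tolerance = 0.02)
  expect_equal(mean(is.na(co$hdl)), 0.36, tolerance = 0.02)
  expect_equal(mean(is.na(co$ses_quintile)), 0.06, tolerance = 0.05)
  expect_equal(mean(co$smoking_source == "assumed_nonsmoker"), 0.50,
               tolerance = 0.02)
  age <- g$truth$age
  r <- cor(as.numeric(is.na(co$sbp)), age)
  expect_gt(abs(r), 0.05)  # MAR, not MCAR
  # no-masking configuration leaves the table complete
  g0 <- generate_cohort(synthetic_scenario("null_calibration", seed = 3,
                                           n_men = 2000, n_women = 2000))
  expect_false(anyNA(g0$cohort$sbp))
  expect_false(anyNA(g0$cohort$ses_quintile))
})

test_that("cohort and truth agree on unmasked fields; generation is deterministic", {
  cfg <- synthetic_scenario("ethnicity_multipliers", seed = 41,
                            n_men = 3000, n_women = 3000)
  g1 <- generate_cohort(cfg)
  g2 <- generate_cohort(cfg)
  expect_identical(g1$cohort, g2$cohort)
  expect_identical(g1$truth, g2$truth)
  obs <- !is.na(g1$cohort$sbp)
  expect_equal(g1$cohort$sbp[obs], g1$truth$sbp[obs])
  expect_equal(g1$cohort$ethnicity, g1$truth$ethnicity)
})

test_that("follow-up and event-rate structure lands near the design table", {
  g <- generate_cohort(synthetic_scenario("table1_default", seed = 29,
                                          n_men = 30000, n_women = 30000))
  d <- build_analysis_cohort(g$cohort)$data
  expect_lt(abs(median(d$time) - 9.9), 0.5)
  men <- d$sex == "male"
  rates <- c(mean(d$status[men] == "cvd_event"),
             mean(d$status[!men] == "cvd_event"),
             mean(d$status[men] == "competing_death"),
             mean(d$status[!men] == "competing_death"))
  design <- c(0.057, 0.034, 0.028, 0.024)
  expect_true(all(abs(rates / design - 1) < 0.20),
              info = paste(round(rates, 4), collapse = " "))
  # outcome proxy flags near the configured sensitivity
  cases <- d$status == "cvd_event"
  expect_equal(mean(d$med_proxy_start[cases]), 0.93, tolerance = 0.02)
})

test_that("self-consistency: unit multipliers give OE near 1 without any pipeline help", {
  g <- generate_cohort(synthetic_scenario("null_calibration", seed = 53,
                                          n_men = 25000, n_women = 25000))
  d <- build_analysis_cohort(g$cohort)$data
  tr <- g$truth[match(d$person_id, g$truth$person_id), ]
  for (s in c("male", "female")) {
    i <- d$sex == s
    r <- oe_ratio(d$time[i], d$status[i], tr$p_low[i])
    expect_true(r$ci[1] <= 1 && 1 <= r$ci[2] ||
                  abs(r$oe_ratio - 1) < 0.08,
                info = sprintf("%s OE %.3f", s, r$oe_ratio))
  }
})
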