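#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the published baseline table of the Dutch primary-care
#' validation cohort: sex-specific cohort sizes, ethnicity and income-
#' quintile composition, truncated-normal age on [40, 70), correlated
#' systolic blood pressure, cholesterol, HDL and smoking marginals, a 50%
#' smoking-missingness source structure (missing assumed non-smoking),
#' staggered entry with deregistration tuned to a 9.9-year median follow-up,
#' competing non-CVD mortality, missing-at-random lab/income masking, and a
#' statin+antithrombotic outcome proxy sensitivity of 0.93.
#'
#' True 10-year CVD risk is designed as a stratum multiplier times the
#' low-risk-region SCORE2 prediction (capped), so subgroup observed/expected
#' ratios are recoverable design parameters.
#'
#' @param n_men,n_women Cohort sizes by sex.
#' @param multipliers Function \code{(sex, ethnicity, ses_quintile) ->
#'   multiplier}, or a single number applied everywhere.
#' @param seed Integer seed.
#' @param ... Overrides for any default listed in the function definition.
#' @return List of class \code{synthetic_cohort_config}.
#' @export
synthetic_cohort_config <- function(n_men = 74880, n_women = 80133,
                                    multipliers = 1, seed = 1L, ...) {
  cfg <- list(
    n_men = n_men, n_women = n_women, seed = seed,
    ethnicity_mix = list(
      male = c(dutch = 0.640, surinamese = 0.055, other = 0.305),
      female = c(dutch = 0.621, surinamese = 0.069, other = 0.310)),
    ses_mix = list(
      male = c(0.159, 0.127, 0.176, 0.233, 0.306),
      female = c(0.168, 0.139, 0.173, 0.206, 0.261)),
    age = list(male = c(mean = 48.1, sd = 8.6),
               female = c(mean = 48.3, sd = 8.8), min = 40, max = 70),
    sbp = list(male = c(mean = 138, sd = 21), female = c(mean = 134, sd = 22)),
    tchol = list(male = c(mean = 5.5, sd = 1.1),
                 female = c(mean = 5.5, sd = 1.1)),
    hdl = list(male = c(mean = 1.2, sd = 0.3),
               female = c(mean = 1.5, sd = 0.4)),
    smoking = c(male = 0.334, female = 0.321),
    age_sbp_cor = 0.3,
    competing_cif_10y = c(male = 0.033, female = 0.027),
    prevalent_fraction = 0.55,      # entered at the study start
    incident_span_years = 12,       # incident entry uniform over this span
    dereg_rate = 0.025,             # deregistration hazard per year
    study_start = as.Date("2007-01-01"),
    admin_end = as.Date("2020-07-01"),
    missing = c(sbp = 0.31, tchol = 0.35, hdl = 0.36, smoking = 0.50,
                ses = 0.06),
    mar_beta_age = 0.3, mar_beta_ses = -0.15,
    med_proxy_sensitivity = 0.93, med_proxy_fpr = 0.05,
    cvd_death_fraction = 0.25,      # share of CVD endpoints that are deaths
    risk_cap = 0.95, horizon = 10,
    reference_events = c(male = 4251, female = 2715, total = 6966))
  dots <- list(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), names(cfg))
    if (length(unknown)) stop("unknown config fields: ",
                              paste(unknown, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  if (is.numeric(multipliers)) {
    mval <- multipliers
    cfg$multipliers <- function(sex, ethnicity, ses) rep(mval, length(sex))
  } else cfg$multipliers <- multipliers
  for (s in c("male", "female")) {
    if (abs(sum(cfg$ethnicity_mix[[s]]) - 1) > 0.02)
      stop("ethnicity mix for ", s, " must sum to 1")
    cfg$ethnicity_mix[[s]] <- cfg$ethnicity_mix[[s]] /
      sum(cfg$ethnicity_mix[[s]])
    cfg$ses_mix[[s]] <- cfg$ses_mix[[s]] / sum(cfg$ses_mix[[s]])
  }
  stopifnot(all(cfg$missing >= 0 & cfg$missing <= 1))
  class(cfg) <- "synthetic_cohort_config"
  cfg
}

#' Named generator scenarios
#'
#' Four presets: \code{table1_default} (sex-level multipliers equal to the
#' study's overall observed/expected ratios, 1.30 men / 1.22 women),
#' \code{ethnicity_multipliers} (sex-by-ethnicity multipliers from the
#' ethnic-subgroup results: Dutch 1.21/1.15, Surinamese 1.92/1.86, other
#' 1.40/1.20), \code{ses_multipliers} (sex-by-income-quintile multipliers
#' log-linearly interpolated between the printed extreme quintiles, men
#' 1.54 to 1.17, women 1.64 to 0.94), and \code{null_calibration}
#' (multiplier 1 everywhere, no missingness: isolates the validation
#' machinery).
#'
#' @param name Scenario name.
#' @param seed Integer seed.
#' @param ... Further overrides passed to
#'   \code{\link{synthetic_cohort_config}}.
#' @return A \code{synthetic_cohort_config}.
#' @export
synthetic_scenario <- function(name = c("table1_default",
                                        "ethnicity_multipliers",
                                        "ses_multipliers",
                                        "null_calibration"),
                               seed = 1L, ...) {
  name <- match.arg(name)
  mult <- switch(name,
    table1_default = function(sex, ethnicity, ses)
      c(male = 1.30, female = 1.22)[sex],
    ethnicity_multipliers = local({
      tab <- rbind(male = c(dutch = 1.21, surinamese = 1.92, other = 1.40),
                   female = c(dutch = 1.15, surinamese = 1.86, other = 1.20))
      function(sex, ethnicity, ses) tab[cbind(sex, ethnicity)]
    }),
    ses_multipliers = local({
      interp <- function(m1, m5) exp(log(m1) + (0:4) / 4 * (log(m5) - log(m1)))
      tab <- rbind(male = interp(1.54, 1.17), female = interp(1.64, 0.94))
      colnames(tab) <- 1:5
      function(sex, ethnicity, ses) tab[cbind(sex, as.character(ses))]
    }),
    null_calibration = 1)
  extra <- if (name == "null_calibration")
    list(missing = c(sbp = 0, tchol = 0, hdl = 0, smoking = 0, ses = 0))
  else list()
  do.call(synthetic_cohort_config,
          c(list(multipliers = mult, seed = seed), extra, list(...)))
}

#' Constant cause-specific hazards matching two target cumulative incidences
#'
#' Under independent constant hazards \eqn{\lambda_1, \lambda_2}, the
#' cause-1 cumulative incidence at horizon h is
#' \eqn{(\lambda_1/\Lambda)(1 - e^{-\Lambda h})} with
#' \eqn{\Lambda = \lambda_1 + \lambda_2}; the inversion for a target pair
#' \eqn{(p_1, p_2)} is closed-form: \eqn{\Lambda = -\log(1 - p_1 - p_2)/h},
#' \eqn{\lambda_1 = \Lambda\, p_1/(p_1 + p_2)}.
#'
#' @param target_cif Cause-1 (CVD) cumulative incidence at the horizon.
#' @param competing_cif Cause-2 (non-CVD death) cumulative incidence.
#' @param horizon Horizon in years.
#' @return List (or, for vector input, data.frame) with
#'   \code{lambda_event}, \code{lambda_competing}.
#' @export
invert_two_cause_hazards <- function(target_cif, competing_cif, horizon = 10) {
  p1 <- target_cif; p2 <- competing_cif
  if (any(p1 < 0 | p2 < 0)) stop("cumulative incidences must be non-negative")
  if (any(p1 + p2 >= 1))
    stop("infeasible target: cause-specific incidences must sum below 1")
  tot <- p1 + p2
  Lambda <- ifelse(tot > 0, -log1p(-tot) / horizon, 0)
  l1 <- ifelse(tot > 0, Lambda * p1 / tot, 0)
  l2 <- Lambda - l1
  if (length(p1) == 1L && length(p2) == 1L)
    list(lambda_event = l1, lambda_competing = l2)
  else data.frame(lambda_event = l1, lambda_competing = l2)
}

# Bounded age sampler matching the printed cohort moments exactly.
# A normal truncated to [40, 70) cannot reach the printed (mean, sd) pair —
# its maximal spread at that mean falls short — so ages are drawn from a
# moment-matched scaled Beta on the same support. The solved shape is
# J-shaped (density highest near the lower bound), which is what a dynamic
# cohort with steady inflow of newly eligible 40-year-olds looks like.
.rboundedage <- function(n, mean, sd, lo, hi) {
  m <- (unname(mean) - lo) / (hi - lo)
  v <- (unname(sd) / (hi - lo))^2
  if (v >= m * (1 - m))
    stop("infeasible (mean, sd) pair for a bounded age distribution")
  a <- m * (m * (1 - m) / v - 1)
  b <- a * (1 - m) / m
  lo + (hi - lo) * stats::rbeta(n, a, b)
}

#' Generate a synthetic validation cohort
#'
#' Draws covariates per sex/ethnicity/income cell, computes each person's
#' low-risk-region SCORE2 prediction, sets the designed true 10-year CVD
#' probability to the stratum multiplier times that prediction (capped),
#' solves the two-cause constant-hazard inversion jointly with the
#' competing-mortality target, draws event/competing/censoring times and
#' calendar dates, and applies missing-at-random masking. Deterministic
#' given the config seed.
#'
#' @param config A \code{\link{synthetic_cohort_config}} (or scenario).
#' @param model SCORE2 model used for the design predictions.
#' @return List of class \code{synthetic_cohort} with \code{cohort} (raw
#'   schema table, maskable fields masked), \code{truth} (per-person design
#'   record: true probabilities, hazards, latent times and pre-masking
#'   values; for oracle checks only) and \code{n_capped}.
#' @export
generate_cohort <- function(config = synthetic_cohort_config(),
                            model = score2_model()) {
  cfg <- config
  set.seed(cfg$seed)
  n <- cfg$n_men + cfg$n_women
  sex <- rep(c("male", "female"), c(cfg$n_men, cfg$n_women))

  ethnicity <- character(n); ses <- integer(n)
  age <- numeric(n); sbp <- numeric(n); tchol <- numeric(n); hdl <- numeric(n)
  smoking <- logical(n)
  for (s in c("male", "female")) {
    i <- which(sex == s); ni <- length(i)
    ethnicity[i] <- sample(names(cfg$ethnicity_mix[[s]]), ni, TRUE,
                           prob = cfg$ethnicity_mix[[s]])
    ses[i] <- sample.int(5L, ni, TRUE, prob = cfg$ses_mix[[s]])
    a <- cfg$age[[s]]
    age[i] <- .rboundedage(ni, a["mean"], a["sd"], cfg$age$min, cfg$age$max)
    zage <- (age[i] - a["mean"]) / a["sd"]
    b <- cfg$sbp[[s]]; r <- cfg$age_sbp_cor
    sbp[i] <- b["mean"] + b["sd"] * (r * zage + sqrt(1 - r^2) * stats::rnorm(ni))
    tc <- cfg$tchol[[s]]
    tchol[i] <- stats::rnorm(ni, tc["mean"], tc["sd"])
    h <- cfg$hdl[[s]]
    hdl[i] <- stats::rnorm(ni, h["mean"], h["sd"])
    smoking[i] <- stats::runif(ni) < cfg$smoking[[s]]
  }
  sbp <- pmin(pmax(sbp, 80), 240)
  tchol <- pmin(pmax(tchol, 2.5), 12)
  hdl <- pmin(pmax(hdl, 0.4), tchol - 0.5)
  glucose <- 5.1 + 0.02 * (age - 48) + 0.005 * (sbp - 136) +
    stats::rnorm(n, 0, 0.8)
  egfr <- 100 - 0.6 * (age - 48) + stats::rnorm(n, 0, 12)

  # smoking source structure: the printed prevalence is the post-assumption
  # analysis prevalence, so "missing" records are drawn from the non-smokers
  smoking_source <- rep("coded", n)
  for (s in c("male", "female")) {
    i <- which(sex == s)
    n_missing <- round(cfg$missing["smoking"] * length(i))
    nonsmokers <- i[!smoking[i]]
    miss_i <- sample(nonsmokers, min(n_missing, length(nonsmokers)))
    smoking_source[miss_i] <- "assumed_nonsmoker"
    txt <- sample(i[smoking[i]], round(0.3 * sum(smoking[i])))
    smoking_source[txt] <- "text_mined"
  }

  # design prediction and true risk
  profiles <- data.frame(age = age, sex = sex, smoking = smoking,
                         sbp = sbp, tchol = tchol, hdl = hdl)
  p_low <- predict(model, profiles, region = "low")
  mult <- cfg$multipliers(sex, ethnicity, ses)
  p2 <- cfg$competing_cif_10y[sex]
  cap <- pmin(cfg$risk_cap, 0.99 - p2)
  p1 <- mult * p_low
  n_capped <- sum(p1 > cap)
  if (n_capped) warning(n_capped, " designed risks capped at the ceiling")
  p1 <- pmin(p1, cap)
  hz <- invert_two_cause_hazards(p1, p2, cfg$horizon)
  Lambda <- hz$lambda_event + hz$lambda_competing

  # Latent uniforms are stratified (randomly permuted, jittered systematic
  # grids) within sex x ethnicity x income cells: each person's marginal
  # draw is exactly U(0,1), but cell-level event counts concentrate on
  # their expectation, so designed subgroup quantities are recovered with
  # far less Monte-Carlo noise at a given cohort size.
  cell <- interaction(sex, ethnicity, ses, drop = TRUE)
  strat_u <- function(by = cell) {
    u <- numeric(n)
    for (idx in split(seq_len(n), by)) {
      k <- length(idx)
      u[idx] <- (sample.int(k) - stats::runif(k)) / k
    }
    u
  }

  # entry and censoring first (entry mixture and deregistration share the
  # stratified-quantile device) ...
  u_entry <- strat_u()
  prevalent <- u_entry < cfg$prevalent_fraction
  entry_offset <- ifelse(prevalent, 0,
                         (u_entry - cfg$prevalent_fraction) /
                           (1 - cfg$prevalent_fraction) *
                           cfg$incident_span_years)
  entry <- cfg$study_start + round(entry_offset * 365.25)
  admin_t <- as.numeric(cfg$admin_end - entry) / 365.25
  age80_t <- 80 - age
  dereg_t <- if (cfg$dereg_rate > 0) -log1p(-strat_u()) / cfg$dereg_rate
             else rep(Inf, n)

  # ... so the event-time grid can be stratified within censoring bands:
  # otherwise the random coupling of independent stratified margins would
  # re-introduce near-binomial noise in observed-event counts
  cens_pre <- pmin(admin_t, age80_t, dereg_t)
  cell_band <- interaction(cell, cut(pmin(cens_pre, cfg$horizon),
                                     breaks = c(0, 2, 4, 6, 8, 9.99, Inf)),
                           drop = TRUE)
  t_total <- ifelse(Lambda > 0,
                    -log1p(-strat_u(cell_band)) / pmax(Lambda, 1e-300), Inf)
  is_cvd <- strat_u(cell_band) <
    ifelse(Lambda > 0, hz$lambda_event / Lambda, 0)
  cens_t <- pmin(admin_t, age80_t, dereg_t)
  observed_event <- t_total <= cens_t
  time <- pmin(t_total, cens_t)

  birth_date <- entry - round(age * 365.25)
  # prevalent persons were registered before the study window; incident
  # persons register on their entry date (registering earlier would pull
  # their reconstructed entry back to the study start)
  reg_start <- entry
  reg_start[prevalent] <- (entry - round(stats::runif(n, 0.5, 15) *
                                           365.25))[prevalent]
  reg_end <- as.Date(ifelse(is.finite(dereg_t),
                            entry + round(dereg_t * 365.25),
                            as.Date("2030-01-01")),
                     origin = "1970-01-01")

  cvd_case <- observed_event & is_cvd
  comp_case <- observed_event & !is_cvd
  fatal <- cvd_case & stats::runif(n) < cfg$cvd_death_fraction
  event_date <- entry + round(time * 365.25)
  cvd_event_date <- as.Date(ifelse(cvd_case & !fatal, event_date, NA),
                            origin = "1970-01-01")
  cvd_event_code <- ifelse(cvd_case & !fatal,
                           sample(c("K75", "K90.3"), n, TRUE), NA)
  death_date <- as.Date(ifelse(fatal | comp_case, event_date, NA),
                        origin = "1970-01-01")
  death_icd10 <- ifelse(fatal, sample(c("I21", "I63", "I46"), n, TRUE),
                        ifelse(comp_case,
                               sample(c("C34", "J44", "A41"), n, TRUE), NA))
  med_proxy <- ifelse(cvd_case,
                      stats::runif(n) < cfg$med_proxy_sensitivity,
                      stats::runif(n) < cfg$med_proxy_fpr)

  meas_date <- function() entry - sample(0:365, n, replace = TRUE)
  src <- function() sample(c("GP", "hospital"), n, TRUE, prob = c(0.85, 0.15))

  cohort <- data.frame(
    person_id = sprintf("p%07d", seq_len(n)),
    birth_date = birth_date, sex = sex,
    registration_start = reg_start, registration_end = reg_end,
    smoking = ifelse(smoking_source == "assumed_nonsmoker", NA, smoking),
    smoking_source = smoking_source,
    sbp = sbp, sbp_date = meas_date(), sbp_source = src(),
    tchol = tchol, tchol_date = meas_date(), tchol_source = src(),
    hdl = hdl, hdl_date = meas_date(), hdl_source = src(),
    glucose = glucose, egfr = egfr,
    ses_quintile = ses, ethnicity = ethnicity,
    cvd_event_date = cvd_event_date, cvd_event_code = cvd_event_code,
    death_date = death_date, death_icd10 = death_icd10,
    prior_cvd = FALSE, diabetes = FALSE, statin_use = FALSE,
    diabetes_medication = FALSE,
    med_proxy_start = med_proxy,
    stringsAsFactors = FALSE)

  truth <- data.frame(
    person_id = cohort$person_id, sex = sex, ethnicity = ethnicity,
    ses_quintile = ses, age = age, sbp = sbp, tchol = tchol, hdl = hdl,
    smoking = smoking, p_low = p_low, multiplier = mult,
    p_true = p1, competing_cif = as.numeric(p2),
    lambda_event = hz$lambda_event, lambda_competing = hz$lambda_competing,
    event_time = t_total, is_cvd = is_cvd, censor_time = cens_t,
    time = time, observed_event = observed_event,
    stringsAsFactors = FALSE)

  cohort <- mask_missing(cohort, cfg)
  structure(list(cohort = cohort, truth = truth, config = cfg,
                 n_capped = n_capped),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$cohort), "persons (seed",
      x$config$seed, ")\n")
  cat("  CVD events observed:", sum(x$truth$observed_event & x$truth$is_cvd),
      " competing deaths:", sum(x$truth$observed_event & !x$truth$is_cvd),
      "\n")
  invisible(x)
}

#' Missing-at-random masking of labs and income
#'
#' Masks systolic blood pressure, cholesterol, HDL and the income quintile
#' with probabilities that follow a logistic model in age (and, for the
#' labs, the income quintile), with the intercept calibrated by root-finding
#' so each variable's marginal missingness matches its configured rate.
#' Smoking missingness is carried by the source flags set at generation
#' (see \code{\link{synthetic_cohort_config}}).
#'
#' @param cohort Cohort table in the raw schema.
#' @param config Generator configuration (rates and MAR coefficients).
#' @return The masked cohort table.
#' @export
mask_missing <- function(cohort, config) {
  cfg <- config
  entry_age <- as.numeric(
    (if (!is.null(cohort$entry_date)) cohort$entry_date
     else pmax(cohort$registration_start, cfg$study_start)) -
      cohort$birth_date) / 365.25
  zage <- (entry_age - mean(entry_age)) / max(stats::sd(entry_age), 1e-9)
  ses0 <- ifelse(is.na(cohort$ses_quintile), 3, cohort$ses_quintile)
  lab_lin <- cfg$mar_beta_age * zage + cfg$mar_beta_ses * (ses0 - 3)
  ses_lin <- cfg$mar_beta_age * zage
  mask_one <- function(values, rate, lin) {
    if (rate <= 0) return(values)
    a <- stats::uniroot(function(a) mean(stats::plogis(a + lin)) - rate,
                        c(-20, 20))$root
    values[stats::runif(length(values)) < stats::plogis(a + lin)] <- NA
    values
  }
  cohort$sbp <- mask_one(cohort$sbp, cfg$missing["sbp"], lab_lin)
  cohort$tchol <- mask_one(cohort$tchol, cfg$missing["tchol"], lab_lin)
  cohort$hdl <- mask_one(cohort$hdl, cfg$missing["hdl"], lab_lin)
  cohort$ses_quintile <- mask_one(cohort$ses_quintile, cfg$missing["ses"],
                                  ses_lin)
  for (v in c("sbp", "tchol", "hdl")) {
    dcol <- paste0(v, "_date"); scol <- paste0(v, "_source")
    cohort[[dcol]][is.na(cohort[[v]])] <- NA
    cohort[[scol]][is.na(cohort[[v]])] <- NA
  }
  cohort
}
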