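# shared fixtures built in code

score2_test_model <- local({
  m <- NULL
  function() {
    if (is.null(m)) m <<- score2_model()
    m
  }
})

# a tiny raw-schema cohort with fully specified fields
make_raw_cohort <- function(n = 6, seed = 1) {
  set.seed(seed)
  entry <- as.Date("2008-06-01")
  data.frame(
    person_id = sprintf("x%03d", seq_len(n)),
    birth_date = entry - round(runif(n, 42, 68) * 365.25),
    sex = rep_len(c("male", "female"), n),
    registration_start = entry - 400,
    registration_end = as.Date("2030-01-01"),
    smoking = rep_len(c(TRUE, FALSE, NA), n),
    smoking_source = rep_len(c("coded", "coded", "assumed_nonsmoker"), n),
    sbp = round(runif(n, 110, 180)),
    sbp_date = entry - 30, sbp_source = "GP",
    tchol = round(runif(n, 4, 8), 1),
    tchol_date = entry - 30, tchol_source = "GP",
    hdl = round(runif(n, 0.8, 2.2), 1),
    hdl_date = entry - 30, hdl_source = "GP",
    glucose = round(runif(n, 4, 7), 1),
    egfr = round(runif(n, 60, 110)),
    ses_quintile = rep_len(1:5, n),
    ethnicity = rep_len(c("dutch", "surinamese", "other"), n),
    cvd_event_date = as.Date(NA), cvd_event_code = NA_character_,
    death_date = as.Date(NA), death_icd10 = NA_character_,
    prior_cvd = FALSE, diabetes = FALSE, statin_use = FALSE,
    diabetes_medication = FALSE, med_proxy_start = FALSE,
    stringsAsFactors = FALSE)
}

# random valid risk profiles for property checks
random_profiles <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(
    age = runif(n, 40, 69.99),
    sex = sample(c("male", "female"), n, TRUE),
    smoking = runif(n) < 0.3,
    sbp = runif(n, 90, 200),
    tchol = runif(n, 3, 9),
    hdl = runif(n, 0.6, 2.5),
    stringsAsFactors = FALSE)
}
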