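#' Default CVD event and exclusion code lists
#'
#' ICD-10 cause-of-death codes counting as CVD death (I10-I25, R96, I46,
#' I47-I51, I61-I65 except I62.0, G45, I67-I69 except I67.1, I70-I72) and the
#' primary-care ICPC codes counting as a first CVD event (K75 myocardial
#' infarction, K90 stroke, except K90.1). Matching is by code prefix with an
#' explicit exception list.
#'
#' @return List with \code{cvd_death_icd10}, \code{cvd_death_exceptions},
#'   \code{cvd_event_icpc}, \code{cvd_event_exceptions}.
#' @export
default_event_codes <- function() {
  list(
    cvd_death_icd10 = c(
      sprintf("I%02d", 10:25), "R96", "I46", sprintf("I%02d", 47:51),
      sprintf("I%02d", 61:65), "G45", sprintf("I%02d", 67:72)),
    cvd_death_exceptions = c("I62.0", "I620", "I67.1", "I671"),
    cvd_event_icpc = c("K75", "K90"),
    cvd_event_exceptions = c("K90.1", "K90.01"))
}

# prefix match against a code list honouring exceptions
.code_matches <- function(code, list, exceptions) {
  code <- toupper(trimws(as.character(code)))
  ok <- rep(FALSE, length(code))
  for (p in list) ok <- ok | startsWith(code, p)
  for (e in exceptions) ok <- ok & !startsWith(code, toupper(e))
  ok & !is.na(code)
}

#' Is an ICD-10 cause of death a CVD death?
#' @param code Character ICD-10 codes.
#' @param codes Code map from \code{\link{default_event_codes}}.
#' @return Logical vector.
#' @export
is_cvd_death <- function(code, codes = default_event_codes()) {
  .code_matches(code, codes$cvd_death_icd10, codes$cvd_death_exceptions)
}

#' Is an ICPC code a qualifying CVD event?
#' @inheritParams is_cvd_death
#' @return Logical vector.
#' @export
is_cvd_event_code <- function(code, codes = default_event_codes()) {
  .code_matches(code, codes$cvd_event_icpc, codes$cvd_event_exceptions)
}

.cohort_required <- c("person_id", "birth_date", "sex",
                      "registration_start", "registration_end")
.cohort_optional <- c(
  "smoking", "smoking_source", "sbp", "sbp_date", "sbp_source",
  "tchol", "tchol_date", "tchol_source", "hdl", "hdl_date", "hdl_source",
  "glucose", "egfr", "ses_quintile", "ethnicity", "ethnicity_origin",
  "cvd_event_date", "cvd_event_code", "death_date", "death_icd10",
  "prior_cvd", "diabetes", "statin_use", "diabetes_medication",
  "med_proxy_start")
.cohort_date_cols <- c("birth_date", "registration_start", "registration_end",
                       "sbp_date", "tchol_date", "hdl_date",
                       "cvd_event_date", "death_date")
.cohort_logical_cols <- c("smoking", "prior_cvd", "diabetes", "statin_use",
                          "diabetes_medication", "med_proxy_start")

#' Read a person-level cohort table from CSV
#'
#' Validates the schema: required identity/registration columns, ISO dates,
#' \code{sex} in male/female, \code{ses_quintile} in 1..5, \code{ethnicity}
#' in dutch/surinamese/other. Validation failures report the offending rows.
#' Optional columns absent from the file default to missing.
#'
#' @param path CSV file path.
#' @return Validated cohort \code{data.frame}.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("NA", ""))
  validate_cohort(df)
}

#' Validate (and normalise) a cohort table
#' @param df data.frame in the cohort schema.
#' @return The normalised data.frame (dates as \code{Date}, logicals as
#'   logical, missing optional columns added as NA).
#' @export
validate_cohort <- function(df) {
  miss <- setdiff(.cohort_required, names(df))
  if (length(miss))
    stop("cohort table lacks required columns: ", paste(miss, collapse = ", "))
  unknown <- setdiff(names(df), c(.cohort_required, .cohort_optional))
  if (length(unknown))
    stop("cohort table has unknown columns: ", paste(unknown, collapse = ", "))
  for (col in setdiff(.cohort_optional, names(df))) df[[col]] <- NA
  bad_rows <- function(ok, what) {
    if (!all(ok)) stop("invalid ", what, " in rows: ",
                       paste(utils::head(which(!ok), 10L), collapse = ", "))
  }
  for (col in .cohort_date_cols) {
    v <- df[[col]]
    if (!inherits(v, "Date")) {
      parsed <- as.Date(as.character(v), format = "%Y-%m-%d")
      bad_rows(is.na(parsed) == is.na(v), paste0("date in ", col))
      df[[col]] <- parsed
    }
  }
  bad_rows(!is.na(df$sex) & df$sex %in% c("male", "female"), "sex")
  ses <- df$ses_quintile
  bad_rows(is.na(ses) | (ses %in% 1:5), "ses_quintile")
  eth <- df$ethnicity
  bad_rows(is.na(eth) | eth %in% c("dutch", "surinamese", "other"),
           "ethnicity")
  for (col in .cohort_logical_cols) df[[col]] <- as.logical(df[[col]])
  # all-NA optional columns come back from CSV as logical; keep them character
  for (col in c("person_id", "sex", "smoking_source", "sbp_source",
                "tchol_source", "hdl_source", "ethnicity", "ethnicity_origin",
                "cvd_event_code", "death_icd10"))
    if (!is.character(df[[col]])) df[[col]] <- as.character(df[[col]])
  df
}

#' Write a cohort table to CSV
#'
#' Round-trips losslessly through \code{\link{read_cohort}}: dates are
#' written ISO-formatted and missing values as empty fields.
#'
#' @param df Cohort data.frame.
#' @param path Output CSV path.
#' @export
write_cohort <- function(df, path) {
  out <- df
  for (col in intersect(.cohort_date_cols, names(out)))
    out[[col]] <- format(out[[col]], "%Y-%m-%d")
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Cohort entry date
#'
#' Entry is the latest of registration start, the study start and the 40th
#' birthday. A person contributes no entry (NA) when that date falls at or
#' after the 70th birthday, the registration end, or the administrative end
#' of study.
#'
#' @param birth_date,registration_start,registration_end Date vectors.
#' @param study_start,admin_end Study window (defaults 2007-01-01 and
#'   2020-07-01).
#' @return Date vector of entry dates, NA where ineligible.
#' @export
determine_entry <- function(birth_date, registration_start, registration_end,
                            study_start = as.Date("2007-01-01"),
                            admin_end = as.Date("2020-07-01")) {
  if (anyNA(birth_date) || anyNA(registration_start))
    stop("birth and registration-start dates must be present")
  b40 <- add_years(birth_date, 40)
  b70 <- add_years(birth_date, 70)
  entry <- pmax(registration_start, study_start, b40)
  entry[entry >= b70] <- NA
  entry[!is.na(registration_end) & entry >= registration_end] <- NA
  entry[entry >= admin_end] <- NA
  entry
}

# calendar-date arithmetic in whole years (Feb 29 -> Mar 1)
add_years <- function(date, years) {
  lt <- as.POSIXlt(date)
  lt$year <- lt$year + years
  as.Date(lt)
}

#' Apply cohort exclusions
#'
#' Drops persons with a CVD or diabetes history, statin or diabetes
#' medication before entry, ineligible entry dates, or a registration span
#' under six months. Every drop carries a machine-readable reason so that
#' kept + dropped partitions the input (flowchart conservation).
#'
#' @param df Validated cohort table.
#' @param entry Date vector from \code{\link{determine_entry}} (computed if
#'   omitted).
#' @param min_registration_days Minimum total registration span (default
#'   182.625 days = six months).
#' @return List with \code{kept} (data.frame including an \code{entry_date}
#'   column), \code{dropped} (data.frame with \code{reason}), and
#'   \code{flowchart} (named counts).
#' @export
apply_exclusions <- function(df, entry = NULL,
                             min_registration_days = 365.25 / 2) {
  df <- validate_cohort(df)
  if (is.null(entry))
    entry <- determine_entry(df$birth_date, df$registration_start,
                             df$registration_end)
  reason <- rep(NA_character_, nrow(df))
  mark <- function(cond, why) reason[is.na(reason) & cond] <<- why
  span <- as.numeric(df$registration_end - df$registration_start)
  mark(!is.na(span) & span < min_registration_days, "short_registration")
  mark(is.na(entry), "ineligible_entry")
  mark(isTRUE_v(df$prior_cvd), "prior_cvd")
  mark(isTRUE_v(df$diabetes), "diabetes")
  mark(isTRUE_v(df$statin_use), "statin_use")
  mark(isTRUE_v(df$diabetes_medication), "diabetes_medication")
  keep <- is.na(reason)
  kept <- df[keep, , drop = FALSE]
  kept$entry_date <- entry[keep]
  dropped <- df[!keep, , drop = FALSE]
  dropped$reason <- reason[!keep]
  fc <- c(input = nrow(df), kept = nrow(kept),
          table(factor(dropped$reason,
                       levels = c("short_registration", "ineligible_entry",
                                  "prior_cvd", "diabetes", "statin_use",
                                  "diabetes_medication"))))
  list(kept = kept, dropped = dropped, flowchart = fc)
}

# missing binary history flags are treated as absent
isTRUE_v <- function(x) !is.na(x) & x

#' Classify follow-up under competing risks
#'
#' For each person the first occurring of a qualifying CVD event (primary
#' care coded), CVD death, or non-CVD death terminates follow-up; otherwise
#' the person is censored at the earliest of the 80th birthday, the
#' administrative end of study, and deregistration. A CVD event and a death
#' on the same date count once, as a CVD event. Time is in years of 365.25
#' days.
#'
#' @param df Cohort table with an \code{entry_date} column (as produced by
#'   \code{\link{apply_exclusions}}).
#' @param codes Event code map.
#' @param admin_end Administrative end of study.
#' @return data.frame with \code{time} (years), \code{status} (factor
#'   censored / cvd_event / competing_death) and \code{censor_reason}
#'   (age_80 / admin_end / deregistration, NA for events).
#' @export
classify_follow_up <- function(df, codes = default_event_codes(),
                               admin_end = as.Date("2020-07-01")) {
  stopifnot(!is.null(df$entry_date))
  n <- nrow(df)
  entry <- df$entry_date
  b80 <- add_years(df$birth_date, 80)
  reg_end <- df$registration_end
  reg_end[is.na(reg_end)] <- as.Date("9999-12-31")

  ev_date <- df$cvd_event_date
  ev_ok <- !is.na(ev_date) &
    (is.na(df$cvd_event_code) | is_cvd_event_code(df$cvd_event_code, codes))
  ev_date[!ev_ok] <- NA

  death <- df$death_date
  death_cvd <- !is.na(death) & !is.na(df$death_icd10) &
    is_cvd_death(df$death_icd10, codes)
  cvd_death_date <- death
  cvd_death_date[!death_cvd] <- NA
  noncvd_death_date <- death
  noncvd_death_date[death_cvd] <- NA

  cvd_date <- pmin(ev_date, cvd_death_date, na.rm = TRUE)
  cens_date <- pmin(b80, admin_end, reg_end)

  term <- cens_date
  status <- rep("censored", n)
  has_comp <- !is.na(noncvd_death_date) & noncvd_death_date <= term
  term[has_comp] <- noncvd_death_date[has_comp]
  status[has_comp] <- "competing_death"
  has_cvd <- !is.na(cvd_date) & cvd_date <= term
  term[has_cvd] <- cvd_date[has_cvd]
  status[has_cvd] <- "cvd_event"

  if (any(term < entry, na.rm = TRUE))
    stop("terminal date before cohort entry for rows: ",
         paste(utils::head(which(term < entry), 10L), collapse = ", "))
  days <- as.numeric(term - entry)
  days[days == 0] <- 0.5  # same-day event: half-day convention
  reason <- rep(NA_character_, n)
  cens <- status == "censored"
  reason[cens & cens_date == b80] <- "age_80"
  reason[cens & cens_date == reg_end] <- "deregistration"
  reason[cens & cens_date == admin_end] <- "admin_end"
  data.frame(
    time = days / 365.25,
    status = factor(status,
                    levels = c("censored", "cvd_event", "competing_death")),
    censor_reason = reason)
}

#' Baseline value of a measured risk factor
#'
#' Among candidate measurements of one variable for one person, prefers the
#' GP source over hospital; within a source, the latest value at or before
#' entry, otherwise the earliest value after entry within a bounded
#' look-ahead window; otherwise missing.
#'
#' @param measurements data.frame with columns \code{value}, \code{date},
#'   \code{source} ("GP" or "hospital").
#' @param entry_date Cohort entry date.
#' @param window_days Post-entry look-ahead bound (default 365).
#' @return Single numeric value, or NA when no eligible measurement exists.
#' @export
baseline_measurement <- function(measurements, entry_date,
                                 window_days = 365) {
  m <- measurements[!is.na(measurements$value) & !is.na(measurements$date), ,
                    drop = FALSE]
  if (!nrow(m)) return(NA_real_)
  pick <- function(mm) {
    delta <- as.numeric(mm$date - entry_date)
    before <- mm[delta <= 0, , drop = FALSE]
    if (nrow(before)) return(before$value[which.max(before$date)])
    after <- mm[delta > 0 & delta <= window_days, , drop = FALSE]
    if (nrow(after)) return(after$value[which.min(after$date)])
    NA_real_
  }
  for (src in c("GP", "hospital")) {
    v <- pick(m[m$source == src, , drop = FALSE])
    if (!is.na(v)) return(v)
  }
  NA_real_
}

#' Build the analysis cohort from raw records
#'
#' Convenience wrapper: validates, determines entry, applies exclusions and
#' classifies follow-up, returning the analysis-ready table (one row per kept
#' person with \code{entry_date}, \code{age} at entry, \code{time},
#' \code{status}) plus the exclusion flowchart.
#'
#' @inheritParams apply_exclusions
#' @inheritParams classify_follow_up
#' @return List with \code{data} and \code{flowchart}.
#' @export
build_analysis_cohort <- function(df, codes = default_event_codes(),
                                  admin_end = as.Date("2020-07-01")) {
  ex <- apply_exclusions(df)
  kept <- ex$kept
  fu <- classify_follow_up(kept, codes = codes, admin_end = admin_end)
  kept$age <- as.numeric(kept$entry_date - kept$birth_date) / 365.25
  kept$time <- fu$time
  kept$status <- fu$status
  kept$censor_reason <- fu$censor_reason
  # analysis rule: missing smoking is assumed non-smoking
  kept$smoking <- !is.na(kept$smoking) & kept$smoking
  list(data = kept, flowchart = ex$flowchart)
}
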