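#' SCORE2 risk model object
#'
#' Construct a SCORE2 risk model from a coefficient configuration. The
#' configuration carries, per sex, the ordered term list (predictor name,
#' centring constant, scaling constant, age-interaction flag and
#' log-subdistribution-hazard coefficient), the 10-year baseline survival
#' \eqn{S_0(10)}, and the four European risk-region recalibration scale pairs
#' \eqn{(s_1, s_2)}. All numeric content is configuration data, never code:
#' the default configuration shipped with the package transcribes the
#' published SCORE2 model.
#'
#' The model computes, for a profile with linear predictor
#' \eqn{\mathrm{lp}}, the uncalibrated 10-year risk
#' \eqn{r = 1 - S_0(10)^{\exp(\mathrm{lp})}} and the region-recalibrated risk
#' \eqn{1 - \exp(-\exp(s_1 + s_2 \log(-\log(1 - r))))}.
#'
#' @param config Path to a JSON configuration file, or an already-parsed list
#'   with elements \code{male} and \code{female}. Defaults to the
#'   configuration shipped with the package.
#' @return An object of class \code{score2_model}.
#' @examples
#' m <- score2_model()
#' coef(m)$male
#' p <- data.frame(age = 50, sex = "male", smoking = TRUE,
#'                 sbp = 140, tchol = 6.3, hdl = 1.4)
#' predict(m, p, region = "all")
#' @export
score2_model <- function(config = score2_default_config()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- jsonlite::fromJSON(config, simplifyDataFrame = TRUE)
  }
  obj <- list(
    name = config$name %||% "score2",
    version = config$version %||% "unversioned",
    horizon = config$horizon_years %||% 10,
    sexes = list(
      male = .validate_sex_spec(config$male, "male"),
      female = .validate_sex_spec(config$female, "female")
    )
  )
  class(obj) <- "score2_model"
  obj
}

#' Path to the shipped SCORE2 coefficient configuration
#' @return File path of the default JSON coefficient file.
#' @export
score2_default_config <- function() {
  system.file("extdata", "score2_coefficients.json", package = "score2val",
              mustWork = TRUE)
}

score2_regions <- c("low", "moderate", "high", "very_high")

`%||%` <- function(a, b) if (is.null(a)) b else a

.validate_sex_spec <- function(spec, sex) {
  if (is.null(spec)) stop("configuration lacks a spec for sex ", sex)
  tl <- spec$terms
  if (is.data.frame(tl)) tl <- tl else tl <- do.call(rbind.data.frame, tl)
  need <- c("name", "center", "scale", "interacts_with_age", "beta")
  if (!all(need %in% names(tl)))
    stop("term list must carry columns: ", paste(need, collapse = ", "))
  s0 <- spec$s0_10
  if (!is.numeric(s0) || length(s0) != 1L || s0 <= 0 || s0 >= 1)
    stop("baseline_survival_10y must lie strictly in (0, 1)")
  sc <- spec$scales
  if (!setequal(names(sc), score2_regions))
    stop("scales must name exactly the regions: ",
         paste(score2_regions, collapse = ", "))
  sc <- lapply(sc[score2_regions], function(p) {
    p <- as.numeric(unlist(p))
    if (length(p) != 2L || !all(is.finite(p)))
      stop("each region scale must be a finite (scale1, scale2) pair")
    if (p[2L] <= 0) stop("scale2 must be positive for every region")
    p
  })
  if (!any(tl$name == "age" & !tl$interacts_with_age))
    stop("term list must contain a main age term (used for interactions)")
  list(sex = sex, terms = tl, s0_10 = s0, scales = sc)
}

#' @export
print.score2_model <- function(x, ...) {
  cat("SCORE2 risk model (", x$name, ", config version ", x$version, ")\n",
      sep = "")
  cat("  horizon: ", x$horizon, " years\n", sep = "")
  for (s in names(x$sexes)) {
    sp <- x$sexes[[s]]
    cat("  ", s, ": ", nrow(sp$terms), " terms, S0(10) = ", sp$s0_10,
        ", regions: ", paste(score2_regions, collapse = "/"), "\n", sep = "")
  }
  invisible(x)
}

#' @export
coef.score2_model <- function(object, ...) {
  lapply(object$sexes, function(sp) {
    b <- sp$terms$beta
    names(b) <- ifelse(sp$terms$interacts_with_age,
                       paste0(sp$terms$name, ":age"), sp$terms$name)
    b
  })
}

# Evaluate the centred/scaled term values for profiles of one sex.
# `profiles` is a data.frame with columns age, smoking, sbp, tchol, hdl
# (or non_hdl when the configuration is parameterised that way).
# Returns an n x k matrix, one column per configured term.
score2_terms <- function(profiles, spec) {
  tl <- spec$terms
  n <- nrow(profiles)
  get_var <- function(nm) {
    v <- switch(nm,
      age = profiles$age,
      smoking = as.numeric(profiles$smoking),
      sbp = profiles$sbp,
      tchol = profiles$tchol,
      hdl = profiles$hdl,
      non_hdl = if (!is.null(profiles$non_hdl)) profiles$non_hdl
                else profiles$tchol - profiles$hdl,
      stop("unknown predictor in term list: ", nm))
    if (is.null(v)) stop("profile lacks predictor: ", nm)
    if (anyNA(v))
      stop("missing value in predictor '", nm,
           "': imputation must happen upstream of prediction")
    as.numeric(v)
  }
  i_age <- which(tl$name == "age" & !tl$interacts_with_age)[1L]
  cage <- (get_var("age") - tl$center[i_age]) / tl$scale[i_age]
  M <- matrix(0, nrow = n, ncol = nrow(tl))
  for (j in seq_len(nrow(tl))) {
    v <- (get_var(tl$name[j]) - tl$center[j]) / tl$scale[j]
    if (tl$interacts_with_age[j]) v <- v * cage
    M[, j] <- v
  }
  colnames(M) <- ifelse(tl$interacts_with_age,
                        paste0(tl$name, ":age"), tl$name)
  M
}

#' Centred and scaled model terms for a risk-factor profile
#'
#' Applies the configured centring/scaling transforms and age-interaction
#' products, returning one value per model term. Errors if the profile's sex
#' does not match the requested spec or a needed predictor is missing.
#'
#' @param profile One-row data.frame (or list) with \code{age},
#'   \code{sex}, \code{smoking}, \code{sbp}, \code{tchol}, \code{hdl}.
#' @param model A \code{score2_model}.
#' @param sex Which sex spec to use; defaults to \code{profile$sex}.
#' @return Named numeric vector of term values.
#' @export
transform_profile <- function(profile, model, sex = NULL) {
  profile <- as.data.frame(profile, stringsAsFactors = FALSE)
  stopifnot(nrow(profile) == 1L)
  psex <- as.character(profile$sex %||% NA_character_)
  sex <- sex %||% psex
  if (!sex %in% c("male", "female")) stop("sex must be 'male' or 'female'")
  if (!is.na(psex) && nzchar(psex) && psex != sex)
    stop("profile sex ('", psex, "') does not match requested spec ('",
         sex, "')")
  .check_profile(profile)
  drop(score2_terms(profile, model$sexes[[sex]])[1L, ])
}

.check_profile <- function(p) {
  if (!is.null(p$age) && any(!is.na(p$age) & (p$age < 40 | p$age >= 70)))
    warning("age outside the supported [40, 70) range; extrapolating")
  for (v in c("sbp", "tchol", "hdl"))
    if (!is.null(p[[v]]) && any(!is.na(p[[v]]) & p[[v]] <= 0))
      stop(v, " must be positive")
  bad <- !is.null(p$hdl) && !is.null(p$tchol) &&
    any(!is.na(p$hdl) & !is.na(p$tchol) & p$hdl >= p$tchol)
  if (bad)  # can arise from independently imputed lipid pairs
    warning("hdl at or above total cholesterol for some profiles")
  invisible(TRUE)
}

#' Linear predictor from term values
#'
#' Inner product of term values and the configured coefficients.
#'
#' @param terms Numeric vector (or matrix, terms in columns) as produced by
#'   \code{\link{transform_profile}}.
#' @param model A \code{score2_model}.
#' @param sex \code{"male"} or \code{"female"}.
#' @return Numeric linear predictor(s).
#' @export
score2_linear_predictor <- function(terms, model, sex) {
  beta <- model$sexes[[sex]]$terms$beta
  if (is.matrix(terms)) {
    if (ncol(terms) != length(beta))
      stop("term matrix has ", ncol(terms), " columns; expected ",
           length(beta))
    drop(terms %*% beta)
  } else {
    if (length(terms) != length(beta))
      stop("term vector has length ", length(terms), "; expected ",
           length(beta))
    sum(terms * beta)
  }
}

#' Uncalibrated 10-year risk from a linear predictor
#'
#' \eqn{1 - S_0(10)^{\exp(\mathrm{lp})}}; strictly increasing in lp.
#'
#' @param lp Numeric linear predictor(s); must be finite.
#' @param model A \code{score2_model}.
#' @param sex \code{"male"} or \code{"female"}.
#' @return Probabilities in (0, 1).
#' @export
score2_uncalibrated_risk <- function(lp, model, sex) {
  if (any(!is.finite(lp))) stop("linear predictor must be finite")
  s0 <- model$sexes[[sex]]$s0_10
  1 - s0^exp(lp)
}

#' Recalibrate a risk to a target region
#'
#' Applies the region rescaling
#' \eqn{1 - \exp(-\exp(s_1 + s_2\,\log(-\log(1 - r))))} on the
#' complementary-log-log scale. With \eqn{s_1 = 0, s_2 = 1} this is the
#' identity; it is strictly increasing in \code{risk} whenever
#' \eqn{s_2 > 0}.
#'
#' @param risk Probabilities strictly inside (0, 1).
#' @param scale1,scale2 Region scale pair; \code{scale2} must be positive.
#' @return Recalibrated probabilities in (0, 1).
#' @export
recalibrate <- function(risk, scale1, scale2) {
  if (any(!is.finite(risk)) || any(risk <= 0) || any(risk >= 1))
    stop("risk must lie strictly in (0, 1): the cloglog transform is ",
         "undefined at 0 and 1")
  if (!is.finite(scale2) || scale2 <= 0) stop("scale2 must be positive")
  1 - exp(-exp(scale1 + scale2 * log(-log1p(-risk))))
}

#' Predict 10-year CVD risk
#'
#' Composes transform, linear predictor, baseline survival and region
#' recalibration for each row of \code{newdata}. Rows may mix sexes; each row
#' is evaluated under its own sex-specific spec.
#'
#' @param object A \code{score2_model}.
#' @param newdata data.frame with columns \code{age}, \code{sex},
#'   \code{smoking}, \code{sbp}, \code{tchol}, \code{hdl}.
#' @param region One of \code{"low"}, \code{"moderate"}, \code{"high"},
#'   \code{"very_high"} for a single numeric vector, or \code{"all"}
#'   (default) for a data.frame with the linear predictor, uncalibrated risk
#'   and all four region risks.
#' @param ... Unused.
#' @return Numeric vector (single region) or data.frame (\code{"all"}).
#' @export
predict.score2_model <- function(object, newdata, region = "all", ...) {
  if (!region %in% c(score2_regions, "all"))
    stop("unknown region '", region, "'; expected one of ",
         paste(c(score2_regions, "all"), collapse = ", "))
  newdata <- as.data.frame(newdata)
  sex <- as.character(newdata$sex)
  if (anyNA(sex) || !all(sex %in% c("male", "female")))
    stop("newdata$sex must be 'male' or 'female' with no missing values")
  .check_profile(newdata)
  n <- nrow(newdata)
  lp <- numeric(n)
  unc <- numeric(n)
  reg <- matrix(NA_real_, n, length(score2_regions),
                dimnames = list(NULL, score2_regions))
  for (s in unique(sex)) {
    i <- which(sex == s)
    sp <- object$sexes[[s]]
    M <- score2_terms(newdata[i, , drop = FALSE], sp)
    lp_i <- drop(M %*% sp$terms$beta)
    unc_i <- 1 - sp$s0_10^exp(lp_i)
    lp[i] <- lp_i
    unc[i] <- unc_i
    for (r in score2_regions) {
      p <- sp$scales[[r]]
      reg[i, r] <- recalibrate(unc_i, p[1L], p[2L])
    }
  }
  if (region == "all") {
    out <- data.frame(linear_predictor = lp, uncalibrated = unc, reg,
                      check.names = FALSE)
    return(out)
  }
  reg[, region]
}

#' Treatment category against age-specific ESC thresholds
#'
#' Individuals under 50 use the (2.5\%, 7.5\%) cut-offs; individuals 50 and
#' over use (5\%, 10\%). Categories use half-open intervals with the upper
#' boundary inclusive upward: risk at or above the upper threshold is
#' \code{very_high}.
#'
#' @param risk Predicted probabilities in [0, 1].
#' @param age Age in years at prediction (cohort entry).
#' @return data.frame with \code{category} (factor low_to_moderate / high /
#'   very_high) and the thresholds used.
#' @export
treatment_category <- function(risk, age) {
  stopifnot(length(risk) == length(age) || length(age) == 1L)
  if (any(risk < 0 | risk > 1, na.rm = TRUE)) stop("risk must be in [0, 1]")
  age <- rep_len(age, length(risk))
  lower <- ifelse(age < 50, 0.025, 0.05)
  upper <- ifelse(age < 50, 0.075, 0.10)
  cat <- ifelse(risk >= upper, "very_high",
         ifelse(risk >= lower, "high", "low_to_moderate"))
  data.frame(
    category = factor(cat, levels = c("low_to_moderate", "high", "very_high")),
    threshold_lower = lower, threshold_upper = upper)
}
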