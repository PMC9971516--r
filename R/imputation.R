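#' Multiple imputation by chained equations
#'
#' Imputes systolic blood pressure, total and HDL cholesterol (continuous,
#' predictive mean matching) and the household-income quintile (ordinal,
#' predictive mean matching on the numeric quintile scale) by iterated
#' chained equations. Each sweep regresses one incomplete variable on the
#' configured predictors over the currently-completed data, draws regression
#' parameters from their approximate posterior, and fills missing entries
#' with observed donor values matched on the predicted mean (k nearest
#' donors). Observed values are never modified. Smoking must already be
#' resolved upstream (missing assumed non-smoking).
#'
#' The default predictor set mirrors the analysis: age, smoking, the other
#' incomplete variables, the auxiliary correlates fasting glucose and eGFR,
#' ethnicity, follow-up time and the CVD event indicator.
#'
#' @param data Analysis cohort data.frame (see
#'   \code{\link{build_analysis_cohort}}); must carry \code{time} and
#'   \code{status}.
#' @param m Number of completed datasets (default 5).
#' @param maxit Chained-equation sweeps per dataset (default 10; use more,
#'   e.g. 40, when assessing convergence).
#' @param impute_vars Variables allowed to be incomplete.
#' @param predictors Complete variables used on the right-hand side.
#' @param k Number of donor candidates for predictive mean matching.
#' @param seed Integer seed; imputations are reproducible given the seed.
#' @param impute_ses Set \code{FALSE} to leave \code{ses_quintile} missing
#'   (sensitivity analyses).
#' @return Object of class \code{score2_imputation}: list with
#'   \code{imputations} (list of m completed data.frames), \code{m},
#'   \code{chain_mean}/\code{chain_sd} (variable x iteration x m arrays for
#'   convergence assessment) and the call parameters.
#' @export
impute_cohort <- function(data, m = 5, maxit = 10,
                          impute_vars = c("sbp", "tchol", "hdl",
                                          "ses_quintile"),
                          predictors = c("age", "sex", "smoking", "glucose",
                                         "egfr", "ethnicity", "time",
                                         "event"),
                          k = 5L, seed = NULL, impute_ses = TRUE) {
  if (m < 2) stop("m must be at least 2")
  if (!is.null(seed)) set.seed(seed)
  if (!impute_ses) impute_vars <- setdiff(impute_vars, "ses_quintile")
  data <- as.data.frame(data)
  if (is.null(data$event) && !is.null(data$status))
    data$event <- as.integer(data$status == "cvd_event")

  targets <- impute_vars[vapply(impute_vars,
                                function(v) anyNA(data[[v]]), logical(1))]
  for (v in targets)
    if (all(is.na(data[[v]])))
      stop("variable '", v, "' is 100% missing and cannot be imputed")
  other <- setdiff(names(data), c(impute_vars, "person_id"))
  bad <- other[vapply(other, function(v) anyNA(data[[v]]), logical(1))]
  bad <- intersect(bad, c(predictors, "age", "smoking", "time", "event"))
  if (length(bad))
    stop("missingness outside the configured imputation variables: ",
         paste(bad, collapse = ", "))

  if (!length(targets)) {
    return(structure(list(imputations = replicate(m, data, simplify = FALSE),
                          m = m, maxit = maxit, targets = character(0),
                          chain_mean = NULL, chain_sd = NULL),
                     class = "score2_imputation"))
  }

  miss <- lapply(targets, function(v) which(is.na(data[[v]])))
  names(miss) <- targets
  chain_mean <- array(NA_real_, c(length(targets), maxit, m),
                      dimnames = list(targets, NULL, NULL))
  chain_sd <- chain_mean
  imputations <- vector("list", m)

  for (im in seq_len(m)) {
    cur <- data
    for (v in targets)  # initialise from the observed margin
      cur[[v]][miss[[v]]] <- sample(cur[[v]][-miss[[v]]],
                                    length(miss[[v]]), replace = TRUE)
    for (it in seq_len(maxit)) {
      for (v in targets) {
        rhs <- unique(c(predictors, setdiff(targets, v)))
        rhs <- intersect(rhs, names(cur))
        X <- .imp_design(cur, rhs)
        y <- cur[[v]]
        idx <- miss[[v]]
        draw <- .pmm_draw(y, X, idx, k = k)
        if (v == "ses_quintile") draw <- as.integer(round(draw))
        cur[[v]][idx] <- draw
        chain_mean[v, it, im] <- mean(cur[[v]][idx])
        chain_sd[v, it, im] <- stats::sd(cur[[v]][idx])
      }
    }
    imputations[[im]] <- cur
  }
  structure(list(imputations = imputations, m = m, maxit = maxit,
                 targets = targets, chain_mean = chain_mean,
                 chain_sd = chain_sd),
            class = "score2_imputation")
}

# numeric design matrix with intercept; factors expanded to dummies
.imp_design <- function(df, vars) {
  cols <- list(`(Intercept)` = rep(1, nrow(df)))
  for (v in vars) {
    x <- df[[v]]
    if (is.null(x)) next
    if (is.logical(x)) cols[[v]] <- as.numeric(x)
    else if (is.character(x) || is.factor(x)) {
      f <- factor(x)
      for (l in levels(f)[-1L]) cols[[paste0(v, l)]] <- as.numeric(f == l)
    } else cols[[v]] <- as.numeric(x)
  }
  do.call(cbind, cols)
}

# Bayesian-ish linear regression + predictive mean matching.
# Returns donor-sampled values for rows `idx` (the missing rows of y).
.pmm_draw <- function(y, X, idx, k = 5L, ridge = 1e-5) {
  obs <- setdiff(seq_along(y), idx)
  Xo <- X[obs, , drop = FALSE]
  yo <- y[obs]
  XtX <- crossprod(Xo)
  diag(XtX) <- diag(XtX) * (1 + ridge) + ridge
  Xty <- crossprod(Xo, yo)
  R <- chol(XtX)
  beta_hat <- backsolve(R, forwardsolve(t(R), Xty))
  res <- yo - drop(Xo %*% beta_hat)
  df_res <- max(length(obs) - ncol(Xo), 1L)
  sigma2 <- sum(res^2) / stats::rchisq(1L, df_res)
  # beta* ~ N(beta_hat, sigma2 (X'X)^-1)
  z <- stats::rnorm(ncol(Xo))
  beta_star <- beta_hat + sqrt(sigma2) * backsolve(R, z)
  yhat_obs <- drop(Xo %*% beta_hat)
  yhat_mis <- drop(X[idx, , drop = FALSE] %*% beta_star)
  .pmm_match(yhat_obs, yo, yhat_mis, k = k)
}

# for each target predicted mean, sample one of the k observed donors with
# the nearest predicted means (compiled outward walk over the sorted donors)
.pmm_match <- function(yhat_obs, y_obs, yhat_mis, k = 5L) {
  ord <- order(yhat_obs)
  k <- min(as.integer(k), length(yhat_obs))
  pick <- sample.int(k, length(yhat_mis), replace = TRUE)
  .pmm_match_cpp(yhat_obs[ord], y_obs[ord], yhat_mis, pick)
}

#' @export
print.score2_imputation <- function(x, ...) {
  cat("Chained-equation imputation: m =", x$m, ", sweeps =", x$maxit, "\n")
  cat("  imputed variables:",
      if (length(x$targets)) paste(x$targets, collapse = ", ")
      else "(none were missing)", "\n")
  invisible(x)
}

#' Convergence summary of the imputation chains
#'
#' Per-variable means/SDs of the imputed values across sweeps; a variable is
#' flagged when the chain means still trend in the final third of the sweeps
#' (absolute trend above half the between-chain spread).
#'
#' @param x A \code{score2_imputation}.
#' @return data.frame with one row per imputed variable.
#' @export
imputation_convergence <- function(x) {
  if (!length(x$targets))
    return(data.frame(variable = character(0), trend = numeric(0),
                      flagged = logical(0)))
  it3 <- seq.int(max(1L, floor(x$maxit * 2 / 3)), x$maxit)
  slope <- function(s) {
    s <- as.vector(s)
    if (length(s) < 2) return(0)
    i <- seq_along(s)
    stats::cov(i, s) / stats::var(i)
  }
  out <- lapply(x$targets, function(v) {
    cm <- x$chain_mean[v, it3, , drop = FALSE]
    tail_means <- apply(cm, 3, mean)
    trend <- mean(apply(cm, 3, slope))
    spread <- stats::sd(tail_means)
    data.frame(variable = v, trend = unname(trend),
               flagged = is.finite(spread) && spread > 0 &&
                 abs(trend * length(it3)) > spread / 2)
  })
  do.call(rbind, out)
}

#' Pool estimates across imputations with Rubin's rules
#'
#' Point estimate is the mean of the per-imputation points; the total
#' variance combines the mean within-imputation variance W and the
#' between-imputation variance B as \eqn{T = W + (1 + 1/m) B}. The
#' confidence interval is a normal approximation on the pooling scale,
#' optionally back-transformed (e.g. pool observed/expected ratios on the
#' log scale and exponentiate).
#'
#' @param points Per-imputation point estimates (length >= 2).
#' @param variances Per-imputation variances on the same scale.
#' @param conf Confidence level (default 0.95).
#' @param transform,inverse Optional monotone transform applied before
#'   pooling and its inverse applied to the point and interval afterwards.
#' @return List of class \code{pooled_estimate}: \code{point},
#'   \code{within_var}, \code{between_var}, \code{total_var}, \code{ci}.
#' @export
rubin_pool <- function(points, variances, conf = 0.95,
                       transform = identity, inverse = identity) {
  if (length(points) < 2) stop("Rubin pooling needs at least 2 estimates")
  if (length(points) != length(variances))
    stop("points and variances must have equal length")
  m <- length(points)
  q <- transform(points)
  w <- mean(variances)
  b <- stats::var(q)
  tot <- w + (1 + 1 / m) * b
  qbar <- mean(q)
  zc <- stats::qnorm(1 - (1 - conf) / 2)
  ci <- qbar + c(-1, 1) * zc * sqrt(tot)
  structure(list(point = inverse(qbar), within_var = w, between_var = b,
                 total_var = tot, ci = inverse(ci), m = m),
            class = "pooled_estimate")
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf("pooled estimate %.4g (%.0f%% CI %.4g-%.4g); W=%.3g B=%.3g T=%.3g, m=%d\n",
              x$point, 95, x$ci[1], x$ci[2],
              x$within_var, x$between_var, x$total_var, x$m))
  invisible(x)
}
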