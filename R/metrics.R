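#' Cumulative incidence of the CVD event under competing risks
#'
#' Aalen--Johansen estimator of the cumulative incidence function (CIF) of
#' the event of interest at a fixed horizon, treating the competing event
#' (non-CVD death) as a competing risk and censoring as non-informative.
#' Computed through the multi-state Aalen--Johansen machinery of
#' \pkg{survival}; the variance is the standard counting-process estimate.
#'
#' @param time Follow-up time in years.
#' @param status Factor or integer: 0/"censored", 1/"cvd_event",
#'   2/"competing_death".
#' @param horizon Horizon in years (default 10).
#' @return List with \code{estimate}, \code{variance}, \code{n},
#'   \code{events} (events of interest by the horizon).
#' @export
cumulative_incidence <- function(time, status, horizon = 10) {
  if (horizon <= 0) stop("horizon must be positive")
  st <- .as_status(status)
  if (!length(time)) stop("no outcomes supplied")
  if (all(time <= 0)) stop("all follow-up times are non-positive")
  ev <- sum(st == 1L & time <= horizon)
  if (all(st == 0L))
    return(list(estimate = 0, variance = 0, n = length(time), events = 0L))
  f <- factor(st, levels = 0:2, labels = c("censor", "cvd", "death"))
  fit <- survival::survfit(survival::Surv(time, f) ~ 1)
  sm <- summary(fit, times = horizon, extend = TRUE)
  i <- match("cvd", gsub("\\s", "", sm$states))
  est <- as.numeric(sm$pstate[1L, i])
  se <- as.numeric(sm$std.err[1L, i])
  list(estimate = est, variance = se^2, n = length(time), events = ev)
}

.as_status <- function(status) {
  if (is.factor(status) || is.character(status)) {
    st <- match(as.character(status),
                c("censored", "cvd_event", "competing_death")) - 1L
    if (anyNA(st)) stop("status labels must be censored/cvd_event/competing_death")
    st
  } else {
    st <- as.integer(status)
    if (any(!st %in% 0:2)) stop("integer status must be 0, 1 or 2")
    st
  }
}

#' Observed/expected ratio at a fixed horizon
#'
#' Calibration-in-the-large: the Aalen--Johansen observed cumulative
#' incidence at the horizon divided by the mean predicted probability.
#' Values above 1 indicate underprediction. The confidence interval uses the
#' delta method on log(OE) with the expected value treated as fixed:
#' \eqn{\exp(\log \mathrm{OE} \pm z \sqrt{\mathrm{var}(O)} / O)}.
#'
#' @param time,status Follow-up outcomes (see
#'   \code{\link{cumulative_incidence}}).
#' @param predictions Per-person predicted probabilities, aligned with the
#'   outcomes.
#' @param horizon Horizon in years.
#' @param conf Confidence level.
#' @return List of class \code{calibration_result}: \code{n},
#'   \code{observed_events}, \code{observed_risk}, \code{mean_predicted},
#'   \code{oe_ratio}, \code{ci}, \code{log_oe_var}.
#' @export
oe_ratio <- function(time, status, predictions, horizon = 10, conf = 0.95) {
  if (length(predictions) != length(time))
    stop("predictions must align one-to-one with the outcomes")
  e <- mean(predictions)
  if (!is.finite(e) || e <= 0) stop("mean predicted probability must be positive")
  ci_f <- cumulative_incidence(time, status, horizon)
  o <- ci_f$estimate
  oe <- o / e
  lvar <- if (o > 0) ci_f$variance / o^2 else NA_real_
  zc <- stats::qnorm(1 - (1 - conf) / 2)
  ci <- if (is.finite(lvar)) exp(log(oe) + c(-1, 1) * zc * sqrt(lvar))
        else c(NA_real_, NA_real_)
  structure(list(n = ci_f$n, observed_events = ci_f$events,
                 observed_risk = o, observed_risk_var = ci_f$variance,
                 mean_predicted = e, oe_ratio = oe, log_oe_var = lvar,
                 ci = ci),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("O/E = %.3f (observed %.4f over n=%d, %d events; expected %.4f); CI %.3f-%.3f\n",
              x$oe_ratio, x$observed_risk, x$n, x$observed_events,
              x$mean_predicted, x$ci[1], x$ci[2]))
  invisible(x)
}

#' Decile calibration curve with a smoothed overlay
#'
#' Bins the sample into (by default ten) equal-size groups by predicted risk
#' (stable ties broken by position), computes the Aalen--Johansen observed
#' incidence at the horizon per bin, and overlays a locally weighted
#' (LOESS) curve of observed on predicted risk fitted over a finer grid of
#' quantile bins (weighted by bin size).
#'
#' @inheritParams oe_ratio
#' @param bins Number of calibration bins (default 10).
#' @param span LOESS span (default 0.75, degree 1).
#' @param loess_bins Number of fine bins behind the smoother (default 50,
#'   reduced when n is small).
#' @return Object of class \code{calibration_curve}: \code{bins} data.frame
#'   (mean_predicted, observed, ci_lo, ci_hi, n, events) and \code{loess}
#'   data.frame (predicted, observed) for plotting.
#' @export
calibration_curve <- function(time, status, predictions, horizon = 10,
                              bins = 10, span = 0.75, loess_bins = 50) {
  n <- length(predictions)
  if (n < bins) stop("need at least as many observations as bins")
  if (length(unique(predictions)) < bins) {
    warning("fewer distinct predictions than bins; merging")
    bins <- max(1L, length(unique(predictions)))
  }
  ord <- order(predictions)  # stable: ties keep input order
  grp <- ceiling(seq_len(n) / (n / bins))
  grp[grp > bins] <- bins
  bin_of <- integer(n)
  bin_of[ord] <- grp
  rows <- lapply(seq_len(bins), function(b) {
    i <- bin_of == b
    cif <- cumulative_incidence(time[i], status[i], horizon)
    se <- sqrt(cif$variance)
    data.frame(bin = b, mean_predicted = mean(predictions[i]),
               observed = cif$estimate,
               ci_lo = max(0, cif$estimate - 1.96 * se),
               ci_hi = min(1, cif$estimate + 1.96 * se),
               n = cif$n, events = cif$events)
  })
  bins_df <- do.call(rbind, rows)

  lb <- min(loess_bins, max(bins, floor(n / 50)))
  lo_df <- NULL
  if (lb >= 4 && length(unique(predictions)) >= 4) {
    lgrp <- ceiling(seq_len(n) / (n / lb))
    lgrp[lgrp > lb] <- lb
    lbin <- integer(n)
    lbin[ord] <- lgrp
    pts <- do.call(rbind, lapply(seq_len(lb), function(b) {
      i <- lbin == b
      data.frame(p = mean(predictions[i]),
                 o = cumulative_incidence(time[i], status[i],
                                          horizon)$estimate,
                 w = sum(i))
    }))
    fit <- try(stats::loess(o ~ p, data = pts, weights = pts$w, span = span,
                            degree = 1), silent = TRUE)
    if (!inherits(fit, "try-error")) {
      gx <- seq(min(pts$p), max(pts$p), length.out = 100)
      lo_df <- data.frame(predicted = gx,
                          observed = stats::predict(fit, newdata =
                                                      data.frame(p = gx)))
    }
  }
  structure(list(bins = bins_df, loess = lo_df, horizon = horizon),
            class = "calibration_curve")
}

#' Harrell's concordance for fixed-horizon risk predictions
#'
#' Probability, among comparable pairs, that the person with the earlier
#' event carries the higher predicted risk; prediction ties count one half.
#' Competing deaths are treated as censoring at the death time (the classic
#' Harrell definition), and follow-up is truncated at the prediction horizon
#' by default for consistency with fixed-horizon predictions. Computed with
#' the O(n log n) concordance machinery of \pkg{survival}, with its analytic
#' standard error.
#'
#' @inheritParams oe_ratio
#' @param truncate_at Truncation time in years (default 10); \code{Inf}
#'   disables truncation.
#' @return List of class \code{discrimination_result}: \code{c_statistic},
#'   \code{ci}, \code{variance}, \code{comparable_pairs}, \code{n}.
#' @export
harrells_c <- function(time, status, predictions, truncate_at = 10,
                       conf = 0.95) {
  if (length(time) < 2) stop("need at least two observations")
  st <- .as_status(status)
  ev <- st == 1L & time <= truncate_at
  tt <- pmin(time, truncate_at)
  fit <- survival::concordance(survival::Surv(tt, ev) ~ predictions,
                               reverse = TRUE)
  cnt <- fit$count
  comparable <- sum(cnt[c("concordant", "discordant", "tied.x")])
  if (comparable == 0) stop("no comparable pairs")
  se <- sqrt(fit$var)
  zc <- stats::qnorm(1 - (1 - conf) / 2)
  structure(list(c_statistic = as.numeric(fit$concordance),
                 variance = as.numeric(fit$var),
                 ci = pmin(1, pmax(0, fit$concordance + c(-1, 1) * zc * se)),
                 comparable_pairs = as.numeric(comparable),
                 n = length(time)),
            class = "discrimination_result")
}

#' @export
print.discrimination_result <- function(x, ...) {
  cat(sprintf("Harrell's C = %.3f (CI %.3f-%.3f), %g comparable pairs, n=%d\n",
              x$c_statistic, x$ci[1], x$ci[2], x$comparable_pairs, x$n))
  invisible(x)
}

#' Minimum-events gate for subgroup validation
#'
#' A stratum is externally validated only when it contains at least
#' \code{threshold} observed events of interest (default 200); smaller
#' strata are reported but not scored.
#'
#' @param status Outcome status vector for the stratum.
#' @param time Optional follow-up times; when supplied with
#'   \code{horizon}, only events by the horizon count.
#' @param threshold Minimum event count (default 200).
#' @param horizon Optional horizon restriction.
#' @return Logical: is the stratum evaluable?
#' @export
min_events_gate <- function(status, time = NULL, threshold = 200,
                            horizon = NULL) {
  if (!length(status)) return(FALSE)
  st <- .as_status(status)
  ev <- st == 1L
  if (!is.null(time) && !is.null(horizon)) ev <- ev & time <= horizon
  sum(ev) >= threshold
}
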