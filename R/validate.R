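#' Externally validate SCORE2 on a cohort
#'
#' Runs the full validation pipeline: builds the analysis cohort (entry,
#' exclusions, competing-risk follow-up), multiply imputes the incomplete
#' risk factors, predicts 10-year risk under the requested region models,
#' computes fixed-horizon calibration (observed/expected ratio) and
#' discrimination (Harrell's C) per stratum and per completed dataset, and
#' pools with Rubin's rules (observed/expected on the log scale, C on the
#' identity scale). Strata below the minimum-events gate are reported but
#' flagged non-evaluable. Deterministic given \code{seed}.
#'
#' @param cohort Raw cohort data.frame in the package schema, a
#'   \code{synthetic_cohort}, or a list with an already-built \code{data}
#'   element (from \code{\link{build_analysis_cohort}}).
#' @param model A \code{\link{score2_model}}.
#' @param regions Character vector of region models to evaluate, or
#'   \code{"all"}.
#' @param by Stratification dimensions beyond sex: any of
#'   \code{"ethnicity"}, \code{"ses"}.
#' @param cross Also evaluate the combined ethnicity-by-income strata.
#' @param m,maxit Imputation count and sweeps (see
#'   \code{\link{impute_cohort}}).
#' @param seed Integer seed covering imputation randomness.
#' @param horizon Prediction horizon in years.
#' @param min_events Minimum observed events for an evaluable stratum.
#' @param compute_c Compute Harrell's C (the costly part) per stratum.
#' @param impute_ses Impute the missing income quintile (turn off for
#'   sensitivity analyses).
#' @param subset Optional logical vector over the raw cohort rows.
#' @return Object of class \code{score2_validation}; see
#'   \code{\link{print.score2_validation}}. The \code{results} element is a
#'   data.frame with one row per stratum x region: pooled O, E, OE with CI,
#'   pooled C with CI, event counts and the evaluability flag.
#' @export
score2_validate <- function(cohort, model = score2_model(),
                            regions = "low", by = c("ethnicity", "ses"),
                            cross = FALSE, m = 5, maxit = 10, seed = 1L,
                            horizon = 10, min_events = 200,
                            compute_c = TRUE, impute_ses = TRUE,
                            subset = NULL) {
  set.seed(seed)
  if (identical(regions, "all")) regions <- score2_regions
  stopifnot(all(regions %in% score2_regions))

  if (inherits(cohort, "synthetic_cohort")) cohort <- cohort$cohort
  if (is.data.frame(cohort)) {
    if (!is.null(subset)) cohort <- cohort[subset, , drop = FALSE]
    built <- build_analysis_cohort(cohort)
  } else {
    built <- cohort
    if (!is.null(subset)) built$data <- built$data[subset, , drop = FALSE]
  }
  data <- built$data
  if (!nrow(data)) stop("no eligible persons in the cohort")

  imp <- impute_cohort(data, m = m, maxit = maxit, impute_ses = impute_ses)

  # per-imputation predictions per region (risk factors differ by imputation)
  preds <- lapply(imp$imputations, function(d) {
    out <- lapply(regions, function(r) predict(model, d, region = r))
    names(out) <- regions
    out
  })

  strata <- .make_strata(by, cross)
  time <- data$time
  status <- data$status

  rows <- list()
  for (st in strata) {
    # stratum membership: income quintile may differ across imputations
    idx_im <- lapply(imp$imputations, function(d) .stratum_index(d, st))
    n_st <- round(mean(vapply(idx_im, length, numeric(1))))
    if (n_st == 0) next
    ev_im <- vapply(idx_im, function(i)
      sum(status[i] == "cvd_event"), numeric(1))
    evaluable <- mean(ev_im) >= min_events
    # observed incidence per imputation (region-independent)
    cif_im <- lapply(idx_im, function(i)
      if (length(i)) cumulative_incidence(time[i], status[i], horizon)
      else NULL)
    for (r in regions) {
      oes <- vars <- es <- os <- numeric(imp$m)
      cs <- cvars <- rep(NA_real_, imp$m)
      for (j in seq_len(imp$m)) {
        i <- idx_im[[j]]
        p <- preds[[j]][[r]][i]
        e <- mean(p)
        o <- cif_im[[j]]$estimate
        oes[j] <- o / e
        vars[j] <- if (o > 0) cif_im[[j]]$variance / o^2 else NA_real_
        es[j] <- e; os[j] <- o
        if (compute_c && length(i) >= 2 &&
            sum(status[i] == "cvd_event" & time[i] <= horizon) >= 2) {
          hc <- harrells_c(time[i], status[i], p, truncate_at = horizon)
          cs[j] <- hc$c_statistic
          cvars[j] <- hc$variance
        }
      }
      ok <- is.finite(oes) & oes > 0 & is.finite(vars)
      pooled_oe <- if (sum(ok) >= 2)
        rubin_pool(oes[ok], vars[ok], transform = log, inverse = exp)
      else list(point = NA_real_, ci = c(NA_real_, NA_real_))
      pooled_c <- if (compute_c && sum(is.finite(cs)) >= 2)
        rubin_pool(cs[is.finite(cs)], cvars[is.finite(cs)])
      else list(point = NA_real_, ci = c(NA_real_, NA_real_))
      rows[[length(rows) + 1L]] <- data.frame(
        sex = st$sex, ethnicity = st$ethnicity, ses = st$ses,
        region = r, n = n_st, events = mean(ev_im),
        observed_risk = mean(os), mean_predicted = mean(es),
        oe = pooled_oe$point, oe_lo = pooled_oe$ci[1],
        oe_hi = pooled_oe$ci[2],
        c = pooled_c$point, c_lo = pooled_c$ci[1], c_hi = pooled_c$ci[2],
        evaluable = evaluable, stringsAsFactors = FALSE)
    }
  }
  results <- do.call(rbind, rows)
  structure(list(results = results, m = imp$m, seed = seed,
                 horizon = horizon, regions = regions,
                 min_events = min_events, n = nrow(data),
                 flowchart = built$flowchart,
                 imputation = imp, data = data, predictions = preds),
            class = "score2_validation")
}

.make_strata <- function(by, cross) {
  sexes <- c("male", "female")
  eths <- c("dutch", "surinamese", "other")
  strata <- list()
  add <- function(sex, eth, ses)
    strata[[length(strata) + 1L]] <<- list(sex = sex, ethnicity = eth,
                                           ses = ses)
  for (s in sexes) {
    add(s, "all", "all")
    if ("ethnicity" %in% by) for (e in eths) add(s, e, "all")
    if ("ses" %in% by) for (q in 1:5) add(s, "all", as.character(q))
    if (cross && all(c("ethnicity", "ses") %in% by))
      for (e in eths) for (q in 1:5) add(s, e, as.character(q))
  }
  strata
}

.stratum_index <- function(d, st) {
  i <- d$sex == st$sex
  if (st$ethnicity != "all") i <- i & d$ethnicity == st$ethnicity
  if (st$ses != "all") i <- i & !is.na(d$ses_quintile) &
      d$ses_quintile == as.integer(st$ses)
  which(i)
}

#' @export
print.score2_validation <- function(x, ...) {
  cat("SCORE2 external validation: n =", x$n, ", m =", x$m,
      "imputations, horizon", x$horizon, "y\n")
  ov <- x$results[x$results$ethnicity == "all" & x$results$ses == "all", ]
  for (k in seq_len(nrow(ov)))
    cat(sprintf("  %-6s %-9s OE = %.2f (%.2f-%.2f)%s\n",
                ov$sex[k], ov$region[k], ov$oe[k], ov$oe_lo[k], ov$oe_hi[k],
                if (is.finite(ov$c[k]))
                  sprintf(", C = %.3f (%.3f-%.3f)",
                          ov$c[k], ov$c_lo[k], ov$c_hi[k]) else ""))
  invisible(x)
}

#' @export
summary.score2_validation <- function(object, ...) {
  r <- object$results
  cat("Strata evaluated:", nrow(r), "rows;",
      sum(!r$evaluable), "below the", object$min_events, "event gate\n")
  print(r[, c("sex", "ethnicity", "ses", "region", "n", "events",
              "oe", "oe_lo", "oe_hi", "c", "evaluable")],
        digits = 3, row.names = FALSE)
  invisible(r)
}

#' @export
as.data.frame.score2_validation <- function(x, ...) x$results

#' Best-fitting region model per stratum
#'
#' For every evaluable stratum, the region whose pooled observed/expected
#' ratio is nearest 1 on the log scale (argmin |log OE|); ties break toward
#' the lower-risk region.
#'
#' @param x A \code{score2_validation} evaluated on several regions, or its
#'   results data.frame.
#' @param tie_tol Log-scale tolerance within which OEs count as tied.
#' @return data.frame with one row per stratum and the selected
#'   \code{best_region}.
#' @export
select_best_region <- function(x, tie_tol = 1e-8) {
  r <- if (inherits(x, "score2_validation")) x$results else x
  key <- interaction(r$sex, r$ethnicity, r$ses, drop = TRUE)
  out <- lapply(split(r, key), function(g) {
    g <- g[is.finite(g$oe) & g$oe > 0, , drop = FALSE]
    if (!nrow(g)) return(NULL)
    d <- abs(log(g$oe))
    cand <- which(d <= min(d) + tie_tol)
    ordv <- match(g$region, score2_regions)
    best <- cand[which.min(ordv[cand])]
    data.frame(sex = g$sex[1], ethnicity = g$ethnicity[1], ses = g$ses[1],
               best_region = g$region[best], best_oe = g$oe[best],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(out) <- NULL
  out
}

#' Treatment-eligibility shift from region reassignment
#'
#' Share of individuals whose predicted risk meets the age-specific upper
#' (very-high-risk) treatment threshold under the low-risk model versus
#' under per-stratum assigned region models, by sex. Use
#' \code{use_upper = FALSE} for the lower (high-risk) threshold instead.
#'
#' @param data Completed analysis data.frame (no missing risk factors),
#'   e.g. one imputation from a \code{score2_validation}.
#' @param model A \code{score2_model}.
#' @param assignment data.frame from \code{\link{select_best_region}}, or a
#'   function \code{(sex, ethnicity, ses) -> region}.
#' @param use_upper Use the upper threshold (default) or the lower one.
#' @return data.frame by sex with \code{pct_low_model},
#'   \code{pct_assigned}, in percent.
#' @export
eligibility_shift <- function(data, model, assignment, use_upper = TRUE) {
  all_pred <- predict(model, data, region = "all")
  assign_region <- if (is.function(assignment)) {
    assignment(data$sex, data$ethnicity, data$ses_quintile)
  } else {
    a <- assignment
    key <- paste(a$sex, a$ethnicity, a$ses, sep = "|")
    lookup <- function(sex, eth, ses) {
      for (k in c(paste(sex, eth, ses, sep = "|"),
                  paste(sex, eth, "all", sep = "|"),
                  paste(sex, "all", ses, sep = "|"),
                  paste(sex, "all", "all", sep = "|"))) {
        j <- match(k, key)
        if (!is.na(j)) return(a$best_region[j])
      }
      "low"
    }
    mapply(lookup, data$sex, data$ethnicity,
           as.character(data$ses_quintile))
  }
  thr <- ifelse(data$age < 50, if (use_upper) 0.075 else 0.025,
                if (use_upper) 0.10 else 0.05)
  p_low <- all_pred[["low"]]
  p_assigned <- all_pred[cbind(seq_len(nrow(data)),
                               match(assign_region, names(all_pred)))]
  out <- do.call(rbind, lapply(c("male", "female"), function(s) {
    i <- data$sex == s
    data.frame(sex = s,
               pct_low_model = 100 * mean(p_low[i] >= thr[i]),
               pct_assigned = 100 * mean(p_assigned[i] >= thr[i]))
  }))
  out
}

#' Sensitivity analyses
#'
#' Re-runs the core validation under the study's four sensitivity designs:
#' (1) restricted to persons with at least one actually measured lab value;
#' (2) restricted to a caller-supplied subpopulation, with and without
#' imputation of the missing income quintile; (3) in entry-age strata 40-49
#' and 50-69 (each carrying its own treatment-threshold pair); and (4) the
#' outcome proxy: the fraction of CVD-event cases with a recorded
#' statin-plus-antithrombotic start.
#'
#' @param cohort Raw cohort data.frame.
#' @param model A \code{score2_model}.
#' @param subpop Logical vector over cohort rows for analysis (2); defaults
#'   to the lowest two income quintiles as an urban-core stand-in.
#' @param m,seed Imputation count and seed for the re-runs.
#' @return Named list with elements \code{measured_subset},
#'   \code{subpopulation}, \code{age_strata}, \code{outcome_proxy}.
#' @export
sensitivity_suite <- function(cohort, model = score2_model(), subpop = NULL,
                              m = 5, seed = 1L) {
  run <- function(cohort, subset = NULL, impute_ses = TRUE)
    score2_validate(cohort, model, regions = "low", by = character(0),
                    m = m, seed = seed, compute_c = FALSE,
                    impute_ses = impute_ses, subset = subset)$results

  measured <- !is.na(cohort$sbp) | !is.na(cohort$tchol) | !is.na(cohort$hdl)
  s1 <- run(cohort, subset = measured)

  if (is.null(subpop))
    subpop <- !is.na(cohort$ses_quintile) & cohort$ses_quintile <= 2
  s2 <- list(with_ses_imputation = run(cohort, subset = subpop),
             without_ses_imputation = run(cohort, subset = subpop,
                                          impute_ses = FALSE))

  built <- build_analysis_cohort(cohort)
  age <- built$data$age
  young <- built$data$person_id[age < 50]
  s3 <- list(
    age_40_50 = run(cohort, subset = cohort$person_id %in% young),
    age_50_70 = run(cohort, subset = !cohort$person_id %in% young),
    thresholds = data.frame(stratum = c("age_40_50", "age_50_70"),
                            lower = c(0.025, 0.05), upper = c(0.075, 0.10)))

  cases <- built$data$status == "cvd_event"
  s4 <- list(n_cases = sum(cases),
             proxy_fraction = mean(built$data$med_proxy_start[cases],
                                   na.rm = TRUE))

  list(measured_subset = s1, subpopulation = s2, age_strata = s3,
       outcome_proxy = s4)
}
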