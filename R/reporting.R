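#' Forest plot of observed/expected ratios by stratum
#'
#' One row per stratum, one point (with CI whiskers) per region model, on a
#' log OE axis with a reference line at 1. Base-graphics; deterministic for
#' a given result.
#'
#' @param x A \code{score2_validation}.
#' @param regions Regions to draw (default: all present).
#' @param ... Passed to \code{plot}.
#' @export
plot.score2_validation <- function(x, regions = NULL, ...) {
  r <- x$results
  if (is.null(regions)) regions <- unique(r$region)
  r <- r[r$region %in% regions & is.finite(r$oe), , drop = FALSE]
  if (!nrow(r)) stop("nothing to plot")
  r$label <- paste(r$sex,
                   ifelse(r$ethnicity == "all", "", r$ethnicity),
                   ifelse(r$ses == "all", "", paste0("SES", r$ses)))
  labs <- unique(r$label)
  ypos <- match(r$label, rev(labs))
  cols <- stats::setNames(grDevices::hcl.colors(max(2L, length(regions)),
                                                "Dark 2")[seq_along(regions)],
                          regions)
  off <- seq(-0.25, 0.25, length.out = length(regions))
  names(off) <- regions
  xlim <- range(c(r$oe_lo, r$oe_hi, 1), na.rm = TRUE, finite = TRUE)
  graphics::plot(NA, xlim = xlim, ylim = c(0.5, length(labs) + 0.5),
                 log = "x", yaxt = "n", xlab = "observed / expected (log scale)",
                 ylab = "", ...)
  graphics::axis(2, at = seq_along(labs), labels = rev(labs), las = 1,
                 cex.axis = 0.7)
  graphics::abline(v = 1, lty = 2, col = "grey40")
  for (k in seq_len(nrow(r))) {
    y <- ypos[k] + off[r$region[k]]
    graphics::segments(r$oe_lo[k], y, r$oe_hi[k], y,
                       col = cols[r$region[k]])
    graphics::points(r$oe[k], y, pch = 19, col = cols[r$region[k]])
  }
  graphics::legend("topright", legend = regions, col = cols[regions],
                   pch = 19, bty = "n", cex = 0.8)
  invisible(x)
}

#' Plot a calibration curve
#'
#' Decile points with CI whiskers, the smoothed curve, and the identity
#' line.
#'
#' @param x A \code{\link{calibration_curve}}.
#' @param ... Passed to \code{plot}.
#' @export
plot.calibration_curve <- function(x, ...) {
  b <- x$bins
  lim <- c(0, max(b$mean_predicted, b$ci_hi, na.rm = TRUE) * 1.05)
  graphics::plot(b$mean_predicted, b$observed, xlim = lim, ylim = lim,
                 pch = 19, xlab = "mean predicted risk",
                 ylab = sprintf("observed incidence at %g y", x$horizon),
                 ...)
  graphics::segments(b$mean_predicted, b$ci_lo, b$mean_predicted, b$ci_hi)
  graphics::abline(0, 1, lty = 2, col = "grey40")
  if (!is.null(x$loess))
    graphics::lines(x$loess$predicted, x$loess$observed, col = "firebrick")
  invisible(x)
}

#' Run manifest
#'
#' Metadata identifying a validation run: seed, package version, result
#' checksum and timestamp; embedded in written reports so that figures and
#' tables are traceable to the run that produced them.
#'
#' @param x A \code{score2_validation}.
#' @return Named list.
#' @export
run_manifest <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  utils::write.csv(format(x$results, digits = 10), tf, row.names = FALSE)
  list(seed = x$seed, m = x$m, horizon = x$horizon, n = x$n,
       package_version = as.character(utils::packageVersion("score2val")),
       results_md5 = unname(tools::md5sum(tf)),
       timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE))
}

#' Write a validation report to disk
#'
#' Emits a tidy CSV of every stratum-by-region estimate, a JSON manifest,
#' a Markdown summary, and (optionally) a forest-plot PNG. Every plotted
#' value appears in the CSV; two renders of the same result produce
#' identical CSV bytes.
#'
#' @param x A \code{score2_validation}.
#' @param dir Output directory (created if needed).
#' @param figures Also write the forest-plot PNG.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(x, dir, figures = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- run_manifest(x)
  paths <- c(
    results = file.path(dir, "results.csv"),
    manifest = file.path(dir, "manifest.json"),
    summary = file.path(dir, "summary.md"))
  utils::write.csv(format(x$results, digits = 10), paths["results"],
                   row.names = FALSE)
  jsonlite::write_json(man, paths["manifest"], auto_unbox = TRUE,
                       pretty = TRUE)
  ov <- x$results[x$results$ethnicity == "all" & x$results$ses == "all", ]
  md <- c("# SCORE2 external validation report",
          "", sprintf("- n = %d, m = %d imputations, horizon %g y, seed %d",
                      x$n, x$m, x$horizon, x$seed),
          sprintf("- results checksum: %s", man$results_md5), "",
          "| sex | region | OE (95% CI) | C (95% CI) |",
          "|---|---|---|---|",
          sprintf("| %s | %s | %.2f (%.2f-%.2f) | %s |",
                  ov$sex, ov$region, ov$oe, ov$oe_lo, ov$oe_hi,
                  ifelse(is.finite(ov$c),
                         sprintf("%.3f (%.3f-%.3f)", ov$c, ov$c_lo, ov$c_hi),
                         "-")))
  writeLines(md, paths["summary"])
  if (figures) {
    paths["forest"] <- file.path(dir, "forest.png")
    grDevices::png(paths["forest"], width = 900, height = 700)
    plot(x, main = "OE-ratio by stratum and region model")
    grDevices::dev.off()
  }
  invisible(paths)
}
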