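#' End-to-end agreement analysis of a measurement table
#'
#' Reads a long-format delimited file, fits the two-way random effects model,
#' and assembles the standard agreement report: design dimensions, per-observer
#' summaries, LOAM estimate with confidence interval, Jones-style comparison
#' limits, the three standard deviations with confidence intervals, ICC(A,1)
#' with confidence interval, and any negative-variance warnings. Every number
#' in the report is taken directly from the fitted [loam] object — nothing is
#' re-derived in the report layer.
#'
#' @param file path to a CSV/TSV file; see [read_agreement_table()].
#' @param columns column map; see [read_agreement_table()].
#' @param unit optional measurement unit.
#' @param level confidence level.
#' @param loam_level inner coverage of the limits.
#' @param json optional path: write the report as JSON.
#' @param plot optional path (`.png` or `.pdf`): write the agreement plot. A
#'   plotting failure degrades to a warning; the report is still returned.
#' @param residuals_to optional path: write the model residuals as CSV for
#'   external diagnostics.
#' @return A list of class `loam_report` with elements `dims`, `unit`,
#'   `observer_summary`, `loam`, `jones`, `sigma_A`, `sigma_B`, `sigma_E`,
#'   `icc`, `negative_components`, `fit` (the underlying [loam] object).
#' @export
loam_report <- function(file, columns, unit = NULL, level = 0.95,
                        loam_level = 0.95, json = NULL, plot = NULL,
                        residuals_to = NULL) {
  data <- read_agreement_table(file, columns = columns, unit = unit)
  fit <- loam(data, level = level, loam_level = loam_level)

  iv <- function(x) list(point = x$point, lower = x$lower, upper = x$upper,
                         level = x$level, method = x$method,
                         flags = as.list(x$flags))
  rep_out <- list(
    dims = as.list(fit$dims),
    unit = unit,
    observer_summary = observer_summary(data, "observer"),
    loam = iv(fit$loam),
    jones = fit$jones,
    sigma_A = iv(fit$sigma_A),
    sigma_B = iv(fit$sigma_B),
    sigma_E = iv(fit$sigma_E),
    icc = iv(fit$icc),
    negative_components = names(which(fit$vc$negative)),
    fit = fit)
  class(rep_out) <- "loam_report"

  if (!is.null(json)) {
    jsonlite::write_json(rep_out[setdiff(names(rep_out), "fit")], json,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  if (!is.null(residuals_to)) {
    utils::write.csv(
      cbind(as.data.frame(data), residual = residuals(fit),
            fitted = fitted(fit)),
      residuals_to, row.names = FALSE)
  }
  if (!is.null(plot)) {
    ok <- tryCatch({
      if (grepl("\\.pdf$", plot)) grDevices::pdf(plot, width = 7, height = 5)
      else grDevices::png(plot, width = 1400, height = 1000, res = 200)
      on.exit(grDevices::dev.off(), add = TRUE)
      plot(fit)
      TRUE
    }, error = function(e) {
      warning("agreement plot failed (", conditionMessage(e),
              "); report produced without plot")
      FALSE
    })
    if (!ok) rep_out$plot_failed <- TRUE
  }
  rep_out
}

#' @export
print.loam_report <- function(x, digits = 3, ...) {
  print(summary(x$fit), digits = digits)
  invisible(x)
}
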