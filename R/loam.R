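#' Fit limits of agreement with the mean
#'
#' Fits the additive two-way random effects model
#' \deqn{Y_{ijk} = \mu + A_i + B_j + E_{ijk},}
#' with independent zero-mean Gaussian subject effects \eqn{A_i}, observer
#' effects \eqn{B_j} and residuals \eqn{E_{ijk}}, to a balanced agreement
#' dataset (`a` subjects, `b` observers, `c` replicates per cell), and returns
#' the full agreement analysis: ANOVA variance components, the LOAM point
#' estimate with its Graybill-Wang confidence interval, the Jones-style
#' comparison limits, confidence intervals for \eqn{\sigma_A}, \eqn{\sigma_B}
#' and \eqn{\sigma_E}, and ICC(A,1) with an approximate confidence interval.
#'
#' The limits of agreement with the mean are the symmetric limits within which
#' a stated fraction (95% by default) of differences between an individual
#' measurement and the subject-specific mean are expected to fall. Unlike the
#' earlier residual-only construction, they include inter-observer variation.
#'
#' @param x an [agreement_data] object, a long-format data frame, or a formula
#'   `value ~ subject + observer` (optionally `+ replicate`) together with
#'   `data`.
#' @param ... passed between methods.
#' @return An object of class `loam`; see [print.loam()], [summary.loam()],
#'   [coef.loam()], [confint.loam()], [plot.loam()], [simulate.loam()],
#'   [residuals.loam()].
#'
#' @examples
#' set.seed(1)
#' d <- simulate_loam_data(a = 30, b = 6, c = 2, mu = 20,
#'                         sigma_A = 4, sigma_B = 0.8, sigma_E = 1)
#' fit <- loam(d)
#' fit
#' summary(fit)
#' coef(fit)
#' confint(fit)
#' @export
loam <- function(x, ...) UseMethod("loam")

#' @rdname loam
#' @param level confidence level for every interval reported.
#' @param loam_level inner coverage of the limits themselves (default 0.95,
#'   i.e. the conventional 1.96 multiplier); independent of `level`.
#' @export
loam.agreement_data <- function(x, level = 0.95, loam_level = 0.95, ...) {
  ss <- sums_of_squares(x)
  vc <- variance_components(ss)
  z <- loam_z(loam_level)
  est <- loam_ci(ss, level = level, loam_level = loam_level)
  out <- list(
    data = x,
    dims = dims(x),
    unit = attr(x, "unit"),
    ss = ss,
    vc = vc,
    loam = est,
    jones = jones_loam(ss, z = z),
    sigma_A = sigma_A_ci(vc, ss, level = level),
    sigma_B = sigma_B_ci(vc, ss, level = level),
    sigma_E = sigma_E_ci(ss, level = level),
    icc = icc_ci(ss, level = level),
    level = level,
    loam_level = loam_level,
    z = z,
    grand_mean = mean(x$value))
  class(out) <- "loam"
  out
}

#' @rdname loam
#' @param subject,observer,value,replicate column names in `x` (data frame
#'   method).
#' @param unit optional measurement unit label.
#' @export
loam.data.frame <- function(x, subject = "subject", observer = "observer",
                            value = "value", replicate = NULL, unit = NULL,
                            level = 0.95, loam_level = 0.95, ...) {
  d <- agreement_data(subject = x[[subject]], observer = x[[observer]],
                      value = x[[value]],
                      replicate = if (!is.null(replicate)) x[[replicate]],
                      unit = unit)
  loam(d, level = level, loam_level = loam_level, ...)
}

#' @rdname loam
#' @param data data frame supplying the formula variables.
#' @export
loam.formula <- function(x, data, unit = NULL, level = 0.95,
                         loam_level = 0.95, ...) {
  tms <- stats::terms(x, data = data)
  vars <- attr(tms, "term.labels")
  if (length(vars) < 2L || length(vars) > 3L)
    stop("formula must be value ~ subject + observer [+ replicate]")
  resp <- all.vars(x)[1]
  d <- agreement_data(subject = data[[vars[1]]], observer = data[[vars[2]]],
                      value = data[[resp]],
                      replicate = if (length(vars) == 3L) data[[vars[3]]],
                      unit = unit)
  loam(d, level = level, loam_level = loam_level, ...)
}

fmt_ci <- function(iv, digits) {
  if (length(iv$flags) && "undefined" %in% iv$flags)
    return("NA (undefined: nonpositive variance estimate)")
  sprintf("%s (%s, %s)", format(iv$point, digits = digits),
          format(iv$lower, digits = digits), format(iv$upper, digits = digits))
}

#' @export
print.loam <- function(x, digits = 3, ...) {
  u <- if (!is.null(x$unit)) paste0(" ", x$unit) else ""
  cat(sprintf("Limits of agreement with the mean (two-way random effects model)\n"))
  cat(sprintf("  a = %d subjects, b = %d observers, c = %d replicate(s)\n\n",
              x$dims["a"], x$dims["b"], x$dims["c"]))
  cat(sprintf("  %.0f%% LOAM: +/- %s%s  (%.0f%% CI: %s, %s)\n",
              100 * x$loam_level, format(x$loam$point, digits = digits), u,
              100 * x$level,
              format(x$loam$lower, digits = digits),
              format(x$loam$upper, digits = digits)))
  cat(sprintf("  ICC(A,1): %s\n", fmt_ci(x$icc, digits)))
  invisible(x)
}

#' Summary of a fitted LOAM analysis
#'
#' @param object a [loam] fit.
#' @param ... unused.
#' @return An object of class `summary.loam` with the estimate table and
#'   per-observer summaries.
#' @export
summary.loam <- function(object, ...) {
  structure(list(fit = object,
                 by_observer = observer_summary(object$data, "observer")),
            class = "summary.loam")
}

#' @export
print.summary.loam <- function(x, digits = 3, ...) {
  f <- x$fit
  u <- if (!is.null(f$unit)) paste0(" (", f$unit, ")") else ""
  print(f, digits = digits)
  cat(sprintf("\n  Jones-style %.0f%% limits (residual only): +/- %s\n",
              100 * f$loam_level, format(f$jones, digits = digits)))
  cat(sprintf("\nStandard deviations%s with %.0f%% CIs:\n", u, 100 * f$level))
  cat(sprintf("  sigma_A (inter-subject):  %s\n", fmt_ci(f$sigma_A, digits)))
  cat(sprintf("  sigma_B (inter-observer): %s\n", fmt_ci(f$sigma_B, digits)))
  cat(sprintf("  sigma_E (intra-observer): %s\n", fmt_ci(f$sigma_E, digits)))
  if (any(f$vc$negative))
    cat("\n  Note: negative ANOVA variance estimate(s) for",
        paste(names(which(f$vc$negative)), collapse = ", "),
        "- reported unclipped; consider whether negatively correlated",
        "measurements are plausible or whether more observers are needed.\n")
  cat("\nMeasurements conditional on observer:\n")
  print(x$by_observer, digits = digits, row.names = FALSE)
  invisible(x)
}

#' @export
coef.loam <- function(object, ...) {
  c(mu = object$grand_mean,
    sigma2_A = object$vc$sigma2_A,
    sigma2_B = object$vc$sigma2_B,
    sigma2_E = object$vc$sigma2_E)
}

#' Confidence intervals from a fitted LOAM analysis
#'
#' @param object a [loam] fit.
#' @param parm which intervals to return (default: all).
#' @param level ignored; intervals are computed at the level requested in
#'   [loam()] (re-fit to change it).
#' @param ... unused.
#' @return A matrix with columns `estimate`, `lower`, `upper` and one row per
#'   parameter.
#' @export
confint.loam <- function(object,
                         parm = c("loam", "sigma_A", "sigma_B", "sigma_E",
                                  "icc"),
                         level = NULL, ...) {
  if (!is.null(level) && !isTRUE(all.equal(level, object$level)))
    warning("intervals were computed at level ", object$level,
            "; re-fit with loam(..., level=) to change it")
  parm <- match.arg(parm, several.ok = TRUE)
  rows <- lapply(parm, function(p) {
    iv <- object[[p]]
    c(estimate = iv$point, lower = iv$lower, upper = iv$upper)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- parm
  out
}

#' Residuals of the two-way random effects fit
#'
#' Classical ANOVA residuals
#' \eqn{y_{ijk} - \bar y_{i..} - \bar y_{.j.} + \bar y_{...}}, exported so the
#' usual model diagnostics (residuals vs fitted, normal QQ) can be run with
#' standard tools.
#'
#' @param object a [loam] fit.
#' @param ... unused.
#' @return Numeric vector aligned with `object$data` rows.
#' @export
residuals.loam <- function(object, ...) {
  d <- object$data
  mi <- tapply(d$value, d$subject, mean)
  mj <- tapply(d$value, d$observer, mean)
  as.numeric(d$value - mi[d$subject] - mj[d$observer] + mean(d$value))
}

#' @export
fitted.loam <- function(object, ...) {
  object$data$value - residuals.loam(object)
}

#' Simulate datasets from a fitted LOAM model
#'
#' Parametric simulation from the fitted two-way random effects model at the
#' fitted design dimensions. Negative variance component estimates cannot
#' parameterise a Gaussian simulator and are clamped to zero with a warning
#' (this is the one place the package clamps; estimates themselves are never
#' truncated).
#'
#' @param object a [loam] fit.
#' @param nsim number of datasets.
#' @param seed optional seed passed to [set.seed()].
#' @param ... unused.
#' @return A list of `nsim` [agreement_data] objects.
#' @export
simulate.loam <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  vc <- object$vc
  if (any(vc$negative)) {
    warning("negative variance component estimate(s) clamped to zero for simulation")
  }
  d <- object$dims
  lapply(seq_len(nsim), function(i)
    simulate_loam_data(a = d[["a"]], b = d[["b"]], c = d[["c"]],
                       mu = object$grand_mean,
                       sigma_A = sqrt(max(vc$sigma2_A, 0)),
                       sigma_B = sqrt(max(vc$sigma2_B, 0)),
                       sigma_E = sqrt(vc$sigma2_E),
                       unit = object$unit))
}
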