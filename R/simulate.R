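#' Simulate a balanced agreement dataset
#'
#' Draws one dataset from the two-way random effects model
#' \eqn{Y_{ijk} = \mu + A_i + B_j + E_{ijk}} with
#' \eqn{A_i \sim N(0, \sigma_A^2)}, \eqn{B_j \sim N(0, \sigma_B^2)} and
#' \eqn{E_{ijk} \sim N(0, \sigma_E^2)}, all independent, on a balanced design
#' of `a` subjects, `b` observers and `c` replicates per cell.
#'
#' @param a number of subjects (>= 2).
#' @param b number of observers (>= 2).
#' @param c replicates per subject-by-observer cell (>= 1).
#' @param mu overall mean.
#' @param sigma_A,sigma_B,sigma_E nonnegative standard deviations of the
#'   subject, observer and residual effects.
#' @param seed optional seed; when supplied, [set.seed()] is called first so
#'   the same seed reproduces the same dataset.
#' @param unit optional measurement unit label.
#' @return An [agreement_data] object.
#' @examples
#' d <- simulate_loam_data(a = 10, b = 4, c = 2, mu = 50,
#'                         sigma_A = 5, sigma_B = 1, sigma_E = 0.5, seed = 7)
#' dims(d)
#' @export
simulate_loam_data <- function(a, b, c = 1, mu = 0,
                               sigma_A = 1, sigma_B = 1, sigma_E = 1,
                               seed = NULL, unit = NULL) {
  stopifnot(a >= 2, b >= 2, c >= 1,
            sigma_A >= 0, sigma_B >= 0, sigma_E >= 0)
  if (!is.null(seed)) set.seed(seed)
  A <- stats::rnorm(a, 0, sigma_A)
  B <- stats::rnorm(b, 0, sigma_B)
  idx <- expand.grid(replicate = seq_len(c), observer = seq_len(b),
                     subject = seq_len(a))
  y <- mu + A[idx$subject] + B[idx$observer] +
    stats::rnorm(nrow(idx), 0, sigma_E)
  agreement_data(subject = sprintf("S%02d", idx$subject),
                 observer = sprintf("O%02d", idx$observer),
                 value = y,
                 replicate = idx$replicate,
                 unit = unit)
}

#' Monte Carlo coverage study for the package's confidence intervals
#'
#' Repeatedly simulates balanced datasets from the two-way random effects model
#' at known parameter values, fits the ANOVA estimators, forms the requested
#' confidence interval, and records whether it covers the true value:
#' the true upper LOAM ([loam_population()]) for `target = "loam"`, the true
#' standard deviation for the `sigma_*` targets, or the true
#' \eqn{\sigma_A^2/(\sigma_A^2+\sigma_B^2+\sigma_E^2)} for `target = "icc"`.
#'
#' Replicates where the requested interval is undefined (nonpositive variance
#' component estimate, which can happen for the delta-method intervals) are
#' excluded from the coverage denominator and reported as an exclusion rate —
#' they are informative about the design, not silently dropped.
#'
#' A single root `seed` initialises the generator once; replicates are then
#' drawn sequentially, so a study is reproducible from (spec, `n_reps`,
#' `seed`).
#'
#' @param a,b,c design dimensions.
#' @param mu,sigma_A,sigma_B,sigma_E true model parameters.
#' @param n_reps number of simulated datasets (>= 100).
#' @param target which interval to study: `"loam"`, `"sigma_A"`, `"sigma_B"`,
#'   `"sigma_E"` or `"icc"`.
#' @param level nominal confidence level.
#' @param loam_level inner coverage of the limits (for `target = "loam"`).
#' @param seed root seed for the whole study.
#' @return An object of class `coverage_result`: list with `target`, `n_reps`,
#'   `n_used`, `n_excluded`, `empirical_coverage`, `mean_width`, `mc_se`
#'   (binomial Monte Carlo standard error), `true_value`, `level`.
#' @examples
#' cs <- coverage_study(a = 15, b = 5, mu = 0, sigma_A = 1, sigma_B = 0.3,
#'                      sigma_E = 0.6, n_reps = 200, target = "sigma_E",
#'                      seed = 42)
#' cs
#' @export
coverage_study <- function(a, b, c = 1, mu = 0, sigma_A = 1, sigma_B = 0.5,
                           sigma_E = 0.5, n_reps = 1000,
                           target = c("loam", "sigma_A", "sigma_B", "sigma_E",
                                      "icc"),
                           level = 0.95, loam_level = 0.95, seed = NULL) {
  target <- match.arg(target)
  n_reps <- as.integer(n_reps)
  stopifnot(n_reps >= 100)
  if (!is.null(seed)) set.seed(seed)

  truth <- switch(target,
    loam = loam_population(sigma_B^2, sigma_E^2, b = b, c = c,
                           z = loam_z(loam_level)),
    sigma_A = sigma_A,
    sigma_B = sigma_B,
    sigma_E = sigma_E,
    icc = sigma_A^2 / (sigma_A^2 + sigma_B^2 + sigma_E^2))

  covered <- logical(n_reps)
  widths <- numeric(n_reps)
  usable <- logical(n_reps)
  for (r in seq_len(n_reps)) {
    dat <- simulate_loam_data(a = a, b = b, c = c, mu = mu,
                              sigma_A = sigma_A, sigma_B = sigma_B,
                              sigma_E = sigma_E)
    ss <- sums_of_squares(dat)
    iv <- switch(target,
      loam = loam_ci(ss, level = level, loam_level = loam_level),
      sigma_A = sigma_A_ci(variance_components(ss), ss, level = level),
      sigma_B = sigma_B_ci(variance_components(ss), ss, level = level),
      sigma_E = sigma_E_ci(ss, level = level),
      icc = icc_ci(ss, level = level))
    if ("undefined" %in% iv$flags) {
      usable[r] <- FALSE
    } else {
      usable[r] <- TRUE
      covered[r] <- iv$lower <= truth && truth <= iv$upper
      widths[r] <- iv$upper - iv$lower
    }
  }
  n_used <- as.integer(sum(usable))
  p <- sum(covered[usable]) / n_used
  structure(list(target = target, n_reps = n_reps, n_used = n_used,
                 n_excluded = n_reps - n_used,
                 empirical_coverage = p,
                 mean_width = mean(widths[usable]),
                 mc_se = sqrt(p * (1 - p) / n_used),
                 true_value = truth, level = level),
            class = "coverage_result")
}

#' @export
print.coverage_result <- function(x, digits = 4, ...) {
  cat(sprintf("Coverage study: %s interval, nominal %.0f%%\n",
              x$target, 100 * x$level))
  cat(sprintf("  replicates: %d (%d excluded as undefined)\n",
              x$n_reps, x$n_excluded))
  cat(sprintf("  empirical coverage: %s (MC SE %s)\n",
              format(x$empirical_coverage, digits = digits),
              format(x$mc_se, digits = 2)))
  cat(sprintf("  mean interval width: %s; true value: %s\n",
              format(x$mean_width, digits = digits),
              format(x$true_value, digits = digits)))
  invisible(x)
}
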