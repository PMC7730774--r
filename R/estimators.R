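#' Two-way ANOVA sums of squares for a balanced agreement dataset
#'
#' Decomposes the total sum of squared deviations from the grand mean into a
#' subject part, an observer part and a residual part for the balanced crossed
#' design:
#' \deqn{SSA = bc \sum_i (\bar y_{i..} - \bar y_{...})^2, \quad
#'       SSB = ac \sum_j (\bar y_{.j.} - \bar y_{...})^2, \quad
#'       SSE = \sum_{ijk} (y_{ijk} - \bar y_{i..} - \bar y_{.j.} + \bar y_{...})^2,}
#' with degrees of freedom \eqn{\nu_A = a-1}, \eqn{\nu_B = b-1} and
#' \eqn{\nu_E = abc - a - b + 1} (which is \eqn{(a-1)(b-1)} when `c = 1`).
#'
#' The residual sum of squares is computed from its defining residuals and then
#' cross-checked against `total SS - SSA - SSB`; disagreement beyond numerical
#' tolerance is an internal error.
#'
#' @param data an [agreement_data] object.
#' @return An object of class `loam_ss`: a list with elements `SSA`, `SSB`,
#'   `SSE`, `nu_A`, `nu_B`, `nu_E`, `MSA`, `MSB`, `MSE`, `N`, and `dims`.
#' @examples
#' d <- agreement_data(c(1, 1, 2, 2), c("X", "Y", "X", "Y"), c(1, 2, 3, 5))
#' sums_of_squares(d)
#' @export
sums_of_squares <- function(data) {
  stopifnot(inherits(data, "agreement_data"))
  d <- dims(data)
  a <- d[["a"]]; b <- d[["b"]]; cc <- d[["c"]]
  y <- data$value
  gm <- mean(y)
  mi <- tapply(y, data$subject, mean)   # subject means ybar_i..
  mj <- tapply(y, data$observer, mean)  # observer means ybar_.j.

  SSA <- b * cc * sum((mi - gm)^2)
  SSB <- a * cc * sum((mj - gm)^2)
  resid <- y - mi[data$subject] - mj[data$observer] + gm
  SSE <- sum(resid^2)

  tot <- sum((y - gm)^2)
  if (abs(SSA + SSB + SSE - tot) > 1e-8 * max(1, tot))
    stop("internal error: sums of squares do not decompose the total SS")

  nu_A <- a - 1L
  nu_B <- b - 1L
  nu_E <- a * b * cc - a - b + 1L
  structure(list(SSA = SSA, SSB = SSB, SSE = SSE,
                 nu_A = nu_A, nu_B = nu_B, nu_E = nu_E,
                 MSA = SSA / nu_A, MSB = SSB / nu_B, MSE = SSE / nu_E,
                 N = a * b * cc, dims = d),
            class = "loam_ss")
}

#' @export
print.loam_ss <- function(x, digits = 4, ...) {
  tab <- data.frame(
    term = c("subject", "observer", "residual"),
    SS = c(x$SSA, x$SSB, x$SSE),
    df = c(x$nu_A, x$nu_B, x$nu_E),
    MS = c(x$MSA, x$MSB, x$MSE))
  cat("Two-way ANOVA decomposition (balanced crossed design)\n")
  print(tab, digits = digits, row.names = FALSE)
  invisible(x)
}

#' ANOVA moment estimates of the variance components
#'
#' Closed-form unbiased estimators of the subject, observer and residual
#' variances under the two-way random effects model:
#' \deqn{\hat\sigma^2_A = (MSA - MSE)/(bc), \quad
#'       \hat\sigma^2_B = (MSB - MSE)/(ac), \quad
#'       \hat\sigma^2_E = MSE.}
#'
#' \eqn{\hat\sigma^2_A} and \eqn{\hat\sigma^2_B} can be negative by sampling
#' variation (or genuine model misspecification). Negative estimates are
#' returned as computed and flagged, never truncated to zero: truncation would
#' bias the estimators, and a negative estimate is itself diagnostic
#' information.
#'
#' @param ss a [sums_of_squares()] result.
#' @return An object of class `loam_vc`: list with `sigma2_A`, `sigma2_B`,
#'   `sigma2_E`, logical `negative` (named flags for A and B), and `dims`.
#' @examples
#' d <- agreement_data(c(1, 1, 2, 2), c("X", "Y", "X", "Y"), c(1, 2, 3, 5))
#' variance_components(sums_of_squares(d))
#' @export
variance_components <- function(ss) {
  stopifnot(inherits(ss, "loam_ss"))
  d <- ss$dims
  a <- d[["a"]]; b <- d[["b"]]; cc <- d[["c"]]
  s2A <- (ss$MSA - ss$MSE) / (b * cc)
  s2B <- (ss$MSB - ss$MSE) / (a * cc)
  structure(list(sigma2_A = s2A, sigma2_B = s2B, sigma2_E = ss$MSE,
                 negative = c(A = s2A < 0, B = s2B < 0),
                 dims = d),
            class = "loam_vc")
}

#' @export
print.loam_vc <- function(x, digits = 4, ...) {
  cat("ANOVA variance component estimates:\n")
  cat(sprintf("  sigma^2_A (inter-subject):  %s%s\n",
              format(x$sigma2_A, digits = digits),
              if (x$negative["A"]) "  [negative]" else ""))
  cat(sprintf("  sigma^2_B (inter-observer): %s%s\n",
              format(x$sigma2_B, digits = digits),
              if (x$negative["B"]) "  [negative]" else ""))
  cat(sprintf("  sigma^2_E (intra-observer): %s\n",
              format(x$sigma2_E, digits = digits)))
  invisible(x)
}

#' LOAM point estimate
#'
#' Estimated symmetric 95% (by default) limits of agreement with the mean:
#' \deqn{\pm z \sqrt{(SSB + SSE)/N},}
#' which equals \eqn{\pm z\sqrt{\sum_{ijk}(y_{ijk}-\bar y_{i..})^2 / N}}. The
#' same expression holds for single (`c = 1`) and replicated measurements.
#'
#' @param ss a [sums_of_squares()] result.
#' @param z multiplier for the inner coverage of the limits; the conventional
#'   literal 1.96 by default. Pass `qnorm(0.975)` for the exact quantile, or
#'   set via `loam_z(level)` for other levels.
#' @return The (positive) upper limit; the lower limit is its negation.
#' @examples
#' d <- agreement_data(c(1, 1, 2, 2), c("X", "Y", "X", "Y"), c(1, 2, 3, 5))
#' loam_estimate(sums_of_squares(d))
#' @export
loam_estimate <- function(ss, z = 1.96) {
  stopifnot(inherits(ss, "loam_ss"), z > 0)
  z * sqrt((ss$SSB + ss$SSE) / ss$N)
}

#' Population LOAM under the two-way random effects model
#'
#' The true limits within which a fraction (95% for `z = 1.96`) of the
#' differences \eqn{D_{ijk} = Y_{ijk} - \bar Y_{i..}} fall:
#' \deqn{\pm z \sqrt{\frac{b-1}{b}\sigma^2_B + \frac{bc-1}{bc}\sigma^2_E}.}
#' With `c = 1` this reduces to
#' \eqn{\pm z\sqrt{(b-1)/b\,(\sigma^2_B + \sigma^2_E)}}.
#'
#' @param sigma2_B,sigma2_E true (nonnegative) observer and residual variances.
#' @param b number of observers (>= 2).
#' @param c replicates per subject-by-observer cell.
#' @param z limit multiplier; see [loam_estimate()].
#' @return The (positive) upper population limit.
#' @examples
#' loam_population(sigma2_B = 0.25, sigma2_E = 0.75, b = 4) # 1.96 * sqrt(0.75)
#' @export
loam_population <- function(sigma2_B, sigma2_E, b, c = 1, z = 1.96) {
  if (sigma2_B < 0 || sigma2_E < 0)
    stop("population variances must be nonnegative")
  stopifnot(b >= 2, c >= 1, z > 0)
  z * sqrt((b - 1) / b * sigma2_B + (b * c - 1) / (b * c) * sigma2_E)
}

#' Jones-style limits of agreement with the mean
#'
#' The earlier fixed-effects construction: \eqn{\pm z\,\hat\sigma_E}, the
#' residual standard deviation after removing both subject and observer
#' effects. It excludes inter-observer variation and therefore understates the
#' spread of individual measurements about the subject mean whenever
#' \eqn{\sigma^2_B > 0}; it is provided for comparison with [loam_estimate()].
#'
#' @inheritParams loam_estimate
#' @return The (positive) upper limit \eqn{z\sqrt{SSE/\nu_E}}.
#' @export
jones_loam <- function(ss, z = 1.96) {
  stopifnot(inherits(ss, "loam_ss"), z > 0)
  z * sqrt(ss$SSE / ss$nu_E)
}

#' Intraclass correlation ICC(A,1)
#'
#' Plug-in estimate of the intraclass correlation for absolute agreement of
#' single measurements under the two-way random effects model:
#' \deqn{\widehat{ICC}(A,1) =
#'   \hat\sigma^2_A / (\hat\sigma^2_A + \hat\sigma^2_B + \hat\sigma^2_E).}
#' When a variance component estimate is negative the ratio can fall outside
#' `[0, 1]`; it is returned as computed, with an attribute `out_of_range`.
#'
#' @param vc a [variance_components()] result.
#' @return The ICC(A,1) estimate (attribute `out_of_range` set when it falls
#'   outside the unit interval).
#' @export
icc_a1 <- function(vc) {
  stopifnot(inherits(vc, "loam_vc"))
  denom <- vc$sigma2_A + vc$sigma2_B + vc$sigma2_E
  if (denom == 0)
    stop("degenerate data: total estimated variance is zero")
  icc <- vc$sigma2_A / denom
  attr(icc, "out_of_range") <- icc < 0 || icc > 1
  icc
}

#' z multiplier for a given inner coverage level
#'
#' Returns the conventional literal 1.96 at `level = 0.95` (matching published
#' tables) and the exact normal quantile `qnorm(1 - (1 - level)/2)` otherwise.
#'
#' @param level inner coverage of the limits, in (0, 1).
#' @param exact use the exact quantile even at 0.95.
#' @return A positive scalar.
#' @export
loam_z <- function(level = 0.95, exact = FALSE) {
  stopifnot(level > 0, level < 1)
  if (!exact && isTRUE(all.equal(level, 0.95))) 1.96
  else stats::qnorm(1 - (1 - level) / 2)
}
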