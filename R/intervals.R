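#' Interval estimate container
#'
#' Light S3 container used by all confidence-interval constructors in the
#' package. When a flag (`"undefined"`, `"negative_component"`) is set the
#' bounds may be `NA` or fall outside the usual ordering; otherwise
#' `lower <= point <= upper`.
#'
#' @param point point estimate.
#' @param lower,upper interval end points.
#' @param level confidence level as requested.
#' @param method tag: one of `"graybill_wang"`, `"chi_square_exact"`,
#'   `"delta"`, `"mcgraw_wong"`.
#' @param flags character vector of flags, possibly empty.
#' @return An object of class `interval_estimate`.
#' @keywords internal
#' @export
interval_estimate <- function(point, lower, upper, level, method,
                              flags = character()) {
  structure(list(point = point, lower = lower, upper = upper,
                 level = level, method = method, flags = flags),
            class = "interval_estimate")
}

#' @export
print.interval_estimate <- function(x, digits = 4, ...) {
  cat(sprintf("%s (%d%% CI: %s, %s) [%s]%s\n",
              format(x$point, digits = digits),
              round(100 * x$level),
              format(x$lower, digits = digits),
              format(x$upper, digits = digits),
              x$method,
              if (length(x$flags)) paste0(" flags: ",
                                          paste(x$flags, collapse = ", "))
              else ""))
  invisible(x)
}

# F quantile with infinite denominator df via the exact identity
# F_{p; nu, Inf} = chisq_{p; nu} / nu (avoids relying on qf's handling of Inf).
f_inf <- function(p, nu) stats::qchisq(p, df = nu) / nu

# Graybill-Wang multipliers for the lower (l) and upper (h) bound of a
# nonnegative linear combination of variance components.
gw_multipliers <- function(nu, level) {
  alpha <- 1 - level
  list(l = 1 - 1 / f_inf(1 - alpha / 2, nu),
       h = 1 / f_inf(alpha / 2, nu) - 1)
}

#' Graybill-Wang confidence interval for the upper LOAM
#'
#' Approximate, asymmetric confidence interval for the upper limit of agreement
#' with the mean. A Graybill-Wang interval is first built for the variance
#' combination \eqn{(SSB + SSE)/N} inside the square root, then transformed by
#' square root and multiplication by `z`:
#' \deqn{\left(z\sqrt{(SSB+SSE-L)/N},\; z\sqrt{(SSB+SSE+H)/N}\right),}
#' \deqn{L = \sqrt{l_B^2 SSB^2 + l_E^2 SSE^2}, \quad
#'       H = \sqrt{h_B^2 SSB^2 + h_E^2 SSE^2},}
#' with \eqn{l_x = 1 - 1/F_{1-\alpha/2;\nu_x,\infty}} and
#' \eqn{h_x = 1/F_{\alpha/2;\nu_x,\infty} - 1}. Because \eqn{0 < l_x < 1},
#' \eqn{L \le SSB + SSE} and the lower radicand is never negative. The CI for
#' the lower LOAM is the negation of the end points.
#'
#' @param ss a [sums_of_squares()] result.
#' @param level confidence level of the interval.
#' @param loam_level inner coverage of the limits themselves (sets the `z`
#'   multiplier); independent of `level`.
#' @return An [interval_estimate] with method `"graybill_wang"`.
#' @examples
#' d <- agreement_data(c(1, 1, 2, 2), c("X", "Y", "X", "Y"), c(1, 2, 3, 5))
#' loam_ci(sums_of_squares(d))
#' @export
loam_ci <- function(ss, level = 0.95, loam_level = 0.95) {
  stopifnot(inherits(ss, "loam_ss"), ss$nu_B >= 1, ss$nu_E >= 1)
  z <- loam_z(loam_level)
  mB <- gw_multipliers(ss$nu_B, level)
  mE <- gw_multipliers(ss$nu_E, level)
  L <- sqrt(mB$l^2 * ss$SSB^2 + mE$l^2 * ss$SSE^2)
  H <- sqrt(mB$h^2 * ss$SSB^2 + mE$h^2 * ss$SSE^2)
  S <- ss$SSB + ss$SSE
  interval_estimate(point = z * sqrt(S / ss$N),
                    lower = z * sqrt(max(S - L, 0) / ss$N),
                    upper = z * sqrt((S + H) / ss$N),
                    level = level, method = "graybill_wang")
}

#' Exact confidence interval for the residual standard deviation
#'
#' Pivotal chi-square interval for \eqn{\sigma_E}: since
#' \eqn{SSE/\sigma^2_E \sim \chi^2_{\nu_E}},
#' \deqn{\left(\hat\sigma_E\sqrt{\nu_E/\chi^2_{1-\alpha/2;\nu_E}},\;
#'             \hat\sigma_E\sqrt{\nu_E/\chi^2_{\alpha/2;\nu_E}}\right)}
#' has exactly the nominal coverage under the model.
#'
#' @inheritParams loam_ci
#' @return An [interval_estimate] with method `"chi_square_exact"`.
#' @export
sigma_E_ci <- function(ss, level = 0.95) {
  stopifnot(inherits(ss, "loam_ss"), ss$nu_E >= 1)
  alpha <- 1 - level
  sE <- sqrt(ss$MSE)
  interval_estimate(
    point = sE,
    lower = sE * sqrt(ss$nu_E / stats::qchisq(1 - alpha / 2, ss$nu_E)),
    upper = sE * sqrt(ss$nu_E / stats::qchisq(alpha / 2, ss$nu_E)),
    level = level, method = "chi_square_exact")
}

#' Delta-method confidence interval for the inter-observer standard deviation
#'
#' Approximate symmetric interval
#' \deqn{\hat\sigma_B \pm \frac{z}{ac\,\hat\sigma_B}
#'   \sqrt{\frac{(ac\,\hat\sigma^2_B + \hat\sigma^2_E)^2}{2\nu_B}
#'       + \frac{(\hat\sigma^2_E)^2}{2\nu_E}}.}
#' The lower bound may be negative and is reported as computed. When
#' \eqn{\hat\sigma^2_B \le 0} the delta method is undefined (it divides by
#' \eqn{\hat\sigma_B}); the point is then reported as `NA` with flags
#' `"undefined"` and `"negative_component"` and no bounds — the negative
#' variance estimate itself should be reported and discussed instead.
#'
#' @param vc a [variance_components()] result.
#' @param ss the matching [sums_of_squares()] result.
#' @param level confidence level.
#' @return An [interval_estimate] with method `"delta"`.
#' @export
sigma_B_ci <- function(vc, ss, level = 0.95) {
  stopifnot(inherits(vc, "loam_vc"), inherits(ss, "loam_ss"))
  d <- ss$dims
  ac <- d[["a"]] * d[["c"]]
  if (vc$sigma2_B <= 0) {
    return(interval_estimate(point = NA_real_, lower = NA_real_,
                             upper = NA_real_, level = level,
                             method = "delta",
                             flags = c("undefined", "negative_component")))
  }
  z <- loam_z(level)
  sB <- sqrt(vc$sigma2_B)
  hw <- z / (ac * sB) *
    sqrt((ac * vc$sigma2_B + vc$sigma2_E)^2 / (2 * ss$nu_B) +
           vc$sigma2_E^2 / (2 * ss$nu_E))
  interval_estimate(point = sB, lower = sB - hw, upper = sB + hw,
                    level = level, method = "delta")
}

#' Delta-method confidence interval for the inter-subject standard deviation
#'
#' Approximate symmetric interval
#' \deqn{\hat\sigma_A \pm \frac{z}{bc\,\hat\sigma_A}
#'   \sqrt{\frac{(bc\,\hat\sigma^2_A + \hat\sigma^2_E)^2}{2\nu_A}
#'       + \frac{(\hat\sigma^2_E)^2}{2\nu_E}}.}
#' Undefined (flagged) when \eqn{\hat\sigma^2_A \le 0}; see [sigma_B_ci()].
#'
#' @inheritParams sigma_B_ci
#' @return An [interval_estimate] with method `"delta"`.
#' @export
sigma_A_ci <- function(vc, ss, level = 0.95) {
  stopifnot(inherits(vc, "loam_vc"), inherits(ss, "loam_ss"))
  d <- ss$dims
  bc <- d[["b"]] * d[["c"]]
  if (vc$sigma2_A <= 0) {
    return(interval_estimate(point = NA_real_, lower = NA_real_,
                             upper = NA_real_, level = level,
                             method = "delta",
                             flags = c("undefined", "negative_component")))
  }
  z <- loam_z(level)
  sA <- sqrt(vc$sigma2_A)
  hw <- z / (bc * sA) *
    sqrt((bc * vc$sigma2_A + vc$sigma2_E)^2 / (2 * ss$nu_A) +
           vc$sigma2_E^2 / (2 * ss$nu_E))
  interval_estimate(point = sA, lower = sA - hw, upper = sA + hw,
                    level = level, method = "delta")
}

#' Approximate confidence interval for ICC(A,1)
#'
#' F-based interval with a Satterthwaite denominator degrees of freedom, in the
#' style of McGraw and Wong's absolute-agreement, single-measurement ICC for
#' the two-way random model (their Case 2A). Writing \eqn{\hat r} for the
#' plug-in ICC(A,1), the Satterthwaite df of the combination
#' \eqn{a_0\,MSB + b_0\,MSE} at \eqn{\rho = \hat r} is
#' \deqn{v = \frac{(a_0 MSB + b_0 MSE)^2}
#'                {(a_0 MSB)^2/\nu_B + (b_0 MSE)^2/\nu_E},}
#' with \eqn{a_0 = b\hat r / (a(1-\hat r))} and
#' \eqn{b_0 = 1 + b\hat r (ac - 1)/(a(1-\hat r))}, and the bounds are
#' \deqn{\frac{a\,(MSA - F_L\,MSE)}{F_L\,(b\,MSB + (abc-a-b)MSE) + a\,MSA}
#'  \quad\mathrm{and}\quad
#'       \frac{a\,(F_U\,MSA - MSE)}{b\,MSB + (abc-a-b)MSE + a\,F_U\,MSA},}
#' where \eqn{F_L = F_{1-\alpha/2;\,\nu_A,\,v}} and
#' \eqn{F_U = F_{1-\alpha/2;\,v,\,\nu_A}}. For `c = 1` these are exactly the
#' published single-measurement formulas; for `c > 1` the same construction is
#' applied to the replicated-design mean squares (the coefficients follow from
#' the expected mean squares \eqn{E[MSA] = bc\,\sigma^2_A + \sigma^2_E},
#' \eqn{E[MSB] = ac\,\sigma^2_B + \sigma^2_E}, \eqn{E[MSE] = \sigma^2_E}).
#'
#' @inheritParams loam_ci
#' @return An [interval_estimate] with method `"mcgraw_wong"`. When the
#'   plug-in estimate falls outside `[0, 1)` (negative variance components)
#'   the interval is flagged `"undefined"`.
#' @export
icc_ci <- function(ss, level = 0.95) {
  stopifnot(inherits(ss, "loam_ss"))
  d <- ss$dims
  a <- d[["a"]]; b <- d[["b"]]; cc <- d[["c"]]
  vc <- variance_components(ss)
  r <- as.numeric(icc_a1(vc))
  if (r < 0 || r >= 1) {
    return(interval_estimate(point = r, lower = NA_real_, upper = NA_real_,
                             level = level, method = "mcgraw_wong",
                             flags = "undefined"))
  }
  alpha <- 1 - level
  a0 <- b * r / (a * (1 - r))
  b0 <- 1 + b * r * (a * cc - 1) / (a * (1 - r))
  v <- (a0 * ss$MSB + b0 * ss$MSE)^2 /
    ((a0 * ss$MSB)^2 / ss$nu_B + (b0 * ss$MSE)^2 / ss$nu_E)
  FL <- stats::qf(1 - alpha / 2, ss$nu_A, v)
  FU <- stats::qf(1 - alpha / 2, v, ss$nu_A)
  k  <- b * ss$MSB + (a * b * cc - a - b) * ss$MSE
  lower <- a * (ss$MSA - FL * ss$MSE) / (FL * k + a * ss$MSA)
  upper <- a * (FU * ss$MSA - ss$MSE) / (k + a * FU * ss$MSA)
  interval_estimate(point = r, lower = lower, upper = upper,
                    level = level, method = "mcgraw_wong")
}
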