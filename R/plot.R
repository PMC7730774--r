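#' Data behind an agreement plot
#'
#' One record per measurement: the difference
#' \eqn{d_{ijk} = y_{ijk} - \bar y_{i..}} between a measurement and its
#' subject-specific mean (over all `b * c` values for that subject), the
#' subject mean it is plotted against, and the observer label. Within each
#' subject the differences sum to zero by construction.
#'
#' @param data an [agreement_data] object.
#' @param loam optional [interval_estimate] for the upper LOAM (e.g. from
#'   [loam_ci()] or a [loam] fit); supplies the horizontal limit lines and
#'   confidence band.
#' @return A list of class `agreement_plot_data`: data frame `points`
#'   (`subject`, `observer`, `subject_mean`, `difference`), `loam_lines`
#'   (`c(-point, point)` or `NULL`), `ci_band` (`lower`/`upper` or `NULL`),
#'   and `unit`.
#' @examples
#' d <- agreement_data(c(1, 1, 2, 2), c("X", "Y", "X", "Y"), c(1, 2, 3, 5))
#' agreement_plot_data(d, loam_ci(sums_of_squares(d)))$points
#' @export
agreement_plot_data <- function(data, loam = NULL) {
  stopifnot(inherits(data, "agreement_data"))
  mi <- tapply(data$value, data$subject, mean)
  pts <- data.frame(subject = data$subject,
                    observer = data$observer,
                    subject_mean = as.numeric(mi[data$subject]),
                    difference = data$value - as.numeric(mi[data$subject]),
                    stringsAsFactors = FALSE)
  out <- list(points = pts, loam_lines = NULL, ci_band = NULL,
              unit = attr(data, "unit"))
  if (!is.null(loam)) {
    stopifnot(inherits(loam, "interval_estimate"))
    out$loam_lines <- c(-loam$point, loam$point)
    out$ci_band <- c(lower = loam$lower, upper = loam$upper)
  }
  class(out) <- "agreement_plot_data"
  out
}

#' Agreement plot
#'
#' Scatter of the differences between each measurement and its
#' subject-specific mean against that mean, coloured by observer, with dashed
#' horizontal lines at the estimated limits of agreement with the mean and a
#' shaded band for their confidence interval. Use it to look for
#' trend-with-magnitude (heteroscedasticity), and for observers who sit
#' systematically high, low, or scatter more than the rest.
#'
#' @param x a [loam] fit.
#' @param legend draw an observer legend (sensible for modest `b`).
#' @param ... further arguments to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.loam <- function(x, legend = x$dims[["b"]] <= 12, ...) {
  pd <- agreement_plot_data(x$data, x$loam)
  plot_agreement(pd, legend = legend, ...)
  invisible(x)
}

#' @rdname plot.loam
#' @param pd an [agreement_plot_data()] result.
#' @export
plot_agreement <- function(pd, legend = TRUE, ...) {
  stopifnot(inherits(pd, "agreement_plot_data"))
  pts <- pd$points
  obs <- unique(pts$observer)
  cols <- grDevices::hcl.colors(max(length(obs), 2L), "Dark 3")[
    seq_along(obs)]
  names(cols) <- obs
  u <- if (!is.null(pd$unit)) paste0(" (", pd$unit, ")") else ""
  ylim <- range(pts$difference,
                if (!is.null(pd$ci_band)) c(-pd$ci_band, pd$ci_band))
  graphics::plot(pts$subject_mean, pts$difference, type = "n", ylim = ylim,
                 xlab = paste0("Subject mean", u),
                 ylab = paste0("Difference from subject mean", u), ...)
  if (!is.null(pd$ci_band)) {
    usr <- graphics::par("usr")
    shade <- grDevices::adjustcolor("grey60", alpha.f = 0.35)
    graphics::rect(usr[1], pd$ci_band["lower"], usr[2], pd$ci_band["upper"],
                   col = shade, border = NA)
    graphics::rect(usr[1], -pd$ci_band["upper"], usr[2], -pd$ci_band["lower"],
                   col = shade, border = NA)
  }
  if (!is.null(pd$loam_lines))
    graphics::abline(h = pd$loam_lines, lty = 2)
  graphics::abline(h = 0, col = "grey40")
  graphics::points(pts$subject_mean, pts$difference,
                   col = cols[pts$observer], pch = 16, cex = 0.8)
  if (legend && length(obs) <= 15)
    graphics::legend("topright", legend = obs, col = cols, pch = 16,
                     cex = 0.7, bty = "n", ncol = 2)
  invisible(pd)
}
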