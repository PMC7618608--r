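#' Plot a normalized deviation profile
#'
#' Draws the observed deviation curve (thick line) over the permutation
#' ensemble summary: the permutation average (zero line by construction)
#' flanked by the confidence band (thin lines). Called peaks are marked with
#' dashed verticals, and the small-integer rhythm ratios 1:3, 1:2, 1:1, 2:1
#' and 3:1 are annotated at 0.25, 1/3, 0.5, 2/3 and 0.75.
#'
#' @param x a `rhythm_test_result`.
#' @param main plot title.
#' @param ... further arguments passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot_deviation_profile <- function(x, main = "Normalized deviation", ...) {
  p <- x$profile
  ylim <- range(p$deviation, p$ci_low, p$ci_high, 0)
  graphics::plot(p$grid, p$deviation, type = "n", xlab = "IOI-ratio",
                 ylab = "normalized deviation", main = main, ylim = ylim,
                 ...)
  ticks <- c(`1:3` = 0.25, `1:2` = 1 / 3, `1:1` = 0.5, `2:1` = 2 / 3,
             `3:1` = 0.75)
  graphics::abline(v = ticks, col = "grey85")
  graphics::mtext(names(ticks), side = 3, at = ticks, cex = 0.7,
                  col = "grey40")
  graphics::lines(p$grid, p$ci_low, lwd = 1, col = "grey50")
  graphics::lines(p$grid, p$ci_high, lwd = 1, col = "grey50")
  graphics::abline(h = 0, lwd = 1, col = "grey50")
  graphics::lines(p$grid, p$deviation, lwd = 2.5)
  if (nrow(x$peaks)) {
    graphics::abline(v = x$peaks$ratio_location, lty = 2,
                     col = ifelse(x$peaks$sign == "excess", "firebrick",
                                  "steelblue"))
  }
  graphics::legend("topright", bty = "n", cex = 0.8, legend = c(
    sprintf("max |dev| = %.3f", x$observed_max),
    sprintf("test stat = %.3f", x$test_statistic),
    if (x$significant) "significant" else "not significant"))
  invisible(x)
}

#' @export
plot.rhythm_test_result <- function(x, ...) plot_deviation_profile(x, ...)

#' Text report of a rhythm test result document
#'
#' @param result a `rhythm_test_result` (in memory or read from disk via
#'   [read_results()]).
#' @return character vector of report lines.
#' @export
report_lines <- function(result) {
  p <- result$peaks
  c(
    "Rhythm analysis summary",
    "-----------------------",
    sprintf("ratios analysed : %d", result$n_ratios),
    sprintf("permutations    : %d (stratum mode: %s, seed %s)",
            result$config$n_permutations, result$config$stratum_mode,
            result$seed),
    sprintf("test statistic  : %.6f (empirical %.0f%% quantile of permutation maxima)",
            result$test_statistic, 100 * (1 - result$config$alpha)),
    sprintf("max. deviation  : %.6f%s", result$observed_max,
            if (result$significant) " *" else ""),
    sprintf("significant     : %s", result$significant),
    if (nrow(p)) {
      c("peaks outside the confidence band:",
        sprintf("  %-7s at %.3f (deviation %+.3f)", p$sign,
                p$ratio_location, p$deviation_value))
    } else "no peaks outside the confidence band"
  )
}
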