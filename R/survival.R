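# Control-normalized survival and Bland-Altman agreement statistics.

#' Tumor percent survival from raw bioluminescence measurements
#'
#' Percent survival of each micro-tumor is its raw signal divided by the
#' mean signal of the negative-control group (dose 0), times 100 — so the
#' negative-control group has a defined mean survival of exactly 100 %.
#' Optionally, each day-4 signal can first be divided by the matching
#' pre-treatment (day-1) baseline signal, turning the normalized quantity
#' into per-tumor growth before control normalization; this mode is off by
#' default.
#'
#' @param data data frame with columns `raw_signal` and `group_role`
#'   (`"negative_control"` / `"treated"`), plus any metadata columns
#'   (carried through).
#' @param baseline optional numeric vector of per-target day-1 baseline
#'   signals (same length/order as `data`); all positive.
#' @return `data` with a `survival_pct` column added.
#' @export
tumor_survival <- function(data, baseline = NULL) {
  stopifnot(is.data.frame(data),
            all(c("raw_signal", "group_role") %in% names(data)))
  sig <- data$raw_signal
  if (!is.null(baseline)) {
    stopifnot(length(baseline) == nrow(data), all(baseline > 0))
    sig <- sig / baseline
  }
  neg <- data$group_role == "negative_control"
  if (!any(neg)) stop("no negative-control measurements")
  m <- mean(sig[neg])
  if (!is.finite(m) || m == 0) stop("negative-control mean signal is zero")
  data$survival_pct <- 100 * sig / m
  data
}

#' Slice percent survival from raw death-marker fluorescence
#'
#' Slice (OBSC) toxicity assays carry both a negative and a positive
#' control. The negative-control mean is subtracted from every
#' fluorescence value and the result divided by the post-subtraction
#' positive-control mean, giving percent killing; survival is 100 minus
#' that. A slice at the negative-control mean therefore reads 100 %
#' survival, one at the positive-control mean 0 %, and one halfway in
#' between 50 %.
#'
#' @param data data frame with columns `raw_signal` and `group_role`
#'   (`"negative_control"` / `"positive_control"` / `"treated"`).
#' @return `data` with a `survival_pct` column added.
#' @export
obsc_survival <- function(data) {
  stopifnot(is.data.frame(data),
            all(c("raw_signal", "group_role") %in% names(data)))
  neg <- data$group_role == "negative_control"
  pos <- data$group_role == "positive_control"
  if (!any(neg)) stop("no negative-control measurements")
  if (!any(pos)) stop("no positive-control measurements")
  m_neg <- mean(data$raw_signal[neg])
  m_pos <- mean(data$raw_signal[pos])
  if (m_pos == m_neg) stop("positive and negative control means coincide (zero dynamic range)")
  kill <- 100 * (data$raw_signal - m_neg) / (m_pos - m_neg)
  data$survival_pct <- 100 - kill
  data
}

#' Bland-Altman agreement between automated and manual measurements
#'
#' For paired percent-survival measurements: differences
#' `auto - manual`, averages `(auto + manual)/2`, the mean difference and
#' the 95 % limits of agreement (mean difference plus/minus 1.96 times the
#' SD of the differences), and the fraction of pairs whose absolute
#' difference lies within the agreement threshold (10 % survival by
#' default).
#'
#' @param auto,manual numeric vectors of equal length (at least 2).
#' @param threshold agreement threshold on the absolute difference,
#'   percent survival.
#' @return a `bland_altman` object: list with `mean_difference`, `lower`,
#'   `upper`, `sd_difference`, `fraction_within`, `threshold`, and the
#'   per-pair `table` (average, difference, within).
#' @export
bland_altman <- function(auto, manual, threshold = 10) {
  if (length(auto) != length(manual)) stop("length mismatch")
  stopifnot(length(auto) >= 2)
  d <- auto - manual
  avg <- (auto + manual) / 2
  m <- mean(d)
  s <- sd(d)
  structure(list(mean_difference = m, sd_difference = s,
                 lower = m - 1.96 * s, upper = m + 1.96 * s,
                 fraction_within = mean(abs(d) <= threshold),
                 threshold = threshold,
                 table = data.frame(average = avg, difference = d,
                                    within = abs(d) <= threshold)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman agreement (n = %d)\n", nrow(x$table)))
  cat(sprintf("  mean difference: %.3f%%\n", x$mean_difference))
  cat(sprintf("  95%% limits of agreement: (%.3f%%, %.3f%%)\n",
              x$lower, x$upper))
  cat(sprintf("  within %.3g%% threshold: %.1f%%\n", x$threshold,
              100 * x$fraction_within))
  invisible(x)
}

#' Bland-Altman plot
#'
#' Differences against averages, with the mean difference as a solid line
#' and the 95 % limits of agreement as dashed lines.
#'
#' @param x a `bland_altman` object.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.bland_altman <- function(x, ...) {
  graphics::plot(x$table$average, x$table$difference,
                 xlab = "average of methods (%)",
                 ylab = "difference, automated - manual (%)", ...)
  graphics::abline(h = x$mean_difference, lwd = 2)
  graphics::abline(h = c(x$lower, x$upper), lty = 2, col = "gray40")
  invisible(x)
}
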