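# The eleven dose-response comparison windows and the Drug Sensitivity
# Score.
#
# Every window contrasts on-target tumor kill with off-target slice
# toxicity and is bounded in [-1, 1]: positive values mean the treatment
# hit the tumor harder than the host tissue. No window ever extrapolates:
# every dose search, integral and extremum is confined to the tested dose
# range [0, max dose].

.pred_pct <- function(fit, dose) predict(fit, dose, type = "percent")

.max_dose_of <- function(fit, max_dose) {
  if (!is.null(max_dose)) return(max_dose)
  if (is.null(fit$data)) stop("supply max_dose for data-free fits")
  max(fit$data$dose)
}

.clamp1 <- function(x) pmin(pmax(x, -1), 1)

#' Effective dose of a fitted tumor model
#'
#' The smallest dose in `[0, max_dose]` at which the fitted tumor model
#' predicts `xx` % killing, i.e. survival of `100 - xx` % — located by a
#' grid scan for the first bracketing interval followed by root bisection
#' on the fitted curve. `NA` when the curve never reaches that kill level
#' within the tested range (e.g. a lower asymptote above it).
#'
#' @param fit a converged `obsc_drm` tumor fit.
#' @param xx kill level, one of 10, 25, 50, 75, 90 (any value in (0, 100)
#'   is accepted).
#' @param max_dose upper end of the tested dose range; defaults to the
#'   largest dose in the fit's data.
#' @param grid_n scan resolution.
#' @return the effective dose, or `NA_real_` if undefined.
#' @export
ed_dose <- function(fit, xx, max_dose = NULL, grid_n = 1000L) {
  stopifnot(inherits(fit, "obsc_drm"), isTRUE(fit$converged),
            xx > 0, xx < 100)
  D <- .max_dose_of(fit, max_dose)
  target <- 100 - xx
  grid <- seq(0, D, length.out = grid_n)
  pred <- .pred_pct(fit, grid)
  below <- which(pred <= target)
  if (!length(below)) return(NA_real_)
  i <- below[1L]
  if (i == 1L) return(0)
  f <- function(x) .pred_pct(fit, x) - target
  uniroot(f, c(grid[i - 1L], grid[i]), tol = 1e-10 * max(D, 1))$root
}

#' EDxx window: the tumor/slice survival gap at an effective dose
#'
#' At the dose where the tumor model predicts `xx` % killing, the slice
#' model's survival is evaluated. If slice health exceeds 100 % there the
#' window takes its maximal value 1. Otherwise, with tumor kill
#' `TK = xx` and slice kill `OK = 100 -` slice survival: when the slice
#' is healthier than the tumor (`OK < TK`) the window is
#' `(TK - OK)/TK`, else `(TK - OK)/OK`. Undefined (with `NA` value) when
#' the tumor never reaches the kill level in range.
#'
#' @param tumor_fit,obsc_fit converged `obsc_drm` fits.
#' @param xx kill level in percent.
#' @param max_dose tested dose range maximum; defaults to the tumor
#'   fit's data.
#' @return list with `value` (in `[-1, 1]` or `NA`), `defined`, and
#'   `ed` (the effective dose).
#' @export
edxx_window <- function(tumor_fit, obsc_fit, xx, max_dose = NULL) {
  D <- .max_dose_of(tumor_fit, max_dose)
  ed <- ed_dose(tumor_fit, xx, max_dose = D)
  if (is.na(ed)) return(list(value = NA_real_, defined = FALSE, ed = NA_real_))
  s_obsc <- .pred_pct(obsc_fit, ed)
  if (s_obsc > 100) return(list(value = 1, defined = TRUE, ed = ed))
  tk <- xx
  ok <- 100 - s_obsc
  value <- if (ok == tk) 0 else if (ok < tk) (tk - ok) / tk else (tk - ok) / ok
  list(value = .clamp1(value), defined = TRUE, ed = ed)
}

#' AUC window: difference of areas under the fitted survival curves
#'
#' Areas under the tumor and slice survival curves over `[0, max_dose]`
#' (linear dose scale) by adaptive quadrature. A larger slice AUC means
#' more tumor-selective killing: the window is
#' `(OBSC_AUC - Tumor_AUC)/OBSC_AUC` when the slice AUC is larger, else
#' `(OBSC_AUC - Tumor_AUC)/Tumor_AUC`.
#'
#' @inheritParams edxx_window
#' @return list with `value`, `tumor_auc`, `obsc_auc`, `flag`
#'   (degenerate zero-AUC case).
#' @export
auc_window <- function(tumor_fit, obsc_fit, max_dose = NULL) {
  D <- .max_dose_of(tumor_fit, max_dose)
  auc <- function(fit) {
    integrate(function(x) predict(fit, x, type = "fraction"), 0, D,
              subdivisions = 500L)$value
  }
  at <- auc(tumor_fit); ao <- auc(obsc_fit)
  if (at <= 0 && ao <= 0) {
    return(list(value = 0, tumor_auc = at, obsc_auc = ao, flag = TRUE))
  }
  value <- if (ao > at) (ao - at) / ao else (ao - at) / at
  list(value = .clamp1(value), tumor_auc = at, obsc_auc = ao, flag = FALSE)
}

#' Tumor growth acceleration (TGA) window
#'
#' Tests whether treatment accelerated tumor growth anywhere in the
#' tested range, reading the fitted curve's maximum predicted survival
#' over `[0, max_dose]`: above 150 % the window is -1, above 125 % it is
#' 0, otherwise 1. Set `use_fitted = FALSE` to read the observed
#' dose-group means instead.
#'
#' @param tumor_fit a converged `obsc_drm` tumor fit.
#' @param max_dose tested dose range maximum.
#' @param use_fitted evaluate the fitted curve (default) or observed
#'   group means.
#' @param grid_n grid resolution for the curve maximum.
#' @return window value: -1, 0 or 1.
#' @export
tga_window <- function(tumor_fit, max_dose = NULL, use_fitted = TRUE,
                       grid_n = 1000L) {
  D <- .max_dose_of(tumor_fit, max_dose)
  max_surv <- if (use_fitted) {
    max(.pred_pct(tumor_fit, seq(0, D, length.out = grid_n)))
  } else {
    gm <- .group_means(tumor_fit$data$dose, tumor_fit$data$y)
    100 * max(gm$mean)
  }
  if (max_surv > 150) -1 else if (max_surv > 125) 0 else 1
}

#' Incomplete kill (IK) window
#'
#' Tests whether treatment achieved complete tumor kill, reading the
#' fitted tumor survival at the highest tested dose: above 25 % the
#' window is -1, above 10 % it is 0, otherwise 1.
#'
#' @inheritParams tga_window
#' @return window value: -1, 0 or 1.
#' @export
ik_window <- function(tumor_fit, max_dose = NULL) {
  D <- .max_dose_of(tumor_fit, max_dose)
  s <- .pred_pct(tumor_fit, D)
  if (s > 25) -1 else if (s > 10) 0 else 1
}

#' Max kill (MK) window
#'
#' Compares tumor kill at the highest tested dose (`TK`) to slice kill at
#' the highest dose (`OK`), both `100 -` predicted survival:
#' `(TK - OK)/TK` when `TK > OK`, `(TK - OK)/OK` when `OK > TK`, 0 when
#' equal. Clamped to `[-1, 1]` when a kill is negative (growth at the top
#' dose). Both kills zero is degenerate and returns 0 with a flag.
#'
#' @inheritParams edxx_window
#' @return list with `value`, `tumor_kill`, `obsc_kill`, `flag`.
#' @export
mk_window <- function(tumor_fit, obsc_fit, max_dose = NULL) {
  D <- .max_dose_of(tumor_fit, max_dose)
  tk <- 100 - .pred_pct(tumor_fit, D)
  ok <- 100 - .pred_pct(obsc_fit, D)
  if (tk == 0 && ok == 0) {
    return(list(value = 0, tumor_kill = tk, obsc_kill = ok, flag = TRUE))
  }
  value <- if (tk == ok) 0 else if (tk > ok) (tk - ok) / tk else (tk - ok) / ok
  list(value = .clamp1(value), tumor_kill = tk, obsc_kill = ok, flag = FALSE)
}

#' Biphasic (BP) window
#'
#' Tests whether the three highest dose groups of the tumor replicates
#' differ from each other: a one-way ANOVA across those groups at level
#' `alpha` (0.05). Significant separation means the response is still
#' changing at the top doses (not biphasic-stalled): window 1; otherwise
#' -1. Undefined when fewer than three dose groups exist or any of the
#' top three has fewer than two replicates.
#'
#' @param tumor_data data frame of tumor replicates with columns `dose`
#'   and `survival_pct`.
#' @param alpha significance level.
#' @return list with `value` (1, -1 or `NA`), `defined`, `p_value`.
#' @export
bp_window <- function(tumor_data, alpha = 0.05) {
  stopifnot(all(c("dose", "survival_pct") %in% names(tumor_data)))
  doses <- sort(unique(tumor_data$dose))
  if (length(doses) < 3L) {
    return(list(value = NA_real_, defined = FALSE, p_value = NA_real_))
  }
  top3 <- utils::tail(doses, 3L)
  d <- tumor_data[tumor_data$dose %in% top3, ]
  if (any(table(d$dose) < 2L)) {
    return(list(value = NA_real_, defined = FALSE, p_value = NA_real_))
  }
  if (stats::var(d$survival_pct) == 0) {        # all values identical: F = 0
    return(list(value = -1, defined = TRUE, p_value = 1))
  }
  fit <- aov(survival_pct ~ factor(dose), data = d)
  p <- summary(fit)[[1]][["Pr(>F)"]][1]
  list(value = if (p < alpha) 1 else -1, defined = TRUE, p_value = p)
}

#' Slope window
#'
#' Compares the steepness of the tumor and slice models. The evaluation
#' dose is the tumor's ED50 when the tumor reaches 50 % kill in range,
#' otherwise the highest tested dose. Slope magnitudes `|dS/d(dose)|`
#' (survival fraction per dose unit) come from a central finite
#' difference with step `1e-4 * max_dose`. Both magnitudes below `tol`
#' (both responses flat there) give 0; otherwise `(|T| - |O|)/|T|` when
#' the tumor is steeper, else `(|T| - |O|)/|O|`.
#'
#' @inheritParams edxx_window
#' @param tol flatness tolerance on the slope magnitude.
#' @return list with `value`, `eval_dose`, `tumor_slope`, `obsc_slope`.
#' @export
slope_window <- function(tumor_fit, obsc_fit, max_dose = NULL, tol = 1e-6) {
  D <- .max_dose_of(tumor_fit, max_dose)
  ed50 <- ed_dose(tumor_fit, 50, max_dose = D)
  x0 <- if (is.na(ed50)) D else ed50
  h <- 1e-4 * D
  slope_mag <- function(fit) {
    lo <- max(0, x0 - h); hi <- min(D, x0 + h)
    abs(predict(fit, hi, type = "fraction") -
        predict(fit, lo, type = "fraction")) / (hi - lo)
  }
  st <- slope_mag(tumor_fit); so <- slope_mag(obsc_fit)
  value <- if (st < tol && so < tol) 0
    else if (st == so) 0
    else if (st > so) (st - so) / st
    else (st - so) / so
  list(value = .clamp1(value), eval_dose = x0, tumor_slope = st,
       obsc_slope = so)
}

#' Default window weight table
#'
#' Weights in DSS points per unit window value: AUC 35; MK, IK and ED50
#' 10 each; BP, ED10, ED25, ED75, ED90, TGA and Slope 5 each. They sum to
#' 100, so the DSS spans exactly `[-100, 100]`.
#'
#' @return named numeric vector over the eleven windows.
#' @export
dss_weights <- function() {
  c(ED10 = 5, ED25 = 5, ED50 = 10, ED75 = 5, ED90 = 5,
    AUC = 35, TGA = 5, IK = 10, MK = 10, BP = 5, Slope = 5)
}

#' Compute all eleven DSS windows from paired fits and data
#'
#' @param tumor_fit,obsc_fit converged `obsc_drm` fits for the tumor and
#'   slice responses.
#' @param tumor_data tumor replicate data frame (`dose`, `survival_pct`)
#'   for the biphasic test; defaults to the tumor fit's stored data.
#' @param max_dose tested dose range maximum.
#' @param alpha significance level of the biphasic ANOVA.
#' @param tga_use_fitted see [tga_window()].
#' @return named list of window values (`NA` = undefined), with
#'   attribute `details` carrying the per-window diagnostics.
#' @export
dss_windows <- function(tumor_fit, obsc_fit, tumor_data = NULL,
                        max_dose = NULL, alpha = 0.05,
                        tga_use_fitted = TRUE) {
  D <- .max_dose_of(tumor_fit, max_dose)
  if (is.null(tumor_data) && !is.null(tumor_fit$data)) {
    tumor_data <- data.frame(dose = tumor_fit$data$dose,
                             survival_pct = 100 * tumor_fit$data$y)
  }
  eds <- lapply(c(10, 25, 50, 75, 90), function(xx) {
    edxx_window(tumor_fit, obsc_fit, xx, max_dose = D)
  })
  names(eds) <- paste0("ED", c(10, 25, 50, 75, 90))
  auc <- auc_window(tumor_fit, obsc_fit, max_dose = D)
  mk <- mk_window(tumor_fit, obsc_fit, max_dose = D)
  bp <- if (is.null(tumor_data)) {
    list(value = NA_real_, defined = FALSE, p_value = NA_real_)
  } else bp_window(tumor_data, alpha = alpha)
  sl <- slope_window(tumor_fit, obsc_fit, max_dose = D)
  win <- c(vapply(eds, `[[`, numeric(1), "value"),
           AUC = auc$value,
           TGA = tga_window(tumor_fit, max_dose = D,
                            use_fitted = tga_use_fitted),
           IK = ik_window(tumor_fit, max_dose = D),
           MK = mk$value, BP = bp$value, Slope = sl$value)
  structure(as.list(win),
            details = list(ed = eds, auc = auc, mk = mk, bp = bp,
                           slope = sl, max_dose = D))
}

#' Combine windows and weights into a Drug Sensitivity Score
#'
#' Each window's contribution is its weight times its value; undefined
#' windows (`NA`) contribute 0 points and are flagged. The total is the
#' sum of contributions, so with the default weights the greatest
#' possible DSS is 100 and the lowest is -100.
#'
#' @param windows named list or vector of the eleven window values
#'   (see [dss_windows()]); `NA` marks an undefined window.
#' @param weights named weight vector summing to 100 (see
#'   [dss_weights()]).
#' @return a `dss` object: list with `windows`, `weights`,
#'   `contributions`, `undefined` (names of flagged windows) and `total`.
#' @examples
#' w <- dss_weights()
#' compute_dss(setNames(rep(1, length(w)), names(w)))$total   # 100
#' @export
compute_dss <- function(windows, weights = dss_weights()) {
  if (abs(sum(weights) - 100) > 1e-9) stop("weights must sum to 100")
  windows <- unlist(windows)
  miss <- setdiff(names(weights), names(windows))
  if (length(miss)) stop("missing windows: ", paste(miss, collapse = ", "))
  windows <- windows[names(weights)]
  defined <- !is.na(windows)
  if (any(windows[defined] < -1 - 1e-9 | windows[defined] > 1 + 1e-9)) {
    stop("window values must lie in [-1, 1]")
  }
  contributions <- ifelse(defined, weights * windows, 0)
  structure(list(windows = windows, weights = weights,
                 contributions = contributions,
                 undefined = names(windows)[!defined],
                 total = sum(contributions)),
            class = "dss")
}

#' Score a paired tumor/slice experiment
#'
#' Convenience wrapper: computes the eleven windows from the fitted pair
#' ([dss_windows()]) and folds them into the weighted score
#' ([compute_dss()]).
#'
#' @inheritParams dss_windows
#' @param weights see [dss_weights()].
#' @return a `dss` object (with the window `details` attached as
#'   attribute `details`).
#' @export
dss_score <- function(tumor_fit, obsc_fit, tumor_data = NULL,
                      max_dose = NULL, weights = dss_weights(),
                      alpha = 0.05, tga_use_fitted = TRUE) {
  win <- dss_windows(tumor_fit, obsc_fit, tumor_data = tumor_data,
                     max_dose = max_dose, alpha = alpha,
                     tga_use_fitted = tga_use_fitted)
  out <- compute_dss(win, weights)
  attr(out, "details") <- attr(win, "details")
  out
}

#' @export
print.dss <- function(x, ...) {
  cat("Drug Sensitivity Score\n")
  tab <- data.frame(window = names(x$windows),
                    value = round(unname(x$windows), 4),
                    weight = unname(x$weights),
                    contribution = round(unname(x$contributions), 3))
  print(tab, row.names = FALSE)
  if (length(x$undefined)) {
    cat("  undefined (contribute 0):", paste(x$undefined, collapse = ", "),
        "\n")
  }
  cat(sprintf("  total DSS: %.2f (range -100 to 100)\n", x$total))
  invisible(x)
}

#' Waterfall decomposition of a DSS
#'
#' @param x a `dss` object.
#' @return data frame with one row per window: weight, window value,
#'   contribution and running total.
#' @export
dss_waterfall <- function(x) {
  stopifnot(inherits(x, "dss"))
  data.frame(window = names(x$windows),
             weight = unname(x$weights),
             value = unname(x$windows),
             contribution = unname(x$contributions),
             running_total = cumsum(unname(x$contributions)))
}

#' Waterfall plot of a DSS decomposition
#'
#' @param x a `dss` object.
#' @param ... passed to [graphics::barplot()].
#' @return `x`, invisibly.
#' @export
plot.dss <- function(x, ...) {
  wf <- dss_waterfall(x)
  bp <- graphics::barplot(wf$contribution, names.arg = wf$window,
                          las = 2, ylab = "DSS points", ...)
  graphics::lines(bp, wf$running_total, type = "b", pch = 19,
                  col = "firebrick")
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}
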