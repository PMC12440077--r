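# Fitting, categorization and model selection.
#
# All fitting happens on the survival-fraction scale (1.0 = 100 %) on the
# replicate-level data, never on group means. The user-facing interface
# takes percent survival, the external representation used throughout the
# assay's CSV schemas.

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

.model_frame <- function(formula, data) {
  mf <- stats::model.frame(formula, data)
  if (ncol(mf) != 2L) stop("formula must be of the form response ~ dose")
  dose <- mf[[2L]]
  y <- mf[[1L]] / 100           # percent in, fraction internally
  if (any(dose < 0)) stop("doses must be non-negative")
  list(dose = dose, y = y)
}

#' Default heuristic thresholds for response categorization and plausibility
#'
#' `growth_threshold`: a dose-group mean at or above this survival fraction
#' classifies the experiment as Growth (default 1.10, i.e. 110 %).
#' `plateau_step`: largest between-group change (fraction) still counted as
#' part of a plateau (default 0.15). `plateau_min_run`: minimum number of
#' consecutive dose groups forming a plateau (default 3).
#' `overshoot_factor` and `undershoot_margin` bound model plausibility: a
#' fitted curve may not predict above `overshoot_factor` times the highest
#' group mean (default 1.1) nor below the lowest group mean minus
#' `undershoot_margin` (default 0.50, i.e. 50 % survival).
#'
#' @param growth_threshold,plateau_step,plateau_min_run,overshoot_factor,undershoot_margin
#'   see Description.
#' @return named list of thresholds.
#' @export
heuristic_thresholds <- function(growth_threshold = 1.10,
                                 plateau_step = 0.15,
                                 plateau_min_run = 3L,
                                 overshoot_factor = 1.1,
                                 undershoot_margin = 0.50) {
  stopifnot(growth_threshold > 0, plateau_step > 0, plateau_min_run >= 2,
            overshoot_factor > 0, undershoot_margin > 0)
  list(growth_threshold = growth_threshold, plateau_step = plateau_step,
       plateau_min_run = as.integer(plateau_min_run),
       overshoot_factor = overshoot_factor,
       undershoot_margin = undershoot_margin)
}

#' Heuristic categorization of dose-response behavior
#'
#' Sorts an experiment into one of three categories from its dose-group
#' mean survivals: `Growth` if any group mean reaches the growth threshold
#' (110 % survival by default); otherwise `Plateau` if at least
#' `plateau_min_run` consecutive dose groups change by less than
#' `plateau_step` between neighbours, entered by a change larger than
#' `plateau_step` (so the flat control region at the start of the ladder
#' never counts as a plateau) and either exited by another such change or
#' running to the end of the dose range; otherwise `Decreasing`. A plateau
#' thus separates two regions of killing, or stalls a response at the top
#' of the tested range.
#'
#' @param formula model formula, `survival_pct ~ dose`.
#' @param data data frame holding percent survival and dose.
#' @param thresholds see [heuristic_thresholds()].
#' @return `"Decreasing"`, `"Plateau"` or `"Growth"`.
#' @export
categorize_response <- function(formula, data,
                                thresholds = heuristic_thresholds()) {
  mf <- .model_frame(formula, data)
  gm <- .group_means(mf$dose, mf$y)
  if (length(gm$dose) < 4L) stop("need at least 4 dose groups to categorize")
  if (any(gm$mean >= thresholds$growth_threshold)) return("Growth")
  steps <- diff(gm$mean)
  small <- abs(steps) < thresholds$plateau_step
  min_diffs <- thresholds$plateau_min_run - 1L
  r <- rle(small)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$values)) {
    if (!r$values[k] || r$lengths[k] < min_diffs) next
    i <- starts[k]; j <- ends[k]
    entered <- i > 1L && abs(steps[i - 1L]) > thresholds$plateau_step
    exited <- j == length(steps) ||
      abs(steps[j + 1L]) > thresholds$plateau_step
    if (entered && exited) return("Plateau")
  }
  "Decreasing"
}

# residual function on the fraction scale; non-finite predictions (e.g. an
# RBC.5 parameter combination with no hormesis peak) get a large penalty so
# the optimizer backs away instead of crashing
.resid_fun <- function(fam, fixed, dose, y) {
  function(par) {
    r <- y - fam$fun(c(par, fixed), dose)
    r[!is.finite(r)] <- 1e6
    r
  }
}

.fit_one_start <- function(fam, fixed, dose, y, start) {
  res <- tryCatch(
    minpack.lm::nls.lm(par = start, lower = fam$lower, upper = fam$upper,
                       fn = .resid_fun(fam, fixed, dose, y),
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(res) || !res$info %in% 1:4) return(NULL)
  list(coef = coef(res), rss = res$deviance)
}

#' Fit one dose-response family by bounded nonlinear least squares
#'
#' Fits the named family to replicate-level percent-survival data by
#' Levenberg-Marquardt least squares within the family's box limits
#' (via [minpack.lm::nls.lm()]). Fixed parameters never enter the
#' optimizer. Fitting is multi-start: the family's self-starter supplies
#' the central start and `n_starts - 1` seeded, 10 % multiplicatively
#' jittered copies are tried; the converged fit with the lowest residual
#' sum of squares wins.
#'
#' @inheritParams categorize_response
#' @param family family name (see [drm_families()]).
#' @param fixed optional named numeric vector overriding/augmenting the
#'   family's fixed parameters (e.g. `c(M = 5)` for RBC.5).
#' @param start optional named start values for the free parameters.
#' @param n_starts number of optimizer starts (default 5).
#' @param seed integer seed for the start jitter.
#' @return an object of class `obsc_drm` with components `family`, `coef`
#'   (free-parameter estimates), `fixed`, `params` (all parameters),
#'   `rss`, `n`, `p`, `aic`, `lof`, `converged`, `data`; or with
#'   `converged = FALSE` when no start converges.
#' @seealso [select_drm()] for categorize-fit-rank-select in one call.
#' @export
fit_drm <- function(formula, data, family, fixed = NULL, start = NULL,
                    n_starts = 5, seed = 1) {
  fam <- .get_family(family)
  mf <- .model_frame(formula, data)
  dose <- mf$dose; y <- mf$y
  fam_fixed <- fam$fixed
  if (!is.null(fixed)) fam_fixed[names(fixed)] <- fixed
  if (anyNA(fam_fixed)) {
    stop(family, ": fixed parameter(s) ",
         paste(names(fam_fixed)[is.na(fam_fixed)], collapse = ", "),
         " must be supplied (dynamically defined)")
  }
  k <- length(unique(dose))
  p <- length(fam$free)
  if (p > k - 1L) {
    stop(family, ": ", p, " free parameters need more than ", k,
         " distinct doses (identifiability guard)")
  }
  st0 <- if (is.null(start)) fam$start(dose, y) else start[fam$free]
  st0 <- .clamp(st0, fam$lower, fam$upper)
  starts <- .with_seed(seed, {
    c(list(st0), lapply(seq_len(max(0L, n_starts - 1L)), function(i) {
      .clamp(st0 * runif(length(st0), 0.9, 1.1), fam$lower, fam$upper)
    }))
  })
  best <- NULL
  for (s in starts) {
    r <- .fit_one_start(fam, fam_fixed, dose, y, s)
    if (!is.null(r) && (is.null(best) || r$rss < best$rss)) best <- r
  }
  out <- list(family = family, fixed = fam_fixed, data = data.frame(dose = dose, y = y),
              n = length(y), p = p, converged = !is.null(best))
  if (out$converged) {
    out$coef <- best$coef
    out$params <- c(best$coef, fam_fixed)
    out$rss <- best$rss
    out$aic <- drm_aic(best$rss, out$n, p)
    out$lof <- lack_of_fit_rss(best$rss, p, dose, y)
  }
  class(out) <- "obsc_drm"
  out
}

#' Wrap a known curve as a fitted-model object
#'
#' Builds an `obsc_drm` object directly from a family and a full parameter
#' vector, without data. Useful for constructing reference curves for the
#' DSS windows and in tests.
#'
#' @inheritParams drm_curve
#' @return an `obsc_drm` object (`converged = TRUE`, no data, no fit
#'   statistics).
#' @export
as_drm <- function(family, params) {
  fam <- .get_family(family)
  structure(list(family = family, params = params,
                 coef = params[fam$free], fixed = params[names(fam$fixed)],
                 converged = TRUE),
            class = "obsc_drm")
}

#' Gaussian-likelihood AIC from a residual sum of squares
#'
#' `AIC = n * (log(2 * pi * RSS / n) + 1) + 2 * (p + 1)`, the profile
#' Gaussian likelihood with the error variance estimated, counting the
#' variance as an extra parameter. Lower is better; more negative values
#' reward tighter fits. `RSS` numerically zero returns `-Inf` (a perfect
#' fit wins any comparison).
#'
#' @param rss residual sum of squares.
#' @param n number of observations.
#' @param p number of free model parameters.
#' @return the AIC value.
#' @export
drm_aic <- function(rss, n, p) {
  if (rss < 1e-12) return(-Inf)
  n * (log(2 * pi * rss / n) + 1) + 2 * (p + 1)
}

lack_of_fit_rss <- function(rss_model, p, dose, y) {
  k <- length(unique(dose))
  n <- length(y)
  reps <- table(dose)
  if (!any(reps >= 2) || n <= k || k <= p) return(NA_real_)
  gm <- .group_means(dose, y)
  rss_sat <- sum((y - gm$mean[match(dose, gm$dose)])^2)
  if (rss_sat < 1e-12) {
    return(if (rss_model - rss_sat < 1e-10) 1 else 0)
  }
  f <- max(0, (rss_model - rss_sat) / (k - p)) / (rss_sat / (n - k))
  pf(f, k - p, n - k, lower.tail = FALSE)
}

#' Lack-of-fit test against the saturated cell-means model
#'
#' F-test of the fitted parametric model against the one-way ANOVA model
#' with a free mean per dose group:
#' `F = [(RSS_model - RSS_sat)/(k - p)] / [RSS_sat/(n - k)]` with `k`
#' distinct doses, `n` observations and `p` free parameters; the upper-tail
#' p-value is returned. A value near 1 indicates the parametric curve
#' aligns with the group means as well as the saturated model does.
#' `NA` when there is no replication (no dose with two or more replicates)
#' or no residual degrees of freedom.
#'
#' @param fit a converged `obsc_drm` object carrying its data.
#' @return p-value in `[0, 1]`, or `NA` when unavailable.
#' @export
lack_of_fit <- function(fit) {
  stopifnot(inherits(fit, "obsc_drm"))
  if (!isTRUE(fit$converged) || is.null(fit$data)) {
    stop("lack_of_fit needs a converged fit with data")
  }
  lack_of_fit_rss(fit$rss, fit$p, fit$data$dose, fit$data$y)
}

#' Combined model-selection criterion from AIC and lack-of-fit
#'
#' The piecewise criterion used to rank candidate models (lower is
#' better): `AIC / LoF` when AIC is positive, `AIC * LoF` when AIC is
#' negative, and 0 at AIC = 0. Either branch rewards a more negative AIC
#' and a lack-of-fit p-value closer to 1. With positive AIC and LoF = 0
#' the criterion is `+Inf` (worst). When LoF is unavailable (no
#' replication) the criterion degrades to the AIC alone, with attribute
#' `lof_unavailable = TRUE`.
#'
#' @param aic AIC value.
#' @param lof lack-of-fit p-value in `[0, 1]`, or `NA`.
#' @return the combined criterion.
#' @export
combined_criterion <- function(aic, lof) {
  if (is.na(lof)) return(structure(aic, lof_unavailable = TRUE))
  if (!is.finite(aic)) return(aic)            # -Inf sentinel: perfect fit
  if (aic > 0) {
    if (lof <= 0) return(Inf)
    aic / lof
  } else if (aic < 0) {
    aic * lof
  } else 0
}

#' Plausibility screen for a fitted dose-response model
#'
#' Evaluates the fitted curve on a 1000-point uniform grid over
#' `[0, max dose]`. The fit is plausible iff the maximum prediction does
#' not exceed `overshoot_factor` times the highest observed group mean and
#' the minimum prediction does not fall below the lowest group mean minus
#' `undershoot_margin` (survival fractions).
#'
#' @inheritParams lack_of_fit
#' @param thresholds see [heuristic_thresholds()].
#' @param grid_n number of grid points (default 1000).
#' @return logical flag.
#' @export
plausibility_check <- function(fit, thresholds = heuristic_thresholds(),
                               grid_n = 1000L) {
  stopifnot(inherits(fit, "obsc_drm"), isTRUE(fit$converged),
            !is.null(fit$data))
  gm <- .group_means(fit$data$dose, fit$data$y)
  grid <- seq(0, max(fit$data$dose), length.out = grid_n)
  pred <- drm_curve(fit$family, fit$params, grid)
  eps <- 1e-9
  max(pred) <= thresholds$overshoot_factor * max(gm$mean) + eps &&
    min(pred) >= min(gm$mean) - thresholds$undershoot_margin - eps
}

#' Categorize, fit, rank and select a dose-response model
#'
#' The full multi-step selection pipeline. The experiment is first
#' heuristically categorized (see [categorize_response()]), which fixes
#' the candidate list ([model_registry()]). Every candidate is fitted on
#' the replicate data by bounded multi-start least squares; for RBC.5 the
#' peak dose `M` is fixed dynamically at the nonzero dose with the highest
#' mean survival ([hormesis_peak_dose()]). Converged fits are ranked by
#' ascending combined criterion ([combined_criterion()]), ties broken by
#' fewer free parameters then registry order, and walked best-first
#' through the plausibility screen ([plausibility_check()]); the best
#' plausible fit is returned. If no fit is plausible the best-ranked fit
#' is returned flagged implausible, with a warning.
#'
#' @inheritParams categorize_response
#' @param n_starts,seed multi-start controls passed to [fit_drm()].
#' @return the selected `obsc_drm` fit with extra components `category`,
#'   `cc`, `plausible`, and `candidates` (the full ranking table).
#' @examples
#' d <- simulate_dose_response(sim_curve_spec("LL.4",
#'   c(b = 2, c = 0.1, d = 1, e = 50), doses = c(0, 5, 10, 50, 100, 500)))
#' fit <- select_drm(survival_pct ~ dose, d)
#' coef(fit)
#' @export
select_drm <- function(formula, data, thresholds = heuristic_thresholds(),
                       n_starts = 5, seed = 1) {
  category <- categorize_response(formula, data, thresholds)
  reg <- model_registry(category)
  mf <- .model_frame(formula, data)
  k <- length(unique(mf$dose))

  fits <- list(); rows <- list()
  for (i in seq_along(reg)) {
    fam <- reg[[i]]
    if (length(fam$free) > k - 1L) next     # identifiability guard
    fixed <- NULL
    if (fam$name == "RBC.5") {
      fixed <- c(M = as.numeric(hormesis_peak_dose(mf$dose, mf$y)))
    }
    fit <- fit_drm(formula, data, fam$name, fixed = fixed,
                   n_starts = n_starts, seed = seed + i)
    if (!fit$converged) next
    cc <- combined_criterion(fit$aic, fit$lof)
    fit$cc <- as.numeric(cc)
    fit$category <- category
    fit$plausible <- plausibility_check(fit, thresholds)
    fits[[fam$name]] <- fit
    rows[[fam$name]] <- data.frame(
      family = fam$name, p = fit$p, rss = fit$rss, aic = fit$aic,
      lof = fit$lof, cc = fit$cc, plausible = fit$plausible,
      registry_order = i, stringsAsFactors = FALSE)
  }
  if (!length(fits)) stop("no candidate model converged")
  tab <- do.call(rbind, rows)
  ord <- order(tab$cc, tab$p, tab$registry_order)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  pick <- if (any(tab$plausible)) tab$family[which(tab$plausible)[1L]] else {
    warning("no candidate model passed the plausibility screen; ",
            "returning the best-ranked fit flagged implausible")
    tab$family[1L]
  }
  sel <- fits[[pick]]
  sel$candidates <- tab
  sel$thresholds <- thresholds
  class(sel) <- c("obsc_drm_select", "obsc_drm")
  sel
}
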