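# S3 methods for fitted dose-response models.

#' @export
print.obsc_drm <- function(x, ...) {
  cat("Dose-response model:", x$family, "\n")
  if (!isTRUE(x$converged)) {
    cat("  (did not converge)\n")
    return(invisible(x))
  }
  cat("  parameters:\n")
  print(round(x$params, 6))
  if (!is.null(x$rss)) {
    cat(sprintf("  n = %d, free parameters = %d, RSS = %.6g\n",
                x$n, x$p, x$rss))
    cat(sprintf("  AIC = %.4g, lack-of-fit p = %s\n", x$aic,
                ifelse(is.na(x$lof), "unavailable", sprintf("%.4g", x$lof))))
  }
  invisible(x)
}

#' @export
print.obsc_drm_select <- function(x, ...) {
  cat("Selected dose-response model (category:", x$category, ")\n\n")
  NextMethod()
  cat("\nCandidate ranking (ascending combined criterion):\n")
  print(x$candidates, digits = 4)
  if (!isTRUE(x$plausible)) {
    cat("NOTE: selected fit failed the plausibility screen\n")
  }
  invisible(x)
}

#' @export
summary.obsc_drm <- function(object, ...) {
  print(object)
  if (!is.null(object$data)) {
    gm <- .group_means(object$data$dose, object$data$y)
    cat("\nDose-group mean survival (%):\n")
    print(data.frame(dose = gm$dose, mean_survival = 100 * gm$mean),
          row.names = FALSE)
  }
  invisible(object)
}

#' @export
coef.obsc_drm <- function(object, ...) object$coef

#' Predict survival from a fitted dose-response model
#'
#' @param object an `obsc_drm` fit.
#' @param newdata data frame with a `dose` column, or a numeric dose
#'   vector; defaults to the doses the model was fitted on.
#' @param type `"percent"` (default, 100 = control survival) or
#'   `"fraction"`.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.obsc_drm <- function(object, newdata = NULL,
                             type = c("percent", "fraction"), ...) {
  type <- match.arg(type)
  if (!isTRUE(object$converged)) stop("model did not converge")
  dose <- if (is.null(newdata)) {
    if (is.null(object$data)) stop("no data stored; supply newdata")
    object$data$dose
  } else if (is.data.frame(newdata)) newdata$dose else as.numeric(newdata)
  out <- drm_curve(object$family, object$params, dose)
  if (type == "percent") 100 * out else out
}

#' @export
fitted.obsc_drm <- function(object, ...) predict(object)

#' @export
residuals.obsc_drm <- function(object, type = c("percent", "fraction"), ...) {
  type <- match.arg(type)
  if (is.null(object$data)) stop("no data stored")
  r <- object$data$y - predict(object, type = "fraction")
  if (type == "percent") 100 * r else r
}

#' @export
logLik.obsc_drm <- function(object, ...) {
  if (is.null(object$rss)) stop("no fit statistics stored")
  n <- object$n
  val <- -n / 2 * (log(2 * pi * object$rss / n) + 1)
  structure(val, df = object$p + 1, nobs = n, class = "logLik")
}

#' Plot a fitted dose-response model over its data
#'
#' Draws the replicate percent-survival data and the fitted curve on a
#' dose grid, log-spaced above the smallest nonzero dose.
#'
#' @param x an `obsc_drm` fit with data.
#' @param n_grid grid resolution.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.obsc_drm <- function(x, n_grid = 200L, ...) {
  if (is.null(x$data)) stop("no data stored")
  d <- x$data
  grid <- seq(0, max(d$dose), length.out = n_grid)
  graphics::plot(d$dose, 100 * d$y, xlab = "dose",
                 ylab = "survival (%)", ...)
  graphics::lines(grid, predict(x, grid), col = "firebrick", lwd = 2)
  invisible(x)
}

#' Simulate replicate datasets from a fitted dose-response model
#'
#' Draws `nsim` new replicate datasets from the fitted curve with Gaussian
#' noise whose standard deviation defaults to the fit's residual standard
#' deviation.
#'
#' @param object a converged `obsc_drm` fit with data.
#' @param nsim number of datasets.
#' @param seed integer seed.
#' @param noise_sd noise standard deviation on the fraction scale;
#'   defaults to `sqrt(RSS / (n - p))`.
#' @param ... unused.
#' @return a list of data frames with columns `dose` and `survival_pct`.
#' @export
simulate.obsc_drm <- function(object, nsim = 1, seed = 1, noise_sd = NULL,
                              ...) {
  stopifnot(isTRUE(object$converged), !is.null(object$data))
  if (is.null(noise_sd)) {
    noise_sd <- sqrt(object$rss / max(1, object$n - object$p))
  }
  dose <- object$data$dose
  mu <- predict(object, type = "fraction")
  .with_seed(seed, {
    lapply(seq_len(nsim), function(i) {
      data.frame(dose = dose,
                 survival_pct = 100 * (mu + rnorm(length(mu), 0, noise_sd)))
    })
  })
}
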