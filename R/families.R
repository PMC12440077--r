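#' @importFrom stats approx coef integrate median pf quantile rnorm runif sd
#'   uniroot aov anova lm optimize setNames predict residuals fitted simulate
NULL

# Optimizer box limits stand in for the open intervals of the family tables:
# an open bound (a, Inf) becomes [a + 1e-9, 1e9].
.OPEN_EPS <- 1e-9
.BIG <- 1e9

.finite_lo <- function(a) if (is.finite(a)) a + .OPEN_EPS else -.BIG
.finite_hi <- function(a) if (is.finite(a)) a - .OPEN_EPS else .BIG

# ---- curve functions (survival fraction scale; 1.0 = 100 %) -----------------

.ll4 <- function(p, x) {
  out <- p[["c"]] + (p[["d"]] - p[["c"]]) /
    (1 + exp(p[["b"]] * (log(x) - log(p[["e"]]))))
  out[x == 0] <- p[["d"]]
  out
}

.w14 <- function(p, x) {
  out <- p[["c"]] + (p[["d"]] - p[["c"]]) *
    exp(-exp(p[["b"]] * (log(x) - log(p[["e"]]))))
  out[x == 0] <- p[["d"]]
  out
}

.w24 <- function(p, x) {
  out <- p[["c"]] + (p[["d"]] - p[["c"]]) *
    (1 - exp(-exp(p[["b"]] * (log(x) - log(p[["e"]])))))
  out[x == 0] <- p[["d"]]
  out
}

.exd3 <- function(p, x) {
  p[["c"]] + (p[["d"]] - p[["c"]]) * exp(-x / p[["e"]])
}

.bc5 <- function(p, x) {
  out <- p[["c"]] + (p[["d"]] - p[["c"]] + p[["f"]] * x) /
    (1 + exp(p[["b"]] * (log(x) - log(p[["e"]]))))
  out[x == 0] <- p[["d"]]
  out
}

.crs <- function(p, x) {
  out <- p[["c"]] + (p[["d"]] - p[["c"]] + p[["f"]] * exp(-1 / x^p[["alpha"]])) /
    (1 + exp(p[["b"]] * (log(x) - log(p[["e"]]))))
  out[x == 0] <- p[["d"]]
  out
}

#' Scale parameter of the peak-reparametrized Brain-Cousens model
#'
#' The reparametrized Brain-Cousens curve (RBC.5) replaces the scale
#' parameter `e` of BC.5 with the dose `M` at which the hormesis peak occurs.
#' Setting the derivative of the BC.5 curve to zero at dose `M` and solving
#' for `e` gives the closed form implemented here:
#' with `t = f*M / (b*(d - c + f*M) - f*M)`, `e = M / t^(1/b)`.
#' For `b > 1`, `f > 0` and `d > c` the denominator is always positive, so a
#' peak at `M` exists; otherwise `NA` is returned.
#'
#' @param b,c,d,f Brain-Cousens parameters (slope, lower asymptote, upper
#'   asymptote, hormesis coefficient).
#' @param M dose at which the curve is stationary (the hormesis peak).
#' @return the implied `e` parameter, or `NA_real_` if no peak exists.
#' @export
rbc5_e <- function(b, c, d, f, M) {
  den <- b * (d - c + f * M) - f * M
  if (!is.finite(den) || den <= 0) return(NA_real_)
  t <- f * M / den
  if (!is.finite(t) || t <= 0) return(NA_real_)
  M / t^(1 / b)
}

.rbc5 <- function(p, x) {
  e <- rbc5_e(p[["b"]], p[["c"]], p[["d"]], p[["f"]], p[["M"]])
  if (is.na(e)) return(rep(NA_real_, length(x)))
  .bc5(c(b = p[["b"]], c = p[["c"]], d = p[["d"]], e = e, f = p[["f"]]), x)
}

# ---- starters ---------------------------------------------------------------

.group_means <- function(dose, y) {
  d <- sort(unique(dose))
  m <- vapply(d, function(di) mean(y[dose == di]), numeric(1))
  list(dose = d, mean = m)
}

# dose at which linearly interpolated group means first cross `level`;
# falls back to the maximum dose when they never do
.cross_dose <- function(doses, means, level) {
  for (i in seq_len(length(doses) - 1L)) {
    y1 <- means[i]; y2 <- means[i + 1L]
    if ((y1 - level) * (y2 - level) <= 0 && y1 != y2) {
      return(doses[i] + (level - y1) * (doses[i + 1L] - doses[i]) / (y2 - y1))
    }
  }
  max(doses)
}

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Self-starter for the three-parameter exponential decay model
#'
#' Initial values for EXD.3 from linear interpolation of the dose-group
#' means: `c0` is the smallest group mean (clamped into the parameter box),
#' `d` is fixed at 1, and `e0` is the dose at which the interpolated means
#' cross `c0 + (1 - c0) * exp(-1)` — the dose at which an exponential decay
#' from 1 to `c0` has covered `1 - exp(-1)` of its range. When the means
#' never cross that level, `e0` falls back to the largest dose.
#'
#' @param dose,y numeric vectors of doses and survival fractions
#'   (replicate-level; 1.0 = 100 %).
#' @return named numeric vector with components `c` and `e`.
#' @export
exd_selfstart <- function(dose, y) {
  gm <- .group_means(dose, y)
  c0 <- .clamp(min(gm$mean), .OPEN_EPS, .BIG)
  level <- c0 + (1 - c0) * exp(-1)
  e0 <- .cross_dose(gm$dose, gm$mean, level)
  e0 <- .clamp(e0, 0.0001 + .OPEN_EPS, 10000 - .OPEN_EPS)
  c(c = c0, e = e0)
}

#' Dose of the observed hormesis peak
#'
#' The dynamically defined `M` parameter of the RBC.5 model: the nonzero
#' dose whose group mean survival is largest, ties broken toward the
#' smaller dose. When the means are monotone decreasing the smallest
#' nonzero dose is returned with attribute `degenerate = TRUE`.
#'
#' @inheritParams exd_selfstart
#' @return the peak dose, with a `degenerate` attribute.
#' @export
hormesis_peak_dose <- function(dose, y) {
  gm <- .group_means(dose, y)
  nz <- gm$dose > 0
  if (!any(nz)) stop("no nonzero dose group")
  d <- gm$dose[nz]; m <- gm$mean[nz]
  M <- d[which.max(m)]          # which.max takes the first maximum: small-dose tie-break
  ctrl <- if (any(!nz)) gm$mean[!nz] else 1
  structure(M, degenerate = max(m) <= ctrl && all(diff(m) <= 0))
}

# ---- family registry --------------------------------------------------------

.family_def <- function(name, fun, fixed, lower, upper, start, hormesis = FALSE) {
  list(name = name, fun = fun, fixed = fixed, lower = lower, upper = upper,
       start = start, hormesis = hormesis,
       free = names(lower))
}

.start_sigmoid <- function(dose, y, b0, e_lo = 0.0001, e_hi = .BIG) {
  gm <- .group_means(dose, y)
  c0 <- .clamp(min(gm$mean), .OPEN_EPS, 1 - .OPEN_EPS)
  e0 <- .cross_dose(gm$dose, gm$mean, (1 + c0) / 2)
  e0 <- .clamp(e0, e_lo + .OPEN_EPS, e_hi - .OPEN_EPS)
  c(b = b0, c = c0, e = e0)
}

.start_crs <- function(dose, y, free_c) {
  gm <- .group_means(dose, y)
  h <- max(gm$mean) - 1
  f0 <- if (h > 0.01) 2 * h else 0.1
  e0 <- .clamp(median(gm$dose[gm$dose > 0]), 1e-3, .BIG)
  st <- c(b = 2, d = 1, e = e0, f = f0)
  if (free_c) st <- c(st, c = .clamp(min(gm$mean), .OPEN_EPS, 10 - .OPEN_EPS))
  st[c("b", if (free_c) "c", "d", "e", "f")]
}

.start_bc5 <- function(dose, y) {
  gm <- .group_means(dose, y)
  h <- max(gm$mean) - 1
  Mpk <- gm$dose[which.max(gm$mean)]
  f0 <- if (h > 0.01 && Mpk > 0) .clamp(h / Mpk, 1e-5, .BIG) else 1e-3
  e0 <- .clamp(.cross_dose(gm$dose, gm$mean, 0.5), .OPEN_EPS, .BIG)
  c(b = 2, c = .clamp(min(gm$mean), .OPEN_EPS, .BIG), e = e0, f = f0)
}

.crs_fams <- function(five) {
  alphas <- if (five) c(a = 1, b = 0.5) else c(a = 1, b = 0.5, c = 0.25)
  lapply(seq_along(alphas), function(i) {
    al <- alphas[[i]]
    tag <- names(alphas)[i]
    if (five) {
      .family_def(paste0("CRS.5", tag), .crs,
        fixed = c(alpha = al),
        lower = c(b = 1 + .OPEN_EPS, c = .OPEN_EPS, d = 0.95 + .OPEN_EPS,
                  e = 0.000001 + .OPEN_EPS, f = -10 + .OPEN_EPS),
        upper = c(b = 250 - .OPEN_EPS, c = 10 - .OPEN_EPS, d = 1.05 - .OPEN_EPS,
                  e = .BIG, f = .BIG),
        start = function(dose, y) .start_crs(dose, y, free_c = TRUE),
        hormesis = TRUE)
    } else {
      .family_def(paste0("CRS.4", tag), .crs,
        fixed = c(alpha = al, c = 0),
        lower = c(b = 1 + .OPEN_EPS, d = 0.95 + .OPEN_EPS,
                  e = 0.000001 + .OPEN_EPS, f = -.BIG),
        upper = c(b = 250 - .OPEN_EPS, d = 1.05 - .OPEN_EPS, e = .BIG, f = .BIG),
        start = function(dose, y) .start_crs(dose, y, free_c = FALSE),
        hormesis = TRUE)
    }
  })
}

.FAMILIES <- local({
  fams <- list(
    .family_def("LL.4", .ll4,
      fixed = c(d = 1),
      lower = c(b = 1 + .OPEN_EPS, c = .OPEN_EPS, e = 0.0001 + .OPEN_EPS),
      upper = c(b = .BIG, c = 1 - .OPEN_EPS, e = .BIG),
      start = function(dose, y) .start_sigmoid(dose, y, 2)),
    .family_def("W1.4", .w14,
      fixed = c(d = 1),
      lower = c(b = 1 + .OPEN_EPS, c = .OPEN_EPS, e = 0.0001 + .OPEN_EPS),
      upper = c(b = 50 - .OPEN_EPS, c = 1 - .OPEN_EPS, e = .BIG),
      start = function(dose, y) .start_sigmoid(dose, y, 2)),
    .family_def("W2.4", .w24,
      fixed = c(d = 1),
      lower = c(b = -50 + .OPEN_EPS, c = .OPEN_EPS, e = 0.0001 + .OPEN_EPS),
      upper = c(b = -0.3 - .OPEN_EPS, c = 1 - .OPEN_EPS, e = 10000 - .OPEN_EPS),
      start = function(dose, y) .start_sigmoid(dose, y, -2, e_hi = 10000)),
    .family_def("EXD.3", .exd3,
      fixed = c(d = 1),
      lower = c(c = .OPEN_EPS, e = 0.0001 + .OPEN_EPS),
      upper = c(c = .BIG, e = 10000 - .OPEN_EPS),
      start = function(dose, y) exd_selfstart(dose, y))
  )
  fams <- c(fams, .crs_fams(five = FALSE), .crs_fams(five = TRUE))
  fams <- c(fams, list(
    .family_def("BC.5", .bc5,
      fixed = c(d = 1),
      lower = c(b = 1 + .OPEN_EPS, c = .OPEN_EPS, e = .OPEN_EPS,
                f = 0.000001 + .OPEN_EPS),
      upper = c(b = .BIG, c = .BIG, e = .BIG, f = .BIG),
      start = .start_bc5, hormesis = TRUE),
    .family_def("RBC.5", .rbc5,
      fixed = c(d = 1, M = NA_real_),      # M fixed dynamically at fit time
      lower = c(b = 1 + .OPEN_EPS, c = .OPEN_EPS, f = 0.000001 + .OPEN_EPS),
      upper = c(b = 50 - .OPEN_EPS, c = .BIG, f = .BIG),
      start = function(dose, y) {
        st <- .start_bc5(dose, y)
        st[c("b", "c", "f")]
      },
      hormesis = TRUE)
  ))
  names(fams) <- vapply(fams, `[[`, "", "name")
  fams
})

#' Names of the dose-response model families
#'
#' The eleven families considered by the fitting pipeline: the
#' four-parameter log-logistic (LL.4), both Weibull parameterizations
#' (W1.4, W2.4), three-parameter exponential decay (EXD.3), five
#' Cedergreen-Ritz-Streibig hormesis variants (CRS.4a/b/c with the lower
#' asymptote fixed at 0 and alpha fixed at 1, 0.5 and 0.25; CRS.5a/b with a
#' free lower asymptote and alpha 1 and 0.5), the Brain-Cousens hormesis
#' model (BC.5) and its peak-dose reparametrization (RBC.5).
#'
#' @return character vector of family names.
#' @export
drm_families <- function() names(.FAMILIES)

.get_family <- function(family) {
  fam <- .FAMILIES[[family]]
  if (is.null(fam)) stop("unknown model family: ", family)
  fam
}

#' Evaluate a dose-response family
#'
#' Evaluates the named family at the given doses on the survival-fraction
#' scale (1.0 = 100 % survival). `params` must contain every parameter of
#' the family (free and fixed alike), e.g. `c(b = 2, c = 0, d = 1, e = 50)`
#' for LL.4, or `b, c, d, f, M` for RBC.5.
#'
#' @param family family name (see [drm_families()]).
#' @param params named numeric vector of parameter values.
#' @param dose numeric vector of doses (all `>= 0`).
#' @return numeric vector of predicted survival fractions.
#' @examples
#' drm_curve("LL.4", c(b = 1, c = 0, d = 1, e = 10), c(0, 10))  # 1.0, 0.5
#' @export
drm_curve <- function(family, params, dose) {
  fam <- .get_family(family)
  if (any(dose < 0)) stop("dose must be non-negative")
  need <- unique(c(fam$free, names(fam$fixed)))
  miss <- setdiff(need, names(params))
  if (length(miss)) stop("missing parameters: ", paste(miss, collapse = ", "))
  fam$fun(params, dose)
}

#' Candidate model lists per response category
#'
#' The Decreasing category considers LL.4, W1.4, W2.4 and EXD.3; Plateau
#' adds the five CRS hormesis variants; Growth further adds BC.5 and RBC.5.
#'
#' @param category one of `"Decreasing"`, `"Plateau"`, `"Growth"`.
#' @return list of family definitions (name, fixed parameters, box limits,
#'   self-starter).
#' @export
model_registry <- function(category = c("Decreasing", "Plateau", "Growth")) {
  category <- match.arg(category)
  nm <- switch(category,
    Decreasing = c("LL.4", "W1.4", "W2.4", "EXD.3"),
    Plateau    = c("LL.4", "W1.4", "W2.4", "EXD.3",
                   "CRS.4a", "CRS.4b", "CRS.4c", "CRS.5a", "CRS.5b"),
    Growth     = c("LL.4", "W1.4", "W2.4", "EXD.3",
                   "CRS.4a", "CRS.4b", "CRS.4c", "CRS.5a", "CRS.5b",
                   "BC.5", "RBC.5"))
  .FAMILIES[nm]
}

#' Serialize the model registry to JSON
#'
#' Writes family names, fixed parameters and box limits for each category,
#' so the exact fitting configuration is reviewable as data.
#'
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
registry_json <- function(path) {
  out <- lapply(c("Decreasing", "Plateau", "Growth"), function(cat) {
    lapply(model_registry(cat), function(f) {
      list(family = f$name, fixed = as.list(f$fixed),
           lower = as.list(f$lower), upper = as.list(f$upper))
    })
  })
  names(out) <- c("Decreasing", "Plateau", "Growth")
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
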