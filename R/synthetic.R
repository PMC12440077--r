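# Seeded synthetic plate images and dose-response datasets.
#
# The plate generator emulates the assay's multimodal six-well plate
# images: a grayscale brightfield channel showing two elliptical brain
# slices per well (optionally with bright reflection arcs near the well
# walls), and a signal channel carrying either focal bioluminescent
# micro-tumor spots (one per slice hemisphere, spanning up to a 100-fold
# intensity range) or diffuse cell-death fluorescence. Exhaustive ground
# truth (label image, per-hemisphere integrated spot intensities,
# per-slice mean fluorescence, noiseless channels) accompanies every
# image, so every downstream measurement has an oracle.
#
# All randomness flows from the single integer seed in the spec through
# R's default Mersenne-Twister generator; identical seeds give
# bit-identical output.

#' Specification of a synthetic multimodal plate image
#'
#' @param n_rows,n_cols well-grid dimensions (default 2 x 3, a six-well
#'   plate).
#' @param image_size image height and width in pixels.
#' @param slices_per_well slices per well (default 2: top and bottom).
#' @param slice_axes semi-major and semi-minor axis of each elliptical
#'   slice, pixels.
#' @param slice_angle nominal slice orientation, degrees (each slice gets
#'   a small seeded jitter around this).
#' @param background_level brightfield background intensity.
#' @param slice_level brightfield intensity added inside a slice.
#' @param reflection_artifacts add bright elliptical arcs near the well
#'   walls (exercises fallback segmentation robustness).
#' @param tumor_spots data frame with columns `well_row`, `well_col`
#'   (0-based), `position` (`"top"`/`"bottom"`), `hemisphere`
#'   (`"left"`/`"right"`), `intensity` (integrated signal) and `sigma`
#'   (spot Gaussian width, pixels); or `NULL` for none.
#' @param pi_mean per-slice mean of diffuse death-marker fluorescence
#'   added to the signal channel under each slice mask (scalar or one
#'   value per slice); 0 for none.
#' @param noise_sd Gaussian noise SD added to both channels.
#' @param seed integer seed driving all randomness.
#' @return a `plate_spec` list.
#' @export
plate_spec <- function(n_rows = 2L, n_cols = 3L, image_size = c(480L, 720L),
                       slices_per_well = 2L, slice_axes = c(55, 35),
                       slice_angle = 10, background_level = 100,
                       slice_level = 80, reflection_artifacts = FALSE,
                       tumor_spots = NULL, pi_mean = 0, noise_sd = 1,
                       seed = 1L) {
  stopifnot(n_rows >= 1, n_cols >= 1, length(image_size) == 2,
            slices_per_well %in% 1:2, length(slice_axes) == 2,
            all(slice_axes > 0), background_level >= 0, noise_sd >= 0,
            all(pi_mean >= 0))
  if (!is.null(tumor_spots)) {
    stopifnot(is.data.frame(tumor_spots),
              all(c("well_row", "well_col", "position", "hemisphere",
                    "intensity", "sigma") %in% names(tumor_spots)),
              all(tumor_spots$intensity >= 0))
  }
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 image_size = as.integer(image_size),
                 slices_per_well = as.integer(slices_per_well),
                 slice_axes = slice_axes, slice_angle = slice_angle,
                 background_level = background_level,
                 slice_level = slice_level,
                 reflection_artifacts = isTRUE(reflection_artifacts),
                 tumor_spots = tumor_spots, pi_mean = pi_mean,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "plate_spec")
}

# pixel-center coordinate grids (row-major, 0-based, origin top-left)
.coord_grids <- function(h, w) {
  list(row = matrix(rep(0:(h - 1L), w), h, w),
       col = matrix(rep(0:(w - 1L), each = h), h, w))
}

.ellipse_mask <- function(grids, cy, cx, a, b, theta) {
  ct <- cos(theta); st <- sin(theta)
  dx <- grids$col - cx; dy <- grids$row - cy
  u <- dx * ct + dy * st       # along major axis
  v <- -dx * st + dy * ct
  (u / a)^2 + (v / b)^2 <= 1
}

#' Generate a synthetic plate image with ground truth
#'
#' Renders the brightfield and signal channels described by a
#' [plate_spec()] and returns them with exhaustive ground truth. Slices
#' are placed by rejection sampling: each slice center is jittered inside
#' its well cell and re-drawn (up to `max_retries` times) until the
#' ellipse lies fully inside the cell and does not overlap its
#' well-mate; failure to place raises an error rather than permitting
#' silent overlap.
#'
#' @param spec a [plate_spec()].
#' @param max_retries placement retries per slice before giving up.
#' @return list with `plate` (a `plate_image`: `brightfield`, `signal`
#'   matrices and `channel_kind`) and `truth` (label image, slice table,
#'   spot table, noiseless channels).
#' @export
generate_plate_image <- function(spec, max_retries = 100L) {
  stopifnot(inherits(spec, "plate_spec"))
  h <- spec$image_size[1]; w <- spec$image_size[2]
  cell_h <- h / spec$n_rows; cell_w <- w / spec$n_cols
  a <- spec$slice_axes[1]; b <- spec$slice_axes[2]
  grids <- .coord_grids(h, w)

  .with_seed(spec$seed, {
    labels <- matrix(0L, h, w)
    slices <- NULL
    lab <- 0L
    for (wr in 0:(spec$n_rows - 1L)) for (wc in 0:(spec$n_cols - 1L)) {
      pos_names <- c("top", "bottom")[seq_len(spec$slices_per_well)]
      frac <- if (spec$slices_per_well == 2L) c(0.27, 0.73) else 0.5
      for (si in seq_len(spec$slices_per_well)) {
        placed <- FALSE
        for (try in seq_len(max_retries)) {
          cy <- wr * cell_h + frac[si] * cell_h + runif(1, -8, 8)
          cx <- wc * cell_w + 0.5 * cell_w + runif(1, -12, 12)
          th <- (spec$slice_angle + runif(1, -5, 5)) * pi / 180
          m <- .ellipse_mask(grids, cy, cx, a, b, th)
          idx <- which(m)
          rr <- grids$row[idx]; cc <- grids$col[idx]
          inside <- all(rr >= wr * cell_h, rr < (wr + 1) * cell_h,
                        cc >= wc * cell_w, cc < (wc + 1) * cell_w)
          if (inside && !any(labels[idx] != 0L)) {
            lab <- lab + 1L
            labels[idx] <- lab
            slices <- rbind(slices, data.frame(
              label = lab, well_row = wr, well_col = wc,
              position = pos_names[si], cy = cy, cx = cx, angle = th,
              area = length(idx), stringsAsFactors = FALSE))
            placed <- TRUE
            break
          }
        }
        if (!placed) {
          stop("could not place slice in well (", wr, ",", wc,
               ") without overlap after ", max_retries, " retries")
        }
      }
    }

    bf0 <- matrix(spec$background_level, h, w)
    bf0[labels > 0L] <- bf0[labels > 0L] + spec$slice_level
    if (spec$reflection_artifacts) {
      # bright arcs hugging each well wall (upper-left quadrant of a ring)
      for (wr in 0:(spec$n_rows - 1L)) for (wc in 0:(spec$n_cols - 1L)) {
        cy <- (wr + 0.5) * cell_h; cx <- (wc + 0.5) * cell_w
        ra <- 0.48 * cell_w; rb <- 0.48 * cell_h
        ring <- .ellipse_mask(grids, cy, cx, ra, rb, 0) &
          !.ellipse_mask(grids, cy, cx, ra - 4, rb - 4, 0) &
          grids$row < cy & grids$col < cx
        bf0[ring] <- bf0[ring] + 150
      }
    }

    pim <- rep_len(spec$pi_mean, nrow(slices))
    sig0 <- matrix(0, h, w)
    for (i in seq_len(nrow(slices))) {
      if (pim[i] > 0) sig0[labels == slices$label[i]] <- pim[i]
    }

    spots <- NULL
    if (!is.null(spec$tumor_spots)) {
      for (i in seq_len(nrow(spec$tumor_spots))) {
        sp <- spec$tumor_spots[i, ]
        sl <- slices[slices$well_row == sp$well_row &
                     slices$well_col == sp$well_col &
                     slices$position == sp$position, ]
        if (nrow(sl) != 1L) stop("tumor spot refers to a missing slice")
        u <- c(cos(sl$angle), sin(sl$angle)) * a / 2
        sgn <- if (identical(sp$hemisphere, "left")) -1 else 1
        sy <- sl$cy + sgn * u[2]; sx <- sl$cx + sgn * u[1]
        k <- exp(-((grids$col - sx)^2 + (grids$row - sy)^2) /
                   (2 * sp$sigma^2))
        k <- k / sum(k) * sp$intensity
        sig0 <- sig0 + k
        spots <- rbind(spots, data.frame(
          label = sl$label, well_row = sp$well_row, well_col = sp$well_col,
          position = sp$position, hemisphere = sp$hemisphere,
          intensity = sp$intensity, row = sy, col = sx,
          stringsAsFactors = FALSE))
      }
    }

    bf <- bf0; sig <- sig0
    if (spec$noise_sd > 0) {
      bf <- pmax(bf0 + matrix(rnorm(h * w, 0, spec$noise_sd), h, w), 0)
      sig <- pmax(sig0 + matrix(rnorm(h * w, 0, spec$noise_sd), h, w), 0)
    }

    plate <- structure(list(brightfield = bf, signal = sig,
                            channel_kind = if (any(pim > 0)) "PI" else "BLI"),
                       class = "plate_image")
    truth <- list(labels = labels, slices = slices, spots = spots,
                  pi_mean = data.frame(label = slices$label, pi_mean = pim),
                  brightfield_noiseless = bf0, signal_noiseless = sig0,
                  spec = spec)
    list(plate = plate, truth = truth)
  })
}

#' Ground-truth hemisphere mask of a synthetic slice
#'
#' Reconstructs the left/right hemisphere mask of a generated slice from
#' the stored ellipse geometry: the slice pixels on the requested side of
#' the line through the ellipse center perpendicular to its major axis.
#'
#' @param truth the `truth` component of [generate_plate_image()].
#' @param label slice label id.
#' @param side `"left"` (smaller projection along the major axis) or
#'   `"right"`.
#' @return logical matrix.
#' @export
truth_hemisphere_mask <- function(truth, label, side = c("left", "right")) {
  side <- match.arg(side)
  sl <- truth$slices[truth$slices$label == label, ]
  if (nrow(sl) != 1L) stop("unknown label")
  dm <- dim(truth$labels)
  grids <- .coord_grids(dm[1], dm[2])
  proj <- (grids$col - sl$cx) * cos(sl$angle) +
          (grids$row - sl$cy) * sin(sl$angle)
  m <- truth$labels == label
  if (side == "left") m & (proj <= 0) else m & (proj > 0)
}

#' Specification of a synthetic dose-response experiment
#'
#' @param family model family generating the mean curve (see
#'   [drm_families()]).
#' @param params full named parameter vector for the family.
#' @param doses dose ladder; non-negative, strictly increasing, starting
#'   at 0 (the untreated control).
#' @param n_reps replicates per dose.
#' @param noise_sd Gaussian noise SD on the survival-fraction scale.
#' @param seed integer seed.
#' @param target_prefix prefix for generated target ids.
#' @param dose_units unit label stored with the dataset.
#' @return a `sim_curve_spec` list.
#' @export
sim_curve_spec <- function(family, params, doses, n_reps = 4L,
                           noise_sd = 0.02, seed = 1L,
                           target_prefix = "T", dose_units = "uM") {
  stopifnot(all(doses >= 0), !is.unsorted(doses, strictly = TRUE),
            doses[1] == 0, n_reps >= 1, noise_sd >= 0)
  .get_family(family)                       # errors on unknown family
  drm_curve(family, params, doses)          # errors on missing params
  structure(list(family = family, params = params, doses = doses,
                 n_reps = as.integer(n_reps), noise_sd = noise_sd,
                 seed = as.integer(seed), target_prefix = target_prefix,
                 dose_units = dose_units),
            class = "sim_curve_spec")
}

#' Simulate a replicate dose-response dataset
#'
#' Replicate survival values are the family curve at each dose plus
#' Gaussian noise of the specified SD, converted to percent. Doses of 0
#' are labeled `negative_control`, all others `treated`.
#'
#' @param spec a [sim_curve_spec()].
#' @return data frame with columns `target_id`, `dose`, `dose_units`,
#'   `group_role`, `survival_pct`.
#' @export
simulate_dose_response <- function(spec) {
  stopifnot(inherits(spec, "sim_curve_spec"))
  mu <- drm_curve(spec$family, spec$params, spec$doses)
  .with_seed(spec$seed, {
    dose <- rep(spec$doses, each = spec$n_reps)
    y <- rep(mu, each = spec$n_reps) +
      rnorm(length(dose), 0, spec$noise_sd)
    data.frame(
      target_id = paste0(spec$target_prefix, seq_along(dose)),
      dose = dose, dose_units = spec$dose_units,
      group_role = ifelse(dose == 0, "negative_control", "treated"),
      survival_pct = 100 * y, stringsAsFactors = FALSE)
  })
}

#' Simulate a paired tumor/slice experiment
#'
#' Generates a tumor-toxicity and a slice-toxicity dataset on a shared
#' dose ladder, the paired input of the Drug Sensitivity Score.
#'
#' @param tumor_spec,obsc_spec [sim_curve_spec()]s with identical dose
#'   ladders.
#' @return list with components `tumor` and `obsc`.
#' @export
generate_paired_experiment <- function(tumor_spec, obsc_spec) {
  stopifnot(inherits(tumor_spec, "sim_curve_spec"),
            inherits(obsc_spec, "sim_curve_spec"))
  if (!identical(tumor_spec$doses, obsc_spec$doses)) {
    stop("tumor and slice specs must share the same dose ladder")
  }
  list(tumor = simulate_dose_response(tumor_spec),
       obsc = simulate_dose_response(obsc_spec))
}

#' Write synthetic plate channels and ground truth to disk
#'
#' Channels and the label image go to 16-bit TIFF (one file per channel),
#' ground-truth tables to JSON.
#'
#' @param sim result of [generate_plate_image()].
#' @param dir output directory (created if needed).
#' @param scale intensity mapped to the 16-bit ceiling; defaults to the
#'   maximum over both channels.
#' @return named character vector of written paths, invisibly.
#' @export
write_plate <- function(sim, dir, scale = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(scale)) {
    scale <- max(sim$plate$brightfield, sim$plate$signal, 1)
  }
  paths <- c(brightfield = file.path(dir, "brightfield.tif"),
             signal = file.path(dir, "signal.tif"),
             labels = file.path(dir, "labels.tif"),
             truth = file.path(dir, "truth.json"))
  tiff::writeTIFF(pmin(sim$plate$brightfield / scale, 1),
                  paths[["brightfield"]], bits.per.sample = 16L)
  tiff::writeTIFF(pmin(sim$plate$signal / scale, 1), paths[["signal"]],
                  bits.per.sample = 16L)
  tiff::writeTIFF(sim$truth$labels / 65535, paths[["labels"]],
                  bits.per.sample = 16L)
  jsonlite::write_json(
    list(scale = scale, slices = sim$truth$slices, spots = sim$truth$spots,
         pi_mean = sim$truth$pi_mean),
    paths[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
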