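# Shared fixtures, built in code at test time.

# replicate dataset with exact group means and tiny symmetric jitter
make_dataset <- function(doses, means, reps = 3, jitter = 0.01) {
  stopifnot(length(doses) == length(means))
  offs <- seq(-jitter, jitter, length.out = reps)
  offs <- offs - mean(offs)
  data.frame(
    dose = rep(doses, each = reps),
    survival_pct = 100 * (rep(means, each = reps) + rep(offs, length(doses))))
}

# fitted-model object for a known curve, with attached data so the
# plausibility screen and data-dependent windows can run on it
synthetic_fit <- function(family, params, doses, means = NULL) {
  fit <- as_drm(family, params)
  if (is.null(means)) means <- drm_curve(family, params, doses)
  fit$data <- data.frame(dose = doses, y = means)
  fit
}

# independent triangle-threshold oracle: rebuild the same histogram and
# take the argmax of true perpendicular point-to-chord distances
triangle_oracle_bin <- function(values, n_bins = 256L) {
  rng <- range(values)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  counts <- tabulate(
    pmin(findInterval(values, breaks, rightmost.closed = TRUE), n_bins),
    nbins = n_bins)
  peak <- which.max(counts)
  nz <- which(counts > 0)
  tail_right <- (max(nz) - peak) >= (peak - min(nz))
  tail <- if (tail_right) max(nz) else min(nz)
  if (tail == peak) return(NA_integer_)
  x1 <- peak; y1 <- counts[peak]; x2 <- tail; y2 <- counts[tail]
  len <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
  inner <- if (tail_right) seq(peak, tail) else seq(tail, peak)
  d <- abs((y2 - y1) * inner - (x2 - x1) * counts[inner] +
             x2 * y1 - y2 * x1) / len
  scan <- if (tail_right) seq_along(inner) else rev(seq_along(inner))
  inner[scan[which.max(d[scan])]]
}

# rasterized ellipse mask (semi-axes a >= b, angle in degrees)
ellipse_matrix <- function(h, w, cy, cx, a, b, angle_deg) {
  th <- angle_deg * pi / 180
  row <- matrix(rep(0:(h - 1L), w), h, w)
  col <- matrix(rep(0:(w - 1L), each = h), h, w)
  dx <- col - cx; dy <- row - cy
  u <- dx * cos(th) + dy * sin(th)
  v <- -dx * sin(th) + dy * cos(th)
  (u / a)^2 + (v / b)^2 <= 1
}

iou <- function(a, b) sum(a & b) / sum(a | b)

# full synthetic experiment: tumor plate + slice-toxicity plate -> DSS.
# Wells 1-5 of each plate carry the shared dose ladder; the tumor
# plate's 6th well replicates the top dose, the slice plate's 6th well
# is the positive control.
run_synthetic_experiment <- function(seed = 1, out_dir = NULL) {
  doses <- c(0, 2, 10, 50, 200)
  tum_params <- c(b = 2, c = 0.05, d = 1, e = 30)
  obsc_params <- c(b = 1.5, c = 0.55, d = 1, e = 150)
  well_dose_t <- c(doses, 200)

  # tumor plate: spot intensity proportional to per-tumor survival
  base_i <- 20000
  spots <- do.call(rbind, lapply(1:6, function(wi) {
    wr <- (wi - 1) %/% 3; wc <- (wi - 1) %% 3
    s <- drm_curve("LL.4", tum_params, well_dose_t[wi])
    expand.grid(position = c("top", "bottom"),
                hemisphere = c("left", "right"),
                stringsAsFactors = FALSE) |>
      transform(well_row = wr, well_col = wc,
                intensity = base_i * s, sigma = 3)
  }))
  sim_t <- generate_plate_image(plate_spec(tumor_spots = spots,
                                           noise_sd = 0.5, seed = seed))
  masks_t <- assign_wells(ingest_masks(sim_t$truth$labels))
  meas_t <- measure_plate(sim_t$plate, masks_t, kind = "tumor")
  widx <- meas_t$well_row * 3 + meas_t$well_col + 1
  tumor_raw <- data.frame(
    target_id = meas_t$target_id, dose = well_dose_t[widx],
    dose_units = "uM",
    group_role = ifelse(well_dose_t[widx] == 0, "negative_control",
                        "treated"),
    raw_signal = meas_t$value)

  # slice plate: diffuse death marker; well 6 = positive control
  pi_neg <- 40; pi_pos <- 240
  kill <- 1 - drm_curve("LL.4", obsc_params, doses)
  well_pi <- c(pi_neg + (pi_pos - pi_neg) * kill, pi_pos)
  pi_per_slice <- rep(well_pi, each = 2)
  sim_o <- generate_plate_image(plate_spec(pi_mean = pi_per_slice,
                                           noise_sd = 0.5,
                                           seed = seed + 1))
  masks_o <- assign_wells(ingest_masks(sim_o$truth$labels))
  meas_o <- measure_plate(sim_o$plate, masks_o, kind = "pi")
  widx_o <- meas_o$well_row * 3 + meas_o$well_col + 1
  role_o <- ifelse(widx_o == 6, "positive_control",
                   ifelse(doses[widx_o] == 0, "negative_control", "treated"))
  obsc_raw <- data.frame(
    target_id = meas_o$target_id,
    dose = ifelse(widx_o == 6, max(doses), doses[widx_o]),
    dose_units = "uM", group_role = role_o, raw_signal = meas_o$value)
  # the positive control calibrates the kill scale but is not a dose group
  obsc_surv <- obsc_survival(obsc_raw)
  obsc_surv <- obsc_surv[obsc_surv$group_role != "positive_control", ]

  run_experiment(tumor_survival(tumor_raw), obsc_surv,
                 config = run_config(seed = seed), out_dir = out_dir)
}
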