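# Triangle thresholding, mask bisection, well assignment, measurement.

test_that("triangle threshold equals the exhaustive per-bin distance argmax", {
  set.seed(41)
  for (i in 1:25) {
    vals <- switch(1 + i %% 3,
      c(rep(0, 3000), rgamma(300, shape = 1.5, scale = 40)),
      c(rnorm(2000, 20, 3), rlnorm(150, 4, 0.6)),
      c(rep(0, 5000), runif(80, 100, 255), rnorm(500, 10, 2)))
    vals <- pmax(vals, 0)
    tt <- triangle_threshold(vals)
    expect_identical(tt$bin, triangle_oracle_bin(vals), label = paste("case", i))
  }
})

test_that("triangle threshold separates a sparse bright population", {
  v <- c(rep(0, 9900), rep(255, 100))
  tt <- triangle_threshold(v)
  expect_gt(tt$threshold, 0)
  expect_lt(tt$threshold, 255)
  expect_equal(sum(v > tt$threshold), 100)
  # constant sample: degenerate flag, threshold = the value
  td <- triangle_threshold(rep(7, 50))
  expect_true(td$degenerate)
  expect_equal(td$threshold, 7)
})

test_that("bisected hemispheres partition the parent mask exactly", {
  set.seed(42)
  for (i in 1:12) {
    m <- ellipse_matrix(200, 260, runif(1, 70, 130), runif(1, 80, 180),
                        runif(1, 30, 60), runif(1, 15, 28),
                        runif(1, 0, 180))
    hp <- bisect_mask(m)
    expect_false(any(hp$left & hp$right))
    expect_identical(hp$left | hp$right, m)
  }
})

test_that("bisection halves symmetric masks and tracks the centroid", {
  # axis-aligned ellipse, major 200 px, minor 100 px
  m <- ellipse_matrix(300, 400, 150, 200, 100, 50, 0)
  hp <- bisect_mask(m)
  expect_lt(abs(sum(hp$left) - sum(hp$right)) / sum(m), 0.02)

  # the same ellipse rotated 37 degrees: areas stay equal and the
  # dividing line passes within a pixel of the centroid
  m37 <- ellipse_matrix(400, 400, 200, 200, 100, 50, 37)
  hp37 <- bisect_mask(m37)
  expect_lt(abs(sum(hp37$left) - sum(hp37$right)) / sum(m37), 0.02)
  idx <- which(m37)
  cen <- c(mean((idx - 1) %% 400), mean((idx - 1) %/% 400))  # row, col
  # distance from the centroid to the dividing line
  p1 <- c(hp37$line$row[1], hp37$line$col[1])
  p2 <- c(hp37$line$row[2], hp37$line$col[2])
  v <- p2 - p1
  dist <- abs(v[1] * (cen[2] - p1[2]) - v[2] * (cen[1] - p1[1])) /
    sqrt(sum(v^2))
  expect_lt(dist, 1)

  # perfect circle: ambiguous long axis resolves to a vertical split
  mc <- ellipse_matrix(200, 200, 100, 100, 60, 60, 0)
  hpc <- bisect_mask(mc)
  expect_lt(abs(sum(hpc$left) - sum(hpc$right)) / sum(mc), 0.02)
  idxl <- which(hpc$left); idxr <- which(hpc$right)
  expect_lt(max((idxl - 1) %/% 200), min((idxr - 1) %/% 200) + 1)

  expect_error(bisect_mask(matrix(FALSE, 5, 5)), "2 pixels")
})

test_that("well assignment follows grid arithmetic and top-before-bottom", {
  lab <- matrix(0L, 200, 300)
  lab[55:65, 55:65] <- 1L   # centroid (0.3 H, 0.2 W) -> well (0, 0)
  lab[95:105, 40:50] <- 2L  # same well, lower -> bottom
  ms <- assign_wells(ingest_masks(lab), n_rows = 2, n_cols = 3)
  sl <- ms$slices
  expect_equal(sl$well_row, c(0, 0))
  expect_equal(sl$well_col, c(0, 0))
  expect_equal(sl$position, c("top", "bottom"))
  expect_lt(sl$row[1], sl$row[2])

  # centroid exactly on a cell boundary goes to the lower cell index
  lab2 <- matrix(0L, 200, 300)
  lab2[96:104, 96:104] <- 1L  # centroid (100, 100): boundaries at 100
  ms2 <- assign_wells(ingest_masks(lab2), n_rows = 2, n_cols = 3)
  expect_equal(ms2$slices$well_row, 0)
  expect_equal(ms2$slices$well_col, 0)

  empty <- assign_wells(ingest_masks(matrix(0L, 10, 10)))
  expect_equal(nrow(empty$slices), 0)
})

test_that("mask ingestion preserves labels and validates shape", {
  lab <- matrix(0L, 50, 50)
  lab[10:20, 10:20] <- 3L
  ms <- ingest_masks(lab)
  expect_identical(ms$labels, lab)
  expect_equal(ms$slices$label, 3L)
  plate <- plate_image(matrix(1, 40, 40), matrix(0, 40, 40))
  expect_error(ingest_masks(lab, plate), "shape")
  expect_error(ingest_masks(lab + 0.5), "integer")
})

test_that("mean-fluorescence measurement is exact on constant fields", {
  sig <- matrix(0, 60, 60)
  mask <- ellipse_matrix(60, 60, 30, 30, 20, 12, 15)
  sig[mask] <- 40
  plate <- plate_image(matrix(1, 60, 60), sig, "PI")
  expect_equal(measure_pi(plate, mask)$value, 40)

  one <- matrix(FALSE, 60, 60); one[5, 5] <- TRUE
  sig1 <- matrix(0, 60, 60); sig1[5, 5] <- 7
  expect_equal(measure_pi(plate_image(matrix(1, 60, 60), sig1), one)$value, 7)
  expect_error(measure_pi(plate, matrix(FALSE, 60, 60)), "empty")
})

test_that("tumor measurement recovers spot intensities across a 100x range", {
  spots <- data.frame(well_row = 0, well_col = c(0, 0), position = "top",
                      hemisphere = c("left", "right"),
                      intensity = c(500, 50000), sigma = 3)
  sim <- generate_plate_image(plate_spec(tumor_spots = spots, noise_sd = 0,
                                         seed = 21))
  hp <- bisect_mask(sim$truth$labels == 1)
  vals <- c(measure_tumor_signal(sim$plate, hp$left)$value,
            measure_tumor_signal(sim$plate, hp$right)$value)
  expect_lt(abs(min(vals) - 500) / 500, 0.05)
  expect_lt(abs(max(vals) - 50000) / 50000, 0.05)

  # signal-free hemisphere on a noiseless background measures zero
  hp2 <- bisect_mask(sim$truth$labels == 2)
  expect_equal(measure_tumor_signal(sim$plate, hp2$left)$value, 0)
})

test_that("single-tumor whole-image measurement recovers the spot", {
  spots <- data.frame(well_row = 0, well_col = 0, position = "top",
                      hemisphere = "left", intensity = 2000, sigma = 3)
  sim <- generate_plate_image(plate_spec(
    n_rows = 1, n_cols = 1, image_size = c(240, 240), slices_per_well = 1,
    tumor_spots = transform(spots, position = "top"), noise_sd = 0,
    seed = 5))
  m <- measure_d1t(sim$plate)
  expect_lt(abs(m$value - 2000) / 2000, 0.05)

  blank <- plate_image(matrix(1, 20, 20), matrix(0, 20, 20))
  mb <- measure_d1t(blank)
  expect_true(mb$degenerate)
  expect_equal(mb$value, 0)
})

test_that("fallback segmentation recovers synthetic slices", {
  sim <- generate_plate_image(plate_spec(noise_sd = 1, seed = 33))
  seg <- segment_slices_fallback(sim$plate$brightfield)
  expect_equal(nrow(seg$slices), 12)
  best <- vapply(sim$truth$slices$label, function(l) {
    gt <- sim$truth$labels == l
    max(vapply(seg$slices$label, function(k) iou(gt, seg$labels == k),
               numeric(1)))
  }, numeric(1))
  expect_true(all(best >= 0.9))

  expect_warning(empty <- segment_slices_fallback(matrix(5, 50, 50)),
                 "constant|no component")
  expect_equal(nrow(empty$slices), 0)
})

test_that("segmentation survives reflection artifacts and touching slices", {
  sim <- generate_plate_image(plate_spec(reflection_artifacts = TRUE,
                                         noise_sd = 1, seed = 8))
  seg <- segment_slices_fallback(sim$plate$brightfield)
  best <- vapply(sim$truth$slices$label, function(l) {
    gt <- sim$truth$labels == l
    max(vapply(seg$slices$label, function(k) iou(gt, seg$labels == k),
               numeric(1)))
  }, numeric(1))
  expect_true(all(best >= 0.9))

  # two ellipses touching end to end: the watershed must split them
  bf <- matrix(100, 240, 240)
  m1 <- ellipse_matrix(240, 240, 80, 120, 55, 35, 90)
  m2 <- ellipse_matrix(240, 240, 170, 120, 55, 35, 90)
  bf[m1 | m2] <- 180
  seg2 <- segment_slices_fallback(bf)
  expect_equal(nrow(seg2$slices), 2)
  ious <- vapply(list(m1, m2), function(gt) {
    max(vapply(seg2$slices$label, function(k) iou(gt, seg2$labels == k),
               numeric(1)))
  }, numeric(1))
  expect_true(all(ious >= 0.8))
})

test_that("plate measurement walks wells top before bottom", {
  sim <- generate_plate_image(plate_spec(pi_mean = seq(10, 120, by = 10),
                                         noise_sd = 0, seed = 12))
  masks <- assign_wells(ingest_masks(sim$truth$labels))
  meas <- measure_plate(sim$plate, masks, kind = "pi")
  expect_equal(nrow(meas), 12)
  expect_equal(meas$position,
               rep(c("top", "bottom"), 6))
  # measured means match the generated per-slice means exactly
  expect_equal(meas$value, seq(10, 120, by = 10), tolerance = 1e-10)
})
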