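# Image measurement: well assignment, mask bisection, triangle
# thresholding, and region statistics.
#
# Conventions: images are numeric matrices indexed [row, col], row-major,
# 0-based pixel coordinates with the origin at the top-left pixel center.
# Masks are half-open pixel sets: every parent pixel belongs to exactly
# one hemisphere after bisection.

#' Bundle two co-registered channels as a plate image
#'
#' @param brightfield,signal numeric matrices of identical dimensions,
#'   intensities `>= 0`.
#' @param channel_kind what the signal channel measures: `"BLI"`
#'   (bioluminescence), `"mCherry"`, or `"PI"` (death-marker
#'   fluorescence).
#' @return a `plate_image` object.
#' @export
plate_image <- function(brightfield, signal,
                        channel_kind = c("BLI", "mCherry", "PI")) {
  channel_kind <- match.arg(channel_kind)
  stopifnot(is.matrix(brightfield), is.matrix(signal),
            identical(dim(brightfield), dim(signal)),
            all(brightfield >= 0), all(signal >= 0))
  structure(list(brightfield = brightfield, signal = signal,
                 channel_kind = channel_kind), class = "plate_image")
}

.mask_set <- function(labels, slices) {
  structure(list(labels = labels, slices = slices), class = "mask_set")
}

.centroids <- function(labels) {
  ids <- sort(setdiff(unique(as.integer(labels)), 0L))
  if (!length(ids)) {
    return(data.frame(label = integer(0), row = numeric(0),
                      col = numeric(0), area = integer(0),
                      well_row = integer(0), well_col = integer(0),
                      position = character(0), stringsAsFactors = FALSE))
  }
  h <- nrow(labels)
  rows <- vapply(ids, function(i) mean((which(labels == i) - 1L) %% h),
                 numeric(1))
  cols <- vapply(ids, function(i) mean((which(labels == i) - 1L) %/% h),
                 numeric(1))
  areas <- vapply(ids, function(i) sum(labels == i), integer(1))
  data.frame(label = ids, row = rows, col = cols, area = areas,
             well_row = NA_integer_, well_col = NA_integer_,
             position = NA_character_, stringsAsFactors = FALSE)
}

#' Ingest an externally produced slice label image
#'
#' Wraps a label image (e.g. downloaded from an external ML segmentation
#' service) as a mask set, preserving labels verbatim and computing
#' centroids. Wells and positions stay unassigned until [assign_wells()].
#'
#' @param label_image integer-valued matrix; 0 = background.
#' @param plate optional `plate_image` the masks belong to; when given,
#'   shapes must match.
#' @return a `mask_set`.
#' @export
ingest_masks <- function(label_image, plate = NULL) {
  if (!is.matrix(label_image) || any(label_image != round(label_image))) {
    stop("label image must be an integer-valued matrix")
  }
  if (!is.null(plate) &&
      !identical(dim(label_image), dim(plate$brightfield))) {
    stop("label image shape does not match the plate image")
  }
  labels <- matrix(as.integer(label_image), nrow(label_image))
  .mask_set(labels, .centroids(labels))
}

#' Fallback classical segmentation of slices from a brightfield image
#'
#' A classical pipeline standing in for external ML masks: Gaussian
#' smoothing, Otsu thresholding, hole filling, size filtering, connected
#' components, and a distance-map watershed to split touching slices.
#' Adequacy is defined against synthetic plates, not real tissue.
#'
#' @param brightfield numeric intensity matrix.
#' @param min_area discard components smaller than this many pixels.
#' @param smooth_sigma Gaussian smoothing SD in pixels.
#' @param watershed_tolerance minimum distance-map depth separating two
#'   objects; large values avoid over-splitting single slices.
#' @return a `mask_set`; empty (with a warning) when nothing exceeds
#'   `min_area`.
#' @export
segment_slices_fallback <- function(brightfield, min_area = 200L,
                                    smooth_sigma = 2, watershed_tolerance = 10) {
  stopifnot(is.matrix(brightfield), length(brightfield) > 0)
  rng <- range(brightfield)
  if (diff(rng) == 0) {
    warning("constant image; no slices found")
    return(.mask_set(matrix(0L, nrow(brightfield), ncol(brightfield)),
                     .centroids(matrix(0L, 1, 1))))
  }
  img <- EBImage::Image(t((brightfield - rng[1]) / diff(rng)))
  sm <- EBImage::gblur(img, sigma = smooth_sigma)
  bw <- sm > EBImage::otsu(sm)
  bw <- EBImage::fillHull(bw)
  lab <- EBImage::watershed(EBImage::distmap(bw),
                            tolerance = watershed_tolerance)
  labels <- t(EBImage::imageData(lab))
  # drop undersized components, relabel consecutively
  tab <- table(labels[labels > 0])
  keep <- as.integer(names(tab)[tab >= min_area])
  if (!length(keep)) {
    warning("no component above the minimum area; empty mask set")
    return(.mask_set(matrix(0L, nrow(brightfield), ncol(brightfield)),
                     .centroids(matrix(0L, 1, 1))))
  }
  out <- matrix(0L, nrow(labels), ncol(labels))
  for (i in seq_along(keep)) out[labels == keep[i]] <- i
  .mask_set(out, .centroids(out))
}

#' Assign slices to well-grid cells and top/bottom positions
#'
#' Divides the image into an `n_rows` x `n_cols` grid of equal cells (the
#' absolute well locations are consistent from image to image) and
#' assigns each slice to the cell containing its centroid; a centroid
#' exactly on a cell boundary goes to the lower cell index. Within each
#' well, the slice with the smaller centroid row is `"top"`, the other
#' `"bottom"`; measurement order is top before bottom. Wells holding more
#' than two slices are flagged.
#'
#' @param masks a `mask_set`.
#' @param n_rows,n_cols grid dimensions (default 2 x 3).
#' @param dims image dimensions; defaults to the label image's.
#' @return the `mask_set` with `well_row`, `well_col`, `position` filled
#'   in and slices ordered well-major, top before bottom.
#' @export
assign_wells <- function(masks, n_rows = 2L, n_cols = 3L,
                         dims = dim(masks$labels)) {
  stopifnot(inherits(masks, "mask_set"), n_rows >= 1, n_cols >= 1)
  sl <- masks$slices
  if (!nrow(sl)) return(masks)
  cell_idx <- function(x, extent, n) {
    pmin(pmax(ceiling(x / extent * n) - 1L, 0L), n - 1L)
  }
  sl$well_row <- cell_idx(sl$row, dims[1], n_rows)
  sl$well_col <- cell_idx(sl$col, dims[2], n_cols)
  sl$flag <- FALSE
  for (wr in unique(sl$well_row)) for (wc in unique(sl$well_col)) {
    i <- which(sl$well_row == wr & sl$well_col == wc)
    if (!length(i)) next
    i <- i[order(sl$row[i])]
    sl$position[i] <- c("top", "bottom", paste0("extra", seq_len(length(i))))[
      seq_along(i)]
    if (length(i) > 2L) {
      warning("more than 2 slices in well (", wr, ",", wc, "); flagged")
      sl$flag[i] <- TRUE
    }
  }
  sl <- sl[order(sl$well_row, sl$well_col, sl$row), , drop = FALSE]
  rownames(sl) <- NULL
  .mask_set(masks$labels, sl)
}

# minimum-area rotated bounding rectangle over the convex hull of pixel
# centers (rotating-calipers over hull edge directions)
.min_area_rect <- function(px, py) {
  hull <- grDevices::chull(px, py)
  hx <- px[hull]; hy <- py[hull]
  nh <- length(hull)
  best <- NULL
  for (i in seq_len(nh)) {
    j <- if (i == nh) 1L else i + 1L
    ex <- hx[j] - hx[i]; ey <- hy[j] - hy[i]
    len <- sqrt(ex^2 + ey^2)
    if (len == 0) next
    u <- c(ex, ey) / len; v <- c(-u[2], u[1])
    pu <- hx * u[1] + hy * u[2]
    pv <- hx * v[1] + hy * v[2]
    wu <- diff(range(pu)); wv <- diff(range(pv))
    area <- wu * wv
    if (is.null(best) || area < best$area - 1e-12) {
      best <- list(area = area, u = u, v = v, ru = range(pu), rv = range(pv))
    }
  }
  if (is.null(best)) {     # all hull points coincident or collinear fallback
    best <- list(area = 0, u = c(1, 0), v = c(0, 1), ru = range(px),
                 rv = range(py))
  }
  best
}

#' Bisect a slice mask across its long axis
#'
#' Computes the minimum-area rotated bounding rectangle of the mask and
#' splits the mask by the line through the rectangle center perpendicular
#' to its long axis — the anatomical midline, yielding one mask per slice
#' hemisphere. The halves are disjoint and cover the parent exactly
#' (pixels on the dividing line go to the `left` half). For a square
#' bounding box (e.g. a circular mask) the long axis is taken as the
#' candidate direction closest to horizontal, so the dividing line is
#' vertical.
#'
#' @param mask logical (or 0/1) matrix with at least 2 foreground pixels,
#'   assumed connected.
#' @return a `hemisphere_pair`: list with logical matrices `left` and
#'   `right`, the dividing-`line` endpoints (`row`,`col`), the long-axis
#'   unit vector `axis` and rectangle `center`.
#' @export
bisect_mask <- function(mask) {
  m <- mask != 0
  idx <- which(m)
  if (length(idx) < 2L) stop("mask must contain at least 2 pixels")
  h <- nrow(m)
  py <- (idx - 1L) %% h          # row (y)
  px <- (idx - 1L) %/% h         # col (x)
  rect <- .min_area_rect(px, py)
  wu <- diff(rect$ru); wv <- diff(rect$rv)
  if (abs(wu - wv) <= 0.02 * max(wu, wv)) {
    # near-square bounding box (e.g. a circle): no meaningful long axis;
    # deterministic tie-break takes it as horizontal, so the split is vertical
    long <- c(1, 0); ctr_proj <- mean(range(px))
    perp <- c(0, 1); ctr_perp <- mean(range(py))
    half_other <- diff(range(py)) / 2
  } else if (wu > wv) {
    long <- rect$u; ctr_proj <- mean(rect$ru)
    perp <- rect$v; ctr_perp <- mean(rect$rv); half_other <- wv / 2
  } else {
    long <- rect$v; ctr_proj <- mean(rect$rv)
    perp <- rect$u; ctr_perp <- mean(rect$ru); half_other <- wu / 2
  }
  # orient the axis deterministically (+x, ties +y) so "left" is the
  # smaller-x side regardless of hull traversal direction
  if (long[1] < 0 || (long[1] == 0 && long[2] < 0)) {
    long <- -long
    ctr_proj <- -ctr_proj
  }
  proj <- px * long[1] + py * long[2]
  left <- right <- matrix(FALSE, nrow(m), ncol(m))
  is_left <- proj <= ctr_proj
  left[idx[is_left]] <- TRUE
  right[idx[!is_left]] <- TRUE
  center <- c(col = long[1] * ctr_proj + perp[1] * ctr_perp,
              row = long[2] * ctr_proj + perp[2] * ctr_perp)
  ends <- rbind(center + c(perp[1], perp[2]) * half_other,
                center - c(perp[1], perp[2]) * half_other)
  structure(list(left = left, right = right,
                 line = data.frame(col = ends[, 1], row = ends[, 2]),
                 axis = long,
                 center = c(row = unname(center["row"]),
                            col = unname(center["col"]))),
            class = "hemisphere_pair")
}

#' Triangle (Zack) threshold of an intensity sample
#'
#' Builds a 256-bin histogram spanning the sample range, draws the chord
#' from the histogram peak to the furthest nonzero tail bin, and returns
#' the intensity of the bin with maximum perpendicular distance below
#' that chord, offset one bin toward the signal tail. Designed for dim
#' signals against a large, dark background. A constant-valued sample
#' returns that value with `degenerate = TRUE`.
#'
#' @param values numeric vector of pixel intensities (nonempty).
#' @param n_bins number of histogram bins (default 256).
#' @return list with `threshold`, `degenerate`, and the chosen `bin`.
#' @export
triangle_threshold <- function(values, n_bins = 256L) {
  stopifnot(length(values) > 0)
  rng <- range(values)
  if (diff(rng) == 0) {
    return(list(threshold = rng[1], degenerate = TRUE, bin = NA_integer_))
  }
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  counts <- tabulate(
    pmin(findInterval(values, breaks, rightmost.closed = TRUE), n_bins),
    nbins = n_bins)
  mids <- (breaks[-1] + breaks[-(n_bins + 1L)]) / 2
  peak <- which.max(counts)
  nz <- which(counts > 0)
  left_ext <- peak - min(nz)
  right_ext <- max(nz) - peak
  tail_right <- right_ext >= left_ext
  tail <- if (tail_right) max(nz) else min(nz)
  if (tail == peak) {      # single occupied bin: threshold just past it
    return(list(threshold = mids[peak], degenerate = TRUE, bin = peak))
  }
  # perpendicular distance to the peak->tail chord is a fixed positive
  # multiple of the vertical gap below the chord, so argmax by gap
  inner <- if (tail_right) seq(peak, tail) else seq(tail, peak)
  slope <- (counts[tail] - counts[peak]) / (tail - peak)
  gap <- (counts[peak] + slope * (inner - peak)) - counts[inner]
  scan <- if (tail_right) seq_along(inner) else rev(seq_along(inner))
  best_rel <- scan[which.max(gap[scan])]    # ties resolve toward the peak
  best <- inner[best_rel]
  off <- if (tail_right) 1L else -1L        # one bin toward the signal tail
  thr_bin <- pmin(pmax(best + off, 1L), n_bins)
  list(threshold = mids[thr_bin], degenerate = FALSE, bin = best)
}

.measurement <- function(target_id = NA_character_, value, statistic_kind,
                         threshold_used = NA_real_, degenerate = FALSE,
                         well_row = NA_integer_, well_col = NA_integer_,
                         position = NA_character_,
                         hemisphere = NA_character_) {
  data.frame(target_id = target_id, well_row = well_row,
             well_col = well_col, position = position,
             hemisphere = hemisphere, statistic_kind = statistic_kind,
             value = value, threshold_used = threshold_used,
             degenerate = degenerate, stringsAsFactors = FALSE)
}

#' Measure the integrated tumor signal within one hemisphere
#'
#' Triangle-thresholds the signal-channel pixels inside the hemisphere
#' mask and sums the pixels exceeding the threshold. Signal-free
#' hemispheres are not special-cased: the measurement is then the
#' background noise above threshold (0 for a noiseless background).
#'
#' @param plate a `plate_image`.
#' @param hemi logical hemisphere mask within the image bounds.
#' @param ... metadata columns passed through to the result row.
#' @return one-row measurement data frame (`statistic_kind =
#'   "integrated_above_threshold"`).
#' @export
measure_tumor_signal <- function(plate, hemi, ...) {
  stopifnot(identical(dim(hemi), dim(plate$signal)))
  vals <- plate$signal[hemi != 0]
  if (!length(vals)) stop("empty hemisphere mask")
  tt <- triangle_threshold(vals)
  value <- if (tt$degenerate) 0 else sum(vals[vals > tt$threshold])
  .measurement(value = value, statistic_kind = "integrated_above_threshold",
               threshold_used = tt$threshold, degenerate = tt$degenerate, ...)
}

#' Measure mean death-marker fluorescence under a slice mask
#'
#' @param plate a `plate_image`.
#' @param mask logical whole-slice mask (nonempty).
#' @param ... metadata columns passed through to the result row.
#' @return one-row measurement data frame (`statistic_kind = "mean"`).
#' @export
measure_pi <- function(plate, mask, ...) {
  stopifnot(identical(dim(mask), dim(plate$signal)))
  vals <- plate$signal[mask != 0]
  if (!length(vals)) stop("empty mask")
  .measurement(value = mean(vals), statistic_kind = "mean", ...)
}

#' Measure a single micro-tumor against a dark background
#'
#' For single-tumor images (one fluorescent micro-tumor, dark
#' background): triangle threshold over the whole image, integrated
#' signal above threshold. A constant image yields a flagged zero.
#'
#' @param plate a `plate_image`.
#' @param ... metadata columns passed through to the result row.
#' @return one-row measurement data frame.
#' @export
measure_d1t <- function(plate, ...) {
  vals <- as.vector(plate$signal)
  tt <- triangle_threshold(vals)
  value <- if (tt$degenerate) 0 else sum(vals[vals > tt$threshold])
  .measurement(value = value, statistic_kind = "integrated_above_threshold",
               threshold_used = tt$threshold, degenerate = tt$degenerate, ...)
}

#' Measure every slice on a plate
#'
#' Orchestrates per-slice measurement over a well-assigned mask set, in
#' measurement order (well-major, top slice before bottom). For
#' `kind = "tumor"` each slice is bisected ([bisect_mask()]) and each
#' hemisphere measured by [measure_tumor_signal()]; for `kind = "pi"`
#' the whole-slice mean is measured by [measure_pi()].
#'
#' @param plate a `plate_image`.
#' @param masks a well-assigned `mask_set` (see [assign_wells()]).
#' @param kind `"tumor"` or `"pi"`.
#' @param id_prefix prefix for generated target ids.
#' @return measurement data frame, one row per hemisphere (tumor) or
#'   slice (pi).
#' @export
measure_plate <- function(plate, masks, kind = c("tumor", "pi"),
                          id_prefix = "T") {
  kind <- match.arg(kind)
  sl <- masks$slices
  out <- list(); n <- 0L
  for (i in seq_len(nrow(sl))) {
    m <- masks$labels == sl$label[i]
    if (kind == "pi") {
      n <- n + 1L
      out[[n]] <- measure_pi(plate, m, target_id = paste0(id_prefix, n),
                             well_row = sl$well_row[i],
                             well_col = sl$well_col[i],
                             position = sl$position[i])
    } else {
      hp <- bisect_mask(m)
      for (side in c("left", "right")) {
        n <- n + 1L
        out[[n]] <- measure_tumor_signal(
          plate, hp[[side]], target_id = paste0(id_prefix, n),
          well_row = sl$well_row[i], well_col = sl$well_col[i],
          position = sl$position[i], hemisphere = side)
      }
    }
  }
  do.call(rbind, out)
}
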