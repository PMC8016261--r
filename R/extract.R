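#' Segment the nucleus from the DAPI channel
#'
#' Otsu threshold on the blue raster, keep the largest connected
#' component, and fill holes. Nuclei are assumed one per image.
#'
#' @param blue Numeric matrix (DAPI intensities).
#' @return Logical nucleus mask of the same shape.
#' @export
segment_nucleus <- function(blue) {
  if (!is.matrix(blue) || !is.numeric(blue))
    xs_parameter_error("blue must be a numeric matrix")
  rng <- range(blue)
  if (rng[1] == rng[2])
    xs_segmentation_error("blue channel is constant; cannot segment")
  x <- (blue - rng[1]) / (rng[2] - rng[1])
  th <- EBImage::otsu(EBImage::Image(x))
  mask <- x > th
  if (!any(mask))
    xs_segmentation_error("no foreground after thresholding")
  lab <- EBImage::bwlabel(mask)
  areas <- tabulate(lab[lab > 0])
  biggest <- which.max(areas)
  mask <- lab == biggest
  mask <- EBImage::imageData(EBImage::fillHull(mask * 1L)) > 0
  if (!any(mask))
    xs_segmentation_error("empty nucleus mask")
  mask
}

#' Detect the nucleolus as a low-DAPI region inside the nucleus
#'
#' Pixels below `fraction` of the median in-nucleus blue intensity are
#' candidates; the largest connected candidate component passing a
#' minimum-area filter is returned. An all-`FALSE` mask (no detectable
#' nucleolus) is a valid result. A known ground-truth mask can be passed
#' through unchanged via `override` (bypass mode), since nucleolar
#' territories are often identified by eye.
#'
#' @param blue Numeric matrix (DAPI intensities).
#' @param nucleus_mask Logical nucleus mask.
#' @param fraction Fraction of the median in-nucleus intensity below which
#'   a pixel is a nucleolus candidate (default 0.5).
#' @param min_area Minimum component area in pixels (default 25).
#' @param override Optional logical mask returned as-is.
#' @return Logical nucleolus mask (possibly empty).
#' @export
detect_nucleolus <- function(blue, nucleus_mask, fraction = 0.5,
                             min_area = 25L, override = NULL) {
  if (!is.null(override)) return(override)
  if (!any(nucleus_mask))
    xs_parameter_error("nucleus mask is empty")
  med <- stats::median(blue[nucleus_mask])
  cand <- nucleus_mask & (blue < fraction * med)
  empty <- matrix(FALSE, nrow(blue), ncol(blue))
  if (!any(cand)) return(empty)
  lab <- label_components8(cand)
  areas <- tabulate(lab[lab > 0])
  keep <- which(areas >= min_area)
  if (!length(keep)) return(empty)
  biggest <- keep[which.max(areas[keep])]
  lab == biggest
}

#' Locate the pixel of greatest RNA-FISH signal
#'
#' Returns the (row, col) coordinate of the maximal green value within the
#' nucleus mask. Ties are broken by smallest row, then smallest column, so
#' the result is deterministic.
#'
#' @param green Numeric matrix (RNA FISH intensities).
#' @param nucleus_mask Logical nucleus mask.
#' @return Integer vector `c(row, col)`.
#' @export
find_xist_peak <- function(green, nucleus_mask) {
  if (!any(nucleus_mask))
    xs_parameter_error("nucleus mask is empty")
  vals <- green[nucleus_mask]
  if (min(vals) == max(vals))
    xs_no_peak_error("green channel is constant over the nucleus")
  mx <- max(vals)
  hits <- which(nucleus_mask & green == mx, arr.ind = TRUE)
  hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
  as.integer(hits[1, ])
}

# Pixels traversed by the segment from a to b (inclusive): uniform
# parametric sampling with nearest-pixel rounding. One sample per step of
# the dominant axis, and exactly reversal-symmetric, so extracting the
# reversed segment yields the reversed pixel sequence.
raster_segment <- function(a, b) {
  n <- max(abs(b - a)) + 1L
  if (n == 1L) return(matrix(as.integer(a), 1L, 2L))
  t <- seq(0, 1, length.out = n)
  cbind(as.integer(round(a[1] + t * (b[1] - a[1]))),
        as.integer(round(a[2] + t * (b[2] - a[2]))))
}

#' Measurement chord through the RNA peak
#'
#' A line segment with inclusive integer endpoints, the angle it was placed
#' at (degrees in `[0, 180)`, 0 = along image columns) and its length in
#' samples.
#'
#' @param endpoint_a,endpoint_b Integer `c(row, col)` endpoints.
#' @param angle Angle in degrees.
#' @return An object of class `line_segment`.
#' @export
line_segment <- function(endpoint_a, endpoint_b, angle = NA_real_) {
  n <- max(abs(endpoint_b - endpoint_a)) + 1L
  structure(list(endpoint_a = as.integer(endpoint_a),
                 endpoint_b = as.integer(endpoint_b),
                 angle = angle, n_samples = n),
            class = "line_segment")
}

#' @export
print.line_segment <- function(x, ...) {
  cat(sprintf("<line_segment> (%d,%d) -> (%d,%d), angle %s deg, %d samples\n",
              x$endpoint_a[1], x$endpoint_a[2], x$endpoint_b[1],
              x$endpoint_b[2], format(x$angle), x$n_samples))
  invisible(x)
}

# Walk from `peak` in direction `d` (unit vector) and return the last
# rounded pixel still inside the mask.
walk_ray <- function(mask, peak, d) {
  last <- as.integer(peak)
  k <- 1L
  repeat {
    p <- as.integer(round(peak + k * d))
    if (p[1] < 1L || p[1] > nrow(mask) || p[2] < 1L || p[2] > ncol(mask) ||
        !mask[p[1], p[2]]) break
    last <- p
    k <- k + 1L
  }
  last
}

#' Place the measurement chord through the RNA peak
#'
#' Over a grid of angles (default 1 degree steps in `[0, 180)`), the chord
#' through the peak is clipped to the nucleus mask; chords touching the
#' nucleolus mask are discarded, and the longest remaining chord is
#' returned. This automates, deterministically, the manual step of drawing
#' the widest line through the RNA signal that avoids nucleolar
#' territories. Ties are broken towards the smallest angle.
#'
#' @param nucleus_mask Logical nucleus mask.
#' @param peak Integer `c(row, col)` as from [find_xist_peak()].
#' @param nucleolus_mask Optional logical nucleolus mask.
#' @param angle_step Angle grid step in degrees (default 1).
#' @return A [line_segment()].
#' @export
place_line <- function(nucleus_mask, peak, nucleolus_mask = NULL,
                       angle_step = 1) {
  peak <- as.integer(peak)
  if (!nucleus_mask[peak[1], peak[2]])
    xs_placement_error("peak lies outside the nucleus mask")
  if (!is.null(nucleolus_mask) && nucleolus_mask[peak[1], peak[2]])
    xs_placement_error("peak lies inside the nucleolus mask")
  best <- NULL
  blocked <- FALSE
  for (angle in seq(0, 180 - angle_step, by = angle_step)) {
    th <- angle * pi / 180
    d <- c(sin(th), cos(th))   # angle 0 runs along columns
    a <- walk_ray(nucleus_mask, peak, -d)
    b <- walk_ray(nucleus_mask, peak, d)
    pts <- raster_segment(a, b)
    if (!is.null(nucleolus_mask) &&
        any(nucleolus_mask[cbind(pts[, 1], pts[, 2])])) {
      blocked <- TRUE
      next
    }
    if (nrow(pts) < 10L) next
    if (is.null(best) || nrow(pts) > best$n_samples)
      best <- line_segment(a, b, angle = angle)
  }
  if (is.null(best)) {
    if (blocked)
      xs_no_chord_error("every candidate chord intersects the nucleolus")
    xs_no_chord_error("no chord of at least 10 samples through the peak")
  }
  best
}

#' Extract a line profile from a multi-channel image
#'
#' Samples all three channels at the integer pixel positions traversed by
#' the segment (nearest-pixel rasterisation, no interpolation), running
#' from `endpoint_a` to `endpoint_b`.
#'
#' @param image A [multi_channel_image()].
#' @param line A [line_segment()].
#' @param cell_id,construct,mark,treatment Metadata for the profile.
#' @return A [line_profile()].
#' @export
extract_profile <- function(image, line, cell_id = "cell",
                            construct = NA_character_, mark = NA_character_,
                            treatment = NA_character_) {
  stopifnot(inherits(image, "multi_channel_image"),
            inherits(line, "line_segment"))
  dm <- dim(image$red)
  ends <- rbind(line$endpoint_a, line$endpoint_b)
  if (min(ends) < 1L || max(ends[, 1]) > dm[1] || max(ends[, 2]) > dm[2])
    xs_parameter_error("segment endpoints fall outside the image")
  pts <- raster_segment(line$endpoint_a, line$endpoint_b)
  if (nrow(pts) < 10L)
    xs_too_short_error("segment traverses fewer than 10 samples")
  idx <- cbind(pts[, 1], pts[, 2])
  line_profile(seq_len(nrow(pts)),
               green = image$green[idx], red = image$red[idx],
               blue = image$blue[idx],
               cell_id = cell_id, construct = construct,
               mark = mark, treatment = treatment)
}

#' One-call profile extraction for a single-nucleus image
#'
#' Runs the full extraction chain: nucleus segmentation, nucleolus
#' detection (or a supplied ground-truth mask), RNA peak localisation,
#' chord placement and profile sampling.
#'
#' @param image A [multi_channel_image()].
#' @param nucleolus_mask Optional ground-truth nucleolus mask; when `NULL`
#'   the nucleolus is detected from the DAPI channel.
#' @param nucleolus_fraction,nucleolus_min_area Passed to
#'   [detect_nucleolus()].
#' @param angle_step Passed to [place_line()].
#' @param cell_id,construct,mark,treatment Metadata for the profile.
#' @return A list with elements `profile`, `line`, `nucleus_mask`,
#'   `nucleolus_mask` and `peak`.
#' @export
extract_cell_profile <- function(image, nucleolus_mask = NULL,
                                 nucleolus_fraction = 0.5,
                                 nucleolus_min_area = 25L, angle_step = 1,
                                 cell_id = "cell",
                                 construct = NA_character_,
                                 mark = NA_character_,
                                 treatment = NA_character_) {
  nucleus <- segment_nucleus(image$blue)
  nucleolus <- detect_nucleolus(image$blue, nucleus,
                                fraction = nucleolus_fraction,
                                min_area = nucleolus_min_area,
                                override = nucleolus_mask)
  peak <- find_xist_peak(image$green, nucleus)
  line <- place_line(nucleus, peak, nucleolus_mask = nucleolus,
                     angle_step = angle_step)
  prof <- extract_profile(image, line, cell_id = cell_id,
                          construct = construct, mark = mark,
                          treatment = treatment)
  list(profile = prof, line = line, nucleus_mask = nucleus,
       nucleolus_mask = nucleolus, peak = peak)
}
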