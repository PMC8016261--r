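#' Classify profile pixels by relative RNA-FISH intensity
#'
#' Each sample is labelled against the green maximum of the profile:
#' `positive` when green exceeds `positive_frac` (default 50%) of the
#' maximum, `negative` when below `negative_frac` (default 25%), and
#' `excluded` otherwise. Inequalities are strict, so samples exactly at a
#' threshold are excluded; the excluded band keeps ambiguous shoulder
#' pixels out of both groups.
#'
#' @param profile A [line_profile()].
#' @param positive_frac,negative_frac Classification thresholds as
#'   fractions of the green maximum; `0 < negative_frac < positive_frac < 1`.
#' @return A list with `labels` (factor with levels `positive`, `negative`,
#'   `excluded`) and `green_max`.
#' @examples
#' p <- line_profile(1:10, green = c(100, 80, 10, 5, 30, 0, 0, 0, 0, 0),
#'                   red = rep(1, 10), blue = rep(1, 10))
#' classify_pixels(p)$labels[1:5]
#' @export
classify_pixels <- function(profile, positive_frac = 0.5,
                            negative_frac = 0.25) {
  stopifnot(inherits(profile, "line_profile"))
  if (!(negative_frac > 0 && negative_frac < positive_frac &&
        positive_frac < 1))
    xs_parameter_error("need 0 < negative_frac < positive_frac < 1")
  g <- profile$green
  if (all(g == 0))
    xs_no_signal_error("green channel is all zero; no RNA signal")
  gmax <- max(g)
  lab <- rep("excluded", length(g))
  lab[g > positive_frac * gmax] <- "positive"
  lab[g < negative_frac * gmax] <- "negative"
  list(labels = factor(lab, levels = c("positive", "negative", "excluded")),
       green_max = gmax)
}

#' Per-cell enrichment z-score and cloud-size estimate
#'
#' The core per-cell statistic: the median mark (red) intensity over
#' RNA-positive samples, expressed in units of the spread of the mark over
#' RNA-negative samples,
#' \deqn{z = \frac{\mathrm{median}(red_{+}) - \mathrm{mean}(red_{-})}
#'                {\mathrm{SD}(red_{-})}}
#' with the sample SD (n-1 denominator). A z of 1 means the median mark
#' intensity at the cloud sits one nuclear-background standard deviation
#' above the nuclear average. The relative cloud size is the fraction of
#' measured samples that are RNA-positive.
#'
#' @param profile A [line_profile()].
#' @param labels Output of [classify_pixels()]; computed from `profile`
#'   when omitted.
#' @param positive_frac,negative_frac Passed to [classify_pixels()] when
#'   `labels` is omitted.
#' @return An object of class `enrichment_result`: `z_score`,
#'   `median_pos_red`, `mean_pos_red`, `mean_neg_red`, `sd_neg_red`,
#'   `n_pos`, `n_neg`, `n_excluded`, `cloud_fraction`, `green_max` plus
#'   the profile's metadata labels.
#' @examples
#' p <- line_profile(1:10, green = c(100, 80, 10, 5, 30, 0, 0, 0, 0, 0),
#'                   red = c(50, 60, 10, 20, 15, 12, 18, 11, 19, 14),
#'                   blue = rep(1, 10))
#' compute_enrichment(p)$z_score
#' @export
compute_enrichment <- function(profile, labels = NULL,
                               positive_frac = 0.5, negative_frac = 0.25) {
  stopifnot(inherits(profile, "line_profile"))
  if (is.null(labels))
    labels <- classify_pixels(profile, positive_frac, negative_frac)
  lab <- labels$labels
  red <- profile$red
  pos <- red[lab == "positive"]
  neg <- red[lab == "negative"]
  if (length(pos) < 1L)
    xs_no_cloud_error("no RNA-positive samples on the profile")
  if (length(neg) < 2L)
    xs_undefined_z_error("fewer than 2 RNA-negative samples")
  sd_neg <- stats::sd(neg)
  med_pos <- stats::median(pos)
  mean_neg <- mean(neg)
  # a perfectly flat mark channel carries no enrichment either way: both
  # numerator and denominator vanish, and z is defined as 0; any actual
  # difference over a zero-variance background is unquantifiable
  if (sd_neg == 0 && med_pos != mean_neg)
    xs_undefined_z_error("zero variance in the RNA-negative samples")
  n <- length(red)
  structure(list(z_score = if (sd_neg == 0) 0 else (med_pos - mean_neg) / sd_neg,
                 median_pos_red = med_pos,
                 mean_pos_red = mean(pos),
                 mean_neg_red = mean_neg,
                 sd_neg_red = sd_neg,
                 n_pos = length(pos), n_neg = length(neg),
                 n_excluded = n - length(pos) - length(neg),
                 cloud_fraction = length(pos) / n,
                 green_max = labels$green_max,
                 cell_id = profile$cell_id, construct = profile$construct,
                 mark = profile$mark, treatment = profile$treatment),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(paste0("<enrichment_result> cell '%s': z = %.3f ",
                     "(n+ = %d, n- = %d, excluded = %d, cloud = %.2f)\n"),
              x$cell_id, x$z_score, x$n_pos, x$n_neg, x$n_excluded,
              x$cloud_fraction))
  invisible(x)
}

#' Score a line profile in one call
#'
#' Convenience wrapper: [classify_pixels()] followed by
#' [compute_enrichment()].
#'
#' @inheritParams compute_enrichment
#' @return An `enrichment_result`.
#' @export
score_profile <- function(profile, positive_frac = 0.5,
                          negative_frac = 0.25) {
  compute_enrichment(profile,
                     classify_pixels(profile, positive_frac, negative_frac))
}

#' Score a collection of cells into a per-cell table
#'
#' Accepts a list of [line_profile()] objects or a `synthetic_population`
#' (profile mode) and returns one row per scored cell — the unit of
#' population statistics. Cells whose scoring fails (no signal, undefined
#' z, ...) raise an error unless `on_error = "skip"`, in which case they
#' are dropped and reported in the `skipped` attribute with a
#' machine-readable reason code.
#'
#' @param cells List of profiles or a `synthetic_population`.
#' @param positive_frac,negative_frac Classification thresholds.
#' @param on_error `"stop"` or `"skip"`.
#' @return Data frame with columns `cell_id`, `construct`, `mark`,
#'   `treatment`, `z` and the remaining `enrichment_result` components.
#' @export
score_cells <- function(cells, positive_frac = 0.5, negative_frac = 0.25,
                        on_error = c("stop", "skip")) {
  on_error <- match.arg(on_error)
  if (inherits(cells, "synthetic_population")) {
    if (cells$mode != "profile")
      xs_parameter_error(
        "image-mode populations must go through extract_cell_profile()")
    cells <- cells$cells
  }
  rows <- list()
  skipped <- list()
  for (i in seq_along(cells)) {
    prof <- cells[[i]]
    res <- tryCatch(score_profile(prof, positive_frac, negative_frac),
                    xistscore_error = function(e) e)
    if (inherits(res, "error")) {
      if (on_error == "stop") stop(res)
      skipped[[length(skipped) + 1L]] <-
        data.frame(cell_id = prof$cell_id,
                   reason = class(res)[1], message = conditionMessage(res),
                   stringsAsFactors = FALSE)
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      cell_id = res$cell_id, construct = res$construct, mark = res$mark,
      treatment = res$treatment, z = res$z_score,
      median_pos_red = res$median_pos_red, mean_pos_red = res$mean_pos_red,
      mean_neg_red = res$mean_neg_red, sd_neg_red = res$sd_neg_red,
      n_pos = res$n_pos, n_neg = res$n_neg, n_excluded = res$n_excluded,
      cloud_fraction = res$cloud_fraction, green_max = res$green_max,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cell_id = character(), construct = character(),
               mark = character(), treatment = character(), z = numeric())
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(cell_id = character(), reason = character(),
               message = character())
  out
}

#' Classify cloud morphology as unified or punctate
#'
#' Thresholds the green raster at half its in-nucleus maximum, counts
#' 8-connected components above threshold that pass a minimum-area filter,
#' and calls the cloud `unified` when exactly one component survives —
#' i.e. a single contiguous region of peak RNA signal with no gaps —
#' and `punctate` otherwise.
#'
#' @param green Numeric matrix (RNA FISH intensities).
#' @param nucleus_mask Logical nucleus mask.
#' @param threshold_frac Fraction of the in-mask green maximum (default
#'   0.5).
#' @param min_area Minimum component area in pixels (default 4).
#' @return A list with `morphology` (`"unified"` or `"punctate"`) and
#'   `n_components`.
#' @export
classify_cloud_morphology <- function(green, nucleus_mask,
                                      threshold_frac = 0.5, min_area = 4L) {
  if (!any(nucleus_mask))
    xs_parameter_error("nucleus mask is empty")
  mx <- max(green[nucleus_mask])
  above <- nucleus_mask & (green > threshold_frac * mx)
  if (!any(above))
    xs_no_signal_error("no pixel above the morphology threshold")
  lab <- label_components8(above)
  areas <- tabulate(lab[lab > 0])
  n_comp <- sum(areas >= min_area)
  if (n_comp == 0L)
    xs_no_signal_error("no component passes the minimum-area filter")
  list(morphology = if (n_comp == 1L) "unified" else "punctate",
       n_components = n_comp)
}
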