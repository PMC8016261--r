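#' Specification of a synthetic nucleus
#'
#' Generative parameters for one synthetic IF-FISH nucleus: a bright DAPI
#' disc (optionally containing a dimmer nucleolar disc), an RNA cloud
#' rendered in the green channel as one unified disc or several disjoint
#' foci, and a mark channel drawn as i.i.d. Gaussian background with a
#' focal shift of `effect_delta` background standard deviations inside the
#' cloud footprint. `effect_delta` is therefore the ground-truth value the
#' downstream enrichment z-score estimates.
#'
#' Geometry is in pixels, 1-based row/column coordinates. All stochastic
#' draws are governed by `seed`; the same spec and seed reproduce the scene
#' bit-identically.
#'
#' @param nucleus_radius Nucleus radius in pixels.
#' @param dim Image dimensions (rows, columns); defaults to a square that
#'   fits the nucleus with a margin.
#' @param nucleus_center Nucleus centre (row, col); defaults to the image
#'   centre.
#' @param cloud_center,cloud_radius Centre and radius of the RNA-cloud
#'   footprint.
#' @param nucleolus_center,nucleolus_radius Centre and radius of the
#'   nucleolus, or `nucleolus_center = NULL` for none.
#' @param n_foci Number of RNA foci: 1 renders one unified disc; more than
#'   1 renders that many disjoint small discs inside the cloud footprint
#'   (punctate morphology).
#' @param background_mark_mean,background_mark_sd Mean and SD of the
#'   Gaussian mark-channel background (intensity units; SD must be > 0).
#' @param effect_delta True focal enrichment of the mark inside the cloud,
#'   in units of `background_mark_sd`.
#' @param cloud_green_peak,green_background Green intensity on the cloud
#'   foci and elsewhere.
#' @param blue_nucleus Blue (DAPI) intensity inside the nucleus; the
#'   nucleolus renders at `nucleolus_dim_frac` of it.
#' @param nucleolus_dim_frac Fraction of `blue_nucleus` used inside the
#'   nucleolus.
#' @param green_noise_sd,blue_noise_sd Optional Gaussian noise SDs for the
#'   green and blue channels (default 0: those channels are rendered
#'   noiselessly).
#' @param blur_sigma Optional Gaussian blur (pixels) applied to every
#'   channel after noise; default 0 (off).
#' @param bit_depth 8 or 16; intensities clip to `[0, 2^bit_depth - 1]`.
#' @param seed Integer RNG seed (required).
#' @return An object of class `nucleus_spec`.
#' @export
nucleus_spec <- function(nucleus_radius = 50,
                         dim = rep(2 * nucleus_radius + 27, 2),
                         nucleus_center = (dim + 1) %/% 2,
                         cloud_center = nucleus_center + c(0, 20),
                         cloud_radius = 8,
                         nucleolus_center = nucleus_center + c(0, -20),
                         nucleolus_radius = 10,
                         n_foci = 1L,
                         background_mark_mean = 60,
                         background_mark_sd = 10,
                         effect_delta = 0,
                         cloud_green_peak = 200,
                         green_background = 20,
                         blue_nucleus = 180,
                         nucleolus_dim_frac = 0.4,
                         green_noise_sd = 0,
                         blue_noise_sd = 0,
                         blur_sigma = 0,
                         bit_depth = 8L,
                         seed) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L || is.na(seed))
    xs_parameter_error("an explicit integer 'seed' is required")
  if (background_mark_sd <= 0)
    xs_parameter_error("background_mark_sd must be > 0")
  if (!bit_depth %in% c(8L, 16L))
    xs_parameter_error("bit_depth must be 8 or 16")
  if (n_foci < 1L || n_foci != round(n_foci))
    xs_parameter_error("n_foci must be a positive integer")
  if (nucleus_radius <= 0 || cloud_radius <= 0)
    xs_parameter_error("radii must be positive")

  d_cloud <- sqrt(sum((cloud_center - nucleus_center)^2))
  if (d_cloud + cloud_radius > nucleus_radius)
    xs_geometry_error("cloud footprint must lie entirely inside the nucleus")
  if (!is.null(nucleolus_center)) {
    if (nucleolus_radius <= 0)
      xs_parameter_error("nucleolus_radius must be positive")
    d_nl <- sqrt(sum((nucleolus_center - nucleus_center)^2))
    if (d_nl + nucleolus_radius > nucleus_radius)
      xs_geometry_error("nucleolus must lie entirely inside the nucleus")
    d_nc <- sqrt(sum((nucleolus_center - cloud_center)^2))
    if (d_nc < nucleolus_radius + cloud_radius)
      xs_geometry_error("nucleolus must not overlap the cloud footprint")
  }
  structure(list(nucleus_radius = nucleus_radius, dim = as.integer(dim),
                 nucleus_center = nucleus_center,
                 cloud_center = cloud_center, cloud_radius = cloud_radius,
                 nucleolus_center = nucleolus_center,
                 nucleolus_radius = nucleolus_radius,
                 n_foci = as.integer(n_foci),
                 background_mark_mean = background_mark_mean,
                 background_mark_sd = background_mark_sd,
                 effect_delta = effect_delta,
                 cloud_green_peak = cloud_green_peak,
                 green_background = green_background,
                 blue_nucleus = blue_nucleus,
                 nucleolus_dim_frac = nucleolus_dim_frac,
                 green_noise_sd = green_noise_sd,
                 blue_noise_sd = blue_noise_sd,
                 blur_sigma = blur_sigma,
                 bit_depth = as.integer(bit_depth),
                 seed = as.integer(seed)),
            class = "nucleus_spec")
}

disc_mask <- function(dim, center, radius) {
  r <- matrix(seq_len(dim[1]), dim[1], dim[2])
  c <- matrix(seq_len(dim[2]), dim[1], dim[2], byrow = TRUE)
  (r - center[1])^2 + (c - center[2])^2 <= radius^2
}

# Disjoint foci inside the cloud footprint: centres on a ring at 0.55 R,
# rotated by a seeded offset; focus radius chosen so neighbouring discs
# cannot touch.
foci_geometry <- function(cloud_center, cloud_radius, n_foci, rotation) {
  if (n_foci == 1L)
    return(list(centers = list(cloud_center), radius = cloud_radius))
  ring <- 0.55 * cloud_radius
  f <- floor(0.9 * min(0.35 * cloud_radius, ring * sin(pi / n_foci)))
  if (f < 1)
    xs_geometry_error("cloud_radius too small to place that many disjoint foci")
  ang <- rotation + 2 * pi * (seq_len(n_foci) - 1) / n_foci
  centers <- lapply(ang, function(a)
    cloud_center + c(ring * sin(a), ring * cos(a)))
  list(centers = centers, radius = f)
}

#' Simulate a synthetic IF-FISH nucleus image
#'
#' Renders the three channels described by a [nucleus_spec()] and returns
#' them with the ground-truth masks. The blue channel is the nucleus disc
#' (dimmer inside the nucleolus); the green channel renders the cloud foci
#' over a uniform background, with a mild (10%) parabolic taper towards
#' each focus rim so the RNA signal has a well-defined interior maximum;
#' and the red channel is drawn per pixel from
#' `Normal(background_mark_mean, background_mark_sd)`, shifted by
#' `effect_delta * background_mark_sd` inside the cloud footprint. All
#' channels are rounded to integer counts and clipped to the bit-depth
#' range.
#'
#' @param spec A [nucleus_spec()].
#' @return A list of class `synthetic_nucleus` with elements `image`
#'   (a [multi_channel_image()]), `masks` (logical matrices `nucleus`,
#'   `nucleolus`, `cloud`), `morphology` (`"unified"` or `"punctate"`)
#'   and `spec`.
#' @examples
#' sn <- simulate_nucleus(nucleus_spec(effect_delta = 2, seed = 1))
#' sn$morphology
#' @export
simulate_nucleus <- function(spec) {
  stopifnot(inherits(spec, "nucleus_spec"))
  dm <- spec$dim
  lim <- 2^spec$bit_depth - 1
  nucleus <- disc_mask(dm, spec$nucleus_center, spec$nucleus_radius)
  nucleolus <- if (is.null(spec$nucleolus_center)) {
    matrix(FALSE, dm[1], dm[2])
  } else {
    disc_mask(dm, spec$nucleolus_center, spec$nucleolus_radius) & nucleus
  }
  withr::with_seed(spec$seed, {
    rotation <- if (spec$n_foci > 1L) stats::runif(1, 0, 2 * pi) else 0
    fg <- foci_geometry(spec$cloud_center, spec$cloud_radius,
                        spec$n_foci, rotation)
    foci <- lapply(fg$centers, function(ct) disc_mask(dm, ct, fg$radius))
    cloud <- Reduce(`|`, foci)
    red <- matrix(stats::rnorm(prod(dm), spec$background_mark_mean,
                               spec$background_mark_sd), dm[1], dm[2])
    red[cloud] <- red[cloud] + spec$effect_delta * spec$background_mark_sd
    green <- matrix(spec$green_background, dm[1], dm[2])
    # mild parabolic taper (10%) towards each focus rim: gives the RNA
    # signal a well-defined interior maximum, as in real FISH clouds,
    # while keeping every cloud pixel far above the positive threshold
    rr <- matrix(seq_len(dm[1]), dm[1], dm[2])
    cc <- matrix(seq_len(dm[2]), dm[1], dm[2], byrow = TRUE)
    for (i in seq_along(foci)) {
      ct <- fg$centers[[i]]
      d2 <- (rr - ct[1])^2 + (cc - ct[2])^2
      green[foci[[i]]] <- spec$cloud_green_peak *
        (1 - 0.1 * d2[foci[[i]]] / fg$radius^2)
    }
    blue <- matrix(0, dm[1], dm[2])
    blue[nucleus] <- spec$blue_nucleus
    blue[nucleolus] <- spec$blue_nucleus * spec$nucleolus_dim_frac
    if (spec$green_noise_sd > 0)
      green <- green + stats::rnorm(prod(dm), 0, spec$green_noise_sd)
    if (spec$blue_noise_sd > 0)
      blue <- blue + stats::rnorm(prod(dm), 0, spec$blue_noise_sd)
  })
  if (spec$blur_sigma > 0) {
    red <- EBImage::gblur(red, sigma = spec$blur_sigma)
    green <- EBImage::gblur(green, sigma = spec$blur_sigma)
    blue <- EBImage::gblur(blue, sigma = spec$blur_sigma)
  }
  clipq <- function(x) matrix(pmin(lim, pmax(0, round(x))), dm[1], dm[2])
  img <- multi_channel_image(clipq(red), clipq(green), clipq(blue),
                             bit_depth = spec$bit_depth)
  structure(list(image = img,
                 masks = list(nucleus = nucleus, nucleolus = nucleolus,
                              cloud = cloud),
                 morphology = if (spec$n_foci > 1L) "punctate" else "unified",
                 spec = spec),
            class = "synthetic_nucleus")
}

#' Simulate a line profile directly (fast path)
#'
#' Bypasses image rendering and chord placement: samples `n_pixels`
#' positions along the nuclear diameter that runs through the cloud centre.
#' The green series is `cloud_green_peak` over the cloud segment and
#' `green_background` elsewhere; the red series is Gaussian background with
#' the `effect_delta` shift on the cloud segment, exactly as in
#' [simulate_nucleus()] but without quantisation. The true cloud sample
#' indices are recorded as ground truth.
#'
#' @param spec A [nucleus_spec()].
#' @param n_pixels Number of samples along the chord (at least 10).
#' @param cell_id,construct,mark,treatment Metadata attached to the profile.
#' @return A [line_profile()] with attributes `true_cloud_idx` (integer
#'   indices of cloud samples) and `true_delta`.
#' @export
simulate_profile <- function(spec, n_pixels = 100L, cell_id = "cell",
                             construct = NA_character_, mark = NA_character_,
                             treatment = NA_character_) {
  stopifnot(inherits(spec, "nucleus_spec"))
  if (n_pixels < 10L)
    xs_parameter_error("n_pixels must be at least 10")
  R <- spec$nucleus_radius
  d <- sqrt(sum((spec$cloud_center - spec$nucleus_center)^2))
  s <- (seq_len(n_pixels) - 0.5) * (2 * R) / n_pixels
  cloud_idx <- which(abs(s - (R + d)) <= spec$cloud_radius)
  if (length(cloud_idx) == 0L || length(cloud_idx) == n_pixels)
    xs_degenerate_error("cloud covers none or all of the chord")
  green <- rep(spec$green_background, n_pixels)
  green[cloud_idx] <- spec$cloud_green_peak
  red <- withr::with_seed(spec$seed,
    stats::rnorm(n_pixels, spec$background_mark_mean, spec$background_mark_sd))
  red[cloud_idx] <- red[cloud_idx] +
    spec$effect_delta * spec$background_mark_sd
  blue <- rep(spec$blue_nucleus, n_pixels)
  prof <- line_profile(seq_len(n_pixels), green, red, blue,
                       cell_id = cell_id, construct = construct,
                       mark = mark, treatment = treatment)
  attr(prof, "true_cloud_idx") <- cloud_idx
  attr(prof, "true_delta") <- spec$effect_delta
  prof
}

#' Specification of a synthetic cell population
#'
#' A multi-cell experiment for one construct: each cell receives its own
#' true enrichment drawn from `Normal(delta_mean, delta_sd)`, modelling the
#' cell-to-cell heterogeneity seen in real populations, plus its own RNG
#' seed. The default population size (60 cells) and heterogeneity
#' (`delta_sd = 1.7` z-units) mirror typical measured populations.
#'
#' @param construct_label Construct name attached to every cell.
#' @param n_cells Number of cells (positive).
#' @param delta_mean,delta_sd Mean and SD of the true per-cell enrichment
#'   (z-units; `delta_sd >= 0`).
#' @param morphology `"unified"` (one cloud disc) or `"punctate"`
#'   (`punctate_foci` disjoint foci).
#' @param punctate_foci Number of foci used when `morphology = "punctate"`.
#' @param mark,treatment Metadata labels attached to every cell.
#' @param n_pixels Profile length used in `"profile"` mode.
#' @param geometry Named list of overrides passed to [nucleus_spec()]
#'   (shared geometry / noise parameters).
#' @param seed Integer RNG seed (required); per-cell deltas and seeds are
#'   derived from it reproducibly.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(construct_label, n_cells = 60L,
                            delta_mean = 0, delta_sd = 1.7,
                            morphology = c("unified", "punctate"),
                            punctate_foci = 3L,
                            mark = NA_character_, treatment = NA_character_,
                            n_pixels = 100L, geometry = list(), seed) {
  morphology <- match.arg(morphology)
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L || is.na(seed))
    xs_parameter_error("an explicit integer 'seed' is required")
  if (n_cells < 1L || n_cells != round(n_cells))
    xs_parameter_error("n_cells must be a positive integer")
  if (delta_sd < 0)
    xs_parameter_error("delta_sd must be >= 0")
  structure(list(construct_label = construct_label,
                 n_cells = as.integer(n_cells),
                 delta_mean = delta_mean, delta_sd = delta_sd,
                 morphology = morphology,
                 punctate_foci = as.integer(punctate_foci),
                 mark = mark, treatment = treatment,
                 n_pixels = as.integer(n_pixels),
                 geometry = geometry, seed = as.integer(seed)),
            class = "population_spec")
}

#' Simulate a population of synthetic cells
#'
#' Draws `n_cells` per-cell true enrichment values and seeds from the
#' population spec, then simulates each cell either as a fast-path line
#' profile (`mode = "profile"`, the default) or as a full rendered image
#' (`mode = "image"`).
#'
#' @param pop A [population_spec()].
#' @param mode `"profile"` or `"image"`.
#' @return A list of class `synthetic_population`: `cells` (list of
#'   [line_profile()] or `synthetic_nucleus` objects) and `truth`
#'   (data frame with `cell_id`, `construct`, `true_delta`, `morphology`,
#'   `seed`).
#' @export
simulate_population <- function(pop, mode = c("profile", "image")) {
  stopifnot(inherits(pop, "population_spec"))
  mode <- match.arg(mode)
  n <- pop$n_cells
  drawn <- withr::with_seed(pop$seed, list(
    deltas = stats::rnorm(n, pop$delta_mean, pop$delta_sd),
    seeds = sample.int(.Machine$integer.max - 1L, n)))
  ids <- sprintf("%s_%03d", pop$construct_label, seq_len(n))
  n_foci <- if (pop$morphology == "punctate") pop$punctate_foci else 1L
  cells <- vector("list", n)
  for (i in seq_len(n)) {
    args <- c(list(effect_delta = drawn$deltas[i], n_foci = n_foci,
                   seed = drawn$seeds[i]), pop$geometry)
    spec <- do.call(nucleus_spec, args)
    cells[[i]] <- if (mode == "profile") {
      simulate_profile(spec, n_pixels = pop$n_pixels, cell_id = ids[i],
                       construct = pop$construct_label, mark = pop$mark,
                       treatment = pop$treatment)
    } else {
      simulate_nucleus(spec)
    }
  }
  names(cells) <- ids
  truth <- data.frame(cell_id = ids, construct = pop$construct_label,
                      true_delta = drawn$deltas, morphology = pop$morphology,
                      seed = drawn$seeds, stringsAsFactors = FALSE)
  structure(list(cells = cells, truth = truth, pop = pop, mode = mode),
            class = "synthetic_population")
}

#' Write a synthetic population to disk
#'
#' Profile-mode populations are written as a long-format profile CSV plus a
#' ground-truth CSV; image-mode populations as one RGB TIFF per cell, one
#' mask TIFF per ground-truth mask, and the ground-truth CSV.
#'
#' @param population A `synthetic_population`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_population <- function(population, dir) {
  stopifnot(inherits(population, "synthetic_population"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(population$truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  if (population$mode == "profile") {
    write_profiles_csv(population$cells, file.path(dir, "profiles.csv"))
  } else {
    for (id in names(population$cells)) {
      sn <- population$cells[[id]]
      write_image_tiff(sn$image, file.path(dir, paste0(id, ".tif")))
      for (m in names(sn$masks))
        write_mask_tiff(sn$masks[[m]],
                        file.path(dir, paste0(id, "_mask_", m, ".tif")))
    }
  }
  invisible(dir)
}
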