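#' Multi-channel fluorescence image
#'
#' Container for a three-channel (red = immunofluorescence, green = RNA FISH,
#' blue = DAPI) 2-D microscopy image. Channels are plain numeric matrices in
#' row/column orientation and share a common shape; intensities live on the
#' integer scale of the stated bit depth.
#'
#' @param red,green,blue Numeric matrices of identical dimensions.
#' @param bit_depth Integer, 8 or 16.
#' @return An object of class `multi_channel_image` with fields `red`,
#'   `green`, `blue` and `bit_depth`.
#' @export
multi_channel_image <- function(red, green, blue, bit_depth = 8L) {
  if (!bit_depth %in% c(8L, 16L))
    xs_parameter_error("bit_depth must be 8 or 16")
  chans <- list(red = red, green = green, blue = blue)
  for (nm in names(chans)) {
    ch <- chans[[nm]]
    if (!is.matrix(ch) || !is.numeric(ch))
      xs_parameter_error(sprintf("channel '%s' must be a numeric matrix", nm))
  }
  if (!identical(dim(red), dim(green)) || !identical(dim(red), dim(blue)))
    xs_parameter_error("channels must share the same dimensions")
  lim <- 2^bit_depth - 1
  vals <- c(red, green, blue)
  if (anyNA(vals) || min(vals) < 0 || max(vals) > lim)
    xs_parameter_error(sprintf("intensities must lie within [0, %d]", lim))
  structure(list(red = red, green = green, blue = blue,
                 bit_depth = as.integer(bit_depth)),
            class = "multi_channel_image")
}

#' @export
print.multi_channel_image <- function(x, ...) {
  cat(sprintf("<multi_channel_image> %d x %d pixels, %d-bit\n",
              nrow(x$red), ncol(x$red), x$bit_depth))
  invisible(x)
}

#' Read / write multi-channel images as TIFF
#'
#' `write_image_tiff()` stores the three channels as an RGB TIFF at the
#' image's bit depth; `read_image_tiff()` reads such a file back into a
#' [multi_channel_image()]. Intensities are stored as `value / (2^bit - 1)`,
#' the unit scale the TIFF writer expects, and mapped back to integer counts
#' on read.
#'
#' @param image A `multi_channel_image`.
#' @param path File path.
#' @param bit_depth Bit depth assumed when reading (8 or 16).
#' @return `read_image_tiff()` returns a `multi_channel_image`;
#'   `write_image_tiff()` returns `path` invisibly.
#' @export
write_image_tiff <- function(image, path) {
  stopifnot(inherits(image, "multi_channel_image"))
  lim <- 2^image$bit_depth - 1
  arr <- array(0, dim = c(dim(image$red), 3L))
  arr[, , 1] <- image$red / lim
  arr[, , 2] <- image$green / lim
  arr[, , 3] <- image$blue / lim
  tiff::writeTIFF(arr, path, bits.per.sample = image$bit_depth)
  invisible(path)
}

#' @rdname write_image_tiff
#' @export
read_image_tiff <- function(path, bit_depth = 8L) {
  arr <- tiff::readTIFF(path)
  if (length(dim(arr)) != 3L || dim(arr)[3] < 3L)
    xs_parameter_error("expected an RGB TIFF with three channels")
  lim <- 2^bit_depth - 1
  multi_channel_image(red   = round(arr[, , 1] * lim),
                      green = round(arr[, , 2] * lim),
                      blue  = round(arr[, , 3] * lim),
                      bit_depth = bit_depth)
}

#' Write a binary mask as a single-channel TIFF
#'
#' @param mask Logical matrix.
#' @param path File path.
#' @export
write_mask_tiff <- function(mask, path) {
  tiff::writeTIFF(mask * 1.0, path, bits.per.sample = 8L)
  invisible(path)
}

# 8-connected component labelling of a logical matrix. EBImage's labeller is
# 4-connected; morphology calls require diagonal adjacency, so label
# components here by flood fill over the (small) foreground set.
label_components8 <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  cur <- 0L
  idx <- which(mask)
  for (i in idx) {
    if (lab[i] != 0L) next
    cur <- cur + 1L
    queue <- i
    lab[i] <- cur
    while (length(queue)) {
      p <- queue[[length(queue)]]
      queue <- queue[-length(queue)]
      r <- ((p - 1L) %% nr) + 1L
      c <- ((p - 1L) %/% nr) + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- c + dc
        if (rr < 1L || rr > nr || cc < 1L || cc > nc) next
        q <- (cc - 1L) * nr + rr
        if (mask[q] && lab[q] == 0L) {
          lab[q] <- cur
          queue <- c(queue, q)
        }
      }
    }
  }
  lab
}
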