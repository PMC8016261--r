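#' Line profile along a measurement chord
#'
#' Ordered per-pixel intensity samples of the three fluorescence channels
#' along a single measurement chord through one nucleus. This is the unit of
#' enrichment scoring: the green (RNA FISH) series drives pixel
#' classification and the red (immunofluorescence) series carries the mark
#' intensity being scored.
#'
#' @param position Integer sample indices along the chord, strictly
#'   increasing (1-based).
#' @param green,red,blue Numeric intensity vectors, one value per position.
#' @param cell_id,construct,mark,treatment Metadata labels for the cell.
#' @return An object of class `line_profile`.
#' @export
line_profile <- function(position, green, red, blue,
                         cell_id = "cell", construct = NA_character_,
                         mark = NA_character_, treatment = NA_character_) {
  n <- length(position)
  if (n < 10L)
    xs_too_short_error("a line profile needs at least 10 samples")
  if (length(green) != n || length(red) != n || length(blue) != n)
    xs_parameter_error("position, green, red, blue must have equal length")
  if (anyNA(c(position, green, red, blue)))
    xs_parameter_error("profile values must not contain NA")
  if (any(diff(position) <= 0))
    xs_parameter_error("positions must be strictly increasing")
  structure(list(position = as.integer(position),
                 green = as.numeric(green), red = as.numeric(red),
                 blue = as.numeric(blue),
                 cell_id = cell_id, construct = construct,
                 mark = mark, treatment = treatment),
            class = "line_profile")
}

#' @export
print.line_profile <- function(x, ...) {
  cat(sprintf("<line_profile> cell '%s', %d samples (construct=%s, mark=%s)\n",
              x$cell_id, length(x$position),
              x$construct, x$mark))
  invisible(x)
}

#' @export
length.line_profile <- function(x) length(x$position)

#' @export
as.data.frame.line_profile <- function(x, ...) {
  data.frame(cell_id = x$cell_id, position = x$position,
             green = x$green, red = x$red, blue = x$blue,
             stringsAsFactors = FALSE)
}

#' Read and write line-profile tables
#'
#' Profiles travel as long-format CSV with columns `cell_id`, `position`,
#' `green`, `red`, `blue`; one block of rows per cell. Metadata (construct,
#' mark, treatment) travels in a separate per-cell table and is attached by
#' `cell_id` when reading.
#'
#' @param profiles A list of [line_profile()] objects.
#' @param path CSV file path.
#' @param metadata Optional data frame with columns `cell_id` and any of
#'   `construct`, `mark`, `treatment`.
#' @return `read_profiles_csv()` returns a named list of `line_profile`
#'   objects; `write_profiles_csv()` returns `path` invisibly.
#' @export
write_profiles_csv <- function(profiles, path) {
  tabs <- lapply(profiles, as.data.frame)
  utils::write.csv(do.call(rbind, tabs), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profiles_csv
#' @export
read_profiles_csv <- function(path, metadata = NULL) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "position", "green", "red", "blue")
  if (!all(need %in% names(tab)))
    xs_parameter_error(paste("profile CSV must have columns:",
                             paste(need, collapse = ", ")))
  ids <- unique(tab$cell_id)
  meta_for <- function(id, col) {
    if (is.null(metadata) || !col %in% names(metadata)) return(NA_character_)
    hit <- metadata[[col]][metadata$cell_id == id]
    if (length(hit)) as.character(hit[[1]]) else NA_character_
  }
  out <- lapply(ids, function(id) {
    sub <- tab[tab$cell_id == id, , drop = FALSE]
    sub <- sub[order(sub$position), , drop = FALSE]
    line_profile(sub$position, sub$green, sub$red, sub$blue,
                 cell_id = as.character(id),
                 construct = meta_for(id, "construct"),
                 mark = meta_for(id, "mark"),
                 treatment = meta_for(id, "treatment"))
  })
  names(out) <- as.character(ids)
  out
}
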