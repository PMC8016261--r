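#' Blind a cell table for unbiased scoring
#'
#' Replaces each cell's identity (id plus construct / mark / treatment
#' labels) with an opaque random code so that scoring decisions cannot be
#' influenced by knowledge of the condition. The coding is a seeded random
#' permutation, reproducible from the seed; the returned key is the only
#' route back to the identities.
#'
#' @param records Data frame with a unique id column and identity columns.
#' @param seed Integer RNG seed.
#' @param id_col Name of the unique id column (default `"cell_id"`).
#' @param label_cols Identity columns to strip (default construct, mark,
#'   treatment; columns absent from `records` are ignored).
#' @return A list with `coded` (records with `code` instead of identity)
#'   and `key` (an object of class `blinding_key` mapping codes back).
#' @export
blind_dataset <- function(records, seed,
                          id_col = "cell_id",
                          label_cols = c("construct", "mark", "treatment")) {
  if (!id_col %in% names(records))
    xs_parameter_error(sprintf("records lacks id column '%s'", id_col))
  ids <- records[[id_col]]
  if (anyDuplicated(ids))
    xs_parameter_error("record ids must be unique")
  n <- nrow(records)
  label_cols <- intersect(label_cols, names(records))
  codes <- withr::with_seed(seed,
    sprintf("blind_%05d", sample.int(99999L, n)))
  key <- data.frame(code = codes, records[, c(id_col, label_cols),
                                          drop = FALSE],
                    stringsAsFactors = FALSE)
  attr(key, "seed") <- as.integer(seed)
  attr(key, "id_col") <- id_col
  class(key) <- c("blinding_key", "data.frame")
  coded <- records[, setdiff(names(records), c(id_col, label_cols)),
                   drop = FALSE]
  coded <- cbind(data.frame(code = codes, stringsAsFactors = FALSE), coded)
  list(coded = coded, key = key)
}

#' Unblind coded results
#'
#' Joins identity columns back onto coded rows using the blinding key.
#' Any code absent from the key raises a key-mismatch error.
#'
#' @param coded Data frame with a `code` column (as from
#'   [blind_dataset()], possibly with measurement columns added).
#' @param key The `blinding_key` from [blind_dataset()].
#' @return The table with identities restored and `code` dropped, in the
#'   original column layout (id first, then identity columns, then the
#'   remaining columns).
#' @export
unblind <- function(coded, key) {
  stopifnot(inherits(key, "blinding_key"))
  if (!"code" %in% names(coded))
    xs_parameter_error("coded table lacks a 'code' column")
  idx <- match(coded$code, key$code)
  if (anyNA(idx))
    xs_key_mismatch_error("coded table contains codes absent from the key")
  ident <- key[idx, setdiff(names(key), "code"), drop = FALSE]
  rownames(ident) <- NULL
  rest <- coded[, setdiff(names(coded), "code"), drop = FALSE]
  rownames(rest) <- NULL
  cbind(ident, rest)
}
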