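#' qPCR sample with target and reference CT replicates
#'
#' Cycle-threshold replicates for the induced transcript (target) and the
#' endogenous control gene (reference) in one sample.
#'
#' @param sample_id Sample label.
#' @param ct_target,ct_reference Numeric CT replicates (cycles), at least
#'   one each; values must be positive and below 45.
#' @param role `"test"` or `"control"`.
#' @return An object of class `qpcr_sample`.
#' @export
qpcr_sample <- function(sample_id, ct_target, ct_reference,
                        role = c("test", "control")) {
  role <- match.arg(role)
  if (length(ct_target) < 1L || length(ct_reference) < 1L)
    xs_insufficient_data_error("need at least one CT replicate per gene")
  cts <- c(ct_target, ct_reference)
  if (anyNA(cts) || any(cts <= 0) || any(cts >= 45))
    xs_parameter_error("CT values must be positive and below 45 cycles")
  structure(list(sample_id = sample_id,
                 ct_target = as.numeric(ct_target),
                 ct_reference = as.numeric(ct_reference), role = role),
            class = "qpcr_sample")
}

#' Relative expression by the comparative-CT method
#'
#' Replicates are averaged at the CT level; each sample's delta-CT is
#' `mean(ct_target) - mean(ct_reference)`, the delta-delta-CT is the
#' difference of the test and control delta-CTs, and the relative quantity
#' is `RQ = 2^(-ddCT)`. Equal expression therefore gives RQ = 1.
#'
#' @param test,control [qpcr_sample()] objects.
#' @return A list of class `rq_result`: `rq`, `delta_delta_ct`,
#'   `delta_ct_test`, `delta_ct_control`.
#' @examples
#' t1 <- qpcr_sample("d2", ct_target = c(22, 22.2), ct_reference = c(18, 18.1))
#' c1 <- qpcr_sample("d5", ct_target = c(21, 21.1), ct_reference = c(18, 18),
#'                   role = "control")
#' delta_delta_ct(t1, c1)$rq
#' @export
delta_delta_ct <- function(test, control) {
  stopifnot(inherits(test, "qpcr_sample"), inherits(control, "qpcr_sample"))
  dct_test <- mean(test$ct_target) - mean(test$ct_reference)
  dct_control <- mean(control$ct_target) - mean(control$ct_reference)
  ddct <- dct_test - dct_control
  structure(list(rq = 2^(-ddct), delta_delta_ct = ddct,
                 delta_ct_test = dct_test, delta_ct_control = dct_control,
                 sample_test = test$sample_id,
                 sample_control = control$sample_id),
            class = "rq_result")
}

#' @export
print.rq_result <- function(x, ...) {
  cat(sprintf("<rq_result> %s vs %s: ddCT = %.3f, RQ = %.3f\n",
              x$sample_test, x$sample_control, x$delta_delta_ct, x$rq))
  invisible(x)
}

#' Read CT tables and compute RQ per test sample
#'
#' `read_ct_csv()` reads a long-format CT table (columns `sample_id`,
#' `gene`, `role`, `ct`) into [qpcr_sample()] objects; `rq_table()`
#' computes the relative quantity of each test sample against the control
#' sample.
#'
#' @param path CSV path.
#' @param target_gene,reference_gene Gene labels for the induced
#'   transcript and the endogenous control.
#' @return `read_ct_csv()`: named list of `qpcr_sample`; `rq_table()`:
#'   data frame with one row per test sample.
#' @export
read_ct_csv <- function(path, target_gene, reference_gene) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "gene", "role", "ct")
  if (!all(need %in% names(tab)))
    xs_parameter_error(paste("CT CSV must have columns:",
                             paste(need, collapse = ", ")))
  ids <- unique(tab$sample_id)
  out <- lapply(ids, function(id) {
    sub <- tab[tab$sample_id == id, ]
    qpcr_sample(id,
                ct_target = sub$ct[sub$gene == target_gene],
                ct_reference = sub$ct[sub$gene == reference_gene],
                role = unique(sub$role))
  })
  names(out) <- ids
  out
}

#' @rdname read_ct_csv
#' @param samples Named list of [qpcr_sample()] objects, exactly one of
#'   which has role `"control"`.
#' @export
rq_table <- function(samples) {
  roles <- vapply(samples, `[[`, character(1), "role")
  if (sum(roles == "control") != 1L)
    xs_parameter_error("exactly one sample must have role 'control'")
  control <- samples[[which(roles == "control")]]
  tests <- samples[roles == "test"]
  rows <- lapply(tests, function(s) {
    r <- delta_delta_ct(s, control)
    data.frame(sample_id = s$sample_id, rq = r$rq,
               delta_delta_ct = r$delta_delta_ct,
               delta_ct = r$delta_ct_test,
               control_id = control$sample_id, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
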