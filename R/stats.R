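#' Mann-Whitney U comparison of two z-score populations
#'
#' Two-sided rank-sum comparison of a test population against a control.
#' For small samples (combined n of at most 12) the p-value comes from
#' exact enumeration of all group assignments of the pooled observations
#' (midranks handle ties), with the two-sided p defined as
#' `min(1, 2 * min(P(U <= u), P(U >= u)))`. For larger samples the normal
#' approximation with tie correction and continuity correction is used
#' (delegated to [stats::wilcox.test()]).
#'
#' @param test,control Numeric vectors, each with at least 2 observations.
#' @return A list of class `mw_test`: `U` (statistic for the test group),
#'   `p_value`, `method`, `n_test`, `n_control`.
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))$p_value  # exact, 0.1
#' @export
mann_whitney <- function(test, control) {
  if (length(test) < 2L || length(control) < 2L)
    xs_insufficient_data_error("each group needs at least 2 observations")
  if (anyNA(c(test, control)) || any(!is.finite(c(test, control))))
    xs_parameter_error("observations must be finite")
  m <- length(test); n <- length(control); N <- m + n
  r <- rank(c(test, control))
  U <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  if (N <= 12L) {
    comb <- utils::combn(N, m)
    Us <- colSums(matrix(r[comb], nrow = m)) - m * (m + 1) / 2
    p <- min(1, 2 * min(mean(Us <= U), mean(Us >= U)))
    method <- "exact enumeration"
  } else {
    p <- stats::wilcox.test(test, control, exact = FALSE,
                            correct = TRUE)$p.value
    method <- "normal approximation (tie and continuity corrected)"
  }
  structure(list(U = U, p_value = p, method = method,
                 n_test = m, n_control = n),
            class = "mw_test")
}

#' @export
print.mw_test <- function(x, ...) {
  cat(sprintf("<mw_test> U = %g, p = %.4g (%s; n = %d vs %d)\n",
              x$U, x$p_value, x$method, x$n_test, x$n_control))
  invisible(x)
}

#' Bonferroni-adjusted per-test significance threshold
#'
#' Family-wise control by dividing the nominal level by the number of
#' tests in the family: `alpha / n_tests`, exactly. With a family of 48
#' comparisons the conventional levels 0.05, 0.01 and 0.001 become
#' 1.04e-3, 2.08e-4 and 2.08e-5.
#'
#' @param alpha Family-wise level in (0, 1).
#' @param n_tests Number of tests in the family (positive integer).
#' @return The per-test threshold `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    xs_parameter_error("alpha must lie in (0, 1)")
  if (!is.numeric(n_tests) || n_tests < 1 || n_tests != round(n_tests))
    xs_parameter_error("n_tests must be a positive integer")
  alpha / n_tests
}

#' Star annotation under family-wise adjusted thresholds
#'
#' `"***"` when `p < 0.001 / n_tests`, `"**"` when `p < 0.01 / n_tests`,
#' `"*"` when `p < 0.05 / n_tests`, otherwise `""`.
#'
#' @param p P-value in `[0, 1]`.
#' @param n_tests Family size used for the Bonferroni adjustment.
#' @param alpha_levels Decreasing vector of nominal levels (default
#'   `c(0.05, 0.01, 0.001)`).
#' @return Star string.
#' @export
assign_stars <- function(p, n_tests, alpha_levels = c(0.05, 0.01, 0.001)) {
  if (!is.numeric(p) || p < 0 || p > 1)
    xs_parameter_error("p must lie in [0, 1]")
  levels <- sort(alpha_levels, decreasing = TRUE)
  strrep("*", sum(p < levels / n_tests))
}

#' Fisher exact test of a 2x2 proportion table
#'
#' Two-sided exact test of association in a 2x2 count table (e.g. unified
#' versus punctate cloud counts for two constructs), with the two-sided
#' p-value defined as the sum of hypergeometric probabilities of all
#' tables no more probable than the observed one.
#'
#' @param tab 2x2 matrix of non-negative counts with all margins positive.
#' @return Two-sided p-value.
#' @examples
#' fisher_exact(matrix(c(221, 80, 109, 300), 2))  # unified vs punctate
#' @export
fisher_exact <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L)) || any(tab < 0) || any(tab != round(tab)))
    xs_parameter_error("tab must be a 2x2 matrix of non-negative counts")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    xs_degenerate_table_error("all margins of the 2x2 table must be positive")
  stats::fisher.test(tab)$p.value
}

#' Welch t-test of expression replicates
#'
#' Two-sided unpaired Welch two-sample t-test, used for comparing relative
#' expression (RQ) replicates between conditions.
#'
#' @param test,control Numeric vectors with at least 2 replicates each.
#' @return Two-sided p-value.
#' @export
t_test_rq <- function(test, control) {
  if (length(test) < 2L || length(control) < 2L)
    xs_insufficient_data_error("each group needs at least 2 replicates")
  stats::t.test(test, control, alternative = "two.sided",
                var.equal = FALSE)$p.value
}

#' Interpret a z-score as a nuclear-intensity percentile
#'
#' Under a Gaussian reference for the nuclear background, a cloud whose
#' median mark intensity sits `z` background SDs above the nuclear mean
#' corresponds to the `100 * pnorm(z)` percentile of nuclear intensity
#' (e.g. z = 2.59 is roughly the 99th percentile).
#'
#' @param z Finite z-score (vectorised).
#' @return Percentile(s) in `[0, 100]`.
#' @export
z_to_percentile <- function(z) {
  if (any(!is.finite(z)))
    xs_parameter_error("z must be finite")
  100 * stats::pnorm(z)
}

#' Compare scored populations against a control construct
#'
#' Runs [mann_whitney()] for each planned (test, control) pair of groups
#' in a per-cell score table and annotates each comparison with the
#' family-wise adjusted thresholds and stars. The family size is a
#' required, user-declared input: it is the total number of comparisons
#' in the experiment-wide family, which may exceed the pairs passed here.
#'
#' @param scores Data frame of per-cell scores (as from [score_cells()]).
#' @param plan List of `list(test = , control = )` group-label pairs.
#' @param n_tests Family size for the Bonferroni adjustment.
#' @param alpha_levels Nominal levels (default `c(0.05, 0.01, 0.001)`).
#' @param group_col,value_col Columns holding the group label and the
#'   per-cell statistic.
#' @return Data frame with one row per comparison: group labels, group
#'   sizes, `U`, `p_value`, `n_tests_in_family`, one `threshold_*` column
#'   per level, and `stars`.
#' @export
compare_populations <- function(scores, plan, n_tests,
                                alpha_levels = c(0.05, 0.01, 0.001),
                                group_col = "construct", value_col = "z") {
  if (!group_col %in% names(scores) || !value_col %in% names(scores))
    xs_parameter_error("scores lacks the group or value column")
  levels <- sort(alpha_levels, decreasing = TRUE)
  thr <- vapply(levels, bonferroni_threshold, numeric(1), n_tests = n_tests)
  rows <- lapply(plan, function(pair) {
    x <- scores[[value_col]][scores[[group_col]] == pair$test]
    y <- scores[[value_col]][scores[[group_col]] == pair$control]
    mw <- mann_whitney(x, y)
    row <- data.frame(group_test = pair$test, group_control = pair$control,
                      n_test = mw$n_test, n_control = mw$n_control,
                      U = mw$U, p_value = mw$p_value,
                      n_tests_in_family = n_tests,
                      stars = assign_stars(mw$p_value, n_tests, alpha_levels),
                      stringsAsFactors = FALSE)
    for (i in seq_along(levels))
      row[[sprintf("threshold_%g", levels[i])]] <- thr[i]
    row
  })
  out <- do.call(rbind, rows)
  attr(out, "alpha_levels") <- levels
  attr(out, "adjusted_thresholds") <- thr
  out
}

#' Tabulate unified/punctate morphology proportions per construct
#'
#' @param morphologies Data frame with columns `construct` and
#'   `morphology` (`"unified"` / `"punctate"`), one row per cell.
#' @return Data frame with one row per construct: `construct`,
#'   `n_unified`, `n_punctate`.
#' @export
proportion_table <- function(morphologies) {
  tab <- table(morphologies$construct, morphologies$morphology)
  out <- data.frame(construct = rownames(tab),
                    n_unified = if ("unified" %in% colnames(tab))
                      as.integer(tab[, "unified"]) else 0L,
                    n_punctate = if ("punctate" %in% colnames(tab))
                      as.integer(tab[, "punctate"]) else 0L,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
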