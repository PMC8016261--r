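test_that("Mann-Whitney comparisons match exact enumeration", {
  expect_equal(mann_whitney(c(1, 2, 3), c(4, 5, 6))$U, 0)
  expect_equal(mann_whitney(c(1, 2, 3), c(4, 5, 6))$p_value, 0.1)
  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  expect_error(mann_whitney(1, c(1, 2)),
               class = "xs_insufficient_data_error")

  # random small samples, with and without ties, against the bitmask oracle
  set.seed(7)
  for (i in 1:40) {
    m <- sample(2:6, 1); n <- sample(2:6, 1)
    vals <- if (i %% 2) round(runif(m + n, 0, 5)) else runif(m + n)
    x <- vals[seq_len(m)]; y <- vals[-seq_len(m)]
    expect_equal(mann_whitney(x, y)$p_value, oracle_mw_exact(x, y),
                 tolerance = 1e-12)
  }

  # tie-free exact branch agrees with wilcox.test's exact p
  set.seed(8)
  for (i in 1:20) {
    x <- runif(5); y <- runif(6)
    expect_equal(mann_whitney(x, y)$p_value,
                 wilcox.test(x, y, exact = TRUE)$p.value, tolerance = 1e-12)
  }
})

test_that("the exact path covers where the normal approximation falls short", {
  # At a pooled size of 12 the tie/continuity-corrected normal
  # approximation can still miss the exact two-sided p by more than 1%
  # (worst case ~0.016 even for balanced splits of distinct values) —
  # which is why mann_whitney() enumerates exactly there. Pin both facts:
  # the implementation takes the exact route, and the approximation error
  # at the crossover stays below a modest bound.
  vals <- c(0.3, 1.1, 1.9, 2.2, 3.7, 4.1, 5.6, 6.2, 7.8, 8.3, 9.9, 11.4)
  worst <- 0
  for (m in 3:9) {
    sets <- combn(12, m)
    for (j in seq_len(ncol(sets))) {
      x <- vals[sets[, j]]; y <- vals[-sets[, j]]
      mw <- mann_whitney(x, y)
      expect_match(mw$method, "exact")
      p_approx <- wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
      worst <- max(worst, abs(mw$p_value - p_approx))
    }
  }
  expect_lt(worst, 0.025)
})

test_that("large-sample p tracks the permutation distribution", {
  # two n = 60 samples: approximate p within 0.005 of a 1e5-permutation p
  set.seed(15)
  x <- rnorm(60, 0.35); y <- rnorm(60)
  p <- mann_whitney(x, y)$p_value
  r <- rank(c(x, y))
  mu <- 60 * 61 / 2 + 60 * 60 / 2
  obs <- abs(sum(r[1:60]) - mu)
  perm <- replicate(1e5, abs(sum(r[sample.int(120, 60)]) - mu) >= obs)
  expect_lt(abs(p - mean(perm)), 0.005)
})

test_that("Bonferroni thresholds and stars follow the family size", {
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 48) * 48, 0.05,
               tolerance = 1e-15)
  expect_error(bonferroni_threshold(0.05, 0), class = "xs_parameter_error")
  expect_error(bonferroni_threshold(1.2, 4), class = "xs_parameter_error")

  expect_identical(assign_stars(1e-6, 48), "***")
  expect_identical(assign_stars(5e-4, 48), "*")
  expect_identical(assign_stars(0.02, 48), "")
  expect_identical(assign_stars(3e-4, 48), "*")
  expect_identical(assign_stars(1e-4, 48), "**")
})

test_that("Fisher exact p matches hypergeometric enumeration", {
  expect_equal(fisher_exact(matrix(c(5, 5, 5, 5), 2)), 1)
  expect_equal(fisher_exact(matrix(c(3, 0, 0, 3), 2)), 0.1)
  expect_error(fisher_exact(matrix(c(0, 0, 3, 3), 2)),
               class = "xs_degenerate_table_error")

  # every table with total up to 15 and positive margins
  for (tot in 2:15) for (a in 0:tot) for (b in 0:(tot - a))
    for (cc in 0:(tot - a - b)) {
      d <- tot - a - b - cc
      if ((a + b) == 0 || (cc + d) == 0 || (a + cc) == 0 || (b + d) == 0)
        next
      expect_equal(fisher_exact(matrix(c(a, cc, b, d), 2)),
                   oracle_fisher(a, b, cc, d), tolerance = 1e-10)
    }
})

test_that("Welch t-test matches a from-definition computation", {
  expect_equal(t_test_rq(c(1, 2, 3), c(1, 2, 3)), 1)
  set.seed(5)
  expect_lt(t_test_rq(c(1, 1, 1, 1) + rnorm(4, 0, 1e-6),
                      c(2, 2, 2, 2) + rnorm(4, 0, 1e-6)), 1e-6)
  expect_equal(t_test_rq(c(0.9, 1.1, 1.0), c(0.5, 0.6, 0.55)),
               oracle_welch(c(0.9, 1.1, 1.0), c(0.5, 0.6, 0.55)),
               tolerance = 1e-10)
  expect_error(t_test_rq(1, c(1, 2)), class = "xs_insufficient_data_error")
})

test_that("z-scores convert to nuclear-intensity percentiles", {
  expect_equal(z_to_percentile(0), 50)
  expect_gte(z_to_percentile(2.59), 99)
  grid <- seq(-4, 4, by = 0.25)
  expect_true(all(diff(z_to_percentile(grid)) > 0))
  expect_error(z_to_percentile(Inf), class = "xs_parameter_error")
})

test_that("comparison tables carry thresholds and stars consistently", {
  set.seed(2)
  scores <- data.frame(
    construct = rep(c("full", "dE"), each = 40),
    z = c(rnorm(40, 2.6, 1.7), rnorm(40, 0, 1.7)))
  cmp <- compare_populations(scores,
                             plan = list(list(test = "dE",
                                              control = "full")),
                             n_tests = 48)
  expect_equal(cmp$n_test, 40L)
  expect_equal(cmp$`threshold_0.05`, 0.05 / 48)
  expect_equal(cmp$`threshold_0.001`, 0.001 / 48)
  k <- sum(cmp$p_value < c(0.05, 0.01, 0.001) / 48)
  expect_identical(cmp$stars, strrep("*", k))
})

test_that("blinding hides identities and round-trips exactly", {
  set.seed(3)
  records <- data.frame(cell_id = sprintf("c%02d", 1:60),
                        construct = rep(c("full", "dA"), 30),
                        mark = "H3K27me3", treatment = "5ddox",
                        z = rnorm(60))
  bl <- blind_dataset(records, seed = 12)
  expect_false(any(c("cell_id", "construct", "mark", "treatment") %in%
                     names(bl$coded)))
  expect_equal(unblind(bl$coded, bl$key)[names(records)], records)

  bl2 <- blind_dataset(records, seed = 12)
  expect_identical(bl$coded$code, bl2$coded$code)
  bl3 <- blind_dataset(records, seed = 13)
  expect_false(identical(bl$coded$code, bl3$coded$code))

  bad <- bl$coded
  bad$code[1] <- "blind_xxxxx"
  expect_error(unblind(bad, bl$key), class = "xs_key_mismatch_error")
  expect_error(blind_dataset(rbind(records, records[1, ]), seed = 1),
               class = "xs_parameter_error")
})

test_that("morphology proportion tables feed the Fisher test", {
  morph <- data.frame(construct = rep(c("full", "d3D5E"), c(6, 7)),
                      morphology = c(rep("unified", 5), "punctate",
                                     rep("unified", 2), rep("punctate", 5)))
  tab <- proportion_table(morph)
  expect_equal(tab$n_unified[tab$construct == "full"], 5L)
  expect_equal(tab$n_punctate[tab$construct == "d3D5E"], 5L)
  p <- fisher_exact(matrix(c(5, 2, 1, 5), 2))
  expect_equal(p, oracle_fisher(5, 1, 2, 5), tolerance = 1e-12)
})
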