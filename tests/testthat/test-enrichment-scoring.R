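test_that("pixel classification applies strict relative thresholds", {
  p <- tiny_profile(green = c(100, 80, 10, 5, 30), red = rep(1, 5))
  expect_identical(as.character(classify_pixels(p)$labels),
                   c("positive", "positive", "negative", "negative",
                     "excluded"))
  # boundary values are excluded by strict inequality
  p2 <- tiny_profile(green = c(100, 50, 25, 10), red = rep(1, 4))
  expect_identical(as.character(classify_pixels(p2)$labels),
                   c("positive", "excluded", "excluded", "negative"))
  expect_equal(classify_pixels(p2)$green_max, 100)

  expect_error(classify_pixels(tiny_profile(rep(0, 12), rep(1, 12))),
               class = "xs_no_signal_error")
  expect_error(classify_pixels(p, positive_frac = 0.2, negative_frac = 0.3),
               class = "xs_parameter_error")
})

test_that("labels are invariant under positive scaling of green", {
  set.seed(4)
  for (i in 1:20) {
    g <- runif(15, 0, 300)
    p <- line_profile(1:15, g, rnorm(15, 50, 5), rep(1, 15))
    base <- classify_pixels(p)$labels
    for (a in c(0.25, 2, 7.5)) {
      ps <- line_profile(1:15, a * g, p$red, p$blue)
      expect_identical(classify_pixels(ps)$labels, base)
    }
  }
})

test_that("the z-score matches its hand-computed example", {
  p <- tiny_profile(green = c(100, 80, 10, 5, 30),
                    red = c(50, 60, 10, 20, 15))
  res <- compute_enrichment(p)
  expect_equal(res$median_pos_red, 55)
  expect_equal(res$mean_neg_red, 15)
  expect_equal(res$sd_neg_red, sqrt(50))
  expect_equal(res$z_score, 40 / sqrt(50))
  expect_equal(res$cloud_fraction, 0.4)
  expect_equal(res$n_excluded, 1L)

  # z of exactly 1: positive median one negative-SD above the negative mean
  p1 <- tiny_profile(green = c(100, 100, 0, 0, 0, 0),
                     red = c(mean(c(10, 20, 20, 30)) + sd(c(10, 20, 20, 30)),
                             mean(c(10, 20, 20, 30)) + sd(c(10, 20, 20, 30)),
                             10, 20, 20, 30))
  expect_equal(compute_enrichment(p1)$z_score, 1)

  # flat mark channel: no enrichment either way
  pc <- tiny_profile(green = c(100, 90, 5, 2, 1, 0),
                     red = rep(33, 6))
  expect_equal(compute_enrichment(pc)$z_score, 0)
  # zero-variance background with a real difference is undefined
  pu <- tiny_profile(green = c(100, 5, 2, 1), red = c(50, 33, 33, 33))
  expect_error(compute_enrichment(pu), class = "xs_undefined_z_error")

  # degenerate groups: every pixel positive leaves no negatives
  expect_error(compute_enrichment(
    tiny_profile(green = c(10, 9, 8, 7), red = 1:4)),
    class = "xs_undefined_z_error")
  # a labelling without positives is a no-cloud error
  lab <- list(labels = factor(rep("negative", 4),
                              levels = c("positive", "negative", "excluded")),
              green_max = 10)
  expect_error(compute_enrichment(tiny_profile(c(10, 9, 8, 7), 1:4), lab),
               class = "xs_no_cloud_error")
})

test_that("z-score equals from-definition recomputation on short profiles", {
  set.seed(11)
  checked <- 0
  while (checked < 150) {
    n <- sample(10:12, 1)
    g <- round(runif(n, 0, 255))
    r <- round(runif(n, 0, 255))
    expected <- oracle_z(g, r)
    if (is.null(expected)) next
    p <- line_profile(1:n, g, r, rep(0, n))
    got <- tryCatch(score_profile(p)$z_score,
                    xistscore_error = function(e) NULL)
    if (is.null(got)) next
    expect_equal(got, expected, tolerance = 1e-12)
    checked <- checked + 1
  }
  expect_gte(checked, 150)
})

test_that("z-score is invariant under positive affine transforms of red", {
  set.seed(21)
  for (i in 1:25) {
    n <- sample(c(11, 20, 51), 1)
    g <- runif(n, 0, 200)
    r <- round(runif(n, 0, 200))
    p <- line_profile(1:n, g, r, rep(0, n))
    base <- tryCatch(score_profile(p)$z_score,
                     xistscore_error = function(e) NULL)
    if (is.null(base)) next
    for (ab in list(c(2, 16), c(0.5, 3), c(4, 0))) {
      pt <- line_profile(1:n, g, ab[1] * r + ab[2], p$blue)
      expect_equal(score_profile(pt)$z_score, base, tolerance = 1e-12)
    }
  }
})

test_that("cloud morphology calls unified vs punctate scenes", {
  dm <- c(80, 80)
  mask <- disc(dm, c(40, 40), 35)
  g <- matrix(0, dm[1], dm[2])
  g[disc(dm, c(40, 40), 6)] <- 200
  m1 <- classify_cloud_morphology(g, mask)
  expect_identical(m1$morphology, "unified")
  expect_equal(m1$n_components, 1L)

  g5 <- matrix(0, dm[1], dm[2])
  for (k in 0:4)
    g5[disc(dm, c(40 + round(18 * sin(2 * pi * k / 5)),
                  40 + round(18 * cos(2 * pi * k / 5))), 3)] <- 200
  m5 <- classify_cloud_morphology(g5, mask)
  expect_identical(m5$morphology, "punctate")
  expect_equal(m5$n_components, 5L)

  expect_error(classify_cloud_morphology(matrix(0, 10, 10) - 1,
                                         matrix(TRUE, 10, 10)),
               class = "xs_no_signal_error")

  # synthetic punctate scenes are called punctate in nearly all seeds
  calls <- vapply(1:60, function(s) {
    sn <- simulate_nucleus(nucleus_spec(n_foci = 3, seed = 400 + s))
    classify_cloud_morphology(sn$image$green, sn$masks$nucleus)$morphology
  }, character(1))
  expect_gte(mean(calls == "punctate"), 0.95)
})

test_that("score_cells accounts for every input cell", {
  pop <- simulate_population(population_spec("full", n_cells = 10,
                                             delta_mean = 1, seed = 31))
  cells <- pop$cells
  # corrupt one cell: no RNA signal at all
  cells[[4]] <- line_profile(1:20, rep(0, 20), rnorm(20, 50, 5), rep(1, 20),
                             cell_id = "dead")
  out <- score_cells(cells, on_error = "skip")
  sk <- attr(out, "skipped")
  expect_equal(nrow(out) + nrow(sk), 10L)
  expect_equal(sk$cell_id, "dead")
  expect_equal(sk$reason, "xs_no_signal_error")
  expect_error(score_cells(cells, on_error = "stop"),
               class = "xs_no_signal_error")
})
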