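test_that("nucleus segmentation recovers discs, noisy or clean", {
  # noiseless two-level image: mask equals the disc exactly
  m <- matrix(0, 60, 60)
  tru <- disc(c(60, 60), c(30, 30), 20)
  m[tru] <- 200
  expect_identical(segment_nucleus(m), tru)

  expect_error(segment_nucleus(matrix(0, 20, 20)),
               class = "xs_segmentation_error")

  # disc + Gaussian noise at SNR 5
  for (s in 1:5) {
    sn <- simulate_nucleus(nucleus_spec(blue_nucleus = 150,
                                        blue_noise_sd = 30, seed = s))
    got <- segment_nucleus(sn$image$blue)
    expect_gte(jaccard(got, sn$masks$nucleus), 0.95)
  }
})

test_that("nucleolus detection finds low-DAPI territories", {
  sn <- simulate_nucleus(nucleus_spec(seed = 2))
  nuc <- segment_nucleus(sn$image$blue)
  got <- detect_nucleolus(sn$image$blue, nuc)
  expect_gte(jaccard(got, sn$masks$nucleolus), 0.8)

  # uniform DAPI: empty mask is a valid result
  flat <- simulate_nucleus(nucleus_spec(nucleolus_center = NULL, seed = 2))
  nuc2 <- segment_nucleus(flat$image$blue)
  expect_false(any(detect_nucleolus(flat$image$blue, nuc2)))

  # bypass mode returns the supplied mask unchanged
  expect_identical(detect_nucleolus(sn$image$blue, nuc,
                                    override = sn$masks$nucleolus),
                   sn$masks$nucleolus)
})

test_that("RNA peak localisation is deterministic under ties", {
  g <- matrix(0, 30, 40)
  mask <- matrix(TRUE, 30, 40)
  g[17, 23] <- 9
  expect_identical(find_xist_peak(g, mask), c(17L, 23L))
  g[5, 9] <- 9; g[5, 2] <- 9
  expect_identical(find_xist_peak(g, mask), c(5L, 2L))
  expect_error(find_xist_peak(matrix(1, 30, 40), mask),
               class = "xs_no_peak_error")

  sn <- simulate_nucleus(nucleus_spec(seed = 8))
  pk <- find_xist_peak(sn$image$green, sn$masks$nucleus)
  expect_true(sn$masks$cloud[pk[1], pk[2]])
})

test_that("chord placement maximises width and avoids the nucleolus", {
  dm <- c(61, 61)
  nucleus <- disc(dm, c(31, 31), 25)
  li <- place_line(nucleus, c(31, 31))
  expect_equal(li$angle, 0)
  expect_lte(abs(li$n_samples - 51), 1)  # diameter +- 1 sample

  # nucleolus blocking the horizontal diameter: agree with brute force
  for (off in list(c(0, 10), c(3, -8), c(-5, 0))) {
    nl <- disc(dm, c(31, 31) + off, 5)
    peak <- c(31 - 12, 31)
    got <- place_line(nucleus, peak, nucleolus_mask = nl)
    ref <- oracle_best_chord(nucleus, peak, nucleolus = nl)
    expect_equal(got$n_samples, ref$n)
    expect_equal(got$angle, ref$angle)
    expect_equal(got$endpoint_a, as.integer(ref$a))
    pts_r <- got$endpoint_a[1] + seq(0, 1, length.out = got$n_samples) *
      (got$endpoint_b[1] - got$endpoint_a[1])
    expect_false(any(nl[cbind(round(pts_r),
                              round(got$endpoint_a[2] +
                                      seq(0, 1, length.out = got$n_samples) *
                                      (got$endpoint_b[2] - got$endpoint_a[2])))]))
  }

  # peak inside the nucleolus is a placement error
  nl <- disc(dm, c(31, 31), 5)
  expect_error(place_line(nucleus, c(31, 31), nucleolus_mask = nl),
               class = "xs_placement_error")
  # a nucleolar ring around the peak blocks every chord
  ring <- disc(dm, c(31, 31), 8) & !disc(dm, c(31, 31), 4)
  expect_error(place_line(nucleus, c(31, 31), nucleolus_mask = ring),
               class = "xs_no_chord_error")
})

test_that("profile extraction samples raster pixels faithfully", {
  img <- multi_channel_image(matrix(7, 40, 40), matrix(3, 40, 40),
                             matrix(1, 40, 40))
  li <- line_segment(c(20, 5), c(20, 34))
  prof <- extract_profile(img, li)
  expect_length(prof, 30L)
  expect_true(all(prof$red == 7) && all(prof$green == 3))

  # sampled values occur at the corresponding raster pixels
  set.seed(99)
  rimg <- multi_channel_image(matrix(sample(0:255, 1600, TRUE), 40, 40),
                              matrix(sample(0:255, 1600, TRUE), 40, 40),
                              matrix(sample(0:255, 1600, TRUE), 40, 40))
  li2 <- line_segment(c(3, 7), c(36, 22))
  p2 <- extract_profile(rimg, li2)
  n <- li2$n_samples
  t <- seq(0, 1, length.out = n)
  rows <- round(3 + t * (36 - 3)); cols <- round(7 + t * (22 - 7))
  expect_equal(p2$red, rimg$red[cbind(rows, cols)])

  # reversed endpoints give the exact reversal
  p2r <- extract_profile(rimg, line_segment(c(36, 22), c(3, 7)))
  expect_equal(p2r$red, rev(p2$red))
  expect_equal(p2r$green, rev(p2$green))

  expect_error(extract_profile(img, line_segment(c(20, 5), c(20, 9))),
               class = "xs_too_short_error")
})

test_that("end-to-end cloud fraction matches the chord's true coverage", {
  for (s in 1:5) {
    sn <- simulate_nucleus(nucleus_spec(effect_delta = 2, seed = 100 + s))
    ex <- extract_cell_profile(sn$image,
                               nucleolus_mask = sn$masks$nucleolus)
    res <- score_profile(ex$profile)
    n <- ex$line$n_samples
    t <- seq(0, 1, length.out = n)
    rows <- round(ex$line$endpoint_a[1] +
                    t * (ex$line$endpoint_b[1] - ex$line$endpoint_a[1]))
    cols <- round(ex$line$endpoint_a[2] +
                    t * (ex$line$endpoint_b[2] - ex$line$endpoint_a[2]))
    geom_frac <- mean(sn$masks$cloud[cbind(rows, cols)])
    expect_lt(abs(res$cloud_fraction - geom_frac), 0.05)
  }
})
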