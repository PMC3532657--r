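test_that("bar targets: unblurred full-contrast groups measure CTF = 1 and are seed-deterministic", {
  spec <- small_spec()
  freqs <- 1000 / (6.5 * c(4, 8))
  bt <- make_bar_target(spec, freqs, blur_sigma = 0, contrast = 1, noise = "off")
  rimg <- normalize_by_exposure(bt$image)
  for (i in seq_len(nrow(bt$groups))) {
    m <- measure_bar_contrast(rimg, bt$groups[i, ])
    expect_equal(ctf_modulus(m), 1.0)
  }
  b1 <- make_bar_target(spec, freqs, blur_sigma = 5, noise = "on", seed = 11L)
  b2 <- make_bar_target(spec, freqs, blur_sigma = 5, noise = "on", seed = 11L)
  expect_identical(b1$image$pixels, b2$image$pixels)
})

test_that("bar targets reject frequencies beyond Nyquist, naming the limit", {
  spec <- small_spec()  # 6.5 um pitch -> Nyquist 76.9 cycles/mm
  expect_error(make_bar_target(spec, c(20, 100)), "Nyquist")
  expect_error(make_bar_target(spec, 100), "76.9")
})

test_that("blurred bar contrast matches the 1-D convolution oracle", {
  spec <- acquisition_spec(pixel_pitch = 2, frame_shape = c(400L, 300L),
                           exposure_time = 50)
  freqs <- 1000 / (2 * c(8, 16, 32))
  bt <- make_bar_target(spec, freqs, blur_sigma = 10, noise = "off")
  rimg <- normalize_by_exposure(bt$image)
  for (i in seq_len(nrow(bt$groups))) {
    meas <- ctf_modulus(measure_bar_contrast(rimg, bt$groups[i, ]))
    orc <- ctf_conv_oracle(freqs[i], 10)
    expect_lt(abs(meas - orc) / orc, 0.02)
  }
})

test_that("microsphere counts scale linearly with exposure and fraction by construction", {
  spec <- acquisition_spec(pixel_pitch = 2, frame_shape = c(240L, 240L),
                           exposure_time = 10)
  ser <- make_microsphere_series(spec, nominal_fractions = c(0.004, 1.0),
                                 exposure_times = c(10, 20),
                                 sphere_diameter = 6, noise = "off", seed = 3L)
  meas <- measure_sphere_series(ser)
  # exposure doubling doubles background-subtracted counts
  bright <- meas[meas$fraction == 1.0, ]
  off <- spec$dark_offset
  expect_equal((bright$mean_counts[bright$exposure_ms == 20] - off) /
                 (bright$mean_counts[bright$exposure_ms == 10] - off), 2)
  # the 0.4%-100% extremes give a rate ratio of exactly 0.004
  r1 <- meas$mean_rate[meas$fraction == 1.0 & meas$exposure_ms == 10]
  r2 <- meas$mean_rate[meas$fraction == 0.004 & meas$exposure_ms == 10]
  expect_equal(r2 / r1, 0.004, tolerance = 1e-9)
})

test_that("microsphere truth rates never exceed full_well / exposure (saturation guard)", {
  spec <- acquisition_spec(pixel_pitch = 2, frame_shape = c(240L, 240L),
                           full_well = 30000)
  for (bright in c(1e4, 1e6, 1e9)) {
    ser <- make_microsphere_series(spec, c(0.5, 1.0), c(50, 250),
                                   brightest_rate = bright, noise = "off",
                                   seed = 5L)
    expect_true(all(ser$truth$rate <= spec$full_well / (250 / 1000) + 1e-9))
  }
})

test_that("impossible microsphere packing errors with the density limit", {
  tiny <- acquisition_spec(pixel_pitch = 6.5, frame_shape = c(12L, 12L))
  expect_error(
    make_microsphere_series(tiny, 1.0, 10, sphere_diameter = 20,
                            n_spheres = 15L, seed = 1L),
    "density limit")
})

test_that("tumor/bed phantoms reproduce stated rates exactly with noise off", {
  spec <- small_spec()
  pair <- make_tumor_bed_pair(spec, tumor_rate = 1200, muscle_rate = 100,
                              heterogeneity_cv = 0, noise = "off", seed = 2L)
  tum <- normalize_by_exposure(pair$tumor)
  mus <- normalize_by_exposure(pair$muscle)
  expect_equal(tumor_to_muscle_ratio(tum, pair$scene$tumor_mask, mus,
                                     matrix(TRUE, 120, 160)), 12.0)
  # round-trip identity: normalized bed equals the specified rate map exactly
  bed <- normalize_by_exposure(pair$bed)
  expect_equal(bed$rates, pair$bed_rates)
})

test_that("a bed without clusters has an all-zero truth mask and classifies negative", {
  spec <- small_spec()
  pair <- make_tumor_bed_pair(spec, residual_clusters = NULL,
                              heterogeneity_cv = 0, noise = "off", seed = 4L)
  expect_false(any(pair$scene$truth_mask))
  model <- calibrate_threshold(normalize_by_exposure(pair$tumor),
                               pair$scene$tumor_mask)
  expect_identical(classify_bed(normalize_by_exposure(pair$bed), model)$status,
                   "negative")
})

test_that("a 16-um cluster at 6.5-um pitch rasterizes to 4-9 truth pixels (oracle)", {
  spec <- small_spec()
  set.seed(71)
  for (i in 1:10) {
    ctr <- c(runif(1, 200, 500), runif(1, 200, 700))
    pair <- make_tumor_bed_pair(spec, residual_clusters = data.frame(
      diameter_um = 16, rate = 2400, center_row_um = ctr[1],
      center_col_um = ctr[2]), heterogeneity_cv = 0, noise = "off", seed = i)
    n_pkg <- sum(pair$scene$truth_mask)
    n_orc <- disc_pixel_count_oracle(ctr, 16, 6.5, n_grid = 160)
    expect_identical(n_pkg, n_orc)
    expect_gte(n_pkg, 4L); expect_lte(n_pkg, 9L)
  }
})

test_that("clusters outside the frame are rejected", {
  spec <- small_spec()
  expect_error(make_tumor_bed_pair(spec, residual_clusters = data.frame(
    diameter_um = 40, rate = 2400, center_row_um = 5, center_col_um = 500)),
    "outside")
})

test_that("noisy uniform regions converge to the specified rate (< 1% at 1e4+ px)", {
  spec <- small_spec()  # 19200 px
  pair <- make_tumor_bed_pair(spec, muscle_rate = 200, heterogeneity_cv = 0,
                              noise = "on", seed = 9L)
  mus <- normalize_by_exposure(pair$muscle)
  expect_lt(abs(mean(mus$rates) - 200) / 200, 0.01)
})

test_that("cohort generation: censoring, determinism, empirical hazard-ratio convergence", {
  all_cens <- simulate_cohort(cohort_spec(10, baseline_hazard = 0,
                                          true_hazard_ratio = 2, seed = 1L))
  expect_true(all(all_cens$event == 0))
  expect_true(all(all_cens$time_months == 12))

  c1 <- simulate_cohort(cohort_spec(25, seed = 42L))
  c2 <- simulate_cohort(cohort_spec(25, seed = 42L))
  expect_identical(c1, c2)

  big <- simulate_cohort(cohort_spec(4000, baseline_hazard = 0.05,
                                     true_hazard_ratio = 3, seed = 7L))
  hr <- hazard_ratio(big[big$arm == "residual_negative", ],
                     big[big$arm == "residual_positive", ])
  expect_lt(abs(hr$hazard_ratio - 3) / 3, 0.1)
})

test_that("Weibull shape option preserves the proportional-hazards structure", {
  big <- simulate_cohort(cohort_spec(3000, baseline_hazard = 0.02,
                                     true_hazard_ratio = 2.5, shape = 1.5,
                                     seed = 13L))
  hr <- hazard_ratio(big[big$arm == "residual_negative", ],
                     big[big$arm == "residual_positive", ])
  expect_lt(abs(hr$hazard_ratio - 2.5) / 2.5, 0.12)
})
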