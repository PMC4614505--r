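test_that("axis tracing recovers a straight fibril to sub-pixel accuracy", {
  img <- generate_fibril_image(fibril_image_spec(
    seed = 1, substrate_roughness_sd = 0), "dry")
  ax <- trace_fibril_axis(img)
  expect_gt(nrow(ax), 150)  # >= 3 fibril widths of crest
  # generator axis is the horizontal centre line
  expect_lt(sqrt(mean((ax$row - (128 - 1) / 2)^2)), 1)
  # blank substrate gives an explicit empty result
  set.seed(2)
  blank <- topography_image(matrix(rnorm(128 * 320, sd = 0.2), 128, 320), 2)
  expect_equal(nrow(trace_fibril_axis(blank)), 0)
})

test_that("axis tracing is rotation invariant", {
  for (ang in c(0, 30)) {
    img <- generate_fibril_image(fibril_image_spec(
      seed = 2, angle_deg = ang, substrate_roughness_sd = 0), "dry")
    ax <- trace_fibril_axis(img)
    # perpendicular deviation from the generator centre line
    th <- ang * pi / 180
    r0 <- (128 - 1) / 2; c0 <- (320 - 1) / 2
    dev <- -(ax$col - c0) * sin(th) + (ax$row - r0) * cos(th)
    expect_lt(sqrt(mean(dev^2)), 1)
  }
})

test_that("cross-section height matches the generated crest", {
  spec <- fibril_image_spec(height_dry = 26, band_amplitude_frac = 0,
                            substrate_roughness_sd = 0)
  img <- generate_fibril_image(spec, "dry")
  ax <- trace_fibril_axis(img)
  p <- extract_profile(img, ax)
  expect_equal(fibril_height(p), 26, tolerance = 0.02)
  expect_equal(attr(p, "apparent_width_nm"), 100, tolerance = 0.15)
})

test_that("height extraction is invariant to substrate tilt and offset", {
  spec <- fibril_image_spec(band_amplitude_frac = 0,
                            substrate_roughness_sd = 0)
  img <- generate_fibril_image(spec, "dry")
  h0 <- fibril_height(extract_profile(img, trace_fibril_axis(img)))
  tilted <- img
  tilted$heights <- img$heights +
    outer(seq_len(128) * 0.05, rep(1, 320)) + 7.3
  h1 <- fibril_height(extract_profile(tilted, trace_fibril_axis(tilted)))
  expect_equal(h1, h0, tolerance = 1e-6)
})

test_that("window averaging is a no-op on noiseless unbanded images", {
  spec <- fibril_image_spec(band_amplitude_frac = 0,
                            substrate_roughness_sd = 0)
  img <- generate_fibril_image(spec, "dry")
  ax <- trace_fibril_axis(img)
  h1 <- fibril_height(extract_profile(img, ax, station = 100,
                                      avg_window = 1))
  h9 <- fibril_height(extract_profile(img, ax, station = 100,
                                      avg_window = 9))
  expect_equal(h1, h9, tolerance = 1e-9)
})

test_that("D-period estimation is pixel-accurate across periods", {
  # error within one pixel equivalent for 50-80 nm banding at 2 nm/px
  for (p in c(50, 67, 80)) {
    spec <- fibril_image_spec(d_period = p, substrate_roughness_sd = 0)
    img <- generate_fibril_image(spec, "dry")
    ax <- trace_fibril_axis(img)
    for (m in c("fft", "autocorrelation")) {
      est <- estimate_d_period(img, ax, method = m)
      expect_lt(abs(est$period_nm - p), 2)
    }
  }
})

test_that("D-period estimate ignores constant height offsets", {
  spec <- fibril_image_spec(substrate_roughness_sd = 0)
  img <- generate_fibril_image(spec, "dry")
  off <- img; off$heights <- img$heights + 50
  expect_equal(estimate_d_period(off)$period_nm,
               estimate_d_period(img)$period_nm, tolerance = 1e-9)
})

test_that("flat crest profiles are flagged low-confidence", {
  spec <- fibril_image_spec(band_amplitude_frac = 0,
                            substrate_roughness_sd = 0.2, seed = 5)
  img <- generate_fibril_image(spec, "dry")
  est <- estimate_d_period(img)
  expect_true(est$low_confidence)
})

test_that("swelling arithmetic and conventions are exact", {
  s0 <- swelling(26, 26)
  expect_equal(s0$S, 1)
  expect_equal(s0$water_volume_fraction, 0)
  expect_equal(s0$normalized_density, 1)
  # S = 2.6 means about two thirds of the wet fibril volume is water
  s <- swelling(26, 26 * 2.6)
  expect_equal(s$S, 2.6, tolerance = 1e-15)
  expect_equal(s$water_volume_fraction, 1 - 1 / 2.6, tolerance = 1e-12)
  expect_equal(round(s$water_volume_fraction, 3), 0.615)
  # isotropic convention squares the fold
  expect_equal(swelling(26, 67.6, "isotropic")$normalized_density,
               1 / 2.6^2, tolerance = 1e-12)
  expect_error(swelling(0, 10), "h_dry")
  # rho_norm strictly decreasing in S
  rho <- vapply(seq(1, 3, by = 0.25),
                function(S) swelling(10, 10 * S)$normalized_density,
                numeric(1))
  expect_true(all(diff(rho) < 0))
})

test_that("printed swelling folds give the printed percent deficit", {
  expect_equal(percent_difference(1.5, 2.6), 42.3, tolerance = 0.01)
})

test_that("shrinkage series reports folds against the reference medium", {
  h <- c(air = 26, PBS = 67.6, EtOH25 = 50, EtOH50 = 40, EtOH100 = 30)
  ss <- shrinkage_series(h)
  expect_equal(ss$fold[ss$medium == "PBS"], 1)
  expect_equal(ss$fold[ss$medium == "air"], 26 / 67.6)
  dehydration <- shrinkage_series(h, order = c("PBS", "EtOH25", "EtOH50",
                                               "EtOH100", "air"))
  expect_true(attr(dehydration, "monotone_decreasing"))
  same <- shrinkage_series(c(air = 30, PBS = 30))
  expect_equal(same$fold, c(1, 1))
  expect_error(shrinkage_series(c(air = 26), reference = "PBS"), ">= 2")
})

test_that("a generated dry/wet pair round-trips the swelling fold", {
  spec <- fibril_image_spec(height_dry = 26, swelling_true = 2.6,
                            substrate_roughness_sd = 0.2, seed = 6)
  dry <- generate_fibril_image(spec, "dry")
  wet <- generate_fibril_image(spec, "wet")
  h_d <- fibril_height(extract_profile(dry, trace_fibril_axis(dry)))
  h_w <- fibril_height(extract_profile(wet, trace_fibril_axis(wet)))
  s <- swelling(h_d, h_w)
  expect_equal(s$S, 2.6, tolerance = 0.05)
  # internal consistency with the series op
  ss <- shrinkage_series(c(air = h_d, PBS = h_w))
  expect_equal(ss$fold[ss$medium == "air"], 1 / s$S, tolerance = 1e-12)
})
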