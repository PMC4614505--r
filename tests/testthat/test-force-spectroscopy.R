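test_that("thermal calibration matches the equipartition arithmetic", {
  # k = kB T / var(d): var 1.69e-2 nm^2 at 294 K gives ~0.24 N/m
  set.seed(1)
  d <- rnorm(2e5, sd = sqrt(1.69e-2))
  d <- d * sqrt(1.69e-2) / sd(d)  # pin the sample variance
  expect_equal(thermal_spring_constant(d, 294, correction = 1),
               1.380649e-23 * 294 / 1.69e-20, tolerance = 1e-6)
  # doubling the variance halves k
  expect_equal(thermal_spring_constant(sqrt(2) * d, 294, 1),
               thermal_spring_constant(d, 294, 1) / 2, tolerance = 1e-9)
  expect_error(thermal_spring_constant(rep(1, 100)), "variance")
})

test_that("thermal calibration recovers a known lever from simulated noise", {
  # equipartition simulation at k = 8.3 N/m (a stiff EtOH-series lever)
  set.seed(2)
  k_true <- 8.3
  var_nm2 <- 1.380649e-23 * 294 / k_true * 1e18
  d <- rnorm(1e5, sd = sqrt(var_nm2))
  expect_equal(thermal_spring_constant(d, 294, correction = 1), k_true,
               tolerance = 0.05)
})

test_that("force/separation conversion obeys its limiting identities", {
  z <- seq(0, 100, length.out = 64)
  # rigid-sample limit: zero deflection means delta = z - z0 and F = 0
  crv <- force_curve(z, rep(0, 64), rep("approach", 64),
                     spring_constant = 0.24)
  fs <- to_force_and_separation(crv, z0 = 40)
  expect_equal(fs$delta_nm, z - 40)
  expect_equal(fs$force_nN, rep(0, 64))
  # F = k d
  crv2 <- force_curve(z, rep(10, 64), rep("approach", 64),
                      spring_constant = 0.24)
  expect_equal(to_force_and_separation(crv2, 40)$force_nN[1], 2.4)
  expect_error(to_force_and_separation(crv, 500), "range")
})

test_that("contact point is found at the generator truth", {
  spec <- curve_sim_spec(1e8, contact_point = 200, points_per_segment = 256)
  crv <- generate_force_curve(spec)
  spacing <- diff(range(crv$z[crv$segment == "approach"])) / 255
  cp <- find_contact_point(crv)
  expect_false(cp$no_contact)
  expect_lt(abs(cp$z0 - 200), spacing)
  # pure-noise curve has no contact
  z <- seq(0, 400, length.out = 128)
  set.seed(3)
  flat <- force_curve(z, rnorm(128, sd = 0.05), rep("approach", 128), 0.24)
  expect_true(find_contact_point(flat)$no_contact)
})

test_that("contact point tolerates noise at the few-sample level", {
  # noise at 2% of max force: median error across seeds within 3 spacings
  errs <- vapply(1:20, function(s) {
    C <- cone_coefficient(1e8)
    spec <- curve_sim_spec(1e8, contact_point = 200,
                           noise_sd = 0.02 * C * 2500,
                           points_per_segment = 256, seed = 400 + s)
    crv <- generate_force_curve(spec)
    spacing <- diff(range(crv$z[crv$segment == "approach"])) / 255
    abs(find_contact_point(crv)$z0 - 200) / spacing
  }, numeric(1))
  expect_lt(median(errs), 3)
})

test_that("contact stiffness matches analytic slopes", {
  d <- seq(0, 100, length.out = 64)
  # F = C d^2 with F(100) = 10 nN: S = 2 C dmax = 0.2 N/m
  expect_equal(as.numeric(contact_stiffness(d, 1e-3 * d^2)), 0.2,
               tolerance = 1e-9)
  # linear law: slope is the coefficient everywhere
  expect_equal(as.numeric(contact_stiffness(d, 0.05 * d)), 0.05,
               tolerance = 1e-9)
  expect_error(contact_stiffness(d[1:6], (1e-3 * d^2)[1:6]), "8")
  # noisy quadratic over 20 seeds within 5%
  errs <- vapply(1:20, function(s) {
    set.seed(500 + s)
    f <- 1e-3 * d^2 + rnorm(64, sd = 0.02)
    abs(as.numeric(contact_stiffness(d, f, fit_fraction = 1)) / 0.2 - 1)
  }, numeric(1))
  expect_lt(median(errs), 0.05)
})

test_that("contact depth follows the Oliver-Pharr relation", {
  expect_equal(contact_depth(100, 10, 0.2, epsilon = 0.75), 62.5)
  expect_equal(contact_depth(100, 10, 0.2, epsilon = 0), 100)
  expect_warning(h <- contact_depth(10, 10, 0.2, epsilon = 0.75),
                 "clipped")
  expect_equal(h, 0)
  # cone identity: for F = C d^2 and eps = 2(pi-2)/pi, h_c = (2/pi) dmax
  S <- 2 * 1e-3 * 100; P <- 1e-3 * 100^2
  expect_equal(contact_depth(100, P, S), 100 * 2 / pi, tolerance = 1e-12)
})

test_that("area function evaluates ideal and calibrated forms", {
  poly_fn <- tip_area_function(coefficients = c(24.5))
  expect_equal(area_at_depth(poly_fn, 10), 2450)
  ideal <- tip_area_function(35)
  expect_equal(area_at_depth(ideal, 0), 0)
  expect_equal(area_at_depth(ideal, 20), pi * tan(35 * pi / 180)^2 * 400,
               tolerance = 1e-12)
  expect_error(area_at_depth(ideal, -1), "non-negative")
})

test_that("reduced modulus arithmetic and scaling laws hold", {
  expect_equal(reduced_modulus(0.2, 2450, beta = 1),
               sqrt(pi) / 2 * 0.2 / sqrt(2450) * 1e9, tolerance = 1e-12)
  expect_equal(reduced_modulus(0.2, 2450, 1) / 1e6, 3.58, tolerance = 0.01)
  # beta within the admissible band scales inversely
  expect_equal(reduced_modulus(0.2, 2450, 1.05),
               reduced_modulus(0.2, 2450, 1) / 1.05)
  expect_error(reduced_modulus(0.2, 2450, 2), "beta")
  # quadrupling the area halves E_r
  expect_equal(reduced_modulus(0.2, 4 * 2450, 1),
               reduced_modulus(0.2, 2450, 1) / 2)
  # monotone in S_c at fixed A_c and decreasing in A_c at fixed S_c
  S <- seq(0.1, 1, by = 0.1)
  expect_true(all(diff(vapply(S, reduced_modulus, numeric(1),
                              A_c = 1000)) > 0))
  A <- seq(500, 5000, by = 500)
  expect_true(all(diff(vapply(A, function(a)
    reduced_modulus(0.5, a), numeric(1))) < 0))
})

test_that("sample modulus inverts the two-body relation", {
  expect_equal(sample_modulus(4e6, 0.5), 3e6)
  expect_equal(sample_modulus(4e6, 0), 4e6)
  # the simplified form under-reads by ~9-10% at the stiff end (13 GPa)
  Er_stiff <- 1 / ((1 - 0.25) / 13e9 + (1 - 0.27^2) / 169e9)
  two <- sample_modulus(Er_stiff, 0.5, "two_body", 169e9, 0.27)
  simp <- sample_modulus(Er_stiff, 0.5, "simplified")
  expect_equal(two, 13e9, tolerance = 1e-9)
  expect_gt(two / simp - 1, 0.09)
  expect_lt(two / simp - 1, 0.10)
  expect_error(sample_modulus(200e9, 0.5, "two_body", 169e9, 0.27),
               "non-physical")
})

test_that("simplified inversion is negligible error in the hydrated regime", {
  # below 100 MPa the two-body correction is under 0.1%
  for (E in c(5e6, 20e6, 100e6)) {
    Er <- 1 / ((1 - 0.25) / E + (1 - 0.27^2) / 169e9)
    rel <- sample_modulus(Er, 0.5, "two_body", 169e9, 0.27) /
      sample_modulus(Er, 0.5, "simplified") - 1
    expect_lt(abs(rel), 1e-3)
  }
})

test_that("unit bookkeeping matches an all-SI hand computation", {
  # package works in N/m and nm^2; redo Eq chain in pure SI
  S_SI <- 0.2                      # N/m
  A_SI <- 2450e-18                 # m^2
  E_r_SI <- sqrt(pi) / 2 * S_SI / sqrt(A_SI)
  expect_equal(reduced_modulus(0.2, 2450), E_r_SI, tolerance = 1e-12)
})

test_that("full analysis flags contact-free curves and batches cleanly", {
  good <- generate_force_curve(curve_sim_spec(1e8, seed = 1))
  flat <- generate_force_curve(curve_sim_spec(1e8, max_indentation = 0,
                                              noise_sd = 0.01, seed = 2))
  out <- analyze_curves(list(good, flat))
  expect_equal(nrow(out), 2)
  expect_true(out$valid[1])
  expect_false(out$valid[2])
  expect_true(is.na(out$E_sample_Pa[2]))
  # config echo present in every row
  expect_equal(out$nu_sample, c(0.5, 0.5))
})
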