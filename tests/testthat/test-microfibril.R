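test_that("triclinic volume matches closed forms and the metric oracle", {
  expect_equal(cell_volume(triclinic_cell(10, 10, 10)), 1000)
  cell <- triclinic_cell(40.0, 27.0, 678, 89.2, 94.6, 105.6)
  v <- cell_volume(cell)
  expect_equal(v, gram_volume(40.0, 27.0, 678, 89.2, 94.6, 105.6),
               tolerance = 1e-12)
  expect_equal(v / 1e5, 7.03, tolerance = 0.001)
  # (a, alpha) <-> (b, beta) permutation symmetry of the formula
  expect_equal(cell_volume(triclinic_cell(27.0, 40.0, 678,
                                          94.6, 89.2, 105.6)), v)
  # volume never exceeds a b c; equality only at right angles
  expect_lt(v, 40 * 27 * 678)
  expect_equal(cell_volume(triclinic_cell(3, 5, 7)), 105)
  expect_error(triclinic_cell(10, 10, 10, 170, 170, 170), "positive-definite")
})

test_that("triclinic volume agrees with the triple-product construction", {
  # randomized valid cells, lattice-vector determinant as oracle
  set.seed(10)
  n_ok <- 0
  while (n_ok < 25) {
    a <- runif(1, 5, 100); b <- runif(1, 5, 100); c <- runif(1, 5, 800)
    ang <- runif(3, 60, 120)
    cell <- tryCatch(triclinic_cell(a, b, c, ang[1], ang[2], ang[3]),
                     error = function(e) NULL)
    if (is.null(cell)) next
    n_ok <- n_ok + 1
    v_oracle <- abs(det(lattice_vectors(cell)))
    expect_equal(cell_volume(cell), v_oracle, tolerance = 1e-9)
    expect_equal(cell_volume(cell),
                 gram_volume(a, b, c, ang[1], ang[2], ang[3]),
                 tolerance = 1e-9)
  }
})

test_that("trimer masses reproduce the hetero/homotrimer bookkeeping", {
  m <- c(a1 = 138.032, a2 = 129.557)
  expect_equal(trimer_mass(m, c(a1 = 2, a2 = 1)), 405.621)
  expect_equal(trimer_mass(m, c(a1 = 3)), 414.096)
  expect_equal(trimer_mass(c(x = 7), c(x = 3)), 21)
  expect_error(trimer_mass(m, c(a1 = 2)), "3 chains")
  # homotrimer is 2% heavier than the heterotrimer
  expect_equal(-percent_difference(414.096, 405.621), 2.09,
               tolerance = 0.005)
})

test_that("density comparison reproduces the equal-mass approximation", {
  # 14% larger cell at equal mass: 12.3% lower density
  d <- density_ratio(1, 1.14, 1, 1)
  expect_equal(d$ratio, 1 / 1.14, tolerance = 1e-12)
  expect_equal(d$percent_difference, 12.28, tolerance = 0.005)
  expect_equal(density_ratio(5, 2, 5, 2)$percent_difference, 0)
  # with the true trimer masses the deficit shrinks to ~10.4%
  d2 <- density_ratio(414.096, 1.14, 405.621, 1)
  expect_equal(d2$percent_difference, 10.45, tolerance = 0.01)
})

test_that("percent differences match the printed group comparisons", {
  expect_equal(percent_difference(5.3, 7.9), 32.91, tolerance = 0.005)
  expect_equal(percent_difference(0.79, 1.05), 24.76, tolerance = 0.005)
  expect_equal(percent_difference(3, 3), 0)
  # lattice axes grow by ~8% and ~2% in the homotrimer cell
  expect_equal(-percent_difference(36.16, 33.41), 8.23, tolerance = 0.005)
  expect_equal(-percent_difference(25.54, 25.08), 1.83, tolerance = 0.005)
})

test_that("stress-strain fitting recovers polynomial laws", {
  eps <- c(0.01, 0.05, 0.1, 0.2)
  sig <- 2e9 * eps + 5e9 * eps^2
  f <- fit_stress_strain(eps, sig, degree = 2)
  expect_equal(f$coefficients, c(0, 2e9, 5e9), tolerance = 1e-6)
  # linear data with degree 2: quadratic term vanishes
  f2 <- fit_stress_strain(eps, 3e9 * eps, degree = 2)
  expect_lt(abs(f2$coefficients[3]) / 3e9, 1e-6)
  expect_error(fit_stress_strain(eps[1:2], sig[1:2], degree = 2), "points")
  expect_error(fit_stress_strain(eps, rep(1e6, 4), degree = 2), "distinct")
  # noisy quadratic: coefficient bias < 2% over 20 seeds
  eps_n <- seq(0.01, 0.2, length.out = 24)
  c2 <- vapply(1:20, function(s) {
    set.seed(600 + s)
    y <- 5e9 * eps_n^2 + rnorm(24, sd = 1e6)
    fit_stress_strain(eps_n, y, degree = 2)$coefficients[3]
  }, numeric(1))
  expect_lt(abs(mean(c2) / 5e9 - 1), 0.02)
})

test_that("tangent modulus solves the fitted law at a stress level", {
  eps <- seq(0.01, 0.3, length.out = 16)
  lin <- fit_stress_strain(eps, 2e9 * eps, degree = 1)
  expect_equal(tangent_modulus(lin, 1e8), 2e9, tolerance = 1e-6)
  # sigma = a eps^2: tangent at sigma* is 2 sqrt(a sigma*)
  quad <- fit_stress_strain(eps, 4e9 * eps^2, degree = 2)
  expect_equal(tangent_modulus(quad, 1.5e8), 2 * sqrt(4e9 * 1.5e8),
               tolerance = 1e-4)
  expect_error(tangent_modulus(lin, 1e12), "range")
  # bare coefficients need a strain range
  expect_equal(tangent_modulus(c(0, 2e9), 1e8, strain_range = c(0, 0.3)),
               2e9, tolerance = 1e-6)
  expect_error(tangent_modulus(c(0, 2e9), 1e8), "strain_range")
})

test_that("series built to the printed endpoint tangents differ by 25%", {
  # two monotone quadratics whose tangents at 150 MPa are 1.05 and
  # 0.79 GPa; construct sigma = a eps^2 with tangent 2 sqrt(a sigma*)
  sig_star <- 150e6
  a_wt <- (1.05e9 / 2)^2 / sig_star
  a_oim <- (0.79e9 / 2)^2 / sig_star
  eps <- seq(0.01, 0.8, length.out = 12)
  f_wt <- fit_stress_strain(eps, a_wt * eps^2, degree = 2)
  f_oim <- fit_stress_strain(eps, a_oim * eps^2, degree = 2)
  t_wt <- tangent_modulus(f_wt, sig_star)
  t_oim <- tangent_modulus(f_oim, sig_star)
  expect_equal(t_wt / 1e9, 1.05, tolerance = 1e-4)
  expect_equal(t_oim / 1e9, 0.79, tolerance = 1e-4)
  expect_equal(percent_difference(t_oim, t_wt), 24.76, tolerance = 0.01)
  # tangent of a monotone polynomial stays positive across its range
  for (lev in c(30e6, 75e6, 150e6)) {
    expect_gt(tangent_modulus(f_wt, lev), 0)
  }
})
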