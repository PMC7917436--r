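test_that("Huang-Rhys factors from gradients: scaling and two-route oracle", {
  expect_equal(huang_rhys_from_gradient(c(100, 1400), c(0, 0))$modes$huang_rhys,
               c(0, 0))
  s1 <- huang_rhys_from_gradient(1400, 1e-4)$modes$huang_rhys
  s2 <- huang_rhys_from_gradient(1400, 2e-4)$modes$huang_rhys
  expect_equal(s2 / s1, 4)  # quadratic in the gradient
  # independent route: Delta = g / w^2, S = w * Delta^2 / 2 (hbar = 1)
  w_cm1 <- 1234; g <- 3.7e-5
  w <- w_cm1 / 219474.6313632
  delta <- g / w^2
  expect_equal(huang_rhys_from_gradient(w_cm1, g)$modes$huang_rhys,
               w * delta^2 / 2, tolerance = 1e-12)
  expect_error(huang_rhys_from_gradient(0, 1), "frequency")
})

test_that("no vibronic coupling gives a single symmetric peak at the origin", {
  sd0 <- spectral_density(1400, 0)
  ls <- cumulant_lineshape(sd0, temperature = 0, broadening = 50,
                           grid = seq(-6000, 6000, by = 1))
  expect_equal(ls$grid[which.max(ls$intensity)], 0)
  half <- (length(ls$grid) + 1) / 2
  expect_equal(ls$intensity[half + 1:1000], ls$intensity[half - 1:1000],
               tolerance = 1e-6)
  expect_equal(pracma::trapz(ls$grid, ls$intensity), 1, tolerance = 1e-6)
})

test_that("T->0 single-mode spectrum reproduces the Poisson progression", {
  # cumulant is exact for displaced harmonic oscillators: peak areas at
  # n*w follow e^-S S^n / n!; checked for every peak holding >= 1% of the
  # total area
  for (S in c(0.3, 0.7)) {
    sdm <- spectral_density(1400, S)
    ls <- cumulant_lineshape(sdm, temperature = 0, broadening = 2,
                             grid = seq(-4000, 12000, by = 1))
    n_check <- which(dpois(0:6, S) >= 0.01) - 1
    areas <- peak_areas(ls, 1400, max(n_check))
    ratios <- areas / areas[1]
    expected <- dpois(0:max(n_check), S) / dpois(0, S)
    expect_lt(max(abs(ratios[n_check + 1] - expected[n_check + 1]) /
                  expected[n_check + 1]), 0.01)
  }
})

test_that("the T->0 first moment above the origin equals lambda", {
  sdm <- spectral_density(1400, 0.7)
  ls <- cumulant_lineshape(sdm, temperature = 0, broadening = 2,
                           grid = seq(-6000, 12000, by = 1))
  m1 <- pracma::trapz(ls$grid, ls$grid * ls$intensity)
  expect_lt(abs(m1 - sdm$reorganization), 25)
})

test_that("area normalization and coverage checking hold on default grids", {
  sdm <- generate_mode_set(synthetic_config(10))
  ls <- cumulant_lineshape(sdm)   # 300 K, Gamma = 100
  expect_equal(pracma::trapz(ls$grid, ls$intensity), 1, tolerance = 1e-6)
  expect_true(all(ls$intensity >= 0))
  expect_error(cumulant_lineshape(sdm, grid = seq(-300, 300, by = 2)),
               "grid too narrow")
  expect_error(cumulant_lineshape(sdm, broadening = -1), "broadening")
})

test_that("ensemble spectra are linear, order-invariant, and match direct
           summation", {
  sdm <- spectral_density(1400, 0.7)
  ls <- cumulant_lineshape(sdm, broadening = 100)
  one <- data.frame(exc_eV = 3.22, mux = 0, muy = 0, muz = 1)
  es1 <- ensemble_spectrum(one, ls)
  w01 <- ev_to_cm1(3.22)
  expect_equal(es1$grid[which.max(es1$intensity)] - w01,
               ls$grid[which.max(ls$intensity)], tolerance = 3)
  two_same <- rbind(one, one)
  es2 <- ensemble_spectrum(two_same, ls, grid = es1$grid)
  expect_equal(es2$intensity, 2 * es1$intensity, tolerance = 1e-12)
  # two records 300 cm^-1 apart, equal dipoles: matches brute-force sum
  recs <- data.frame(exc_eV = c(3.22, 3.22 + 300 / 8065.544),
                     mux = 0, muy = 0, muz = 1)
  es <- ensemble_spectrum(recs, ls)
  brute <- stats::approx(ls$grid + ev_to_cm1(recs$exc_eV[1]), ls$intensity,
                         xout = es$grid, yleft = 0, yright = 0)$y +
           stats::approx(ls$grid + ev_to_cm1(recs$exc_eV[2]), ls$intensity,
                         xout = es$grid, yleft = 0, yright = 0)$y
  expect_equal(es$intensity, brute, tolerance = 1e-12)
  peak <- es$grid[which.max(es$intensity)]
  expect_gt(peak, ev_to_cm1(recs$exc_eV[1]) + ls$grid[which.max(ls$intensity)] - 10)
  expect_lt(peak, ev_to_cm1(recs$exc_eV[2]) + ls$grid[which.max(ls$intensity)] + 10)
  # order invariance
  es_r <- ensemble_spectrum(recs[2:1, ], ls, grid = es$grid)
  expect_equal(es_r$intensity, es$intensity)
})

test_that("population weighting averages spectra pointwise", {
  g <- seq(0, 100, by = 1)
  mk <- function(center) structure(
    list(grid = g, intensity = exp(-(g - center)^2 / 20), metadata = list()),
    class = "lineshape")
  a <- mk(25); b <- mk(75)
  same <- weighted_average_spectra(list(a), 1)
  expect_equal(same$intensity, a$intensity)
  eq <- weighted_average_spectra(list(a, b), c(0.5, 0.5))
  expect_equal(max(eq$intensity), 0.5, tolerance = 1e-6)
  dom <- weighted_average_spectra(list(a, b), c(0.78, 0.22))
  expect_lt(max(abs(dom$intensity - 0.78 * a$intensity - 0.22 * b$intensity)),
            1e-12)
  expect_error(weighted_average_spectra(
    list(a, structure(list(grid = g + 1, intensity = a$intensity),
                      class = "lineshape")), c(1, 1)), "grids")
})

test_that("normalize_and_shift sets the maximum to exactly 1", {
  sdm <- spectral_density(1400, 0.7)
  ls <- cumulant_lineshape(sdm, broadening = 100)
  recs <- data.frame(exc_eV = c(3.22, 3.27), mux = 0, muy = 0, muz = 1)
  es <- ensemble_spectrum(recs, ls)
  ns <- normalize_and_shift(es, shift = -3500)
  expect_identical(max(ns$intensity), 1)
  expect_equal(ns$grid, es$grid - 3500)
  back <- normalize_and_shift(ns, shift = 3500)
  expect_equal(back$grid, es$grid)
  same <- normalize_and_shift(es, shift = 0)
  expect_equal(same$grid, es$grid)
  zero <- structure(list(grid = 1:3, intensity = rep(0, 3),
                         metadata = list()), class = "lineshape")
  expect_error(normalize_and_shift(zero), "all-zero")
})
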