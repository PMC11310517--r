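test_that("exactly linear or constant series report no breakpoint", {
  lin <- isotherm_series(seq(0.01, 0.08, by = 0.01), 3 + 2 * seq(0.01, 0.08, by = 0.01),
                         kind = "conductivity")
  expect_false(fit_breakpoint(lin, "linear")$has_breakpoint)
  const <- isotherm_series(10^seq(-2, 0, length.out = 8), rep(48, 8))
  res <- analyze_series(const, kind = "tension")
  expect_true("no_breakpoint" %in% res$flags)
  expect_true(is.na(res$c_cmc_wt))
})

test_that("a breakpoint fit needs at least six points and three per side", {
  expect_error(isotherm_series(1:5, 1:5, "tension"), "6 points")
  s <- simulate_tension(seed = 1)
  bp <- fit_breakpoint(s, "log10")
  # at least 3 observations on each side of the located breakpoint
  expect_gte(sum(s$concentration < bp$breakpoint), 3)
  expect_gte(sum(s$concentration > bp$breakpoint), 3)
})

test_that("surface excess implements the printed decade-slope convention", {
  expect_identical(surface_excess(0), 0)
  g <- surface_excess(-12.4, 293)
  expect_equal(g, 12.4e-3 / (8.314462618 * 293), tolerance = 1e-12)
  expect_equal(surface_excess(-24.8, 293), 2 * g, tolerance = 1e-12)
  # convention switches: natural-log factor and ionic prefactor
  expect_equal(surface_excess(-12.4, 293, ln10 = TRUE), g / log(10),
               tolerance = 1e-12)
  expect_equal(surface_excess(-12.4, 293, prefactor_n = 2), g / 2,
               tolerance = 1e-12)
  expect_warning(surface_excess(5), "negative")
})

test_that("area per molecule closes the Gibbs-isotherm chain at 32.7 A^2", {
  a <- area_per_molecule(surface_excess(-12.4, 293))
  expect_equal(a, 32.7, tolerance = 0.01)
  expect_equal(area_per_molecule(2 * surface_excess(-12.4, 293)), a / 2,
               tolerance = 1e-12)
  expect_error(area_per_molecule(0))
  expect_error(area_per_molecule(-1e-6))
})

test_that("noiseless isotherms are recovered exactly", {
  s <- simulate_tension(noise_sd = 0, seed = 1)
  res <- analyze_series(s, m_mol = 675.4)
  expect_equal(res$c_cmc_wt, 0.04, tolerance = 1e-4)
  expect_equal(res$gamma0, 48, tolerance = 1e-6)
  expect_equal(res$slope_below, -12.4, tolerance = 1e-4)
  k <- simulate_conductivity(noise_rel = 0, seed = 1)
  resk <- analyze_series(k)
  expect_equal(resk$c_cmc_wt, 0.04, tolerance = 1e-6)
  expect_equal(resk$slope_below, 150, tolerance = 1e-6)
  expect_equal(resk$slope_above, 75, tolerance = 1e-6)
  expect_equal(resk$slope_ratio, 0.5, tolerance = 1e-6)
})

test_that("tension analysis recovers CMC, slope and limiting tension under noise", {
  errs <- vapply(1:20, function(s) {
    res <- analyze_series(simulate_tension(seed = s), m_mol = 675.4)
    c(res$c_cmc_wt / 0.04 - 1, res$gamma0 / 48 - 1, res$slope_below / -12.4 - 1)
  }, numeric(3))
  expect_lt(sqrt(mean(errs[1, ]^2)), 0.10)  # CMC, rms over seeds
  expect_lt(max(abs(errs[1, ])), 0.15)
  expect_lt(max(abs(errs[2, ])), 0.02)      # limiting tension
  expect_lt(max(abs(errs[3, ])), 0.05)      # pre-CMC slope
  # molar conversion under 1 g/cm^3: 10 * wt% / M
  res <- analyze_series(simulate_tension(seed = 3), m_mol = 675.4)
  expect_equal(res$c_cmc_m, 10 * res$c_cmc_wt / 675.4, tolerance = 1e-12)
})

test_that("conductivity analysis recovers the breakpoint and both slopes", {
  errs <- vapply(1:20, function(s) {
    res <- analyze_series(simulate_conductivity(seed = s))
    c(res$c_cmc_wt / 0.04 - 1, res$slope_below / 150 - 1, res$slope_above / 75 - 1)
  }, numeric(3))
  expect_lt(sqrt(mean(errs[1, ]^2)), 0.10)
  expect_lt(sqrt(mean(errs[2, ]^2)), 0.05)
  expect_lt(sqrt(mean(errs[3, ]^2)), 0.05)
  expect_lt(max(abs(errs[2, ])), 0.10)
  expect_lt(max(abs(errs[3, ])), 0.10)
})

test_that("tension and conductivity CMCs agree when generated from one truth", {
  agree <- vapply(1:20, function(s) {
    at <- analyze_series(simulate_tension(seed = s), m_mol = 675.4)
    ac <- analyze_series(simulate_conductivity(seed = s + 100))
    at$c_cmc_wt / ac$c_cmc_wt - 1
  }, numeric(1))
  expect_lt(sqrt(mean(agree^2)), 0.15)
})

test_that("breakpoint estimator bias vanishes as noise vanishes", {
  bias_at <- function(noise) {
    mean(vapply(1:12, function(s)
      analyze_series(simulate_tension(noise_sd = noise, seed = s),
                     m_mol = 675.4)$c_cmc_wt, numeric(1))) / 0.04 - 1
  }
  biases <- abs(vapply(c(0.6, 0.15, 0.01), bias_at, numeric(1)))
  expect_lt(biases[3], 0.005)
  expect_lt(biases[3], biases[1])
})
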