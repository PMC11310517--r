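test_that("dimensionless reduction has the correct limiting behaviour", {
  st0 <- dimensionless_state(yukawa_params(72.37, 0.0483, 0, 0.0049))
  expect_identical(st0$gamma0, 0)
  st_nosalt <- dimensionless_state(yukawa_params(72.37, 0.0483, 14.73, 0))
  expect_identical(st_nosalt$k, 0)
  expect_true(is.finite(st_nosalt$gamma0) && st_nosalt$gamma0 > 0)
  # dilute lipopeptide condition: k = sigma / debye length ~ 144.74 / 43.5
  st <- dimensionless_state(yukawa_params(72.37, 0.0483, 14.73, 0.0049))
  expect_equal(st$k, 144.74 / debye_length(0.0049, 293), tolerance = 1e-12)
  expect_equal(st$k, 3.33, tolerance = 0.01)
})

test_that("Percus-Yevick closed form has the exact compressibility limit", {
  expect_equal(sq_hard_sphere_py(0.2, 40, 0), rep(1, 1))
  s0 <- sq_hard_sphere_py(1e-9, 40, 0.1)
  expect_equal(s0, (1 - 0.1)^4 / (1 + 2 * 0.1)^2, tolerance = 1e-9)
  # seam between the series and trigonometric branches
  r_hs <- 40
  q_seam <- 0.05 / (2 * r_hs)
  expect_equal(sq_hard_sphere_py(q_seam * 0.999, r_hs, 0.3),
               sq_hard_sphere_py(q_seam * 1.001, r_hs, 0.3), tolerance = 1e-6)
  expect_error(sq_hard_sphere_py(0.1, 40, 0.7), "phi")
})

test_that("PY closed form agrees with the numerical OZ solver at zero tail", {
  Q <- seq(0.1, 25, length.out = 200)
  s_oz <- oz_msa_reference_reduced(Q, phi = 0.2, k = 3, gamma0 = 0)
  expect_lt(max(abs(s_oz - sq_hard_sphere_py(Q / 80, 40, 0.2))), 1e-3)
  expect_lt(attr(s_oz, "residual"), 1e-8)
})

test_that("OZ solver returns the ideal-gas limit at vanishing density", {
  s <- oz_msa_reference_reduced(c(1, 5, 10), phi = 1e-6, k = 3, gamma0 = 1)
  expect_lt(max(abs(s - 1)), 1e-3)
})

test_that("OZ solver validates its grid and reports convergence", {
  expect_error(oz_msa_reference_reduced(1, 0.1, 3, 1, n_grid = 2^10), "n_grid")
  expect_error(oz_msa_reference_reduced(1, 0.1, 3, 1, extent = 10), "extent")
  s <- oz_msa_reference_reduced(c(1, 5), 0.1, 3, 5)
  expect_true(attr(s, "iterations") >= 1)
  expect_lt(attr(s, "residual"), 1e-8)
})

test_that("RMSA collapses onto the ideal gas and PY hard-sphere limits", {
  q <- seq(0.001, 0.3, length.out = 150)
  s_dilute <- sq_hayter_penfold(q, yukawa_params(72.37, 1e-12, 14.73, 0.0049))
  expect_lt(max(abs(s_dilute - 1)), 1e-4)
  # uncharged: the Baxter-factorized solution against the direct closed form
  s_uncharged <- sq_hayter_penfold(q, yukawa_params(40, 0.2, 0, 0.01))
  expect_lt(max(abs(s_uncharged - sq_hard_sphere_py(q, 40, 0.2))), 1e-4)
})

test_that("RMSA matches the numerical OZ oracle for the dilute micelle row", {
  yp <- yukawa_params(72.37, 0.0483, 14.73, 0.0049)
  q <- seq(0.005, 0.3, length.out = 120)
  s_an <- sq_hayter_penfold(q, yp)
  st <- dimensionless_state(yp)
  s <- attr(s_an, "rescaling_s")
  s_oz <- oz_msa_reference_reduced(q * 144.74 / s, st$phi / s^3, st$k / s,
                                   st$gamma0 * s * exp(-st$k * (1 / s - 1)))
  expect_lt(max(abs(s_an - s_oz)), 0.02)
})

test_that("S(q) is positive, tends to 1 at large q, and is suppressed at q = 0", {
  yp <- yukawa_params(72.37, 0.0483, 14.73, 0.0049)
  q <- c(1e-6, default_q_grid(150), seq(50, 80, length.out = 20) / 144.74)
  q <- sort(q)
  s <- sq_hayter_penfold(q, yp)
  expect_true(all(s > 0))
  tail_idx <- q * 144.74 > 50
  expect_lt(max(abs(s[tail_idx] - 1)), 1e-3)
  expect_lt(s[1], 1)  # repulsion suppresses forward scattering
})

test_that("stronger charge suppresses forward scattering monotonically", {
  s0 <- vapply(c(0, 5, 10, 20, 40, 80), function(z)
    sq_hayter_penfold(1e-6, yukawa_params(72.37, 0.0483, z, 0.0049))[1],
    numeric(1))
  expect_true(all(diff(s0) < 0))
})

test_that("rescaling enforces a non-negative contact value", {
  for (z in c(15, 40, 120)) {
    s <- sq_hayter_penfold(0.01, yukawa_params(60, 0.1, z, 0.003))
    expect_gte(attr(s, "g_contact"), -1e-6)
    expect_lte(attr(s, "rescaling_s"), 1)
  }
  # without rescaling the raw MSA contact value goes negative here
  s_raw <- sq_hayter_penfold(0.01, yukawa_params(60, 0.1, 40, 0.003),
                             rescale = FALSE)
  expect_lt(attr(s_raw, "g_contact"), 0)
})

test_that("reduced-state evaluation is continuous across the small-q seam", {
  s <- sq_rmsa_reduced(c(0.0499, 0.0501), phi = 0.1, k = 3, gamma0 = 5)
  expect_lt(abs(s[1] - s[2]), 1e-4)
})

test_that("parameter validation rejects unphysical states", {
  expect_error(yukawa_params(72, 0.7, 10, 0.01), "phi")
  expect_error(yukawa_params(72, -0.1, 10, 0.01), "phi")
  expect_error(yukawa_params(-1, 0.1, 10, 0.01), "r_hs")
  expect_error(yukawa_params(72, 0.1, -3, 0.01), "z_eff")
  expect_error(sq_rmsa_reduced(1, 0.1, -1, 1))
})
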