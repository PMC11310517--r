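test_that("sphere amplitude factor has the exact limits and bounds", {
  expect_identical(sphere_form_amplitude(0), 1)
  expect_equal(sphere_form_amplitude(pi), 3 / pi^2)
  # first zero sits at the first positive root of tan(x) = x
  root <- uniroot(function(x) tan(x) - x, c(4.2, 4.6), tol = 1e-12)$root
  expect_lt(abs(sphere_form_amplitude(root)), 1e-10)
  expect_equal(root, 4.4934, tolerance = 1e-4)
  x <- seq(0, 60, length.out = 4000)
  expect_true(all(abs(sphere_form_amplitude(x)) <= 1))
  # the series branch agrees with the closed form where both are accurate
  x <- 0.0099  # inside the series branch
  expect_equal(sphere_form_amplitude(x), 3 * (sin(x) - x * cos(x)) / x^3,
               tolerance = 1e-9)
  expect_error(sphere_form_amplitude(-1))
})

test_that("core-shell amplitude reduces to uniform spheres in degenerate limits", {
  q <- seq(0, 0.4, length.out = 80)
  # equal contrasts: uniform sphere of the outer radius
  f <- core_shell_amplitude(q, 10, 25, contrast_core = 2, contrast_shell = 2)
  uniform <- 2 * 4 * pi * 25^3 / 3 * sphere_form_amplitude(q * 25)
  expect_equal(f, uniform, tolerance = 1e-12)
  # vanishing core: uniform sphere with the shell contrast
  f0 <- core_shell_amplitude(q, 1e-8, 25, contrast_core = 7, contrast_shell = 1)
  expect_equal(f0, 4 * pi * 25^3 / 3 * sphere_form_amplitude(q * 25),
               tolerance = 1e-12)
  expect_error(core_shell_amplitude(0.1, 20, 15), "r_core")
})

test_that("forward amplitude equals the volume arithmetic of the table row", {
  ri <- 14.08; ro <- 26.59; mu <- -1.614
  v_o <- 4 * pi * ro^3 / 3; v_i <- 4 * pi * ri^3 / 3
  expect_equal(core_shell_amplitude(0, ri, ro, mu, 1), v_o + v_i * (mu - 1),
               tolerance = 1e-12)
})

test_that("polydispersity average matches a brute-force trapezoid quadrature", {
  p <- core_shell_params(14.08, 26.59, sigma_r = 4.42, mu = -1.614, eta = 0.118)
  q <- default_q_grid(60)
  pq <- form_factor_intensity(q, p, n_quad = 64)
  # brute-force oracle: dense trapezoid over the same truncated support
  lo <- max(p$r_core + 0.1, p$r_outer - 4 * p$sigma_r)
  hi <- p$r_outer + 4 * p$sigma_r
  rr <- seq(lo, hi, length.out = 5e4)
  w <- dnorm(rr, p$r_outer, p$sigma_r) *
    c(0.5, rep(1, length(rr) - 2), 0.5)   # trapezoid weights
  w <- w / sum(w)
  # vectorised |F(q; R)|^2 over the q x R grid
  phi_o <- 3 * (sin(outer(q, rr)) - outer(q, rr) * cos(outer(q, rr))) / outer(q, rr)^3
  phi_i <- sphere_form_amplitude(q * p$r_core)
  v_o <- 4 * pi * rr^3 / 3; v_i <- 4 * pi * p$r_core^3 / 3
  f <- sweep(phi_o, 2, v_o, `*`) + outer(phi_i * v_i * (p$mu - 1), rep(1, length(rr)))
  brute <- p$eta * drop(f^2 %*% w) / (4 * pi * p$r_outer^3 / 3)^2
  expect_equal(pq, brute, tolerance = 1e-6)
})

test_that("quadrature is converged: doubling the order changes nothing", {
  p <- core_shell_params(14.08, 26.59, sigma_r = 5.3, mu = -1.614, eta = 1)
  q <- default_q_grid(80)
  expect_equal(form_factor_intensity(q, p, 64), form_factor_intensity(q, p, 128),
               tolerance = 1e-8)
})

test_that("zero polydispersity returns the monodisperse intensity exactly", {
  p <- core_shell_params(14.08, 26.59, sigma_r = 0, mu = -1.614, eta = 0.118,
                         bg = 0)
  q <- default_q_grid(50)
  mono <- p$eta * core_shell_amplitude(q, p$r_core, p$r_outer, p$mu, 1)^2 /
    (4 * pi * p$r_outer^3 / 3)^2
  expect_identical(form_factor_intensity(q, p), mono)
})

test_that("polydispersity fills in the form-factor minimum monotonically", {
  min_ratio <- function(sg) {
    p <- core_shell_params(14.71, 27.05, sigma_r = sg, mu = -1.761, eta = 1)
    q <- default_q_grid(400)
    min(form_factor_intensity(q, p) / form_factor_intensity(0, p))
  }
  ratios <- vapply(c(0, 1, 2, 4), min_ratio, numeric(1))
  expect_true(all(diff(ratios) > 0))
})

test_that("intensity is non-negative and q = 0 is a valid evaluation point", {
  p <- core_shell_params(14.08, 26.59, sigma_r = 4.42, mu = -1.614, eta = 0.118)
  q <- c(0, default_q_grid(100))
  pq <- form_factor_intensity(q, p)
  expect_true(all(pq >= 0))
  expect_true(all(is.finite(pq)))
})

test_that("low-q slope reproduces the analytic core-shell radius of gyration", {
  p <- core_shell_params(14.08, 26.59, sigma_r = 0, mu = -1.614, eta = 1)
  rg <- core_shell_rg(p)
  q <- seq(5e-4, 0.3 / p$r_outer, length.out = 60)
  lnp <- log(form_factor_intensity(q, p))
  # quadratic-in-q^2 fit isolates the leading Guinier slope on qR_o < 0.3
  cf <- coef(lm(lnp ~ I(q^2) + I(q^4)))
  expect_equal(sqrt(-3 * cf[[2]]), rg, tolerance = 1e-3)
})

test_that("invalid inputs are rejected with informative errors", {
  p <- core_shell_params(14, 26, sigma_r = 4, mu = -1.6, eta = 1)
  expect_error(form_factor_intensity(c(0.2, 0.1), p), "increasing")
  expect_error(form_factor_intensity(c(-0.1, 0.1), p), "non-negative")
  # a width that pushes >1% of the size distribution below the core radius
  expect_error(form_factor_intensity(0.1, core_shell_params(14, 15.5, sigma_r = 8)),
               "mass")
  expect_error(core_shell_params(-1, 26))
  expect_error(core_shell_params(14, 12))
  expect_error(core_shell_params(14, 26, eta = -1))
})
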