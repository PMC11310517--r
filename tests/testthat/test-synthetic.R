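test_that("zero-noise simulation equals the intensity model exactly", {
  tr <- default_micelle_truth()
  cv <- simulate_saxs(tr$form, tr$yukawa, noise_a = 0, seed = 1)
  expect_identical(cv$intensity, model_intensity(cv$q, tr$form, tr$yukawa))
})

test_that("simulation is a pure function of truth and seed", {
  tr <- default_micelle_truth()
  c1 <- simulate_saxs(tr$form, tr$yukawa, seed = 11)
  c2 <- simulate_saxs(tr$form, tr$yukawa, seed = 11)
  c3 <- simulate_saxs(tr$form, tr$yukawa, seed = 12)
  expect_identical(c1$intensity, c2$intensity)
  expect_false(identical(c1$intensity, c3$intensity))
})

test_that("replicate mean converges on the model and has the stated variance", {
  tr <- default_micelle_truth()
  im <- model_intensity(default_q_grid(), tr$form, tr$yukawa)
  reps <- vapply(1:20, function(s)
    simulate_saxs(tr$form, tr$yukawa, seed = s)$intensity,
    numeric(length(im)))
  sd_q <- attr(simulate_saxs(tr$form, tr$yukawa, seed = 1), "truth")$noise_a *
    sqrt(im)
  z <- (rowMeans(reps) - im) / (sd_q / sqrt(20))
  # 200 grid points: allow the expected extreme of standard normal draws
  expect_lt(max(abs(z)), 4)
  expect_lt(mean(abs(z)), 1.2)
  # empirical sd tracks the declared noise model within sampling error
  pick <- c(10, 50, 100, 150, 190)
  reps100 <- vapply(9001:9100, function(s)
    simulate_saxs(tr$form, tr$yukawa, seed = s)$intensity[pick],
    numeric(length(pick)))
  ratio <- apply(reps100, 1, sd) / sd_q[pick]
  expect_true(all(abs(ratio - 1) < 0.2))
})

test_that("noise options behave as declared", {
  tr <- default_micelle_truth()
  cv_rel <- simulate_saxs(tr$form, tr$yukawa, noise_model = "relative",
                          noise_a = 0.01, seed = 2)
  im <- model_intensity(cv_rel$q, tr$form, tr$yukawa)
  expect_equal(cv_rel$uncertainty, 0.01 * im, tolerance = 1e-12)
  cv_exp <- simulate_saxs(tr$form, tr$yukawa, seed = 2, exposure_scale = 4)
  cv_ref <- simulate_saxs(tr$form, tr$yukawa, seed = 2)
  expect_equal(cv_exp$uncertainty, cv_ref$uncertainty / 4, tolerance = 1e-12)
  expect_error(simulate_saxs(tr$form, exposure_scale = 0), "exposure")
})

test_that("concentration series encodes the stated monotone trends", {
  curves <- simulate_concentration_series(seed = 1)
  expect_length(curves, 6)
  truths <- lapply(curves, attr, "truth")
  ro <- vapply(truths, function(t) t$form$r_outer, numeric(1))
  eta <- vapply(truths, function(t) t$form$eta, numeric(1))
  expect_true(all(diff(ro) > 0))
  expect_true(all(diff(eta) > 0))
  conc <- vapply(curves, function(cv) attr(cv, "concentration"), numeric(1))
  expect_equal(eta / conc, rep(eta[1] / conc[1], 6), tolerance = 1e-12)
  # dilute curves carry no structure factor; concentrated ones do
  expect_true(all(vapply(truths[1:2], function(t) is.null(t$yukawa), logical(1))))
  expect_true(all(!vapply(truths[3:6], function(t) is.null(t$yukawa), logical(1))))
  # generated forward-scattering suppression deepens with concentration
  s0 <- vapply(truths[3:6], function(t)
    sq_hayter_penfold(1e-6, t$yukawa)[1], numeric(1))
  expect_true(all(diff(s0) < 0))
  rhs <- vapply(truths[3:6], function(t) t$yukawa$r_hs, numeric(1))
  expect_true(all(diff(rhs) < 0))
})

test_that("single-concentration series degenerates to one simulated curve", {
  one <- simulate_concentration_series(concentrations = 0.5, seed = 4)
  expect_length(one, 1)
  direct <- simulate_saxs(default_micelle_truth()$form,
                          default_micelle_truth()$yukawa,
                          seed = 4, sample_id = attr(one[[1]], "sample_id"),
                          concentration = 0.5)
  expect_equal(one[[1]]$intensity, direct$intensity, tolerance = 1e-12)
  expect_error(simulate_concentration_series(c(1, 0.5)), "increasing")
})

test_that("tension generator is exact without noise and bounded below", {
  s <- simulate_tension(noise_sd = 0, seed = 1)
  tr <- attr(s, "truth")
  above <- s$concentration >= tr$c_cmc
  expect_true(all(s$value[above] == tr$gamma0))
  expect_true(all(diff(s$value[!above]) < 0))
  decades <- diff(range(log10(s$concentration)))
  expect_true(all(s$value >= tr$gamma0 - 1e-9))
  expect_true(all(s$value <= tr$gamma0 + abs(tr$slope_below) * decades + 1e-9))
  expect_error(simulate_tension(c_grid = c(0.05, 0.06, 0.07, 0.08, 0.09, 0.1)),
               "span")
})

test_that("conductivity generator is exact without noise and validates slopes", {
  s <- simulate_conductivity(noise_rel = 0, seed = 1)
  tr <- attr(s, "truth")
  below <- s$concentration < tr$c_cmc
  expect_equal(diff(s$value[below]) / diff(s$concentration[below]),
               rep(tr$slope_pre, sum(below) - 1), tolerance = 1e-9)
  expect_error(simulate_conductivity(slope_pre = 50, slope_post = 80), "shallower")
  # equal slopes: a degenerate truth that the analysis flags as no breakpoint
  flat <- simulate_conductivity(slope_pre = 100, slope_post = 100,
                                noise_rel = 0.01, seed = 2)
  expect_true("no_breakpoint" %in% analyze_series(flat)$flags)
})
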