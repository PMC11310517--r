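test_that("intensity model degenerates correctly", {
  q <- default_q_grid(60)
  form0 <- core_shell_params(14, 26, 4, -1.6, eta = 0, bg = 2e-4)
  expect_equal(model_intensity(q, form0), rep(2e-4, 60), tolerance = 1e-15)
  form <- core_shell_params(14, 26, 4, -1.6, eta = 0.1, bg = 2e-4)
  no_sq <- model_intensity(q, form, NULL)
  tiny_phi <- model_intensity(q, form, yukawa_params(72, 1e-11, 15, 0.005))
  expect_equal(tiny_phi, no_sq, tolerance = 1e-4)
})

test_that("model and generator agree exactly at zero noise (round trip)", {
  tr <- default_micelle_truth()
  cv <- simulate_saxs(tr$form, tr$yukawa, noise_a = 0, seed = 1)
  expect_identical(cv$intensity, model_intensity(cv$q, tr$form, tr$yukawa))
})

test_that("a noiseless curve is a fixed point of the fit", {
  tr <- default_micelle_truth()
  cv <- simulate_saxs(tr$form, tr$yukawa, noise_a = 0, seed = 1,
                      concentration = 0.5)
  fit <- fit_saxs(cv, init = p1_truth_vec())
  expect_true(fit$converged)
  expect_equal(unname(fit$estimate), unname(p1_truth_vec()), tolerance = 1e-6)
  expect_lt(fit$redchi2, 1e-12)
})

test_that("fitting is deterministic given curve, init and seeds", {
  tr <- default_micelle_truth()
  cv <- simulate_saxs(tr$form, tr$yukawa, seed = 9, concentration = 0.5)
  f1 <- fit_saxs(cv, n_starts = 3, start_seed = 7)
  f2 <- fit_saxs(cv, n_starts = 3, start_seed = 7)
  expect_identical(f1$estimate, f2$estimate)
})

test_that("core-shell geometry is recovered from noisy single curves", {
  ct <- conc_truth()
  errs <- vapply(1:6, function(s) {
    cv <- relative_noise_curve(ct, seed = s, concentration = 2)
    fit <- fit_saxs(cv, init = ct$vec)
    fit$estimate / ct$vec - 1
  }, numeric(10))
  expect_lt(max(abs(errs["r_core", ])), 0.03)
  expect_lt(max(abs(errs["r_outer", ])), 0.03)
  expect_lt(max(abs(errs["eta", ])), 0.05)
})

test_that("the dilute micelle row round-trips through simulate and refit", {
  # with the salt content and charge known, geometry and hard-sphere radius
  # are tightly identifiable
  tr <- default_micelle_truth()
  truth <- p1_truth_vec()
  for (s in c(2, 5)) {
    cv <- simulate_saxs(tr$form, tr$yukawa, noise_model = "relative",
                        noise_a = 0.01, seed = s, concentration = 0.5)
    fit <- fit_saxs(cv, init = truth, fixed = c("z_eff", "ionic_strength"))
    err <- fit$estimate / truth - 1
    expect_lt(abs(err[["r_core"]]), 0.03)
    expect_lt(abs(err[["r_outer"]]), 0.03)
    expect_lt(abs(err[["r_hs"]]), 0.03)
  }
})

test_that("reduced chi-square of the generating model is near one", {
  tr <- default_micelle_truth()
  chis <- vapply(1:10, function(s) {
    cv <- simulate_saxs(tr$form, tr$yukawa, seed = s, concentration = 0.5)
    fit_saxs(cv, init = p1_truth_vec())$redchi2
  }, numeric(1))
  expect_true(all(chis > 0.5 & chis < 2))
})

test_that("fixed parameters are honoured and reported", {
  tr <- default_micelle_truth()
  cv <- simulate_saxs(tr$form, tr$yukawa, seed = 2, concentration = 0.5)
  fit <- fit_saxs(cv, init = c(z_eff = 14.73, ionic_strength = 0.0049),
                  fixed = c("z_eff", "ionic_strength"))
  expect_identical(fit$estimate[["z_eff"]], 14.73)
  expect_identical(fit$estimate[["ionic_strength"]], 0.0049)
  expect_true(all(is.na(fit$se[c("z_eff", "ionic_strength")])) ||
                !any(c("z_eff", "ionic_strength") %in% names(fit$se)))
  td <- tidy(fit)
  expect_true(all(td$fixed[td$term %in% c("z_eff", "ionic_strength")]))
})

test_that("fits demand enough points and reject unknown parameters", {
  tr <- default_micelle_truth()
  cv <- simulate_saxs(tr$form, NULL, q = default_q_grid(12), seed = 1,
                      concentration = 0.2)
  expect_error(fit_saxs(cv, include_sq = TRUE), "points")
  cv2 <- simulate_saxs(tr$form, NULL, seed = 1, concentration = 0.2)
  expect_error(fit_saxs(cv2, init = c(radius = 5)), "unknown parameter")
})

test_that("a single dilute curve in a series equals the plain form fit", {
  tr <- default_micelle_truth()
  cv <- simulate_saxs(tr$form, NULL, seed = 6, concentration = 0.2)
  series <- fit_saxs_series(list(cv))
  single <- fit_saxs(cv, include_sq = FALSE)
  expect_equal(series$fit[[1]]$estimate, single$estimate, tolerance = 1e-12)
  expect_false(series$fit[[1]]$include_sq)
})

test_that("staged series fit recovers sizes and reproduces the S(0) suppression", {
  curves <- simulate_concentration_series(seed = 3)
  sf <- fit_saxs_series(curves)
  expect_true(all(sf$converged))
  ro_true <- vapply(curves, function(cv) attr(cv, "truth")$form$r_outer, numeric(1))
  ro_fit <- vapply(sf$fit, function(f) f$estimate[["r_outer"]], numeric(1))
  expect_lt(max(abs(ro_fit / ro_true - 1)), 0.03)
  expect_true(all(diff(ro_fit) > 0))
  s0_fit <- vapply(sf$fit, function(f)
    if (is.null(f$yukawa)) 1 else sq_hayter_penfold(1e-6, f$yukawa)[1],
    numeric(1))
  expect_true(all(diff(s0_fit[3:6]) < 0))
  expect_true(all(s0_fit[3:6] < 1))
})

test_that("one corrupt curve does not abort the series", {
  curves <- simulate_concentration_series(concentrations = c(0.1, 0.2, 0.5),
                                          seed = 2)
  # a curve whose q window misses the fit range entirely
  bad <- saxs_curve(seq(0.4, 0.6, length.out = 20), rep(1e-3, 20),
                    sample_id = "bad", concentration = 0.3)
  sf <- fit_saxs_series(c(curves[1:2], list(bad), curves[3]))
  expect_identical(sum(is.na(sf$error)), 3L)
  expect_match(sf$error[3], "points")
  expect_true(all(sf$converged[-3]))
})

test_that("the charged structure factor beats hard spheres on charged data", {
  tr <- default_micelle_truth()
  cv <- simulate_saxs(tr$form, tr$yukawa, seed = 11, concentration = 0.5)
  cmp <- compare_structure_factors(cv)
  expect_lt(cmp$redchi2_hp, cmp$redchi2_py)
  expect_lt(cmp$redchi2_hp, 2)
})

test_that("with zero charge the two structure factors are statistically tied", {
  form <- default_micelle_truth()$form
  yk0 <- yukawa_params(60, 0.15, 0, 0.01)
  cv <- simulate_saxs(form, yk0, seed = 13, concentration = 1)
  init <- c(r_hs = 60, phi = 0.15)
  cmp <- compare_structure_factors(cv, init = init)
  expect_equal(cmp$redchi2_hp, cmp$redchi2_py, tolerance = 0.1)
})

test_that("hard spheres need jamming-level packing to mimic strong charge", {
  yk <- yukawa_params(60, 0.18, 120, 0.002)
  fm <- core_shell_params(14.6, 28.4, 4, -1.5, 0.3, 1e-3)
  cv <- simulate_saxs(fm, yk, seed = 21, concentration = 2)
  init <- c(r_core = 14.6, r_outer = 28.4, sigma_r = 4, mu = -1.5, eta = 0.3,
            bg = 1e-3, r_hs = 60, phi = 0.18, z_eff = 120,
            ionic_strength = 0.002)
  cmp <- compare_structure_factors(cv, init = init)
  expect_lt(cmp$redchi2_hp, cmp$redchi2_py)
  expect_gt(cmp$py_phi, 0.55)
  expect_true(cmp$py_phi_unphysical)
})
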