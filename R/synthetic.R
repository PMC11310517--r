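#' Default ground-truth parameter blocks for a charged lipopeptide micelle
#'
#' Realistic generating truths for the synthetic-data module: a cationic
#' C16 lipopeptide micelle at 0.5 wt percent in water (core radius about
#' 14 Angstrom, outer radius about 27 Angstrom, moderate charge, dilute
#' TFA-counterion ionic strength). These are the default study conditions
#' every simulated test exercises.
#'
#' The intensity scale `eta` is set so that the forward scattering matches
#' the absolute level measured for such micelles (about 0.018 cm^-1 per
#' 0.2 wt percent), well above the flat background.
#'
#' @return A list with elements `form` ([core_shell_params()]), `yukawa`
#'   ([yukawa_params()]) and `concentration` (wt percent).
#' @examples
#' default_micelle_truth()
#' @export
default_micelle_truth <- function() {
  list(
    form = core_shell_params(r_core = 14.08, r_outer = 26.59, sigma_r = 4.42,
                             mu = -1.614, eta = 0.118, bg = 3.695e-4),
    yukawa = yukawa_params(r_hs = 72.37, phi = 0.0483, z_eff = 14.73,
                           ionic_strength = 0.0049, temperature = 293),
    concentration = 0.5
  )
}

#' Default logarithmic q grid
#'
#' 200 log-spaced points spanning the usable small-angle window of a
#' bench/synchrotron SAXS curve.
#'
#' @param n Number of points.
#' @param q_min,q_max Window in inverse Angstrom.
#' @return Strictly increasing numeric vector.
#' @export
default_q_grid <- function(n = 200, q_min = 0.005, q_max = 0.35) {
  exp(seq(log(q_min), log(q_max), length.out = n))
}

#' Simulate a noisy absolute-intensity SAXS curve
#'
#' Evaluates the combined intensity model and adds Gaussian noise with a
#' photon-counting-like standard deviation
#' `s(q) = noise_a * sqrt(I_model(q) + noise_b) / exposure_scale`; the
#' uncertainty column of the returned curve is set to `s(q)`. With
#' `noise_a = 0` the curve equals the model exactly. Deterministic given
#' `seed`.
#'
#' @param form A [core_shell_params()] truth.
#' @param yukawa A [yukawa_params()] truth or `NULL` (no structure factor).
#' @param q Measurement grid (default [default_q_grid()]).
#' @param noise_a Noise amplitude; the default gives roughly 1 percent
#'   relative noise at the forward-scattering level.
#' @param noise_b Additive variance floor inside the square root, cm^-1.
#' @param noise_model `"counting"` (the default, intensity-dependent
#'   square-root standard deviation) or `"relative"`, in which case
#'   `s(q) = noise_a * I_model(q) / exposure_scale` (constant fractional
#'   error, e.g. `noise_a = 0.01` for 1 percent noise).
#' @param exposure_scale Exposure (counting-time) scale; higher means less
#'   noise. Must be positive.
#' @param seed Integer seed (required for reproducibility).
#' @param sample_id,concentration Metadata attached to the curve.
#' @return A [saxs_curve()]; the generating truth is attached as attribute
#'   `truth` (a list with `form`, `yukawa`, `noise_a`, `noise_b`,
#'   `exposure_scale`, `seed`).
#' @examples
#' tr <- default_micelle_truth()
#' simulate_saxs(tr$form, tr$yukawa, seed = 1)
#' @export
simulate_saxs <- function(form, yukawa = NULL, q = default_q_grid(),
                          noise_a = NULL, noise_b = 0,
                          noise_model = c("counting", "relative"),
                          exposure_scale = 1,
                          seed = 1, sample_id = "synthetic",
                          concentration = NA_real_) {
  stopifnot(inherits(form, "core_shell_params"))
  noise_model <- match.arg(noise_model)
  if (exposure_scale <= 0) stop("`exposure_scale` must be positive", call. = FALSE)
  i_model <- model_intensity(q, form, yukawa)
  if (is.null(noise_a))
    noise_a <- if (noise_model == "counting") 0.01 * sqrt(max(i_model)) else 0.01
  sd_q <- if (noise_model == "counting")
    noise_a * sqrt(i_model + noise_b) / exposure_scale
  else noise_a * i_model / exposure_scale
  noise <- if (noise_a > 0)
    withr::with_seed(seed, stats::rnorm(length(q), 0, sd_q))
  else rep(0, length(q))
  cv <- saxs_curve(q, i_model + noise,
                   uncertainty = if (noise_a > 0) sd_q else NULL,
                   sample_id = sample_id, concentration = concentration,
                   temperature = if (is.null(yukawa)) 293 else yukawa$temperature)
  attr(cv, "truth") <- list(form = form, yukawa = yukawa, noise_a = noise_a,
                            noise_b = noise_b, noise_model = noise_model,
                            exposure_scale = exposure_scale, seed = seed)
  cv
}

#' Simulate a concentration series of SAXS curves
#'
#' Generates per-concentration ground truths by monotone trends around a
#' base truth, emulating how real micellar dilution series behave: the
#' outer radius grows by `ro_per_decade` Angstrom per decade of
#' concentration, the volume fraction and the intensity scale grow
#' proportionally to concentration, the hard-sphere radius shrinks as a
#' power of concentration, and the effective charge stays constant. The
#' structure factor is applied only at concentrations at or above
#' `sq_threshold` (dilute curves are form-factor only, matching how such
#' data are modelled).
#'
#' @param concentrations Strictly increasing wt-percent values (at least
#'   2... a single value degenerates to [simulate_saxs()]).
#' @param base Base truth list as from [default_micelle_truth()] (defines
#'   the parameters at `base$concentration`).
#' @param ro_per_decade Outer-radius growth per decade of concentration,
#'   Angstrom.
#' @param rhs_exponent Power-law exponent of the hard-sphere radius versus
#'   concentration (negative: shrinks).
#' @param sq_threshold Concentration at and above which the structure
#'   factor is applied, wt percent.
#' @param q,noise_a,noise_b,exposure_scale Passed to [simulate_saxs()].
#' @param seed Integer seed; curve `i` uses `seed + i - 1`.
#' @return A list of [saxs_curve()] objects (each carrying its `truth`
#'   attribute), sorted by concentration.
#' @export
simulate_concentration_series <- function(concentrations = c(0.1, 0.2, 0.5, 1, 2, 5),
                                          base = default_micelle_truth(),
                                          ro_per_decade = 2,
                                          rhs_exponent = -0.25,
                                          sq_threshold = 0.5,
                                          q = default_q_grid(),
                                          noise_a = NULL, noise_b = 0,
                                          noise_model = c("counting", "relative"),
                                          exposure_scale = 1, seed = 1) {
  noise_model <- match.arg(noise_model)
  stopifnot(length(concentrations) >= 1)
  if (any(diff(concentrations) <= 0))
    stop("`concentrations` must be strictly increasing", call. = FALSE)
  c0 <- base$concentration
  lapply(seq_along(concentrations), function(i) {
    cc <- concentrations[i]
    ratio <- cc / c0
    form <- core_shell_params(
      r_core = base$form$r_core,
      r_outer = base$form$r_outer + ro_per_decade * log10(ratio),
      sigma_r = base$form$sigma_r,
      mu = base$form$mu,
      eta = base$form$eta * ratio,
      bg = base$form$bg * ratio)
    yk <- NULL
    if (cc >= sq_threshold) {
      yk <- yukawa_params(
        r_hs = base$yukawa$r_hs * ratio^rhs_exponent,
        # proportional growth, capped at a packing the screened-sphere model
        # can still describe (real micellar systems grow sublinearly)
        phi = min(0.35, base$yukawa$phi * ratio),
        z_eff = base$yukawa$z_eff,
        ionic_strength = base$yukawa$ionic_strength * ratio,
        temperature = base$yukawa$temperature,
        eps_r = base$yukawa$eps_r)
    }
    simulate_saxs(form, yk, q = q, noise_a = noise_a, noise_b = noise_b,
                  noise_model = noise_model,
                  exposure_scale = exposure_scale, seed = seed + i - 1,
                  sample_id = sprintf("synthetic_%gwt", cc),
                  concentration = cc)
  })
}

#' Simulate a surface-tension dilution series
#'
#' Piecewise-linear Langmuir-type isotherm: below the CMC the tension
#' falls linearly in log10 concentration with slope `slope_below`
#' (mN per m per decade, negative); at and above the CMC it plateaus at
#' `gamma0`. Gaussian noise of standard deviation `noise_sd` is added.
#' Deterministic given `seed`.
#'
#' @param c_cmc True CMC in wt percent.
#' @param slope_below Pre-CMC slope, mN per m per decade (negative).
#' @param gamma0 Limiting surface tension above the CMC, mN per m.
#' @param noise_sd Gaussian noise, mN per m.
#' @param c_grid Concentration grid spanning the CMC with at least 3
#'   points on each side (default: 20 log-spaced points over two decades
#'   around the CMC, a typical tensiometry dilution series).
#' @param temperature Temperature in kelvin.
#' @param seed Integer seed.
#' @return An [isotherm_series()] with the truth attached as attribute
#'   `truth`.
#' @examples
#' analyze_series(simulate_tension(seed = 7), m_mol = 675.4)
#' @export
simulate_tension <- function(c_cmc = 0.04, slope_below = -12.4, gamma0 = 48,
                             noise_sd = 0.3, c_grid = NULL, temperature = 293,
                             seed = 1) {
  stopifnot(c_cmc > 0, slope_below <= 0)
  if (is.null(c_grid))
    c_grid <- 10^seq(log10(c_cmc) - 1.2, log10(c_cmc) + 0.8, length.out = 20)
  if (sum(c_grid < c_cmc) < 3 || sum(c_grid > c_cmc) < 3)
    stop("`c_grid` must span the CMC with at least 3 points on each side",
         call. = FALSE)
  y <- ifelse(c_grid < c_cmc,
              gamma0 + slope_below * (log10(c_grid) - log10(c_cmc)),
              gamma0)
  if (noise_sd > 0)
    y <- y + withr::with_seed(seed, stats::rnorm(length(y), 0, noise_sd))
  s <- isotherm_series(c_grid, y, kind = "tension", temperature = temperature)
  attr(s, "truth") <- list(c_cmc = c_cmc, slope_below = slope_below,
                           gamma0 = gamma0, noise_sd = noise_sd, seed = seed)
  s
}

#' Simulate a conductivity dilution series
#'
#' Continuous two-segment linear conductivity versus concentration with a
#' slope drop at the CMC (the micellar branch is shallower). Gaussian
#' noise with standard deviation `noise_rel` times the local value is
#' added. Deterministic given `seed`.
#'
#' @param c_cmc True CMC in wt percent.
#' @param slope_pre Pre-CMC slope, microsiemens per cm per wt percent.
#' @param slope_post Post-CMC slope; must not exceed `slope_pre`.
#' @param intercept Conductivity at zero concentration (background),
#'   microsiemens per cm.
#' @param noise_rel Relative Gaussian noise level (default 0.01).
#' @param c_grid Concentration grid spanning the CMC (default: 18 linear
#'   points from a tenth of the CMC to five times the CMC).
#' @param temperature Temperature in kelvin.
#' @param seed Integer seed.
#' @return An [isotherm_series()] with attribute `truth`.
#' @export
simulate_conductivity <- function(c_cmc = 0.04, slope_pre = 150,
                                  slope_post = 75, intercept = 5,
                                  noise_rel = 0.01, c_grid = NULL,
                                  temperature = 293, seed = 1) {
  stopifnot(c_cmc > 0)
  if (slope_post > slope_pre)
    stop("`slope_post` must not exceed `slope_pre` (micellar branch is shallower)",
         call. = FALSE)
  if (is.null(c_grid))
    c_grid <- seq(c_cmc / 10, 5 * c_cmc, length.out = 18)
  if (sum(c_grid < c_cmc) < 3 || sum(c_grid > c_cmc) < 3)
    stop("`c_grid` must span the CMC with at least 3 points on each side",
         call. = FALSE)
  y <- ifelse(c_grid < c_cmc,
              intercept + slope_pre * c_grid,
              intercept + slope_pre * c_cmc + slope_post * (c_grid - c_cmc))
  if (noise_rel > 0)
    y <- y + withr::with_seed(seed, stats::rnorm(length(y), 0, noise_rel * abs(y)))
  s <- isotherm_series(c_grid, y, kind = "conductivity", temperature = temperature)
  attr(s, "truth") <- list(c_cmc = c_cmc, slope_pre = slope_pre,
                           slope_post = slope_post, intercept = intercept,
                           noise_rel = noise_rel, seed = seed)
  s
}
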