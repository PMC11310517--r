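#' Construct a SAXS scattering curve
#'
#' Tidy container for one absolute-intensity SAXS measurement: a tibble
#' with columns `q` (inverse Angstrom), `intensity` (cm^-1) and
#' `uncertainty` (cm^-1, `NA` when not measured), with sample metadata as
#' attributes.
#'
#' @param q Momentum transfer, strictly increasing and positive.
#' @param intensity Absolute intensities, cm^-1 (finite; negative values
#'   are allowed for background-subtracted data but flagged with a warning).
#' @param uncertainty Optional per-point uncertainties, cm^-1, positive.
#' @param sample_id Sample label.
#' @param concentration Concentration in wt percent (optional).
#' @param temperature Temperature in kelvin.
#' @return A tibble of class `"saxs_curve"`.
#' @export
saxs_curve <- function(q, intensity, uncertainty = NULL, sample_id = "",
                       concentration = NA_real_, temperature = 293) {
  stopifnot(is.numeric(q), is.numeric(intensity),
            length(q) == length(intensity))
  if (length(q) < 10) stop("a scattering curve needs at least 10 points", call. = FALSE)
  if (any(q <= 0) || any(diff(q) <= 0))
    stop("`q` must be positive and strictly increasing", call. = FALSE)
  if (any(!is.finite(intensity))) stop("`intensity` must be finite", call. = FALSE)
  if (any(intensity < 0))
    warning("negative intensities present (background-subtracted data?)")
  if (!is.null(uncertainty)) {
    stopifnot(length(uncertainty) == length(q))
    if (any(uncertainty <= 0)) stop("`uncertainty` must be positive", call. = FALSE)
  }
  out <- tibble::tibble(q = q, intensity = intensity,
                        uncertainty = uncertainty %||% NA_real_)
  class(out) <- c("saxs_curve", class(out))
  attr(out, "sample_id") <- sample_id
  attr(out, "concentration") <- concentration
  attr(out, "temperature") <- temperature
  out
}

#' Combined SAXS intensity model
#'
#' `I(q) = P(q) S(q) + BG` in the monodisperse approximation: the
#' polydispersity-averaged core-shell form factor times the RMSA structure
#' factor (S = 1 when `yukawa` is absent), plus the flat background.
#'
#' @param q Evaluation grid, inverse Angstrom (strictly increasing,
#'   `q >= 0` allowed).
#' @param form A [core_shell_params()] block.
#' @param yukawa A [yukawa_params()] block, or `NULL` for form factor only.
#' @param n_quad Quadrature order for the polydispersity average.
#' @return Model intensity in cm^-1.
#' @examples
#' fp <- core_shell_params(14.08, 26.59, 4.42, -1.614, 2.913e-6, 3.695e-4)
#' model_intensity(c(0.01, 0.05, 0.2), fp)
#' @export
model_intensity <- function(q, form, yukawa = NULL, n_quad = 64) {
  p <- form_factor_intensity(q, form, n_quad)
  s <- if (is.null(yukawa)) 1 else as.numeric(sq_hayter_penfold(q, yukawa))
  p * s + form$bg
}

# default fit bounds (spanning observed micellar parameter ranges with margin)
.fit_bounds <- function() {
  list(
    lower = c(r_core = 5, r_outer = 7, sigma_r = 0, mu = -5, eta = 1e-12,
              bg = 0, r_hs = 10, phi = 1e-6, z_eff = 0, ionic_strength = 1e-4),
    upper = c(r_core = 30, r_outer = 60, sigma_r = 10, mu = 5, eta = 10,
              bg = 1, r_hs = 300, phi = 0.4, z_eff = 300, ionic_strength = 0.5)
  )
}

.default_init <- function(include_sq) {
  init <- c(r_core = 14, r_outer = 26, sigma_r = 4, mu = -1.5,
            eta = 0.1, bg = 3e-4)
  if (include_sq)
    init <- c(init, r_hs = 70, phi = 0.05, z_eff = 15, ionic_strength = 5e-3)
  init
}

.params_from_vector <- function(p, include_sq, temperature, eps_r) {
  form <- core_shell_params(p[["r_core"]], p[["r_outer"]], p[["sigma_r"]],
                            p[["mu"]], p[["eta"]], p[["bg"]])
  yukawa <- NULL
  if (include_sq)
    yukawa <- yukawa_params(p[["r_hs"]], p[["phi"]], p[["z_eff"]],
                            p[["ionic_strength"]], temperature, eps_r)
  list(form = form, yukawa = yukawa)
}

#' Fit a SAXS curve with the core-shell (+ RMSA) model
#'
#' Bounded weighted least squares (Levenberg-Marquardt,
#' [minpack.lm::nls.lm()]) of the combined intensity model to one absolute
#' scattering curve. Weights are the measured uncertainties where present,
#' otherwise a photon-counting proxy `sqrt(max(I, eps))`. Any parameter can
#' be held fixed by name. Parameters pinned at a bound are flagged, not
#' failed.
#'
#' @param curve A [saxs_curve()].
#' @param init Named initial-parameter vector (subset of
#'   `r_core, r_outer, sigma_r, mu, eta, bg, r_hs, phi, z_eff,
#'   ionic_strength`); unnamed defaults fill the rest.
#' @param fixed Character vector of parameter names to hold at their
#'   initial values.
#' @param include_sq Include the charged-sphere structure factor (default:
#'   decided by the curve concentration against `sq_threshold`).
#' @param sq_threshold Concentration (wt percent) at and above which the
#'   structure factor is included when `include_sq` is `NULL` (default 0.5).
#' @param q_range Fit window in inverse Angstrom (default `c(0.005, 0.35)`).
#' @param structure `"hp"` for the charged RMSA structure factor or
#'   `"py"` for the uncharged hard-sphere reference (in which case `z_eff`
#'   and `ionic_strength` are dropped).
#' @param n_quad Polydispersity quadrature order.
#' @param bounds Optional list with named numeric vectors `lower` and/or
#'   `upper` overriding individual default parameter bounds.
#' @param n_starts Number of optimizer starts (default 1). Additional
#'   starts jitter the free structure-factor parameters log-uniformly
#'   within a factor of 2.5, deterministically from `start_seed`; the best
#'   final deviance wins.
#' @param start_seed Seed of the multi-start jitter (logged in the result).
#' @param control Passed to [minpack.lm::nls.lm.control()].
#' @return An object of class `"saxs_fit"`; see [tidy.saxs_fit()],
#'   [glance.saxs_fit()], [augment.saxs_fit()].
#' @export
fit_saxs <- function(curve, init = NULL, fixed = character(),
                     include_sq = NULL, sq_threshold = 0.5,
                     q_range = c(0.005, 0.35), structure = c("hp", "py"),
                     n_quad = 64, bounds = NULL, n_starts = 1, start_seed = 1,
                     control = minpack.lm::nls.lm.control(maxiter = 200)) {
  stopifnot(inherits(curve, "saxs_curve"))
  structure_kind <- match.arg(structure)
  conc <- attr(curve, "concentration")
  temperature <- attr(curve, "temperature") %||% 293
  eps_r <- water_permittivity(temperature)
  if (is.null(include_sq))
    include_sq <- !is.na(conc) && conc >= sq_threshold

  keep <- curve$q >= q_range[1] & curve$q <= q_range[2]
  q <- curve$q[keep]
  y <- curve$intensity[keep]
  dy <- curve$uncertainty[keep]
  w <- if (all(is.finite(dy))) dy else sqrt(pmax(y, 1e-12))

  par_names <- names(.default_init(include_sq))
  if (structure_kind == "py" && include_sq)
    par_names <- setdiff(par_names, c("z_eff", "ionic_strength"))
  p0 <- .default_init(include_sq)[par_names]
  if (!is.null(init)) {
    bad <- setdiff(names(init), names(.default_init(TRUE)))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "),
                          call. = FALSE)
    p0[intersect(names(init), par_names)] <- init[intersect(names(init), par_names)]
  }
  if (structure_kind == "py" && include_sq) {
    # uncharged reference: z_eff = 0 pins S to the PY hard-sphere form
    fixed <- union(fixed, c("z_eff", "ionic_strength"))
    p0 <- c(p0, z_eff = 0, ionic_strength = 1e-3)
    par_names <- names(p0)
  }
  free <- setdiff(par_names, fixed)
  if (length(q) < length(free) + 5)
    stop("too few points in the fit window (need at least ",
         length(free) + 5, ")", call. = FALSE)
  b <- .fit_bounds()
  if (!is.null(bounds)) {
    if (!is.null(bounds$lower)) b$lower[names(bounds$lower)] <- bounds$lower
    if (!is.null(bounds$upper)) b$upper[names(bounds$upper)] <- bounds$upper
  }
  lower <- b$lower[free]; upper <- b$upper[free]
  p_full <- p0

  resid_fn <- function(pf) {
    p_full[free] <- pf
    mod <- tryCatch({
      pars <- .params_from_vector(p_full, include_sq, temperature, eps_r)
      model_intensity(q, pars$form, pars$yukawa, n_quad)
    }, error = function(e) NULL)
    if (is.null(mod) || any(!is.finite(mod))) return(rep(1e6, length(y)))
    (y - mod) / w
  }

  starts <- list(pmin(pmax(p0[free], lower), upper))
  if (n_starts > 1) {
    sq_free <- intersect(free, c("r_hs", "phi", "z_eff", "ionic_strength"))
    jit <- withr::with_seed(start_seed,
      replicate(n_starts - 1,
                stats::runif(length(sq_free), -0.4, 0.4), simplify = FALSE))
    for (jf in jit) {
      st <- starts[[1]]
      st[sq_free] <- pmin(pmax(st[sq_free] * 10^jf, lower[sq_free]),
                          upper[sq_free])
      starts[[length(starts) + 1]] <- st
    }
  }
  lmfit <- NULL
  for (st in starts) {
    cand <- minpack.lm::nls.lm(par = st, lower = lower, upper = upper,
                               fn = resid_fn, control = control)
    if (is.null(lmfit) || cand$deviance < lmfit$deviance) lmfit <- cand
  }
  p_full[free] <- lmfit$par
  dof <- length(y) - length(free)
  redchi2 <- lmfit$deviance / dof
  # parameter uncertainties from the local curvature
  se <- rep(NA_real_, length(free)); names(se) <- free
  cov <- tryCatch(redchi2 * solve(lmfit$hessian), error = function(e) NULL)
  if (!is.null(cov)) {
    d <- diag(cov); d[d < 0] <- NA
    se <- sqrt(d); names(se) <- free
  }
  at_bound <- free[(abs(p_full[free] - lower) < 1e-8 * pmax(1, abs(lower))) |
                     (abs(p_full[free] - upper) < 1e-8 * pmax(1, abs(upper)))]
  pars <- .params_from_vector(p_full, include_sq, temperature, eps_r)
  converged <- lmfit$info %in% 1:4
  if (!converged)
    warning("fit did not converge: ", lmfit$message)
  structure(list(
    form = pars$form, yukawa = pars$yukawa,
    estimate = p_full, se = se, fixed = fixed, free = free,
    include_sq = include_sq, structure = structure_kind,
    redchi2 = redchi2, n_points = length(y), dof = dof,
    converged = converged, info = lmfit$info, message = lmfit$message,
    niter = lmfit$niter, at_bound = at_bound,
    n_starts = n_starts, start_seed = start_seed,
    q_range = q_range, n_quad = n_quad,
    curve = curve, weights = w, q_fit = q
  ), class = "saxs_fit")
}

#' @export
print.saxs_fit <- function(x, ...) {
  cat(sprintf("<SAXS core-shell%s fit: %s>\n",
              if (x$include_sq) paste0(" x S(q)[", x$structure, "]") else "",
              attr(x$curve, "sample_id")))
  cat(sprintf("  %d points, reduced chi-square %.3f, %s\n", x$n_points,
              x$redchi2, if (x$converged) "converged" else "NOT converged"))
  if (length(x$at_bound)) cat("  at bound:", paste(x$at_bound, collapse = ", "), "\n")
  est <- x$estimate
  cat("  ", paste(sprintf("%s=%.4g", names(est), est), collapse = ", "), "\n")
  invisible(x)
}

#' Fit a concentration series of SAXS curves
#'
#' Staged strategy over a dilution series sorted by concentration: curves
#' below `sq_threshold` wt percent are fitted with the form factor only;
#' the medians of their form parameters then seed the concentrated fits,
#' which include the structure factor. Per-curve failures are caught and
#' reported without aborting the series.
#'
#' @param curves List of [saxs_curve()] objects with `concentration`
#'   attributes, sorted by concentration.
#' @param sq_threshold Structure-factor threshold concentration, wt percent.
#' @param init,fixed,q_range,n_quad Passed to [fit_saxs()].
#' @param n_starts Optimizer starts for the concentrated (structure-factor)
#'   fits; multi-start guards against local minima of the
#'   structure-factor parameters (default 6).
#' @return A tibble of class `"saxs_series_fit"` with one row per curve:
#'   `sample_id`, `concentration`, `converged`, `error` and a `fit`
#'   list-column.
#' @export
fit_saxs_series <- function(curves, sq_threshold = 0.5, init = NULL,
                            fixed = character(), q_range = c(0.005, 0.35),
                            n_quad = 64, n_starts = 6) {
  stopifnot(length(curves) >= 1,
            all(vapply(curves, inherits, logical(1), "saxs_curve")))
  conc <- vapply(curves, function(cv) attr(cv, "concentration"), numeric(1))
  if (any(is.na(conc))) stop("all curves need a `concentration` attribute", call. = FALSE)
  if (is.unsorted(conc, strictly = FALSE))
    stop("`curves` must be sorted by concentration", call. = FALSE)

  fit_one <- function(cv, use_sq, seed_init, starts) {
    tryCatch(list(fit = fit_saxs(cv, init = seed_init, fixed = fixed,
                                 include_sq = use_sq, q_range = q_range,
                                 n_quad = n_quad, n_starts = starts),
                  error = NA_character_),
             error = function(e) list(fit = NULL, error = conditionMessage(e)))
  }
  dilute <- conc < sq_threshold
  res <- vector("list", length(curves))
  for (i in which(dilute)) res[[i]] <- fit_one(curves[[i]], FALSE, init, 1)

  # dilute-fit medians (and their per-concentration intensity scale) seed the
  # concentrated fits; otherwise per-curve parameters are free
  med <- NULL
  ok_dilute <- which(dilute)[!vapply(res[which(dilute)], function(r) is.null(r$fit), logical(1))]
  if (length(ok_dilute)) {
    form_names <- c("r_core", "r_outer", "sigma_r", "mu", "eta", "bg")
    med <- apply(vapply(res[ok_dilute],
                        function(r) r$fit$estimate[form_names], numeric(6)), 1, stats::median)
    names(med) <- form_names
    c_med <- stats::median(conc[ok_dilute])
    med <- c(med, eta_per_c = unname(med["eta"] / c_med),
             bg_per_c = unname(med["bg"] / c_med))
  }
  for (i in which(!dilute)) {
    seed_init <- init
    if (!is.null(med)) {
      scaled <- c(med[c("r_core", "r_outer", "sigma_r", "mu")],
                  eta = unname(med[["eta_per_c"]] * conc[i]),
                  bg = unname(med[["bg_per_c"]] * conc[i]))
      seed_init <- c(scaled, init[setdiff(names(init), names(scaled))])
    }
    res[[i]] <- fit_one(curves[[i]], TRUE, seed_init, n_starts)
  }

  out <- tibble::tibble(
    sample_id = vapply(curves, function(cv) attr(cv, "sample_id") %||% "", character(1)),
    concentration = conc,
    converged = vapply(res, function(r) !is.null(r$fit) && r$fit$converged, logical(1)),
    error = vapply(res, function(r) if (is.null(r$fit)) r$error else NA_character_, character(1)),
    fit = lapply(res, function(r) r$fit)
  )
  class(out) <- c("saxs_series_fit", class(out))
  out
}

#' Compare charged (RMSA) and hard-sphere (PY) structure-factor fits
#'
#' Fits the same curve from the same initial values with the
#' Hayter-Penfold RMSA structure factor and with the uncharged
#' Percus-Yevick hard-sphere structure factor, and reports both
#' reduced chi-squares and parameter sets. A PY volume fraction pushed
#' above `phi_flag` (crystallization/jamming territory) is flagged as the
#' classic signature of unscreened charge masquerading as packing.
#'
#' @param curve A [saxs_curve()].
#' @param init,fixed,q_range Passed to [fit_saxs()].
#' @param phi_flag Flag threshold for the PY volume fraction (default 0.55).
#' @return A list of class `"sq_comparison"` with elements `hp`, `py`
#'   (both `"saxs_fit"`), `redchi2_hp`, `redchi2_py`, and
#'   `py_phi_unphysical`.
#' @export
compare_structure_factors <- function(curve, init = NULL, fixed = character(),
                                      q_range = c(0.005, 0.35), phi_flag = 0.55) {
  hp <- fit_saxs(curve, init = init, fixed = fixed, include_sq = TRUE,
                 structure = "hp", q_range = q_range)
  # let the PY volume fraction wander into jamming so the flag can fire
  py <- fit_saxs(curve, init = init, fixed = fixed, include_sq = TRUE,
                 structure = "py", q_range = q_range,
                 bounds = list(upper = c(phi = 0.6399)))
  structure(list(hp = hp, py = py,
                 redchi2_hp = hp$redchi2, redchi2_py = py$redchi2,
                 py_phi = py$estimate[["phi"]],
                 py_phi_unphysical = py$estimate[["phi"]] > phi_flag),
            class = "sq_comparison")
}

#' @export
print.sq_comparison <- function(x, ...) {
  cat("<structure-factor comparison>\n")
  cat(sprintf("  RMSA (charged): reduced chi-square %.3f\n", x$redchi2_hp))
  cat(sprintf("  PY hard sphere: reduced chi-square %.3f (phi = %.3f%s)\n",
              x$redchi2_py, x$py_phi,
              if (x$py_phi_unphysical) ", UNPHYSICAL" else ""))
  invisible(x)
}
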