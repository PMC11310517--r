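#' Core-shell sphere form-factor parameters
#'
#' Parameter block for a spherical micelle with a hydrophobic core of radius
#' `r_core` and a shell extending to `r_outer`, with Gaussian polydispersity
#' of the outer radius. Mirrors the row schema of a SAXS fit-parameter table.
#'
#' @param r_core Inner (core) radius in Angstrom. Must be positive.
#' @param r_outer Mean outer radius in Angstrom. Must exceed `r_core`.
#' @param sigma_r Gaussian standard deviation of the outer radius, Angstrom.
#' @param mu Ratio of core to shell scattering contrast (dimensionless; for
#'   an alkyl core in water against a hydrated peptide shell this is
#'   typically negative).
#' @param eta Absolute scale factor carrying the intensity units of
#'   cm^-1. Internally the shell contrast is set to 1 and the core contrast
#'   to `mu`; `eta` multiplies the polydispersity-averaged squared amplitude
#'   divided by the square of the mean outer-sphere volume, so it lumps the
#'   (contrast x volume)^2 prefactor into a single parameter.
#' @param bg Flat incoherent background, cm^-1.
#' @return A list of class `"core_shell_params"`.
#' @examples
#' core_shell_params(r_core = 14.08, r_outer = 26.59, sigma_r = 4.42,
#'                   mu = -1.614, eta = 2.913e-6, bg = 3.695e-4)
#' @export
core_shell_params <- function(r_core, r_outer, sigma_r = 0, mu = 1,
                              eta = 1, bg = 0) {
  stopifnot(is.numeric(r_core), is.numeric(r_outer), is.numeric(sigma_r),
            is.numeric(mu), is.numeric(eta), is.numeric(bg))
  if (r_core <= 0) stop("`r_core` must be positive", call. = FALSE)
  if (r_outer <= r_core) stop("`r_outer` must exceed `r_core`", call. = FALSE)
  if (sigma_r < 0) stop("`sigma_r` must be non-negative", call. = FALSE)
  if (eta < 0) stop("`eta` must be non-negative", call. = FALSE)
  if (bg < 0) stop("`bg` must be non-negative", call. = FALSE)
  if (!is.finite(mu)) stop("`mu` must be finite", call. = FALSE)
  structure(list(r_core = r_core, r_outer = r_outer, sigma_r = sigma_r,
                 mu = mu, eta = eta, bg = bg),
            class = "core_shell_params")
}

#' @export
print.core_shell_params <- function(x, ...) {
  cat("<core-shell sphere form factor>\n")
  cat(sprintf("  r_core  %8.3f A\n  r_outer %8.3f A (sigma %.3f A)\n", x$r_core, x$r_outer, x$sigma_r))
  cat(sprintf("  mu      %8.4f\n  eta     %8.4g cm^-1\n  bg      %8.4g cm^-1\n", x$mu, x$eta, x$bg))
  invisible(x)
}

#' Yukawa (screened-Coulomb) structure-factor parameters
#'
#' Parameter block for the Hayter-Penfold RMSA structure factor of charged
#' spheres: hard-sphere radius, effective volume fraction, effective charge,
#' ionic strength, temperature and solvent permittivity. The interaction
#' diameter is `sigma = 2 * r_hs`.
#'
#' @param r_hs Hard-sphere radius in Angstrom.
#' @param phi Effective hard-sphere volume fraction; must lie in
#'   `[0, 0.64)` (random close packing).
#' @param z_eff Effective macroion charge in elementary-charge units
#'   (non-negative).
#' @param ionic_strength Ionic strength in mol per litre.
#' @param temperature Temperature in kelvin (default 293 K).
#' @param eps_r Relative permittivity of the solvent; defaults to pure water
#'   at `temperature` via [water_permittivity()].
#' @return A list of class `"yukawa_params"`.
#' @examples
#' yukawa_params(r_hs = 72.37, phi = 0.0483, z_eff = 14.73,
#'               ionic_strength = 0.0049)
#' @export
yukawa_params <- function(r_hs, phi, z_eff, ionic_strength,
                          temperature = 293,
                          eps_r = water_permittivity(temperature)) {
  stopifnot(is.numeric(r_hs), is.numeric(phi), is.numeric(z_eff),
            is.numeric(ionic_strength), is.numeric(temperature), is.numeric(eps_r))
  if (r_hs <= 0) stop("`r_hs` must be positive", call. = FALSE)
  if (phi < 0 || phi >= 0.64) stop("`phi` must lie in [0, 0.64)", call. = FALSE)
  if (z_eff < 0) stop("`z_eff` must be non-negative", call. = FALSE)
  if (ionic_strength < 0) stop("`ionic_strength` must be non-negative", call. = FALSE)
  if (temperature <= 0) stop("`temperature` must be positive", call. = FALSE)
  if (eps_r <= 1) stop("`eps_r` must exceed 1", call. = FALSE)
  structure(list(r_hs = r_hs, phi = phi, z_eff = z_eff,
                 ionic_strength = ionic_strength, temperature = temperature,
                 eps_r = eps_r),
            class = "yukawa_params")
}

#' @export
print.yukawa_params <- function(x, ...) {
  cat("<Yukawa / RMSA structure-factor parameters>\n")
  cat(sprintf("  r_hs  %8.3f A (sigma = %.3f A)\n  phi   %8.4f\n  z_eff %8.3f e\n",
              x$r_hs, 2 * x$r_hs, x$phi, x$z_eff))
  cat(sprintf("  I     %8.4g M,  T = %.1f K,  eps_r = %.2f\n",
              x$ionic_strength, x$temperature, x$eps_r))
  invisible(x)
}
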