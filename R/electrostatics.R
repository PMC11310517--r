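#' Debye screening length of an electrolyte
#'
#' `kappa^-1 = sqrt(eps_r eps0 kB T / (2 e^2 I))` with the ionic strength
#' `I` converted from mol per litre to a number density. For 0.0049 M at
#' 293 K in water this gives about 43 Angstrom, the screening length scale
#' of dilute micellar TFA-salt solutions.
#'
#' @param ionic_strength Ionic strength in mol per litre; must be positive
#'   (zero would give an infinite screening length, signalled as a distinct
#'   error).
#' @param temperature Temperature in kelvin.
#' @param eps_r Relative permittivity of the solvent (default: pure water
#'   at `temperature`).
#' @return Debye length in Angstrom.
#' @examples
#' debye_length(0.0049, temperature = 293)
#' @export
debye_length <- function(ionic_strength, temperature = 293,
                         eps_r = water_permittivity(temperature)) {
  stopifnot(is.numeric(ionic_strength), temperature > 0, eps_r > 1)
  if (any(ionic_strength == 0))
    stop("ionic_strength = 0: screening length is infinite", call. = FALSE)
  if (any(ionic_strength < 0))
    stop("`ionic_strength` must be positive", call. = FALSE)
  n_ions <- ionic_strength * 1000 * .const$N_A  # ions per m^3
  lam_m <- sqrt(eps_r * .const$eps0 * .const$kB * temperature /
                  (2 * .const$e^2 * n_ions))
  lam_m / .const$ang
}

#' Inverse Debye screening length
#'
#' Convenience inverse of [debye_length()].
#'
#' @inheritParams debye_length
#' @return `kappa` in inverse Angstrom.
#' @export
debye_kappa <- function(ionic_strength, temperature = 293,
                        eps_r = water_permittivity(temperature)) {
  1 / debye_length(ionic_strength, temperature, eps_r)
}

#' Surface potential of a charged sphere from its effective charge
#'
#' Converts an effective macroion charge (in elementary charges) into a
#' surface potential. With `screened = TRUE` the screened form
#' `psi0 = z_eff e / (pi eps_r eps0 sigma (2 + kappa sigma))` is evaluated;
#' with `screened = FALSE` its unscreened (`kappa -> 0`) limit
#' `psi0 = z_eff e / (2 pi eps_r eps0 sigma)`. Both conventions are
#' first-class outputs of the package because derived reports quote both.
#'
#' @param z_eff Effective charge in elementary-charge units.
#' @param sigma Interaction diameter (`2 r_hs`) in Angstrom.
#' @param kappa Inverse screening length in inverse Angstrom (ignored when
#'   `screened = FALSE`).
#' @param eps_r Relative solvent permittivity.
#' @param screened Include the `kappa sigma` screening term (default TRUE).
#' @return Surface potential in millivolt.
#' @examples
#' surface_potential(14.73, sigma = 144.74, screened = FALSE, eps_r = 80.1)
#' @export
surface_potential <- function(z_eff, sigma, kappa = 0,
                              eps_r = water_permittivity(293),
                              screened = TRUE) {
  stopifnot(is.numeric(z_eff), is.numeric(sigma), is.numeric(kappa), kappa >= 0)
  if (sigma <= 0) stop("`sigma` must be positive", call. = FALSE)
  sig_m <- sigma * .const$ang
  denom_factor <- if (screened) 2 + kappa * sigma else 2
  psi_v <- z_eff * .const$e / (pi * eps_r * .const$eps0 * sig_m * denom_factor)
  psi_v * 1e3
}

#' Effective charge from a surface potential
#'
#' Exact algebraic inverse of [surface_potential()] (matching `screened`
#' convention): recovers the effective charge in elementary-charge units
#' from a surface (zeta) potential.
#'
#' @param psi0 Surface potential in millivolt.
#' @inheritParams surface_potential
#' @return Effective charge `z_eff` (elementary charges).
#' @examples
#' effective_charge_from_potential(37, sigma = 144.74, screened = FALSE,
#'                                 eps_r = 80.1)
#' @export
effective_charge_from_potential <- function(psi0, sigma, kappa = 0,
                                            eps_r = water_permittivity(293),
                                            screened = TRUE) {
  stopifnot(is.numeric(psi0), kappa >= 0)
  if (sigma <= 0) stop("`sigma` must be positive", call. = FALSE)
  sig_m <- sigma * .const$ang
  denom_factor <- if (screened) 2 + kappa * sigma else 2
  (psi0 * 1e-3) * pi * eps_r * .const$eps0 * sig_m * denom_factor / .const$e
}

#' Inter-micellar screened-Coulomb (Yukawa) pair potential
#'
#' Repulsive pair potential between two charged spheres of diameter `sigma`
#' at centre separations at or beyond contact (`sigma`):
#' `U(r) = pi eps0 eps_r sigma^2 psi0^2 exp(-kappa (r - sigma)) / r`,
#' the dimensionally consistent one-Yukawa form whose contact value is
#' `U(sigma) = pi eps0 eps_r sigma psi0^2`.
#'
#' @param r Centre-centre separations in Angstrom, all `>= sigma`.
#' @param sigma Interaction diameter in Angstrom.
#' @param psi0 Surface potential in millivolt.
#' @param kappa Inverse screening length in inverse Angstrom.
#' @param eps_r Relative solvent permittivity.
#' @param temperature Temperature in kelvin (sets the `kB T` energy unit).
#' @return A tibble of class `"potential_curve"` with columns `r` (Angstrom),
#'   `u_kt` (units of `kB T`) and `u_joule`; the parameters are stored as
#'   attributes.
#' @examples
#' pair_potential(seq(145, 400, by = 5), sigma = 144.74, psi0 = 37,
#'                kappa = 1 / 43.1)
#' @export
pair_potential <- function(r, sigma, psi0, kappa,
                           eps_r = water_permittivity(temperature),
                           temperature = 293) {
  stopifnot(is.numeric(r), sigma > 0, kappa >= 0, temperature > 0)
  if (any(r < sigma)) stop("all `r` must be >= sigma (hard-core contact)", call. = FALSE)
  sig_m <- sigma * .const$ang
  r_m <- r * .const$ang
  u_j <- pi * .const$eps0 * eps_r * sig_m^2 * (psi0 * 1e-3)^2 *
    exp(-kappa * (r - sigma)) / r_m
  out <- tibble::tibble(r = r, u_kt = u_j / (.const$kB * temperature), u_joule = u_j)
  class(out) <- c("potential_curve", class(out))
  attr(out, "context") <- list(sigma = sigma, psi0 = psi0, kappa = kappa,
                               eps_r = eps_r, temperature = temperature)
  out
}

#' Contact potential of the inter-micellar interaction
#'
#' `U(sigma) / kB T` for a [yukawa_params()] block: the pair-potential value
#' at hard-sphere contact, using the surface potential derived from the
#' effective charge. The default (`screened = FALSE`) uses the unscreened
#' surface-potential convention; set `screened = TRUE` for the screened one.
#'
#' @param params A [yukawa_params()] block.
#' @param screened Which surface-potential convention to use.
#' @return Contact potential in units of `kB T`.
#' @examples
#' contact_potential(yukawa_params(72.37, 0.0483, 14.73, 0.0049))
#' @export
contact_potential <- function(params, screened = FALSE) {
  stopifnot(inherits(params, "yukawa_params"))
  sigma <- 2 * params$r_hs
  kappa <- if (params$ionic_strength > 0)
    debye_kappa(params$ionic_strength, params$temperature, params$eps_r)
  else 0
  psi0 <- surface_potential(params$z_eff, sigma, kappa, params$eps_r, screened)
  pc <- pair_potential(sigma, sigma, psi0, kappa, params$eps_r, params$temperature)
  pc$u_kt[1]
}

#' Export a potential curve as two-column text
#'
#' Writes separation (Angstrom) and energy (`kB T`) columns with a
#' commented header.
#'
#' @param curve A `"potential_curve"` tibble from [pair_potential()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_potential_curve <- function(curve, path) {
  stopifnot(inherits(curve, "potential_curve"))
  ctx <- attr(curve, "context")
  hdr <- c("# inter-micellar pair potential",
           sprintf("# sigma_A: %.6g | psi0_mV: %.6g | kappa_invA: %.6g | eps_r: %.6g | T_K: %.6g",
                   ctx$sigma, ctx$psi0, ctx$kappa, ctx$eps_r, ctx$temperature),
           "# r_A  U_kBT")
  writeLines(c(hdr, sprintf("%.6g %.8g", curve$r, curve$u_kt)), path)
  invisible(path)
}
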