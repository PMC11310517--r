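#' Tanford volume of an alkyl chain
#'
#' Empirical volume of a saturated alkyl chain, `v = 27.4 + 26.9 n`
#' cubic Angstrom, where `n` is the number of chain carbons excluding the
#' terminal methyl group (n = 15 for a palmitoyl C16 chain).
#'
#' @param n_carbons Integer carbon count (excluding terminal CH3).
#' @return Chain volume in cubic Angstrom.
#' @examples
#' tanford_volume(15)
#' @export
tanford_volume <- function(n_carbons) {
  stopifnot(is.numeric(n_carbons))
  if (any(n_carbons < 0) || any(n_carbons != round(n_carbons)))
    stop("`n_carbons` must be a non-negative integer", call. = FALSE)
  27.4 + 26.9 * n_carbons
}

#' Electron density of a molecular volume
#'
#' @param n_electrons Number of electrons in the volume.
#' @param volume Volume in cubic Angstrom (positive).
#' @return Electron density in electrons per cubic Angstrom.
#' @examples
#' electron_density(129, tanford_volume(15))  # alkyl core of a C16 chain
#' @export
electron_density <- function(n_electrons, volume) {
  stopifnot(is.numeric(n_electrons), is.numeric(volume))
  if (any(volume <= 0)) stop("`volume` must be positive", call. = FALSE)
  n_electrons / volume
}

# squared contrast-volume factor [r0 v_p (rho_l - rho_0)]^2 in cm^2 g^-2
.contrast_factor_sq <- function(v_p, rho_l, rho_0) {
  drho_cm <- (rho_l - rho_0) * 1e24        # e A^-3 -> e cm^-3
  (.const$r0_cm * v_p * drho_cm)^2
}

#' Absolute forward scattering of a micellar solution
#'
#' `I(0) = c_mic M_mic [r0 v_p (rho_l - rho_0)]^2 / NA`, the absolute
#' forward intensity of a dilute solution of micelles of molar mass
#' `m_mic`. Electron densities are supplied in electrons per cubic Angstrom
#' and converted internally.
#'
#' @param m_mic Micelle molar mass, g per mol.
#' @param c_mic Micelle mass concentration, g per cm^3.
#' @param v_p Partial specific volume, cm^3 per g.
#' @param rho_l Solute (lipopeptide) electron density, e per cubic Angstrom.
#' @param rho_0 Solvent electron density, e per cubic Angstrom (0.333 for
#'   water).
#' @return Forward intensity `I(0)` in cm^-1.
#' @examples
#' forward_intensity(4.38e4, c_mic = 0.002, v_p = 1.15,
#'                   rho_l = 0.299, rho_0 = 0.333)
#' @export
forward_intensity <- function(m_mic, c_mic, v_p, rho_l, rho_0 = 0.333) {
  stopifnot(m_mic >= 0, c_mic > 0, v_p > 0)
  c_mic * m_mic * .contrast_factor_sq(v_p, rho_l, rho_0) / .const$N_A
}

#' Micelle molar mass and association number from forward scattering
#'
#' Inverts the absolute forward-intensity relation:
#' `M_mic = I(0) NA / (c_mic [r0 v_p (rho_l - rho_0)]^2)`, and, when the
#' monomer molar mass is given, the association number `p = M_mic / M_mol`.
#'
#' @param i0 Forward intensity in cm^-1.
#' @param m_mol Monomer molar mass, g per mol (optional; enables `p`).
#' @inheritParams forward_intensity
#' @return A one-row tibble with columns `m_mic` (g per mol) and `p`
#'   (`NA` when `m_mol` is not supplied).
#' @examples
#' micelle_mass(0.0176, c_mic = 0.002, v_p = 1.15, rho_l = 0.299,
#'              rho_0 = 0.333, m_mol = 675.4)
#' @export
micelle_mass <- function(i0, c_mic, v_p, rho_l, rho_0 = 0.333, m_mol = NULL) {
  stopifnot(i0 >= 0, c_mic > 0, v_p > 0)
  if (abs(rho_l - rho_0) < 1e-4)
    stop("contrast match: |rho_l - rho_0| too small to determine a mass",
         call. = FALSE)
  m_mic <- i0 * .const$N_A / (c_mic * .contrast_factor_sq(v_p, rho_l, rho_0))
  tibble::tibble(m_mic = m_mic,
                 p = if (is.null(m_mol)) NA_real_ else m_mic / m_mol)
}

#' Association number from core area and head-group area
#'
#' `p = 4 pi R_core^2 / A`: number of molecules whose head groups of area
#' `A` tile the surface of a spherical core of radius `R_core`.
#'
#' @param r_core Core radius in Angstrom.
#' @param area Area per molecule in square Angstrom.
#' @return Association number (real; round only for display).
#' @examples
#' association_from_area(14.08, 32.7)
#' @export
association_from_area <- function(r_core, area) {
  if (any(r_core <= 0) || any(area <= 0))
    stop("`r_core` and `area` must be positive", call. = FALSE)
  4 * pi * r_core^2 / area
}

#' Head-group separation: Bragg-like estimate vs core-shell model
#'
#' Compares the nearest head-group separation inferred from the position of
#' the secondary form-factor maximum, `d = 2 pi / q_max`, with the
#' core-shell model estimate `r_core + r_outer` (twice the mid-shell
#' radius). The two numbers are reported side by side, not judged.
#'
#' @param q_max Position of the secondary intensity maximum, inverse
#'   Angstrom.
#' @param r_core,r_outer Fitted core and outer radii in Angstrom (optional;
#'   `d_model` is `NA` when absent).
#' @return A one-row tibble with columns `d_bragg` and `d_model` (Angstrom).
#' @examples
#' headgroup_separation(0.172, r_core = 14.71, r_outer = 26.51)
#' @export
headgroup_separation <- function(q_max, r_core = NULL, r_outer = NULL) {
  if (q_max <= 0) stop("`q_max` must be positive", call. = FALSE)
  d_model <- NA_real_
  if (!is.null(r_core) && !is.null(r_outer)) {
    if (!(r_outer >= r_core && r_core > 0))
      stop("need 0 < r_core <= r_outer", call. = FALSE)
    d_model <- r_core + r_outer
  }
  tibble::tibble(d_bragg = 2 * pi / q_max, d_model = d_model)
}
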