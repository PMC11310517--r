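#' Hard-sphere scattering amplitude factor
#'
#' The normalised amplitude of a uniform sphere,
#' `Phi(x) = 3 (sin x - x cos x) / x^3` with `x = qR`. Evaluated by series
#' expansion near the origin so that `Phi(0) = 1` exactly.
#'
#' @param x Dimensionless `qR`, non-negative (vectorised).
#' @return `Phi(x)`, bounded by 1 in absolute value.
#' @examples
#' sphere_form_amplitude(c(0, pi, 4.4934))
#' @export
sphere_form_amplitude <- function(x) {
  stopifnot(is.numeric(x), all(x >= 0))
  out <- numeric(length(x))
  small <- x < 1e-2
  xs <- x[small]
  # 3(sin x - x cos x)/x^3 = 1 - x^2/10 + x^4/280 - ...
  out[small] <- 1 - xs^2 / 10 + xs^4 / 280
  xl <- x[!small]
  out[!small] <- 3 * (sin(xl) - xl * cos(xl)) / xl^3
  out
}

#' Core-shell sphere scattering amplitude
#'
#' Amplitude of a two-phase sphere: a core of radius `r_core` and contrast
#' `contrast_core` embedded in a shell extending to `r_outer` with contrast
#' `contrast_shell` (both relative to the solvent),
#' `F(q) = V_o drho_sh Phi(q r_outer) + V_i (drho_c - drho_sh) Phi(q r_core)`.
#' `F(0)` equals the total excess scattering mass.
#'
#' @param q Momentum transfer in inverse Angstrom (vectorised, `q >= 0`).
#' @param r_core,r_outer Core and outer radii in Angstrom, `0 < r_core < r_outer`.
#' @param contrast_core,contrast_shell Excess scattering contrasts
#'   (arbitrary units).
#' @return Amplitude in contrast x Angstrom^3 units.
#' @examples
#' core_shell_amplitude(0, 14.08, 26.59, contrast_core = -1.614)
#' @export
core_shell_amplitude <- function(q, r_core, r_outer,
                                 contrast_core = 1, contrast_shell = 1) {
  stopifnot(is.numeric(q), all(q >= 0))
  if (!(r_core > 0 && r_outer > r_core))
    stop("need 0 < r_core < r_outer", call. = FALSE)
  v_o <- 4 * pi * r_outer^3 / 3
  v_i <- 4 * pi * r_core^3 / 3
  v_o * contrast_shell * sphere_form_amplitude(q * r_outer) +
    v_i * (contrast_core - contrast_shell) * sphere_form_amplitude(q * r_core)
}

# Gauss-Legendre nodes/weights on [lo, hi] (cached per order)
.gl_cache <- new.env(parent = emptyenv())
.gauss_legendre <- function(n) {
  key <- as.character(n)
  if (is.null(.gl_cache[[key]])) .gl_cache[[key]] <- pracma::gaussLegendre(n, -1, 1)
  .gl_cache[[key]]
}

#' Polydispersity-averaged core-shell form factor intensity
#'
#' Gaussian-weighted average of the squared core-shell amplitude over the
#' outer radius, with the core radius held fixed. The Gaussian is truncated
#' to `[max(r_core + 0.1, r_outer - 4 sigma_r), r_outer + 4 sigma_r]` and the
#' weights renormalised; the average is evaluated by fixed-order
#' Gauss-Legendre quadrature. The returned intensity is
#' `eta * <|F(q)|^2> / V_o(mean)^2` (shell contrast 1, core contrast `mu`),
#' before addition of the flat background, so `sigma_r = 0` returns the
#' monodisperse intensity exactly.
#'
#' @param q Evaluation grid in inverse Angstrom; strictly increasing,
#'   `q >= 0` (`q = 0` is allowed, for forward-scattering extrapolation).
#' @param params A [core_shell_params()] block.
#' @param n_quad Gauss-Legendre quadrature order (default 64).
#' @return Numeric vector `P(q)` in cm^-1 (before background).
#' @examples
#' p <- core_shell_params(14.08, 26.59, sigma_r = 4.42, mu = -1.614, eta = 2.9e-6)
#' form_factor_intensity(c(0, 0.01, 0.1), p)
#' @export
form_factor_intensity <- function(q, params, n_quad = 64) {
  stopifnot(inherits(params, "core_shell_params"), is.numeric(q))
  if (any(q < 0)) stop("`q` must be non-negative", call. = FALSE)
  if (length(q) > 1 && any(diff(q) <= 0))
    stop("`q` must be strictly increasing", call. = FALSE)
  ri <- params$r_core; ro <- params$r_outer; sg <- params$sigma_r
  v_mean <- 4 * pi * ro^3 / 3
  if (sg == 0) {
    f <- core_shell_amplitude(q, ri, ro, params$mu, 1)
    return(params$eta * f^2 / v_mean^2)
  }
  # truncated support must retain >= 99% of the Gaussian mass above r_core
  if (stats::pnorm(ri, mean = ro, sd = sg) > 0.01)
    stop("`sigma_r` too large: truncated size distribution loses > 1% of its mass below `r_core`",
         call. = FALSE)
  lo <- max(ri + 0.1, ro - 4 * sg)
  hi <- ro + 4 * sg
  gl <- .gauss_legendre(n_quad)
  nodes <- (hi + lo) / 2 + (hi - lo) / 2 * gl$x
  w <- (hi - lo) / 2 * gl$w * stats::dnorm(nodes, mean = ro, sd = sg)
  w <- w / sum(w)
  # |F(q; R)|^2 on the q x nodes grid
  f2 <- vapply(nodes, function(r_o)
    core_shell_amplitude(q, ri, r_o, params$mu, 1)^2, numeric(length(q)))
  p <- drop(f2 %*% w)
  params$eta * p / v_mean^2
}

#' Radius of gyration of a monodisperse core-shell sphere
#'
#' Analytic radius of gyration from the second moment of the excess
#' scattering-contrast profile (shell contrast 1, core contrast `mu`), used
#' for Guinier-consistency checks of the low-q form factor.
#'
#' @param params A [core_shell_params()] block (`sigma_r` is ignored).
#' @return Radius of gyration in Angstrom.
#' @export
core_shell_rg <- function(params) {
  stopifnot(inherits(params, "core_shell_params"))
  ri <- params$r_core; ro <- params$r_outer; mu <- params$mu
  m5 <- (ro^5 - ri^5) + mu * ri^5
  m3 <- (ro^3 - ri^3) + mu * ri^3
  if (m3 == 0) stop("zero net contrast: radius of gyration undefined", call. = FALSE)
  sqrt(3 / 5 * m5 / m3)
}
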