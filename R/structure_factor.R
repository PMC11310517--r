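#' Reduced (dimensionless) state of a charged-sphere system
#'
#' Reduces a [yukawa_params()] block to the three dimensionless numbers that
#' determine the RMSA structure factor: the volume fraction `phi`, the
#' reduced screening constant `k = kappa * sigma`, and the reduced contact
#' potential `gamma0 = pi eps0 eps_r sigma psi0^2 / (kB T)`, where `psi0` is
#' the screened surface potential computed from the effective charge.
#'
#' @param params A [yukawa_params()] block.
#' @return A list with elements `phi`, `k`, `gamma0`, plus the intermediate
#'   `kappa` (inverse Angstrom) and `psi0_mv` (screened surface potential,
#'   millivolt).
#' @examples
#' dimensionless_state(yukawa_params(72.37, 0.0483, 14.73, 0.0049))
#' @export
dimensionless_state <- function(params) {
  stopifnot(inherits(params, "yukawa_params"))
  sigma <- 2 * params$r_hs
  kappa <- if (params$ionic_strength > 0)
    1 / debye_length(params$ionic_strength, params$temperature, params$eps_r)
  else 0
  psi0_mv <- surface_potential(params$z_eff, sigma, kappa,
                               eps_r = params$eps_r, screened = TRUE)
  sig_m <- sigma * .const$ang
  gamma0 <- pi * .const$eps0 * params$eps_r * sig_m * (psi0_mv * 1e-3)^2 /
    (.const$kB * params$temperature)
  list(phi = params$phi, k = kappa * sigma, gamma0 = gamma0,
       kappa = kappa, psi0_mv = psi0_mv)
}

# ---- one-Yukawa MSA via Baxter Wiener-Hopf factorization ------------------
#
# Reduced units sigma = 1.  Closure: h(r) = -1 inside the core,
# c(r) = -gamma0 exp(-k (r - 1)) / r outside.  The Baxter factor function is
#   q(t) = a/2 t^2 + b t + c0 + Cc e^{-k t}   (0 < t < 1)
#   q(t) = Ds e^{k} e^{-k t}                  (t > 1)
# Matching the factorized Ornstein-Zernike equations term by term gives six
# algebraic residuals in (a, b, c0, Cc, Ds, Hs); Hs is the (scaled) Yukawa
# moment of the outside total correlation, which closes the system.  The
# equations were derived symbolically and are frozen here; the Percus-Yevick
# hard-sphere coefficients solve them exactly at gamma0 = 0.

.msa_residuals <- function(x, eta, k, gamma0) {
  a <- x[1]; b <- x[2]; c0 <- x[3]; Cc <- x[4]; Ds <- x[5]; Hs <- x[6]
  ek <- exp(-k); e2k <- exp(-2 * k)
  cont <- Cc * ek - Ds + a / 2 + b + c0
  E1 <- (6 * Cc * Ds * eta * k^2 * e2k - 12 * Ds * a * eta + 12 * Ds * a * eta * ek -
           12 * Ds * b * eta * k + 6 * Ds * eta * k^2 * (-Ds + a + 2 * b + 2 * c0) * ek +
           12 * Ds * eta * k * (a + b) * ek +
           k^2 * (-6 * Cc * Ds * eta - 12 * Ds * c0 * eta + Ds * k + gamma0)) / k^2
  E2_r <- 12 * Cc * eta / k - 12 * Cc * eta * ek / k + 12 * Ds * eta / k +
    2 * a * eta + a + 6 * b * eta + 12 * c0 * eta - 1
  E2_1 <- 12 * Cc * eta * ek / k - 12 * Cc * eta / k^2 + 12 * Cc * eta * ek / k^2 -
    12 * Ds * eta / k - 12 * Ds * eta / k^2 - 1.5 * a * eta - 4 * b * eta + b - 6 * c0 * eta
  E2_E <- -Cc * k + 12 * Ds * Hs * eta + 12 * Ds * eta / k + 12 * Ds * eta / k^2
  E3 <- 0.5 * (-12 * Cc * Hs * eta * k^4 * e2k - 12 * Cc * eta * k^3 * e2k -
                 12 * Cc * eta * k^2 * e2k -
                 12 * Hs * eta * k^4 * (a + 2 * b + 2 * c0) * ek +
                 24 * a * eta - 24 * a * eta * ek +
                 eta * k^4 * (12 * Cc * Hs + 24 * Hs * c0 - a - 4 * b - 12 * c0) +
                 4 * eta * k^3 * (-3 * Cc + 6 * Hs * b - a - 3 * b) -
                 12 * eta * k^3 * (2 * Hs * a + 2 * Hs * b + a + 2 * b + 2 * c0) * ek +
                 12 * eta * k^2 * (Cc + 2 * Hs * a + 2 * b + 2 * c0) -
                 12 * eta * k^2 * (2 * Hs * a + 3 * a + 4 * b + 2 * c0) * ek +
                 24 * eta * k * (a + b) - 24 * eta * k * (2 * a + b) * ek +
                 k^5 * (Ds - 2 * Hs)) / k^5
  c(cont, E1, E2_r, E2_1, E2_E, E3)
}

.msa_py_start <- function(eta) {
  a <- (1 + 2 * eta) / (1 - eta)^2
  b <- -3 * eta / (2 * (1 - eta)^2)
  c(a, b, -(a / 2 + b), 0, 0, 0)
}

.msa_newton <- function(x0, eta, k, gamma0, tol = 1e-11, max_iter = 60) {
  x <- x0
  f <- .msa_residuals(x, eta, k, gamma0)
  for (it in seq_len(max_iter)) {
    if (max(abs(f)) < tol) return(list(x = x, ok = TRUE))
    # numerical Jacobian (central differences)
    J <- matrix(0, 6, 6)
    for (j in 1:6) {
      hj <- 1e-7 * max(1, abs(x[j]))
      xp <- x; xp[j] <- x[j] + hj
      xm <- x; xm[j] <- x[j] - hj
      J[, j] <- (.msa_residuals(xp, eta, k, gamma0) -
                   .msa_residuals(xm, eta, k, gamma0)) / (2 * hj)
    }
    step <- tryCatch(solve(J, -f), error = function(e) NULL)
    if (is.null(step)) return(list(x = x, ok = FALSE))
    lam <- 1
    repeat {
      xn <- x + lam * step
      fn <- .msa_residuals(xn, eta, k, gamma0)
      if (all(is.finite(fn)) && max(abs(fn)) < max(abs(f))) break
      lam <- lam / 2
      if (lam < 1e-6) return(list(x = x, ok = max(abs(f)) < 1e-8))
    }
    x <- xn; f <- fn
  }
  list(x = x, ok = max(abs(f)) < 1e-8)
}

# Solve the coefficient system, tracking the physical branch by continuation
# in gamma0 from the hard-sphere (PY) limit.
.msa_solve <- function(eta, k, gamma0) {
  if (k <= 0) stop("reduced screening constant k must be positive", call. = FALSE)
  x <- .msa_py_start(eta)
  if (gamma0 <= 0) {
    sol <- .msa_newton(x, eta, k, 0)
    if (!sol$ok) stop("MSA coefficient solve failed to converge", call. = FALSE)
    return(sol$x)
  }
  # adaptive continuation in gamma0 along the physical branch from the PY limit
  g_cur <- 0
  step <- gamma0 / max(1, ceiling(log2(1 + gamma0)))
  fails <- 0
  while (g_cur < gamma0) {
    g_next <- min(gamma0, g_cur + step)
    sol <- .msa_newton(x, eta, k, g_next)
    if (sol$ok) {
      x <- sol$x; g_cur <- g_next
      step <- step * 1.5
    } else {
      step <- step / 4
      fails <- fails + 1
      if (fails > 40 || step < gamma0 * 1e-8)
        stop("MSA coefficient solve failed to converge (phi = ", signif(eta, 4),
             ", k = ", signif(k, 4), ", gamma0 = ", signif(gamma0, 4), ")",
             call. = FALSE)
    }
  }
  x
}

.msa_gcontact <- function(x, k) {
  # g(1+) = q'(1-) - q'(1+)
  x[1] + x[2] - k * (x[4] * exp(-k) - x[5])
}

# S(Q) from the Baxter factor function: S = 1/|Qhat|^2,
# Qhat(Q) = 1 - 12 eta int_0^inf q(t) e^{i Q t} dt  (elementary closed form).
.msa_sq <- function(Q, x, eta, k) {
  a <- x[1]; b <- x[2]; c0 <- x[3]; Cc <- x[4]; Ds <- x[5]
  out <- numeric(length(Q))
  big <- Q >= 0.05
  if (any(big)) {
    z <- 1i * Q[big]
    ez <- exp(z)
    I0 <- (ez - 1) / z
    I1 <- (ez * (z - 1) + 1) / z^2
    I2 <- (ez * (z^2 - 2 * z + 2) - 2) / z^3
    Ic <- (exp(z - k) - 1) / (z - k)
    tail <- Ds * ez / (k - z)
    Qhat <- 1 - 12 * eta * (a / 2 * I2 + b * I1 + c0 * I0 + Cc * Ic + tail)
    out[big] <- 1 / Mod(Qhat)^2
  }
  if (any(!big)) {
    # moment series: Qhat = 1 - 12 eta sum_n (iQ)^n M_n / n!
    n_max <- 16L
    An <- numeric(n_max + 1)        # int_0^1 t^n e^{-k t} dt
    if (k < 2) {
      for (n in 0:n_max) {
        j <- 0:40
        An[n + 1] <- sum((-k)^j / (factorial(j) * (n + j + 1)))
      }
    } else {
      ek <- exp(-k)
      An[1] <- (1 - ek) / k
      for (n in 1:n_max) An[n + 1] <- (n * An[n] - ek) / k
    }
    Bn <- numeric(n_max + 1)        # e^{k} int_1^inf t^n e^{-k t} dt
    Bn[1] <- 1 / k
    for (n in 1:n_max) Bn[n + 1] <- (n * Bn[n] + 1) / k
    n <- 0:n_max
    Mn <- a / 2 / (n + 3) + b / (n + 2) + c0 / (n + 1) + Cc * An + Ds * Bn
    for (i in which(!big)) {
      zq <- (1i * Q[i])^n
      Qhat <- 1 - 12 * eta * sum(zq * Mn / factorial(n))
      out[i] <- 1 / Mod(Qhat)^2
    }
  }
  out
}

#' Rescaled-MSA structure factor in reduced units
#'
#' Analytic one-Yukawa MSA structure factor at reduced state
#' `(phi, k, gamma0)`, with the Hansen-Hayter rescaling applied when the
#' unrescaled contact value `g(1+)` is negative. This is the dimensionless
#' engine behind [sq_hayter_penfold()], exposed for validation against
#' [oz_msa_reference_reduced()].
#'
#' @param Q Reduced momentum transfer `q * sigma` (non-negative).
#' @param phi Volume fraction in `[0, 0.64)`.
#' @param k Reduced screening constant `kappa * sigma` (positive).
#' @param gamma0 Reduced contact potential `beta U(sigma)` (non-negative).
#' @param rescale Apply the RMSA rescaling (default TRUE).
#' @param g_tol Contact-value tolerance of the rescaling bisection.
#' @return `S(Q)` with attributes `rescaling_s` and `g_contact`.
#' @examples
#' sq_rmsa_reduced(c(0.5, 2, 7), phi = 0.0483, k = 3.3, gamma0 = 1.5)
#' @export
sq_rmsa_reduced <- function(Q, phi, k, gamma0, rescale = TRUE, g_tol = 1e-6) {
  stopifnot(is.numeric(Q), all(Q >= 0), gamma0 >= 0, k > 0)
  if (phi < 0 || phi >= 0.64) stop("`phi` must lie in [0, 0.64)", call. = FALSE)
  if (phi < 1e-10) {
    out <- rep(1, length(Q))
    attributes(out) <- c(attributes(out), list(rescaling_s = 1, g_contact = NA_real_))
    return(out)
  }
  x <- .msa_solve(phi, k, gamma0)
  g1 <- .msa_gcontact(x, k)
  s <- 1
  if (rescale && g1 < -g_tol) {
    scaled <- function(s)
      list(eta = phi / s^3, k = k / s, g = gamma0 * s * exp(-k * (1 / s - 1)))
    # warm-start the coefficient solve from the previous bisection point;
    # successive scalings differ little, so one Newton usually suffices
    x_warm <- x
    solve_warm <- function(eta, k, g) {
      sol <- .msa_newton(x_warm, eta, k, g)
      if (!sol$ok) sol <- list(x = .msa_solve(eta, k, g), ok = TRUE)
      x_warm <<- sol$x
      sol$x
    }
    g_of_s <- function(s) {
      p <- scaled(s)
      .msa_gcontact(solve_warm(p$eta, p$k, p$g), p$k)
    }
    s_min <- max(1e-6, (phi / 0.63)^(1 / 3))
    hi <- 1; lo <- NA
    s_try <- 0.98
    while (s_try > s_min) {
      if (g_of_s(s_try) >= 0) { lo <- s_try; break }
      hi <- s_try
      s_try <- s_try - 0.02
    }
    if (is.na(lo)) {
      if (g_of_s(s_min) >= 0) lo <- s_min
      else stop("RMSA rescaling failed: no scaling in (", signif(s_min, 3),
                ", 1] yields a non-negative contact value", call. = FALSE)
    }
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      gm <- g_of_s(mid)
      if (abs(gm) < g_tol) { lo <- mid; break }
      if (gm >= 0) lo <- mid else hi <- mid
      if (hi - lo < 1e-13) break
    }
    s <- lo
    p <- scaled(s)
    x <- solve_warm(p$eta, p$k, p$g)
    g1 <- .msa_gcontact(x, p$k)
    out <- .msa_sq(Q / s, x, p$eta, p$k)
  } else {
    out <- .msa_sq(Q, x, phi, k)
  }
  attributes(out) <- c(attributes(out), list(rescaling_s = s, g_contact = g1))
  out
}

#' Hayter-Penfold RMSA structure factor for charged spheres
#'
#' Analytic mean-spherical-approximation (MSA) structure factor of a
#' one-Yukawa (screened-Coulomb) fluid of charged hard spheres, with the
#' Hansen-Hayter rescaling: whenever the unrescaled MSA yields a negative
#' pair-correlation value at contact, the hard-sphere diameter is enlarged
#' (scaling factor `s` found by bisection) until `g(sigma+) = 0`, and the
#' structure factor of the rescaled system is evaluated on the original q
#' grid. The analytic solution is obtained via the Baxter factorization of
#' the Ornstein-Zernike equation (equivalent to the original Hayter-Penfold
#' algebra); the numerical reference solver [oz_msa_reference()] provides an
#' independent check.
#'
#' @param q Momentum transfer grid in inverse Angstrom (`q >= 0` allowed).
#' @param params A [yukawa_params()] block.
#' @param rescale Apply the RMSA rescaling when the MSA contact value is
#'   negative (default `TRUE`; `FALSE` gives the raw MSA).
#' @param g_tol Contact-value tolerance of the rescaling bisection.
#' @return Numeric vector `S(q)` (dimensionless, positive) with attributes
#'   `rescaling_s` (diameter scale factor, 1 when no rescaling was needed),
#'   `g_contact` (contact value of the evaluated solution) and `state`
#'   (the reduced state from [dimensionless_state()]).
#' @examples
#' yp <- yukawa_params(72.37, 0.0483, 14.73, 0.0049)
#' sq_hayter_penfold(c(0.01, 0.05, 0.1), yp)
#' @export
sq_hayter_penfold <- function(q, params, rescale = TRUE, g_tol = 1e-6) {
  stopifnot(inherits(params, "yukawa_params"), is.numeric(q), all(q >= 0))
  st <- dimensionless_state(params)
  # floor keeps the Yukawa range finite on the reduced scale at I -> 0
  out <- sq_rmsa_reduced(q * 2 * params$r_hs, st$phi, max(st$k, 1e-3),
                         st$gamma0, rescale = rescale, g_tol = g_tol)
  attr(out, "state") <- st
  out
}

#' Percus-Yevick hard-sphere structure factor
#'
#' Analytic structure factor of a pure hard-sphere fluid in the
#' Percus-Yevick approximation (Wertheim closed form), used as the
#' uncharged reference model.
#'
#' @param q Momentum transfer grid in inverse Angstrom.
#' @param r_hs Hard-sphere radius in Angstrom.
#' @param phi Volume fraction in `[0, 0.64)`.
#' @return Numeric vector `S(q)`.
#' @examples
#' sq_hard_sphere_py(c(0.01, 0.1), r_hs = 40, phi = 0.2)
#' @export
sq_hard_sphere_py <- function(q, r_hs, phi) {
  stopifnot(is.numeric(q), all(q >= 0), r_hs > 0)
  if (phi < 0 || phi >= 0.64) stop("`phi` must lie in [0, 0.64)", call. = FALSE)
  if (phi == 0) return(rep(1, length(q)))
  Q <- q * 2 * r_hs
  al <- (1 + 2 * phi)^2 / (1 - phi)^4
  be <- -6 * phi * (1 + phi / 2)^2 / (1 - phi)^4
  de <- phi * al / 2
  out <- numeric(length(Q))
  big <- Q >= 0.05
  if (any(big)) {
    Qb <- Q[big]; s <- sin(Qb); cc <- cos(Qb)
    I2 <- (s - Qb * cc) / Qb^3
    I3 <- (2 * Qb * s - (Qb^2 - 2) * cc - 2) / Qb^4
    I5 <- ((4 * Qb^3 - 24 * Qb) * s - (Qb^4 - 12 * Qb^2 + 24) * cc + 24) / Qb^6
    rc <- -24 * phi * (al * I2 + be * I3 + de * I5)
    out[big] <- 1 / (1 - rc)
  }
  if (any(!big)) {
    j <- 0:6
    for (i in which(!big)) {
      # moments of the PY direct correlation function
      mom <- sum((-1)^j * Q[i]^(2 * j) / factorial(2 * j + 1) *
                   (al / (2 * j + 3) + be / (2 * j + 4) + de / (2 * j + 6)))
      out[i] <- 1 / (1 + 24 * phi * mom)
    }
  }
  out
}
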