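# discrete sine transform (DST-I) via FFT of the odd extension
.dst1 <- function(x) {
  n <- length(x)
  y <- c(0, x, 0, -rev(x))
  -Im(stats::fft(y))[2:(n + 1)] / 2
}

#' Numerical Ornstein-Zernike / MSA reference solver (reduced units)
#'
#' Iterative solution of the Ornstein-Zernike equation under the MSA
#' closure for a hard-core one-Yukawa fluid on a radial grid, using forward
#' and inverse spherical Fourier (sine) transforms. The Picard fixed-point
#' iteration is stabilised by Anderson (DIIS) mixing and by continuation in
#' the Yukawa coupling with warm starts, which keeps the iteration on the
#' physical solution branch at strong coupling. This is the brute-force
#' oracle used to validate the analytic RMSA solution; it knows nothing of
#' the Baxter factorization.
#'
#' @param Q Reduced momentum transfer `q * sigma` at which to return `S`.
#' @param phi Volume fraction.
#' @param k Reduced screening constant `kappa * sigma`.
#' @param gamma0 Reduced contact potential `beta U(sigma)`.
#' @param n_grid Number of radial grid points (at least 2^12).
#' @param extent Radial extent of the grid in units of `sigma` (at least 40).
#' @param tol Convergence tolerance on the maximum change of the Fourier
#'   transform of the direct correlation function between iterations.
#' @param max_iter Iteration budget per continuation step; failure to
#'   converge is an error reporting the residual reached.
#' @param depth Anderson mixing history depth.
#' @return `S(Q)` with attributes `iterations` and `residual`.
#' @examples
#' \donttest{
#' oz_msa_reference_reduced(c(1, 5, 10), phi = 0.2, k = 3, gamma0 = 0)
#' }
#' @export
oz_msa_reference_reduced <- function(Q, phi, k, gamma0,
                                     n_grid = 2^12, extent = 40,
                                     tol = 1e-8, max_iter = 5000,
                                     depth = 3) {
  stopifnot(is.numeric(Q), all(Q >= 0), phi >= 0, phi < 0.64,
            gamma0 >= 0, k > 0)
  if (n_grid < 2^12) stop("`n_grid` must be at least 2^12", call. = FALSE)
  if (extent < 40) stop("`extent` must be at least 40 diameters", call. = FALSE)
  n <- as.integer(n_grid)
  # place the hard-core boundary halfway between grid points: the jump in
  # c(r) at r = 1 then integrates with second-order accuracy
  m <- round((n + 1) / extent - 0.5)
  dr <- 1 / (m + 0.5)
  r <- seq_len(n) * dr
  dq <- pi / ((n + 1) * dr)
  qg <- seq_len(n) * dq
  rho <- 6 * phi / pi
  fwd <- function(f) 4 * pi * dr * .dst1(f * r) / qg      # 3D FT
  inv <- function(F) dq * .dst1(F * qg) / (2 * pi^2 * r)  # inverse
  # continuation in the Yukawa coupling (steps of at most 1 kT at contact)
  # with warm starts keeps the iteration on the physical branch
  g_seq <- seq(0, gamma0, by = 1)[-1]
  if (!length(g_seq) || g_seq[length(g_seq)] < gamma0) g_seq <- c(g_seq, gamma0)
  cvec <- ifelse(r < 1, -1, 0)
  res <- Inf
  iters_tot <- 0
  mix <- 0.05
  for (g in g_seq) {
    bu <- ifelse(r > 1, g * exp(-k * (r - 1)) / r, 0)
    cvec <- ifelse(r < 1, cvec, -bu)
    hist_x <- list(); hist_f <- list()
    res <- Inf
    for (it in seq_len(max_iter)) {
      ch <- fwd(cvec)
      gam_h <- rho * ch^2 / (1 - rho * ch)
      gam <- inv(gam_h)
      c_new <- ifelse(r < 1, -1 - gam, -bu)   # fixed-point map value
      res <- max(abs(fwd(c_new) - ch))
      if (res < tol) { cvec <- c_new; iters_tot <- iters_tot + it; break }
      hist_x[[length(hist_x) + 1]] <- cvec
      hist_f[[length(hist_f) + 1]] <- c_new - cvec
      if (length(hist_x) > depth + 1) { hist_x <- hist_x[-1]; hist_f <- hist_f[-1] }
      mk <- length(hist_x)
      stepped <- FALSE
      if (mk >= 2) {
        d_f <- vapply(2:mk, function(j) hist_f[[j]] - hist_f[[1]], numeric(n))
        d_x <- vapply(2:mk, function(j) hist_x[[j]] - hist_x[[1]], numeric(n))
        theta <- tryCatch(
          solve(crossprod(d_f) + 1e-12 * diag(mk - 1), crossprod(d_f, -hist_f[[1]])),
          error = function(e) NULL)
        if (!is.null(theta)) {
          cvec <- drop(hist_x[[1]] + d_x %*% theta + 0.5 * (hist_f[[1]] + d_f %*% theta))
          stepped <- TRUE
        }
      }
      if (!stepped) cvec <- cvec + mix * (c_new - cvec)
    }
    if (res >= tol)
      stop("OZ/MSA reference solver did not converge within ", max_iter,
           " iterations (residual ", signif(res, 3), ")", call. = FALSE)
  }
  iters <- iters_tot
  S_grid <- 1 / (1 - rho * fwd(cvec))
  S <- stats::spline(qg, S_grid, xout = pmax(Q, dq))$y
  attributes(S) <- c(attributes(S), list(iterations = iters, residual = res))
  S
}

#' Numerical OZ/MSA reference structure factor
#'
#' Physical-units wrapper around [oz_msa_reference_reduced()]: reduces a
#' [yukawa_params()] block with [dimensionless_state()] and returns `S(q)`
#' on a q grid in inverse Angstrom.
#'
#' @param q Momentum transfer in inverse Angstrom.
#' @param params A [yukawa_params()] block.
#' @inheritParams oz_msa_reference_reduced
#' @return `S(q)` with convergence attributes.
#' @export
oz_msa_reference <- function(q, params, n_grid = 2^12, extent = 40,
                             tol = 1e-8, max_iter = 20000) {
  stopifnot(inherits(params, "yukawa_params"))
  st <- dimensionless_state(params)
  oz_msa_reference_reduced(q * 2 * params$r_hs, st$phi, max(st$k, 1e-3),
                           st$gamma0, n_grid, extent, tol, max_iter)
}
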