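#' Construct a concentration-indexed isotherm series
#'
#' A tidy container for surface-tension or conductivity dilution series:
#' a tibble with columns `concentration` and `value`, plus the measurement
#' kind and temperature as attributes.
#'
#' @param concentration Concentrations, strictly increasing and positive
#'   (wt percent unless you track molar units yourself).
#' @param value Measured property: surface tension in mN per m
#'   (`kind = "tension"`) or conductivity in microsiemens per cm
#'   (`kind = "conductivity"`).
#' @param kind `"tension"` or `"conductivity"`.
#' @param temperature Temperature in kelvin.
#' @return A tibble of class `"isotherm_series"`.
#' @export
isotherm_series <- function(concentration, value,
                            kind = c("tension", "conductivity"),
                            temperature = 293) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(concentration), is.numeric(value),
            length(concentration) == length(value))
  if (length(concentration) < 6)
    stop("an isotherm series needs at least 6 points", call. = FALSE)
  if (any(concentration <= 0) || any(diff(concentration) <= 0))
    stop("`concentration` must be positive and strictly increasing", call. = FALSE)
  if (any(!is.finite(value))) stop("`value` must be finite", call. = FALSE)
  out <- tibble::tibble(concentration = concentration, value = value)
  class(out) <- c("isotherm_series", class(out))
  attr(out, "kind") <- kind
  attr(out, "temperature") <- temperature
  out
}

#' Two-segment breakpoint fit of a colligative-property series
#'
#' Fits a continuous piecewise-linear model with a single breakpoint to
#' `value` versus (transformed) `concentration` by least squares: the
#' breakpoint abscissa is scanned over a grid of interior candidate
#' positions (at least 3 points on each side) and refined by golden-section
#' search ([stats::optimize()]). When the two-segment fit improves the
#' residual sum of squares over a single straight line by less than
#' `min_improvement` (fractional), the series is flagged as having no
#' breakpoint.
#'
#' @param data A data frame with columns `concentration` and `value` (e.g.
#'   an [isotherm_series()]).
#' @param x_transform `"log10"` (surface tension convention) or `"linear"`
#'   (conductivity convention) abscissa.
#' @param min_improvement Minimum fractional SSE improvement of the
#'   two-segment model over one line (default 0.05).
#' @return An object of class `"breakpoint_fit"`: a list with the breakpoint
#'   on the concentration scale (`breakpoint`, `NA` if none), the fitted
#'   `value` at the breakpoint, the two segment slopes (per transformed-x
#'   unit), `sse`, `sse_line`, `improvement` and the data.
#' @examples
#' set.seed(1)
#' s <- simulate_tension(seed = 1)
#' fit_breakpoint(s, "log10")
#' @export
fit_breakpoint <- function(data, x_transform = c("log10", "linear"),
                           min_improvement = 0.05) {
  x_transform <- match.arg(x_transform)
  stopifnot(is.data.frame(data),
            all(c("concentration", "value") %in% names(data)))
  conc <- data$concentration
  y <- data$value
  n <- length(y)
  if (n < 6) stop("need at least 6 points for a breakpoint fit", call. = FALSE)
  if (any(conc <= 0) && x_transform == "log10")
    stop("`concentration` must be positive for a log10 abscissa", call. = FALSE)
  x <- if (x_transform == "log10") log10(conc) else conc

  sse_at <- function(xb) {
    X <- cbind(1, pmin(x - xb, 0), pmax(x - xb, 0))
    fit <- stats::lm.fit(X, y)
    sum(fit$residuals^2)
  }
  # one straight line reference
  line_fit <- stats::lm.fit(cbind(1, x), y)
  sse_line <- sum(line_fit$residuals^2)

  # candidate interior breakpoints: >= 3 points on each side
  cand <- x[3:(n - 2)]
  cand <- cand + c(diff(cand) / 2, 0)  # midpoints plus last interior knot
  sse_grid <- vapply(cand, sse_at, numeric(1))
  i_best <- which.min(sse_grid)
  lo <- if (i_best == 1) x[3] else cand[i_best - 1]
  hi <- if (i_best == length(cand)) x[n - 2] else cand[i_best + 1]
  opt <- stats::optimize(sse_at, c(lo, hi), tol = 1e-9)
  xb <- opt$minimum
  sse <- opt$objective
  # an SSE at numerical-noise level (exactly linear or constant data) is a
  # fit to nothing: report no breakpoint rather than a 0/0 improvement
  sse_floor <- 1e-20 * max(sum(y^2), 1)
  improvement <- if (sse_line > sse_floor) 1 - sse / sse_line else 0

  X <- cbind(1, pmin(x - xb, 0), pmax(x - xb, 0))
  cf <- stats::lm.fit(X, y)$coefficients
  has_break <- improvement >= min_improvement
  structure(list(
    breakpoint = if (has_break) (if (x_transform == "log10") 10^xb else xb) else NA_real_,
    breakpoint_x = if (has_break) xb else NA_real_,
    value_at_breakpoint = if (has_break) unname(cf[1]) else NA_real_,
    slope_below = if (has_break) unname(cf[2]) else unname(line_fit$coefficients[2]),
    slope_above = if (has_break) unname(cf[3]) else unname(line_fit$coefficients[2]),
    has_breakpoint = has_break,
    sse = sse, sse_line = sse_line, improvement = improvement,
    x_transform = x_transform, n = n,
    data = tibble::as_tibble(data[c("concentration", "value")])
  ), class = "breakpoint_fit")
}

#' @export
print.breakpoint_fit <- function(x, ...) {
  cat("<two-segment breakpoint fit>\n")
  if (x$has_breakpoint) {
    cat(sprintf("  breakpoint at %.5g (%s abscissa), value %.4g\n",
                x$breakpoint, x$x_transform, x$value_at_breakpoint))
    cat(sprintf("  slopes: %.4g (below) / %.4g (above); SSE improvement %.1f%%\n",
                x$slope_below, x$slope_above, 100 * x$improvement))
  } else {
    cat(sprintf("  no breakpoint (SSE improvement %.1f%% < threshold)\n",
                100 * x$improvement))
  }
  invisible(x)
}

#' Surface excess from the pre-CMC surface-tension slope
#'
#' Gibbs/Langmuir adsorption: `Gamma = -slope / (n R T)` with the slope of
#' surface tension against log10 of concentration (mN per m per decade), as
#' conventionally read off adsorption isotherm plots. Set `ln10 = TRUE` to
#' apply the natural-log variant (divides by ln 10), and `prefactor_n = 2`
#' for the ionic-surfactant convention.
#'
#' @param slope Surface-tension slope below the CMC, mN per m per decade of
#'   concentration.
#' @param temperature Temperature in kelvin.
#' @param prefactor_n Gibbs prefactor (1 default, 2 for fully dissociated
#'   1:1 ionic surfactants).
#' @param ln10 Apply the ln(10) conversion of the decade slope to a
#'   natural-log slope (default FALSE: slope used as printed, per decade).
#' @return Surface excess in mol per square metre (negative values are
#'   flagged with a warning).
#' @examples
#' surface_excess(-12.4, temperature = 293)
#' @export
surface_excess <- function(slope, temperature = 293, prefactor_n = 1,
                           ln10 = FALSE) {
  stopifnot(is.numeric(slope), temperature > 0, prefactor_n %in% c(1, 2))
  slope_si <- slope * 1e-3                       # mN/m -> N/m per decade
  if (ln10) slope_si <- slope_si / log(10)
  g <- -slope_si / (prefactor_n * .const$R * temperature)
  if (any(g < 0))
    warning("negative surface excess (positive tension slope below the CMC)")
  g
}

#' Area per molecule at the air-water interface
#'
#' `A = 1 / (Gamma NA)`, converted to square Angstrom per molecule.
#'
#' @param gamma_excess Surface excess in mol per square metre (positive).
#' @return Area per molecule in square Angstrom.
#' @examples
#' area_per_molecule(surface_excess(-12.4, 293))
#' @export
area_per_molecule <- function(gamma_excess) {
  if (any(gamma_excess <= 0))
    stop("`gamma_excess` must be positive", call. = FALSE)
  1e20 / (gamma_excess * .const$N_A)
}

#' CMC analysis of a surface-tension or conductivity series
#'
#' Composes the breakpoint fit with the adsorption-isotherm quantities.
#' Surface-tension series are fitted on a log10 concentration abscissa and
#' yield the CMC, the limiting surface tension above it, the surface excess
#' from the pre-CMC slope and the area per molecule. Conductivity series
#' are fitted on a linear abscissa and yield the CMC and the pre/post slope
#' ratio (a degree-of-ionization proxy). Concentrations in wt percent are
#' converted to mol per litre when `m_mol` is given, assuming a dilute
#' solution density of 1 g per cm^3.
#'
#' @param data An [isotherm_series()] or data frame with columns
#'   `concentration` (wt percent) and `value`.
#' @param kind `"tension"` or `"conductivity"`; defaults to the series
#'   attribute when present.
#' @param m_mol Monomer molar mass in g per mol (optional; enables molar
#'   CMC).
#' @param temperature Temperature in kelvin; defaults to the series
#'   attribute or 293.
#' @param prefactor_n,ln10 Conventions passed to [surface_excess()].
#' @param min_improvement Passed to [fit_breakpoint()].
#' @return An object of class `"cmc_analysis"`; see [tidy.cmc_analysis()].
#' @examples
#' analyze_series(simulate_tension(seed = 2), m_mol = 675.4)
#' @export
analyze_series <- function(data, kind = NULL, m_mol = NULL,
                           temperature = NULL, prefactor_n = 1, ln10 = FALSE,
                           min_improvement = 0.05) {
  if (is.null(kind)) kind <- attr(data, "kind")
  if (is.null(kind)) stop("`kind` must be given (\"tension\" or \"conductivity\")",
                          call. = FALSE)
  kind <- match.arg(kind, c("tension", "conductivity"))
  if (is.null(temperature)) temperature <- attr(data, "temperature") %||% 293
  bp <- fit_breakpoint(data,
                       x_transform = if (kind == "tension") "log10" else "linear",
                       min_improvement = min_improvement)
  c_cmc_wt <- bp$breakpoint
  c_cmc_m <- if (!is.null(m_mol) && !is.na(c_cmc_wt)) 10 * c_cmc_wt / m_mol else NA_real_
  gamma0 <- Gamma <- area <- NA_real_
  flags <- character()
  if (!bp$has_breakpoint) flags <- c(flags, "no_breakpoint")
  if (kind == "tension" && bp$has_breakpoint) {
    gamma0 <- bp$value_at_breakpoint
    Gamma <- withCallingHandlers(
      surface_excess(bp$slope_below, temperature, prefactor_n, ln10),
      warning = function(w) {
        flags <<- c(flags, "negative_surface_excess")
        invokeRestart("muffleWarning")
      })
    area <- if (Gamma > 0) area_per_molecule(Gamma) else NA_real_
  }
  structure(list(kind = kind, breakpoint_fit = bp,
                 c_cmc_wt = c_cmc_wt, c_cmc_m = c_cmc_m,
                 gamma0 = gamma0, surface_excess = Gamma, area = area,
                 slope_below = bp$slope_below, slope_above = bp$slope_above,
                 slope_ratio = if (kind == "conductivity" && bp$has_breakpoint)
                   bp$slope_above / bp$slope_below else NA_real_,
                 temperature = temperature, flags = flags,
                 data = bp$data), class = "cmc_analysis")
}

#' @export
print.cmc_analysis <- function(x, ...) {
  cat(sprintf("<CMC analysis (%s series, %d points)>\n", x$kind, nrow(x$data)))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  if (!is.na(x$c_cmc_wt)) {
    cat(sprintf("  CMC: %.4g wt%%", x$c_cmc_wt))
    if (!is.na(x$c_cmc_m)) cat(sprintf(" (%.3g M)", x$c_cmc_m))
    cat("\n")
    if (x$kind == "tension") {
      cat(sprintf("  gamma0: %.3f mN/m | Gamma: %.3g mol/m^2 | A: %.3g A^2\n",
                  x$gamma0, x$surface_excess, x$area))
    } else {
      cat(sprintf("  slopes %.4g -> %.4g (ratio %.3f)\n",
                  x$slope_below, x$slope_above, x$slope_ratio))
    }
  }
  invisible(x)
}
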