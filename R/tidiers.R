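#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' Tidy a SAXS fit
#'
#' One row per model parameter with estimate, standard error (from the
#' local curvature; `NA` for fixed parameters) and bound/fixed flags.
#'
#' @param x A `"saxs_fit"` from [fit_saxs()].
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`, `fixed`,
#'   `at_bound`.
#' @export
tidy.saxs_fit <- function(x, ...) {
  terms <- names(x$estimate)
  tibble::tibble(
    term = terms,
    estimate = unname(x$estimate),
    std.error = unname(x$se[terms]),
    fixed = terms %in% x$fixed,
    at_bound = terms %in% x$at_bound
  )
}

#' Glance at a SAXS fit
#'
#' @param x A `"saxs_fit"`.
#' @param ... Unused.
#' @return A one-row tibble with fit-quality and convergence diagnostics.
#' @export
glance.saxs_fit <- function(x, ...) {
  tibble::tibble(
    redchi2 = x$redchi2, n = x$n_points, dof = x$dof,
    converged = x$converged, include_sq = x$include_sq,
    structure = if (x$include_sq) x$structure else NA_character_,
    niter = x$niter, n_at_bound = length(x$at_bound)
  )
}

#' Augment a SAXS curve with fitted values
#'
#' @param x A `"saxs_fit"`.
#' @param ... Unused.
#' @return The fitted-window portion of the curve with `.fitted`, `.resid`
#'   and weighted `.std.resid` columns.
#' @export
augment.saxs_fit <- function(x, ...) {
  fitted <- model_intensity(x$q_fit, x$form, x$yukawa, x$n_quad)
  keep <- x$curve$q >= x$q_range[1] & x$curve$q <= x$q_range[2]
  out <- tibble::as_tibble(x$curve)[keep, ]
  out$.fitted <- fitted
  out$.resid <- out$intensity - fitted
  out$.std.resid <- out$.resid / x$weights
  out
}

#' Tidy a SAXS series fit
#'
#' @param x A `"saxs_series_fit"` from [fit_saxs_series()].
#' @param ... Unused.
#' @return A tibble with one row per curve and parameter.
#' @export
tidy.saxs_series_fit <- function(x, ...) {
  rows <- purrr::pmap(list(x$sample_id, x$concentration, x$fit),
                      function(id, cc, f) {
                        if (is.null(f)) return(NULL)
                        dplyr::mutate(tidy(f), sample_id = id, concentration = cc,
                                      .before = 1)
                      })
  dplyr::bind_rows(rows)
}

#' Glance at a SAXS series fit
#'
#' @param x A `"saxs_series_fit"`.
#' @param ... Unused.
#' @return One row per curve of fit diagnostics.
#' @export
glance.saxs_series_fit <- function(x, ...) {
  rows <- purrr::pmap(list(x$sample_id, x$concentration, x$fit, x$error),
                      function(id, cc, f, err) {
                        base <- tibble::tibble(sample_id = id, concentration = cc,
                                               error = err)
                        if (is.null(f)) return(base)
                        dplyr::bind_cols(base, glance(f))
                      })
  dplyr::bind_rows(rows)
}

#' Tidy a breakpoint fit
#'
#' @param x A `"breakpoint_fit"` from [fit_breakpoint()].
#' @param ... Unused.
#' @return A one-row tibble of breakpoint location, segment slopes and fit
#'   quality.
#' @export
tidy.breakpoint_fit <- function(x, ...) {
  tibble::tibble(
    breakpoint = x$breakpoint, value_at_breakpoint = x$value_at_breakpoint,
    slope_below = x$slope_below, slope_above = x$slope_above,
    has_breakpoint = x$has_breakpoint,
    sse = x$sse, sse_line = x$sse_line, improvement = x$improvement,
    x_transform = x$x_transform, n = x$n
  )
}

#' @rdname tidy.breakpoint_fit
#' @export
glance.breakpoint_fit <- function(x, ...) tidy(x, ...)

#' Tidy a CMC analysis
#'
#' @param x A `"cmc_analysis"` from [analyze_series()].
#' @param ... Unused.
#' @return A one-row tibble: CMC (wt percent and molar), limiting surface
#'   tension, surface excess, area per molecule, slopes and flags.
#' @export
tidy.cmc_analysis <- function(x, ...) {
  tibble::tibble(
    kind = x$kind, c_cmc_wt = x$c_cmc_wt, c_cmc_m = x$c_cmc_m,
    gamma0 = x$gamma0, surface_excess = x$surface_excess, area = x$area,
    slope_below = x$slope_below, slope_above = x$slope_above,
    slope_ratio = x$slope_ratio,
    flags = paste(x$flags, collapse = ";")
  )
}

#' @rdname tidy.cmc_analysis
#' @export
glance.cmc_analysis <- function(x, ...) {
  dplyr::bind_cols(tidy(x), tibble::tibble(n = nrow(x$data),
                                           temperature = x$temperature))
}
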