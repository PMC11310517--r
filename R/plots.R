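#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a SAXS curve
#'
#' Log-log intensity versus q with error bars where uncertainties are
#' present.
#'
#' @param object A [saxs_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.saxs_curve <- function(object, ...) {
  df <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$q, y = .data$intensity)) +
    ggplot2::geom_point(shape = 1, size = 1) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(q ~ (ring(A)^-1)),
                  y = expression(I(q) ~ (cm^-1)),
                  title = attr(object, "sample_id"))
  if (all(is.finite(df$uncertainty)))
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = pmax(.data$intensity - .data$uncertainty, 1e-12),
                   ymax = .data$intensity + .data$uncertainty),
      linewidth = 0.2, alpha = 0.5)
  p
}

#' Plot a SAXS fit
#'
#' Data points with the fitted model curve overlaid on log-log axes.
#'
#' @param object A `"saxs_fit"` from [fit_saxs()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.saxs_fit <- function(object, ...) {
  aug <- augment(object)
  autoplot(object$curve) +
    ggplot2::geom_line(data = aug,
                       ggplot2::aes(x = .data$q, y = .data$.fitted),
                       colour = "red3") +
    ggplot2::labs(subtitle = sprintf("reduced chi-square %.2f", object$redchi2))
}

#' Plot a fitted concentration series
#'
#' One panel per curve, data plus fits.
#'
#' @param object A `"saxs_series_fit"` from [fit_saxs_series()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.saxs_series_fit <- function(object, ...) {
  dfs <- purrr::map2(object$fit, object$concentration, function(f, cc) {
    if (is.null(f)) return(NULL)
    dplyr::mutate(augment(f), concentration = cc)
  })
  df <- dplyr::bind_rows(dfs)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$q)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$intensity), shape = 1, size = 0.8) +
    ggplot2::geom_line(ggplot2::aes(y = .data$.fitted), colour = "red3") +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~concentration, scales = "free_y",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = expression(q ~ (ring(A)^-1)), y = expression(I(q) ~ (cm^-1)))
}

#' Plot an inter-micellar potential curve
#'
#' @param object A `"potential_curve"` from [pair_potential()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.potential_curve <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$r, y = .data$u_kt)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(r ~ (ring(A))), y = expression(U(r) / k[B] * T))
}

#' Plot a CMC analysis
#'
#' Data with the two fitted segments and the breakpoint marked.
#'
#' @param object A `"cmc_analysis"` from [analyze_series()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cmc_analysis <- function(object, ...) {
  bp <- object$breakpoint_fit
  df <- bp$data
  x <- if (bp$x_transform == "log10") log10(df$concentration) else df$concentration
  xb <- bp$breakpoint_x
  pred <- if (bp$has_breakpoint)
    bp$value_at_breakpoint + bp$slope_below * pmin(x - xb, 0) +
      bp$slope_above * pmax(x - xb, 0)
  else NA_real_
  df$.fitted <- pred
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$concentration,
                                        y = .data$value)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "concentration (wt%)",
                  y = if (object$kind == "tension")
                    expression(gamma ~ (mN ~ m^-1))
                  else expression(kappa[cond] ~ (mu * S ~ cm^-1)))
  if (bp$x_transform == "log10") p <- p + ggplot2::scale_x_log10()
  if (bp$has_breakpoint)
    p <- p + ggplot2::geom_line(ggplot2::aes(y = .data$.fitted), colour = "red3") +
      ggplot2::geom_vline(xintercept = object$c_cmc_wt, linetype = 2)
  p
}
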