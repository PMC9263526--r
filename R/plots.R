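#' Plot an uptake experiment
#'
#' Bulk-concentration ratio against time; the characteristic finite-bath
#' curve falls from 1 towards \eqn{\alpha/(1+\alpha)}.
#'
#' @param object An [uptake_experiment()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.uptake_experiment <- function(object, ...) {
  d <- dplyr::mutate(object$data, ratio = .data$conc_mg_L / object$C_0)
  ggplot2::ggplot(d, ggplot2::aes(.data$time_s, .data$ratio)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = equilibrium_ratio(object$system$alpha),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "time (s)", y = expression(C[B](t) / C[0]),
                  title = object$label) +
    ggplot2::theme_minimal()
}

#' Plot a diffusion fit over its data
#'
#' @param object A [fit_diffusion()] result.
#' @param n_curve Number of points of the fitted curve.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.diffusion_fit <- function(object, n_curve = 200, ...) {
  exp <- object$experiment
  tmax <- max(exp$data$time_s)
  curve <- tibble::tibble(
    time_s = seq(0, tmax, length.out = n_curve),
    ratio = bulk_concentration_ratio(seq(0, tmax, length.out = n_curve),
                                     object$D_e, exp$system))
  autoplot(exp) +
    ggplot2::geom_line(data = curve,
                       ggplot2::aes(.data$time_s, .data$ratio),
                       colour = "#d95f02") +
    ggplot2::labs(subtitle = sprintf("D_e = %.2e m^2/s", object$D_e))
}

#' Plot a molecular-weight scaling law
#'
#' Fitted points (when the law was fitted from data) and the power-law line
#' on log-log axes, optionally with a comparison law.
#'
#' @param object A [scaling_fit()].
#' @param reference Optional second [scaling_fit()] drawn for comparison.
#' @param mw_range Molecular-weight range of the drawn lines, Da.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.scaling_fit <- function(object, reference = NULL,
                                 mw_range = c(62, 4000), ...) {
  grid <- tibble::tibble(
    mw_da = 10^seq(log10(mw_range[1]), log10(mw_range[2]), length.out = 50))
  lines <- dplyr::mutate(grid, D_m2_s = predict_diffusivity(.data$mw_da, object),
                         law = object$label %||% "fitted")
  if (!is.null(reference)) {
    lines <- dplyr::bind_rows(
      lines,
      dplyr::mutate(grid,
                    D_m2_s = predict_diffusivity(.data$mw_da, reference),
                    law = reference$label %||% "reference"))
  }
  p <- ggplot2::ggplot(lines,
                       ggplot2::aes(.data$mw_da, .data$D_m2_s,
                                    colour = .data$law)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "molecular weight (Da)", y = expression(D~(m^2/s))) +
    ggplot2::theme_minimal()
  if (!is.null(object$data)) {
    p <- p + ggplot2::geom_point(data = object$data, inherit.aes = FALSE,
                                 ggplot2::aes(.data$mw_da, .data$D_m2_s))
  }
  p
}

#' Plot a penetration table
#'
#' Relative core concentration after the contact time against molecular
#' weight (log axis), as produced by [assess_penetration()].
#'
#' @param table The [assess_penetration()] tibble.
#' @return A ggplot.
#' @export
plot_penetration <- function(table) {
  ggplot2::ggplot(table, ggplot2::aes(.data$mw_da, .data$core_pct)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "molecular weight (Da)",
                  y = expression(C / C[b] ~ "(%)")) +
    ggplot2::theme_minimal()
}
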