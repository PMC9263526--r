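#' Construct a molecular-weight scaling law from known coefficients
#'
#' A scaling fit records the power law \eqn{\log_{10} D = a \log_{10} MW + b}
#' together with the standard errors of slope and intercept. Use this
#' constructor to enter a law whose coefficients are reported in the
#' literature (raw data unavailable); laws fitted from data come from
#' [fit_loglog()].
#'
#' @param slope,intercept Coefficients of the base-10 log-log law; `intercept`
#'   is \eqn{\log_{10}} of a diffusivity in m^2/s.
#' @param se_slope,se_intercept Standard errors (> 0).
#' @param n Number of (MW, D) points behind the law (\eqn{\ge 3}).
#' @param temperature_K Temperature the law refers to (default 25 C).
#' @param label Optional label.
#'
#' @return An object of class `scaling_fit`.
#' @examples
#' scaling_fit(-0.597, -7.951, 0.020, 0.077, n = 11, label = "water")
#' @export
scaling_fit <- function(slope, intercept, se_slope, se_intercept, n,
                        temperature_K = 298.15, label = NULL) {
  stopifnot(se_slope > 0, se_intercept > 0, n >= 3, temperature_K > 0)
  structure(
    list(slope = slope, intercept = intercept,
         se_slope = se_slope, se_intercept = se_intercept,
         n = as.integer(n), temperature_K = temperature_K, label = label,
         data = NULL),
    class = "scaling_fit")
}

#' Reference scaling law for PEG diffusion in water
#'
#' The literature log-log law for polyethylene-glycol diffusivity in water at
#' 25 degrees C: slope \eqn{-0.597 \pm 0.020}, intercept
#' \eqn{-7.951 \pm 0.077} (base-10, D in m^2/s), n = 11 molecular weights.
#' Used as the comparison baseline for granule-derived laws.
#'
#' @return A [scaling_fit()].
#' @examples
#' predict_diffusivity(1000, water_reference_law())
#' @export
water_reference_law <- function() {
  scaling_fit(-0.597, -7.951, 0.020, 0.077, n = 11, label = "water")
}

#' Fit a log-log diffusivity vs molecular-weight law
#'
#' Ordinary least squares of \eqn{\log_{10} D} on \eqn{\log_{10} MW}
#' (base 10 throughout). Standard errors come from the usual OLS variance
#' formulas via [stats::lm()].
#'
#' @param data A data frame with columns `mw_da` (molecular weight, Da) and
#'   `D_m2_s` (diffusivity, m^2/s); one row per solute. At least 3 rows with
#'   non-identical molecular weights.
#' @param temperature_K Temperature the diffusivities refer to.
#' @param label Optional label.
#'
#' @return A `scaling_fit` with the input data attached.
#' @examples
#' d <- tibble::tibble(mw_da = c(62, 200, 1000, 4000),
#'                     D_m2_s = 10^(-8.07 - 0.564 * log10(mw_da)))
#' fit_loglog(d)
#' @export
fit_loglog <- function(data, temperature_K = 298.15, label = NULL) {
  stopifnot(is.data.frame(data))
  missing_cols <- setdiff(c("mw_da", "D_m2_s"), names(data))
  if (length(missing_cols)) {
    abort(sprintf("scaling data is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "granulediff_input_error")
  }
  if (nrow(data) < 3) {
    abort("at least 3 (MW, D) points are required",
          class = "granulediff_input_error")
  }
  stopifnot(all(data$mw_da > 0), all(data$D_m2_s > 0))
  if (length(unique(data$mw_da)) < 2) {
    abort("all molecular weights identical: no leverage for a slope",
          class = "granulediff_input_error")
  }
  m <- lm(log10(D_m2_s) ~ log10(mw_da), data = data)
  cf <- summary(m)$coefficients
  out <- scaling_fit(slope = cf[2, 1], intercept = cf[1, 1],
                     se_slope = cf[2, 2], se_intercept = cf[1, 2],
                     n = nrow(data), temperature_K = temperature_K,
                     label = label)
  out$data <- tibble::as_tibble(data[, c("mw_da", "D_m2_s")])
  out
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf(
    "<scaling_fit>%s log10 D = %.3f (+/- %.3f) * log10 MW + %.3f (+/- %.3f), n = %d\n",
    if (!is.null(x$label)) paste0(" [", x$label, "]") else "",
    x$slope, x$se_slope, x$intercept, x$se_intercept, x$n))
  invisible(x)
}

#' Predict a diffusivity from a scaling law
#'
#' Evaluates \eqn{D = 10^{b + a \log_{10} MW}} at the law's temperature.
#'
#' @param mw_da Molecular weight(s), Da (vectorised, > 0).
#' @param fit A [scaling_fit()].
#' @return Diffusivity(ies) in m^2/s.
#' @examples
#' predict_diffusivity(1000, scaling_fit(-0.564, -8.070, 0.044, 0.126, 11))
#' @export
predict_diffusivity <- function(mw_da, fit) {
  stopifnot(all(mw_da > 0), inherits(fit, "scaling_fit"))
  10^(fit$intercept + fit$slope * log10(mw_da))
}

#' Compare two scaling laws by t-tests on slope and intercept
#'
#' Two-independent-regressions comparison: for each coefficient,
#' \deqn{t = \frac{|a_1 - a_2|}{\sqrt{SE_{a_1}^2 + SE_{a_2}^2}},}
#' with \eqn{df = n_1 + n_2 - 4} degrees of freedom (two slopes and two
#' intercepts estimated) and two-sided p-values from Student's t. The printed
#' standard errors are used directly, with no pooled residual variance, so
#' laws known only through published coefficients can be compared.
#'
#' @param fa,fb Two [scaling_fit()] objects. The comparison is symmetric.
#' @return A one-row tibble of class `regression_comparison` with
#'   `t_slope`, `t_intercept`, `df`, `p_slope`, `p_intercept`.
#' @examples
#' granule <- scaling_fit(-0.564, -8.070, 0.044, 0.126, 11, label = "granule")
#' compare_fits(granule, water_reference_law())
#' @export
compare_fits <- function(fa, fb) {
  stopifnot(inherits(fa, "scaling_fit"), inherits(fb, "scaling_fit"))
  df <- fa$n + fb$n - 4L
  t_slope <- abs(fa$slope - fb$slope) /
    sqrt(fa$se_slope^2 + fb$se_slope^2)
  t_intercept <- abs(fa$intercept - fb$intercept) /
    sqrt(fa$se_intercept^2 + fb$se_intercept^2)
  out <- tibble::tibble(
    t_slope = t_slope,
    t_intercept = t_intercept,
    df = df,
    p_slope = 2 * pt(-t_slope, df),
    p_intercept = 2 * pt(-t_intercept, df))
  class(out) <- c("regression_comparison", class(out))
  out
}

#' @describeIn fit_loglog Broom-style coefficient table.
#' @param x A `scaling_fit`.
#' @param ... Unused.
#' @export
tidy.scaling_fit <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope),
    std.error = c(x$se_intercept, x$se_slope))
}

#' @describeIn fit_loglog Broom-style one-row summary.
#' @export
glance.scaling_fit <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 se_slope = x$se_slope, se_intercept = x$se_intercept,
                 n = x$n, temperature_K = x$temperature_K)
}
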