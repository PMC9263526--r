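#' Describe the geometry of a finite-bath uptake experiment
#'
#' A granule system bundles the quantities that fix the shape of the uptake
#' curve: the (mean) granule radius, the total granule volume, the liquid
#' volume, their ratio \eqn{\alpha = V_W / V_G}, and the experiment
#' temperature. All granules are treated as identical spheres of the mean
#' radius, which mirrors how such experiments are analysed: the size
#' distribution only enters the Monte-Carlo uncertainty analysis.
#'
#' @param radius_m Mean granule radius in metres.
#' @param granule_volume_L Total granule volume \eqn{V_G} in litres.
#' @param liquid_volume_L Liquid (water) volume \eqn{V_W} in litres.
#' @param temperature_C Experiment temperature in degrees Celsius.
#'
#' @return A list of class `granule_system` with fields `radius_m`,
#'   `granule_volume_L`, `liquid_volume_L`, `alpha`, `temperature_K`.
#'
#' @examples
#' granule_system(1.1e-3, granule_volume_L = 0.06, liquid_volume_L = 0.24,
#'                temperature_C = 4)
#' @export
granule_system <- function(radius_m, granule_volume_L, liquid_volume_L,
                           temperature_C = 4) {
  stopifnot(radius_m > 0, granule_volume_L > 0, liquid_volume_L > 0,
            temperature_C > -273.15)
  structure(
    list(radius_m = radius_m,
         granule_volume_L = granule_volume_L,
         liquid_volume_L = liquid_volume_L,
         alpha = liquid_volume_L / granule_volume_L,
         temperature_K = temperature_C + 273.15),
    class = "granule_system")
}

#' @export
print.granule_system <- function(x, ...) {
  cat(sprintf(
    "<granule_system> R = %.3g mm, V_G = %.3g L, V_W = %.3g L, alpha = %.3g, T = %.1f K\n",
    x$radius_m * 1e3, x$granule_volume_L, x$liquid_volume_L, x$alpha,
    x$temperature_K))
  invisible(x)
}

#' Equilibrium bulk-concentration ratio of a finite bath
#'
#' When the whole granule volume is accessible and the solute partitions 1:1
#' between bulk liquid and granule water, the bulk concentration relaxes to
#' \eqn{C_{eq}/C_0 = \alpha / (1 + \alpha)}.
#'
#' @param alpha Liquid-to-granule volume ratio (> 0).
#' @return The dimensionless equilibrium ratio.
#' @examples
#' equilibrium_ratio(4)  # 0.8
#' @export
equilibrium_ratio <- function(alpha) {
  stopifnot(alpha > 0)
  alpha / (1 + alpha)
}

#' Bulk-liquid concentration during finite-bath uptake
#'
#' Evaluates the analytical series for the decline of the bulk-liquid
#' concentration when a non-reactive solute diffuses from a well-mixed finite
#' volume into a population of identical, initially solute-free spheres:
#' \deqn{\frac{C_B(t)}{C_B(t_0)} = \frac{1}{1+\alpha}\left(\alpha +
#'   \sum_{n=1}^{\infty} \frac{6\alpha(1+\alpha)\,
#'   e^{-D q_n^2 t / R^2}}{9 + 9\alpha + q_n^2 \alpha^2}\right),}
#' with \eqn{q_n} the eigenvalues from [compute_roots()]. The series is
#' truncated once a term's magnitude drops below `series_tol` (evaluated at
#' the smallest positive `t` requested) or `max_terms` is reached; at exactly
#' `t = 0` the value 1 is returned analytically because the series converges
#' only slowly there.
#'
#' @param t Time(s) since the start of the experiment, seconds (vectorised).
#' @param D Effective diffusion coefficient, m^2/s.
#' @param system A [granule_system()].
#' @param series_tol Truncation tolerance on the magnitude of a series term.
#' @param max_terms Maximum number of eigenvalue terms.
#'
#' @return Numeric vector of \eqn{C_B(t)/C_B(t_0)}, each value in
#'   \eqn{[\alpha/(1+\alpha),\, 1]}. Warns when `max_terms` is reached with an
#'   unresolved tail.
#'
#' @examples
#' sys <- granule_system(1.1e-3, 0.06, 0.24)
#' bulk_concentration_ratio(c(0, 600, 1800, 21600), 1e-10, sys)
#' @export
bulk_concentration_ratio <- function(t, D, system, series_tol = 1e-10,
                                     max_terms = 200) {
  stopifnot(all(t >= 0), D > 0, inherits(system, "granule_system"))
  alpha <- system$alpha
  R <- system$radius_m
  qs <- root_values(alpha, max_terms)
  coefs <- 6 * alpha * (1 + alpha) / (9 + 9 * alpha + qs^2 * alpha^2)
  out <- numeric(length(t))
  out[t == 0] <- 1
  pos <- which(t > 0)
  if (length(pos)) {
    tp <- t[pos]
    rate <- D / R^2
    # terms decay monotonically in n at fixed t; truncate on the slowest-
    # decaying (smallest) positive time
    tmin <- min(tp)
    keep <- which(coefs * exp(-rate * qs^2 * tmin) >= series_tol)
    n_used <- if (length(keep)) max(keep) else 1L
    if (n_used == max_terms &&
        coefs[max_terms] * exp(-rate * qs[max_terms]^2 * tmin) >= series_tol) {
      # tail bound: sum_{n>N} c_n <= c_N * sum 1/n^2 comparison via integral
      tail_bound <- coefs[max_terms] * exp(-rate * qs[max_terms]^2 * tmin) *
        max_terms
      warn(sprintf(
        "uptake series truncated at max_terms = %d before reaching tol %.1e (tail bound %.2e)",
        max_terms, series_tol, tail_bound))
    }
    q_use <- qs[seq_len(n_used)]
    c_use <- coefs[seq_len(n_used)]
    ex <- exp(-outer(q_use^2, rate * tp))        # n_used x length(tp)
    s <- as.vector(crossprod(ex, c_use))   # coefs already carry 6a(1+a)/denom
    out[pos] <- (alpha + s) / (1 + alpha)
  }
  pmin(pmax(out, alpha / (1 + alpha)), 1)
}

#' Solute concentration in the granule core (infinite bath)
#'
#' Evaluates the centre concentration of a sphere exposed to a constant bulk
#' concentration \eqn{C_b}:
#' \deqn{\frac{C}{C_b} = 1 + 2 \sum_{n=1}^{\infty} (-1)^n
#'   e^{-D n^2 \pi^2 t / R^2}.}
#' Used to judge how deeply a solute of a given diffusivity penetrates a
#' granule within a fixed contact time (for example an anaerobic feeding
#' period). At `t = 0` the value 0 is returned analytically; tiny negative
#' round-off is clamped to 0.
#'
#' @param t Time(s), seconds (vectorised).
#' @param D Diffusion coefficient, m^2/s.
#' @param R Sphere radius, m.
#' @param series_tol Truncation tolerance on a term's magnitude.
#' @param max_terms Maximum number of terms.
#'
#' @return Numeric vector of \eqn{C/C_b} values in \eqn{[0, 1]}. For
#'   dimensionless times \eqn{D t / R^2 < 10^{-4}} the alternating series
#'   converges very slowly; a warning reports the alternating-tail bound when
#'   it exceeds `series_tol`.
#'
#' @examples
#' core_concentration_ratio(3600, 1.1e-10, 1e-3)  # ~0.96
#' @export
core_concentration_ratio <- function(t, D, R, series_tol = 1e-10,
                                     max_terms = 500) {
  stopifnot(all(t >= 0), D > 0, R > 0)
  out <- numeric(length(t))
  pos <- which(t > 0)
  if (length(pos)) {
    tau <- D * t[pos] / R^2
    n <- seq_len(max_terms)
    ex <- exp(-outer(n^2 * pi^2, tau))           # max_terms x length(tau)
    signs <- (-1)^n
    vals <- 1 + 2 * as.vector(crossprod(ex, signs))
    # alternating series: truncation error bounded by first omitted term
    tail_bound <- 2 * exp(-(max_terms + 1)^2 * pi^2 * min(tau))
    if (tail_bound > series_tol) {
      warn(sprintf(
        "core-penetration series truncated at %d terms; alternating tail bound %.2e exceeds tol %.1e (smallest D*t/R^2 = %.2e)",
        max_terms, tail_bound, series_tol, min(tau)))
    }
    out[pos] <- vals
  }
  pmin(pmax(out, 0), 1)
}

#' Accessible granule volume fraction from an equilibrium mass balance
#'
#' When the measured equilibrium concentration lies above the full-access
#' expectation \eqn{\alpha/(1+\alpha) \cdot C_0}, part of the granule volume
#' is inaccessible to the solute (size exclusion). The accessible fraction
#' follows from the closed mass balance
#' \eqn{C_{eq}(f\,V_G + V_W) = C_0 V_W}, i.e.
#' \deqn{f = \left(\frac{C_0}{C_{eq}} - 1\right) \frac{V_W}{V_G}.}
#'
#' @param C_0 Initial bulk concentration, mg/L.
#' @param C_eq Measured equilibrium bulk concentration, mg/L (must not exceed
#'   `C_0`: an equilibrium above the start would mean apparent production).
#' @param V_G Granule volume (any volume unit, same as `V_W`).
#' @param V_W Liquid volume.
#'
#' @return A one-row tibble with `f_accessible`, `C_0`, `C_eq` and a logical
#'   `flagged` that is `TRUE` when the computed fraction falls outside
#'   \eqn{[0, 1]} (pathological inputs).
#'
#' @examples
#' # alpha = 4, only 65% of the granule volume accessible:
#' accessible_fraction(1000, 1000 * 4 / 4.65, V_G = 0.06, V_W = 0.24)
#' @export
accessible_fraction <- function(C_0, C_eq, V_G, V_W) {
  stopifnot(C_0 > 0, C_eq > 0, V_G > 0, V_W > 0)
  if (C_eq > C_0) {
    abort("C_eq exceeds C_0: apparent production of solute; check inputs")
  }
  f <- (C_0 / C_eq - 1) * V_W / V_G
  tibble::tibble(f_accessible = f, C_0 = C_0, C_eq = C_eq,
                 flagged = f < 0 | f > 1)
}

#' Dynamic viscosity of liquid water
#'
#' Kestin-type correlation for 0-40 degrees C, anchored at
#' \eqn{\mu(20^\circ C) = 1.002\times 10^{-3}} Pa s:
#' \deqn{\log_{10}\frac{\mu(T)}{\mu(20)} = \frac{20 - T_C}{T_C + 96}
#'   \left(1.2364 - 1.37\times10^{-3}(20 - T_C) +
#'   5.7\times10^{-6}(20 - T_C)^2\right).}
#' Reproduces the standard tabulated values (1.5673, 1.3059, 1.0016, 0.8900
#' mPa s at 4, 10, 20, 25 degrees C) to better than 0.1%.
#'
#' @param temperature_K Absolute temperature(s), K (vectorised).
#' @return Dynamic viscosity in Pa s.
#' @examples
#' water_viscosity(298.15)  # ~8.90e-4
#' @export
water_viscosity <- function(temperature_K) {
  stopifnot(all(temperature_K > 0))
  tc <- temperature_K - 273.15
  d <- 20 - tc
  1.002e-3 * 10^((d / (tc + 96)) * (1.2364 - 1.37e-3 * d + 5.7e-6 * d^2))
}

#' Convert a diffusion coefficient between temperatures
#'
#' Applies the Stokes-Einstein proportionality \eqn{D \mu / T = const}:
#' \deqn{D_{to} = D_{from} \cdot \frac{T_{to}}{T_{from}} \cdot
#'   \frac{\mu_{from}}{\mu_{to}}.}
#' Viscosities default to [water_viscosity()] at the two temperatures but can
#' be overridden with measured values.
#'
#' @param D Diffusion coefficient(s) at `T_from`, m^2/s.
#' @param T_from,T_to Absolute temperatures, K.
#' @param mu_from,mu_to Dynamic viscosities of water at the two temperatures,
#'   Pa s; default from [water_viscosity()].
#'
#' @return Diffusion coefficient(s) at `T_to`, m^2/s. The quantity
#'   \eqn{D\mu/T} is preserved exactly, so the conversion round-trips.
#'
#' @examples
#' convert_diffusivity_temperature(1e-10, T_from = 277.15, T_to = 298.15)
#' @export
convert_diffusivity_temperature <- function(D, T_from, T_to,
                                            mu_from = water_viscosity(T_from),
                                            mu_to = water_viscosity(T_to)) {
  stopifnot(all(D > 0), T_from > 0, T_to > 0, mu_from > 0, mu_to > 0)
  D * (T_to / T_from) * (mu_from / mu_to)
}
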