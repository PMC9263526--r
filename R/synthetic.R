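#' Specify a synthetic transient-uptake experiment
#'
#' Ground-truth description of a finite-bath uptake experiment, mirroring the
#' canonical bench design: 25 bulk samples of 0.5 mL from a 300 mL working
#' volume, a liquid-to-granule volume ratio of about 4, temperature 4 C, and
#' an initial solute concentration around 1000 mg/L. Samples are placed on a
#' geometric (dense-early) schedule because the uptake curve is steepest at
#' the start; measurement noise is multiplicative Gaussian, matching the
#' roughly constant relative error of refractive-index detection.
#'
#' @param D_true True effective diffusivity, m^2/s.
#' @param radius_m Granule radius, m.
#' @param total_volume_L Total working volume (liquid + granules), L.
#' @param alpha Liquid-to-granule volume ratio.
#' @param C_0 Initial bulk concentration, mg/L (the dosed mass follows as
#'   `C_0 * liquid_volume`).
#' @param temperature_C Experiment temperature, C.
#' @param mw_da Solute molecular weight, Da (metadata only).
#' @param n_samples Number of bulk samples (>= 5).
#' @param t_min_s,t_max_s First and last sampling time, s.
#' @param noise_cv Coefficient of variation of the multiplicative Gaussian
#'   measurement noise.
#' @param sample_volume_L Volume removed per sample, L.
#' @param replacement_mode `"none"` (ideal curve) or `"expected_final"`
#'   (each sample volume is replaced by solution at the expected equilibrium
#'   concentration and the perturbation is simulated numerically).
#' @param f_accessible Accessible fraction of the granule volume; values
#'   below 1 emulate size-excluded solutes by raising the effective
#'   volume ratio to `alpha / f_accessible`.
#' @param seed Integer seed making the generated experiment reproducible.
#' @param label Optional solute label.
#'
#' @return A list of class `synthetic_spec`.
#' @examples
#' synthetic_spec(D_true = 3e-10, seed = 1)
#' @export
synthetic_spec <- function(D_true, radius_m = 1.1e-3, total_volume_L = 0.3,
                           alpha = 4, C_0 = 1000, temperature_C = 4,
                           mw_da = NA_real_, n_samples = 25, t_min_s = 30,
                           t_max_s = 21600, noise_cv = 0.02,
                           sample_volume_L = 5e-4,
                           replacement_mode = c("none", "expected_final"),
                           f_accessible = 1, seed = NULL, label = NULL) {
  replacement_mode <- match.arg(replacement_mode)
  stopifnot(D_true > 0, radius_m > 0, total_volume_L > 0, alpha > 0,
            C_0 > 0, n_samples >= 5, t_min_s > 0, t_max_s > t_min_s,
            noise_cv >= 0, sample_volume_L > 0,
            f_accessible > 0, f_accessible <= 1)
  structure(
    list(D_true = D_true, radius_m = radius_m,
         total_volume_L = total_volume_L, alpha = alpha, C_0 = C_0,
         temperature_C = temperature_C, mw_da = mw_da,
         n_samples = as.integer(n_samples), t_min_s = t_min_s,
         t_max_s = t_max_s, noise_cv = noise_cv,
         sample_volume_L = sample_volume_L,
         replacement_mode = replacement_mode,
         f_accessible = f_accessible, seed = seed, label = label),
    class = "synthetic_spec")
}

sampling_schedule <- function(spec) {
  n <- spec$n_samples
  spec$t_min_s * (spec$t_max_s / spec$t_min_s)^((seq_len(n) - 1) / (n - 1))
}

#' Generate a synthetic uptake experiment with known truth
#'
#' Evaluates the finite-bath forward model at the spec's sampling schedule,
#' applies multiplicative Gaussian measurement noise, and (optionally)
#' simulates the sampling-replacement perturbation numerically: at each
#' sampling time the sample volume is removed and replaced by solution at
#' the expected final concentration, and diffusion continues from the
#' perturbed bulk state via the finite-volume oracle. A spec with
#' `f_accessible < 1` generates the curve of a partially excluded solute
#' (effective volume ratio `alpha / f_accessible`). Deterministic under the
#' spec's seed.
#'
#' @param spec A [synthetic_spec()].
#' @param n_radial Radial cells for the numerical path (only used when
#'   `replacement_mode = "expected_final"`).
#'
#' @return An [uptake_experiment()] whose true parameters are attached in
#'   attribute `"truth"`.
#' @examples
#' exp <- generate_experiment(synthetic_spec(D_true = 3e-10, seed = 7))
#' attr(exp, "truth")$D_true
#' @export
generate_experiment <- function(spec, n_radial = 100) {
  stopifnot(inherits(spec, "synthetic_spec"))
  V_G <- spec$total_volume_L / (1 + spec$alpha)
  V_W <- spec$total_volume_L - V_G
  times <- sampling_schedule(spec)
  alpha_eff <- spec$alpha / spec$f_accessible
  if (spec$replacement_mode == "none") {
    sys_eff <- granule_system(spec$radius_m,
                              granule_volume_L = V_W / alpha_eff,
                              liquid_volume_L = V_W,
                              temperature_C = spec$temperature_C)
    ratio <- bulk_concentration_ratio(times, spec$D_true, sys_eff)
    conc <- spec$C_0 * ratio
  } else {
    conc <- simulate_sampled_uptake(spec, times, alpha_eff, n_radial)
  }
  conc <- with_seed_(spec$seed,
                     conc * (1 + rnorm(length(conc), sd = spec$noise_cv)))
  conc <- pmax(conc, 1e-6 * spec$C_0)
  sys <- granule_system(spec$radius_m, granule_volume_L = V_G,
                        liquid_volume_L = V_W,
                        temperature_C = spec$temperature_C)
  out <- uptake_experiment(
    tibble::tibble(time_s = times, conc_mg_L = conc), sys,
    solute_mass_mg = spec$C_0 * V_W, mw_da = spec$mw_da, label = spec$label)
  attr(out, "truth") <- spec
  out
}

# piecewise numerical simulation of the sampling-replacement protocol: the
# bulk state is perturbed at every sampling instant, so the analytic series
# (which assumes an undisturbed bath) no longer applies exactly
simulate_sampled_uptake <- function(spec, times, alpha_eff, n_radial) {
  V_W <- spec$total_volume_L * spec$alpha / (1 + spec$alpha)
  C_exp <- spec$C_0 * equilibrium_ratio(spec$alpha)
  state <- list(C = rep(0, n_radial), C_b = spec$C_0)
  t_prev <- 0
  conc <- numeric(length(times))
  for (i in seq_along(times)) {
    sol <- simulate_uptake_numeric(
      spec$D_true, spec$radius_m, alpha_eff, state$C_b,
      t_grid = c(0, times[i] - t_prev), n_radial = n_radial,
      C_init = state$C)
    conc[i] <- tail(sol$bulk, 1)
    state$C <- sol$concentration[nrow(sol$concentration), ]
    # sample removed (no concentration change; bath well mixed), replaced
    # by an equal volume at the expected final concentration
    state$C_b <- (conc[i] * (V_W - spec$sample_volume_L) +
                    C_exp * spec$sample_volume_L) / V_W
    t_prev <- times[i]
  }
  conc
}

#' Finite-volume oracle for finite-bath sphere diffusion
#'
#' Independent numerical solution of
#' \eqn{\partial C/\partial t = D (\partial^2 C/\partial r^2 +
#' (2/r)\,\partial C/\partial r)} in a sphere, symmetric at the centre and
#' coupled at \eqn{r = R} to a well-mixed finite bath through the solute
#' mass balance. The sphere is discretised in conservative finite-volume
#' form (the flux leaving the bath is exactly the flux entering the outer
#' shell), so total mass is conserved to the ODE solver tolerance; time
#' integration uses [deSolve::ode()] (lsoda). This is the verification
#' oracle for the analytical series, not a substitute for it.
#'
#' @param D Diffusivity, m^2/s.
#' @param R Sphere radius, m.
#' @param alpha Liquid-to-granule volume ratio (use a very large value for
#'   an effectively infinite bath).
#' @param C_0 Initial bulk concentration, mg/L.
#' @param t_grid Output times, s (first entry may be 0).
#' @param n_radial Number of radial cells (>= 50).
#' @param C_init Optional initial in-sphere concentration profile
#'   (length `n_radial`, cell averages; default solute-free).
#' @param rtol,atol Solver tolerances.
#'
#' @return A list of class `oracle_solution`: `r` (cell centres), `times`,
#'   `concentration` (time x radial matrix), `bulk` (bulk trace),
#'   `center` (parabolic extrapolation of the centre concentration) and
#'   `mass` (total solute per unit granule volume, for conservation checks).
#' @examples
#' sol <- simulate_uptake_numeric(1e-10, 1.1e-3, 4, 1000,
#'                                t_grid = c(0, 900, 1800), n_radial = 60)
#' sol$bulk
#' @export
simulate_uptake_numeric <- function(D, R, alpha, C_0, t_grid, n_radial = 100,
                                    C_init = NULL, rtol = 1e-10,
                                    atol = 1e-10) {
  stopifnot(D > 0, R > 0, alpha > 0, C_0 > 0, n_radial >= 50,
            all(diff(t_grid) > 0), t_grid[1] >= 0)
  N <- as.integer(n_radial)
  dr <- R / N
  r_face <- (1:N) * dr                     # outer face of each cell
  r_cent <- ((1:N) - 0.5) * dr
  v <- (r_face^3 - c(0, head(r_face, -1))^3) / R^3   # volume fractions
  a <- 3 * r_face^2 / R^3                  # face area per granule volume
  a_in <- c(0, head(a, -1))
  rhs <- function(t, y, parms) {
    C <- y[1:N]
    C_b <- y[N + 1]
    flux_in <- c(0, D * (C[-1] - C[-N]) / dr)      # across inner faces
    flux_out <- c(D * (C[-1] - C[-N]) / dr,
                  D * (C_b - C[N]) / (dr / 2))     # across outer faces
    dC <- (a * flux_out - a_in * flux_in) / v
    dC_b <- -(1 / alpha) * a[N] * flux_out[N]
    list(c(dC, dC_b))
  }
  y0 <- c(if (is.null(C_init)) rep(0, N) else C_init, C_0)
  t_solve <- if (t_grid[1] == 0) t_grid else c(0, t_grid)
  sol <- deSolve::ode(y0, t_solve, rhs, parms = NULL, method = "lsoda",
                      rtol = rtol, atol = atol * C_0)
  if (attr(sol, "istate")[1] < 0) {
    abort("PDE oracle integration failed (lsoda did not complete)")
  }
  keep <- match(t_grid, t_solve)
  conc <- sol[keep, 1 + (1:N), drop = FALSE]
  bulk <- sol[keep, N + 2]
  mass <- as.vector(conc %*% v) + alpha * bulk
  structure(
    list(r = r_cent, times = t_grid, concentration = unname(conc),
         bulk = unname(bulk),
         center = unname((9 * conc[, 1] - conc[, 2]) / 8),
         mass = unname(mass)),
    class = "oracle_solution")
}

#' Draw a synthetic COD fractionation table
#'
#' Generates one plant row from a profile of means and standard deviations,
#' for exercising the fraction-summary bookkeeping including its closure
#' warning. Concentrations are drawn from truncated-at-zero Gaussians; a
#' drawn soluble COD exceeding the drawn total is clamped to the total and
#' flagged.
#'
#' @param profile A data frame with columns `field`, `mean`, `sd` covering at
#'   least `total_cod`, `soluble_cod` and the four ultrafiltration classes;
#'   see [cod_profile()] for profiles built from the shipped influent table.
#' @param plant Plant name for the generated row.
#' @param seed Integer seed.
#'
#' @return A one-row tibble in [read_cod_table()] layout with a logical
#'   column `clamped`.
#' @examples
#' generate_cod_table(cod_profile("Utrecht"), seed = 1)
#' @export
generate_cod_table <- function(profile, plant = "synthetic", seed = NULL) {
  stopifnot(is.data.frame(profile),
            all(c("field", "mean", "sd") %in% names(profile)))
  need <- c("total_cod", "soluble_cod", cod_class_cols)
  missing_f <- setdiff(need, profile$field)
  if (length(missing_f)) {
    abort(sprintf("profile is missing field(s): %s",
                  paste(missing_f, collapse = ", ")),
          class = "granulediff_input_error")
  }
  draws <- with_seed_(seed, {
    v <- rnorm(nrow(profile), profile$mean, profile$sd)
    pmax(v, 0)
  })
  names(draws) <- profile$field
  clamped <- FALSE
  if (draws["soluble_cod"] > draws["total_cod"]) {
    draws["soluble_cod"] <- draws["total_cod"]
    clamped <- TRUE
  }
  out <- tibble::as_tibble(as.list(draws))
  dplyr::bind_cols(tibble::tibble(plant = plant), out,
                   tibble::tibble(clamped = clamped))
}

#' Mean/SD profile of one plant from the shipped influent table
#'
#' @param plant Plant name present in [influent_cod_fractions()].
#' @return A tibble with columns `field`, `mean`, `sd` suitable for
#'   [generate_cod_table()].
#' @examples
#' cod_profile("Bath")
#' @export
cod_profile <- function(plant) {
  d <- influent_cod_fractions()
  row <- d[d$plant == plant, , drop = FALSE]
  if (nrow(row) != 1) {
    abort(sprintf("unknown plant '%s'", plant),
          class = "granulediff_input_error")
  }
  fields <- c("total_cod", "soluble_cod", cod_class_cols, "vfa_cod")
  tibble::tibble(
    field = fields,
    mean = vapply(fields, function(f) row[[f]], numeric(1)),
    sd = vapply(fields, function(f) row[[paste0(f, "_sd")]] %||% 0,
                numeric(1)))
}
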