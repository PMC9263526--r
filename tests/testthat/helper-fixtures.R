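# shared fixtures: the canonical bench design (alpha ~ 4, 300 mL, 25 x 0.5 mL
# samples at 4 C) with a known true diffusivity
default_system <- function() granule_system(1.1e-3, 0.06, 0.24, 4)

quick_spec <- function(D_true = 3e-10, noise_cv = 0, seed = 1, ...) {
  synthetic_spec(D_true = D_true, noise_cv = noise_cv, seed = seed, ...)
}

quick_fit <- function(exp, n_starts = 12, seed = 1, ...) {
  fit_diffusion(exp, n_starts = n_starts, seed = seed, ...)
}

# granule-law coefficients used throughout: slope/intercept (log10, D in
# m^2/s) with their standard errors, 11 molecular weights
granule_law <- function() {
  scaling_fit(-0.564, -8.070, 0.044, 0.126, n = 11, label = "granule")
}
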