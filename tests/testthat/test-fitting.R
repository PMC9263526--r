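test_that("initial concentration follows from dosed mass and liquid volume", {
  expect_equal(estimate_initial_concentration(300, 0.3), 1000)
  expect_equal(estimate_initial_concentration(150, 0.24), 625)
  expect_error(estimate_initial_concentration(0, 0.3))
})

test_that("noiseless fits recover the true D across three decades", {
  for (D_true in c(1e-11, 1e-10, 1e-9)) {
    exp <- generate_experiment(quick_spec(D_true = D_true))
    fit <- quick_fit(exp)
    expect_lt(abs(fit$D_e / D_true - 1), 1e-3, label = paste("D =", D_true))
  }
})

test_that("the objective is unit-free: rescaling mass and signal together", {
  spec <- quick_spec(D_true = 2e-10, noise_cv = 0.02, seed = 11)
  exp <- generate_experiment(spec)
  scaled <- uptake_experiment(
    dplyr::mutate(exp$data, conc_mg_L = conc_mg_L * 7.3),
    exp$system, solute_mass_mg = exp$solute_mass_mg * 7.3)
  f1 <- quick_fit(exp, seed = 5)
  f2 <- quick_fit(scaled, seed = 5)
  expect_equal(f1$D_e, f2$D_e, tolerance = 1e-9)
})

test_that("appending the analytic equilibrium tail barely moves the fit", {
  spec <- quick_spec(D_true = 3e-10, noise_cv = 0.02, seed = 21)
  exp <- generate_experiment(spec)
  C_eq <- exp$C_0 * equilibrium_ratio(exp$system$alpha)
  tail_data <- tibble::tibble(time_s = max(exp$data$time_s) + c(1, 2, 3) * 3600,
                              conc_mg_L = C_eq)
  exp2 <- uptake_experiment(dplyr::bind_rows(exp$data, tail_data),
                            exp$system, exp$solute_mass_mg)
  f1 <- quick_fit(exp, seed = 5)
  f2 <- quick_fit(exp2, seed = 5)
  expect_lt(abs(f2$D_e / f1$D_e - 1), 0.01)
})

test_that("fits are bit-reproducible under a fixed seed", {
  exp <- generate_experiment(quick_spec(noise_cv = 0.02, seed = 31))
  f1 <- quick_fit(exp, seed = 99)
  f2 <- quick_fit(exp, seed = 99)
  expect_identical(f1$D_e, f2$D_e)
  s1 <- monte_carlo_sd(exp, f1, n_sims = 60, seed = 7)
  s2 <- monte_carlo_sd(exp, f1, n_sims = 60, seed = 7)
  expect_identical(as.numeric(s1), as.numeric(s2))
})

test_that("noisy recovery operates at the sampling-theory precision floor", {
  # independent yardstick: the Cramer-Rao bound for ln D given this exact
  # schedule and 2% multiplicative noise (sensitivity by central difference)
  D_true <- 3e-10
  sys <- default_system()
  tt <- 30 * (21600 / 30)^((0:24) / 24)
  h <- 0.01
  r <- bulk_concentration_ratio(tt, D_true, sys)
  sens <- (bulk_concentration_ratio(tt, D_true * exp(h), sys) -
             bulk_concentration_ratio(tt, D_true * exp(-h), sys)) / (2 * h)
  crlb_sd <- 1 / sqrt(sum((sens / (0.02 * r))^2))
  errs <- vapply(1:50, function(s) {
    exp <- generate_experiment(quick_spec(D_true = D_true, noise_cv = 0.02,
                                          seed = 1000 + s))
    fit <- fit_diffusion(exp, n_starts = 8, seed = s)
    fit$D_e / D_true - 1
  }, numeric(1))
  # an efficient, essentially unbiased estimator: median |error| within a
  # factor 2 of the bound-implied value (0.674 * sd), bias small relative
  # to the sampling spread
  expect_lt(median(abs(errs)), 2 * 0.674 * crlb_sd)
  expect_lt(abs(median(errs)), 0.05)
})

test_that("a flat concentration series pins D at the lower bound", {
  sys <- default_system()
  d <- tibble::tibble(time_s = seq(60, 21600, length.out = 25),
                      conc_mg_L = 1000)
  exp <- uptake_experiment(d, sys, solute_mass_mg = 240)
  expect_warning(fit <- fit_diffusion(exp, n_starts = 8, seed = 1),
                 "bound")
  expect_equal(fit$D_e, fit$start_bounds[1], tolerance = 1e-2)
})

test_that("Monte-Carlo sd is zero when every input CV is zero", {
  exp <- generate_experiment(quick_spec(seed = 41))
  fit <- quick_fit(exp)
  s <- monte_carlo_sd(exp, fit, cv_radius = 0, cv_granule_volume = 0,
                      cv_concentration = 0, n_sims = 25, seed = 2)
  expect_equal(as.numeric(s), 0, tolerance = 1e-12)
})

test_that("default CVs give a relative sd of the order tens of percent", {
  # qualitative check against the reported 28-34% spread for this design
  exp <- generate_experiment(quick_spec(D_true = 3e-10, noise_cv = 0.02,
                                        seed = 51))
  fit <- quick_fit(exp)
  s <- monte_carlo_sd(exp, fit, n_sims = 300, seed = 8)
  rel <- as.numeric(s) / fit$D_e
  expect_gt(rel, 0.10)
  expect_lt(rel, 0.60)
})

test_that("tidy, glance and augment expose the fit in tabular form", {
  exp <- generate_experiment(quick_spec(seed = 61))
  fit <- quick_fit(exp)
  td <- tidy(fit)
  expect_equal(td$term, c("D_e", "D_e_25C"))
  expect_equal(td$estimate[1], fit$D_e)
  gl <- glance(fit)
  expect_equal(gl$n_obs, 25L)
  au <- generics::augment(fit)
  expect_true(all(abs(au$.resid) < 1e-8))  # noiseless fixture
})
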