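test_that("bulk ratio hits its analytic end points", {
  sys <- default_system()
  expect_identical(bulk_concentration_ratio(0, 1e-10, sys), 1)
  # all exponentials vanish: alpha/(1+alpha)
  expect_equal(bulk_concentration_ratio(1e9, 1e-10, sys), 0.8,
               tolerance = 1e-12)
  expect_equal(equilibrium_ratio(4), 0.8)
  expect_equal(equilibrium_ratio(1), 0.5)
  expect_equal(equilibrium_ratio(1e12), 1, tolerance = 1e-9)
})

test_that("bulk ratio is monotonically non-increasing and bounded", {
  sys <- default_system()
  t <- c(0, 10^seq(1, 6, length.out = 40))
  for (D in c(1e-11, 1e-10, 1e-9)) {
    r <- bulk_concentration_ratio(t, D, sys)
    expect_true(all(diff(r) <= 1e-12))
    expect_true(all(r >= 0.8 - 1e-12 & r <= 1))
  }
})

test_that("bulk series matches the finite-volume PDE oracle", {
  cases <- list(
    list(D = 1e-10, R = 1.1e-3, alpha = 4),
    list(D = 3e-10, R = 1.1e-3, alpha = 4),
    list(D = 1e-11, R = 5e-4,  alpha = 2),
    list(D = 5e-10, R = 2e-3,  alpha = 6),
    list(D = 1e-9,  R = 1e-3,  alpha = 10))
  for (cs in cases) {
    sys <- granule_system(cs$R, 0.3 / (1 + cs$alpha),
                          0.3 * cs$alpha / (1 + cs$alpha))
    tau_times <- c(0.005, 0.02, 0.08, 0.3) * cs$R^2 / cs$D
    sol <- simulate_uptake_numeric(cs$D, cs$R, cs$alpha, 1000,
                                   t_grid = c(0, tau_times), n_radial = 200)
    an <- bulk_concentration_ratio(c(0, tau_times), cs$D, sys) * 1000
    expect_lt(max(abs(sol$bulk / an - 1)), 1e-4)
  }
})

test_that("solute lost from the bath equals solute inside the spheres", {
  # dual route: bath drop from the analytic series, sphere content from the
  # numerical oracle (volumes normalised to V_G = 1, V_W = alpha)
  cases <- list(c(1e-10, 1.1e-3, 4), c(3e-10, 1.1e-3, 4), c(1e-11, 5e-4, 2),
                c(5e-10, 2e-3, 6), c(2e-10, 1e-3, 1))
  for (cs in cases) {
    D <- cs[1]; R <- cs[2]; alpha <- cs[3]
    sys <- granule_system(R, 0.3 / (1 + alpha), 0.3 * alpha / (1 + alpha))
    t <- c(0.02, 0.1, 0.4) * R^2 / D
    sol <- simulate_uptake_numeric(D, R, alpha, 1000, t_grid = c(0, t),
                                   n_radial = 200)
    sphere_mass <- as.vector(sol$concentration[-1, , drop = FALSE] %*%
                               diff(c(0, (seq_len(200) / 200)^3)))
    bath_loss <- alpha * (1000 - bulk_concentration_ratio(t, D, sys) * 1000)
    expect_lt(max(abs(sphere_mass / bath_loss - 1)), 1e-3)
  }
})

test_that("core penetration series behaves at its end points", {
  expect_identical(core_concentration_ratio(0, 1e-10, 1e-3), 0)
  expect_equal(core_concentration_ratio(1e9, 1e-10, 1e-3), 1)
  # direct alternating-series evaluation at D*t/R^2 = 0.40306 (<= 5 terms)
  expect_equal(core_concentration_ratio(0.40306 * 1e-6 / 1e-10, 1e-10, 1e-3),
               0.9625558, tolerance = 1e-5)
})

test_that("core penetration is monotone in t and matches the oracle center", {
  t <- 10^seq(2, 5, length.out = 30)
  r <- core_concentration_ratio(t, 1e-10, 1e-3)
  expect_true(all(diff(r) >= -1e-12))
  # infinite-bath boundary emulated with a huge alpha
  tg <- c(0.01, 0.05, 0.2, 0.6) * 1e-6 / 1e-10
  sol <- simulate_uptake_numeric(1e-10, 1e-3, 1e6, 1000,
                                 t_grid = c(0, tg), n_radial = 200)
  an <- core_concentration_ratio(tg, 1e-10, 1e-3) * 1000
  expect_lt(max(abs(sol$center[-1] - an)) / 1000, 1e-4)
})

test_that("water viscosity reproduces the standard table", {
  # 4, 10, 20, 25 C reference values in mPa s
  tK <- c(277.15, 283.15, 293.15, 298.15)
  ref <- c(1.5673e-3, 1.3059e-3, 1.0016e-3, 0.8900e-3)
  expect_equal(water_viscosity(tK), ref, tolerance = 1e-3)
})

test_that("temperature conversion preserves D*mu/T and round-trips", {
  D <- 1e-10
  D25 <- convert_diffusivity_temperature(D, 277.15, 298.15)
  expect_equal(convert_diffusivity_temperature(D25, 298.15, 277.15), D,
               tolerance = 1e-12)
  expect_identical(convert_diffusivity_temperature(D, 290, 290), D)
  # closed form with the standard viscosities: 1e-10 * (298.15/277.15)
  #   * (1.5673/0.8900) = 1.894e-10
  expect_equal(D25, 1.894e-10, tolerance = 2e-3)
  # invariant D*mu/T identical on both sides
  expect_equal(D * water_viscosity(277.15) / 277.15,
               D25 * water_viscosity(298.15) / 298.15, tolerance = 1e-14)
})

test_that("accessible fraction inverts the equilibrium mass balance", {
  # full access at alpha = 4: C_eq/C_0 = 0.8 maps back to f = 1
  res <- accessible_fraction(1000, 800, V_G = 0.06, V_W = 0.24)
  expect_equal(res$f_accessible, 1, tolerance = 1e-12)
  expect_false(res$flagged)
  # no uptake at all: f = 0
  expect_equal(accessible_fraction(1000, 1000, 0.06, 0.24)$f_accessible, 0)
  # partial exclusion: C_eq/C_0 = 4/4.65 inverts to f = 0.65
  res <- accessible_fraction(1000, 1000 * 4 / 4.65, 0.06, 0.24)
  expect_equal(res$f_accessible, 0.65, tolerance = 1e-10)
  # apparent production is an error
  expect_error(accessible_fraction(1000, 1001, 0.06, 0.24), "production")
  # pathological equilibrium below alpha/(1+alpha) flags f > 1
  expect_true(accessible_fraction(1000, 700, 0.06, 0.24)$flagged)
})
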