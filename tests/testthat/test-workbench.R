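test_that("run_fit recovers the truth from files and writes a report", {
  dir <- withr::local_tempdir()
  csv <- file.path(dir, "exp.csv"); meta <- file.path(dir, "exp.yaml")
  out <- file.path(dir, "fit.json")
  run_simulate(quick_spec(D_true = 3e-10, noise_cv = 0, seed = 3), csv, meta)
  rep <- run_fit(csv, meta, out_path = out, n_starts = 10, n_sims = 20,
                 seed = 1)
  expect_equal(rep$mode, "diffusion")
  expect_lt(abs(rep$D_e_m2_s / 3e-10 - 1), 1e-3)
  expect_true(file.exists(out))
  disk <- jsonlite::read_json(out)
  expect_equal(disk$D_e_m2_s, rep$D_e_m2_s, tolerance = 1e-12)
  expect_match(rep$config_hash, "^[0-9a-f]+$")
})

test_that("missing columns and files raise input errors", {
  dir <- withr::local_tempdir()
  csv <- file.path(dir, "bad.csv"); meta <- file.path(dir, "exp.yaml")
  run_simulate(quick_spec(seed = 3), file.path(dir, "ok.csv"), meta)
  readr::write_csv(tibble::tibble(t = 1:10, conc = 1:10), csv)
  expect_error(run_fit(csv, meta), class = "granulediff_input_error")
  expect_error(run_fit(csv, meta), "time_s")
  expect_error(run_fit(file.path(dir, "nope.csv"), meta),
               class = "granulediff_input_error")
})

test_that("a partially excluded solute triggers the accessibility path", {
  dir <- withr::local_tempdir()
  csv <- file.path(dir, "exp.csv"); meta <- file.path(dir, "exp.yaml")
  run_simulate(quick_spec(D_true = 5e-11, noise_cv = 0.005, seed = 13,
                          t_max_s = 86400, f_accessible = 0.65,
                          mw_da = 10000),
               csv, meta)
  expect_warning(rep <- run_fit(csv, meta, n_starts = 5, n_sims = 5,
                                seed = 1),
                 "equilibrium mismatch")
  expect_equal(rep$mode, "restricted_access")
  expect_lt(abs(rep$f_accessible - 0.65), 0.03)
  expect_null(rep$D_e_m2_s)
})

test_that("run_scaling compares against the water reference", {
  dir <- withr::local_tempdir()
  csv <- file.path(dir, "mw.csv")
  mw <- c(62, 200, 600, 1000, 4000)
  readr::write_csv(tibble::tibble(mw_da = mw,
                                  D_m2_s = 10^(-8.07 - 0.564 * log10(mw))),
                   csv)
  out <- file.path(dir, "scaling.json")
  rep <- run_scaling(csv, out_path = out)
  expect_equal(rep$fit$slope, -0.564, tolerance = 1e-8)
  expect_equal(rep$comparison$df, 5 + 11 - 4)
  expect_true(file.exists(out))
  # a fit compared against itself is exactly null
  self <- run_scaling(csv, reference = fit_loglog(readr::read_csv(
    csv, show_col_types = FALSE)))
  expect_equal(self$comparison$t_slope, 0)
  # fewer than 3 points is an input error
  readr::write_csv(tibble::tibble(mw_da = c(62, 200),
                                  D_m2_s = c(1e-9, 5e-10)), csv)
  expect_error(run_scaling(csv), class = "granulediff_input_error")
})

test_that("run_penetration produces a monotone table with known anchors", {
  tab <- run_penetration(granule_law())
  expect_true(all(diff(tab$core_ratio) < 0))
  expect_gte(tab$core_ratio[tab$mw_da == 1000], 0.93)
  z <- run_penetration(granule_law(), mw_da = c(100, 1000), time_s = 0)
  expect_equal(z$core_ratio, c(0, 0))
})

test_that("run_cod writes JSON and text reports with the quoted ranges", {
  dir <- withr::local_tempdir()
  out <- file.path(dir, "cod.json"); txt <- file.path(dir, "cod.txt")
  src <- system.file("extdata", "cod_fractions_influent.csv",
                     package = "granulediff")
  res <- suppressWarnings(run_cod(src, out_path = out, txt_path = txt))
  expect_equal(nrow(res$summary), 3)
  r <- res$ranges
  expect_equal(r$min_pct[r$metric == "particulate_pct_of_total"], 62)
  expect_true(file.exists(out) && file.exists(txt))
  # empty file errors
  empty <- file.path(dir, "empty.csv")
  writeLines("plant,total_cod", empty)
  expect_error(run_cod(empty), class = "granulediff_input_error")
})

test_that("autoplot methods return ggplot objects", {
  exp <- generate_experiment(quick_spec(seed = 3))
  fit <- quick_fit(exp)
  expect_s3_class(autoplot(exp), "ggplot")
  expect_s3_class(autoplot(fit), "ggplot")
  expect_s3_class(autoplot(granule_law(), reference = water_reference_law()),
                  "ggplot")
  expect_s3_class(plot_penetration(run_penetration(granule_law())), "ggplot")
})
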