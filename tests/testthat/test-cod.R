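test_that("per-plant shares use the measured denominators", {
  s <- suppressWarnings(summarize_fractions(influent_cod_fractions()))
  u <- s[s$plant == "Utrecht", ]
  expect_equal(u$particulate_pct_of_total, 100 * (605 - 175) / 605,
               tolerance = 1e-12)  # 71%
  expect_equal(u$lt1kda_pct_of_soluble, 100 * 106 / 175, tolerance = 1e-12)
  expect_equal(u$lt10kda_pct_of_soluble, 100 * (106 + 17) / 175,
               tolerance = 1e-12)
})

test_that("cross-plant ranges reproduce the quoted whole-percent ranges", {
  s <- suppressWarnings(summarize_fractions(influent_cod_fractions()))
  r <- fraction_ranges(s)
  get <- function(m) unlist(r[r$metric == m, c("min_pct", "max_pct")],
                            use.names = FALSE)
  expect_equal(get("particulate_pct_of_total"), c(62, 77))
  expect_equal(get("lt1kda_pct_of_soluble"), c(61, 69))
  expect_equal(get("lt10kda_pct_of_soluble"), c(70, 87))
  expect_equal(get("lt1kda_pct_of_total"), c(15, 26))
  # VFA share of soluble is reported but carries no published-range claim
  expect_true(all(is.finite(get("vfa_pct_of_soluble"))))
})

test_that("summaries are scale invariant", {
  tab <- influent_cod_fractions()
  num <- vapply(tab, is.numeric, logical(1))
  tab2 <- tab
  tab2[num] <- tab[num] * 3.7
  s1 <- suppressWarnings(summarize_fractions(tab))
  s2 <- suppressWarnings(summarize_fractions(tab2))
  cols <- setdiff(names(s1), c("plant", "closure_residual_mg_L"))
  expect_equal(s1[cols], s2[cols], tolerance = 1e-12)
})

test_that("closure is a warning, not a failure", {
  # two plants close within 2 mg/L, one does not; the summary still returns
  expect_warning(s <- summarize_fractions(influent_cod_fractions()),
                 "Harnaschpolder")
  expect_equal(nrow(s), 3)
  resid <- setNames(s$closure_residual_mg_L, s$plant)
  expect_lte(abs(resid[["Utrecht"]]), 2)
  expect_lte(abs(resid[["Bath"]]), 2)
  expect_gt(abs(resid[["Harnaschpolder"]]), 2)
})

test_that("degenerate tables error", {
  tab <- influent_cod_fractions()
  expect_error(summarize_fractions(tab[0, ]), "no COD tables")
  tab$soluble_cod[1] <- 0
  expect_error(summarize_fractions(tab), "denominator")
  expect_error(summarize_fractions(dplyr::select(tab, -"total_cod")),
               "missing")
})

test_that("a plant with soluble == total has zero particulate share", {
  tab <- influent_cod_fractions()[1, ]
  tab$soluble_cod <- tab$total_cod <- 500
  tab$cod_100kda_045um <- 100; tab$cod_10_100kda <- 100
  tab$cod_1_10kda <- 100; tab$cod_lt_1kda <- 200
  s <- summarize_fractions(tab)
  expect_equal(s$particulate_pct_of_total, 0)
})

test_that("penetration chain is monotone in MW and hits the known cases", {
  g <- granule_law()
  tab <- assess_penetration(c(62, 106, 200, 400, 1000, 2000, 4000), g)
  expect_true(all(diff(tab$core_ratio) < 0))
  expect_gte(tab$core_ratio[tab$mw_da == 1000], 0.93)
  expect_equal(tab$core_ratio[tab$mw_da == 62], 1, tolerance = 1e-4)
  expect_equal(assess_penetration(1000, g, time_s = 0)$core_ratio, 0)
})

test_that("synthetic COD tables are reproducible and exact at sd = 0", {
  p <- cod_profile("Utrecht")
  t1 <- generate_cod_table(p, seed = 5)
  t2 <- generate_cod_table(p, seed = 5)
  expect_identical(t1, t2)
  p0 <- dplyr::mutate(p, sd = 0)
  t0 <- generate_cod_table(p0, plant = "Utrecht", seed = 1)
  ref <- influent_cod_fractions()[1, ]
  expect_equal(t0$total_cod, ref$total_cod)
  expect_equal(t0$cod_lt_1kda, ref$cod_lt_1kda)
  # adversarial profile: soluble above total is clamped and flagged
  pa <- p0
  pa$mean[pa$field == "soluble_cod"] <- 2 * pa$mean[pa$field == "total_cod"]
  ta <- generate_cod_table(pa, seed = 1)
  expect_true(ta$clamped)
  expect_equal(ta$soluble_cod, ta$total_cod)
})
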