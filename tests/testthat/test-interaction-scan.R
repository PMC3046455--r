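# Grid enumeration and the 1-df product-term interaction test.

test_that("grid enumeration is SNP-major and sized |snps| x |factors|", {
  full <- scan_grid()
  expect_equal(nrow(full), 72L)
  expect_equal(length(unique(full$snp)), 12L)
  expect_equal(length(unique(full$factor)), 6L)

  g1 <- scan_grid(small_catalog(1), "menarche")
  expect_equal(nrow(g1), 1L)

  g <- scan_grid(small_catalog(3), c("menarche", "n_births"))
  expect_equal(nrow(g), 6L)
  expect_equal(g$snp, rep(small_catalog(3)$name, each = 2))
  expect_equal(g$factor, rep(c("menarche", "n_births"), 3))

  dup <- rbind(small_catalog(1), small_catalog(1))
  expect_error(scan_grid(dup, "menarche"), class = "gxe_config_error")
  expect_error(scan_grid(small_catalog(1), character(0)),
               class = "gxe_config_error")
})

test_that("the interaction test recovers a generative interaction OR", {
  cfg <- small_config(n_cases = 2000, n_controls = 2000, n_studies = 2,
                      k_snps = 3, snp_ors = 1.0,
                      main_effect_ors = c(n_births = 0.95),
                      interaction_ors = data.frame(snp = "11p15-rs3817198",
                                                   factor = "n_births",
                                                   or = 1.3))
  co <- simulate_cohort(cfg, seed = 404)
  res <- interaction_test(co, "11p15-rs3817198", "n_births", cfg$catalog)
  expect_true(is.na(res$flag))
  expect_equal(res$df, 1L)
  expect_true(res$ci[1] < 1.3 && 1.3 < res$ci[2])
  expect_lt(res$p, 0.01)
  expect_equal(res$or_int, exp(res$beta_int), tolerance = 1e-12)
  # the non-null pair attains the scan minimum
  sc <- gxe_scan(co, catalog = cfg$catalog)
  expect_equal(nrow(sc), 18L)
  top <- which.min(sc$p)
  expect_equal(sc$snp[top], "11p15-rs3817198")
  expect_equal(sc$factor[top], "n_births")
})

test_that("the interaction log-OR is invariant to shifting the factor", {
  cfg <- small_config(n_cases = 700, n_controls = 700, k_snps = 1)
  co <- simulate_cohort(cfg, seed = 19)
  r1 <- interaction_test(co, "rs2981582", "menarche", cfg$catalog)
  shifted <- co
  shifted$menarche_age <- shifted$menarche_age + 7L
  r2 <- interaction_test(shifted, "rs2981582", "menarche", cfg$catalog)
  expect_equal(r1$beta_int, r2$beta_int, tolerance = 1e-6)
  expect_equal(r1$lrt_stat, r2$lrt_stat, tolerance = 1e-6)
})

test_that("degenerate subsets yield flagged rows, and counts are right", {
  cfg <- small_config(n_cases = 200, n_controls = 200, k_snps = 3)
  co <- simulate_cohort(cfg, seed = 23)
  # constant factor -> flag
  const <- co
  const$menarche_age <- 13L
  r <- interaction_test(const, "rs2981582", "menarche", cfg$catalog)
  expect_false(is.na(r$flag))
  expect_true(is.na(r$p))
  # no BMI data at all -> both BMI factors flagged for every SNP
  nobmi <- co
  nobmi$bmi <- NA_real_
  sc <- gxe_scan(nobmi, catalog = cfg$catalog)
  expect_equal(nrow(sc), 18L)
  expect_equal(sum(!is.na(sc$flag)), 6L)
  expect_true(all(sc$factor[!is.na(sc$flag)] %in% c("bmi_lt55", "bmi_ge55")))
  expect_equal(sum(is.na(sc$flag)), 12L)
})

test_that("flipping the risk allele leaves the interaction p unchanged", {
  # dosage -> 2 - dosage is a reparameterisation of the same model space
  cfg <- small_config(n_cases = 500, n_controls = 500, k_snps = 1,
                      interaction_ors = data.frame(snp = "10q26-rs2981582",
                                                   factor = "menarche",
                                                   or = 1.1))
  co <- simulate_cohort(cfg, seed = 29)
  r1 <- interaction_test(co, "rs2981582", "menarche", cfg$catalog)
  flipped <- co
  flipped$rs2981582 <- 2L - flipped$rs2981582
  r2 <- interaction_test(flipped, "rs2981582", "menarche", cfg$catalog)
  expect_equal(r1$p, r2$p, tolerance = 1e-6)
  expect_equal(r1$beta_int, -r2$beta_int, tolerance = 1e-5)
})
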