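# Per-allele ORs, risk-factor trends and joint-model stratified ORs.

test_that("per-allele OR recovers the generative effect and flags degeneracy", {
  cfg <- small_config(n_cases = 1500, n_controls = 1500, k_snps = 1,
                      snp_ors = 1.22)
  co <- simulate_cohort(cfg, seed = 101)
  res <- per_allele_or(co, "rs2981582", cfg$catalog)
  expect_true(res$ci[1] < 1.22 && 1.22 < res$ci[2])
  expect_equal(res$n_cases + res$n_controls, nrow(co))
  # age adjustment never changes the rows used (age always present)
  res_age <- per_allele_or(co, "rs2981582", cfg$catalog, adjust_age = TRUE)
  expect_equal(res_age$fit$n_used, res$fit$n_used)
  # monomorphic dosage column
  mono <- co
  mono$rs2981582 <- 0L
  expect_error(per_allele_or(mono, "rs2981582", cfg$catalog),
               class = "gxe_degenerate_error")
})

test_that("risk-factor trend ORs recover the generative trend effects", {
  # one effect at a time: reproductive variables are correlated by
  # construction, so a joint config would confound the marginal trends
  targets <- list(menarche = c(menarche = 0.96),
                  ever_birth = c(ever_birth = 0.84),
                  n_births = c(n_births = 0.89),
                  age_first_birth = c(age_first_birth = 1.07^(1 / 5)))
  for (f in names(targets)) {
    cfg <- small_config(n_cases = 2000, n_controls = 2000, n_studies = 1,
                        k_snps = 1, main_effect_ors = targets[[f]])
    co <- simulate_cohort(cfg, seed = 200 + match(f, names(targets)))
    truth <- unname(targets[[f]])^risk_factor_spec(f)$report_per
    res <- risk_factor_trend(co, f)
    expect_true(res$ci[1] < truth && truth < res$ci[2],
                label = paste("CI for", f, "covers generative OR"))
    if (f == "age_first_birth") {
      expect_equal(res$report_per, 5)
      expect_equal(res$or, res$or_per_unit^5, tolerance = 1e-10)
      expect_equal(truth, 1.07, tolerance = 1e-12)
    }
  }
})

test_that("trend fit rejects a constant factor", {
  co <- toy_cohort()
  co$menarche_age <- 13L
  expect_error(risk_factor_trend(co, "menarche"),
               class = "gxe_degenerate_error")
})

test_that("joint-model stratified ORs equal separate per-category fits", {
  # single study: the joint model factorises across categories, so the
  # per-category slopes must match independent glm() fits exactly
  cfg <- small_config(n_cases = 600, n_controls = 600, n_studies = 1,
                      k_snps = 1, snp_ors = 1.3,
                      interaction_ors = data.frame(snp = "10q26-rs2981582",
                                                   factor = "n_births",
                                                   or = 1.2))
  co <- simulate_cohort(cfg, seed = 77)
  st <- stratified_per_allele_ors(co, "rs2981582", "n_births", cfg$catalog)
  sub <- analysis_subset(co, "rs2981582", "n_births", cfg$catalog)
  cats <- categorize(factor_values(sub, risk_factor_spec("n_births")),
                     "n_births")
  for (k in which(!st$flagged)) {
    i <- cats == st$category[k]
    oracle <- glm(sub$is_case[i] ~ sub$rs2981582[i], family = binomial())
    expect_equal(unname(log(st$or[k])), unname(coef(oracle)[2]),
                 tolerance = 1e-6)
  }
  expect_equal(sum(st$n_cases) + sum(st$n_controls), nrow(sub))
  expect_equal(st$category,
               risk_factor_spec("n_births")$category_labels[
                 seq_len(nrow(st))])
})

test_that("a generative interaction produces a monotone stratified gradient", {
  cfg <- small_config(n_cases = 3000, n_controls = 3000, n_studies = 2,
                      k_snps = 1, snp_ors = 1.0,
                      interaction_ors = data.frame(snp = "10q26-rs2981582",
                                                   factor = "n_births",
                                                   or = 1.25))
  co <- simulate_cohort(cfg, seed = 303)
  st <- stratified_per_allele_ors(co, "rs2981582", "n_births", cfg$catalog)
  expect_false(any(st$flagged))
  expect_true(all(diff(log(st$or)) > 0))
  expect_lt(attr(st, "homogeneity")$p, 0.05)
})

test_that("categories with a single outcome class are flagged, not fatal", {
  cfg <- small_config(n_cases = 300, n_controls = 300, n_studies = 1,
                      k_snps = 1)
  co <- simulate_cohort(cfg, seed = 88)
  # push all parity-1 women into the case class only
  co$is_case[!is.na(co$n_live_births) & co$n_live_births == 1] <- 1L
  st <- stratified_per_allele_ors(co, "rs2981582", "n_births", cfg$catalog)
  expect_true(st$flagged[st$category == "1"])
  expect_true(is.na(st$or[st$category == "1"]))
  expect_true(all(!st$flagged[st$category != "1"]))
})
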