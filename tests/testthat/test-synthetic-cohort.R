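# Generator: Hardy-Weinberg dosages, the generative logit, ascertainment,
# determinism and structural invariants.

test_that("genotype draws follow Hardy-Weinberg proportions", {
  set.seed(42)
  q <- 0.38
  n <- 100000
  d <- draw_genotypes(q, n)
  hw <- c((1 - q)^2, 2 * q * (1 - q), q^2)   # (0.3844, 0.4712, 0.1444)
  obs <- tabulate(d + 1L, 3L) / n
  se <- sqrt(hw * (1 - hw) / n)
  expect_true(all(abs(obs - hw) < 3 * se))
  # mean dosage within 3 binomial SEs of 2q
  expect_lt(abs(mean(d) - 2 * q), 3 * sqrt(2 * q * (1 - q) / n))
  expect_true(all(draw_genotypes(0, 500) == 0L))
  expect_true(all(draw_genotypes(1, 500) == 2L))
  expect_error(draw_genotypes(1.2, 10), class = "gxe_config_error")
})

make_records <- function(cfg, dosage = 0L, n_births = 2L, parous = 1L,
                         bmi = 25.5, age = 50L, menarche = 13L, afb = 25L) {
  rec <- data.frame(study = "A", age = age, menarche_age = menarche,
                    parous = parous, n_live_births = n_births,
                    age_first_birth = afb, bmi = bmi)
  for (rsid in cfg$catalog$rsid) rec[[rsid]] <- 0L
  rec[[cfg$catalog$rsid[1]]] <- dosage
  rec
}

test_that("the generative logit is the study intercept under the global null", {
  cfg <- small_config()
  rec <- make_records(cfg, dosage = 2L)
  expect_equal(disease_logit(rec, cfg, intercepts = c(A = -2.2)), -2.2)
  expect_error(disease_logit(rec, cfg, intercepts = c(B = 0)),
               class = "gxe_config_error")
})

test_that("per-allele and interaction effects enter the logit multiplicatively", {
  # dosage 2 at a SNP with per-allele OR 1.22, everything else null
  cat1 <- small_catalog(1)
  cat1$or_per_allele <- 1.22
  cfg <- sim_config(studies = data.frame(label = "A", n_cases = 10,
                                         n_controls = 10),
                    catalog = cat1)
  rec <- make_records(cfg, dosage = 2L)
  expect_equal(disease_logit(rec, cfg, 0), 2 * log(1.22), tolerance = 1e-12)

  # interaction OR 1.05 per allele per birth, dosage 1, 3 births, mains null
  cat1$or_per_allele <- 1
  cfg2 <- sim_config(studies = data.frame(label = "A", n_cases = 10,
                                          n_controls = 10),
                     catalog = cat1,
                     interaction_ors = data.frame(snp = cat1$name,
                                                  factor = "n_births",
                                                  or = 1.05))
  rec2 <- make_records(cfg2, dosage = 1L, n_births = 3L)
  expect_equal(disease_logit(rec2, cfg2, 0), 3 * log(1.05),
               tolerance = 1e-12)

  # with no interaction, the joint effect is exactly OR_g^d * OR_e^e
  cat1$or_per_allele <- 1.3
  cfg3 <- sim_config(studies = data.frame(label = "A", n_cases = 10,
                                          n_controls = 10),
                     catalog = cat1,
                     main_effect_ors = c(n_births = 0.89))
  for (d in 0:2) for (e in 1:4) {
    eta_de <- disease_logit(make_records(cfg3, dosage = d, n_births = e),
                            cfg3, 0)
    eta_00 <- disease_logit(make_records(cfg3, dosage = 0L, n_births = 0L),
                            cfg3, 0)
    expect_equal(eta_de - eta_00, d * log(1.3) + e * log(0.89),
                 tolerance = 1e-12)
  }
})

test_that("simulated cohorts hit target sizes exactly and deterministically", {
  cfg <- sim_config(studies = data.frame(label = c("S1", "S2", "S3"),
                                         n_cases = 100, n_controls = 150),
                    catalog = small_catalog(2))
  co <- simulate_cohort(cfg, seed = 5)
  expect_equal(nrow(co), 750L)
  expect_equal(unname(table(co$study, co$is_case)[, "1"]), rep(100L, 3))
  expect_equal(unname(table(co$study, co$is_case)[, "0"]), rep(150L, 3))

  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_cohort(co, p1)
  write_cohort(simulate_cohort(cfg, seed = 5), p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  co2 <- simulate_cohort(cfg, seed = 6)
  expect_false(identical(co$rs2981582, co2$rs2981582))
})

test_that("parity fields are structurally consistent", {
  cfg <- small_config(missingness = list(parity = 0.1, menarche = 0.1))
  co <- simulate_cohort(cfg, seed = 9)
  nullip <- !is.na(co$parous) & co$parous == 0
  expect_true(all(is.na(co$n_live_births[nullip])))
  expect_true(all(is.na(co$age_first_birth[nullip])))
  par <- !is.na(co$parous) & co$parous == 1 & !is.na(co$age_first_birth)
  expect_true(all(co$age_first_birth[par] < co$age[par]))
  expect_true(all(co$n_live_births[par & !is.na(co$n_live_births)] >= 1))
  # ER/PR assigned to cases only
  expect_true(all(is.na(co$er[co$is_case == 0])))
  expect_true(all(co$er[co$is_case == 1] %in%
                    c("positive", "negative", "unknown")))
})

test_that("adding a study leaves existing studies' records unchanged", {
  cfg2 <- small_config(n_studies = 2)
  cfg3 <- sim_config(studies = rbind(cfg2$studies,
                                     data.frame(label = "Z", n_cases = 300,
                                                n_controls = 300)),
                     catalog = cfg2$catalog)
  co2 <- simulate_cohort(cfg2, seed = 31)
  co3 <- simulate_cohort(cfg3, seed = 31)
  keep <- co3$study %in% c("A", "B")
  expect_equal(as.data.frame(co3[keep, ]), as.data.frame(co2),
               ignore_attr = TRUE)
})
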