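# Cohort schema, genotype/risk-factor codings and analysis subsets.

test_that("dosage encoding counts risk alleles and rejects foreign alleles", {
  cat12 <- default_snp_catalog()
  # 10q26-rs2981582 is a C/T SNP with risk allele T
  expect_identical(encode_dosage("CT", "rs2981582", cat12), 1L)
  expect_identical(encode_dosage("TT", "rs2981582", cat12), 2L)
  expect_identical(encode_dosage("CC", "rs2981582", cat12), 0L)
  expect_identical(encode_dosage("TC", "rs2981582", cat12), 1L)
  expect_identical(encode_dosage(NA, "rs2981582", cat12), NA_integer_)
  err <- expect_error(encode_dosage("AG", "rs2981582", cat12),
                      class = "gxe_invalid_call")
  expect_match(conditionMessage(err), "rs2981582")
  expect_match(conditionMessage(err), "AG")
})

test_that("dosage of a call plus dosage of its allele-swapped call is 2", {
  cat12 <- default_snp_catalog()
  for (i in seq_len(nrow(cat12))) {
    snp <- cat12[i, ]
    a <- snp$other_allele; r <- snp$risk_allele
    calls <- c(paste0(a, a), paste0(a, r), paste0(r, a), paste0(r, r))
    swapped <- chartr(paste0(a, r), paste0(r, a), calls)
    expect_equal(encode_dosage(calls, snp) + encode_dosage(swapped, snp),
                 rep(2L, 4))
  }
})

test_that("categorize assigns the documented epidemiological bins", {
  expect_equal(as.character(categorize(27, "age_first_birth")), "25-29")
  expect_equal(as.character(categorize(12, "menarche")), "12")
  expect_equal(as.character(categorize(30.0, "bmi_lt55")), ">=30.00")
  expect_equal(as.character(categorize(24.99, "bmi_ge55")), "<=24.99")
  expect_equal(as.character(categorize(25.0, "bmi_lt55")), "25.00-29.99")
  expect_equal(as.character(categorize(c(19, 20, 29, 30), "age_first_birth")),
               c("<=19", "20-24", "25-29", ">=30"))
  expect_true(is.na(categorize(NA, "menarche")))
})

test_that("every value falls in exactly one category and counts add up", {
  set.seed(11)
  for (f in risk_factor_names()) {
    spec <- risk_factor_spec(f)
    v <- switch(f,
                menarche = sample(8:19, 200, TRUE),
                ever_birth = sample(0:1, 200, TRUE),
                n_births = sample(1:9, 200, TRUE),
                age_first_birth = sample(14:45, 200, TRUE),
                stats::rlnorm(200, log(26), 0.2))
    v[sample(200, 20)] <- NA
    cats <- categorize(v, spec)
    expect_true(all(is.na(cats) == is.na(v)))
    expect_equal(sum(table(cats)), sum(!is.na(v)))
  }
})

test_that("analysis subsets apply missingness, parity and age-stratum rules", {
  co <- toy_cohort()
  # n_births: 2 missing dosage, 1 nulliparous -> 7 of 10 rows remain
  sub <- analysis_subset(co, "rs2981582", "n_births")
  expect_equal(nrow(sub), 7L)
  expect_equal(attr(sub, "n"), 7L)
  expect_true(all(sub$parous == 1))
  # all < 55 for bmi_ge55 -> explicit empty-analysis condition
  young <- co
  young$age <- pmin(young$age, 54L)
  expect_error(analysis_subset(young, "rs2981582", "bmi_ge55"),
               class = "gxe_empty_analysis")
  # no missingness in SNP or factor -> identity subset
  full <- co
  full$rs2981582 <- 1L
  sub2 <- analysis_subset(full, "rs2981582", "menarche")
  expect_equal(nrow(sub2), nrow(co))
  # idempotence
  sub3 <- analysis_subset(sub, "rs2981582", "n_births")
  expect_equal(as.data.frame(sub3), as.data.frame(sub))
})

test_that("cohort validation enforces record-level invariants", {
  co <- toy_cohort()
  expect_silent(validate_cohort(co))
  bad <- co; bad$rs2981582[1] <- 3L
  expect_error(validate_cohort(bad), class = "gxe_schema_error")
  bad <- co; bad$age_first_birth[1] <- bad$age[1] + 1L
  expect_error(validate_cohort(bad), class = "gxe_schema_error")
  bad <- co; bad$bmi[2] <- -1
  expect_error(validate_cohort(bad), class = "gxe_schema_error")
  bad <- co[, setdiff(names(co), "parous")]
  expect_error(validate_cohort(bad), class = "gxe_schema_error")
})

test_that("cohort TSV round-trips through read/write", {
  co <- toy_cohort()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cohort(co, path)
  back <- read_cohort(path)
  expect_equal(as.data.frame(back), as.data.frame(co))
})

test_that("the default catalog and its JSON round-trip are consistent", {
  cat12 <- default_snp_catalog()
  expect_equal(nrow(cat12), 12L)
  expect_true(all(cat12$risk_allele_freq > 0 & cat12$risk_allele_freq < 1))
  # risk-allele frequency may exceed 0.5 (2q35 locus)
  expect_true(any(cat12$risk_allele_freq > 0.5))
  path <- withr::local_tempfile(fileext = ".json")
  write_snp_catalog(cat12, path)
  expect_equal(as.data.frame(read_snp_catalog(path)),
               as.data.frame(cat12))
})
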