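# Shared fixtures: small catalogs/configs and a hand-built toy cohort.

small_catalog <- function(k = 3) {
  cat <- default_snp_catalog()
  cat[seq_len(k), , drop = FALSE]
}

# a null-by-default simulation config (SNP per-allele ORs reset to 1 unless
# supplied) whose generative terms match the analysis models exactly, so
# interaction p-values are exactly sized under the null
small_config <- function(n_cases = 300, n_controls = 300, n_studies = 2,
                         k_snps = 3, snp_ors = 1, main_effect_ors = NULL,
                         interaction_ors = NULL, missingness = NULL) {
  cat <- small_catalog(k_snps)
  cat$or_per_allele <- snp_ors
  sim_config(
    studies = data.frame(label = LETTERS[seq_len(n_studies)],
                         n_cases = n_cases, n_controls = n_controls),
    catalog = cat,
    main_effect_ors = main_effect_ors,
    interaction_ors = interaction_ors,
    missingness = missingness)
}

# fully deterministic 10-row cohort for schema/subset tests
toy_cohort <- function() {
  data.frame(
    study = rep(c("S1", "S2"), each = 5),
    is_case = rep(c(1L, 0L), 5),
    age = c(45L, 52L, 60L, 38L, 49L, 57L, 44L, 63L, 51L, 47L),
    menarche_age = c(12L, 13L, 11L, 14L, 15L, 12L, 13L, 13L, 12L, 14L),
    parous = c(1L, 1L, 1L, 0L, 1L, 1L, 1L, 1L, 1L, 1L),
    n_live_births = c(2L, 1L, 3L, NA, 4L, 2L, 1L, 2L, 3L, 1L),
    age_first_birth = c(24L, 28L, 21L, NA, 26L, 30L, 23L, 27L, 25L, 29L),
    bmi = c(23.5, 27.1, 31.2, 22.0, 25.5, 28.9, 24.4, 30.1, 26.7, 23.9),
    er = c("positive", NA, "negative", NA, "positive",
           NA, "unknown", NA, "positive", NA),
    pr = c("positive", NA, "negative", NA, "negative",
           NA, "unknown", NA, "positive", NA),
    rs2981582 = c(1L, 0L, 2L, 1L, NA, 0L, 1L, 2L, NA, 1L),
    stringsAsFactors = FALSE)
}
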