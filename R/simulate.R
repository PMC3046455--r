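# Multi-study synthetic case-control cohort generator.
#
# The generative model mirrors the analysis model: a per-study logistic
# disease model with multiplicative per-allele SNP effects, log-linear
# risk-factor trend effects and optional per-allele-per-unit interaction
# effects. Case-control ascertainment is emulated by retrospective
# (rejection) sampling from the population model until the target numbers
# of cases and controls are reached, with study intercepts auto-calibrated
# to a configurable disease prevalence.

#' Simulation configuration
#'
#' Assembles and validates the generative model for [simulate_cohort()].
#'
#' @param studies data frame with columns `label`, `n_cases`, `n_controls`
#'   (and optionally `population_based`, logical).
#' @param catalog a [snp_catalog()]; `risk_allele_freq` drives the
#'   Hardy-Weinberg genotype draws and `or_per_allele` the per-allele
#'   disease odds ratios.
#' @param main_effect_ors named numeric vector of trend ORs per coded unit
#'   for `menarche` (per year), `ever_birth` (parous vs not), `n_births`
#'   (per live birth), `age_first_birth` (per year), `bmi_lt55` and
#'   `bmi_ge55` (per kg/m^2), plus `age` (per year).
#' @param interaction_ors data frame with columns `snp`, `factor`, `or`
#'   giving interaction ORs per risk allele per coded unit of the factor;
#'   pairs not listed have interaction OR 1 (no interaction).
#' @param factor_models list of population distributions: `menarche`
#'   (`values`, `probs`), `age_first_birth` (`values`, `probs`),
#'   `parous_prob`, `n_births` (`base`, `slope`, `max` — a shifted Poisson
#'   whose mean decreases with age at first birth), `bmi` (`meanlog`,
#'   `sdlog`), `age` (`mean`, `sd`, `min`, `max`).
#' @param missingness list of per-field missingness rates applied after
#'   sampling: `menarche`, `parity`, `age_first_birth` (additional, among
#'   parous), `bmi`, `dosage` (scalar or named per rsID).
#' @param subtype_model ER/PR subtype model for cases: `p_er_pos`,
#'   `p_pr_pos_given_er_pos`, `p_pr_pos_given_er_neg`, `unknown_rate`, and
#'   optional `er_dosage_log_or` (named per SNP) letting ER status depend on
#'   genotype.
#' @param prevalence list with `target` expected disease prevalence used to
#'   calibrate study intercepts and the admissible `band`.
#' @return a list of class `"sim_config"`.
#' @seealso [bcac_sim_config()] for the packaged 21-study default.
#' @export
sim_config <- function(studies,
                       catalog = default_snp_catalog(),
                       main_effect_ors = NULL,
                       interaction_ors = NULL,
                       factor_models = NULL,
                       missingness = NULL,
                       subtype_model = NULL,
                       prevalence = NULL) {
  studies <- as.data.frame(studies)
  if (!all(c("label", "n_cases", "n_controls") %in% names(studies))) {
    stop_gxe("gxe_config_error",
             "studies needs columns label, n_cases, n_controls")
  }
  if (anyDuplicated(studies$label)) {
    stop_gxe("gxe_config_error", "duplicate study labels")
  }
  if (any(studies$n_cases < 1 | studies$n_controls < 1)) {
    stop_gxe("gxe_config_error", "study sizes must be >= 1")
  }
  validate_snp_catalog(catalog)

  me_default <- c(menarche = 1, ever_birth = 1, n_births = 1,
                  age_first_birth = 1, bmi_lt55 = 1, bmi_ge55 = 1, age = 1)
  me <- me_default
  if (!is.null(main_effect_ors)) {
    unknown <- setdiff(names(main_effect_ors), names(me_default))
    if (length(unknown)) {
      stop_gxe("gxe_config_error", "unknown main_effect_ors: ",
               paste(unknown, collapse = ", "))
    }
    me[names(main_effect_ors)] <- main_effect_ors
  }
  if (any(me <= 0)) stop_gxe("gxe_config_error", "ORs must be positive")

  if (is.null(interaction_ors)) {
    interaction_ors <- data.frame(snp = character(), factor = character(),
                                  or = numeric())
  }
  interaction_ors <- as.data.frame(interaction_ors)
  if (nrow(interaction_ors)) {
    if (!all(interaction_ors$snp %in% c(catalog$name, catalog$rsid))) {
      stop_gxe("gxe_config_error", "interaction_ors names a SNP not in catalog")
    }
    if (!all(interaction_ors$factor %in% risk_factor_names())) {
      stop_gxe("gxe_config_error", "interaction_ors names an unknown factor")
    }
    if (any(interaction_ors$or <= 0)) {
      stop_gxe("gxe_config_error", "interaction ORs must be positive")
    }
    # normalise SNP identifiers to catalog names
    i <- match(interaction_ors$snp, catalog$rsid)
    interaction_ors$snp[!is.na(i)] <- catalog$name[i[!is.na(i)]]
  }

  fm <- list(
    menarche = list(values = 9:18,
                    probs = local({
                      p <- stats::dnorm(9:18, mean = 13, sd = 1.5)
                      p / sum(p)
                    })),
    age_first_birth = list(values = 14:45,
                           probs = local({
                             p <- stats::dnorm(14:45, mean = 25, sd = 4.5)
                             p / sum(p)
                           })),
    parous_prob = 0.85,
    n_births = list(base = 1.4, slope = 0.05, max = 10),
    bmi = list(meanlog = log(25.5), sdlog = 0.17),
    age = list(mean = 57, sd = 10, min = 25, max = 80)
  )
  if (!is.null(factor_models)) fm <- utils::modifyList(fm, factor_models)
  if (fm$parous_prob < 0 || fm$parous_prob > 1) {
    stop_gxe("gxe_config_error", "parous_prob must be in [0,1]")
  }

  miss <- list(menarche = 0, parity = 0, age_first_birth = 0, bmi = 0,
               dosage = 0)
  if (!is.null(missingness)) miss <- utils::modifyList(miss, missingness)
  if (any(unlist(miss) < 0) || any(unlist(miss) > 1)) {
    stop_gxe("gxe_config_error", "missingness rates must be in [0,1]")
  }

  sub <- list(p_er_pos = 0.75, p_pr_pos_given_er_pos = 0.8,
              p_pr_pos_given_er_neg = 0.3, unknown_rate = 0.25,
              er_dosage_log_or = NULL)
  if (!is.null(subtype_model)) sub <- utils::modifyList(sub, subtype_model)

  prev <- list(target = 0.10, band = c(0.05, 0.20))
  if (!is.null(prevalence)) prev <- utils::modifyList(prev, prevalence)
  if (prev$target < prev$band[1] || prev$target > prev$band[2]) {
    stop_gxe("gxe_config_error",
             "prevalence target outside the admissible band")
  }

  structure(list(studies = studies, catalog = catalog,
                 main_effect_ors = me, interaction_ors = interaction_ors,
                 factor_models = fm, missingness = miss,
                 subtype_model = sub, prevalence = prev),
            class = "sim_config")
}

#' Packaged default: a BCAC-like 21-study configuration
#'
#' Twenty-one case-control studies (11 of them flagged population-based)
#' with realistic per-study case/control counts totalling roughly 26,000
#' cases and 32,000 controls, the default 12-SNP catalog (frequencies and
#' per-allele ORs), protective trend effects for later menarche, parity and
#' higher parity count, an adverse effect of later first birth, an inverse
#' BMI effect confined to women under 55, and a single built-in interaction:
#' OR 1.05 per risk allele of 11p15-rs3817198 (LSP1) per live birth.
#' Missingness rates are set so per-analysis sample sizes vary across the
#' grid, as in pooled consortium data.
#'
#' @param scale multiplier applied to every study's case and control count
#'   (rounded up), for reduced-size runs; default 1.
#' @return a [sim_config()].
#' @export
bcac_sim_config <- function(scale = 1) {
  studies <- data.frame(
    label = c("ABCFS", "BBCC", "BBCS", "CGPS", "CNIO-BCS", "GENICA",
              "GESBC", "KBCP", "kConFab-AOCS", "LMBC", "MARIE", "MCBCS",
              "MCCS", "NC-BCFR", "OFBCR", "PBCS", "SASBAC", "SBCS",
              "SEARCH", "UCIBCS", "USRT"),
    n_cases = c(1239, 1200, 1338, 1450, 351, 917, 573, 430, 323, 818,
                2573, 1049, 682, 266, 982, 1937, 1408, 970, 6352, 795, 696),
    n_controls = c(610, 806, 1242, 6555, 649, 967, 859, 388, 171, 804,
                   5294, 1045, 749, 154, 328, 2322, 1400, 1088, 5282,
                   465, 1030),
    population_based = c(TRUE, FALSE, FALSE, TRUE, FALSE, TRUE, TRUE,
                         FALSE, FALSE, FALSE, TRUE, FALSE, TRUE, TRUE,
                         TRUE, TRUE, TRUE, FALSE, FALSE, TRUE, FALSE)
  )
  if (scale != 1) {
    studies$n_cases <- pmax(1L, ceiling(studies$n_cases * scale))
    studies$n_controls <- pmax(1L, ceiling(studies$n_controls * scale))
  }
  sim_config(
    studies = studies,
    catalog = default_snp_catalog(),
    main_effect_ors = c(menarche = 0.96, ever_birth = 0.84,
                        n_births = 0.89, age_first_birth = 1.07^(1 / 5),
                        bmi_lt55 = 0.97, bmi_ge55 = 1.00, age = 1.03),
    interaction_ors = data.frame(snp = "11p15-rs3817198",
                                 factor = "n_births", or = 1.05),
    missingness = list(menarche = 0.18, parity = 0.12,
                       age_first_birth = 0.15, bmi = 0.30, dosage = 0.12)
  )
}

#' Draw Hardy-Weinberg genotype dosages
#'
#' Independent risk-allele counts with genotype probabilities
#' `((1-q)^2, 2q(1-q), q^2)`, i.e. Binomial(2, q) draws.
#'
#' @param freq risk-allele frequency `q` in `[0, 1]`.
#' @param n number of draws.
#' @param seed optional seed for a self-contained draw; by default the
#'   current RNG stream is used.
#' @return integer vector of dosages in `{0, 1, 2}`.
#' @export
draw_genotypes <- function(freq, n, seed = NULL) {
  if (!is.numeric(freq) || length(freq) != 1L || is.na(freq) ||
      freq < 0 || freq > 1) {
    stop_gxe("gxe_config_error", "freq must be a single value in [0,1]")
  }
  if (!is.null(seed)) {
    return(with_substream(seed, "genotypes", expr = stats::rbinom(n, 2L, freq)))
  }
  stats::rbinom(n, 2L, freq)
}

# interaction log-OR lookup matrix: snp name x factor name
interaction_beta_matrix <- function(config) {
  cat <- config$catalog
  m <- matrix(0, nrow(cat), length(risk_factor_names()),
              dimnames = list(cat$name, risk_factor_names()))
  io <- config$interaction_ors
  if (nrow(io)) m[cbind(io$snp, io$factor)] <- log(io$or)
  m
}

#' Linear predictor of the generative disease model
#'
#' Computes the log-odds of disease for each record: study intercept +
#' per-allele SNP effects + risk-factor trend effects (menarche, parity,
#' number of births and age at first birth among parous women, BMI within
#' its age stratum, age) + any configured dosage-by-factor interaction
#' terms. Continuous covariates enter centred at typical values (menarche
#' 13, age at first birth 25, BMI 25.5, age 55), which affects only the
#' interpretation of the intercept; interaction products use the factor's
#' natural scale.
#'
#' @param records data frame with columns `study`, `age`, `menarche_age`,
#'   `parous`, `n_live_births`, `age_first_birth`, `bmi` and one dosage
#'   column per catalog rsID (complete, no missing values).
#' @param config a [sim_config()].
#' @param intercepts named numeric vector of per-study intercepts (a single
#'   unnamed value is recycled).
#' @return numeric vector of log-odds.
#' @export
disease_logit <- function(records, config, intercepts = 0) {
  st <- as.character(records$study)
  if (length(intercepts) == 1L && is.null(names(intercepts))) {
    alpha <- rep(intercepts, nrow(records))
  } else {
    if (!all(st %in% names(intercepts))) {
      stop_gxe("gxe_config_error", "unknown study label in records: ",
               paste(setdiff(st, names(intercepts)), collapse = ", "))
    }
    alpha <- unname(intercepts[st])
  }
  me <- log(config$main_effect_ors)
  par <- records$parous
  lt55 <- as.numeric(records$age < 55)
  eta <- alpha +
    me[["age"]] * (records$age - 55) +
    me[["menarche"]] * (records$menarche_age - 13) +
    me[["ever_birth"]] * par +
    par * me[["n_births"]] * records$n_live_births +
    par * me[["age_first_birth"]] * (records$age_first_birth - 25) +
    (records$bmi - 25.5) * (lt55 * me[["bmi_lt55"]] +
                            (1 - lt55) * me[["bmi_ge55"]])
  cat <- config$catalog
  bsnp <- log(cat$or_per_allele)
  for (k in seq_len(nrow(cat))) {
    eta <- eta + bsnp[k] * records[[cat$rsid[k]]]
  }
  bint <- interaction_beta_matrix(config)
  if (any(bint != 0)) {
    fvals <- cbind(menarche = records$menarche_age,
                   ever_birth = par,
                   n_births = par * records$n_live_births,
                   age_first_birth = par * records$age_first_birth,
                   bmi_lt55 = lt55 * records$bmi,
                   bmi_ge55 = (1 - lt55) * records$bmi)
    nz <- which(bint != 0, arr.ind = TRUE)
    for (r in seq_len(nrow(nz))) {
      snp_i <- nz[r, 1]; fac_j <- nz[r, 2]
      eta <- eta + bint[snp_i, fac_j] *
        records[[cat$rsid[snp_i]]] * fvals[, fac_j]
    }
  }
  unname(as.vector(eta))
}

# population covariate draws for one study (no missingness yet; parity
# fields drawn for everyone, blanked for nulliparous at assembly)
draw_population <- function(n, config, study_label) {
  fm <- config$factor_models
  a <- fm$age
  u <- stats::runif(n, stats::pnorm(a$min, a$mean, a$sd),
                    stats::pnorm(a$max, a$mean, a$sd))
  age <- round(stats::qnorm(u, a$mean, a$sd))
  menarche <- sample(fm$menarche$values, n, replace = TRUE,
                     prob = fm$menarche$probs)
  parous <- stats::rbinom(n, 1L, fm$parous_prob)
  afb <- sample(fm$age_first_birth$values, n, replace = TRUE,
                prob = fm$age_first_birth$probs)
  afb <- pmin(afb, age - 1L)   # first birth strictly before current age
  lam <- pmax(0.2, fm$n_births$base - fm$n_births$slope * (afb - 20))
  nb <- pmin(1L + stats::rpois(n, lam), fm$n_births$max)
  bmi <- stats::rlnorm(n, fm$bmi$meanlog, fm$bmi$sdlog)
  out <- data.frame(study = rep(study_label, n), age = age,
                    menarche_age = menarche, parous = parous,
                    n_live_births = nb, age_first_birth = afb, bmi = bmi,
                    stringsAsFactors = FALSE)
  for (k in seq_len(nrow(config$catalog))) {
    out[[config$catalog$rsid[k]]] <-
      stats::rbinom(n, 2L, config$catalog$risk_allele_freq[k])
  }
  out
}

# solve for the study intercept giving the target expected prevalence on a
# calibration sample of covariates drawn from the current stream
calibrate_intercept <- function(config, study_label, n_cal = 3000) {
  pop <- draw_population(n_cal, config, study_label)
  eta0 <- disease_logit(pop, config, intercepts = 0)
  target <- config$prevalence$target
  f <- function(a) mean(stats::plogis(a + eta0)) - target
  sol <- tryCatch(stats::uniroot(f, c(-30, 10), tol = 1e-8),
                  error = function(e) NULL)
  if (is.null(sol)) {
    stop_gxe("gxe_generation_error",
             "cannot calibrate study intercept for '", study_label,
             "' to prevalence ", target)
  }
  prev <- target
  band <- config$prevalence$band
  if (prev < band[1] || prev > band[2]) {
    stop_gxe("gxe_generation_error", "prevalence outside admissible band")
  }
  sol$root
}

sim_study <- function(config, study_row, master_seed, max_attempts = 40) {
  label <- study_row$label
  with_substream(master_seed, "study", label, "population", expr = {
    alpha <- calibrate_intercept(config, label)
    need_ca <- study_row$n_cases
    need_co <- study_row$n_controls
    prev <- config$prevalence$target
    cases <- list(); controls <- list()
    attempts <- 0L
    while (need_ca > 0L || need_co > 0L) {
      attempts <- attempts + 1L
      if (attempts > max_attempts) {
        stop_gxe("gxe_generation_error",
                 "attempt budget exhausted sampling study '", label, "'")
      }
      n_block <- ceiling(1.3 * max(need_ca / prev, need_co / (1 - prev)))
      n_block <- min(max(n_block, 100L), 400000L)
      pop <- draw_population(n_block, config, label)
      p <- stats::plogis(disease_logit(pop, config, intercepts = alpha))
      y <- as.integer(stats::runif(n_block) < p)
      if (need_ca > 0L) {
        idx <- which(y == 1L)
        take <- idx[seq_len(min(length(idx), need_ca))]
        if (length(take)) {
          cases[[length(cases) + 1L]] <- pop[take, , drop = FALSE]
          need_ca <- need_ca - length(take)
        }
      }
      if (need_co > 0L) {
        idx <- which(y == 0L)
        take <- idx[seq_len(min(length(idx), need_co))]
        if (length(take)) {
          controls[[length(controls) + 1L]] <- pop[take, , drop = FALSE]
          need_co <- need_co - length(take)
        }
      }
    }
    out <- rbind(do.call(rbind, cases), do.call(rbind, controls))
    out$is_case <- rep(c(1L, 0L), c(study_row$n_cases, study_row$n_controls))
    out
  })
}

apply_missingness <- function(study_df, config, master_seed) {
  label <- study_df$study[1]
  miss <- config$missingness
  n <- nrow(study_df)
  blank <- function(rate, field_key) {
    if (rate <= 0) return(rep(FALSE, n))
    with_substream(master_seed, "study", label, "miss", field_key,
                   expr = stats::runif(n) < rate)
  }
  study_df$menarche_age[blank(miss$menarche, "menarche")] <- NA_integer_
  mp <- blank(miss$parity, "parity")
  study_df$parous[mp] <- NA_integer_
  study_df$n_live_births[mp] <- NA_integer_
  study_df$age_first_birth[mp] <- NA_integer_
  ma <- blank(miss$age_first_birth, "afb")
  study_df$age_first_birth[ma] <- NA_integer_
  study_df$bmi[blank(miss$bmi, "bmi")] <- NA_real_
  drate <- miss$dosage
  for (rsid in config$catalog$rsid) {
    r <- if (length(drate) > 1L) (drate[[rsid]] %||% 0) else drate
    study_df[[rsid]][blank(r, paste0("dosage_", rsid))] <- NA_integer_
  }
  study_df
}

assign_subtypes <- function(study_df, config, master_seed) {
  label <- study_df$study[1]
  sub <- config$subtype_model
  n <- nrow(study_df)
  study_df$er <- NA_character_
  study_df$pr <- NA_character_
  ci <- which(study_df$is_case == 1L)
  if (!length(ci)) return(study_df)
  with_substream(master_seed, "study", label, "subtype", expr = {
    eta <- rep(stats::qlogis(sub$p_er_pos), length(ci))
    if (!is.null(sub$er_dosage_log_or)) {
      for (rsid in names(sub$er_dosage_log_or)) {
        d <- study_df[[rsid]][ci]
        d[is.na(d)] <- 0
        eta <- eta + sub$er_dosage_log_or[[rsid]] * d
      }
    }
    er_pos <- stats::runif(length(ci)) < stats::plogis(eta)
    p_pr <- ifelse(er_pos, sub$p_pr_pos_given_er_pos,
                   sub$p_pr_pos_given_er_neg)
    pr_pos <- stats::runif(length(ci)) < p_pr
    unk <- stats::runif(length(ci)) < sub$unknown_rate
    study_df$er[ci] <- ifelse(unk, "unknown",
                              ifelse(er_pos, "positive", "negative"))
    study_df$pr[ci] <- ifelse(unk, "unknown",
                              ifelse(pr_pos, "positive", "negative"))
  })
  study_df
}

#' Simulate a multi-study case-control cohort
#'
#' Per study: the intercept of the generative disease model is calibrated so
#' the expected population prevalence equals the configured target, records
#' are drawn from the population model, disease status is sampled from the
#' logistic probability, and cases and controls are accumulated by rejection
#' until the target counts are met (a bounded attempt budget guards against
#' infeasible configurations). Missingness and ER/PR case subtypes are then
#' applied. A single master seed spawns per-study, per-field substreams, so
#' the output is fully determined by `(config, seed)` and adding a study
#' leaves existing studies' records unchanged.
#'
#' @param config a [sim_config()].
#' @param seed integer master seed.
#' @return a validated cohort data frame (class `"gxe_cohort"`); rows are
#'   grouped by study, cases before controls, with attributes `"seed"` and
#'   `"intercepts"` recording the calibration.
#' @examples
#' cfg <- bcac_sim_config(scale = 0.01)
#' cohort <- simulate_cohort(cfg, seed = 1)
#' table(cohort$study, cohort$is_case)
#' @export
simulate_cohort <- function(config, seed) {
  if (!inherits(config, "sim_config")) {
    stop_gxe("gxe_config_error", "config must be a sim_config object")
  }
  if (!is_count(abs(seed) + 1)) {
    stop_gxe("gxe_config_error", "seed must be a single integer")
  }
  parts <- vector("list", nrow(config$studies))
  for (i in seq_len(nrow(config$studies))) {
    srow <- config$studies[i, ]
    df <- sim_study(config, srow, seed)
    df <- assign_subtypes(df, config, seed)
    df <- apply_missingness(df, config, seed)
    parts[[i]] <- df
  }
  cohort <- do.call(rbind, parts)
  rownames(cohort) <- NULL
  # parity fields are undefined (missing) for nulliparous women
  nullip <- !is.na(cohort$parous) & cohort$parous == 0L
  cohort$n_live_births[nullip] <- NA_integer_
  cohort$age_first_birth[nullip] <- NA_integer_
  cohort <- cohort[, c(cohort_fixed_cols, config$catalog$rsid)]
  cohort <- validate_cohort(cohort, config$catalog)
  attr(cohort, "seed") <- seed
  cohort
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation config:", nrow(x$studies), "studies,",
      nrow(x$catalog), "SNPs;",
      sum(x$studies$n_cases), "cases /",
      sum(x$studies$n_controls), "controls\n")
  io <- x$interaction_ors
  if (nrow(io)) {
    cat("interactions:\n")
    for (r in seq_len(nrow(io))) {
      cat("  ", io$snp[r], "x", io$factor[r], ": OR", io$or[r], "\n")
    }
  } else cat("no interaction effects (all ORs 1)\n")
  invisible(x)
}
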