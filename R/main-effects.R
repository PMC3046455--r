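# Descriptive model families: overall per-allele SNP ORs, age/study-adjusted
# risk-factor trend ORs, and category-stratified per-allele ORs obtained
# from a single joint model.

#' Per-allele odds ratio for one SNP
#'
#' Study-adjusted logistic regression with the risk-allele dosage entered
#' linearly (multiplicative per-allele model). With `adjust_age = TRUE` the
#' model additionally adjusts for age both categorically (bins <=34, 35-39,
#' ..., 70-74, >=75) and continuously; `adjust_factor` further adds the
#' category dummies of a risk factor and restricts to its availability
#' subset, mirroring subset analyses by risk-factor data availability.
#'
#' @param cohort cohort data frame.
#' @param snp SNP name (catalog `name` or rsID).
#' @param catalog a [snp_catalog()].
#' @param adjust_age add categorical + continuous age adjustment.
#' @param adjust_factor optional factor name; adds its category main-effect
#'   dummies and restricts rows to the factor's analysis subset.
#' @param level confidence level.
#' @return list with `or`, `ci` (length 2), `n_cases`, `n_controls`, `fit`.
#' @export
per_allele_or <- function(cohort, snp, catalog = default_snp_catalog(),
                          adjust_age = FALSE, adjust_factor = NULL,
                          level = 0.95) {
  srow <- catalog_row(catalog, snp)
  if (!is.null(adjust_factor)) {
    spec <- risk_factor_spec(adjust_factor)
    sub <- analysis_subset(cohort, srow, spec, catalog)
  } else {
    sub <- cohort[!is.na(cohort[[srow$rsid]]), , drop = FALSE]
    if (!nrow(sub)) {
      stop_gxe("gxe_empty_analysis", "no genotyped subjects for ", srow$name)
    }
  }
  d <- sub[[srow$rsid]]
  if (max(d) == min(d)) {
    stop_gxe("gxe_degenerate_error", "SNP ", srow$name,
             " is monomorphic in the analysis subset")
  }
  X <- cbind(design_base(sub, adjust_age = adjust_age), dosage = d)
  if (!is.null(adjust_factor)) {
    cats <- categorize(factor_values(sub, spec), spec)
    X <- cbind(X, dummy_cols(cats, paste0(spec$name, ":")))
  }
  fit <- fit_logistic(X, sub$is_case)
  ci <- wald_or_ci(fit, "dosage", level)
  list(snp = srow$name, or = unname(ci["or"]),
       ci = unname(ci[c("ci_low", "ci_high")]),
       n_cases = sum(sub$is_case == 1), n_controls = sum(sub$is_case == 0),
       fit = fit)
}

#' Risk-factor trend odds ratio
#'
#' Logistic regression of case status on the factor's continuous coding,
#' adjusted for study and for age (categorical bins plus continuous). The
#' trend OR is reported per `report_per` units of the factor (5 years for
#' age at first birth, 1 unit otherwise). Designed for population-based
#' style cohorts; the function itself is design-agnostic.
#'
#' @param cohort cohort data frame.
#' @param factor factor name or [risk_factor_spec()].
#' @param level confidence level.
#' @return list with `or` and `ci` on the reporting scale, `or_per_unit`
#'   and `ci_per_unit` on the model (per coded unit) scale, `n_cases`,
#'   `n_controls`, `fit`.
#' @export
risk_factor_trend <- function(cohort, factor, level = 0.95) {
  spec <- if (is.character(factor)) risk_factor_spec(factor) else factor
  v <- factor_values(cohort, spec)
  keep <- !is.na(v) & !is.na(cohort$age)
  if (!is.null(spec$age_range)) {
    keep <- keep & cohort$age >= spec$age_range[1] &
      cohort$age < spec$age_range[2]
  }
  if (spec$parous_only) keep <- keep & !is.na(cohort$parous) &
      cohort$parous == 1
  sub <- cohort[keep, , drop = FALSE]
  if (!nrow(sub)) {
    stop_gxe("gxe_empty_analysis", "no usable rows for factor ", spec$name)
  }
  vv <- (v[keep] - spec$offset) / spec$scale
  if (max(vv) == min(vv)) {
    stop_gxe("gxe_degenerate_error", "factor ", spec$name,
             " is constant in the analysis subset")
  }
  X <- cbind(design_base(sub, adjust_age = TRUE), factor = vv)
  fit <- fit_logistic(X, sub$is_case)
  ci <- wald_or_ci(fit, "factor", level)
  k <- spec$report_per
  list(factor = spec$name,
       or = unname(ci["or"])^k,
       ci = unname(ci[c("ci_low", "ci_high")])^k,
       or_per_unit = unname(ci["or"]),
       ci_per_unit = unname(ci[c("ci_low", "ci_high")]),
       report_per = k, unit = spec$unit,
       n_cases = sum(sub$is_case == 1), n_controls = sum(sub$is_case == 0),
       fit = fit)
}

#' Per-allele ORs stratified by risk-factor category, from one joint model
#'
#' Fits a single study-adjusted logistic model containing the factor's
#' category main-effect dummies plus one dosage slope per category
#' (category-specific per-allele log-ORs), and reports the per-category
#' per-allele OR with its Wald CI. A homogeneity LRT compares this model to
#' the common-slope model (category dummies + a single dosage term).
#' Categories in which only one outcome class (or no subject) is observed
#' are flagged and their OR omitted; the other categories are still
#' returned.
#'
#' @param cohort cohort data frame.
#' @param snp SNP name.
#' @param factor factor name or spec.
#' @param catalog a [snp_catalog()].
#' @param adjust_age add age adjustment terms (default `FALSE`: study-only
#'   adjustment, as in the interaction models).
#' @param level confidence level.
#' @return an object of class `"stratified_or_table"`: a data frame with
#'   one row per category (`category`, `or`, `ci_low`, `ci_high`, `se_log`,
#'   `n_cases`, `n_controls`, `flagged`) plus attributes `snp`, `factor`,
#'   `homogeneity` (the LRT against a common slope) and `fit`.
#' @export
stratified_per_allele_ors <- function(cohort, snp, factor,
                                      catalog = default_snp_catalog(),
                                      adjust_age = FALSE, level = 0.95) {
  spec <- if (is.character(factor)) risk_factor_spec(factor) else factor
  srow <- catalog_row(catalog, snp)
  sub <- analysis_subset(cohort, srow, spec, catalog)
  d <- sub[[srow$rsid]]
  cats <- categorize(factor_values(sub, spec), spec)
  cats <- droplevels(factor(cats, ordered = FALSE))
  present <- levels(cats)
  if (length(present) < 2L) {
    stop_gxe("gxe_degenerate_error",
             "fewer than two non-empty categories for ", spec$name)
  }
  # usable categories: both outcome classes and polymorphic dosage
  ok <- vapply(present, function(l) {
    i <- cats == l
    length(unique(sub$is_case[i])) == 2L && max(d[i]) > min(d[i])
  }, logical(1))
  use <- present[ok]
  if (!length(use)) {
    stop_gxe("gxe_degenerate_error",
             "no category supports a per-allele OR for ", srow$name)
  }
  keep <- cats %in% use
  sub2 <- sub[keep, , drop = FALSE]
  cats2 <- droplevels(cats[keep])
  d2 <- d[keep]
  X <- design_base(sub2, adjust_age = adjust_age)
  X <- cbind(X, dummy_cols(cats2, paste0(spec$name, ":")))
  # common slope plus per-category deviations: nests the common-OR model,
  # per-category log-ORs are contrasts beta_dosage (+ deviation)
  dev_cols <- NULL
  if (length(use) > 1L) {
    dev_cols <- vapply(levels(cats2)[-1L], function(l) d2 * (cats2 == l),
                       numeric(nrow(sub2)))
    colnames(dev_cols) <- paste0("dosage@", levels(cats2)[-1L])
  }
  Xnull <- cbind(X, dosage = d2)
  fit0 <- fit_logistic(Xnull, sub2$is_case)
  if (is.null(dev_cols)) {
    fit <- fit0
    hom <- list(statistic = NA_real_, df = 0L, p = NA_real_)
  } else {
    fit <- fit_logistic(cbind(Xnull, dev_cols), sub2$is_case)
    hom <- lrt(fit, fit0)
  }

  q <- stats::qnorm(1 - (1 - level) / 2)
  ref <- use[1L]
  res <- do.call(rbind, lapply(present, function(l) {
    i <- cats == l
    nca <- sum(sub$is_case[i] == 1); nco <- sum(sub$is_case[i] == 0)
    if (l %in% use) {
      if (l == ref) {
        b <- unname(fit$coefficients["dosage"])
        se <- sqrt(unname(diag(fit$cov)["dosage"]))
      } else {
        term <- paste0("dosage@", l)
        b <- unname(fit$coefficients["dosage"] + fit$coefficients[term])
        se <- sqrt(fit$cov["dosage", "dosage"] + fit$cov[term, term] +
                     2 * fit$cov["dosage", term])
      }
      data.frame(category = l, or = exp(b), ci_low = exp(b - q * se),
                 ci_high = exp(b + q * se), se_log = se,
                 n_cases = nca, n_controls = nco, flagged = FALSE)
    } else {
      data.frame(category = l, or = NA_real_, ci_low = NA_real_,
                 ci_high = NA_real_, se_log = NA_real_,
                 n_cases = nca, n_controls = nco, flagged = TRUE)
    }
  }))
  rownames(res) <- NULL
  structure(res, snp = srow$name, factor = spec$name,
            homogeneity = hom, fit = fit, level = level,
            class = c("stratified_or_table", "data.frame"))
}

#' @export
print.stratified_or_table <- function(x, ...) {
  cat("Per-allele ORs for ", attr(x, "snp"), " stratified by ",
      attr(x, "factor"), "\n", sep = "")
  print.data.frame(cbind(as.data.frame(x)[, c("category", "n_cases",
                                              "n_controls")],
                         round(as.data.frame(x)[, c("or", "ci_low",
                                                    "ci_high")], 3),
                         flagged = x$flagged),
                   row.names = FALSE)
  hom <- attr(x, "homogeneity")
  if (!is.na(hom$p)) {
    cat("homogeneity LRT: chi2 =", round(hom$statistic, 3),
        "df =", hom$df, "p =", signif(hom$p, 3), "\n")
  }
  invisible(x)
}

#' Forest plot of stratified per-allele ORs
#'
#' Horizontal forest plot on the log-OR scale: one box per risk-factor
#' category with its confidence interval; box area is inversely
#' proportional to the squared standard error of the log OR (side length
#' proportional to 1/SE).
#'
#' @param x a [stratified_per_allele_ors()] table.
#' @param xlim optional OR axis limits.
#' @param ... passed to [graphics::plot.default()].
#' @export
plot.stratified_or_table <- function(x, xlim = NULL, ...) {
  d <- as.data.frame(x)[!x$flagged, , drop = FALSE]
  if (!nrow(d)) {
    stop_gxe("gxe_input_error", "nothing to plot: all categories flagged")
  }
  ypos <- rev(seq_len(nrow(d)))
  if (is.null(xlim)) xlim <- range(c(d$ci_low, d$ci_high, 1))
  graphics::plot(NA, xlim = log(xlim), ylim = c(0.5, nrow(d) + 0.5),
                 yaxt = "n", xaxt = "n",
                 xlab = "per-allele OR (log scale)", ylab = "",
                 main = paste(attr(x, "snp"), "by", attr(x, "factor")), ...)
  ticks <- pretty(xlim, n = 6)
  ticks <- ticks[ticks > 0]
  graphics::axis(1, at = log(ticks), labels = ticks)
  graphics::axis(2, at = ypos, labels = d$category, las = 1)
  graphics::abline(v = 0, lty = 2, col = "grey50")
  graphics::segments(log(d$ci_low), ypos, log(d$ci_high), ypos)
  half <- 0.12 * (1 / d$se_log) / max(1 / d$se_log)
  graphics::symbols(log(d$or), ypos, squares = 2 * half, inches = FALSE,
                    add = TRUE, bg = "grey30", fg = "grey30")
  invisible(x)
}
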