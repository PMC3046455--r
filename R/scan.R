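# The 1-df product-term interaction scan across the SNP x risk-factor grid.

#' Enumerate the interaction test grid
#'
#' Deterministic SNP-major ordering: every SNP crossed with every factor, in
#' the order the factors are listed. The default 12-SNP catalog and six
#' factors give the 72-test grid.
#'
#' @param snps a [snp_catalog()] (or character vector of names resolved in
#'   `catalog`).
#' @param factors character vector of factor names.
#' @param catalog catalog used to resolve `snps` given as names.
#' @return data frame of class `"scan_grid"` with columns `snp`, `factor`.
#' @examples
#' nrow(scan_grid())  # 72
#' @export
scan_grid <- function(snps = default_snp_catalog(),
                      factors = risk_factor_names(),
                      catalog = default_snp_catalog()) {
  if (is.character(snps)) {
    snps <- do.call(rbind, lapply(snps, catalog_row, catalog = catalog))
  }
  if (!nrow(snps) || !length(factors)) {
    stop_gxe("gxe_config_error", "empty SNP or factor list")
  }
  if (anyDuplicated(snps$name)) {
    stop_gxe("gxe_config_error", "duplicate SNP names in grid")
  }
  bad <- setdiff(factors, risk_factor_names())
  if (length(bad)) {
    stop_gxe("gxe_config_error", "unknown factor(s): ",
             paste(bad, collapse = ", "))
  }
  grid <- data.frame(
    snp = rep(snps$name, each = length(factors)),
    factor = rep(factors, times = nrow(snps)),
    stringsAsFactors = FALSE)
  structure(grid, class = c("scan_grid", "data.frame"))
}

# design pieces for one interaction test; shared by interaction_test() and
# the bootstrap/permutation adjustment (which refits the same designs
# against simulated outcomes)
interaction_design <- function(cohort, snp, spec,
                               catalog = default_snp_catalog(),
                               adjust_age = FALSE) {
  if (is.character(spec)) spec <- risk_factor_spec(spec)
  srow <- catalog_row(catalog, snp)
  sub <- analysis_subset(cohort, srow, spec, catalog)
  idx <- match(rownames(sub), rownames(cohort))
  d <- sub[[srow$rsid]]
  f <- factor_values(sub, spec)
  y <- sub$is_case
  if (length(unique(y)) < 2L) {
    stop_gxe("gxe_degenerate_error", "single outcome class in subset")
  }
  if (max(d) == min(d)) {
    stop_gxe("gxe_degenerate_error", "dosage constant in subset for ",
             srow$name)
  }
  if (max(f) == min(f)) {
    stop_gxe("gxe_degenerate_error", "factor ", spec$name,
             " constant in subset")
  }
  base <- design_base(sub, adjust_age = adjust_age)
  Xnull <- cbind(base, dosage = d, factor = f)
  Xfull <- cbind(Xnull, "dosage:factor" = d * f)
  list(snp = srow$name, factor = spec$name,
       Xfull = Xfull, Xnull = Xnull, y = y, idx = idx,
       n_cases = sum(y == 1), n_controls = sum(y == 0))
}

#' One-degree-of-freedom interaction test for a (SNP, factor) pair
#'
#' Fits the interaction model — study dummies, per-allele dosage, the
#' factor's continuous coding, and a single product term for dosage times
#' factor — on the pair's complete-case analysis subset, and compares it by
#' likelihood-ratio test to the same model without the product term. The
#' interaction OR is the multiplicative change in the per-allele OR per
#' coded unit of the factor.
#'
#' @param cohort cohort data frame.
#' @param snp SNP name.
#' @param factor factor name or [risk_factor_spec()].
#' @param catalog a [snp_catalog()].
#' @param adjust_age optionally add age adjustment (categorical bins plus
#'   continuous) for sensitivity runs; the primary models adjust for study
#'   only.
#' @param level confidence level for the interaction OR.
#' @return a list of class `"gxe_interaction"`: `snp`, `factor`,
#'   `beta_int`, `or_int`, `ci`, `lrt_stat`, `df` (always 1), `p`,
#'   `n_cases`, `n_controls`, plus the full and null `gxe_fit`s. If the
#'   subset is degenerate or the fit separates, a flagged result is
#'   returned with `flag` holding the condition message and numeric fields
#'   `NA`.
#' @export
interaction_test <- function(cohort, snp, factor,
                             catalog = default_snp_catalog(),
                             adjust_age = FALSE, level = 0.95) {
  spec <- if (is.character(factor)) risk_factor_spec(factor) else factor
  res <- tryCatch({
    des <- interaction_design(cohort, snp, spec, catalog, adjust_age)
    full <- fit_logistic(des$Xfull, des$y)
    null <- fit_logistic(des$Xnull, des$y)
    test <- lrt(full, null)
    ci <- wald_or_ci(full, "dosage:factor", level)
    list(snp = des$snp, factor = spec$name,
         beta_int = unname(full$coefficients["dosage:factor"]),
         or_int = unname(ci["or"]),
         ci = unname(ci[c("ci_low", "ci_high")]),
         lrt_stat = test$statistic, df = test$df, p = test$p,
         n_cases = des$n_cases, n_controls = des$n_controls,
         flag = NA_character_, fit_full = full, fit_null = null)
  }, gxe_error = function(e) {
    list(snp = if (is.character(snp)) snp else snp$name,
         factor = spec$name,
         beta_int = NA_real_, or_int = NA_real_, ci = c(NA_real_, NA_real_),
         lrt_stat = NA_real_, df = 1L, p = NA_real_,
         n_cases = NA_integer_, n_controls = NA_integer_,
         flag = conditionMessage(e), fit_full = NULL, fit_null = NULL)
  })
  class(res) <- "gxe_interaction"
  res
}

#' @export
print.gxe_interaction <- function(x, ...) {
  cat("Interaction test:", x$snp, "x", x$factor, "\n")
  if (!is.na(x$flag)) {
    cat("  flagged:", x$flag, "\n")
    return(invisible(x))
  }
  cat(sprintf("  OR_int = %.4f (%.4f to %.4f) per allele per unit\n",
              x$or_int, x$ci[1], x$ci[2]))
  cat(sprintf("  LRT chi2 = %.4f, df = %d, p = %.4g   (n = %d cases / %d controls)\n",
              x$lrt_stat, x$df, x$p, x$n_cases, x$n_controls))
  invisible(x)
}

#' Run the interaction scan over a grid
#'
#' Applies [interaction_test()] to every (SNP, factor) pair of the grid, in
#' grid order. Pairs whose analysis subset is degenerate (e.g. a factor
#' entirely missing) yield flagged rows rather than errors, and are
#' excluded from the minimum p-value (with a warning available in the
#' summary).
#'
#' @param cohort cohort data frame.
#' @param grid a [scan_grid()]; defaults to the full catalog-by-factors
#'   grid restricted to SNPs with dosage columns present in `cohort`.
#' @param catalog a [snp_catalog()].
#' @param adjust_age passed to [interaction_test()].
#' @return an object of class `"gxe_scan"`: data frame with one row per
#'   test (`snp`, `factor`, `n_cases`, `n_controls`, `beta_int`, `or_int`,
#'   `ci_low`, `ci_high`, `lrt_stat`, `df`, `p`, `flag`) plus attributes
#'   `grid`, `adjust_age` and `results` (the full per-test objects).
#' @export
gxe_scan <- function(cohort, grid = NULL, catalog = default_snp_catalog(),
                     adjust_age = FALSE) {
  if (is.null(grid)) {
    present <- catalog[catalog$rsid %in% names(cohort), , drop = FALSE]
    grid <- scan_grid(present, risk_factor_names(), catalog)
  }
  results <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    results[[i]] <- interaction_test(cohort, grid$snp[i], grid$factor[i],
                                     catalog, adjust_age)
  }
  tab <- do.call(rbind, lapply(results, function(r) {
    data.frame(snp = r$snp, factor = r$factor,
               n_cases = r$n_cases, n_controls = r$n_controls,
               beta_int = r$beta_int, or_int = r$or_int,
               ci_low = r$ci[1], ci_high = r$ci[2],
               lrt_stat = r$lrt_stat, df = r$df, p = r$p,
               flag = r$flag, stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  structure(tab, grid = grid, adjust_age = adjust_age, results = results,
            catalog = catalog,
            class = c("gxe_scan", "data.frame"))
}

#' @export
print.gxe_scan <- function(x, digits = 4, ...) {
  n_flag <- sum(!is.na(x$flag))
  cat("Interaction scan:", nrow(x), "tests",
      if (n_flag) paste0("(", n_flag, " flagged)"), "\n")
  df <- as.data.frame(x)
  num <- c("or_int", "ci_low", "ci_high", "lrt_stat", "p")
  df[num] <- lapply(df[num], signif, digits = digits)
  print.data.frame(df[, c("snp", "factor", "n_cases", "n_controls",
                          "or_int", "ci_low", "ci_high", "p", "flag")],
                   row.names = FALSE)
  invisible(x)
}

#' @export
summary.gxe_scan <- function(object, alpha = 0.05, ...) {
  ok <- is.na(object$flag) & !is.na(object$p)
  m <- sum(ok)
  top <- which.min(ifelse(ok, object$p, Inf))
  out <- list(
    n_tests = nrow(object), n_used = m, n_flagged = nrow(object) - m,
    min_p = object$p[top],
    top_snp = object$snp[top], top_factor = object$factor[top],
    top_or_int = object$or_int[top],
    bonferroni_threshold = bonferroni_threshold(alpha, m),
    sidak_min_p = sidak(object$p[top], m))
  class(out) <- "summary.gxe_scan"
  out
}

#' @export
print.summary.gxe_scan <- function(x, ...) {
  cat("Interaction scan summary\n")
  cat("  tests:", x$n_tests, "(", x$n_flagged, "flagged )\n")
  cat(sprintf("  smallest unadjusted p = %.4g for %s x %s (OR_int %.3f)\n",
              x$min_p, x$top_snp, x$top_factor, x$top_or_int))
  cat(sprintf("  per-test threshold for family-wise 0.05: %.4g\n",
              x$bonferroni_threshold))
  cat(sprintf("  Sidak-adjusted smallest p (independence): %.4g\n",
              x$sidak_min_p))
  invisible(x)
}

#' Write a scan as TSV
#'
#' @param scan a `gxe_scan`.
#' @param path output path.
#' @export
write_scan <- function(scan, path) {
  utils::write.table(as.data.frame(scan), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
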