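# Risk-factor specifications: continuous codings, category systems and
# applicability (subset) rules for the six modifiers in the scan grid.

#' Names of the six risk factors in the interaction grid
#'
#' Age at menarche, ever having had a live birth, number of live births and
#' age at first birth (both parous women only), and BMI assessed separately
#' in women aged under 55 and 55 or older (age as a surrogate for menopausal
#' status).
#'
#' @return character vector of length 6.
#' @export
risk_factor_names <- function() {
  c("menarche", "ever_birth", "n_births", "age_first_birth",
    "bmi_lt55", "bmi_ge55")
}

#' Risk-factor specification
#'
#' Returns the coding, category system and applicability rule for one of the
#' six risk factors. The continuous coding is the scale on which the factor
#' enters models (years, live births, kg/m^2; ever-birth as 0/1);
#' `report_per` is the increment used when reporting trend ORs (5 years for
#' age at first birth, 1 unit otherwise), so reported OR = fitted OR ^
#' `report_per`. Category edges follow the conventional epidemiological
#' groupings: menarche at most 11, 12, 13, 14, 15-plus years; live births
#' 1, 2, 3, 4-plus; age at first birth to 19, 20-24, 25-29, 30-plus years;
#' BMI to 24.99, 25.00-29.99, 30.00-plus kg/m^2.
#'
#' @param name one of [risk_factor_names()].
#' @return a list of class `"risk_factor_spec"` with elements `name`,
#'   `label`, `column` (cohort column holding the raw value), `breaks`,
#'   `category_labels`, `offset`, `scale`, `report_per`, `parous_only`,
#'   `age_range` (allowed `[min, max)` age interval or `NULL`), `unit`.
#' @export
risk_factor_spec <- function(name = risk_factor_names()) {
  name <- match.arg(name)
  base <- list(offset = 0, scale = 1, report_per = 1,
               parous_only = FALSE, age_range = NULL)
  spec <- switch(name,
    menarche = list(
      label = "age at menarche", column = "menarche_age", unit = "year",
      breaks = c(-Inf, 11, 12, 13, 14, Inf),
      category_labels = c("<=11", "12", "13", "14", ">=15")),
    ever_birth = list(
      label = "ever had a live birth", column = "parous", unit = "0/1",
      breaks = c(-Inf, 0.5, Inf),
      category_labels = c("no", "yes")),
    n_births = list(
      label = "number of live births", column = "n_live_births",
      unit = "live birth",
      breaks = c(-Inf, 1, 2, 3, Inf),
      category_labels = c("1", "2", "3", ">=4"),
      parous_only = TRUE),
    age_first_birth = list(
      label = "age at first birth", column = "age_first_birth",
      unit = "year", report_per = 5,
      breaks = c(-Inf, 19, 24, 29, Inf),
      category_labels = c("<=19", "20-24", "25-29", ">=30"),
      parous_only = TRUE),
    bmi_lt55 = list(
      label = "BMI (age < 55)", column = "bmi", unit = "kg/m^2",
      breaks = c(-Inf, 24.99, 29.99, Inf),
      category_labels = c("<=24.99", "25.00-29.99", ">=30.00"),
      age_range = c(-Inf, 55)),
    bmi_ge55 = list(
      label = "BMI (age >= 55)", column = "bmi", unit = "kg/m^2",
      breaks = c(-Inf, 24.99, 29.99, Inf),
      category_labels = c("<=24.99", "25.00-29.99", ">=30.00"),
      age_range = c(55, Inf))
  )
  out <- utils::modifyList(base, spec)
  out$name <- name
  class(out) <- "risk_factor_spec"
  out
}

#' @export
print.risk_factor_spec <- function(x, ...) {
  cat("Risk factor:", x$name, "(", x$label, ")\n")
  cat("  coded per", x$unit,
      if (x$report_per != 1) paste0("(reported per ", x$report_per, " ",
                                    x$unit, "s)") else "", "\n")
  cat("  categories:", paste(x$category_labels, collapse = ", "), "\n")
  if (x$parous_only) cat("  parous women only\n")
  if (!is.null(x$age_range)) {
    cat("  age stratum: [", x$age_range[1], ",", x$age_range[2], ")\n")
  }
  invisible(x)
}

# raw model-entry values of a factor for each cohort row (NA where missing
# or inapplicable); ever_birth is the 0/1 parity indicator
factor_values <- function(cohort, spec) {
  v <- as.numeric(cohort[[spec$column]])
  if (spec$name %in% c("n_births", "age_first_birth")) {
    # defined for parous women only
    v[is.na(cohort$parous) | cohort$parous == 0] <- NA
  }
  v
}

# coded (model-scale) values: (raw - offset) / scale
factor_coded <- function(cohort, spec) {
  (factor_values(cohort, spec) - spec$offset) / spec$scale
}

#' Assign risk-factor values to reporting categories
#'
#' Bins raw factor values into the factor's ordered category system. Values
#' are assigned to exactly one category; missing values yield `NA` rather
#' than an error.
#'
#' @param value numeric vector of raw factor values.
#' @param spec a [risk_factor_spec()] (or a factor name).
#' @return an ordered factor with the spec's category labels.
#' @examples
#' categorize(c(27, 19, 31, NA), "age_first_birth")
#' @export
categorize <- function(value, spec) {
  if (is.character(spec)) spec <- risk_factor_spec(spec)
  cut(as.numeric(value), breaks = spec$breaks,
      labels = spec$category_labels,
      right = TRUE, ordered_result = TRUE)
}

# the age category system used for age adjustment in main-effect models
age_categories <- function(age) {
  cut(age, breaks = c(-Inf, 34, 39, 44, 49, 54, 59, 64, 69, 74, Inf),
      labels = c("<=34", "35-39", "40-44", "45-49", "50-54",
                 "55-59", "60-64", "65-69", "70-74", ">=75"),
      right = TRUE, ordered_result = TRUE)
}

#' Complete-case analysis subset for one (SNP, risk factor) pair
#'
#' Restricts a cohort to rows usable in the interaction model for the given
#' SNP and factor: non-missing risk-allele dosage, non-missing factor value,
#' parous women only for parity-count and age-at-first-birth factors, and
#' the relevant age stratum for the BMI factors. No imputation is performed;
#' each (SNP, factor) pair has its own complete-case subset, so per-analysis
#' sample sizes differ across the grid.
#'
#' @param cohort a cohort data frame (see [read_cohort()]).
#' @param snp SNP name or catalog row; its dosage column must exist.
#' @param factor factor name or [risk_factor_spec()].
#' @param catalog catalog used to resolve `snp` names.
#' @return the subset data frame, with attribute `"n"` (row count). An empty
#'   subset raises a condition of class `"gxe_empty_analysis"`.
#' @export
analysis_subset <- function(cohort, snp, factor,
                            catalog = default_snp_catalog()) {
  if (is.character(factor)) factor <- risk_factor_spec(factor)
  if (is.character(snp) && length(snp) == 1L) {
    snp <- catalog_row(catalog, snp)
  }
  dcol <- snp$rsid
  if (!dcol %in% names(cohort)) {
    stop_gxe("gxe_config_error", "cohort lacks dosage column '", dcol, "'")
  }
  keep <- !is.na(cohort[[dcol]]) & !is.na(factor_values(cohort, factor))
  if (!is.null(factor$age_range)) {
    keep <- keep & !is.na(cohort$age) &
      cohort$age >= factor$age_range[1] & cohort$age < factor$age_range[2]
  }
  if (factor$parous_only) {
    keep <- keep & !is.na(cohort$parous) & cohort$parous == 1
  }
  out <- cohort[keep, , drop = FALSE]
  if (nrow(out) == 0L) {
    stop_gxe("gxe_empty_analysis",
             "empty analysis subset for SNP ", snp$name,
             " and factor ", factor$name)
  }
  attr(out, "n") <- nrow(out)
  out
}
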