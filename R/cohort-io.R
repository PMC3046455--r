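# Cohort table I/O and validation.
#
# A cohort is a plain data frame, one row per woman, with the fixed columns
#   study, is_case, age, menarche_age, parous, n_live_births,
#   age_first_birth, bmi, er, pr
# followed by one integer dosage column (0/1/2/NA) per SNP, named by rsID.
# On disk it is a UTF-8 TSV with a header row and "NA" for missing values.

cohort_fixed_cols <- c("study", "is_case", "age", "menarche_age", "parous",
                       "n_live_births", "age_first_birth", "bmi", "er", "pr")

#' Validate a cohort table
#'
#' Checks the schema and the record-level invariants: `is_case` is 0/1;
#' dosages are in 0/1/2 or missing; `n_live_births >= 1` where parous and
#' present; `age_first_birth` does not exceed age; `bmi > 0` where present.
#'
#' @param cohort data frame to validate.
#' @param catalog catalog whose rsIDs must appear as dosage columns
#'   (`NULL` skips the catalog check; any `rs*` columns are then taken as
#'   dosages).
#' @return the cohort, invisibly, with class `"gxe_cohort"` prepended.
#' @export
validate_cohort <- function(cohort, catalog = NULL) {
  missing_cols <- setdiff(cohort_fixed_cols, names(cohort))
  if (length(missing_cols)) {
    stop_gxe("gxe_schema_error", "cohort lacks column(s): ",
             paste(missing_cols, collapse = ", "))
  }
  dcols <- cohort_dosage_cols(cohort, catalog)
  if (!length(dcols)) {
    stop_gxe("gxe_schema_error", "cohort has no dosage columns")
  }
  if (!all(cohort$is_case %in% c(0L, 1L))) {
    stop_gxe("gxe_schema_error", "is_case must be 0/1 with no missing values")
  }
  for (d in dcols) {
    v <- cohort[[d]]
    if (!all(is.na(v) | v %in% 0:2)) {
      stop_gxe("gxe_schema_error", "dosage column ", d,
               " has values outside {0,1,2,NA}")
    }
  }
  par <- !is.na(cohort$parous) & cohort$parous == 1
  nb <- cohort$n_live_births
  if (any(par & !is.na(nb) & nb < 1)) {
    stop_gxe("gxe_schema_error", "parous records must have n_live_births >= 1")
  }
  afb <- cohort$age_first_birth
  if (any(!is.na(afb) & !is.na(cohort$age) & afb > cohort$age)) {
    stop_gxe("gxe_schema_error", "age_first_birth exceeds age for some records")
  }
  if (any(!is.na(cohort$bmi) & cohort$bmi <= 0)) {
    stop_gxe("gxe_schema_error", "bmi must be positive where present")
  }
  if (!inherits(cohort, "gxe_cohort")) {
    class(cohort) <- c("gxe_cohort", class(cohort))
  }
  invisible(cohort)
}

cohort_dosage_cols <- function(cohort, catalog = NULL) {
  if (!is.null(catalog)) {
    miss <- setdiff(catalog$rsid, names(cohort))
    if (length(miss)) {
      stop_gxe("gxe_schema_error", "cohort lacks dosage column(s): ",
               paste(miss, collapse = ", "))
    }
    return(catalog$rsid)
  }
  grep("^rs[0-9]+$", names(cohort), value = TRUE)
}

#' Read / write a cohort TSV
#'
#' Tab-separated, header row, `NA` for missing, UTF-8; dosages stored as
#' integers. [write_cohort()] is byte-deterministic for a given cohort, so
#' re-running a seeded simulation reproduces the file exactly.
#'
#' @param path file path.
#' @param catalog optional catalog for schema validation.
#' @return [read_cohort()] returns a validated cohort data frame;
#'   [write_cohort()] invisibly returns `path`.
#' @export
read_cohort <- function(path, catalog = NULL) {
  cohort <- utils::read.delim(path, sep = "\t", header = TRUE,
                              na.strings = "NA", stringsAsFactors = FALSE,
                              check.names = FALSE, fileEncoding = "UTF-8")
  for (d in cohort_dosage_cols(cohort, catalog)) {
    cohort[[d]] <- as.integer(cohort[[d]])
  }
  validate_cohort(cohort, catalog)
}

#' @rdname read_cohort
#' @param cohort a cohort data frame.
#' @export
write_cohort <- function(cohort, path) {
  num <- vapply(cohort, is.double, logical(1))
  out <- as.data.frame(cohort)
  # fixed decimal formatting keeps the file byte-stable across platforms
  for (j in which(num)) out[[j]] <- formatC(out[[j]], format = "fg",
                                            digits = 10, width = 1)
  out[is.na(cohort)] <- "NA"
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @export
print.gxe_cohort <- function(x, ...) {
  dcols <- cohort_dosage_cols(x)
  cat("Case-control cohort: ", nrow(x), " subjects (",
      sum(x$is_case == 1), " cases / ", sum(x$is_case == 0), " controls), ",
      length(unique(x$study)), " studies, ", length(dcols), " SNPs\n",
      sep = "")
  tab <- table(x$study, factor(x$is_case, c(0, 1), c("controls", "cases")))
  print(tab)
  invisible(x)
}
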