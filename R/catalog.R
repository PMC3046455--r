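# SNP catalog: definitions of the loci under study, their risk alleles,
# risk-allele frequencies and (for simulation defaults) per-allele ORs.

#' Construct a SNP catalog
#'
#' A SNP catalog is a data frame with one row per locus and columns
#' `name` (locus-rsID label, unique), `gene` (free-text gene label),
#' `other_allele` and `risk_allele` (single characters), `risk_allele_freq`
#' (population frequency of the risk allele, strictly between 0 and 1) and
#' `or_per_allele` (per-allele odds ratio used as the simulation default).
#' The `rsid` column is derived from `name` and names the dosage columns of
#' a cohort table.
#'
#' Note that `risk_allele_freq` is the frequency of the *risk* allele, which
#' may exceed 0.5 (it is not constrained to be the minor allele).
#'
#' @param name character vector of unique locus-rsID labels, e.g.
#'   `"10q26-rs2981582"`.
#' @param risk_allele,other_allele single-character allele codes per SNP.
#' @param risk_allele_freq numeric in (0, 1).
#' @param gene gene label(s); free text.
#' @param or_per_allele per-allele odds ratio defaults for simulation;
#'   must be positive.
#' @return a `data.frame` of class `"snp_catalog"`.
#' @seealso [default_snp_catalog()], [read_snp_catalog()]
#' @export
snp_catalog <- function(name, risk_allele, other_allele,
                        risk_allele_freq, gene = NA_character_,
                        or_per_allele = 1) {
  n <- length(name)
  cat <- data.frame(
    name = as.character(name),
    gene = rep_len(as.character(gene), n),
    other_allele = rep_len(toupper(as.character(other_allele)), n),
    risk_allele = rep_len(toupper(as.character(risk_allele)), n),
    risk_allele_freq = rep_len(as.numeric(risk_allele_freq), n),
    or_per_allele = rep_len(as.numeric(or_per_allele), n),
    stringsAsFactors = FALSE
  )
  cat$rsid <- sub("^.*-(rs[0-9]+)$", "\\1", cat$name)
  validate_snp_catalog(cat)
  class(cat) <- c("snp_catalog", "data.frame")
  cat
}

validate_snp_catalog <- function(cat) {
  if (anyDuplicated(cat$name)) {
    stop_gxe("gxe_config_error", "duplicate SNP names in catalog: ",
             paste(cat$name[duplicated(cat$name)], collapse = ", "))
  }
  if (anyDuplicated(cat$rsid)) {
    stop_gxe("gxe_config_error", "duplicate rsIDs in catalog")
  }
  bad <- !is.finite(cat$risk_allele_freq) |
    cat$risk_allele_freq <= 0 | cat$risk_allele_freq >= 1
  if (any(bad)) {
    stop_gxe("gxe_config_error",
             "risk_allele_freq must lie strictly in (0,1) for: ",
             paste(cat$name[bad], collapse = ", "))
  }
  if (any(!is.finite(cat$or_per_allele) | cat$or_per_allele <= 0)) {
    stop_gxe("gxe_config_error", "or_per_allele must be positive")
  }
  if (any(nchar(cat$risk_allele) != 1L | nchar(cat$other_allele) != 1L)) {
    stop_gxe("gxe_config_error", "alleles must be single characters")
  }
  if (any(cat$risk_allele == cat$other_allele)) {
    stop_gxe("gxe_config_error", "risk and other allele must differ")
  }
  invisible(cat)
}

#' The default 12-SNP catalog
#'
#' Twelve common breast cancer susceptibility variants with their risk
#' alleles, risk-allele frequencies and per-allele odds ratios, shipped with
#' the package as a JSON file and used as the simulator's default genetic
#' architecture. One locus (2q35-rs13387042) has a risk-allele frequency
#' above 0.5.
#'
#' @return a [snp_catalog()] with 12 rows.
#' @export
default_snp_catalog <- function() {
  path <- system.file("extdata", "snp_catalog.json", package = "gxeminp",
                      mustWork = TRUE)
  read_snp_catalog(path)
}

#' Read / write a SNP catalog as JSON
#'
#' @param path file path of a JSON catalog with a top-level `snps` array.
#' @return [read_snp_catalog()] returns a `snp_catalog`;
#'   [write_snp_catalog()] invisibly returns `path`.
#' @export
read_snp_catalog <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$snps)) {
    stop_gxe("gxe_config_error", "catalog JSON lacks a 'snps' array: ", path)
  }
  s <- obj$snps
  snp_catalog(name = s$name, risk_allele = s$risk_allele,
              other_allele = s$other_allele,
              risk_allele_freq = s$risk_allele_freq,
              gene = s$gene %||% NA_character_,
              or_per_allele = s$or_per_allele %||% 1)
}

#' @rdname read_snp_catalog
#' @param catalog a `snp_catalog`.
#' @export
write_snp_catalog <- function(catalog, path) {
  cols <- c("name", "gene", "other_allele", "risk_allele",
            "risk_allele_freq", "or_per_allele")
  jsonlite::write_json(list(snps = as.data.frame(catalog)[, cols]),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

catalog_row <- function(catalog, snp) {
  i <- match(snp, catalog$name)
  if (is.na(i)) i <- match(snp, catalog$rsid)
  if (is.na(i)) {
    stop_gxe("gxe_config_error", "SNP not in catalog: ", snp)
  }
  catalog[i, , drop = FALSE]
}

#' Count risk alleles in genotype calls
#'
#' Converts biallelic genotype calls (two-character strings such as `"CT"`)
#' into risk-allele dosages 0/1/2 under the multiplicative per-allele coding.
#' Missing calls (`NA` or `""`) propagate as `NA`. A call containing an
#' allele that is not one of the SNP's two alleles is an error, not a silent
#' `NA`.
#'
#' @param calls character vector of two-letter genotype calls.
#' @param snp a single-row subset of a [snp_catalog()], or a SNP name looked
#'   up in `catalog`.
#' @param catalog catalog used when `snp` is given as a name.
#' @return integer vector of risk-allele counts with `NA` for missing calls.
#' @examples
#' cat12 <- default_snp_catalog()
#' encode_dosage(c("CT", "TT", "CC", NA), "10q26-rs2981582", cat12)
#' @export
encode_dosage <- function(calls, snp, catalog = default_snp_catalog()) {
  if (is.character(snp) && length(snp) == 1L) {
    snp <- catalog_row(catalog, snp)
  }
  calls <- toupper(as.character(calls))
  calls[calls == ""] <- NA_character_
  out <- rep(NA_integer_, length(calls))
  ok <- !is.na(calls)
  if (!any(ok)) return(out)
  if (any(nchar(calls[ok]) != 2L)) {
    stop_gxe("gxe_invalid_call",
             "genotype calls must be two-letter strings for SNP ", snp$name)
  }
  a1 <- substr(calls, 1L, 1L)
  a2 <- substr(calls, 2L, 2L)
  valid <- c(snp$risk_allele, snp$other_allele)
  bad <- ok & (!(a1 %in% valid) | !(a2 %in% valid))
  if (any(bad)) {
    stop_gxe("gxe_invalid_call",
             "invalid genotype call(s) for SNP ", snp$name,
             " (alleles ", snp$other_allele, "/", snp$risk_allele, "): ",
             paste(unique(calls[bad]), collapse = ", "))
  }
  out[ok] <- (a1[ok] == snp$risk_allele) + (a2[ok] == snp$risk_allele)
  out
}

#' @export
print.snp_catalog <- function(x, ...) {
  cat("SNP catalog:", nrow(x), "loci\n")
  df <- as.data.frame(x)
  df$alleles <- paste0(df$other_allele, "/", df$risk_allele)
  print.data.frame(df[, c("name", "gene", "alleles",
                          "risk_allele_freq", "or_per_allele")],
                   row.names = FALSE, ...)
  invisible(x)
}
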