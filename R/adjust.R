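# Single-step min-p family-wise adjustment of the interaction scan, by
# parametric bootstrap (outcomes redrawn from each test's fitted null
# model) or by within-study permutation of case-control labels.

#' Fitted null-model case probabilities for one test
#'
#' Fits the main-effects-only model (study dummies, per-allele dosage,
#' continuous risk factor — everything in the interaction model except the
#' product term) on the test's analysis subset and returns each subject's
#' fitted probability of being a case. These probabilities generate the
#' dummy case-control statuses of the parametric bootstrap.
#'
#' @param cohort cohort data frame.
#' @param snp SNP name.
#' @param factor factor name or [risk_factor_spec()].
#' @param catalog a [snp_catalog()].
#' @return numeric vector of fitted probabilities (one per subset subject),
#'   with attribute `"idx"` giving each subject's row position in `cohort`.
#' @export
null_probabilities <- function(cohort, snp, factor,
                               catalog = default_snp_catalog()) {
  spec <- if (is.character(factor)) risk_factor_spec(factor) else factor
  des <- interaction_design(cohort, snp, spec, catalog)
  fit <- fit_logistic(des$Xnull, des$y)
  probs <- stats::plogis(drop(cbind(1, des$Xnull) %*% fit$coefficients))
  attr(probs, "idx") <- des$idx
  probs
}

# Precompute everything the replicate loop needs: per-test centered design
# matrices with intercept, null probabilities, and warm-start coefficients.
# Flagged scan rows are carried along but excluded from the minimum.
minp_prep <- function(scan, cohort, catalog = NULL) {
  if (!inherits(scan, "gxe_scan")) {
    stop_gxe("gxe_input_error", "scan must be a gxe_scan object")
  }
  catalog <- catalog %||% attr(scan, "catalog") %||% default_snp_catalog()
  grid <- attr(scan, "grid")
  adjust_age <- attr(scan, "adjust_age") %||% FALSE
  active <- which(is.na(scan$flag))
  if (!length(active)) {
    stop_gxe("gxe_input_error", "no unflagged tests to adjust")
  }
  tests <- lapply(active, function(i) {
    des <- interaction_design(cohort, grid$snp[i], grid$factor[i],
                              catalog, adjust_age)
    ctr_f <- colMeans(des$Xfull)
    ctr_n <- colMeans(des$Xnull)
    Xf <- cbind(1, sweep(des$Xfull, 2L, ctr_f))
    Xn <- cbind(1, sweep(des$Xnull, 2L, ctr_n))
    sf <- irls_logit_cpp(Xf, des$y, c(stats::qlogis(mean(des$y)),
                                      rep(0, ncol(des$Xfull))),
                         1e-8, 100L, 15, FALSE)
    sn <- irls_logit_cpp(Xn, des$y, c(stats::qlogis(mean(des$y)),
                                      rep(0, ncol(des$Xnull))),
                         1e-8, 100L, 15, FALSE)
    if (sf$status != 0L || sn$status != 0L) {
      stop_gxe("gxe_convergence_error",
               "null-model fit failed for ", grid$snp[i], " x ",
               grid$factor[i])
    }
    probs <- stats::plogis(drop(Xn %*% sn$coefficients))
    list(snp = grid$snp[i], factor = grid$factor[i],
         Xfull = Xf, Xnull = Xn, idx = des$idx, y = des$y,
         start_full = drop(sf$coefficients),
         start_null = drop(sn$coefficients),
         null_probs = probs)
  })
  list(tests = tests, active = active, n_cohort = nrow(cohort),
       study = as.character(cohort$study),
       y_cohort = cohort$is_case,
       p_unadj = scan$p[active])
}

# LRT p-values for all tests against a block of simulated outcome columns;
# outcomes[[t]] is an n_t x chunk 0/1 matrix
chunk_pvalues <- function(prep, outcomes) {
  vapply(seq_along(prep$tests), function(t) {
    tt <- prep$tests[[t]]
    stats <- lrt_batch_cpp(tt$Xfull, tt$Xnull, outcomes[[t]],
                           tt$start_full, tt$start_null, 1e-8, 100L, 15)
    stats::pchisq(stats, df = 1, lower.tail = FALSE)
  }, numeric(ncol(outcomes[[1]])))
}

replicate_uniforms <- function(prep, seed, b_range) {
  # one uniform per cohort subject per replicate, from a replicate-indexed
  # substream: results do not depend on chunking or worker count
  vapply(b_range, function(b) {
    with_substream(seed, "replicate", b,
                   expr = stats::runif(prep$n_cohort))
  }, numeric(prep$n_cohort))
}

replicate_permutations <- function(prep, seed, b_range) {
  studies <- prep$study
  split_idx <- split(seq_along(studies), studies)
  vapply(b_range, function(b) {
    with_substream(seed, "permutation", b, expr = {
      y <- prep$y_cohort
      for (ii in split_idx) y[ii] <- y[ii][sample.int(length(ii))]
      as.numeric(y)
    })
  }, numeric(prep$n_cohort))
}

#' One parametric-bootstrap replicate: the minimum p across the grid
#'
#' Draws a single uniform per subject, assigns dummy case status per test
#' by comparing the uniform with the test's fitted null probability, refits
#' the interaction and main-effects models per test against the real
#' covariates, and returns the minimum likelihood-ratio p-value across the
#' grid. Exposed mainly for inspection and testing; [adjust_minp()] runs
#' the full replicate loop.
#'
#' @param scan a [gxe_scan()] result.
#' @param cohort cohort data frame the scan was computed on.
#' @param seed replicate seed (replicate `b` of a run with master seed `s`
#'   uses the `(s, b)` substream).
#' @param b replicate index.
#' @param prep precomputed internals (from a prior call), to avoid
#'   refitting null models; when supplied, `scan`/`cohort` are ignored.
#' @return the minimum p-value (scalar); `NA` if every test's replicate fit
#'   failed.
#' @export
bootstrap_replicate <- function(scan, cohort, seed, b = 1L, prep = NULL) {
  prep <- prep %||% minp_prep(scan, cohort)
  U <- replicate_uniforms(prep, seed, b)
  outcomes <- lapply(prep$tests, function(tt) {
    matrix(as.numeric(U[tt$idx, 1] < tt$null_probs), ncol = 1)
  })
  P <- chunk_pvalues(prep, outcomes)
  if (all(is.na(P))) NA_real_ else min(P, na.rm = TRUE)
}

#' Adjusted p-value from a replicate min-p sample
#'
#' The strict rule is `#(min-p < p) / B`; the `add_one` rule is
#' `(#(min-p < p) + 1) / (B + 1)`, which cannot return exactly zero.
#'
#' @param p unadjusted p-value(s).
#' @param minp numeric vector of replicate minimum p-values (`NA`s dropped).
#' @param tie_rule `"strict"` or `"add_one"`.
#' @return adjusted p-value(s) in `[0, 1]`.
#' @export
p_adjust_from_minp <- function(p, minp, tie_rule = c("strict", "add_one")) {
  tie_rule <- match.arg(tie_rule)
  minp <- minp[!is.na(minp)]
  B <- length(minp)
  if (!B) stop_gxe("gxe_input_error", "empty replicate sample")
  cnt <- vapply(p, function(pi) sum(minp < pi), numeric(1))
  if (tie_rule == "strict") cnt / B else (cnt + 1) / (B + 1)
}

#' Min-p multiple-testing adjustment of an interaction scan
#'
#' Single-step family-wise adjustment. For each of `B` replicates a dummy
#' case-control status is generated for every subject — by sampling from
#' the test-specific fitted null probabilities (`method = "bootstrap"`, one
#' shared uniform per subject per replicate compared against each test's
#' probabilities) or by permuting observed labels within study
#' (`method = "permutation"`) — each test's interaction model is refitted
#' against the real covariates, and the minimum likelihood-ratio p-value
#' across the grid is recorded. Each test's adjusted p-value is the
#' proportion of replicate minima below its unadjusted p-value.
#'
#' Replicate fits that fail to converge are dropped from that replicate's
#' minimum (counted in the result); the run errors if more than 1% of all
#' replicate fits fail. Flagged scan rows are excluded from the family with
#' a warning.
#'
#' @param scan a [gxe_scan()] result.
#' @param cohort the cohort the scan was computed on.
#' @param B number of replicates (default 10,000).
#' @param seed master seed; replicate `b` uses substream `(seed, b)`.
#' @param tie_rule `"strict"` (proportion strictly below, can be exactly 0)
#'   or `"add_one"` (`(count + 1) / (B + 1)`).
#' @param method `"bootstrap"` (parametric) or `"permutation"`
#'   (within-study label permutation).
#' @param catalog catalog (defaults to the scan's).
#' @param chunk replicates per block in the inner loop (memory/speed
#'   trade-off only; results are chunk-invariant).
#' @return an object of class `"gxe_adjusted"`: the scan data frame plus
#'   `p_adjusted`, with attributes `B`, `seed`, `method`, `tie_rule`,
#'   `minp` (the replicate min-p sample), `n_failed_fits`,
#'   `n_dropped_replicates`.
#' @export
adjust_minp <- function(scan, cohort, B = 10000L, seed,
                        tie_rule = c("strict", "add_one"),
                        method = c("bootstrap", "permutation"),
                        catalog = NULL, chunk = 100L) {
  tie_rule <- match.arg(tie_rule)
  method <- match.arg(method)
  if (!is_count(B)) stop_gxe("gxe_input_error", "B must be a positive integer")
  if (B < 100L) {
    warning("B = ", B, " gives adjusted p-values with resolution 1/", B,
            "; increase B for more precision", call. = FALSE)
  }
  if (any(!is.na(scan$flag))) {
    warning(sum(!is.na(scan$flag)),
            " flagged test(s) excluded from the min-p family", call. = FALSE)
  }
  prep <- minp_prep(scan, cohort, catalog)
  m <- length(prep$tests)
  minp <- rep(NA_real_, B)
  n_failed <- 0L
  done <- 0L
  while (done < B) {
    b_range <- (done + 1L):min(done + chunk, B)
    if (method == "bootstrap") {
      U <- replicate_uniforms(prep, seed, b_range)
      outcomes <- lapply(prep$tests, function(tt) {
        (U[tt$idx, , drop = FALSE] < tt$null_probs) + 0
      })
    } else {
      Yp <- replicate_permutations(prep, seed, b_range)
      outcomes <- lapply(prep$tests, function(tt) {
        Yp[tt$idx, , drop = FALSE]
      })
    }
    P <- chunk_pvalues(prep, outcomes)   # chunk-length x m (or vector)
    P <- matrix(P, ncol = m)
    n_failed <- n_failed + sum(is.na(P))
    minp[b_range] <- apply(P, 1L, function(r) {
      if (all(is.na(r))) NA_real_ else min(r, na.rm = TRUE)
    })
    done <- done + length(b_range)
  }
  if (n_failed > 0.01 * B * m) {
    stop_gxe("gxe_convergence_error", n_failed, " of ", B * m,
             " replicate fits failed to converge (> 1%)")
  }
  dropped <- sum(is.na(minp))
  p_adj <- rep(NA_real_, nrow(scan))
  p_adj[prep$active] <- p_adjust_from_minp(prep$p_unadj, minp, tie_rule)
  out <- as.data.frame(scan)
  out$p_adjusted <- p_adj
  structure(out, B = B, seed = seed, method = method, tie_rule = tie_rule,
            minp = minp, n_failed_fits = n_failed,
            n_dropped_replicates = dropped,
            class = c("gxe_adjusted", "data.frame"))
}

#' @rdname adjust_minp
#' @export
permutation_adjust <- function(scan, cohort, B = 10000L, seed,
                               tie_rule = c("strict", "add_one"),
                               catalog = NULL, chunk = 100L) {
  adjust_minp(scan, cohort, B = B, seed = seed, tie_rule = tie_rule,
              method = "permutation", catalog = catalog, chunk = chunk)
}

#' @export
print.gxe_adjusted <- function(x, digits = 4, ...) {
  cat("Min-p adjusted interaction scan (", attr(x, "method"),
      ", B = ", attr(x, "B"), ", tie rule ", attr(x, "tie_rule"), ")\n",
      sep = "")
  df <- as.data.frame(x)
  num <- c("or_int", "p", "p_adjusted")
  df[num] <- lapply(df[num], signif, digits = digits)
  print.data.frame(df[order(df$p), c("snp", "factor", "or_int", "p",
                                     "p_adjusted")],
                   row.names = FALSE)
  nf <- attr(x, "n_failed_fits")
  if (nf) cat(nf, "replicate fit(s) failed and were dropped\n")
  invisible(x)
}

#' Closed-form baselines for the family-wise adjustment
#'
#' [sidak()] gives the exact single-step adjustment for independent tests,
#' `1 - (1 - p)^m`, the large-B limit of the min-p adjustment when tests
#' are independent. [bonferroni_threshold()] gives the per-test
#' significance level `alpha / m` controlling the family-wise error rate at
#' `alpha`; for the 72-test grid at `alpha = 0.05` this is 0.000694, i.e.
#' 0.0007 at one significant figure.
#'
#' @param p unadjusted p-value(s) in `[0, 1]`.
#' @param m number of tests (>= 1).
#' @param alpha target family-wise error rate.
#' @return adjusted p-value(s) / per-test threshold.
#' @export
sidak <- function(p, m) {
  if (any(p < 0 | p > 1, na.rm = TRUE) || m < 1) {
    stop_gxe("gxe_input_error", "need 0 <= p <= 1 and m >= 1")
  }
  1 - (1 - p)^m
}

#' @rdname sidak
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (alpha <= 0 || alpha >= 1 || m < 1) {
    stop_gxe("gxe_input_error", "need 0 < alpha < 1 and m >= 1")
  }
  alpha / m
}
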