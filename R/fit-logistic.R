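# Logistic regression by IRLS, likelihood-ratio tests and Wald intervals.
# All model fitting in the package funnels through fit_logistic(); the hot
# bootstrap loops reuse the same compiled routine via lrt_batch_cpp.

#' Fit a binary logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood logistic regression with Newton/IRLS iterations,
#' step-halving when a step would decrease the likelihood, convergence
#' declared when every score component is below `tol`, and explicit error
#' conditions for (quasi-)complete separation (coefficient divergence past
#' `beta_cap` with a non-vanishing score) and rank deficiency. Continuous
#' columns are centered internally for numerical stability; estimates are
#' returned on the original scale.
#'
#' @param x numeric predictor matrix (one column per term, no intercept
#'   column; an intercept is always added). Column names become term names.
#' @param y binary outcome vector (0/1), same length as `nrow(x)`.
#' @param start optional starting coefficients (intercept first).
#' @param tol convergence tolerance on the maximum absolute score component.
#' @param maxit maximum number of IRLS iterations.
#' @param beta_cap divergence threshold for separation detection.
#' @param check_rank check the design for full column rank before fitting
#'   (skip only in inner loops where the design is already vetted).
#' @return an object of class `"gxe_fit"`: list with `coefficients`
#'   (named), `cov` (named covariance matrix of the estimates),
#'   `log_likelihood`, `n_used`, `converged`, `iterations`, `max_score`,
#'   `term_names`.
#' @examples
#' x <- cbind(exposure = rep(c(1, 0, 1, 0), c(30, 10, 20, 40)))
#' y <- rep(c(1, 1, 0, 0), c(30, 10, 20, 40))
#' exp(coef(fit_logistic(x, y))["exposure"])  # cross-product ratio 6
#' @export
fit_logistic <- function(x, y, start = NULL, tol = 1e-8, maxit = 100L,
                         beta_cap = 15, check_rank = TRUE) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.numeric(y)
  if (length(y) != nrow(x)) {
    stop_gxe("gxe_input_error", "length(y) must equal nrow(x)")
  }
  if (anyNA(x) || anyNA(y)) {
    stop_gxe("gxe_input_error", "missing values in design or outcome; ",
             "build the analysis subset first")
  }
  if (!all(y %in% c(0, 1))) {
    stop_gxe("gxe_input_error", "outcome must be binary 0/1")
  }
  if (all(y == 1) || all(y == 0)) {
    stop_gxe("gxe_degenerate_error", "outcome contains a single class")
  }
  if (ncol(x) && is.null(colnames(x))) {
    colnames(x) <- paste0("x", seq_len(ncol(x)))
  }
  terms <- c("(Intercept)", colnames(x))

  const <- apply(x, 2L, function(v) max(v) == min(v))
  if (any(const)) {
    stop_gxe("gxe_degenerate_error", "constant predictor column(s): ",
             paste(colnames(x)[const], collapse = ", "))
  }
  ctr <- colMeans(x)
  xc <- sweep(x, 2L, ctr)
  X <- cbind(1, xc)
  if (check_rank) {
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
      dep <- terms[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
      stop_gxe("gxe_collinear_error",
               "design is rank deficient; dependent term(s): ",
               paste(dep, collapse = ", "))
    }
  }
  if (is.null(start)) {
    pbar <- mean(y)
    start <- c(log(pbar / (1 - pbar)), rep(0, ncol(x)))
  } else {
    # translate original-scale start to the centered parameterization
    start <- c(start[1L] + sum(start[-1L] * ctr), start[-1L])
  }

  res <- irls_logit_cpp(X, y, start, tol, as.integer(maxit), beta_cap, TRUE)
  status <- res$status
  beta_c <- drop(res$coefficients)
  if (status == 2L) {
    worst <- terms[which.max(abs(beta_c))]
    stop_gxe("gxe_separation_error",
             "perfect or quasi-complete separation detected (term '",
             worst, "' diverging)")
  }
  if (status == 3L) {
    stop_gxe("gxe_collinear_error",
             "singular information matrix during IRLS")
  }

  # back-transform from the centered parameterization
  Tm <- diag(length(beta_c))
  Tm[1L, -1L] <- -ctr
  beta <- drop(Tm %*% beta_c)
  cov <- Tm %*% res$cov %*% t(Tm)
  names(beta) <- terms
  dimnames(cov) <- list(terms, terms)

  structure(list(
    coefficients = beta,
    cov = cov,
    log_likelihood = res$loglik,
    n_used = length(y),
    converged = status == 0L,
    iterations = res$iterations,
    max_score = res$max_score,
    term_names = terms
  ), class = "gxe_fit")
}

#' @export
coef.gxe_fit <- function(object, ...) object$coefficients

#' @export
vcov.gxe_fit <- function(object, ...) object$cov

#' @export
logLik.gxe_fit <- function(object, ...) {
  structure(object$log_likelihood,
            df = length(object$coefficients),
            nobs = object$n_used, class = "logLik")
}

#' @export
print.gxe_fit <- function(x, ...) {
  cat("Logistic regression fit (IRLS), n =", x$n_used,
      if (!x$converged) "[NOT CONVERGED]", "\n")
  se <- sqrt(diag(x$cov))
  tab <- data.frame(beta = x$coefficients, se = se,
                    OR = exp(x$coefficients))
  print(round(tab, 4))
  cat("log-likelihood:", format(x$log_likelihood, digits = 8), "\n")
  invisible(x)
}

#' @export
summary.gxe_fit <- function(object, level = 0.95, ...) {
  se <- sqrt(diag(object$cov))
  z <- object$coefficients / se
  q <- stats::qnorm(1 - (1 - level) / 2)
  tab <- data.frame(
    beta = object$coefficients, se = se, z = z,
    p = 2 * stats::pnorm(-abs(z)),
    OR = exp(object$coefficients),
    ci_low = exp(object$coefficients - q * se),
    ci_high = exp(object$coefficients + q * se))
  structure(list(table = tab, fit = object, level = level),
            class = "summary.gxe_fit")
}

#' @export
print.summary.gxe_fit <- function(x, ...) {
  cat("Logistic regression fit, n =", x$fit$n_used, "\n")
  print(round(x$table, 4))
  invisible(x)
}

#' @export
predict.gxe_fit <- function(object, newdata = NULL,
                            type = c("response", "link"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    stop_gxe("gxe_input_error",
             "supply 'newdata' (a predictor matrix matching the fit terms)")
  }
  X <- cbind(1, as.matrix(newdata))
  eta <- drop(X %*% object$coefficients)
  if (type == "link") eta else stats::plogis(eta)
}

#' Likelihood-ratio test between nested logistic fits
#'
#' @param full,null `gxe_fit` objects; `null`'s terms must be a subset of
#'   `full`'s and both must be fitted to the same rows (identical term sets
#'   give statistic 0, df 0, p 1).
#' @return a list with `statistic` (`2 * (llik_full - llik_null)`, floored
#'   at 0), `df` (difference in parameter count) and `p` (chi-square upper
#'   tail).
#' @export
lrt <- function(full, null) {
  if (!inherits(full, "gxe_fit") || !inherits(null, "gxe_fit")) {
    stop_gxe("gxe_input_error", "lrt() expects two gxe_fit objects")
  }
  if (!all(null$term_names %in% full$term_names) ||
      length(null$term_names) > length(full$term_names)) {
    stop_gxe("gxe_nesting_error",
             "null model terms must be a subset of the full model's")
  }
  if (full$n_used != null$n_used) {
    stop_gxe("gxe_nesting_error",
             "models fitted to different numbers of rows (",
             full$n_used, " vs ", null$n_used, ")")
  }
  stat <- 2 * (full$log_likelihood - null$log_likelihood)
  if (stat < -1e-6) {
    stop_gxe("gxe_nesting_error",
             "full model has lower likelihood than null; models not nested")
  }
  stat <- max(stat, 0)
  df <- length(full$term_names) - length(null$term_names)
  p <- if (df == 0L) 1 else stats::pchisq(stat, df = df, lower.tail = FALSE)
  list(statistic = stat, df = df, p = p)
}

#' Wald odds ratio and confidence interval for one term
#'
#' @param fit a `gxe_fit`.
#' @param term term name (or index into the coefficient vector).
#' @param level confidence level.
#' @return named numeric vector `c(or, ci_low, ci_high)`.
#' @export
wald_or_ci <- function(fit, term, level = 0.95) {
  b <- unname(fit$coefficients[term])
  if (length(b) != 1L || is.na(b)) {
    stop_gxe("gxe_input_error", "unknown term: ", term)
  }
  v <- unname(diag(fit$cov)[term])
  if (!is.finite(v) || v <= 0) {
    stop_gxe("gxe_degenerate_error",
             "non-positive variance for term ", term)
  }
  q <- stats::qnorm(1 - (1 - level) / 2)
  se <- sqrt(v)
  c(or = exp(b), ci_low = exp(b - q * se), ci_high = exp(b + q * se))
}

# ---- design construction helpers ------------------------------------------

# 0/1 dummy columns for a factor, dropping the first (reference) level;
# levels ordered deterministically by label
dummy_cols <- function(f, prefix) {
  f <- factor(f)
  lev <- levels(f)
  if (length(lev) < 2L) return(NULL)
  out <- vapply(lev[-1L], function(l) as.numeric(f == l),
                numeric(length(f)))
  colnames(out) <- paste0(prefix, lev[-1L])
  out
}

# standard design block: study dummies (reference = first sorted label),
# optional age adjustment (categorical bins + continuous age)
design_base <- function(data, adjust_age = FALSE) {
  out <- dummy_cols(data$study, "study:")
  if (adjust_age) {
    out <- cbind(out, dummy_cols(age_categories(data$age), "age:"),
                 age = data$age)
  }
  out
}
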