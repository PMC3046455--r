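# Monte-Carlo power for the 1-df interaction test: power to detect a given
# interaction OR at a given significance level, and the minimum detectable
# interaction OR at a target power.

#' Specify a single-study design for power simulation
#'
#' The exposure (risk factor) distribution must be given explicitly — power
#' against an interaction OR depends strongly on it, so there is no hidden
#' default. Supported distributions: `list(type = "discrete", values,
#' probs)`, `list(type = "bernoulli", p)`, `list(type = "lognormal",
#' meanlog, sdlog)`.
#'
#' @param n_cases,n_controls target sample sizes.
#' @param freq risk-allele frequency, strictly inside (0, 1).
#' @param factor_dist exposure distribution (see Details).
#' @param or_snp per-allele main-effect OR.
#' @param or_factor factor trend main-effect OR per unit.
#' @param prevalence population disease prevalence used to calibrate the
#'   intercept of the generative model.
#' @return a list of class `"power_design"`.
#' @export
power_design <- function(n_cases, n_controls, freq, factor_dist,
                         or_snp = 1.1, or_factor = 1.0,
                         prevalence = 0.10) {
  if (!is_count(n_cases) || !is_count(n_controls)) {
    stop_gxe("gxe_config_error", "sample sizes must be positive integers")
  }
  if (!is.numeric(freq) || freq <= 0 || freq >= 1) {
    stop_gxe("gxe_config_error",
             "freq must lie strictly in (0,1); degenerate designs have no ",
             "genotype variation")
  }
  if (is.null(factor_dist$type) ||
      !factor_dist$type %in% c("discrete", "bernoulli", "lognormal")) {
    stop_gxe("gxe_config_error",
             "factor_dist must be discrete, bernoulli or lognormal")
  }
  if (or_snp <= 0 || or_factor <= 0) {
    stop_gxe("gxe_config_error", "ORs must be positive")
  }
  structure(list(n_cases = n_cases, n_controls = n_controls, freq = freq,
                 factor_dist = factor_dist, or_snp = or_snp,
                 or_factor = or_factor, prevalence = prevalence),
            class = "power_design")
}

draw_factor_dist <- function(dist, n) {
  switch(dist$type,
         discrete = sample(dist$values, n, replace = TRUE, prob = dist$probs),
         bernoulli = stats::rbinom(n, 1L, dist$p),
         lognormal = stats::rlnorm(n, dist$meanlog, dist$sdlog))
}

# draw one retrospective case-control dataset from the design; returns
# list(d, f, y) of length n_cases + n_controls
power_draw <- function(design, beta_int, alpha0) {
  need_ca <- design$n_cases; need_co <- design$n_controls
  prev <- design$prevalence
  d_out <- integer(0); f_out <- numeric(0); y_out <- integer(0)
  attempts <- 0L
  while (need_ca > 0L || need_co > 0L) {
    attempts <- attempts + 1L
    if (attempts > 60L) {
      stop_gxe("gxe_generation_error", "power_draw attempt budget exhausted")
    }
    n <- min(400000L,
             max(200L, ceiling(1.3 * max(need_ca / prev,
                                         need_co / (1 - prev)))))
    d <- stats::rbinom(n, 2L, design$freq)
    f <- draw_factor_dist(design$factor_dist, n)
    eta <- alpha0 + log(design$or_snp) * d + log(design$or_factor) * f +
      beta_int * d * f
    y <- as.integer(stats::runif(n) < stats::plogis(eta))
    ca <- which(y == 1L)[seq_len(min(sum(y == 1L), need_ca))]
    co <- which(y == 0L)[seq_len(min(sum(y == 0L), need_co))]
    take <- c(ca, co)
    d_out <- c(d_out, d[take]); f_out <- c(f_out, f[take])
    y_out <- c(y_out, y[take])
    need_ca <- need_ca - length(ca); need_co <- need_co - length(co)
  }
  list(d = d_out, f = f_out, y = y_out)
}

power_calibrate <- function(design, beta_int, seed) {
  with_substream(seed, "power_cal", expr = {
    n <- 20000L
    d <- stats::rbinom(n, 2L, design$freq)
    f <- draw_factor_dist(design$factor_dist, n)
    eta0 <- log(design$or_snp) * d + log(design$or_factor) * f +
      beta_int * d * f
    fcal <- function(a) mean(stats::plogis(a + eta0)) - design$prevalence
    sol <- tryCatch(stats::uniroot(fcal, c(-30, 10), tol = 1e-8),
                    error = function(e) NULL)
    if (is.null(sol)) {
      stop_gxe("gxe_generation_error", "cannot calibrate power design")
    }
    sol$root
  })
}

interaction_p_simple <- function(d, f, y) {
  Xn <- cbind(d = d - mean(d), f = f - mean(f))
  prod <- d * f
  Xf <- cbind(Xn, df = prod - mean(prod))
  s0 <- c(stats::qlogis(mean(y)), 0, 0)
  f1 <- irls_logit_cpp(cbind(1, Xf), y, c(s0, 0), 1e-8, 100L, 15, FALSE)
  f0 <- irls_logit_cpp(cbind(1, Xn), y, s0, 1e-8, 100L, 15, FALSE)
  if (f1$status != 0L || f0$status != 0L) return(NA_real_)
  stats::pchisq(max(0, 2 * (f1$loglik - f0$loglik)), df = 1,
                lower.tail = FALSE)
}

#' Monte-Carlo power of the interaction test
#'
#' Simulates `n_sims` retrospective case-control datasets from the design
#' with the given interaction OR, applies the 1-df product-term LRT to
#' each, and reports the fraction of datasets with p below `alpha`,
#' together with its binomial Monte-Carlo standard error
#' `sqrt(power * (1 - power) / n_sims)`. Simulated datasets whose fits do
#' not converge are dropped (counted).
#'
#' @param design a [power_design()].
#' @param or_int interaction OR per allele per exposure unit.
#' @param alpha significance level, in (0, 1).
#' @param n_sims number of simulated datasets (>= 100).
#' @param seed master seed; dataset `s` uses substream `(seed, s)`.
#' @return a list of class `"gxe_power"`: `power`, `se`, `n_sims`,
#'   `n_used`, `alpha`, `or_int`, `design`, `seed`.
#' @export
estimate_power <- function(design, or_int, alpha, n_sims, seed) {
  if (!inherits(design, "power_design")) {
    stop_gxe("gxe_config_error", "design must be a power_design")
  }
  if (alpha <= 0 || alpha >= 1) {
    stop_gxe("gxe_config_error", "alpha must be in (0,1)")
  }
  if (!is_count(n_sims) || n_sims < 100) {
    stop_gxe("gxe_config_error", "n_sims must be an integer >= 100")
  }
  if (or_int <= 0) stop_gxe("gxe_config_error", "or_int must be positive")
  beta_int <- log(or_int)
  alpha0 <- power_calibrate(design, beta_int, seed)
  p <- vapply(seq_len(n_sims), function(s) {
    with_substream(seed, "power_sim", s, expr = {
      dat <- power_draw(design, beta_int, alpha0)
      interaction_p_simple(dat$d, dat$f, dat$y)
    })
  }, numeric(1))
  used <- sum(!is.na(p))
  pw <- mean(p < alpha, na.rm = TRUE)
  structure(list(power = pw, se = sqrt(pw * (1 - pw) / used),
                 n_sims = n_sims, n_used = used, alpha = alpha,
                 or_int = or_int, design = design, seed = seed),
            class = "gxe_power")
}

#' @export
print.gxe_power <- function(x, ...) {
  cat(sprintf(
    "Power %.3f (MC SE %.3f) to detect interaction OR %.3f at alpha %.4g\n",
    x$power, x$se, x$or_int, x$alpha))
  cat(sprintf("  design: %d cases / %d controls, freq %.2f, %d sims\n",
              x$design$n_cases, x$design$n_controls, x$design$freq,
              x$n_used))
  invisible(x)
}

#' Minimum detectable interaction OR at a target power
#'
#' Evaluates the Monte-Carlo power over an ascending grid of interaction
#' ORs and returns the smallest grid value whose estimated power reaches
#' the target, together with the whole power curve. If no grid value meets
#' the target the result carries `unmet = TRUE` (and `min_or = NA`) rather
#' than erroring, so the curve can still be inspected.
#'
#' @param design a [power_design()].
#' @param alpha significance level.
#' @param target_power required power (default 0.90).
#' @param grid ascending vector of interaction ORs (length > 1).
#' @param n_sims simulated datasets per grid point.
#' @param seed master seed (each grid point gets its own substream).
#' @return list of class `"gxe_power_curve"`: `min_or`, `unmet`, `curve`
#'   (data frame `or_int`, `power`, `se`), `alpha`, `target_power`.
#' @export
min_detectable_or <- function(design, alpha, target_power = 0.90, grid,
                              n_sims, seed) {
  if (length(grid) < 2L || is.unsorted(grid, strictly = TRUE)) {
    stop_gxe("gxe_config_error",
             "grid must be an ascending vector of length > 1")
  }
  curve <- do.call(rbind, lapply(seq_along(grid), function(k) {
    pw <- estimate_power(design, grid[k], alpha, n_sims,
                         seed = substream_seed(seed, "grid", k))
    data.frame(or_int = grid[k], power = pw$power, se = pw$se)
  }))
  hit <- which(curve$power >= target_power)
  structure(list(
    min_or = if (length(hit)) curve$or_int[hit[1]] else NA_real_,
    unmet = !length(hit), curve = curve, alpha = alpha,
    target_power = target_power, design = design),
    class = "gxe_power_curve")
}

#' @export
print.gxe_power_curve <- function(x, ...) {
  if (x$unmet) {
    cat("Target power", x$target_power, "not reached on the grid\n")
  } else {
    cat(sprintf("Minimum detectable interaction OR at power >= %.2f: %.3f\n",
                x$target_power, x$min_or))
  }
  print(round(x$curve, 4), row.names = FALSE)
  invisible(x)
}
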