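# IRLS logistic core against closed forms and the glm() oracle.

test_that("a 2x2 design recovers the cross-product ratio exactly", {
  # cases: 30 exposed / 10 unexposed; controls: 20 exposed / 40 unexposed
  x <- cbind(exposure = rep(c(1, 0, 1, 0), c(30, 10, 20, 40)))
  y <- rep(c(1, 1, 0, 0), c(30, 10, 20, 40))
  fit <- fit_logistic(x, y)
  expect_equal(unname(exp(coef(fit)["exposure"])), (30 * 40) / (10 * 20),
               tolerance = 1e-8)
  # random 2x2 tables: saturated-model closed form holds every time
  set.seed(4)
  for (r in 1:5) {
    tab <- matrix(sample(5:60, 4), 2)
    x2 <- cbind(e = rep(c(1, 0, 1, 0), tab))
    y2 <- rep(c(1, 1, 0, 0), tab)
    expect_equal(unname(exp(coef(fit_logistic(x2, y2))["e"])),
                 (tab[1] * tab[4]) / (tab[2] * tab[3]), tolerance = 1e-8)
  }
})

test_that("the intercept-only fit returns the case fraction", {
  y <- rep(c(1, 0), c(37, 63))
  fit <- fit_logistic(matrix(numeric(0), nrow = 100, ncol = 0), y)
  expect_equal(unname(stats::plogis(coef(fit)[1])), 0.37, tolerance = 1e-10)
})

test_that("estimates, covariance and likelihood match glm()", {
  set.seed(21)
  n <- 400
  x <- cbind(a = rnorm(n), b = rbinom(n, 2, 0.3), c = runif(n, 20, 35))
  eta <- -0.5 + 0.4 * x[, "a"] - 0.3 * x[, "b"] + 0.05 * x[, "c"]
  y <- rbinom(n, 1, plogis(eta))
  fit <- fit_logistic(x, y)
  oracle <- glm(y ~ x, family = binomial())
  expect_equal(unname(coef(fit)), unname(coef(oracle)), tolerance = 1e-6)
  expect_equal(unname(vcov(fit)), unname(vcov(oracle)), tolerance = 1e-5)
  expect_equal(as.numeric(logLik(fit)), as.numeric(logLik(oracle)),
               tolerance = 1e-8)
  expect_true(fit$converged)
  expect_lt(fit$max_score, 1e-8)
})

test_that("separation and rank deficiency raise typed errors", {
  x <- cbind(z = c(rep(1, 20), rep(0, 20)))
  y <- c(rep(1, 20), rep(0, 20))
  err <- expect_error(fit_logistic(x, y), class = "gxe_separation_error")
  expect_match(conditionMessage(err), "z")
  set.seed(2)
  x2 <- cbind(a = rnorm(50))
  x2 <- cbind(x2, twice_a = 2 * x2[, "a"])
  expect_error(fit_logistic(x2, rbinom(50, 1, 0.5)),
               class = "gxe_collinear_error")
  expect_error(fit_logistic(cbind(k = rep(1, 20)), rbinom(20, 1, 0.5)),
               class = "gxe_degenerate_error")
  expect_error(fit_logistic(cbind(a = rnorm(20)), rep(1, 20)),
               class = "gxe_degenerate_error")
})

test_that("the LRT is the chi-square upper tail with df = added terms", {
  set.seed(31)
  n <- 300
  x <- cbind(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  y <- rbinom(n, 1, plogis(0.3 * x[, "a"]))
  full <- fit_logistic(x, y)
  null <- fit_logistic(x[, "a", drop = FALSE], y)
  out <- lrt(full, null)
  expect_equal(out$df, 2L)
  expect_gte(out$statistic, 0)
  expect_equal(out$p,
               pchisq(out$statistic, 2, lower.tail = FALSE),
               tolerance = 1e-12)
  # identical models: statistic 0, p 1
  same <- lrt(full, full)
  expect_equal(same$statistic, 0, tolerance = 1e-8)
  expect_equal(same$p, 1)
  # non-nested or different-n comparisons are rejected
  expect_error(lrt(null, full), class = "gxe_nesting_error")
  null2 <- fit_logistic(x[-1, "a", drop = FALSE], y[-1])
  expect_error(lrt(full, null2), class = "gxe_nesting_error")
})

test_that("Wald intervals are exp(beta +/- z se) and nest across levels", {
  fake <- structure(list(coefficients = c("(Intercept)" = 0.2, b = 0),
                         cov = diag(c(0.04, 0.01)),
                         term_names = c("(Intercept)", "b")),
                    class = "gxe_fit")
  dimnames(fake$cov) <- list(fake$term_names, fake$term_names)
  ci <- wald_or_ci(fake, "b")
  expect_equal(unname(ci["or"]), 1)
  expect_equal(unname(ci["ci_low"]), exp(-qnorm(0.975) * 0.1),
               tolerance = 1e-10)   # 0.8219
  expect_equal(unname(ci["ci_high"]), exp(qnorm(0.975) * 0.1),
               tolerance = 1e-10)   # 1.2166
  ci99 <- wald_or_ci(fake, "b", level = 0.99)
  expect_lt(ci99["ci_low"], ci["ci_low"])
  expect_gt(ci99["ci_high"], ci["ci_high"])
  fake$cov[2, 2] <- 0
  expect_error(wald_or_ci(fake, "b"), class = "gxe_degenerate_error")
})

test_that("LRT is invariant to affine recoding and ORs rescale as predicted", {
  set.seed(55)
  n <- 500
  x <- runif(n, 10, 20)
  y <- rbinom(n, 1, plogis(-1 + 0.12 * x))
  f1 <- fit_logistic(cbind(v = x), y)
  f0 <- fit_logistic(matrix(numeric(0), n, 0), y)
  f1b <- fit_logistic(cbind(v = (x - 15) / 5), y)
  expect_equal(lrt(f1, f0)$statistic, lrt(f1b, f0)$statistic,
               tolerance = 1e-6)
  # per-5-unit OR equals the per-unit OR to the 5th power
  expect_equal(unname(exp(coef(f1b)["v"])),
               unname(exp(coef(f1)["v"]))^5, tolerance = 1e-6)
})

test_that("null LRT p-values are uniform", {
  set.seed(77)
  p <- replicate(400, {
    n <- 150
    x <- cbind(a = rnorm(n), b = rnorm(n))
    y <- rbinom(n, 1, plogis(0.4 * x[, "a"]))
    lrt(fit_logistic(x, y), fit_logistic(x[, "a", drop = FALSE], y))$p
  })
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})
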