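sim_lmm_data <- function(n, q, beta, sigma_u, sigma_e, seed) {
  set.seed(seed)
  g <- factor(sample(seq_len(q), n, replace = TRUE))
  X <- cbind(`(Intercept)` = 1, x1 = rnorm(n), x2 = rnorm(n))
  y <- as.numeric(X %*% beta) + rnorm(q, sd = sigma_u)[g] + rnorm(n, sd = sigma_e)
  list(y = y, X = X, g = g)
}

test_that("with a single batch the fit collapses to ordinary least squares", {
  set.seed(31)
  n <- 60
  X <- cbind(1, rnorm(n), rnorm(n))
  y <- X %*% c(1, 2, -1) + rnorm(n)
  fit <- fit_lmm(y, X, batch = rep("b1", n))
  ols <- qr.solve(X, y)
  expect_lt(max(abs(fit$beta - ols)), 1e-8)
  expect_equal(fit$lambda, 0)
  expect_equal(fit$sigma2_u, 0)
})

test_that("profile maximization matches the dense grid+refine oracle on random fixtures", {
  for (s in 1:20) {
    d <- sim_lmm_data(50, 5, c(0.5, 1, -0.5), sigma_u = runif(1, 0, 1.5),
                      sigma_e = 1, seed = 600 + s)
    fit <- fit_lmm(d$y, d$X, d$g)
    oracle <- dense_lmm_oracle(d$y, d$X, d$g)
    expect_lt(abs(fit$loglik - oracle), 1e-6)
  }
})

test_that("returned solution dominates a 200-point lambda grid", {
  d <- sim_lmm_data(80, 8, c(0, 1, 1), 1, 1, seed = 32)
  fit <- fit_lmm(d$y, d$X, d$g)
  grid <- c(0, exp(seq(log(1e-8), log(1e3), length.out = 200)))
  ll <- vapply(grid, function(l) dense_lmm_loglik(l, d$y, d$X, d$g), numeric(1))
  expect_gte(fit$loglik + 1e-8, max(ll))
})

test_that("the fit agrees with lme4 maximum likelihood", {
  skip_if_not_installed("lme4")
  d <- sim_lmm_data(150, 10, c(1, 0.5, -0.3), 1.2, 1, seed = 33)
  fit <- fit_lmm(d$y, d$X, d$g)
  dd <- data.frame(y = d$y, x1 = d$X[, 2], x2 = d$X[, 3], g = d$g)
  lf <- lme4::lmer(y ~ x1 + x2 + (1 | g), data = dd, REML = FALSE)
  expect_equal(fit$loglik, as.numeric(stats::logLik(lf)), tolerance = 1e-6)
  expect_equal(unname(fit$beta), unname(lme4::fixef(lf)), tolerance = 1e-6)
  expect_equal(fit$sigma2_u, as.numeric(lme4::VarCorr(lf)$g), tolerance = 1e-4)
  # BLUPs agree too
  expect_equal(unname(ranef(fit)), unname(lme4::ranef(lf)$g[, 1]), tolerance = 1e-4)
})

test_that("variance components are recovered at 40 batches x 25 subjects", {
  ratios <- vapply(seq_len(50), function(s) {
    set.seed(700 + s)
    g <- gl(40, 25)
    n <- 1000
    X <- cbind(1, rnorm(n))
    y <- as.numeric(X %*% c(0, 1)) + rnorm(40, sd = 2)[g] + rnorm(n)
    fit <- fit_lmm(y, X, g)
    fit$sigma2_u / fit$sigma2_e
  }, numeric(1))
  expect_lt(abs(stats::median(ratios) - 4) / 4, 0.3)
})

test_that("formula interface and methods are coherent", {
  set.seed(34)
  d <- data.frame(x = rnorm(120), g = gl(12, 10))
  d$y <- 2 + 0.7 * d$x + rnorm(12, sd = 0.8)[d$g] + rnorm(120)
  fit <- fit_lmm(y ~ x, data = d, batch = "g")
  expect_s3_class(fit, "lmm_fit")
  expect_named(coef(fit), c("(Intercept)", "x"))
  expect_equal(length(fitted(fit)), 120)
  expect_equal(fitted(fit) + residuals(fit), d$y, tolerance = 1e-12)
  expect_equal(residuals(fit, "marginal") - residuals(fit, "conditional"),
               unname(ranef(fit)[as.integer(d$g)]), tolerance = 1e-12)
  expect_output(print(fit), "Linear mixed model")
  s <- summary(fit)
  expect_true(all(is.finite(s$coefficients[, "Std. Error"])))
  expect_equal(as.numeric(logLik(fit)), fit$loglik)
  # predictions: population level vs batch level
  p0 <- predict(fit)
  pb <- predict(fit, batch = d$g)
  expect_equal(pb - p0, unname(ranef(fit)[as.integer(d$g)]), tolerance = 1e-12)
  # simulate round-trip: refitting simulated data recovers the coefficients
  ysim <- simulate(fit, nsim = 1, seed = 35)[, 1]
  fit2 <- fit_lmm(ysim, cbind(1, d$x), d$g)
  expect_lt(abs(fit2$beta[2] - fit$beta[2]), 0.3)
})

test_that("fitter input validation", {
  X <- cbind(1, rnorm(20))
  expect_error(fit_lmm(rnorm(10), X, gl(2, 10)), "length")
  expect_error(fit_lmm(c(rnorm(19), NA), X, gl(2, 10)), "finite")
  expect_error(fit_lmm(rnorm(20), cbind(X, X[, 2]), gl(2, 10)), "singular")
  expect_error(fit_lmm(rnorm(5), cbind(1, rnorm(5), rnorm(5), rnorm(5)), gl(1, 5)),
               "n >= p")
})

test_that("nested LRT has the documented degenerate and reference behaviour", {
  d <- sim_lmm_data(100, 8, c(1, 0.4, 0), 0.5, 1, seed = 36)
  full <- fit_lmm(d$y, d$X, d$g)
  red <- fit_lmm(d$y, d$X[, 1:2], d$g)
  out <- lrt_nested(full, red)
  expect_gte(out$statistic, 0)
  expect_equal(out$df, 1)
  expect_equal(out$p_value,
               stats::pchisq(out$statistic, 1, lower.tail = FALSE))
  # identical models: statistic 0, p 1
  self <- lrt_nested(full, full)
  expect_equal(self$statistic, 0)
  expect_equal(self$p_value, 1)
  # chi-square reference point: stat 3.84, df 1 -> p ~ 0.05
  expect_equal(stats::pchisq(3.84, 1, lower.tail = FALSE), 0.05, tolerance = 1e-3)
  # statistic nonnegative across random nested fixtures
  for (s in 1:10) {
    d2 <- sim_lmm_data(60, 6, c(0, 0, 0), 1, 1, seed = 800 + s)
    f2 <- fit_lmm(d2$y, d2$X, d2$g)
    r2 <- fit_lmm(d2$y, d2$X[, 1, drop = FALSE], d2$g)
    expect_gte(lrt_nested(f2, r2)$statistic, 0)
  }
  expect_error(lrt_nested(red, full), "not nested")
})
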