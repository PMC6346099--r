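# ---- internal profiled-likelihood machinery -------------------------------
#
# Model: y = X beta + Z u + e,  u ~ N(0, sigma2_u I_q) over q batches,
# e ~ N(0, sigma2_e I_n).  Marginally y ~ N(X beta, sigma2_e V(lambda)),
# V = I + lambda Z Z', lambda = sigma2_u / sigma2_e.  For fixed lambda the
# GLS beta and ML sigma2_e are closed form; the 1-D profile over lambda is
# maximized on the log scale.  Because Z is a single grouping factor,
# V^{-1} acts batch-wise: V_j^{-1} = I - c_j J with c_j = lambda/(1+lambda n_j),
# log|V| = sum_j log(1 + lambda n_j).  Everything needed per likelihood
# evaluation reduces to batch sums, so a scan over thousands of transcripts
# reuses one precomputation of the design.

.lmm_bounds <- c(1e-8, 1e3)   # lambda search range
.lmm_tol <- 1e-8              # tolerance on log(lambda)

.lmm_precompute <- function(X, batch) {
  batch <- droplevels(as.factor(batch))
  n <- nrow(X)
  p <- ncol(X)
  if (n < p + 2) .stopf("need n >= p + 2 (n = %d, p = %d)", n, p)
  if (qr(X)$rank < p) .stopf("singular fixed design")
  bi <- as.integer(batch)
  nj <- as.numeric(tabulate(bi, nlevels(batch)))
  list(X = X, XtX = crossprod(X), Sx = rowsum(X, bi), nj = nj,
       n = n, p = p, bi = bi, levels = levels(batch))
}

# profile loglik (and optionally the full solution) at a given lambda
.lmm_profile <- function(lambda, pre, Xty, By, yty, want_fit = FALSE) {
  cj <- lambda / (1 + lambda * pre$nj)
  A <- pre$XtX - crossprod(pre$Sx, cj * pre$Sx)
  b <- Xty - crossprod(pre$Sx, cj * By)[, 1]
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(ch)) return(if (want_fit) NULL else -Inf)
  beta <- backsolve(ch, forwardsolve(t(ch), b))
  rss <- (yty - sum(cj * By^2)) - sum(b * beta)
  if (rss <= 0) return(if (want_fit) NULL else -Inf)
  n <- pre$n
  ll <- -0.5 * n * (log(2 * pi) + 1) - 0.5 * n * log(rss / n) -
    0.5 * sum(log1p(lambda * pre$nj))
  if (!want_fit) return(ll)
  sigma2 <- rss / n
  list(loglik = ll, beta = beta, sigma2_e = sigma2,
       sigma2_u = lambda * sigma2, lambda = lambda,
       cov_unscaled = chol2inv(ch))
}

# maximize the profile over lambda for one response
.lmm_fit_core <- function(pre, Xty, By, yty) {
  obj <- function(loglam) .lmm_profile(exp(loglam), pre, Xty, By, yty)
  ll0 <- .lmm_profile(0, pre, Xty, By, yty)
  if (length(pre$nj) == 1L || all(pre$nj == 1)) {
    # a single batch (or one subject per batch) cannot separate the
    # intercept variance from noise: fix lambda at 0 (OLS limit)
    fit <- .lmm_profile(0, pre, Xty, By, yty, want_fit = TRUE)
  } else {
    opt <- stats::optimize(obj, interval = log(.lmm_bounds), maximum = TRUE,
                           tol = .lmm_tol)
    lam <- if (ll0 + 1e-10 >= opt$objective) 0 else exp(opt$maximum)
    fit <- .lmm_profile(lam, pre, Xty, By, yty, want_fit = TRUE)
  }
  if (is.null(fit)) {
    fit <- list(loglik = NA_real_, beta = rep(NA_real_, pre$p),
                sigma2_e = NA_real_, sigma2_u = NA_real_, lambda = NA_real_,
                cov_unscaled = NULL, converged = FALSE)
  } else fit$converged <- is.finite(fit$loglik)
  fit
}

.lmm_response_stats <- function(pre, y) {
  list(Xty = crossprod(pre$X, y)[, 1], By = rowsum(y, pre$bi)[, 1],
       yty = sum(y^2))
}

# ---- user-facing fitter ----------------------------------------------------

#' Fit a Gaussian linear mixed model with one random intercept
#'
#' Maximum-likelihood fit of `y = X beta + u[batch] + e`, with a shared
#' Gaussian random intercept per batch (scan date) and iid Gaussian
#' noise. The likelihood is profiled: for a fixed variance ratio
#' `lambda = sigma2_u / sigma2_e` the GLS coefficients and the residual
#' variance are closed form, and `lambda` is maximized by bounded
#' one-dimensional search on the log scale (range `1e-8` to `1e3`,
#' tolerance `1e-8`), admitting the `lambda = 0` boundary. With a single
#' batch the model degenerates to ordinary least squares.
#'
#' @param y numeric response vector, or a formula (with `data`).
#' @param X fixed-effect design matrix including the intercept column;
#'   ignored when `y` is a formula.
#' @param batch grouping labels (factor or coercible), one per subject.
#'   When `y` is a formula, `batch` may be a column name in `data`.
#' @param data data.frame for the formula interface.
#' @return An object of class `lmm_fit` with components `beta` (named
#'   coefficients), `sigma2_u`, `sigma2_e`, `lambda`, `loglik`
#'   (maximized ML log-likelihood), `n`, `converged`, and enough state
#'   for `fitted`, `residuals`, `ranef` and `simulate` methods.
#' @examples
#' d <- data.frame(x = rnorm(60), g = gl(6, 10))
#' d$y <- 1 + 2 * d$x + rnorm(6)[d$g] + rnorm(60)
#' fit <- fit_lmm(y ~ x, data = d, batch = "g")
#' coef(fit)
#' @export
fit_lmm <- function(y, X = NULL, batch, data = NULL) {
  if (inherits(y, "formula")) {
    if (is.null(data)) .stopf("the formula interface needs `data`")
    mf <- stats::model.frame(y, data)
    X <- stats::model.matrix(attr(mf, "terms"), mf)
    if (is.character(batch) && length(batch) == 1) batch <- data[[batch]]
    y <- stats::model.response(mf)
  }
  y <- as.numeric(y)
  X <- as.matrix(X)
  if (length(y) != nrow(X)) .stopf("length(y) != nrow(X)")
  if (anyNA(y) || any(!is.finite(y))) .stopf("y must be finite")
  if (length(batch) != length(y)) .stopf("batch labels must match y")
  pre <- .lmm_precompute(X, batch)
  st <- .lmm_response_stats(pre, y)
  core <- .lmm_fit_core(pre, st$Xty, st$By, st$yty)
  beta <- stats::setNames(core$beta, colnames(X))
  resid_m <- y - as.numeric(X %*% ifelse(is.na(beta), 0, beta))
  lam <- core$lambda
  u <- if (isTRUE(core$converged) && !is.na(lam)) {
    rj <- rowsum(resid_m, pre$bi)[, 1]
    lam * rj / (1 + lam * pre$nj)
  } else rep(NA_real_, length(pre$nj))
  structure(list(beta = beta, sigma2_u = core$sigma2_u,
                 sigma2_e = core$sigma2_e, lambda = lam,
                 loglik = core$loglik, n = pre$n, p = pre$p,
                 converged = isTRUE(core$converged),
                 batch_levels = pre$levels, u = stats::setNames(u, pre$levels),
                 batch_index = pre$bi, y = y, X = X,
                 cov_unscaled = core$cov_unscaled),
            class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("Linear mixed model (ML), single random intercept\n")
  cat(sprintf("  n = %d, batches = %d, logLik = %.4f%s\n", x$n,
              length(x$batch_levels), x$loglik,
              if (x$converged) "" else " (NOT converged)"))
  cat(sprintf("  sigma2_u = %.4g, sigma2_e = %.4g (lambda = %.4g)\n",
              x$sigma2_u, x$sigma2_e, x$lambda))
  cat("Fixed effects:\n")
  print(round(x$beta, 4))
  invisible(x)
}

#' @export
summary.lmm_fit <- function(object, ...) {
  se <- if (!is.null(object$cov_unscaled))
    sqrt(diag(object$cov_unscaled) * object$sigma2_e) else rep(NA_real_, object$p)
  z <- object$beta / se
  tab <- cbind(Estimate = object$beta, `Std. Error` = se, `z value` = z,
               `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  out <- list(coefficients = tab, sigma2_u = object$sigma2_u,
              sigma2_e = object$sigma2_e, loglik = object$loglik,
              n = object$n, converged = object$converged)
  class(out) <- "summary.lmm_fit"
  out
}

#' @export
print.summary.lmm_fit <- function(x, ...) {
  cat("Linear mixed model (ML) summary\n")
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  cat(sprintf("sigma2_u = %.4g, sigma2_e = %.4g, logLik = %.4f, n = %d\n",
              x$sigma2_u, x$sigma2_e, x$loglik, x$n))
  invisible(x)
}

#' @export
coef.lmm_fit <- function(object, ...) object$beta

#' @export
logLik.lmm_fit <- function(object, ...) {
  structure(object$loglik, df = object$p + 2, nobs = object$n, class = "logLik")
}

#' Batch random-intercept predictions (BLUPs)
#'
#' @param object an `lmm_fit`.
#' @param ... unused.
#' @return Named vector of per-batch best linear unbiased predictions.
#' @export
ranef <- function(object, ...) UseMethod("ranef")

#' @rdname ranef
#' @export
ranef.lmm_fit <- function(object, ...) object$u

#' @export
fitted.lmm_fit <- function(object, ...) {
  as.numeric(object$X %*% object$beta) + unname(object$u[object$batch_index])
}

#' @export
residuals.lmm_fit <- function(object, type = c("conditional", "marginal"), ...) {
  type <- match.arg(type)
  r <- object$y - as.numeric(object$X %*% object$beta)
  if (type == "conditional") r <- r - unname(object$u[object$batch_index])
  r
}

#' Predict from a fitted mixed model
#'
#' @param object an `lmm_fit`.
#' @param newX design matrix with the same columns as the fit; defaults
#'   to the training design.
#' @param batch optional batch labels for the new rows; known levels
#'   contribute their BLUP, unknown levels predict at the population
#'   level.
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
predict.lmm_fit <- function(object, newX = object$X, batch = NULL, ...) {
  eta <- as.numeric(as.matrix(newX) %*% object$beta)
  if (!is.null(batch)) {
    idx <- match(as.character(batch), object$batch_levels)
    add <- unname(ifelse(is.na(idx), 0, object$u[idx]))
    eta <- eta + add
  }
  eta
}

#' @export
simulate.lmm_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  q <- length(object$batch_levels)
  mu <- as.numeric(object$X %*% object$beta)
  out <- replicate(nsim, {
    u <- stats::rnorm(q, sd = sqrt(object$sigma2_u))
    mu + u[object$batch_index] + stats::rnorm(object$n, sd = sqrt(object$sigma2_e))
  })
  as.data.frame(out)
}

#' @export
plot.lmm_fit <- function(x, ...) {
  graphics::plot(fitted(x), residuals(x), xlab = "Fitted values",
                 ylab = "Conditional residuals",
                 main = "Mixed-model residuals", ...)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}

# ---- nested-model inference -----------------------------------------------

#' Likelihood-ratio test between nested ML mixed-model fits
#'
#' `statistic = 2 * (logLik_full - logLik_reduced)`, floored at zero,
#' referred to a chi-square with degrees of freedom equal to the
#' difference in fixed-effect count. Both fits must be ML fits of the
#' same response with the same batch structure, the reduced fixed
#' effects a subset of the full ones.
#'
#' @param full,reduced `lmm_fit` objects.
#' @return A list with `statistic`, `df`, `p_value` (`NA` with a warning
#'   if either fit did not converge).
#' @export
lrt_nested <- function(full, reduced) {
  stopifnot(inherits(full, "lmm_fit"), inherits(reduced, "lmm_fit"))
  if (full$n != reduced$n) .stopf("fits use different numbers of subjects")
  if (!all(names(reduced$beta) %in% names(full$beta)))
    .stopf("models are not nested: reduced fixed effects must be a subset of the full ones")
  df <- full$p - reduced$p
  if (df < 0) .stopf("models are not nested: full model is smaller")
  if (!full$converged || !reduced$converged) {
    warning("unconverged fit: p-value set to NA")
    return(list(statistic = NA_real_, df = df, p_value = NA_real_))
  }
  stat <- max(0, 2 * (full$loglik - reduced$loglik))
  p <- if (df == 0) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  list(statistic = stat, df = df, p_value = p)
}

#' Benjamini-Hochberg false-discovery control
#'
#' Step-up q-values (adjusted p-values with cumulative-minimum
#' enforcement) and the discovery mask at level `alpha`. Missing
#' p-values are excluded from the procedure and propagate as `NA`.
#'
#' @param p_values numeric vector of p-values in \[0, 1\] (`NA` allowed).
#' @param alpha FDR level, default 0.05.
#' @return A list with `q_values` (same order as input) and
#'   `significant` (logical mask; `NA` stays `NA`).
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.5))
#' @export
bh_fdr <- function(p_values, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) .stopf("alpha must lie in (0, 1)")
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1)) .stopf("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p_values))
  q[ok] <- stats::p.adjust(p_values[ok], method = "BH")
  list(q_values = q, significant = q <= alpha)
}

#' Power of the fixed-effects F test in a linear model
#'
#' Cohen's-f2 parameterization: `power = P(F' > F_crit)` where `F'` is
#' noncentral F with `u` and `v` degrees of freedom and noncentrality
#' `f2 * (u + v + 1)`, and `F_crit` is the `1 - alpha` central-F
#' quantile.
#'
#' @param u numerator degrees of freedom (tested coefficients).
#' @param v denominator (residual) degrees of freedom.
#' @param f2 Cohen's f-squared effect size (>= 0).
#' @param alpha significance level in (0, 1).
#' @return Power in \[0, 1\]; exactly `alpha` at `f2 = 0`.
#' @examples
#' power_linear_model(u = 1, v = 100, f2 = 0.15, alpha = 0.05)
#' @export
power_linear_model <- function(u, v, f2, alpha = 0.05) {
  if (u < 1 || v < 1) .stopf("degrees of freedom must be >= 1")
  if (f2 < 0) .stopf("f2 must be >= 0")
  if (alpha <= 0 || alpha >= 1) .stopf("alpha must lie in (0, 1)")
  if (f2 == 0) return(alpha)  # central case: the test exactly attains its level
  crit <- stats::qf(1 - alpha, u, v)
  stats::pf(crit, u, v, ncp = f2 * (u + v + 1), lower.tail = FALSE)
}

#' Effect size reaching a target power
#'
#' Inverts [power_linear_model()] over `f2` by root finding.
#'
#' @inheritParams power_linear_model
#' @param power target power in (alpha, 1).
#' @return The Cohen's f2 giving `power` at (`u`, `v`, `alpha`).
#' @export
f2_for_power <- function(u, v, power, alpha = 0.05) {
  if (power <= alpha || power >= 1) .stopf("power must lie in (alpha, 1)")
  stats::uniroot(function(f2) power_linear_model(u, v, f2, alpha) - power,
                 lower = 0, upper = 100, tol = 1e-10)$root
}
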