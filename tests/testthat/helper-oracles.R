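# Independent oracles used across the suite. Each recomputes a quantity by
# a route the implementation does not share: dense-matrix likelihoods,
# exhaustive enumeration, closed-form normal equations, quadrature.

# ML log-likelihood of the single-random-intercept model by dense V algebra
dense_lmm_loglik <- function(lambda, y, X, batch) {
  batch <- as.factor(batch)
  Z <- stats::model.matrix(~ batch - 1)
  n <- length(y)
  V <- diag(n) + lambda * tcrossprod(Z)
  Vi <- solve(V)
  A <- t(X) %*% Vi %*% X
  beta <- solve(A, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  rss <- as.numeric(t(r) %*% Vi %*% r)
  sigma2 <- rss / n
  as.numeric(-0.5 * n * (log(2 * pi) + 1) - 0.5 * n * log(sigma2) -
               0.5 * determinant(V, logarithm = TRUE)$modulus[1])
}

# grid + refine maximization of the dense profile likelihood
dense_lmm_oracle <- function(y, X, batch) {
  grid <- c(0, exp(seq(log(1e-8), log(1e3), length.out = 200)))
  ll <- vapply(grid, function(l) dense_lmm_loglik(l, y, X, batch), numeric(1))
  i <- which.max(ll)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(function(l) dense_lmm_loglik(l, y, X, batch),
                         lower = lo, upper = max(hi, 1e-10), maximum = TRUE,
                         tol = 1e-12)
  max(opt$objective, ll[i])
}

# exact simplex-constrained least squares by active-set enumeration:
# minimize ||b - R f||^2 s.t. f >= 0 and (sum f <= 1 | sum f == 1)
simplex_ls_oracle <- function(R, b, equality = FALSE) {
  k <- ncol(R)
  best <- NULL; best_obj <- Inf
  consider <- function(f) {
    if (any(f < -1e-10)) return()
    f <- pmax(f, 0)
    obj <- sum((b - R %*% f)^2)
    if (obj < best_obj - 1e-15) { best_obj <<- obj; best <<- f }
  }
  for (sz in 1:k) {
    combs <- utils::combn(k, sz)
    for (ci in seq_len(ncol(combs))) {
      S <- combs[, ci]
      Rs <- R[, S, drop = FALSE]
      # unconstrained-sum stationary point (valid if sum <= 1, inequality case)
      if (!equality) {
        fs <- tryCatch(qr.solve(Rs, b), error = function(e) NULL)
        if (!is.null(fs) && all(fs >= -1e-10) && sum(fs) <= 1 + 1e-10) {
          f <- numeric(k); f[S] <- fs; consider(f)
        }
      }
      # sum-to-one stationary point (KKT with equality constraint)
      m <- length(S)
      kkt <- rbind(cbind(crossprod(Rs), rep(1, m)), c(rep(1, m), 0))
      sol <- tryCatch(solve(kkt, c(crossprod(Rs, b), 1)), error = function(e) NULL)
      if (!is.null(sol)) {
        f <- numeric(k); f[S] <- sol[seq_len(m)]; consider(f)
      }
    }
  }
  list(f = best, objective = best_obj)
}

# brute-force knn imputation oracle matching the package's distance dialect
knn_impute_oracle <- function(x, k) {
  out <- x
  p <- ncol(x)
  ctr <- x - rowMeans(x, na.rm = TRUE)
  for (f in seq_len(nrow(x))) for (s in seq_len(p)) {
    if (!is.na(x[f, s])) next
    d <- rep(Inf, nrow(x))
    for (g in seq_len(nrow(x))) {
      if (g == f || is.na(x[g, s])) next
      common <- which(!is.na(x[f, ]) & !is.na(x[g, ]))
      if (!length(common)) next
      d[g] <- sqrt(sum((ctr[f, common] - ctr[g, common])^2) * p / length(common))
    }
    nb <- order(d)[seq_len(min(k, sum(is.finite(d))))]
    out[f, s] <- mean(x[nb, s])
  }
  out
}

# VIF by closed-form normal equations
vif_oracle <- function(X) {
  vapply(seq_len(ncol(X)), function(j) {
    y <- X[, j]
    Z <- cbind(1, X[, -j, drop = FALSE])
    beta <- solve(crossprod(Z), crossprod(Z, y))
    rss <- sum((y - Z %*% beta)^2)
    tss <- sum((y - mean(y))^2)
    1 / (1 - (1 - rss / tss))
  }, numeric(1))
}

# exhaustive hypergeometric tail: enumerate every size-n draw from the
# background and count draws with overlap >= observed
hyper_tail_oracle <- function(background, pathway, n_hits, observed) {
  draws <- utils::combn(length(background), n_hits)
  inpw <- background %in% pathway
  cnt <- apply(draws, 2, function(ix) sum(inpw[ix]))
  mean(cnt >= observed)
}

# power by quadrature of the noncentral-F density
power_quadrature_oracle <- function(u, v, f2, alpha) {
  crit <- stats::qf(1 - alpha, u, v)
  stats::integrate(function(x) stats::df(x, u, v, ncp = f2 * (u + v + 1)),
                   crit, Inf, rel.tol = 1e-10)$value
}

# small helper fixtures -----------------------------------------------------

small_cohort <- function(n = 80, n_cases = 30, seed = 42, ...) {
  generate_cohort(n, n_cases, config = cohort_config(...), seed = seed)
}

small_reference <- function(n_cpg = 30, seed = 7, k = 6) {
  set.seed(seed)
  matrix(stats::runif(n_cpg * k), n_cpg, k,
         dimnames = list(sprintf("cpg%03d", seq_len(n_cpg)),
                         WBC_CELL_TYPES[seq_len(k)]))
}
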