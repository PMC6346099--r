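#' Estimate white-blood-cell fractions from methylation beta-values
#'
#' Reference-based cell-mixture deconvolution: each subject's methylation
#' profile is projected onto purified-leukocyte reference signatures by
#' constrained least squares (fractions nonnegative, sum at most one —
#' or exactly one with `constraint = "equality"`), and the solution is
#' renormalized onto the unit simplex. The nonnegative least-squares
#' subproblem is solved by the Lawson-Hanson active-set algorithm
#' ([pracma::lsqnonneg()]); the sum-to-one constraint is imposed through
#' a heavily weighted augmentation row and is exact after the final
#' renormalization.
#'
#' @param meth CpG x subject matrix of beta-values in \[0, 1\];
#'   rownames are CpG ids.
#' @param reference CpG x cell-type matrix of purified-cell mean
#'   beta-values; rownames are CpG ids, colnames the cell types.
#' @param constraint `"inequality"` (sum of fractions at most 1 before
#'   renormalization; default) or `"equality"` (sum exactly 1 in the
#'   least-squares objective).
#' @return A subject x cell-type matrix of fractions; each row lies on
#'   the unit simplex.
#' @examples
#' ref <- matrix(runif(60), 10, 6,
#'               dimnames = list(sprintf("cpg%02d", 1:10), WBC_CELL_TYPES))
#' truef <- generate_wbc_proportions(4, rep(8, 6), seed = 1)
#' m <- generate_methylation(truef, ref, noise_sd = 0)
#' round(estimate_cell_fractions(m, ref) - truef, 6)
#' @export
estimate_cell_fractions <- function(meth, reference,
                                    constraint = c("inequality", "equality")) {
  constraint <- match.arg(constraint)
  meth <- as.matrix(meth)
  reference <- as.matrix(reference)
  shared <- intersect(rownames(meth), rownames(reference))
  if (!length(shared)) .stopf("no shared CpGs between methylation matrix and reference")
  k <- ncol(reference)
  if (length(shared) < k)
    .stopf("need at least %d shared CpGs (one per cell type); got %d", k, length(shared))
  R <- reference[shared, , drop = FALSE]
  if (qr(R)$rank < k) .stopf("reference is rank-deficient on the shared CpGs")
  B <- meth[shared, , drop = FALSE]

  # sum-to-one enforced through a weighted augmentation row
  w <- 1000 * max(abs(R))
  Raug <- rbind(R, rep(w, k))

  out <- matrix(NA_real_, ncol(B), k,
                dimnames = list(colnames(B), colnames(reference)))
  for (j in seq_len(ncol(B))) {
    b <- B[, j]
    f <- if (constraint == "equality") {
      .sum1_refine(R, b, pracma::lsqnonneg(Raug, c(b, w))$x)
    } else {
      f0 <- pracma::lsqnonneg(R, b)$x
      if (sum(f0) > 1 + 1e-10)
        .sum1_refine(R, b, pracma::lsqnonneg(Raug, c(b, w))$x)
      else f0
    }
    s <- sum(f)
    if (s <= 0) .stopf("degenerate profile for subject %s: all-zero projection",
                       colnames(B)[j] %||% j)
    out[j, ] <- f / s
  }
  out
}

# exact equality-constrained least squares on the active set found by the
# penalty solve: KKT system for min ||b - R_S f|| s.t. sum(f) = 1, f_S > 0
.sum1_refine <- function(R, b, f) {
  S <- which(f > 1e-12)
  if (!length(S)) return(f)
  Rs <- R[, S, drop = FALSE]
  k <- length(S)
  kkt <- rbind(cbind(crossprod(Rs), rep(1, k)), c(rep(1, k), 0))
  sol <- tryCatch(solve(kkt, c(crossprod(Rs, b), 1)), error = function(e) NULL)
  if (is.null(sol) || any(sol[seq_len(k)] < -1e-10)) return(f)
  out <- numeric(length(f))
  out[S] <- pmax(sol[seq_len(k)], 0)
  out
}
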