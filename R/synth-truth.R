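#' Ground-truth generative parameters for synthetic expression
#'
#' Container for the planted per-transcript effects used by
#' [generate_expression()]: the generative model per subject i and
#' transcript t is
#' \deqn{Y_{ti} = \alpha_t + P_i' \beta^{pcb}_t + W_i' \beta^{wbc}_t +
#'       \sum_{p,w} \beta^{int}_{tpw} P_{ip} W_{iw} + F_i' \beta^{fe}_t +
#'       u_{t,b(i)} + e_{ti},}
#' with \eqn{u_{t,b} \sim N(0, \sigma^2_u)} a per-batch random intercept,
#' \eqn{e_{ti} \sim N(0, \sigma^2_e)} residual noise, \eqn{P_i} the
#' standardized log PCB levels (the same scale the scan fits on by
#' default), \eqn{W_i} the leukocyte fractions, and \eqn{F_i} optional
#' confounder covariates. `sex_specific_mask` zeroes the exposure-related
#' contributions (`beta_pcb`, `beta_wbc`, `beta_inter`) for subjects of
#' the non-targeted sex, so that female-only or male-only responses can be
#' planted.
#'
#' @param n_transcripts number of transcripts.
#' @param alpha intercepts, recycled to length `n_transcripts`.
#' @param beta_pcb `n_transcripts` x 6 matrix (or scalar, recycled) of
#'   main effects per congener.
#' @param beta_wbc `n_transcripts` x 6 matrix of cell-fraction effects.
#' @param beta_inter `n_transcripts` x 6 x 6 array of PCB-by-cell-type
#'   interaction effects (congener index second, cell type third).
#' @param beta_fe matrix of confounder effects whose columns name cohort
#'   covariates (`age`, `bmi`); default none.
#' @param sigma2_u batch random-intercept variance (>= 0).
#' @param sigma2_e residual variance (> 0).
#' @param sex_specific_mask per-transcript factor in
#'   `{"both", "F", "M"}`; recycled.
#' @return A list of class `simulation_truth`.
#' @export
simulation_truth <- function(n_transcripts,
                             alpha = 0,
                             beta_pcb = 0,
                             beta_wbc = 0,
                             beta_inter = 0,
                             beta_fe = NULL,
                             sigma2_u = 0.2,
                             sigma2_e = 1,
                             sex_specific_mask = "both") {
  if (sigma2_u < 0 || sigma2_e <= 0) .stopf("variances must satisfy sigma2_u >= 0, sigma2_e > 0")
  tmat <- function(x, nc) {
    if (is.matrix(x)) {
      stopifnot(nrow(x) == n_transcripts, ncol(x) == nc)
      x
    } else matrix(x, n_transcripts, nc)
  }
  if (!is.array(beta_inter) || length(dim(beta_inter)) != 3) {
    beta_inter <- array(beta_inter, dim = c(n_transcripts, 6, 6))
  } else stopifnot(all(dim(beta_inter) == c(n_transcripts, 6, 6)))
  dimnames(beta_inter) <- list(NULL, PCB_CONGENERS, WBC_CELL_TYPES)
  mask <- factor(rep_len(sex_specific_mask, n_transcripts),
                 levels = c("both", "F", "M"))
  if (anyNA(mask)) .stopf("sex_specific_mask entries must be 'both', 'F' or 'M'")
  structure(list(n_transcripts = n_transcripts,
                 alpha = rep_len(alpha, n_transcripts),
                 beta_pcb = tmat(beta_pcb, 6),
                 beta_wbc = tmat(beta_wbc, 6),
                 beta_inter = beta_inter,
                 beta_fe = beta_fe,
                 sigma2_u = sigma2_u, sigma2_e = sigma2_e,
                 sex_specific_mask = mask),
            class = "simulation_truth")
}

#' Plant a PCB-by-cell-type interaction effect in a truth object
#'
#' @param truth a [simulation_truth()] object.
#' @param transcripts integer indices of transcripts to receive the effect.
#' @param pcb congener label (e.g. `"156"`).
#' @param wbc cell-type label (e.g. `"B"`).
#' @param effect interaction coefficient on the standardized-log-PCB by
#'   raw-fraction product scale.
#' @param sex `"both"`, `"F"` or `"M"`: which subjects express the effect.
#' @return The modified truth object.
#' @export
plant_interaction <- function(truth, transcripts, pcb, wbc, effect, sex = "both") {
  stopifnot(inherits(truth, "simulation_truth"))
  pcb <- match.arg(as.character(pcb), PCB_CONGENERS)
  wbc <- match.arg(wbc, WBC_CELL_TYPES)
  truth$beta_inter[transcripts, pcb, wbc] <- effect
  truth$sex_specific_mask[transcripts] <- sex
  truth
}

# standardized log exposures: the scale the default scan fits on
.std_log_pcb <- function(cohort) {
  p <- log(as.matrix(cohort[, .pcb_cols()]))
  scale(p)
}

#' Generate a synthetic expression matrix from a cohort and ground truth
#'
#' Builds the linear predictor described in [simulation_truth()], adds a
#' per-transcript batch random intercept (shared by all subjects in a
#' batch) and iid Gaussian noise.
#'
#' @param cohort a cohort from [generate_cohort()].
#' @param truth a [simulation_truth()] object.
#' @param n_transcripts must match `truth$n_transcripts` (defaulted).
#' @param seed integer seed.
#' @return A numeric `n_transcripts` x `n` matrix, rownames `tx...`,
#'   colnames the cohort subject ids.
#' @examples
#' coh <- generate_cohort(80, 30, seed = 1)
#' tr <- simulation_truth(50)
#' y <- generate_expression(coh, tr, seed = 2)
#' dim(y)
#' @export
generate_expression <- function(cohort, truth, n_transcripts = truth$n_transcripts,
                                seed = 1) {
  stopifnot(inherits(truth, "simulation_truth"))
  if (n_transcripts != truth$n_transcripts)
    .stopf("n_transcripts (%d) does not match truth (%d)", n_transcripts, truth$n_transcripts)
  validate_cohort(cohort)
  n <- nrow(cohort)
  set.seed(seed)

  P <- .std_log_pcb(cohort)                       # n x 6
  W <- as.matrix(cohort[, .wbc_cols()])           # n x 6
  mask_f <- truth$sex_specific_mask               # per transcript
  sexF <- cohort$sex == "F"

  # exposure-linked part, per transcript: beta_pcb P' + beta_wbc W' + interactions
  expo <- truth$beta_pcb %*% t(P) + truth$beta_wbc %*% t(W)
  bi <- truth$beta_inter
  if (any(bi != 0)) {
    nz <- which(apply(bi != 0, c(2, 3), any), arr.ind = TRUE)
    for (k in seq_len(nrow(nz))) {
      p <- nz[k, 1]; w <- nz[k, 2]
      expo <- expo + bi[, p, w, drop = TRUE] %o% (P[, p] * W[, w])
    }
  }
  # sex-specific masking of the exposure-linked contributions
  allowed <- matrix(1, truth$n_transcripts, n)
  allowed[mask_f == "F", !sexF] <- 0
  allowed[mask_f == "M", sexF] <- 0
  lp <- truth$alpha + expo * allowed

  if (!is.null(truth$beta_fe)) {
    fe_cols <- colnames(truth$beta_fe)
    FE <- vapply(fe_cols, function(cn) {
      v <- cohort[[cn]]
      if (is.numeric(v)) as.numeric(scale(v)) else as.numeric(v == levels(factor(v))[2])
    }, numeric(n))
    lp <- lp + truth$beta_fe %*% t(FE)
  }

  b <- as.integer(cohort$batch)
  q <- nlevels(cohort$batch)
  u <- matrix(stats::rnorm(truth$n_transcripts * q, sd = sqrt(truth$sigma2_u)),
              truth$n_transcripts, q)
  eps <- matrix(stats::rnorm(truth$n_transcripts * n, sd = sqrt(truth$sigma2_e)),
                truth$n_transcripts, n)
  y <- lp + u[, b, drop = FALSE] + eps
  dimnames(y) <- list(sprintf("tx%05d", seq_len(truth$n_transcripts)),
                      cohort$subject_id)
  y
}

#' Generate synthetic methylation beta-values from known cell fractions
#'
#' Mixes a purified-cell reference signature linearly by the supplied
#' fractions, adds Gaussian noise, and clips to \[0, 1\]. This is the
#' fixture generator for testing the deconvolution stage.
#'
#' @param fractions `n` x `k` matrix of cell fractions; rows must lie on
#'   the unit simplex within `1e-8`.
#' @param reference CpG x cell-type matrix of mean beta-values in
#'   \[0, 1\]; columns must match the columns of `fractions`.
#' @param noise_sd nonnegative noise standard deviation.
#' @param seed integer seed.
#' @return A CpG x `n` matrix of beta-values in \[0, 1\].
#' @export
generate_methylation <- function(fractions, reference, noise_sd = 0.02, seed = 1) {
  fractions <- as.matrix(fractions)
  reference <- as.matrix(reference)
  if (ncol(reference) != ncol(fractions))
    .stopf("reference columns (%d) must match fraction columns (%d)",
           ncol(reference), ncol(fractions))
  if (noise_sd < 0) .stopf("noise_sd must be >= 0")
  if (any(fractions < -1e-8) || any(abs(rowSums(fractions) - 1) > 1e-8))
    .stopf("fraction rows must lie on the unit simplex within 1e-8")
  set.seed(seed)
  m <- reference %*% t(fractions)
  if (noise_sd > 0)
    m <- m + matrix(stats::rnorm(length(m), sd = noise_sd), nrow(m), ncol(m))
  m[m < 0] <- 0
  m[m > 1] <- 1
  if (is.null(rownames(m))) rownames(m) <- sprintf("cpg%04d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("S%04d", seq_len(ncol(m)))
  m
}
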