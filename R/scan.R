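#' Specification of one transcriptome scan
#'
#' Bundles the modelling choices of a scan: the variable of interest, the
#' confounder set, which leukocyte fractions enter as confounders
#' (granulocytes — the dominant, simplex-closing fraction — are excluded
#' by default), the batch column carrying the random intercept, the
#' exposure transformation applied before fitting, the test, and the FDR
#' level.
#'
#' @param variable_of_interest PCB congener label (`"156"` or
#'   `"PCB156"`); ignored by [interaction_scan()], which names its own
#'   product term.
#' @param confounders cohort columns entering as fixed effects. Defaults
#'   to cohort, sex, type of future cancer, age, BMI and smoking status.
#'   Columns that are constant within the analyzed subset (e.g. sex in a
#'   sex stratum) are dropped automatically.
#' @param wbc_confounders leukocyte fractions entering as fixed effects.
#' @param random_effect cohort column with the batch labels.
#' @param fdr_alpha Benjamini-Hochberg level within the scan, default
#'   0.05 (`fdr_alpha = 0.2` reproduces the relaxed preset).
#' @param exposure_transform one of `"none"`, `"log"`, `"zscore"`,
#'   `"log_zscore"` (default: serum PCB levels are right-skewed, so they
#'   are log-transformed then standardized within the analyzed subset).
#' @param test `"lrt"` (likelihood-ratio, default) or `"wald"`.
#' @return A list of class `scan_spec`.
#' @export
scan_spec <- function(variable_of_interest = "153",
                      confounders = c("cohort_label", "sex", "cancer_type",
                                      "age", "bmi", "smoking"),
                      wbc_confounders = setdiff(WBC_CELL_TYPES, "Gran"),
                      random_effect = "batch",
                      fdr_alpha = 0.05,
                      exposure_transform = c("log_zscore", "log", "zscore", "none"),
                      test = c("lrt", "wald")) {
  if (fdr_alpha <= 0 || fdr_alpha >= 1) .stopf("fdr_alpha must lie in (0, 1)")
  voi <- sub("^PCB", "", as.character(variable_of_interest))
  if (!voi %in% PCB_CONGENERS)
    .stopf("variable_of_interest must name one of congeners %s",
           paste(PCB_CONGENERS, collapse = ", "))
  bad <- setdiff(wbc_confounders, WBC_CELL_TYPES)
  if (length(bad)) .stopf("unknown cell type(s): %s", paste(bad, collapse = ", "))
  structure(list(variable_of_interest = voi, confounders = confounders,
                 wbc_confounders = wbc_confounders,
                 random_effect = random_effect, fdr_alpha = fdr_alpha,
                 exposure_transform = match.arg(exposure_transform),
                 test = match.arg(test)),
            class = "scan_spec")
}

#' Transform a raw exposure vector for modelling
#'
#' @param x strictly positive exposure levels.
#' @param method `"none"`, `"log"`, `"zscore"` or `"log_zscore"`.
#' @return Transformed numeric vector. Z-scoring uses the mean and sd of
#'   the supplied values, so scan results are invariant to affine
#'   rescaling of the raw exposure when a z-scored transform is used.
#' @export
transform_exposure <- function(x, method = c("log_zscore", "log", "zscore", "none")) {
  method <- match.arg(method)
  if (method %in% c("log", "log_zscore")) {
    if (any(x <= 0)) .stopf("log transform requires strictly positive exposures")
    x <- log(x)
  }
  if (method %in% c("zscore", "log_zscore")) x <- as.numeric(scale(x))
  x
}

# confounder + leukocyte design (with intercept); constant columns dropped
.confounder_design <- function(cohort, spec) {
  n <- nrow(cohort)
  cols <- list(`(Intercept)` = rep(1, n))
  for (cn in spec$confounders) {
    v <- cohort[[cn]]
    if (is.null(v)) .stopf("confounder '%s' not found in cohort", cn)
    if (is.numeric(v)) {
      cols[[cn]] <- v
    } else {
      v <- droplevels(as.factor(v))
      if (nlevels(v) > 1) {
        mm <- stats::model.matrix(~v)[, -1, drop = FALSE]
        colnames(mm) <- paste0(cn, "_", levels(v)[-1])
        for (j in seq_len(ncol(mm))) cols[[colnames(mm)[j]]] <- mm[, j]
      }
    }
  }
  for (ct in spec$wbc_confounders) cols[[paste0("wbc_", ct)]] <- cohort[[paste0("wbc_", ct)]]
  X <- do.call(cbind, cols)
  keep <- c(TRUE, apply(X[, -1, drop = FALSE], 2, stats::sd) > 0)
  X[, keep, drop = FALSE]
}

.align_expression <- function(expression, cohort) {
  ids <- cohort$subject_id
  cn <- colnames(expression)
  if (is.null(cn)) {
    if (ncol(expression) != length(ids))
      .stopf("expression has %d columns for %d subjects", ncol(expression), length(ids))
    return(expression)
  }
  if (identical(cn, ids)) return(expression)
  if (setequal(cn, ids)) return(expression[, ids, drop = FALSE])
  .stopf("expression subjects do not match the cohort")
}

# shared scan engine over a full/reduced design pair
.run_scan <- function(expression, cohort, Xfull, Xred, spec, voi_col, label) {
  batch <- cohort[[spec$random_effect]]
  preF <- .lmm_precompute(Xfull, batch)
  preR <- .lmm_precompute(Xred, batch)
  Y <- as.matrix(expression)
  nt <- nrow(Y)
  XtyF <- crossprod(preF$X, t(Y))
  XtyR <- crossprod(preR$X, t(Y))
  By <- t(rowsum(t(Y), preF$bi))            # nt x q
  yty <- rowSums(Y^2)
  vark <- apply(Y, 1, stats::var)
  voi_idx <- match(voi_col, colnames(Xfull))

  beta <- stat <- p <- rep(NA_real_, nt)
  conv <- rep(FALSE, nt)
  df <- ncol(Xfull) - ncol(Xred)
  for (t in seq_len(nt)) {
    if (!is.finite(vark[t]) || vark[t] < 1e-12) next
    fitF <- .lmm_fit_core(preF, XtyF[, t], By[t, ], yty[t])
    if (!isTRUE(fitF$converged)) next
    beta[t] <- fitF$beta[voi_idx]
    if (spec$test == "wald") {
      se <- sqrt(fitF$cov_unscaled[voi_idx, voi_idx] * fitF$sigma2_e)
      z <- fitF$beta[voi_idx] / se
      stat[t] <- z^2
      p[t] <- 2 * stats::pnorm(-abs(z))
      conv[t] <- TRUE
    } else {
      fitR <- .lmm_fit_core(preR, XtyR[, t], By[t, ], yty[t])
      if (!isTRUE(fitR$converged)) next
      stat[t] <- max(0, 2 * (fitF$loglik - fitR$loglik))
      # small-sample reference: map the ML LRT onto the F scale that is
      # exact in the no-batch-variance (OLS) limit; asymptotically this
      # coincides with the chi-square reference but avoids its far-tail
      # anticonservativeness at transcriptome-scan sample sizes
      n <- nrow(cohort)
      v2 <- n - ncol(Xfull)
      fstat <- (exp(stat[t] / n) - 1) * v2 / df
      p[t] <- stats::pf(fstat, df, v2, lower.tail = FALSE)
      conv[t] <- TRUE
    }
  }
  fdr <- bh_fdr_safe(p, spec$fdr_alpha)
  out <- data.frame(transcript_id = rownames(Y) %||% sprintf("tx%05d", seq_len(nt)),
                    beta = beta, lrt_stat = stat, p = p, q = fdr$q_values,
                    converged = conv, stringsAsFactors = FALSE)
  structure(out, class = c("scan_result", "data.frame"),
            spec = spec, n = nrow(cohort), label = label,
            n_skipped = sum(!conv), df = df)
}

bh_fdr_safe <- function(p, alpha) {
  if (all(is.na(p))) return(list(q_values = p, significant = rep(NA, length(p))))
  bh_fdr(p, alpha)
}

#' Transcriptome-wide mixed-model scan for a PCB main effect
#'
#' Per transcript, fits the full model (confounders + leukocyte
#' fractions + the transformed PCB of interest, with a batch random
#' intercept) and the reduced model without the PCB, takes the
#' likelihood-ratio p-value, and applies Benjamini-Hochberg control
#' across the scan. Transcripts with essentially zero variance are
#' flagged and excluded from the FDR denominator.
#'
#' @param expression transcript x subject matrix; column names must
#'   match `cohort$subject_id`.
#' @param cohort a cohort `data.frame`.
#' @param spec a [scan_spec()].
#' @return A `scan_result` data.frame: `transcript_id`, `beta` (effect
#'   of the variable of interest), `lrt_stat`, `p`, `q`, `converged`;
#'   the scan configuration and stratum size are attached as attributes.
#' @export
lmm_scan <- function(expression, cohort, spec = scan_spec()) {
  validate_cohort(cohort)
  expression <- .align_expression(expression, cohort)
  Xred <- .confounder_design(cohort, spec)
  voi <- paste0("PCB", spec$variable_of_interest)
  x <- transform_exposure(cohort[[paste0("pcb_", spec$variable_of_interest)]],
                          spec$exposure_transform)
  Xfull <- cbind(Xred, stats::setNames(data.frame(x), voi))
  Xfull <- as.matrix(Xfull)
  .run_scan(expression, cohort, Xfull, Xred, spec, voi,
            label = sprintf("PCB%s main effect", spec$variable_of_interest))
}

#' Transcriptome-wide scan for a PCB-by-leukocyte interaction
#'
#' The full model carries the PCB main effect, the cell-fraction main
#' effect and their product; the reduced model drops only the product,
#' so the likelihood-ratio test has one degree of freedom.
#'
#' @inheritParams lmm_scan
#' @param pcb congener label (`"118"`, ..., `"180"`).
#' @param wbc cell-type label (`"NK"`, `"B"`, `"Mono"`, `"Gran"`,
#'   `"CD8T"`, `"CD4T"`).
#' @return A `scan_result` data.frame (see [lmm_scan()]); `beta` is the
#'   interaction coefficient.
#' @export
interaction_scan <- function(expression, cohort, pcb, wbc, spec = scan_spec()) {
  validate_cohort(cohort)
  pcb <- sub("^PCB", "", as.character(pcb))
  if (!pcb %in% PCB_CONGENERS) .stopf("unknown congener '%s'", pcb)
  wbc <- match.arg(wbc, WBC_CELL_TYPES)
  expression <- .align_expression(expression, cohort)

  # the interaction cell type must have its main effect in both models;
  # if adding it closes the simplex (all six fractions + intercept),
  # drop one other fraction to keep the design full rank
  wset <- union(spec$wbc_confounders, wbc)
  if (length(wset) == length(WBC_CELL_TYPES))
    wset <- setdiff(wset, setdiff(wset, wbc)[length(wset) - 1])
  spec2 <- spec
  spec2$wbc_confounders <- wset
  Xconf <- .confounder_design(cohort, spec2)

  x <- transform_exposure(cohort[[paste0("pcb_", pcb)]], spec$exposure_transform)
  w <- cohort[[paste0("wbc_", wbc)]]
  main <- paste0("PCB", pcb)
  inter <- paste0("PCB", pcb, ":", wbc)
  Xred <- cbind(Xconf, stats::setNames(data.frame(x), main))
  Xred <- as.matrix(Xred)
  Xfull <- cbind(Xred, stats::setNames(data.frame(x * w), inter))
  Xfull <- as.matrix(Xfull)
  .run_scan(expression, cohort, Xfull, Xred, spec, inter,
            label = sprintf("PCB%s x %s interaction", pcb, wbc))
}

#' @export
print.scan_result <- function(x, ...) {
  sp <- attr(x, "spec")
  cat(sprintf("Scan: %s (n = %d, %d transcripts, test = %s)\n",
              attr(x, "label"), attr(x, "n"), nrow(x), sp$test))
  nsig <- sum(x$q <= sp$fdr_alpha, na.rm = TRUE)
  cat(sprintf("  BH-significant at FDR %.2g: %d; skipped/flagged: %d\n",
              sp$fdr_alpha, nsig, attr(x, "n_skipped")))
  print(utils::head(as.data.frame(x)[order(x$p), ], 5))
  invisible(x)
}

#' @export
summary.scan_result <- function(object, ...) {
  sp <- attr(object, "spec")
  list(label = attr(object, "label"), n = attr(object, "n"),
       n_transcripts = nrow(object),
       n_significant = sum(object$q <= sp$fdr_alpha, na.rm = TRUE),
       n_skipped = attr(object, "n_skipped"),
       fdr_alpha = sp$fdr_alpha,
       min_p = suppressWarnings(min(object$p, na.rm = TRUE)))
}

#' @export
plot.scan_result <- function(x, ...) {
  graphics::hist(x$p, breaks = 40, col = "grey", border = "white",
                 xlab = "LRT p-value", main = attr(x, "label"), ...)
  graphics::abline(h = sum(!is.na(x$p)) / 40, lty = 2)
  invisible(x)
}

#' Interaction effect size reaching a target power in a given cohort
#'
#' Converts a target power into the PCB-by-cell-type interaction
#' coefficient that achieves it for this cohort's realized design: the
#' product term is residualized on the full set of other covariates, the
#' Cohen's f2 for the target power is found by [f2_for_power()], and the
#' coefficient follows from the noncentrality identity
#' `ncp = beta^2 * SSR(x) / sigma2_e`. When a scan tests many
#' transcripts at once, `alpha` should be the effective per-test level
#' of the multiplicity procedure, not the nominal one; for a
#' Benjamini-Hochberg scan with a fraction `pi1` of true effects the
#' self-consistent level is approximately
#' `fdr_alpha * pi1 * power` (the expected step-up threshold).
#'
#' @inheritParams interaction_scan
#' @param power target per-test power.
#' @param alpha per-test significance level at which the power is to be
#'   achieved.
#' @param sigma2_e residual variance of the generative model.
#' @return The interaction coefficient (positive scalar).
#' @export
interaction_effect_for_power <- function(cohort, pcb, wbc, spec = scan_spec(),
                                         power = 0.8, alpha = 0.002,
                                         sigma2_e = 1) {
  validate_cohort(cohort)
  pcb <- sub("^PCB", "", as.character(pcb))
  wbc <- match.arg(wbc, WBC_CELL_TYPES)
  wset <- union(spec$wbc_confounders, wbc)
  if (length(wset) == length(WBC_CELL_TYPES))
    wset <- setdiff(wset, setdiff(wset, wbc)[length(wset) - 1])
  spec2 <- spec
  spec2$wbc_confounders <- wset
  Xconf <- .confounder_design(cohort, spec2)
  x <- transform_exposure(cohort[[paste0("pcb_", pcb)]], spec$exposure_transform)
  w <- cohort[[paste0("wbc_", wbc)]]
  Xred <- cbind(Xconf, x)
  r <- stats::lm.fit(Xred, x * w)$residuals
  ssr <- sum(r^2)
  v <- nrow(cohort) - ncol(Xred) - 1
  f2 <- f2_for_power(1, v, power, alpha)
  sqrt(f2 * (1 + v + 1) * sigma2_e / ssr)
}

#' Transcripts declared significant by a scan
#'
#' @param x a `scan_result`.
#' @param alpha FDR level; defaults to the scan's own level.
#' @return Character vector of transcript ids with `q <= alpha`.
#' @export
significant_transcripts <- function(x, alpha = NULL) {
  stopifnot(inherits(x, "scan_result"))
  alpha <- alpha %||% attr(x, "spec")$fdr_alpha
  x$transcript_id[!is.na(x$q) & x$q <= alpha]
}
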