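#' Variance inflation factors of a design matrix
#'
#' For every column j, `VIF_j = 1 / (1 - R2_j)` where `R2_j` is the
#' coefficient of determination of column j regressed (with intercept) on
#' all other columns. Exact collinearity is reported as `Inf`, not an
#' error. Categorical covariates must be pre-expanded to dummy columns.
#'
#' @param design numeric matrix or data.frame of covariates (no
#'   intercept column); at least two columns, no missing values, more
#'   rows than columns.
#' @param threshold retained for the report; see [screen_variables()].
#' @return An object of class `vif_report`: a list with `vif` (named,
#'   possibly `Inf`), `retained`, `excluded`, `removal_order`,
#'   `threshold`.
#' @examples
#' x <- cbind(a = rnorm(50), b = rnorm(50))
#' compute_vif(x)$vif
#' @export
compute_vif <- function(design, threshold = 4) {
  X <- as.matrix(design)
  storage.mode(X) <- "double"
  if (anyNA(X)) .stopf("design contains missing values")
  if (ncol(X) < 2) .stopf("VIF needs at least 2 columns")
  if (nrow(X) <= ncol(X)) .stopf("need more rows (%d) than columns (%d)", nrow(X), ncol(X))
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    .stopf("constant column(s): %s", paste(colnames(X)[sds == 0], collapse = ", "))
  v <- vapply(seq_len(ncol(X)), function(j) {
    y <- X[, j]
    Z <- cbind(1, X[, -j, drop = FALSE])
    fit <- stats::lm.fit(Z, y)
    rss <- sum(fit$residuals^2)
    tss <- sum((y - mean(y))^2)
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-12) Inf else max(1 / (1 - r2), 1)
  }, numeric(1))
  names(v) <- colnames(X)
  structure(list(vif = v, retained = colnames(X), excluded = character(0),
                 removal_order = character(0), threshold = threshold),
            class = "vif_report")
}

#' Iteratively screen covariates on variance inflation
#'
#' Removes the worst (highest-VIF) covariate at or above the threshold,
#' recomputes, and repeats until every retained covariate has VIF below
#' the threshold. The removal order is recorded. The default threshold of
#' 4 encodes the usual multicollinearity rule of thumb for deciding which
#' covariates may share a regression model.
#'
#' @inheritParams compute_vif
#' @param threshold exclusion cutoff, default 4.
#' @return A `vif_report` whose `vif` refers to the retained columns.
#' @export
screen_variables <- function(design, threshold = 4) {
  X <- as.matrix(design)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  removed <- character(0)
  repeat {
    if (ncol(X) < 2) break
    rep0 <- compute_vif(X, threshold)
    if (max(rep0$vif) < threshold) {
      return(structure(list(vif = rep0$vif, retained = colnames(X),
                            excluded = removed, removal_order = removed,
                            threshold = threshold),
                       class = "vif_report"))
    }
    worst <- names(rep0$vif)[which.max(rep0$vif)]
    removed <- c(removed, worst)
    X <- X[, setdiff(colnames(X), worst), drop = FALSE]
  }
  # screening reduced the design below the 2 columns VIF needs
  v <- stats::setNames(rep(NA_real_, ncol(X)), colnames(X))
  structure(list(vif = v, retained = colnames(X), excluded = removed,
                 removal_order = removed, threshold = threshold),
            class = "vif_report")
}

#' @export
print.vif_report <- function(x, ...) {
  cat("Variance inflation report (threshold ", x$threshold, ")\n", sep = "")
  print(round(x$vif, 3))
  if (length(x$excluded))
    cat("excluded (in order):", paste(x$removal_order, collapse = ", "), "\n")
  invisible(x)
}

#' Expand a cohort into the numeric design used for VIF screening
#'
#' Builds the covariate matrix of the dependency analysis: the six
#' log-transformed PCB levels, cohort, sex and smoking dummies, age, BMI
#' and the leukocyte fractions. Granulocytes — the dominant, simplex-
#' constrained fraction — are dropped by default before VIF is computed,
#' since the six fractions summing to one force perfect collinearity.
#'
#' @param cohort a cohort `data.frame`.
#' @param drop_granulocytes drop the `wbc_Gran` column (default `TRUE`).
#' @return A numeric matrix, one dummy column per non-reference factor
#'   level.
#' @export
cohort_design_for_vif <- function(cohort, drop_granulocytes = TRUE) {
  validate_cohort(cohort)
  wbc <- .wbc_cols()
  if (drop_granulocytes) wbc <- setdiff(wbc, "wbc_Gran")
  X <- cbind(log(as.matrix(cohort[, .pcb_cols()])),
             cohort_EPIC = as.numeric(cohort$cohort_label == "EPIC"),
             sex_M = as.numeric(cohort$sex == "M"),
             age = cohort$age, bmi = cohort$bmi,
             smoking_former = as.numeric(cohort$smoking == "former"),
             smoking_current = as.numeric(cohort$smoking == "current"),
             as.matrix(cohort[, wbc]))
  X
}
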