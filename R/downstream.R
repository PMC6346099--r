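#' Per-congener sex comparison of exposure levels
#'
#' Two-sample t-test of female versus male exposure for each congener,
#' on the same transformation the scans use (default log). Welch's
#' unequal-variance form is the default; `var_equal = TRUE` gives the
#' classical Student form.
#'
#' @param cohort a cohort `data.frame` with both sexes present.
#' @param transform exposure transformation (see [transform_exposure()]).
#' @param var_equal use the pooled-variance Student t instead of Welch.
#' @return A data.frame with one row per congener: `congener`, `t`, `p`,
#'   `mean_F`, `mean_M`.
#' @export
exposure_sex_ttest <- function(cohort, transform = "log", var_equal = FALSE) {
  validate_cohort(cohort)
  if (nlevels(droplevels(cohort$sex)) < 2) .stopf("both sexes must be present")
  isF <- cohort$sex == "F"
  res <- lapply(PCB_CONGENERS, function(cg) {
    x <- transform_exposure(cohort[[paste0("pcb_", cg)]], transform)
    tt <- stats::t.test(x[isF], x[!isF], var.equal = var_equal)
    data.frame(congener = cg, t = unname(tt$statistic), p = tt$p.value,
               mean_F = mean(x[isF]), mean_M = mean(x[!isF]))
  })
  do.call(rbind, res)
}

#' Overlap of a hit list with a known gene list
#'
#' @param hits nonempty character vector of hit gene ids.
#' @param known character vector of genes already linked to the exposure.
#' @return A list with `n_overlap`, `fraction_of_hits`
#'   (`|hits ∩ known| / |hits|`) and `novel` (hits not in `known`).
#' @export
gene_list_overlap <- function(hits, known) {
  hits <- unique(as.character(hits))
  known <- unique(as.character(known))
  if (!length(hits)) .stopf("empty hit list")
  ov <- intersect(hits, known)
  list(n_overlap = length(ov),
       fraction_of_hits = length(ov) / length(hits),
       novel = setdiff(hits, known))
}

#' Hypergeometric over-representation analysis
#'
#' For each pathway, the upper-tail hypergeometric probability of seeing
#' at least the observed overlap between the hit list and the pathway
#' within the background universe, with Benjamini-Hochberg q-values
#' across the supplied pathway collection.
#'
#' @param hits character vector of hit genes; must be a subset of
#'   `background`.
#' @param pathways a named list of character vectors (e.g. from
#'   [read_gmt()]), or a single character vector for one pathway.
#' @param background the gene universe (e.g. all genes surviving
#'   preprocessing).
#' @return A data.frame with one row per pathway: `pathway`,
#'   `n_pathway` (members in background), `overlap`, `p`, `q`.
#' @export
ora_hypergeometric <- function(hits, pathways, background) {
  hits <- unique(as.character(hits))
  background <- unique(as.character(background))
  if (!all(hits %in% background)) .stopf("hits must be a subset of the background")
  if (!is.list(pathways)) pathways <- list(pathway = pathways)
  N <- length(background)
  n <- length(hits)
  rows <- lapply(names(pathways), function(nm) {
    pw <- intersect(unique(as.character(pathways[[nm]])), background)
    if (!length(pw)) .stopf("pathway '%s' has no members in the background", nm)
    K <- length(pw)
    k <- length(intersect(hits, pw))
    # P(X >= k), X ~ Hypergeom(N, K, n)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(pathway = nm, n_pathway = K, overlap = k, p = p)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)$q_values
  out
}

#' Two-group differential expression and tail signature
#'
#' Per-gene Welch t-test and log2 fold change between two groups (the
#' matrix is assumed to hold log2-scale intensities, so the fold-change
#' cutoff `fc_cut` is applied as `|log2FC| >= log2(fc_cut)`). Genes are
#' significant when they pass both the fold-change and BH-adjusted
#' p-value cutoffs; the signature keeps only significant genes in the
#' top and bottom `tail_frac` of fold change.
#'
#' @param expression gene x subject matrix of log2 intensities.
#' @param group_labels 2-level factor (or coercible) over subjects.
#' @param fc_cut fold-change cutoff on the natural scale, default 1.5.
#' @param q_cut adjusted-p cutoff, default 0.05.
#' @param tail_frac tail fraction for the signature, default 0.05.
#' @return A list: `table` (gene, log2_fc, t, p, q, significant),
#'   `up` and `down` (character vectors, the signature gene sets).
#' @export
diff_expr_signature <- function(expression, group_labels, fc_cut = 1.5,
                                q_cut = 0.05, tail_frac = 0.05) {
  x <- as.matrix(expression)
  g <- droplevels(as.factor(group_labels))
  if (nlevels(g) != 2) .stopf("exactly two groups required")
  i1 <- g == levels(g)[1]; i2 <- g == levels(g)[2]
  if (sum(i1) < 2 || sum(i2) < 2) .stopf("each group needs at least 2 subjects")
  m1 <- rowMeans(x[, i1, drop = FALSE]); m2 <- rowMeans(x[, i2, drop = FALSE])
  v1 <- apply(x[, i1, drop = FALSE], 1, stats::var)
  v2 <- apply(x[, i2, drop = FALSE], 1, stats::var)
  n1 <- sum(i1); n2 <- sum(i2)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  q <- bh_fdr(p, q_cut)$q_values
  lfc <- m1 - m2
  sig <- !is.na(q) & q <= q_cut & abs(lfc) >= log2(fc_cut)
  ids <- rownames(x) %||% as.character(seq_len(nrow(x)))
  tab <- data.frame(gene = ids, log2_fc = lfc, t = tstat, p = p, q = q,
                    significant = sig, stringsAsFactors = FALSE)
  up_thr <- stats::quantile(lfc, 1 - tail_frac, na.rm = TRUE)
  dn_thr <- stats::quantile(lfc, tail_frac, na.rm = TRUE)
  list(table = tab,
       up = ids[sig & lfc >= up_thr],
       down = ids[sig & lfc <= dn_thr])
}

#' Remove estimated batch effects from an expression matrix
#'
#' Fits, per transcript, the confounder-only mixed model of the scan and
#' subtracts the predicted batch random intercepts (BLUPs), leaving
#' expression on its original scale but free of the scan-date offsets.
#'
#' @inheritParams lmm_scan
#' @return A matrix of the same shape as `expression`.
#' @export
batch_correct <- function(expression, cohort, spec = scan_spec()) {
  validate_cohort(cohort)
  expression <- .align_expression(expression, cohort)
  X <- .confounder_design(cohort, spec)
  batch <- cohort[[spec$random_effect]]
  pre <- .lmm_precompute(X, batch)
  Y <- as.matrix(expression)
  Xty <- crossprod(pre$X, t(Y))
  By <- t(rowsum(t(Y), pre$bi))
  yty <- rowSums(Y^2)
  out <- Y
  for (t in seq_len(nrow(Y))) {
    fit <- .lmm_fit_core(pre, Xty[, t], By[t, ], yty[t])
    if (!isTRUE(fit$converged) || is.na(fit$lambda)) next
    resid_m <- Y[t, ] - as.numeric(pre$X %*% fit$beta)
    rj <- rowsum(resid_m, pre$bi)[, 1]
    u <- fit$lambda * rj / (1 + fit$lambda * pre$nj)
    out[t, ] <- Y[t, ] - u[pre$bi]
  }
  out
}

#' Correlation of expression with time to diagnosis
#'
#' Pearson (default) or Spearman correlation, per gene, between
#' batch-corrected expression of future cases and their time from
#' sampling to diagnosis.
#'
#' @param expression_hits gene x subject matrix restricted to future
#'   cases (batch-correct first; see [batch_correct()]).
#' @param time_to_diagnosis positive times, one per column.
#' @param method `"pearson"` or `"spearman"`.
#' @return A data.frame with `gene`, `r`, `p` (`NA` with a reason
#'   attribute when a gene or the time vector is constant).
#' @export
ttd_correlation <- function(expression_hits, time_to_diagnosis,
                            method = c("pearson", "spearman")) {
  method <- match.arg(method)
  x <- as.matrix(expression_hits)
  tt <- as.numeric(time_to_diagnosis)
  if (ncol(x) != length(tt)) .stopf("time vector must match expression columns")
  if (ncol(x) < 3) .stopf("need at least 3 future cases")
  if (anyNA(tt)) .stopf("time_to_diagnosis must be complete (future cases only)")
  const_t <- stats::sd(tt) == 0
  ids <- rownames(x) %||% as.character(seq_len(nrow(x)))
  rows <- lapply(seq_len(nrow(x)), function(i) {
    if (const_t || stats::sd(x[i, ]) == 0)
      return(data.frame(gene = ids[i], r = NA_real_, p = NA_real_))
    ct <- stats::cor.test(x[i, ], tt, method = method, exact = FALSE)
    data.frame(gene = ids[i], r = unname(ct$estimate), p = ct$p.value)
  })
  out <- do.call(rbind, rows)
  if (const_t) attr(out, "reason") <- "constant time-to-diagnosis"
  out
}

#' Stratified scan-count table
#'
#' Orchestrates scans over a stratification plan and a grid of congeners
#' (optionally crossed with cell types for interaction scans) and
#' tabulates the number of BH-significant transcripts per cell. For the
#' sex-by-future-case plan the table mirrors the published layout:
#' per (sex, cell type, congener) the control count, the future-case
#' count, and their overlap.
#'
#' @inheritParams lmm_scan
#' @param strata_plan one of `"all"`, `"sex"`, `"sex_case"`.
#' @param pcbs congener labels to scan.
#' @param wbcs cell types for interaction scans, or `NULL` for
#'   main-effect scans. Granulocytes are not scanned by default.
#' @param min_n strata smaller than this yield `NA` counts (default 30).
#' @return A data.frame of class `count_table`; for `"sex_case"` the
#'   columns are `sex`, `cell_type`, `pcb`, `controls`, `overlap`,
#'   `future_cases`; otherwise `stratum`, `cell_type`, `pcb`,
#'   `n_significant`.
#' @export
stratified_scan_counts <- function(expression, cohort,
                                   strata_plan = c("sex_case", "sex", "all"),
                                   pcbs = PCB_CONGENERS,
                                   wbcs = setdiff(WBC_CELL_TYPES, "Gran"),
                                   spec = scan_spec(), min_n = 30) {
  strata_plan <- match.arg(strata_plan)
  validate_cohort(cohort)
  expression <- .align_expression(expression, cohort)

  run_cell <- function(sub_idx, pcb, wbc) {
    if (sum(sub_idx) < min_n) return(NULL)
    co <- droplevels(cohort[sub_idx, ])
    ex <- expression[, sub_idx, drop = FALSE]
    res <- if (is.null(wbc)) {
      sp <- spec; sp$variable_of_interest <- pcb
      lmm_scan(ex, co, sp)
    } else interaction_scan(ex, co, pcb, wbc, spec)
    significant_transcripts(res)
  }

  wlist <- if (is.null(wbcs)) list(NULL) else as.list(wbcs)
  grid <- expand.grid(pcb = pcbs, wbc = seq_along(wlist), stringsAsFactors = FALSE)

  if (strata_plan == "sex_case") {
    rows <- list()
    for (sx in c("F", "M")) for (g in seq_len(nrow(grid))) {
      pcb <- grid$pcb[g]; wbc <- wlist[[grid$wbc[g]]]
      ctrl <- run_cell(cohort$sex == sx & !cohort$future_case, pcb, wbc)
      case <- run_cell(cohort$sex == sx & cohort$future_case, pcb, wbc)
      rows[[length(rows) + 1]] <- data.frame(
        sex = sx, cell_type = wbc %||% NA_character_, pcb = pcb,
        controls = if (is.null(ctrl)) NA_integer_ else length(ctrl),
        overlap = if (is.null(ctrl) || is.null(case)) NA_integer_
                  else length(intersect(ctrl, case)),
        future_cases = if (is.null(case)) NA_integer_ else length(case),
        stringsAsFactors = FALSE)
    }
  } else {
    strata <- switch(strata_plan,
                     all = list(all = rep(TRUE, nrow(cohort))),
                     sex = list(F = cohort$sex == "F", M = cohort$sex == "M"))
    rows <- list()
    for (snm in names(strata)) for (g in seq_len(nrow(grid))) {
      pcb <- grid$pcb[g]; wbc <- wlist[[grid$wbc[g]]]
      hit <- run_cell(strata[[snm]], pcb, wbc)
      rows[[length(rows) + 1]] <- data.frame(
        stratum = snm, cell_type = wbc %||% NA_character_, pcb = pcb,
        n_significant = if (is.null(hit)) NA_integer_ else length(hit),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("count_table", "data.frame")
  out
}
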