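#' Default configuration for the synthetic cohort generator
#'
#' Distribution parameters for [generate_cohort()]. Exposures are
#' log-normal per congener with a shared Gaussian-copula correlation
#' (serum PCB congeners are strongly mutually correlated); females receive
#' an upward location shift on the log scale for congeners 118, 156, 170
#' and 180, mirroring the sex difference reported for those congeners.
#' Leukocyte fractions are Dirichlet over the six cell types with
#' concentrations centred on typical whole-blood proportions (granulocytes
#' dominant). Follow-up time to diagnosis for future cases is
#' truncated-normal, mean 5.96 y, sd 2.85 y, bounded to \[2, 17\] years.
#'
#' @param pcb_meanlog named 6-vector, log-scale location per congener
#'   (arbitrary serum concentration units).
#' @param pcb_sdlog named 6-vector, log-scale spread per congener.
#' @param pcb_corr pairwise correlation of the Gaussian copula across
#'   congeners, in \[0, 1).
#' @param sex_shift_sd upward shift (in units of `pcb_sdlog`) of the
#'   female log-location for `shifted_congeners`.
#' @param shifted_congeners congener labels receiving the female shift.
#' @param wbc_concentration named 6-vector of Dirichlet concentrations in
#'   the order `NK, B, Mono, Gran, CD8T, CD4T`.
#' @param n_batches number of scan-date batches; each batch receives at
#'   least two subjects.
#' @param sex_prob probability a subject is female.
#' @param cohort_prob probability of the "NSHDS"-like cohort label.
#' @param age_mean,age_sd,bmi_mean,bmi_sd Gaussian covariate parameters.
#' @param smoking_prob probabilities for never/former/current smoking.
#' @param followup_mean,followup_sd,followup_range truncated-normal
#'   parameters (years) for time to diagnosis of future cases.
#'
#' @return A named list of class `cohort_config`.
#' @export
cohort_config <- function(pcb_meanlog = log(c(`118` = 20, `138` = 60, `153` = 120,
                                              `156` = 10, `170` = 30, `180` = 80)),
                          pcb_sdlog = rep(0.5, 6),
                          pcb_corr = 0.6,
                          sex_shift_sd = 0.5,
                          shifted_congeners = c("118", "156", "170", "180"),
                          wbc_concentration = c(NK = 4, B = 3, Mono = 4,
                                                Gran = 36, CD8T = 5, CD4T = 8),
                          n_batches = 20,
                          sex_prob = 0.5,
                          cohort_prob = 0.5,
                          age_mean = 53.3, age_sd = 7.8,
                          bmi_mean = 26, bmi_sd = 4,
                          smoking_prob = c(never = 0.5, former = 0.3, current = 0.2),
                          followup_mean = 5.96, followup_sd = 2.85,
                          followup_range = c(2, 17)) {
  pcb_meanlog <- rep_len(pcb_meanlog, 6)
  pcb_sdlog <- rep_len(pcb_sdlog, 6)
  if (any(pcb_sdlog <= 0)) .stopf("pcb_sdlog must be strictly positive")
  if (any(wbc_concentration <= 0)) .stopf("wbc_concentration must be strictly positive")
  if (pcb_corr < 0 || pcb_corr >= 1) .stopf("pcb_corr must lie in [0, 1)")
  if (followup_sd <= 0 || age_sd <= 0 || bmi_sd <= 0) .stopf("distribution scales must be positive")
  if (n_batches < 1) .stopf("n_batches must be >= 1")
  bad <- setdiff(shifted_congeners, PCB_CONGENERS)
  if (length(bad)) .stopf("unknown congener(s): %s", paste(bad, collapse = ", "))
  structure(list(pcb_meanlog = pcb_meanlog, pcb_sdlog = pcb_sdlog,
                 pcb_corr = pcb_corr, sex_shift_sd = sex_shift_sd,
                 shifted_congeners = shifted_congeners,
                 wbc_concentration = wbc_concentration, n_batches = n_batches,
                 sex_prob = sex_prob, cohort_prob = cohort_prob,
                 age_mean = age_mean, age_sd = age_sd,
                 bmi_mean = bmi_mean, bmi_sd = bmi_sd,
                 smoking_prob = smoking_prob,
                 followup_mean = followup_mean, followup_sd = followup_sd,
                 followup_range = followup_range),
            class = "cohort_config")
}

# Dirichlet draws via normalized gammas; rows renormalized to exact sum 1.
.rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  s <- rowSums(x)
  if (any(s == 0)) {
    # pathological underflow with tiny concentrations: put mass on the
    # largest-concentration component
    j <- which.max(alpha)
    x[s == 0, j] <- 1
    s <- rowSums(x)
  }
  x / s
}

# truncated normal by rejection (bounds are a few sd wide here)
.rtruncnorm <- function(n, mean, sd, lower, upper) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    draw <- stats::rnorm(length(need), mean, sd)
    ok <- draw >= lower & draw <= upper
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

#' Generate a synthetic prospective cohort
#'
#' Draws a subject table with the structure the scans assume: two cohort
#' labels, sex, age, BMI, smoking, six correlated log-normal serum PCB
#' levels (female-shifted for congeners 118/156/170/180 by default),
#' Dirichlet white-blood-cell fractions, a scan-date batch label with at
#' least two subjects per batch, future-lymphoma case status and, for
#' future cases, a truncated-normal time to diagnosis.
#'
#' @param n number of subjects.
#' @param n_cases number of future cases (`future_case = TRUE`).
#' @param config a [cohort_config()] list.
#' @param seed integer seed; the same seed reproduces the cohort exactly.
#'
#' @return A `data.frame` with one row per subject and columns
#'   `subject_id`, `cohort_label`, `sex`, `age`, `bmi`, `smoking`,
#'   `pcb_118` ... `pcb_180`, `wbc_NK` ... `wbc_CD4T`, `batch`,
#'   `future_case`, `time_to_diagnosis` (NA for controls), `cancer_type`.
#' @examples
#' coh <- generate_cohort(n = 64, n_cases = 27, seed = 1)
#' table(coh$future_case)
#' @export
generate_cohort <- function(n = 512, n_cases = 217, config = cohort_config(),
                            seed = 1) {
  if (n_cases < 0 || n_cases > n) .stopf("n_cases must lie in [0, n]")
  if (n < 1) .stopf("n must be positive")
  cfg <- config
  set.seed(seed)

  sex <- factor(ifelse(stats::runif(n) < cfg$sex_prob, "F", "M"), levels = c("F", "M"))
  cohort_label <- factor(ifelse(stats::runif(n) < cfg$cohort_prob, "NSHDS", "EPIC"),
                         levels = c("NSHDS", "EPIC"))
  age <- stats::rnorm(n, cfg$age_mean, cfg$age_sd)
  bmi <- stats::rnorm(n, cfg$bmi_mean, cfg$bmi_sd)
  smoking <- factor(sample(names(cfg$smoking_prob), n, replace = TRUE,
                           prob = cfg$smoking_prob),
                    levels = c("never", "former", "current"))

  # exposures: equicorrelated Gaussian copula on the log scale
  r <- cfg$pcb_corr
  sigma <- matrix(r, 6, 6); diag(sigma) <- 1
  z <- matrix(stats::rnorm(n * 6), n, 6) %*% chol(sigma)
  shift <- as.numeric(PCB_CONGENERS %in% cfg$shifted_congeners) * cfg$sex_shift_sd
  loc <- matrix(cfg$pcb_meanlog, n, 6, byrow = TRUE) +
    outer(as.numeric(sex == "F"), shift * cfg$pcb_sdlog)
  pcb <- exp(loc + z %*% diag(cfg$pcb_sdlog))
  colnames(pcb) <- .pcb_cols()

  wbc <- generate_wbc_proportions(n, cfg$wbc_concentration,
                                  seed = NULL)  # continue current RNG stream
  colnames(wbc) <- .wbc_cols()

  # batches: at least two subjects per level, remainder uniform
  nb <- min(cfg$n_batches, floor(n / 2))
  base <- rep(seq_len(nb), 2)
  extra <- if (n > 2 * nb) sample.int(nb, n - 2 * nb, replace = TRUE) else integer(0)
  batch <- factor(paste0("batch", sample(c(base, extra))),
                  levels = paste0("batch", seq_len(nb)))

  future_case <- sample(c(rep(TRUE, n_cases), rep(FALSE, n - n_cases)))
  ttd <- rep(NA_real_, n)
  if (n_cases > 0)
    ttd[future_case] <- .rtruncnorm(n_cases, cfg$followup_mean, cfg$followup_sd,
                                    cfg$followup_range[1], cfg$followup_range[2])
  cancer_type <- factor(ifelse(future_case, "lymphoma", "none"),
                        levels = c("none", "lymphoma"))

  out <- data.frame(subject_id = sprintf("S%04d", seq_len(n)),
                    cohort_label = cohort_label, sex = sex, age = age, bmi = bmi,
                    smoking = smoking, pcb, wbc, batch = batch,
                    future_case = future_case, time_to_diagnosis = ttd,
                    cancer_type = cancer_type,
                    stringsAsFactors = FALSE)
  rownames(out) <- out$subject_id
  out
}

#' Draw leukocyte-fraction vectors from a Dirichlet distribution
#'
#' @param n number of rows to draw.
#' @param concentration strictly positive 6-vector of Dirichlet
#'   concentrations, order `NK, B, Mono, Gran, CD8T, CD4T`.
#' @param seed integer seed, or `NULL` to continue the current RNG stream.
#' @return An `n` x 6 matrix; each row is on the unit simplex.
#' @examples
#' w <- generate_wbc_proportions(5, rep(10, 6), seed = 1)
#' rowSums(w)
#' @export
generate_wbc_proportions <- function(n, concentration, seed = 1) {
  if (any(concentration <= 0)) .stopf("concentration entries must be > 0")
  if (!is.null(seed)) set.seed(seed)
  w <- .rdirichlet(n, concentration)
  colnames(w) <- names(concentration) %||% WBC_CELL_TYPES[seq_along(concentration)]
  w
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate the structural invariants of a cohort table
#'
#' Checks simplex white-blood-cell fractions, strictly positive PCB
#' levels, time-to-diagnosis present exactly for future cases, and the
#' expected column set. Called internally by the scan functions.
#'
#' @param cohort a cohort `data.frame` as from [generate_cohort()].
#' @return `cohort`, invisibly, if valid; otherwise an error.
#' @export
validate_cohort <- function(cohort) {
  need <- c("subject_id", "cohort_label", "sex", "age", "bmi", "smoking",
            .pcb_cols(), .wbc_cols(), "batch", "future_case",
            "time_to_diagnosis", "cancer_type")
  miss <- setdiff(need, names(cohort))
  if (length(miss)) .stopf("cohort is missing column(s): %s", paste(miss, collapse = ", "))
  w <- as.matrix(cohort[, .wbc_cols()])
  if (any(w < 0) || any(abs(rowSums(w) - 1) > 1e-12))
    .stopf("wbc fractions must be nonnegative and sum to 1 within 1e-12")
  if (any(as.matrix(cohort[, .pcb_cols()]) <= 0))
    .stopf("pcb levels must be strictly positive")
  tt <- cohort$time_to_diagnosis
  if (any(cohort$future_case & (is.na(tt) | tt <= 0)))
    .stopf("future cases must have positive time_to_diagnosis")
  if (any(!cohort$future_case & !is.na(tt)))
    .stopf("controls must have missing time_to_diagnosis")
  invisible(cohort)
}
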