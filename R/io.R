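#' Read and write the package's TSV and GMT dialects
#'
#' Cohort tables are written one row per subject with the fixed header
#' produced by [generate_cohort()]. Feature matrices (expression,
#' methylation, reference signatures) are written features-in-rows with
#' the feature id as first column `feature_id`. Gene sets use the
#' standard GMT layout (set name, description, then members,
#' tab-separated). Simulation truth round-trips through JSON.
#'
#' @param cohort,x,sets,truth object to write.
#' @param path file path.
#' @name pcbscan-io
NULL

#' @rdname pcbscan-io
#' @export
write_cohort_tsv <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname pcbscan-io
#' @export
read_cohort_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  d$cohort_label <- factor(d$cohort_label, levels = c("NSHDS", "EPIC"))
  d$sex <- factor(d$sex, levels = c("F", "M"))
  d$smoking <- factor(d$smoking, levels = c("never", "former", "current"))
  d$batch <- factor(d$batch)
  d$cancer_type <- factor(d$cancer_type, levels = c("none", "lymphoma"))
  d$future_case <- as.logical(d$future_case)
  if (!"time_to_diagnosis" %in% names(d)) d$time_to_diagnosis <- NA_real_
  rownames(d) <- d$subject_id
  validate_cohort(d)
  d
}

#' @rdname pcbscan-io
#' @export
write_matrix_tsv <- function(x, path) {
  d <- data.frame(feature_id = rownames(x) %||% as.character(seq_len(nrow(x))),
                  as.data.frame(x, check.names = FALSE),
                  check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname pcbscan-io
#' @export
read_matrix_tsv <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  storage.mode(m) <- "double"
  m
}

#' Read a long-format probe table
#'
#' Columns `probe_id`, `subject_id`, `intensity`, `pixel_fraction`; the
#' input of [filter_probes_by_pixels()].
#'
#' @param path TSV file path.
#' @return A data.frame.
#' @export
read_probe_table <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("probe_id", "subject_id", "intensity", "pixel_fraction")
  miss <- setdiff(need, names(d))
  if (length(miss)) .stopf("probe table missing column(s): %s", paste(miss, collapse = ", "))
  d
}

#' @rdname pcbscan-io
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) .stopf("malformed GMT line: '%s'", substr(l, 1, 40))
    unique(f[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  sets
}

#' @rdname pcbscan-io
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "na", sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname pcbscan-io
#' @export
write_truth_json <- function(truth, path) {
  stopifnot(inherits(truth, "simulation_truth"))
  obj <- list(n_transcripts = truth$n_transcripts,
              alpha = truth$alpha,
              beta_pcb = truth$beta_pcb,
              beta_wbc = truth$beta_wbc,
              beta_inter = as.vector(truth$beta_inter),
              beta_fe = truth$beta_fe,
              sigma2_u = truth$sigma2_u, sigma2_e = truth$sigma2_e,
              sex_specific_mask = as.character(truth$sex_specific_mask))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname pcbscan-io
#' @export
read_truth_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  nt <- obj$n_transcripts
  simulation_truth(nt,
                   alpha = obj$alpha,
                   beta_pcb = matrix(unlist(obj$beta_pcb), nt, 6),
                   beta_wbc = matrix(unlist(obj$beta_wbc), nt, 6),
                   beta_inter = array(obj$beta_inter, dim = c(nt, 6, 6)),
                   beta_fe = obj$beta_fe,
                   sigma2_u = obj$sigma2_u, sigma2_e = obj$sigma2_e,
                   sex_specific_mask = obj$sex_specific_mask)
}

#' Write a scan result with its configuration sidecar
#'
#' The result goes to `<path>` as TSV (`transcript_id`, `beta`,
#' `lrt_stat`, `p`, `q`, `converged`); the scan configuration and
#' stratum size go to `<path>.json`.
#'
#' @param x a `scan_result`.
#' @param path output TSV path.
#' @export
write_scan_tsv <- function(x, path) {
  stopifnot(inherits(x, "scan_result"))
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  sp <- attr(x, "spec")
  jsonlite::write_json(list(spec = unclass(sp), n = attr(x, "n"),
                            label = attr(x, "label"),
                            n_skipped = attr(x, "n_skipped")),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
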