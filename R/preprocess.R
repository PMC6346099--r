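#' Filter probes on pixel coverage
#'
#' Microarray scanners report, per probe and array, the fraction of the
#' maximum possible pixel count actually observed. Probe measurements
#' whose fraction falls below the cutoff are set to missing ("at least"
#' semantics: a fraction exactly at the cutoff is retained).
#'
#' @param probes long-format `data.frame` with columns `probe_id`,
#'   `subject_id`, `intensity`, `pixel_fraction` (each fraction in
#'   \[0, 1\]).
#' @param min_fraction retention cutoff, default 0.75.
#' @return A probe x subject intensity matrix with `NA` where filtered.
#' @export
filter_probes_by_pixels <- function(probes, min_fraction = 0.75) {
  if (!nrow(probes)) .stopf("empty probe table")
  need <- c("probe_id", "subject_id", "intensity", "pixel_fraction")
  miss <- setdiff(need, names(probes))
  if (length(miss)) .stopf("probe table missing column(s): %s", paste(miss, collapse = ", "))
  if (min_fraction < 0 || min_fraction > 1) .stopf("min_fraction must lie in [0, 1]")
  pf <- probes$pixel_fraction
  if (any(pf < 0 | pf > 1, na.rm = TRUE)) .stopf("pixel_fraction must lie in [0, 1]")
  val <- ifelse(!is.na(pf) & pf >= min_fraction, probes$intensity, NA_real_)
  pid <- factor(probes$probe_id, levels = unique(probes$probe_id))
  sid <- factor(probes$subject_id, levels = unique(probes$subject_id))
  out <- matrix(NA_real_, nlevels(pid), nlevels(sid),
                dimnames = list(levels(pid), levels(sid)))
  out[cbind(as.integer(pid), as.integer(sid))] <- val
  out
}

#' Quantile-normalize an expression matrix across arrays
#'
#' Standard between-array quantile normalization: each column is replaced
#' by the mean sorted profile (row means of the column-sorted matrix),
#' assigned back by within-column rank. Ties receive the average of the
#' reference values at the tied positions.
#'
#' @param x numeric matrix, features in rows, arrays in columns; no
#'   missing values (impute first, see [knn_impute()]).
#' @return A matrix of the same shape; every column has an identical
#'   sorted value vector.
#' @examples
#' quantile_normalize(cbind(a = c(1, 2, 3), b = c(4, 6, 8)))
#' @export
quantile_normalize <- function(x) {
  x <- as.matrix(x)
  if (anyNA(x)) .stopf("matrix contains missing values; run knn_impute() first")
  if (!nrow(x) || !ncol(x)) .stopf("empty matrix")
  ref <- rowMeans(apply(x, 2, sort))
  out <- apply(x, 2, function(col) {
    r <- rank(col, ties.method = "average")
    lo <- floor(r); hi <- ceiling(r)
    (ref[lo] + ref[hi]) / 2
  })
  dimnames(out) <- dimnames(x)
  out
}

#' k-nearest-neighbour imputation of missing expression values
#'
#' Each missing cell of a feature is replaced by the mean of the values,
#' at that position, of the `k` nearest features. Distance between two
#' features is Euclidean over their co-observed positions, computed on
#' mean-centred profiles and rescaled by `sqrt(p / p_obs)` to make
#' distances comparable across different overlap sizes. Observed cells
#' are never altered.
#'
#' @param x numeric matrix, features in rows.
#' @param k number of neighbours, default 15. If fewer complete
#'   candidates are available, all available ones are used (with a
#'   warning).
#' @return The matrix with missing entries imputed.
#' @export
knn_impute <- function(x, k = 15) {
  x <- as.matrix(x)
  if (k < 1) .stopf("k must be >= 1")
  if (!anyNA(x)) return(x)
  obs <- !is.na(x)
  all_missing <- rownames(x)[rowSums(obs) == 0] %||% which(rowSums(obs) == 0)
  if (any(rowSums(obs) == 0))
    .stopf("feature(s) entirely missing: %s",
           paste(utils::head(all_missing, 5), collapse = ", "))
  p <- ncol(x)
  ctr <- x - rowMeans(x, na.rm = TRUE)
  out <- x
  todo <- which(rowSums(!obs) > 0)
  for (f in todo) {
    miss_pos <- which(!obs[f, ])
    d <- .knn_distances(ctr, obs, f, p)
    for (s in miss_pos) {
      cand <- which(obs[, s] & is.finite(d))
      cand <- cand[cand != f]
      if (!length(cand)) .stopf("no neighbour observed at position %d for feature %d", s, f)
      kk <- min(k, length(cand))
      if (kk < k) warning(sprintf("feature %d: only %d usable neighbours (k = %d)", f, kk, k))
      nb <- cand[order(d[cand])[seq_len(kk)]]
      out[f, s] <- mean(x[nb, s])
    }
  }
  out
}

# scaled Euclidean distances from feature f to all features over
# pairwise-complete positions (Inf where no overlap)
.knn_distances <- function(ctr, obs, f, p) {
  common <- obs & rep(obs[f, ], each = nrow(obs))
  diff2 <- (ctr - rep(ctr[f, ], each = nrow(ctr)))^2
  diff2[!common] <- 0
  novl <- rowSums(common)
  d <- sqrt(rowSums(diff2) * p / pmax(novl, 1))
  d[novl == 0] <- Inf
  d
}

#' Run the default preprocessing pipeline
#'
#' Pixel filtering, then k-nearest-neighbour imputation, then quantile
#' normalization. The imputation/normalization order is configurable.
#'
#' @param probes a long-format probe table (see
#'   [filter_probes_by_pixels()]).
#' @param min_fraction pixel-coverage cutoff.
#' @param k imputation neighbours.
#' @param impute_first if `FALSE`, normalize on complete rows before
#'   imputation instead.
#' @return A normalized probe x subject matrix.
#' @export
preprocess_pipeline <- function(probes, min_fraction = 0.75, k = 15,
                                impute_first = TRUE) {
  m <- filter_probes_by_pixels(probes, min_fraction)
  if (impute_first) {
    quantile_normalize(knn_impute(m, k))
  } else {
    complete <- rowSums(is.na(m)) == 0
    m[complete, ] <- quantile_normalize(m[complete, , drop = FALSE])
    knn_impute(m, k)
  }
}
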