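#' Half-minimum imputation
#'
#' Replaces each missing intensity with half of the minimum observed
#' intensity of that feature across all samples, emulating values below the
#' detection limit. The un-imputed matrix must be retained separately for
#' absence calls; imputation is for clustering only.
#'
#' @inheritParams feature_matrix
#' @param per_feature If `TRUE` (default) the minimum is taken per feature;
#'   if `FALSE`, half the global minimum of the matrix is used everywhere.
#' @return A feature tibble with no missing intensities.
#' @export
impute_half_min <- function(features, per_feature = TRUE) {
  m <- intensity_matrix(features)
  if (!anyNA(m)) return(features)
  n_obs <- rowSums(!is.na(m))
  if (any(n_obs == 0)) {
    stop("cannot impute feature(s) with no observed values: ",
         paste(rownames(m)[n_obs == 0], collapse = ", "))
  }
  if (per_feature) {
    fill <- apply(m, 1, min, na.rm = TRUE) / 2
    idx <- which(is.na(m), arr.ind = TRUE)
    m[idx] <- fill[idx[, 1]]
  } else {
    m[is.na(m)] <- min(m, na.rm = TRUE) / 2
  }
  set_intensities(features, m)
}

#' Log transform and z-scale per feature
#'
#' Natural log, then per-feature centring to mean 0 and scaling to standard
#' deviation 1 across samples. Requires strictly positive intensities, i.e.
#' run after [impute_half_min()].
#'
#' @inheritParams feature_matrix
#' @param drop_constant Features whose log intensities have zero variance
#'   cannot be z-scaled; drop them with a warning (default) or error.
#' @return A transformed feature tibble (constant features removed when
#'   `drop_constant = TRUE`).
#' @export
log_z_transform <- function(features, drop_constant = TRUE) {
  m <- intensity_matrix(features)
  if (anyNA(m)) stop("missing values present; impute before transforming")
  if (any(m <= 0)) stop("intensities must be strictly positive for the log step")
  lm_ <- log(m)
  sds <- apply(lm_, 1, stats::sd)
  const <- sds == 0
  if (any(const)) {
    if (!drop_constant) {
      stop("zero-variance feature(s): ", paste(rownames(m)[const], collapse = ", "))
    }
    warning(sum(const), " zero-variance feature(s) dropped before z-scaling")
    features <- features[!const, , drop = FALSE]
    lm_ <- lm_[!const, , drop = FALSE]
    sds <- sds[!const]
  }
  z <- (lm_ - rowMeans(lm_)) / sds
  set_intensities(features, z)
}

#' Kolmogorov–Smirnov normality QC
#'
#' One-sample KS test of each transformed feature against the standard
#' normal. Purely a quality-control report: results are never used to drop
#' features.
#'
#' @inheritParams feature_matrix
#' @return A tibble `feature_id`, `statistic`, `p` (`NA` for degenerate
#'   constant features).
#' @export
ks_normality <- function(features) {
  m <- intensity_matrix(features)
  res <- purrr::map_dfr(seq_len(nrow(m)), function(i) {
    x <- m[i, ]
    x <- x[!is.na(x)]
    if (length(unique(x)) < 2) {
      return(tibble::tibble(statistic = NA_real_, p = NA_real_))
    }
    kt <- suppressWarnings(stats::ks.test(x, "pnorm"))
    tibble::tibble(statistic = unname(kt$statistic), p = kt$p.value)
  })
  dplyr::mutate(res, feature_id = features$feature_id, .before = 1)
}
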