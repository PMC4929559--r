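#' Feature matrices and sample metadata
#'
#' A feature matrix is an ordinary (wide) tibble: one row per LC/MS feature
#' with the descriptor columns `feature_id`, `mz` (Th), `rt` (minutes) and
#' `mode` (`"neg"` or `"pos"`), followed by one intensity column per sample.
#' Missing intensities (`NA`) mean the peak picker did not detect the feature
#' in that sample. Sample metadata is a second tibble with columns
#' `sample_id`, `accession`, `replicate`, `batch` and `is_blank`; every
#' intensity column of the feature tibble must appear exactly once in
#' `sample_id`.
#'
#' All preprocessing functions take the feature tibble as their first
#' argument and return a tibble of the same shape, so steps chain with the
#' pipe.
#'
#' @param features A wide feature tibble as described above.
#' @param samples A sample metadata tibble.
#' @return `feature_meta_cols()` returns the names of the descriptor columns
#'   present in `features`; `sample_cols()` the names of the intensity
#'   columns; `intensity_matrix()` a numeric matrix (features x samples) with
#'   `feature_id` rownames.
#' @name feature_matrix
NULL

.meta_col_universe <- c("feature_id", "mz", "rt", "mode")

#' @rdname feature_matrix
#' @export
feature_meta_cols <- function(features) {
  intersect(.meta_col_universe, names(features))
}

#' @rdname feature_matrix
#' @export
sample_cols <- function(features) {
  setdiff(names(features), .meta_col_universe)
}

#' @rdname feature_matrix
#' @export
intensity_matrix <- function(features) {
  sc <- sample_cols(features)
  m <- as.matrix(features[, sc, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- features$feature_id
  m
}

# Rebuild a wide feature tibble from a features x samples matrix, keeping
# the descriptor columns of `template` (row order must match).
set_intensities <- function(template, m) {
  stopifnot(nrow(template) == nrow(m))
  out <- template
  out[, colnames(m)] <- tibble::as_tibble(m)
  out
}

#' Validate a feature matrix / sample metadata pair
#'
#' Checks the structural invariants: descriptor columns present, positive
#' m/z, nonnegative retention times, a single ionisation mode, nonnegative
#' intensities, and a one-to-one correspondence between intensity columns
#' and metadata rows. Ion modes are processed separately throughout, hence
#' the single-mode requirement.
#'
#' @inheritParams feature_matrix
#' @param transformed If `TRUE`, skip the nonnegativity check (log/z-scaled
#'   matrices legitimately hold negative values).
#' @return `features`, invisibly. Errors on violation.
#' @export
validate_feature_matrix <- function(features, samples = NULL,
                                    transformed = FALSE) {
  need <- c("feature_id", "mz", "rt", "mode")
  miss <- setdiff(need, names(features))
  if (length(miss) > 0) {
    stop("feature matrix lacks column(s): ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(features$feature_id)) stop("duplicated feature_id")
  if (any(features$mz <= 0)) stop("m/z must be positive")
  if (any(features$rt < 0)) stop("retention time must be nonnegative")
  if (length(unique(features$mode)) > 1) {
    stop("feature matrix mixes ionisation modes; process each mode separately")
  }
  m <- intensity_matrix(features)
  if (ncol(m) == 0) stop("feature matrix has no sample columns")
  if (!transformed && any(m < 0, na.rm = TRUE)) {
    stop("intensities must be nonnegative")
  }
  if (!is.null(samples)) {
    need_s <- c("sample_id", "accession", "replicate", "batch", "is_blank")
    miss_s <- setdiff(need_s, names(samples))
    if (length(miss_s) > 0) {
      stop("sample metadata lacks column(s): ", paste(miss_s, collapse = ", "))
    }
    sc <- sample_cols(features)
    if (!setequal(sc, samples$sample_id) || anyDuplicated(samples$sample_id)) {
      stop("sample metadata must cover every intensity column exactly once")
    }
  }
  invisible(features)
}

#' Read and write feature matrix / sample metadata TSV files
#'
#' The on-disk dialect is a plain TSV: `feature_id`, `mz`, `rt`, `mode`,
#' then one column per sample; sample metadata is a TSV with columns
#' `sample_id`, `accession`, `replicate`, `batch`, `is_blank`.
#'
#' @inheritParams feature_matrix
#' @param path File path.
#' @return The tibble read, or the input invisibly for writers.
#' @export
read_feature_matrix <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname read_feature_matrix
#' @export
write_feature_matrix <- function(features, path) {
  readr::write_tsv(features, path)
  invisible(features)
}

#' @rdname read_feature_matrix
#' @export
read_sample_metadata <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(is_blank = readr::col_logical()))
}

#' @rdname read_feature_matrix
#' @export
write_sample_metadata <- function(samples, path) {
  readr::write_tsv(samples, path)
  invisible(samples)
}
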