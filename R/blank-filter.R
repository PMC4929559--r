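#' Blank filtering of metabolic features
#'
#' Separates genuine exudate features from experimental background by
#' comparing accessions against the culture-medium blank on the transformed
#' (and typically batch-corrected) matrix. A feature is retained when
#'
#' 1. the omnibus Welch heteroscedastic one-way test across all groups
#'    (accessions plus blank), Benjamini–Hochberg adjusted across features,
#'    gives `p_adj < alpha`, and
#' 2. the post-hoc two-sample Welch test against the blank is significant
#'    (unadjusted `p < alpha`) in at least one accession.
#'
#' @inheritParams feature_matrix
#' @param alpha Significance level for both stages (default 0.05).
#' @return A tibble with one row per feature: `feature_id`, `mz`, `rt`,
#'   `p`, `p_adj` (omnibus), `posthoc_min_p`, and the logical `retained`.
#'   Groups left exactly constant by half-minimum imputation have their
#'   zero variance floored at the feature's smallest positive group
#'   variance so the tests stay defined.
#' @export
blank_filter <- function(features, samples, alpha = 0.05) {
  validate_feature_matrix(features, samples, transformed = TRUE)
  if (!any(samples$is_blank)) stop("blank filtering requires blank samples")
  m <- intensity_matrix(features)
  meta <- samples[match(colnames(m), samples$sample_id), ]
  grp <- ifelse(meta$is_blank, "BLANK", meta$accession)
  blank_idx <- which(meta$is_blank)
  acc_levels <- unique(meta$accession[!meta$is_blank])

  p_omnibus <- vapply(seq_len(nrow(m)), function(i) {
    welch_anova_p(m[i, ], grp)
  }, numeric(1))
  p_adj <- bh_adjust(p_omnibus)

  posthoc_min_p <- vapply(seq_len(nrow(m)), function(i) {
    blank_vals <- m[i, blank_idx]
    ps <- vapply(acc_levels, function(a) {
      welch_t_p(m[i, grp == a], blank_vals)
    }, numeric(1))
    min(ps)
  }, numeric(1))

  tibble::tibble(
    feature_id = features$feature_id,
    mz = features$mz,
    rt = features$rt,
    p = p_omnibus,
    p_adj = p_adj,
    posthoc_min_p = posthoc_min_p,
    retained = p_adj < alpha & posthoc_min_p < alpha
  )
}
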