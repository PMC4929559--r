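#' Run the full absence-pattern / stop-codon matching pipeline
#'
#' Chains the whole workflow on a dataset (either a `rhizolink_sim` object
#' or a list with the same components read from disk):
#'
#' 1. retain the raw detection matrix for absence calls;
#' 2. half-minimum imputation, log transform, per-feature z-scaling;
#' 3. surrogate-variable batch correction;
#' 4. blank filtering (omnibus Welch + BH, post-hoc Welch vs blank);
#' 5. absence patterns on the pre-imputation matrix of retained features;
#' 6. isotope annotation and the monoisotopic + median-intensity filters;
#' 7. variant handling: CDS restriction, mismatch distance matrix,
#'    premature-stop calling, enzyme stop patterns;
#' 8. exact matching of absence patterns against stop patterns;
#' 9. UPGMA clustering of the corrected exudate samples (and of the genetic
#'    distances), cut at a correlation threshold.
#'
#' @param dataset List with `features`, `samples`, `variants`,
#'   `gene_models`, `genome`, `enzyme_gene_ids`.
#' @param alpha Significance level for the blank filter (default 0.05).
#' @param n_sv Surrogate variables: `"auto"` or an integer.
#' @param min_median Median-intensity threshold for candidates (default
#'   10000).
#' @param policy Monoisotopic policy (`"strict"` default).
#' @param threshold Correlation threshold for the dendrogram cut (default
#'   0.95).
#' @param lod Optional explicit limit of detection for absence calls.
#' @param au If `TRUE`, compute multiscale-bootstrap AU support for the
#'   metabolic dendrogram.
#' @param au_B,au_scales,au_seed Bootstrap parameters for the AU step.
#' @return An object of class `rhizolink_result`: a list with `blank`
#'   (blank-filter table), `corrected` (corrected transformed matrix),
#'   `patterns`, `annotations`, `candidates` (filtered patterns), `status`
#'   (premature-stop calls), `stop_patterns`, `match`
#'   (`rhizolink_match`), `metabolic_tree`, `metabolic_clusters`,
#'   `genetic_tree`, `genetic_dist`, `au` (optional), and `funnel` (a
#'   one-row tibble of stage counts).
#' @export
run_pipeline <- function(dataset, alpha = 0.05, n_sv = "auto",
                         min_median = 10000, policy = "strict",
                         threshold = 0.95, lod = NULL, au = FALSE,
                         au_B = 100, au_scales = seq(0.5, 1.4, by = 0.1),
                         au_seed = 1) {
  features <- dataset$features
  samples <- dataset$samples
  validate_feature_matrix(features, samples)
  accessions <- unique(samples$accession[!samples$is_blank])

  # (2-3) impute -> log/z -> SVA
  transformed <- features |>
    impute_half_min() |>
    log_z_transform()
  corrected <- sva_correct(transformed, samples, n_sv = n_sv)

  # (4) blank filter on the corrected matrix
  blank <- blank_filter(corrected, samples, alpha = alpha)
  retained_ids <- blank$feature_id[blank$retained]
  detect <- features[features$feature_id %in% retained_ids, , drop = FALSE]

  # (5-6) absence patterns on the pre-imputation detection matrix
  patterns <- absence_patterns(detect, samples, lod = lod)
  annotations <- detect_isotopes(detect)
  candidates <- filter_candidates(patterns, annotations,
                                  min_median = min_median, policy = policy)

  # (7) genetics
  status <- protein_status(dataset$gene_models, dataset$variants,
                           dataset$genome, accessions)
  stop_patterns <- enzyme_stop_patterns(status, dataset$enzyme_gene_ids,
                                        accessions)
  cds_variants <- restrict_to_cds(dataset$variants, dataset$gene_models)
  gdist <- mismatch_distance(dataset$variants, accessions)
  gdist_cds <- mismatch_distance(cds_variants, accessions)

  # (8) pattern matching
  match <- match_patterns(candidates, stop_patterns)

  # (9) clustering
  exu_cols <- c(feature_meta_cols(corrected),
                samples$sample_id[!samples$is_blank])
  corr_exu <- corrected[corrected$feature_id %in% retained_ids,
                        exu_cols, drop = FALSE]
  metabolic_tree <- upgma(correlation_distance(corr_exu))
  metabolic_clusters <- cut_at_correlation(metabolic_tree, threshold)
  genetic_tree <- upgma(gdist_cds)
  au_support <- if (au) {
    multiscale_bootstrap_au(corr_exu, scales = au_scales, B = au_B,
                            seed = au_seed)
  } else NULL

  tally <- table(factor(pmin(match$candidates$pattern_length, 3), levels = 1:3))
  funnel <- tibble::tibble(
    n_features = nrow(features),
    n_blank_retained = length(retained_ids),
    n_absent_ge1 = sum(patterns$pattern_length >= 1),
    n_absent_len1 = sum(patterns$pattern_length == 1),
    n_absent_len2 = sum(patterns$pattern_length == 2),
    n_monoisotopic = sum(patterns$feature_id %in%
                           monoisotopic_filter(annotations, policy)$feature_id &
                           patterns$pattern_length >= 1),
    n_intensity_pass = nrow(candidates),
    n_matched = nrow(match$candidates),
    n_matched_len1 = as.integer(tally[1]),
    n_matched_len2 = as.integer(tally[2]),
    n_matched_len3 = as.integer(tally[3]),
    n_variant_loci = attr(gdist, "n_loci"),
    n_cds_variant_loci = attr(gdist_cds, "n_loci"),
    n_stop_genes = nrow(stop_patterns),
    n_metabolic_clusters = length(unique(metabolic_clusters$cluster))
  )
  structure(
    list(blank = blank, corrected = corrected, patterns = patterns,
         annotations = annotations, candidates = candidates,
         status = status, stop_patterns = stop_patterns, match = match,
         metabolic_tree = metabolic_tree,
         metabolic_clusters = metabolic_clusters,
         genetic_tree = genetic_tree, genetic_dist = gdist_cds,
         au = au_support, funnel = funnel),
    class = "rhizolink_result"
  )
}

#' @export
print.rhizolink_result <- function(x, ...) {
  f <- x$funnel
  cat("Absence-pattern / stop-codon matching pipeline\n")
  cat(sprintf("  features:            %d\n", f$n_features))
  cat(sprintf("  blank-differential:  %d\n", f$n_blank_retained))
  cat(sprintf("  absent in >=1 acc.:  %d (len 1: %d, len 2: %d)\n",
              f$n_absent_ge1, f$n_absent_len1, f$n_absent_len2))
  cat(sprintf("  monoisotopic:        %d\n", f$n_monoisotopic))
  cat(sprintf("  intensity-passing:   %d\n", f$n_intensity_pass))
  cat(sprintf("  matched to genes:    %d (len 1/2/3: %d/%d/%d)\n",
              f$n_matched, f$n_matched_len1, f$n_matched_len2, f$n_matched_len3))
  cat(sprintf("  variant loci:        %d (%d in CDS), stop-pattern genes: %d\n",
              f$n_variant_loci, f$n_cds_variant_loci, f$n_stop_genes))
  cat(sprintf("  metabolic clusters at cut: %d\n", f$n_metabolic_clusters))
  invisible(x)
}
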