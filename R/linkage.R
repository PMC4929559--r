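#' Per-feature absence patterns across accessions
#'
#' A feature is absent in an accession when it is below the limit of
#' detection in all replicates of that accession — operationally, when every
#' replicate value in the pre-imputation detection matrix is missing (or
#' below an explicit `lod` when one is given). Blank samples are excluded.
#' The pattern length is the number of absent accessions.
#'
#' @inheritParams feature_matrix
#' @param lod Optional numeric limit of detection; values strictly below it
#'   also count as undetected.
#' @return A tibble `feature_id`, `mz`, `rt`, `absent` (list of named
#'   logical vectors over accessions), `pattern_key` (comma-joined absent
#'   accessions in canonical order), `pattern_length`, `median_intensity`
#'   (median of detected values).
#' @export
absence_patterns <- function(features, samples, lod = NULL) {
  validate_feature_matrix(features, samples)
  m <- intensity_matrix(features)
  meta <- samples[match(colnames(m), samples$sample_id), ]
  keep <- !meta$is_blank
  m <- m[, keep, drop = FALSE]
  acc <- meta$accession[keep]
  accessions <- unique(acc)
  if (any(table(acc) == 0)) stop("accession with zero replicates")
  detected <- !is.na(m)
  if (!is.null(lod)) detected <- detected & (m >= lod)
  absent_mat <- vapply(accessions, function(a) {
    rowSums(detected[, acc == a, drop = FALSE]) == 0
  }, logical(nrow(m)))
  if (is.null(dim(absent_mat))) {
    absent_mat <- matrix(absent_mat, nrow = nrow(m),
                         dimnames = list(NULL, accessions))
  }
  rownames(absent_mat) <- NULL
  med <- vapply(seq_len(nrow(m)), function(i) {
    x <- m[i, detected[i, ]]
    if (length(x) == 0) NA_real_ else stats::median(x)
  }, numeric(1))
  tibble::tibble(
    feature_id = features$feature_id,
    mz = features$mz,
    rt = features$rt,
    absent = lapply(seq_len(nrow(m)), function(i) absent_mat[i, ]),
    pattern_key = unname(apply(absent_mat, 1, function(x) {
      paste(accessions[x], collapse = ",")
    })),
    pattern_length = unname(rowSums(absent_mat)),
    median_intensity = med
  )
}

#' Filter absence patterns to matching candidates
#'
#' Applies the candidate filters: pattern length within
#' `[min_len, max_len]`, a monoisotopic annotation, and a minimal median
#' intensity over detected values.
#'
#' @param patterns Output of [absence_patterns()].
#' @param annotations Output of [detect_isotopes()].
#' @param min_median Minimal median intensity (default 10000).
#' @param min_len Minimal pattern length (default 1).
#' @param max_len Maximal pattern length (default `Inf`).
#' @param policy Monoisotopic policy, see [monoisotopic_filter()].
#' @return The filtered pattern tibble with a `monoisotopic` column.
#' @export
filter_candidates <- function(patterns, annotations, min_median = 10000,
                              min_len = 1, max_len = Inf,
                              policy = c("strict", "permissive")) {
  policy <- match.arg(policy)
  mono_ids <- monoisotopic_filter(annotations, policy)$feature_id
  out <- patterns |>
    dplyr::mutate(monoisotopic = .data$feature_id %in% mono_ids) |>
    dplyr::filter(
      .data$pattern_length >= min_len,
      .data$pattern_length <= max_len,
      .data$monoisotopic,
      !is.na(.data$median_intensity),
      .data$median_intensity >= min_median
    )
  out
}

#' Match absence patterns against stop-codon patterns
#'
#' A feature matches a gene iff their boolean accession patterns are
#' identical (exact set equality of affected accessions). Every matching
#' gene is listed per feature; features matching no gene are reported as
#' unmatched.
#'
#' @param feature_patterns Filtered pattern tibble ([filter_candidates()]).
#' @param stop_patterns Stop-pattern tibble ([enzyme_stop_patterns()]).
#' @return A list with `candidates` (tibble: `feature_id`, `mz`, `rt`,
#'   `pattern_key`, `pattern_length`, `median_intensity`, `genes` list
#'   column, `n_genes`) and `unmatched` (the features with no matching
#'   gene).
#' @export
match_patterns <- function(feature_patterns, stop_patterns) {
  if (nrow(stop_patterns) > 0) {
    acc_g <- names(stop_patterns$pattern[[1]])
    acc_f <- if (nrow(feature_patterns) > 0) {
      names(feature_patterns$absent[[1]])
    } else {
      acc_g
    }
    if (!setequal(acc_f, acc_g)) {
      stop("accession universes of features and genes differ")
    }
    # rebuild keys on the gene side in the feature-side canonical order so
    # string equality is exact set equality
    gene_keys <- vapply(stop_patterns$pattern, function(p) {
      paste(acc_f[p[acc_f]], collapse = ",")
    }, character(1))
    gene_lists <- split(stop_patterns$gene_id, gene_keys)
  } else {
    gene_lists <- list()
  }
  hit <- feature_patterns$pattern_key %in% names(gene_lists) &
    feature_patterns$pattern_length > 0
  candidates <- feature_patterns[hit, , drop = FALSE]
  genes <- unname(gene_lists[candidates$pattern_key])
  out <- candidates |>
    dplyr::select(feature_id, mz, rt, pattern_key, pattern_length,
                  median_intensity) |>
    dplyr::mutate(genes = if (nrow(candidates)) genes else list(),
                  n_genes = vapply(.data$genes, base::length, integer(1))) |>
    dplyr::arrange(.data$pattern_length, .data$mz)
  unmatched <- feature_patterns[!hit, , drop = FALSE] |>
    dplyr::select(feature_id, mz, rt, pattern_key, pattern_length,
                  median_intensity) |>
    dplyr::arrange(.data$pattern_length, .data$mz)
  structure(list(candidates = out, unmatched = unmatched),
            class = "rhizolink_match")
}

#' @export
print.rhizolink_match <- function(x, ...) {
  tally <- table(factor(x$candidates$pattern_length, levels = 1:3))
  cat("Gene-metabolite pattern matches\n")
  cat("  candidate features:", nrow(x$candidates),
      sprintf("(length 1/2/3: %s)", paste(tally, collapse = "/")), "\n")
  cat("  unmatched absence features:", nrow(x$unmatched), "\n")
  invisible(x)
}

#' Write and re-read the candidate report
#'
#' Emits a TSV (one row per feature; gene lists and mechanisms
#' comma-joined) plus a JSON report with a summary block tallying candidate
#' features per pattern length. Rows are ordered by pattern length then
#' m/z, so reports are deterministic.
#'
#' @param match A `rhizolink_match` object from [match_patterns()].
#' @param dir Output directory (created if needed).
#' @param status Optional [protein_status()] tibble used to attach
#'   truncation mechanisms to candidate genes.
#' @return The paths written, invisibly.
#' @export
write_report <- function(match, dir, status = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cand <- match$candidates
  mech <- function(gene, key) {
    if (is.null(status)) return(NA_character_)
    accs <- strsplit(key, ",", fixed = TRUE)[[1]]
    st <- status[status$gene_id == gene & status$accession %in% accs, ]
    paste(unique(st$mechanism[st$premature]), collapse = "|")
  }
  flat <- cand |>
    dplyr::mutate(
      genes_joined = vapply(.data$genes, paste, character(1), collapse = ","),
      mechanisms = purrr::map2_chr(.data$genes, .data$pattern_key, function(g, k) {
        paste(vapply(g, mech, character(1), key = k), collapse = ",")
      })
    ) |>
    dplyr::select(feature_id, mz, rt, pattern_key, pattern_length,
                  genes = "genes_joined", mechanisms, median_intensity)
  tsv <- file.path(dir, "candidates.tsv")
  readr::write_tsv(flat, tsv)
  readr::write_tsv(match$unmatched, file.path(dir, "unmatched.tsv"))
  summary <- list(
    n_candidates = nrow(cand),
    n_unmatched = nrow(match$unmatched),
    by_pattern_length = as.list(table(cand$pattern_length))
  )
  json <- file.path(dir, "report.json")
  jsonlite::write_json(
    list(summary = summary, candidates = flat, unmatched = match$unmatched),
    json, auto_unbox = TRUE, digits = NA
  )
  invisible(c(tsv = tsv, json = json))
}

#' @rdname write_report
#' @export
read_report <- function(dir) {
  flat <- readr::read_tsv(file.path(dir, "candidates.tsv"),
                          show_col_types = FALSE,
                          col_types = readr::cols(
                            pattern_key = readr::col_character(),
                            genes = readr::col_character(),
                            mechanisms = readr::col_character()
                          ))
  unmatched <- readr::read_tsv(file.path(dir, "unmatched.tsv"),
                               show_col_types = FALSE,
                               col_types = readr::cols(
                                 pattern_key = readr::col_character()
                               ))
  genes_chr <- as.character(flat$genes)
  genes_chr[is.na(genes_chr)] <- ""
  candidates <- flat |>
    dplyr::mutate(genes = strsplit(genes_chr, ",", fixed = TRUE),
                  n_genes = vapply(.data$genes, base::length, integer(1))) |>
    dplyr::select(feature_id, mz, rt, pattern_key, pattern_length,
                  median_intensity, genes, n_genes)
  structure(list(candidates = candidates, unmatched = unmatched),
            class = "rhizolink_match")
}
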