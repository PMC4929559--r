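# Independent oracles used across the suite. These deliberately take a
# different route than the package code they check.

# Naive O(m^2) Benjamini-Hochberg step-up: p_adj(i) is the smallest
# min(1, m * p(j) / rank(j)) over all j with p(j) >= p(i).
naive_bh <- function(p) {
  m <- length(p)
  r <- rank(p, ties.method = "first")
  vapply(seq_len(m), function(i) {
    js <- which(p >= p[i])
    min(1, min(m * p[js] / r[js]))
  }, numeric(1))
}

# Textbook two-sample Welch t-test, written out from first principles.
naive_welch_t <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(abs(t), df, lower.tail = FALSE))
}

# Brute-force per-locus mismatch distance: for every locus compare every
# accession pair, counting +1 per allele mismatch.
naive_mismatch <- function(variants, accessions) {
  loci <- unique(variants[, c("chrom", "pos", "ref")])
  k <- length(accessions)
  d <- matrix(0, k, k, dimnames = list(accessions, accessions))
  for (l in seq_len(nrow(loci))) {
    vl <- variants[variants$chrom == loci$chrom[l] &
                     variants$pos == loci$pos[l] &
                     variants$ref == loci$ref[l], ]
    allele <- setNames(rep("REF", k), accessions)
    allele[vl$accession] <- vl$alt
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        if (allele[i] != allele[j]) {
          d[i, j] <- d[i, j] + 1
          d[j, i] <- d[i, j]
        }
      }
    }
  }
  d
}

# Frame-1 translation through Biostrings' C implementation (independent of
# the package's codon-table lookup).
oracle_translate <- function(s) {
  n <- (nchar(s) %/% 3) * 3
  as.character(Biostrings::translate(Biostrings::DNAString(substr(s, 1, n))))
}

# One small synthetic dataset shared across test files (generation is
# deterministic, so building it once is purely a speed matter).
small_config <- function(...) {
  defaults <- list(n_genes = 40, n_enzyme_genes = 15, n_features = 80,
                   n_planted_links = 3, seed = 7)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

.fixture_env <- new.env(parent = emptyenv())

small_dataset <- function() {
  if (is.null(.fixture_env$ds)) .fixture_env$ds <- simulate_dataset(small_config())
  .fixture_env$ds
}

small_status <- function() {
  if (is.null(.fixture_env$st)) {
    ds <- small_dataset()
    accs <- unique(ds$samples$accession[!ds$samples$is_blank])
    .fixture_env$st <- protein_status(ds$gene_models, ds$variants,
                                      ds$genome, accs)
  }
  .fixture_env$st
}

non_blank_accessions <- function(ds) {
  unique(ds$samples$accession[!ds$samples$is_blank])
}

# A feature tibble with explicit intensities; sample columns S1..Sn.
make_features <- function(m, mz = NULL, rt = NULL) {
  n <- nrow(m)
  colnames(m) <- if (is.null(colnames(m))) sprintf("S%d", seq_len(ncol(m))) else colnames(m)
  dplyr::bind_cols(
    tibble::tibble(
      feature_id = sprintf("F%03d", seq_len(n)),
      mz = if (is.null(mz)) seq(100, by = 10, length.out = n) else mz,
      rt = if (is.null(rt)) seq(1, by = 0.5, length.out = n) else rt,
      mode = "neg"
    ),
    tibble::as_tibble(m)
  )
}
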