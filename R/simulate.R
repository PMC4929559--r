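#' Configuration for the synthetic exudate/genome generator
#'
#' Defines the study conditions the generator emulates: a panel of
#' accessions grown in replicated batches with culture-medium blanks, an
#' LC/MS feature matrix with log-normal intensities censored below a
#' detection limit, batch effects on the log scale, isotope companion
#' features, and per-accession CDS variants including planted nonsense SNPs
#' (and one frameshift deletion) whose carriers lack the linked features.
#'
#' @param n_accessions Number of accessions (default 19; the MAGIC founder
#'   names are used at 19, `ACC01`... otherwise).
#' @param n_replicates Biological replicates per accession (default 3, one
#'   per batch/experiment).
#' @param n_blanks Number of culture-medium blank samples (default 3).
#' @param n_genes Number of genes (default 200).
#' @param n_enzyme_genes Genes flagged as metabolic enzymes (default 60).
#' @param n_features Number of base LC/MS features before isotope
#'   companions (default 450).
#' @param n_planted_links Planted gene-to-metabolite links (default 5; one
#'   of them uses a frameshift deletion).
#' @param cds_length_codons Range of CDS lengths in codons (default
#'   `c(60, 120)`, including the stop codon).
#' @param lod Limit of detection; intensities below it are censored to
#'   missing (default 500).
#' @param mu_log,sigma_log Mean and replicate-level s.d. of log intensities
#'   (defaults 11 and 0.35, i.e. typical intensities around 6e4).
#' @param batch_effect_sd S.d. of the per-batch additive shift on the log
#'   scale (default 0.3).
#' @param batch_shifts Optional explicit per-batch log-scale shifts
#'   (overrides random draws).
#' @param isotope_fraction Fraction of non-planted features given an M+1
#'   companion (default 0.15; planted features always get one so they carry
#'   a monoisotopic annotation).
#' @param background_variant_rate Mean number of background
#'   (synonymous/missense, never nonsense) variants per gene (default 2).
#' @param blank_feature_fraction Fraction of features that are medium
#'   background, present in blanks (default 0.15).
#' @param decoy_fraction Fraction of non-planted exudate features given a
#'   decoy absence pattern (default 0.25).
#' @param decoy_collide If `TRUE`, two decoys reuse planted absence
#'   patterns so that pattern collisions (multi-gene matches) occur.
#' @param seed Integer seed; identical configurations give identical
#'   datasets.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_accessions = 19, n_replicates = 3, n_blanks = 3,
                       n_genes = 200, n_enzyme_genes = 60, n_features = 450,
                       n_planted_links = 5, cds_length_codons = c(60, 120),
                       lod = 500, mu_log = 11, sigma_log = 0.35,
                       batch_effect_sd = 0.3, batch_shifts = NULL,
                       isotope_fraction = 0.15, background_variant_rate = 2,
                       blank_feature_fraction = 0.15, decoy_fraction = 0.25,
                       decoy_collide = FALSE, seed = 1) {
  cfg <- as.list(environment())
  counts <- c(n_accessions = n_accessions, n_replicates = n_replicates,
              n_blanks = n_blanks, n_genes = n_genes,
              n_enzyme_genes = n_enzyme_genes, n_features = n_features,
              n_planted_links = n_planted_links)
  if (any(counts < 1)) stop("all counts must be >= 1")
  if (n_planted_links > min(n_enzyme_genes, n_features)) {
    stop("n_planted_links must not exceed min(n_enzyme_genes, n_features)")
  }
  if (n_enzyme_genes > n_genes) stop("n_enzyme_genes must not exceed n_genes")
  if (lod <= 0) stop("lod must be positive")
  if (min(cds_length_codons) < 10) stop("cds_length_codons must be >= 10")
  structure(cfg, class = "sim_config")
}

#' The 19 MAGIC founder accessions
#' @return Character vector of accession names.
#' @export
magic_accessions <- function() {
  c("Bur-0", "Can-0", "Col-0", "Ct-1", "Edi-0", "Hi-0", "Kn-0", "Ler-0",
    "Mt-0", "No-0", "Oy-0", "Po-0", "Rsch-4", "Sf-2", "Tsu-0", "Wil-2",
    "Ws-0", "Wu-0", "Zu-0")
}

accession_names <- function(n) {
  if (n == 19) magic_accessions() else sprintf("ACC%02d", seq_len(n))
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

all_codons <- function() {
  b <- c("A", "C", "G", "T")
  as.vector(outer(outer(b, b, paste0), b, paste0))
}

#' Generate synthetic gene models and a reference genome
#'
#' Each gene has a CDS starting with ATG, ending with a single stop codon
#' and free of internal in-frame stops; about 40% of genes carry two CDS
#' segments separated by an intron. Genes are laid out with random
#' intergenic spacers on two chromosomes, on either strand.
#'
#' @param config A [sim_config()].
#' @return A list with `gene_models` (tibble as in [build_gene_models()])
#'   and `genome` (named list of chromosome sequences).
#' @export
generate_gene_models <- function(config) {
  set.seed(config$seed)
  sense <- setdiff(all_codons(), STOP_CODONS)
  n <- config$n_genes
  chrom_seqs <- list(chr1 = character(0), chr2 = character(0))
  cursor <- c(chr1 = 0L, chr2 = 0L)
  rows <- vector("list", n)
  rand_dna <- function(len) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }
  len_range <- seq(config$cds_length_codons[1], config$cds_length_codons[2])
  for (g in seq_len(n)) {
    n_codons <- len_range[sample.int(length(len_range), 1)]
    cds <- paste0("ATG",
                  paste(sample(sense, n_codons - 2, replace = TRUE), collapse = ""),
                  sample(STOP_CODONS, 1))
    strand <- sample(c("+", "-"), 1)
    genomic <- if (strand == "-") revcomp(cds) else cds
    chrom <- if (g %% 2 == 1) "chr1" else "chr2"
    spacer <- sample(80:150, 1)
    two_exon <- stats::runif(1) < 0.4
    L <- nchar(genomic)
    start1 <- cursor[[chrom]] + spacer + 1L
    if (two_exon) {
      cut <- sample(10:(L - 10), 1)
      intron_len <- 60L
      seg <- tibble::tibble(
        start = c(start1, start1 + cut + intron_len),
        end = c(start1 + cut - 1L, start1 + L + intron_len - 1L)
      )
      piece <- paste0(rand_dna(spacer), substr(genomic, 1, cut),
                      rand_dna(intron_len), substr(genomic, cut + 1, L))
    } else {
      seg <- tibble::tibble(start = start1, end = start1 + L - 1L)
      piece <- paste0(rand_dna(spacer), genomic)
    }
    chrom_seqs[[chrom]] <- c(chrom_seqs[[chrom]], piece)
    cursor[[chrom]] <- cursor[[chrom]] + nchar(piece)
    rows[[g]] <- tibble::tibble(
      gene_id = sprintf("GENE%04d", g), chrom = chrom, strand = strand,
      segments = list(seg), cds = cds,
      protein = sub("\\*$", "", translate_dna(cds))
    )
  }
  genome <- lapply(chrom_seqs, paste, collapse = "")
  models <- dplyr::bind_rows(rows)
  list(gene_models = models, genome = genome)
}

# map a CDS coordinate (1-based, in translation orientation) to its genomic
# position; returns list(pos, base) where base is the genomic-strand
# reference base at that position
cds_to_genomic <- function(gene, cds_pos) {
  segs <- dplyr::arrange(gene$segments[[1]], start)
  lens <- segs$end - segs$start + 1L
  L <- sum(lens)
  gpos_in_concat <- if (gene$strand == "+") cds_pos else L - cds_pos + 1L
  cum <- cumsum(lens)
  si <- which(gpos_in_concat <= cum)[1]
  offset <- gpos_in_concat - (if (si == 1) 0L else cum[si - 1])
  segs$start[si] + offset - 1L
}

#' Generate variants and the planted truth records
#'
#' For each planted link, every affected accession receives an edit
#' truncating the gene's predicted protein: a nonsense SNP converting a
#' sense codon to TAA/TAG/TGA, except for one link per dataset which uses a
#' 2-bp frameshift deletion (verified at generation time to yield a
#' premature stop). Background variants are synonymous (or stop-free
#' missense for Met/Trp codons) and never create premature stops.
#'
#' @param config A [sim_config()].
#' @param gene_models,genome Output of [generate_gene_models()].
#' @return A list with `variants` (tibble), `truth` (tibble: `gene_id`,
#'   `feature_id` placeholder, `affected` list, `mechanism`,
#'   `stop_codon_index`) and `enzyme_gene_ids`.
#' @export
generate_variants <- function(config, gene_models, genome) {
  set.seed(config$seed + 1L)
  accs <- accession_names(config$n_accessions)
  enzyme_gene_ids <- sort(sample(gene_models$gene_id, config$n_enzyme_genes))
  planted_genes <- sample(enzyme_gene_ids, config$n_planted_links)
  variants <- list()
  truth <- list()
  used_codons <- stats::setNames(vector("list", nrow(gene_models)),
                                 gene_models$gene_id)

  planted_keys <- character(0)
  for (li in seq_along(planted_genes)) {
    gid <- planted_genes[li]
    gene <- gene_models[gene_models$gene_id == gid, ]
    n_aa <- nchar(gene$protein)
    # distinct affected sets per link, so each planted pattern is
    # identifiable (decoy sampling follows the same rule)
    repeat {
      affected <- sort(sample(accs, sample(1:3, 1)))
      key <- paste(affected, collapse = ",")
      if (!key %in% planted_keys) break
    }
    planted_keys <- c(planted_keys, key)
    mechanism <- if (li == length(planted_genes)) "frameshift" else "nonsense_snp"
    if (mechanism == "nonsense_snp") {
      pick <- find_nonsense_site(gene$cds, lo = 5, hi = n_aa - 3)
      cds_pos <- (pick$codon - 1L) * 3L + pick$offset
      gpos <- cds_to_genomic(gene, cds_pos)
      ref_base <- substr(gene$cds, cds_pos, cds_pos)
      alt_base <- pick$alt
      if (gene$strand == "-") {
        ref_base <- revcomp(ref_base)
        alt_base <- revcomp(alt_base)
      }
      v <- tibble::tibble(accession = affected, chrom = gene$chrom,
                          pos = gpos, ref = ref_base, alt = alt_base)
      stop_idx <- pick$codon
      used_codons[[gid]] <- c(used_codons[[gid]], pick$codon)
    } else {
      # 2-bp frameshift deletion; retry positions until the shifted frame
      # hits a stop before the reference protein ends
      stop_idx <- NA_integer_
      for (try in seq_len(30)) {
        codon <- sample(5:(n_aa - 10), 1)
        cds_pos <- (codon - 1L) * 3L + 1L
        gpos <- if (gene$strand == "+") cds_to_genomic(gene, cds_pos)
                else cds_to_genomic(gene, cds_pos + 2L)
        chrom_seq <- genome[[gene$chrom]]
        ref <- substr(chrom_seq, gpos - 1L, gpos + 1L)  # anchor + 2 deleted
        alt <- substr(chrom_seq, gpos - 1L, gpos - 1L)
        v_try <- tibble::tibble(accession = affected, chrom = gene$chrom,
                                pos = gpos - 1L, ref = ref, alt = alt)
        cds_mut <- apply_variants(gene, v_try[1, ], genome)
        call <- call_premature_stop(cds_mut, gene$protein)
        if (call$premature) {
          v <- v_try
          stop_idx <- call$first_stop_codon_index
          used_codons[[gid]] <- c(used_codons[[gid]], codon - 1L, codon, codon + 1L)
          break
        }
      }
      if (is.na(stop_idx)) stop("could not plant a frameshift in ", gid)
    }
    variants[[length(variants) + 1]] <- v
    truth[[length(truth) + 1]] <- tibble::tibble(
      gene_id = gid, feature_id = NA_character_, affected = list(affected),
      mechanism = mechanism, stop_codon_index = stop_idx
    )
  }

  # background variants: synonymous or stop-free missense, random carriers
  for (gi in seq_len(nrow(gene_models))) {
    gene <- gene_models[gi, ]
    n_bg <- stats::rpois(1, config$background_variant_rate)
    if (n_bg == 0) next
    n_aa <- nchar(gene$protein)
    avail <- setdiff(2:(n_aa - 1), used_codons[[gene$gene_id]])
    n_bg <- min(n_bg, length(avail))
    codons <- avail[sample.int(length(avail), n_bg)]
    for (codon in codons) {
      sub <- benign_substitution(gene$cds, codon)
      if (is.null(sub)) next
      cds_pos <- (codon - 1L) * 3L + sub$offset
      gpos <- cds_to_genomic(gene, cds_pos)
      ref_base <- substr(gene$cds, cds_pos, cds_pos)
      alt_base <- sub$alt
      if (gene$strand == "-") {
        ref_base <- revcomp(ref_base)
        alt_base <- revcomp(alt_base)
      }
      carriers <- sort(sample(accs, sample(1:5, 1)))
      variants[[length(variants) + 1]] <- tibble::tibble(
        accession = carriers, chrom = gene$chrom, pos = gpos,
        ref = ref_base, alt = alt_base
      )
    }
  }

  list(
    variants = dplyr::arrange(dplyr::bind_rows(variants),
                              accession, chrom, pos),
    truth = dplyr::bind_rows(truth),
    enzyme_gene_ids = enzyme_gene_ids
  )
}

# find a single-base substitution turning an internal sense codon into a
# stop codon; searches codons in random order between lo and hi
find_nonsense_site <- function(cds, lo, hi) {
  bases <- c("A", "C", "G", "T")
  for (codon in sample(lo:hi)) {
    cstr <- substr(cds, (codon - 1) * 3 + 1, codon * 3)
    for (offset in sample(1:3)) {
      for (alt in sample(setdiff(bases, substr(cstr, offset, offset)))) {
        mut <- cstr
        substr(mut, offset, offset) <- alt
        if (mut %in% STOP_CODONS) {
          return(list(codon = codon, offset = offset, alt = alt))
        }
      }
    }
  }
  stop("no nonsense site available in CDS (degenerate short gene)")
}

# synonymous single-base substitution at the given codon, or a stop-free
# missense change when the amino acid has no synonymous neighbour
benign_substitution <- function(cds, codon) {
  bases <- c("A", "C", "G", "T")
  cstr <- substr(cds, (codon - 1) * 3 + 1, codon * 3)
  aa <- translate_dna(cstr)
  fallback <- NULL
  for (offset in 3:1) {
    for (alt in setdiff(bases, substr(cstr, offset, offset))) {
      mut <- cstr
      substr(mut, offset, offset) <- alt
      if (mut %in% STOP_CODONS) next
      if (translate_dna(mut) == aa) {
        return(list(offset = offset, alt = alt))
      }
      if (is.null(fallback)) fallback <- list(offset = offset, alt = alt)
    }
  }
  fallback
}

#' Generate the synthetic feature matrix
#'
#' Log-normal replicate intensities with per-batch shifts, censoring below
#' the detection limit, culture-medium background features present in
#' blanks, planted features missing in all replicates of their affected
#' accessions, decoy absence patterns, and M+1 isotope companions at
#' +1.00336 Th with a fixed intensity ratio.
#'
#' @param config A [sim_config()].
#' @param truth Truth tibble from [generate_variants()]; its `feature_id`
#'   column is filled in by this function.
#' @return A list with `features`, `samples`, `truth` (feature ids
#'   assigned), `feature_info` (per-feature class and planted pattern) and
#'   `batch_shifts`.
#' @export
generate_feature_matrix <- function(config, truth) {
  set.seed(config$seed + 2L)
  accs <- accession_names(config$n_accessions)
  n_batch <- config$n_replicates
  samples <- tibble::tibble(
    sample_id = c(
      sprintf("%s_r%d", rep(accs, each = config$n_replicates),
              rep(seq_len(config$n_replicates), times = length(accs))),
      sprintf("BLANK_r%d", seq_len(config$n_blanks))
    ),
    accession = c(rep(accs, each = config$n_replicates),
                  rep("BLANK", config$n_blanks)),
    replicate = c(rep(seq_len(config$n_replicates), times = length(accs)),
                  seq_len(config$n_blanks)),
    batch = c(rep(seq_len(config$n_replicates), times = length(accs)),
              ((seq_len(config$n_blanks) - 1L) %% n_batch) + 1L),
    is_blank = c(rep(FALSE, length(accs) * config$n_replicates),
                 rep(TRUE, config$n_blanks))
  )
  batch_shifts <- config$batch_shifts
  if (is.null(batch_shifts)) {
    batch_shifts <- stats::rnorm(n_batch, 0, config$batch_effect_sd)
  }

  nf <- config$n_features
  n_planted <- nrow(truth)
  classes <- rep("exudate", nf)
  classes[seq_len(n_planted)] <- "planted"
  n_bg <- round(config$blank_feature_fraction * nf)
  if (n_bg > 0 && n_planted + n_bg <= nf) {
    classes[(n_planted + 1):(n_planted + n_bg)] <- "background"
  }
  classes <- classes[sample.int(nf)]  # shuffle positions
  ids <- sprintf("F%04d", seq_len(nf))
  planted_idx <- which(classes == "planted")
  truth$feature_id <- ids[planted_idx]

  # absence pattern per feature: planted -> truth pattern; decoys -> random
  # subsets avoiding (by default) the planted patterns
  planted_keys <- vapply(truth$affected, paste, character(1), collapse = ",")
  absent <- vector("list", nf)
  exu_idx <- which(classes == "exudate")
  decoy_idx <- exu_idx[stats::runif(length(exu_idx)) < config$decoy_fraction]
  for (i in seq_len(nf)) absent[[i]] <- character(0)
  for (k in seq_along(planted_idx)) absent[[planted_idx[k]]] <- truth$affected[[k]]
  for (i in decoy_idx) {
    repeat {
      cand <- sort(sample(accs, sample(1:3, 1)))
      if (config$decoy_collide ||
          !(paste(cand, collapse = ",") %in% planted_keys)) break
    }
    absent[[i]] <- cand
  }
  if (config$decoy_collide && length(decoy_idx) >= 2) {
    absent[[decoy_idx[1]]] <- truth$affected[[1]]
    absent[[decoy_idx[2]]] <- truth$affected[[min(2, nrow(truth))]]
  }

  mz <- round(stats::runif(nf, 100, 1000), 4)
  rt <- round(stats::runif(nf, 0.5, 12), 3)
  mu_i <- stats::rnorm(nf, config$mu_log, 0.5)

  n_samp <- nrow(samples)
  m <- matrix(NA_real_, nf, n_samp, dimnames = list(ids, samples$sample_id))
  shift <- batch_shifts[samples$batch]
  for (i in seq_len(nf)) {
    vals <- exp(mu_i[i] + shift + stats::rnorm(n_samp, 0, config$sigma_log))
    if (classes[i] != "background") vals[samples$is_blank] <- NA
    if (length(absent[[i]]) > 0) {
      vals[samples$accession %in% absent[[i]]] <- NA
    }
    vals[!is.na(vals) & vals < config$lod] <- NA
    m[i, ] <- vals
  }
  # guarantee the absence-pattern operator recovers exactly the planted
  # pattern: every non-absent accession keeps at least one detected value
  for (i in seq_len(nf)) {
    for (a in setdiff(accs, absent[[i]])) {
      cols <- which(samples$accession == a)
      if (all(is.na(m[i, cols]))) m[i, cols[1]] <- exp(mu_i[i])
    }
  }

  # isotope companions: always for planted features, randomly otherwise
  has_iso <- stats::runif(nf) < config$isotope_fraction
  has_iso[planted_idx] <- TRUE
  iso_ratio <- stats::runif(nf, 0.15, 0.45)
  iso_rows <- which(has_iso)
  iso_m <- matrix(NA_real_, length(iso_rows), n_samp,
                  dimnames = list(paste0(ids[iso_rows], "_M1"), samples$sample_id))
  for (k in seq_along(iso_rows)) {
    i <- iso_rows[k]
    vals <- m[i, ] * iso_ratio[i] * exp(stats::rnorm(n_samp, 0, 0.05))
    vals[!is.na(vals) & vals < config$lod] <- NA
    iso_m[k, ] <- vals
  }

  features <- dplyr::bind_rows(
    tibble::tibble(feature_id = ids, mz = mz, rt = rt, mode = "neg"),
    tibble::tibble(feature_id = paste0(ids[iso_rows], "_M1"),
                   mz = round(mz[iso_rows] + ISOTOPE_DELTA, 4),
                   rt = rt[iso_rows], mode = "neg")
  )
  full <- rbind(m, iso_m)
  features <- dplyr::bind_cols(
    features,
    tibble::as_tibble(full[features$feature_id, , drop = FALSE])
  )

  feature_info <- tibble::tibble(
    feature_id = ids, class = classes,
    absent = absent,
    has_isotope_companion = has_iso,
    is_decoy = seq_len(nf) %in% decoy_idx
  )
  list(features = features, samples = samples, truth = truth,
       feature_info = feature_info, batch_shifts = batch_shifts)
}

#' Simulate a complete paired dataset
#'
#' Runs [generate_gene_models()], [generate_variants()] and
#' [generate_feature_matrix()] under one seed and bundles the results.
#'
#' @param config A [sim_config()].
#' @return An object of class `rhizolink_sim`: a list with `config`,
#'   `genome`, `gene_models`, `enzyme_gene_ids`, `variants`, `features`,
#'   `samples`, `truth`, `feature_info`, `batch_shifts`.
#' @examples
#' ds <- simulate_dataset(sim_config(n_genes = 20, n_features = 40,
#'                                   n_enzyme_genes = 10, n_planted_links = 2))
#' ds$truth
#' @export
simulate_dataset <- function(config = sim_config()) {
  gm <- generate_gene_models(config)
  gv <- generate_variants(config, gm$gene_models, gm$genome)
  fm <- generate_feature_matrix(config, gv$truth)
  structure(
    list(config = config, genome = gm$genome, gene_models = gm$gene_models,
         enzyme_gene_ids = gv$enzyme_gene_ids, variants = gv$variants,
         features = fm$features, samples = fm$samples, truth = fm$truth,
         feature_info = fm$feature_info, batch_shifts = fm$batch_shifts),
    class = "rhizolink_sim"
  )
}

#' @export
print.rhizolink_sim <- function(x, ...) {
  cat("Synthetic exudate/genome dataset\n")
  cat(sprintf("  %d accessions x %d replicates + %d blanks\n",
              x$config$n_accessions, x$config$n_replicates, x$config$n_blanks))
  cat(sprintf("  %d features (%d with isotope companions), %d genes (%d enzymes)\n",
              nrow(x$features), sum(grepl("_M1$", x$features$feature_id)),
              nrow(x$gene_models), length(x$enzyme_gene_ids)))
  cat(sprintf("  %d variant records, %d planted links\n",
              nrow(x$variants), nrow(x$truth)))
  invisible(x)
}

#' Write a synthetic dataset to plain-text files
#'
#' Emits `genome.fasta`, `genes.gff3`, `variants.tsv`, `variants.vcf`,
#' `features.tsv`, `samples.tsv`, `enzyme_genes.txt` and `truth.json` into
#' `dir`.
#'
#' @param dataset A `rhizolink_sim` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  genome <- Biostrings::DNAStringSet(unlist(dataset$genome))
  Biostrings::writeXStringSet(genome, file.path(dir, "genome.fasta"))
  write_gene_models_gff3(dataset$gene_models, file.path(dir, "genes.gff3"))
  write_variant_table(dataset$variants, file.path(dir, "variants.tsv"))
  write_vcf(dataset$variants, file.path(dir, "variants.vcf"),
            accessions = accession_names(dataset$config$n_accessions))
  write_feature_matrix(dataset$features, file.path(dir, "features.tsv"))
  write_sample_metadata(dataset$samples, file.path(dir, "samples.tsv"))
  writeLines(dataset$enzyme_gene_ids, file.path(dir, "enzyme_genes.txt"))
  truth <- dataset$truth
  jsonlite::write_json(
    lapply(seq_len(nrow(truth)), function(i) list(
      gene_id = truth$gene_id[i], feature_id = truth$feature_id[i],
      affected_accessions = truth$affected[[i]],
      mechanism = truth$mechanism[i],
      stop_codon_index = truth$stop_codon_index[i]
    )),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

write_gene_models_gff3 <- function(gene_models, path) {
  seg <- gene_models |>
    dplyr::select(gene_id, chrom, strand, segments) |>
    tidyr::unnest(segments)
  # GFF3 phase: bases to skip to reach a codon start, in translation order
  seg <- seg |>
    dplyr::group_by(gene_id) |>
    dplyr::arrange(start, .by_group = TRUE) |>
    dplyr::mutate(
      len = end - start + 1L,
      phase = {
        lens <- if (strand[1] == "-") rev(len) else len
        ph <- (3L - (cumsum(dplyr::lag(lens, default = 0L)) %% 3L)) %% 3L
        if (strand[1] == "-") rev(ph) else ph
      }
    ) |>
    dplyr::ungroup()
  gene_rng <- seg |>
    dplyr::group_by(gene_id, chrom, strand) |>
    dplyr::summarise(start = min(start), end = max(end), .groups = "drop")
  gr_gene <- GenomicRanges::GRanges(
    gene_rng$chrom, IRanges::IRanges(gene_rng$start, gene_rng$end),
    strand = gene_rng$strand, type = "gene", ID = gene_rng$gene_id
  )
  gr_cds <- GenomicRanges::GRanges(
    seg$chrom, IRanges::IRanges(seg$start, seg$end), strand = seg$strand,
    type = "CDS", ID = paste0(seg$gene_id, ".cds"), Parent = seg$gene_id,
    phase = seg$phase
  )
  gr <- c(gr_gene, gr_cds)
  gr$source <- "rhizolink"
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a dataset written by [write_dataset()]
#'
#' Re-parses the emitted FASTA/GFF3/TSV/JSON files into the in-memory
#' objects used by the pipeline.
#'
#' @param dir Directory holding the files.
#' @return A list with the same components as a `rhizolink_sim` (minus
#'   `config`, `feature_info` and `batch_shifts`, which are generator
#'   internals).
#' @export
read_dataset <- function(dir) {
  genome <- as_genome(file.path(dir, "genome.fasta"))
  gene_models <- build_gene_models(file.path(dir, "genes.gff3"), genome)
  truth_raw <- jsonlite::read_json(file.path(dir, "truth.json"))
  truth <- tibble::tibble(
    gene_id = vapply(truth_raw, `[[`, character(1), "gene_id"),
    feature_id = vapply(truth_raw, `[[`, character(1), "feature_id"),
    affected = lapply(truth_raw, function(x) unlist(x$affected_accessions)),
    mechanism = vapply(truth_raw, `[[`, character(1), "mechanism"),
    stop_codon_index = vapply(truth_raw, function(x)
      as.integer(x$stop_codon_index), integer(1))
  )
  list(
    genome = genome,
    gene_models = gene_models,
    enzyme_gene_ids = read_enzyme_list(file.path(dir, "enzyme_genes.txt")),
    variants = read_variant_table(file.path(dir, "variants.tsv")),
    features = read_feature_matrix(file.path(dir, "features.tsv")),
    samples = read_sample_metadata(file.path(dir, "samples.tsv")),
    truth = truth
  )
}
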