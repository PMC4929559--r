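#' Variant tables
#'
#' Variants are tidy tibbles with columns `accession`, `chrom`, `pos`
#' (1-based reference coordinate), `ref` and `alt` (SNPs, insertions and
#' deletions; `ref != alt`). Accessions absent from a record carry the
#' reference allele. Multi-allelic records are split into biallelic rows on
#' reading.
#'
#' The plain-text dialect is a TSV `accession  chrom  pos  ref  alt`;
#' multi-sample VCF v4.2 is supported through \pkg{vcfR} (haploid genotypes
#' coded as homozygous `1/1`).
#'
#' @param path File path.
#' @return A variant tibble.
#' @export
read_variant_table <- function(path) {
  v <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(
                         accession = readr::col_character(),
                         chrom = readr::col_character(),
                         pos = readr::col_integer(),
                         ref = readr::col_character(),
                         alt = readr::col_character()
                       ))
  split_multiallelic(v)
}

#' @rdname read_variant_table
#' @param variants A variant tibble.
#' @export
write_variant_table <- function(variants, path) {
  readr::write_tsv(variants, path)
  invisible(variants)
}

#' @rdname read_variant_table
#' @param accessions Accession universe for the VCF sample columns; defaults
#'   to the accessions present in `variants`.
#' @export
write_vcf <- function(variants, path, accessions = NULL) {
  if (is.null(accessions)) accessions <- sort(unique(variants$accession))
  loci <- variants |>
    dplyr::distinct(chrom, pos, ref, alt) |>
    dplyr::arrange(chrom, pos, ref, alt)
  carrier <- variants |>
    dplyr::mutate(key = paste(chrom, pos, ref, alt, sep = "\r"))
  keys <- paste(loci$chrom, loci$pos, loci$ref, loci$alt, sep = "\r")
  gt <- matrix("0/0", nrow = nrow(loci), ncol = length(accessions),
               dimnames = list(NULL, accessions))
  idx <- cbind(match(carrier$key, keys), match(carrier$accession, accessions))
  gt[idx] <- "1/1"
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", accessions), collapse = "\t")
  )
  body <- paste(loci$chrom, loci$pos, ".", loci$ref, loci$alt, ".", "PASS",
                ".", "GT", apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(variants)
}

#' @rdname read_variant_table
#' @export
read_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- tibble::as_tibble(vcfR::getFIX(v))
  gt <- vcfR::extract.gt(v, element = "GT")
  alt_carrier <- gt != "0/0" & gt != "0|0" & gt != "0" & !is.na(gt)
  rows <- which(alt_carrier, arr.ind = TRUE)
  out <- tibble::tibble(
    accession = colnames(gt)[rows[, 2]],
    chrom = fix$CHROM[rows[, 1]],
    pos = as.integer(fix$POS[rows[, 1]]),
    ref = fix$REF[rows[, 1]],
    alt = fix$ALT[rows[, 1]]
  )
  split_multiallelic(dplyr::arrange(out, accession, chrom, pos))
}

split_multiallelic <- function(variants) {
  variants |>
    dplyr::mutate(alt = strsplit(.data$alt, ",", fixed = TRUE)) |>
    tidyr::unnest(alt) |>
    dplyr::filter(.data$ref != .data$alt)
}

#' Build gene models from GFF3 and a reference genome
#'
#' Collects `CDS` features per gene (attribute `Parent`, falling back to
#' `ID`), orders segments along the chromosome, splices the reference CDS
#' (reverse-complemented for minus-strand genes) and translates it.
#'
#' @param gff_path GFF3 file (1-based, inclusive coordinates).
#' @param genome Named character vector of chromosome sequences, or a
#'   `Biostrings::DNAStringSet`, or the path to a FASTA file.
#' @return A gene-model tibble: `gene_id`, `chrom`, `strand`, `segments`
#'   (list of tibbles with `start`, `end`), `cds` (spliced sequence) and
#'   `protein` (reference protein, no terminal stop).
#' @export
build_gene_models <- function(gff_path, genome) {
  genome <- as_genome(genome)
  gr <- rtracklayer::import(gff_path)
  cds <- gr[gr$type == "CDS"]
  parent_raw <- S4Vectors::mcols(cds)$Parent
  parent <- if (is.null(parent_raw)) rep(NA_character_, length(cds)) else {
    vapply(as.list(parent_raw), function(x) {
      if (length(x) == 0 || is.na(x[1])) NA_character_ else as.character(x[1])
    }, character(1))
  }
  if (all(is.na(parent))) {
    parent <- as.character(S4Vectors::mcols(cds)$ID)
  }
  parent <- sub("\\.cds[0-9]*$", "", parent)
  df <- tibble::tibble(
    gene_id = parent,
    chrom = as.character(GenomicRanges::seqnames(cds)),
    strand = as.character(GenomicRanges::strand(cds)),
    start = GenomicRanges::start(cds),
    end = GenomicRanges::end(cds)
  )
  models <- df |>
    dplyr::arrange(gene_id, start) |>
    dplyr::group_by(gene_id, chrom, strand) |>
    dplyr::summarise(segments = list(tibble::tibble(start = start, end = end)),
                     .groups = "drop")
  models$cds <- purrr::pmap_chr(models, function(gene_id, chrom, strand, segments) {
    splice_cds(genome[[chrom]], segments, strand)
  })
  models$protein <- vapply(models$cds, function(s) {
    aa <- translate_dna(s)
    sub("\\*.*$", "", aa)
  }, character(1), USE.NAMES = FALSE)
  validate_gene_models(models)
  models
}

validate_gene_models <- function(models) {
  for (i in seq_len(nrow(models))) {
    cds <- models$cds[i]
    if (nchar(cds) %% 3 != 0) stop(models$gene_id[i], ": CDS length not a multiple of 3")
    if (substr(cds, 1, 3) != "ATG") stop(models$gene_id[i], ": CDS must start with ATG")
    aa <- translate_dna(cds)
    stops <- gregexpr("*", aa, fixed = TRUE)[[1]]
    if (length(stops) != 1 || stops[1] != nchar(aa)) {
      stop(models$gene_id[i], ": reference CDS must have exactly one terminal stop")
    }
  }
  invisible(models)
}

splice_cds <- function(chrom_seq, segments, strand) {
  parts <- substring(chrom_seq, segments$start, segments$end)
  s <- paste(parts, collapse = "")
  if (strand == "-") s <- revcomp(s)
  s
}

as_genome <- function(genome) {
  if (is.character(genome) && length(genome) == 1 && file.exists(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
  }
  if (methods::is(genome, "DNAStringSet")) {
    genome <- stats::setNames(as.character(genome), names(genome))
  }
  # FASTA headers may carry descriptions after the ID
  names(genome) <- sub("\\s.*$", "", names(genome))
  as.list(genome)
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# Standard-code translation of frame 1, reading off Biostrings' genetic
# code table codon by codon (a partial terminal codon is ignored).
translate_dna <- function(s) {
  n <- (nchar(s) %/% 3) * 3
  if (n < 3) return("")
  codons <- substring(s, seq(1L, n, 3L), seq(3L, n, 3L))
  paste(unname(Biostrings::GENETIC_CODE[codons]), collapse = "")
}

#' Restrict variants to coding sequence
#'
#' Keeps variant records whose reference span intersects a CDS segment and
#' annotates each with the owning gene. Optionally checks the `ref` allele
#' against the reference genome and errors on disagreement.
#'
#' @param variants A variant tibble.
#' @param gene_models A gene-model tibble from [build_gene_models()] or the
#'   generator.
#' @param genome Optional reference genome (see [build_gene_models()]); when
#'   supplied, `ref` alleles are verified.
#' @return The CDS-restricted variant tibble with an extra `gene_id` column
#'   (one row per overlapping gene).
#' @export
restrict_to_cds <- function(variants, gene_models, genome = NULL) {
  if (!is.null(genome)) {
    genome <- as_genome(genome)
    obs <- vapply(seq_len(nrow(variants)), function(i) {
      substr(genome[[variants$chrom[i]]], variants$pos[i],
             variants$pos[i] + nchar(variants$ref[i]) - 1L)
    }, character(1))
    bad <- obs != variants$ref
    if (any(bad)) {
      stop("ref allele mismatch at: ",
           paste(utils::head(paste0(variants$chrom[bad], ":", variants$pos[bad]), 5),
                 collapse = ", "))
    }
  }
  seg <- gene_models |>
    dplyr::select(gene_id, chrom, segments) |>
    tidyr::unnest(segments)
  out <- purrr::map_dfr(split(seg, seg$chrom), function(sc) {
    vc <- variants[variants$chrom == sc$chrom[1], , drop = FALSE]
    if (nrow(vc) == 0) return(NULL)
    q <- IRanges::IRanges(vc$pos, vc$pos + nchar(vc$ref) - 1L)
    s <- IRanges::IRanges(sc$start, sc$end)
    hits <- IRanges::findOverlaps(q, s)
    dplyr::bind_cols(
      vc[S4Vectors::queryHits(hits), , drop = FALSE],
      tibble::tibble(gene_id = sc$gene_id[S4Vectors::subjectHits(hits)])
    )
  })
  dplyr::arrange(dplyr::distinct(out), accession, chrom, pos, gene_id)
}

#' Pairwise mismatch distance between accessions
#'
#' For each variant locus every accession pair is compared; a mismatch
#' (different alleles, accessions missing from a record counting as
#' reference) increases the pair's distance by 1. The result is the sum
#' over all loci — a Hamming distance between allele vectors.
#'
#' @param variants A variant tibble (optionally CDS-restricted).
#' @param accessions Character vector of all accessions (defines the matrix
#'   and covers accessions with no variants).
#' @return A [stats::dist] object over `accessions`, with attribute
#'   `n_loci` (number of distinct variant loci compared).
#' @export
mismatch_distance <- function(variants, accessions) {
  v <- dplyr::distinct(variants, accession, chrom, pos, ref, alt)
  loci <- v |>
    dplyr::distinct(chrom, pos, ref) |>
    dplyr::mutate(locus = dplyr::row_number())
  v <- dplyr::left_join(v, loci, by = c("chrom", "pos", "ref"))
  k <- length(accessions)
  # allele code per (locus, accession): 0 = reference, j = j-th alt allele
  allele <- matrix(0L, nrow = nrow(loci), ncol = k,
                   dimnames = list(NULL, accessions))
  alt_codes <- v |>
    dplyr::group_by(locus) |>
    dplyr::mutate(code = match(alt, sort(unique(alt)))) |>
    dplyr::ungroup()
  allele[cbind(alt_codes$locus, match(alt_codes$accession, accessions))] <-
    alt_codes$code
  d <- matrix(0, k, k, dimnames = list(accessions, accessions))
  for (i in seq_len(k - 1)) {
    for (j in seq((i + 1), k)) {
      d[i, j] <- d[j, i] <- sum(allele[, i] != allele[, j])
    }
  }
  out <- stats::as.dist(d)
  attr(out, "n_loci") <- nrow(loci)
  out
}

#' Apply one accession's variants to a gene and return its CDS
#'
#' Edits (substitutions, insertions, deletions) are applied to the genomic
#' window of the gene from right to left so reference coordinates stay
#' valid, segment boundaries are shifted or clamped across indels, and the
#' edited segments are spliced (and reverse-complemented for minus-strand
#' genes). Variants spanning intron boundaries are therefore applied on the
#' genomic sequence before splicing.
#'
#' @param gene One row of a gene-model tibble.
#' @param variants Variant tibble already restricted to this gene and one
#'   accession.
#' @param genome Reference genome (see [build_gene_models()]).
#' @return The accession's CDS sequence (character scalar).
#' @export
apply_variants <- function(gene, variants, genome) {
  genome <- as_genome(genome)
  segments <- gene$segments[[1]]
  w_start <- min(segments$start)
  w_end <- max(segments$end)
  window <- substr(genome[[gene$chrom]], w_start, w_end)
  segs <- segments |> dplyr::arrange(start)
  starts <- segs$start - w_start + 1L
  ends <- segs$end - w_start + 1L
  if (nrow(variants) > 0) {
    v <- dplyr::arrange(variants, dplyr::desc(pos))
    sp <- v$pos
    ep <- v$pos + nchar(v$ref) - 1L
    ord <- order(v$pos)
    if (any(sp[ord][-1] <= ep[ord][-length(ord)])) {
      stop("overlapping variants in ", gene$gene_id)
    }
    for (i in seq_len(nrow(v))) {
      p1 <- v$pos[i] - w_start + 1L
      p2 <- p1 + nchar(v$ref[i]) - 1L
      if (p2 < 1 || p1 > nchar(window)) next
      obs <- substr(window, p1, p2)
      if (obs != v$ref[i]) {
        stop("ref allele mismatch at ", gene$chrom, ":", v$pos[i],
             " (expected ", v$ref[i], ", found ", obs, ")")
      }
      window <- paste0(substr(window, 1, p1 - 1L), v$alt[i],
                       substr(window, p2 + 1L, nchar(window)))
      delta <- nchar(v$alt[i]) - nchar(v$ref[i])
      if (delta != 0) {
        starts <- shift_boundary(starts, p1, p2, delta, is_start = TRUE)
        ends <- shift_boundary(ends, p1, p2, delta, is_start = FALSE)
      }
    }
  }
  parts <- substring(window, starts, ends)
  s <- paste(parts[ends >= starts], collapse = "")
  if (gene$strand == "-") s <- revcomp(s)
  s
}

# Shift a vector of segment boundaries across an edit replacing [p1, p2]
# with a delta length change; boundaries inside a deleted span clamp to its
# edges.
shift_boundary <- function(b, p1, p2, delta, is_start) {
  out <- b
  after <- b > p2
  out[after] <- b[after] + delta
  inside <- b >= p1 & b <= p2
  if (any(inside)) {
    # within the replaced span: clamp starts to the span start, ends to the
    # end of the replacement
    out[inside] <- if (is_start) p1 else p2 + delta
  }
  out
}

#' Call a premature stop from an accession CDS
#'
#' Translates the CDS with the standard genetic code from position 1 and
#' compares the first in-frame stop with the reference protein length.
#'
#' @param accession_cds CDS sequence (character scalar).
#' @param reference_protein Reference protein sequence (no terminal stop).
#' @return A one-row tibble: `premature` and `first_stop_codon_index`
#'   (1-based codon index of the first stop, `NA` if none).
#' @export
call_premature_stop <- function(accession_cds, reference_protein) {
  tibble::as_tibble(premature_call(accession_cds, reference_protein))
}

premature_call <- function(accession_cds, reference_protein) {
  ref_len <- nchar(reference_protein)
  if (nchar(accession_cds) < 3) {
    return(list(premature = TRUE, first_stop_codon_index = NA_integer_))
  }
  aa <- translate_dna(accession_cds)
  stop_at <- regexpr("*", aa, fixed = TRUE)[1]
  premature <- stop_at != -1 && stop_at < ref_len + 1
  list(
    premature = premature,
    first_stop_codon_index = if (stop_at == -1) NA_integer_ else as.integer(stop_at)
  )
}

#' Premature-stop status for every gene x accession pair
#'
#' Applies each accession's CDS variants per gene, translates, and
#' classifies the truncation mechanism: `"deletion"` when deletions remove
#' more than 10% of the reference CDS (large structural loss counts as
#' loss-of-function even without an early stop codon), `"frameshift"` when
#' an indel of length not divisible by 3 precedes the first stop,
#' `"nonsense_snp"` for substitution-induced stops, `"none"` otherwise.
#'
#' @param gene_models Gene-model tibble.
#' @param variants Variant tibble (will be CDS-restricted internally).
#' @param genome Reference genome.
#' @param accessions Accession universe.
#' @param large_deletion_frac Fraction of reference CDS length whose removal
#'   alone marks the protein non-functional (default 0.1).
#' @return A tibble `gene_id`, `accession`, `premature`,
#'   `first_stop_codon_index`, `mechanism`.
#' @export
protein_status <- function(gene_models, variants, genome, accessions,
                           large_deletion_frac = 0.1) {
  genome <- as_genome(genome)
  cds_variants <- restrict_to_cds(variants, gene_models, genome)
  # default grid: reference-like, non-premature
  out <- tibble::tibble(
    gene_id = rep(gene_models$gene_id, each = length(accessions)),
    accession = rep(accessions, times = nrow(gene_models)),
    premature = FALSE,
    first_stop_codon_index = NA_integer_,
    mechanism = "none"
  )
  if (nrow(cds_variants) == 0) return(out)
  key <- paste(out$gene_id, out$accession, sep = "\r")
  pairs <- dplyr::distinct(cds_variants, gene_id, accession)
  pairs <- pairs[pairs$accession %in% accessions, , drop = FALSE]
  for (i in seq_len(nrow(pairs))) {
    gene <- gene_models[gene_models$gene_id == pairs$gene_id[i], ]
    av <- cds_variants[cds_variants$gene_id == pairs$gene_id[i] &
                         cds_variants$accession == pairs$accession[i], ,
                       drop = FALSE]
    cds <- apply_variants(gene, av, genome)
    call <- premature_call(cds, gene$protein)
    deleted <- sum(pmax(nchar(av$ref) - nchar(av$alt), 0))
    big_del <- deleted > large_deletion_frac * nchar(gene$cds)
    frameshift <- any((nchar(av$alt) - nchar(av$ref)) %% 3 != 0)
    premature <- call$premature || big_del
    mechanism <- if (!premature) "none"
      else if (big_del) "deletion"
      else if (frameshift) "frameshift"
      else if (any(nchar(av$ref) == 1 & nchar(av$alt) == 1)) "nonsense_snp"
      else "none"
    at <- match(paste(pairs$gene_id[i], pairs$accession[i], sep = "\r"), key)
    out$premature[at] <- premature
    out$first_stop_codon_index[at] <- call$first_stop_codon_index
    out$mechanism[at] <- mechanism
  }
  out
}

#' Stop-codon patterns for enzyme genes
#'
#' Reduces per-accession protein status to one boolean pattern per enzyme
#' gene (TRUE = predicted protein prematurely terminated), dropping genes
#' with no premature accession. Enzyme IDs missing from the gene models are
#' reported and skipped.
#'
#' @param status Output of [protein_status()].
#' @param enzyme_gene_ids Character vector of enzyme gene IDs.
#' @param accessions Canonical accession ordering for the patterns.
#' @return A tibble `gene_id`, `pattern` (list of named logical vectors),
#'   `pattern_key` (canonical comma-joined affected accessions),
#'   `n_premature`.
#' @export
enzyme_stop_patterns <- function(status, enzyme_gene_ids, accessions) {
  if (length(enzyme_gene_ids) == 0) stop("empty enzyme gene list")
  missing <- setdiff(enzyme_gene_ids, unique(status$gene_id))
  if (length(missing) > 0) {
    message(length(missing), " enzyme gene(s) not in gene models, skipped: ",
            paste(utils::head(missing, 5), collapse = ", "))
  }
  st <- status[status$gene_id %in% enzyme_gene_ids, , drop = FALSE]
  purrr::map_dfr(split(st, st$gene_id), function(g) {
    pat <- stats::setNames(rep(FALSE, length(accessions)), accessions)
    pat[g$accession[g$premature]] <- TRUE
    if (!any(pat)) return(NULL)
    tibble::tibble(
      gene_id = g$gene_id[1],
      pattern = list(pat),
      pattern_key = paste(accessions[pat], collapse = ","),
      n_premature = sum(pat)
    )
  })
}

#' Read an enzyme gene list (one gene ID per line)
#'
#' @param path File path.
#' @return Character vector of gene IDs.
#' @export
read_enzyme_list <- function(path) {
  ids <- readLines(path)
  ids[nzchar(trimws(ids))]
}
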