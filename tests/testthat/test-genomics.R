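# a tiny hand-built gene for targeted edits: one chromosome, one gene,
# '+' strand, two CDS segments with a 6-bp intron
tiny_gene <- function() {
  # CDS: ATG CAA GGT TTC TGA  -> protein MQGF
  cds <- "ATGCAAGGTTTCTGA"
  exon1 <- substr(cds, 1, 7)
  exon2 <- substr(cds, 8, 15)
  intron <- "GTAAAG"
  chrom <- paste0("AAAA", exon1, intron, exon2, "TTTT")
  gene <- tibble::tibble(
    gene_id = "G1", chrom = "chrX", strand = "+",
    segments = list(tibble::tibble(start = c(5, 18), end = c(11, 25))),
    cds = cds, protein = "MQGF"
  )
  list(gene = gene, genome = list(chrX = chrom))
}

test_that("variants are restricted to CDS and annotated with their gene", {
  tg <- tiny_gene()
  true_base <- function(p) substr(tg$genome$chrX, p, p)
  v <- tibble::tibble(
    accession = c("a1", "a1", "a1"),
    chrom = "chrX",
    pos = c(6L, 13L, 2L),        # CDS, intron, upstream
    ref = vapply(c(6L, 13L, 2L), true_base, character(1)),
    alt = c("A", "A", "G")
  )
  out <- restrict_to_cds(v, tg$gene)
  expect_equal(nrow(out), 1)
  expect_equal(out$pos, 6L)
  expect_equal(out$gene_id, "G1")
  # ref-allele verification against the genome
  expect_silent(restrict_to_cds(v, tg$gene, genome = tg$genome))
  v_bad <- v
  v_bad$ref[1] <- setdiff(c("A", "C", "G", "T"), true_base(6L))[1]
  expect_error(restrict_to_cds(v_bad, tg$gene, genome = tg$genome), "mismatch")
})

test_that("mismatch distance counts hand-tallied private variants", {
  accs <- c("a1", "a2", "a3")
  v <- tibble::tibble(
    accession = c("a1", "a1", "a1", "a2", "a2"),
    chrom = "chr1", pos = c(10L, 20L, 30L, 40L, 50L),
    ref = "A", alt = "T"
  )
  d <- as.matrix(mismatch_distance(v, accs))
  expect_equal(d["a1", "a2"], 5)  # 3 + 2 private, none shared
  expect_equal(d["a1", "a3"], 3)
  expect_equal(d["a2", "a3"], 2)
  # identical variant sets are at distance zero
  v2 <- dplyr::bind_rows(v, dplyr::mutate(v[1:3, ], accession = "a3"))
  d2 <- as.matrix(mismatch_distance(v2, accs))
  expect_equal(d2["a1", "a3"], 0)
})

test_that("mismatch distance equals the brute-force per-locus oracle", {
  set.seed(23)
  accs <- sprintf("a%d", 1:5)
  for (i in 1:5) {
    n <- 60
    v <- tibble::tibble(
      accession = sample(accs, n, replace = TRUE),
      chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
      pos = sample(1:30, n, replace = TRUE),
      ref = "A",
      alt = sample(c("C", "G", "T"), n, replace = TRUE)
    )
    v <- dplyr::distinct(v, accession, chrom, pos, .keep_all = TRUE)
    mine <- as.matrix(mismatch_distance(v, accs))
    ref <- naive_mismatch(as.data.frame(v), accs)
    expect_equal(mine, ref)
    # order invariance
    shuffled <- v[sample(nrow(v)), ]
    expect_equal(as.matrix(mismatch_distance(shuffled, accs)), mine)
    # triangle inequality (Hamming distance over allele vectors)
    for (x in 1:5) for (y in 1:5) for (z in 1:5) {
      expect_lte(mine[x, y], mine[x, z] + mine[z, y])
    }
  }
})

test_that("applying no variants returns the reference CDS", {
  tg <- tiny_gene()
  no_variants <- tibble::tibble(accession = character(0), chrom = character(0),
                                pos = integer(0), ref = character(0),
                                alt = character(0))
  out <- apply_variants(tg$gene, no_variants, tg$genome)
  expect_equal(out, tg$gene$cds)
})

test_that("a nonsense SNP lands at the expected codon", {
  tg <- tiny_gene()
  # CDS codon 2 is CAA; its first base sits at CDS position 4 = genome pos 8
  v <- tibble::tibble(accession = "a1", chrom = "chrX", pos = 8L,
                      ref = "C", alt = "T")
  cds <- apply_variants(tg$gene, v, tg$genome)
  expect_equal(substr(cds, 4, 6), "TAA")
  call <- call_premature_stop(cds, tg$gene$protein)
  expect_true(call$premature)
  expect_equal(call$first_stop_codon_index, 2L)
})

test_that("edits across the intron boundary hit the genomic sequence", {
  tg <- tiny_gene()
  # delete the last CDS base of exon1 plus two intron bases (3-bp deletion)
  v <- tibble::tibble(accession = "a1", chrom = "chrX", pos = 10L,
                      ref = substr(tg$genome$chrX, 10, 13),
                      alt = substr(tg$genome$chrX, 10, 10))
  cds <- apply_variants(tg$gene, v, tg$genome)
  # one coding base lost -> frameshifted CDS shorter by 1
  expect_equal(nchar(cds), nchar(tg$gene$cds) - 1)
})

test_that("overlapping variants are rejected", {
  tg <- tiny_gene()
  v <- tibble::tibble(accession = "a1", chrom = "chrX", pos = c(8L, 9L),
                      ref = c("CA", "AA"), alt = c("C", "A"))
  expect_error(apply_variants(tg$gene, v, tg$genome), "overlapping")
})

test_that("reference sequences are never called premature", {
  ds <- small_dataset()
  for (i in seq_len(nrow(ds$gene_models))) {
    call <- call_premature_stop(ds$gene_models$cds[i], ds$gene_models$protein[i])
    expect_false(call$premature)
  }
})

test_that("planted truncations are called at the recorded codon", {
  ds <- small_dataset()
  st <- small_status()
  prem <- st[st$premature, ]
  for (i in seq_len(nrow(ds$truth))) {
    g <- ds$truth$gene_id[i]
    called <- prem[prem$gene_id == g, ]
    expect_setequal(called$accession, ds$truth$affected[[i]])
    expect_true(all(called$first_stop_codon_index == ds$truth$stop_codon_index[i]))
    expect_true(all(called$mechanism == ds$truth$mechanism[i]))
  }
  # no stop calls beyond the planted genes (background variants are benign)
  expect_setequal(unique(prem$gene_id), ds$truth$gene_id)
})

test_that("premature calls agree with the Biostrings translation oracle", {
  ds <- small_dataset()
  accs <- non_blank_accessions(ds)
  cds_v <- restrict_to_cds(ds$variants, ds$gene_models)
  pairs <- dplyr::distinct(cds_v, gene_id, accession)
  set.seed(31)
  pick <- pairs[sample(nrow(pairs), min(40, nrow(pairs))), ]
  for (i in seq_len(nrow(pick))) {
    gene <- ds$gene_models[ds$gene_models$gene_id == pick$gene_id[i], ]
    av <- cds_v[cds_v$gene_id == pick$gene_id[i] &
                  cds_v$accession == pick$accession[i], ]
    cds <- apply_variants(gene, av, ds$genome)
    aa_oracle <- oracle_translate(cds)
    stop_oracle <- regexpr("*", aa_oracle, fixed = TRUE)[1]
    premature_oracle <- stop_oracle != -1 && stop_oracle < nchar(gene$protein) + 1
    call <- call_premature_stop(cds, gene$protein)
    expect_equal(call$premature, premature_oracle)
  }
})

test_that("enzyme stop patterns collect exactly the premature accessions", {
  accs <- c("acc1", "acc2", "acc7")
  status <- tibble::tibble(
    gene_id = rep(c("G1", "G2"), each = 3),
    accession = rep(accs, 2),
    premature = c(FALSE, TRUE, TRUE, FALSE, FALSE, FALSE),
    first_stop_codon_index = NA_integer_,
    mechanism = c("none", "nonsense_snp", "nonsense_snp", rep("none", 3))
  )
  out <- enzyme_stop_patterns(status, c("G1", "G2"), accs)
  expect_equal(nrow(out), 1)  # G2 has no premature accession -> dropped
  expect_equal(out$gene_id, "G1")
  expect_equal(out$pattern_key, "acc2,acc7")
  expect_message(enzyme_stop_patterns(status, c("G1", "G9"), accs), "skipped")
  expect_error(enzyme_stop_patterns(status, character(0), accs), "empty")
})

test_that("a large CDS deletion is loss-of-function even without an early stop", {
  tg <- tiny_gene()
  # drop 6 coding bases (40% of the CDS) in frame: no new stop, still a loss
  v <- tibble::tibble(accession = "a1", chrom = "chrX", pos = 5L,
                      ref = substr(tg$genome$chrX, 5, 11),
                      alt = substr(tg$genome$chrX, 5, 5))
  st <- protein_status(tg$gene, v, tg$genome, "a1")
  expect_true(st$premature)
  expect_equal(st$mechanism, "deletion")
})
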