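# a compact hand-built detection matrix over 4 accessions x 2 replicates
mini_detect <- function() {
  accs <- c("Can-0", "Zu-0", "Wu-0", "Col-0")
  samples <- tibble::tibble(
    sample_id = sprintf("%s_r%d", rep(accs, each = 2), rep(1:2, 4)),
    accession = rep(accs, each = 2),
    replicate = rep(1:2, 4), batch = rep(1:2, 4), is_blank = FALSE
  )
  m <- matrix(5e4, nrow = 3, ncol = 8,
              dimnames = list(NULL, samples$sample_id))
  m[1, samples$accession %in% c("Can-0", "Zu-0")] <- NA  # absent in 2
  m[2, samples$accession == "Wu-0"] <- NA                # absent in 1
  # feature 3 detected everywhere
  list(features = make_features(m), samples = samples)
}

test_that("a feature undetected in Can-0 and Zu-0 has a pattern of length two", {
  md <- mini_detect()
  pat <- absence_patterns(md$features, md$samples)
  expect_equal(pat$pattern_length, c(2, 1, 0))
  expect_equal(pat$pattern_key[1], "Can-0,Zu-0")
  expect_equal(pat$pattern_key[2], "Wu-0")
  expect_equal(pat$pattern_key[3], "")
})

test_that("one surviving replicate defeats the absence call, an lod revives it", {
  md <- mini_detect()
  f <- md$features
  f[[md$samples$sample_id[1]]][1] <- 300  # Can-0 r1 weakly detected
  pat <- absence_patterns(f, md$samples)
  expect_equal(pat$pattern_key[1], "Zu-0")
  pat_lod <- absence_patterns(f, md$samples, lod = 500)
  expect_equal(pat_lod$pattern_key[1], "Can-0,Zu-0")
})

test_that("planted features reproduce their truth absence patterns", {
  ds <- small_dataset()
  pat <- absence_patterns(ds$features, ds$samples)
  for (i in seq_len(nrow(ds$truth))) {
    row <- pat[pat$feature_id == ds$truth$feature_id[i], ]
    expect_equal(row$pattern_key,
                 paste(sort(ds$truth$affected[[i]]), collapse = ","))
  }
  # decoy features likewise match the generator's record
  info <- ds$feature_info[ds$feature_info$is_decoy, ]
  for (i in seq_len(nrow(info))) {
    row <- pat[pat$feature_id == info$feature_id[i], ]
    expect_equal(row$pattern_key, paste(info$absent[[i]], collapse = ","))
  }
})

test_that("candidate filters enforce length, annotation and median intensity", {
  md <- mini_detect()
  pat <- absence_patterns(md$features, md$samples)
  ann <- tibble::tibble(
    feature_id = pat$feature_id,
    group_id = 1:3,
    isotope_role = c("monoisotopic", "isotope_1", "monoisotopic"),
    monoisotopic = c(TRUE, FALSE, TRUE),
    parent_id = NA_character_
  )
  out <- filter_candidates(pat, ann, min_median = 10000)
  expect_equal(out$feature_id, "F001")   # F002 fails the flag, F003 length 0
  # boundary: median below the threshold by one unit
  pat2 <- pat
  pat2$median_intensity[1] <- 9999
  expect_equal(nrow(filter_candidates(pat2, ann, min_median = 10000)), 0)
  # brute-force filter oracle on the synthetic dataset
  ds <- small_dataset()
  spat <- absence_patterns(ds$features, ds$samples)
  sann <- detect_isotopes(ds$features)
  got <- filter_candidates(spat, sann, min_median = 10000)
  mono <- sann$feature_id[sann$isotope_role == "monoisotopic"]
  want <- spat$feature_id[spat$pattern_length >= 1 &
                            spat$feature_id %in% mono &
                            !is.na(spat$median_intensity) &
                            spat$median_intensity >= 10000]
  expect_setequal(got$feature_id, want)
})

stop_pattern_for <- function(gene_id, affected, accessions) {
  pat <- setNames(accessions %in% affected, accessions)
  tibble::tibble(gene_id = gene_id, pattern = list(pat),
                 pattern_key = paste(accessions[pat], collapse = ","),
                 n_premature = sum(pat))
}

test_that("a Wu-0-only absence matches exactly the gene with a Wu-0-only stop", {
  md <- mini_detect()
  accs <- unique(md$samples$accession)
  pat <- absence_patterns(md$features, md$samples)
  ann <- tibble::tibble(feature_id = pat$feature_id, group_id = 1:3,
                        isotope_role = "monoisotopic", monoisotopic = TRUE,
                        parent_id = NA_character_)
  cand <- filter_candidates(pat, ann, min_median = 10000)
  stops <- dplyr::bind_rows(
    stop_pattern_for("UGT-like", "Wu-0", accs),
    stop_pattern_for("other-enzyme", "Can-0", accs)
  )
  match <- match_patterns(cand, stops)
  wu <- match$candidates[match$candidates$pattern_key == "Wu-0", ]
  expect_equal(nrow(wu), 1)
  expect_equal(wu$genes[[1]], "UGT-like")
  expect_equal(wu$n_genes, 1L)
})

test_that("a two-accession absence matches a gene lost in exactly those two", {
  accs <- c("Bur-0", "Can-0", "Ler-0", "Col-0")
  samples <- tibble::tibble(
    sample_id = sprintf("%s_r%d", rep(accs, each = 2), rep(1:2, 4)),
    accession = rep(accs, each = 2), replicate = rep(1:2, 4),
    batch = rep(1:2, 4), is_blank = FALSE
  )
  m <- matrix(6e4, 1, 8, dimnames = list(NULL, samples$sample_id))
  m[1, samples$accession %in% c("Can-0", "Ler-0")] <- NA
  f <- make_features(m)
  pat <- absence_patterns(f, samples)
  ann <- tibble::tibble(feature_id = "F001", group_id = 1L,
                        isotope_role = "monoisotopic", monoisotopic = TRUE,
                        parent_id = NA_character_)
  cand <- filter_candidates(pat, ann)
  stops <- dplyr::bind_rows(
    stop_pattern_for("SCT-like", c("Can-0", "Ler-0"), accs),
    stop_pattern_for("other", "Bur-0", accs)
  )
  match <- match_patterns(cand, stops)
  expect_equal(nrow(match$candidates), 1)
  expect_equal(match$candidates$genes[[1]], "SCT-like")
  expect_equal(match$candidates$pattern_key, "Can-0,Ler-0")
})

test_that("no absent features gives an empty but valid match", {
  md <- mini_detect()
  pat <- absence_patterns(md$features[3, ], md$samples)
  ann <- tibble::tibble(feature_id = "F001", group_id = 1L,
                        isotope_role = "monoisotopic", monoisotopic = TRUE,
                        parent_id = NA_character_)
  cand <- filter_candidates(pat, ann)
  stops <- stop_pattern_for("G1", "Wu-0", unique(md$samples$accession))
  match <- match_patterns(cand, stops)
  expect_equal(nrow(match$candidates), 0)
})

test_that("mismatched accession universes are an error", {
  md <- mini_detect()
  pat <- absence_patterns(md$features, md$samples)
  ann <- tibble::tibble(feature_id = pat$feature_id, group_id = 1:3,
                        isotope_role = "monoisotopic", monoisotopic = TRUE,
                        parent_id = NA_character_)
  cand <- filter_candidates(pat, ann)
  stops <- stop_pattern_for("G1", "Wu-0", c("Wu-0", "Cvi-0"))
  expect_error(match_patterns(cand, stops), "universe")
})

test_that("matching equals the brute-force double loop over pairs", {
  ds <- small_dataset()
  spat <- absence_patterns(ds$features, ds$samples)
  sann <- detect_isotopes(ds$features)
  cand <- filter_candidates(spat, sann)
  accs <- non_blank_accessions(ds)
  stops <- enzyme_stop_patterns(small_status(), ds$enzyme_gene_ids, accs)
  match <- match_patterns(cand, stops)
  got <- tidy(match)
  want <- list()
  for (i in seq_len(nrow(cand))) {
    for (j in seq_len(nrow(stops))) {
      f_set <- names(which(cand$absent[[i]]))
      g_set <- names(which(stops$pattern[[j]]))
      if (length(f_set) > 0 && setequal(f_set, g_set)) {
        want[[length(want) + 1]] <- paste(cand$feature_id[i], stops$gene_id[j])
      }
    }
  }
  expect_setequal(paste(got$feature_id, got$gene_id), unlist(want))
})

test_that("the candidate set shrinks as filters tighten", {
  ds <- small_dataset()
  spat <- absence_patterns(ds$features, ds$samples)
  sann <- detect_isotopes(ds$features)
  n_strict <- nrow(filter_candidates(spat, sann, policy = "strict"))
  n_perm <- nrow(filter_candidates(spat, sann, policy = "permissive"))
  expect_lte(n_strict, n_perm)
  n_low <- nrow(filter_candidates(spat, sann, min_median = 1000))
  n_high <- nrow(filter_candidates(spat, sann, min_median = 1e6))
  expect_lte(n_high, n_low)
})

test_that("reports round-trip through disk with deterministic ordering", {
  ds <- small_dataset()
  spat <- absence_patterns(ds$features, ds$samples)
  sann <- detect_isotopes(ds$features)
  cand <- filter_candidates(spat, sann)
  accs <- non_blank_accessions(ds)
  stops <- enzyme_stop_patterns(small_status(), ds$enzyme_gene_ids, accs)
  match <- match_patterns(cand, stops)
  dir <- withr::local_tempdir()
  write_report(match, dir, status = small_status())
  back <- read_report(dir)
  expect_equal(back$candidates$feature_id, match$candidates$feature_id)
  expect_equal(back$candidates$pattern_key, match$candidates$pattern_key)
  expect_equal(back$candidates$genes, match$candidates$genes)
  expect_equal(back$unmatched$feature_id, match$unmatched$feature_id)
  # empty report stays valid
  empty <- match_patterns(cand[0, ], stops)
  dir2 <- withr::local_tempdir()
  write_report(empty, dir2)
  back2 <- read_report(dir2)
  expect_equal(nrow(back2$candidates), 0)
})
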