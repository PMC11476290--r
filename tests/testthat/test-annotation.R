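test_that("align_read finds unique loci, overhangs and decoys", {
  b <- default_bundle()
  loci <- b$loci
  uniq <- loci[loci$is_decoy == FALSE][1]
  hits <- align_read(uniq$mature_seq, b)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$mirna, uniq$mirna)
  expect_equal(hits$mismatches, 0L)
  expect_equal(hits$overhang, 0L)

  # mature + non-templated AA: same locus, 2 nt overhang
  hits2 <- align_read(paste0(uniq$mature_seq, "AA"), b)
  expect_equal(hits2$mirna[1], uniq$mirna)
  expect_equal(hits2$overhang[1], 2L)

  # decoy mature sequence: two equally ranked hits
  dec <- loci[loci$is_decoy == TRUE]
  hits3 <- align_read(dec$mature_seq, b)
  best <- hits3[hits3$mismatches == hits3$mismatches[1] &
                  hits3$overhang == hits3$overhang[1]]
  expect_equal(nrow(best), 2L)
  expect_equal(sum(best$mirna %in% dec$mirna, na.rm = TRUE), 1L)
})

test_that("align_read agrees with a Biostrings exhaustive scan", {
  b <- default_bundle()
  loci <- b$loci[b$loci$strand == "+"]
  seqs <- c(loci$mature_seq[1],
            local({ s <- loci$mature_seq[2]; substr(s, 5, 5) <-
              setdiff(c("A", "C", "G", "T"), substr(s, 5, 5))[1]; s }),
            b$loci[b$loci$is_decoy == TRUE]$mature_seq)
  for (q in seqs) {
    got <- align_read(q, b)
    got_fwd <- sort(got[got$strand == "+" & got$overhang == 0L]$start)
    oracle <- Biostrings::matchPattern(
      Biostrings::DNAString(q), Biostrings::DNAString(b$genome),
      max.mismatch = 1)
    expect_identical(got_fwd, sort(BiocGenerics::start(oracle)) - 1L)
  }
})

test_that("annotate_read decomposes edits, shifts and discards correctly", {
  b <- default_bundle()
  idx <- isomirome:::align_index(b)
  lrow <- idx$loci[idx$loci$strand == "+" & idx$loci$is_decoy == FALSE][1]

  edited <- lrow$mature_seq
  substr(edited, 5, 5) <- "G"   # offset 4 is A at this locus? use its own base
  # use a position guaranteed to be a non-A base change: plant A->G at edit_pos
  edited <- lrow$mature_seq
  ep <- lrow$edit_pos
  substr(edited, ep + 1L, ep + 1L) <- "G"
  ann <- annotate_read(edited, lrow$mirna, lrow$sense_mature_start, b)
  expect_equal(ann$five_prime_shift, 0L)
  expect_equal(ann$nta, "")
  expect_equal(ann$sub_pos, ep)
  expect_equal(ann$sub_ref, "A")
  expect_equal(ann$sub_alt, "G")

  # mature minus its first base: 5' shift +1
  trimmed <- substr(lrow$mature_seq, 2L, nchar(lrow$mature_seq))
  ann2 <- annotate_read(trimmed, lrow$mirna, lrow$sense_mature_start + 1L, b)
  expect_equal(ann2$five_prime_shift, 1L)
  expect_equal(ann2$n_sub, 0L)

  # two internal mismatches: discarded
  multi <- lrow$mature_seq
  for (p in c(4L, 9L)) {
    substr(multi, p, p) <- setdiff(c("A", "C", "G", "T"),
                                   substr(multi, p, p))[1]
  }
  expect_message(
    res <- annotate_read(multi, lrow$mirna, lrow$sense_mature_start, b),
    "multi_substitution")
  expect_null(res)
})

test_that("collapse combines 3' variants of an edit and drops final-two-base hits", {
  b <- default_bundle()
  idx <- isomirome:::align_index(b)
  lrow <- idx$loci[idx$loci$strand == "+" & idx$loci$is_decoy == FALSE][1]
  ep <- lrow$edit_pos
  g <- idx$genome[["+"]]
  mat <- lrow$mature_seq
  L <- nchar(mat)

  edited <- mat; substr(edited, ep + 1L, ep + 1L) <- "G"
  # same edit, templated 3' extension of one base
  ext <- substr(g, lrow$sense_mature_start + 1L, lrow$sense_mature_end + 1L)
  substr(ext, ep + 1L, ep + 1L) <- "G"
  # edit in the last base only: no EDIT_AI key
  lastbase <- mat
  substr(lastbase, L, L) <- if (substr(mat, L, L) == "A") "G" else
    substr(mat, L, L)
  reads <- data.table::data.table(
    id = sprintf("r%d", 1:5),
    seq = c(edited, edited, ext, mat, mat),
    qual = strrep("?", nchar(c(edited, edited, ext, mat, mat))))
  ann <- annotate_sample(reads, b)$annotations
  keys <- collapse_isomirs(ann, "EDIT_AI")
  expect_equal(nrow(keys), 1L)
  expect_equal(keys$count, 3L)   # both 3' forms combined
  expect_equal(keys$position, ep)
  expect_equal(keys$five_prime_shift, 0L)

  # a read whose only substitution is within its final two bases
  if (substr(mat, L, L) == "A") {
    ann2 <- annotate_sample(data.table::data.table(
      id = "x", seq = lastbase, qual = strrep("?", L)), b)$annotations
    expect_equal(nrow(collapse_isomirs(ann2, "EDIT_AI")), 0L)
  }
})

test_that("one read can contribute to both a 5' key and an NTA key", {
  b <- default_bundle()
  idx <- isomirome:::align_index(b)
  lrow <- idx$loci[idx$loci$strand == "+" & idx$loci$is_decoy == FALSE][1]
  g <- idx$genome[["+"]]
  # 2 nt 5' extension into the precursor plus a 1 nt A tail
  ext5 <- substr(g, lrow$sense_mature_start - 1L, lrow$sense_mature_end)
  read <- paste0(ext5, "A")
  ann <- annotate_sample(data.table::data.table(
    id = "r", seq = read, qual = strrep("?", nchar(read))), b)$annotations
  expect_equal(ann$status, "ok")
  expect_equal(ann$five_prime_shift, -2L)
  expect_equal(ann$nta, "A")
  fp <- collapse_isomirs(ann, "FIVE_PRIME")
  na <- collapse_isomirs(ann, "NTA_A")
  expect_equal(fp$five_prime_shift, -2L)
  expect_equal(fp$count, 1L)
  expect_equal(na$position, 1L)
  expect_equal(na$count, 1L)
})

test_that("isomiR names follow the nomenclature and round-trip", {
  expect_equal(name_isomir(list(mirna = "hsa-miR-200b-3p", kind = "EDIT_AI",
                                five_prime_shift = 0L, position = 4L,
                                base = NA)),
               "hsa-miR-200b-3p 0 4 AI")
  expect_equal(name_isomir(list(mirna = "hsa-miR-140-3p",
                                kind = "FIVE_PRIME",
                                five_prime_shift = 1L, position = NA,
                                base = NA)),
               "hsa-miR-140-3p 1")
  expect_equal(name_isomir(list(mirna = "hsa-miR-99a-5p", kind = "NTA_A",
                                five_prime_shift = NA, position = 1L,
                                base = "A")),
               "hsa-miR-99a-5p 1A")

  # property: parse . name = identity over generated keys
  set.seed(1)
  keys <- data.table::data.table(
    mirna = sample(c("hsa-miR-99a-5p", "hsa-let-7d-3p", "sim-miR-3-5p"),
                   60, TRUE),
    kind = sample(c("EDIT_AI", "FIVE_PRIME", "NTA_A", "NTA_U", "NTA_C",
                    "NTA_G"), 60, TRUE))
  keys[, five_prime_shift := data.table::fifelse(
    kind %in% c("EDIT_AI", "FIVE_PRIME"), sample(-2:2, 60, TRUE),
    NA_integer_)]
  keys[, position := data.table::fifelse(
    kind == "EDIT_AI", sample(0:16, 60, TRUE),
    data.table::fifelse(kind == "FIVE_PRIME", NA_integer_,
                        sample(1:2, 60, TRUE)))]
  keys[, base := data.table::fifelse(grepl("NTA", kind),
                                     sub("NTA_", "", kind), NA_character_)]
  keys <- keys[!(kind == "FIVE_PRIME" & five_prime_shift == 0L)]
  nm <- name_isomir(keys)
  back <- parse_isomir_name(nm)
  expect_equal(back$mirna, keys$mirna)
  expect_equal(back$kind, keys$kind)
  expect_equal(back$position, keys$position)
  expect_equal(back$five_prime_shift, keys$five_prime_shift)
})

test_that("quantification: RPM definition, family totals, conservation", {
  expect_equal(rpm(10, 1e6), 10)
  expect_error(rpm(10, 0), "positive")
  b <- default_bundle()
  sim <- simulate_sample(b, flat_profile(b, edit = 0.15, ntaA = 0.1,
                                         fivep = 0.1),
                         5000L, ADAPTER_A, seed = 77L)
  ps <- process_sample(sim$reads, ADAPTER_A, b)
  q <- quantify_counts(ps$annotations)
  ok <- ps$annotations[ps$annotations$status == "ok"]
  expect_equal(sum(q$family$count), q$total_mapped)
  expect_equal(sum(q$family$rpm), 1e6)
  # family >= any constituent key count
  for (k in c("EDIT_AI", "FIVE_PRIME", "NTA_A")) {
    keys <- collapse_isomirs(ps$annotations, k)
    m <- merge(keys, q$family, by = "mirna", suffixes = c("_key", "_fam"))
    expect_true(all(m$count_key <= m$count_fam))
  }
  expect_error(quantify_counts(ok[0]), "zero")
})

test_that("error-free annotation recovers every planted event exactly", {
  b <- default_bundle()
  pr <- flat_profile(b, edit = 0.12, fivep = 0.1, ntaA = 0.1, ntaU = 0.08)
  sim <- simulate_sample(b, pr, 6000L, ADAPTER_A, seed = 5L)
  ps <- process_sample(sim$reads, ADAPTER_A, b)
  ann <- ps$annotations
  expect_equal(sum(ann$count), 6000L)
  expect_true(all(ann$status == "ok"))
  truth_n <- sim$truth[, .N, by = .(mirna, event)]
  # edits
  ed <- collapse_isomirs(ann, "EDIT_AI")
  tn <- truth_n[event == "edit"]
  m <- merge(ed, tn, by = "mirna", all = TRUE)
  expect_equal(m$count, m$N)
  # 5' shifts
  fp <- collapse_isomirs(ann, "FIVE_PRIME")
  tn5 <- truth_n[event == "five_prime"]
  m5 <- merge(fp, tn5, by = "mirna", all = TRUE)
  expect_equal(m5$count, m5$N)
  # A and U tails (1 nt and 2 nt keys together)
  for (ev in c("nta_A", "nta_U")) {
    kk <- collapse_isomirs(ann, paste0("NTA_", sub("nta_", "", ev)))
    tt <- truth_n[event == ev]
    agg <- kk[, .(count = sum(count)), by = mirna]
    ma <- merge(agg, tt, by = "mirna", all = TRUE)
    expect_equal(ma$count, ma$N)
  }
})
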