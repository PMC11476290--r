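# IsomiR annotation: align trimmed reads to the reference, decompose each
# read into 5' shift, templated 3' end, non-templated 3' additions (NTA)
# and substitutions, and collapse reads into the four type-specific
# isomiR identities.
#
# All per-read offsets live on the mature-miRNA sense strand: the genome
# is searched both as-is and reverse-complemented, and a minus-strand
# locus is annotated against the reverse-complemented ("sense") genome,
# so downstream code never sees strand arithmetic.
#
# Alignment strategy: every read start position with at most one internal
# mismatch and at most 3 nt of 3' overhang must contain an exact seed
# k-mer among two disjoint seeds drawn from the first 2k read bases
# (pigeonhole over one mismatch). Seed hits against a precomputed k-mer
# position index of the toy genome are then verified by direct string
# comparison, which simultaneously yields the annotation. k = 8 for reads
# of >= 19 nt, k = 6 for 15-18 nt.

ISOMIR_KINDS <- c("FIVE_PRIME", "NTA_A", "NTA_U", "NTA_C", "NTA_G", "EDIT_AI")

# ---- alignment index -------------------------------------------------------

build_kmer_index <- function(g, k) {
  n <- nchar(g)
  starts <- seq_len(n - k + 1L)
  kmers <- substring(g, starts, starts + k - 1L)
  list2env(split(starts, kmers), envir = new.env(parent = emptyenv()))
}

align_index <- function(bundle) {
  cache <- bundle_cache(bundle)
  if (is.null(cache$index)) {
    g_fwd <- bundle$genome
    g_rev <- revcomp(g_fwd)
    glen <- nchar(g_fwd)
    loci <- data.table::copy(bundle$loci)
    # Sense coordinates: offsets into the strand genome (fwd string for
    # '+' loci, revcomp string for '-').
    loci[, sense_mature_start := ifelse(strand == "+", mature_start,
                                        glen - mature_end)]
    loci[, sense_mature_end := ifelse(strand == "+", mature_end,
                                      glen - mature_start)]
    loci[, sense_hairpin_start := ifelse(strand == "+", hairpin_start,
                                         glen - hairpin_end)]
    loci[, sense_hairpin_end := ifelse(strand == "+", hairpin_end,
                                       glen - hairpin_start)]
    cache$index <- list(
      genome = list("+" = g_fwd, "-" = g_rev),
      glen = glen,
      kmer = list(
        "+" = list("8" = build_kmer_index(g_fwd, 8L),
                   "6" = build_kmer_index(g_fwd, 6L)),
        "-" = list("8" = build_kmer_index(g_rev, 8L),
                   "6" = build_kmer_index(g_rev, 6L))),
      loci = loci
    )
  }
  cache$index
}

# Candidate starts (1-based) from two disjoint exact seeds.
seed_candidates <- function(seqs, k, idx) {
  offs <- c(0L, k)
  out <- vector("list", length(offs))
  for (j in seq_along(offs)) {
    off <- offs[j]
    kmers <- substr(seqs, off + 1L, off + k)
    pos <- mget(kmers, envir = idx, ifnotfound = list(integer(0)))
    nn <- lengths(pos)
    out[[j]] <- data.table::data.table(
      qi = rep(seq_along(seqs), nn),
      start = unlist(pos, use.names = FALSE) - off)
  }
  unique(data.table::rbindlist(out))
}

# Verify candidates of a single read length against one strand genome.
# Returns one row per retained hit with annotation-grade detail.
verify_candidates <- function(seqs, cand, g, L, max_mismatch, max_overhang) {
  glen <- nchar(g)
  cand <- cand[start >= 1L & start + L - 1L <= glen]
  if (nrow(cand) == 0L) return(NULL)
  refs <- substring(g, cand$start, cand$start + L - 1L)
  qm <- seq_matrix(seqs[cand$qi], L)
  rm_ <- seq_matrix(refs, L)
  neq <- qm != rm_
  total_mm <- rowSums(neq)
  last_match <- max.col(!neq, ties.method = "last")
  run <- L - last_match
  overhang <- pmin(run, max_overhang)
  internal <- total_mm - overhang
  keep <- internal <= max_mismatch & total_mm < L
  if (!any(keep)) return(NULL)
  kidx <- which(keep)
  # Substitution detail (at most one internal mismatch per retained hit).
  sub_pos <- rep(NA_integer_, length(kidx))
  sub_ref <- rep(NA_character_, length(kidx))
  sub_alt <- rep(NA_character_, length(kidx))
  has_sub <- internal[kidx] > 0L
  for (ii in which(has_sub)) {
    r <- kidx[ii]
    p <- which(neq[r, seq_len(L - overhang[r])])
    sub_pos[ii] <- p[1] - 1L          # 0-based read offset
    sub_ref[ii] <- rm_[r, p[1]]
    sub_alt[ii] <- qm[r, p[1]]
  }
  data.table::data.table(
    qi = cand$qi[kidx],
    sense_start = cand$start[kidx] - 1L,   # 0-based
    mismatches = internal[kidx],
    overhang = overhang[kidx],
    sub_pos = sub_pos, sub_ref = sub_ref, sub_alt = sub_alt)
}

# All hits for a character vector of sequences; list parallel to seqs.
align_batch <- function(seqs, bundle, max_mismatch = 1L, max_overhang = 3L) {
  idx <- align_index(bundle)
  lens <- nchar(seqs)
  hits <- vector("list", 4L)
  hi <- 0L
  for (L in sort(unique(lens))) {
    sel <- which(lens == L)
    k <- if (L >= 19L) 8L else 6L
    for (std in c("+", "-")) {
      cand <- seed_candidates(seqs[sel], k, idx$kmer[[std]][[as.character(k)]])
      v <- verify_candidates(seqs[sel], cand, idx$genome[[std]], L,
                             max_mismatch, max_overhang)
      if (!is.null(v)) {
        v[, qi := sel[qi]]
        v[, strand := std]
        hi <- hi + 1L
        if (hi > length(hits)) hits <- c(hits, vector("list", length(hits)))
        hits[[hi]] <- v
      }
    }
  }
  if (hi == 0L) return(data.table::data.table())
  data.table::rbindlist(hits[seq_len(hi)])
}

# Attach locus assignments to a hit table (sense windows, same strand).
assign_locus <- function(hits, bundle, pad = 6L) {
  idx <- align_index(bundle)
  loci <- idx$loci
  hits[, mirna := NA_character_]
  for (std in c("+", "-")) {
    lo <- loci[strand == std]
    if (nrow(lo) == 0L) next
    o <- order(lo$sense_hairpin_start)
    ws <- lo$sense_hairpin_start[o] - pad
    we <- lo$sense_hairpin_end[o] + pad
    sel <- which(hits$strand == std)
    if (!length(sel)) next
    iv <- findInterval(hits$sense_start[sel], ws)
    ok <- iv >= 1L & hits$sense_start[sel] < we[pmax(iv, 1L)]
    hits[sel[ok], mirna := lo$mirna[o][iv[ok]]]
  }
  hits
}

#' Align one sequence to the reference genome
#'
#' Exhaustively reports genomic start positions at which the sequence (or
#' a prefix, allowing a 3' non-templated overhang of up to
#' `max_overhang` nt) matches with at most `max_mismatch` internal
#' mismatches. Hits are ranked by (mismatches, overhang). Positions that
#' fall within an annotated hairpin (with a small pad) carry the locus
#' name; other positions have `mirna = NA`.
#'
#' @param seq a DNA sequence of 15-30 nt.
#' @param bundle a `ReferenceBundle`.
#' @param max_mismatch maximum internal mismatches (default 1).
#' @param max_overhang maximum 3' overhang treated as non-templated
#'   (default 3).
#' @return data.table with columns `mirna`, `strand`, `start` (0-based
#'   position of the matched interval on the forward genome),
#'   `sense_start` (0-based position of the read 5' end on the strand
#'   genome), `mismatches`, `overhang`, ordered best-first. Zero rows if
#'   unaligned.
#' @export
align_read <- function(seq, bundle, max_mismatch = 1L, max_overhang = 3L) {
  L <- nchar(seq)
  if (L < 15L || L > 30L) stopf("align_read expects 15-30 nt (got %d)", L)
  hits <- align_batch(seq, bundle, max_mismatch, max_overhang)
  if (nrow(hits) == 0L) {
    return(data.table::data.table(mirna = character(0), strand = character(0),
                                  start = integer(0), sense_start = integer(0),
                                  mismatches = integer(0), overhang = integer(0)))
  }
  hits <- assign_locus(hits, bundle)
  glen <- nchar(bundle$genome)
  hits[, start := ifelse(strand == "+", sense_start,
                         glen - (sense_start + L - overhang))]
  data.table::setorder(hits, mismatches, overhang, sense_start)
  hits[, .(mirna, strand, start, sense_start, mismatches, overhang)]
}

# ---- per-read annotation ---------------------------------------------------

# Core decomposition of one aligned sequence against one locus.
annotate_at <- function(seq, locus_row, sense_start, genome_sense,
                        max_overhang = 3L) {
  L <- nchar(seq)
  ref <- substr(genome_sense, sense_start + 1L, sense_start + L)
  q <- strsplit(seq, "", fixed = TRUE)[[1]]
  r <- strsplit(ref, "", fixed = TRUE)[[1]]
  neq <- q != r
  if (all(neq)) return(list(discard = "unaligned"))
  last_match <- max(which(!neq))
  overhang <- min(L - last_match, max_overhang)
  internal <- which(neq[seq_len(L - overhang)])
  if (length(internal) > 1L) return(list(discard = "multi_substitution"))
  shift5 <- sense_start - locus_row$sense_mature_start
  shift3 <- (sense_start + L - overhang) - locus_row$sense_mature_end
  if (abs(shift3) > 2L) return(list(discard = "three_prime_distance"))
  list(
    mirna = locus_row$mirna,
    five_prime_shift = as.integer(shift5),
    three_prime_shift = as.integer(shift3),
    nta = if (overhang > 0L) substr(seq, L - overhang + 1L, L) else "",
    sub_pos = if (length(internal)) internal[1] - 1L else NA_integer_,
    sub_ref = if (length(internal)) r[internal[1]] else NA_character_,
    sub_alt = if (length(internal)) q[internal[1]] else NA_character_,
    n_sub = length(internal),
    discard = NA_character_
  )
}

#' Annotate one aligned read against a miRNA locus
#'
#' Decomposes a read into its 5' shift (positive = trimmed relative to
#' the canonical 5' end, negative = extension into the precursor), its
#' templated 3' end, a non-templated 3' tail (the maximal 3' suffix that
#' does not match the genomic continuation, capped at 3 nt), and internal
#' substitutions. Reads with two or more substitutions, or whose
#' templated 3' end lies more than 2 nt from the canonical end, are
#' discarded.
#'
#' @param seq the read sequence (trimmed insert).
#' @param mirna locus name the read was aligned to.
#' @param sense_start 0-based start of the read on the strand genome, as
#'   reported by [align_read()]'s `sense_start`.
#' @param bundle a `ReferenceBundle`.
#' @return a list (`mirna`, `five_prime_shift`, `three_prime_shift`,
#'   `nta`, `sub_pos`, `sub_ref`, `sub_alt`, `n_sub`) or `NULL` when
#'   discarded (the reason is messaged; batched annotation counts every
#'   discard reason in its audit).
#' @export
annotate_read <- function(seq, mirna, sense_start, bundle) {
  idx <- align_index(bundle)
  li <- which(idx$loci[["mirna"]] == mirna)
  locus_row <- idx$loci[li]
  if (nrow(locus_row) != 1L) stopf("unknown locus '%s'", mirna)
  ann <- annotate_at(seq, locus_row, sense_start,
                     idx$genome[[locus_row$strand]])
  if (!is.na(ann$discard)) {
    message(sprintf("read discarded: %s", ann$discard))
    return(NULL)
  }
  ann$discard <- NULL
  ann
}

# ---- batched, memoized annotation -----------------------------------------

# Annotate unique sequences with memoization across samples (sequences
# recur heavily between samples of one experiment). Returns a data.table
# keyed by seq with the best-hit annotation and hit-multiplicity columns.
annotate_sequences <- function(seqs, bundle) {
  cache <- bundle_cache(bundle)
  if (is.null(cache$memo)) cache$memo <- new.env(parent = emptyenv())
  memo <- cache$memo
  known <- vapply(seqs, function(s) !is.null(memo[[s]]), logical(1),
                  USE.NAMES = FALSE)
  new_seqs <- seqs[!known]
  if (length(new_seqs)) {
    lens <- nchar(new_seqs)
    alignable <- lens >= 15L & lens <= 30L
    rows <- annotate_new_sequences(new_seqs[alignable], bundle)
    for (i in seq_along(rows)) memo[[new_seqs[alignable][i]]] <- rows[[i]]
    for (s in new_seqs[!alignable]) {
      memo[[s]] <- list(status = "unaligned", mirna = NA_character_,
                        five_prime_shift = NA_integer_,
                        three_prime_shift = NA_integer_, nta = NA_character_,
                        sub_pos = NA_integer_, sub_ref = NA_character_,
                        sub_alt = NA_character_, n_sub = NA_integer_,
                        mismatches = NA_integer_, overhang = NA_integer_,
                        n_best = 0L, n_best_other = 0L)
    }
  }
  recs <- lapply(seqs, function(s) memo[[s]])
  out <- data.table::rbindlist(recs)
  out[, seq := seqs]
  out
}

annotate_new_sequences <- function(seqs, bundle) {
  n <- length(seqs)
  if (n == 0L) return(list())
  idx <- align_index(bundle)
  hits <- align_batch(seqs, bundle)
  rows <- vector("list", n)
  unaligned_row <- list(status = "unaligned", mirna = NA_character_,
                        five_prime_shift = NA_integer_,
                        three_prime_shift = NA_integer_, nta = NA_character_,
                        sub_pos = NA_integer_, sub_ref = NA_character_,
                        sub_alt = NA_character_, n_sub = NA_integer_,
                        mismatches = NA_integer_, overhang = NA_integer_,
                        n_best = 0L, n_best_other = 0L)
  for (i in seq_len(n)) rows[[i]] <- unaligned_row
  if (nrow(hits) == 0L) return(rows)
  hits <- assign_locus(hits, bundle)
  data.table::setorder(hits, qi, mismatches, overhang)
  hit_split <- split(hits, by = "qi", keep.by = TRUE)
  qi_of <- as.integer(names(hit_split))
  loci <- idx$loci
  for (j in seq_along(hit_split)) {
    h <- hit_split[[j]]
    i <- qi_of[j]
    best_mm <- h$mismatches[1]; best_ov <- h$overhang[1]
    is_best <- h$mismatches == best_mm & h$overhang == best_ov
    n_best <- sum(is_best)
    # Among rank-equal hits, prefer one inside an annotated locus; true
    # multi-locus or locus-vs-genome ties are resolved later by the
    # cross-mapping filter.
    cand <- h[is_best]
    pick <- cand[!is.na(mirna)][1]
    if (is.na(pick$mirna)) {
      rows[[i]] <- modifyList(unaligned_row,
                              list(status = "off_locus",
                                   mismatches = best_mm, overhang = best_ov,
                                   n_best = n_best, n_best_other = n_best))
      next
    }
    locus_row <- loci[loci$mirna == pick$mirna]
    ann <- annotate_at(seqs[i], locus_row, pick$sense_start,
                       idx$genome[[pick$strand]])
    n_best_other <- sum(is_best) - sum(cand$mirna %in% pick$mirna, na.rm = TRUE)
    if (!is.na(ann$discard)) {
      rows[[i]] <- modifyList(unaligned_row,
                              list(status = ann$discard, mirna = pick$mirna,
                                   mismatches = best_mm, overhang = best_ov,
                                   n_best = n_best, n_best_other = n_best_other))
    } else {
      ann$discard <- NULL
      rows[[i]] <- c(list(status = "ok"), ann,
                     list(mismatches = best_mm, overhang = best_ov,
                          n_best = n_best, n_best_other = n_best_other))
    }
  }
  rows
}

#' Annotate all reads of one sample
#'
#' Collapses reads to unique sequences, aligns and annotates each unique
#' sequence (memoized across samples sharing the reference), and returns
#' the per-sequence annotation table with read counts, plus an audit of
#' discard reasons.
#'
#' @param reads data.table with a `seq` column (trimmed, quality-passed
#'   inserts).
#' @param bundle a `ReferenceBundle`.
#' @return list with `annotations` (data.table, one row per unique
#'   sequence: annotation fields, `count`, `status`) and `audit` (named
#'   integer vector of read counts per status).
#' @export
annotate_sample <- function(reads, bundle) {
  tab <- data.table::as.data.table(reads)[, .(count = .N), by = seq]
  ann <- annotate_sequences(tab$seq, bundle)
  ann[, count := tab$count]
  audit <- tapply(ann$count, ann$status, sum)
  list(annotations = ann[], audit = audit)
}

# ---- collapsing and nomenclature ------------------------------------------

#' Collapse annotated reads into type-specific isomiR identities
#'
#' Reads of one sample are combined into isomiR keys according to the
#' positions that matter for each type: 5' isomiRs key on (miRNA,
#' 5' shift), ignoring all 3' variation; NTA isomiRs key on (miRNA, tail
#' base, tail position 1 or 2 relative to the canonical 3' end), ignoring
#' 5' variation; A-to-I edited isomiRs key on (miRNA, 5' shift, edited
#' position in isomiR coordinates), ignoring the final two bases of each
#' read, so a read whose only substitution lies in its final two bases is
#' combined with its unsubstituted counterpart and never seeds an edit
#' key.
#'
#' @param annotations annotation table from [annotate_sample()].
#' @param kind one of `"FIVE_PRIME"`, `"NTA_A"`, `"NTA_U"`, `"NTA_C"`,
#'   `"NTA_G"`, `"EDIT_AI"`.
#' @return data.table of keys with columns `mirna`, `kind`,
#'   `five_prime_shift`, `position`, `base`, `name`, `count` (columns
#'   irrelevant to the kind are `NA`).
#' @export
collapse_isomirs <- function(annotations, kind) {
  kind <- match.arg(kind, ISOMIR_KINDS)
  a <- data.table::as.data.table(annotations)[status == "ok"]
  # When a combined multi-sample table is passed, keys stay per sample.
  extra_by <- intersect("sample_id", names(a))
  a[, seq_len_ := nchar(seq)]
  # A single substitution confined to the final two read bases is treated
  # as 3' noise: the read behaves as its unsubstituted counterpart.
  a[, sub_internal := n_sub > 0L & sub_pos < seq_len_ - 2L]
  empty <- data.table::data.table(
    mirna = character(0), kind = character(0),
    five_prime_shift = integer(0), position = integer(0), base = character(0),
    name = character(0), count = integer(0))
  if (length(extra_by)) {
    empty <- cbind(data.table::data.table(sample_id = character(0)), empty)
  }
  if (kind == "EDIT_AI") {
    e <- a[sub_internal == TRUE & sub_ref == "A" & sub_alt == "G"]
    if (nrow(e) == 0L) return(empty)
    e[, position := sub_pos]
    out <- e[, .(count = sum(count)),
             by = c(extra_by, "mirna", "five_prime_shift", "position")]
    out[, `:=`(kind = "EDIT_AI", base = NA_character_)]
  } else if (kind == "FIVE_PRIME") {
    f <- a[five_prime_shift != 0L & sub_internal == FALSE]
    if (nrow(f) == 0L) return(empty)
    out <- f[, .(count = sum(count)),
             by = c(extra_by, "mirna", "five_prime_shift")]
    out[, `:=`(kind = "FIVE_PRIME", position = NA_integer_,
               base = NA_character_)]
  } else {
    b_dna <- c(NTA_A = "A", NTA_U = "T", NTA_C = "C", NTA_G = "G")[[kind]]
    b_rna <- sub("T", "U", b_dna)
    nta_len <- nchar(a$nta)
    keep <- a$sub_internal == FALSE & nta_len >= 1L & nta_len <= 2L &
      a$nta == strrep(b_dna, nta_len)
    nt <- a[keep]
    if (nrow(nt) == 0L) return(empty)
    nt[, position := three_prime_shift + nchar(nta)]
    nt <- nt[position %in% c(1L, 2L)]
    if (nrow(nt) == 0L) return(empty)
    out <- nt[, .(count = sum(count)), by = c(extra_by, "mirna", "position")]
    out[, `:=`(kind = kind, five_prime_shift = NA_integer_, base = b_rna)]
  }
  out[, name := name_isomir(.SD), .SDcols = c("mirna", "kind",
                                              "five_prime_shift", "position",
                                              "base")]
  cols <- c(extra_by, "mirna", "kind", "five_prime_shift", "position",
            "base", "name", "count")
  out[, cols, with = FALSE]
}

#' Canonical isomiR name strings
#'
#' All names begin with the canonical miRNA name. 5' isomiRs append the
#' 5' shift; A-to-I edited isomiRs append the shift, the 0-based edited
#' position in isomiR coordinates, and `AI`; NTA isomiRs append the tail
#' position (1 or 2, relative to the canonical 3' end) fused to the tail
#' base letter (A/U/C/G).
#'
#' @param key data.frame/list with fields `mirna`, `kind`,
#'   `five_prime_shift`, `position`, `base` (vectorized).
#' @return character vector of names, e.g. `"mir-X 0 4 AI"`,
#'   `"mir-X 1"`, `"mir-X 1A"`.
#' @export
name_isomir <- function(key) {
  key <- as.list(key)
  n <- length(key$mirna)
  out <- character(n)
  ed <- key$kind == "EDIT_AI"
  fp <- key$kind == "FIVE_PRIME"
  nta <- !ed & !fp
  out[ed] <- paste(key$mirna[ed], key$five_prime_shift[ed],
                   key$position[ed], "AI")
  out[fp] <- paste(key$mirna[fp], key$five_prime_shift[fp])
  out[nta] <- paste0(key$mirna[nta], " ", key$position[nta], key$base[nta])
  out
}

#' Parse an isomiR name back into its key
#'
#' Inverse of [name_isomir()].
#'
#' @param name character vector of isomiR names.
#' @return data.table with columns `mirna`, `kind`, `five_prime_shift`,
#'   `position`, `base`.
#' @export
parse_isomir_name <- function(name) {
  parts <- strsplit(name, " ", fixed = TRUE)
  rows <- lapply(parts, function(p) {
    np <- length(p)
    if (np >= 4L && p[np] == "AI") {
      data.table::data.table(
        mirna = paste(p[seq_len(np - 3L)], collapse = " "),
        kind = "EDIT_AI",
        five_prime_shift = as.integer(p[np - 2L]),
        position = as.integer(p[np - 1L]), base = NA_character_)
    } else if (grepl("^[12][AUCG]$", p[np])) {
      base <- substr(p[np], 2L, 2L)
      data.table::data.table(
        mirna = paste(p[seq_len(np - 1L)], collapse = " "),
        kind = paste0("NTA_", base),
        five_prime_shift = NA_integer_,
        position = as.integer(substr(p[np], 1L, 1L)), base = base)
    } else {
      data.table::data.table(
        mirna = paste(p[seq_len(np - 1L)], collapse = " "),
        kind = "FIVE_PRIME",
        five_prime_shift = as.integer(p[np]),
        position = NA_integer_, base = NA_character_)
    }
  })
  data.table::rbindlist(rows)
}

#' IsomiR and miRNA-family quantification
#'
#' Computes reads-per-million for keyed counts and the per-miRNA family
#' totals, where a family combines the canonical miRNA's reads with those
#' of all of its isomiRs (every non-discarded read assigned to the
#' locus).
#'
#' @param annotations annotation table of one sample
#'   ([annotate_sample()]).
#' @return list with `family` (data.table `mirna`, `count`, `rpm`) and
#'   `total_mapped` (total miRNA-mapped reads in the sample). A sample
#'   with zero mapped reads is rejected.
#' @export
quantify_counts <- function(annotations) {
  a <- data.table::as.data.table(annotations)[status == "ok"]
  total <- sum(a$count)
  if (total == 0L) stopf("sample has zero miRNA-mapped reads")
  fam <- a[, .(count = sum(count)), by = mirna]
  fam[, rpm := count * 1e6 / total]
  list(family = fam[], total_mapped = total)
}

#' Reads-per-million
#'
#' @param count raw read count(s).
#' @param total_mapped total miRNA-mapped reads of the sample.
#' @return `count * 1e6 / total_mapped`.
#' @export
rpm <- function(count, total_mapped) {
  if (any(total_mapped <= 0)) stopf("total mapped reads must be positive")
  count * 1e6 / total_mapped
}
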