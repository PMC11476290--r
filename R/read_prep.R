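# Read preparation: Phred arithmetic, 3' adapter trimming, all-base
# quality filtering, and the per-sample coverage gate.

#' Per-base error probability implied by a Phred score
#'
#' @param q Phred score(s), non-negative.
#' @return `10^(-q/10)`, the probability that the base call is wrong.
#'   Phred 25 corresponds to 0.32% when rounded to two decimals as a
#'   percentage, the substitution-error floor used by the confidence
#'   filter.
#' @export
#' @examples
#' phred_error_rate(25)   # 0.0031623
phred_error_rate <- function(q) {
  if (any(q < 0)) stopf("Phred scores must be non-negative")
  10^(-q / 10)
}

#' Trim the 3' adapter from a single read
#'
#' Searches for the earliest occurrence of the adapter (anchored on its
#' first `anchor_len` bases, allowing one mismatch there to tolerate a
#' sequencing error at the junction) and removes it and everything 3' of
#' it; qualities are trimmed in lockstep.
#'
#' @param read list with elements `id`, `seq`, `qual` (Phred+33 string).
#' @param adapter non-empty adapter sequence.
#' @param min_len minimum insert length retained after trimming.
#' @param max_insert reads longer than this with no adapter hit are
#'   flagged untrimmed (kept when `keep_untrimmed`).
#' @param keep_untrimmed keep reads in which no adapter was found.
#' @return the trimmed read (with logical element `trimmed`), or `NULL`
#'   when the read is rejected; [trim_reads()] reports per-read rejection
#'   reasons.
#' @export
trim_adapter <- function(read, adapter, min_len = 15L, max_insert = 30L,
                         keep_untrimmed = TRUE) {
  res <- trim_reads(data.table::data.table(id = read$id, seq = read$seq,
                                           qual = read$qual),
                    adapter, min_len = min_len, max_insert = max_insert,
                    keep_untrimmed = keep_untrimmed)
  if (!res$keep[1]) return(NULL)
  list(id = res$id[1], seq = res$seq[1], qual = res$qual[1],
       trimmed = res$trimmed[1])
}

#' Vectorized 3' adapter trimming
#'
#' @param reads data.table/data.frame with columns `id`, `seq`, `qual`.
#' @inheritParams trim_adapter
#' @param anchor_len number of leading adapter bases used as the search
#'   anchor (at most one mismatch is tolerated within the anchor).
#' @return data.table with columns `id`, `seq`, `qual`, `trimmed`,
#'   `keep`, `reason` (`"ok"`, `"untrimmed"`, `"empty_insert"`,
#'   `"short"`).
#' @export
trim_reads <- function(reads, adapter, min_len = 15L, max_insert = 30L,
                       keep_untrimmed = TRUE, anchor_len = 10L) {
  if (!nzchar(adapter)) stopf("adapter must be non-empty")
  reads <- data.table::as.data.table(reads)
  n <- nrow(reads)
  if (n == 0L) {
    return(data.table::data.table(id = character(0), seq = character(0),
                                  qual = character(0), trimmed = logical(0),
                                  keep = logical(0), reason = character(0)))
  }
  alen <- min(anchor_len, nchar(adapter))
  anchor <- substr(adapter, 1L, alen)
  seqs <- reads$seq
  lens <- nchar(seqs)
  max_s <- max(lens) - alen + 1L

  # Pass 1: earliest exact anchor occurrence.
  pos <- rep(NA_integer_, n)
  if (max_s >= 1L) {
    for (s in seq_len(max_s)) {
      unset <- is.na(pos)
      if (!any(unset)) break
      hit <- unset & (substr(seqs, s, s + alen - 1L) == anchor)
      pos[hit] <- s
    }
  }

  # Pass 2: one mismatch within the anchor, via exact half-anchors.
  miss <- which(is.na(pos) & lens >= alen)
  if (length(miss)) {
    half <- alen %/% 2L
    a1 <- substr(anchor, 1L, half)
    a2 <- substr(anchor, half + 1L, alen)
    for (i in miss) {
      L <- lens[i]
      for (s in seq_len(L - alen + 1L)) {
        cand <- substr(seqs[i], s, s + half - 1L) == a1 ||
          substr(seqs[i], s + half, s + alen - 1L) == a2
        if (cand) {
          mm <- sum(strsplit(substr(seqs[i], s, s + alen - 1L), "")[[1]] !=
                      strsplit(anchor, "")[[1]])
          if (mm <= 1L) { pos[i] <- s; break }
        }
      }
    }
  }

  trimmed <- !is.na(pos)
  ins_len <- ifelse(trimmed, pos - 1L, lens)
  out <- data.table::data.table(
    id = reads$id,
    seq = substr(seqs, 1L, ins_len),
    qual = substr(reads$qual, 1L, ins_len),
    trimmed = trimmed
  )
  reason <- rep("ok", n)
  reason[!trimmed & lens > max_insert] <- "untrimmed"
  reason[trimmed & ins_len == 0L] <- "empty_insert"
  reason[reason == "ok" & ins_len < min_len] <- "short"
  keep <- reason == "ok" | (reason == "untrimmed" & keep_untrimmed)
  out[, keep := keep]
  out[, reason := reason]
  out[]
}

#' All-bases quality filter
#'
#' A read passes only if every base has Phred quality at or above
#' `min_q`; a single sub-threshold base removes the read.
#'
#' @param read list with a `qual` element (Phred+33 string), or a bare
#'   quality string.
#' @param min_q minimum acceptable Phred score (default 25).
#' @return logical scalar.
#' @export
quality_filter <- function(read, min_q = 25L) {
  qual <- if (is.list(read)) read$qual else read
  quality_pass(qual, min_q)[1]
}

#' @rdname quality_filter
#' @param qual character vector of Phred+33 quality strings.
#' @return `quality_pass`: logical vector, one entry per read.
#' @export
quality_pass <- function(qual, min_q = 25L) {
  min_phred(qual) >= min_q
}

#' Sample coverage gate
#'
#' @param n_reads total read count of a sample.
#' @param threshold minimum read count; samples below it are excluded
#'   from all downstream analyses. The default mirrors deep production
#'   libraries; synthetic runs pass a scaled value.
#' @return TRUE iff `n_reads >= threshold`.
#' @export
coverage_filter <- function(n_reads, threshold = 5e6) {
  if (any(n_reads < 0)) stopf("read counts must be non-negative")
  n_reads >= threshold
}

#' Read a 4-line FASTQ file
#'
#' @param path FASTQ path (Phred+33).
#' @return data.table with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  data.table::data.table(
    id = names(x),
    seq = as.character(x),
    qual = as.character(S4Vectors::mcols(x)$qualities)
  )
}

#' Write reads to a 4-line FASTQ file
#'
#' @param reads data.table with columns `id`, `seq`, `qual`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$id
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qual))
  invisible(path)
}
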