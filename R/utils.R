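# Internal helpers shared across modules.

# Session-scoped caches (alignment seed indexes and per-sequence annotation
# memos), keyed by a bundle fingerprint. Never serialized with results.
.isomirome_cache <- new.env(parent = emptyenv())

`%||%` <- function(a, b) if (is.null(a)) b else a

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse-complement DNA strings
#'
#' @param x character vector of DNA sequences (alphabet ACGT).
#' @return character vector of reverse complements.
#' @keywords internal
revcomp <- function(x) {
  vapply(x, function(s) {
    if (nchar(s) == 0L) return("")
    intToUtf8(rev(utf8ToInt(chartr("ACGT", "TGCA", s))))
  }, character(1), USE.NAMES = FALSE)
}

clamp01 <- function(x) pmin(1, pmax(0, x))

rand_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# Split equal-length strings into a character matrix (rows = strings).
seq_matrix <- function(x, len) {
  if (length(x) == 0L) return(matrix(character(0), 0, len))
  matrix(unlist(strsplit(x, "", fixed = TRUE), use.names = FALSE),
         nrow = length(x), ncol = len, byrow = TRUE)
}

# Minimum Phred score per quality string (Phred+33). Vectorized via the
# unique values, which collapses the common case of few distinct strings.
min_phred <- function(qual) {
  uq <- unique(qual)
  mins <- vapply(uq, function(s) {
    if (nchar(s) == 0L) return(Inf)
    min(utf8ToInt(s)) - 33
  }, numeric(1))
  unname(mins[match(qual, uq)])
}

phred_char <- function(q) intToUtf8(q + 33L)

# Deterministic sub-seeds below 2^31, derived from a master seed.
derive_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

# Fingerprint used to key session caches for a reference bundle.
bundle_uid <- function(genome, loci_names) {
  n <- nchar(genome)
  paste(n, substr(genome, 1L, 48L), substr(genome, max(1L, n - 47L), n),
        paste(loci_names, collapse = "|"), sep = ":")
}

bundle_cache <- function(bundle) {
  uid <- bundle$uid
  if (is.null(.isomirome_cache[[uid]])) {
    .isomirome_cache[[uid]] <- new.env(parent = emptyenv())
  }
  .isomirome_cache[[uid]]
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
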