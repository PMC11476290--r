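# Synthetic reference: a single-contig toy genome carrying miRNA hairpin
# loci (with mature-miRNA coordinates and a designated A-to-I editing site),
# a tRNA region, decoy copies of one mature sequence, and a variant
# blacklist. All genomic coordinates are 0-based half-open on the forward
# strand; every per-locus offset used downstream is expressed on the
# mature-miRNA sense strand.

#' Configuration for the synthetic reference genome
#'
#' Defines the layout of the toy genome that stands in for a real genome
#' assembly plus miRNA annotation: how many hairpin loci to plant, the
#' mature length, where A-to-I editing sites sit within each mature
#' sequence, which locus is duplicated elsewhere in the genome (a decoy
#' that must be removed by the cross-mapping filter), and which edit site
#' is blacklisted as a known variant.
#'
#' @param n_loci number of miRNA hairpin loci (>= 8).
#' @param mature_len length of each mature miRNA in nt.
#' @param hairpin_pad nt of precursor flanking the mature sequence on each
#'   side; the hairpin interval is the mature interval plus this pad.
#' @param genome_len total genome length in nt.
#' @param edit_positions integer vector (recycled over loci) giving the
#'   0-based position of the editable adenosine within each mature
#'   sequence. Positions 1-7 lie in the seed region.
#' @param adjacent_u logical vector (recycled) - whether the base 5' of the
#'   edit site is forced to U (the preference of ADAR-family enzymes).
#' @param minus_strand_loci indices of loci annotated on the minus strand.
#' @param decoy_locus index of the locus whose mature sequence (plus 3 nt
#'   of flank) is copied elsewhere; `NA` disables the decoy.
#' @param decoy_copies total number of genomic copies of the decoy mature
#'   sequence (>= 2 when a decoy locus is set).
#' @param blacklist_locus index of the locus whose edit site is entered in
#'   the variant blacklist; `NA` disables it.
#' @param n_trna number of tRNA-like regions.
#' @param trna_len length of each tRNA region.
#' @return a list of class `reference_config`.
#' @export
reference_config <- function(n_loci = 12L,
                             mature_len = 22L,
                             hairpin_pad = 20L,
                             genome_len = 50000L,
                             edit_positions = c(4L, 2L, 7L, 5L, 3L, 6L,
                                                1L, 9L, 10L, 16L, 8L, 12L),
                             adjacent_u = c(rep(TRUE, 9L), FALSE, TRUE, FALSE),
                             minus_strand_loci = 4L,
                             decoy_locus = NULL,
                             decoy_copies = 2L,
                             blacklist_locus = NULL,
                             n_trna = 1L,
                             trna_len = 75L) {
  if (n_loci < 8L) stopf("at least 8 miRNA loci are required (got %d)", n_loci)
  if (is.null(decoy_locus)) decoy_locus <- n_loci
  if (is.null(blacklist_locus)) blacklist_locus <- n_loci - 1L
  cfg <- list(
    n_loci = as.integer(n_loci),
    mature_len = as.integer(mature_len),
    hairpin_pad = as.integer(hairpin_pad),
    genome_len = as.integer(genome_len),
    edit_positions = rep_len(as.integer(edit_positions), n_loci),
    adjacent_u = rep_len(adjacent_u, n_loci),
    minus_strand_loci = as.integer(minus_strand_loci),
    decoy_locus = as.integer(decoy_locus),
    decoy_copies = as.integer(decoy_copies),
    blacklist_locus = as.integer(blacklist_locus),
    n_trna = as.integer(n_trna),
    trna_len = as.integer(trna_len)
  )
  class(cfg) <- "reference_config"
  cfg
}

#' Build a synthetic reference bundle
#'
#' Generates the toy genome and plants the configured miRNA hairpins,
#' tRNA region(s) and decoy copies. Mature sequences are guaranteed to be
#' unique in the genome (on either strand) except for the designated decoy,
#' whose sequence occurs at exactly `decoy_copies` genomic sites. Each
#' locus carries a designated editable adenosine; at least one site has a
#' 5'-adjacent U by default.
#'
#' @param config a [reference_config()].
#' @param seed integer seed; the bundle is deterministic given the seed.
#' @return an object of class `ReferenceBundle`: a list with elements
#'   `genome` (character scalar), `loci` (data.table with mirna, strand,
#'   genomic hairpin/mature intervals, hairpin and mature sequences in
#'   sense orientation, and the edit site), `trna_regions`,
#'   `decoy_regions`, `blacklist` and `config`.
#' @export
make_reference <- function(config = reference_config(), seed = 1L) {
  stopifnot(inherits(config, "reference_config"))
  set.seed(seed)
  n <- config$n_loci
  glen <- config$genome_len
  mlen <- config$mature_len
  pad <- config$hairpin_pad

  genome <- rand_dna(glen)

  # Evenly spaced, jittered slots for hairpins, tRNAs and decoy copies.
  n_slots <- n + config$n_trna + max(0L, config$decoy_copies - 1L)
  slot_span <- (glen - 200L) %/% n_slots
  hp_len <- mlen + 2L * pad
  w_max <- max(hp_len, config$trna_len, mlen + 6L)
  if (slot_span <= w_max + 20L) {
    stopf("genome of %d nt is too short for %d feature slots", glen, n_slots)
  }
  starts <- 100L + (seq_len(n_slots) - 1L) * slot_span +
    sample.int(slot_span - w_max - 10L, n_slots, replace = TRUE)
  check_no_overlap(starts, w_max, n_slots)

  strand <- rep("+", n)
  strand[config$minus_strand_loci] <- "-"

  loci_rows <- vector("list", n)
  for (i in seq_len(n)) {
    mature <- make_mature_seq(mlen, config$edit_positions[i], config$adjacent_u[i])
    m_start <- starts[i] + pad              # 0-based
    m_end <- m_start + mlen
    planted <- if (strand[i] == "+") mature else revcomp(mature)
    substr(genome, m_start + 1L, m_end) <- planted
    # The two bases templated 3' of the mature end are fixed to C/G
    # (alternating order across loci) so that A/U non-templated tails are
    # never coincidentally templated and C/G tails are each detectable at
    # half the loci.
    cont <- if (i %% 2L == 1L) "CG" else "GC"
    if (strand[i] == "+") {
      substr(genome, m_end + 1L, m_end + 2L) <- cont
    } else {
      substr(genome, m_start - 1L, m_start) <- revcomp(cont)
    }
    loci_rows[[i]] <- data.table::data.table(
      mirna = sprintf("sim-miR-%d-5p", i),
      contig = "chrS",
      strand = strand[i],
      hairpin_start = starts[i], hairpin_end = starts[i] + hp_len,
      mature_start = m_start, mature_end = m_end,
      edit_pos = config$edit_positions[i],
      is_decoy = identical(i, config$decoy_locus)
    )
  }
  loci <- data.table::rbindlist(loci_rows)

  # tRNA regions.
  trna <- data.table::data.table(start = integer(0), end = integer(0),
                                 strand = character(0))
  for (j in seq_len(config$n_trna)) {
    s <- starts[n + j]
    substr(genome, s + 1L, s + config$trna_len) <- rand_dna(config$trna_len)
    trna <- rbind(trna, data.table::data.table(
      start = s, end = s + config$trna_len, strand = "+"))
  }

  # Decoy copies: duplicate the decoy mature sequence (plus 3 nt flanks)
  # at additional genomic sites.
  decoy_regions <- data.table::data.table(start = integer(0), end = integer(0))
  if (!is.na(config$decoy_locus) && config$decoy_copies >= 2L) {
    dl <- loci[config$decoy_locus]
    frag <- substr(genome, dl$mature_start + 1L - 3L, dl$mature_end + 3L)
    for (k in seq_len(config$decoy_copies - 1L)) {
      s <- starts[n + config$n_trna + k]
      substr(genome, s + 1L, s + nchar(frag)) <- frag
      decoy_regions <- rbind(decoy_regions, data.table::data.table(
        start = s, end = s + nchar(frag)))
    }
  }

  # Sense sequences are read back from the final genome so that decoy /
  # tRNA planting can never silently desynchronize annotation and genome.
  loci[, hairpin_seq := sense_slice(genome, hairpin_start, hairpin_end, strand)]
  loci[, mature_seq := sense_slice(genome, mature_start, mature_end, strand)]

  # Uniqueness: regenerate a colliding mature sequence is not attempted;
  # with a random 50 kb genome a 22-mer collision is vanishingly rare, so
  # a collision is treated as a configuration error.
  occ <- vapply(seq_len(n), function(i)
    count_occurrences(genome, loci$mature_seq[i]), integer(1))
  expected <- ifelse(loci$is_decoy, config$decoy_copies, 1L)
  if (any(occ != expected)) {
    bad <- which(occ != expected)[1]
    stopf("mature sequence of %s occurs %d times in the genome (expected %d)",
          loci$mirna[bad], occ[bad], expected[bad])
  }

  blacklist <- data.table::data.table(mirna = character(0), offset = integer(0),
                                      alt = character(0))
  if (!is.na(config$blacklist_locus)) {
    bl <- loci[config$blacklist_locus]
    blacklist <- data.table::data.table(
      mirna = bl$mirna, offset = bl$edit_pos, alt = "G")
  }

  bundle <- list(genome = genome, loci = loci, trna_regions = trna,
                 decoy_regions = decoy_regions, blacklist = blacklist,
                 config = config,
                 uid = bundle_uid(genome, loci$mirna))
  class(bundle) <- "ReferenceBundle"
  validate_bundle(bundle)
  bundle
}

make_mature_seq <- function(mlen, edit_pos, adjacent_u) {
  s <- rand_dna(mlen)
  substr(s, edit_pos + 1L, edit_pos + 1L) <- "A"
  if (adjacent_u && edit_pos >= 1L) {
    substr(s, edit_pos, edit_pos) <- "T"
  }
  s
}

sense_slice <- function(genome, start0, end0, strand) {
  s <- substr(rep(genome, length(start0)), start0 + 1L, end0)
  ifelse(strand == "-", revcomp(s), s)
}

check_no_overlap <- function(starts, width, n) {
  o <- order(starts)
  s <- starts[o]
  bad <- which(s[-1] < s[-length(s)] + width)
  if (length(bad)) {
    stopf("requested intervals for features %d and %d overlap",
          o[bad[1]], o[bad[1] + 1L])
  }
  invisible(TRUE)
}

count_occurrences <- function(genome, pattern) {
  cnt <- function(g, p) {
    hits <- gregexpr(p, g, fixed = TRUE)[[1]]
    if (hits[1] == -1L) 0L else length(hits)
  }
  cnt(genome, pattern) + cnt(genome, revcomp(pattern))
}

validate_bundle <- function(bundle) {
  loci <- bundle$loci
  if (any(loci$mature_start < loci$hairpin_start |
          loci$mature_end > loci$hairpin_end)) {
    stopf("a mature interval extends outside its hairpin interval")
  }
  if (!all(strsplit(bundle$genome, "")[[1]] %in% DNA_BASES)) {
    stopf("genome contains characters outside {A,C,G,T}")
  }
  o <- order(loci$hairpin_start)
  hs <- loci$hairpin_start[o]; he <- loci$hairpin_end[o]
  if (any(hs[-1] < he[-length(he)])) {
    i <- which(hs[-1] < he[-length(he)])[1]
    stopf("hairpin intervals of %s and %s overlap",
          loci$mirna[o[i]], loci$mirna[o[i + 1L]])
  }
  invisible(bundle)
}

#' Construct a reference bundle from explicit components
#'
#' Assembles a `ReferenceBundle` from a caller-supplied genome and locus
#' table; used for handcrafted references in examples and tests. Sense
#' hairpin/mature sequences are derived from the genome.
#'
#' @param genome character scalar, the genome sequence (ACGT).
#' @param loci data.frame with columns mirna, strand, hairpin_start,
#'   hairpin_end, mature_start, mature_end and optionally edit_pos.
#' @param trna_regions,decoy_regions,blacklist optional tables as in
#'   [make_reference()].
#' @return a `ReferenceBundle`.
#' @export
new_reference_bundle <- function(genome, loci, trna_regions = NULL,
                                 decoy_regions = NULL, blacklist = NULL) {
  loci <- data.table::as.data.table(loci)
  if (is.null(loci$edit_pos)) loci[, edit_pos := NA_integer_]
  if (is.null(loci$is_decoy)) loci[, is_decoy := FALSE]
  if (is.null(loci$contig)) loci[, contig := "chrS"]
  loci[, hairpin_seq := sense_slice(genome, hairpin_start, hairpin_end, strand)]
  loci[, mature_seq := sense_slice(genome, mature_start, mature_end, strand)]
  bundle <- list(
    genome = genome, loci = loci,
    trna_regions = data.table::as.data.table(
      trna_regions %||% data.frame(start = integer(0), end = integer(0),
                                   strand = character(0))),
    decoy_regions = data.table::as.data.table(
      decoy_regions %||% data.frame(start = integer(0), end = integer(0))),
    blacklist = data.table::as.data.table(
      blacklist %||% data.frame(mirna = character(0), offset = integer(0),
                                alt = character(0))),
    config = NULL,
    uid = bundle_uid(genome, loci$mirna))
  class(bundle) <- "ReferenceBundle"
  validate_bundle(bundle)
  bundle
}

#' @export
print.ReferenceBundle <- function(x, ...) {
  cat(sprintf("ReferenceBundle: %d nt genome, %d miRNA loci, %d tRNA region(s), %d decoy region(s), %d blacklist entries\n",
              nchar(x$genome), nrow(x$loci), nrow(x$trna_regions),
              nrow(x$decoy_regions), nrow(x$blacklist)))
  invisible(x)
}

#' Write a reference bundle to plain-text files
#'
#' Writes the genome as FASTA, loci as a BED-like TSV (0-based, half-open,
#' with a strand column), and the tRNA/decoy/blacklist tables as TSVs.
#'
#' @param bundle a `ReferenceBundle`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_reference <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- Biostrings::DNAStringSet(bundle$genome)
  names(g) <- "chrS"
  Biostrings::writeXStringSet(g, file.path(dir, "genome.fa"))
  data.table::fwrite(bundle$loci[, .(mirna, contig, strand, hairpin_start,
                                     hairpin_end, mature_start, mature_end,
                                     edit_pos, is_decoy)],
                     file.path(dir, "loci.tsv"), sep = "\t")
  data.table::fwrite(bundle$trna_regions, file.path(dir, "trna.tsv"), sep = "\t")
  data.table::fwrite(bundle$decoy_regions, file.path(dir, "decoys.tsv"), sep = "\t")
  data.table::fwrite(bundle$blacklist, file.path(dir, "blacklist.tsv"), sep = "\t")
  invisible(dir)
}

#' Read a reference bundle written by [write_reference()]
#'
#' @param dir directory containing genome.fa and the annotation TSVs.
#' @return a `ReferenceBundle`.
#' @export
read_reference <- function(dir) {
  g <- Biostrings::readDNAStringSet(file.path(dir, "genome.fa"))
  genome <- as.character(g[[1]])
  loci <- data.table::fread(file.path(dir, "loci.tsv"))
  trna <- data.table::fread(file.path(dir, "trna.tsv"))
  decoys <- data.table::fread(file.path(dir, "decoys.tsv"))
  bl_path <- file.path(dir, "blacklist.tsv")
  blacklist <- if (file.exists(bl_path)) data.table::fread(bl_path) else NULL
  new_reference_bundle(genome, loci, trna_regions = trna,
                       decoy_regions = decoys, blacklist = blacklist)
}
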