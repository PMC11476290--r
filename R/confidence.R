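# Confidence filtering: decide which isomiRs are genuinely expressed and
# which are sequencing artifacts. Candidate isomiRs are screened against a
# variant blacklist, tested per sample against a plate-aware binomial
# sequencing-error model with Benjamini-Hochberg correction, required to
# reach 1 RPM and the error-test pass each in >= 10% of a group's
# samples, purged of cross-mapping sequences, and finally called
# high-confidence when expressed in at least one group in at least two
# cohorts.

SUBSTITUTION_FLOOR <- function() phred_error_rate(25)   # 0.32% printed
NTA_FIVEP_ERROR_RATE <- 0.02

#' Tally substitution evidence for the error model
#'
#' Counts, per read position and substitution type, how many reads mapped
#' to canonical sequences (no 5' shift, no non-templated tail, at most
#' one substitution) carry each mismatch, and how many cover the position
#' at all. Restricting the tally to canonical-like reads keeps the error
#' model from being fed by the isomiRs it will later judge.
#'
#' @param annotations annotation table of one sample
#'   ([annotate_sample()]).
#' @param bundle a `ReferenceBundle`.
#' @return data.table with columns `position` (0-based read offset),
#'   `type` (e.g. `"A>G"`), `matches`, `mismatches`.
#' @export
tally_errors <- function(annotations, bundle) {
  a <- data.table::as.data.table(annotations)[
    status == "ok" & five_prime_shift == 0L & nta == "" & n_sub <= 1L]
  if (nrow(a) == 0L) {
    return(data.table::data.table(position = integer(0), type = character(0),
                                  matches = integer(0), mismatches = integer(0)))
  }
  loci <- bundle$loci
  mseq <- stats::setNames(loci$mature_seq, loci$mirna)
  # Coverage of (position, reference base) by all tallied reads.
  a[, L := pmin(nchar(seq), nchar(mseq[mirna]))]
  cov <- a[, .(n = sum(count)), by = .(mirna, L)]
  cov_rows <- cov[, .(position = seq_len(L) - 1L, n = n), by = .(mirna, L)]
  cov_rows[, ref := substring(mseq[mirna], position + 1L, position + 1L)]
  coverage <- cov_rows[, .(covered = sum(n)), by = .(position, ref)]
  # Observed mismatches by (position, type).
  mm <- a[n_sub == 1L & !is.na(sub_pos),
          .(mismatches = sum(count)), by = .(position = sub_pos,
                                             ref = sub_ref, alt = sub_alt)]
  grid <- data.table::CJ(position = coverage$position, alt = DNA_BASES,
                         unique = TRUE)
  out <- merge(grid, coverage, by = "position", allow.cartesian = TRUE)
  out <- out[alt != ref]
  out <- merge(out, mm, by = c("position", "ref", "alt"), all.x = TRUE)
  out[is.na(mismatches), mismatches := 0L]
  out[, type := paste0(ref, ">", alt)]
  out[, matches := covered - mismatches]
  out[, .(position, type, matches, mismatches)]
}

#' Plate-aware sequencing-error model
#'
#' For substitutions, the effective error rate at a given plate, read
#' position and substitution type is the greater of the Phred-25
#' expectation (0.32%) and the rate observed among reads mapped to
#' canonical sequences on the same plate. Positions with no coverage fall
#' back to the floor. For 5' shifts and non-templated additions the rate
#' is a deliberately conservative constant of 2%.
#'
#' @param tallies data.table with columns `plate`, `position`, `type`,
#'   `matches`, `mismatches` (e.g. [tally_errors()] outputs aggregated by
#'   plate).
#' @return an object of class `ErrorRateModel`.
#' @export
estimate_error_rates <- function(tallies) {
  t <- data.table::as.data.table(tallies)
  stopifnot(all(c("plate", "position", "type", "matches", "mismatches") %in%
                  names(t)))
  t <- t[, .(matches = sum(matches), mismatches = sum(mismatches)),
         by = .(plate, position, type)]
  t[, observed := ifelse(matches + mismatches > 0,
                         mismatches / (matches + mismatches), NA_real_)]
  floor <- SUBSTITUTION_FLOOR()
  t[, effective := pmax(floor, observed)]
  t[is.na(observed), effective := floor]
  model <- list(rates = t[], floor = floor,
                nta_fivep_rate = NTA_FIVEP_ERROR_RATE,
                plates = unique(t$plate))
  class(model) <- "ErrorRateModel"
  model
}

#' Query the error model
#'
#' @param model an `ErrorRateModel`.
#' @param plate plate identifier (must be known to the model).
#' @param position 0-based read position (substitutions only).
#' @param type substitution type such as `"A>G"`, or one of
#'   `"FIVE_PRIME"`, `"NTA"` for the constant 2% channel.
#' @return the effective error rate (vectorized over
#'   `plate`/`position`/`type`).
#' @export
query_error_rate <- function(model, plate, position = NA_integer_,
                             type = "A>G") {
  stopifnot(inherits(model, "ErrorRateModel"))
  n <- max(length(plate), length(position), length(type))
  plate <- rep_len(plate, n); position <- rep_len(position, n)
  type <- rep_len(type, n)
  unknown <- setdiff(unique(plate), model$plates)
  if (length(unknown)) stopf("unknown plate id: %s", unknown[1])
  out <- rep(model$floor, n)
  const <- type %in% c("FIVE_PRIME", "NTA")
  out[const] <- model$nta_fivep_rate
  qi <- which(!const)
  if (length(qi)) {
    q <- data.table::data.table(plate = plate[qi], position = position[qi],
                                type = type[qi])
    eff <- model$rates[q, on = c("plate", "position", "type"),
                       mult = "first"]$effective
    eff[is.na(eff)] <- model$floor
    out[qi] <- eff
  }
  out
}

#' @export
print.ErrorRateModel <- function(x, ...) {
  cat(sprintf("ErrorRateModel: %d plate(s), substitution floor %.4g, 5'/NTA rate %.2g\n",
              length(x$plates), x$floor, x$nta_fivep_rate))
  invisible(x)
}

#' Binomial sequencing-error test
#'
#' The probability, under a baseline per-read error rate `e`, of seeing
#' at least `k_isomir` modified reads among `k_isomir + k_counterpart`
#' reads of otherwise identical sequence - the upper tail of
#' Binomial(n, e) at `k_isomir`. A small value means the isomiR's reads
#' are unlikely to all be sequencing errors of its counterpart.
#'
#' @param k_isomir reads carrying the isomiR's characteristic event.
#' @param k_counterpart otherwise identical reads lacking the event.
#' @param e baseline error rate in (0, 1).
#' @return the tail probability; 1 when `n = 0` (nothing observed).
#' @export
binomial_error_test <- function(k_isomir, k_counterpart, e) {
  if (any(e <= 0 | e >= 1)) stopf("error rate must lie strictly in (0, 1)")
  if (any(k_isomir < 0 | k_counterpart < 0)) stopf("counts must be non-negative")
  n <- k_isomir + k_counterpart
  p <- stats::pbinom(k_isomir - 1, n, e, lower.tail = FALSE)
  p[n == 0] <- 1
  p
}

#' Reject the sequencing-error hypothesis per sample
#'
#' Benjamini-Hochberg adjusts the binomial error-test p-values of all
#' candidate isomiRs of one type within one sample; the error hypothesis
#' is rejected (the isomiR "passes") when the adjusted p-value is below
#' `alpha` and the isomiR has at least `min_reads` reads.
#'
#' @param p raw binomial error-test p-values (one family: one sample, one
#'   isomiR type).
#' @param reads raw read counts matching `p`.
#' @param alpha adjusted-p threshold (default 0.05).
#' @param min_reads minimum raw reads (default 3).
#' @return data.table with columns `p`, `p_adjusted`, `pass`.
#' @export
reject_error_hypothesis <- function(p, reads, alpha = 0.05, min_reads = 3L) {
  stopifnot(length(p) == length(reads))
  adj <- stats::p.adjust(p, method = "BH")
  data.table::data.table(p = p, p_adjusted = adj,
                         pass = adj < alpha & reads >= min_reads)
}

#' Group-level expression call
#'
#' An isomiR is expressed in a sample group when it reaches 1 RPM in at
#' least `min_fraction` of the group's samples and passes the
#' sequencing-error rejection in at least `min_fraction` of the group's
#' samples - the two criteria counted independently. miRNAs use the RPM
#' criterion only.
#'
#' @param rpm_pass logical vector: per sample, >= 1 RPM.
#' @param err_pass logical vector: per sample, error hypothesis rejected.
#'   Ignored when `mirna_mode`.
#' @param min_fraction required fraction of samples (default 0.10; the
#'   boundary counts, so 1 of 10 samples meets it).
#' @param mirna_mode apply the RPM criterion only.
#' @return logical scalar.
#' @export
expressed_in_group <- function(rpm_pass, err_pass = NULL, min_fraction = 0.10,
                               mirna_mode = FALSE) {
  if (length(rpm_pass) == 0L) stopf("group has no retained samples")
  a <- mean(rpm_pass) >= min_fraction
  if (mirna_mode) return(a)
  if (is.null(err_pass) || length(err_pass) != length(rpm_pass)) {
    stopf("err_pass must match rpm_pass per sample")
  }
  a && mean(err_pass) >= min_fraction
}

#' Blacklist filter for known variants
#'
#' Discards isomiRs whose characteristic substitution or non-templated
#' addition coincides with a blacklisted variant (known SNPs or somatic
#' mutations supplied as a table of miRNA, mature-relative 0-based
#' offset, and alternative base). 5' isomiRs carry no substitution and
#' are always kept.
#'
#' @param keys data.table of isomiR keys (columns `mirna`, `kind`,
#'   `five_prime_shift`, `position`, `base`).
#' @param blacklist data.table with columns `mirna`, `offset`, `alt`.
#' @param bundle `ReferenceBundle`; required to place NTA tails in
#'   mature coordinates.
#' @return logical vector: TRUE = keep.
#' @export
blacklist_filter <- function(keys, blacklist, bundle = NULL) {
  keys <- data.table::as.data.table(keys)
  n <- nrow(keys)
  if (n == 0L) return(logical(0))
  if (is.null(blacklist) || nrow(blacklist) == 0L) return(rep(TRUE, n))
  offset <- rep(NA_integer_, n)
  alt <- rep(NA_character_, n)
  ed <- keys$kind == "EDIT_AI"
  offset[ed] <- keys$five_prime_shift[ed] + keys$position[ed]
  alt[ed] <- "G"
  nta <- keys$kind %in% c("NTA_A", "NTA_U", "NTA_C", "NTA_G")
  if (any(nta)) {
    if (is.null(bundle)) stopf("bundle required to locate NTA keys")
    mlen <- stats::setNames(nchar(bundle$loci$mature_seq), bundle$loci$mirna)
    offset[nta] <- mlen[keys$mirna[nta]] - 1L + keys$position[nta]
    alt[nta] <- chartr("U", "T", keys$base[nta])
  }
  tagged <- paste(keys$mirna, offset, alt)
  listed <- paste(blacklist$mirna, blacklist$offset, blacklist$alt)
  keep <- !(tagged %in% listed)
  keep[is.na(offset)] <- TRUE        # 5' keys: nothing to match
  keep
}

#' Cross-mapping filter
#'
#' Discards an isomiR when its most highly expressed sequence maps to
#' any other genomic site as well as it maps to its own stem-loop
#' region: another site cross-maps when its mismatch count is lower, or
#' equal with a 3' overhang no longer than the home alignment's (equal
#' overhangs tie, and a tie discards). Sequences ending in CCA - the
#' tail post-transcriptionally added to tRNAs - are additionally
#' re-searched without the CCA and discarded if the trimmed sequence
#' maps within an annotated tRNA region.
#'
#' @param mirna home locus of the isomiR.
#' @param seq the isomiR's most highly expressed sequence.
#' @param bundle a `ReferenceBundle`.
#' @return TRUE = keep, FALSE = discard.
#' @export
cross_map_filter <- function(mirna, seq, bundle) {
  hits <- align_read(seq, bundle)
  hit_locus <- hits[["mirna"]]
  home <- hits[which(hit_locus == mirna)]
  if (nrow(home) == 0L) return(FALSE)      # no longer maps home at all
  h_mm <- home$mismatches[1]; h_ov <- home$overhang[1]
  other <- hits[which(is.na(hit_locus) | hit_locus != mirna)]
  if (nrow(other)) {
    cross <- other$mismatches < h_mm |
      (other$mismatches == h_mm & other$overhang <= h_ov)
    if (any(cross)) return(FALSE)
  }
  if (nrow(bundle$trna_regions) && grepl("CCA$", seq) && nchar(seq) > 6L) {
    trimmed <- substr(seq, 1L, nchar(seq) - 3L)
    if (maps_to_trna(trimmed, bundle)) return(FALSE)
  }
  TRUE
}

# Exact search of a (possibly short) fragment against tRNA regions.
maps_to_trna <- function(frag, bundle) {
  glen <- nchar(bundle$genome)
  for (std in c("+", "-")) {
    g <- if (std == "+") bundle$genome else revcomp(bundle$genome)
    m <- gregexpr(frag, g, fixed = TRUE)[[1]]
    if (m[1] == -1L) next
    for (s in m) {
      fs <- if (std == "+") s - 1L else glen - (s - 1L + nchar(frag))
      fe <- fs + nchar(frag)
      if (any(fs < bundle$trna_regions$end & fe > bundle$trna_regions$start)) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' Cross-cohort high-confidence call
#'
#' An isomiR (or miRNA) is high-confidence when it is expressed in at
#' least one of the two sample groups in at least two of the three
#' cohorts.
#'
#' @param expressed data.table with columns `name`, `cohort`, `group`,
#'   `expressed` (logical), covering exactly the cohorts of the study
#'   design.
#' @param min_cohorts minimum number of cohorts (default 2).
#' @return data.table with columns `name`, `high_confidence`.
#' @export
high_confidence <- function(expressed, min_cohorts = 2L) {
  e <- data.table::as.data.table(expressed)
  by_cohort <- e[, .(any_group = any(expressed)), by = .(name, cohort)]
  out <- by_cohort[, .(high_confidence = sum(any_group) >= min_cohorts),
                   by = name]
  out[]
}
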