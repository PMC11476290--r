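# Modification-rate statistics: isomiR frequencies, cross-cohort
# z-scores, per-sample modification rates, paired ANL/LUAD differential
# tables, enzyme correlations, median-split survival, and catalog
# summaries of the high-confidence editing sites.

#' IsomiR frequency
#'
#' The frequency of an isomiR in a sample is its expression divided by
#' the combined expression of its canonical miRNA and all of that
#' miRNA's isomiRs (the family total). Undefined (NA) when the family
#' has no expression in the sample.
#'
#' @param isomir_rpm isomiR expression (RPM or counts).
#' @param family_rpm family expression on the same scale.
#' @return frequency in `[0, 1]`, or NA where `family_rpm` is 0.
#' @export
isomir_frequency <- function(isomir_rpm, family_rpm) {
  if (any(isomir_rpm < 0 | family_rpm < 0)) stopf("expression must be >= 0")
  if (any(isomir_rpm > family_rpm + 1e-9)) {
    stopf("isomiR expression exceeds its family total")
  }
  ifelse(family_rpm == 0, NA_real_, isomir_rpm / family_rpm)
}

#' Frequency z-scores across all samples of all cohorts
#'
#' Standardizes each isomiR's frequency over every sample of every
#' cohort (sample mean and n-1 standard deviation over the defined
#' entries); undefined frequencies stay undefined. An isomiR with no
#' spread gets z = 0 everywhere, with a warning.
#'
#' @param freq numeric matrix, rows = isomiRs, columns = samples; NA =
#'   undefined.
#' @return matrix of the same shape.
#' @export
zscore_matrix <- function(freq) {
  stopifnot(is.matrix(freq))
  z <- freq
  flat <- character(0)
  for (i in seq_len(nrow(freq))) {
    x <- freq[i, ]
    ok <- !is.na(x)
    if (sum(ok) < 2L || stats::sd(x[ok]) == 0) {
      z[i, ok] <- 0
      flat <- c(flat, rownames(freq)[i] %||% as.character(i))
      next
    }
    z[i, ok] <- (x[ok] - mean(x[ok])) / stats::sd(x[ok])
  }
  if (length(flat)) {
    warnf("%d isomiR(s) with no frequency spread set to z = 0 (e.g. %s)",
          length(flat), flat[1])
  }
  z
}

#' Sample-wide modification rates
#'
#' The overall rate of one modification type in a sample is the mean
#' frequency z-score over all high-confidence isomiRs of that type in
#' that sample; isomiRs with an undefined z-score in a sample are
#' excluded from that sample's mean.
#'
#' @param z z-score matrix from [zscore_matrix()] (rows = isomiRs,
#'   columns = samples).
#' @param kinds character vector (length `nrow(z)`): isomiR type of each
#'   row.
#' @return data.table with columns `sample_id`, `kind`, `rate`,
#'   `n_isomirs`; `rate` is NA when no isomiR of the type is defined in
#'   the sample.
#' @export
modification_rate <- function(z, kinds) {
  stopifnot(is.matrix(z), length(kinds) == nrow(z))
  out <- vector("list", length(unique(kinds)))
  for (j in seq_along(unique(kinds))) {
    k <- unique(kinds)[j]
    zz <- z[kinds == k, , drop = FALSE]
    out[[j]] <- data.table::data.table(
      sample_id = colnames(zz),
      kind = k,
      rate = colMeans(zz, na.rm = TRUE),
      n_isomirs = colSums(!is.na(zz)))
  }
  res <- data.table::rbindlist(out)
  res[n_isomirs == 0L, rate := NA_real_]
  res[]
}

#' Paired ANL/LUAD differential tests
#'
#' Paired-sample t-tests between ANL and LUAD members of each patient
#' pair, per cohort. In `"rates"` mode a single test per cohort is
#' reported at alpha 0.05; in `"frequencies"` mode one test per isomiR
#' is run and Benjamini-Hochberg adjusted across the isomiRs of the
#' cohort, with significance at FDR < 0.05. Pairs with an undefined
#' value on either side are dropped; fewer than 3 usable pairs flags the
#' test as not run.
#'
#' @param x `"rates"` mode: named numeric vector (names = sample ids).
#'   `"frequencies"` mode: numeric matrix, rows = isomiRs, columns =
#'   sample ids.
#' @param samples sample sheet with `sample_id`, `cohort`, `group`,
#'   `patient_id`.
#' @param mode `"rates"` or `"frequencies"`.
#' @param alpha significance threshold (raw p for rates, FDR for
#'   frequencies).
#' @return data.table: per cohort (and isomiR in frequency mode):
#'   `n_pairs`, `mean_anl`, `mean_luad`, `t`, `p`, (`fdr`),
#'   `significant`, `direction` (`"higher_in_LUAD"`/`"lower_in_LUAD"`).
#' @export
paired_differential <- function(x, samples, mode = c("rates", "frequencies"),
                                alpha = 0.05) {
  mode <- match.arg(mode)
  s <- data.table::as.data.table(samples)
  if (mode == "rates") x <- matrix(x, nrow = 1, dimnames = list("rate", names(x)))
  rows <- list()
  for (co in unique(s$cohort)) {
    sc <- s[cohort == co]
    anl <- sc[group == "ANL"]; luad <- sc[group == "LUAD"]
    luad <- luad[match(anl$patient_id, luad$patient_id)]
    for (i in seq_len(nrow(x))) {
      va <- x[i, anl$sample_id]; vl <- x[i, luad$sample_id]
      ok <- !is.na(va) & !is.na(vl)
      n <- sum(ok)
      d <- vl[ok] - va[ok]
      if (n < 3L) {
        tt <- list(statistic = NA_real_, p.value = NA_real_)
      } else if (stats::sd(d) < 10 * .Machine$double.eps *
                 max(1, abs(mean(d)))) {
        # a constant difference: null when zero, else overwhelming
        tt <- if (mean(d) == 0) list(statistic = 0, p.value = 1)
        else list(statistic = sign(mean(d)) * Inf, p.value = 0)
      } else {
        tt <- stats::t.test(vl[ok], va[ok], paired = TRUE)
      }
      rows[[length(rows) + 1L]] <- data.table::data.table(
        cohort = co, name = rownames(x)[i], n_pairs = n,
        mean_anl = mean(va[ok]), mean_luad = mean(vl[ok]),
        t = unname(tt$statistic), p = tt$p.value)
    }
  }
  out <- data.table::rbindlist(rows)
  if (mode == "frequencies") {
    out[, fdr := stats::p.adjust(p, method = "BH"), by = cohort]
    out[, significant := !is.na(fdr) & fdr < alpha]
  } else {
    out[, significant := !is.na(p) & p < alpha]
  }
  out[, direction := data.table::fifelse(mean_luad > mean_anl,
                                         "higher_in_LUAD", "lower_in_LUAD")]
  out[is.na(p), direction := NA_character_]
  out[]
}

#' Correlations of isomiR frequencies with modifying-enzyme expression
#'
#' Spearman correlations (tumor samples only) of each isomiR's frequency
#' - or of sample-wide modification rates - with the expression of two
#' candidate enzymes; p-values are BH-adjusted per enzyme across the
#' tested isomiRs. Each isomiR is then assigned to the first enzyme, the
#' second enzyme, or "Neither": an enzyme claims an isomiR when their
#' correlation is positive and FDR-significant; if both qualify, the
#' larger rho wins (flagged).
#'
#' @param freq numeric matrix (rows = isomiRs, columns = sample ids).
#' @param enzymes data.frame/data.table: `sample_id` plus one column per
#'   enzyme gene.
#' @param samples sample sheet; only `group == "LUAD"` samples (of
#'   `cohort`, when given) are used.
#' @param genes the two enzyme columns to test (default
#'   `c("ADAR", "ADARB1")`).
#' @param cohort optional cohort restriction.
#' @param alpha FDR threshold for group assignment.
#' @return data.table: `name`, rho/p/fdr per enzyme, `group`,
#'   `both_positive` flag.
#' @export
correlate_enzymes <- function(freq, enzymes, samples,
                              genes = c("ADAR", "ADARB1"),
                              cohort = NULL, alpha = 0.05) {
  stopifnot(length(genes) == 2L)
  s <- data.table::as.data.table(samples)[group == "LUAD"]
  if (!is.null(cohort)) {
    in_cohort <- s[["cohort"]] %in% cohort
    s <- s[in_cohort]
  }
  ids <- intersect(s$sample_id, colnames(freq))
  if (length(ids) < 5L) stopf("need >= 5 tumor samples with measurements")
  e <- data.table::as.data.table(enzymes)
  ev <- lapply(genes, function(g) e[[g]][match(ids, e$sample_id)])
  rows <- lapply(seq_len(nrow(freq)), function(i) {
    f <- freq[i, ids]
    res <- lapply(ev, function(v) {
      ok <- !is.na(f) & !is.na(v)
      if (sum(ok) < 5L || stats::sd(f[ok]) == 0 || stats::sd(v[ok]) == 0) {
        return(list(rho = NA_real_, p = NA_real_))
      }
      ct <- suppressWarnings(stats::cor.test(f[ok], v[ok],
                                             method = "spearman"))
      list(rho = unname(ct$estimate), p = ct$p.value)
    })
    data.table::data.table(
      name = rownames(freq)[i] %||% as.character(i),
      rho_1 = res[[1]]$rho, p_1 = res[[1]]$p,
      rho_2 = res[[2]]$rho, p_2 = res[[2]]$p)
  })
  out <- data.table::rbindlist(rows)
  out[, fdr_1 := stats::p.adjust(p_1, method = "BH")]
  out[, fdr_2 := stats::p.adjust(p_2, method = "BH")]
  pos1 <- !is.na(out$fdr_1) & out$fdr_1 < alpha & out$rho_1 > 0
  pos2 <- !is.na(out$fdr_2) & out$fdr_2 < alpha & out$rho_2 > 0
  grp <- rep("Neither", nrow(out))
  grp[pos1 & !pos2] <- genes[1]
  grp[pos2 & !pos1] <- genes[2]
  both <- pos1 & pos2
  grp[both] <- ifelse(out$rho_1[both] >= out$rho_2[both], genes[1], genes[2])
  out[, group := grp]
  out[, both_positive := both]
  data.table::setnames(out,
                       c("rho_1", "p_1", "fdr_1", "rho_2", "p_2", "fdr_2"),
                       c(paste0(c("rho_", "p_", "fdr_"), genes[1]),
                         paste0(c("rho_", "p_", "fdr_"), genes[2])))
  out[]
}

#' Median-split log-rank survival test
#'
#' Patients are split into above-median and at-or-below-median groups of
#' the analyzed quantity (ties go to the lower arm) and compared by a
#' two-group log-rank test.
#'
#' @param values per-patient values of the quantity.
#' @param os_time overall-survival times.
#' @param os_event event indicators (1 = death observed).
#' @return list: `p`, `statistic` (log-rank chi-square), `n_high`,
#'   `n_low`, `events_high`, `events_low`, `flag` (`"ok"`,
#'   `"no_split"`, `"arm_without_events"`).
#' @export
median_split_survival <- function(values, os_time, os_event) {
  ok <- !is.na(values) & !is.na(os_time) & !is.na(os_event)
  values <- values[ok]; os_time <- os_time[ok]; os_event <- os_event[ok]
  if (length(values) < 10L) stopf("need >= 10 patients with survival data")
  high <- values > stats::median(values)
  if (all(high) || !any(high)) {
    return(list(p = NA_real_, statistic = NA_real_,
                n_high = sum(high), n_low = sum(!high),
                events_high = NA_integer_, events_low = NA_integer_,
                flag = "no_split"))
  }
  sd_ <- survival::survdiff(survival::Surv(os_time, os_event) ~ high)
  p <- stats::pchisq(sd_$chisq, df = 1, lower.tail = FALSE)
  ev_high <- sum(os_event[high]); ev_low <- sum(os_event[!high])
  flag <- if (ev_high == 0L || ev_low == 0L) "arm_without_events" else "ok"
  list(p = p, statistic = unname(sd_$chisq),
       n_high = sum(high), n_low = sum(!high),
       events_high = ev_high, events_low = ev_low, flag = flag)
}

#' Summary statistics of an A-to-I editing-site catalog
#'
#' For a table of edited isomiRs (one row per site), reports how many
#' sites fall within the seed sequence (0-based isomiR positions 1-7,
#' i.e. nucleotides 2-8) and tallies the nucleotides immediately 5' and
#' 3' of the edited adenosine.
#'
#' @param catalog data.frame with columns `mirna`, `five_prime_shift`,
#'   `edited_position` (0-based, isomiR coordinates), `adjacent_5p`,
#'   `adjacent_3p` (single bases, RNA alphabet).
#' @return list: `n_sites`, `n_seed`, `seed_pct`, `adjacent_5p_counts`,
#'   `adjacent_3p_counts`, `adjacent_5p_u_pct`.
#' @export
summarize_catalog <- function(catalog) {
  ct <- data.table::as.data.table(catalog)
  stopifnot(all(c("mirna", "edited_position") %in% names(ct)))
  if (any(ct$edited_position < 0L)) {
    stopf("edited position outside the isomiR")
  }
  in_seed <- ct$edited_position >= 1L & ct$edited_position <= 7L
  a5 <- table(factor(ct$adjacent_5p, levels = c("A", "C", "G", "U")))
  a3 <- table(factor(ct$adjacent_3p, levels = c("A", "C", "G", "U")))
  list(
    n_sites = nrow(ct),
    n_seed = sum(in_seed),
    seed_pct = 100 * sum(in_seed) / nrow(ct),
    adjacent_5p_counts = a5,
    adjacent_3p_counts = a3,
    adjacent_5p_u_pct = 100 * unname(a5["U"]) / nrow(ct)
  )
}

#' Build an editing-site catalog from experiment keys
#'
#' Looks up, for each high-confidence edited isomiR, the nucleotides
#' adjacent to the edited adenosine; when the adjacent base lies outside
#' the mature sequence it is read from the precursor (hairpin) sequence.
#'
#' @param keys data.table of EDIT_AI keys (`mirna`, `five_prime_shift`,
#'   `position`).
#' @param bundle a `ReferenceBundle`.
#' @return a catalog table suitable for [summarize_catalog()].
#' @export
catalog_from_keys <- function(keys, bundle) {
  k <- data.table::as.data.table(keys)
  loci <- bundle$loci
  m_off <- ifelse(loci$strand == "+", loci$mature_start - loci$hairpin_start,
                  loci$hairpin_end - loci$mature_end)
  li <- match(k$mirna, loci$mirna)
  hp_pos <- m_off[li] + k$five_prime_shift + k$position   # 0-based in hairpin
  hp <- loci$hairpin_seq[li]
  base_at <- function(s, p) {
    ifelse(p >= 0L & p < nchar(s), substring(s, p + 1L, p + 1L), NA_character_)
  }
  to_rna <- function(b) chartr("T", "U", b)
  data.table::data.table(
    mirna = k$mirna,
    five_prime_shift = k$five_prime_shift,
    edited_position = k$position,
    edited_base = to_rna(base_at(hp, hp_pos)),
    adjacent_5p = to_rna(base_at(hp, hp_pos - 1L)),
    adjacent_3p = to_rna(base_at(hp, hp_pos + 1L)))
}

#' Spectrum of non-templated addition bases
#'
#' Counts expressed NTA isomiRs by tail base within each cohort and
#' sample group.
#'
#' @param expressed data.table with columns `name`, `kind`, `cohort`,
#'   `group`, `expressed`.
#' @return data.table `cohort`, `group`, `base`, `n`.
#' @export
nta_base_spectrum <- function(expressed) {
  e <- data.table::as.data.table(expressed)
  e <- e[grepl("^NTA_", kind) & expressed == TRUE]
  e[, base := sub("NTA_", "", kind)]
  e[, .(n = data.table::uniqueN(name)), by = .(cohort, group, base)]
}

#' Collapse probe-level expression to gene level
#'
#' When a gene is measured by several probes, the probe with the highest
#' mean expression across samples is kept; mean ties keep the
#' lexicographically lowest probe identifier.
#'
#' @param probes data.table: `probe_id` plus one column per sample.
#' @param probe_map data.table: `probe_id`, `gene`.
#' @param genes optional genes to report; genes absent from the map are
#'   flagged in `attr(, "missing")`.
#' @return data.table: `gene`, `probe_id`, one column per sample.
#' @export
collapse_probes <- function(probes, probe_map, genes = NULL) {
  p <- data.table::as.data.table(probes)
  map <- data.table::as.data.table(probe_map)
  sample_cols <- setdiff(names(p), "probe_id")
  p[, mean_expr := rowMeans(.SD), .SDcols = sample_cols]
  m <- merge(map, p, by = "probe_id")
  data.table::setorder(m, gene, -mean_expr, probe_id)
  out <- m[, .SD[1L], by = gene]
  missing <- character(0)
  if (!is.null(genes)) {
    missing <- setdiff(genes, out$gene)
    out <- out[gene %in% genes]
  }
  out[, mean_expr := NULL]
  res <- out[]
  attr(res, "missing") <- missing
  res
}
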