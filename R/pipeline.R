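# End-to-end orchestration: simulated (or file-based) cohorts in,
# high-confidence isomiR catalog, modification-rate statistics and
# analysis tables out.

#' Preprocess and annotate one sample
#'
#' Adapter trimming, all-base quality filtering and annotation of the
#' surviving inserts.
#'
#' @param reads data.table `id`, `seq`, `qual`.
#' @param adapter 3' adapter sequence.
#' @param bundle a `ReferenceBundle`.
#' @param min_len minimum insert length (default 15).
#' @param min_q minimum per-base Phred score (default 25).
#' @param min_stack optional minimum unique-sequence read count
#'   (read-stack height) before annotation; 0 disables.
#' @return list: `annotations`, `audit` (named counts incl. trimming and
#'   quality losses), `n_input`, `n_pass`.
#' @export
process_sample <- function(reads, adapter, bundle, min_len = 15L,
                           min_q = 25L, min_stack = 0L) {
  n_input <- nrow(reads)
  tr <- trim_reads(reads, adapter, min_len = min_len)
  audit <- c(input = n_input,
             trim_rejected = sum(!tr$keep),
             untrimmed_kept = sum(tr$keep & tr$reason == "untrimmed"))
  tr <- tr[keep == TRUE]
  qp <- quality_pass(tr$qual, min_q)
  audit <- c(audit, low_quality = sum(!qp))
  tr <- tr[qp]
  if (min_stack > 0L) {
    tab <- tr[, .N, by = seq]
    keep_seq <- tab[N >= min_stack]$seq
    audit <- c(audit, below_stack = nrow(tr) - sum(tr$seq %in% keep_seq))
    tr <- tr[seq %in% keep_seq]
  }
  ann <- annotate_sample(tr, bundle)
  list(annotations = ann$annotations, audit = c(audit, ann$audit),
       n_input = n_input, n_pass = nrow(tr))
}

# Candidate isomiR keys of one experiment with per-sample counts and the
# "otherwise identical" counterpart counts used by the binomial error
# test: reads sharing the key's anchoring coordinates but lacking its
# characteristic event (the unedited base for edits, the canonical 5'
# end for 5' shifts, a tail-free 3' end for NTAs).
candidate_keys <- function(ann_all) {
  ok <- ann_all[status == "ok"]
  ok[, seq_len_ := nchar(seq)]
  ok[, sub_internal := n_sub > 0L & sub_pos < seq_len_ - 2L]
  kinds <- ISOMIR_KINDS
  cand <- data.table::rbindlist(
    lapply(kinds, function(k) collapse_isomirs(ok, k)))

  tot_ms <- ok[, .(tot = sum(count)), by = .(sample_id, mirna,
                                             five_prime_shift)]
  sub_at <- ok[sub_internal == TRUE,
               .(n_sub_at = sum(count)),
               by = .(sample_id, mirna, five_prime_shift, position = sub_pos)]
  tot_m0 <- tot_ms[five_prime_shift == 0L,
                   .(sample_id, mirna, tot0 = tot)]
  no_tail <- ok[nta == "", .(tot_notail = sum(count)),
                by = .(sample_id, mirna)]

  cand[, counterpart := NA_real_]
  ed <- cand$kind == "EDIT_AI"
  if (any(ed)) {
    x <- cand[ed]
    x <- tot_ms[x, on = c("sample_id", "mirna", "five_prime_shift")]
    x <- sub_at[x, on = c("sample_id", "mirna", "five_prime_shift",
                          "position")]
    cand[ed, counterpart := pmax(0, x$tot - data.table::fifelse(
      is.na(x$n_sub_at), 0, as.numeric(x$n_sub_at)) )]
  }
  fp <- cand$kind == "FIVE_PRIME"
  if (any(fp)) {
    x <- tot_m0[cand[fp], on = c("sample_id", "mirna")]
    cand[fp, counterpart := data.table::fifelse(is.na(x$tot0), 0,
                                                as.numeric(x$tot0))]
  }
  nta <- grepl("^NTA_", cand$kind)
  if (any(nta)) {
    x <- no_tail[cand[nta], on = c("sample_id", "mirna")]
    cand[nta, counterpart := data.table::fifelse(is.na(x$tot_notail), 0,
                                                 as.numeric(x$tot_notail))]
  }
  cand[]
}

# Most highly expressed read sequence backing each isomiR key (summed
# over all samples), as input to the cross-mapping filter.
key_top_sequences <- function(ann_all, keys) {
  ok <- ann_all[status == "ok"]
  ok[, seq_len_ := nchar(seq)]
  ok[, sub_internal := n_sub > 0L & sub_pos < seq_len_ - 2L]
  top_of <- function(contrib, by_cols) {
    s <- contrib[, .(n = sum(count)), by = c(by_cols, "seq")]
    data.table::setorderv(s, c(by_cols, "n"), c(rep(1L, length(by_cols)), -1L))
    s[, .SD[1L], by = by_cols]
  }
  out <- vector("list", 6L)
  ed <- ok[sub_internal == TRUE & sub_ref == "A" & sub_alt == "G"]
  ed[, position := sub_pos]
  out[[1]] <- top_of(ed, c("mirna", "five_prime_shift", "position"))[
    , kind := "EDIT_AI"]
  fp <- ok[five_prime_shift != 0L & sub_internal == FALSE]
  out[[2]] <- top_of(fp, c("mirna", "five_prime_shift"))[
    , `:=`(kind = "FIVE_PRIME", position = NA_integer_)]
  i <- 2L
  for (k in c("NTA_A", "NTA_U", "NTA_C", "NTA_G")) {
    b_dna <- c(NTA_A = "A", NTA_U = "T", NTA_C = "C", NTA_G = "G")[[k]]
    nt <- ok[sub_internal == FALSE & nchar(nta) >= 1L & nchar(nta) <= 2L &
               nta == strrep(b_dna, nchar(nta))]
    if (nrow(nt)) {
      nt[, position := three_prime_shift + nchar(nta)]
      nt <- nt[position %in% c(1L, 2L)]
    }
    i <- i + 1L
    out[[i]] <- if (nrow(nt)) {
      top_of(nt, c("mirna", "position"))[
        , `:=`(kind = k, five_prime_shift = NA_integer_)]
    } else NULL
  }
  tops <- data.table::rbindlist(out[!vapply(out, is.null, logical(1))],
                                fill = TRUE)
  merge(keys, tops[, .(mirna, kind, five_prime_shift, position, seq)],
        by = c("mirna", "kind", "five_prime_shift", "position"),
        all.x = TRUE, sort = FALSE)
}

#' Run the full isomiRome analysis on a simulated cohort set
#'
#' Per sample: trimming, quality filtering, coverage gating and
#' annotation. Across samples: plate-wise error-rate estimation, the
#' per-sample binomial error test with BH correction, the 1-RPM and
#' error-test prevalence criteria per cohort and group, blacklist and
#' cross-mapping filters, the two-of-three-cohorts high-confidence call,
#' frequency/z-score/modification-rate statistics, paired ANL/LUAD
#' differential tables, enzyme correlations, median-split survival and
#' the editing-site catalog summary.
#'
#' @param cs an `IsomirCohortSet` from [simulate_cohorts()].
#' @param min_coverage per-sample read-count gate (scaled for synthetic
#'   depth; production libraries use 5e6).
#' @param alpha error-test FDR threshold within a sample (default 0.05).
#' @param min_fraction group prevalence required by the expression
#'   criteria (default 0.10).
#' @param bh_family `"per_type"` (BH across the candidate isomiRs of one
#'   type within a sample) or `"joint"` (across all types of a sample).
#' @param do_stats compute downstream statistics (set FALSE to stop
#'   after the high-confidence catalog).
#' @param verbose print per-sample progress.
#' @return an object of class `IsomirExperiment`; see Details in the
#'   package vignette.
#' @export
run_experiment <- function(cs, min_coverage = 1000L, alpha = 0.05,
                           min_fraction = 0.10,
                           bh_family = c("per_type", "joint"),
                           do_stats = TRUE, verbose = FALSE) {
  stopifnot(inherits(cs, "IsomirCohortSet"))
  bh_family <- match.arg(bh_family)
  bundle <- cs$bundle
  samples <- data.table::copy(cs$samples)

  ann_list <- vector("list", nrow(samples))
  audits <- vector("list", nrow(samples))
  kept <- logical(nrow(samples))
  for (i in seq_len(nrow(samples))) {
    sid <- samples$sample_id[i]
    sim <- sample_reads(cs, sid)
    if (!coverage_filter(nrow(sim$reads), min_coverage)) {
      audits[[i]] <- c(input = nrow(sim$reads), low_coverage = 1L)
      next
    }
    ps <- process_sample(sim$reads, samples$adapter[i], bundle)
    ps$annotations[, sample_id := sid]
    ann_list[[i]] <- ps$annotations
    audits[[i]] <- ps$audit
    kept[i] <- TRUE
    if (verbose) message(sprintf("processed %s (%d/%d)", sid, i,
                                 nrow(samples)))
  }
  samples <- samples[kept]
  ann_all <- data.table::rbindlist(ann_list[kept])

  # Plate-aware error model from canonical-mapped reads.
  tallies <- ann_all[samples[, .(sample_id, plate)], on = "sample_id"][
    , tally_errors(.SD, bundle), by = plate]
  error_model <- estimate_error_rates(tallies)

  # Candidate keys, blacklist screen, binomial error test.
  cand <- candidate_keys(ann_all)
  keys <- unique(cand[, .(mirna, kind, five_prime_shift, position, base,
                          name)])
  keep_bl <- blacklist_filter(keys, bundle$blacklist, bundle)
  n_blacklisted <- sum(!keep_bl)
  keys <- keys[keep_bl]
  cand <- cand[name %in% keys$name]

  cand <- samples[, .(sample_id, cohort, group, plate)][cand,
                                                        on = "sample_id"]
  cand[, e := query_error_rate(error_model, plate,
                               position = data.table::fifelse(
                                 kind == "EDIT_AI", position, NA_integer_),
                               type = data.table::fifelse(
                                 kind == "EDIT_AI", "A>G",
                                 data.table::fifelse(kind == "FIVE_PRIME",
                                                     "FIVE_PRIME", "NTA")))]
  cand[, p := binomial_error_test(count, counterpart, e)]
  fam_cols <- if (bh_family == "per_type") c("sample_id", "kind") else
    "sample_id"
  cand[, c("p_adjusted", "err_pass") := {
    r <- reject_error_hypothesis(p, count, alpha)
    list(r$p_adjusted, r$pass)
  }, by = fam_cols]

  # Expression (RPM) per key and per family.
  totals <- ann_all[status == "ok", .(total = sum(count)), by = sample_id]
  fam <- ann_all[status == "ok", .(count = sum(count)),
                 by = .(sample_id, mirna)]
  fam <- totals[fam, on = "sample_id"]
  fam[, rpm := count * 1e6 / total]
  cand <- totals[cand, on = "sample_id"]
  cand[, rpm := count * 1e6 / total]
  cand[, rpm_pass := rpm >= 1]

  # Group-level expression flags over the union of candidate keys.
  grp_sizes <- samples[, .(n_samples = .N), by = .(cohort, group)]
  flags <- cand[, .(n_rpm = sum(rpm_pass), n_err = sum(err_pass)),
                by = .(name, kind, cohort, group)]
  grid <- data.table::CJ(name = keys$name, cg = seq_len(nrow(grp_sizes)),
                         unique = TRUE)
  grid <- cbind(grid[, .(name)], grp_sizes[grid$cg])
  flags <- merge(grid, flags, by = c("name", "cohort", "group"),
                 all.x = TRUE)
  flags[is.na(n_rpm), n_rpm := 0L]
  flags[is.na(n_err), n_err := 0L]
  flags[, kind := keys$kind[match(name, keys$name)]]
  flags[, expressed := n_rpm / n_samples >= min_fraction &
          n_err / n_samples >= min_fraction]

  # Cross-mapping filter on keys expressed somewhere.
  expressed_names <- unique(flags[expressed == TRUE]$name)
  tops <- key_top_sequences(ann_all, keys[name %in% expressed_names])
  n_crossmap <- 0L
  if (nrow(tops)) {
    keep_cm <- vapply(seq_len(nrow(tops)), function(i) {
      if (is.na(tops$seq[i])) return(TRUE)
      cross_map_filter(tops$mirna[i], tops$seq[i], bundle)
    }, logical(1))
    n_crossmap <- sum(!keep_cm)
    dropped <- tops$name[!keep_cm]
    flags[name %in% dropped, expressed := FALSE]
    keys <- keys[!name %in% dropped]
    cand <- cand[!name %in% dropped]
  }

  hc <- high_confidence(flags)
  keys <- merge(keys, hc, by = "name", all.x = TRUE, sort = FALSE)
  keys[is.na(high_confidence), high_confidence := FALSE]

  # miRNA (family) expression flags: RPM criterion only.
  fam_flags <- samples[, .(sample_id, cohort, group)][fam, on = "sample_id"]
  fam_flags <- fam_flags[, .(n_rpm = sum(rpm >= 1)), by = .(mirna, cohort,
                                                            group)]
  fgrid <- data.table::CJ(mirna = unique(fam$mirna),
                          cg = seq_len(nrow(grp_sizes)), unique = TRUE)
  fgrid <- cbind(fgrid[, .(mirna)], grp_sizes[fgrid$cg])
  fam_flags <- merge(fgrid, fam_flags, by = c("mirna", "cohort", "group"),
                     all.x = TRUE)
  fam_flags[is.na(n_rpm), n_rpm := 0L]
  fam_flags[, expressed := n_rpm / n_samples >= min_fraction]
  fam_hc <- high_confidence(fam_flags[, .(name = mirna, cohort, group,
                                          expressed)])

  # Matrices: RPM and frequency (NA where the family is silent).
  sample_ids <- samples$sample_id
  mat_of <- function(dt, rows) {
    m <- matrix(0, length(rows), length(sample_ids),
                dimnames = list(rows, sample_ids))
    m[cbind(match(dt$name, rows), match(dt$sample_id, sample_ids))] <- dt$rpm
    m
  }
  family_rpm <- {
    rows <- sort(unique(fam$mirna))
    m <- matrix(0, length(rows), length(sample_ids),
                dimnames = list(rows, sample_ids))
    m[cbind(match(fam$mirna, rows), match(fam$sample_id, sample_ids))] <-
      fam$rpm
    m
  }
  isomir_rpm <- mat_of(cand[, .(name, sample_id, rpm)], sort(keys$name))
  isomir_freq <- isomir_rpm /
    family_rpm[keys$mirna[match(rownames(isomir_rpm), keys$name)], ,
               drop = FALSE]
  isomir_freq[family_rpm[keys$mirna[match(rownames(isomir_rpm), keys$name)],
                         , drop = FALSE] == 0] <- NA

  audit <- c(
    n_samples_dropped_coverage = sum(!kept),
    n_keys_blacklisted = n_blacklisted,
    n_keys_crossmapped = n_crossmap)

  expt <- list(samples = samples, bundle = bundle,
               error_model = error_model,
               candidates = cand, keys = keys, flags = flags,
               family = fam, family_flags = fam_flags, family_hc = fam_hc,
               family_rpm = family_rpm, isomir_rpm = isomir_rpm,
               isomir_freq = isomir_freq,
               audit = audit, sample_audits = audits,
               enzyme_probes = cs$enzyme_probes, probe_map = cs$probe_map)
  class(expt) <- "IsomirExperiment"
  if (!do_stats) return(expt)
  compute_statistics(expt, cs)
}

# Downstream statistics attached to an IsomirExperiment.
compute_statistics <- function(expt, cs) {
  keys <- expt$keys
  hc_names <- keys[high_confidence == TRUE]$name
  samples <- expt$samples

  if (length(hc_names) >= 1L) {
    freq_hc <- expt$isomir_freq[hc_names, , drop = FALSE]
    z <- suppressWarnings(zscore_matrix(freq_hc))
    kinds <- keys$kind[match(rownames(z), keys$name)]
    rates <- modification_rate(z, kinds)
    rate_wide <- data.table::dcast(rates, sample_id ~ kind,
                                   value.var = "rate")
    rate_tests <- data.table::rbindlist(lapply(
      setdiff(unique(kinds), character(0)), function(k) {
        v <- stats::setNames(rates[kind == k]$rate, rates[kind == k]$sample_id)
        out <- paired_differential(v, samples, mode = "rates")
        out[, kind := k]
        out
      }))
    iso_tests <- data.table::rbindlist(lapply(unique(kinds), function(k) {
      m <- freq_hc[kinds == k, , drop = FALSE]
      out <- paired_differential(m, samples, mode = "frequencies")
      out[, kind := k]
      out
    }))
  } else {
    z <- NULL; rates <- NULL; rate_wide <- NULL
    rate_tests <- NULL; iso_tests <- NULL
  }

  # Enzyme expression: probe collapse, then editing correlations in the
  # tumor samples of the first cohort (the designated training cohort).
  enzymes <- NULL; edit_cor <- NULL
  if (!is.null(expt$enzyme_probes)) {
    gene_tab <- collapse_probes(expt$enzyme_probes, expt$probe_map)
    sample_cols <- setdiff(names(gene_tab), c("gene", "probe_id"))
    enzymes <- data.table::data.table(sample_id = sample_cols,
                                      t(as.matrix(gene_tab[, ..sample_cols])))
    data.table::setnames(enzymes, c("sample_id", gene_tab$gene))
    edit_names <- keys[high_confidence == TRUE & kind == "EDIT_AI"]$name
    main_cohort <- samples$cohort[1]
    n_luad <- sum(samples$cohort == main_cohort & samples$group == "LUAD")
    if (length(edit_names) >= 1L && n_luad >= 5L) {
      edit_cor <- correlate_enzymes(
        expt$isomir_freq[edit_names, , drop = FALSE],
        enzymes, samples, genes = c("ADAR", "ADARB1"), cohort = main_cohort)
    }
  }

  # Median-split survival of the editing rate, per cohort (LUAD only).
  surv <- NULL
  if (!is.null(rates)) {
    sr <- rates[kind == "EDIT_AI"]
    surv_rows <- list()
    for (co in unique(samples$cohort)) {
      sl <- samples[cohort == co & group == "LUAD" & !is.na(os_time)]
      v <- sr$rate[match(sl$sample_id, sr$sample_id)]
      if (sum(!is.na(v)) >= 10L) {
        ms <- median_split_survival(v, sl$os_time, sl$os_event)
        surv_rows[[co]] <- data.table::data.table(
          cohort = co, p = ms$p, statistic = ms$statistic, flag = ms$flag)
      }
    }
    if (length(surv_rows)) surv <- data.table::rbindlist(surv_rows)
  }

  # Editing-site catalog and NTA spectrum of the high-confidence set.
  edit_keys <- keys[high_confidence == TRUE & kind == "EDIT_AI"]
  catalog <- if (nrow(edit_keys)) catalog_from_keys(edit_keys, expt$bundle)
  else NULL
  catalog_summary <- if (!is.null(catalog)) summarize_catalog(catalog)
  else NULL
  spectrum <- nta_base_spectrum(expt$flags)

  expt$z <- z
  expt$rates <- rates
  expt$rate_wide <- rate_wide
  expt$rate_tests <- rate_tests
  expt$isomir_tests <- iso_tests
  expt$enzymes <- enzymes
  expt$edit_correlations <- edit_cor
  expt$survival <- surv
  expt$catalog <- catalog
  expt$catalog_summary <- catalog_summary
  expt$nta_spectrum <- spectrum
  expt
}

#' @export
print.IsomirExperiment <- function(x, ...) {
  nk <- nrow(x$keys)
  nhc <- sum(x$keys$high_confidence)
  cat(sprintf("IsomirExperiment: %d samples, %d candidate isomiR keys, %d high-confidence\n",
              nrow(x$samples), nk, nhc))
  if (nhc) {
    tab <- table(x$keys[x$keys$high_confidence == TRUE]$kind)
    cat("  high-confidence by type:",
        paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}
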