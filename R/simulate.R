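# Synthetic cohorts with planted ground truth. Three cohorts of paired
# non-malignant (ANL) / tumor (LUAD) small-RNA libraries are simulated
# from the toy reference: every read is a (possibly 5'-shifted, A-to-I
# edited, or 3'-tailed) mature sequence followed by the library's 3'
# adapter, truncated to the machine read length, with per-base
# substitution errors at the sample's plate rate and Phred-33 qualities.
# LUAD samples carry additive shifts on the modification frequencies of
# designated loci (editing and adenylation down, uridylation up), and
# per-sample editing levels are coupled to the expression of two
# editing enzymes and to overall survival.

#' Configuration of the synthetic three-cohort study
#'
#' Defaults encode the simulated study design: three cohorts of 20
#' ANL/LUAD pairs each, ~50,000 reads per sample, two sequencing plates
#' per cohort with different error rates, one cohort using a different
#' 3' adapter chemistry, and additive LUAD effects of -0.05 on editing
#' and adenylation frequencies and +0.05 on uridylation at six planted
#' loci per modification type.
#'
#' @param n_pairs integer vector: ANL/LUAD pairs per cohort.
#' @param cohorts cohort names.
#' @param adapters per-cohort 3' adapter sequences.
#' @param n_reads reads per sample.
#' @param read_len machine read length (insert + adapter prefix).
#' @param plate_error_rates per-plate substitution error rates, recycled
#'   over the plates of each cohort.
#' @param n_plates plates per cohort.
#' @param baseline named list of baseline modification frequencies
#'   (`edit`, `five_prime`, `nta_a`, `nta_u`, `nta_c`, `nta_g`).
#' @param effects named list of additive LUAD shifts (`edit`, `nta_a`,
#'   `nta_u`).
#' @param edit_effect_loci,adenyl_effect_loci,uridyl_effect_loci locus
#'   indices carrying each LUAD effect.
#' @param shift_5p per-locus 5' shift planted for the 5'-isomiR channel
#'   (positive = trimmed, negative = extended into the precursor).
#' @param patient_sd,sample_sd,site_sd biological noise (frequency
#'   scale): shared per patient, per sample, and per sample-site.
#' @param kappa_enzyme coupling of per-sample enzyme latents to editing
#'   frequencies at enzyme-associated loci.
#' @param adar_like_loci,adarb1_like_loci loci whose editing couples to
#'   the ADAR-like and ADARB1-like enzyme latents.
#' @param lowq_frac fraction of reads given one sub-25-quality base, to
#'   exercise the quality filter.
#' @param qual_hi,qual_lo Phred scores of ordinary and planted
#'   low-quality bases.
#' @param beta_os log-hazard decrease per standard deviation of a
#'   sample's editing level; `median_months`, `censor_months` shape the
#'   overall-survival simulation.
#' @param min_abundance minimum per-locus share of the library.
#' @return a list of class `cohort_config`.
#' @export
cohort_config <- function(n_pairs = c(20L, 20L, 20L),
                          cohorts = c("cohortA", "cohortB", "cohortC"),
                          adapters = c("ATCTCGTATGCCGTCTTCTGCTTGT",
                                       "ATCTCGTATGCCGTCTTCTGCTTGT",
                                       "TGGAATTCTCGGGTGCCAAGG"),
                          n_reads = 50000L,
                          read_len = 36L,
                          plate_error_rates = c(0.002, 0.005),
                          n_plates = 2L,
                          baseline = list(edit = 0.12, five_prime = 0.10,
                                          nta_a = 0.10, nta_u = 0.07,
                                          nta_c = 0.004, nta_g = 0.004),
                          effects = list(edit = -0.05, nta_a = -0.05,
                                         nta_u = 0.05),
                          edit_effect_loci = 1:6,
                          adenyl_effect_loci = 2:7,
                          uridyl_effect_loci = 3:8,
                          shift_5p = NULL,
                          patient_sd = 0.012,
                          sample_sd = 0.006,
                          site_sd = 0.004,
                          kappa_enzyme = 0.03,
                          adar_like_loci = c(9L, 10L),
                          adarb1_like_loci = 1:6,
                          lowq_frac = 0.01,
                          qual_hi = 30L,
                          qual_lo = 20L,
                          beta_os = 0.8,
                          median_months = 36,
                          censor_months = 60,
                          min_abundance = 0.005) {
  stopifnot(length(n_pairs) == length(cohorts),
            length(adapters) == length(cohorts))
  cfg <- as.list(environment())
  class(cfg) <- "cohort_config"
  cfg
}

# Per-locus variant sequences and their event labels.
locus_variants <- function(bundle) {
  loci <- bundle$loci
  m_off <- ifelse(loci$strand == "+", loci$mature_start - loci$hairpin_start,
                  loci$hairpin_end - loci$mature_end)
  out <- vector("list", nrow(loci))
  for (i in seq_len(nrow(loci))) {
    mat <- loci$mature_seq[i]
    hp <- loci$hairpin_seq[i]
    ep <- loci$edit_pos[i]
    edit <- mat
    if (!is.na(ep)) substr(edit, ep + 1L, ep + 1L) <- "G"
    out[[i]] <- c(canonical = mat, edit = edit,
                  nta_A1 = paste0(mat, "A"), nta_A2 = paste0(mat, "AA"),
                  nta_U1 = paste0(mat, "T"), nta_U2 = paste0(mat, "TT"),
                  nta_C1 = paste0(mat, "C"), nta_G1 = paste0(mat, "G"),
                  five_prime = NA_character_,   # filled per profile shift
                  m_off = m_off[i], hairpin = hp)
  }
  names(out) <- loci$mirna
  out
}

five_prime_variant <- function(mature, hairpin, m_off, shift) {
  if (shift > 0L) {
    substr(mature, shift + 1L, nchar(mature))
  } else if (shift < 0L) {
    paste0(substr(hairpin, m_off + shift + 1L, m_off), mature)
  } else {
    mature
  }
}

#' Simulate one small-RNA library
#'
#' Draws `n_reads` reads from the locus abundance weights; each read is a
#' canonical mature sequence or one planted variant (A-to-I edit, 5'
#' shift, or a 1-2 nt homopolymer 3' tail, with tail length 2 used for
#' 25% of A/U tail events), concatenated with the 3' adapter and cut to
#' the machine read length. Per-base substitution errors are drawn at the
#' profile's plate error rate; a configured fraction of reads receives
#' one sub-threshold-quality base.
#'
#' @param bundle a `ReferenceBundle`.
#' @param profile list with `sites` (data.table: `mirna`, `weight`,
#'   `freq_edit`, `freq_5p`, `shift_5p`, `freq_ntaA`, `freq_ntaU`,
#'   `freq_ntaC`, `freq_ntaG`), `plate_error_rate`, `lowq_frac`,
#'   `read_len`, `qual_hi`, `qual_lo`.
#' @param n_reads number of reads (>= 1).
#' @param adapter non-empty 3' adapter sequence.
#' @param seed integer seed; output is byte-identical across reruns.
#' @return list with `reads` (data.table `id`, `seq`, `qual`) and
#'   `truth` (data.table `id`, `mirna`, `event`).
#' @export
simulate_sample <- function(bundle, profile, n_reads, adapter, seed) {
  if (n_reads < 1L) stopf("n_reads must be >= 1")
  if (!nzchar(adapter)) stopf("adapter must be non-empty")
  sites <- data.table::as.data.table(profile$sites)
  freq_cols <- c("freq_edit", "freq_5p", "freq_ntaA", "freq_ntaU",
                 "freq_ntaC", "freq_ntaG")
  fr <- as.matrix(sites[, freq_cols, with = FALSE])
  if (any(fr < 0 | fr > 1)) stopf("modification frequencies must lie in [0, 1]")
  if (any(rowSums(fr) > 1)) {
    stopf("competing modification frequencies at one locus sum to > 1")
  }
  rate <- profile$plate_error_rate
  if (rate < 0 || rate > 1) stopf("plate error rate must lie in [0, 1]")
  read_len <- profile$read_len %||% 36L
  lowq_frac <- profile$lowq_frac %||% 0
  qual_hi <- profile$qual_hi %||% 30L
  qual_lo <- profile$qual_lo %||% 20L

  set.seed(seed)
  nl <- nrow(sites)
  events <- c("edit", "five_prime", "nta_A1", "nta_A2", "nta_U1", "nta_U2",
              "nta_C1", "nta_G1", "canonical")
  # Per-locus event probabilities (A/U tails: 75% 1 nt, 25% 2 nt).
  pm <- cbind(fr[, "freq_edit"], fr[, "freq_5p"],
              0.75 * fr[, "freq_ntaA"], 0.25 * fr[, "freq_ntaA"],
              0.75 * fr[, "freq_ntaU"], 0.25 * fr[, "freq_ntaU"],
              fr[, "freq_ntaC"], fr[, "freq_ntaG"])
  cum <- t(apply(pm, 1L, cumsum))

  loc <- sample.int(nl, n_reads, replace = TRUE, prob = sites$weight)
  u <- stats::runif(n_reads)
  ev_idx <- rowSums(u > cum[loc, , drop = FALSE]) + 1L
  ev <- events[ev_idx]

  vars <- locus_variants(bundle)
  var_seq <- matrix(NA_character_, nl, length(events),
                    dimnames = list(sites$mirna, events))
  for (i in seq_len(nl)) {
    v <- vars[[sites$mirna[i]]]
    var_seq[i, ] <- c(v[["edit"]],
                      five_prime_variant(v[["canonical"]], v[["hairpin"]],
                                         as.integer(v[["m_off"]]),
                                         sites$shift_5p[i]),
                      v[["nta_A1"]], v[["nta_A2"]], v[["nta_U1"]],
                      v[["nta_U2"]], v[["nta_C1"]], v[["nta_G1"]],
                      v[["canonical"]])
  }
  inserts <- var_seq[cbind(loc, ev_idx)]
  reads <- substr(paste0(inserts, adapter), 1L, read_len)

  # Sequencing errors at the plate rate.
  n_err <- stats::rbinom(n_reads, read_len, rate)
  one <- which(n_err == 1L)
  if (length(one)) {
    pos <- sample.int(read_len, length(one), replace = TRUE)
    cur <- substr(reads[one], pos, pos)
    step <- sample.int(3L, length(one), replace = TRUE)
    alt <- DNA_BASES[(match(cur, DNA_BASES) - 1L + step) %% 4L + 1L]
    substr(reads[one], pos, pos) <- alt
  }
  multi <- which(n_err >= 2L)
  for (i in multi) {
    pos <- sample.int(read_len, n_err[i])
    for (p in pos) {
      cur <- substr(reads[i], p, p)
      substr(reads[i], p, p) <- sample(setdiff(DNA_BASES, cur), 1L)
    }
  }

  qual <- rep(strrep(phred_char(qual_hi), read_len), n_reads)
  n_lowq <- stats::rbinom(1L, n_reads, lowq_frac)
  if (n_lowq > 0L) {
    li <- sample.int(n_reads, n_lowq)
    lp <- sample.int(read_len, n_lowq, replace = TRUE)
    substr(qual[li], lp, lp) <- phred_char(qual_lo)
  }

  ids <- sprintf("read%07d", seq_len(n_reads))
  event_out <- c(edit = "edit", five_prime = "five_prime", nta_A1 = "nta_A",
                 nta_A2 = "nta_A", nta_U1 = "nta_U", nta_U2 = "nta_U",
                 nta_C1 = "nta_C", nta_G1 = "nta_G",
                 canonical = "canonical")[ev]
  list(
    reads = data.table::data.table(id = ids, seq = reads, qual = qual),
    truth = data.table::data.table(id = ids, mirna = sites$mirna[loc],
                                   event = unname(event_out),
                                   n_errors = n_err)
  )
}

#' Validate an ANL/LUAD paired sample sheet
#'
#' Every patient of a paired cohort must contribute exactly one ANL and
#' one LUAD sample.
#'
#' @param samples data.table with columns `sample_id`, `cohort`,
#'   `group`, `patient_id`.
#' @return the sheet, invisibly; errors on the first unpaired patient.
#' @export
validate_sample_sheet <- function(samples) {
  s <- data.table::as.data.table(samples)
  chk <- s[, .(n_anl = sum(group == "ANL"), n_luad = sum(group == "LUAD")),
           by = .(cohort, patient_id)]
  bad <- chk[n_anl != 1L | n_luad != 1L]
  if (nrow(bad)) {
    stopf("unpaired patient '%s' in paired cohort '%s'",
          bad$patient_id[1], bad$cohort[1])
  }
  invisible(samples)
}

#' Simulate the full three-cohort study
#'
#' Builds the paired sample sheet (patients, groups, plates, tumor
#' stages, survival), plants per-sample true modification frequencies
#' with the configured LUAD effects, biological noise and enzyme
#' coupling, and generates a probe-level expression table for six
#' miRNA-modifying enzymes. Reads themselves are materialized lazily per
#' sample by [sample_reads()] (or written as FASTQ when `dir` is given),
#' keeping memory flat at full study size.
#'
#' @param config a [cohort_config()].
#' @param seed master seed; all per-sample seeds derive from it.
#' @param bundle optional `ReferenceBundle` (a default one is built from
#'   `seed` when omitted).
#' @param dir when non-NULL, write FASTQ files, the sample sheet, truth
#'   tables, enzyme expression and the reference to this directory.
#' @return an object of class `IsomirCohortSet`: list with `bundle`,
#'   `samples` (sample sheet incl. plate, stage, survival, per-sample
#'   seed), `truth` (per sample x locus true frequencies),
#'   `enzyme_expr` (gene-level), `enzyme_probes` + `probe_map`
#'   (probe-level), `weights`, `config`.
#' @export
simulate_cohorts <- function(config = cohort_config(), seed = 1L,
                             bundle = NULL, dir = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (is.null(bundle)) bundle <- make_reference(seed = seed)
  loci <- bundle$loci
  nl <- nrow(loci)
  set.seed(seed)

  # Locus abundance shares (fixed across samples).
  w <- stats::rlnorm(nl, 0, 0.7)
  w <- pmax(w / sum(w), config$min_abundance)
  w <- w / sum(w)

  shift_5p <- config$shift_5p %||%
    rep_len(c(1L, -1L, -2L, 1L, -1L), nl)

  # Sample sheet.
  sheets <- vector("list", length(config$cohorts))
  for (ci in seq_along(config$cohorts)) {
    co <- config$cohorts[ci]
    np <- config$n_pairs[ci]
    patient <- sprintf("%s_p%02d", co, seq_len(np))
    sheets[[ci]] <- data.table::data.table(
      cohort = co,
      patient_id = rep(patient, each = 2L),
      group = rep(c("ANL", "LUAD"), np),
      # Both samples of a pair are sequenced on the same plate, so plate
      # batch effects are orthogonal to the ANL/LUAD contrast.
      plate = sprintf("%s_plate%d", co,
                      rep(rep_len(seq_len(config$n_plates), np), each = 2L))
    )
  }
  samples <- data.table::rbindlist(sheets)
  samples[, sample_id := paste(patient_id, group, sep = "_")]
  samples[, adapter := config$adapters[match(cohort, config$cohorts)]]
  samples[, plate_rate := rep_len(config$plate_error_rates,
                                  config$n_plates)[
                                    as.integer(sub(".*plate", "", plate))]]
  samples[, n_reads := config$n_reads]
  ns <- nrow(samples)

  # Tumor stage (LUAD only); classifiers use stage I/II samples.
  stages <- c("IA", "IB", "II", "III")
  samples[, stage := NA_character_]
  samples[group == "LUAD",
          stage := sample(stages, .N, replace = TRUE,
                          prob = c(0.35, 0.25, 0.25, 0.15))]

  # Latents: enzyme copulas (per sample) and biological noise.
  zA <- stats::rnorm(ns); zB <- stats::rnorm(ns)
  types <- c("edit", "five_prime", "nta_a", "nta_u")
  # Patient effects are shared within a pair.
  pid <- match(samples$patient_id, unique(samples$patient_id))
  pe <- matrix(stats::rnorm(length(unique(pid)) * length(types), 0,
                            config$patient_sd),
               ncol = length(types), dimnames = list(NULL, types))[pid, ]
  se <- matrix(stats::rnorm(ns * length(types), 0, config$sample_sd),
               ns, length(types), dimnames = list(NULL, types))

  is_luad <- as.numeric(samples$group == "LUAD")
  base <- config$baseline
  eff <- config$effects

  truth_list <- vector("list", nl)
  for (li in seq_len(nl)) {
    f_edit <- base$edit + is_luad * eff$edit * (li %in% config$edit_effect_loci) +
      pe[, "edit"] + se[, "edit"] +
      config$kappa_enzyme * (zA * (li %in% config$adar_like_loci) +
                               zB * (li %in% config$adarb1_like_loci)) +
      stats::rnorm(ns, 0, config$site_sd)
    f_a <- base$nta_a + is_luad * eff$nta_a * (li %in% config$adenyl_effect_loci) +
      pe[, "nta_a"] + se[, "nta_a"] + stats::rnorm(ns, 0, config$site_sd)
    f_u <- base$nta_u + is_luad * eff$nta_u * (li %in% config$uridyl_effect_loci) +
      pe[, "nta_u"] + se[, "nta_u"] + stats::rnorm(ns, 0, config$site_sd)
    f_5p <- base$five_prime + pe[, "five_prime"] + se[, "five_prime"] +
      stats::rnorm(ns, 0, config$site_sd)
    truth_list[[li]] <- data.table::data.table(
      sample_id = samples$sample_id,
      mirna = loci$mirna[li],
      weight = w[li],
      shift_5p = shift_5p[li],
      freq_edit = clamp01(f_edit),
      freq_5p = clamp01(f_5p),
      freq_ntaA = clamp01(f_a),
      freq_ntaU = clamp01(f_u),
      freq_ntaC = base$nta_c,
      freq_ntaG = base$nta_g
    )
  }
  truth <- data.table::rbindlist(truth_list)
  data.table::setorder(truth, sample_id, mirna)

  # Per-sample editing level drives survival (LUAD samples only).
  lvl <- truth[, .(edit_level = mean(freq_edit)), by = sample_id]
  samples <- merge(samples, lvl, by = "sample_id", sort = FALSE)
  z_edit <- if (stats::sd(samples$edit_level) > 0) {
    as.numeric(scale(samples$edit_level))
  } else {
    rep(0, ns)
  }
  lambda <- log(2) / config$median_months * exp(-config$beta_os * z_edit)
  t_event <- stats::rexp(ns, rate = lambda)
  samples[, os_time := pmin(t_event, config$censor_months)]
  samples[, os_event := as.integer(t_event <= config$censor_months)]
  samples[group == "ANL", `:=`(os_time = NA_real_, os_event = NA_integer_)]

  samples[, seed := derive_seeds(seed + 7L, ns)]
  validate_sample_sheet(samples)

  # Enzyme expression: ADAR-like up in LUAD, ADARB1-like down; editing
  # couples positively to both latents. TENT-family genes shift without
  # coupling. Probe-level values exercise probe collapsing.
  genes <- c("ADAR", "ADARB1", "TENT2", "TENT4B", "TENT3A", "TENT3B")
  shifts <- c(0.8, -0.8, 0, 0, 0.5, 0.5)
  gex <- vapply(seq_along(genes), function(gi) {
    latent <- if (genes[gi] == "ADAR") zA else if (genes[gi] == "ADARB1") zB
    else stats::rnorm(ns)
    10 + 1.2 * latent + shifts[gi] * is_luad + stats::rnorm(ns, 0, 0.3)
  }, numeric(ns))
  colnames(gex) <- genes
  enzyme_expr <- data.table::data.table(sample_id = samples$sample_id, gex)
  probe_rows <- lapply(seq_along(genes), function(gi) {
    data.table::data.table(
      probe_id = sprintf("%s_probe%d", genes[gi], 1:2),
      gene = genes[gi])
  })
  probe_map <- data.table::rbindlist(probe_rows)
  pvals <- rbind(t(gex), 0.4 * t(gex) +
                   matrix(stats::rnorm(length(genes) * ns, 0, 0.3),
                          length(genes), ns))
  rownames(pvals) <- c(sprintf("%s_probe1", genes), sprintf("%s_probe2", genes))
  enzyme_probes <- data.table::data.table(
    probe_id = rownames(pvals),
    pvals)
  data.table::setnames(enzyme_probes, c("probe_id", samples$sample_id))

  cs <- list(bundle = bundle, samples = samples[], truth = truth,
             enzyme_expr = enzyme_expr, enzyme_probes = enzyme_probes,
             probe_map = probe_map, weights = w, config = config)
  class(cs) <- "IsomirCohortSet"

  if (!is.null(dir)) write_cohorts(cs, dir)
  cs
}

#' Materialize the reads of one simulated sample
#'
#' @param cs an `IsomirCohortSet`.
#' @param sample_id sample identifier from the sheet.
#' @return as [simulate_sample()].
#' @export
sample_reads <- function(cs, sample_id) {
  sel <- which(cs$samples[["sample_id"]] == sample_id)
  s <- cs$samples[sel]
  if (nrow(s) != 1L) stopf("unknown sample '%s'", sample_id)
  sel_truth <- which(cs$truth[["sample_id"]] == sample_id)
  sites <- cs$truth[sel_truth]
  profile <- list(
    sites = sites,
    plate_error_rate = s$plate_rate,
    lowq_frac = cs$config$lowq_frac,
    read_len = cs$config$read_len,
    qual_hi = cs$config$qual_hi,
    qual_lo = cs$config$qual_lo
  )
  simulate_sample(cs$bundle, profile, s$n_reads, s$adapter, s$seed)
}

#' Write a simulated cohort set to disk
#'
#' FASTQ per sample plus sample sheet, truth tables, enzyme expression
#' and the reference bundle, all as plain text.
#'
#' @param cs an `IsomirCohortSet`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_cohorts <- function(cs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_reference(cs$bundle, file.path(dir, "reference"))
  for (co in unique(cs$samples$cohort)) {
    cdir <- file.path(dir, co)
    dir.create(cdir, showWarnings = FALSE)
    ids <- cs$samples[cs$samples$cohort == co]$sample_id
    for (sid in ids) {
      sim <- sample_reads(cs, sid)
      write_fastq(sim$reads, file.path(cdir, paste0(sid, ".fastq")))
    }
    data.table::fwrite(cs$samples[cs$samples$cohort == co,
                                  .(sample_id, cohort, group, patient_id,
                                    plate, stage, os_time, os_event)],
                       file.path(cdir, "samples.tsv"), sep = "\t")
  }
  data.table::fwrite(cs$samples, file.path(dir, "samples_full.tsv"), sep = "\t")
  data.table::fwrite(cs$truth, file.path(dir, "truth.tsv"), sep = "\t")
  data.table::fwrite(cs$enzyme_expr, file.path(dir, "enzyme_expression.tsv"),
                     sep = "\t")
  data.table::fwrite(cs$enzyme_probes, file.path(dir, "enzyme_probes.tsv"),
                     sep = "\t")
  data.table::fwrite(cs$probe_map, file.path(dir, "probe_map.tsv"), sep = "\t")
  invisible(dir)
}

#' @export
print.IsomirCohortSet <- function(x, ...) {
  cat(sprintf("IsomirCohortSet: %d cohorts, %d samples (%d pairs), %d loci, %d reads/sample\n",
              length(unique(x$samples$cohort)), nrow(x$samples),
              nrow(x$samples) %/% 2L, nrow(x$bundle$loci),
              x$config$n_reads))
  invisible(x)
}
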