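# data.table non-standard evaluation columns.
utils::globalVariables(c(
  ".", ".N", ".SD", "N", "adapter", "alt", "any_group", "base", "cg",
  "cohort", "count", "counterpart", "covered", "e", "edit_level",
  "err_pass", "expressed", "fdr", "fdr_1", "fdr_2", "five_prime_shift",
  "gene", "group", "hairpin_end", "hairpin_seq", "hairpin_start",
  "high_confidence", "is_decoy", "keep", "kind", "L", "mature_end",
  "mature_seq", "mature_start", "mean_expr", "mirna", "mismatches",
  "n_anl", "n_err", "n_errors", "n_isomirs", "n_luad", "n_reads",
  "n_rpm", "n_samples", "n_sub", "n_sub_at", "name", "nta", "os_event",
  "os_time", "p", "p_adjusted", "patient_id", "plate", "plate_rate",
  "position", "probe_id", "qi", "qual", "rate", "reason", "rho_1",
  "rho_2", "rpm_pass", "sample_id", "seed", "sense_hairpin_end",
  "sense_hairpin_start", "sense_mature_end", "sense_mature_start",
  "seq_len_", "shift_5p", "significant", "stage", "start", "status",
  "strand", "sub_alt", "sub_internal", "sub_pos", "sub_ref", "tot",
  "tot0", "tot_notail", "total", "three_prime_shift", "..sample_cols",
  "both_positive"))
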