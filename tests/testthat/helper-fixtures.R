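# Shared fixtures, built in code and memoized per test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

default_bundle <- function() {
  fixture("bundle", function() make_reference(seed = 101L))
}

# A small but complete three-cohort study (6 pairs, 8k reads) and its
# processed experiment, reused by integration-style tests.
small_cohorts <- function() {
  fixture("small_cs", function() {
    simulate_cohorts(cohort_config(n_pairs = c(6L, 6L, 6L),
                                   n_reads = 8000L),
                     seed = 301L, bundle = default_bundle())
  })
}

small_experiment <- function() {
  fixture("small_ex", function() run_experiment(small_cohorts()))
}

# Independent Benjamini-Hochberg step-up oracle (textbook definition).
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Independent binomial upper-tail oracle by explicit term summation in
# log space (never calls pbinom).
binom_tail_oracle <- function(k, n, e) {
  if (n == 0L) return(1)
  if (k <= 0L) return(1)
  if (k > n) return(0)
  i <- k:n
  sum(exp(lchoose(n, i) + i * log(e) + (n - i) * log1p(-e)))
}

# Error-free single-locus profile helper.
flat_profile <- function(bundle, edit = 0, fivep = 0, ntaA = 0, ntaU = 0,
                         ntaC = 0, ntaG = 0, rate = 0, lowq = 0,
                         weights = NULL) {
  loci <- bundle$loci
  nl <- nrow(loci)
  list(
    sites = data.table::data.table(
      mirna = loci$mirna,
      weight = weights %||% rep(1 / nl, nl),
      shift_5p = rep_len(c(1L, -1L, -2L), nl),
      freq_edit = rep_len(edit, nl),
      freq_5p = rep_len(fivep, nl),
      freq_ntaA = rep_len(ntaA, nl),
      freq_ntaU = rep_len(ntaU, nl),
      freq_ntaC = rep_len(ntaC, nl),
      freq_ntaG = rep_len(ntaG, nl)),
    plate_error_rate = rate,
    lowq_frac = lowq,
    read_len = 36L,
    qual_hi = 30L,
    qual_lo = 20L)
}

ADAPTER_A <- "ATCTCGTATGCCGTCTTCTGCTTGT"
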