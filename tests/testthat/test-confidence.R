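test_that("error model takes the max of floor and observed, per plate", {
  tall <- data.table::data.table(
    plate = c("p1", "p1", "p2"),
    position = c(4L, 4L, 4L),
    type = "A>G",
    matches = c(999L, 990L, 0L),
    mismatches = c(1L, 10L, 0L))
  m <- estimate_error_rates(tall)
  floor <- phred_error_rate(25)
  # observed 11/2000 = 0.0055 on p1 exceeds the floor
  expect_equal(query_error_rate(m, "p1", 4L, "A>G"), 11 / 2000)
  # zero coverage on p2 falls back to the floor
  expect_equal(query_error_rate(m, "p2", 4L, "A>G"), floor)
  # a different position falls back to the floor
  expect_equal(query_error_rate(m, "p1", 9L, "A>G"), floor)
  # observed below the floor is raised to it
  t2 <- data.table::data.table(plate = "p1", position = 0L, type = "C>T",
                               matches = 9990L, mismatches = 10L)
  expect_equal(query_error_rate(estimate_error_rates(t2), "p1", 0L, "C>T"),
               floor)
  # 5'/NTA channels use the conservative 2% constant
  expect_equal(query_error_rate(m, "p1", type = "NTA"), 0.02)
  expect_equal(query_error_rate(m, "p2", type = "FIVE_PRIME"), 0.02)
  expect_error(query_error_rate(m, "p9", 4L, "A>G"), "unknown plate")
})

test_that("binomial error test matches its closed-form corners", {
  expect_equal(binomial_error_test(0, 100, 0.01), 1)
  expect_equal(binomial_error_test(5, 0, 1 - 1e-12), 1, tolerance = 1e-9)
  expect_equal(binomial_error_test(0, 0, 0.01), 1)
  expect_error(binomial_error_test(3, 10, 0), "strictly")
  expect_error(binomial_error_test(-1, 10, 0.01), "non-negative")
  # worked example: k = 3 of n = 100 at the Phred-25 floor
  e <- 0.0032
  oracle <- binom_tail_oracle(3L, 100L, e)
  expect_equal(binomial_error_test(3, 97, e), oracle, tolerance = 1e-12)
})

test_that("binomial tail agrees with the summation oracle for all n <= 200", {
  max_diff <- 0
  for (e in c(0.0032, 0.01, 0.02)) {
    for (n in c(1L, 2L, 5L, 10L, 50L, 100L, 200L)) {
      for (k in unique(pmin(c(0L, 1L, 2L, 3L, 5L, n %/% 2L, n - 1L, n), n))) {
        d <- abs(binomial_error_test(k, n - k, e) -
                   binom_tail_oracle(k, n, e))
        max_diff <- max(max_diff, d)
      }
    }
  }
  expect_lt(max_diff, 1e-10)
})

test_that("binomial tail is monotone in count and error rate", {
  n <- 150L
  e <- 0.01
  p_by_k <- binomial_error_test(0:n, n - (0:n), e)
  expect_true(all(diff(p_by_k) <= 1e-15))
  es <- c(0.001, 0.0032, 0.01, 0.02, 0.1, 0.5)
  p_by_e <- binomial_error_test(5, 145, es)
  expect_true(all(diff(p_by_e) >= -1e-15))
})

test_that("BH rejection follows the step-up procedure and the 3-read rule", {
  # hand-checkable step-up: (0.001, 0.02, 0.04, 0.8), m = 4
  r <- reject_error_hypothesis(c(0.001, 0.02, 0.04, 0.8), reads = c(5, 5, 5, 5))
  expect_equal(r$p_adjusted, c(0.004, 0.04, 0.04 * 4 / 3, 0.8))
  expect_equal(r$pass, c(TRUE, TRUE, FALSE, FALSE))
  # fewer than three reads fails regardless of p
  r2 <- reject_error_hypothesis(1e-9, reads = 2)
  expect_false(r2$pass)
  # a single candidate keeps its raw p
  r3 <- reject_error_hypothesis(0.01, reads = 5)
  expect_equal(r3$p_adjusted, 0.01)
  expect_true(r3$pass)
})

test_that("BH adjustment matches an independent oracle on random vectors", {
  set.seed(11)
  max_diff <- 0
  for (i in 1:200) {
    m <- sample(1:60, 1)
    p <- runif(m)^sample(1:3, 1)
    got <- reject_error_hypothesis(p, reads = rep(5, m))$p_adjusted
    max_diff <- max(max_diff, max(abs(got - bh_oracle(p))))
  }
  expect_lt(max_diff, 1e-12)
})

test_that("group expression requires both criteria in >= 10% of samples", {
  expect_true(expressed_in_group(c(TRUE, rep(FALSE, 9)),
                                 c(TRUE, rep(FALSE, 9))))
  expect_false(expressed_in_group(rep(c(TRUE, FALSE), 5), rep(FALSE, 10)))
  expect_true(expressed_in_group(c(TRUE, TRUE, rep(FALSE, 8)),
                                 mirna_mode = TRUE))
  expect_false(expressed_in_group(c(TRUE, rep(FALSE, 19)),
                                  c(TRUE, rep(FALSE, 19))))
  expect_error(expressed_in_group(logical(0), logical(0)), "no retained")
})

test_that("blacklist filter matches substitutions and NTAs exactly", {
  b <- default_bundle()
  bl_mirna <- b$blacklist$mirna[1]
  bl_off <- b$blacklist$offset[1]
  keys <- data.table::data.table(
    mirna = rep(bl_mirna, 4),
    kind = c("EDIT_AI", "EDIT_AI", "EDIT_AI", "FIVE_PRIME"),
    five_prime_shift = c(0L, -1L, 0L, 1L),
    position = c(bl_off, bl_off + 1L, bl_off + 3L, NA),
    base = NA_character_)
  keep <- blacklist_filter(keys, b$blacklist, b)
  # direct hit and the shifted key landing on the same mature offset drop
  expect_equal(keep, c(FALSE, FALSE, TRUE, TRUE))
  # same offset, different alternative base is kept
  bl2 <- data.table::data.table(mirna = bl_mirna, offset = bl_off, alt = "T")
  expect_true(all(blacklist_filter(keys[1], bl2, b)))
  # NTA key matching a blacklisted tail base at the tail offset drops
  mlen <- nchar(b$loci$mature_seq[1])
  keys_nta <- data.table::data.table(
    mirna = b$loci$mirna[1], kind = "NTA_A", five_prime_shift = NA_integer_,
    position = 1L, base = "A")
  bl3 <- data.table::data.table(mirna = b$loci$mirna[1], offset = mlen,
                                alt = "A")
  expect_false(blacklist_filter(keys_nta, bl3, b))
})

test_that("cross-mapping discards decoys and keeps unique loci", {
  b <- default_bundle()
  dec <- b$loci[b$loci$is_decoy == TRUE]
  uniq <- b$loci[b$loci$is_decoy == FALSE & b$loci$strand == "+"][1]
  expect_false(cross_map_filter(dec$mirna, dec$mature_seq, b))
  expect_true(cross_map_filter(uniq$mirna, uniq$mature_seq, b))
})

test_that("CCA-ending isomiRs mapping into tRNA space are discarded", {
  # Handcrafted genome: one locus whose mature sequence ends in CCA and
  # whose CCA-trimmed sequence also occurs inside an annotated tRNA gene.
  set.seed(21)
  g <- paste(sample(c("A", "C", "G", "T"), 3000, TRUE), collapse = "")
  core <- paste(sample(c("A", "C", "G", "T"), 19, TRUE), collapse = "")
  mat <- paste0(core, "CCA")
  substr(g, 501, 522) <- mat
  substr(g, 1601, 1619) <- core     # inside the tRNA region below
  loci <- data.frame(mirna = "mir-cca", strand = "+",
                     hairpin_start = 480L, hairpin_end = 542L,
                     mature_start = 500L, mature_end = 522L)
  bb <- new_reference_bundle(g, loci,
                             trna_regions = data.frame(start = 1590L,
                                                       end = 1665L,
                                                       strand = "+"))
  expect_false(cross_map_filter("mir-cca", mat, bb))
  # without the tRNA annotation the same sequence survives
  bb2 <- new_reference_bundle(g, loci)
  expect_true(cross_map_filter("mir-cca", mat, bb2))
})

test_that("high confidence needs two of three cohorts, any group", {
  f <- function(rows) high_confidence(rows)$high_confidence
  base <- data.table::CJ(name = "k", cohort = c("c1", "c2", "c3"),
                         group = c("ANL", "LUAD"))
  e1 <- data.table::copy(base)[, expressed := FALSE]
  e1[cohort == "c1" & group == "ANL", expressed := TRUE]
  e1[cohort == "c3" & group == "LUAD", expressed := TRUE]
  expect_true(f(e1))
  e2 <- data.table::copy(base)[, expressed := FALSE]
  e2[cohort == "c2", expressed := TRUE]    # both groups, one cohort
  expect_false(f(e2))
  e3 <- data.table::copy(base)[, expressed := FALSE]
  expect_false(f(e3))
})
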