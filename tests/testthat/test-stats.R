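test_that("isomiR frequency definition and undefined handling", {
  expect_equal(isomir_frequency(10, 100), 0.1)
  expect_equal(isomir_frequency(0, 100), 0)
  expect_true(is.na(isomir_frequency(0, 0)))
  expect_error(isomir_frequency(101, 100), "exceeds")
  expect_error(isomir_frequency(-1, 100), ">= 0")
})

test_that("z-scores standardize per isomiR and propagate undefined values", {
  m <- matrix(c(0.1, 0.3,
                0.2, 0.2,
                0.1, NA), nrow = 3, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  expect_warning(z <- zscore_matrix(m), "no frequency spread")
  # hand computation with the n-1 standard deviation
  expect_equal(unname(z["a", ]), c(-1, 1) / sqrt(2), tolerance = 1e-12)
  expect_equal(unname(z["b", ]), c(0, 0))
  expect_true(is.na(z["c", "s2"]))

  # property: defined entries have mean 0 and sd 1 within 1e-10
  set.seed(3)
  mm <- matrix(runif(300), 10, 30,
               dimnames = list(paste0("i", 1:10), paste0("s", 1:30)))
  mm[sample(length(mm), 40)] <- NA
  zz <- zscore_matrix(mm)
  for (i in 1:10) {
    v <- zz[i, !is.na(zz[i, ])]
    expect_lt(abs(mean(v)), 1e-10)
    expect_lt(abs(sd(v) - 1), 1e-10)
  }
})

test_that("modification rate averages defined z-scores only", {
  z <- matrix(c(0, 0,
                1, NA,
                -1, NA), nrow = 3, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  r <- modification_rate(z, kinds = rep("EDIT_AI", 3))
  expect_equal(r[r$sample_id == "s1"]$rate, 0)
  expect_equal(r[r$sample_id == "s2"]$rate, 0)   # only the defined zero
  expect_equal(r[r$sample_id == "s2"]$n_isomirs, 1L)
  z2 <- matrix(NA_real_, 1, 1, dimnames = list("a", "s1"))
  r2 <- modification_rate(z2, "EDIT_AI")
  expect_true(is.na(r2$rate))
})

test_that("paired differential: identical vectors, dropped pairs, directions", {
  sheet <- data.table::data.table(
    sample_id = c(paste0("p", 1:6, "_A"), paste0("p", 1:6, "_T")),
    cohort = "c1", group = rep(c("ANL", "LUAD"), each = 6),
    patient_id = rep(paste0("p", 1:6), 2))
  v <- setNames(rep(0.5, 12), sheet$sample_id)
  r <- paired_differential(v, sheet, mode = "rates")
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  # a pair with NA on one side is dropped
  v2 <- setNames(c(1:6 / 10, 1:6 / 10 + 0.2), sheet$sample_id)
  v2["p3_T"] <- NA
  r2 <- paired_differential(v2, sheet, mode = "rates")
  expect_equal(r2$n_pairs, 5L)
  expect_equal(r2$direction, "higher_in_LUAD")
  expect_true(r2$significant)
  # fewer than 3 usable pairs: flagged, no test
  v3 <- v2; v3[c("p1_T", "p2_T", "p4_T", "p5_T")] <- NA
  r3 <- paired_differential(v3, sheet, mode = "rates")
  expect_true(is.na(r3$p))
})

test_that("per-isomiR differential controls FDR on null data", {
  set.seed(5)
  n_pairs <- 20L
  sheet <- data.table::data.table(
    sample_id = c(paste0("p", 1:n_pairs, "_A"), paste0("p", 1:n_pairs, "_T")),
    cohort = "c1", group = rep(c("ANL", "LUAD"), each = n_pairs),
    patient_id = rep(paste0("p", 1:n_pairs), 2))
  n_iso <- 100L
  false_frac <- replicate(30, {
    m <- matrix(rnorm(n_iso * 2 * n_pairs, 0.2, 0.02), n_iso,
                dimnames = list(paste0("i", 1:n_iso), sheet$sample_id))
    res <- paired_differential(m, sheet, mode = "frequencies")
    mean(res$significant)
  })
  # expected false-positive fraction at FDR 0.05 stays near/below 5%
  expect_lt(mean(false_frac), 0.05 + 3 * sd(false_frac) / sqrt(30))
})

test_that("per-isomiR differential flags exactly the shifted features", {
  set.seed(6)
  n_pairs <- 16L
  sheet <- data.table::data.table(
    sample_id = c(paste0("p", 1:n_pairs, "_A"), paste0("p", 1:n_pairs, "_T")),
    cohort = "c1", group = rep(c("ANL", "LUAD"), each = n_pairs),
    patient_id = rep(paste0("p", 1:n_pairs), 2))
  reps <- replicate(25, {
    m <- matrix(rnorm(16 * 2 * n_pairs, 0.2, 0.02), 16,
                dimnames = list(paste0("i", 1:16), sheet$sample_id))
    m[1:8, sheet$group == "LUAD"] <- m[1:8, sheet$group == "LUAD"] - 0.05
    res <- paired_differential(m, sheet, mode = "frequencies")
    v <- sum(res$significant[match(paste0("i", 9:16), res$name)])
    r <- sum(res$significant)
    c(all_true = all(res$significant[match(paste0("i", 1:8), res$name)] &
                       res$direction[match(paste0("i", 1:8), res$name)] ==
                       "lower_in_LUAD"),
      fdp = if (r > 0) v / r else 0)
  })
  # every planted feature recovered with the right sign in >= 90% of
  # replicates, and the realized false-discovery proportion is controlled
  expect_gte(mean(reps["all_true", ]), 0.9)
  expect_lte(mean(reps["fdp", ]),
             0.05 + 3 * sd(reps["fdp", ]) / sqrt(ncol(reps)))
})

test_that("enzyme correlations: perfect monotone, null calibration, grouping", {
  sheet <- data.table::data.table(
    sample_id = paste0("s", 1:30), cohort = "c1", group = "LUAD",
    patient_id = paste0("s", 1:30))
  x <- seq(0.01, 0.3, length.out = 30)
  freq <- matrix(x, 1, dimnames = list("iso1", sheet$sample_id))
  enz <- data.table::data.table(sample_id = sheet$sample_id,
                                ADAR = exp(x), ADARB1 = rnorm(30))
  r <- correlate_enzymes(freq, enz, sheet)
  expect_equal(r$rho_ADAR, 1)
  expect_equal(r$group, "ADAR")

  # null calibration: raw p < 0.05 in about 5% of independent pairs
  set.seed(8)
  n <- 100L
  sheet2 <- data.table::data.table(
    sample_id = paste0("s", 1:n), cohort = "c1", group = "LUAD",
    patient_id = paste0("s", 1:n))
  hits <- replicate(40, {
    fr <- matrix(rnorm(20 * n), 20, dimnames = list(paste0("i", 1:20),
                                                    sheet2$sample_id))
    en <- data.table::data.table(sample_id = sheet2$sample_id,
                                 ADAR = rnorm(n), ADARB1 = rnorm(n))
    rr <- correlate_enzymes(fr, en, sheet2)
    mean(rr$p_ADAR < 0.05)
  })
  expect_lt(abs(mean(hits) - 0.05), 3 * sqrt(0.05 * 0.95 / (40 * 20)))

  # coupling to one enzyme only assigns that enzyme's group
  set.seed(9)
  latent <- rnorm(30)
  fr3 <- matrix(0.2 + 0.05 * latent + rnorm(30, 0, 0.01), 1,
                dimnames = list("isoA", sheet$sample_id))
  enz3 <- data.table::data.table(sample_id = sheet$sample_id,
                                 ADAR = rnorm(30),
                                 ADARB1 = latent + rnorm(30, 0, 0.2))
  r3 <- correlate_enzymes(fr3, enz3, sheet)
  expect_equal(r3$group, "ADARB1")
})

test_that("median-split survival: ties, nulls, planted hazard, degenerate arms", {
  # two identical arms: statistic 0, p = 1
  values <- rep(c(0, 1), each = 10)
  times <- rep(1:10, 2)
  events <- rep(1L, 20)
  r <- median_split_survival(values, times, events)
  expect_equal(r$statistic, 0, tolerance = 1e-12)
  expect_equal(r$p, 1)

  # all values identical: no split
  r2 <- median_split_survival(rep(1, 20), times, events)
  expect_equal(r2$flag, "no_split")

  # planted hazard ratio 2: p < 0.05 in >= 80% of replicates at n = 200
  set.seed(10)
  power <- replicate(40, {
    v <- rnorm(200)
    lam <- 0.02 * 2^(v > median(v))
    t <- rexp(200, lam)
    ev <- as.integer(t < 100); t <- pmin(t, 100)
    median_split_survival(v, t, ev)$p < 0.05
  })
  expect_gte(mean(power), 0.8)

  # an arm without events is computed but flagged
  ev3 <- c(rep(1L, 10), rep(0L, 10))
  r3 <- median_split_survival(values, times, ev3)
  expect_equal(r3$flag, "arm_without_events")
  expect_false(is.na(r3$p))
})

test_that("catalog summary: seed window and adjacent-base tallies", {
  ct <- data.table::data.table(
    mirna = c("m1", "m2", "m3"),
    five_prime_shift = c(0L, 0L, -1L),
    edited_position = c(0L, 4L, 16L),
    adjacent_5p = c("U", "U", "A"),
    adjacent_3p = c("C", "G", "A"))
  s <- summarize_catalog(ct)
  expect_equal(s$n_sites, 3L)
  expect_equal(s$n_seed, 1L)      # only position 4; 0 and 16 are outside
  expect_equal(unname(s$adjacent_5p_counts["U"]), 2L)
  expect_error(summarize_catalog(data.table::data.table(
    mirna = "m", five_prime_shift = 0L, edited_position = -1L,
    adjacent_5p = "U", adjacent_3p = "C")), "outside")
})

test_that("catalog built from experiment keys reads precursor context", {
  b <- default_bundle()
  keys <- data.table::data.table(
    mirna = b$loci$mirna[1:2],
    five_prime_shift = c(0L, 0L),
    position = b$loci$edit_pos[1:2])
  ct <- catalog_from_keys(keys, b)
  expect_equal(ct$edited_base, c("A", "A"))
  # the configured 5'-adjacent U shows up in RNA alphabet
  expect_equal(ct$adjacent_5p, c("U", "U"))
})

test_that("probe collapsing keeps the highest-mean probe with a stable tiebreak", {
  probes <- data.table::data.table(
    probe_id = c("g1_p1", "g1_p2", "g2_p1", "g3_p2", "g3_p1"),
    s1 = c(5, 9, 1, 2, 2), s2 = c(5, 9, 1, 2, 2))
  map <- data.table::data.table(
    probe_id = c("g1_p1", "g1_p2", "g2_p1", "g3_p1", "g3_p2"),
    gene = c("g1", "g1", "g2", "g3", "g3"))
  out <- collapse_probes(probes, map)
  expect_equal(out[out$gene == "g1"]$probe_id, "g1_p2")   # mean 9 beats 5
  expect_equal(out[out$gene == "g2"]$probe_id, "g2_p1")   # single probe
  expect_equal(out[out$gene == "g3"]$probe_id, "g3_p1")   # tie: lowest id
  out2 <- collapse_probes(probes, map, genes = c("g1", "g9"))
  expect_equal(attr(out2, "missing"), "g9")
})

test_that("isomiR share of the published catalog is reproduced from counts", {
  share <- isomir_sequence_share()
  expect_equal(share, 100 * 457 / 1111, tolerance = 1e-12)
})
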