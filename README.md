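# isomirome

Tumors rewire not only which microRNAs they express but how those
miRNAs are post-transcriptionally modified. The variant molecules —
**isomiRs** — carry 5′-end shifts, non-templated 3′ additions
(adenylation, uridylation) or A-to-I editing (adenosine read as G by the
sequencer), and the *rate* at which a miRNA is modified can separate
tumor from normal tissue even when its overall expression does not.
`isomirome` is an R package for exactly this kind of analysis in paired
tumor/normal small-RNA sequencing studies: it detects the four isomiR
types from reads, separates them from sequencing error, quantifies
per-sample modification rates, tests paired group differences,
correlates editing with ADAR-family enzyme expression, runs median-split
survival analysis, and evaluates isomiRs as cross-cohort machine-learning
biomarkers. It is aimed at computational biologists who want a tested,
self-contained re-implementation of this analysis style that runs
end-to-end on simulated data with planted ground truth.

## The method in brief

For an isomiR *i* of miRNA *m* in sample *s*, the frequency is

```
f_is = RPM(i, s) / RPM(family of m, s)
```

where the family combines the canonical miRNA and all of its isomiRs.
An isomiR is separated from sequencing error by a binomial test: with
*k* modified reads among *n* otherwise identical reads and a baseline
error rate *e*, the error hypothesis is rejected when

```
P(X >= k),  X ~ Binomial(n, e)
```

falls below 0.05 after Benjamini–Hochberg correction within the sample
(and k >= 3). For substitutions, `e = max(10^-2.5, observed rate of the
same substitution at the same read position on the same sequencing
plate)`; for 5′ shifts and 3′ tails, a conservative `e = 0.02`.
Candidates must also reach 1 RPM and the error-test pass each in ≥10%
of a group's samples, survive blacklist (known SNP/somatic variant) and
cross-mapping filters (including the tRNA CCA-tail trap), and be
expressed in at least two of three cohorts to count as high-confidence.
A sample's modification rate per isomiR type is the mean z-score of the
type's high-confidence isomiR frequencies, standardized across all
samples of all cohorts. Classifiers (radial-basis SVM, 300-tree random
forest) separate normal lung (ANL) from stage I/II adenocarcinoma
(LUAD); cross-cohort models train on one cohort with differential
features and tuned hyperparameters, and report rank AUC on the held-out
cohorts.

## Worked example

Summarize a published catalog of 16 high-confidence A-to-I editing
sites in human lung tissue (shipped with the package):

```r
library(isomirome)
s <- summarize_catalog(lung_editing_catalog())
sprintf("%d editing sites; %.2f%% in the seed region; %.0f%% with a 5' adjacent U",
        s$n_sites, s$seed_pct, s$adjacent_5p_u_pct)
#> "16 editing sites; 81.25% in the seed region; 75% with a 5' adjacent U"
```

A seed-region edit (isomiR positions 1–7, 0-based) re-targets the
miRNA, and a 5′-adjacent uracil is the sequence context ADAR-family
enzymes prefer — both percentages are diagnostic summaries a catalog of
true editing sites should reproduce.

Then a small simulated study — three cohorts of six ANL/LUAD pairs,
8,000 reads per sample, with editing and adenylation deficits and a
uridylation excess planted in the tumor group:

```r
cs <- simulate_cohorts(cohort_config(n_pairs = c(6, 6, 6),
                                     n_reads = 8000), seed = 1)
ex <- run_experiment(cs)
ex
#> IsomirExperiment: 36 samples, 170 candidate isomiR keys, 61 high-confidence
#>   high-confidence by type: EDIT_AI=10, FIVE_PRIME=11, NTA_A=20, NTA_U=20

ex$rate_tests[ex$rate_tests$kind == "EDIT_AI",
              c("cohort", "n_pairs", "t", "p", "significant", "direction")]
#>     cohort n_pairs         t          p significant     direction
#> 1: cohortA       6 -1.684815 0.15283979       FALSE lower_in_LUAD
#> 2: cohortB       6 -3.615499 0.01529171        TRUE lower_in_LUAD
#> 3: cohortC       6 -1.639270 0.16208205       FALSE lower_in_LUAD
```

All ten clean loci yield a high-confidence edit key, and the planted
editing deficit points the right way in every cohort — though at six
pairs only one cohort reaches significance; the default design
(`cohort_config()`, 20 pairs and ~50k reads per sample) is powered to
make all three significant, which is what the acceptance suite checks.
The decoy locus (planted twice in the genome) and the blacklisted edit
site are absent from the high-confidence set: `ex$audit` counts what
each filter removed.

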