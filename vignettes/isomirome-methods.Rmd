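---
title: "Methods: isomiR detection, error modelling and biomarker evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: isomiR detection, error modelling and biomarker evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope

`isomirome` implements a complete small-RNA analysis chain for four types
of miRNA sequence variants (isomiRs): 5' shifted, 3' adenylated, 3'
uridylated and A-to-I edited. It covers read preparation, locus
annotation, a sequencing-error-aware confidence filter, per-sample
modification-rate statistics with paired tumor/normal comparisons,
correlation and survival analyses, and SVM/random-forest biomarker
evaluation across cohorts. Because the real cohorts this kind of study
uses are controlled-access or very large, the package ships a
synthetic-data generator that plants known modification frequencies in
simulated paired cohorts; every downstream claim the test suite makes is
checked against that planted truth.

## The measurement model

A sequenced small-RNA read is modelled as a mature miRNA variant
followed by the library's 3' adapter, truncated to the machine read
length, with independent per-base substitution errors. After adapter
trimming and an all-bases Phred >= 25 filter, each insert is aligned to
the reference and decomposed into:

* a 5' shift (positive = trimmed relative to the canonical 5' end,
  negative = extension into the precursor),
* a templated 3' end (at most 2 nt from the canonical end, else the read
  is discarded),
* a non-templated 3' tail: the maximal 3' suffix that does not match the
  genomic continuation, capped at 3 nt, and
* internal substitutions (reads with two or more are discarded).

Collapsing then ignores the positions irrelevant to each isomiR type:
5' keys ignore all 3' variation, NTA keys ignore 5' variation and keep
only homopolymer tails whose final base sits 1 or 2 nt past the
canonical end, and edit keys ignore the final two read bases entirely -
a read whose only substitution lies there is pooled with its
unsubstituted counterpart. An isomiR's *frequency* in a sample is its
reads-per-million divided by its miRNA family total (canonical plus all
isomiRs of the miRNA); it is undefined when the family is silent.

Inherent ambiguities of this decomposition are worth naming: a
substitution in the final read base is indistinguishable from a 1-nt
tail (it is treated as 3' variation, which the edit collapse ignores
anyway), and a tail base identical to the genomic continuation is
invisible. The synthetic reference sidesteps the second ambiguity by
fixing the two bases 3' of each mature end to C/G, so planted A/U tails
are always observable; real genomes do not offer that guarantee, and on
real data tail counts at such loci are a lower bound.

## The confidence filter

Candidate isomiRs pass four screens, in order:

1. **Blacklist**: keys whose characteristic substitution or tail matches
   a known variant (SNP or somatic mutation supplied as a table of
   miRNA, mature-relative offset and alternative base) are discarded.
2. **Binomial error test, per sample**: the count of an isomiR's reads
   and the count of otherwise identical reads lacking its characteristic
   event enter the upper tail of Binomial(n, e). For substitutions, e is
   the greater of the Phred-25 expectation (10^-2.5, i.e. 0.32%) and the
   observed rate of the same substitution type at the same read position
   among canonical-mapped reads on the same sequencing plate - plates
   are a known batch-effect axis in small-RNA data. For 5' shifts and
   non-templated tails e is a deliberately conservative 2%. Within each
   sample the p-values of one isomiR type are Benjamini-Hochberg
   adjusted; the error hypothesis is rejected at adjusted p < 0.05 with
   at least 3 reads. The BH family is per type per sample by default (a
   `bh_family = "joint"` switch pools the types) - the per-type family
   is the more conservative reading and keeps types independent.
3. **Expression per group**: an isomiR is expressed in a cohort's ANL or
   LUAD group when it reaches 1 RPM in >= 10% of the group's samples and
   passes the error rejection in >= 10% of the group's samples, counted
   independently. miRNAs use the RPM criterion only.
4. **Cross-mapping**: an expressed isomiR is discarded when its most
   highly expressed sequence maps to another genomic site as well as to
   its own stem-loop (equal mismatch count; a longer 3' overhang at the
   other site rescues the key). Sequences ending in CCA - the tail
   ligated onto every mature tRNA - are re-searched without it and
   discarded if the trimmed sequence lies in an annotated tRNA gene.

A key is **high-confidence** when it is expressed in at least one group
in at least two of the three cohorts.

The "otherwise identical" counterpart is anchored per type: for an edit,
reads with the same 5' shift whose base at the edited position is the
reference; for a tail, tail-free reads of the miRNA; for a 5' shift,
reads with the canonical 5' end. The plate error model is estimated only
from reads mapped with no 5' shift, no tail and at most one substitution,
so the model is not fed by the very isomiRs it will judge. Pooling
"same type, same position" across loci means that a genuine editing
hotspot inflates the position's observed rate; with many loci sharing a
position this can swallow real signal, which is why the synthetic
reference places each locus's editing site at a distinct mature position
- mirroring the variety of real editing catalogs.

## Rates, differentials, correlations, survival

For every high-confidence isomiR a z-score standardizes its frequency
across *all samples of all cohorts* (n-1 denominator); undefined
frequencies stay undefined and are excluded sample-wise. A sample's
modification rate for one type is the mean of its defined z-scores. Rates
and per-isomiR frequencies are compared between paired ANL and LUAD
samples by paired t-tests, per cohort: rates at p < 0.05, per-isomiR
tables BH-adjusted within cohort at FDR < 0.05. Enzyme correlations are
Spearman's rho in tumor samples only, BH-adjusted per enzyme across
isomiRs; an isomiR joins an enzyme's group only on a positive,
FDR-significant correlation, with the larger rho winning (and flagged)
if both enzymes qualify. Survival uses a median split of the analyzed
quantity with a two-group log-rank test; ties go to the at-or-below-median
arm (an arbitrary but fixed choice), and an arm without events is
computed but flagged. Constant paired differences are treated as p = 1
when zero and p = 0 otherwise, since the t statistic degenerates.
Spearman p-values follow `cor.test`: exact where feasible without ties,
the asymptotic approximation otherwise.

Probe-level expression tables are collapsed to genes by keeping the
probe with the highest mean across samples; mean ties keep the
lexicographically lowest probe identifier for determinism.

## Classifiers

All classifiers separate ANL from stage I/II LUAD samples, on miRNA RPM
or one isomiR type's RPM or frequency; frequency features undefined in
any included sample are dropped. Single-cohort performance uses every
feature expressed in the cohort (high-confidence or not): SVMs report
the mean error of stratified 10-fold cross-validation with
standardization refitted inside each training fold; random forests grow
300 trees and report out-of-bag error. Cross-cohort evaluation trains on
one cohort using only features differentially expressed/frequent there
(paired, FDR < 0.05), tunes hyperparameters by seeded random search -
SVM box constraint and kernel scale log-uniform on [1e-3, 1e3]
(radial-basis kernel, gamma = 1/scale^2) minimizing 5-fold CV error; RF
minimum leaf size <= 20 and per-node feature fraction <= 70% minimizing
out-of-bag error - and reports rank-statistic AUC (midranks for ties)
per held-out cohort. Standardization statistics come from the training
cohort alone. Random search replaces Bayesian optimization with the same
objectives and bounds: at 24 iterations over a 2-parameter box it probes
the response surface densely enough for these problem sizes, and it is
reproducible from a single seed. The kernel family is radial basis; a
tuned kernel scale presumes a scaled kernel, and RBF is the conventional
choice.

## What the generator emulates - and what it does not

`simulate_cohorts()` builds three cohorts of paired ANL/LUAD samples
(default 20 pairs each, ~50,000 reads per sample, read length 36 nt)
over a 50 kb single-contig genome carrying 12 hairpin loci, one tRNA
gene, one decoy locus whose mature sequence occurs twice in the genome,
and one blacklisted editing site. Defaults plant: editing at 12% of a
family's reads (ANL baseline), 5' shifts at 10%, adenylation 10%,
uridylation 7%, C/G tails at 0.4% each; LUAD shifts editing and
adenylation by -0.05 and uridylation by +0.05 at six loci per type.
Biological noise is additive on the frequency scale: a patient effect
(sd 0.012) shared within each pair, a sample effect (sd 0.006) shared
across a sample's loci of one type, and a per-site effect (sd 0.004).
Two plates per cohort with substitution error rates 0.002 and 0.005
(both members of a pair co-plated), one cohort with a different adapter
chemistry, per-sample editing coupled to an ADAR-like and an
ADARB1-like enzyme latent (coupling 0.03 on the frequency scale, chosen
so the correlation structure is resolvable at 20 tumor samples), an
exponential survival model whose log-hazard decreases by 0.8 per
standard deviation of the sample's editing level, and a 1% rate of reads
carrying one sub-25-quality base.

The generator does **not** emulate: realistic base-caller error spectra
(errors are uniform over read positions and substitution types), indels,
PCR duplicates or UMIs, 3' templated trimming variation, ligation bias,
multi-isomiR reads (events are mutually exclusive per read), or
expression variation linked to RNA structure. Consequently, green tests
demonstrate that the statistical machinery recovers planted truth under
its own assumptions - they do not certify performance on real libraries,
where adapter chemistry, error structure and isomiR co-occurrence are
richer.

Thresholds that the method states as absolutes scale with depth: the
5-million-read coverage gate and the "family RPM >= 50" power boundary
refer to production libraries; at synthetic depth the package applies a
scaled coverage gate (1,000 reads by default) and evaluates power at
matched absolute family coverage (the abundance floor of 0.005 gives
>= 100 family reads per sample, the count RPM 50 implies at a
2-million-read library).

## Problem sizes used by the test suite

Unit tests run on handcrafted reads and a 6-pair, 8,000-read study. The
acceptance suite uses: 200 null samples of 10,000 reads for
false-positive calibration; 15 runs of a 5-pair, 20,000-read cohort with
all channels planted at key-level frequency 0.05 for detection power;
one full default study (3 x 20 pairs, 50,000 reads per sample) for
parameter recovery; and 12-pair, 8,000-read studies with doubled or
zeroed effects for classifier evaluation. These sizes were chosen so the
binomial and t-test regimes match the full design while the whole suite
stays comfortably re-runnable on a laptop.

## Alignment internals

The toy genome is searched exactly, not heuristically: every candidate
start with at most one internal mismatch and at most 3 nt of 3' overhang
contains an exact seed k-mer among two disjoint seeds in the first 2k
read bases (pigeonhole over the single allowed mismatch; k = 8 for reads
of 19 nt and longer, k = 6 below). Seed hits from a precomputed k-mer
position index of both genome strands are verified by direct string
comparison, which yields the annotation in the same pass; verified
annotations are memoized per sequence across samples. Equal-rank
multi-locus hits are not resolved at annotation time - the read is
assigned to its annotated locus and the cross-mapping filter later
discards keys whose best sequence has an equally good foreign site,
matching the filter's role as the designated arbiter of ambiguity.

## Known limitations

* The genome is small and synthetic; alignment exactness claims do not
  transfer to genome-scale repetitive structure.
* Editing keys ignore all 3' variation; if a study required
  tail-resolved editing states the collapse would need a finer key.
* The error model treats the 2% tail/5' floor as plate-independent, and
  estimates substitution rates from position-pooled canonical reads;
  loci sharing an editing hotspot position therefore shadow each other.
* Survival simulation couples hazard to editing only; competing risks
  and covariates are out of scope.
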