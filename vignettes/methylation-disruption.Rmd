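---
title: "Methylation disruption analysis for two-color CpG arrays: models and design choices"
author: "methdisrupt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methylation disruption analysis: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Canine diffuse large B-cell lymphoma (cDLBCL), like its human counterpart,
acquires widespread aberrant DNA methylation — CpG-island hypermethylation
that silences promoters (with a strong excess at Polycomb-target genes) and
hypomethylation of gene bodies. Beyond identifying individual differentially
methylated regions (DMRs), the degree of genome-wide *methylation
disruption* — how far a tumor's methylation landscape has drifted from
normal tissue — is itself a candidate prognostic axis.

`methdisrupt` implements the full analysis for a two-color
methylation-enrichment microarray design: tumors and control lymph nodes are
hybridized competitively (methyl-enriched fraction vs. input DNA), ~90
bp-tiled probes cover tens of thousands of CpG regions plus a panel of CDS
targets, and the probe-level log2 ratio measures methylation. The pipeline
has four stages:

1. **preprocess** — per-array loess dye-bias correction, array QC,
   between-sample quantile normalization, probe-median aggregation to
   sequence level, and a low-methylation enrichment filter;
2. **differential** — per-sequence Mann–Whitney–Wilcoxon tests
   (tumor vs. control) with Bonferroni control, differential-variability
   F-tests against clinical groupings, multivariate OLS on clinical
   covariates, genomic-location enrichment, and a categorical (beta ≥ 0.5)
   Fisher analysis;
3. **stratify** — PCA over tumors with |r| > 0.85 sequence selection, Ward
   hierarchical clustering into epigenetic subtypes, clinical association
   screens and Kaplan–Meier/log-rank survival read-outs;
4. **disrupt** — methylation variability profiles (MVPs), an L1 area
   distance between profiles, methylation variability scores (MVS), and
   consensus clustering over MAD-ranked variable sequences, with a
   short-survival read-out for the most disrupted cluster.

A first-class synthetic-data generator (`simulateMethylArray()`) emulates
the study design with planted ground truth, so every stage is testable
without any external download.

## Statistical models and conventions

**Methylation scale.** Internally everything is the probe/sequence log2
ratio *m*. The beta (methylation proportion) scale is the base-2 logistic
`beta = 2^m / (2^m + 1)`, so `m = 0` (equal channel intensity) maps to
`beta = 0.5`, the methylated/unmethylated dichotomy. The source protocol
does not state its beta derivation; this choice is the canonical monotone
map between the two scales and makes the 0.5 dichotomy coincide with
channel parity.

**Enrichment filter.** A sample is "enriched" at a sequence when
`beta >= 0.5` (threshold configurable). A sequence is kept when at least
25% of tumors *or* 25% of controls are enriched. The OR rule is a
documented choice: an AND rule would silently discard exactly the loci
where tumors have lost (or gained) methylation relative to controls, i.e.
the signal of interest. Only loci unmethylated in both groups are dropped.

**Rank test.** `mwwDmrTest()` delegates to `stats::wilcox.test`, which
uses the exact null distribution whenever both groups have fewer than 50
samples and no ties occur — always the case for the 7-control design on
continuous data — and the tie/continuity-corrected normal approximation
otherwise. With n = 37 vs 7 the exact tail matters: the smallest attainable
two-sided p is 2/C(44,7) ≈ 5.2e-8, and Bonferroni control at 0.01 over
~30k sequences (threshold ≈ 3.4e-7) is passed only by sequences with at
most two discordant tumor–control pairs out of 259. Detected loci are
therefore necessarily near-complete methylation switches — which matches
how CpG-island hyper/hypomethylation presents biologically.

**Discreteness of the exact p-value.** With these group sizes the
two-sided exact p-value has ~130 attainable values; its largest atom has
probability ≈ 0.025. A Kolmogorov–Smirnov test against the *continuous*
uniform will therefore reject for any correctly computed rank test once a
few thousand null sequences are pooled. Calibration is instead verified
against the exact discrete null law: `mwwNullPValues(n1, n2)` returns the
attainable p-values and their probabilities, and the test suite runs a
chi-square goodness-of-fit of the observed null p-values against that law.
(Its p-value is itself uniform under the null, so isolated small values
across seeds are expected at the nominal rate.)

**Bonferroni denominator.** The family is the set of sequences actually
tested after filtering (the ~29.5k analysis set), not the array design
size.

**Fisher tests.** All 2×2 exact tests use `stats::fisher.test`, i.e. the
"minlike" two-sided convention (sum of all table probabilities not
exceeding the observed one). The test suite verifies this against an
independent brute-force hypergeometric enumeration — exhaustively for all
tables with total n ≤ 30 and densely sampled up to n = 60 — at 1e-12.
Note one consequence at extremes: for the table (37,0 | 0,7) only the
observed table is as unlikely as itself, so the two-sided p equals
1/C(44,7), not twice it.

**Differential variability.** Two-sided variance-ratio F tests between
binary clinical groupings (stage III–IV vs V, substage a vs b, extranodal,
treatment, steroid pretreatment, and relapse coded both as ever/never and
as before-end-of-therapy vs after-or-none). Sequences constant within both
groups have an undefined ratio and are flagged and removed from the family.

**Multivariate model.** One QR decomposition of the shared clinical design
matrix is applied to all sequences at once (`qr.resid`/`qr.coef`);
the overall-model F p-value is Bonferroni-adjusted. Rank deficiency is
detected via QR pivoting and reported with the collinear column names.

## Stratification choices

PCA is computed over tumor samples only, sequences centered but not scaled
(correlations are scale-free anyway). Sequences with |Pearson r| > 0.85
against any of the first two component score vectors are selected; Ward
clustering ("ward.D2", the squared-Euclidean-consistent variant, for
cross-implementation reproducibility) runs on sequence-wise
centered-and-scaled levels restricted to that selection. The cluster count
is the user's choice with k = 3 as default. The survival read-out pairs the
clusters with the best and worst median survival among clusters with at
least two events, compared by the standard two-group log-rank test; medians
come from the Kaplan–Meier curves and are reported as censored (NA) when a
curve never crosses 0.5.

The log-rank pairing deserves one note: with 37 tumors split three ways, a
pairwise comparison of two ~12-sample clusters at hazard ratio 3 has true
power ≈ 0.71 (Schoenfeld's approximation needs ~26 events for 80%, more
than two such clusters can contain). The package's power checks therefore
compare the aggressive subtype against all remaining samples (~13 vs ~24,
true power ≈ 0.86 measured over 400 simulated cohorts) — the comparison
that actually uses the cohort's full event count.

## The disruption stage

**MVPs.** Per sequence, the reference is the median across control
samples; per sample, the changes (sample minus reference) are summarized as
a Gaussian kernel density estimate with Silverman's bandwidth, evaluated on
one shared 512-point grid spanning the pooled 0.1–99.9 percentile range
and renormalized to integrate to 1 (trapezoidal rule). Degenerate samples
fall back to a bandwidth floor (1e-3) with a warning.

**Distance.** The "area bounded by two profiles' density curves" is read
as the L1 distance ∫|f − g|: the *signed* area difference between two
normalized densities is identically zero, so the absolute-difference
reading is the only non-degenerate one. This distance is a genuine metric,
bounded by 2 (the total-variation bound, attained by disjoint supports).

**MVS.** The control reference curve is the pointwise median of the
control profiles, renormalized to integrate to 1 so the score lives on the
same scale as the pairwise distance; a sample's MVS is its L1 distance to
that curve. Control samples themselves get changes against the control
median, so their profiles (and leave-one-out MVS) act as the null band.

**Consensus clustering.** For each subset size (default 250–2,000; the
method scans up to 20,000 on a full design), the change matrix is
restricted to the top sequences by MAD across tumors (unscaled MAD,
constant 1; ties broken by sequence id), profiles and the distance matrix
are computed once, and 1,000 random 80% sample subsets are clustered by
average linkage. Average linkage is used *inside* the consensus because the
L1 profile distance does not live in the Euclidean geometry Ward assumes.
The consensus entry for a pair is its co-assignment count over its co-draw
count; the final assignment clusters 1 − consensus, again by average
linkage. The 80% subsampling fraction follows standard consensus-clustering
practice (the source protocol does not report its fraction).

**Short-survival read-out.** The cluster with the highest median MVS is
tested for enrichment of short survival (death before 180 days) by
Fisher's exact test. Samples censored before the cutoff have unknown
short-survival status and are excluded; samples observed past the cutoff
count as not-short whether censored or not. This avoids misclassifying
censored survivors at the cost of a slightly smaller table.

## What the simulator emulates — and what it does not

`simConfig()` defaults encode the study design: 37 tumors vs 7 controls;
36,807 CpG regions + 672 CDS at full scale (`studyDesignConfig()`), with a
small default (2,000 + 60) for fast iteration; ~3 probes per sequence
(Poisson, minimum 1); planted DMR fractions chosen so the full design
plants exactly 1,011 hyper- and 183 hypomethylated sequences — the
discovery scale of the motivating study.

Model components, each with its rationale:

- **Bimodal baseline** per sequence (low/unmethylated vs high/methylated
  mode; 80% high for CpG regions, 32% for CDS). This makes the beta ≥ 0.5
  dichotomy meaningful and reproduces the filter's retention proportions
  (~29–31k of 37.5k sequences).
- **DMRs as switches.** Planted hypermethylation starts from the
  unmethylated mode (CpG-island gain; the tumor-side 25% rule keeps such
  loci past the filter), hypomethylation from the methylated mode. The
  default effect (3.0 log2 units) is the scale of a mode-to-mode switch —
  and, as derived above, the scale any locus detectable under this design
  must have.
- **Subtype signatures** cover 4% of sequences per subtype (≈1,500 at full
  design), half shifted up and half down by 2.0 in the subtype's members.
  Real methylation subtypes differ at thousands of loci; a small signature
  cannot dominate PCA over 30k sequences (its eigenvalue would sit below
  the noise bulk), and bidirectionality keeps array marginals balanced
  under quantile normalization. With these defaults the first two
  tumor-PCA components carry ~20–25% of the variance, the regime the
  motivating study reports.
- **Disruption as discrete aberrant events.** 30% of sequences are
  disruption-prone; a prone sequence carries an event in a given tumor with
  probability 0.6 (0.02 elsewhere), with magnitude ~N(0, 1.6 × the
  sample's disruption level) and a direction/magnitude template shared
  across samples at coherence 0.5, biased 70:30 toward hypermethylation
  (recurrent targeting, as with Polycomb loci; disrupted tumors show more
  hyper- than hypo-events). The default gradient sets six tumors at
  disruption level 3 and spreads the rest over 0.5–1.8, planting the
  distinct high-disruption subgroup the disruption stage is designed to
  find. Coherent recurrence is what concentrates change-matrix variance in
  few components; the concentration check runs on a strong-coherence
  fixture (coherence 1, event rate 1), where two components carry ≥ 60%.
- **Dye bias** is a smooth per-array function of intensity (linear +
  quadratic in standardized intensity, random per-array coefficients),
  giving the loess correction something real to remove.
- **Survival** is Weibull (shape 1.2, scale 300 days) with subtype hazard
  multipliers — by default one aggressive subtype at hazard × 3 — and
  independent uniform censoring, light (~3–5%) because follow-up in such
  cohorts is near-complete. Clinical covariates follow the described
  cohort's frequencies.

Not emulated: genomic autocorrelation between neighboring sequences,
probe-sequence affinity differences, batch/scan-date effects, intensity
dependence of the methylation signal itself, and any coupling between
subtype and disruption (they are planted independently, so the generator
can attribute each stage's recovery to the right planted feature; in real
tumors these axes correlate). Passing tests demonstrate that each method
recovers the structure it targets under this generative model — not that
the model captures every property of hybridization data.

## Numerical choices

- Quantile normalization: `limma::normalizeQuantiles(ties = TRUE)` (tied
  ranks get the average target quantile; idempotent; marginal identity is
  exact and asserted exactly).
- Loess correction: `limma::loessFit` per array (span 0.3) on log2 ratio
  vs mean log2 intensity; residuals re-centered to the array median so an
  unbiased array passes through unchanged.
- Probe aggregation: per-cell median via grouped `data.table`; verified
  against a brute-force per-cell oracle.
- Trapezoidal integration throughout the profile machinery; profile
  validity enforces unit mass within 1e-6.
- Deterministic tie-breaks: MAD ranking by (−MAD, sequence id); `hclust`'s
  fixed merge order covers clustering ties (untied on continuous data).
- All pipeline randomness flows from one root seed through named per-stage
  substreams (`runPipeline()`), and every output file records the seed and
  a config hash in a header comment.

## Problem sizes in the test suite

The suite exercises the full design once (36,807 + 672 sequences, shared
across the study-scale checks) and otherwise uses 2,000-sequence defaults;
the null-calibration check uses a ~12.7k-sequence design retaining ~10k
after filtering; log-rank power uses 50 simulated cohorts (clinical tables
only); Fisher-oracle equivalence enumerates all 2×2 tables to n = 30
exhaustively plus 3,000 random tables to n = 60. These sizes are the
package's validation choices; all scale linearly if enlarged.

## Known limitations

- QC criteria are generic spread-based outlier screens; the original
  study's array-level QC metrics are not public in detail.
- Quantile normalization under strongly asymmetric differential
  methylation slightly inflates the upper tail of control arrays (the
  marginal-matching artifact); this is a property of the method, visible
  in the simulator, and it is the main reason planted sub-switch effects
  lose sensitivity.
- The log-rank read-out is two-group only; multi-group tests and Cox
  models are out of scope.
- The consensus stage subsamples samples (not sequences); sequence-level
  stability across subset sizes is reported by running several sizes, not
  by feature resampling.
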