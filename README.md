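# methdisrupt

Genome-wide DNA methylation analysis for two-color CpG-enrichment
microarrays in a tumor-versus-control design, built around canine diffuse
large B-cell lymphoma (cDLBCL) profiled against control lymph nodes.

Methylation is measured as the log2 ratio *m* of a methyl-enriched channel
over input DNA, per ~90 bp probe, aggregated to target CpG regions and CDS
by the probe median. The package implements the full analysis:

- **Preprocessing** — per-array loess dye-bias correction of *m* against
  mean intensity, array QC, between-sample quantile normalization, probe
  median aggregation, and a low-methylation filter (a sequence is kept when
  ≥ 25% of tumors or of controls are methylation-enriched,
  β = 2^m/(2^m+1) ≥ 0.5).
- **Differential methylation** — per-sequence two-sided
  Mann–Whitney–Wilcoxon tests with Bonferroni control (significant when
  p·N < 0.01 over the N tested sequences), differential-variability
  F-tests against clinical groupings, multivariate OLS on clinical
  covariates, Fisher-exact genomic-location enrichment, and a categorical
  analysis of β values dichotomized at 0.5.
- **Epigenetic subtyping** — PCA over tumors, selection of sequences with
  |Pearson r| > 0.85 against the leading component scores, Ward (ward.D2)
  hierarchical clustering on centered-and-scaled levels, clinical
  association screens, and Kaplan–Meier/log-rank survival comparisons.
- **Methylation disruption** — per-sample *methylation variability
  profiles* (MVPs): kernel density curves of the differential methylation
  of each sample against the control-median reference; the L1 area
  distance d(f,g) = ∫|f−g| between profiles; the *methylation variability
  score* MVS(s) = d(f_s, ref), where ref is the renormalized pointwise
  median of the control profiles; and consensus clustering (1,000 random
  80% sample subsets, average linkage on the profile distance) over the
  top-MAD variable sequences, with a Fisher test for short survival
  (< 180 days) in the most disrupted cluster.
- **A synthetic-data generator** emulating the study design (37 tumors vs
  7 controls; 36,807 CpG regions + 672 CDS; planted methylation switches,
  subtype signatures, and a disruption gradient with known ground truth),
  so the entire pipeline is testable offline.

Data containers are Bioconductor-style: probe data live in a `ProbeSet`
and sequence-level matrices in a `MethylExperiment` (both extending
`SummarizedExperiment`), annotation in a `GRanges`, profiles and consensus
results in dedicated S4 classes with accessors.

## Worked example

```r
library(methdisrupt)

sim <- simulateMethylArray(simConfig(seed = 1))
sim
#> MethylSimulation: 6154 probes over 2060 sequences; 37 tumors / 7 controls
#>   planted: 70 hyper, 12 hypo, 3 subtypes

probes <- quantileNormalize(qcFilterArrays(loessDyeCorrect(sim$probes))$probes)
ms <- filterLowMethylation(aggregateToSequences(probes, sim$annotation))
metadata(ms)$filter_report
#>     retained dropped
#> CDS       16      44
#> CpG     1669     331

dmr <- mwwDmrTest(ms)            # 71 significant: 59 hyper, 12 hypo
sel <- pcaSelectSequences(ms)
sel
#> PCASelection: 109 sequences at |r| > 0.85
#>   variance explained: PC1 10.5%, PC2 9.7%
#>    PC1 : 52 sequences
#>    PC2 : 57 sequences
clusters <- wardCluster(ms, k = 3, sequenceIds = sel$selected)
clusters
#> ClusterAssignment: 37 samples in 3 clusters ( ward.D2 linkage, euclidean distance )
#> cluster
#>  1  2  3
#> 12 12 13

chg  <- differentialMatrix(ms)
mvs  <- mvsScores(mvpProfiles(chg))
cons <- consensusCluster(chg, subsetSizes = 500, k = 3,
                         nResamples = 1000, seed = 7)[["500"]]
clusterAssignment(cons)[paste0("T0", 1:6)]
#> T01 T02 T03 T04 T05 T06
#>   1   1   1   1   1   1
flagDisruptedGroup(cons, mvs, sim$clinical)
#> Most disrupted cluster: 1 ( 6 samples )
#>   median MVS per cluster: 1 = 0.471, 2 = 0.405, 3 = 0.427
#>   short LSS (< 180 d): Fisher p = 1 , OR = 0.729
```

Reading the output: the 71 recovered DMRs are the planted methylation
switches that survive the low-methylation filter and the Bonferroni-exact
rank test; Ward clustering on the 109 PC-correlated sequences recovers the
three planted subtypes exactly (cluster sizes 12/12/13 match the planted
allocation); consensus clustering over the 500 most variable sequences
isolates precisely the six tumors planted at the top of the disruption
gradient (samples T01–T06), and that cluster carries the highest median
methylation variability score (0.471 vs 0.405/0.427). The short-survival
Fisher p of 1 is correct here: the generator plants survival on the
subtype axis, independent of disruption, so no association is expected at
this demo's scale. Scores separate much more sharply at the full 37k-sequence
design, where density estimates are smooth (see the acceptance script).

`runPipeline(pipelineConfig(seed = 1))` runs all stages end to end and
writes TSV/BED outputs with seed and config-hash provenance headers; a
command-line wrapper with `simulate` / `preprocess` / `diff-meth` /
`stratify` / `disrupt` / `run-all` subcommands is installed at
`inst/scripts/methdisrupt.R`.

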