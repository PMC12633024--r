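---
title: "Classifying homologous recombination deficiency and profiling tumor immunogenomics with hrdimmune"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying homologous recombination deficiency and profiling tumor immunogenomics with hrdimmune}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrdimmune)
```

## The problem

Tumors that have lost homologous recombination (HR), most prominently
through biallelic inactivation of *BRCA1* or *BRCA2*, repair
double-strand breaks by error-prone pathways and accumulate a
characteristic set of genomic lesions: a near-flat single-base
substitution spectrum (the Sig3/SBS3 pattern), small deletions at
microhomologies (the ID6 pattern of microhomology-mediated end joining),
and allele-specific copy-number "scars" — long stretches of loss of
heterozygosity (LOH), allelic imbalance extending to telomeres, and
abrupt large-scale copy-number transitions. HR-deficient (HRD) tumors
respond to PARP inhibition and platinum, so classifying HRD from
routinely available exome-scale data matters clinically. The same
genomic state also reshapes the tumor microenvironment: depending on the
tissue, HRD tumors can be more or less inflamed than their HR-proficient
(HRP) counterparts, and recurrent LOH of immune-gene loci contributes to
immune evasion.

`hrdimmune` implements this whole analysis chain as composable R
functions: mutational-signature features, indel and scar features, a
semi-supervised gradient-boosted HRD classifier, single-sample GSEA
(ssGSEA) inflammation scoring, binned LOH/amplification profiling, and
the association statistics linking genomic state to immune cell
fractions. A synthetic-cohort generator with ground-truth labels makes
every stage testable without access to controlled data.

## Feature extraction

**SBS96 catalogs.** Every usable somatic SNV is counted into one of 96
pyrimidine-strand trinucleotide channels (`build_catalog()`);
purine-reference substitutions are reverse-complemented. The channel
order is substitution-major and fixed (`sbs96_channels()`).

**Signature features.** Three views of the same catalog quantify the
Sig3/HRD pattern (`hrd_features()`):

* `sig3_likelihood`: the posterior probability of the HRD-like spectrum
  against a clock-like/background alternative under multinomial
  sampling. Likelihoods are computed in log space with a `1e-9`
  pseudocount on the spectra, because a single zero-probability channel
  would otherwise annihilate the product. A zero-count catalog returns
  the prior (0.5 by default) — with no mutations there is no evidence
  either way.
* `sig3_cosine`: plain cosine similarity to the HRD-like spectrum.
* `sig3_exposure` and its fraction: non-negative least squares refitting
  over the packaged spectrum panel (Lawson–Hanson NNLS).

The packaged panel (`spectrum_panel()`) contains six synthetic but
COSMIC-shaped spectra — flat background, clock-like (CpG C>T), HRD-like
(near-flat with a mild T>A/T>C tilt so NNLS can tell it from pure flat),
MMR-deficiency-like, POLE-like, and an 8-oxo-G artifact spectrum. They
are versioned stand-ins; analyses of real cohorts should substitute
reference spectra.

**Microhomology deletions.** Deletions of ≥ 5 bp are split by whether
the deleted sequence shares ≥ 2 bp with an immediate flank
(`count_microhomology_deletions()`). The microhomology length is the
larger of the deleted sequence's prefix match against the 3′ flank and
suffix match against the 5′ flank, capped below the deletion length —
the convention of the indel-signature literature; deletions are assumed
left-aligned. Flanking sequence can come from an inline column (as the
simulator emits) or a genome sequence accessor, so no reference FASTA is
needed for testing.

**Scar scores.** From allele-specific segments (`compute_scars()`):
HRD-LOH counts merged LOH regions (minor copy < 1) longer than 15 Mb
that do not span a whole chromosome; TAI counts merged allelic-imbalance
regions reaching a telomere without overlapping the centromere; LST
counts breakpoints between adjacent ≥ 10 Mb segments per chromosome arm
after 3-Mb smoothing. The smoothing first coalesces equal-copy-number
neighbors, then removes sub-3-Mb segments, then coalesces across the
gaps they leave; coalescing first makes the score invariant under
segment splits that preserve copy-number values, which is both the
sensible physical property and a tested invariant. GIS is the sum of the
three. These constants (15 Mb, 10 Mb, 3 Mb, telomere tolerance 10 kb)
follow the scores' original definitions and are arguments, not claims.

**Triage and artifact filtering.** Before HRD classification, samples
are triaged into MMRP / MMRD / POLE from the MSI score, the MMR- and
POLE-like NNLS exposure fractions, and TMB
(`triage_hypermutation()`; defaults: MSI ≥ 3.5, exposure fraction ≥ 0.3
with TMB ≥ 10/Mb for MMRD, ≥ 100/Mb for POLE). Hypermutators are never
relabeled HRD downstream. Samples dominated by the 8-oxo-G artifact
spectrum (exposure fraction ≥ 0.2) are removed entirely
(`filter_artifact_samples()`). TMB uses a configurable exome footprint,
38 Mb by default.

## The HRD classifier

Training is semi-supervised (`train_hrd_classifier()`):

1. **Seed labels.** Samples with biallelic *BRCA1*/*2* loss
   (`call_biallelic()`: a deep deletion alone, two independent hits, or
   one hit plus locus LOH) are positives. Each seed recruits its 3 most
   similar BRCA-wild-type samples — cosine similarity on z-scored
   features — keeping one instance of samples recruited repeatedly.
   Everything else starts negative.
2. **Step 1.** A gradient-boosted tree ensemble (xgboost; binary
   log-loss; no row/column subsampling, so fits are deterministic) is
   selected by stratified 5-fold cross-validated AUC over a small grid
   (trees ∈ {100, 300}, depth ∈ {2, 3}, learning rate ∈ {0.05, 0.1})
   and refit on all samples.
3. **Relabeling.** Negatives scoring ≥ 0.5 become positive, positives
   scoring < 0.5 become negative (`relabel()`; thresholds configurable).
4. **Step 2.** A second classifier is trained on the revised labels with
   full re-optimization of the grid.

The protocol runs pan-cancer, per tumor type (for types with more than
10 seed-positive training samples and at least 30 samples; both
thresholds configurable), and once for the pooled remaining types. A
sample is called HRD when both its pan-cancer and tumor-type scores
reach 0.5, HRP when both are below, and HRD-low otherwise
(`classify_hrd()`). Finally, biallelic *BRCA1*/*2* samples that were not
called HRD are overridden to HRD with a flag, and the summary reports
the overridden share of all HRD labels (`finalize_labels()`).

**Evaluation convention.** Recovery experiments score samples with
out-of-fold cross-validation scores and exclude the seed-positive set
from the evaluation. Seed positives are labeled from BRCA status rather
than from features, and the neighbor augmentation deliberately copies
each seed's feature neighborhood into the labels; scoring those samples
therefore measures the labeling construction, not generalization — under
a null generator it alone produces an apparent AUC near 0.58, while the
non-seeded out-of-fold AUC sits at 0.5 as it should. The same convention
is applied to signal and null experiments alike.

## Inflammation scoring

`ssgsea()` implements the single-sample ranked-walk enrichment
statistic: genes are ranked by expression per sample, and the score is
the integrated difference between the `|rank|^τ`-weighted running
fraction of in-set genes and the uniform running fraction of out-of-set
genes, with τ = 0.25 and cohort range normalization as defaults (the
community defaults; both configurable, and the test suite's properties
are normalization-agnostic). The Inflammation Score (IS) is the plain
mean of four signature scores (`inflammation_score()`); a z-then-average
variant can be had by standardizing inputs first. The packaged four gene
sets are synthetic placeholders for testing; real analyses should supply
the published type-I IFN, chemokine, activated-CD8 and IFN-γ signatures.

Inflammation status is assigned per tumor type from IS tertiles computed
on eligible samples only — viral-negative and non-hypermutated — but the
resulting thresholds label every sample of the type
(`tertile_status()`). Hot means IS > T2; samples exactly at a threshold
take the lower status, consistent with strict inequalities; degenerate
thresholds (T1 = T2) flag the type and leave everyone intermediate.
`z_is` standardizes IS with the eligible samples' moments, so eligible
samples have mean 0 and sd 1 within type by construction.

Associations: `compare_is()` (Welch t, positive when HRD is higher),
`regress_is()` (OLS of z-scored IS on HRD status and TMB), and
`regress_is_on_genomics()` (OLS on per-region LOH fractions plus an
oncogene-amplification indicator over the `default_oncogene_panel()`).
Rank-deficient designs are an error naming the collinear columns.

## Copy-number profiles and regions

`compute_baseline()` takes segment-length-weighted means of major and
minor copy number over segments > 100 kb, per chromosome, then
aggregates across chromosomes weighted by qualifying coverage.
`bin_profiles()` divides the genome into 100-kb bins with
overlap-weighted copy numbers; LOH is weighted minor < 1, and
amplification is reported as the deviation of weighted major from the
sample baseline, which removes the confounding of total copy number by
the pervasive LOH of HRD genomes. Zero-coverage bins are missing, not
zero; the Y chromosome is dropped and X is profiled only in female
samples. `gene_calls()` assigns each gene the segment containing its
midpoint and applies the rules: relative amplification at ≥ 2 copies
over the sample baseline total, focal when log10(segment length) < 6.5,
LOH at minor < 1, deep deletion at total < 0.5.

`group_region_stats()` summarises per-sample LOH fractions and mean
amplification deviations over regions with one-sample-t 95% CIs per
group and Welch tests between groups. `differential_regions()` tests
every bin between two groups, adjusts by Benjamini–Hochberg across bins,
and reports maximal runs of significant bins (≥ 10 bins by default,
merging across gaps ≤ 2 bins) with direction. Two degenerate cases are
handled explicitly: zero variance in both groups with equal means is
uninformative (p = 1, flagged), while complete separation is maximally
significant — without this, a region with LOH in every sample of one
group and none of the other would paradoxically be discarded.

`cooccurrence()` reports the sample odds ratio ad/bc (Haldane 0.5
correction when a cell is empty, flagged) with the two-sided Fisher
exact p. `ddr_enrichment()`, `pair_epistasis()` and `ora()` wrap the
same machinery for per-gene enrichment, joint-dysfunction tests and
hypergeometric over-representation; multiple testing is
Benjamini–Hochberg throughout. `tme_delta()` z-scores cell fractions
within tumor type and reports group differences ΔZ with Welch tests;
`cluster_celltypes()` clusters cell types across stacked ΔZ tables
(Euclidean, average linkage, k = 5 by default) and
`correlate_celltypes()` gives the Pearson matrices with significance
masks.

## The synthetic cohort

`simulate_cohort(cohort_config())` generates every input of the pipeline
with ground truth. The default configuration is the packaged study
condition: 600 samples in three tumor types — OVX (n = 250, HRD
prevalence 0.35, an ovarian-like "deficient-hot/proficient-cold" type),
LUX (n = 200, prevalence 0.25, "deficient-cold/proficient-hot"), GIX
(n = 150, prevalence 0.15, partly viral-positive). Hypermutators are
drawn first (5% MMRD with MSI ≈ 10 and 15× burden, 2% POLE at 150×
burden — the ultramutator regime); 1% of samples are dominated by the
artifact spectrum.

Per sample, SNV counts are log-normal (median 80) and catalogs are
multinomial draws from the condition's spectrum mixture (HRD: 60%
HRD-like; HRP: clock-dominated). Deletions carry explicit ref/alt and
flanking sequence, with ≥ 2 bp microhomologies planted at Poisson rates
12 (HRD) versus 1 (HRP) — effect sizes in the range reported for real
HRD tumors — plus non-MH deletions (6 vs 3) and sub-5-bp distractors.
Segments come from a per-chromosome Poisson breakpoint process with
per-segment LOH/amplification probabilities of 0.35/0.20 (HRD) versus
0.04/0.08 (HRP) and occasional whole-chromosome LOH (exercising the
whole-chromosome exclusion). One regional effect is planted by default:
chr3:50–55 Mb forced to LOH with probability 0.8 in HRD versus 0.2 in
non-HRD samples of the dCpH group. Half of HRD samples receive a
biallelic BRCA1/2 loss through a mix of mechanisms (somatic + LOH,
germline + LOH, silencing + LOH, deep deletion, two somatic hits); 5% of
HRP samples get monoallelic distractors.

The latent inflammation of a sample is
`effect(group) × HRD + β_region × regionLOH + β_OG × OGamp + N(0,1)`
with effects +1.2/−1.2 (dHpC/dCpH), −0.8 and −0.5; expression adds this
latent value, scaled by amplitude 1.0, to the four signature gene sets
over a Gaussian baseline with noise sd 0.5, and cell fractions are
Dirichlet draws whose cytotoxic "cluster 1" weights are tilted by
`exp(0.6 × latent)`. `zero_effects = TRUE` keeps the cohort structure
but equalizes every HRD-dependent rate (signatures, indels, scars,
regions, DDR/TP53 alteration rates, inflammation effects) for null
calibration.

What the simulator does **not** emulate: clonal structure and subclonal
copy number, linkage between expression and copy number dosage,
realistic gene-level mutation recurrence, segmentation noise from real
SNP arrays, or batch structure in expression. Passing tests therefore
demonstrate that the statistics recover what the generative model
plants, at desk-scale sample sizes, not that the pipeline is robust to
every artifact of real TCGA-scale data.

## Numerical choices and edge cases

* Likelihood pseudocount `1e-9`; log-space normalization before
  exponentiation.
* Cosine of a zero catalog is an error (not 0); the Sig3 posterior of a
  zero catalog is the prior.
* Degenerate Welch tests: equal-mean zero-variance → p = 1, flagged;
  separated zero-variance → p = 0.
* Tertile ties take the lower status; degenerate thresholds flag the
  tumor type.
* Odds ratios with an empty cell use the Haldane 0.5 correction,
  flagged; constant vectors give an undefined OR with p = 1.
* Determinism: simulation is a pure function of the config seed;
  xgboost runs single-threaded without subsampling, so training is a
  pure function of (data, grid, seed); fold assignment is seeded.
* Problem sizes in the shipped experiments (600-sample default cohort,
  200-sample region experiments, 20-seed null replicates) were chosen so
  the full suite runs comfortably on a laptop-class single core while
  keeping binomial/Poisson sampling error well inside the asserted
  tolerances.

## Known limitations

The classifier's per-tumor-type models need enough biallelic seeds to
train, and fall back to a pooled model otherwise — small cohorts get
pan-cancer-dominated scores. The SigMA-style likelihood here is a
two-model Bayes comparison against a single negative spectrum, not the
WGS-trained multivariate classifier of the original tool; both the
likelihood and the NNLS exposure are exposed as separate features so the
downstream model can weight them. Scar scores depend on segmentation
quality; no attempt is made to re-segment or to estimate purity/ploidy.
The binary silencing and germline inputs are consumed as given.
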