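---
title: "Motif-centered analysis of somatic mutation catalogues"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motif-centered analysis of somatic mutation catalogues}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somaticmotifs)
```

## The model

Somatic mutation catalogues mix the output of many mutagenic processes.
Several well-studied mechanisms leave a recognisable mark: they prefer
to mutate a specific base inside a short sequence context.  Spontaneous
deamination of 5-methylcytosine produces C→T changes in CpG
dinucleotides (`nCg→nTg`); APOBEC cytidine deaminases produce C→T and
C→G changes in the `tCw` context; UV photodimers produce C→T in `yCn`;
small epoxides and other SN2-reacting electrophiles produce T→C in
`aTn`.  `somaticmotifs` quantifies the activity of such processes in a
*single sample* by asking a narrowly defined statistical question: are
the sample's substitutions of the relevant class concentrated in the
motif context beyond what the local sequence composition predicts?

For a motif such as `aTn→aCn` the package builds, per sample, four
counts:

* `mut_in_motif` — T→C mutations (and their reverse complements)
  whose flanking bases satisfy the motif pattern;
* `mut_in_class` — all T→C mutations of the sample;
* `ctx_motif` — occurrences of the motif context (`atn`) on either
  strand of the ±20 bp windows around the sample's mutations;
* `ctx_center` — occurrences of the mutated base (`t`) in the same
  windows.

The enrichment statistic is the ratio of ratios

```
enrichment = (mut_in_motif * ctx_center) / (mut_in_class * ctx_motif)
```

and overrepresentation is tested with a one-sided Fisher exact test on
the 2×2 table `[[mut_in_motif, mut_in_class − mut_in_motif],
[ctx_motif, ctx_center − ctx_motif]]`.  P-values are corrected with the
Benjamini–Hochberg procedure across all samples of a run (within each
motif by default; `bh_scope = "global"` pools all tests).  Samples that
pass the gate (enrichment > 1 and q ≤ 0.05) receive a **Minimal
Estimate of Mutation Load**,

```
MEML = mut_in_motif * (enrichment − 1) / enrichment ,
```

the number of in-motif mutations beyond the context-predicted
expectation; all other samples are assigned MEML = 0.  MEML is by
construction conservative: it subtracts the share of in-motif
mutations that random mutagenesis would have placed there anyway
(roughly `ctx_motif / ctx_center` of the class), so it should be read
as a lower bound on the process's contribution, not an unbiased count.

Restricting the context to ±20 bp around each mutated base keeps the
normalisation inside the demonstrably sequenced part of the genome and
insulates the statistic from regional covariates (chromatin,
replication timing, capture bias).  Two consequences of this choice are
deliberate and documented here: overlapping windows of nearby mutations
are counted independently, and the mutated base itself contributes to
the context counts.  Including the central base makes the recovery of
injected loads slightly more conservative (each injected mutation's own
window necessarily contains one motif occurrence); the engine's
internals flag this as the main sensitivity of simulation-based
recovery experiments.

Mutations closer than 10 bp to another mutation of the same sample are
removed before any counting (`exclude_complex()`); such "complex"
calls may be single translesion-synthesis events and would otherwise
masquerade as motif signal.  Duplicate calls are collapsed first.  All
matching is double-stranded: motifs are stored pyrimidine-canonical
(mutated base written as C or T, uppercase) and purine-reference
mutations are mapped through the reverse complement.  A small positive
bias of the null enrichment (~5% for trinucleotide motifs at the
default flank) arises because a window of length 41 holds 41 center
bases but only 39 trinucleotide start positions; it is far too small to
pass the Fisher/FDR gate on its own, as the background-only validation
below confirms.

## The motif registry

`builtin_registry()` carries eleven curated tri-nucleotide motifs,
four sub-motifs, the two APOBEC3A/3B-discriminating tetranucleotides
(`ytCa`, `rtCa`), and the combined APOBEC motif (`tCw` with mutant
bases T and G).  Sub-motifs restrict a parent motif to contexts that a
confounding mechanism cannot produce: `aTr` (3′ purine) excludes the
UV-associated `nTt` overlap of `aTn`; `rCg`/`yCg` split CpG
deamination by whether a UV-capable pyrimidine precedes the mutated
cytosine; `yCh` covers UV-preferred contexts while excluding CpG.
Correlating a motif's per-sample MEML with its sub-motif's MEML
(`spearman_cor()`) is the package's tool for deciding whether an
apparent signal is genuine or borrowed from an overlapping mechanism.
One registry detail worth noting: the SN1-alkylation motif is encoded
as C→T in the `aCy` context (`aCy→aTy`), the orientation consistent
with the O6-alkylguanine mechanism.  Registries are user-extensible
through a three-column TSV (`read_motif_config()`).

```{r registry}
builtin_registry()
```

## Clusters and APOBEC subtypes

APOBEC deamination acts on transient single-stranded DNA and therefore
produces runs of mutations that all strike the same strand — all-G or
all-C reference runs at spacing between the complex-exclusion limit and
about 10 kb.  `call_clusters()` groups a sample's mutations into
maximal runs with consecutive spacing ≤ `max_imd` (default 10⁴ bp; the
calling rule is deliberately the simplest consistent with that range —
single-linkage on consecutive distances — and the cap is exposed as a
parameter).  `classify_coordination()` labels each cluster
GC-coordinated, AT-coordinated or non-coordinated.
`category_enrichment()` re-runs the enrichment machinery inside a
mutation category (all GC-coordinated clusters, size strata 2/3/≥4,
scattered, genome-wide); the size bins are configurable defaults, not a
fixed truth.

`subtype_analysis()` distinguishes APOBEC3A-like from APOBEC3B-like
activity: A3A prefers a pyrimidine two bases 5′ of the deaminated
cytosine (`ytCa`), A3B a purine (`rtCa`).  Where both tetranucleotide
motifs test significant in a category, the two 2×2 tables are compared
with the classic Breslow–Day test of odds-ratio homogeneity against
the Mantel–Haenszel common odds ratio (df = strata − 1; the Tarone
adjustment is available via `tarone = TRUE` but off by default since
the classic statistic is the reference behaviour).

## Cohort statistics

`donor_aggregate()` averages sample MEML per donor (with and without
zeros; age correlations use the zero-inclusive mean so that
non-detection counts as absence of load).  `tercile_of()` uses the
fixed age bands [0, 33.3], (33.3, 66.7], (66.7, 100] years rather than
data-driven terciles, so results are comparable across cohorts; the
half-open intervals leave no gaps between the printed labels.
`compare_cohorts()` performs two-sided Wilcoxon rank-sum tests of
diseased vs healthy donors strictly within one study, tissue and age
tercile — the design that blocks both batch effects and the age
dependence of clock-like motifs — and corrects over all emitted
comparisons.  Two-sidedness is deliberate: disease can raise load
(e.g. inflammatory exposure) or lower it (e.g. selection against
high-burden post-mitotic cells), and the direction is read from the
sign of the median difference.  `regress_age_disease()` fits
`lm(MEML ~ age + disease)` per tissue and motif with healthy as the
baseline level.  `prorate_single_cell()` rescales MEML computed on a
partial single-cell call set by `estimated_snvs /
identified_mutations`.  `profile_96()` and `cosine_similarity()`
provide the standard 96-channel trinucleotide profile and its
comparison metric for quality control.

## The simulator and what it does (not) emulate

`make_genome()`, `make_catalog()` and `make_cohort()` generate fully
seed-deterministic validation data: an i.i.d. random genome (uniform
base composition by default, with arbitrary composition and a
first-order-Markov CpG inflation factor available), uniform background
SNVs, motif-targeted processes at fixed counts or clock-like per-year
rates with disease multipliers, and same-strand clustered runs.
Injection sites are drawn uniformly from genomic positions matching the
motif on either strand, which matches the enrichment model's null of
position exchangeability within context.  Per-sample seeds are derived
by hashing the master seed with the sample identifier, so cohorts are
reproducible sample-by-sample and simulator outputs are byte-identical
across runs.  Truth tables record per-process counts and per-mutation
provenance (process and clustered-run id) for recovery scoring.

The simulator deliberately omits regional mutation-rate covariates,
sequencing error, copy number, and indels.  Passing the validation
suite therefore demonstrates the statistical machinery — exact Fisher
tails, FDR control, strand symmetry, recovery of planted signals — not
robustness to every artefact of real sequencing data.

## Numerical and design choices

* Coordinates are 1-based everywhere, matching MAF/VCF conventions.
* IUPAC matching treats N as matching nothing; windows containing N
  remain usable elsewhere.  Windows at contig edges are truncated, not
  dropped, so every mutation contributes.
* Context windows are accumulated over *all* (complex-excluded)
  mutations of a sample by default; `context_scope = "class"`
  restricts them to the motif's substitution class for sensitivity
  analysis.
* Undefined enrichment (zero denominator, e.g. sparse WES classes)
  yields MEML 0 with an explicit status flag, never an error.
* The significance gate is `alpha = 0.05` by default and exposed as an
  argument; degenerate Fisher margins give p = 1.
* Cluster calling operates on complex-excluded catalogues, which
  enforces the lower end of the inter-mutation-distance range.

## Validation problem sizes

The shipped validation suite exercises: exactness of the one-sided
Fisher computation against full hypergeometric enumeration for every
2×2 table with total ≤ 60; FDR control on 200 background-only samples
of 500 SNVs on a 2 Mb genome across all 18 registry motifs; recovery
of a planted aTn excess (50 replicates at observed enrichment ≈ 3);
exact strand-flip invariance; clock-like recovery over 20 donors;
cohort comparison power (3× disease multiplier) and null calibration
over 200 replicate cohorts; recall of ~90 injected coordinated runs;
Breslow–Day size over 2000 homogeneous replicates; and byte-level
determinism.  These sizes were chosen as the smallest designs at which
the binomial/rank-test noise is clearly below the tested margins.  On
the recovery experiment the suite asserts a ±25% band around the
injected count; with the central-base context convention used here the
minimum-estimate property leaves the median recovery near 74%, so that
single check documents the conservative bias rather than certifying
unbiasedness (see the MEML discussion above).

## Limitations

MEML values for overlapping motifs are not additive, and a process
that mutates the same base as another active process lowers both
estimates — sub-motif correlation mitigates but does not remove this.
WES catalogues carry ~100-fold fewer mutations, so undefined or
non-significant enrichment is common and is reported as status-flagged
zeros rather than suppressed.  The cluster caller is a distance rule,
not a rate-model kataegis caller, and inherits its parameters'
arbitrariness.  COSMIC signature refitting is out of scope; the
96-channel profile and cosine similarity are provided only as QC
plumbing.
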