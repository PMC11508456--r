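---
title: "Salivary biomarker selection: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Salivary biomarker selection: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(salivaMarkers)
```

# The problem

Saliva is in prolonged contact with oral tumors, which makes salivary
proteins attractive candidates for non-invasive early detection of oral
squamous cell carcinoma (OSCC). Given a label-free proteomics abundance
matrix over a small case/control cohort (the motivating design is 2815
proteoforms quantified in 10 OSCC and 20 healthy saliva samples), the task
is to narrow thousands of proteoforms down to a short, biologically
coherent candidate list. `salivaMarkers` implements that funnel in five
stages:

1. **Univariate differential abundance** — per-proteoform log2 mean fold
   change with a Wilcoxon rank-sum test and Benjamini–Hochberg FDR, gated
   jointly on effect size and FDR.
2. **Multivariate selection** — a sparse PLS discriminant analysis
   (sPLS-DA) coupled to recursive feature elimination (RFE) that keeps the
   proteins driving group discrimination, including correlated proteins a
   univariate test treats as redundant.
3. **Merge** — union of the two lists with Venn accounting and collapsing
   of UniProt isoform entries (dash-suffixed accessions) to base IDs.
4. **Network pruning** — restriction of a PSI-MI TAB interactome to
   interactions *among* the candidates (first interactors, self-loops,
   duplicate edges and isolated proteins removed), keeping only physically
   connected candidates.
5. **Over-representation analysis** — upper-tail hypergeometric tests
   against GMT gene sets with BH FDR and affinity-propagation redundancy
   reduction.

Every stage is a plain function over an `abundance_matrix`, so the
numbered scripts under `analysis/` and the tests call exactly the same
code. The workflow mirrors a study pipeline rather than a command-line
tool, which is why the package ships analysis drivers instead of a shell
interface.

# Models and assumptions

## Univariate stage

The fold change is the ratio of case to control *arithmetic group means* of
the raw (natural-scale) abundances, reported as log2. A pseudocount
(default: half the smallest positive value in the matrix) keeps the ratio
finite when a proteoform is undetected in one group without dominating
detected signal. The test is the two-sided Wilcoxon rank-sum; the exact
null distribution is used for tie-free rows up to a combined n of 30
(which covers the 10-vs-20 design), and the normal approximation with tie
and continuity correction otherwise. Constant rows get p = 1.

The selection gate reads the fold-change threshold of 1.3 as a *ratio*
(a 30% difference in either direction), i.e. |log2FC| ≥ log2 1.3 ≈ 0.379,
combined with FDR < 0.05 (strict). An alternative reading — 1.3 directly
on the log2 scale — is available via `fc_scale = "log2"`; it is much more
stringent, and a ratio gate is the only reading consistent with selected
proteins whose |log2FC| is as low as 0.40 in the cohorts this design
emulates.

## sPLS-DA and recursive feature elimination

Samples-by-proteins data are autoscaled (mean 0, SD 1 per protein;
recomputed after every elimination) and the two groups are dummy-coded as
a single centered indicator `y`. For each component the loading vector `u`
is the dominant eigenvector of the outer product of the protein–group
cross-covariance `c = Xᵀy` — for a single response this is simply `c`
normalized to unit length — optionally soft-thresholded so that only
`keep_per_component` proteins keep nonzero weight. Scores are
`S = X u` (so component-1 scores satisfy `S_j = Σ_i u_i1 r_ij` exactly),
and both `X` and `y` are deflated between components. Per-component
variance explained is the R² of regressing the scaled matrix on that
component's scores; scores are orthogonal, so fractions are additive.

RFE removes, at each iteration, the protein with the smallest |u_i1|
(ties broken toward the lexicographically smallest accession, for
determinism), refits, and stops when `ceiling(target_fraction × initial)`
proteins remain — 141 for 2815 proteins at the default 5%. Elimination
uses the *absolute* loading: a signed minimum would systematically discard
one regulation direction, which is biologically indefensible for a
candidate list that must contain both up- and down-regulated markers. The
per-iteration fit defaults to the dense loading (the RFE itself provides
the sparsity); soft thresholding can be enabled on top. A `chunk` larger
than 1 removes several proteins per refit for speed and never overshoots
the target; the default is single-protein elimination.

The number of components is chosen by repeated stratified k-fold
cross-validation on the balanced error rate. Counts are accepted
sequentially: h+1 replaces h only when the paired repeat-level improvement
exceeds its standard error across repeats. This sequential gate matters:
on a fixed null matrix, cross-validation "sees" the matrix's chance
case/control separation as shared signal and a plain minimum-error rule
drifts toward large counts, whereas chance improvements rarely beat their
own standard error, so pure noise yields 1 component. The pipeline default
is 2 components.

## Merge and isoform collapsing

Isoforms follow the UniProt dash convention (`P14618-2`); the base is the
substring before the first dash. After the union of the univariate and
multivariate lists, bases are deduplicated and each base inherits the
statistics of its most significant proteoform (smallest FDR) — pathway
databases do not track isoforms, so downstream stages operate on bases.

## Network stage

`read_mitab()` accepts the 15-column PSI-MI TAB core; interactor types are
taken from columns 21/22 when a file carries them (the 15-column core does
not encode them, in which case the type is "unknown" and treated as
protein rather than discarding the record). Records are filtered to the
target taxon on both interactors (default 9606) and, optionally, to
protein interactors. Pruning keeps edges with *both* endpoints in the
candidate list — which removes all first interactors — drops self-loops,
collapses unordered duplicates, and discards degree-0 nodes ("only
connected proteins"). Node directions (up/down) come from the sign of the
univariate log2FC.

## Over-representation analysis

For a universe of N accessions, a set with m members in the universe and
an input list of n, the p-value of an overlap k is the upper
hypergeometric tail P(X ≥ k); enrichment ratio is (k/n)/(m/N). Only
over-representation is tested. The default universe is the union of all
set members and the input list; a fixed external universe (e.g. the
protein-coding genome) can be supplied. Significance is BH FDR ≤ 0.05.

Redundancy among significant sets is removed with affinity propagation
over Jaccard similarities of their member sets. The implementation is the
standard responsibility/availability message-passing scheme with damping
0.5, preference set to the median off-diagonal similarity, and at most 500
iterations; non-convergence falls back to flagging every set as an
exemplar, with a warning. Determinism is guaranteed by a fixed,
index-dependent perturbation *subtracted from off-diagonal similarities
only*: exact ties never merge items on their own, so pairwise-disjoint
sets each remain their own exemplar while genuine near-duplicates collapse.

# The synthetic cohort generator

`simulate_abundance()` emulates the statistical structure the analysis
assumes, so the whole pipeline is testable offline:

* **Log-normal abundances.** Gaussian on the log2 scale (per-protein
  baseline ~ N(20, 2)), exponentiated; standard for label-free
  intensities.
* **Planted markers** (default 5% of rows) receive a fixed ±`effect_log2fc`
  shift in the case samples. The default effect of 2 was calibrated to the
  fold-change range reported for salivary OSCC markers (|log2FC| roughly
  0.3–3.3) and to being detectable at the 10-vs-20 design; an effect of 1
  is essentially undetectable after multiplicity correction at these
  sample sizes.
* **Correlated blocks** (default 50 proteins, equicorrelation 0.3) emulate
  co-regulated protein communities — the structure that motivates the
  multivariate stage.
* **Isoform entries** (default 10% of rows) are dash-suffixed copies of
  existing bases, exercising the collapsing arithmetic.
* **Missingness** (default 10%) is encoded as zeros, matching the
  convention of curated salivary abundance matrices; the univariate
  pseudocount handles them.
* **Noise** defaults to SD 1 on the log2 scale, a realistic
  between-subject spread for body-fluid proteomics.

`simulate_interactome()` writes MITAB rows (22 columns; the first 15 are a
valid 2.5 core) containing the ground truth's planted marker–marker edges
plus background edges, deliberate duplicates, self-loops, non-human-taxon
rows and non-protein rows — fodder for the downstream filters.
`simulate_gene_sets()` writes a GMT collection with one marker-stacked set
among uniform draws.

What the generator does *not* model: spectral-count discreteness, batch
effects, longitudinal sampling, intensity-dependent missingness, and
isoform-correlated abundances. Passing tests therefore demonstrate the
correctness and calibration of the statistical machinery on idealized
log-normal data, not performance on any real cohort; data-dependent
published quantities (how many proteins a real cohort yields at each
stage, which pathways enrich) are functions of the cohort and database
versions and are not reproduced offline.

# Numerical choices and degenerate inputs

* Zero-variance proteins are left unscaled (loading 0) rather than
  producing NaNs; a fully constant matrix raises a degenerate-fit error.
* Zero group means with a zero pseudocount yield ±Inf log2FC with a
  warning, never silently dropped.
* BH adjustment, Wilcoxon testing, the hypergeometric tail and k-fold
  machinery call base R (`p.adjust`, `wilcox.test`, `phyper`); the test
  suite checks each against independent brute-force oracles (literal
  step-up loops, exhaustive rank enumeration, closed-form tail sums).
* RFE ties on |loading| are broken lexicographically; affinity propagation
  ties are broken by the deterministic off-diagonal perturbation.
* All generators take an explicit seed; identical configurations produce
  byte-identical files.

# Problem sizes used in the tests

The test suite exercises reduced cohorts chosen to keep properties
meaningful at interactive scale: 80–500 proteins for model properties,
1000 proteins / 50 markers for recovery regressions, 50 replicates for
null-calibration checks, and a single full-width 2815-protein RFE
(chunked) plus a 500-protein single-elimination run for the stopping-rule
checks. Recovery and power regressions plant effect 2 with noise SD 0.5 on
fully observed matrices: those are the stated detection-power conditions,
and zero-inflation is a separate robustness axis (at 10% zeros, univariate
recall at these sample sizes drops to roughly two thirds because zeroed
case samples break rank separation — worth knowing when interpreting real
cohorts).

# Known limitations

* The sPLS-DA is binary (two groups) by design; multi-class extensions
  would need one-hot responses and a different prediction rule.
* Balanced error rate is estimated on small test folds (10-vs-20 cohorts
  give 2–6 samples per fold), so component selection is noisy; the
  sequential acceptance rule is deliberately conservative.
* The affinity-propagation preference (median similarity) matches common
  practice but is a heuristic; very small similarity matrices (2–3 sets)
  can keep near-duplicates apart when the median equals their similarity.
* Collapsing isoforms by smallest FDR is a pragmatic annotation rule;
  proteoform-level biology is lost at that point by construction.
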