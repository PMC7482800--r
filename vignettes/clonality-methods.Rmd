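---
title: "Methods: discriminating lung metastasis from second primary tumors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discriminating lung metastasis from second primary tumors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonemark)
```

# The problem and the model

A patient presents with squamous cell carcinomas in both the esophagus
(T) and the lung (D), often with a regional lymph-node metastasis (LN).
If the lung lesion is a metastasis (LM) the two tumors descend from one
founding clone and share its ancestral somatic alterations; if it is an
independent second primary (SPT) the overlap of somatic alterations is
expected to be empty up to coincidence. `clonemark` operationalizes this
dichotomy: tumors are compared within a patient on shared nonsynonymous
mutations (the decisive axis), and on B-allele frequencies, mutation
spectra, mutational signatures and focal somatic copy-number alterations
(advisory axes).

The package assumes variant calling and effect annotation happened
upstream (tumor/normal paired calling of the MuTect family); its inputs
are candidate calls with per-compartment depths and alt-read counts,
segmented (or windowed) log2 copy ratios, and a cohort manifest naming
each sample's role.

# Stage by stage

## High-confidence filtering

An SNV passes iff tumor depth ≥ `min_depth_tumor` (10) **and** normal
depth ≥ `min_depth_normal` (10) **and** tumor VAF > `min_vaf_tumor`
(0.10) **and** normal VAF < `max_vaf_normal` (0.02) **and** tumor
alt-reads ≥ `min_alt_reads` (3). The VAF bounds are deliberately strict
inequalities: a VAF of exactly 0.10 fails, and boundary behavior is
pinned by tests. Records with zero depth in either compartment are
rejected with reason `zero_depth` rather than evaluating an undefined
VAF. For indels no tumor-VAF rule is imposed; instead the record must be
absent from a caller-supplied germline key set and carry zero alt reads
in the normal — a conservative stand-in for a germline-subtraction
pipeline whose realignment steps are out of scope. The "alt coverage ≥ 3"
rule is read as *tumor* alt reads, since normal alt support is already
bounded by the 2% rule.

## Partition, trees, BAF

Mutation identity is the exact tuple (chrom, pos, ref, alt) — fuzzy
matching would manufacture sharing for indels. With three tumors, keys in
all three are trunk, in exactly two branch, in one private; with two
tumors the pairwise intersection is the trunk. The verdict statistic
`td_shared_count` is trunk plus the T&D branch. The partition is asserted
to be a disjoint cover on every run; an independent brute-force Venn
oracle re-derives it in the tests.

Phylogenies use counts of *distinct mutated genes* per set (two variants
in one gene count once). A strict tree cannot display three mutually
overlapping branch sets, so the tree keeps the largest branch (by gene
count, ties broken by order) as its single internal node and folds the
other branch genes into the terminal edges; terminal edges are computed
as "distinct genes in the sample minus distinct genes on its ancestral
path", which makes the root-to-leaf path length equal the sample's
distinct mutated gene count exactly. Trees carry a zero-length
`Germline` leaf and are exported as Newick.

The BAF comparison pairs tumor VAFs over the union of two callsets'
keys (zero where absent) and reports the fraction of keys with VAF ≥ τ
in both samples. τ = 0.05 (VAF units) is an explicit knob: the original
analysis presented these distributions visually without a numeric rule,
so the statistic is labelled an operationalization in reports.

## Spectra and signatures

Spectra are strand-collapsed into the pyrimidine frame (a G>A call is
counted as C>T after reverse complementation), giving 6-class and
96-context counts. Two spectra are contrasted with an uncorrected
Pearson chi-square on the 2 × k 6-class table; classes absent from both
profiles are dropped, and classes with expected counts below 1 are
pooled into an `other` column so the asymptotic test is not applied to
empty cells. Degenerate tables (fewer than two classes after pooling)
return statistic 0 with p = 1 rather than erroring on identical small
callsets.

Signature refitting normalizes the 96-vector to sum 1 and solves the
nonnegative least-squares problem against the catalog
(`pracma::lsqnonneg`), then iteratively zeroes signatures whose
normalized weight falls below `weight_floor` and refits on the
survivors. `weight_floor = 0.06` follows the published default of the
refitting tool the original analysis used, which states none itself.
Reported weights are the surviving raw coefficients, so their sum is the
explained fraction (capped at 1); the residual is the L2 norm of the
unexplained part. On noise-free sparse mixtures with all weights above
the floor this recovers weights to < 1e-3, which the tests assert.

The bundled catalog is **synthetic**: the real 30-signature COSMIC v2
matrix is not redistributed here. Signatures that the defaults depend on
are shaped to their real counterparts' class composition (signature 1:
C>T concentrated at NpCpG; 4, 24, 29: C>A-dominated with distinct
context weights; 5 and 3 near-flat; 6: C>T; 16: T>C); the remainder are
reproducible sparse random profiles. Conclusions about *which* biological
process dominates a real tumor require the real catalog, loaded with
`read_signature_catalog()`.

Candidate significantly-mutated genes are a recurrence listing (non-silent
mutations in ≥ 2 patients, optionally intersected with a census set). No
background mutation model is fitted, so these are explicitly *candidates*,
not significance-tested driver calls.

## Focal SCNA

Segments are rasterized onto fixed 1-kb windows (0-based half-open
internally; SEG input is 1-based inclusive) by length-weighted averaging;
uncovered windows are missing, never zero. The per-window G-score folds
frequency and amplitude into one mean: `g_amp = Σ max(log2, 0) / n`,
`g_del = Σ max(−log2, 0) / n`, with the denominator counting only
samples covering that window (windows missing everywhere stay `NA`).

The permutation null circularly shifts each sample's window vector by an
independent uniform offset within each chromosome and recomputes the
per-window G. This preserves each sample's marginal distribution and
spatial autocorrelation while destroying cross-sample alignment — the
recurrence signal being tested. P-values are `(1 + #null ≥ obs) /
(1 + n_perm)`, hence never zero and super-uniform under the null (the
calibration is tested at the 5% level over pure-noise grids). Maximal
runs of contiguous significant windows (p < 0.05) form focal regions;
the peak extends around the G maximum while G ≥ 95% of it.

Level calls per region × sample use the mean log2 ratio `m`: +2 if
m > 0.9; +1 if 0.1 < m ≤ 0.9; 0 if |m| ≤ 0.1; −1 if −1.3 ≤ m < −0.1;
−2 if m < −1.3. The printed thresholds leave the boundary values
unassigned; boundaries go to the *less extreme* tier (conservative), and
each boundary is pinned by a test. Cosine similarity between two samples
is computed on their numeric level vectors over the regions non-missing
in both (amp and del regions concatenated); appending regions neutral in
both samples provably changes nothing, and an all-zero restricted vector
returns 0 by definition rather than 0/0.

This is a G-score/permutation skeleton, not full GISTIC2: no arbitrated
peel-off, no arm-level separation, no purity/ploidy correction. It is
reported as "GISTIC-like" accordingly.

## Verdict

`td_shared_count ≥ min_shared` (default 1) ⇒ metastasis, else second
primary. The default mirrors the strict dichotomy the clonal argument
implies — any truly somatic shared mutation is strong evidence of common
origin, given that the cross-patient control shows (near) zero sharing
between unrelated tumors. In real data a single shared call can be an
artifact, so `min_shared` is exposed. SCNA cosine (reference bounds
0.8/0.6, the published group medians), spectra concordance and
signature-1 dominance are recorded as named booleans with a concordance
count; when they disagree with the mutation rule the verdict carries a
conflict flag but is not changed, since the mutation axis is the decisive
one and no adjudication rule for such conflicts was ever stated.

# The synthetic cohort

The generator exists so that every stage has a verifiable, ground-truthed
input without access-controlled data. Per patient it draws:

- a mutation-union size U uniform in `mutations_per_tumor_range`
  (default 13–237, the published per-tumor range; the published median of
  71 refers to per-tumor counts, which here are the trunk plus the
  tumor's branch/private share of U);
- a trunk fraction f uniform in `trunk_fraction_range` (default
  0.12–0.705, the published span). The trunk *size* is the deterministic
  `round(f·U)` — the parameter is meant to be controllable, so recovery
  error measures filtering/readout noise, not assignment noise — and the
  remaining mutations are assigned multinomially: 12% / 4% / 4% of the
  non-trunk mass to the T&LN / T&D / LN&D branches and the rest private
  in equal thirds. Independent patients instead share a drawn fraction
  between T and LN only and give D a disjoint mutation set;
- trinucleotide contexts through the catalog: related tumors from
  `{Sig1: 0.8, Sig5: 0.2}` (age-dominated, C>T-heavy), independent D
  tumors from `{Sig4: 0.5, Sig29: 0.3, Sig1: 0.2}` (tobacco-style,
  C>A-heavy) — reproducing the reported spectral contrast between the
  regimes;
- read counts: tumor depth ~ Poisson(149) (the published mean coverage),
  alt reads ~ Binomial(depth, purity × CCF/2) with purity 0.8 (plausible
  for macrodissected FFPE tumors), CCF 1.0 for trunk/branch and 0.6 for
  private mutations (creating the separated BAF clusters the clonal
  analysis relies on, without modeling subclonal phylogenies); normal
  alt reads ~ Binomial(depth, 0.001);
- focal SCNA levels for T per region from {0: 0.6, ±1: 0.1, ±2: 0.1};
  partner tumors share a fraction `s` of the pair's pooled aberrant
  regions (LN always at the related rate 0.8; D at 0.8 when related,
  0.05 when independent). The partner copies `round(2·A·s/(1+s))` of T's
  A aberrant regions at identical levels and draws its remaining
  aberrations on T-neutral regions, preserving the per-tumor aberration
  rate. Under this construction the expected level-vector cosine of a
  pair is approximately `2s/(1+s)`: ≈ 0.89 at s = 0.8 and ≈ 0.10 at
  s = 0.05, matching the published > 0.8 / < 0.6 group medians with
  margin;
- log2 ratios as level midpoints (+2 → 1.2, +1 → 0.5, 0 → 0, −1 → −0.7,
  −2 → −1.6) plus Gaussian noise σ = 0.1 per 5-kb segment chunk. The
  noise is applied at segment resolution rather than once per 30-kb
  region because level calls average over a region's windows: a single
  σ = 0.1 draw per region would misclassify roughly a third of
  copy-neutral regions against the ±0.1 neutral band, which real
  marker-level noise averaging does not do.

Cohort allocation to regimes is deterministic (`round(n ×
fraction_spt)` independent patients), and a fixed seed reproduces the
cohort byte-identically.

**What the generator does not emulate:** germline variation, sequencing
artifacts (FFPE damage, strand bias), subclonal copy number and clonal
evolution beyond a two-level tree, indels, synonymous mutations, and
real genome geography (the default genome is a toy 3 × 10 Mb model).
Passing tests on synthetic cohorts therefore demonstrate that the
*computations* are correct and that the pipeline separates the two
regimes under the stated generative assumptions — not that real tumors
satisfy those assumptions.

# Numerical and design choices

- Coordinates: 1-based inclusive on disk (VCF/MAF/SEG convention),
  0-based half-open for window arithmetic, converted in one place.
- Chromosome names are normalized to the no-"chr" form on input.
- Signature catalog columns must sum to 1 within 1e-3 (then
  renormalized); anything further off is an error, not a warning.
- `lsqnonneg` solves the NNLS subproblems exactly (active set), so
  noise-free recovery is limited only by conditioning of the catalog.
- Permutation p-values use the add-one estimator, so `n_perm` bounds the
  smallest attainable p at `1/(1 + n_perm)`.
- Degenerate inputs: empty callsets partition to an error only when all
  samples are empty; zero-mutation spectra refuse the chi-square;
  all-missing regions yield `NA` level calls excluded pairwise from the
  cosine; an empty cohort yields an empty report.
- Problem sizes in the test suite (package choices): 2,000 randomized
  records for the filter oracle, 500 random patients for the partition
  oracle, 100 simulated patients for trunk-fraction recovery, 100
  pure-noise replicates at 500 permutations for calibration, and
  20-patient cohorts at 150–200 permutations for the separation and
  end-to-end checks.

# Limitations

The verdict rule is intentionally simple; it does not model the
probability that a shared call is artifactual (`min_shared` is the only
lever). Signature attributions with the synthetic catalog are
qualitative. The SCNA stage tests recurrence across the *cohort*, so a
focal region private to a single patient pair contributes to similarity
only if it reaches cohort-level significance. CCF estimation, subclonal
deconvolution and formal clone-tree inference are out of scope.
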