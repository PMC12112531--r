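---
title: "Methods: global transcriptome accounting and corticosterone response analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: global transcriptome accounting and corticosterone response analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`cortseq` analyses bulk RNA-seq count matrices from glucocorticoid
(corticosterone) treatment experiments in two complementary ways: a global
accounting of the transcriptome (who is expressed, at what level, and who
carries the transcript mass) and a differential analysis of the treatment
response (which genes change, how replicably, in which cell types, and at
what net cost in transcripts). This vignette records the models, the
tunable parameters, and the numerical decisions behind each stage, in the
order a typical analysis runs.

```{r, eval = FALSE}
library(cortseq)
sim <- simulate_counts(sim_config(n_genes = 2000, seed = 1))
cpm <- compute_cpm(sim$counts)
tier_summary(cpm, sim$annotation)
```

## Expression units and tiers

All expression is measured in counts per million (CPM): a gene's count in
a sample divided by the sample's total counts, times one million. Each
sample's CPM column therefore sums to exactly 1e6, which the suite asserts
to floating tolerance.

Genes are grouped by their mean CPM across all samples into six decade
tiers: residual `[0, 0.1)`, low `[0.1, 1)`, lower medium `[1, 10)`, upper
medium `[10, 100)`, high `[100, 1000)` and top `[1000, Inf)`. The
boundaries are conventionally written as strict inequalities in prose
("below 0.1", "above 1000"); a total partition needs a boundary rule, and
we use left-closed/right-open intervals throughout, so 0.1 CPM is "low"
and 1000 CPM is "top". Mean expression is the arithmetic mean of
per-sample CPM over all samples.

`tier_summary()` reports, per tier, the gene count, the percentage of
detected genes (CPM > 0 in at least one sample), the tier's share of total
transcripts, and the biotype composition. The transcript share is computed
from summed mean CPM rather than summed raw counts; the two agree exactly
only when library sizes are equal, and the mean-CPM convention was chosen
because it matches the unit in which tiers are defined. The predicted-gene
flag is derived from the annotation description containing the phrase
"predicted gene" (case-insensitive); it is independent of biotype, so the
biotype percentages within a tier may overlap and are not expected to sum
to 100.

## Duplicate gene symbols

Annotation tables occasionally map one symbol to several stable gene ids.
Entries sharing a symbol *and* a biotype are collapsed into one row with
counts summed per sample; entries whose copies carry different biotypes
(a protein-coding gene alongside a processed pseudogene, say) are left
separate, since they are genuinely different genes that happen to share a
name. The surviving key is the lexicographically smallest gene id — the
choice is arbitrary but deterministic, and the merge report retains the
full id list. Merging conserves the total count and is idempotent; both
are asserted in the suite. Biotype equality is exact string equality; we
do not attempt to interpret composite biotype labels.

## Marker-based dataset validation

`marker_correlation_qc()` computes all pairwise Pearson correlations
across samples within small marker sets — gene groups with known
functional or anatomical relationships whose expression should correlate
(immediate-early genes, hemoglobin genes, ribosomal proteins), and control
sets that should not. Classification thresholds are package defaults, not
biological constants: a "high" set passes when every pairwise r is at
least 0.6; a "none" set passes when every pair is weak (|r| < 0.4) or
insignificant (p > 0.05); a "loose" set passes when the median r falls in
[0.2, 0.6). At least three samples are required; with fewer, a correlation
carries no information and the function refuses to run.

## Expression filtering and the threshold formula

Statistical testing is restricted to genes with
`CPM >= min_count / median(library size) * 1e6` in at least `n_min`
samples, where `n_min` is the smallest group size and `min_count` defaults
to 10 reads. The boundary is inclusive. With a median depth of 30 million
reads the formula gives 0.33 CPM; at the desk-scale depth the simulator
uses (about one million reads) the same formula scales to about 10 CPM, so
the filter behaves identically relative to depth. The filter is monotone
in `min_count` (raising it never adds genes), which the suite asserts.

## Normalization and negative-binomial testing

The testing stage is implemented in the package from first principles so
that every numerical choice is explicit.

**TMM factors.** Between-sample scaling factors are the weighted trimmed
mean of M-values with the published defaults: reference sample chosen by
closest upper-quartile CPM to the mean upper quartile, log-ratios and
abundances computed over genes expressed in both sample and reference,
30% trimming on each M tail and 5% on each A tail, inverse-delta-method
weights, and a final rescaling so the factors' geometric mean is 1. A
test compares the factors with both a step-by-step transcription of the
procedure and an established implementation.

**Common dispersion.** Counts follow a negative-binomial model with
variance `mu + phi * mu^2` and one common dispersion `phi` shared across
genes. `phi` is estimated by pooled method of moments on
library-equalized counts (`sum(v - m) / sum(m^2)` over gene-by-group
cells with at least two samples), floored at 1e-6. Common — not tagwise
or trended — dispersion is deliberate: it keeps the stand-in transparent,
and every test function accepts an injected `phi` so simulations can use
the truth. Parameter recovery at `phi = 0.1` and the Poisson limit are
part of the suite.

**Two-group exact test.** Counts are first equalized: rescaled to the
geometric mean of the effective (TMM-scaled) library sizes and rounded
half-to-even. Group sums of equalized NB counts are treated as NB with
size `n_i / phi`, and the split of the total between the two groups gives
an exact conditional null distribution. The two-sided p-value is the
total conditional probability of all splits at most as likely as the one
observed (with a 1 + 1e-10 relative slack on the equality comparison).
For numerical economy the support is restricted to the region holding all
but 1e-14 of each marginal's mass; outcomes outside it contribute
negligible probability. A gene with zero counts everywhere is reported as
p = 1, log2FC = 0, not an error. Fold changes come from normalized group
mean CPM with a prior count of 0.125 per group (converted to the CPM
scale) so zeros stay finite. This stage is calibrated, not matched
bit-for-bit to any external tool: type-I error on null simulations must
stay within [0.03, 0.07] at the 5% level, and strong planted effects must
be recovered with the correct sign.

**Batch-adjusted model.** The pooled comparison fits, per gene, an NB
log-linear model `log mu = log(effective library) + batch + treatment` by
iteratively reweighted least squares with the common dispersion, and
tests the treatment coefficient by a likelihood-ratio chi-square against
the batch-only model. "Batch" here is the timepoint at which a control
group was sacrificed — the pooled design's systematic control-vs-control
differences. A design in which treatment is expressible as a linear
combination of batch indicators is refused as confounded. With a single
batch the model collapses to two-group NB regression and agrees with the
exact test in ranking (Spearman rho > 0.9 on simulated data).

**Multiple testing.** Benjamini–Hochberg step-up adjustment (via
`p.adjust`), significance at adjusted p < 0.05 throughout. BH is
order-preserving and capped at 1; it is *not* a fixed point of itself on
general monotone inputs, so no idempotence is claimed or tested.

## Replicability across treatment durations

A gene is *replicable* when it is significant at two or more treatment
durations with the same direction of significant change; directions at
non-significant timepoints are ignored. Replicable genes are tiered into
"all three" and "exactly two". Venn region counts over the per-timepoint
and pooled significant sets are computed by membership-pattern
enumeration. The magnitude-versus-expression relationship is the Pearson
correlation between |log2FC| and log10 mean CPM over significant genes; a
negative value means highly expressed genes respond with proportionally
smaller fold changes. At least three significant genes are required.

## Cell-expression specificity

For a gene and a cell-type category, the specificity score is the highest
atlas expression within the category divided by the highest expression in
any cell type outside it; a zero denominator is replaced by 0.0001. The
score is computed for every category and the best (category, score) pair
is kept. The category map must cover every atlas cell type, which removes
any ambiguity about unmapped cell types. Ties across categories (equal
best scores to within 1e-12 relative) are broken by map order and
flagged. Genes absent from the atlas — after optional synonym updating —
yield "ND" records and enter the ND fraction rather than erroring.
Scores are binned as [1,2), [2,3) and >= 3, matching the conventional
"1.99"/"2.99" phrasing; a < 1 bin exists as a sanity check and stays
empty whenever the map is total. Scores are scale-invariant in the
gene's atlas row.

## Transcript budget

The budget quantifies what the response costs in transcripts. It is
computed on raw counts, not CPM: per differentially expressed gene, the
difference between mean treated and mean control counts; summed over
up-regulated genes (gained), summed in absolute value over down-regulated
genes (lost), with the net change expressed as a percentage of the mean
control total. Per-timepoint totals are compared with a Mann–Whitney U
test reporting `U = min(U1, U2)`: exact doubled-tail p for tie-free
samples up to n = 12 per group, otherwise the tie-corrected normal
approximation without continuity correction — the exact route makes the
variant auditable against exhaustive enumeration, which the suite does at
n = (4,4) and (8,8).

## Clustering and CDT/GTR output

Before clustering, each gene's CPM profile is divided by its own maximum
(max-ratio transform), mapping every gene into [0,1] with its peak at 1;
all-zero rows are left at zero and flagged, and the transform is
idempotent. Genes are clustered agglomeratively with distance
`1 - uncentered correlation` (`sum(xy) / sqrt(sum(x^2) sum(y^2))`, equal
weights — correlation about zero, not the mean) and complete linkage, so
node similarities never increase toward the root. The distance matrix is
the package's own; the agglomeration itself is delegated to `hclust`,
and a brute-force O(n^3) agglomerator in the test suite confirms the
trees on 100 random instances. Ties in merge order are broken by
`hclust`'s bookkeeping; with continuous data exact ties have probability
zero. Only genes are clustered; sample order stays as given, and no
optimal leaf ordering is applied.

Results are written as a Cluster 3.0 / Java TreeView CDT + GTR pair:
the CDT holds the transformed table with GID/ORF/NAME/GWEIGHT columns and
an EWEIGHT row, rows in dendrogram leaf order; the GTR lists one line per
internal node with its two children and the merge similarity. The
package's own readers round-trip both files exactly, asserted in the
suite. `node_correlation_summary()` reports, for each gene of a subset,
the similarity of the first node on its leaf-to-root path whose other
branch contains another subset gene — one defensible construction of
"the correlation at which a gene joins its cluster"; the exact summary
used in prior descriptions of such dendrograms is not standardized, and
this reading is recorded as a package decision.

## Referential gene-list comparison

Significant genes, split by replicability tier, are intersected with
referential lists after synonym updating on both sides (an old symbol
mapping to two current symbols is an error; symbols unknown to the map
are reported unresolved and left unchanged). Each list member carries
up/down report tallies, and a preferential direction is assigned by one
of two rules, both with inclusive boundaries: the *stress* rule (at least
75% of reports in one direction) or the *glucocorticoid* rule (one
direction reported at least three times as often as the other). The
comparison reports per-tier overlap counts, the percentage of the tier
explained (one decimal), and how many overlapping genes agree with their
preferential direction.

## The synthetic-data generator

`simulate_counts()` produces data with the statistical structure the
analysis assumes, plus full ground truth. Its defaults are the study
conditions: six groups (control and corticosterone at 5, 14 and 28 days)
of eight sequenced samples; per-gene true CPM drawn from a six-tier
mixture (weights 0.46 / 0.20 / 0.16 / 0.12 / 0.055 / 0.005 from residual
to top, log10-uniform within tiers) that reproduces a heavy-tailed
transcriptome in which a few percent of genes carry most transcripts;
NB noise with common dispersion 0.1, a typical between-animal value for
bulk tissue; planted effects on 5% of genes following
`|log2FC| = a - b log10(CPM)` (defaults a = 2, b = 0.5, random signs,
truncated at zero) so effect sizes shrink with expression — the linear
rule in log space is a modeling choice, not a claim about the underlying
biology; per-timepoint additive log2 batch offsets (SD 0.5) on a random
5% of genes, mirroring control-group differences without modeling their
cause; and three marker modules of three genes sharing a per-sample
lognormal latent factor (loading 1, latent SD 0.5) to give the
correlation structure the QC stage expects. Library sizes are lognormal
around one million reads with CV 0.1 — a deliberate desk-scale depth
(not the 30 M of a production run) chosen so the full suite runs in tens
of seconds; all depth-dependent logic goes through the threshold formula
and scales with it.

Two facts about the generator matter for interpretation. First, the drawn
"true CPM" values are rates per million *nominal* reads; the realized
library is their sum, so with few simulated genes the realized empirical
CPM is the drawn value times `1e6 / sum(true CPM)`. Truth-based tests
account for this renormalization. Second, the generator emulates the
marginal and correlation structure the pipeline assumes — it does not
emulate gene-length effects, GC bias, alignment artifacts, cell-level
heterogeneity, or tagwise dispersion. A passing suite therefore shows the
pipeline's statistics are correct under its stated model, not that the
model captures every property of real libraries.

`simulate_atlas()` plants, per category, genes whose within-category
maximum is a chosen multiple of their out-of-category maximum;
`simulate_reference_list()` draws each member's up-reports from a
binomial with configurable direction probability. Both return truth
tables, and all three generators take explicit seeds with no hidden
global state.

## Problem sizes and runtime choices

The suite exercises the statistics at sizes chosen to make sampling error
negligible while keeping runs short: 20,000 genes for the tier-mixture
goodness of fit, 5,000 genes at 8 vs 8 and dispersion 0.1 for the type-I
calibration of both NB tests, 50 pipeline replicates of 1,000 genes for
the fold-change-versus-expression sign recovery, 100 random 8-gene
instances for the clustering oracle, and exhaustive enumeration (12,870
assignments at n = 8,8) for the U test. The complete suite runs in well
under a minute on a single core.

## Known limitations

- Common dispersion only; genes with genuinely gene-specific dispersion
  will be mis-calibrated at the margins.
- The exact test's library equalization rounds counts; at very low
  depths the rounding loses information relative to quantile-matching
  approaches.
- The joining-node reading of per-gene cluster correlation is one of
  several defensible constructions (correlation to the cluster mean is
  another); results near a threshold can differ between constructions.
- Symbol-level matching only in referential comparisons; probe-level
  re-annotation of legacy platforms is out of scope.
- The transcript budget inherits the direction labels of the DE stage;
  genes called in the wrong direction contribute with the wrong sign.
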