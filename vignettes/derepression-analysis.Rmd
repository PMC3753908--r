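---
title: "Calling clustered gene derepression: models, tests and design choices"
author: "derepress package authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling clustered gene derepression: models, tests and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(derepress)
```

## The analysis problem

When an epigenetic repressor is lost, silenced loci are usually derepressed
only partially and only in part. On the inactive X chromosome the ceiling is
structural: a gene that shifts from monoallelic to biallelic expression can at
most double its output, so the expected fold changes sit between 1.2 and 2 —
small enough that single-gene testing at a conventional false-discovery rate
misses many true targets. Two properties rescue the analysis. First, the
affected genes are not scattered: they occur in chromosomal clusters of a few
genes spanning tens of kilobases to about a megabase. Second, the clusters
share local sequence features (repeat families) that can be detected by
comparison with random chromosomal regions. This package implements that full
chain — moderated differential expression, probe-to-gene aggregation,
positional clustering, repeat enrichment and CpG-methylation comparison — as
composable, seeded, testable stages.

## Differential expression model

The input is an already-normalized log2 expression matrix (probe sets x
samples) with a two-group design (wild type vs mutant). Per probe set the
statistic is a two-sample pooled-variance t on the log2 values, with
empirical-Bayes moderation of the variance: the per-probe sample variances
$s_g^2$ (residual df $d$) are assumed exchangeable draws from a scaled
inverse chi-square prior with df $d_0$ and scale $s_0^2$, giving the
posterior variance

$$\tilde s_g^2 = \frac{d_0 s_0^2 + d\, s_g^2}{d_0 + d},$$

a moderated $t_g = \overline{\Delta}_g / \sqrt{\tilde s_g^2 (1/n_1 + 1/n_2)}$
and a reference t distribution with $d_0 + d$ df. The prior is fitted by
method of moments on $\log s_g^2$ (digamma/trigamma moment equations, with a
Newton inversion of the trigamma function); when the observed spread of
$\log s_g^2$ is no larger than the sampling spread, $d_0 = \infty$ and every
posterior variance equals $s_0^2$. With `shrinkage = FALSE` the classic
pooled t (df $n_1+n_2-2$) is returned; that switch exists because the
unshrunk statistic has a closed form that the test suite checks to 1e-12,
and the shrunk path is cross-checked against an independent implementation
(limma) in the suite.

P-values are adjusted by the Benjamini–Hochberg step-up over **all** probes
jointly (not per chromosome). Probe sets are then classified by two fixed FDR
categories — stringent (FDR ≤ 0.10) and relaxed (0.10 < FDR ≤ 0.30) — and by
direction on the *non-log* actual change $2^{\mathrm{log2fc}}$: up if > 1,
down if < 1, with strict inequalities, so an actual change of exactly 1 has
no direction. The relaxed threshold is deliberately permissive: at FDR 30%
roughly a third of the calls are expected to be false, and the downstream
positional test is what separates signal structure from that noise. A probe
set with an actual change of 1.25 is reported as 25% upregulated.

Gene-level calls use the uniqueness-filtered probe map (a probe set mapped to
more than one gene is nonspecific and discarded; probes mapped to no gene are
dropped and tallied separately, and reported percentages keep the full array
as denominator). A gene is upregulated iff it has at least one upregulated
and no downregulated probe set at the relaxed FDR; downregulated
symmetrically; both directions at once is conflicted; no significant probe
set means no change. The expression value of an up/downregulated gene is the
arithmetic mean of the non-log actual changes of its same-direction
significant probe sets — non-log, because gene-level fold changes in the
1.2–2 band are conventionally quoted on the natural scale.

## Positional clustering test

The clustering statistic for a called gene set is the **median of successive
start-to-start gaps** after sorting by position. Gene starts (not midpoints
or spans) anchor the distances; the alternative anchors change nothing
qualitatively at these scales and the start is the only anchor that is
well-defined for every annotation dialect the package reads. Successive gaps
(rather than all pairwise distances) make the statistic a local packing
measure: it is small exactly when many called genes have a called neighbour
nearby.

The null resamples $k$ distinct genes uniformly without replacement from the
same chromosome's annotated genes (the universe is whatever annotation is
handed in, so restricting to array-represented genes is a subsetting step,
and that restricted universe is the natural default since the called set
itself can only come from the array). Two p-values are computed from
`n_iter` (default 1000) resamples:

* `p_empirical` = (1 + #{null ≤ observed}) / (n_iter + 1) — assumption-free,
  bounded below by 1/(n_iter+1), the headline number;
* `p_parametric` — the lower-tail probability of the observed value under a
  normal fit to the null medians, reported because the null is close to
  normal at these sample sizes and a parametric tail can be quoted below the
  empirical resolution.

Cluster *detection* is deliberately separate from the significance test. The
rule is max-gap chaining: position-sorted called genes are chained while the
successive gap is at most `max_gap_bp` (default 500 kb), and maximal chains
with at least 2 genes become clusters. The 500 kb default sits between the
within-cluster gaps the generator plants (≤ 450 kb) and the expected gap of
random gene sets at realistic densities (megabases); it is exposed as an
argument everywhere because no principled universal value exists.

## Repeat enrichment test

Families are screened only if they occur at least once in **every** detected
cluster — a feature explaining susceptibility must be present wherever the
effect is. For each candidate family the observed sample is the per-cluster
element count (any-overlap, half-open; a midpoint mode exists for partition
audits). The null pools, over `n_iter` iterates, the counts in one random
region per cluster of exactly the cluster's size, placed uniformly on the
chromosome with no exclusion mask (regions may overlap each other and any
annotation). Because every null region matches a cluster's size exactly, raw
counts are comparable and no density normalization is applied; a per-kb mode
exists for unequal-size audits. Significance is a one-sided Wilcoxon rank-sum
(observed greater), exact by full enumeration of rank splits when both
samples have at most 12 values and the split count stays below 2e5,
otherwise the tie-corrected normal approximation with continuity correction
— counts are heavily tied, which rules out the textbook exact-null tables.
The pooled null (all iterates, all sizes) is the default; a stratified
variant that compares each cluster only with its own-size regions and
combines the per-cluster tail probabilities by Fisher's method is available,
since the two readings of "1,000 randomly selected regions of identical
size" are both defensible. No multiple-testing correction is applied across
families by default (raw rank-sum p-values are reported for every candidate;
a BH switch exists and is logged in the output).

## Methylation comparison

The percent-methylation table is taken downstream of the measurement
chemistry: one percentage per CpG unit per sample. Per sample, the amplicon
mean averages non-missing units (units first, then embryos — consistent with
quoting a per-embryo methylation level before averaging embryos); dropouts
are excluded pairwise, never imputed. Groups are compared by a two-sided
unpaired pooled-variance (Student) t on the per-sample amplicon means,
flagged at p ≤ 0.05, with Welch available as a flag; comparisons with fewer
than two usable samples in a group are marked not testable rather than
silently dropped.

Clone calling assumes clones are pre-aligned and equal-length to the
reference amplicon (in-silico clones are; real trace cleanup happens
upstream). At each reference CpG cytosine, C reads methylated, T
unmethylated, anything else ambiguous; every non-CpG reference cytosine is a
conversion-QC position, and clones whose non-CpG conversion rate falls below
`min_conversion` (default 0.97 — a standard QC practice; the threshold is
configurable and recorded) are flagged and excluded from summaries.
Per-CpG summaries are M/(M+U) over accepted clones with ambiguous calls
excluded from both numerator and denominator.

## What the synthetic generator emulates

`sim_config()` defaults are the study conditions the pipeline is designed
around, chosen once:

| parameter | default | rationale |
|---|---|---|
| `n_genes_x` | 569 | X-linked genes represented on a whole-genome array |
| `chrom_length_bp` | 166 Mb | mouse X chromosome scale |
| `affected_fraction` | 0.10 | ~10% of X genes derepressed |
| `fold_range` | 1.2–2 | monoallelic-to-biallelic ceiling |
| `n_clusters` | 9 | observed number of clustered regions |
| `cluster_gene_range` | 2–12 | observed cluster sizes |
| `cluster_span_range` | 65 kb–1.5 Mb | observed cluster spans |
| `clustered_fraction` | 0.7 | ~70% of affected genes cluster |
| `n_samples_per_group` | 3 | embryos per genotype |
| `noise_sd` | 0.25 log2 units | free parameter: no within-group variance is published; chosen so a 2-fold shift at n = 3 is detectable but a 1.2-fold shift is not trivially so |
| `probes_per_gene_range` | 1–3 | typical probe-set redundancy |
| `multi_map_fraction` | 0.10 | exercises the uniqueness filter |
| `enrichment_factor` | 8 | in-cluster repeat density multiple |
| `background_repeat_density` | 20 /Mb/family | desk-scale repeat background |

Geometry choices the generator makes beyond those numbers: cluster sizes are
drawn with probability proportional to 1/size (cluster-size distributions
are right-skewed, and nine clusters of mean size ~7 would not fit inside the
~40-gene clustered budget); cluster spans are capped so that no planted
intra-cluster gap exceeds 450 kb (a planted "cluster" whose members are
farther apart than any chaining threshold would not be a cluster under any
detection rule — the recovery tests are about the chaining rule, not label
noise); planted spans are placed in separate chromosome blocks with ≥ 1.5 Mb
clearance; and scattered affected genes are kept ≥ 600 kb away from planted
spans so that the truth table's "unclustered" label is true. Unaffected
genes are placed uniformly and may fall inside cluster spans — in real data
not every gene inside a cluster is derepressed.

Baseline log2 expression is Normal(6, 2) truncated at 0 — only the dynamic
range matters, since every statistic works on group differences. The mutant
shift is a mean shift of +log2(fold) (no allele-level simulation; allele-
specific assays are out of scope), probe sets add a fixed affinity offset,
and noise is i.i.d. Gaussian. Repeats are homogeneous Poisson per family;
enriched families receive additional in-cluster elements at
(factor − 1) x background so the in-cluster density is factor x background,
with at least one element per cluster guaranteed when factor > 1 (the
candidate filter requires presence in every cluster); at factor = 1 the
guarantee is suppressed so enriched and background families are statistically
indistinguishable, which the calibration tests rely on. Methylation values
are per-unit truncated Gaussians around the group mean of the amplicon: with
the default panel (wild-type means 30–50%, planted losses of 20 percentage
points, sd 5, n = 3 embryos/group) the per-embryo amplicon mean averages 6–8
units, which is what gives the group comparison its power.

What the generator does **not** emulate: probe-level microarray physics (no
RMA simulation — the pipeline consumes a normalized matrix), correlated
noise between samples or probes, sequence composition of repeats, read-level
errors in clones beyond conversion state, and allele-resolved methylation.
Passing recovery tests therefore demonstrate that the statistics recover the
planted structure under clean sampling assumptions, not that they are robust
to array artefacts.

## Numerical and degenerate-input choices

* All genomic coordinates are 0-based half-open internally; conversions
  happen only at I/O (GFF3 and GRanges are 1-based). String positions in the
  bisulfite module are 1-based, the R convention for text.
* Report-time percentages round half-up to 2 decimals; full precision is
  kept internally.
* Zero within-group variance with a nonzero difference: p is reported as 0
  with a warning on the unshrunk path (shrinkage makes the posterior
  variance positive, so the moderated path has no such degeneracy).
* Exactly-1 actual changes get direction "none" (strict inequalities).
* `p_empirical` can never be 0 by construction; the Wilcoxon normal
  approximation is floored at the smallest positive double.
* Determinism: every stochastic operation takes a seed; the pipeline derives
  one substream per stage from the root seed via a stable label hash, so
  adding a stage never perturbs earlier stages' draws, and identical
  config + seed gives byte-identical reports and output tables.

## Problem sizes used by the test suite

The suite favours many small, fast cases over few large ones: calibration
runs use 100–150-gene chromosomes of 30–60 Mb with 100–200 resampling
iterates per replicate (200 replicates for the uniformity and rejection-rate
checks, 50 for the empirical-FDR check), while the recovery checks run the
full default configuration (569 genes, 166 Mb, 1000 iterates) at a fixed
seed. The resampling-null unbiasedness check compares a 2000-iterate run
against an independent 20,000-iterate oracle.

## Known limitations

* The cluster-calling rule (max-gap chaining) is a surrogate: no published
  delimitation rule exists for the observed clustered regions, so detected
  cluster boundaries should be read as operational, not biological.
* At the relaxed FDR the called gene set contains an expected ~30% false
  calls; spurious two-gene "clusters" formed by such calls dilute both the
  median-gap statistic and the enrichment screen. The planted-truth recovery
  results quantify the statistics; pipeline-level results inherit DE power
  and FDR behaviour.
* The enrichment null samples regions uniformly with no assembly-gap or
  composition mask (an option exists for gap masks); on real genomes a
  composition-matched null would be stricter.
* Linear scans and dense resampling are designed for desk-scale inputs
  (hundreds of genes, tens of thousands of repeat elements); none of the
  data structures index overlaps.
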