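---
title: "Methods: from spatially barcoded reads to perturbation maps"
author: "spotscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from spatially barcoded reads to perturbation maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spotscreen)
```

This vignette explains the models and procedures in `spotscreen`, the
assumptions behind them, the tunable parameters and their defaults, and the
places where a genuinely open design choice had to be made. Nothing here
states an empirical result that the test suite or `scripts/acceptance.R`
does not itself compute.

## The measurement model

A deterministic-barcoding spatial screen tiles a tissue section into a grid
of spots: microchannel $i$ of the first microfluidic pass deposits barcode
$A_i$, channel $j$ of the second pass deposits $B_j$, and the pair
$(i, j)$ addresses one spot (50 µm pitch by default; the direct-capture
chemistry carries separate C/D barcodes for the sgRNA reads, declared the
same way). One sequencing mate carries the spatial structure:

```
[barcode1 (8 nt)] [linker1 (10 nt)] [barcode2 (8 nt)] [linker2 (10 nt)] [UMI (10 nt)]
```

and the other carries the payload: the ~20-nt sgRNA spacer followed by the
scaffold flank. Linker and flank sequences are configuration values of the
chemistry profile; every length is overridable but defaults to the numbers
above. All of this is declared, not hard-coded: a `read_layout` is an
ordered list of anchor / barcode / UMI / payload segments, and
`validate_profile()` checks the declaration against the whitelists and grid
before any read is touched.

## Demultiplexing

**Matching model.** All matching is substitution-only Hamming matching with
*unique-best-hit* semantics: a query is assigned to the single reference
entry within the mismatch budget, and any tie at the minimal distance is
rejected. This reproduces the behavior of a short-read aligner run with a
mismatch cap and a multi-mapping filter, but deterministically and without
an external dependency. Budgets default to 1 substitution for 8-mer
barcodes, 2 for spacers, and exact match for UMI whitelist lookup.

**Safety gating.** Correcting $m$ substitutions is unambiguous only when
the whitelist's minimum pairwise Hamming distance is at least $2m + 1$.
`demux_reads()` computes that distance and lowers the requested budget (with
a warning) when the whitelist cannot support it. At the default distance-4
whitelists the simulator emits, a single error is always corrected and a
double error is rejected rather than misassigned — which is why the
error-tolerance checks can demand *zero* false assignments to non-tissue
spots rather than merely few.

**Stage order and accounting.** Stages run in a fixed order — segment
extraction, UMI whitelist lookup, barcode axis 1, barcode axis 2, spacer —
and a read's drop reason is its first failing stage. One read, one record:
`assigned + dropped = input` is asserted on every run. Whether
off-whitelist UMIs drop the read or pass through is exposed
(`umi_filter`); dropping is the default. Base qualities are ignored.

**UMI handling.** The UMI whitelist is built from the data with the
standard rules: candidates 10–12 nt after flank trimming, truncated to
10 nt, any N rejected. Deduplication keeps distinct (spot, sgRNA, UMI)
triples; an optional directional single-mismatch collapse (merge a UMI into
a ≥2×-more-abundant neighbor at Hamming distance 1) is off by default
because no collapse rule is part of the published procedure.

## Spot assignment and spatial statistics

A spot with no detected sgRNA is `non_perturbed`; with exactly one,
`unique`. With several, it is `resolved` to the top sgRNA only when the top
count is ≥ 10 *and every other detected sgRNA has exactly one count*;
otherwise `ambiguous`. The "exactly 1" reading is deliberate and strict; a
lenient at-most-1 variant is equivalent on integer counts and the
`resolve_other_max` / `resolve_other_exact` arguments expose both. Ties for
the top count are `ambiguous` — resolution should never depend on an
arbitrary tie-break. The implementation is validated against an exhaustive
re-evaluation of the rule over all count multisets with up to 4 sgRNAs and
counts up to 15.

sgRNA *area* is the number of spots with at least one UMI of that sgRNA
(physical area = spots × pitch² when a pitch is set); *perturbation burden*
is the count and fraction of region spots carrying any sgRNA. The
colocalization statistic for an sgRNA pair is not part of the published
procedure, so two explicit reconstructions are provided: the Jaccard index
of the detection spot sets, and a neighborhood score (fraction of one set's
spots with a partner spot within Chebyshev radius 1), both with a
permutation null that redraws the two sets uniformly over tissue spots with
sizes preserved.

## Expression normalization and clustering

Raw counts are library-size normalized and log-transformed,
$\ln(1 + 10^4 c / \text{libsize})$, then z-scaled per gene with clipping at
±10. The original analysis used a regularized variance-stabilizing
transform at this step; that is a third-party method, not this package's
contribution, so the deliberately simple log-CPM + z-scale layer stands in
its position and the `lognorm` slot is pluggable.

Clustering follows the standard single-cell recipe: PCA (truncated, top 50
components), retaining the smallest number of PCs explaining ≥ 80% of the
captured variance — a formalized elbow rule, since "chosen by elbow plot"
is visual; a shared-nearest-neighbor graph (k = 20, Jaccard weights, pruned
below 1/15); and modularity-based Leiden community detection over a
resolution grid (0.2–1.6 by 0.2). **Resolution selection** deserves a note:
total within-cluster sum-of-squares decreases monotonically as partitions
get finer, so "minimize WSS" cannot select a resolution on its own. The
implemented rule treats the average silhouette width as the primary
criterion among partitions with more than 3 clusters, with WSS breaking
silhouette near-ties (0.01 band) in favor of the tighter partition. UMAP
(min.dist = 0.01) is computed for visualization only; no downstream
statistic depends on it. One seed fans out to every stochastic step.

## Perturbation signatures and scores

Spots labeled unique/resolved to an sgRNA with detection area ≥ 4 spots are
candidate-perturbed; area counts any UMI (the alternative — counting only
assigned spots — is exposed upstream via the area vector argument).
Non-perturbed spots form the NP pool. A spot's **signature** is its lognorm
expression minus the mean of its k = 20 nearest NP spots in PC space,
searched within the spot's expression cluster when that cluster holds at
least k NP spots and globally otherwise ("splitting by cluster"). The
neighbor subtraction cancels shared local biology so the
perturbation-specific component remains; its cost is a selection bias — the
NP spots nearest to a perturbed spot are those whose noise most resembles
it — which attenuates recovered effect sizes. The tests therefore compare
mean signatures against the *realized* expression shift rather than the
generative effect vector.

Per target $t$, the differential vector $v_t$ is the mean signature of
$t$-spots minus the mean NP signature, restricted to the top 100 genes by
absolute differential. The raw score of spot $i$ is the projection
$\langle s_i, v_t\rangle / \lVert v_t\rVert$. **Scaling is this package's
own convention**, the largest reconstruction in the module: raw scores are
divided by the 95th percentile of their absolute values over $t$-spots and
NP spots, placing typical scores in roughly $[-1, 1]$ so that the fixed
±0.2 thresholds are meaningful. Both the quantile and thresholds are
arguments. Classification: own-target score > 0.2 ⇒ perturbed; < −0.2 ⇒
NP; else unresolved; targets with fewer than 3 spots get NaN and a warning.

Score profiles of classified spots are reduced and clustered with the same
strategy (pUMAP). A perturbation is *major* in a cluster when its perturbed
spots are strictly more than 20% of the cluster; clusters without a major
perturbation are labeled `"NP + n"`, n = distinct perturbations present.

## Differential expression and enrichment

Spot-level DE is a per-gene two-sided Wilcoxon rank-sum test on lognorm
values using the normal approximation with tie correction (no continuity
correction; fully tied genes report p = 1), BH-adjusted. Fold-changes are
computed on de-logged means with a 10⁻⁹ pseudocount. "Pseudo-replicate"
testing is not defined in the published text; it is implemented as the most
standard reading — spots randomly partitioned (seeded) into r = 3
pseudobulk means per group, exact r-vs-r Wilcoxon — with plain spot-level
Wilcoxon as the default mode and the method recorded in the result. Note
the exact r = 3 test floors at p = 0.1, which is why the pseudobulk variant
is a robustness check rather than a significance engine at small r.

Preranked GSEA uses the weighted Kolmogorov–Smirnov running sum with weight
$|r|^{0.1}$, gene sets filtered to 2–500 members present in the ranking,
significance by seeded gene-label permutation (the adaptive multilevel
refinement of the reference implementation is third-party internals and is
not reproduced), and removal of the three uninformatively broad set names
"Translation", "Transcription", "Gene Expression" (exact, case-sensitive).
The ranking is expected to be restricted upstream to DE genes at adjusted
p < 0.2 with log2 fold-changes as the statistic. tRNA counts aggregate per
amino-acid isotype parsed from feature names (unparseable features go to
`unknown`, conserving totals); miRNA–target analysis is a Spearman
correlation against a *user-supplied* target list — target prediction is
out of scope.

## The recapitulation benchmark

The pooled assay reports, per sgRNA, the fraction of tumor sample lobes in
which it was detected; the spatial assay reports its detection area. The
benchmark treats the pooled fraction as a continuous predictor of the
binary spatial response (area > 2 spots), sweeping all thresholds for the
ROC; the AUC is the trapezoidal integral, which equals the pairwise
Mann–Whitney statistic with half-credit for ties (asserted to 10⁻¹² on
random instances). The published benchmark value on real liver-tumor data
(AUC 0.724) depends on sequencing data that is not desk-reproducible; this
package reproduces the construction, and on synthetic tables the AUC
reflects whatever the detection model makes of the clone geography.

## The simulator: what it emulates and what it does not

The generator produces: tissue as seeded random-growth blobs (60% of a
50×50 grid by default, 3 regions); clones as contiguous 4-connected
footprints, one sgRNA each, with log-normal sizes (clonal growth is
multiplicative; mean 100 spots, sdlog 0.8, floor 5, rescaled into an 80%
tissue budget when a heavy-tailed draw overshoots); ambient stray
molecules (5% rates) drawn from sgRNAs actually present in the section,
which is what lysate diffusion produces and what keeps absent library
members at area 0; negative-binomial counts over a 600-gene panel (500
coding, 40 tRNAs over 20 isotypes, 30 miRNAs, 30 lncRNAs; log-normal
baseline means, dispersions 0.2–0.8) with multiplicative knockout effects
(2× on 50 genes per target by default); and reads assembled exactly per
the declared layout — Poisson(25)-many molecules per clone spot, 6 reads
per molecule (≈2×10⁵ reads for the default scene), i.i.d. substitution
errors at a configurable rate, truth recorded before corruption. Barcode
whitelists are sampled from the full 8-mer space under a minimum pairwise
distance of 4; distance 5 is unattainable at 100 barcodes (random maximal
codes top out near 45), and distance 4 already guarantees
single-substitution correction with double errors rejected.

What the simulator does **not** emulate: PCR chimeras and duplication-rate
structure, indels (matching is substitution-only by design), cell-type
mixtures within spots, spatial expression gradients unrelated to clones,
and genome-alignable transcriptome reads (the expression matrix is
generated directly). Passing tests therefore demonstrate the correctness
of the computational chain under its stated error model — not performance
on tissue-specific artifacts of real sections.

## Numerical choices and degenerate inputs

Ties in barcode or spacer matching reject the read; ties for the top sgRNA
make a spot ambiguous; tied ROC scores take half-credit; constant genes
z-scale to 0 and report p = 1; zero-total spots are dropped with a warning
at normalization; an empty perturbation target (< 3 spots) yields NaN
scores and is excluded downstream; permutation p-values use the add-one
estimator $(1 + \#\{\text{perm} \ge \text{obs}\})/(1 + n)$ and are never 0.
Problem sizes in the test suite (50×50 scenes, ~2×10⁵ reads, 900-spot
recovery scenes, 65 536-row rule enumerations) were chosen so the full
pipeline exercises every stage at realistic scale while the whole suite
runs in about a minute.

## Known limitations

The perturbation-score scaling is a reconstruction; results near the ±0.2
thresholds should be read with that in mind, and the NP false-positive
rate of the threshold rule sits near 10–15% under the default NB noise.
The pseudobulk Wilcoxon at r = 3 cannot reach p below 0.1. The DC
chemistry's transcriptome/sgRNA disambiguation by whitelist identity is a
stated convention, not a published mechanism. Colocalization statistics
are reconstructions. Indel-containing reads are dropped, not rescued.
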