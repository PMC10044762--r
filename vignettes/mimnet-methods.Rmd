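---
title: "Methods: network-based phenotype scoring and core regulatory networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network-based phenotype scoring and core regulatory networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mimnet)
```

## The map model and its assumptions

A molecular interaction map is a signed directed graph with two node
classes. *Gene* nodes stand for anything that regulates — in curated
disease maps this includes proteins, metabolites and non-coding RNAs, all
collapsed to one class here because the propagation and motif mathematics
treat every non-phenotype species identically. *Phenotype* nodes are
readouts for processes (NETosis, apoptotic cell clearance, ...). Three
structural rules follow from reading phenotypes strictly as readouts:

* phenotype nodes are sinks — edges leaving them are dropped at load with
  a warning rather than rejected, since curated exports occasionally
  contain them;
* no admissible path may pass *through* a phenotype node;
* self-loops are legal in the map but never enter feedback-loop motifs.

Gene symbols are matched between map and expression tables
case-insensitively after trimming; unmatched significant genes are counted
and reported, never fatal, because map coverage of a transcriptome is
always partial.

## Influence propagation

The influence of gene $i$ on phenotype $p$ is
$I(i,p)=\sum_q \mathrm{sgn}(q)\,\alpha^{\mathrm{len}(q)-1}$ over simple
directed phenotype-free paths of length $\le D$. Two choices deserve
justification:

* **Simple paths, not walks.** Inflammation maps are rich in feedback
  loops; walk-based propagation diverges or needs spectral damping on such
  graphs, while simple-path enumeration is exact, finite and testable
  against brute-force enumeration.
* **Attenuation $\alpha = 0.5$, depth $D = 5$ (defaults).** Halving per
  step means a three-step route carries a quarter of the weight of a
  direct edge — indirect regulation matters but cannot swamp direct
  evidence — and contributions beyond five steps would be $\le 1/16$ of a
  direct edge, below the noise floor of fold-change data. Both are exposed
  in `influence_params()` so other propagation schemes can be
  approximated.

The matrix builder walks backwards from each phenotype once (depth-first,
accumulating sign products), which visits each simple reverse path exactly
once; the per-pair scorer `influence_score()` walks forwards. The two
independent traversals agreeing with each other and with igraph-based
exhaustive path enumeration (on all random graphs up to 8 nodes, 50 seeds,
tolerance 1e-12) is part of the test suite.

Note one property that is sometimes assumed but is false in general:
negating *every* edge sign does not negate $I$; each path term is
multiplied by $(-1)^{\mathrm{len}}$, so only odd-length contributions flip.
The suite asserts this parity behaviour explicitly, along with the true
symmetry (flipping one bridge edge that carries all paths flips the
score).

## Phenotype activity and its null

Activity is the influence-weighted signed fold-change sum over significant
genes. Signed fold changes (rather than $|FC|$) are used so that
"upregulated phenotype" and "downregulated phenotype" are meaningful —
a set-overrepresentation test cannot produce a direction. Normalisation
divides by the maximum absolute activity *within a (contrast, time)*:
values are comparable across time for one phenotype, and deliberately not
across phenotypes, whose upstream universes differ in size and density.
An all-zero time point stays all-zero rather than being rescaled.

The permutation null shuffles (log2FC, padj) tuples across the *measured
mapped* genes only — not the whole genome — preserving the map-coverage
structure and the marginal distribution of significance; each permutation
re-selects its own significant set. P-values use add-one smoothing,
$(1+\#\{|A^{perm}|\ge|A|\})/(1+n_{perm})$, so they are never zero and the
test is exact-level conservative. With an empty overlay every p-value is 1
by convention.

## Perturbation semantics

Perturbation predictions are linear superposition over the influence
matrix: $L_p=\sum_g I(g,p)\,v_g$ with $v_g\in\{+1,-1\}$. This is a
deliberate modelling simplification — no fixed point iteration, no
saturation — chosen because a static linear readout is exactly
reproducible, additive over disjoint perturbation sets, antisymmetric
under sign flips, and consistent with the influence matrix column by
column (all four properties are tested exactly). Dynamic or Boolean
simulation is out of scope.

## Core regulatory networks

Motifs are directed 3-cycles among the genes upstream of the target
phenotype (within depth $D$). Both orientations of a triangle are distinct
motifs because they are distinct edge sets. Features are min-max
normalised over the candidate population; a constant feature maps to 0.5
so it contributes equally to every motif instead of degenerating to 0 or
1. Scores are the weighted feature sums over the full 27-point grid
$\{0.33,0.66,1.0\}^3$, and the selection is the union over scenarios of
each scenario's top-m (default 5, with deterministic lexicographic
tie-breaks). A single-pass union is used rather than iterative re-ranking
after removal; the union of per-scenario winners already contains every
motif that is best under some weighting, which is the Pareto-set reading
we adopt. Weighted-sum scalarisation cannot surface points interior to a
non-convex front, but with `top_m > 1` near-optimal motifs under each
weighting are retained as well. A candidate cap (descending influence
feature, default 20 000) guards against combinatorial blow-up on dense
maps.

By construction, if motif A dominates motif B on all three features (one
strictly), A is selected whenever B is — checked over random motif
populations in the suite.

## DEG handling choices

* Uniqueness in the two-contrast split is across *all* time points;
  commonality does not require a shared time point.
* "Opposite direction" for a common gene: a shared significant time point
  with conflicting signs decides first; if the contrasts share no
  significant time point, the signs of each contrast's maximum-|log2FC|
  significant estimate are compared. The underlying definition (up in one
  treatment, down in the other, over the whole course) does not fix a
  shared-time rule, so the fallback branch is recorded in the output
  metadata of `write_venn_json()`.
* The late-induction filter requires the focal-time base mean to strictly
  exceed *every* earlier base mean, separating genuine late induction from
  fold changes created by collapsing control expression; genes missing an
  earlier base mean are excluded, not guessed.
* Cell-type scores average significant markers only, and any sign
  disagreement among significant markers excludes the cell type
  (`opposing_markers`). Strict unanimity was chosen over majority voting:
  with panels of ~7 markers per type, a single genuinely opposing marker
  is more plausibly a mixture of cell states than noise, and the
  downstream interpretation (a coherent shift in composition) requires
  coherence.

## Preprocessing stand-ins

Size factors are the median-of-ratios estimator (verified in the suite
against `DESeq2::estimateSizeFactorsForMatrix`). The DE step is an
explicitly simple stand-in — Welch t-test on log2(normalised + 0.5) with
Benjamini–Hochberg adjustment per (contrast, time) — because the package's
contribution is downstream of DE: externally computed DE tables in the
long TSV layout are first-class input and swapping engines must not change
any contract. Degenerate genes (identical values in both groups, including
all-zero) get p = 1 by convention. PCA outlier screening works per
(contrast, group, time) stratum on log2(normalised + 1), gene-centred,
using distance from the centroid in the PC1–PC2 plane with a
median + 3 MAD cut — a concrete rule standing in for the common but rarely
specified practice of "inspecting the PCA"; strata under 4 samples are
skipped because a MAD of 3 distances is meaningless. Pseudo-counts differ
on purpose: +1 inside the PCA transform (robustness), +0.5 inside the DE
transform (less fold-change compression at low counts).

## The synthetic study generator

`sim_config()` fixes the emulated conditions: 60 map genes, 4 phenotype
sinks (one per inflammation phase), background edges with
preferential-attachment-like in-degree (expected out-degree 1.6, 30%
inhibiting), one planted activating 3-cycle wired straight to the first
phenotype, and per-phenotype planted regulator modules of 10 genes
(alternating up/down, |log2FC| 3; motif genes carry |log2FC| 4 so they sit
in the top decile). Counts are negative binomial (dispersion 0.05,
log-normal baselines around 100, log-normal library sizes, sd 0.15) over
two groups × 7 replicates, mirroring a seven-animals-per-arm design over
time points 12–192 h; planted effects appear in the treatment group at
120 h. All generators are deterministic given the mandatory seed.

What the generator does **not** emulate: correlated co-expression beyond
the planted structure, batch effects, varying sequencing depth per time
point, partial map coverage of the transcriptome, and the heavy curation
biases of real disease maps. Passing the recovery benchmarks therefore
demonstrates that the machinery is correct and well-calibrated under its
own assumptions, not that effect sizes of this magnitude are guaranteed to
be recovered from real tissue RNA-seq.

Benchmark problem sizes (chosen to make each run a few seconds while
keeping every rate estimable over 20 seeds): single planted time point for
recovery runs, 199 permutations for significance benchmarks (smallest
attainable p ≈ 0.005), 20 seeds per rate. The cell-composition benchmark
simulates the marker panel alone, so its only planted signal is the marker
shift; the phenotype and motif benchmarks use the full study.

## Worked CRN example

```{r crn-demo}
cfg <- sim_config(seed = 7, time_points = 120)
st  <- simulate_study(cfg)
infl <- influence_matrix(st$map)
deg <- simple_de(st$counts, st$metadata, "trt_vs_ctl", 120)
ov  <- overlay(st$map, deg, "trt_vs_ctl")
crn <- extract_crn(st$map, st$truth$focal_phenotype, infl, ov, 120)
crn
sort(st$truth$motifs[[1]])  # the planted feedback loop
crn$motifs[, c("motif_id", "F_I", "F_ES", "F_FC", "best_S")]
```

## Known limitations

* The influence/enrichment contract is this package's own concrete,
  oracle-testable formulation of network propagation; tools built on other
  propagation schemes will produce different numeric phenotype levels.
* Path enumeration is exponential in the worst case; the depth cap and
  candidate cap make defaults tractable on sparse curated maps, but very
  dense maps may need a smaller `max_depth`.
* Linear perturbation ignores saturation and feedback dynamics.
* Marker-based cell profiling reflects shifts in marker expression, which
  confounds per-cell expression change with composition change; it is not
  deconvolution.
* The interfaces are R functions plus the small text formats documented in
  the readers/writers (SIF, node-attribute TSV, long DE TSV, GMT,
  GraphML); there is no shell front-end.
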