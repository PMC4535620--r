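---
title: "Methods: serotype transcriptome landscapes with serosom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: serotype transcriptome landscapes with serosom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The analysis problem

*Paramecium tetraurelia* expresses exactly one member of its surface
antigen (SAg) multigene family at a time; the active member defines the
cell's serotype, a heritable, epigenetically stabilized state.  Bulk
RNA-seq of serotype-pure cultures under different environmental programs
asks several questions at once: which genes are differentially expressed
between states, whether large groups of genes are co-regulated with the
active SAg, whether those groups persist through environmental shifts but
collapse under heat shock, whether global transcriptome similarity is
driven by expression level or by shared trends, whether SAg activation
perturbs neighbouring subtelomeric genes (telomere position effect), and
which functional categories the differential genes enrich.

`serosom` implements that analysis as a tested pipeline over a gene x
sample count matrix, together with a synthetic-data generator that
reproduces the statistical structure the analysis assumes and carries
ground-truth labels, so every stage can be validated by recovery rather
than by inspection.

# Expression units and normalization

Counts are converted with the standard closed forms

* RPKM(g, s) = 10^9 K(g,s) / (L(g) * sum_g K(g,s)),
* TPM: length-normalized rates rescaled so each column sums to 10^6,

and log10-transformed with a pseudocount of 1 (the log base and
pseudocount are conventions of this package; both are arguments).
Between-sample depth factors use the median-of-ratios estimator on the
genes expressed in every sample, rescaled to geometric mean 1.
Landscapes and clustering consume log-TPM; fold changes and MA plots use
depth-normalized counts.

# Differential expression

The DE stage is a deliberately small, fully specified negative-binomial
Wald test, not a reimplementation of a full GLM framework: per gene the
log2 ratio of depth-normalized group means (offset 0.5 avoids
infinities), a delta-method standard error from Var(K) = mu + alpha mu^2,
and a two-sided normal p-value; Benjamini–Hochberg step-up correction
(own implementation, cross-checked against `p.adjust` and a brute-force
oracle in the tests) with differential calls at FDR < 0.01.  There is no
Cox–Reid adjustment, no fold-change shrinkage and no independent
filtering.

Dispersion is method-of-moments on normalized counts, pooled within
condition groups, with a log-log linear mean–dispersion trend.  The
final dispersion is the **maximum** of the per-gene value and the trend.
With triplicates the moment estimator underestimates alpha for roughly
half the genes, which makes a plain raw/trend blend anticonservative
(null p < 0.05 fraction ~0.087 in our calibration runs); the trend floor
— the conservative sharing mode of the first-generation NB DE tools —
restores calibration (~0.056) while keeping power above 0.9 for |LFC| =
2 at mu >= 100, alpha <= 0.2, 3 vs 3.  A blend weight remains exposed
(`trend_weight`, default 0).

One consequence of the NB variance is that p-values are not exactly
invariant to multiplying a sample's column and its size factor by the
same constant: the shot-noise term q/f scales with depth.  Fold changes
and normalized means are exactly invariant; the tests assert p-values to
5% relative tolerance under such rescaling.

# SOM landscapes and regulated spots

Genes (observations, dimension = samples) are mean-centered across
samples and fed to an online Kohonen map on a 20 x 20 lattice: Gaussian
neighbourhood, learning rate 0.5 -> 0.01 and radius 10 -> 1, both linear
in the presentation step, codebook initialized from random data rows,
20 epochs, fully deterministic given the seed.  Centering makes each
landscape's MaxEXP positive and MinEXP negative in typical data, which
the classification rule below needs; a raw mode is retained for
ablation.

Two per-sample landscapes exist and serve different purposes:

* `landscape()` — the **member-mean** field: each unit carries the
  arithmetic mean of its member genes' (centered) expression in the
  sample.  This is the gene-level summary; empty units carry the
  codebook value and are flagged and excluded from extrema and
  classification.
* `metagene_landscape()` — the **prototype** field: the trained codebook
  entries themselves.  Because neighbourhood training averages each
  prototype over on the order of a hundred genes, this field is the
  noise-damped version of the former.

Classification applies the strict multiplicative band: a unit with value
de is over-expressed iff de > 0.9 * MaxEXP and under-expressed iff
de < 0.9 * MinEXP, extrema per sample by default (a global mode is
available), factor configurable.  Classification and spot detection
default to the prototype field, and this choice is load-bearing: on the
raw member means, best-matching-unit assignment *sorts* per-gene
sampling noise into units, so across a homogeneous co-regulated module
the between-unit spread of the member mean is close to the per-gene
noise sd, and a band defined as the top tenth of the range degenerates
to the noise tail (in our planted-module experiments it captured ~4% of
the module; on the prototype field the same rule captures 84–99%).  For
the same reason the final neighbourhood radius does not collapse below
1: the residual smoothing is what makes the band a spot selector.  The
price is a few percent of quantization accuracy relative to the
data-row initial codebook, asserted as such in the tests.

Regulated spots are maximal connected components of same-class units
(8-neighbour adjacency by default, 4 available), ordered by gene count
then row-major anchor; member genes come from the assignment.  In sign
regimes where MaxEXP <= 0 or MinEXP >= 0 the affected side is classified
`none` with a warning — the printed rule has no sensible reading there.

# Serotype co-regulation and persistence

The active SAg of a condition is the family member with the highest mean
TPM (the generator's mutual exclusion keeps the runner-up below 2%).
The SAg spot is the over-spot containing it.  Two quantities formalize
the visual spot comparisons of this kind of study, and both are
artifact-defined conventions rather than literature definitions:

* **persistence** of a parent spot in a derived sample = the maximum
  Jaccard index between the parent spot's gene set and any derived
  over-spot;
* the **co-regulation group** of the SAg = genes whose (sample, class)
  spot-incidence pattern equals the SAg's exactly.

The heat-shock contrast tabulates per-replicate log2 fold changes of the
cytosolic HSP panel and the active SAg.  Note that with exchangeable
simulated replicates the across-replicate HSP/SAg rank correlation is
noise (the real study's inverse correlation came from one replicate
being shocked less); tests therefore assert the signs of the fold
changes, not the sign of that correlation.

# Transcriptome similarity

Sample-by-sample distances on unscaled log-TPM columns under both study
metrics — Euclidean (level-sensitive) and 1 − Pearson (trend-sensitive)
— followed by UPGMA (average linkage, `hclust`), with Newick export via
`ape`.  Profiles that are proportional plus an offset have Pearson
distance 0 but large Euclidean distance; this is exactly how two
cold-adapted states with different absolute levels can separate under
one metric and reunite under the other.

# Subtelomeric position-effect scan

Coordinates are 1-based inclusive (GFF3); the distance of a gene to a
telomeric position is measured in bp from the nearest feature edge and
in gene rank (number of intervening genes), minimized over scaffold ends
and, by default, internal telomeric sites (toggleable).  The spreading
test is this package's formalization of a visual analysis: over the
genes between a focal SAg and its telomere, pooled across scaffolds, the
statistic is the Spearman correlation between the ON−OFF difference of
mean log10 expression and proximity to the telomere; the null permutes
the ON/OFF sample labels, with a +1 correction so p is never 0.  The
generator's ON/OFF design is 3 vs 9 — one serotype-pure triplicate
against the three other serotype states — matching the study design;
a balanced 3 vs 3 design has only 20 label splits, so permutation
p-values cannot reach 0.05 regardless of effect size.  Synthetic
subtelomeres place the focal SAg near one scaffold end (tight intergenic
spacing telomere-side, wide internally), so its nearest telomeric
position is always the downstream end; planted spreading silences
neighbours by a factor `decay` (default 0.5) per gene step compounding
toward the telomere.

# GO enrichment

An OBO-lite reader (id, name, is_a; `part_of` accepted as is-a with a
warning) feeds a rooted acyclic DAG; associations are propagated to all
ancestors on load (idempotent; ancestor counts monotone).  Two tests are
provided: term-for-term upper-tail hypergeometric, and parent-child-union
— the same tail probability with both population and study restricted to
genes annotated to the union of the term's parents (root: p = 1; on a
flat DAG the two coincide exactly, which the tests assert).  BH
correction runs across terms within each direction; the reporting
threshold defaults to FDR <= 0.02.

# The synthetic generator

`simulate_dataset()` draws NB counts (Var = mu + alpha mu^2) for a
7-condition x 3-replicate design: three serotype-pure baselines (A.31,
D.24, H.14), a spontaneous serotype variant (B.24, selected out of
D.24), a cold-adapted derivative (B.6), a starved derivative (D.starv)
and a 20-minute heat shock (D.HS).  Defaults, all config-exposed:

* gene-wise dispersion log-normal, median 0.005, sdlog 1 — the study's
  replicates are aliquots of one clonal master culture, so biological
  variance is near the technical floor;
* baseline means log-normal (meanlog log 100, sdlog 1.5) for the
  MA-plot-like dynamic range; planted module genes drawn high-expressed
  (meanlog log 1000, sdlog 0.5), as spot genes are in this system;
* one planted co-regulated module of 500 genes per serotype, x 2^2 in
  conditions where its serotype is active (`lfc_module = 2`);
* the 8-member SAg family: active member mean 5000 counts, inactive
  members 1% of the condition's active level (100x exclusivity against
  the >= 50x requirement); family members share a 2 kb length, as
  closely related paralogs do, which keeps exclusivity identical on
  count and TPM scales;
* heat shock multiplies the active SAg and its module by 0.1
  ("drastic" decay) and six cytosolic HSP genes by 32; cold/starvation
  copy the parent condition and perturb 20% of background genes by
  log2 effects ~ N(0, 1), leaving module genes untouched;
* per-sample library factors uniform in [0.5, 2].

Ground truth (active SAg per condition, module membership, noise-free
condition means, dispersions, library factors) is returned alongside the
counts, plus a subtelomeric gene map and a three-level GO DAG with one
planted enriched term annotating part of the first module.

What the generator does **not** emulate — and hence what green tests do
not establish about real data: read-level effects and multi-mapping
between near-identical paralogs (quantification starts from counts),
isoforms, correlated gene–gene noise within replicates, batch structure,
partially penetrant serotype switches within a culture, and any
dependence between dispersion and condition.  Recovery results on this
generator validate the machinery, not the biology.

# Numerical conventions and scale

Pseudocount 1 for log10; +0.5 offset inside DE fold changes; BMU and
UPGMA ties break to the lowest index; permutation p-values carry the +1
correction; seeds derive per stage from the global seed through a fixed
affine map below 2^31.  The shipped tests and the acceptance script run
at desk scale — 6,000 genes, 21 samples, 20 x 20 lattice, 10–20
simulation repeats and 100–500 permutations per check — sizes chosen so
the whole validation battery reruns in minutes while keeping every
Monte-Carlo bound well away from its threshold.

# Known limitations

The DE stage trades the full GLM machinery for specifiability; its
calls are conservative by construction.  The 0.9-extremum rule is
scale-free but shift-sensitive: it presupposes centered data and is
ill-posed when either extremum has the wrong sign.  Exact-incidence
co-regulation is brittle to single classification flips at spot
boundaries (by design: it is an exact rule; relax by post-filtering if
needed).  The spreading test conditions on the annotated gene order and
does not model intergenic distance beyond rank.  Newick export encodes
ultrametric heights; non-ultrametric trees are out of scope.
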