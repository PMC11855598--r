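---
title: "Methods: clonal evolution from flow-sorted tumor populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clonal evolution from flow-sorted tumor populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonesort)
```

`clonesort` analyzes tumors whose biopsies have been separated by
fluorescence-activated sorting of nuclei into distinct tumor populations
(by DNA content and a tumor marker) before whole-exome sequencing. This
vignette documents the models behind each stage, the tunable parameters,
and the choices made where the methodology was genuinely open.

## FACS ploidy and purity

Ploidy is estimated as twice the ratio of geometric means of DAPI
intensity between a tumor population and the matched marker-negative
diploid population. Geometric means are the natural location statistic for
flow intensities, which are approximately log-normal; the estimator is
scale invariant, so no instrument calibration is needed. Estimates are
reported to one decimal, the precision at which sorted-population tables
are usually compiled. A historical DNA index converts to ploidy as
`2 * index`.

Automatic gating (`gate_populations()`) replaces the manual gates an
operator would draw: the marker threshold is Otsu's threshold on log
marker intensity, and population centers are modes of a kernel-smoothed
log-DAPI density, with peaks at twice an existing peak interpreted as that
population's G2/M compartment rather than a separate population. Tumor
gates include the G2/M window (cycling tumor nuclei belong to their
population) unless that window would collide with another tumor
population's G0/G1 window; the normal gate includes its own G2/M window,
which cannot collide with tumor gates because gates are rectangles in
(marker, DAPI) space and differ in the marker dimension. Pre-sort purity
is the tumor-gate event count over the tumor-plus-normal-gate count,
excluding ungated events (debris, doublets).

## Variant filtering

The cascade operates per population: keep a call if VAF ≥ 1% and it has at
least 3 supporting reads; keep it with only 2 supporting reads if the same
variant passes the primary rule in another sorted population of the same
patient (cross-population confirmation makes a weak call credible);
remove variants observed in ≥ 2 samples of a panel of normals everywhere.
"Supporting reads" is interpreted as alt-supporting reads — consistent
with a 2-read relaxation, which would be vacuous for total depth — but a
`count_mode = "total"` switch is provided. The VAF floor is applied per
population, never rescued by the relaxation. Discards are tallied by the
first failing rule (panel, VAF, reads), which makes the tally a partition
of the input; the cascade is idempotent by construction.

The TMB denominator is a required input (default 35.7 Mb, a typical
whole-exome capture footprint); it is not a constant of the method and
reported TMB scales inversely with it.

## Cancer cell fractions

With purity $p$, tumor total copy number $C_t$, normal copy number $C_n$,
and multiplicity $m$ (mutated copies per carrying cell), the expected VAF
of a mutation at CCF $f$ is

$$ \mathrm{VAF} = \frac{m f p}{p C_t + (1-p) C_n}. $$

The CCF estimate inverts this at the observed VAF. Multiplicity is the
rounded copy-number-scaled VAF clamped to $[1, C_t]$; the rounded quantity
is really $m f$, so $m$ is identified for clonal and near-clonal mutations
while a subclonal multi-copy mutation is deliberately under-called in $m$
(rather than over-called in CCF) — the same degeneracy any purity/CN
based caller faces without a prior over karyotypes, which is out of scope
here. Raw CCF estimates are clipped to $[0, 1.2]$ (retaining the raw
value) and capped at 1 for classification.

Interval estimation uses the Jeffreys Beta$(a+\tfrac12, r+\tfrac12)$
posterior on the VAF (good small-count behavior, no sampler), with the
usual boundary modification at 0 and $n$, pushed through the monotone
VAF→CCF map and clipped to $[0,1]$. The clonal probability is the
posterior mass of CCF ≥ 0.9, which aligns the probabilistic rule with the
descriptive convention that CCF ≥ 0.9 is clonal; a mutation is classified
clonal when that probability exceeds 0.5 **or** the 95% interval's lower
bound exceeds 0.9. Both thresholds are arguments.

A fallback purity estimator inverts the dilution model at the median VAF
of candidate truncal heterozygous mutations, for when no allele-specific
copy-number fit is available.

## Mutation clustering

Mutations are clustered on their joint multi-population read counts with a
finite mixture of binomials: component $k$ carries a CCF vector
$\phi_k$ over the populations, mapped per mutation to an expected VAF
through the coefficient $c_{ip} = m_{ip} p_p / (p_p C_{t,ip} + (1-p_p) C_n)$.
The M-step uses the moment update
$\phi_{kp} = \sum_i r_{ik} a_{ip} / \sum_i r_{ik} d_{ip} c_{ip}$, the
exact MLE when $c_{ip}$ is constant within a population and a close
approximation otherwise. Initialization is k-means++-style seeding on the
per-mutation CCF point estimates; for each candidate $K$ the EM runs
briefly from 20 seeded restarts, the best restart by likelihood is run to
convergence (relative tolerance $10^{-8}$, cap 300 iterations), and $K$ is
selected by BIC over $1..K_{\max}$ (default 8) with $KP + K - 1$
parameters. Everything is deterministic given the seed. This is a
deliberate replacement of Dirichlet-process samplers used for the same
task: a finite mixture with BIC is reproducible, fast at the scale of a
few thousand exome mutations, and exposes its assumptions.

Clusters with fewer than 5 mutations are discarded (their mutations are
reported unassigned, not forced into other clusters); a cluster of exactly
5 is kept.

## Clone trees and metastasis seeding

Cluster CCF vectors are arranged into a rooted tree under two standard
constraints, both with an absolute tolerance of 0.05 (CCF estimates at
exome depth carry noise of a few percent): **containment** — a child's CCF
may not exceed its parent's in any population — and the **sum rule** — in
each population a node's children may not jointly exceed it. The root is
the single cluster clonal everywhere; each remaining cluster attaches to
its *minimum containing superset*, the containing cluster with the
smallest total CCF (ties to the smaller label). Clusters with no
containing cluster are flagged unplaced, and sum-rule violations are
reported rather than silently repaired; both indicate that no single tree
explains the clusters. When several clusters sit within tolerance of
clonal everywhere (typically an over-split trunk), the one with the
highest total CCF roots the tree and the others attach beneath it by
containment.

A metastasis is traced to the primary population it shares clusters with
*exclusively*: for metastasis $M$, each primary $P$ scores the number of
clusters present (CCF > 0.1) in both $M$ and $P$ and absent from every
other primary. The presence threshold of 0.1 separates genuine lineage
presence from noise around zero at typical depths and is configurable.
Ties and zero-evidence cases fall back to the highest pairwise
copy-number profile correlation; with no correlation matrix they are
flagged unresolved rather than guessed.

## Maximum parsimony

Binary presence/absence matrices (populations × mutations, plus an
all-zero germline outgroup) are scored by Fitch small parsimony over an
exhaustive enumeration of unrooted topologies, rooted at the outgroup.
The topology count grows as $(2L-5)!!$, so the search is capped at 10
populations — far above the 2–4 sorted populations per patient this
design produces. All minimum-score topologies are returned; the
lexicographically smallest Newick string is the canonical primary tree.
Branch lengths are mutation counts: each homoplasy-free column is
assigned to the branch subtending exactly its carriers; homoplasic
columns are counted but not assigned. Trunk classification offers two
conventions, patient-level (`strict`: trunk = present in all populations;
default, matching how whole-patient trees are drawn) and biopsy-level
(`paper`: trunk = present in ≥ 2 populations), because both conventions
are in circulation.

## Mutational signatures

Spectra over the standard 96 pyrimidine-centered trinucleotide channels
are refit by non-negative least squares against a reference matrix with
unit-sum columns; fitted weights are normalized to fractions and the
residual norm reported. No sparsity penalty or signature pre-selection is
applied — which signatures to include is a data choice made by supplying
the reference. Contributions below 5% (strictly) are pooled into
"others" for display. The package ships a small synthetic four-signature
reference (UV-like, platinum-like, alkylating-like, flat) so tests and
simulations need no external database; any COSMIC-format TSV is accepted.
Refitting is provided per population and per mutation set (e.g. private
mutations of a branch), since either unit of analysis is legitimate.

## Copy number

Categories are called on integer total copy number relative to rounded
ploidy: 0 is a homozygous deletion, below ploidy a loss, equal neutral,
above by 1–2 a gain, and ≥ 3 above an amplification (the offset is an
argument; published log-ratio thresholds vary and are rarely printed).
Profile concordance is Pearson correlation of log ratios rasterized to
1 Mb bins over bins covered in both profiles, with the t-transform
p-value. Coordinates are 0-based half-open throughout; homozygous
deletions intersect a gene table under strict half-open semantics, so
abutting intervals do not overlap.

## The synthetic-data generator

`simulate_patient()` emulates the data structure of a sorted-population
study: 2–4 populations per patient with distinct ploidies, truncal /
shared / private mutation clusters with stated CCF vectors, binomial read
sampling `alt ~ Bin(depth, VAF)` with Poisson depths (default mean 150,
typical exome coverage), log-normal FACS intensities (DAPI CV 5%, a
standard instrument figure; G2/M fraction 10%), and multinomial
trinucleotide contexts from per-cluster signature mixtures.
`patient1_config()` is the reference scenario: a polygenomic primary
(ploidies 1.7 and 2.7, pre-sort purities 19% and 41%) and two metastases,
six clusters in two trajectories (cluster sizes 500, 298, 150, 199, 34,
227), post-sort purities 0.88–0.95, with the trajectory CCFs chosen to
respect containment and the per-population sum rule. The generator's
defaults are the package's study conditions and are not adjusted per
analysis.

What the generator does **not** emulate — and what passing recovery tests
therefore cannot certify on real data: sequencing error and mapping
artifacts (alt reads at true-CCF-zero sites are exactly zero),
subclonal copy number within a sorted population, sorting
cross-contamination between populations, overdispersed depths, and
germline leakage past the panel of normals. Recovery results (ARI,
seeding accuracy) on simulated patients are upper bounds on real-data
performance, demonstrating correctness of the inference machinery rather
than robustness to artifacts.

## Problem sizes and determinism

The test suite and the acceptance script use desk-scale sizes chosen to
exercise every code path with tight statistical checks: ~1,400 mutations ×
4 populations per simulated patient, 20-patient recovery studies, 2,000
sites for interval coverage, 10,000 FACS events, 5,000-mutation spectra,
and 200 random matrices (≤ 5 populations, ≤ 12 mutations) for the
parsimony brute-force comparison. All stochastic stages take explicit
seeds; sub-seeds are derived with `derive_seed()` so one master seed
reproduces an entire analysis, including byte-identical pipeline outputs.

## Known limitations

* Multiplicity is a point estimate; subclonal multi-copy mutations are
  under-called in $m$ (see above).
* The clone-tree builder returns one tree (plus flags); it does not
  enumerate alternative topologies when the containment relation is
  ambiguous within tolerance.
* Purity enters as a fixed per-population constant; uncertainty in purity
  is not propagated into CCF intervals.
* FACS gating assumes log-normal, well-separated populations; heavily
  overlapping DAPI distributions (ploidy differences below ~2 CV) will
  merge.
* The signature refit is unpenalized least squares; with many highly
  correlated reference columns, exposures of similar signatures are only
  jointly identified.
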