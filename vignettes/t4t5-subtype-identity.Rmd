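---
title: "Quantifying T4/T5 subtype identity: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying T4/T5 subtype identity: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The biological problem

T4 and T5 neurons of the *Drosophila* optic lobe are the first
direction-selective cells of the motion pathway. Each exists in four
subtypes (a--d), distinguished by two tightly coupled anatomical
properties: the preferred orientation of the dendritic arbor (four
directions roughly 90 degrees apart) and the lobula-plate layer (1--4)
that the axon innervates — each layer receives axons of exactly one
subtype. During pupal development (roughly 36--72 h after puparium
formation, APF) dendrites grow in their subtype-specific direction,
while the transcriptomes of the eight T4/T5 populations (2 types x 4
subtypes) express a compact combinatorial transcription-factor code: a
Dac/Ab class marking subtypes a,b, a mutually exclusive Omb/Pros class
marking c,d, and the GATA factor Grain marking b,c. Gaining Grain
converts a to b and d to c; losing it converts b to a and c to d, with
dendrite orientation and axon layer converting together.

`t4t5id` implements the quantitative procedures that establish these
claims — orientation polar histograms, an L1 similarity index,
normalized axon positions, expression QC/differential filtering, the
code itself and its perturbation maps — and pairs them with a
synthetic-data generator that produces populations with known ground
truth, so every stage of the pipeline is testable end to end without
any imaging or sequencing data.

## Dendrite orientation

For a dendrite image (or point set), a vector is drawn from the
dendrite's *first branching point* to every suprathreshold pixel. The
vector angles, measured in degrees counterclockwise from the +x axis,
are assigned to 12 half-open bins of 30 degrees, `[30k, 30(k+1))`, and
bin masses are normalized by the total vector count. Conventions the
original description leaves open are fixed as follows:

* pixels exactly at the center are excluded (their angle is undefined);
* bins are half-open on the right, so a rotation by a multiple of the
  bin width permutes bins exactly;
* 3D inputs are reduced by maximal intensity projection along z before
  histogramming;
* the intensity threshold, a manual step in the original workflow,
  defaults to Otsu's method on the image (via `EBImage::otsu`) and can
  be overridden by an absolute value. Sensitivity to this choice can be
  explored by passing a vector of thresholds to
  `orientation_histogram` in a caller-side loop; the histogram itself
  never guesses.

Two orientation histograms are compared with the similarity index

S(h1, h2) = sum_k |h1_k - h2_k|,

the L1 distance between normalized histograms: 0 for identical
orientation distributions, at most 2 for disjoint ones. It is a true
metric (symmetric, triangle inequality, zero iff equal), which the test
suite asserts on random inputs. `classify_by_dendrite` assigns a neuron
the subtype of the nearest reference histogram; exact ties are broken
deterministically in the order a < b < c < d and flagged — the
procedure the original analysis never needed because real data produce
no exact ties.

For cross-stage displays, `scale_histogram` multiplies an early-stage
histogram by the ratio of its vector count to a late-stage count, so
that bin masses sum to the scale factor rather than to 1; such scaled
histograms are display objects and are rejected by `similarity_index`.

Averages of histograms report the per-bin mean and the standard error
of the mean (sample SD / sqrt(n)); with n = 1 the s.e.m. is reported as
0 with an explicit flag rather than NA, so downstream tabulation never
mixes types.

## Axon position and layers

The subtype of a neuron can be read independently from its axon: the
position of the axon reference point along the anteroposterior axis of
the lobula plate, normalized by the local extent of the neuropil at
that proximodistal position, with 0 the most posterior and 1 the most
anterior edge. Out-of-bound points are clamped and flagged. The measure
is invariant under joint translation and scaling of the frame and the
point, which the suite asserts.

The four layers are recovered from a sample of positions by
one-dimensional k-means. Because the original work does not name a
clustering algorithm, we use Lloyd's algorithm with deterministic
initialization at the (2i-1)/2k quantiles, which removes all seed
dependence; clusters are reported in ascending order with boundaries at
midpoints of adjacent cluster means. Positions exactly on a boundary go
to the lower group (an arbitrary but fixed tie rule). Layer numbering
relative to the normalized axis is not stated numerically in the
source text, so the mapping defaults to `posterior_first` (layer 1
nearest position 0) and is an explicit configuration choice
(`layer_order`), not an anatomical claim. The axon reference point may
be the axon's first branching point or first bouton; the skeleton
metadata records which convention produced it.

## Expression rules

* **QC.** Cells with fewer than 200 total counts, or with more than 10%
  of counts in mitochondrial-like or heat-shock-like genes, are
  removed; then genes detected (count > 0) in fewer than 3 cells are
  removed. The source text fixes the thresholds but not the order of
  operations; we apply cell filters first, recompute the gene filter on
  the surviving submatrix, and iterate the pair to a fixed point so the
  filter is idempotent — re-running it on its own output removes
  nothing. Every removal is reported with its reason.
* **Normalization.** Per-cell scaling to a common total (10,000) with
  `log(1+x)`. This is deliberately plain: the variance-stabilizing and
  batch-integration machinery of the original workflow is out of scope
  here, and the synthetic data is generated batch-free.
* **Differential expression.** A gene passes for cluster A over B iff
  detection fraction in A >= 0.5, the difference of detection fractions
  is >= 0.5, and the fold change on the normalized-mean scale, with
  pseudocount 0.01 on both sides, is >= 2. The threshold trio mirrors
  the original high-stringency filter; we interpret its fold-change
  requirement as "two-fold" on the normalized-mean scale because the
  log base of the original tool setting cannot be recovered from the
  text, and both the threshold and the pseudocount are arguments.
  Detection is count > 0 by default (`detect_min`). With a
  detection-difference threshold of 0.5 the rule is anti-symmetric: a
  gene can pass in at most one direction.
* **Stage consistency.** Per-stage passing sets combine into the
  any-stage union and the all-stage intersection, plus a per-gene
  profile of passing stages.
* **Cluster identity.** With eight clusters, the T4/T5 split thresholds
  the type marker at the midpoint between the two groupwise means;
  within each type the a,b/c,d split uses the a,b marker (cross-checked
  against the c,d marker), and the b,c marker separates b from a and c
  from d. The midpoint rule is a reproducible stand-in for assignment
  by inspection; any marker whose groups overlap under it aborts with
  an error naming the marker.
* **Dynamics.** From per-stage marked-subtype sets a gene is
  `type_specific` (differential only between types, or subtype-patterned
  in one type only), `late_only` (subtype-differential exclusively at
  stages >= 60 h APF), `switching` (the marked set changes across
  stages), or `stable_subtype_specific` otherwise. A gene whose only
  differential stage is a single early stage is treated as stable by
  this precedence; the category `"none"` is returned when no signal
  exists at any stage.
* **TF code.** `tf_code` enforces mutual exclusivity of the Dac/Ab and
  Omb/Pros class flags. Decoding maps (ab, Grain-) to a, (ab, Grain+)
  to b, (cd, Grain+) to c, (cd, Grain-) to d; encoding is the exact
  inverse. Perturbations only set or clear the Grain flag, so
  overexpression maps {a,b,c,d} onto {b,c} and knockdown onto {a,d},
  and the two maps invert each other on their images. The Ab and Pros
  factors are folded into their class flags, as the class behaves as a
  unit in the code.
* **Grain score.** Per optic lobe and subtype: mean cell-body
  fluorescence of the subtype divided by the mean over the Lim1-negative
  (non-T4/T5) cell bodies of that lobe (at least 10 required). The
  score is invariant under global intensity rescaling.

## The synthetic-data generator

The generator defines the study conditions under which the pipeline is
validated; its defaults are fixed once and all of them are plain
`sim_config` arguments.

* **Branch directions** are von Mises draws (Best--Fisher sampler)
  around per-subtype angles, default a = 0, b = 180, c = 90, d = 270
  degrees. The absolute angles are not printed in the source material —
  only the four-directions structure with opposite (a,b) and (c,d)
  pairs matters, and the config validates exactly that structure.
  Concentration defaults to kappa = 3, enough that a 200-branch circular
  mean recovers the generating angle within 10 degrees in >= 99% of
  seeds; kappa = 0 produces orientation-free arbors for chance-level
  controls.
* **Arbor size** follows a piecewise profile over stages (fractions of
  maximum cable length 0.15, 0.30, 0.55, 0.80, 1.00, 0.75 for 24, 36,
  48, 60, 72 h APF and adult): monotone growth from 36 to 72 h and
  pruning into adulthood, matching the qualitative developmental curve;
  the values are configurable because only their shape is constrained.
* **Axon positions** are normal draws around layer centers 0.2, 0.4,
  0.6, 0.8 on the normalized axis. The default spread is
  `layer_sd = 0.02`: the published axon-position clusters show no
  overlap across more than 200 neurons, which at a 0.2 center spacing
  implies roughly five-sigma separation; 0.02 reproduces that
  cleanly-separated regime. The clustering-recovery checks in the test
  suite additionally exercise sigma = 0.03 as test-local noise.
* **Clones.** Neurons come in neuroblast clones of exactly four
  (2 T4 + 2 T5) sharing a retinotopic position, with unperturbed
  subtype multisets {a,a,b,b} or {c,c,d,d}. Perturbations act on each
  neuron's TF code *before* morphogenesis with probability
  `conversion_penetrance` (default 1), so dendrites and axons convert
  together — the identity-conversion model. A `retarget_only` flag in
  `run_perturbation_experiment` simulates the rejected alternative
  (axons move, dendrites do not) as a negative control; under it the
  dendrite-axon agreement collapses while layer occupancy still shifts.
  Complete penetrance is a modeling choice: the in-vivo knockdown data
  (13 neurons, 12 clearly converted) cannot distinguish 100% from
  slightly lower penetrance, hence the parameter.
* **Counts** are negative binomial per gene per cluster (mean/size
  parameterization; size `nb_dispersion = 2`, a typical droplet-data
  overdispersion; the generative model is our choice since none is
  published). About two dozen genes suffice: one T4/T5 type marker, two
  a,b and two c,d class markers, three b,c markers, one single-subtype
  gene, one late-only gene (differential only at stages >= 60), one
  switching gene (marks a,b at 36 h, c,d from 48 h — and nothing at
  24 h, so it never enters the all-stage intersection), eight
  housekeeping genes, three mitochondrial-like and two heat-shock-like
  genes, and one rare gene detected in two cells to exercise the gene
  filter. Marker on/off means default to 25 and 0.2, housekeeping to
  40, placing ordinary cells near 500 total counts. A configurable
  fraction of cells (default 5%) is generated to fail QC by
  construction: depth scaled to ~150 counts, or mitochondrial-like /
  heat-shock-like means inflated past the 10% fraction.
* **Cell bodies.** Per optic lobe, 15 Lim1-positive cell bodies per
  subtype (about 60, matching the scale of the original measurement)
  and 12 Lim1-negative background bodies; subtypes b,c draw intensities
  enriched threefold (configurable) over the shared background, with
  Gaussian noise.
* **Determinism.** One global integer seed; every sub-generator derives
  its child seed from it by a fixed affine map below 2^31, so identical
  configurations reproduce byte-identical populations, images, count
  matrices and reports (timestamps aside).

What the generator does **not** emulate: optics and point-spread
functions, 3D image stacks (images are 2D, mirroring analysis of
maximal projections), realistic transcriptome breadth, doublets and
ambient RNA, batch structure, and any true developmental dynamics of
layer formation. Passing tests therefore demonstrate the correctness
and internal consistency of the *procedures* under the stated
statistical structure, not their robustness to every artifact of real
imaging or sequencing data.

## The in-silico experiments

`run_wildtype_experiment` simulates an unperturbed population, computes
every neuron's orientation histogram and relative axon position,
derives layer boundaries by clustering an *independent* control
population (same configuration, derived seed), builds per-subtype
reference orientations from that control, and reports both subtype
calls, their agreement, clone compositions, and the stage-wise volume
profile. Using an independent control for references — rather than the
classified population itself — keeps the chance-level control honest:
with self-referencing, a kappa = 0 population classifies above chance
because each neuron is contained in its own reference average;
with leave-one-out references it lands below chance for the symmetric
reason.

`run_perturbation_experiment` applies `perturb_code` to every ground
truth code before morphology generation and runs the identical
classification against the control references.
`run_expression_experiment` chains generation, QC, normalization,
identity assignment, per-stage DEG filtering over all 28 cluster pairs,
stage-consistency sets, dynamics categories and the Grain score, and
reports how completely the configured program was recovered.

Problem sizes used throughout the shipped tests and the acceptance
script: populations of 8--768 neurons (16 per subtype per type per
stage at most), 200 branches per neuron, 30 cells per cluster across
five stages (1200 cells, 24 genes), four optic lobes of ~72 cell
bodies — sizes chosen to match the scale of the original datasets
(226 reconstructed neurons, thousands of cells) closely enough that
every statistical check is meaningful while the whole suite runs in
well under ten minutes on one CPU.

## Known limitations

* The first-branch-point detector assumes compartment labels are
  trustworthy; it does not infer dendrite/axon identity from geometry.
* Pixel-based orientation histograms saturate in densely covered
  directions (a pixel is counted once however many branches cross it),
  so they are flatter than branch-angle histograms of the same neuron;
  both inputs are supported and the tests exercise both.
* `assign_cluster_identity` requires exactly eight clusters and a
  separable marker program; it reports failure rather than guessing.
* The DEG filter is the published threshold rule; it is deliberately
  not a significance test and reports no p-values.
* Absolute dendrite volumes are in arbitrary cable-volume units unless
  the skeleton metadata carries physical units; only normalized
  profiles are compared across stages.
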