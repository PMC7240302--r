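# t4t5id

Quantitative subtype identification of *Drosophila* T4/T5 neurons from
morphology and gene expression.

T4 and T5 are the first direction-selective neurons of the fly visual
system. Each comes in four subtypes (a–d) defined by two coupled
properties: the preferred orientation of the dendritic arbor (four
directions ~90° apart) and the lobula-plate layer (1–4) innervated by
the axon. Developmentally, subtype identity is written in a minimal
combinatorial transcription-factor code — a Dac/Ab class (subtypes
a,b), a mutually exclusive Omb/Pros class (c,d), and Grain (b,c) — and
changing the Grain bit converts identities within the (a,b) and (c,d)
pairs, moving dendrite orientation and axon layer together.

`t4t5id` implements the analysis pipeline behind these statements as
reusable, tested R functions, together with a synthetic-data generator
that emulates the study's imaging and single-cell inputs with known
ground truth, so the whole pipeline runs end to end with no external
data.

## What it computes

* **Dendrite orientation** — polar histograms of the vectors from the
  dendrite's first branching point to every suprathreshold pixel
  (12 bins of 30°, masses normalized to the vector count, `h_k ≥ 0`,
  `Σ_k h_k = 1`), from images, point sets or SWC skeletons
  (`orientation_histogram`, `first_branch_point`,
  `rasterize_dendrite`).
* **Similarity index** — `S(h1, h2) = Σ_k |h1_k − h2_k|` between
  normalized histograms (0 = identical orientation, max 2), with
  matrices of query × reference indexes and nearest-reference subtype
  calls (`similarity_index`, `similarity_matrix`,
  `classify_by_dendrite`).
* **Axon position** — the normalized anteroposterior position
  `p = (x − posterior) / (anterior − posterior) ∈ [0, 1]` of the axon
  reference point in the lobula plate, deterministic 1D k-means layer
  clustering, and the layer→subtype call (`relative_axon_position`,
  `cluster_axon_positions`, `classify_subtype_from_axon`).
* **Expression rules** — QC (cells < 200 counts, > 10% mitochondrial-
  or heat-shock-like counts; genes detected in < 3 cells), depth
  normalization, the threshold DEG filter (detection fraction ≥ 0.5,
  detection difference ≥ 0.5, fold change ≥ 2), any-/all-stage DEG
  sets, marker-based cluster identity, and expression-dynamics
  categories (`qc_filter`, `pairwise_deg`, `stage_consistent_degs`,
  `assign_cluster_identity`, `categorize_dynamics`).
* **The TF code** — encode/decode between subtypes and
  (Dac/Ab, Omb/Pros, Grain) triples, Grain gain/loss perturbation maps
  (gain: {a,b,c,d}→{b,c}; loss: {a,b,c,d}→{a,d}), and the cell-body
  Grain enrichment score (`tf_code`, `decode_tf_code`, `perturb_code`,
  `grain_score`).
* **In-silico experiments** — wild-type, Grain-overexpression and
  Grain-knockdown populations simulated, classified and reported end
  to end (`run_wildtype_experiment`, `run_perturbation_experiment`,
  `run_expression_experiment`), plus a thin CLI (`exec/t4t5id`) with
  subcommands `simulate`, `orient`, `similarity`, `axon-classify`,
  `decode`, `deg`, `perturb`, `report`.

The methods vignette (`vignettes/t4t5-subtype-identity.Rmd`) documents
every convention, default and design choice, and what the synthetic
data does and does not emulate.

## Worked example

```r
library(t4t5id)

cfg <- sim_config(n_neurons_per_subtype = 4,
                  stages = c("36", "72", "adult"), seed = 42)
wt <- run_wildtype_experiment(cfg)
wt
#> t4t5_report — wild type
#>   96 neurons, 24 clones
#>   axon-call accuracy:      1.000
#>   dendrite-call accuracy:  1.000
#>   dendrite-axon agreement: 1.000
#>   layer occupancy: 1: 0.25  2: 0.25  3: 0.25  4: 0.25
#>   homogeneous clones:      0.000
wt$volume_profile
#>   stage mean_volume normalized
#> 1    36    119.3203  0.3031942
#> 2    72    393.5442  1.0000000
#> 3 adult    295.8325  0.7517135
```

Every neuron's subtype is recovered from both its dendrite orientation
and its axon position, the two calls agree, the four layers are equally
occupied, and no wild-type clone is homogeneous (clones contain two
subtypes). Dendrite volume triples between 36 and 72 h APF and is
pruned by about a quarter into adulthood.

Grain overexpression converts subtypes a,d into b,c before
morphogenesis, so all axons land in layers 2 and 3 and every clone
becomes homogeneous:

```r
ov <- run_perturbation_experiment(sim_config(n_neurons_per_subtype = 4,
                                             stages = "adult", seed = 42),
                                  "overexpression")
ov
#> t4t5_report — grain overexpression
#>   32 neurons, 8 clones
#>   axon-call accuracy:      1.000
#>   dendrite-call accuracy:  1.000
#>   dendrite-axon agreement: 1.000
#>   layer occupancy: 1: 0.00  2: 0.50  3: 0.50  4: 0.00
#>   homogeneous clones:      1.000

decode_tf_code(perturb_code(encode_subtype("a"), "overexpression"))
#> [1] "b"
```

On the expression side, the pipeline recovers the configured marker
program from simulated counts:

```r
er <- run_expression_experiment(sim_config(seed = 42))
er
#> t4t5_expression_report
#>   cells: 1200 simulated, 1161 after QC (24 genes)
#>   cluster identity accuracy: 1.000
#>   DEGs: 11 at any stage, 9 at all stages (stable markers recovered)
#>   Grain score by subtype: a=1.00  b=3.00  c=3.00  d=1.02
```

All eight clusters per stage map onto their true (type, subtype)
identities, the all-stage DEG intersection is exactly the nine stable
marker genes (the late-only and switching genes pass only at some
stages), and the Grain cell-body score is ~3 in subtypes b,c versus ~1
in a,d, matching the configured threefold enrichment.

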