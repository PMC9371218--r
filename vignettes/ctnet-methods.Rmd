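---
title: "Detecting CT motion artifacts with complex networks: models and choices"
author: "ctnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting CT motion artifacts with complex networks: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the approach

Patient movement during a head CT acquisition leaves shading, streaking and
ghosting in the reconstructed slice. Such motion artifacts can obscure or
mimic pathology, so flagging degraded slices automatically — with high
*sensitivity*, since a missed artifact slice is the costly error — is a
practical image-quality task.

`ctnet` treats the task as a network-classification problem. Each slice is
mapped to a **pixel-level graph**: vertices are pixels, and an undirected,
unweighted edge joins pixels `i` and `j` exactly when

* their spatial distance is at most a radius `r` (inclusive), and
* their grey-level difference satisfies `|I_i − I_j| ≤ t` on the 0–255 scale.

The whole dataset additionally forms a **slice-level graph**: vertices are
slices, with an edge whenever two slices share both their anatomical region
label and their quality label. Classical topological statistics of these
graphs — average degree `2|E|/|V|`, the local clustering coefficient
`C_i = 2·T_i / (k_i(k_i−1))` (`T_i` = edges among the `k_i` neighbours of
`i`), its average, the degree distribution `P(k)` and the average shortest
path length — summarize each slice far more compactly than the raw pixels.
The detector concatenates the pixel-graph statistics with six physical
intensity statistics and feeds them to a standard classifier (RBF-kernel
SVM or a 1000-tree random forest).

The mechanism that makes the topological features informative is simple:
a clean CT slice carries appreciable high-frequency quantum noise, so
neighbouring pixels often differ by more than `t` and many candidate edges
are rejected. Motion smears the reconstruction — equivalent to averaging
displaced copies of the slice — which *suppresses* that noise, shrinks local
grey differences, and therefore **increases** both the average degree and the
average clustering coefficient of the pixel graph. Denser graph, worse slice.

## The pixel-graph edge rule

Two gates define an edge, and both are deliberate choices:

* **Radius gate.** `dist(i, j) ≤ r`, inclusive, with `r = 3` as default and
  Euclidean distance on integer (row, col) coordinates (Chebyshev is
  available via `graph_params(metric = "chebyshev")`). At `r = 3` every
  interior pixel has exactly 28 candidate neighbours.
* **Grey-difference gate.** `|I_i − I_j| ≤ t`, with `t = 10` by default on
  the 0–255 scale. The gate is conjunctive with the radius gate on purpose:
  with a radius-only rule every same-sized image would produce the identical
  graph and the topology could not distinguish image content at all. `t` is
  a first-class knob of `graph_params()`; intensities are quantized to
  integer 0–255 at generation/IO time precisely so this gate operates on a
  fixed scale.
* **Vertex set.** By default *every* pixel is a vertex, including air.
  Because air pixels are numerous and mutually similar they compress class
  contrast somewhat; `foreground_min` optionally masks near-zero background
  when that matters.

## Topology conventions

* **Average degree** uses the handshake form `2|E|/|V|`. A "number of edges
  over number of vertices" variant (without the factor 2) disagrees with
  every printed reference value we could check it against, and the handshake
  form is the standard convention, so the package uses it throughout.
* **Clustering.** `C_i := 0` when `k_i ≤ 1` (the formula is 0/0 there), and
  the average runs over *all* vertices including those zeros;
  `average_clustering(g, include_low_degree = FALSE)` switches to the
  neighbour-bearing subset. Per-vertex values are computed from per-vertex
  triangle counts; an exhaustive neighbour-pair scan serves as the test
  oracle.
* **Average path length** is the mean over unordered *connected* vertex
  pairs; disconnected pairs are excluded rather than treated as infinite.
  This convention is forced by the slice-level graph, which is provably a
  disjoint union of cliques (plus isolated slices) and would otherwise have
  no finite path length at all. On an edgeless graph the quantity is
  undefined and is reported as `NA` by `topo_summary()`.

The slice-level edge relation ("same region *and* same label") is an
equivalence on the non-isolated slices, so each connected component is a
clique; every vertex in a component of size ≥ 3 has `C_i = 1` exactly. That
is why realistic datasets produce slice-graph average clustering values very
near 1 — the statistic mostly reflects how many (region, label) groups have
at least three members.

**Leakage.** Slice-graph edges are defined by the very label the classifier
must predict. The pipeline therefore builds slice-level graphs from
*training* records only and uses them as a consistency diagnostic (artifact
class denser than clean class), never as a test-time feature. Likewise the
feature standardization (z-scores) is fit on training rows only.

## The synthetic phantom generator

The study conditions the package targets are a balanced 600-slice dataset
(300 with motion artifacts, 300 without) of 128 × 128 head CT slices drawn
from a handful of anatomical regions. Clinical CT collections of that kind
are rarely shareable, so `ctnet` ships a generator that emulates those
conditions end to end and is itself first-class, tested code.

* **Anatomy.** `generate_phantom()` composes ellipses: a bright skull
  annulus (≈225), a mid-grey brain with a gentle craniocaudal gradient
  (≈115 ± 18), two darker ventricles (≈60), air ≈0. The ellipse geometry is
  a fixed function of the region label, plus small seeded jitter (≤ ±0.015
  in normalized units), so same-region slices resemble each other more than
  cross-region slices — the property that makes region labels meaningful.
* **Noise.** Tissue receives Gaussian noise with sd 10 grey levels —
  comparable, after 8-bit windowing, to the quantum mottle of a routine head
  CT — and air a faint sd 1.2. The noise scale matters: it sets how many
  grey-difference gates fail in a *clean* slice, which is the headroom the
  artifact model consumes.
* **Artifacts.** `apply_motion_artifact()` works in the image domain:
  (a) *ghosting* — the slice is blended (weight `0.65·severity`) with the
  average of four copies displaced by small rigid motions (≤ ~3.5 px, ≤ ~2°),
  which both duplicates edges and suppresses high-frequency noise;
  (b) two to four narrow *streaks* through the object (amplitude
  `20·severity`); (c) a smooth low-frequency *shading* field (amplitude
  `12·severity`). A sinogram-domain model (corrupting projections before
  filtered back-projection) would be more physical but requires acquisition
  parameters the task does not otherwise need; the image-domain model
  reproduces the relevant phenomenology behind the same interface.
* **Severity** is drawn per corrupted slice from Uniform(0.4, 1.0): strong
  enough to be visible at 128 × 128, wide enough that mild cases approach
  the clean class instead of making the problem trivial.
* **Region composition.** Clean slices cycle round-robin through the
  regions. Artifact slices cycle through a *weighted* pattern (region `g`
  gets weight `K − g + 1`, e.g. proportions 3:2:1 for three regions). This
  mirrors clinical collections, in which motion-degraded slices cluster
  unevenly across scan levels, and it is what makes the artifact-class
  slice-level graph denser (larger average degree) than the clean-class one
  — with equal per-class region counts the two slice graphs would be
  statistically identical by construction.

What the generator does **not** model: reconstruction physics (no sinogram,
no beam hardening, no dose-dependent noise texture), anatomical variability
beyond ellipse jitter, pathology, or 3D context. Tests passing on this
synthetic data therefore demonstrate that the pipeline's machinery is
correct and that the topological mechanism behaves as designed; they do not
certify clinical performance, for which the package would need to be run on
real labeled slices (PNG/TIFF input plus a manifest CSV is all it takes).

## Classifiers and evaluation

* SVM: RBF kernel, `cost = 1`, `gamma = 1/p` on the standardized features —
  the conventional defaults when no tuning protocol is specified. RF: 1000
  trees, seeded. Both consume the identical feature table.
* Split: stratified 80:20 by quality label, `round(ratio · n)` training
  slices per class, seeded and reproducible.
* Metrics: accuracy `(TP+TN)/N`, sensitivity `TP/(TP+FN)`, specificity
  `TN/(FP+TN)` with the artifact class positive; AUC as the normalized
  Mann–Whitney rank statistic of the continuous scores (SVM margin, RF vote
  fraction), with midranks for ties.

## Numerical choices and degenerate inputs

* Intensities are clipped then rounded to integers 0–255 at every
  image-producing step; PNG round-trips are exact.
* Constant images: sd, skewness, kurtosis and entropy are reported as 0 (the
  moment ratios are 0/0 and a one-bin histogram carries no information).
* A 1 × 1 image yields the zero topological feature vector.
* Empty graphs: average degree/clustering error on 0 vertices; the average
  path length of an edgeless graph is undefined (`NA` in summaries).
* All stochastic steps (phantom jitter and noise, artifact draws, severity,
  splits, RF training) take explicit seeds, derive per-item sub-seeds below
  2^31, and restore the caller's RNG state.

## Problem sizes used by the shipped experiments

The packaged tests and the reproduction script run the full 600-slice,
128 × 128 study analog (feature extraction over ~16k-vertex pixel graphs
with ~10^5 edges per slice) and, for the direction checks, ten independent
200-slice datasets. These sizes keep a complete run in the minutes range on
a single core while leaving the class-direction effects far from marginal.

## Known limitations

* The physical feature set (mean, sd, skewness, kurtosis, histogram entropy,
  mean gradient magnitude) is one reasonable instantiation of "intensity
  statistics"; it is configurable simply by supplying your own feature
  table to `run_madm_cn(features = ...)`.
* The pixel-graph average path length is exposed but off by default in
  feature extraction: exact all-pairs BFS on 16k vertices is an order of
  magnitude costlier than the other statistics.
* Region labels are taken as given (clinically they are annotated manually);
  the package does not infer them.
* Synthetic results transfer to clinical data only to the extent the noise
  and artifact phenomenology transfer; the generator's parameters are
  defaults to be overridden, not truths.
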