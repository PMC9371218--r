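# ctnet — complex-network motion-artifact detection for head CT slices

Patient movement during a head CT acquisition produces shading, streaking
and ghosting in the reconstructed slices. Motion artifacts can obscure or
mimic pathology, so radiology workflows want degraded slices flagged
automatically — and with high **sensitivity**, because the costly error is
an artifact slice that slips through. `ctnet` implements an interpretable,
graph-based detector for this task, aimed at researchers working on CT
image-quality assessment who want an alternative to opaque CNN baselines
that also runs happily on small labeled datasets.

## The method

Each slice becomes a **pixel-level network** `G = (V, E)`: vertices are
pixels, and an undirected, unweighted edge joins pixels *i*, *j* exactly
when both gates pass,

```
dist(i, j) ≤ r        (spatial radius, default r = 3, Euclidean)
|I_i − I_j| ≤ t       (grey-level difference, default t = 10 on 0–255)
```

The dataset additionally forms a **slice-level network**: slices are
vertices, joined when they share both anatomical region and quality label
(a disjoint union of cliques, used as a training-time consistency
diagnostic). Each slice is summarized by topological statistics of its
pixel graph —

* average degree `⟨k⟩ = 2|E| / |V|`,
* average clustering coefficient, `C_i = 2·T_i / (k_i (k_i − 1))` with
  `T_i` the edges among the `k_i` neighbours of `i`,
* edge count `|E|` (and optionally the average shortest-path length) —

concatenated with six physical intensity statistics (mean, sd, skewness,
kurtosis, histogram entropy, mean gradient magnitude), and classified with
an RBF-kernel SVM or a 1000-tree random forest. Motion smearing suppresses
high-frequency noise, so corrupted slices pass the grey-difference gate more
often: their pixel graphs are *denser* (larger `⟨k⟩` and clustering), which
is the interpretable signal behind the classifier. Evaluation reports
accuracy, sensitivity `TP/(TP+FN)`, specificity `TN/(FP+TN)` and the
rank-statistic AUC, with the artifact class positive.

Because clinical CT datasets with labeled artifacts are rarely shareable,
the package includes a first-class synthetic generator: ellipse-based head
phantoms in several region geometries, half of them corrupted by an
image-domain motion model (ghost blending, directional streaks,
low-frequency shading). Real data enters the same pipeline as PNG/TIFF
slices plus a manifest CSV (`slice_id,region_label,quality_label,image_path`).

## Worked example

```r
library(ctnet)

dir <- file.path(tempdir(), "demo")
man <- generate_dataset(30, 30, n_regions = 3, size = 128, seed = 3,
                        out_dir = dir)
rep <- run_madm_cn(man, "svm_rbf", seed = 5)
print(rep)
```

```
MADM-CN run: svm_rbf, r = 3, t = 10, split 48/12, seed 5
  class-consistency (artifact denser than clean): ok
Artifact detection evaluation (positive = artifact)
  TP 6  FP 0  FN 0  TN 6
  accuracy:    100.00%
  sensitivity: 100.00%
  specificity: 100.00%
  AUC:         1.0000
```

Reading the output: of the 60 generated slices, 48 trained the model and 12
were held out; all 6 held-out artifact slices were flagged (sensitivity
100%) with no false alarms. The consistency line confirms the topological
mechanism on the training set: the artifact class has the denser pixel
graphs (larger mean average degree *and* clustering), so the features the
classifier relies on point the expected way. On the full 600-slice default
dataset the same pipeline is near-ceiling as well; the separation comes
mostly from `topo_avg_degree` and `topo_avg_clustering`.

Individual stages are exposed too:

```r
img <- generate_phantom(1, size = 128, seed = 7)
bad <- apply_motion_artifact(img, severity = 0.8, seed = 7)
g   <- build_pixel_graph(bad, graph_params(radius = 3, grey_threshold = 10))
topo_summary(g, path_length = FALSE)
physical_features(bad)
```

A command-line interface wrapping the same functions ships in
`inst/cli/ctnet.R`:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "ctnet.R", package = "ctnet"))')
Rscript "$CLI" simulate --n-clean 30 --n-artifact 30 --regions 3 \
    --size 128 --seed 3 --out demo
Rscript "$CLI" run --manifest demo/manifest.csv --classifier svm \
    --seed 5 --report report.json
```

## Scope notes

Deep-learning baselines, sinogram-level reconstruction physics, DICOM
parsing and automatic region labeling are out of scope. The methods
vignette (`vignettes/ctnet-methods.Rmd`) documents the model conventions,
generator design and numerical choices in detail.
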