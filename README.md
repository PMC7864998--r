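# trex

Post-hoc explainability for semantic segmentation models trained on
**ambiguous multi-grader ground truth**.

When several experts annotate the same medical images, they disagree — not
because some are wrong, but because the true boundaries are genuinely
ambiguous. A model trained on such labels inherits that ambiguity, and its
"accuracy" against any single grader is an incomplete story. `trex`
implements the T-REX (Traceable Relevance Explainability) procedure: it
treats the model as one more grader and quantifies, visualizes, and tests
where the model sits inside the ensemble of its human teachers. The
motivating application is retinal OCT B-scan segmentation into four
compartments (vitreous, retina, choroid, sclera) delimited by three
annotated boundary lines (ILM, CCi, CSI), but the machinery applies to any
small panel of pixel-wise label maps on a common grid.

## What it computes

For gradings $a, b$ of the same scan, the **Hamming distance**

$$d_H(a,b) \;=\; \frac{1}{HW}\,\#\{(r,c) : a_{rc} \neq b_{rc}\}
\;=\; 1 - \text{pixel accuracy}$$

is a true metric on label maps. It is evaluated across all compartments at
once and per compartment (binary membership maps, same $HW$ denominator, so
the four per-compartment distances sum to twice the overall one). From the
per-scan distance table the package derives:

* **Mean distance matrices** per scope, the heatmap-table view of grading
  variability (reported in percent);
* **Metric MDS embeddings** (Torgerson classical scaling refined by
  SMACOF-style stress majorization) placing graders and model in the plane
  so that point distances reproduce mean Hamming distances;
* the **neural recording**: the pairs-by-scans heatmap of per-scan
  distances, which exposes scan-level structure that means hide;
* **unpaired Monte-Carlo permutation tests** on the difference of means
  between all pooled inter-grader distances (group A) and all grader-model
  distances (group B), with an exhaustive small-sample oracle;
* a bundled **synthetic multi-grader generator** — layered scenes with
  controllable per-grader boundary bias and smooth noise, plus a consensus
  model — used as the package's fully controlled testbed, and the standard
  mirror/rotate training-set augmentation.

## Worked example

```r
library(trex)

cfg <- scene_config(n_scans = 40, seed = 42)   # 512x512 scenes, 3 graders + model
fit <- trex(simulate_study(cfg), n_resamples = 9999, seed = 42)
fit
```

```
T-REX analysis: 40 scans, graders g1, g2, g3, model cnn
Mean overall Hamming distance (%):
      g1   g2   g3  cnn
g1  0.00 2.19 3.29 1.54
g2  2.19 0.00 1.63 0.68
g3  3.29 1.63 0.00 1.91
cnn 1.54 0.68 1.91 0.00
Pooled means (overall): inter-grader 2.37%, grader-model 1.37%
Model mean distance smaller than inter-grader mean on 100.0% of scans
Permutation p (two-sided) by scope: all=0.0002 vitreous=0.0002 retina=0.0002 choroid=0.0002 sclera=0.0002
```

Reading it: graders disagree on about 2.4% of pixels on average (mostly at
the choroid–sclera interface, where the synthetic graders carry systematic
biases), while the consensus model sits closer to every grader than the
graders sit to each other — scan by scan, not just on average — and the
permutation p-values are at the floor attainable with 9,999 resamples
(`2/(B+1) = 2e-4`). `plot(fit)` draws the MDS map (graders as black
triangles, model as a red dot), `plot(fit, "recording")` the per-scan
heatmap, and `write_trex_report(fit, "out/")` writes every figure together
with value-identical CSV/JSON twins.

A thin CLI over the same functions lives at `inst/cli/trex.R`
(`simulate`, `distances`, `report`, `permtest` subcommands; see its header).

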