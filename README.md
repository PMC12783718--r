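# cladescan

Explainable image classification and outline morphometrics for **cryptic
clade divergence**: are genetically defined clades that look identical to
the human eye nevertheless morphologically distinct — and if so, where?

The package is written for evolutionary biologists working with
standardized specimen photographs (the motivating system is intertidal
limpets with Northern/Southern phylogeographic clades, including
keyhole-bearing fissurellids). It implements the full analysis chain:

1. **Seeded resampling classification.** Per iteration, specimens are split
   into training / validation / a class-balanced *Even-test* / the
   remaining *Full-test* pool (with a cap on specimens per sampling
   location, surplus routed to the test pool), a small convolutional
   classifier is trained from scratch, and performance is scored as
   macro-F1, `F1 = 2PR/(P+R)` averaged over classes.
2. **Mixed-group randomized-label control.** Clade labels are replaced by
   two synthetic classes containing equal numbers of true-Northern and
   true-Southern specimens; real signal is thereby removed and the control
   should score at chance (~0.5). A clade-based model is only trusted in so
   far as it beats its control.
3. **SmoothGrad saliency.** Absolute input gradients of the class logit,
   averaged over noise-perturbed copies of the image, show where the model
   looks; `region_fraction()` turns maps into an *attention enrichment*
   number (saliency share of a region ÷ its area share).
4. **Mask-based shape descriptors.** Sub-pixel contours normalized to
   major-axis length 1.0; circularity `4πA/P²`, eccentricity
   `√(a²−b²)/a`, solidity `A/A_hull`, extent `A/A_bbox` (object-aligned),
   and minor-axis length `b/a`, compared between clades with Mann–Whitney
   U tests.
5. **Karcher-mean outlines.** Per-clade average shapes by iterative
   alignment (FFT-based roll + rotation) and point-wise averaging, six
   landmarks at the 25/50/75% height levels, and the derived clade
   contrasts (percent minor-axis narrowing; quartile-over-central width
   ratio).

Because real photograph collections and large pretrained backbones are
beyond the scope of a self-contained package, `cladescan` ships a
**synthetic shell-image generator** with plantable clade effects of known
size — keyhole narrowing and central pinch, ridge irregularity, intensity
bands, overlapping size distributions — so that every pipeline stage is
validated by parameter recovery. See the methods vignette
(`vignettes/cladescan-methods.Rmd`) for the generative model and all design
choices.

## Worked example

Generate a small keyhole-bearing dataset, train one clade-based classifier
and one mixed-group control, and compare:

```r
library(cladescan)

cfg  <- generator_config("keyhole_like", n_per_clade = 200, image_size = 64,
                         seed = 101)
recs <- generate_dataset(cfg, "my_dataset")
imgs <- load_images(recs)

proto <- protocol_config(n_train_per_class = 60, n_val_per_class = 15,
                         n_even_test_per_class = 20, n_iterations = 1,
                         base_seed = 500)
mcfg  <- model_config(input_size = 64, seed = 1)

split <- make_split(recs, proto, iteration_id = 1)
model <- train_classifier(split, imgs, mcfg, aug = proto$augmentation)
evaluate_f1(model, imgs, split$even_test_ids, split$label_map)$macro_f1
#> [1] 1

mixed  <- make_mixed_groups(recs, seed = 42)
msplit <- make_split(mixed, proto, 1, label_col = "mixed_class")
mmodel <- train_classifier(msplit, imgs, mcfg, aug = proto$augmentation)
evaluate_f1(mmodel, imgs, msplit$even_test_ids, msplit$label_map)$macro_f1
#> [1] 0.4444444
```

The clade-based model separates the clades perfectly while the control sits
at chance: the classifier is using genuine clade structure, not memorized
noise. Where is it looking?

```r
kmasks <- load_images(recs, "keyhole_mask_path")
en <- attention_enrichment(model,
        recs[recs$specimen_id %in% split$even_test_ids, ], imgs, kmasks,
        seed = 7)
mean(en$enrichment); mean(en$area_fraction)
#> [1] 5.16794
#> [1] 0.0453186
```

Saliency mass inside the keyhole is ~5× its area share — the model's
attention is concentrated on the planted discriminative structure, which
occupies under 5% of the image. Finally, the morphometric confirmation on
the high-resolution dataset:

```r
shape <- generate_dataset(generator_config("keyhole_like", n_per_clade = 200,
                                           image_size = 128, seed = 103),
                          "my_dataset_128")
kc <- karcher_contrast(shape, region = "keyhole")
kc$contrast
#> $pct_minor_axis_narrower
#> [1] 11.50471
#>
#> $quartile_over_central_ratio_N
#> [1] 1.407572
#>
#> $quartile_over_central_ratio_S
#> [1] 0.8659054
```

The pipeline recovers the planted contrasts: the Northern Karcher-mean
keyhole is ~12% narrower along the fitted minor axis, and its
quartile-to-central width ratio is ~1.41 against the elliptical 0.866 of
the Southern form (planted values: 12.0% and 1.425).

## The analysis workflow

Numbered drivers under `analysis/` reproduce the full study on synthetic
data, writing tables to `results/` (datasets and figures go to `scratch/`):

| script | what it does |
|---|---|
| `01_simulate.R` | generates the four study datasets (strong/weak preset × 64/128 px) |
| `02_classify.R` | 20-iteration classification runs: clade-based, mixed control, weak preset |
| `03_saliency.R` | SmoothGrad attention enrichment for clade vs control models |
| `04_shapes.R` | keyhole shape metrics and per-metric clade comparisons |
| `05_karcher.R` | Karcher means, landmarks, clade contrasts, per-location means |
| `06_keyhole_crop.R` | keyhole-crop re-classification experiment |

Run them in order from the repository root, e.g.
`Rscript analysis/01_simulate.R`.

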