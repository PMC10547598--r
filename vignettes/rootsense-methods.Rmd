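---
title: "rootsense: methods, assumptions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{rootsense: methods, assumptions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rootsense)
```

## The problem

Sweetpotato breeding programmes screen boiled-root sensory attributes with
trained panels. Two of the attributes that drive consumer acceptance are
scored on 0–10 scales: **flesh-colour intensity**, anchored at
0 = white, 1 = cream, 3 = yellow, 5 = yellow-orange, 8 = orange and
10 = deep orange, and **mealiness by hand**, the ease with which the boiled
flesh crumbles into fine particles when rubbed (0 = not mealy, 10 =
extremely mealy). Panel scoring is slow (tens of minutes per sample per
panelist), which caps throughput at exactly the stage of a breeding cycle
where hundreds of genotypes need screening.

`rootsense` implements an image-based surrogate: photographs of boiled root
cross-sections on a calibrated imaging board are reduced to colour and
texture features, and regression models map those features onto the panel
scales. A third, unbounded target — the positive peak force of a
wedge-fracture texture test, a firmness proxy — shares the texture feature
pipeline.

## Pipeline stages

1. **Detection.** Root regions are located with a deterministic,
   training-free detector: the Euclidean RGB distance of every pixel from
   the border-estimated background colour is thresholded with Otsu's
   method, the binary map is cleaned by morphological opening and closing,
   and connected components become detections. Confidence is a component's
   mean contrast normalized by the image's largest component contrast. The
   published system used a fine-tuned one-stage convolutional detector;
   reproducing that would require its annotated photographs and pretrained
   weights, neither of which is distributable here, so the package ships
   the classical detector behind the same contract plus an import path for
   externally produced detections (`read_annotations()` with a confidence
   column). The evaluation side — `iou()` and `evaluate_map()` with greedy
   one-to-one matching and all-point interpolated AP — is implemented
   faithfully so *any* detector can be scored.
2. **Segmentation.** Inside each detected box, pixels are clustered with
   K-means (`k = 2`, Lloyd iterations from k-means++ starts, `n_init`
   restarts, best inertia kept). The cluster holding the majority of the
   box's border pixels is declared background — inside any correct box the
   background surrounds the root — with exact ties broken toward the
   lower-saturation centroid. Per-box root masks are unioned and every
   non-root pixel is set to black.
3. **Colour features.** All masked pixels of an image are pooled (the
   panel scores one sample per image) into mean RGB, mean HSV (hexcone,
   hue in degrees), mean CIELAB (sRGB linearisation, D65 illuminant —
   matching the 6500 K capture lights), per-channel histograms and
   K-means dominant colours. The default model feature row is the nine
   colour-space means (`colour-v1` schema); histograms and dominant
   colours are available for exploration.
4. **Texture features.** Graininess — the visual surrogate for mealiness —
   is quantified inside the 2-px-eroded mask interior: Canny edge density,
   8-connected edge-component count, mean gradient magnitude of the
   smoothed luminance, and mean 5×5 local variance. Background pixels are
   replaced by the mean masked luminance before filtering, which makes all
   four statistics invariant to image content outside the mask and keeps
   the root outline from counting as grain.
5. **Modelling.** Regression families: linear, k-nearest-neighbours,
   CART, RBF ε-SVR, random forest, gradient boosting and a dense neural
   network; classification (tree families) targets the anchor class codes.
   Defaults mirror the published training setups (e.g. the 100-estimator
   forest for flesh-colour; the depth-8, 20-estimator forest and the
   5-layer network with Adam, learning rate 1e-4 and early stopping for
   mealiness). Metrics are MAE, MSE, R² and macro-averaged one-vs-rest
   precision/recall/F1, with per-variety error analysis ranked by absolute
   error.

## The synthetic world

No image or panel dataset is deposited with the source study ("available
on request"), so verification rests on a generator whose ground truth is
exact by construction:

* Roots are smooth convex blobs — ellipses with a low-frequency radial
  perturbation `1 + Σ aₖ cos(kθ + φₖ)`, k ∈ {2,3,4}, amplitudes ≤ 0.05 —
  filled with `round(colour_score_to_rgb(score))`. The analytic blob area
  `πab(1 + Σaₖ²/2)` is carried in the ground truth so mask conservation is
  testable.
* Mealiness is encoded by speckle grain through two affine maps:
  `density(m) = 0.004·m` speckles px⁻² and `contrast(m) = 6·m` intensity
  levels. The slopes are a package convention chosen once: at `m = 10` a
  typical root carries a dense, high-contrast grain, and at `m = 0` the
  root is perfectly smooth. Bright and dark speckles are balanced so the
  mask-mean colour stays score-faithful for mealy roots. The source study
  gives no quantitative mealiness-to-texture link; this encoding is a test
  harness for parameter recovery, not a biological claim.
* The background is near-black (the post-segmentation convention), pixel
  noise is i.i.d. Gaussian (default sd 5 intensity levels, a plausible
  sensor-noise scale for 8-bit captures), and scenes are bit-reproducible
  for a fixed seed.

What a green synthetic test does establish: the implementation of every
stage is internally correct, monotone where it must be, and able to
recover known scores well above the field's 0.80 R² comparability
threshold. What it does not establish: performance on real boiled roots,
whose illumination, specularity, fibre structure and inter-variety
variation the generator does not model. The published real-data numbers
(flesh-colour R² 0.92, mealiness R² 0.85, detector mAP 0.995) are
therefore *not* claimed by this package.

## Numerical choices and edge cases

* **Boxes** are 0-based half-open `(x_min, y_min, x_max, y_max)`, so areas
  are plain products and IoU needs no ±1 arithmetic. Annotation files are
  normalized centre format, written at 6 decimals (lossless for any
  realistic image size).
* **K-means** restarts default to 5 (50 in the oracle-equivalence test);
  degenerate input (fewer distinct pixels than k) is an error at the API,
  and `segment_image()` skips such boxes with a warning rather than
  failing a whole image. `assemble_colour_features()` reduces the
  dominant-colour k when a root has fewer distinct colours.
* **Canny**: non-maximum suppression quantizes the gradient direction to
  four bins and uses a strict comparison against the forward neighbour so
  an exact plateau yields a single 1-px edge; hysteresis keeps weak edges
  only when 8-connected to a strong edge; erosion treats out-of-bounds as
  background. Fixed thresholds are exposed as `edge_params()` because they
  are the fragile part of edge-based graininess — which is also why the
  default model feature row uses the three smooth statistics and reports
  the raw component count without feeding it to models.
* **Early stopping** halts when the best validation MAE has not improved
  by strictly more than 0.005 for 100 consecutive epochs (so a constant
  validation curve stops at epoch 101), or at 5000 epochs.
* **Ties** resolve conservatively toward the paler class: exact midpoints
  in `nearest_scale_class()` and mode ties in `label_policy()` both return
  the lower code.
* **Splits** are seeded, unstratified, floor-allocated with the remainder
  to the last part; 152 items at (0.60, 0.25, 0.15) give the published
  91/38/23 counts.
* Predictions are clipped to [0, 10] for the two panel attributes and left
  unclipped for positive force.

## Design decisions that were genuinely open

* The anchor palette is not defined colorimetrically anywhere; the default
  is a plausible boiled-flesh progression whose green channel decreases
  strictly from white to deep orange. Only ordering matters to the tests,
  and the palette is a `colour_scale()` argument.
* Between-anchor interpolation is linear in RGB — the simplest monotone
  map over an ordinal scale.
* The published random-forest parameter list reads "max_features = 1"
  among otherwise-default values; it is interpreted as the library default
  of *all* features (fraction 1.0), not a single feature per split.
* The neural network's layer widths are unstated beyond "five layers
  (3 hidden)"; the default is input→64→32→16→1 with rectified-linear
  activations, configurable. Inputs are standardized internally (stored
  with the model) so the published learning rate is usable on 0–255
  features.
* Classification averaging is macro, with per-class values always
  reported so weighted averages can be recomputed.
* The embedding interface replaces pretrained-CNN feature extraction: the
  default provider is an offline handcrafted block (9 colour means, 3
  texture statistics, 16-bin grey histogram; length 28), and adapters for
  real backbones can be registered at run time. No network access is ever
  required.
* Config files are YAML rather than TOML: the target environment ships a
  YAML parser and no TOML parser, and the contract (single declarative
  key-value document, flags override file values) is unchanged.

## Known limitations

* The classical detector assumes the capture regime (roots brighter and
  more saturated than a dark uniform board); it is not a general object
  detector, and label cards or bright debris will be detected unless boxes
  are supplied externally.
* Texture features assume the grain is resolvable at capture resolution;
  heavy JPEG compression would blur speckle contrast.
* The minimal TIFF codec reads/writes uncompressed 8-bit grey/RGB only.
* Model artefacts are R serializations with a metadata header; they are
  run-time outputs, not exchange formats.
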