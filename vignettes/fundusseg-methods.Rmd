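---
title: "Methods: multi-class optic nerve head segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-class optic nerve head segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fundusseg)
```

## The problem

A color fundus photograph of the optic nerve head contains a nested set of
anatomical structures whose geometry carries diagnostic weight: the optic
disc, the optic cup inside it (their ratio — the cup-to-disc ratio, CDR — is
a standard glaucoma indicator; values above roughly 0.3 raise suspicion),
the retinal vessels crossing the disc, and, in atrophic eyes, the
peripapillary atrophy (PPA) annuli — the beta zone hugging the disc boundary
and the alpha zone outside it. `fundusseg` implements a complete toolkit for
segmenting all six classes (background, disc, cup, vessels, PPA beta, PPA
alpha) from such images: preprocessing, three network architectures, a
multi-label Dice objective with an analytic gradient, a disc-centered polar
transformation, patch-based training/prediction protocols, evaluation
metrics, mask codecs, and a synthetic phantom generator so that every stage
is testable without clinical data.

## Networks

Three architectures are provided, all built on a compact computational-graph
engine written for this package (forward and reverse passes with
RcppArmadillo kernels, Adam optimization, seeded Glorot-uniform
initialization — the convolutional default of the major deep-learning
frameworks, chosen for its stable early training):

* **Custom U-Net** (`build_custom_unet()`): four down-sampling blocks
  (Conv–Dropout–Conv, 3×3 kernels, filters 8→64, 2×2 max pooling between
  blocks), a 128-filter centre block, four up-sampling blocks (2×2 stride-2
  transposed convolution, skip concatenation, Conv–Dropout–Conv, filters
  64→8) and a final 1×1 softmax convolution over six classes. All
  convolutions use size-preserving padding, so a 512×512×3 input yields a
  512×512×6 probability map with 485,862 parameters.
  `layer_table()` emits the per-layer outline and
  `verify_against_reference()` checks it against the packaged printed
  reference (`reference_layer_table()`). Two rows of that reference are
  typographical defects — a second down-sampling-1 convolution printed with
  284 parameters where the shape formula `k_h·k_w·C_in·F + F` gives 584 (and
  the identical layer elsewhere is printed as 584), and the centre transposed
  convolution's output size printed without the stride-2 doubling — so
  verification tolerates exactly those two rows; the parameter counts
  themselves are still enforced.
* **MSU-Net** (`build_msu_net()`): the multi-scale, multi-label variant for
  joint disc/cup work. A mean-pooled image pyramid is concatenated before
  each matching encoder block, and the head is a 1×1 convolution with an
  independent sigmoid per class (K = 2), so a pixel may be disc and cup at
  once — the natural encoding of nested anatomy.
* **BU-Net** (`build_bu_net()`): deep supervision on top of any of the above.
  Each of M auxiliary 1×1 sigmoid heads on the decoder stages produces a
  K-channel map up-sampled to the input resolution; training fuses the
  per-head multi-label Dice losses with weights a_m (default M = 4, a_m =
  0.25 — four heads pair naturally with the 0.25 weight so the fusion weights
  sum to one) and adds the final-layer loss.

A small backbone registry (`build_backbone_unet()`; `tiny_resnet` with
residual stages, `tiny_vgg` with plain double-convolution stages) supports
encoder swapping. Weights are always randomly initialized: no pretrained
weights ship with the package, and `pretrained = TRUE` is an error rather
than a silent download.

## The multi-label Dice objective

For probabilities $p_{k,i} \in [0,1]$ and binary targets
$g_{k,i} \in \{0,1\}$ over $K$ classes and $N$ pixels,

$$L_s = 1 - \sum_k^K 2 w_k \frac{\sum_i p_{k,i} g_{k,i}}
  {\sum_i p_{k,i}^2 + \sum_i g_{k,i}^2 + \varepsilon},\qquad \sum_k w_k = 1.$$

With $K=1$, $w=1$ this is the classic soft-Dice loss; the disc/cup
configuration uses $w_k = 0.5$. The analytic gradient implemented in
`multilabel_dice_grad()` is, per class,

$$\frac{\partial L_s}{\partial p_{k,i}} = 2 w_k\left[
  \frac{-g_{k,i}}{D_k} + \frac{2\,p_{k,i} \sum_i p g}{D_k^2}\right],
  \qquad D_k = \sum_i p^2 + \sum_i g^2 + \varepsilon.$$

Only class $k$'s terms appear — the cross-class sum sometimes written in
front of this expression is vacuous, as the finite-difference oracle in the
test suite confirms. $\varepsilon$ (default $10^{-7}$) keeps empty classes
finite; with $\varepsilon = 0$ an empty-vs-empty class is a hard error.
Empty-over-empty IoU and Dice are defined as 1 throughout the metrics, which
keeps the macro mean IoU meaningful when a class is absent. Reported "IoU"
is micro-averaged (pooled intersections over pooled unions) while "mean IoU"
is the unweighted macro mean over all K classes — the only reading under
which IoU ≥ mean IoU, as observed in practice.

## Polar transformation

`to_polar()` resamples an image about the disc center into an
(angle × radius) raster: row *b* samples angle
$\theta_b = \mathrm{rot} + 2\pi b / B$ (default $B = 400$ angular bins,
rotation −90° so the first bin points up) and column *s* radius
$r_s = r_\mathrm{max}\, s/(S-1)$. Radial sample count is not dictated by the
method; the default of 400 gives a square polar raster. Coordinates are
(u, v) = (column, row), 0-based, pixel-center sampling — fixed so tests are
bit-stable. The transform makes the nested disc/cup a layered structure,
equalizes the cup-to-background pixel ratio through interpolation, and turns
Cartesian rotation into a cyclic row shift (a cheap augmentation; the test
suite checks this equivariance analytically). `from_polar()` inverts the
resampling with angular wrap-around; a binary disk survives the 400-bin
round trip with Jaccard ≥ 0.98 inside the sampled radius. Both full-frame
and cropped-ROI use are supported simply by the choice of center and radius.
When no disc-center annotation exists, `detect_disc_center()` falls back to
the brightness centroid of the thresholded brightest pixels — the disc is
the brightest structure in a fundus image.

## Preprocessing and ground-truth composition

`contour_threshold()` marks pixels strictly above mean + k·SD (population
standard deviation; k typically 1–3). `fill_polygon()` rasterizes expert
contours with the even–odd rule on pixel centers (chosen for determinism),
`alpha_composite()` blends extracted structures (scalar or per-pixel alpha),
`rgba_to_rgb()` flattens transparency, and `resize_raster()` resamples by
pixel-center alignment (order 0 is mandatory for class masks, so ids are
never invented). `compose_ground_truth()` merges per-structure binary masks
into one six-class mask with the fixed precedence cup > vessels > disc >
beta > alpha > background: the cup lies inside the disc, vessels cross the
disc, beta abuts the disc and alpha lies outside beta, so an earlier class
never loses pixels to a later one. `split_dataset()` shuffles uniformly
under a stated seed (default 42, 80:20) without stratification.

## Mask codecs

Masks travel as single-channel PNG (raw ids, byte-exact) or as run-length
encoded text: row-major, 0-based starts, one `"start length class"` line per
maximal run under a `"H W"` header — the simplest exactly invertible
dialect, a repository convention since no byte layout is prescribed by the
method. The display legend maps ids to the standard web colors of the named
scheme (yellow alpha, yellow-green beta, medium-sea-green cup, dark-blue
disc, dark-cyan vessels, black background); `color_to_labels()` inverts it
by nearest color within an explicit tolerance and refuses unmappable pixels
loudly.

## Synthetic phantoms

`generate_phantom()` draws a seeded, byte-reproducible scene with the
anatomical structure the method assumes: elliptical disc (semi-axis 12–17 %
of the image side), cup scaled by a CDR drawn from 0.2–0.7 with
center jitter bounded so the cup stays strictly inside the disc, 3–6
random-walk vessels emanating from the disc, beta and alpha annuli
(3.5–5 % widths) hugging the disc, a circular field-of-view aperture,
radial illumination falloff (amplitude 0.25) and Gaussian noise (σ = 6 on
the 0–255 scale). Class colors are distinct but noise and shading overlap
them, so the segmentation task is learnable yet non-trivial. The phantom is
a structural fixture, not a pathology simulator: it has none of the texture,
vessel branching statistics, or lesion variability of clinical photographs,
so metrics obtained on phantoms say the pipeline is correct, not that it
matches clinical-grade accuracy. Geometry defaults scale with image size;
at 64×64 the vessels are about one pixel wide — faithful to what
down-sampling clinical imagery to that size produces, and deliberately hard.

## Training protocols

`train_config()` encodes the reference protocol: Adam, learning rate 1e-4,
batch size 1, categorical cross-entropy for the six-class model (the
multi-label Dice objective for MSU/BU variants), seed 42, no shuffling
within epochs, 5-fold cross-validation via `kfold_cv()`. The patch protocol
(`patch_config()`) extracts 48×48 patches at random offsets (9500 per image,
90/10 train/validation split, regions outside the field of view included)
and predicts by overlap averaging with stride 5; final windows clamp to the
border and per-pixel averages divide by the exact cover count, which keeps
border pixels unbiased. Argmax ties break to the lowest class id.
Post-processing of thresholded probability maps (largest connected
component, hole filling — via EBImage) is optional and on by default in
`segment_disc_cup()`, which also clips the cup to the disc.

## Desk-scale behaviour and known limitations

The test suite trains the custom topology at 64×64 on 40 phantoms for 30
epochs (about 90 s per seed on one CPU; sizes were chosen so the whole suite
stays interactive). Under that protocol, held-out pixel accuracy is
typically 0.89–0.94 and macro mean IoU 0.35–0.54 across seeds, still
improving at the epoch budget (the same run reaches mean IoU ≈ 0.58 by
epoch 100). The shortfall concentrates in the one-pixel vessels — almost
unlearnable in 1200 optimization steps — and in late-emerging small classes
under the unweighted cross-entropy objective, which starves rare classes
early. These are properties of the protocol at desk scale, not defects of
the gradient machinery: the analytic gradients match finite differences to
3×10⁻⁶ everywhere. Other limitations: batch size is fixed at 1 in practice
(the reference protocol's setting); there is no GPU path; JPEG output is
refused for masks by design; and the backbone registry is intentionally
small, providing the interface rather than a model zoo.
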