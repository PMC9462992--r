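---
title: "Automatic measurement of the angle of progression: models, losses and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automatic measurement of the angle of progression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aopmeter)
```

## The measurement problem

During the second stage of labor, fetal head (FH) descent is monitored on
transperineal ultrasound by the *angle of progression* (AoP): the angle
between the long axis of the pubic symphysis (PS) and the line from the
inferior (right) PS endpoint tangent to the fetal skull contour. Clinical
anchors place the zero station near 116°, with larger angles indicating
deeper descent. The angle is only defined on a *standard plane* — a view
that contains both the PS and the FH.

`aopmeter` implements the full automatic pipeline: (1) standard-plane
recognition, (2) PS/FH segmentation, (3) PS-endpoint localization by
Gaussian-heatmap regression, and (4) ellipse-fit/tangent geometry that turns
those outputs into the angle. Because clinical images cannot ship with a
package, a synthetic phantom generator with *analytically known* ground
truth for every task makes each stage testable at desk scale.

## The multitask network

One shared convolutional encoder feeds three task decoders:

* **Encoder** — five blocks of two 3×3 convolution + batch-norm + ReLU
  layers; blocks 1–4 end in 2×2 max-pooling followed by an efficient
  channel-attention (ECA) unit, so the bottleneck sits at 1/16 resolution.
  Five blocks with four downsampling stages is the only topology consistent
  with decoders that use four upsampling blocks and restore full
  resolution; the fifth block is the bottleneck.
* **Task 1 (classification)** — two residual blocks on the bottleneck,
  global average pooling, a fully connected layer and a softmax over
  {nonstandard, standard}.
* **Task 2 (segmentation)** — four upsampling blocks with U-Net skip
  connections from the encoder, a 1×1 convolution and a per-pixel softmax
  over {background, PS, FH}.
* **Task 3 (endpoint heatmaps)** — four upsampling blocks ending in a
  sigmoid over three heatmaps; at every level an attention-fusion module
  (AFM) gates the current segmentation-decoder features with a mask learned
  from the coarser-level shared and task-specific features and concatenates
  the gated features into the landmark branch.

The ECA unit pools each channel, runs a shared 1-D convolution of
adaptively chosen odd size \(k = |(\log_2 C + b)/\gamma|_{odd}\) (with
\(\gamma = 2\), \(b = 1\); truncate, then add one if even) across the
channel axis, and multiplies the channels by the resulting sigmoid weights.

Where the published description leaves the exact AFM tensor taps open, we
take the "shared" stream to be the Task-2 decoder: \(S_{i-1}\) and
\(L_{i-1}\) are the Task-2 and Task-3 features of the coarser level,
concatenated through a 1×1 convolution, then a 1×1 convolution +
batch-norm + sigmoid produces a single-channel mask that is upsampled and
applied multiplicatively to the current Task-2 features. A single-channel
(spatial) mask is the simplest reading of an "attention mask with intensity
in [0, 1]" and keeps the unit light. Upsampling is bilinear interpolation
followed by 3×3 convolution, chosen over transposed convolution to avoid
checkerboard artifacts; the reference description does not commit to
either.

### The autodiff core

No deep-learning runtime is part of the package's dependency set; the
network, its gradients and the Adam optimizer are implemented on a compact
reverse-mode tape (R closures over RcppArmadillo kernels for im2col
convolution, pooling and bilinear resampling). Every operator's analytic
gradient is validated against central finite differences in the test suite;
the residual mismatches observed there shrink with the step size, which
identifies them as truncation error of the difference quotient near
ReLU/max-pool kinks rather than bias.

## Losses

With \(y\) the ground truth and \(p\) the prediction:

* **Cross-entropy** (Task 1): \(-y\log\hat y-(1-y)\log(1-\hat y)\),
  predictions clamped at \(10^{-7}\).
* **Dice loss** (Task 2): \(1-2\sum yp/(\sum y+\sum p)\), pooled over the
  two foreground classes; background is excluded. Empty–empty is defined
  as 0.
* **Shape-constrained loss** (Task 2): for pixel pairs \((p,q)\) inside the
  ground-truth region and \(r\) on the rasterized segment between them,
  \(B\,(y_p-p_p)(y_q-p_q)(p_p+p_q-2p_r)\), where \(B=1\) when all three
  ground-truth labels belong to the class (we read the published indicator
  condition, which repeats \(y_{ip}\) twice, as the obvious
  \(y_{ip}=y_{iq}=y_{ir}=1\)). The term penalizes a depressed prediction
  between two confident endpoints — a concave notch — and so encodes the
  convex prior appropriate for the skull contour. It is applied to the FH
  class only by default (the elliptic shape condition is relaxed to
  convexity for the head), configurable to include the PS.
* **Heatmap MSE** (Task 3): \(\sum_k\delta_k\,\mathrm{mean}_{ij}
  (H_k-\hat H_k)^2\) with \(\delta=(1.0,0.8,0.6)\). The mean (rather than
  sum) over pixels makes the magnitude resolution-independent, which the
  published form leaves open.
* **Total** (stage 1):
  \(w_1(\theta_1 L_D+\theta_2 L_{SC})+(1-w_1)L_{MSE}\) with \(w_1=0.5\)
  and \(\theta_i=e^{-s_i}\) under the standard log-variance
  (homoscedastic-uncertainty) parameterization, each learnable \(s_i\)
  adding an \(s_i/2\) regularizer. With \(s_i\) frozen at 0 this reduces to
  the plain weighted sum.

### Monte-Carlo form of the shape loss

The exhaustive triple sum is \(O(N^2 L)\) in the number of foreground
pixels and segment length — infeasible at training resolution. We therefore
define the loss value as the mean over ordered foreground pairs of the mean
over the rasterized segment (lattice points at \(t = 0\ldots L\) steps,
\(L\) the Chebyshev distance, endpoints included), and estimate it by
drawing pairs uniformly and a lattice point uniformly on each segment. The
estimator is unbiased for exactly the exhaustive value, which the
acceptance suite verifies on 12×12 fixtures against an independent
brute-force triple loop and by a 3-standard-error check at \(10^5\)
triplets. Three heatmaps exist for two endpoints; the published weights
\(\delta_1>\delta_2>\delta_3\) are assigned right endpoint, left endpoint,
PS-axis midpoint — the right endpoint is the AoP vertex and hence the most
important landmark, and the midpoint map stabilizes the axis.

As printed, individual triplet terms are signed: a *raised* prediction
between two under-confident endpoints produces a negative term. Used
directly as a training objective this is exploitable — the optimizer drives
the loss negative by distorting the probability field, and in controlled
A/B runs on phantoms the segmentation Dice collapses rather than improves.
The **training** form of the loss therefore keeps only the
concavity-violating terms (\(c = p_p+p_q-2p_r > 0\)), a pure penalty that
is zero for convex predictions, which is the shape-prior intent. The
*measurement* form (`shape_constrained_loss()`), its exhaustive mode and
the brute-force oracle in the tests retain the signed formula exactly as
printed, so the hand-computed example values agree to machine precision.
At the optimum both forms are zero.

## Two-stage training

Stage 1 trains the encoder and the Task-2/Task-3 decoders on
standard-plane images only (nonstandard planes carry no segmentation or
endpoint labels), with Adam at \(lr_0=10^{-4}\), a step scheduler (×0.1
every 20 epochs), batch size 2, Kaiming-initialized convolutions, random
rotation in (−30°, 30°) and random isotropic scaling in (0.9, 1.1) — the
scaling range is unstated in the reference and 10% is a conventional
choice. Kaiming initialization covers the convolution weights; the bias of
the sigmoid heatmap head is initialized to −2 so the predicted maps start
near the background prior (~0.12) rather than 0.5 — heatmap targets are
overwhelmingly background, and a zero-initialized head spends a large part
of a short training budget merely suppressing it. Stage 2 loads the shared
encoder from the stage-1 checkpoint and
trains the classification head with cross-entropy on both strata. The
encoder is **frozen by default** in stage 2: fine-tuning it would silently
degrade the already-trained segmentation and landmark branches, and the
reference is ambiguous on this point; a flag exposes the alternative. With
a frozen encoder no augmentation is applied in stage 2, and the bottleneck
features are precomputed once per image. Model selection uses the
validation total loss (stage 1) and validation accuracy (stage 2); no
selection rule is published. A non-finite loss aborts with a diagnostic;
gradient clipping is off by default.

## Geometry

The FH contour is the ordered outer boundary of the largest connected
component of the predicted FH class. The ellipse is fitted by the direct
least-squares conic method with the ellipse-specific constraint
\(4AC-B^2=1\), solved in the numerically stable block form on centered
coordinates, so the fit always returns an ellipse. Because boundary pixel
*centers* sit about half a pixel inside the true region edge, a first fit
supplies the outward conic-gradient direction along which each boundary
point is pushed 0.5 px before the final fit; this removes a systematic
~1° underestimate of the tangent angle at phantom scale.

Tangents from the right PS endpoint are constructed through the polar line
(chord of contact) of the point with respect to the conic — exact,
branch-free, and certifiable: substituting the candidate line into the
conic must give a vanishing discriminant, which the tests assert at
\(10^{-6}\) on 1000 random fixtures. Of the two tangency points the one
giving the **larger** angle at the right endpoint is kept (the tangent
along the leading, distal head contour); the appendix that specifies the
published selection rule is not available, so the rule is a documented
package decision with a `"min-angle"` override, with ties broken toward
larger *y*. The AoP is the angle at the right endpoint between the ray to
the left endpoint and the ray to the tangent point, reported in (0°, 180°].
All geometry runs in original-image coordinates (predictions are mapped
back through the recorded resize scaling), making the angle
resolution-independent; it is invariant under rigid motions and uniform
scaling by construction, which the suite checks to \(10^{-9}\) degrees
analytically and to 0.5° under mask rasterization.

## The phantom generator

Each standard-plane phantom draws a PS capsule (rotated rectangle with
semicircular caps; its axis endpoints are the landmarks) and an FH ellipse
placed beyond a clearance gap from the right endpoint, such that the
analytic AoP — computed from the *drawn* shapes by the same tangent
geometry, before any rasterization — falls in a clinically plausible range
(75–165°; the zero-station anchor is ~116°). Ranges scale with image size;
at the 96 × 96 desk scale the FH semi-major axis spans 19–27 px and the PS
axis 23–33 px. Rejection sampling discards draws whose shapes overlap,
leave the frame, or put the right endpoint inside the ellipse; exhausting
the budget signals an incompatible specification.

Speckle is modeled multiplicatively, \(I' = I(1 + s\,g)\) with \(g\)
standard normal and \(s = 0.25\) by default, clipped to [0, 255] — strong
enough to defeat trivial thresholding while leaving the structures visible,
which is the role speckle plays here; the reference gives no image
statistics, so contrast levels (background 30, PS 230, FH 200) are free
parameters of the phantom. Nonstandard planes drop the FH, drop the PS,
truncate the FH at the frame edge, or contain noise only.

What the phantom does **not** emulate: acoustic shadowing, attenuation,
refraction artifacts, speckle correlation, soft-tissue texture, probe
variation, or anatomical variability beyond affine shape ranges. Passing
the end-to-end tests therefore demonstrates that the pipeline recovers
known geometry through segmentation and landmark regression under
multiplicative noise — not clinical-grade performance.

## Problem sizes and numerical choices

The end-to-end recovery test and the acceptance script run 96 × 96
phantoms with `base_channels = 8`, 260 images of 26 synthetic patients
split patient-wise 160/40/60, 25 stage-1 epochs and 15 stage-2 epochs —
small enough for a laptop CPU, large enough that classification accuracy,
FH Dice and the AoP error are meaningfully constrained (the suite requires
accuracy ≥ 0.90, mean FH Dice ≥ 0.85 and mean |ΔAoP| ≤ 10°). Heatmap
σ is 6 px at network resolution (unstated in the reference;
configurable). Batch-norm uses ε = 10⁻⁵ and momentum 0.1 with batch
statistics in training and running statistics at inference. Heatmap argmax
ties break in row-major order (first by *y*, then *x*). The network input
size default (384, 416) reads the clinical "416 × 384" as width × height;
both are divisible by 16 so either reading works, and the convention is
recorded in the configuration.

## Known limitations

* The tape-based network is CPU-bound and double-precision; clinical-scale
  training (base 64, 416 × 384, 200 epochs) is expressible but slow.
* The AFM tensor taps and the Task-1 ResBlock widths follow the documented
  package decisions above; other readings of the schematic are possible.
* Bland–Altman limits use the sample (n−1) standard deviation, the
  clinical convention; segmentation accuracy is reported as per-pixel
  accuracy over all classes.
* The phantom's simplifications listed above bound what desk-scale results
  say about clinical data.
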