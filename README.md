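# aopmeter

Fully automatic measurement of the fetal **angle of progression (AoP)**
from transperineal-ultrasound-like images.

During the second stage of labor, fetal head (FH) descent is monitored on
transperineal ultrasound via the AoP: the angle between the long axis of
the pubic symphysis (PS) and the line from the inferior PS endpoint tangent
to the fetal skull contour (zero station ≈ 116°). Measuring it by hand
requires selecting a *standard plane* (a view containing both PS and FH)
and identifying three key points — a skilled, error-prone task. `aopmeter`
automates the whole chain for researchers working on intrapartum ultrasound
image analysis:

1. **Standard-plane recognition, PS/FH segmentation and PS-endpoint
   localization** by one multitask encoder–decoder network: a shared
   five-block convolutional encoder with efficient channel attention (ECA;
   1-D channel convolution of adaptive odd size
   \(k=|(\log_2 C+b)/\gamma|_{odd}\), γ=2, b=1), a residual classification
   head, a U-Net segmentation decoder, and a Gaussian-heatmap landmark
   decoder coupled to the segmentation stream by attention-fusion (AFM)
   gates. Training is two-stage (segmentation + landmarks first with an
   uncertainty-weighted total loss
   \(w_1(\theta_1 L_{Dice}+\theta_2 L_{shape})+(1-w_1)L_{MSE}\) including a
   convex shape prior on the skull; then the classifier on the frozen
   encoder with cross-entropy), with Adam, a step learning-rate schedule
   and rotation/scaling augmentation. The network, gradients and optimizer
   run on a compact reverse-mode autodiff tape over RcppArmadillo kernels —
   no deep-learning runtime required.
2. **Geometry**: direct least-squares ellipse fit (4AC−B²=1 constraint) of
   the FH contour, tangents from the right PS endpoint via the polar line
   of the conic, max-angle tangent selection, and the angle at the PS
   inferior endpoint.
3. **Evaluation**: accuracy/precision/sensitivity/specificity, per-class
   and pooled Dice, endpoint distances in mm, PS-axis angle (APT), |ΔAoP|,
   Pearson correlation and Bland–Altman limits of agreement (mean ± 1.96
   SD), with `tidy()`/`glance()`/`autoplot()` methods.
4. **Phantoms**: a seeded generator of ultrasound-like images (bright
   convex FH ellipse, PS capsule with known endpoints, multiplicative
   speckle, nonstandard-plane modes) whose AoP is known *analytically*, so
   every stage is testable without clinical data.

## A worked example

Measure the AoP on a phantom whose ground truth is known analytically:

```r
library(aopmeter)

spec <- phantom_spec(96, 96)          # desk-scale phantom specification
s <- generate_standard(spec, patient_id = "P001", seed = 42)
s
#> <phantom_sample> standard  patient=P001  seed=42  96x96  AoP=94.03 deg

res <- measure_aop(s$mask, s$left_endpoint, s$right_endpoint)
res
#> <aop_result> AoP = 94.25 deg  tangent=(50.25, 29.35)
abs(res$aop_deg - s$aop_true)
#> [1] 0.2186314
```

The geometry recovered the analytic angle to within a quarter of a degree;
the residual is rasterization error of the 96 × 96 mask. The full neural
pipeline is driven the same way:

```r
man <- generate_dataset(spec, n_standard = 130, n_nonstandard = 130,
                        n_patients = 26, seed = 1, out_dir = "dataset")
plan <- split_by_patient(man, ratios = c(16, 4, 6), seed = 1)   # 160/40/60
# ... train_stage1() / train_stage2(), then:
# predict_aop(model, image)        one image -> class, endpoints, AoP
# predict_manifest() |> evaluate_report()   full scored test-set report
```

A shell interface mirrors the pipeline stages
(`inst/cli/aopmeter.R phantom|train|measure|evaluate --config cfg.yaml`).

On the held-out test patients of that desk-scale run the evaluation report
prints classification accuracy, Dice scores, endpoint distances, APT,
mean |ΔAoP| and the Bland–Altman agreement of automatic versus reference
angles — see `vignettes/aop-measurement.Rmd` for what each quantity means
and the design decisions behind the models.

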