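---
title: "renoquant: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{renoquant: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

renoquant measures glomerular filtration rate (GFR) from quantitative
99mTc-DTPA kidney SPECT/CT. The chain has three scientific pieces: a 3D
convolutional network that segments the functioning renal parenchyma on the
CT of the hybrid scan, an activity-quantification step that turns the
parenchymal volume of interest (VOI) into percent injected dose (%ID) on
the attenuation- and scatter-corrected SPECT, and a calibrated linear
conversion from %ID to GFR. This vignette records the model, its
assumptions, the tunable parameters, and the design decisions taken where
the problem was genuinely open.

## The quantification model

99mTc-DTPA is filtered by the glomeruli and neither reabsorbed nor
secreted, so the parenchymal tracer content shortly after injection is
proportional to the filtration rate. With a quantitative SPECT volume
$A(\mathbf{x})$ in Bq/ml and a parenchyma VOI $V$,

$$\%\mathrm{ID} = 100 \cdot \frac{\sum_{\mathbf{x}\in V} A(\mathbf{x})\,v}{A_\mathrm{inj}},$$

with $v$ the voxel volume (ml) and $A_\mathrm{inj}$ the injected activity
(nominally 370 MBq). Per-kidney GFR follows the calibrated affine
conversion

$$\mathrm{GFR}\ (\mathrm{ml/min}) = \%\mathrm{ID} \times 9.1462 + 23.0653,$$

applied to each kidney individually, and the bilateral total is normalized
to body surface area by $\mathrm{total} = \sum \mathrm{GFR} \times 1.73 /
\mathrm{BSA}$ with the Dubois surface
$\mathrm{BSA} = 0.007184\, W^{0.425} H^{0.725}$ (W kg, H cm). The
calibration constants (slope, intercept, and the 152.5 cpm/µCi system
sensitivity that converts raw counts to activity) are scanner-chain
constants taken as given; `renoquant` reproduces them exactly and treats
them as non-tunable. Two unit pathways feed `compute_pid()`: direct
activity concentration (`Bq_per_ml`, the phantom default) and raw
`counts`, which pass through the system sensitivity with a 1-minute
default acquisition. No decay correction is applied: the 2–3 minutes
between injection and acquisition is below 0.6% of the 6.01 h 99mTc
half-life, far inside the other error sources.

## The segmentation network

The network is a modified 3D U-net. Both paths have five resolution
levels at full scale (three at desk scale). The contraction path uses
leaky-ReLU *pre-activation* residual blocks of 3×3×3 convolutions,
2×2×2 stride-2 convolutions for down-sampling, and an element-wise sum
junction that forwards the down-sampled map added to a further 3×3×3
convolution of itself. The expansion path mirrors it with 2×2×2
transposed convolutions, copy-and-concatenate skip connections from the
matching contraction level, and per level a 3×3×3 then a 1×1×1
convolution. Immediately before the sigmoid, the outputs of the last
three expansion-path convolutions are projected to one channel by 1×1×1
convolutions and summed. 3D spatial dropout (rate 0.3) — dropping whole
feature-map channels — regularizes training at batch size 1, in place of
batch normalization, which is ill-posed for single-volume batches.

Where the architecture description leaves freedom, the package fixes
these interpretations (all configurable in `segnet_config()`):

* **Channel widths** double per level from `base_channels` (32 full
  scale, 8 desk scale) — the standard U-net progression.
* **Leaky-ReLU slope** 0.01.
* **Dropout placement**: after each contraction-path residual block
  (including the bottom level), where adjacent-voxel correlation is
  strongest.
* **Three-way head sum**: interpreted as the final 3×3×3, 1×1×1 and an
  extra 3×3×3 head convolution, each projected to one channel before the
  sigmoid.
* **Ablation flags**: `use_residual_blocks = FALSE` collapses a block to
  a single pre-activated convolution; `use_elementwise_sum = FALSE`
  removes the sum junctions and the two extra head projections;
  `use_skip_connections = FALSE` removes the concatenations. Each strictly
  reduces the parameter count; the package asserts only that ordering,
  not any performance ordering, which is a data-scale question.

The training loss is the soft Dice
$1 - (2\sum p t + \varepsilon)/(\sum p + \sum t + \varepsilon)$ with
$\varepsilon = 1$ voxel (configurable): small enough to be negligible
against a kidney-sized overlap, large enough to keep empty-mask gradients
bounded. The optimizer is ADAM with $\beta_1 = 0.9$, $\beta_2 = 0.999$
and $\varepsilon_\mathrm{ADAM} = 0$; with a literal zero epsilon a
parameter whose second-moment estimate is exactly zero would divide 0/0,
so such entries receive the correct limiting update of zero. The initial
learning rate is 5e-4, halved when the *training* loss has not improved
by a relative 1e-4 for 10 consecutive epochs (which loss drives the
plateau is unstated in the source material; training loss is the choice
here because the desk-scale runs keep no validation split during
training). The full-scale schedule is 80 epochs × 272 iterations; the
desk-scale reference experiment uses 60 epochs × 20 iterations. The
desk preset also lowers the spatial dropout rate to 0.15: dropping whole
channels at 0.3 removes a third of an 8-channel feature map per layer,
which over-regularizes the narrow desk-scale network (the full-scale
default remains 0.3).

The engine is implemented from scratch in RcppArmadillo (single
precision). Feature maps carry a one-voxel zero halo so each 3×3×3
convolution is a sum of 27 accumulating GEMMs on contiguous
column-offset views (no shifted copies); stride-2 and transposed 2×2×2
convolutions gather/scatter between the padded lattices of adjacent
levels, and the backward pass uses hand-derived adjoints. The sigmoid
head starts from a negative bias so the initial foreground probability
sits near the prevalence rather than 0.5. Backpropagation is verified in the test
suite by a directional finite-difference check that converges to the
analytic derivative as the step shrinks. CT input is clamped to the [−100, 200] HU
soft-tissue window and scaled about 40 HU by 1/50 before entering the
network, so the few-HU parenchyma contrasts of non-contrast CT are
resolvable at the input.

Inference thresholds the sigmoid output at 0.5 (its midpoint), keeps at
most the two largest 26-connected components (at most two kidneys), and
assigns laterality from each component centroid's world-x coordinate
relative to the mid-sagittal plane. An all-background prediction is a
warning, not an error: single-kidney subjects legitimately produce fewer
components.

## Geometry and preprocessing

Volumes are axis-aligned RAS+ lattices with voxel-center world mapping
(`volume_grid`). The clinical-geometry pipeline resamples CT, SPECT and
VOIs to a common 256×256×232 grid at 1.726 mm and crops a 192×128×96
window for training. That common grid does not exactly tile the native CT
field of view, so resampling is centered on the shared volume center and
trims/pads symmetrically — this preserves kidney centering. The crop
window is likewise centered on the grid by default (overridable), since
nothing in the acquisition fixes where the window was placed. Masks are
resampled trilinearly and re-thresholded at 0.5 rather than
nearest-neighbour, matching the intent of the VOI smoothing step;
`smooth_mask()` (Gaussian at one voxel, closing radius 1 by default)
removes the slice-wise discontinuity of stacked 2D ROIs.

## What the phantom generator emulates

No clinical data ships with the package; the `phantom` module generates
paired CT-like and SPECT-like volumes with known ground truth.
Each subject has up to two bean-shaped kidneys (ellipsoid with a medial
pelvis compartment carved out by a second, tilted ellipsoid), posed and
sized from anatomical ranges (semi-axes around 20–28 × 22–30 × 42–55 mm,
lateral offsets 38–52 mm). The CT is a compartment-mean HU field (soft
tissue 40, parenchyma 35, cyst 10, tumor 30, urine 5, contrast pelvis
≥150, stone ≥300, air < −900) smoothed at 0.7 voxel to emulate
reconstruction texture, plus per-compartment Gaussian noise (±10 body,
±5 parenchyma, …). The deliberate weak contrasts — parenchyma vs soft
tissue 5 HU, tumor vs parenchyma 5 HU — encode the clinical difficulty
that parenchyma-isodense structures are nearly invisible on
non-contrast CT. Residual pelvis contrast appears in 22.6% of subjects
(the rate observed when contrast CT precedes the SPECT/CT), single-kidney
subjects at 1%, kidney donors at 28%, and stone patients carry ureter or
renal stones whose sizes drive the clinical grouping rule (ureter stone
any size or renal stone > 10 mm ⇒ symptomatic; small renal stone or
stone-free contralateral ⇒ asymptomatic; donor ⇒ normal).

The SPECT volume paints uniform parenchymal uptake per kidney at a
sampled true %ID (normal/asymptomatic 3.5–4.5%, symptomatic 2.2–3.2% —
centered on clinically typical per-kidney GFRs of roughly 60 and 50
ml/min through the affine conversion), blurs with a 12 mm FWHM Gaussian
point-spread surrogate for reconstructed SPECT resolution, and adds
Poisson count noise through the 152.5 cpm/µCi sensitivity. The activity
scale is calibrated per kidney *after* the blur so that integrating the
noise-free volume over that kidney's truth VOI returns exactly the
sampled %ID; this makes the generator's bookkeeping closed (recovery is
exact with noise off, sub-percent with noise on) while keeping a
realistic nonzero PSF. The ground-truth VOI excludes pelvis, cysts,
stones and tumors by construction.

`emulate_manual_voi()` reproduces how manual references are actually
drawn: 2D ROIs on every 2nd–3rd coronal slice (≤30 per kidney), optional
±1-voxel in-plane jitter, shape-based interpolation of per-slice signed
distance fields in between, then `smooth_mask()`. Because only drawn
slices honour lesion exclusions, a stone confined to undrawn slices is
wrongly included — the characteristic interpolation failure of manual
VOIs, reproduced as a constructed scenario in the test suite.

What the phantom does **not** emulate: real abdominal anatomy (no organs
other than a body ellipsoid and kidneys), projection-domain SPECT physics
(attenuation, scatter and collimator response are assumed already
corrected, as on the quantitative reconstruction), breathing or
registration error between CT and SPECT, and inter-expert variability of
manual drawing beyond slice sparsity and jitter. Passing desk-scale tests
therefore demonstrates that the pipeline's machinery is correct and that
the network can learn weak-contrast 3D segmentation — not that clinical
performance on patient data is guaranteed.

## The desk-scale reference experiment

The package's reference experiment (`run_e2e()`, also behind
`renoquant e2e` and the acceptance script) generates 25 phantoms on the
desk-scale grids (CT 64×64×48 at 3.452 mm, SPECT 48³), splits 20/5,
trains the 3-level/8-channel network on 48³ windows for 60 epochs of 20
single-volume ADAM steps (~12 minutes on one CPU core), then segments
the 5 held-out phantoms, quantifies GFR with predicted and ground-truth
VOIs, and reports mean Dice plus agreement statistics (OLS R², MAPE,
Bland–Altman bias with 1.96·SD limits). Held-out Dice well above 0.9 is
expected at this scale: phantom geometry is far easier than clinical CT,
which is precisely why the desk-scale bar can sit at the clinical-cohort
mean of 0.89 while remaining a meaningful end-to-end regression check.
The cohort sizes, window and schedule are the package's fixed reference
configuration, chosen once so the experiment completes comfortably on a
laptop-class CPU.

## Numerical choices and degenerate inputs

* Trilinear resampling uses a fill value outside the source field of view
  (0 for masks and activity, −1000 HU for CT) and clamps nothing inside.
* The Dice of two empty masks is defined as 1 (perfect agreement on
  absence).
* `%ID` above 100 — possible under count noise — is clamped to 100 with a
  warning rather than an error.
* An empty VOI side reports %ID 0 with a warning (single-kidney support).
* R² is the OLS coefficient of determination of automatic on manual GFR,
  identical to squared Pearson correlation for simple regression; both
  conventions therefore agree.
* Bland–Altman limits use the standard bias ± 1.96·SD of paired
  differences.
* Named hypothesis tests in the group report (paired t, Wilcoxon, ANOVA,
  Kruskal–Wallis) are delegated to `stats` and surfaced as report fields
  only; no test asserts their p-values beyond construction-driven
  ordering.
* The k-fold harness marks a failing fold, continues, and flags the
  failure, so one crashed training run does not void a cross-validation.

## Known limitations

The desk-scale network shares code with the full-scale configuration but
not its capacity; the 0.89 desk-scale Dice bar does not transfer claims
to clinical CT. Phantom HU statistics are plausible but not fit to any
patient distribution (no per-structure HU data exist to match), so
phantom realism is validated by property — exclusion rules, bookkeeping
closure, failure-mode reproduction — rather than by distribution
matching. Whether the common resampling grid should inherit the CT or
SPECT frame origin is exposed as a configuration choice rather than
decided; both volumes are assumed co-registered by the hybrid scanner,
and rigid or deformable registration is out of scope.
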