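---
title: "Score-based diffusion prediction of delivered radiotherapy dose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Score-based diffusion prediction of delivered radiotherapy dose}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(scoredose)
```

## The problem

Before a modulated radiotherapy plan (IMRT/VMAT) is delivered to a patient,
pre-treatment patient-specific quality assurance (prePSQA) verifies that the
dose the machine actually delivers agrees with the dose the treatment
planning system (TPS) computed. The measurement step — delivering the plan
to a detector system and reconstructing the delivered dose — is the
bottleneck. `scoredose` models the *conditional distribution* of the
measured dose (MDose) given the planned dose (RTDose, optionally plus CT)
and predicts the delivered dose (PDose) by sampling from that distribution,
so that a measurement-like dose map can be obtained from the plan alone.

Unlike a regression network that maps plan to measurement with a single
forward pass, the generative route learns the score (the gradient of the
log-density) of dose images at a continuum of noise levels and *generates*
the prediction by gradually denoising a pure-noise image while the plan is
held fixed as conditioning. In practice this yields smoother, better-matched
profiles than direct regression at the price of an iterative sampler.

## Model

### Forward and reverse SDE

Data are diffused by the Itô SDE \(dx = f(x,t)\,dt + g(t)\,dw\) on
\(t \in [0, 1]\). Two standard parameterizations are implemented behind one
schedule interface ([noise_schedule()]):

* **VE** (variance exploding): \(f = 0\), perturbation kernel
  \(x_t = x_0 + \sigma(t) z\) with geometric scales
  \(\sigma_i = \sigma_{\min}(\sigma_{\max}/\sigma_{\min})^{i/N}\);
* **VP** (variance preserving): \(f = -\tfrac12\beta(t)x\),
  \(g = \sqrt{\beta(t)}\) with linear \(\beta(t)\); unit-variance data keep
  total variance 1.

The package defaults to VE with \(\sigma_{\min} = 0.01\),
\(\sigma_{\max} = 0.6\), \(N = 1500\). The choice is deliberate: the
predictor update used at sampling time is the sigma-indexed
variance-exploding discretization
\(\hat x_i = x_{i+1} + (\sigma_{i+1}^2 - \sigma_i^2)\,s_\Theta
+ \sqrt{\sigma_{i+1}^2 - \sigma_i^2}\,z\),
and the "initial noise scale" knob (0.6 / 6e2 / 6e5) only has meaning on a
VE scale axis, even though the forward process is sometimes written in VP
form. Both schedules satisfy their closed-form perturbation kernels
([perturbation_kernel()]), which the test suite checks by Monte Carlo.

Time is discrete internally (\(N + 1\) scales, \(t = i/N\)): the sampler is
a discrete loop, and a discrete index keeps training and sampling on exactly
the same scales.

### Training: denoising score matching

The network \(s_\Theta(x, \sigma)\) is regressed onto the analytic score of
the Gaussian perturbation kernel centred on the clean image,
\(\nabla_{x_t}\log p_t(x_t|x_0) = -(x_t - m(t)x_0)/s(t)^2\), weighted by
\(\lambda(\sigma)\):

\[
\Theta^* = \arg\min_\Theta\;
E_i\, E_{x_0}\, E_{x_t|x_0}\,
\lambda(\sigma_i)\,\lVert s_\Theta(x_t, i) - \nabla_{x_t}\log p_i(x_t|x_0)\rVert_2^2 .
\]

\(\lambda(\sigma) = \sigma^2\) (the default; `lambda_weighting` in
[train_config()]) makes every scale contribute an order-1 term: the loss
becomes \(\lVert \sigma s_\Theta + z\rVert^2\) per pixel, so a perfect score
scores 0 and the zero function scores 1 at every scale. Internally the
network predicts the noise component \(\hat\varepsilon\) and the score is
\(-\hat\varepsilon/\sigma\); this is an exact reparameterization, not an
approximation, and keeps the regression target unit-scale across five
decades of \(\sigma\).

Only the target channel is ever perturbed. The conditioning channels
(RTDose, optionally CT) enter the network clean at every noise level, both
in training and sampling — that is what makes the model conditional.

### Sampling: predictor, corrector, data consistency

[sample_dose()] initializes the target channel as
\(N(0, \sigma_{\max}^2)\) noise and anneals down the schedule. Each outer
iteration applies the VE predictor above, then `M_corrector` annealed
Langevin refinements
\(\tilde x = \hat x + \epsilon s_\Theta + \sqrt{2\epsilon} z\). The Langevin
step size is never specified in the usual statement of the algorithm; the
package uses the signal-to-noise rule
\(\epsilon = 2 (r \lVert z\rVert / \lVert s_\Theta\rVert)^2\) with
\(r = 0.16\) (`snr_r`), which for a Gaussian target gives a stationary
variance inflated by only \(1/(1 - r^2) \approx 2.6\%\) — inside the 5%
band the stationarity test enforces. After every move the conditioning
channels are rewritten into the stack (data consistency,
[apply_data_consistency()]), so they are bit-identical to the input at every
iteration — an invariant the acceptance suite checks literally.

Two final touches, both toggleable in [sampler_config()]: a last-scale
denoising step \(x + \sigma_0^2 s_\Theta\) (removes the residual
\(\sigma_{\min}\) noise), and clipping to \([0, 1.2]\) of normalized dose
(dose is physically non-negative; a measured dose may mildly exceed the
planned maximum).

The outer iteration count equals the schedule's \(N\) by construction — a
deliberate config-level error otherwise — because the iteration count *is*
the discretization count of the reverse SDE.

### The score network

No deep-learning runtime is used: the package carries its own compact CPU
implementation of a time-conditioned U-Net — im2col + BLAS GEMM
convolutions with hand-derived backpropagation and an Adam optimizer. The
gradients are verified against finite differences on every parameter tensor
in the unit tests, which is a stronger correctness statement than most
framework ports can make.

Architecture (see [score_model_config()]): `depth` resolution levels
(downsampling by 2 between levels), one residual block per level on each
side with concatenated skip connections, a middle block, 3x3 kernels, SiLU
activations, and a sinusoidal embedding of \(\log\sigma\) passed through a
two-layer MLP and injected into every residual block as a per-channel bias.
The final convolution is zero-initialized so the model starts as the zero
score. Channel semantics are fixed by convention: channel 1 the noised
MDose, channel 2 RTDose, channel 3 (optional) CT or a duplicated RTDose
(the "three-channel, no CT" mode: when a third channel is wanted without a
CT, duplicating the planned dose is the neutral choice, and it is recorded
here as a convention rather than silently assumed).

Two fixed coordinate channels (meshgrid in \([-1,1]\)) are appended before
the first convolution (`use_coords`). Rationale: a plain CNN is
translation-equivariant, but one component of the delivery error the
synthetic cohort emulates — the calibration field — is fixed in space;
coordinate features let the network represent it. This is an architectural
design choice of this package, recorded here because nothing in the
standard score-network recipes decides it.

Default width is 128 feature maps (the 64-vs-128 comparison is exposed as
`base_width`), depth 4, multipliers (1, 2, 2, 4). The desk-scale experiment
below uses a smaller instance.

## The synthetic cohort

Clinical prePSQA data are not publicly available, so the package ships a
paired-phantom generator ([make_case()], [make_dataset()]) whose
planned-to-measured transform is *known*:

* **CT**: elliptical body (intensity 0.3) with `n_structures` internal
  ellipses of distinct intensity in 0.4–0.9;
* **RTDose**: a sum of anisotropic Gaussian kernels centred inside the
  body, zeroed outside it, normalized to max = 1 — the per-case
  normalization convention (all dose channels on the case's planned-dose
  maximum) that makes "%" metrics well-defined;
* **MDose** = `clip(calib * shift(blur(RTDose)) + noise, 0, Inf)` with
  defaults blur \(\sigma = 1.5\) px (detector resolution), shift
  \((0.5, 0.5)\) px (setup error), a \(\pm 5\%\) multiplicative calibration
  field of period 16 px (systematic output error, fixed across cases — a
  miscalibration, not case noise), and 1% additive measurement noise.

Site labels (H&N / chest / abdomen) are stratification tags drawn at the
clinical cohort's proportions (115 : 87 : 98 per 300 cases), so a 300-case
cohort split 4:1 reproduces the 240/60 partition exactly, stratified within
one case per site.

What the phantoms do *not* emulate: realistic beam/arc geometry, Monte
Carlo dose transport, detector-array sampling, CT noise/artefacts, or 3-D
volumes (slices are the unit of computation). Passing the end-to-end test
therefore demonstrates that the machinery — schedule, objective, network,
sampler, conditioning — correctly learns and inverts a known
planned-to-measured transform at realistic magnitudes; it does not
demonstrate clinical-grade accuracy on real VMAT plans.

## Evaluation

[dose_ssim()] is the Gaussian-weighted SSIM (11-pixel window,
\(\sigma = 1.5\), \(k_1 = 0.01\), \(k_2 = 0.03\), data range 1.0 — the
constants are recorded with every metrics report because the source
material leaves them unstated); windows are cropped so boundary handling
cannot leak into the mean, and the implementation agrees with the reference
scientific-python implementation to \(10^{-9}\) on frozen fixtures.
RMSE and MAE are reported in percent of the normalized dose scale. Metrics
default to the whole grid (matching full-image reporting, background
included); a body-mask variant is available by flag. [summarize_by_site()]
produces the quartile/IQR/outlier numbers a per-site box plot displays, and
[planned_vs_measured()] gives the no-model baseline any useful predictor
must beat.

## The desk-scale experiment

[run_synthetic_experiment()] is the package's reference experiment and the
basis of the acceptance checks; its defaults are the study conditions,
chosen once for a single-CPU desk run:

* 600 cases on 32x32 grids, split 4:1 (480/120), standard error model;
* VE schedule with \(N = 300\) scales on 0.01..0.6 (the sampler runs 300
  iterations — the shape of the 1000/1500/2000 iteration ablation at
  desk scale);
* network: base width 16, depth 2, 32-dimensional time embedding,
  coordinate channels on (~95k parameters);
* training: 16 epochs, batch 8, Adam at 1.5e-3, EMA decay 0.995 (an EMA
  horizon of ~200 steps against ~860 total steps; the returned weights are
  the EMA);
* sampling: 20 held-out test cases, predictor + 1 corrector,
  \(r = 0.16\), final denoise and clipping on.

The learning rate sits above the customary 2e-4 default because this network
is two orders of magnitude smaller than production score models and is
trained for ~860 steps, not hundreds of thousands; 2e-4 would leave it far
from converged on this budget. Success criteria are relative, not absolute:
mean SSIM(PDose, MDose) of at least 0.85, and mean MAE(PDose, MDose)
strictly below mean MAE(RTDose, MDose) — i.e. the sampler's output must be
closer to the measurement than the plan it was conditioned on, which is
exactly the claim that the model learned the planned-to-measured transform
rather than copying its input.

## Numerical and design notes

* **Randomness** is routed through explicit seeds: every config object
  carries one, [withr::with_seed()] scopes all draws, and low-level
  operations accept pre-drawn noise `z` for exactness in tests.
* **Degenerate inputs**: the VP kernel has zero variance at \(t = 0\), so
  [score_target()] refuses it; a zero-norm score in the corrector falls
  back to \(\sigma_i^2 \cdot 10^{-4}\) with a warning; `epochs = 0` returns
  the model unchanged with an empty trace; `M_corrector = 0` runs
  predictor-only.
* **Odd spatial sizes** are reflection-padded to the next multiple of
  \(2^{\text{depth}-1}\) and cropped on output.
* **Determinism**: identical seeds give byte-identical manifests, loss
  traces and sample files (uncompressed NIfTI, no timestamps anywhere);
  this holds per platform/BLAS, which is how the determinism checks are
  run.
* **Checkpoints** archive weights + config + schedule + seed and restore
  bit-identical forward behaviour.

## Limitations

Slices, not volumes; phantom, not clinical, data; a compact network sized
for CPUs (widen `base_width`/`depth` for real data); gamma-index and
DVH-based pass/fail analysis are out of scope; and absolute clinical
metric values cannot be reproduced without the original patient cohort.
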