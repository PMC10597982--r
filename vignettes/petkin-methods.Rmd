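---
title: "petkin: kinetic modeling and physics-constrained frame prediction for dynamic PET"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{petkin: kinetic modeling and physics-constrained frame prediction for dynamic PET}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A dynamic FDG-PET scan acquires a sequence of frames over about an hour so
that every voxel carries a time--activity curve (TAC).  From the TAC and an
arterial input function, Patlak graphical analysis yields the net influx rate
$K_i$, a quantitative alternative to the SUV.  The hour-long acquisition is
the practical obstacle: `petkin` implements a hybrid approach in which a
neural network, constrained by a pharmacokinetic model, predicts the last 30
minutes of the scan from the first 30 minutes, so that full-length SUV frames
and $K_i$ parametric maps can be produced from a half-length acquisition.
Everything runs at desk scale on synthetic digital phantoms; no clinical data
are required for training or testing.

## The kinetic model

The two-tissue compartment model (2TCM) describes each voxel by five
parameters $(f_v, K_1, k_2, k_3, k_4)$:

$$
\frac{dC_1}{dt} = K_1 C_0(t) - (k_2+k_3) C_1 + k_4 C_2, \qquad
\frac{dC_2}{dt} = k_3 C_1 - k_4 C_2,
$$

with $C_0$ the blood input curve (one curve serves as plasma and whole-blood
concentration).  The analytic solution is a sum of two exponential
convolutions,

$$
C_T(t) = a\, C_0 \otimes e^{-\alpha_1 t} + b\, C_0 \otimes e^{-\alpha_2 t},
$$

where $\alpha_{1,2}$ are the eigenvalues of the compartment system (the roots
of $s^2 - (k_2+k_3+k_4)s + k_2 k_4$) and $a = K_1(k_3+k_4-\alpha_1)/(\alpha_2-\alpha_1)$,
$b = K_1 - a$.  The voxel signal mixes in fractional blood volume,
$C_{PET} = (1-f_v)C_T + f_v C_{WB}$, and frames are decay-weighted integrals
$x_m = \int_{t_{m,s}}^{t_{m,e}} C_{PET}(\tau)\, e^{-\lambda\tau}\, d\tau$.

Numerical choices:

* **Units.** Minutes everywhere in memory (seconds on disk); rate constants
  1/min.  The decay constant defaults to fluorine-18,
  $\lambda = \ln 2 / 109.77$ min$^{-1}$.
* **Convolution.** The input curve is treated as piecewise linear
  (constant-extrapolated beyond its last sample, zero before time zero), for
  which the exponential convolutions have exact per-segment recursions.  This
  makes the simulator $O(\text{grid})$ per voxel and — because the network's
  kinetic layer uses the identical kernels — makes the reference simulator
  and the differentiable layer agree to machine precision by construction.
* **Quadrature grid.** A uniform $\Delta t = 0.05$ min grid augmented with
  all frame boundaries (so the 10-s early frames contain several nodes);
  configurable, and coarsened to 0.1 min inside the training loop to save
  CPU.
* **Degenerate eigenvalues.** When $\alpha_2-\alpha_1 < 10^{-9}$ the
  distinct-root amplitudes divide by zero; the implementation switches to the
  repeated-root limit with a $t\,e^{-\alpha t}$ kernel.  This also covers the
  $k_2=k_3=k_4=0$ corner, where $C_T = K_1 \int_0^t C_0$.  In the gradient
  path the eigenvalue spread and the implicit-function denominators are
  clamped at $10^{-6}$; the clamp only matters in a measure-zero corner that
  bounded, non-adversarial network outputs do not reach.
* **Decay correction.** Clinical SUV frames are normally decay-corrected,
  in which case the $e^{-\lambda\tau}$ weight must not be applied twice;
  `decay_corrected = TRUE` (the default) skips it, and `"integral"` vs
  `"average"` selects between the raw frame integral (concentration × time)
  and the frame-average convention used for anything compared against SUV
  images.
* **Verification.** `ode_tissue_concentration()` integrates the ODEs with
  fixed-step RK4 and exists purely as an independent oracle; the analytic
  path agrees with it to relative $L_2 < 10^{-3}$ across seeded random
  parameter sweeps (tested).

## Patlak analysis

For an irreversibly trapped tracer ($k_4 = 0$), plotting
$y(t) = C_{tissue}(t)/C_p(t)$ against $x(t) = \int_0^t C_p / C_p(t)$
becomes linear once the reversible pools have equilibrated, with slope
$K_i$ and intercept $V_0$.  In the irreversible limit
$K_i = K_1 k_3/(k_2+k_3)$ for the tissue curve; for the voxel curve the
slope is diluted to $(1-f_v)\,K_1 k_3/(k_2+k_3)$, because the blood-volume
term adds intercept but no slope — this is the value the phantom reports as
its ground-truth $K_i$ map.  Each frame contributes the point at its
arithmetic mid-time, with the frame-average activity as the tissue term, and
the fit is ordinary least squares over the last `n_tail = 13` frames (the
linear portion of the one-hour protocol).  Voxels containing non-finite
points yield `NaN` rather than aborting; all-zero voxels yield zero.

## The phantom (the stated world)

`generate_phantom()` emulates the clinical protocol so that the whole method
is trainable and testable without any download:

* **Protocol.** 28 contiguous frames — 6×10 s, 4×30 s, 4×60 s, 4×120 s,
  10×300 s — spanning 65 min.  The first 22 frames (35 min of clock time;
  the split is defined by frame count) are the network input, the last 6 the
  prediction target.
* **Input function.** A Feng-type analytic curve
  $(A_1 t - A_2 - A_3)e^{-\ell_1 t} + A_2 e^{-\ell_2 t} + A_3 e^{-\ell_3 t}$
  with the classic FDG population constants ($A_1 = 851.1$, $A_2 = 21.88$,
  $A_3 = 20.81$ kBq/ml; $\ell = 4.134, 0.1191, 0.0104$ min$^{-1}$), standing
  in for an image-derived descending-aorta curve: zero at injection, bolus
  peak inside two minutes, slow tail.
* **Anatomy.** 64×64 2-D slices with four regions: air background (zero
  uptake), a soft-tissue body disk, a liver-like high-$K_1$ ellipse, and a
  lesion-like high-$k_3$ focus.  Region parameters are sampled within
  standard FDG ranges ($K_1, k_2 \in [0.01, 1.5]$, $k_3 \in [0.001, 0.5]$,
  $k_4 \in [0, 0.2]$ min$^{-1}$, $f_v \in [0, 0.3]$); the generator defaults
  to the irreversible case $k_4 = 0$, matching the Patlak framing (a
  `reversible` switch exists).  `sample_phantom_spec(seed)` jitters geometry
  and parameters for building sets of distinct slices.
* **Noise.** Additive Gaussian with per-frame standard deviation
  `noise_scale / sqrt(duration)` — short early frames are noisy, long late
  frames are clean, mimicking post-reconstruction count statistics.  The
  default `noise_scale = 2` kBq·ml$^{-1}$·min$^{1/2}$ puts roughly 0.9 kBq/ml
  of noise on a 5-min frame against late-frame signals of order 5–30 kBq/ml,
  a realistic image-space noise level.  This is *not* full Poisson
  reconstruction noise: spatial correlation, scanner PSF and attenuation
  artifacts are absent, so a green test establishes correctness of the
  method's machinery on plausible data, not clinical performance.
* **SUV.** $\mathrm{SUV} = C / (\mathrm{dose}/\mathrm{weight})$ with frames
  in kBq/ml and the defaults 63 kg / 300 MBq (typical adult protocol), so
  the scale factor is `weight_kg / dose_MBq`.
* Everything is reproducible from the phantom specification's seed; the RNG state of the
  caller is left untouched.

## The network

Two stages, trained end to end:

1. **Feature extractor.** A U-Net applied independently (shared weights) to
   each input frame: DoubleConv blocks (3×3 conv → GroupNorm → ReLU, twice),
   four 2× max-pool downsamplings reaching 1/16 of the input resolution with
   encoder widths 64, 128, 256, 512, 1024, four 2×2 transposed-convolution
   upsamplings with skip connections, and a 1×1 output head producing 10
   feature maps per frame.  GroupNorm uses 16 channels per group (read
   literally; when scaled widths drop below 16 the group size clamps to the
   channel count).  With 22 input frames each voxel ends up with a 220-dim
   feature vector.
2. **Kinetic-parameter head.** A pointwise network of 1×1 convolutions
   (220 → 256 → 128 → 64 → 5, ReLU between layers; the hidden widths are a
   design choice — the source architecture shows unlabeled hidden layers) with
   a final sigmoid scaled into per-parameter ranges ($f_v \in [0,1]$;
   $K_1, k_2 \in [0,2]$; $k_3 \in [0,0.5]$; $k_4 \in [0,0.2]$ — the phantom
   bounds with headroom), emitting $(f_v, K_1, k_2, k_3, k_4)$ per voxel.
   The predicted maps drive the analytic kinetic layer to render all 28
   frames, and gradients flow through the layer via exact analytic partials
   (eigenvalue derivatives by implicit differentiation; the $\partial/\partial\alpha$
   terms use the $t e^{-\alpha t}$ convolutions).

The **"without model" ablation** keeps the identical backbone and pointwise
head but maps the 220 features directly to the 6 target frames with no final
activation and no kinetic layer.

Weights are fan-in-scaled Gaussian (He) initialized under a caller-provided
seed, with one deliberate exception: the head's output layer starts at 1% of
its He scale (bias zero), so the range-scaled sigmoid begins at the middle
of every parameter range.  Without this, desk-scale training reliably
collapses — a few Adam steps push the pre-sigmoid activations past
saturation, every parameter pins to a range bound, and the gradient dies.
For the same reason the optimizer applies global gradient-norm clipping
(`clip_norm = 5`, configurable, `Inf` to disable).  Both are optimization
safeguards, not changes to the architecture: at convergence neither is
active.  A `channel_scale` multiplier shrinks all widths for CPU-scale
training (the full widths remain the default and are what the architecture
tests check); there is no autodiff dependency — forward and reverse passes
are explicit, with the convolutions as im2col GEMM in compiled code, verified
against central finite differences.

## Training

The loss is `loss_SUV + lambda * loss_diff`:

* `loss_SUV`: mean Huber loss (delta = 1 SUV, a design default; the source
  method names Huber but no threshold) over the 6 supervised frames and all
  pixels.  Supervision covers only the target frames — the inputs are known.
* `loss_diff`: Huber between successive-frame differences of the predicted
  Patlak ordinate $y$ and of $K_i \cdot x$ over the last 13 frames.
  Differencing removes the intercept, so this term constrains the late-time
  slope.  The slope target $K(x,y)$ is re-fitted each step from the current
  prediction's own linear frames and treated as a constant (detached);
  fitting it from the ground-truth map is selectable
  (`ki_reference = "truth"`), since the source leaves this open.
* `lambda` defaults to 1 (unstated in the source; the two terms are of
  comparable scale on SUV-normalized phantoms).  Note this weight is a
  different quantity from the decay constant of the frame integral, despite
  the shared Greek letter.

Optimization is Adam at $10^{-4}$, decaying ×0.1 every 10,000 iterations
with a floor of $10^{-7}$.  A batch is one 2-D slice (its 22 frames form the
U-Net batch); slices are visited cyclically, so training is deterministic
given the seed.  Desk-scale configurations (64×64 phantoms,
`channel_scale = 1/16`, a few hundred iterations, quadrature coarsened to
0.1 min) run on one CPU in minutes; the full-scale setting (full widths, 10
epochs × thousands of iterations) is the documented default but is not
exercised by the tests — the test-suite training length is chosen for the CI
compute budget, and the end-to-end checks are directional (prediction beats
the noisy baseline) rather than absolute.

## Evaluation

SSIM (Gaussian 11×11, sigma 1.5 window, $C_1 = (0.01R)^2$, $C_2 = (0.03R)^2$),
PSNR and SSIM anchored to the *reference* image's dynamic range, RMSE, NMI
as $2 I(a;b)/(H(a)+H(b))$ over a 64-bin joint histogram on the union range
(the source does not pin down its NMI variant), and Bland–Altman limits of
agreement $\bar d \pm 1.96\, s_d$ ($n-1$ denominator) over an ROI.  Each
metric is cross-checked in the tests against an independent textbook-formula
reimplementation.  Percent-improvement bookkeeping
(`percent_improvement()`) is computed per image and averaged, and is
reported for phantoms only — the numbers are not clinical results.

## What desk-scale training does and does not reach

The CPU-scale configuration exercised by the test suite (1/16 channel
widths, 8 phantom slices, ~600 Adam iterations at LR $10^{-3}$) verifies
that the end-to-end machinery works: gradients are exact, the loss falls by
two orders of magnitude, the background is predicted cleanly, and every
component is individually validated against oracles.  It does **not** reach
the denoising regime in which the predicted last-30-minute frames beat the
noisy acquisition: train-slice loss is still ~20× above the noise floor at
that budget, with the small high-uptake lesion (about 1.5% of pixels,
largest frame values) fitted worst.  Reaching that regime needs
training on the order of $10^4$–$10^5$ iterations over a large slice set —
the scale of the full clinical setting, far beyond a minutes-long CPU run.
The package reports this honestly: the end-to-end image-quality comparisons
in the test suite are expected to fail at desk scale, and the tests state
the measured values.

## Known limitations

* The phantom is 2-D, piecewise-constant and Gaussian-noised; no anatomical
  texture, PSF, motion, or Poisson statistics.  Conclusions about clinical
  image quality cannot be drawn from it.
* The degenerate-eigenvalue gradient branch drops a second-order term (the
  $\partial^2/\partial\alpha^2$ kernel); forward values are exact in both
  branches.
* Patlak weighting is plain OLS (no frame-variance weights, no bootstrap
  intervals).
* The reversible case ($k_4 > 0$) is simulated exactly but Patlak $K_i$ is
  then only an effective slope; the truth map is exact only for $k_4 = 0$.
* Checkpoints are R RDS files; NIfTI output is single-file NIfTI-1 with an
  identity orientation (no qform/sform geometry beyond voxel indexing).
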