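---
title: "Residual-shifting diffusion for MRI motion-artifact correction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Residual-shifting diffusion for MRI motion-artifact correction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(rsmoco)
```

## The problem

Rigid head motion during a structural brain MRI acquisition makes the
sequentially acquired phase-encode lines of k-space mutually
inconsistent, which appears in the reconstructed magnitude image as
ghosting (replicas of bright rim tissue) and ringing (oscillatory
stripes inside the skull). Since raw k-space is rarely archived,
retrospective correction has to work in the image domain: given only
the corrupted magnitude image $y$, estimate the motion-free image $x$.

`rsmoco` implements a *residual-shifting* denoising diffusion model for
this task, together with everything needed to exercise it end to end
without external data: a k-space motion simulator that manufactures
paired training data from motion-free images, a seeded brain-like
phantom generator, a compact trainable denoiser, and paired
image-quality metrics.

## The residual-shifting diffusion model

Classical image-restoration diffusion models diffuse the clean image
all the way to pure Gaussian noise and then spend hundreds of reverse
steps walking back. When the degraded image is itself close to the
clean one — as in motion corruption — that is wasteful. The idea here
is to make the *forward* process drift from $x$ toward $y$ by
progressively adding the residual $r = y - x$, so the terminal state of
the diffusion already sits at the corrupted image (plus noise), and the
reverse process only has to bridge a short gap.

A monotone shifting sequence $0 = \beta_0 < \beta_1 < \dots < \beta_N
\le 1$ controls the drift, with increments $\alpha_t = \beta_t -
\beta_{t-1}$. One forward step is

$$q(x_t \mid x_{t-1}, y) = \mathcal N\!\big(x_t;\; x_{t-1} + \alpha_t r,\;
\gamma^2 \alpha_t I\big),$$

and because Gaussian increments compose, the state at any step has the
closed-form marginal

$$q(x_t \mid x, y) = \mathcal N\!\big(x_t;\; x + \beta_t r,\;
\gamma^2 \beta_t I\big).$$

The global scale $\gamma$ sets how much exploratory noise accompanies
the drift. The reverse-time posterior given the clean image is also
Gaussian, with

$$\mu_q = \frac{\beta_{t-1}}{\beta_t} x_t + \frac{\alpha_t}{\beta_t} x,
\qquad
\Sigma_q = \gamma^2 \frac{\beta_{t-1}}{\beta_t}\alpha_t I .$$

The residual cancels out of this posterior — only $x$ (or an estimate
of it) is needed — which is what makes an $x_0$-prediction network the
natural parameterisation: a denoiser $f_\theta(x_t, y, \ell_t)$
estimates the clean image, the posterior mean is formed with $x$
replaced by $f_\theta$, and noise of variance $\Sigma_q$ is injected.
With the convention $\beta_0 = 0$, the $t = 1$ posterior collapses onto
the prediction with zero variance: the final reverse step is exact and
noiseless, and a perfect denoiser makes the whole sampler an exact
inverse (a property the test suite asserts bit-for-bit).

### The noise schedule

The shifting sequence interpolates geometrically between its endpoints,

$$\beta_t = \beta_1 \left(\frac{\beta_N}{\beta_1}\right)^{\left(\frac{t-1}{N-1}\right)^p},$$

so $\beta_1$ and $\beta_N$ are attained exactly and the growth-rate
exponent $p$ shapes the interior: smaller $p$ front-loads the noise.
Defaults are $N = 20$ forward steps, $p = 0.3$, $\gamma = 2$,
$\beta_N = 0.999$ (terminal state essentially at $y$) and $\beta_1 =
(0.04/\gamma)^2$, which keeps the step-1 noise magnitude
$\gamma\sqrt{\beta_1} = 0.04$ small enough that $x_1$ is essentially
the clean image. One stated interior reading deserves a note: the
geometric-interpolation form above is the only reading of the scheduler
under which the sequence continuously attains both endpoints, so it is
the one implemented.

```{r schedule}
sched <- build_schedule(schedule_config(n_steps = 20))
head(schedule_table(sched), 4)
```

```{r schedule-plot}
ggplot2::autoplot(sched)
```

### Training and few-step sampling

Training (the standard diffusion recipe) draws a pair $(x, y)$, a step
$t \sim \mathrm{Uniform}\{1..N\}$, forms $x_t$ from the marginal, and
minimises the combined per-pixel loss
$\lVert f_\theta - x \rVert_2^2 + \lVert f_\theta - x \rVert_1$ with
equal weights; an `l2_only` switch reproduces the pure-$\ell_2$
ablation. The $\ell_1$ term promotes sharpness, the $\ell_2$ term
penalises large deviations; no reweighting is attempted.

Sampling uses a *shorter* schedule — four steps by default, built with
the same endpoints, $p$ and $\gamma$ — initialised at $x_N \sim
\mathcal N(y, \gamma^2\beta_N I)$ and iterating the posterior update
with $\varepsilon = 0$ at $t = 1$. Exactly $N$ denoiser calls are made.
Because the training and sampling schedules have different lengths, the
denoiser is conditioned on the *continuous* noise level
$\ell_t = \sqrt{\beta_t}$ rather than the integer index; a model
trained under the 20-step schedule is thereby queried consistently at
the 4-step sampler's own $\beta$ values. This is an engineering
resolution of a genuinely open interface question, and it is the reason
`noise_level()` exists as a first-class operation.

## The denoiser

The estimator is a U-shaped encoder/decoder over three resolution
levels (channel widths 16/32/64 in the `tiny` preset) whose two
lowest-resolution levels carry pairs of windowed self-attention blocks
— an unshifted and a cyclically shifted 4-pixel window partition —
in place of conventional global attention, which keeps cost linear in
image size and lets the same weights run at any compatible resolution.
The noisy state and the conditioning image enter as a 2-channel stack;
the noise level enters through a sinusoidal embedding of
$\log \ell$ followed by a small MLP, modulating every residual block
via a per-channel scale and shift (FiLM). The network predicts
$\hat x$ directly, parameterised as $y$ plus a learned correction, so
an untrained model starts near the identity restorer.

Simplifications relative to full-scale Swin implementations, chosen for
a dependency-free R implementation at desk scale: shifted windows use a
cyclic roll without an attention mask; residual blocks are
unnormalised (layer norm is used inside the attention blocks); no
relative-position bias. The architecture's exact block counts and
widths are not prescribed anywhere authoritative, so `tiny`
(≈360k parameters, the test default) and `paper` (base width 64,
depth 4) presets are shipped as declared stand-ins.

The network, its backpropagation and the Adam optimizer are implemented
natively in R on top of BLAS matrix multiplication: convolutions as an
im2col gather plus one matrix product (the stride-1 adjoint is itself a
convolution with flipped kernels), attention per 4×4 window. The test
suite verifies every analytic gradient against central finite
differences, which is the load-bearing correctness check for the whole
trainer.

Desk-scale training uses Adam with a 50-step linear warmup, cosine
decay from a peak rate of $2\times10^{-3}$, global gradient-norm
clipping at 1 (the high-noise states at large $t$ otherwise produce
occasional destabilising outlier gradients with a batch of one), and an
exponential moving average of the weights (decay 0.998) installed at
the end — all standard diffusion-training practice. Full-scale
optimizer metadata (RAdam, cosine annealing $2\times10^{-4} \to
2\times10^{-5}$, 5000 warmup steps, batch 32, 100 epochs) is recorded
in the run configuration for provenance; the algorithm itself is
optimizer-agnostic.

## The motion simulator

Motion between phase-encode excitations is emulated in k-space: random
slabs of contiguous phase-encode lines (widths uniform on 3–7, total
budget 7/10/15 lines for the minor/moderate/heavy presets) are replaced
by the corresponding lines of a rigidly moved copy of the image, with
one rotation (uniform ±7°) and in-plane translation (uniform ±5 mm per
axis, at the configured pixel spacing) per slab.

One design point matters for exactness. A magnitude image is treated as
a real-valued, zero-phase object, and the spectrum of a real object is
conjugate-symmetric: line $k$ and line $-k$ are complex-conjugate
duplicates of a single acquired measurement. Replacing a line *without*
its mirror breaks that symmetry, the inverse transform becomes complex,
and taking its modulus smears second-order differences across *every*
k-space line — measurably, at the $10^{-3}$–$10^{-2}$ relative level —
so "exactly $n$ lines were perturbed" would no longer be a checkable
property of the output image. The simulator therefore replaces each
slab's lines together with their conjugate mirrors (values taken from
the moved image's own Hermitian spectrum), keeping the composite
spectrum Hermitian and the reconstruction real. Consequences, all
verified by tests:

* lines outside the slabs are bit-identical to the original spectrum;
* exactly `n_lines` distinct conjugate-line classes differ for every
  seed (`count_differing_lines()` counts classes, since a line and its
  mirror are one measurement);
* zero-amplitude motion reproduces the input to FFT round-off
  ($<10^{-6}$ relative);
* Gibbs ringing may make the corrupted image slightly undershoot zero;
  values are kept as-is rather than clipped, precisely to preserve the
  line-locality above.

Slab placement is uniform over all feasible positions (the k-space
centre included; an `exclude_center` option exists, default off), with
the constraints that slabs never collide as conjugate-line classes and
the last drawn slab is truncated so the budget is met exactly. Each
slab carries one piecewise-constant motion; per-line trajectories,
through-plane and non-rigid motion, and the additive thermal-noise term
of the degradation model are out of scope (an optional Gaussian-noise
flag exists, default off).

## Phantoms, and what the tests do and do not show

The phantom generator composes a T1-weighted-looking axial slice from
ellipses: a bright fat/skull annulus (so ghosting of bright rim tissue
is visible), mid-intensity parenchyma, dark ventricle pairs, and 4–8
random internal structures, clipped to $[0, 1]$, deterministic per
seed. Compared with real brain MRI these phantoms are piecewise-smooth,
noise-free, single-contrast and small (64×64 in the standard suite), so
passing tests demonstrate that the *machinery* — simulator exactness,
posterior algebra, sampler inversion, trainability, metric behaviour —
is correct at desk scale. They do not certify restoration quality on
clinical data, which would require the full-scale datasets and training
budget this package deliberately does not depend on.

Note also a scale effect: a 7–15-line budget on a 64-line grid is a far
larger fraction of k-space than the same budget on a 256-line clinical
matrix, so corrupted-image NMSE values here (several percent to tens of
percent) are much larger than the sub-percent values typical of
full-scale experiments. Severity ordering — NMSE rising and SSIM
falling from minor to heavy — is preserved, and is what the acceptance
suite checks.

```{r simulate}
ph <- make_phantom(phantom_config(64), seed = 1)
res <- corrupt(ph, motion_config("heavy"), seed = 7)
count_differing_lines(ph, res$image)
round(nmse(ph, res$image), 2)
```

## Metrics

NMSE is reported in percent, $100\,\lVert \hat x - x\rVert^2 /
\lVert x\rVert^2$. PSNR is $10\log_{10}(\mathrm{range}^2/\mathrm{MSE})$
with an infinity sentinel for identical images. SSIM uses the standard
11×11 Gaussian window ($\sigma = 1.5$, $K_1 = 0.01$, $K_2 = 0.03$),
averaged over fully valid window positions, and is cross-checked in the
tests against an independent brute-force implementation. The PSNR/SSIM
data range is the per-pair maximum of the reference image, and metrics
are computed per slice with per-severity aggregation. Pixel-wise
Pearson correlation over flattened images completes the report.

## Numerical choices and degenerate inputs

* Schedule values are precomputed; the telescoping identity
  $\sum_{s\le t}\alpha_s = \beta_t$ holds to within one unit in the
  last place (exact bitwise equality of a rounded sum is not a
  guarantee IEEE arithmetic can make across widely separated
  magnitudes, and the tests assert the ulp-level bound instead).
  Strict monotonicity is asserted wherever double precision can
  resolve the closed-form increment; extreme corners (e.g. $p = 10$
  with $N = 64$) have interior increments below machine epsilon.
* Invalid configurations (non-increasing endpoints, $N < 2$,
  non-positive $p$ or $\gamma$, infeasible line budgets, too-small
  grids, all-zero slices) are rejected with errors rather than
  repaired.
* Every stochastic operation takes an explicit seed and is a pure
  function of (inputs, seed); RNG state is restored afterwards
  (`withr::local_seed`), so library calls never perturb a caller's
  random stream.
* The sampler draws one fresh noise field per reverse step (i.i.d. per
  pixel); the terminal state uses variance $\gamma^2\beta_N$, the
  schedule-consistent choice, rather than the $\gamma^2$ approximation.
* Ties in slab placement, window partitions and softmax maxima are
  resolved deterministically.

## Problem sizes

The standard fixture suite is 20 phantoms at 64×64 (36 training pairs
after the 60/20/20 split across three severity levels), and the
end-to-end check trains the tiny denoiser for 2000 steps at batch 1 —
sizes chosen so the whole suite, including finite-difference gradient
checks and Monte-Carlo consistency sweeps, runs comfortably on a single
CPU. The `paper` preset and larger suites use the identical code paths.

## Known limitations

* The simulator models piecewise-constant rigid motion per slab;
  smooth motion trajectories, spin-history and $B_0$ effects are not
  modelled.
* Phantom realism is deliberately limited (see above); no claim about
  in-vivo performance is made from these tests.
* The denoiser presets are stand-ins for an architecture whose exact
  layout is not publicly specified; results depend on this choice.
* 3-D volumes are handled slice-by-slice; no through-plane modelling.
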