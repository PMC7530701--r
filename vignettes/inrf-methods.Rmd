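---
title: "Modelling vision with an intrinsically nonlinear receptive field"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling vision with an intrinsically nonlinear receptive field}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
library(inrf)
```

## The model

The classical receptive field (RF) of a visual neuron is a linear
weighting of the stimulus, optionally followed by a pointwise
nonlinearity (the "L+NL" standard model).  This package implements an
alternative summation model, the intrinsically nonlinear receptive
field (INRF),

$$\mathrm{INRF}(x) \;=\; \sum_i m_i\, I(y_i)\;-\;\lambda \sum_i w_i\,
  \sigma\!\big(I(y_i) - (g * I)(x)\big),$$

in which a set of linear dendrites sums the input with weights $m$,
while a second set applies a sigmoid-like nonlinearity $\sigma$ to each
input sample *after shifting it by a local average* $(g*I)(x)$ of the
signal around the output location, and sums the results with weights
$w$.  The shift is what makes the operator different in kind from the
standard model: the nonlinearity applied to a given input sample
depends on the output location it is contributing to, so the operator
is not shift-invariant and cannot be written as any convolution
followed by a fixed pointwise function.  Expressing it with linear
filters would need one filter per pixel plus two
(`count_lnl_filters()`), which is why the model is called
*intrinsically* nonlinear.

Two limiting cases anchor the implementation and its tests:

* with a linear "nonlinearity" $\sigma(z) = \alpha z$, the model
  collapses to one convolution with
  $k = m - \lambda\alpha\, w + \lambda\alpha (\sum_i w_i)\, g$
  (`reduce_to_linear()`); with Gaussian $m$, $g$ and a wider Gaussian
  $w$, $k$ has the classical center–surround (difference-of-Gaussians)
  shape;
* with normalized $m$, $g$ and $\sigma(0) = 0$, constant signals are
  exact fixed points.

The operator is also a regularized form of local histogram
equalization: replacing $\sigma$ by the sign function and $g*I$ by a
local mean recovers the steady state of a histogram-equalization flow,
which connects the model to the efficient-representation principle.

## Evaluation strategies

Three evaluators share one mathematical contract:

* `inrf_points()` — the literal double summation at selected points;
  this is the reference semantics ("oracle") and the one used wherever
  only a handful of outputs is needed.
* `inrf_oracle()` — the same, at every grid point.
* `inrf_apply()` — the fast path.  Because the nonlinear term depends
  on $x$ only through the scalar $c(x) = (g*I)(x)$, it can be computed
  per intensity level: $T_\ell = w * \sigma(I - c_\ell)$ by ordinary
  (separable, compiled) convolution, with $T(x)$ read at the level
  matching $c(x)$.  When $c$ takes at most `levels` distinct values —
  true for every piecewise-constant laboratory stimulus in the
  experiments — the decomposition uses exactly those values and the
  result is exact to rounding ($<10^{-10}$).  Otherwise `levels`
  values are placed uniformly over $[\min c, \max c]$ and $T(x)$ is
  linearly interpolated between the two bracketing levels; with 64
  levels and the brightness-model kernels the maximum deviation from
  the literal evaluator on smooth random images is of order $10^{-4}$
  (the tests assert $<10^{-3}$).  Interpolation error concentrates
  where $I(y) - c(x)$ crosses zero, because the power nonlinearity has
  unbounded slope there.

Boundary handling is mirror (half-sample symmetric, edge repeated) by
default — it avoids artificial edge darkening in brightness displays —
with replicate, periodic and zero available.  Mirror extension is
applied recursively, so kernels wider than the image are legal.
Periodic boundaries give exact translation equivariance, which the
property tests use.  One deliberate exception: a `constant_full`
kernel with unset size (the ON/OFF experiment's $w$, printed as "width
512, value 1/512") is evaluated as an exact global mean with every
sample weighted once.  Realizing it as a centered odd-width box under
mirror folding would count an edge sample twice, and at
$\lambda = 1000$ that single duplicated tap biases the response by
about 2 units and visibly shifts the OFF→ON transition.

All arithmetic is double precision; $\lambda$ is applied exactly as
configured, with no renormalization by kernel mass.

## The experiments and their parameters

Except for the ON/OFF simulation, all experiments share one parameter
set (in degrees of visual angle): Gaussian $m$ with sd $0.81^\circ$,
Gaussian $w$ with sd $2.77^\circ$, $g$ a Dirac delta,
$\lambda = 3.875$, and $\sigma(z) = z^{0.625}$ for $z \ge 0$,
$-|z|^{0.775}$ for $z < 0$.  The presets realize these at each
display's pixel scale.

### ON/OFF polarity reversal

A 512-sample bar signal (alternating black/white bars of width $b$, a
64-sample center segment at test value $u$) is blurred with a Gaussian
of sd 4 samples, passed through the INRF with box $m$ and $g$ of width
85 (value 1/85), full-signal constant $w$, $\lambda = 1000$ and the
piecewise sinusoid $\sigma(z) = \sin(\pi z)$ for $|z| < 0.5$,
$\mathrm{sign}(z)\sin(\pi z)^2$ otherwise, then half-wave rectified
(`max(0, ·)` — the package's reading of "rectified").  The signal and
segment widths are even, so there is no exactly centered sample; the
center response averages the two central outputs, which restores the
symmetry the discrete grid breaks (reading a single sample shifts the
local mean by ~0.006 and the measured transition by ~0.06).  At
$b = 128$ the unit responds only below the 0.5 background average
(OFF); at $b = 4$ only above it (ON); the sweep over $u$ in steps of
0.01 locates both transitions within 0.05 of 0.5.  The sinusoid is
applied literally for all $|z|$, including $|z| > 1.5$ where its
behaviour is unconstrained by the experiments.

### Brightness scaling (crispening)

Displays are 1280×960 at 64 px/deg with eleven 1°-diameter circles on
the horizontal meridian.  Eleven circles with full 1° gaps would span
1344 px, which does not fit the monitor, so centers are spaced evenly
with a 32 px margin (~1.8° center-to-center) — still far beyond the
$m$ radius, keeping probes independent.  Circle luminances are probed
on a linear scale from display black (0.65 cd/m²) to white (75 cd/m²).
The front end is a Naka–Rushton response $L^n/(L^n + S^n)$ with
$n = 0.74$ and $S = 0.5\cdot 18 + 0.5\cdot 10^{0.63\log_{10} b_k + 1}$
from the display's mean luminance $b_k$ — a luminance-adaptation rule;
then the model (INRF-B, or an L+NL baseline) is evaluated at the
eleven circle centers with the literal summation, since nothing else
of the output field is used.

Crispening is quantified by `slope_peak_statistic()`: finite-difference
slopes of model output against the *photoreceptor response* of the
probe, with peak locations reported in luminance.  Slopes against raw
luminance would be dominated at the dark end by the front end itself
(its derivative diverges as $L \to 0$), for every model and every
background alike; the response axis is shared by all conditions and
isolates the ganglion-stage behaviour the experiment contrasts.  On
that axis the INRF shows its maximum slope at the probe nearest a
uniform background's level for all five printed levels, and no peak
anchored at the adaptation level of a salt-and-pepper surround — the
$\sigma$-kink follows the actual surround values (display black and
white), not their mixture.  The L+NL baseline fitted to the uniform
condition (DoG 30/60 px, $\lambda = 2$, exponents 0.5/0.7) keeps its
peak at the surround's *adaptation level* on salt-and-pepper
backgrounds: the DoG output crosses zero where the probe response
equals the surround's mean response, which for a 50% mixture is ~17
cd/m², not the 37.8 cd/m² mean luminance, because the photoreceptor
response is concave (`adaptation_level()` computes this).  Mixture
fractions 0.25/0.5/0.75 are mean-matched to the printed uniform levels
56.41/37.83/19.24 cd/m²; fractions 0 and 1 are degenerate (they *are*
uniform displays) and are excluded from uniform-versus-mixture
comparisons.

### White's illusion under bandpass noise

The grating geometry is a declared convention (the underlying
psychophysics lives in external work the experiment emulates): eight
1°-wide bars at 24 px/deg (192×192 canvas), with two identical gray
patches one bar wide and two bars tall on opposite bar polarities.
The resolution was chosen so that the whole battery — six noise bands,
25 realizations each, plus the reproducibility and scaling checks —
runs in a few minutes; the kernels scale with degrees, so the model is
the same in visual-angle terms.  Noise is white Gaussian filtered to a
one-octave annulus (isotropic) centered at one of six log-spaced
frequencies between 0.5 and 9 c/deg (the exact printed bands are not
available; these defaults are config-exposed and flagged as
unverified), scaled to an exact rms of 0.2 with exactly zero mean.
Noisy values are clipped to the displayable $[0,1]$ before the
front end, which here is a plain power law $v^{2.2}$ (display
linearization; the exponent is a config default, not a printed value)
— no Naka–Rushton stage in this experiment.  Illusion strength is the
difference of mean model output over the two patch regions of the
25-realization average, with polarity fixed by the noise-free
illusion; per-band noise streams are derived from the band frequency,
so a run on a subset of bands reproduces the same strengths.  The fast
evaluator with 16 levels is used; patch means are insensitive to the
residual interpolation error.  Only sign, reproducibility and
$1/\sqrt{n}$ dispersion scaling are asserted — matching the observer
trend quantitatively would require the external stimulus details.

### Irradiation illusion

A 1024-sample binary signal with a 400-sample central step, blurred
with a Gaussian of sd 20, passed through $NR(v) = v/(v + 0.18)$ (the
semisaturation 0.18 is mid-gray on the $[0,1]$ scale), then the INRF
($m$ sd 100, $w$ sd 342, delta $g$, $\lambda = 3.875$) and clipping to
$[0, 1]$.  "Perceived size" is not defined by a printed measure; the
package uses the mid-threshold width: the count of samples on the
figure's side of the midpoint between the clipped profile's central
and outer plateau levels.  Under the full pipeline the white-on-black
width exceeds the black-on-white width; with $\lambda = 0$ and an
identity front end the pipeline is polarity-symmetric and both widths
are equal, which the tests use as a control.

### Image quality metric

`inrf_iq()` converts both images to CIELAB lightness (sRGB → XYZ with
the D65 white of the sRGB standard — the colorimetric stage plays the
photoreceptor's role here), applies INRF-B to each at full resolution,
and reports the root-mean-square difference of the outputs, on the
model's output scale as written.  A sequential two-stage variant is
exposed (`stages = 2`) but untargeted.  The external-database harness
(`evaluate_mos_correlation()`, `tid2013_pair_table()`) correlates the
negated score with mean opinion scores and reports both the signed and
absolute correlation; the database itself is not bundled and no
correlation value is asserted.

### The trainable layer

`inrf_layer_spec()` / `inrf_layer_forward()` implement the
multi-channel network form: $g$ is a delta and one learnable kernel
serves as both $m$ and $w$, so each output channel computes
$k * x - \lambda \sum_d k_d\, \sigma(x(\cdot + d) - x(\cdot))$, summed
over input channels with per-(input, output) kernels — the
cross-channel wiring of the nonlinear term follows the linear term's,
a declared convention where the published description is not specific.
Boundary handling is zero padding (the convention of the layers it
replaces), $\lambda$ is a fixed hyperparameter, and the operator is
*linear in its weights*, so the weight gradient is an exact
correlation with per-offset features; the tests verify it against
central finite differences.  `train_demo()` trains a one-layer
classifier (layer → global average pooling → logistic head) on seeded
synthetic 8×8 blobs-versus-bars images with full-batch Adam.  The
pooled features are batch-normalized — as in the networks this layer
drops into — because their common-mode intensity offset otherwise
dominates the logistic head and stalls optimization; with it, training
reaches zero error within 20 epochs on every seed tried.

## Randomness and reproducibility

Every generator is a pure function of its configuration including the
seed: seeded draws run in a local RNG scope and restore the caller's
RNG state.  Pipelines derive per-stage streams from one top-level seed
by fixed offsets (kept within 32-bit integer range).  Determinism is
asserted bitwise in the tests.

## Problem sizes in the test battery

The suites run the printed parameters at the experiments' native
scales (1280×960 crispening displays, 512-sample ON/OFF signals,
1024-sample irradiation signals).  Whole-field brute-force evaluation
with the 1425-tap brightness kernels is quadratic and is reserved for
small grids; on 32×32 smooth images the fast path is checked against
the literal evaluator at a 150-point random sample, and the quality
metric's property tests use 40×56 synthetic gradients (unit tests use
small-kernel variants of the same checks).  White's illusion runs 25
realizations per band over six bands, plus 100 at one band for the
dispersion-scaling check.

## What the synthetic stimuli do and do not show

The generators emulate the laboratory stimuli: calibrated two-level or
uniform backgrounds, exact geometry, seeded noise.  They contain none
of the structure of natural images (1/f spectra, occlusions, chromatic
variation), no temporal dimension, and no observer noise; passing
tests therefore demonstrate that the implementation reproduces the
models' behaviour on controlled stimuli, not that the models predict
perception of natural scenes.  Fitting model parameters to human data
is out of scope — the printed parameter values are used as given.

## Known limitations

* Kernels are shift-invariant; the general position-dependent
  $m(x, y_i)$ the model admits is not implemented, matching how every
  experiment instantiates it.
* $\sigma$ is fixed in shape; spatially varying nonlinearities are
  future work in the source line of research.
* The interpolated fast path degrades gracefully but is least accurate
  exactly at $\sigma$'s kink; raise `levels` where that matters.
* The external image-quality correlation harness is provided untested
  against the real database, which cannot be redistributed here.
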