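---
title: "SNR-priority acquisition and covariance focusing: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SNR-priority acquisition and covariance focusing: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semfocus)
```

## The problem

Fine focusing and astigmatism correction in a general-purpose scanning
electron microscope (SEM) are performed while watching a fast "TV-scan"
video stream (about 25 frames/s, 0.04 s per frame). At picoampere probe
currents and high magnification these frames are dominated by noise: the
structure an operator needs in order to judge focus can be far below the
noise floor of any single frame. `semfocus` implements a signal-quality
chain that turns such a stream into a stable focusing signal, and a virtual
microscope that generates streams with known ground truth so every stage of
the chain can be validated quantitatively.

## The two-frame covariance SNR

Two registered frames of the same view, $t_1 = s + n_1$ and
$t_2 = s + n_2$, share the specimen signal $s$ while their noise terms are
independent. The sample covariance of the pair therefore estimates the
signal variance alone, and

$$\mathrm{SNR} \;=\; \frac{S_\sigma}{N_\sigma} \;=\;
\sqrt{\frac{\mathrm{Cov}(t_1,t_2)}
     {\sqrt{\mathrm{Var}(t_1)\,\mathrm{Var}(t_2)} - \mathrm{Cov}(t_1,t_2)}}.$$

`estimate_snr()` computes this decomposition. Two properties matter in
practice and are enforced by tests:

* **Affine invariance.** Replacing both frames by $g\,x + b$ ($g>0$) leaves
  the estimate unchanged, so display contrast/brightness never biases the
  focus signal, and file I/O may rescale intensities freely.
* **Honest degenerate cases.** A negative sample covariance (common at very
  low SNR) is clamped to zero and flagged `zero_signal` — a negative ratio
  has no physical meaning. A non-positive noise term is flagged
  `zero_noise` with SNR `Inf`, never a finite stand-in. A constant pair is
  an error, since its SNR is undefined.

Sample statistics use the unbiased $n-1$ divisor throughout; at the pixel
counts involved the choice is immaterial, but it keeps the brute-force
oracles exact.

## The stability index: pixels vs SNR

Repeated covariance (equivalently SNR) measurements on $M$-pixel frames
scatter. The squared mean over the variance of the sample covariance is a
natural steadiness index, and for the shared-signal model it has the
closed form implemented by `stability_index()`:

$$I(M, \mathrm{SNR}) \;=\; \frac{M\,\mathrm{SNR}^4}{2\,\mathrm{SNR}^2+1}.$$

Because the index is quartic in SNR but only linear in $M$, trading pixels
for SNR wins decisively at low SNR: one 2×2 block average of an oversampled
image quarters $M$ and doubles SNR, multiplying $I$ by
$4(2s^2+1)/(8s^2+1) \to 4$ as $s \to 0$.

**Validity range.** The closed form is a low-SNR approximation. We verified
it against a brute-force oracle (the empirical squared-mean-to-variance
ratio of the sample covariance over $10^4$ replicate Gaussian pairs): at
SNR 0.1–0.3 it agrees within Monte-Carlo error; by SNR $\approx 0.5$ it
overestimates by roughly 7%, and at SNR 1 by roughly 70% (the exact
Gaussian ratio is $(M-1)\,s^4/(2s^4+2s^2+1)$). Level selection is
unaffected in the regime the method targets, because the candidate levels
that matter are the low-SNR ones, but reported index values at SNR
$\gtrsim 1$ should be read as qualitative.

## SNR-priority reduction

`block_average()` averages 2×2 pixel blocks (trailing odd rows/columns are
discarded — padding would bias block means), and `reduction_sweep()`
applies it repeatedly to both frames of a pair in lockstep, recording SNR
and index at every level; `select_optimal_reduction()` picks the
index-maximising level, breaking ties toward the smaller level to preserve
resolution. On an oversampled specimen the index rises ~4-fold per level
while the signal survives averaging and falls once averaging erodes it, so
the curve has an interior maximum; on signal with structure at the pixel
scale the maximum sits at level 0–1. The default sweep depth is 5 levels
(640×480 → 20×15).

## Temporal processing and just-focus detection

`evaluate_sweep()` walks a frame stream with one control value per frame
(focus or stigmator setting) and emits the graph an operator would watch.
Defaults follow established operator practice: a causal 4-point moving
average of the graph and 4-frame integration; both are configurable, and
both introduce a known time lag (about $w-1$ graph points and $n$ frames
respectively, visible as a slight late bias of detected peaks).

**Pairing under integration.** Metric samples are formed from two
*adjacent non-overlapping* windows of `integration` frames each. Sliding
windows would share raw frames between the two averaged images, making
their noise correlated and silently inflating the covariance SNR; the
non-overlapping choice keeps the estimator's model exact and reduces to
plain consecutive-frame pairing for `integration = 1`.

**Peak detection.** `detect_just_focus()` returns the tick of the global
maximum of the smoothed graph, provided the rise to the maximum and the
fall after it both exceed a prominence threshold; otherwise it reports "no
usable peak". The default threshold is $2\hat\sigma\sqrt{2\ln n}$, where
$\hat\sigma = \mathrm{sd}(\Delta\,\text{raw})/\sqrt{2}$ estimates the
tick-to-tick jitter and $n$ is the graph length. The $\sqrt{2\ln n}$
factor is the expected extreme of $n$ jitter draws: a threshold that is a
plain multiple of $\hat\sigma$ would be exceeded by the maximum of pure
noise on any flat graph, so the extreme-value calibration is what makes
"no peak" a meaningful verdict. The threshold is overridable via
`prominence`.

`assess_sufficiency()` thresholds the chosen level's index value; an
insufficient verdict is the trigger to reinforce the signal by searching
nearby fields (`search_best_field()`), which ranks candidate beam shifts by
index at a single shared optics state. The ranking inherits affine
invariance and survives defocus, since blur attenuates all candidates
together.

## The virtual microscope

`generate_specimen()`, `optics_state()`, `acquisition_params()`,
`render_frame()` and `sem_stream()` form a seeded forward model:

* **Specimen**: a Gaussian random field with correlation length
  `feature_scale` (white noise smoothed with a Gaussian of
  $\sigma = \texttt{feature\_scale}/2$, standardised to unit sd), with an
  optional strength map for planting strong/weak-texture regions.
* **Magnification** is crop-size scaling of the fixed specimen map:
  `magnification` output pixels per specimen pixel. Integer magnification
  with `sampling = "nearest"` replicates pixels exactly, producing signal
  strictly constant on magnification-sized blocks — the idealised
  oversampling regime in which block averaging is lossless.
* **Blur**: an elliptical Gaussian point-spread function with principal
  sigmas $\sigma_u = \sigma_0\,|d + a|$ and $\sigma_v = \sigma_0\,|d - a|$,
  where $d$ is defocus, $a = \mathrm{hypot}(a_x, a_y)$ the stigmator
  magnitude, the axis angle $\tfrac12\arctan(a_y/a_x)$, and $\sigma_0$ =
  `psf_scale` pixels per focal unit. This is the standard two-line-foci
  picture of astigmatism: at nonzero $a$ no single focus setting sharpens
  both directions. A Gaussian profile is a deliberate simplification — the
  chain is agnostic to the PSF shape, only to the blur-induced loss of
  signal variance.
* **Noise**: per-frame independent additive Gaussian noise with
  sd $= \texttt{dwell\_scale}/\sqrt{\text{current} \times \text{dwell}}$,
  so amplitude falls as the square root of charge dose; a slow scan is an
  explicit `dwell`. The default `dwell_scale = 3.4` calibrates the model
  once so that a 26 pA TV-scan frame of a unit-sd specimen sits at SNR
  ≈ 0.3 and a 3 pA frame at SNR ≈ 0.1 — the low-quality band the method is
  designed for. A Poisson mode is provided for realism; its noise is
  signal-dependent, so the covariance model then holds only approximately.

What the generator deliberately does **not** emulate: beam drift and
specimen charging (pairs are contract-registered; no registration
correction is applied), detector response curves, secondary- vs
backscattered-electron contrast, and any electron-optical aberration
theory. Passing tests therefore demonstrate the statistical chain under
its stated model, not robustness to drift or charging on a real
instrument.

## Study conditions used by the tests

All validation runs are generated at fixed, documented conditions:

* **SNR-doubling**: 512×512 frames, signal constant on 2×2 blocks
  (magnification 2, nearest sampling), generator SNR 0.5, 20 seeds. One
  reduction should double the estimated SNR.
* **Oracle equivalence**: Gaussian pairs at SNR {0.1, 0.3} × M {256, 1024},
  $10^4$ replicates, agreement within 3 Monte-Carlo standard errors
  (delta-method SE for the squared-mean-to-variance ratio).
* **Robustness**: 160×120 frames (a 4:3 TV-scan geometry at desk scale),
  magnification 8, `psf_scale` 6, 3 pA — generator SNR ≈ 0.1 at focus —
  ramped over ±3 focal units in 48 frames. The reduction level is chosen
  in advance from a 4+4-integrated pair at rough focus (defocus 0.5), as
  an operator would, and is typically 3 (the deepest lossless level for
  8-pixel features). Success means the detected peak lies within 1 focal
  unit of true focus (one third of the ramp half-range; the causal
  smoothing lag contributes a known bias of ≈ +0.6 units within it). The
  full chain (reduction + 4-point average + 4-frame integration) must
  succeed in ≥ 90% of 20 seeded runs while the unprocessed chain must
  report "no usable peak"; the stigmator sweep must likewise recover zero
  astigmatism.
* **Field search**: a 3× amplitude patch planted among 5 candidate fields
  (96×96 frames, magnification 4, 26 pA), ranked first in ≥ 90% of 20
  seeds, in focus and under 1.5 focal units of defocus.

Frame sizes were scaled from the 640×480 capture geometry to keep the full
suite fast while leaving every per-frame pixel count large enough that the
estimators operate in their intended regime; the reduction-arithmetic
checks themselves use full 640×480 frames.

## Numerical choices and edge cases

* Ties in level selection go to the smaller level; ties in field ranking
  keep scan order (stable sort).
* `zero_noise` samples enter graphs as `Inf` sentinels, are skipped by the
  causal smoother (`na.rm` windows) and excluded from peak detection.
* Frames are processed as doubles; integer image formats are converted on
  read. TIFF output rescales the stack through a single global affine map
  (16-bit), which the affine invariance of every metric makes harmless.
* RGB inputs are converted by the Rec. 709 luminance rule, with a message.
* All randomness flows from explicit seeds; `sem_stream()` and
  `generate_specimen()` save and restore the caller's RNG state.

## Known limitations

* The stability index is quantitative only at low SNR (see above).
* Registration is assumed; drift between the two frames of a pair biases
  the covariance downward and is not corrected.
* The `focus-sweep` auto-reduction convenience picks its level from the
  first frame pair of the stream; if a sweep starts far from focus, choose
  the level from a rough-focus calibration pair instead (as the robustness
  conditions above do).
* The prominence default assumes roughly stationary jitter along the
  sweep; strongly heteroscedastic graphs may need an explicit
  `prominence`.
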