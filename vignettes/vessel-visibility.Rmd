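---
title: "How angiovis enhances vessel visibility"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How angiovis enhances vessel visibility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

X-ray coronary angiograms show contrast-filled vessels as dark tubes on a
brighter, cluttered background. Visibility — especially of small vessels,
of luminal content, and of interventional tools such as wires and stent
markers — is limited by quantum (photon-counting) noise, non-uniform
illumination, broad bony structures, and low contrast when the dye washes
out or the radiation dose is reduced. `angiovis` implements a per-frame
enhancement pipeline whose core operator is modeled on *lateral
facilitation*, the collinear contour-integration mechanism of early visual
cortex: weak, aligned edge responses reinforce one another along their
shared orientation, completing interrupted lines while leaving unaligned
noise below threshold.

## The pipeline

### 1. Multiscale oriented edge extraction

The frame $I(x,y)\in[0,1]$ is decomposed into a Gaussian pyramid
$I_j$, $j = 1..n$ (default $n = 8$): each level is pre-smoothed
(Gaussian, $\sigma = 1$ px, an anti-aliasing choice) and Lanczos-3
downsampled by two with ceiling dimensions. A fixed-size cosine-phase
Gabor bank
$$G_\theta(x,y) \propto e^{-(x^2+y^2)/\sigma^2}\cos\!\big(\tfrac{2\pi}{\lambda}u_\theta\big),
\qquad u_\theta = -x\sin\theta + y\cos\theta,$$
with $\sigma = 8$ px, $\lambda = 12$ px and 8 orientations evenly spaced
on $[0°, 180°)$, is correlated with every level (reflective borders,
"same" output). The bank angle is the *preferred bar orientation*, so the
facilitation mask below can reuse it directly. Each kernel is DC-corrected
and scaled to unit L2 norm so responses are comparable across
orientations. A cosine-phase Gabor is 180°-periodic, which is why eight
distinct filters span the half-circle even though orientations are often
quoted on the full circle.

Per pixel and scale the orientation with the largest response magnitude
wins (ties to the lowest index) over the *whole* bank, keeping the signed
response $S$. $S$ is split into nonnegative polarity channels
$c_P = \max(S, 0)$ and $c_N = \max(-S, 0)$, which the pipeline carries
separately until the final recombination. Within each channel the bottom
5 % of nonzero magnitudes (type-1 quantile) is treated as noise and gated
to exactly zero; surviving values are untouched. A `max * 0.95` gate is
available as `noise.mode = "max_fraction"`. Responses are then passed
through Naka–Rushton gain control
$$R = \frac{c^{\,n}}{c^{\,n} + \sigma_{NR}^{\,n}}, \qquad n = 2,\;
\sigma_{NR} = 0.1,$$
the standard saturating contrast-response curve ($R(\sigma_{NR}) = 1/2$
exactly). The printed parameter compound "$\sigma_{NR}n = 0.1$" is read
as $\sigma_{NR} = 0.1$ — a plausible semi-saturation for unit-norm
responses on $[0,1]$ images; `nr.sigma_is_power = TRUE` selects the
alternative reading $\sigma_{NR}^n = 0.1$.

### 2. Lateral-facilitation line completion

Each responding unit projects a sub-threshold *additive signal* along its
preferred orientation: an anisotropic Gaussian in coordinates rotated by
$\theta$ (collinear decay $\sigma_x$, orthogonal decay $\sigma_y$), with
the classical receptive-field disk ($d \le r_{RF}$, default
$r_{RF} = \sigma = 8$ px) zeroed so no unit facilitates itself. Table
defaults give $\sigma_x = \sigma_y \in [0.05, 0.1]$ per scale in relative
units; these cannot literally be pixel counts, so they are converted by
the scale image's width (`lf.pixel_scale_mode = "width"`), which makes
the facilitation reach grow with coarser scales. A floor of 0.25 px keeps
the mask well-formed on the smallest levels. The facilitation field of
one orientation channel is the unit's own gain-controlled response plus
the superposition of all same-oriented neighbors' additive signals —
realized as one dense correlation with the mask, which is mathematically
identical to the pairwise neighbor sum.

The field is then thresholded at the scale's $\gamma_j$-th percentile
(99, 80, 97, 97, 96, 96, 96, 96 across scales) of its **nonzero** values.
Two numerical decisions matter here:

* *Nonzero support.* Taken over all pixels, the percentile collapses to
  zero whenever fewer than $100-\gamma_j$ percent of pixels respond —
  always true for sparse scenes at $\gamma_1 = 99$ — and the stage stops
  thresholding anything. The nonzero convention mirrors the edge-stage
  noise floor and keeps the quota meaningful regardless of how much of
  the frame responds.
* *Soft step with an exact-zero tail.* Values below the gate are set to
  exactly zero; values at or above it are scaled by a logistic
  $H(\mathrm{LF} - thr)$ of steepness $k = 10/thr$, so $H(0) = 1/2$ and
  $k \to \infty$ recovers the hard threshold. A plain logistic never
  reaches zero, which would make "nonzero after thresholding" — the
  property the noise-suppression quota and the gap-closure checks rest
  on — vacuous. A pixel is called *activated* when its gate factor
  exceeds $1/2$.

Polarities recombine as $P - N$; orientations collapse through the
signed power pair
$T_j = \sum_\theta |\cdot|^{m_1}\mathrm{sign}(\cdot)$,
$T'_j = \mathrm{sign}(T_j)|T_j|^{1/m_1}$ (default $m_1 = 1$); scales
collapse by Lanczos-upsampling every $T'_j$ to full resolution and
applying the same power pair with $m_2 = 2$, weights $\tau_j = 1$ and
normalization $\gamma = 1/8$, yielding the compound texture image $TE$.
The inverse root is applied by default (it is what keeps the output on
the input intensity range, matching the explicit inverse in the
orientation step); the literal power is available as
`lf.literal_scale_power`. The $\tau_j$ weights are nowhere specified, so
the neutral choice 1 is used. The facilitation strength $a = 1$ ties the
additive signal's magnitude to the gain-controlled response that induces
it.

### 3. Blood-vessel ROI extraction

Per scale, the compound map is binarized by Otsu's threshold — computed
in-package over a 256-bin histogram by between-class-variance
maximization — applied to the map's **magnitude** by default. The
as-printed signed variant is available (`roi.use_magnitude = FALSE`) but
degenerates in practice: the signed maps are near-symmetric about zero
with a large zero background, so the threshold lands below zero and the
"foreground" becomes most of the frame. Magnitude thresholding marks the
strong-texture (vessel edge) pixels, which is what the ROI is for.

Each mask is morphologically closed with a disk of the scale's radius
(0, 2, 3, 4, 5, 5, 5, 6 px), capped at one eighth of the level's linear
size — a disk wider than that erases the level's spatial structure
outright on 8–16 px coarse levels. Only the largest 8-connected
component(s) survive. Masks are Lanczos-upsampled to full resolution,
re-binarized at 0.5 so all scales share one grid, fused by width-3
stride-1 sliding medians (8 scales give exactly 6 fused masks), summed
into a vote image, and thresholded at $\tau$ (default 0: the union, which
maximizes small-vessel retention).

### 4. Dynamic-range-balanced integration

The texture is masked by the ROI, split into polarities
$T_P = \max(0, T_{wb})$, $T_N = \max(0, -T_{wb})$, and blended:
$$IE = I + \alpha\left[\frac{T_P}{1+\beta I} -
\frac{T_N}{1+\beta-\beta I}\right], \qquad \alpha = 0.4,\; \beta = 4.$$
The divisors suppress brightening where the frame is already bright and
darkening where it is already dark. The formula can overshoot $[0,1]$;
the output is clipped and the clipped-pixel fraction reported (no
re-normalization rule is defined, and min–max rescaling would couple the
whole frame's brightness to a single extreme pixel). Outside the ROI the
output equals the input exactly. Frames of a cine run are processed
independently.

## The phantom generator

Clinical angiograms are not shipped; the test substrate is a seeded
synthetic phantom. It emulates, multiplicatively: a bright background
(0.65) under a smooth random illumination field (±15 %), broad
low-contrast Gaussian "bone" blobs (2 blobs, 8 % absorption), a recursive
branching vessel tree rendered as Gaussian-profile dark tubes (root
caliber 6 px tapering toward 1.2 px, 25 % peak absorption, depth 4), an
optional 1-px wire with marker dots, and Poisson quantum noise
`Poisson(photon_scale * I) / photon_scale` (default photon scale 2000;
dose reductions divide it). Ground truth includes the vessel and tool
masks and a background sample region at least 8 px away from any
structure and outside bone cores.

The contrast-to-noise ratio used throughout is
$\mathrm{CNR} = |\mu_{bg} - \mu_{vessel}| / \sigma_{bg}$, the common
angiography convention; published CNR-improvement figures use varying,
often unstated definitions, so comparisons are meaningful only within
one convention.

What the phantom does **not** emulate: cardiac and respiratory motion,
scatter and beam-hardening physics, 3-D foreshortening and vessel
overlap, detector blur, or the anatomical variety of real backgrounds.
Passing phantom tests shows the pipeline behaves as designed under the
modeled degradations, not that clinical image quality is improved —
that judgement belongs to readers of clinical data.

## Numerical choices

* All work is double precision; outputs are quantized only on write.
* Correlation uses FFT convolution with kernels flipped, after periodic
  mirror padding (well-defined even when the fixed 33-px kernel exceeds a
  coarse pyramid level, which it does by design).
* Edge responses below $10^{-12}$ are snapped to exact zero so flat
  frames are exact fixpoints of the whole pipeline.
* Percentiles use the type-1 (inverse empirical CDF) quantile, making
  thresholds attained data values with predictable strict-inequality
  behavior; argmax ties go to the lowest orientation index; component-size
  ties go to the earliest row-major anchor pixel.
* Lanczos-3 weights are row-normalized (constants are preserved exactly)
  with edge clamping; downsampling widens the kernel by the scale factor.
* Test and acceptance problem sizes: 256×256 phantoms (the pipeline then
  holds 6 pyramid levels; the coarsest level is kept at or above 8 px),
  20 seeds per dose condition, and 256×256 two-bar fixtures for the
  line-completion checks. These sizes exercise every stage, including the
  coarse-scale fusion, while keeping the suite quick to run.

## Known limitations

* Enhanced texture is applied wherever the multiscale ROI votes, and the
  ROI deliberately favors recall; bone edges inside it get enhanced too,
  which can inflate background variance on some frames — the familiar
  bony-artifact drawback of this enhancement family.
* The perpendicular-bar control of the line-completion property is
  contaminated at close range: a finite crossing bar's end caps carry
  genuine energy at the probed orientation, which collinearly facilitates
  with the probed line near the junction. With facilitation disabled the
  control is exactly zero.
* DICOM input is not supported (no R reader available); PNG and 8/16-bit
  TIFF are.
* No temporal (inter-frame) processing of any kind.
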