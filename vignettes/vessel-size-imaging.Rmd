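---
title: "Vessel size imaging from dual-echo DSC-MRI: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vessel size imaging from dual-echo DSC-MRI: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vsimri)
```

## The measurement

During the first pass of a gadolinium bolus, paramagnetic contrast agent
transiently raises the transverse relaxation rates of tissue water. A
hybrid echo-planar acquisition records a gradient-echo (GRE) and a
spin-echo (SE) signal simultaneously at every repetition time. The two
echoes see the vasculature differently: the GRE response ($\Delta R_2^*$)
is sensitive to vessels of all calibers, while the SE response
($\Delta R_2$) peaks at capillary scale. Their ratio therefore carries
information about mean vessel size, which the Kiselev model turns into a
per-voxel estimate.

The pipeline implements, per voxel:

1. **Relaxometry.** With $S(0)$ the pre-bolus baseline mean,
   $$\Delta R_2^*(t) = -\tfrac{1}{TE_{GRE}}\ln\tfrac{S_{GRE}(t)}{S_{GRE}(0)},
   \qquad
   \Delta R_2(t) = -\tfrac{1}{TE_{SE}}\ln\tfrac{S_{SE}(t)}{S_{SE}(0)}.$$
2. **Blood volume.** Trapezoidal integration over the first-pass window
   $[t_0, t_1]$ gives raw CBV (from $\Delta R_2^*$) and microvascular CBV
   (from $\Delta R_2$). Both are normalized by their mean over
   contralateral normal-appearing white matter (NAWM), and CBV is
   additionally rescaled so that its NAWM median equals 3.2% blood
   volume, the literature white-matter value.
3. **Vessel size.**
   $$VS = 0.867\,\sqrt{CBV \cdot ADC}\;
   \frac{\Delta R_2^{*\max}}{(\Delta R_2^{\max})^{3/2}},$$
   with CBV as a unitless fraction (3.2% enters as 0.032), ADC in
   $\mu m^2/s$ and the peak rates in $s^{-1}$. This is the only unit
   convention under which the expression is dimensionally a length in
   micrometres, and it is the convention the package fixes.

No contrast-leakage correction is applied anywhere; the pipeline targets
non-enhancing tumors where leakage is negligible by inclusion.

## Quality control

Frames 1–4 are discarded to reach steady state (`trimInitial`). The
baseline window is every remaining frame before the known injection frame
(bolus given 20 TRs after the acquisition start), and baseline SD uses the
$n-1$ divisor — both fixed so tests can be bit-exact. A voxel survives
`qcFilter` only if the bolus drops its signal by at least 2 baseline
standard deviations **on both echoes**, and its signal stays positive
wherever the log-ratio is evaluated. Excluded voxels carry reason codes
and propagate as missing values into every downstream map and ROI
statistic — never as zeros, which would bias means.

One property of the 2-SD rule is worth knowing: with no bolus at all, the
expected extreme of $n$ post-injection noise frames grows like
$\sqrt{2\ln n}$ SD, so over a long acquisition (~100 frames) a majority of
pure-noise voxels *pass* the rule. The rule is a guard against weak bolus
response, not a noise detector; the test suite exercises its intended
regime on short windows.

## Bolus-window detection

The entrance and exit times $t_0, t_1$ are found once, globally: the
$\Delta R_2^*$ curve is averaged over the valid tumor+NAWM voxels, and the
window extends outward from the peak to the last frames at or above a
fraction of the peak value. The default fraction is **1% of peak**. The
choice matters more than it looks: for a gamma-variate (or any
near-Gaussian) first pass, the mass lying above 10% of the peak saturates
at about 96.8% no matter how sharp the bolus is, so a 10% cutoff
systematically clips 3–4% from every CBV integral. At 1% the window holds
over 99% of the analytic bolus mass and the frame-resolution trapezoid
reproduces the closed-form gamma-variate integral to 0.4%. Averaging over
thousands of mask voxels keeps the mean curve's noise floor two orders of
magnitude below this threshold at realistic SNR. The normalization step
divides the window choice out of normalized CBV entirely; it matters only
for the (also ratio-based) vessel-size map through the peak rates, which
are window-insensitive.

## The digital phantom

No patient data ship with the package, so every stage is validated
against `simulateDsc`, a block-geometry phantom (equal-width tissue slabs
across 15 slices, matching a partial-brain acquisition) with known ground
truth. The forward model inverts the relaxometry equations exactly:

$$\Delta R_2^*(t) = A\,\mathrm{cbv}\,C(t), \quad
  \Delta R_2(t) = A\,\mathrm{ucbv}\,C(t), \quad
  S(t) = S(0)\,e^{-TE\,\Delta R(t)} + \varepsilon,$$

with $C(t)$ a unit-peak gamma-variate
$((t-t_a)/\alpha\beta)^\alpha e^{\alpha-(t-t_a)/\beta}$ and $\varepsilon$
additive Gaussian noise (Rician optional; the Gaussian default keeps the
log-ratio inversion exact in expectation at high SNR). Defaults mirror the
acquisition the pipeline targets: TR 1.5 s, TE 18.6/69 ms, 120 frames,
bolus arrival 20 TRs in, $\alpha = 3$, $\beta = 3$ frames (time-to-peak
9 frames ≈ 13.5 s), amplitude $A = 400\,s^{-1}$ per unit blood-volume
fraction, which puts the NAWM peak $\Delta R_2^*$ at a plausible
10 $s^{-1}$. Recirculation is off by default so the closed-form integral
$e^\alpha \beta\, \Gamma(\alpha+1) / \alpha^\alpha$ is exact for recovery
tests; a delayed scaled copy can be enabled.

The five default tissue classes (NAWM, grey matter, three tumor types
spanning low/high blood volume) carry CBV fractions 0.025–0.06, ADC
700–1300 $\mu m^2/s$, and truth vessel sizes **derived self-consistently**
by pushing the class constants through the Kiselev formula
(`impliedVesselSize`), so the recovered vessel-size ranking must match the
truth ranking by construction rather than by luck.

```{r phantom}
ph <- simulateDsc(gridShape = c(20L, 10L, 4L), noiseSd = 0, seed = 1)
ph
```

What the phantom does **not** emulate: realistic anatomy, partial-volume
mixing at class borders, motion, $B_0$ inhomogeneity, contrast
extravasation, arterial input variability, and slice gaps. Passing the
recovery tests therefore demonstrates that the estimator chain is correct
and self-consistent — not that it is robust to those physical effects.

## ROI summaries

`summarizeRoi` reports mean, median and a hot-spot value over valid tumor
voxels. The hot spot is the mean of all voxels at or above the 90th
percentile (threshold inclusive, read as "top decile"), pooled across all
supra-threshold clusters together; the cluster count (26-connectivity
connected components in 3D) is reported but never changes the value.
Percentiles interpolate linearly between order statistics (R type 7), the
convention under which the worked 1…100 example is exactly reproducible.

## Histology morphometry

`segmentVessels` deliberately keeps segmentation simple and fully
documented: Otsu threshold, morphological opening (disc radius 1 px),
hole filling, connected components, minimum-area filter. Because Otsu
always splits a histogram, a contrast guard (default 0.1 on the [0, 1]
intensity scale) returns zero objects on blank or noise-only images
rather than speckle.

Per object: area, equivalent radius $\sqrt{area/\pi}$, and roundness
$P^2 / 4\pi A$ — inverse circularity, 1 for a circle, larger for
elongated or crenated profiles. The perimeter $P$ uses a Kulpa-weighted
chain code (axis steps × 0.948, diagonal steps × 1.340): a raw pixel-edge
count overestimates a disk's perimeter by ~27% and would push disk
roundness to ~1.6. Calibration on rasterized shapes: a radius-50 disk
measures 0.990, a 2:1 ellipse matches the Ramanujan-perimeter oracle
(≈1.19) within 0.011. The opening erodes diagonal boundary staircases and
biases roundness of smooth convex objects about −2%; at the default
settings a segmented radius-50 disk reports 0.97. Both effects sit within
the ±0.02-per-source discretization tolerance quoted for objects of
≥40 px diameter; below that the bands widen.

Two-ROI pooling follows field practice: density = pooled stained area /
pooled ROI area (%), radius and roundness = unweighted means over all
objects from both ROIs.

## Group statistics

`compareGroups` implements the normality-gated decision tree. Shapiro–Wilk
runs per group; only if **every** group is consistent with normality
(all $p > \alpha$, default 0.05) does the comparison use one-way ANOVA,
followed by Tukey HSD when the omnibus test is significant. Otherwise it
uses Kruskal–Wallis followed by Dunn's test with tie-corrected rank
variance and Bonferroni correction over the three pairs. The all-groups
gate is the conservative reading of "normality of each subtype was
examined", and it is declared rather than implicit. A constant-valued
group (Shapiro–Wilk undefined) is flagged and routed to the rank branch.
Parameters (CBV, µCBV, vessel size) are tested independently; no
correction is applied across parameters.

```{r stats}
compareGroups(list(Oligo = c(1, 2, 3), Astro = c(2, 3, 4), GBM = c(3, 4, 5)))
```

## Numerical conventions, in one place

- Sample SD: $n-1$ divisor.
- Percentile: R `quantile` type 7; hot-spot threshold inclusive (≥).
- Bolus window: 1% of mean-curve peak, contiguous around the peak.
- Integration: trapezoid at TR spacing; negative excursions integrated
  as-is (no clipping — normalization is relative).
- Invalid voxels: `NA` sentinel with reason codes, excluded from every
  statistic; never zero-filled.
- Vessel-size units: CBV fraction × $\mu m^2/s$ × $s^{-1}$ powers ⇒ µm.
- Clusters: 26-connectivity in 3D.
- Perimeter: Kulpa weights on the traced 8-connected contour.
- RNG: single integer seed per simulation; bit-reproducible outputs.

## Problem sizes used by the test suite

Unit and property tests run on 5–64 voxel-wide phantoms; the end-to-end
recovery check uses the full acquisition geometry (64 × 64 × 15 voxels,
120 frames, of which 116 are analysed after trimming) noiselessly and at
SNR 50, recovering programmed NAWM-relative CBV and µCBV ratios within 2%
and 5% respectively. The null-calibration of the statistics module uses
1000 seeded replicates of 3 × 12 Gaussian samples and checks the omnibus
rejection rate against 0.05 ± 0.02.

## Known limitations

- The proportionality constants linking blood-volume fraction to peak
  relaxation-rate change in the phantom are conventions; absolute raw CBV
  has no physical calibration until the NAWM normalization/scaling step,
  which is exactly why the pipeline normalizes.
- The global bolus window assumes a single dominant first pass; severe
  dispersion or double-peaked input functions would need per-voxel
  windows.
- ADC units are the caller's responsibility (declared in the study
  config); the vessel-size map is only meaningful with ADC in
  $\mu m^2/s$.
- Segmentation is intensity-based and will undersplit touching vessel
  profiles; the slide simulator only generates disjoint profiles, so this
  limit is untested by construction.
- Slice gaps are ignored in volume statistics.
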