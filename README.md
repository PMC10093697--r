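# vsimri — vessel size imaging from dual-echo DSC-MRI

`vsimri` turns simultaneously acquired gradient-echo / spin-echo dynamic
susceptibility contrast (DSC) MRI time series into quantitative maps of
cerebral blood volume (CBV), microvascular CBV (µCBV) and mean vessel
size, and carries the results through tumor-ROI summaries and three-group
statistics. It is aimed at perfusion-MRI researchers studying glioma
microvasculature — in particular the non-enhancing adult-type diffuse
glioma subtypes (Oligo, Astro, GBM) — and at anyone who needs a tested,
reproducible reference implementation of the vessel-size-imaging chain.
A companion histology module quantifies vessel density, radius and
roundness on stained-slide images for MRI–histology comparison.

## The model

Per voxel, with $S(0)$ the pre-bolus baseline mean:

$$\Delta R_2^*(t) = -\frac{1}{TE_{GRE}}\ln\frac{S_{GRE}(t)}{S_{GRE}(0)},
\qquad
\Delta R_2(t) = -\frac{1}{TE_{SE}}\ln\frac{S_{SE}(t)}{S_{SE}(0)}$$

$$CBV = \int_{t_0}^{t_1}\!\Delta R_2^*(t)\,dt,
\qquad
\mu CBV = \int_{t_0}^{t_1}\!\Delta R_2(t)\,dt$$

Both integrals (trapezoidal, over the detected first-pass window) are
normalized to their mean over contralateral normal-appearing white matter
(NAWM); CBV is further scaled so its NAWM median equals 3.2% blood
volume. Mean vessel size then follows the Kiselev model:

$$VS = 0.867\,\sqrt{CBV \cdot ADC}\;
\frac{\Delta R_2^{*\max}}{(\Delta R_2^{\max})^{3/2}}
\quad [\mu m],$$

with CBV a unitless fraction, ADC in µm²/s and peak rates in 1/s. Voxels
whose bolus signal drop is under 2 baseline standard deviations on either
echo are excluded up front and stay missing (`NA`) throughout.

Because no patient data ship with the package, a digital phantom
(`simulateDsc`, `simulateSlide`) generates dual-echo series, ADC maps,
masks and stained slides with known ground truth; every stage is tested
against it.

## Worked example

Simulate a noisy five-class phantom (SNR ≈ 50), run the map chain, and
summarize the tumor ROI:

```r
library(vsimri)

ph <- simulateDsc(gridShape = c(32L, 16L, 6L), noiseSd = 17, seed = 1)
ph
#> PhantomOutput (seed 1): 5 tissue classes
#>    label   cbv  ucbv vesselSize  adc
#>     NAWM 0.025 0.005  14.507685  700
#>       GM 0.055 0.013  12.071690  800
#>  tumor-A 0.060 0.016  11.812378 1100
#>  tumor-B 0.045 0.009  18.995018 1200
#>  tumor-C 0.050 0.018   8.186759 1300

s  <- trimInitial(ph@series, 4)              # discard non-steady-state frames
b  <- estimateBaseline(s)
v  <- qcFilter(s, b)                         # 2-SD drop rule, both echoes
cu <- toRelaxation(s, b, v)                  # dR2*(t), dR2(t) in 1/s
w  <- detectBolusWindow(cu, mask = ph@tumorMask | ph@nawmMask)
maps <- computeParamMaps(cu, w, ph@adc, ph@nawmMask)
maps
#> ParamMaps on a 32 x 16 x 6 grid
#>   valid voxels: 3072 / 3072
#>   vessel size (valid): median 11.72 um

summarizeRoi(vesselSize(maps), ph@tumorMask, maps@validity, parameter = "VesselSize")
#>   parameter     mean   median  hotspot nValidVoxels nHotspotVoxels nClusters
#>  VesselSize 12.23908 11.31078 20.43408         1824            183         1
```

The tumor mask pools the three tumor slabs (true vessel sizes 11.8, 19.0
and 8.2 µm), so the ROI mean of 12.2 µm sits where the class mixture puts
it, and the hot spot (mean of the top decile, 183 voxels in 1 connected
cluster) is dominated by the largest-vessel class. The normalized CBV
mean over the same ROI recovers the programmed tumor-to-NAWM blood-volume
ratio (classes 2.4×, 1.8×, 2.0× → ROI mean ≈ 2.05).

Three-group comparison uses the normality-gated decision tree
(Shapiro–Wilk → ANOVA/Tukey or Kruskal–Wallis/Dunn–Bonferroni):

```r
compareGroups(list(Oligo = c(1, 2, 3), Astro = c(2, 3, 4), GBM = c(3, 4, 5)))
#> GroupComparison: parameter
#>   groups: Oligo (n=3), Astro (n=3), GBM (n=3)
#>   omnibus: one-way ANOVA F = 3 , p = 0.125
#>   no post hoc (omnibus p > 0.05 or not requested)
```

End-to-end study runs (`runSubject`, `runStudy`) read a YAML config with
per-subject NIfTI paths and subtype labels, write maps, per-subject ROI
summaries and a group-comparison CSV; `inst/cli/vsimri.R` wraps the same
functions for shell use.

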