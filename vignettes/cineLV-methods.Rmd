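---
title: "Left-ventricular volumetry from cine MRI: models, phantom, and cohort statistics"
author: "cineLV"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Left-ventricular volumetry from cine MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cineLV)
```

# The measurement problem

Preclinical hypertrophy studies track how the left ventricle (LV) of a
mouse remodels under a pressor challenge such as chronic angiotensin II
(AngII) infusion, and whether a candidate treatment (here the decoy receptor
sRAGE) attenuates that remodeling. Short-axis cine MRI makes this possible
longitudinally: a movie of the beating heart is acquired on a stack of
1-mm slices perpendicular to the long axis, and six parameters are read off
per exam — end-diastolic and end-systolic cavity (blood) volume (EDbv,
ESbv), end-diastolic myocardial volume and mass (EDmv, EDmw), ejection
fraction (EF) and mean wall thickness at end-diastole (LVWT).

`cineLV` implements this measurement chain, a synthetic beating-LV phantom
with closed-form ground truth so that every stage can be validated without
animal data, a cohort simulator that reproduces the published group-level
summary statistics of a four-group AngII/sRAGE design, and the statistical
layer such a study uses.

# The volumetric model

Within a per-slice LV region of interest (ROI, cavity plus myocardium) the
bright blood pool is separated from the darker myocardium by signal
intensity. Writing $A_{LV}$ and $A_b$ for the ROI and blood areas of slice
$n$ and $t$ for the slice thickness, disc (Simpson) summation gives

$$\mathrm{blood\ volume} = \sum_n A_{b,n}\, t, \qquad
  \mathrm{myocardial\ volume} = \sum_n (A_{LV} - A_b)_n\, t,$$

myocardial mass is $\rho \sum_n (A_{LV}-A_b)_n t$ with myocardial density
$\rho = 1.05$ g/mL (so a volume in mm³ maps to mass in mg with factor
1.05), and

$$\mathrm{EF}(\%) = \frac{\mathrm{EDbv} - \mathrm{ESbv}}{\mathrm{EDbv}}
  \times 100 .$$

End-diastole is the cine frame whose blood area, summed over all slices, is
largest; end-systole the frame where it is smallest. The all-slice sum
yields one coherent cardiac phase per exam; a per-slice variant
(`selectEdEs(..., perSlice = TRUE)`) is available since acquisitions are
sometimes analysed that way. Ties break to the lowest frame index, and a
series with no frame-to-frame variation is flagged with a degenerate-motion
warning.

Wall thickness is measured on one ED short-axis slice (by default the
mid-ventricular slice, i.e. the slice with the largest ED blood area) by
casting ten rays from the blood-pool centroid at 36° spacing, starting at
the image +x axis. Each ray's thickness is the distance from the
endocardial crossing (where the blood mask is left) to the epicardial
crossing (where the ROI is left); crossings are located with subpixel
precision by sampling the mask bilinearly every 0.25 px and interpolating
the 0.5-level crossing linearly. The mean of the ten rays is reported in
µm. A ray that reaches the image border while still inside the ROI is an
error naming the angle, since its epicardial crossing would be an artifact
of the field of view.

Internally all lengths are mm (volumes mm³, masses mg); LVWT is reported in
µm. Report rounding is one decimal, half away from zero — the convention of
published parameter tables.

## Segmentation

The intensity separation is Otsu's threshold computed per (phase, slice)
from the ROI intensities alone, followed by restriction to the largest
4-connected component and filling of interior holes, so disconnected bright
artifacts and speckle holes do not enter the area. A fixed threshold can be
substituted (`method = "fixed"`) for data where an automatic threshold is
not wanted. A non-empty ROI with constant intensity is an error (no
threshold separates one level), and the blood mask is a subset of the ROI
by construction, so $A_b \le A_{LV}$ always holds.

# The phantom

The synthetic LV is a half prolate ellipsoid of bright blood, truncated
flat at the base plane, inside a myocardial shell. Both the endocardial and
epicardial surfaces are half-ellipsoids sharing the base and apex planes;
the wall therefore thins toward the apex, as a real LV does, and every
short-axis slice through the phantom shows both cavity and muscle. The
closed forms are

$$V_{\mathrm{cavity}} = \tfrac{2}{3}\pi a^2 c, \qquad
  V_{\mathrm{shell}} = \tfrac{2}{3}\pi\,(R^2 - a^2)\,c,$$

with $a$ the equatorial endocardial radius, $R = a + w$ the epicardial
radius ($w$ the wall thickness) and $c$ the apex-to-base length.
Contraction follows

$$a(\varphi) = a_{ES} + (a_{ED} - a_{ES})
  \frac{1 + \cos(2\pi\varphi/n_{\mathrm{phases}})}{2},$$

so frame 1 is exactly ED and frame $n/2 + 1$ exactly ES, and the epicardial
radius is adjusted per frame to conserve the shell volume (incompressible
myocardium): $R(\varphi)^2 = a(\varphi)^2 + R_{ED}^2 - a_{ED}^2$.

Voxelization is centre-of-pixel membership on a grid whose origin lies at
the symmetric centre of the matrix, with slices sampled at their centres.
The generated ROI emulates an analyst's annotation: a (phase, slice) cell
whose cavity voxelizes to zero pixels (an unresolvably small end-systolic
cavity on the apex slice) is left un-delineated, exactly as a rater skips a
slice with no visible cavity; the rendered image is unaffected.

Noise, when enabled, is Rician — the law of magnitude-reconstructed MRI:
$I = \sqrt{(I_0 + n_1)^2 + n_2^2}$, $n_{1,2} \sim N(0, \sigma)$. With the
default signal levels (blood 1000, myocardium 400, background 50),
$\sigma = 50$ gives blood SNR ≈ 20.

## Default geometry

The acquisition grid follows a 9.4T mouse protocol: 256 × 256 matrix at
0.125 mm in-plane, 1-mm slices, 35 cine frames. The LV dimensions were
chosen once to be realistic for a healthy adult C57BL/6 mouse and match the
scale of the published group means: length 6 mm, ED endocardial radius
2.0 mm, ES radius 1.05 mm, wall 0.85 mm. These give EDbv ≈ 50.3 mm³,
EF ≈ 72.4 %, EDmv ≈ 51.8 mm³ and LVWT = 850 µm — cavity volume, EF and wall
thickness in the reported healthy range (the shell volume of the idealized
two-surface shape sits somewhat below a real LV's muscle volume, which has
an apical cap and papillary muscle this geometry deliberately omits).

`solvePhantomGeometry()` inverts the closed forms: given target EDbv, ESbv
and EDmv it returns the radii and wall (at fixed length) whose analytic
truth matches those volumes exactly, which is how `phantomCohort()` turns
each simulated animal into an image-level test case.

## Discretization behaviour

Two discretization errors combine in a measured volume:

* the **slice-summation error** of the midpoint disc rule, which decreases
  like $O(t^{3/2})$ (the exponent is limited by the square-root shape of
  the apex) and is strictly monotone in the slice thickness when computed
  on exact areas;
* the **pixelation error** of the per-slice areas, a lattice-counting
  (Gauss-circle) term of a few tenths of a percent at 0.125-mm pixels whose
  sign oscillates erratically with the radius-to-pixel ratio.

At the paper's fixed pixel size the pixelation term dominates below
t ≈ 1 mm, so convergence properties are asserted on the component the
refinement actually controls: slice refinement on the disc-summation error
of analytic areas, and pixel refinement on the summed per-slice
$|A_{\mathrm{vox}} - A_{\mathrm{exact}}|$, which decreases strictly over
0.25 / 0.125 / 0.0625 mm. The full-chain accuracy bounds (volumes within
5 %, EF within 3 points, LVWT within one pixel) are asserted at the paper
geometry directly; the noise-free full chain lands well inside them
(EDbv 0.16 %, EDmv 0.86 %, EF 0.08 points, LVWT 11 µm).

# The cohort simulator

`simulateCohort()` draws per-animal values of the six parameters at both
timepoints from normal distributions with the published group × timepoint
means and SDs (four groups: saline n = 10, AngII n = 9, sRAGE n = 10,
AngII+sRAGE n = 10), truncated at zero (EF also below 100) by rejection —
redrawing, not clipping, so no point mass accumulates at the bounds.

Within-animal structure uses a single animal-level standard normal $z$,
drawn once per animal and applied to every parameter and both timepoints:

$$v = \mu + \sigma\left(\sqrt{\rho}\, z + \sqrt{1-\rho}\; e\right),
  \qquad e \sim N(0, 1) \text{ independent.}$$

Each marginal keeps exactly the specified SD, each parameter's pre/post
correlation is $\rho$ (default 0.8 — the published summaries do not
constrain it, so this is a configurable stand-in encoding strong tracking
of an animal's own baseline), and the shared $z$ makes the drawn volumes of
one animal mutually consistent: an animal that runs large runs large in
EDbv and ESbv alike, so the implied phantom geometry is always valid.
Rejection redraws the whole animal, which preserves this joint structure.

Two caveats follow from the truncation. For cells whose normal has
negligible mass below zero the simulated means match the specification to
Monte-Carlo accuracy; for the one heavy-truncation cell of the reference
table (post-AngII ESbv, 26.3 ± 18.2 mm³, ≈ 7 % mass below zero) the
truncated mean sits visibly above the nominal one — an unavoidable property
of positivity-constrained sampling that the tests assert rather than hide.
Note also that EDmw is drawn from its own published distribution rather
than derived as 1.05 × EDmv, because the published table itself reports
per-group means that are not exactly in that ratio (both being averages of
rounded per-animal values); phantom ground truth, by contrast, enforces the
ratio exactly.

Animal-level covariates emulate the post-mortem measurements: heart weight
HW = 1.0 × EDmw + 40 mg + N(0, 12.6) and cross-sectional area
CSA = 1.7 × EDmv − 50.6 % + N(0, 24), calibrated once so the cohort-level
correlations are ≈ 0.79 (HW vs EDmw) and ≈ 0.73 (CSA vs EDmv), the
strengths reported for the MRI-histology comparison; body weight is an
independent N(26, 1.5) g.

# The statistical layer

* **Pre vs post within a group**: Student's t-test, paired on per-animal
  differences (the same animals are imaged twice); an unpaired Welch
  variant is available since the published methods do not state the
  pairing. All-zero differences are reported as "no change" (p = 1) rather
  than an undefined statistic.
* **Between groups**: one-way ANOVA followed by all pairwise comparisons
  with the pooled within-group SD (the classic Bonferroni procedure; Welch
  pairwise via `poolSd = FALSE`), the raw p multiplied by the number of
  pairs (6 for four groups) and capped at 1. Significance of pairwise rows
  uses the adjusted p at α = 0.05.
* **Delta analysis**: per-animal Δ = post − pre compared between groups
  through the same machinery — the analysis in which treatment effects on
  progression are most visible, since each animal is its own baseline.
* **Regression**: OLS with Pearson r and its two-sided p, and pointwise
  95 % bands — confidence $t\,s\sqrt{1/n + (x-\bar x)^2/S_{xx}}$ and
  prediction $t\,s\sqrt{1 + 1/n + (x-\bar x)^2/S_{xx}}$ — via
  `lm()`/`predict()`. The prediction band strictly contains the confidence
  band and both are symmetric about the fit.
* Sample SDs use the n − 1 denominator; every simulation routine takes an
  explicit seed.

The suite calibrates this layer against independent oracles: the paired
test against exact sign-flip enumeration (all $2^8$ flips at n = 8), the
ANOVA F p against 10 000 label permutations, type-I error at n = 10 over
2000 null cohorts (observed ≈ 0.046), Bonferroni family-wise error under
the global four-group null (observed ≈ 0.03, conservative as expected), and
prediction-band coverage (≈ 0.95).

# What the tests do and do not show

The phantom validates the geometry-to-number chain: disc summation, ED/ES
selection, threshold segmentation and ray casting, with exactly known
truth. It deliberately omits papillary muscles and trabeculation, flow and
motion artifacts, partial-volume fading at basal/apical slices,
through-plane motion, non-circular cross-sections, receive-coil intensity
bias, and rater variability in the manual ROIs — so a passing suite
demonstrates correctness of the computation, not accuracy on real scans.
Likewise the cohort simulator reproduces group summary statistics, not
per-animal biology; the published per-animal raw values, the histology R²
(0.63) and CSA percentages are not recoverable from group summaries, so
those stages are validated as parameter-recovery and band-coverage
properties at the study's sample size (n = 39) instead.

Problem sizes used by the suite were chosen to keep the full run fast while
exercising the paper-scale geometry where it matters: module tests use
64–128-px phantoms with 2–10 frames; the acceptance layer runs the
256 × 256 × 35-frame geometry, 20 noise replicates for segmentation
fidelity, 2000 null replicates for calibration, and 500 cohort replicates
for the effect-direction rates.

# Reproducibility

Every stochastic routine takes an explicit integer seed; no hidden global
state is consulted. `runPipeline()` writes all artifacts plus a manifest
(config echo, package and R version, output inventory), and a rerun with
the same config and seed reproduces every CSV byte-identically. Numeric
CSVs are serialized at 17 significant digits, which round-trips doubles
exactly. NIfTI stacks round-trip exactly (float64 with spacings in
`pixdim`); multi-page TIFF stores float32 normalized to [0, 1] with the
scale and geometry in a JSON sidecar, so its round-trip is exact to ~1e-7
relative — the NIfTI path is the lossless one.
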