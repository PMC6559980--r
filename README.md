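# cineLV

Left-ventricular (LV) volumetry and cohort statistics for short-axis
cardiac CINE-MRI, aimed at preclinical hypertrophy studies — e.g. tracking
whether chronic angiotensin II (AngII) infusion enlarges the mouse LV and
whether a treatment such as soluble RAGE (sRAGE) attenuates the remodeling.

From a 4D cine stack (phase × slice × row × col, with voxel spacing
metadata) and per-slice LV regions of interest, the package measures the
six standard parameters per exam:

- blood-pool separation by signal intensity (per-slice Otsu within the ROI,
  largest 4-connected component, holes filled);
- end-diastole/end-systole selection as the cine frames with the
  largest/smallest all-slice blood area;
- disc (Simpson) summation: blood volume `Σ A_b·t`, myocardial volume
  `Σ (A_LV − A_b)·t`, mass `1.05 · Σ (A_LV − A_b)·t` (ρ = 1.05 g/mL);
- ejection fraction `EF(%) = (EDbv − ESbv)/EDbv × 100`;
- mean LV wall thickness from ten radial rays on the ED mid-ventricular
  slice, with subpixel boundary localization.

Because no public per-animal data accompany such studies, the package
ships a synthetic beating-LV phantom (half-ellipsoid cavity in an
incompressible myocardial shell, voxelized on the 256 × 256 / 0.125 mm /
1 mm / 35-frame acquisition grid, optional Rician noise) whose six
parameters are known in closed form, plus a cohort simulator reproducing
published group summary statistics with configurable within-animal pre/post
coupling and correlated heart-weight / histology covariates. The
statistical layer provides paired pre/post t-tests, four-group ANOVA with
Bonferroni-corrected pairwise comparisons, per-animal delta analysis, and
OLS regression with 95% confidence and prediction bands.

## Worked example

```r
library(cineLV)

ph  <- generatePhantom(PhantomSpec())     # paper-geometry phantom, noise-free
ph$truth
#> PhantomTruth: EDbv 50.265 / ESbv 13.854 mm^3, EDmv 51.805 mm^3, EDmw 54.395 mg
#>   EF 72.44%, LVWT 850.0 um

computeParams(ph$stack, ph$roi)           # segment -> ED/ES -> volumetry
#> CardiacParams: EDbv 50.2 / ESbv 13.9 mm^3, EDmv 52.2 mm^3, EDmw 54.9 mg
#>   EF 72.4%, LVWT 838.9 um (ED phase 1, ES phase 17)
```

The measured chain recovers the analytic truth within 0.2% (EDbv), 0.9%
(EDmv), 0.1 EF points and 11 µm of wall thickness at this geometry. The
cohort layer:

```r
tab <- simulateCohort(cohortSpec(seed = 1L))   # 4 groups, pre+post, n=39
head(summarizeCohort(tab)[, c(1:5, 10)], 4)
#>    group timepoint  n EDbv_mean EDbv_sd EDmw_mean
#> 1 saline       pre 10      42.8     3.1      77.9
#> 2 saline      post 10      44.8     4.7      90.9
#> 3  AngII       pre  9      46.5     3.0      75.5
#> 4  AngII      post  9      70.3    19.6     113.0

deltaAnalysis(tab, "EDmw")[2, c("groups", "p_value", "adjusted_p", "significant")]
#>              groups  p_value adjusted_p significant
#> 2 AngII|AngII+sRAGE 8.15e-04    4.89e-03       TRUE
```

With this seed the simulated cohort shows the expected pattern: AngII
roughly doubles the gain in myocardial mass relative to saline, and the
per-animal ΔEDmw of the AngII+sRAGE group is significantly below that of
AngII after Bonferroni correction — the attenuation signal the delta
analysis is designed to expose. `runPipeline(pipelineConfig(...))` chains
simulate → segment → measure → stats into a run directory with a manifest,
byte-reproducible under a fixed seed.

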