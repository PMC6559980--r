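Package: cineLV
Title: Left-Ventricular Volumetry and Cohort Statistics for Cardiac
    CINE-MRI
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying left-ventricular (LV) anatomy and
    function from short-axis cardiac CINE-MRI stacks, aimed at preclinical
    (mouse) hypertrophy studies. Provides intensity-based blood-pool
    segmentation within an LV region of interest, end-diastole/end-systole
    phase selection, Simpson disc-summation blood and myocardial volumes,
    myocardial mass (density 1.05 g/mL), ejection fraction, and radial
    ten-ray wall-thickness measurement. Includes a synthetic beating-LV
    phantom with analytically known parameters, a cohort simulator
    reproducing published group summary statistics, and the accompanying
    statistical layer: paired pre/post t-tests, four-group ANOVA with
    Bonferroni-corrected pairwise comparisons, per-animal delta analysis,
    and linear regression with 95 percent confidence and prediction bands.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    RNifti,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
biocViews: Software, Visualization, CellBiology
Config/testthat/edition: 3
RoxygenNote: 7.3.3
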