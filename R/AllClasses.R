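#' @import methods
NULL

#' CineStack: a 4D short-axis cine image stack
#'
#' Container for a cardiac cine acquisition: a 4D intensity array indexed as
#' (phase, slice, row, col) together with the in-plane pixel spacing and the
#' slice thickness. All lengths are stored in millimetres; in-plane spacing is
#' assumed isotropic (row spacing equals column spacing). Voxel indices are
#' interpreted with a pixel-centre coordinate convention.
#'
#' @slot intensities numeric 4D array, dimensions (phase, slice, row, col);
#'   finite and non-negative.
#' @slot pixelSpacing in-plane pixel spacing in mm.
#' @slot sliceThickness slice thickness in mm.
#'
#' @seealso [readStack()], [writeStack()], [generatePhantom()]
#' @export
setClass("CineStack",
  representation(
    intensities    = "array",
    pixelSpacing   = "numeric",
    sliceThickness = "numeric"
  )
)

setValidity("CineStack", function(object) {
  msgs <- character()
  d <- dim(object@intensities)
  if (length(d) != 4L)
    msgs <- c(msgs, "intensities must be a 4D array (phase, slice, row, col)")
  if (length(object@pixelSpacing) != 1L || !is.finite(object@pixelSpacing) ||
      object@pixelSpacing <= 0)
    msgs <- c(msgs, "pixelSpacing must be a single positive number (mm)")
  if (length(object@sliceThickness) != 1L ||
      !is.finite(object@sliceThickness) || object@sliceThickness <= 0)
    msgs <- c(msgs, "sliceThickness must be a single positive number (mm)")
  if (anyNA(object@intensities) || any(!is.finite(object@intensities)))
    msgs <- c(msgs, "intensities must be finite")
  else if (any(object@intensities < 0))
    msgs <- c(msgs, "intensities must be non-negative")
  if (length(msgs)) msgs else TRUE
})

#' MaskStack: a boolean mask aligned with a CineStack
#'
#' Boolean 4D array aligned voxel-for-voxel with a [CineStack-class].
#' The label records what the mask delineates: `"lv_roi"` for the whole-LV
#' region of interest (cavity plus myocardium) or `"blood"` for the bright
#' blood pool. A blood mask is expected to be a subset of its ROI mask.
#'
#' @slot mask logical 4D array, dimensions (phase, slice, row, col).
#' @slot label character, one of `"lv_roi"`, `"blood"`.
#'
#' @export
setClass("MaskStack",
  representation(mask = "array", label = "character")
)

setValidity("MaskStack", function(object) {
  msgs <- character()
  if (length(dim(object@mask)) != 4L)
    msgs <- c(msgs, "mask must be a 4D array (phase, slice, row, col)")
  if (!is.logical(object@mask))
    msgs <- c(msgs, "mask must be logical")
  if (length(object@label) != 1L || !object@label %in% c("lv_roi", "blood"))
    msgs <- c(msgs, "label must be one of 'lv_roi', 'blood'")
  if (length(msgs)) msgs else TRUE
})

#' PhantomSpec: parametric geometry of the synthetic beating LV
#'
#' The synthetic left ventricle is a half prolate ellipsoid (truncated flat at
#' the base plane, long axis perpendicular to the slices) surrounded by a
#' myocardial shell. Endocardial equatorial radius varies sinusoidally over
#' the cardiac cycle between its end-diastolic value (phase 1) and its
#' end-systolic value (phase `nPhases/2 + 1`); the epicardial radius is
#' adjusted per phase so the shell (myocardial) volume is conserved
#' (incompressible myocardium).
#'
#' Defaults follow a 9.4T mouse short-axis protocol: 256 x 256 matrix,
#' 0.125 mm pixels, 1 mm slices, 35 cine frames.
#'
#' @slot matrixSize pixels per side of the square acquisition matrix.
#' @slot pixelSpacing in-plane pixel size, mm.
#' @slot sliceThickness slice thickness, mm.
#' @slot nPhases number of cine frames per heartbeat.
#' @slot lvLength apex-to-base extent of the endocardial half-ellipsoid, mm.
#' @slot endoRadiusED,endoRadiusES equatorial endocardial radius at
#'   end-diastole / end-systole, mm.
#' @slot wallThicknessED myocardial wall thickness at end-diastole, mm.
#' @slot intensityBlood,intensityMyo,intensityBg mean signal of blood,
#'   myocardium and background (bright-blood contrast requires
#'   blood > myocardium > background).
#' @slot noiseSigma Rician noise parameter, signal units; 0 disables noise.
#' @slot seed integer seed for the noise draw.
#'
#' @seealso [PhantomSpec()], [generatePhantom()]
#' @export
setClass("PhantomSpec",
  representation(
    matrixSize      = "integer",
    pixelSpacing    = "numeric",
    sliceThickness  = "numeric",
    nPhases         = "integer",
    lvLength        = "numeric",
    endoRadiusED    = "numeric",
    endoRadiusES    = "numeric",
    wallThicknessED = "numeric",
    intensityBlood  = "numeric",
    intensityMyo    = "numeric",
    intensityBg     = "numeric",
    noiseSigma      = "numeric",
    seed            = "integer"
  )
)

setValidity("PhantomSpec", function(object) {
  msgs <- character()
  pos <- function(x) length(x) == 1L && is.finite(x) && x > 0
  if (!pos(object@pixelSpacing))   msgs <- c(msgs, "pixelSpacing must be > 0")
  if (!pos(object@sliceThickness)) msgs <- c(msgs, "sliceThickness must be > 0")
  if (!pos(object@lvLength))       msgs <- c(msgs, "lvLength must be > 0")
  if (object@matrixSize < 8L)      msgs <- c(msgs, "matrixSize too small")
  if (object@nPhases < 2L)         msgs <- c(msgs, "nPhases must be >= 2")
  if (!pos(object@wallThicknessED))
    msgs <- c(msgs, "wallThicknessED must be > 0")
  if (!(object@endoRadiusES <= object@endoRadiusED))
    msgs <- c(msgs, "endoRadiusES must not exceed endoRadiusED")
  if (!(object@intensityBlood > object@intensityMyo &&
        object@intensityMyo > object@intensityBg))
    msgs <- c(msgs,
      "bright-blood contrast requires intensityBlood > intensityMyo > intensityBg")
  if (object@noiseSigma < 0) msgs <- c(msgs, "noiseSigma must be >= 0")
  fov <- object@matrixSize * object@pixelSpacing
  need <- 2 * (object@endoRadiusED + object@wallThicknessED)
  if (fov < need)
    msgs <- c(msgs, sprintf(
      "geometry exceeds field of view: FOV %.3f mm < 2 x (endoRadiusED + wallThicknessED) = %.3f mm",
      fov, need))
  if (length(msgs)) msgs else TRUE
})

#' PhantomTruth: analytic ground-truth LV parameters of a phantom
#'
#' Closed-form counterparts of the six measured parameters for a
#' [PhantomSpec-class] geometry: half-ellipsoid blood volumes at ED and ES,
#' the myocardial shell volume and mass at ED, the ejection fraction, and the
#' equatorial wall thickness at ED.
#'
#' @slot edbvTrue,esbvTrue analytic blood volumes, mm^3.
#' @slot edmvTrue analytic ED myocardial (shell) volume, mm^3.
#' @slot edmwTrue ED myocardial mass, mg (1.05 mg/mm^3).
#' @slot efTrue ejection fraction, percent.
#' @slot lvwtTrue equatorial ED wall thickness, micrometres.
#'
#' @export
setClass("PhantomTruth",
  representation(
    edbvTrue = "numeric", esbvTrue = "numeric", edmvTrue = "numeric",
    edmwTrue = "numeric", efTrue = "numeric", lvwtTrue = "numeric"
  )
)

setValidity("PhantomTruth", function(object) {
  msgs <- character()
  if (any(c(object@edbvTrue, object@esbvTrue, object@edmvTrue,
            object@edmwTrue, object@lvwtTrue) <= 0))
    msgs <- c(msgs, "volumes, mass and wall thickness must be positive")
  ef <- (object@edbvTrue - object@esbvTrue) / object@edbvTrue * 100
  if (abs(ef - object@efTrue) > 1e-9 * max(1, abs(ef)))
    msgs <- c(msgs, "efTrue inconsistent with edbvTrue/esbvTrue")
  if (abs(object@edmwTrue - 1.05 * object@edmvTrue) >
      1e-9 * object@edmwTrue)
    msgs <- c(msgs, "edmwTrue must equal 1.05 x edmvTrue")
  if (length(msgs)) msgs else TRUE
})

#' CardiacParams: the six measured LV parameters of one exam
#'
#' Results of the full volumetry chain for one animal and one exam:
#' end-diastolic and end-systolic blood volume (EDbv, ESbv, mm^3), the
#' end-diastolic myocardial volume and mass (EDmv mm^3, EDmw mg with density
#' 1.05 mg/mm^3), the ejection fraction (EF, percent) and the mean LV wall
#' thickness at ED (LVWT, micrometres). End-systolic myocardial volume/mass
#' are carried optionally (NA when not computed).
#'
#' @slot edbv,esbv blood volumes at ED / ES, mm^3.
#' @slot edmv myocardial volume at ED, mm^3.
#' @slot edmw myocardial mass at ED, mg.
#' @slot ef ejection fraction, percent.
#' @slot lvwt mean wall thickness at ED, micrometres.
#' @slot esmv,esmw optional ES myocardial volume (mm^3) and mass (mg).
#' @slot edPhase,esPhase selected ED / ES phase indices (1-based).
#'
#' @export
setClass("CardiacParams",
  representation(
    edbv = "numeric", esbv = "numeric", edmv = "numeric", edmw = "numeric",
    ef = "numeric", lvwt = "numeric", esmv = "numeric", esmw = "numeric",
    edPhase = "integer", esPhase = "integer"
  ),
  prototype(esmv = NA_real_, esmw = NA_real_,
            edPhase = NA_integer_, esPhase = NA_integer_)
)

setValidity("CardiacParams", function(object) {
  msgs <- character()
  if (any(c(object@edbv, object@esbv, object@edmv) < 0))
    msgs <- c(msgs, "volumes must be non-negative")
  if (object@edmv > 0 &&
      abs(object@edmw - 1.05 * object@edmv) > 1e-12 * object@edmw)
    msgs <- c(msgs, "edmw must equal 1.05 x edmv")
  if (!is.na(object@esmv) && object@esmv > 0 &&
      abs(object@esmw - 1.05 * object@esmv) > 1e-12 * object@esmw)
    msgs <- c(msgs, "esmw must equal 1.05 x esmv")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "CineStack", function(object) {
  d <- dim(object@intensities)
  cat(sprintf(
    "CineStack: %d phases x %d slices x %d x %d\n  pixel spacing %.4g mm, slice thickness %.4g mm\n  intensity range [%.4g, %.4g]\n",
    d[1], d[2], d[3], d[4], object@pixelSpacing, object@sliceThickness,
    min(object@intensities), max(object@intensities)))
})

setMethod("show", "MaskStack", function(object) {
  d <- dim(object@mask)
  cat(sprintf(
    "MaskStack '%s': %d phases x %d slices x %d x %d (%d voxels set)\n",
    object@label, d[1], d[2], d[3], d[4], sum(object@mask)))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(
    "PhantomSpec: %dx%d @ %.4g mm, %d slices of %.4g mm cover the LV\n  endo radius ED %.3g / ES %.3g mm, wall %.3g mm, length %.3g mm\n  %d phases, noise sigma %.3g, seed %d\n",
    object@matrixSize, object@matrixSize, object@pixelSpacing,
    phantomSliceCount(object), object@sliceThickness,
    object@endoRadiusED, object@endoRadiusES, object@wallThicknessED,
    object@lvLength, object@nPhases, object@noiseSigma, object@seed))
})

setMethod("show", "PhantomTruth", function(object) {
  cat(sprintf(
    "PhantomTruth: EDbv %.3f / ESbv %.3f mm^3, EDmv %.3f mm^3, EDmw %.3f mg\n  EF %.2f%%, LVWT %.1f um\n",
    object@edbvTrue, object@esbvTrue, object@edmvTrue, object@edmwTrue,
    object@efTrue, object@lvwtTrue))
})

setMethod("show", "CardiacParams", function(object) {
  cat(sprintf(
    "CardiacParams: EDbv %.1f / ESbv %.1f mm^3, EDmv %.1f mm^3, EDmw %.1f mg\n  EF %.1f%%, LVWT %.1f um (ED phase %d, ES phase %d)\n",
    object@edbv, object@esbv, object@edmv, object@edmw, object@ef,
    object@lvwt, object@edPhase, object@esPhase))
})
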