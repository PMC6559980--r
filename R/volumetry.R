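#' Simpson disc-summation volumes
#'
#' `discVolume` implements the disc (Simpson) summation: the volume enclosed
#' by a stack of short-axis areas is the sum of each slice area times the
#' slice thickness, `V = sum_n A_n t`. `myocardialVolume` applies the same
#' rule to the muscle ring, `V = sum_n (A_LV - A_b)_n t`, requiring the blood
#' area never to exceed the ROI area. Areas in mm^2, thickness in mm,
#' volumes in mm^3.
#'
#' @param areas per-slice areas, mm^2 (may be empty: volume 0).
#' @param thickness slice thickness, mm.
#' @return volume in mm^3.
#' @export
discVolume <- function(areas, thickness) {
  stopifnot(length(thickness) == 1L, thickness > 0)
  if (length(areas) == 0L) return(0)
  if (any(areas < 0)) stop("negative slice area")
  sum(areas) * thickness
}

#' @rdname discVolume
#' @param aLv,aB per-slice LV ROI and blood areas, mm^2.
#' @export
myocardialVolume <- function(aLv, aB, thickness) {
  stopifnot(length(aLv) == length(aB))
  if (any(aB > aLv))
    stop("blood area exceeds LV ROI area on some slice")
  discVolume(aLv - aB, thickness)
}

#' Myocardial mass from myocardial volume
#'
#' Mass = density x volume with myocardial density 1.05 g/mL, i.e. a volume
#' in mm^3 maps to mass in mg with factor 1.05.
#'
#' @param volume myocardial volume, mm^3.
#' @return mass in mg.
#' @export
myocardialMass <- function(volume) {
  stopifnot(all(volume >= 0))
  myocardialDensity() * volume
}

#' Ejection fraction
#'
#' `EF (%) = (EDbv - ESbv) / EDbv * 100`. The value is returned as computed
#' (not clamped), so inconsistent inputs are visible to the caller.
#'
#' @param edbv end-diastolic blood volume, mm^3 (> 0).
#' @param esbv end-systolic blood volume, mm^3 (>= 0).
#' @return ejection fraction, percent.
#' @export
ejectionFraction <- function(edbv, esbv) {
  stopifnot(esbv >= 0)
  if (edbv <= 0) stop("EDbv must be positive")
  (edbv - esbv) / edbv * 100
}

# Bilinear interpolation of matrix m at fractional (row, col); coordinates
# outside the grid return 0 (background).
bilinearAt <- function(m, r, c) {
  nr <- nrow(m); nc <- ncol(m)
  if (r < 1 || r > nr || c < 1 || c > nc) return(0)
  r0 <- floor(r); c0 <- floor(c)
  r1 <- min(r0 + 1L, nr); c1 <- min(c0 + 1L, nc)
  fr <- r - r0; fc <- c - c0
  m[r0, c0] * (1 - fr) * (1 - fc) + m[r1, c0] * fr * (1 - fc) +
    m[r0, c1] * (1 - fr) * fc + m[r1, c1] * fr * fc
}

# Walk a ray from (row0, col0) at `angle` (degrees; 0 = +col axis, measured
# counter-clockwise) through a {0,1} mask sampled bilinearly, and return the
# distance (pixels) at which the interpolated value first drops below 0.5,
# refined by linear interpolation between samples. NA if no crossing inside
# the image.
rayCrossing <- function(mask, row0, col0, angle, step = 0.25) {
  dc <- cos(angle * pi / 180); dr <- -sin(angle * pi / 180)
  maxD <- sqrt(nrow(mask)^2 + ncol(mask)^2)
  dPrev <- 0
  vPrev <- bilinearAt(mask, row0, col0)
  if (vPrev < 0.5) return(NA_real_)
  d <- step
  while (d <= maxD) {
    r <- row0 + dr * d; c <- col0 + dc * d
    if (r < 1 || r > nrow(mask) || c < 1 || c > ncol(mask))
      return(NA_real_)                    # left the image while still inside
    v <- bilinearAt(mask, r, c)
    if (v < 0.5)
      return(dPrev + (vPrev - 0.5) / (vPrev - v) * (d - dPrev))
    dPrev <- d; vPrev <- v
    d <- d + step
  }
  NA_real_
}

#' Radial wall-thickness measurement
#'
#' Measures the LV wall on one short-axis slice by casting `nLines` rays at
#' equally spaced angles (36 degrees apart for the default ten, starting at
#' the image +x axis) from the blood-pool centroid. Along each ray the wall
#' thickness is the distance from the endocardial boundary (where the blood
#' mask is left) to the epicardial boundary (where the LV ROI is left), both
#' located with subpixel precision by linear interpolation of the bilinearly
#' sampled mask crossings. The mean of the rays is the reported wall
#' thickness, in micrometres.
#'
#' @param blood a `blood` \linkS4class{MaskStack}.
#' @param roi the aligned `lv_roi` \linkS4class{MaskStack}.
#' @param phase phase index to measure (normally the ED phase).
#' @param slice slice index (normally mid-ventricular).
#' @param pixelSpacing in-plane pixel size, mm.
#' @param nLines number of rays (default 10).
#' @return list with `thicknesses` (um, one per ray), `meanThickness` (um),
#'   `angles` (degrees), `slice` (the slice measured).
#' @export
wallThickness <- function(blood, roi, phase, slice, pixelSpacing,
                          nLines = 10L) {
  stopifnot(nLines >= 1L)
  bl <- maskArray(blood)[phase, slice, , ] * 1
  rm <- maskArray(roi)[phase, slice, , ] * 1
  if (!any(bl > 0) || !any(rm > 0))
    stop("blood and ROI masks must be non-empty on the measured slice")
  idx <- which(bl > 0, arr.ind = TRUE)
  row0 <- mean(idx[, 1]); col0 <- mean(idx[, 2])
  if (bl[round(row0), round(col0)] == 0)
    stop("blood centroid falls outside the blood mask (non-convex pool?)")
  angles <- (seq_len(nLines) - 1L) * 360 / nLines
  th <- vapply(angles, function(a) {
    dEndo <- rayCrossing(bl, row0, col0, a)
    dEpi <- rayCrossing(rm, row0, col0, a)
    if (is.na(dEpi))
      stop(sprintf("ray at %.0f degrees does not exit the ROI within the image",
                   a))
    if (is.na(dEndo) || dEndo > dEpi)
      stop(sprintf("ray at %.0f degrees has no endocardial crossing", a))
    (dEpi - dEndo) * pixelSpacing * 1000
  }, numeric(1))
  list(thicknesses = th, meanThickness = mean(th), angles = angles,
       slice = slice)
}

#' Full volumetry chain for one exam
#'
#' Runs segmentation, ED/ES selection and the volumetric formulas on a cine
#' stack and its LV ROI: blood-pool separation per (phase, slice)
#' ([segmentBlood()]), global ED/ES phase selection ([selectEdEs()]), disc
#' summation of blood and muscle areas, mass at 1.05 mg/mm^3, ejection
#' fraction, and the ten-ray wall thickness at ED on the mid-ventricular
#' slice (the slice with the largest ED blood area; configurable).
#'
#' @param stack a \linkS4class{CineStack}.
#' @param roi the aligned `lv_roi` \linkS4class{MaskStack}.
#' @param nLines rays for the wall measurement (default 10).
#' @param lvwtSlice slice index for the wall measurement, or `NULL` for the
#'   mid-ventricular rule.
#' @param includeES also compute ES myocardial volume/mass (default TRUE).
#' @param method,threshold forwarded to [segmentBlood()].
#' @return a \linkS4class{CardiacParams}.
#' @examples
#' ph <- generatePhantom(PhantomSpec(matrixSize = 96L, pixelSpacing = 0.125,
#'                                   endoRadiusED = 1.6, endoRadiusES = 1.0,
#'                                   wallThicknessED = 0.7, lvLength = 5,
#'                                   nPhases = 8L))
#' computeParams(ph$stack, ph$roi)
#' @export
computeParams <- function(stack, roi, nLines = 10L, lvwtSlice = NULL,
                          includeES = TRUE, method = c("otsu", "fixed"),
                          threshold = NULL) {
  seg <- segmentBlood(stack, roi, method = method, threshold = threshold)
  sel <- selectEdEs(seg$areas)
  t <- sliceThickness(stack)
  aED <- seg$areas[seg$areas$phase == sel$edPhase, ]
  aES <- seg$areas[seg$areas$phase == sel$esPhase, ]
  edbv <- discVolume(aED$a_b_mm2, t)
  esbv <- discVolume(aES$a_b_mm2, t)
  edmv <- myocardialVolume(aED$a_lv_mm2, aED$a_b_mm2, t)
  if (is.null(lvwtSlice))
    lvwtSlice <- aED$slice[which.max(aED$a_b_mm2)]
  wt <- wallThickness(seg$blood, roi, sel$edPhase, lvwtSlice,
                      pixelSpacing(stack), nLines = nLines)
  esmv <- esmw <- NA_real_
  if (includeES) {
    esmv <- myocardialVolume(aES$a_lv_mm2, aES$a_b_mm2, t)
    esmw <- myocardialMass(esmv)
  }
  new("CardiacParams",
      edbv = edbv, esbv = esbv, edmv = edmv, edmw = myocardialMass(edmv),
      ef = ejectionFraction(edbv, esbv), lvwt = wt$meanThickness,
      esmv = esmv, esmw = esmw,
      edPhase = as.integer(sel$edPhase), esPhase = as.integer(sel$esPhase))
}

#' Dice similarity of two masks
#'
#' `2|A n B| / (|A| + |B|)`; 1 when both masks are empty.
#'
#' @param a,b logical arrays of equal shape (or \linkS4class{MaskStack}s).
#' @return Dice coefficient in \[0, 1\].
#' @export
diceCoefficient <- function(a, b) {
  if (is(a, "MaskStack")) a <- maskArray(a)
  if (is(b, "MaskStack")) b <- maskArray(b)
  stopifnot(identical(dim(a), dim(b)))
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}
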