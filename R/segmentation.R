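#' Separate the bright blood pool from myocardium within the LV ROI
#'
#' For every (phase, slice) with a non-empty ROI, an Otsu threshold is
#' computed from the ROI intensities alone and pixels above it are taken as
#' blood (bright-blood contrast). The candidate blood mask is then restricted
#' to its largest 4-connected component and interior holes are filled, so
#' isolated bright artifacts and speckle holes do not enter the area. Areas
#' are pixel counts times `pixelSpacing^2`; by construction the blood area
#' never exceeds the ROI area.
#'
#' An alternative fixed threshold can be supplied for data where Otsu is not
#' wanted (`method = "fixed"` with `threshold`).
#'
#' @param stack a \linkS4class{CineStack}.
#' @param roi an aligned `lv_roi` \linkS4class{MaskStack}. Slices with an
#'   empty ROI are skipped (areas 0); a constant-intensity non-empty ROI is
#'   an error (no threshold separates one level).
#' @param method `"otsu"` (default) or `"fixed"`.
#' @param threshold intensity cutoff when `method = "fixed"`.
#' @return list with `blood` (a `blood` \linkS4class{MaskStack}) and `areas`,
#'   a data.frame (phase, slice, a_lv_mm2, a_b_mm2).
#' @export
segmentBlood <- function(stack, roi, method = c("otsu", "fixed"),
                         threshold = NULL) {
  method <- match.arg(method)
  validObject(stack); validObject(roi)
  if (!identical(dim(intensities(stack)), dim(maskArray(roi))))
    stop("roi is not aligned with the stack")
  if (maskLabel(roi) != "lv_roi") stop("roi must be an 'lv_roi' mask")
  if (method == "fixed" && (is.null(threshold) || !is.finite(threshold)))
    stop("method = 'fixed' requires a finite threshold")
  arr <- intensities(stack)
  msk <- maskArray(roi)
  nP <- nPhases(stack); nS <- nSlices(stack)
  px2 <- pixelSpacing(stack)^2
  blood <- array(FALSE, dim = dim(msk))
  rows <- vector("list", nP * nS)
  k <- 0L
  for (p in seq_len(nP)) for (s in seq_len(nS)) {
    k <- k + 1L
    inRoi <- msk[p, s, , ]
    nRoi <- sum(inRoi)
    if (nRoi == 0L) {
      rows[[k]] <- data.frame(phase = p, slice = s, a_lv_mm2 = 0,
                              a_b_mm2 = 0)
      next
    }
    sl <- arr[p, s, , ]
    v <- sl[inRoi]
    rng <- range(v)
    if (rng[1] == rng[2])
      stop(sprintf(
        "constant-intensity ROI at phase %d slice %d: threshold undefined",
        p, s))
    thr <- if (method == "otsu") {
      EBImage::otsu(matrix(v, nrow = 1L), range = rng, levels = 256L)
    } else threshold
    cand <- inRoi & (sl > thr)
    if (any(cand)) {
      lab <- EBImage::bwlabel(cand * 1)       # 4-connected components
      sizes <- tabulate(lab[lab > 0L])
      main <- (lab == which.max(sizes)) * 1
      filled <- EBImage::fillHull(main) > 0
      cand <- filled & inRoi                  # a_b <= a_lv guaranteed
    }
    blood[p, s, , ] <- cand
    rows[[k]] <- data.frame(phase = p, slice = s, a_lv_mm2 = nRoi * px2,
                            a_b_mm2 = sum(cand) * px2)
  }
  areas <- do.call(rbind, rows)
  rownames(areas) <- NULL
  list(blood = MaskStack(blood, "blood"), areas = areas)
}

#' Select the end-diastolic and end-systolic phases
#'
#' ED is the phase whose blood area, summed over all slices, is largest; ES
#' the phase where it is smallest (the frames displayed with the largest or
#' smallest blood pool). Ties are broken toward the lowest phase index; a
#' series with no phase-to-phase variation selects phase 1 for both and
#' warns that no motion was detected.
#'
#' @param areas the per-(phase, slice) area table from [segmentBlood()].
#' @param perSlice select extrema per slice instead of from the all-slice
#'   sum (default FALSE, one coherent cardiac phase per exam).
#' @return list(edPhase, esPhase), 1-based phase indices; with
#'   `perSlice = TRUE` a data.frame (slice, edPhase, esPhase).
#' @export
selectEdEs <- function(areas, perSlice = FALSE) {
  stopifnot(all(c("phase", "a_b_mm2") %in% names(areas)))
  if (perSlice) {
    out <- lapply(sort(unique(areas$slice)), function(s) {
      sub <- areas[areas$slice == s, ]
      if (all(sub$a_b_mm2 == 0)) return(NULL)
      sel <- selectEdEs(sub)
      data.frame(slice = s, edPhase = sel$edPhase, esPhase = sel$esPhase)
    })
    return(do.call(rbind, out))
  }
  tot <- tapply(areas$a_b_mm2, areas$phase, sum)
  phases <- as.integer(names(tot))
  if (length(phases) < 2L) stop("at least 2 phases are required")
  if (all(tot == 0)) stop("blood area is zero in every phase")
  ord <- order(phases)
  tot <- tot[ord]; phases <- phases[ord]
  ed <- phases[which.max(tot)]   # which.max/min take the first maximum
  es <- phases[which.min(tot)]
  if (max(tot) - min(tot) == 0)
    warning("degenerate motion: blood area identical in all phases")
  list(edPhase = ed, esPhase = es)
}
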