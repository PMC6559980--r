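#' @rdname CineStack-class
#' @param object a \linkS4class{CineStack} or \linkS4class{MaskStack}.
#' @export
setGeneric("pixelSpacing", function(object) standardGeneric("pixelSpacing"))

#' @rdname CineStack-class
#' @export
setGeneric("sliceThickness",
           function(object) standardGeneric("sliceThickness"))

#' @rdname CineStack-class
#' @export
setGeneric("nPhases", function(object) standardGeneric("nPhases"))

#' @rdname CineStack-class
#' @export
setGeneric("nSlices", function(object) standardGeneric("nSlices"))

#' @rdname CineStack-class
#' @export
setGeneric("intensities", function(object) standardGeneric("intensities"))

#' @rdname MaskStack-class
#' @param object a \linkS4class{MaskStack}.
#' @export
setGeneric("maskArray", function(object) standardGeneric("maskArray"))

#' @rdname MaskStack-class
#' @export
setGeneric("maskLabel", function(object) standardGeneric("maskLabel"))

#' Tabular view of measured cardiac parameters
#'
#' Flattens a \linkS4class{CardiacParams} or \linkS4class{PhantomTruth} into a
#' one-row data.frame with the six canonical columns
#' `EDbv, ESbv, EDmv, EDmw, LVWT, EF` (units mm^3 / mg / um / percent).
#'
#' @param object the object to flatten.
#' @return a one-row data.frame.
#' @export
setGeneric("asParamsRow", function(object) standardGeneric("asParamsRow"))

setMethod("pixelSpacing", "CineStack", function(object) object@pixelSpacing)
setMethod("sliceThickness", "CineStack",
          function(object) object@sliceThickness)
setMethod("nPhases", "CineStack",
          function(object) dim(object@intensities)[1L])
setMethod("nSlices", "CineStack",
          function(object) dim(object@intensities)[2L])
setMethod("intensities", "CineStack", function(object) object@intensities)

setMethod("nPhases", "MaskStack", function(object) dim(object@mask)[1L])
setMethod("nSlices", "MaskStack", function(object) dim(object@mask)[2L])
setMethod("maskArray", "MaskStack", function(object) object@mask)
setMethod("maskLabel", "MaskStack", function(object) object@label)

setMethod("asParamsRow", "CardiacParams", function(object) {
  data.frame(EDbv = object@edbv, ESbv = object@esbv, EDmv = object@edmv,
             EDmw = object@edmw, LVWT = object@lvwt, EF = object@ef)
})

setMethod("asParamsRow", "PhantomTruth", function(object) {
  data.frame(EDbv = object@edbvTrue, ESbv = object@esbvTrue,
             EDmv = object@edmvTrue, EDmw = object@edmwTrue,
             LVWT = object@lvwtTrue, EF = object@efTrue)
})

#' Construct a CineStack
#'
#' @param intensities 4D numeric array (phase, slice, row, col).
#' @param pixelSpacing in-plane pixel spacing, mm.
#' @param sliceThickness slice thickness, mm.
#' @return a \linkS4class{CineStack}.
#' @export
CineStack <- function(intensities, pixelSpacing, sliceThickness) {
  new("CineStack", intensities = intensities,
      pixelSpacing = as.numeric(pixelSpacing),
      sliceThickness = as.numeric(sliceThickness))
}

#' Construct a MaskStack
#'
#' @param mask logical 4D array (phase, slice, row, col).
#' @param label `"lv_roi"` or `"blood"`.
#' @return a \linkS4class{MaskStack}.
#' @export
MaskStack <- function(mask, label = c("lv_roi", "blood")) {
  label <- match.arg(label)
  storage.mode(mask) <- "logical"
  new("MaskStack", mask = mask, label = label)
}
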