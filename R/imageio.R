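#' Read a 4D cine stack from disk
#'
#' Supported formats: NIfTI-1 (`.nii`/`.nii.gz`, 4D, voxel spacings taken
#' from `pixdim`) and multi-page TIFF with a JSON sidecar carrying the
#' geometry (`pixel_spacing_mm`, `slice_thickness_mm`, `n_phases`,
#' `n_slices`, and the `intensity_scale` the pages were normalized by).
#' Geometry is never guessed: a stack without usable spacing metadata is
#' rejected.
#'
#' On disk, NIfTI dimensions are (col, row, slice, phase); in memory the
#' canonical axis order is (phase, slice, row, col). TIFF pages are ordered
#' phase-major: page `(p - 1) * n_slices + s` holds phase `p`, slice `s`.
#'
#' @param path file path (`.nii`, `.nii.gz`, `.tif`/`.tiff`).
#' @param format `"nifti"`, `"tiff"`, or `"auto"` (from the extension).
#' @return a \linkS4class{CineStack}.
#' @export
readStack <- function(path, format = c("auto", "nifti", "tiff")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.nii(\\.gz)?$", path)) "nifti" else "tiff"
  if (format == "nifti") {
    img <- RNifti::readNifti(path)
    a <- as.array(img)
    if (length(dim(a)) == 3L)
      stop("3D NIfTI: a cine stack must be 4D (col, row, slice, phase)")
    if (length(dim(a)) != 4L)
      stop("expected a 4D NIfTI, got ", length(dim(a)), "D")
    pd <- RNifti::pixdim(img)
    if (length(pd) < 3L || any(!is.finite(pd[1:3])) || any(pd[1:3] <= 0))
      stop("NIfTI is missing voxel spacing metadata (pixdim); refusing to guess")
    if (abs(pd[1] - pd[2]) > 1e-6 * pd[1])
      stop("anisotropic in-plane spacing is not supported")
    # (col,row,slice,phase) -> (phase,slice,row,col)
    arr <- aperm(a, c(4, 3, 2, 1))
    return(CineStack(arr, pixelSpacing = pd[1], sliceThickness = pd[3]))
  }
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stop("TIFF sidecar not found: ", sidecar,
         " (geometry metadata is required; refusing to guess)")
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  need <- c("pixel_spacing_mm", "slice_thickness_mm", "n_phases", "n_slices")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stop("TIFF sidecar missing field(s): ", paste(miss, collapse = ", "))
  pages <- tiff::readTIFF(path, all = TRUE)
  nP <- as.integer(meta$n_phases); nS <- as.integer(meta$n_slices)
  if (length(pages) != nP * nS)
    stop(sprintf("TIFF has %d pages but sidecar promises %d phases x %d slices",
                 length(pages), nP, nS))
  scale <- if (!is.null(meta$intensity_scale)) meta$intensity_scale else 1
  d <- dim(pages[[1]])
  arr <- array(0, dim = c(nP, nS, d[1], d[2]))
  for (p in seq_len(nP)) for (s in seq_len(nS))
    arr[p, s, , ] <- pages[[(p - 1L) * nS + s]] * scale
  CineStack(arr, pixelSpacing = meta$pixel_spacing_mm,
            sliceThickness = meta$slice_thickness_mm)
}

#' Write a cine stack to disk
#'
#' NIfTI output stores intensities as float64 with voxel spacings in
#' `pixdim`, so a read-back reproduces the stack exactly. TIFF output stores
#' 32-bit float pages normalized to \[0, 1\] by the stack maximum, with the
#' scale and geometry recorded in a JSON sidecar (`<path>.json`); read-back
#' is exact to float32 precision.
#'
#' @param stack a \linkS4class{CineStack}.
#' @param path output path.
#' @param format `"auto"` (extension), `"nifti"` or `"tiff"`.
#' @return `path`, invisibly.
#' @export
writeStack <- function(stack, path, format = c("auto", "nifti", "tiff")) {
  format <- match.arg(format)
  validObject(stack)
  if (format == "auto")
    format <- if (grepl("\\.nii(\\.gz)?$", path)) "nifti" else "tiff"
  arr <- intensities(stack)
  if (format == "nifti") {
    onDisk <- aperm(arr, c(4, 3, 2, 1))   # -> (col,row,slice,phase)
    img <- RNifti::asNifti(onDisk)
    RNifti::pixdim(img) <- c(pixelSpacing(stack), pixelSpacing(stack),
                             sliceThickness(stack), 1)
    RNifti::writeNifti(img, path, datatype = "double")
    return(invisible(path))
  }
  scale <- max(arr)
  if (scale <= 0) scale <- 1
  nP <- nPhases(stack); nS <- nSlices(stack)
  pages <- vector("list", nP * nS)
  for (p in seq_len(nP)) for (s in seq_len(nS))
    pages[[(p - 1L) * nS + s]] <- arr[p, s, , ] / scale
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  jsonlite::write_json(
    list(pixel_spacing_mm = pixelSpacing(stack),
         slice_thickness_mm = sliceThickness(stack),
         n_phases = nP, n_slices = nS, intensity_scale = scale),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read or write a mask stack as NIfTI uint8
#'
#' @param mask a \linkS4class{MaskStack}.
#' @param path NIfTI path.
#' @param label mask label for the object read back.
#' @param pixelSpacing,sliceThickness geometry written into `pixdim`.
#' @return `writeMask`: the path, invisibly; `readMask`: a
#'   \linkS4class{MaskStack}.
#' @export
writeMask <- function(mask, path, pixelSpacing = 1, sliceThickness = 1) {
  validObject(mask)
  onDisk <- aperm(array(as.integer(maskArray(mask)), dim(maskArray(mask))),
                  c(4, 3, 2, 1))
  img <- RNifti::asNifti(onDisk)
  RNifti::pixdim(img) <- c(pixelSpacing, pixelSpacing, sliceThickness, 1)
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' @rdname writeMask
#' @export
readMask <- function(path, label = c("lv_roi", "blood")) {
  label <- match.arg(label)
  a <- as.array(RNifti::readNifti(path))
  if (length(dim(a)) != 4L) stop("mask NIfTI must be 4D")
  MaskStack(aperm(a, c(4, 3, 2, 1)) != 0, label)
}

#' Write and read parameter tables as CSV
#'
#' Tables round-trip losslessly: numeric columns are serialized with 17
#' significant digits, enough to reproduce any double exactly. Cohort tables
#' keep the canonical column order (`animal_id, group, timepoint, EDbv,
#' ESbv, EDmv, EDmw, LVWT, EF, ...`); a list of
#' \linkS4class{CardiacParams} is flattened through [asParamsRow()].
#'
#' @param table a data.frame, or a (possibly named) list of
#'   \linkS4class{CardiacParams}.
#' @param path CSV path.
#' @return `writeParams`: the path, invisibly; `readParams`: a data.frame.
#' @export
writeParams <- function(table, path) {
  if (!is.data.frame(table)) {
    rows <- lapply(table, asParamsRow)
    table <- do.call(rbind, rows)
    if (!is.null(names(rows))) table <- cbind(id = names(rows), table)
  }
  out <- table
  for (j in seq_along(out))
    if (is.double(out[[j]]))
      out[[j]] <- formatC(out[[j]], digits = 17, format = "g")
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname writeParams
#' @export
readParams <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
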