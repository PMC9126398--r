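#' ADC volume container
#'
#' Wraps a 3D grid of apparent diffusion coefficient (ADC) values, in units of
#' 10^-6 mm^2/s, together with its physical geometry. The array is indexed
#' `[row, col, slice]`; in-plane spacing is isotropic (maps are upsampled to a
#' square matrix at the scanner).
#'
#' @param values Numeric 3D array of ADC values, all finite and >= 0.
#' @param pixel_spacing In-plane pixel spacing in mm.
#' @param slice_thickness Slice thickness in mm.
#' @return An object of class `adc_volume`.
#' @export
adc_volume <- function(values, pixel_spacing = 1, slice_thickness = 4) {
  if (!is.array(values) || length(dim(values)) != 3) {
    stop("`values` must be a 3D array [row, col, slice]")
  }
  if (any(!is.finite(values))) stop("ADC values must all be finite")
  if (any(values < 0)) stop("ADC values must be non-negative")
  if (pixel_spacing <= 0 || slice_thickness <= 0) {
    stop("`pixel_spacing` and `slice_thickness` must be positive")
  }
  structure(
    list(values = values, pixel_spacing = pixel_spacing,
         slice_thickness = slice_thickness),
    class = "adc_volume"
  )
}

#' @export
print.adc_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<adc_volume> %d x %d x %d, %.3g mm pixels, %.3g mm slices\n",
              d[1], d[2], d[3], x$pixel_spacing, x$slice_thickness))
  invisible(x)
}

#' 3D mask container
#'
#' A logical 3D array congruent with an [adc_volume()], marking the member
#' voxels of a lesion or of the peripheral-zone parenchyma.
#'
#' @param values Logical (or 0/1 numeric) 3D array.
#' @param allow_empty Permit an all-FALSE mask (placement queries accept empty
#'   slices; lesion-level statistics do not accept empty masks).
#' @return An object of class `lesion_mask`.
#' @export
lesion_mask <- function(values, allow_empty = FALSE) {
  if (!is.array(values) || length(dim(values)) != 3) {
    stop("mask must be a 3D array [row, col, slice]")
  }
  if (is.numeric(values)) {
    r <- round(values)
    if (any(!r %in% c(0, 1))) {
      stop("mask values must be 0/1 (after rounding); found other values")
    }
    values <- r == 1
  }
  if (!is.logical(values)) stop("mask must be logical or 0/1 numeric")
  if (any(is.na(values))) stop("mask must not contain NA")
  if (!allow_empty && !any(values)) stop("mask is empty")
  structure(list(values = values), class = "lesion_mask")
}

#' @export
print.lesion_mask <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<lesion_mask> %d x %d x %d, %d voxels set\n",
              d[1], d[2], d[3], sum(x$values)))
  invisible(x)
}

check_congruent <- function(volume, mask) {
  if (!identical(dim(volume$values), dim(mask$values))) {
    stop("volume and mask grids differ: ",
         paste(dim(volume$values), collapse = "x"), " vs ",
         paste(dim(mask$values), collapse = "x"))
  }
  invisible(TRUE)
}

#' Mask volume in cm^3
#' @param mask A [lesion_mask()].
#' @param volume The congruent [adc_volume()] supplying voxel geometry.
#' @return Volume of the masked region in cm^3.
#' @export
mask_volume_cm3 <- function(mask, volume) {
  sum(mask$values) * volume$pixel_spacing^2 * volume$slice_thickness / 1000
}
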