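#' ROI kernel footprints
#'
#' A `kernel_mask` is the set of integer (row, col) pixel offsets, relative to
#' an anchor pixel at (0, 0), that make up a 2D region of interest (ROI) of
#' exactly `n_pixels` pixels. The reference-ADC computation slides these
#' footprints over every slice of a lesion mask. Two families are provided:
#' odd-sided squares and "near-circular" kernels built from the `n` offsets
#' closest to the anchor in Euclidean distance, with ties broken by ascending
#' (distance, row, col). The near-circular family is nested: the kernel of
#' size `n` is a subset of every larger kernel.
#'
#' @param n_pixels Number of pixels in the footprint.
#' @param offsets Integer matrix with columns `row`, `col`.
#' @param shape Either `"square"` or `"near_circular"`.
#' @return An object of class `kernel_mask`.
#' @keywords internal
new_kernel_mask <- function(n_pixels, offsets, shape) {
  stopifnot(is.matrix(offsets), ncol(offsets) == 2, nrow(offsets) == n_pixels)
  storage.mode(offsets) <- "integer"
  colnames(offsets) <- c("row", "col")
  structure(
    list(n_pixels = as.integer(n_pixels), offsets = offsets, shape = shape),
    class = "kernel_mask"
  )
}

#' @export
print.kernel_mask <- function(x, ...) {
  cat(sprintf("<kernel_mask> %d pixels, %s\n", x$n_pixels, x$shape))
  invisible(x)
}

#' Square ROI kernel
#'
#' Builds the odd-sided square footprint centred on the anchor pixel, e.g.
#' `side = 3` is the 3x3 block of 9 pixels used as the instructed-measurement
#' ROI.
#'
#' @param side Odd positive integer side length.
#' @return A [new_kernel_mask()] object with `side^2` offsets.
#' @examples
#' make_square_kernel(3)
#' @export
make_square_kernel <- function(side) {
  if (length(side) != 1 || !is.finite(side) || side < 1 || side %% 2 != 1) {
    stop("`side` must be a single odd positive integer, got: ", side)
  }
  h <- (side - 1) / 2
  grid <- expand.grid(row = -h:h, col = -h:h)
  grid <- grid[order(grid$row, grid$col), , drop = FALSE]
  new_kernel_mask(side^2, as.matrix(grid), "square")
}

#' Near-circular ROI kernel
#'
#' The `n_pixels` offsets with smallest Euclidean distance from the anchor,
#' ties broken by ascending (distance, row, col). This makes construction
#' deterministic and the family nested across sizes: the k-pixel kernel is
#' always a subset of the (k+1)-pixel kernel.
#'
#' @param n_pixels Positive integer pixel count.
#' @return A [new_kernel_mask()] object.
#' @examples
#' make_near_circular_kernel(5)  # the plus/cross
#' @export
make_near_circular_kernel <- function(n_pixels) {
  if (length(n_pixels) != 1 || !is.finite(n_pixels) || n_pixels < 1 ||
      n_pixels %% 1 != 0) {
    stop("`n_pixels` must be a single positive integer, got: ", n_pixels)
  }
  # candidate radius comfortably larger than the disc that holds n pixels
  r <- ceiling(sqrt(n_pixels / pi)) + 2
  grid <- expand.grid(row = -r:r, col = -r:r)
  d <- sqrt(grid$row^2 + grid$col^2)
  ord <- order(d, grid$row, grid$col)
  sel <- as.matrix(grid[ord[seq_len(n_pixels)], , drop = FALSE])
  rownames(sel) <- NULL
  new_kernel_mask(n_pixels, sel, "near_circular")
}

#' The ROI sizes of the measurement protocol
#'
#' Pixel counts of the nine sliding-ROI sizes evaluated by the reference
#' computation.
#' @export
roi_study_sizes <- function() c(1L, 2L, 3L, 5L, 9L, 17L, 25L, 33L, 49L)

#' Kernel for a protocol ROI size
#'
#' Dispatches over the nine protocol pixel counts: sizes with an odd square
#' root (1, 9, 25, 49) map to square kernels, the rest to near-circular ones.
#' `shape_policy = "all_near_circular"` forces the near-circular family for
#' every size, and `allow_any = TRUE` accepts pixel counts outside the
#' protocol set (always near-circular unless a square exists).
#'
#' @param n_pixels Pixel count.
#' @param shape_policy `"protocol"` (squares where an odd square exists) or
#'   `"all_near_circular"`.
#' @param allow_any Accept sizes outside the protocol set.
#' @return A [new_kernel_mask()] object with exactly `n_pixels` offsets.
#' @examples
#' kernel_for_size(9)   # 3x3 square
#' kernel_for_size(2)   # {(0,0), (-1,0)}
#' @export
kernel_for_size <- function(n_pixels,
                            shape_policy = c("protocol", "all_near_circular"),
                            allow_any = FALSE) {
  shape_policy <- match.arg(shape_policy)
  if (!allow_any && !(n_pixels %in% roi_study_sizes())) {
    stop("ROI size ", n_pixels, " is not in the protocol set {",
         paste(roi_study_sizes(), collapse = ","),
         "}; use allow_any = TRUE to override")
  }
  side <- sqrt(n_pixels)
  if (shape_policy == "protocol" && side %% 1 == 0 && side %% 2 == 1) {
    make_square_kernel(side)
  } else {
    make_near_circular_kernel(n_pixels)
  }
}

#' ROI area in mm^2
#'
#' @param n_pixels Pixel count of the ROI.
#' @param pixel_spacing In-plane pixel spacing in mm.
#' @return Area in mm^2 (`n_pixels * pixel_spacing^2`).
#' @examples
#' roi_area_mm2(9, 0.85)  # 6.5025
#' @export
roi_area_mm2 <- function(n_pixels, pixel_spacing) {
  if (any(!is.finite(pixel_spacing)) || any(pixel_spacing <= 0)) {
    stop("`pixel_spacing` must be positive and finite")
  }
  if (any(n_pixels < 1)) stop("`n_pixels` must be >= 1")
  n_pixels * pixel_spacing^2
}

#' Nearest protocol ROI size for a physical area
#'
#' Converts a drawn ROI area to the protocol pixel count whose area is
#' closest, used when simulating free-hand readers who report areas in mm^2.
#'
#' @inheritParams roi_area_mm2
#' @param area_mm2 ROI area in mm^2.
#' @param sizes Candidate pixel counts (default the protocol set).
#' @return One element of `sizes`.
#' @export
size_for_area_mm2 <- function(area_mm2, pixel_spacing,
                              sizes = roi_study_sizes()) {
  if (area_mm2 <= 0) stop("`area_mm2` must be positive")
  px <- area_mm2 / pixel_spacing^2
  sizes[which.min(abs(sizes - px))]
}
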