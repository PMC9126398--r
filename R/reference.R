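#' Reference ADC values by exhaustive sliding-ROI search
#'
#' The observer-independent lesion reference is the minimum, over all slices
#' and all fully contained placements, of the mean ADC under a kernel
#' footprint — the value an ideal reader would obtain by placing a 2D ROI of
#' that size exactly over the lowest-ADC area of the lesion. Placement
#' requires full containment: every pixel of the footprint must lie inside
#' the lesion mask on that slice. When a size does not fit anywhere, the
#' next-smaller size's value is carried forward (see
#' [multi_size_reference()]).
#'
#' @name reference_adc
NULL

reference_value <- function(requested_size, effective_size, value, anchor,
                            n_placements) {
  structure(
    list(requested_size = as.integer(requested_size),
         effective_size = as.integer(effective_size),
         value = as.numeric(value),
         anchor = anchor,                 # c(slice, row, col), 1-based
         n_placements = as.integer(n_placements)),
    class = "reference_value"
  )
}

#' @export
print.reference_value <- function(x, ...) {
  cat(sprintf(
    "<reference_value> size %d (effective %d): %.1f at slice %d, (%d, %d); %d placements\n",
    x$requested_size, x$effective_size, x$value,
    x$anchor[["slice"]], x$anchor[["row"]], x$anchor[["col"]],
    x$n_placements))
  invisible(x)
}

#' No-fit signal
#'
#' Returned by [min_mean_adc()] when a kernel has no fully contained
#' placement on any slice of the mask. A signal rather than an error, so the
#' multi-size driver can apply the smaller-size fallback.
#' @return An object of class `adc_no_fit`.
#' @export
no_fit <- function() structure(list(), class = "adc_no_fit")

#' @rdname no_fit
#' @param x Object to test.
#' @export
is_no_fit <- function(x) inherits(x, "adc_no_fit")

#' Valid kernel placements on a mask slice
#'
#' Anchor positions (1-based row, col) at which every offset of the kernel
#' footprint lands inside the grid and on a TRUE mask pixel. Returned sorted
#' by (row, col) so downstream minima have a deterministic first-in-scan-order
#' tie-break.
#'
#' @param mask_slice Logical matrix (one slice of a mask).
#' @param kernel A [kernel_for_size()] footprint.
#' @return Integer matrix with columns `row`, `col`; zero rows when nothing
#'   fits (an empty slice is allowed and yields zero rows).
#' @export
valid_placements <- function(mask_slice, kernel) {
  if (!is.matrix(mask_slice) || !is.logical(mask_slice)) {
    stop("`mask_slice` must be a logical matrix")
  }
  if (!inherits(kernel, "kernel_mask")) stop("`kernel` must be a kernel_mask")
  nr <- nrow(mask_slice)
  nc <- ncol(mask_slice)
  valid <- mask_slice
  off <- kernel$offsets
  for (k in seq_len(nrow(off))) {
    dr <- off[k, 1]
    dc <- off[k, 2]
    if (dr == 0 && dc == 0) next
    sh <- matrix(FALSE, nr, nc)
    r0 <- max(1, 1 - dr); r1 <- min(nr, nr - dr)
    c0 <- max(1, 1 - dc); c1 <- min(nc, nc - dc)
    if (r0 <= r1 && c0 <= c1) {
      sh[r0:r1, c0:c1] <- mask_slice[(r0:r1) + dr, (c0:c1) + dc, drop = FALSE]
    }
    valid <- valid & sh
    if (!any(valid)) break
  }
  w <- which(valid, arr.ind = TRUE)
  w <- w[order(w[, 1], w[, 2]), , drop = FALSE]
  dimnames(w) <- list(NULL, c("row", "col"))
  w
}

#' Minimum sliding-kernel mean ADC
#'
#' Evaluates the kernel mean at every valid placement on every slice of the
#' mask and returns the minimum with its anchor. Ties go to the first
#' placement in (slice, row, col) scan order.
#'
#' @param volume An [adc_volume()].
#' @param mask A congruent [lesion_mask()].
#' @param kernel A [kernel_for_size()] footprint.
#' @return A `reference_value`, or [no_fit()] when no placement exists.
#' @export
min_mean_adc <- function(volume, mask, kernel) {
  check_congruent(volume, mask)
  d <- dim(mask$values)
  nr <- d[1]
  lin_off <- kernel$offsets[, 1] + kernel$offsets[, 2] * nr
  best_val <- Inf
  best_anchor <- NULL
  n_place <- 0L
  for (s in seq_len(d[3])) {
    ms <- mask$values[, , s]
    if (!any(ms)) next
    anchors <- valid_placements(ms, kernel)
    if (nrow(anchors) == 0) next
    vs <- volume$values[, , s]
    base <- anchors[, 1] + (anchors[, 2] - 1L) * nr
    idx <- outer(base, lin_off, "+")
    means <- rowMeans(matrix(vs[as.vector(idx)], nrow = nrow(anchors)))
    n_place <- n_place + nrow(anchors)
    j <- which.min(means)
    if (means[j] < best_val) {   # strict: keeps first slice on exact ties
      best_val <- means[j]
      best_anchor <- c(slice = s, row = unname(anchors[j, 1]),
                       col = unname(anchors[j, 2]))
    }
  }
  if (is.null(best_anchor)) return(no_fit())
  reference_value(kernel$n_pixels, kernel$n_pixels, best_val, best_anchor,
                  n_place)
}

#' Multi-size reference ADC with smaller-size fallback
#'
#' Runs [min_mean_adc()] for each requested ROI size in ascending order. When
#' a size has no fully contained placement, the representative value of the
#' next-smaller size is substituted (recursively), recorded in
#' `effective_size`. Including size 1 guarantees a base case for any
#' non-empty mask.
#'
#' @inheritParams min_mean_adc
#' @param sizes Ascending pixel counts; default the nine protocol sizes.
#' @param shape_policy Passed to [kernel_for_size()].
#' @param allow_any Passed to [kernel_for_size()].
#' @return Named list (one `reference_value` per size, names = sizes).
#' @export
multi_size_reference <- function(volume, mask, sizes = roi_study_sizes(),
                                 shape_policy = "protocol",
                                 allow_any = FALSE) {
  check_congruent(volume, mask)
  if (!any(mask$values)) stop("mask is empty: no ROI definable")
  if (is.unsorted(sizes, strictly = TRUE)) {
    stop("`sizes` must be strictly ascending")
  }
  out <- vector("list", length(sizes))
  names(out) <- as.character(sizes)
  prev <- NULL
  for (i in seq_along(sizes)) {
    kern <- kernel_for_size(sizes[i], shape_policy = shape_policy,
                            allow_any = allow_any)
    rv <- min_mean_adc(volume, mask, kern)
    if (is_no_fit(rv)) {
      if (is.null(prev)) {
        stop("no ROI of the smallest requested size (", sizes[i],
             " px) fits within the mask; include size 1 in `sizes`")
      }
      rv <- reference_value(sizes[i], prev$effective_size, prev$value,
                            prev$anchor, prev$n_placements)
    }
    out[[i]] <- rv
    prev <- rv
  }
  out
}

#' Percentile of ADC within a mask
#'
#' The q-th percentile of the multiset of masked voxel values. The default
#' convention is linear interpolation between order statistics
#' (`stats::quantile` type 7); `"lower"` is the inverse empirical CDF
#' (type 1) and `"nearest"` type 3, since the convention of the histogram
#' tool that produced any given published value may differ.
#'
#' @inheritParams min_mean_adc
#' @param q Percentile in \[0, 100\].
#' @param method Interpolation convention.
#' @return The percentile value.
#' @examples
#' v <- adc_volume(array(1:100, c(10, 10, 1)))
#' m <- lesion_mask(array(TRUE, c(10, 10, 1)))
#' percentile_adc(v, m, 10)  # 10.9
#' @export
percentile_adc <- function(volume, mask, q,
                           method = c("linear", "lower", "nearest")) {
  method <- match.arg(method)
  check_congruent(volume, mask)
  if (!any(mask$values)) stop("mask is empty")
  if (length(q) != 1 || !is.finite(q) || q < 0 || q > 100) {
    stop("`q` must be a single value in [0, 100]")
  }
  type <- c(linear = 7, lower = 1, nearest = 3)[[method]]
  vals <- volume$values[mask$values]
  unname(stats::quantile(vals, q / 100, type = type, names = FALSE))
}

#' Median parenchyma ADC
#'
#' Median ADC over a peripheral-zone parenchyma mask — the per-patient
#' summary used as a surrogate for technical (scanner/coil) effects on ADC.
#'
#' @inheritParams percentile_adc
#' @param pz_mask Parenchyma mask.
#' @return Median ADC in 10^-6 mm^2/s.
#' @export
median_pz_adc <- function(volume, pz_mask, method = "linear") {
  percentile_adc(volume, pz_mask, 50, method = method)
}

#' Reference results as a data frame
#'
#' Flattens a [multi_size_reference()] result (plus optional whole-lesion
#' percentile) into one row per ROI size. Anchor coordinates are 0-based
#' (slice, row, col), the convention used by the CSV interface.
#'
#' @param refmap Result of [multi_size_reference()].
#' @param lesion_id Identifier copied to every row.
#' @return A data.frame with columns lesion_id, size, effective_size, value,
#'   anchor_slice, anchor_row, anchor_col.
#' @export
reference_table <- function(refmap, lesion_id = 1L) {
  do.call(rbind, lapply(refmap, function(rv) {
    data.frame(lesion_id = lesion_id,
               size = rv$requested_size,
               effective_size = rv$effective_size,
               value = rv$value,
               anchor_slice = unname(rv$anchor[["slice"]]) - 1L,
               anchor_row = unname(rv$anchor[["row"]]) - 1L,
               anchor_col = unname(rv$anchor[["col"]]) - 1L)
  }))
}
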