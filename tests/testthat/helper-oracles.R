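# Independent oracles and small builders used across the test files.

# Rank every offset in a (2r+1)^2 window by (Euclidean distance, row, col)
# and return the first n — a from-scratch reconstruction of the
# near-circular family.
oracle_nearest_offsets <- function(n, r = 8) {
  g <- expand.grid(row = -r:r, col = -r:r)
  d <- sqrt(g$row^2 + g$col^2)
  g <- g[order(d, g$row, g$col), ]
  as.matrix(g[seq_len(n), ])
}

# Containment check for a single anchor, written longhand.
oracle_fits <- function(mask_slice, offsets, r, c) {
  for (k in seq_len(nrow(offsets))) {
    rr <- r + offsets[k, 1]
    cc <- c + offsets[k, 2]
    if (rr < 1 || rr > nrow(mask_slice) || cc < 1 || cc > ncol(mask_slice) ||
        !mask_slice[rr, cc]) {
      return(FALSE)
    }
  }
  TRUE
}

# All valid anchors by looping over every pixel.
oracle_placements <- function(mask_slice, offsets) {
  out <- NULL
  for (r in seq_len(nrow(mask_slice))) {
    for (c in seq_len(ncol(mask_slice))) {
      if (oracle_fits(mask_slice, offsets, r, c)) out <- rbind(out, c(r, c))
    }
  }
  if (is.null(out)) out <- matrix(integer(0), 0, 2)
  out
}

# A random volume + mask pair on a small grid.
random_case <- function(seed, dims = c(8, 8, 2), p_mask = 0.6) {
  set.seed(seed)
  vol <- adc_volume(array(runif(prod(dims), 400, 1600), dims))
  m <- array(runif(prod(dims)) < p_mask, dims)
  if (!any(m)) m[1, 1, 1] <- TRUE
  list(volume = vol, mask = lesion_mask(m))
}

# Tidy measurement table from a wide lesion x reader matrix (one session).
table_from_matrix <- function(m, session = 1) {
  data.frame(
    lesion_id = rep(seq_len(nrow(m)), ncol(m)),
    reader_id = rep(seq_len(ncol(m)), each = nrow(m)),
    session = session,
    adc_value = as.vector(m)
  )
}

# An idealised reader: fixed 9-pixel ROI, no jitter, exact contour.
ideal_profile <- function() {
  reader_profile(area_median_mm2 = 9, area_sdlog = 0, jitter_sd = 0,
                 s2_jitter_sd = 0, contour_sd = 0, contour_bias = 0)
}
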