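#' Synthetic ADC phantom configuration
#'
#' The phantom emulates the structure the reference computation assumes: a
#' higher-ADC parenchyma background (spatially correlated Gaussian texture),
#' an ellipsoidal lesion of intermediate ADC, and a small low-ADC focus
#' inside it — the sparse high-grade component of a heterogeneous tumour —
#' plus i.i.d. Gaussian voxel noise. All ADC values are in 10^-6 mm^2/s.
#'
#' Defaults give a lesion of roughly 0.5 cm^3 (the scale of the study
#' lesions) on a 1 mm / 4 mm grid with parenchyma around 1400, lesion base
#' 900 and focus 600.
#'
#' @param dim Grid dimensions c(rows, cols, slices).
#' @param pixel_spacing In-plane spacing, mm.
#' @param slice_thickness Slice thickness, mm.
#' @param background_mean,background_sd Parenchyma ADC level and the SD of
#'   its smooth spatial texture.
#' @param lesion_center Voxel c(row, col, slice); default grid centre.
#' @param lesion_radii Ellipsoid semi-axes in voxels c(row, col, slice).
#' @param lesion_adc Lesion base ADC.
#' @param focus_center Centre of the low-ADC focus; default the lesion
#'   centre.
#' @param focus_radius Focus sphere radius, in-plane voxels (scaled by the
#'   spacing/thickness ratio through slices).
#' @param focus_adc Focus ADC; must be below `lesion_adc`, which must be
#'   below `background_mean`.
#' @param noise_sd SD of i.i.d. voxel noise.
#' @param seed RNG seed used by [generate_phantom()].
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(dim = c(64, 64, 7),
                           pixel_spacing = 1.0,
                           slice_thickness = 4.0,
                           background_mean = 1400,
                           background_sd = 100,
                           lesion_center = NULL,
                           lesion_radii = c(7.5, 9, 1.6),
                           lesion_adc = 900,
                           focus_center = NULL,
                           focus_radius = 2.2,
                           focus_adc = 600,
                           noise_sd = 50,
                           seed = 1L) {
  if (is.null(lesion_center)) lesion_center <- ceiling(dim / 2)
  if (is.null(focus_center)) focus_center <- lesion_center
  cfg <- list(dim = dim, pixel_spacing = pixel_spacing,
              slice_thickness = slice_thickness,
              background_mean = background_mean,
              background_sd = background_sd,
              lesion_center = lesion_center, lesion_radii = lesion_radii,
              lesion_adc = lesion_adc,
              focus_center = focus_center, focus_radius = focus_radius,
              focus_adc = focus_adc, noise_sd = noise_sd,
              seed = as.integer(seed))
  if (!(focus_adc < lesion_adc && lesion_adc < background_mean)) {
    stop("need focus_adc < lesion_adc < background_mean")
  }
  if (noise_sd < 0 || background_sd < 0) stop("SDs must be >= 0")
  class(cfg) <- "phantom_config"
  cfg
}

ellipsoid_mask <- function(dim, center, radii) {
  r <- (seq_len(dim[1]) - center[1]) / radii[1]
  c <- (seq_len(dim[2]) - center[2]) / radii[2]
  s <- (seq_len(dim[3]) - center[3]) / radii[3]
  arr <- outer(outer(r^2, c^2, "+"), s^2, "+")
  arr <= 1
}

#' Brute-force minimum sliding-kernel mean
#'
#' Independent enumeration of every anchor on every slice: containment is
#' checked offset by offset and means are accumulated in a plain loop. Used
#' to compute phantom ground truth and as the oracle the optimised
#' [min_mean_adc()] path is validated against; intentionally not shared with
#' that path.
#'
#' @inheritParams min_mean_adc
#' @return List with `value`, `anchor` (slice, row, col), `n_placements`, or
#'   [no_fit()].
#' @export
brute_force_min_mean <- function(volume, mask, kernel) {
  d <- dim(mask$values)
  off <- kernel$offsets
  best <- Inf
  best_anchor <- NULL
  n_place <- 0L
  for (s in seq_len(d[3])) {
    for (r in seq_len(d[1])) {
      for (cc in seq_len(d[2])) {
        total <- 0
        ok <- TRUE
        for (k in seq_len(nrow(off))) {
          rr <- r + off[k, 1]
          ccc <- cc + off[k, 2]
          if (rr < 1 || rr > d[1] || ccc < 1 || ccc > d[2] ||
              !mask$values[rr, ccc, s]) {
            ok <- FALSE
            break
          }
          total <- total + volume$values[rr, ccc, s]
        }
        if (ok) {
          n_place <- n_place + 1L
          m <- total / nrow(off)
          if (m < best) {
            best <- m
            best_anchor <- c(slice = s, row = r, col = cc)
          }
        }
      }
    }
  }
  if (is.null(best_anchor)) return(no_fit())
  list(value = best, anchor = best_anchor, n_placements = n_place)
}

#' Generate a synthetic ADC phantom with known ground truth
#'
#' Builds the volume described by a [phantom_config()], the lesion and
#' peripheral-zone masks, and (optionally) the ground-truth minimum-mean
#' reference for each ROI size. Ground truth is computed with the
#' brute-force enumerator, not the optimised search path, so recovery tests
#' compare two independent routes. Identical (config, seed) pairs give
#' bit-identical phantoms.
#'
#' @param config A [phantom_config()].
#' @param compute_truth Compute the per-size ground-truth map (brute force;
#'   the cost is noticeable on large grids).
#' @param truth_sizes Sizes for the truth map.
#' @return A `phantom_truth` list: `volume` ([adc_volume()]), `lesion` and
#'   `pz` ([lesion_mask()]), `truth` (named per-size minimum-mean values),
#'   `truth_anchors`, and the `config`.
#' @export
generate_phantom <- function(config = phantom_config(),
                             compute_truth = TRUE,
                             truth_sizes = roi_study_sizes()) {
  d <- config$dim
  lesion <- ellipsoid_mask(d, config$lesion_center, config$lesion_radii)
  # focus is spherical in physical units; slice axis scaled by thickness
  fr <- config$focus_radius
  focus <- ellipsoid_mask(
    d, config$focus_center,
    c(fr, fr, max(fr * config$pixel_spacing / config$slice_thickness, 0.51)))
  if (any(focus & !lesion)) stop("focus must lie entirely inside the lesion")
  if (!any(lesion)) stop("lesion mask is empty; enlarge radii")

  set.seed(config$seed)
  vals <- array(config$background_mean, d)
  if (config$background_sd > 0) {
    # block-constant correlated texture: one N(0, sd) draw per 8x8 patch
    nbr <- ceiling(d[1] / 8)
    nbc <- ceiling(d[2] / 8)
    for (s in seq_len(d[3])) {
      coarse <- matrix(stats::rnorm(nbr * nbc, 0, config$background_sd),
                       nbr, nbc)
      fine <- coarse[rep(seq_len(nbr), each = 8)[seq_len(d[1])],
                     rep(seq_len(nbc), each = 8)[seq_len(d[2])]]
      vals[, , s] <- vals[, , s] + fine
    }
  }
  vals[lesion] <- config$lesion_adc
  vals[focus] <- config$focus_adc
  if (config$noise_sd > 0) {
    vals <- vals + array(stats::rnorm(prod(d), 0, config$noise_sd), d)
  }
  vals <- pmax(vals, 0)

  # peripheral-zone stand-in: a larger ellipsoid shell around the lesion
  pz <- ellipsoid_mask(d, config$lesion_center,
                       pmin(config$lesion_radii * 2.2 + 3, d / 2 - 1)) &
    !lesion
  volume <- adc_volume(vals, config$pixel_spacing, config$slice_thickness)
  lesion_m <- lesion_mask(lesion)
  out <- list(volume = volume, lesion = lesion_m,
              pz = lesion_mask(pz), config = config,
              truth = NULL, truth_anchors = NULL, refmap = NULL)
  if (compute_truth) {
    truth <- numeric(0)
    anchors <- list()
    prev <- NULL
    for (n in truth_sizes) {
      bf <- brute_force_min_mean(volume, lesion_m, kernel_for_size(n))
      if (is_no_fit(bf)) bf <- prev   # same fallback rule as the pipeline
      truth[as.character(n)] <- bf$value
      anchors[[as.character(n)]] <- bf$anchor
      prev <- bf
    }
    out$truth <- truth
    out$truth_anchors <- anchors
  }
  class(out) <- "phantom_truth"
  out
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("<phantom_truth> %s grid, lesion %d voxels",
              paste(dim(x$volume$values), collapse = "x"),
              sum(x$lesion$values)))
  if (!is.null(x$truth)) {
    cat("; truth[9] =", round(x$truth[["9"]], 1))
  }
  cat("\n")
  invisible(x)
}

#' Virtual reader profile
#'
#' Behavioural parameters of one simulated radiologist. In the free-ROI
#' session the reader draws an ROI whose area follows a log-normal
#' distribution (median/sigma on the log scale) and centres it near the true
#' lowest-ADC location with Gaussian placement jitter; in the instructed
#' session the size is fixed at 9 pixels with (smaller) jitter; in the
#' whole-lesion session the reader's contour differs from the reference mask
#' by a random morphological dilation or erosion.
#'
#' @param area_median_mm2 Median free-session ROI area, mm^2.
#' @param area_sdlog SD of log area.
#' @param jitter_sd Free-session anchor jitter SD, pixels.
#' @param s2_jitter_sd Instructed-session anchor jitter SD, pixels.
#' @param contour_sd SD of the signed morphological radius (pixels) applied
#'   to the lesion contour in the whole-lesion session (positive draws
#'   dilate, negative erode, rounded to integer radii).
#' @param contour_bias Mean of the signed radius — a reader's habitual
#'   tendency to contour generously (positive) or tightly (negative).
#' @return A `reader_profile` list.
#' @export
reader_profile <- function(area_median_mm2 = 12, area_sdlog = 0.6,
                           jitter_sd = 1.2, s2_jitter_sd = 0.6,
                           contour_sd = 0.9, contour_bias = 0) {
  if (area_median_mm2 <= 0 || area_sdlog < 0 || jitter_sd < 0 ||
      s2_jitter_sd < 0 || contour_sd < 0) {
    stop("profile scale parameters must be positive (jitters >= 0)")
  }
  structure(list(area_median_mm2 = area_median_mm2, area_sdlog = area_sdlog,
                 jitter_sd = jitter_sd, s2_jitter_sd = s2_jitter_sd,
                 contour_sd = contour_sd, contour_bias = contour_bias),
            class = "reader_profile")
}

#' Default panel of 10 virtual readers
#'
#' Free-session ROI-area medians span the 7.5-103 mm^2 range reported for
#' human readers (one reader habitually draws very large ROIs); jitter and
#' contour parameters are heterogeneous so that agreement with the computed
#' reference spans a wide band in the free session and a narrow one in the
#' instructed session.
#'
#' @param n_readers Number of profiles (recycled from the panel of 10).
#' @return List of [reader_profile()] objects.
#' @export
default_reader_profiles <- function(n_readers = 10) {
  areas  <- c(13.2, 7.5, 12.6, 10.5, 8.4, 103, 11.9, 23.3, 15.8, 24.2)
  jit    <- c(2.4, 1.8, 1.0, 1.5, 1.2, 3.4, 1.0, 2.6, 1.6, 1.9)
  jit2   <- c(1.4, 1.1, 0.5, 1.1, 0.55, 1.4, 0.5, 1.1, 0.55, 0.8)
  csd    <- c(4.6, 2.5, 1.8, 2.1, 2.5, 4.6, 1.6, 3.7, 2.3, 2.5)
  cbias  <- c(2.5, 1.0, -1.6, -1.0, 1.6, 4.1, 0.0, 3.1, 2.1, -2.1)
  idx <- rep_len(seq_len(10), n_readers)
  lapply(seq_len(n_readers), function(i) {
    j <- idx[i]
    reader_profile(areas[j], 0.7, jit[j], jit2[j], csd[j], cbias[j])
  })
}

disc_offsets <- function(radius) {
  r <- ceiling(radius)
  grid <- expand.grid(row = -r:r, col = -r:r)
  grid <- grid[sqrt(grid$row^2 + grid$col^2) <= radius + 1e-9, , drop = FALSE]
  new_kernel_mask(nrow(grid), as.matrix(grid), "near_circular")
}

dilate_slice <- function(mask_slice, se) {
  nr <- nrow(mask_slice)
  nc <- ncol(mask_slice)
  out <- matrix(FALSE, nr, nc)
  for (k in seq_len(nrow(se$offsets))) {
    dr <- se$offsets[k, 1]
    dc <- se$offsets[k, 2]
    r0 <- max(1, 1 - dr); r1 <- min(nr, nr - dr)
    c0 <- max(1, 1 - dc); c1 <- min(nc, nc - dc)
    if (r0 <= r1 && c0 <= c1) {
      out[r0:r1, c0:c1] <- out[r0:r1, c0:c1] |
        mask_slice[(r0:r1) + dr, (c0:c1) + dc, drop = FALSE]
    }
  }
  out
}

erode_slice <- function(mask_slice, se) {
  w <- valid_placements(mask_slice, se)
  out <- matrix(FALSE, nrow(mask_slice), ncol(mask_slice))
  out[w] <- TRUE
  out
}

perturb_mask <- function(mask, radius_signed) {
  r <- round(abs(radius_signed))
  if (r == 0) return(mask)
  se <- disc_offsets(r)
  vals <- mask$values
  for (s in seq_len(dim(vals)[3])) {
    if (!any(vals[, , s])) next
    vals[, , s] <- if (radius_signed > 0) {
      dilate_slice(vals[, , s], se)
    } else {
      erode_slice(vals[, , s], se)
    }
  }
  if (!any(vals)) return(mask)   # erosion removed everything: keep contour
  lesion_mask(vals)
}

# A human ROI: anchored at the jittered target, clipped into the lesion mask,
# but the footprint may spill beyond the contour (pixels outside the grid are
# dropped). This is how free-hand ROIs behave on a viewer: the contour is not
# a hard boundary.
measure_jittered <- function(volume, mask, kernel, anchor, jitter_sd) {
  target_r <- anchor[["row"]] + stats::rnorm(1, 0, jitter_sd)
  target_c <- anchor[["col"]] + stats::rnorm(1, 0, jitter_sd)
  s <- anchor[["slice"]]
  in_mask <- which(mask$values[, , s], arr.ind = TRUE)
  in_mask <- in_mask[order(in_mask[, 1], in_mask[, 2]), , drop = FALSE]
  d2 <- (in_mask[, 1] - target_r)^2 + (in_mask[, 2] - target_c)^2
  j <- which.min(d2)                       # ties: first in (row, col) order
  rr <- in_mask[j, 1] + kernel$offsets[, 1]
  cc <- in_mask[j, 2] + kernel$offsets[, 2]
  d <- dim(volume$values)
  keep <- rr >= 1 & rr <= d[1] & cc >= 1 & cc <= d[2]
  mean(volume$values[, , s][cbind(rr[keep], cc[keep])])
}

ref_entry <- function(truth, size) {
  rm <- truth$refmap
  if (is.null(rm)) {
    stop("phantom_truth has no reference map; run attach_reference() first")
  }
  rm[[as.character(size)]]
}

#' Attach pipeline reference values to a phantom
#'
#' Computes the per-size minimum-mean references ([multi_size_reference()])
#' and the whole-lesion 10th percentile for a phantom, storing them for the
#' reader simulator.
#'
#' @param truth A `phantom_truth`.
#' @param sizes ROI sizes.
#' @return The `phantom_truth` with `refmap` and `p10` filled in.
#' @export
attach_reference <- function(truth, sizes = roi_study_sizes()) {
  truth$refmap <- multi_size_reference(truth$volume, truth$lesion, sizes)
  truth$p10 <- percentile_adc(truth$volume, truth$lesion, 10)
  truth
}

#' Simulate one reader measuring one lesion
#'
#' Session 1 (free ROI): the reader samples an ROI area from their
#' log-normal size habit, the nearest protocol kernel is placed at the true
#' minimum-mean location for that size plus Gaussian jitter (snapped to the
#' nearest fully contained placement), and the kernel mean is reported.
#' Session 2 (instructed): as session 1 but the size is fixed at 9 pixels
#' and the jitter is the reader's instructed-session jitter. Session 3
#' (whole lesion): the lesion contour is perturbed by a random morphological
#' dilation/erosion and the 10th percentile of the perturbed mask is
#' reported.
#'
#' Randomness comes from the current RNG state; seed it before calling for
#' reproducibility.
#'
#' @param truth A `phantom_truth` with reference values attached
#'   ([attach_reference()]).
#' @param profile A [reader_profile()].
#' @param session 1, 2 or 3.
#' @return One-row data.frame: adc_value, roi_size_mm2, roi_volume_cm3.
#' @export
simulate_reader_session <- function(truth, profile, session) {
  if (!session %in% 1:3) stop("unknown session: ", session)
  vol <- truth$volume
  if (session %in% c(1, 2)) {
    if (session == 1) {
      area <- stats::rlnorm(1, log(profile$area_median_mm2),
                            profile$area_sdlog)
      n <- size_for_area_mm2(area, vol$pixel_spacing)
      jitter <- profile$jitter_sd
    } else {
      n <- 9L
      jitter <- profile$s2_jitter_sd
    }
    rv <- ref_entry(truth, n)
    kern <- kernel_for_size(n)
    val <- measure_jittered(vol, truth$lesion, kern, rv$anchor, jitter)
    data.frame(adc_value = val,
               roi_size_mm2 = roi_area_mm2(n, vol$pixel_spacing),
               roi_volume_cm3 = NA_real_)
  } else {
    r_signed <- stats::rnorm(1, profile$contour_bias, profile$contour_sd)
    pm <- perturb_mask(truth$lesion, r_signed)
    data.frame(adc_value = percentile_adc(vol, pm, 10),
               roi_size_mm2 = NA_real_,
               roi_volume_cm3 = mask_volume_cm3(pm, vol))
  }
}

sample_lesion_config <- function(base) {
  focus_adc <- min(max(stats::rnorm(1, 700, 170), 350), 1050)
  lesion_adc <- focus_adc + stats::runif(1, 150, 320)
  lesion_adc <- min(lesion_adc, base$background_mean - 30)
  radii <- c(stats::runif(1, 6, 9), stats::runif(1, 6.5, 10),
             stats::runif(1, 1.2, 2.2))
  fr <- stats::runif(1, 1.6, 3.0)
  center <- ceiling(base$dim / 2)
  # focus offset kept well inside the lesion
  max_off <- pmax(radii[1:2] * 0.35 - 1, 0)
  off <- round(stats::runif(2, -max_off, max_off))
  phantom_config(
    dim = base$dim, pixel_spacing = base$pixel_spacing,
    slice_thickness = base$slice_thickness,
    background_mean = base$background_mean,
    background_sd = base$background_sd,
    lesion_center = center, lesion_radii = radii,
    lesion_adc = lesion_adc,
    focus_center = c(center[1:2] + off, center[3]), focus_radius = fr,
    focus_adc = focus_adc, noise_sd = base$noise_sd,
    seed = sample.int(2147483646, 1))
}

#' Run a complete virtual reader study
#'
#' Generates `n_lesions` heterogeneous phantoms (lesion size, focus contrast
#' and geometry varying across lesions), computes the pipeline reference
#' values for each, and simulates every reader measuring every lesion in all
#' three sessions — a complete block design ready for [agreement_report()].
#'
#' @param n_lesions Number of lesions (>= 2).
#' @param n_readers Number of readers (>= 2).
#' @param profiles List of [reader_profile()]s, one per reader.
#' @param seed Integer seed; the full output is reproducible from it.
#' @param base_config Phantom geometry/noise shared across lesions.
#' @return List with `measurements` (tidy table), `reference` (lesion_id,
#'   ref_9px, ref_p10), and `references_by_size` (long per-size table).
#' @export
run_virtual_study <- function(n_lesions = 40, n_readers = 10,
                              profiles = default_reader_profiles(n_readers),
                              seed = 1L,
                              base_config = phantom_config()) {
  if (n_lesions < 2 || n_readers < 2) stop("need >= 2 lesions and readers")
  if (length(profiles) != n_readers) {
    stop("`profiles` must have one entry per reader")
  }
  meas <- vector("list", n_lesions * n_readers * 3)
  refs <- vector("list", n_lesions)
  ref_long <- vector("list", n_lesions)
  ii <- 0L
  for (les in seq_len(n_lesions)) {
    set.seed((seed * 100003L + les * 7919L) %% 2147483647L)
    cfg <- sample_lesion_config(base_config)
    ph <- generate_phantom(cfg, compute_truth = FALSE)
    ph <- attach_reference(ph)
    refs[[les]] <- data.frame(lesion_id = les,
                              ref_9px = ph$refmap[["9"]]$value,
                              ref_p10 = ph$p10)
    ref_long[[les]] <- reference_table(ph$refmap, lesion_id = les)
    for (rd in seq_len(n_readers)) {
      set.seed((seed * 100003L + les * 7919L + rd * 104729L) %% 2147483647L)
      for (s in 1:3) {
        row <- simulate_reader_session(ph, profiles[[rd]], s)
        ii <- ii + 1L
        meas[[ii]] <- cbind(data.frame(lesion_id = les, reader_id = rd,
                                       session = s), row)
      }
    }
  }
  list(measurements = do.call(rbind, meas),
       reference = do.call(rbind, refs),
       references_by_size = do.call(rbind, ref_long))
}
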