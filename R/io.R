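#' Image and table I/O
#'
#' ADC maps and masks travel as NIfTI volumes; measurement and cohort tables
#' as tidy CSV (or XLSX when readxl is installed) with a user-supplied column
#' map so sheet-schema drift never requires code changes. Coordinates written
#' to CSV are 0-based (slice, row, col).
#'
#' @name io
NULL

#' Read an ADC volume from NIfTI
#'
#' @param path NIfTI file (.nii or .nii.gz).
#' @param unit_scale Multiplier applied to stored values to convert to
#'   10^-6 mm^2/s (e.g. `1e6` when the file stores mm^2/s).
#' @return An [adc_volume()] with spacing taken from the header. If in-plane
#'   spacing is anisotropic a warning is issued and the first spacing is
#'   used.
#' @export
read_adc_volume <- function(path, unit_scale = 1) {
  img <- RNifti::readNifti(path)
  vals <- array(as.numeric(img) * unit_scale, dim = dim(img))
  pd <- RNifti::pixdim(img)
  if (length(pd) >= 2 && abs(pd[1] - pd[2]) > 1e-6) {
    warning("anisotropic in-plane spacing (", pd[1], " x ", pd[2],
            " mm); using ", pd[1], " mm")
  }
  adc_volume(vals, pixel_spacing = pd[1],
             slice_thickness = if (length(pd) >= 3) pd[3] else 1)
}

#' Read a 0/1 mask from NIfTI
#'
#' @inheritParams read_adc_volume
#' @param volume Optional [adc_volume()] to check grid congruence against.
#' @return A [lesion_mask()]. Values other than 0/1 (after rounding) are an
#'   error.
#' @export
read_mask <- function(path, volume = NULL) {
  img <- RNifti::readNifti(path)
  m <- lesion_mask(array(as.numeric(img), dim = dim(img)))
  if (!is.null(volume)) check_congruent(volume, m)
  m
}

#' Write a volume or mask to NIfTI
#'
#' @param x An [adc_volume()] or [lesion_mask()].
#' @param path Output path (.nii or .nii.gz).
#' @param geometry For masks, an [adc_volume()] supplying voxel geometry.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(x, path, geometry = NULL) {
  if (inherits(x, "adc_volume")) {
    img <- RNifti::asNifti(x$values)
    RNifti::pixdim(img) <- c(x$pixel_spacing, x$pixel_spacing,
                             x$slice_thickness)
  } else if (inherits(x, "lesion_mask")) {
    img <- RNifti::asNifti(array(as.integer(x$values), dim = dim(x$values)))
    if (!is.null(geometry)) {
      RNifti::pixdim(img) <- c(geometry$pixel_spacing,
                               geometry$pixel_spacing,
                               geometry$slice_thickness)
    }
  } else {
    stop("`x` must be an adc_volume or lesion_mask")
  }
  RNifti::writeNifti(img, path)
  invisible(path)
}

read_any_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop("readxl is required to read XLSX files")
    }
    as.data.frame(readxl::read_excel(path))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
}

apply_column_map <- function(df, column_map, required) {
  if (!is.null(column_map)) {
    for (target in names(column_map)) {
      src <- column_map[[target]]
      if (!src %in% names(df)) {
        stop("mapped column '", src, "' (for ", target, ") not in file; ",
             "available: ", paste(names(df), collapse = ", "))
      }
      names(df)[names(df) == src] <- target
    }
  }
  miss <- setdiff(required, names(df))
  if (length(miss) > 0) {
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         "; supply a column_map. Available: ",
         paste(names(df), collapse = ", "))
  }
  df
}

#' Read a reader-study measurement table
#'
#' Expects (possibly via `column_map`) columns lesion_id, reader_id, session,
#' adc_value, and optionally roi_size_mm2 / roi_volume_cm3. Validates that
#' values are finite and positive, sessions are in 1-3, and that each session
#' forms a complete block (every reader measured every lesion); violations
#' are errors naming the offending rows or cells.
#'
#' @param path CSV or XLSX file.
#' @param column_map Named character vector mapping canonical names to the
#'   file's column names, e.g. `c(adc_value = "ADC")`.
#' @return A validated data.frame.
#' @export
read_measurement_table <- function(path, column_map = NULL) {
  df <- read_any_table(path)
  df <- apply_column_map(df, column_map,
                         c("lesion_id", "reader_id", "session", "adc_value"))
  if (nrow(df) == 0) stop("measurement table is empty")
  bad <- which(!is.finite(df$adc_value) | df$adc_value <= 0)
  if (length(bad) > 0) {
    stop("non-positive or non-finite adc_value in row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  if (!all(df$session %in% 1:3)) {
    stop("session must be 1, 2 or 3; bad row(s): ",
         paste(utils::head(which(!df$session %in% 1:3), 5), collapse = ", "))
  }
  for (s in sort(unique(df$session))) check_complete_block(df, s)
  df
}

cohort_vocab <- list(pathology_class = c("benign", "GS6", "csPCa"),
                     zone = c("PZ", "TZ"))

#' Read a cohort table
#'
#' Expects (via `column_map` as needed) columns patient_id, lesion_id,
#' scanner_model, endorectal_coil, pathology_class, zone, and optionally
#' median_pz_adc, ref_9px, ref_p10. Categorical fields are validated against
#' a fixed vocabulary (pathology_class: benign/GS6/csPCa; zone: PZ/TZ);
#' invalid rows abort the read with their row numbers unless
#' `skip_invalid = TRUE`, in which case they are dropped with a warning.
#'
#' @inheritParams read_measurement_table
#' @param skip_invalid Drop invalid rows instead of erroring.
#' @return A validated data.frame.
#' @export
read_cohort_table <- function(path, column_map = NULL, skip_invalid = FALSE) {
  df <- read_any_table(path)
  if (nrow(df) == 0) stop("cohort table is empty")
  df <- apply_column_map(df, column_map,
                         c("patient_id", "lesion_id", "scanner_model",
                           "pathology_class", "zone"))
  bad <- which(!df$pathology_class %in% cohort_vocab$pathology_class |
                 !df$zone %in% cohort_vocab$zone)
  for (col in c("median_pz_adc", "ref_9px", "ref_p10")) {
    if (col %in% names(df)) {
      bad <- union(bad, which(!is.na(df[[col]]) & df[[col]] <= 0))
    }
  }
  bad <- sort(bad)
  if (length(bad) > 0) {
    msg <- paste0("invalid cohort row(s): ",
                  paste(utils::head(bad, 10), collapse = ", "),
                  " (pathology_class must be one of ",
                  paste(cohort_vocab$pathology_class, collapse = "/"),
                  "; zone PZ/TZ; ADC fields positive)")
    if (!skip_invalid) stop(msg)
    warning(msg, "; rows dropped")
    df <- df[-bad, , drop = FALSE]
  }
  df
}

#' Write per-size reference values to CSV
#'
#' @param ref_table A [reference_table()] data.frame (anchors already
#'   0-based).
#' @param path Output CSV.
#' @return `path`, invisibly.
#' @export
write_reference_csv <- function(ref_table, path) {
  utils::write.csv(ref_table, path, row.names = FALSE)
  invisible(path)
}

#' Machine-readable analysis report
#'
#' Serialises an [agreement_report()] result (plus anything else in
#' `results`) to JSON, with the sections `loa`, `icc`, `friedman`,
#' `posthoc` always present (empty when absent from `results`).
#'
#' @param results Named list, e.g. from [agreement_report()].
#' @param path Output JSON path; `NULL` returns the JSON string.
#' @return The JSON string, invisibly when written to a file.
#' @export
report_json <- function(results, path = NULL) {
  sections <- c("loa", "icc", "friedman", "posthoc")
  for (s in sections) if (is.null(results[[s]])) results[[s]] <- list()
  js <- jsonlite::toJSON(results, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", null = "null", pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
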