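# File-format adapters: 8-bit RGB PNG/TIFF images, schema-checked CSV
# tables, versioned JSON manifests.

MANIFEST_VERSION <- 1L

#' Read and write field images
#'
#' Lossless 8-bit RGB round trips. PNG is the default interchange format
#' (write-then-read is byte-identical); TIFF is supported when the `tiff`
#' package is installed. Grayscale or alpha-channel inputs are rejected:
#' the pipeline contract is 8-bit 3-channel RGB.
#'
#' @param image A [field_image()].
#' @param path Output/input file path.
#' @param pixel_scale Pixel scale to attach on read (px/um).
#' @param source_id Source id to attach on read; defaults to the file name.
#' @return `read_field_image()` returns a [field_image()];
#'   `write_field_image()` returns `path` invisibly.
#' @export
write_field_image <- function(image, path) {
  stopifnot(inherits(image, "field_image"))
  arr <- image$pixels / 255
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(arr, target = path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      abort("writing TIFF requires the 'tiff' package")
    }
    tiff::writeTIFF(arr, where = path, bits.per.sample = 8L)
  } else {
    abort(sprintf("unsupported image format '.%s' (use .png or .tif)", ext))
  }
  invisible(path)
}

#' @rdname write_field_image
#' @export
read_field_image <- function(path, pixel_scale = 1.9, source_id = NULL) {
  ext <- tolower(tools::file_ext(path))
  arr <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      abort("reading TIFF requires the 'tiff' package")
    }
    out <- tiff::readTIFF(path)
    if (is.list(out)) out[[1]] else out
  } else {
    abort(sprintf("unsupported image format '.%s' (use .png or .tif)", ext))
  }
  if (length(dim(arr)) != 3 || dim(arr)[3] != 3) {
    abort("image must be 3-channel RGB (8 bits per channel)")
  }
  px <- array(as.integer(round(arr * 255)), dim = dim(arr))
  field_image(px, pixel_scale = pixel_scale,
              source_id = source_id %||% basename(path))
}

# Schema-checked CSV reader: aborts naming the first missing column.
read_schema_csv <- function(path, required) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    abort(sprintf("%s: missing required column '%s'",
                  basename(path), missing_cols[1]))
  }
  as_tibble(df)
}

#' Read a per-cell scores table
#'
#' Schema: `patient_id, roi_id, score, atypical, bin` (extra columns pass
#' through). Aborts naming the first missing column.
#'
#' @param path CSV path.
#' @return Tibble.
#' @export
read_scores_csv <- function(path) {
  read_schema_csv(path, c("patient_id", "roi_id", "score"))
}

#' Read a per-patient features table
#'
#' Schema: `patient_id, class, n_cells, pct_atypical, mean_all,
#' mean_atypical` (an empty `mean_atypical` field means undefined).
#'
#' @param path CSV path.
#' @return Tibble.
#' @export
read_features_csv <- function(path) {
  read_schema_csv(path,
                  c("patient_id", "class", "n_cells", "pct_atypical",
                    "mean_all", "mean_atypical"))
}

write_table_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Versioned JSON manifests
#'
#' Run artifacts (ground truth, ROI tables, fitted models, run metadata)
#' are stored as JSON with a `manifest_version` field; reading a manifest
#' with an unknown version fails explicitly rather than guessing.
#'
#' @param x Named list to serialise.
#' @param path JSON path.
#' @return `read_manifest()` returns the parsed list (without the version
#'   field); `write_manifest()` returns `path` invisibly.
#' @export
write_manifest <- function(x, path) {
  stopifnot(is.list(x))
  x$manifest_version <- MANIFEST_VERSION
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  v <- x$manifest_version
  if (is.null(v) || !identical(as.integer(v), MANIFEST_VERSION)) {
    abort(sprintf("unsupported manifest version '%s' in %s (expected %d)",
                  v %||% "<missing>", basename(path), MANIFEST_VERSION))
  }
  x$manifest_version <- NULL
  x
}
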