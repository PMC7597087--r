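# Readers and writers for the image formats the tool touches: PNG and TIFF
# for 2D grayscale images and label maps, NIfTI for 3D volumes, CSV for seed
# coordinate lists. Intensities are scaled to [0, 1] on read by the
# container's bit-depth maximum; label images round-trip bit-exactly.

file_format <- function(path) {
  low <- tolower(path)
  if (grepl("\\.png$", low)) "png"
  else if (grepl("\\.tiff?$", low)) "tiff"
  else if (grepl("\\.nii(\\.gz)?$", low)) "nifti"
  else if (grepl("\\.csv$", low)) "csv"
  else stop("unsupported file format: ", path)
}

to_gray <- function(arr, path) {
  if (length(dim(arr)) == 3L) {
    nc <- dim(arr)[3L]
    if (nc >= 3L) {
      warning("RGB input ", basename(path), " converted to luminance")
      arr <- 0.2126 * arr[, , 1L] + 0.7152 * arr[, , 2L] + 0.0722 * arr[, , 3L]
    } else {
      arr <- arr[, , 1L]   # gray + alpha, or single channel in a 3D slot
    }
  }
  arr
}

nifti_type_max <- function(hdr) {
  # bit-depth maximum for common integer NIfTI datatypes; floating point
  # volumes are scaled by their own maximum
  switch(as.character(hdr$datatype),
         "2" = 255, "4" = 32767, "256" = 127, "512" = 65535, "768" = 2^32 - 1,
         NA_real_)
}

#' Read an image or volume as a feature grid
#'
#' Reads a 2D grayscale PNG/TIFF or a 3D NIfTI volume and returns intensities
#' scaled to [0, 1]. PNG and TIFF are decoded to [0, 1] by their bit depth;
#' RGB inputs are collapsed to luminance with a warning. Integer NIfTI
#' volumes are divided by their datatype maximum (8/12/16-bit scales);
#' floating-point or unrecognized volumes by their own maximum when they
#' exceed 1. The scaling applied and, for NIfTI, the image header are kept
#' as attributes for write-time passthrough.
#'
#' @param path File path (`.png`, `.tif(f)`, `.nii`, `.nii.gz`).
#' @return A matrix (2D) or array (3D) of intensities in [0, 1], with
#'   attributes `scale` and, for NIfTI, `nifti_header`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("cannot read ", path, ": no such file")
  fmt <- file_format(path)
  if (fmt == "png" || fmt == "tiff") {
    arr <- if (fmt == "png") png::readPNG(path) else tiff::readTIFF(path)
    img <- to_gray(arr, path)
    attr(img, "scale") <- 1        # decoders already map to [0, 1]
    return(img)
  }
  if (fmt == "nifti") {
    vol <- RNifti::readNifti(path)
    hdr <- RNifti::niftiHeader(vol)
    arr <- array(as.numeric(vol), dim = dim(vol))
    tmax <- nifti_type_max(hdr)
    if (is.na(tmax)) tmax <- max(arr, 1)
    arr <- arr / tmax
    arr[] <- pmin(pmax(arr, 0), 1)
    attr(arr, "scale") <- tmax
    attr(arr, "nifti_header") <- hdr
    return(arr)
  }
  stop("cannot read ", path, " as an image")
}

#' Write / read a label image
#'
#' Label grids (integer values, 0 = unlabeled or background) are stored as
#' integer images: 8-bit gray PNG/TIFF (labels up to 255) or NIfTI volumes.
#' `read_labels(write_labels(x, path))` is the identity. For NIfTI output a
#' `reference` image read with [read_image()] passes its header (affine
#' included) through to the label volume.
#'
#' @param labels Integer label grid (2D matrix or 3D array).
#' @param path Output path; format chosen by extension.
#' @param reference Optional NIfTI feature grid whose header is reused.
#' @return `write_labels` returns `path` invisibly; `read_labels` returns an
#'   integer label grid.
#' @export
write_labels <- function(labels, path, reference = NULL) {
  fmt <- file_format(path)
  lab <- as.integer(labels)
  if (anyNA(lab) || any(lab < 0L)) stop("labels must be integers >= 0")
  if (fmt == "png" || fmt == "tiff") {
    if (length(dim(labels)) != 2L) stop(fmt, " label output must be 2D")
    if (max(lab) > 255L)
      stop("label values exceed the 8-bit container (max 255)")
    img <- matrix(lab, dim(labels)[1L], dim(labels)[2L]) / 255
    if (fmt == "png") png::writePNG(img, path)
    else tiff::writeTIFF(img, path, bits.per.sample = 8L)
  } else if (fmt == "nifti") {
    arr <- array(lab, dim = dim(labels))
    tmpl <- attr(reference, "nifti_header")
    if (!is.null(tmpl)) {
      RNifti::writeNifti(RNifti::asNifti(arr, reference = tmpl), path)
    } else {
      RNifti::writeNifti(arr, path)
    }
  } else stop("unsupported label format: ", path)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  fmt <- file_format(path)
  if (fmt == "png" || fmt == "tiff") {
    arr <- to_gray(if (fmt == "png") png::readPNG(path)
                   else tiff::readTIFF(path), path)
    lab <- round(arr * 255)
  } else if (fmt == "nifti") {
    vol <- RNifti::readNifti(path)
    lab <- round(array(as.numeric(vol), dim = dim(vol)))
  } else stop("unsupported label format: ", path)
  storage.mode(lab) <- "integer"
  lab
}

#' Read / write seed maps
#'
#' Seeds travel either as a label image (0 = unlabeled, read through
#' [read_labels()]) or as a CSV of `row, col[, slice], label` rows (1-based
#' coordinates). A seed image containing only zeros yields an empty seed map
#' with a warning.
#'
#' @param path Seed file (`.csv`, or any label-image format).
#' @return `read_seeds` returns a seed data frame; `write_seeds` returns
#'   `path` invisibly.
#' @export
read_seeds <- function(path) {
  if (file_format(path) == "csv") {
    df <- read.csv(path)
    need <- c("row", "col", "label")
    if (!all(need %in% names(df)))
      stop("seed CSV needs columns row, col[, slice], label")
    return(df)
  }
  grid <- read_labels(path)
  idx <- which(grid > 0L, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    warning("seed image ", basename(path), " contains no labeled pixels")
  }
  df <- as.data.frame(idx)
  names(df) <- c("row", "col", "slice")[seq_len(ncol(idx))]
  df$label <- grid[idx]
  df
}

#' @rdname read_seeds
#' @param seeds Seed data frame to write.
#' @export
write_seeds <- function(seeds, path) {
  if (file_format(path) != "csv")
    stop("write_seeds writes CSV; use write_labels for seed images")
  write.csv(seeds, path, row.names = FALSE)
  invisible(path)
}

#' Seed map from / to a label grid
#'
#' @param grid Integer label grid (0 = unlabeled).
#' @return `seeds_from_grid`: a seed data frame. `seeds_to_grid`: an integer
#'   label grid of the given shape.
#' @export
seeds_from_grid <- function(grid) {
  idx <- which(grid > 0L, arr.ind = TRUE)
  df <- as.data.frame(idx)
  names(df) <- c("row", "col", "slice")[seq_len(ncol(idx))]
  df$label <- grid[idx]
  df
}

#' @rdname seeds_from_grid
#' @param seeds Seed data frame.
#' @param shape Grid extents.
#' @export
seeds_to_grid <- function(seeds, shape) {
  resolve_seeds(seeds, as.integer(shape))$labels
}
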