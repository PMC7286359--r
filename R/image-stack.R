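#' Image stack and projection containers
#'
#' `image_stack()` wraps one fluorescence channel's 3-D intensity volume
#' together with its physical calibration. Voxel arrays are ordered
#' `(z, y, x)`; under the package-wide axis convention, ventral is
#' increasing `y` and anterior is decreasing `x`.
#'
#' All public voxel/pixel coordinates in this package are **0-based**, and
#' index ranges are **half-open** `[lo, hi)`, matching the conventions of
#' the image formats the package reads and writes. Conversion to R's
#' 1-based array indexing happens internally.
#'
#' @param voxels 3-D numeric array, dimensions `(z, y, x)`, finite and
#'   non-negative.
#' @param voxel_size Numeric length-3, physical voxel size in micrometres
#'   as `(z, y, x)`; all entries strictly positive.
#' @param channel Channel label, e.g. `"ligand"`, `"pip2"`, `"red"`.
#' @return An object of class `image_stack`.
#' @examples
#' s <- image_stack(array(1, c(3, 4, 4)), voxel_size = c(0.13, 0.1, 0.1))
#' dim_zyx(s)
#' @export
image_stack <- function(voxels, voxel_size = c(0.13, 0.1, 0.1), channel = "") {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    abort_acq("`voxels` must be a 3-D array ordered (z, y, x)", "acquant_bad_param")
  if (!is.numeric(voxel_size) || length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0))
    abort_acq("`voxel_size` must be 3 strictly positive numbers (z, y, x) in um",
              "acquant_bad_param")
  if (any(!is.finite(voxels)))
    abort_acq("stack intensities must be finite", "acquant_bad_param")
  structure(
    list(voxels = voxels, voxel_size = as.numeric(voxel_size),
         channel = as.character(channel)),
    class = "image_stack")
}

#' @rdname image_stack
#' @param x An `image_stack`.
#' @return `dim_zyx()`: the integer `(z, y, x)` extent.
#' @export
dim_zyx <- function(x) {
  stopifnot(inherits(x, "image_stack"))
  dim(x$voxels)
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<image_stack> %s  %d x %d x %d (z,y,x) voxels, %.3g x %.3g x %.3g um\n",
              if (nzchar(x$channel)) x$channel else "(unlabelled)",
              d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  cat(sprintf("  intensity range [%.4g, %.4g]\n", min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @param pixels 2-D numeric matrix `(y, x)`.
#' @param provenance List describing how the projection was made (source
#'   stack label, z-range, processing steps).
#' @rdname image_stack
#' @export
projection <- function(pixels, provenance = list()) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    abort_acq("`pixels` must be a numeric matrix (y, x)", "acquant_bad_param")
  structure(list(pixels = pixels, provenance = provenance), class = "projection")
}

#' @export
print.projection <- function(x, ...) {
  cat(sprintf("<projection> %d x %d (y,x), range [%.4g, %.4g]\n",
              nrow(x$pixels), ncol(x$pixels), min(x$pixels), max(x$pixels)))
  if (length(x$provenance))
    cat("  provenance:", paste(names(x$provenance), collapse = ", "), "\n")
  invisible(x)
}

sidecar_path <- function(path) paste0(path, ".yaml")

#' Read and write calibrated TIFF stacks
#'
#' Stacks are stored as multi-page grayscale TIFF plus a YAML sidecar
#' (`<path>.yaml`) carrying the calibration (voxel size in um, channel
#' label, storage encoding). Integer data up to 16 bit round-trips
#' bit-identically; other data is stored as 32-bit float scaled to
#' `[0, 1]` with the scale factor recorded in the sidecar.
#'
#' @param path TIFF file path.
#' @param voxel_size Optional calibration override when no sidecar exists.
#' @return `read_stack()` returns an [image_stack()].
#' @export
read_stack <- function(path, voxel_size = NULL) {
  if (!file.exists(path))
    abort_acq(sprintf("no such file: %s", path), "acquant_io_error")
  meta <- NULL
  if (file.exists(sidecar_path(path))) meta <- yaml::read_yaml(sidecar_path(path))
  if (is.null(voxel_size)) {
    if (is.null(meta$voxel_size_um))
      abort_acq(paste0("missing calibration for ", path,
                       ": supply `voxel_size` or a sidecar ", sidecar_path(path),
                       " with a `voxel_size_um: [z, y, x]` entry"),
                "acquant_missing_calibration")
    voxel_size <- as.numeric(meta$voxel_size_um)
  }
  integer_data <- is.null(meta$encoding) || identical(meta$encoding, "uint16")
  pages <- tiff::readTIFF(path, all = TRUE, as.is = integer_data)
  if (!is.list(pages)) pages <- list(pages)
  for (p in pages) {
    if (length(dim(p)) > 2L)
      abort_acq("multi-sample (RGB) TIFF pages are not supported; expected grayscale",
                "acquant_unsupported_format")
  }
  shp <- vapply(pages, dim, integer(2))
  if (any(shp[1, ] != shp[1, 1]) || any(shp[2, ] != shp[2, 1]))
    abort_acq("TIFF pages have mismatched shapes", "acquant_unsupported_format")
  vox <- array(0, c(length(pages), shp[1, 1], shp[2, 1]))
  for (i in seq_along(pages)) vox[i, , ] <- pages[[i]]
  if (!integer_data && !is.null(meta$scale_factor))
    vox <- vox * meta$scale_factor
  image_stack(vox, voxel_size = voxel_size,
              channel = if (!is.null(meta$channel)) meta$channel else "")
}

#' @param stack An [image_stack()].
#' @rdname read_stack
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  v <- stack$voxels
  is_int <- all(v == round(v)) && max(v) <= 65535 && min(v) >= 0
  pages <- lapply(seq_len(dim(v)[1]), function(z) v[z, , ])
  meta <- list(voxel_size_um = stack$voxel_size, channel = stack$channel)
  if (is_int) {
    tiff::writeTIFF(lapply(pages, function(p) p / 65535), path, bits.per.sample = 16L)
    meta$encoding <- "uint16"
  } else {
    sf <- max(v, 1e-12)
    tiff::writeTIFF(lapply(pages, function(p) p / sf), path, bits.per.sample = 32L)
    meta$encoding <- "float32"
    meta$scale_factor <- sf
  }
  yaml::write_yaml(meta, sidecar_path(path))
  invisible(path)
}
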