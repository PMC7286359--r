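#' Flat-field / dark-field illumination correction
#'
#' Applies the standard two-image correction: each slice becomes
#' `(raw - dark) / (flat - dark) * mean(flat - dark)`, so a spatially
#' uniform specimen imaged under the recorded illumination field comes out
#' uniform at its original mean level. Output is clamped at 0.
#'
#' @param stack An [image_stack()].
#' @param flatfield,darkfield [projection()] objects (blank and dark-field
#'   images) whose shape matches the stack's slices. `darkfield` defaults
#'   to all-zero.
#' @return A corrected [image_stack()].
#' @export
correct_illumination <- function(stack, flatfield, darkfield = NULL) {
  stopifnot(inherits(stack, "image_stack"), inherits(flatfield, "projection"))
  d <- dim(stack$voxels)
  if (is.null(darkfield)) darkfield <- projection(matrix(0, d[2], d[3]))
  stopifnot(inherits(darkfield, "projection"))
  if (!identical(dim(flatfield$pixels), d[2:3]) ||
      !identical(dim(darkfield$pixels), d[2:3]))
    abort_acq("flat/dark field shape does not match slice shape", "acquant_bad_param")
  denom <- flatfield$pixels - darkfield$pixels
  bad <- sum(denom <= 0)
  if (bad > 0)
    abort_acq(sprintf("flat - dark is not strictly positive (%d pixel(s) <= 0)", bad),
              "acquant_bad_calibration")
  gain <- mean(denom) / denom
  out <- stack$voxels
  for (z in seq_len(d[1]))
    out[z, , ] <- pmax((out[z, , ] - darkfield$pixels) * gain, 0)
  image_stack(out, stack$voxel_size, stack$channel)
}

#' Summed z-projection of a slab
#'
#' Pixelwise sum over the slices in `z_range`, the projection used for all
#' intensity measurements in this pipeline (polarity indices are ratios of
#' means over a summed projection of the slab spanning the anchor cell;
#' biosensor ratios use the five central slices around the nuclear focus).
#'
#' @param stack An [image_stack()].
#' @param z_range Half-open 0-based slice range `c(lo, hi)`; default the
#'   full stack.
#' @return A [projection()] whose provenance records the source channel
#'   and z-range.
#' @export
sum_projection <- function(stack, z_range = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  nz <- dim(stack$voxels)[1]
  if (is.null(z_range)) z_range <- c(0L, nz)
  z_range <- as.integer(z_range)
  if (length(z_range) != 2L || z_range[1] < 0L || z_range[2] > nz ||
      z_range[1] >= z_range[2])
    abort_acq(sprintf("empty or out-of-bounds z_range [%d, %d) for %d slices",
                      z_range[1], z_range[2], nz), "acquant_bad_param")
  idx <- (z_range[1] + 1L):z_range[2]
  px <- if (length(idx) == 1L) stack$voxels[idx, , ]
        else apply(stack$voxels[idx, , , drop = FALSE], c(2, 3), sum)
  projection(px, provenance = list(channel = stack$channel,
                                   z_range = z_range, op = "sum_projection"))
}

#' Central-slice window around a focus plane
#'
#' Returns the `k`-slice half-open z-range centred on `focus_z` (for even
#' `k`, the extra slice falls below the focus), truncated at the stack
#' boundaries with a warning.
#'
#' @param stack An [image_stack()].
#' @param focus_z 0-based focus slice (e.g. the focus of the nuclear H2B
#'   signal).
#' @param k Number of slices (default 5, the window used for biosensor
#'   quantification).
#' @return Integer `c(lo, hi)`, half-open, 0-based.
#' @export
central_slices <- function(stack, focus_z, k = 5L) {
  stopifnot(inherits(stack, "image_stack"))
  nz <- dim(stack$voxels)[1]
  focus_z <- as.integer(focus_z); k <- as.integer(k)
  if (k < 1L) abort_acq("`k` must be >= 1", "acquant_bad_param")
  if (focus_z < 0L || focus_z >= nz)
    abort_acq("`focus_z` outside the stack", "acquant_bad_param")
  lo <- focus_z - k %/% 2L
  hi <- lo + k
  tlo <- max(lo, 0L); thi <- min(hi, nz)
  if (tlo != lo || thi != hi)
    warning(sprintf("central_slices window [%d, %d) truncated to [%d, %d) at stack boundary",
                    lo, hi, tlo, thi))
  c(tlo, thi)
}

#' Background subtraction outside a mask
#'
#' Subtracts the median intensity of the pixels *outside* `mask` (the
#' region of interest, e.g. the AC footprint) from the whole projection
#' and clamps at 0. The median is robust against the bright in-mask tail
#' leaking into the background estimate.
#'
#' @param proj A [projection()].
#' @param mask Logical matrix, same shape; `TRUE` marks the object.
#' @return Background-subtracted [projection()]; the subtracted level is
#'   recorded in provenance.
#' @export
subtract_background <- function(proj, mask) {
  stopifnot(inherits(proj, "projection"))
  if (!is.logical(mask) || !identical(dim(mask), dim(proj$pixels)))
    abort_acq("`mask` must be a logical matrix matching the projection",
              "acquant_bad_param")
  if (all(mask) || !any(mask))
    abort_acq("mask must be non-empty and strictly smaller than the image",
              "acquant_bad_param")
  bg <- stats::median(proj$pixels[!mask])
  projection(pmax(proj$pixels - bg, 0),
             provenance = c(proj$provenance,
                            list(background_subtracted = bg,
                                 background_estimator = "median outside mask")))
}
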