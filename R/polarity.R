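# AC segmentation and the dorso-ventral / anterior-posterior polarity
# indices computed on summed z-projections.

# 8-connected component of `bin` containing the (1-based) seed index,
# by iterated 3x3 dilation restricted to `bin`.
flood_component8 <- function(bin, seed_rc) {
  comp <- matrix(FALSE, nrow(bin), ncol(bin))
  comp[seed_rc[1], seed_rc[2]] <- TRUE
  repeat {
    grown <- comp
    grown[-1, ] <- grown[-1, ] | comp[-nrow(comp), ]
    grown[-nrow(comp), ] <- grown[-nrow(comp), ] | comp[-1, ]
    grown[, -1] <- grown[, -1] | grown[, -ncol(comp)]
    grown[, -ncol(comp)] <- grown[, -ncol(comp)] | grown[, -1]
    grown <- grown & bin
    if (identical(grown, comp)) break
    comp <- grown
  }
  comp
}

#' Segment the anchor cell in a projection
#'
#' Thresholds the projection with Otsu's method computed inside a window
#' around the seed centroid (robust to other fluorescent cells elsewhere
#' in the frame), keeps the 8-connected supra-threshold component
#' containing the seed, and fills holes. The resulting mask is the "set
#' pixel intensities outside of the AC to zero" step expressed as an
#' explicit ROI.
#'
#' @param proj A [projection()] (summed z-projection across the AC).
#' @param seed_centroid `(y, x)` 0-based pixel coordinates of the AC
#'   nucleus centre.
#' @param window_halfwidth Half-width in pixels of the square Otsu window
#'   centred on the seed; default 24 (about 1.5 nucleus diameters around
#'   a typical AC at 0.1 um pixels). `Inf` uses the whole image.
#' @return List of class `ac_mask`: `pixels` (logical matrix),
#'   `seed_centroid`, `threshold`.
#' @export
segment_ac <- function(proj, seed_centroid, window_halfwidth = 24) {
  stopifnot(inherits(proj, "projection"))
  px <- proj$pixels
  sy <- round(seed_centroid[1]) + 1L; sx <- round(seed_centroid[2]) + 1L
  if (sy < 1L || sy > nrow(px) || sx < 1L || sx > ncol(px))
    abort_acq("seed centroid outside the image", "acquant_bad_param")
  ys <- max(1L, sy - window_halfwidth):min(nrow(px), sy + window_halfwidth)
  xs <- max(1L, sx - window_halfwidth):min(ncol(px), sx + window_halfwidth)
  win <- px[ys, xs]
  mx <- max(win)
  if (mx <= 0)
    abort_acq("segmentation failure: window has no signal", "acquant_segmentation_failure")
  th <- EBImage::otsu(EBImage::Image(win / mx), range = c(0, 1)) * mx
  bin <- px > th
  if (!any(bin))
    abort_acq(sprintf("segmentation failure: no pixel above Otsu threshold %.4g", th),
              "acquant_segmentation_failure", threshold = th)
  if (!bin[sy, sx])
    abort_acq(sprintf("segmentation failure: seed pixel below Otsu threshold %.4g", th),
              "acquant_segmentation_failure", threshold = th)
  comp <- flood_component8(bin, c(sy, sx))
  comp <- EBImage::imageData(EBImage::fillHull(EBImage::Image(comp * 1))) > 0
  structure(list(pixels = comp, seed_centroid = seed_centroid, threshold = th),
            class = "ac_mask")
}

#' Two-compartment polarity index of a masked projection
#'
#' Splits the mask pixels by the line through `split_centroid`
#' perpendicular to the chosen axis and returns the ratio of the two
#' half mean intensities. For the DV axis the ratio is oriented
#' ventral/dorsal (ventral = increasing y), so values above 1 mean
#' ventral enrichment; for the AP axis it is proximal/distal, where the
#' proximal side (toward the nearest VPC) is named by `orientation`.
#' Pixels exactly on the split line belong to neither half.
#'
#' @param proj A [projection()]; intensities should already be
#'   background-subtracted (see [subtract_background()]) --- any constant
#'   offset inside the mask biases the ratio toward 1.
#' @param mask An `ac_mask` from [segment_ac()], or a logical matrix.
#' @param split_centroid `(y, x)` 0-based coordinates of the AC nucleus
#'   centre defining the split line.
#' @param axis `"dv"` or `"ap"`.
#' @param orientation For `"ap"`: which side is proximal to the nearest
#'   VPC, `"anterior"` (decreasing x) or `"posterior"`. Ignored for
#'   `"dv"`.
#' @return List of class `polarity_result`: `index`, the two half means
#'   (named `ventral_mean`/`dorsal_mean` or `proximal_mean`/
#'   `distal_mean`), half pixel areas, `axis`, and `area_imbalance_flag`
#'   (TRUE when the half areas differ by more than 25%, worth reviewing
#'   since the split line need not bisect the mask area).
#' @examples
#' p <- projection(matrix(c(2, 3, 4, 6), 2, 2))  # rows = y
#' m <- matrix(TRUE, 2, 2)
#' polarity_index(p, m, split_centroid = c(0.5, 0.5))$index  # 5/2.5 = 2
#' @export
polarity_index <- function(proj, mask, split_centroid, axis = c("dv", "ap"),
                           orientation = c("anterior", "posterior")) {
  stopifnot(inherits(proj, "projection"))
  axis <- match.arg(axis)
  orientation <- match.arg(orientation)
  m <- if (inherits(mask, "ac_mask")) mask$pixels else mask
  if (!is.logical(m) || !identical(dim(m), dim(proj$pixels)))
    abort_acq("mask must match the projection", "acquant_bad_param")
  ycoord <- matrix(rep(0:(nrow(m) - 1), ncol(m)), nrow(m))
  xcoord <- matrix(rep(0:(ncol(m) - 1), each = nrow(m)), nrow(m))
  if (axis == "dv") {
    hi <- m & ycoord > split_centroid[1]   # ventral
    lo <- m & ycoord < split_centroid[1]   # dorsal
    nm <- c("ventral_mean", "dorsal_mean")
  } else {
    prox_is_anterior <- orientation == "anterior"
    hi <- m & (if (prox_is_anterior) xcoord < split_centroid[2] else xcoord > split_centroid[2])
    lo <- m & (if (prox_is_anterior) xcoord > split_centroid[2] else xcoord < split_centroid[2])
    nm <- c("proximal_mean", "distal_mean")
  }
  if (!any(hi) || !any(lo))
    abort_acq("undefined polarity index: a half-compartment contains no mask pixels",
              "acquant_undefined_index")
  mu_hi <- mean(proj$pixels[hi]); mu_lo <- mean(proj$pixels[lo])
  if (mu_lo == 0)
    abort_acq("infinite polarity index: denominator half has zero mean intensity",
              "acquant_infinite_index")
  areas <- c(sum(hi), sum(lo))
  res <- list(index = mu_hi / mu_lo, axis = axis,
              half_areas = areas,
              area_imbalance_flag = abs(diff(areas)) / mean(areas) > 0.25)
  res[[nm[1]]] <- mu_hi; res[[nm[2]]] <- mu_lo
  structure(res, class = "polarity_result")
}

#' @export
print.polarity_result <- function(x, ...) {
  cat(sprintf("<polarity_result> I_%s = %.4g  (half means %.4g / %.4g, areas %d / %d%s)\n",
              toupper(x$axis), x$index,
              if (x$axis == "dv") x$ventral_mean else x$proximal_mean,
              if (x$axis == "dv") x$dorsal_mean else x$distal_mean,
              x$half_areas[1], x$half_areas[2],
              if (x$area_imbalance_flag) ", area-imbalance flag" else ""))
  invisible(x)
}

#' Classify an animal as polarized
#'
#' Strict threshold exceedance, `index > threshold`. Default thresholds:
#' 1.1 for the ligand reporter and 1.2 for the PIP2 membrane marker
#' (approximately the 10th percentile of wild-type cohorts).
#'
#' @param index Polarity index value(s).
#' @param threshold Classification threshold.
#' @return Logical vector.
#' @export
classify_polarized <- function(index, threshold = 1.1) {
  if (any(!is.finite(index)) || any(index <= 0))
    abort_acq("polarity indices must be finite and positive", "acquant_bad_param")
  index > threshold
}

#' Fraction of a cohort above a polarity threshold, with bootstrap CI
#'
#' @param indices Numeric vector of per-animal polarity indices.
#' @param threshold Threshold (strict `>`).
#' @param n_resamples Bootstrap resamples for the 95% CI.
#' @param seed RNG seed for the bootstrap.
#' @return List: `fraction`, `ci95`, `n`, plus the underlying
#'   [bootstrap_mean()] result.
#' @export
fraction_polarized <- function(indices, threshold = 1.1, n_resamples = 10000L,
                               seed = 1L) {
  if (length(indices) < 1L) abort_acq("empty cohort", "acquant_bad_param")
  hits <- as.numeric(classify_polarized(indices, threshold))
  bs <- bootstrap_mean(hits, n_resamples = n_resamples, seed = seed)
  list(fraction = mean(hits), ci95 = bs$ci95, n = length(indices), bootstrap = bs)
}

#' Per-animal polarity cross-tabulation and depolarization comparison
#'
#' Classifies each animal of a cohort by (ligand polarized?, PIP2
#' polarized?) into a 2x2 table. When a `reference` cohort is given, the
#' fractions of animals with *both* markers depolarized are compared
#' between the two cohorts with Fisher's exact test.
#'
#' @param cohort Data frame with columns `animal_id`, `ligand_index`,
#'   `pip2_index` (paired per animal; `NA` in either index is an error).
#' @param reference Optional second cohort, same format.
#' @param ligand_threshold,pip2_threshold Polarity thresholds (defaults
#'   1.1 and 1.2).
#' @return List: `table` (2x2, ligand rows x PIP2 columns,
#'   polarized/depolarized), `both_depolarized` count; with `reference`,
#'   also `reference_table`, `fisher_p`.
#' @export
depolarization_crosstab <- function(cohort, reference = NULL,
                                    ligand_threshold = 1.1, pip2_threshold = 1.2) {
  tab1 <- crosstab_one(cohort, ligand_threshold, pip2_threshold)
  out <- list(table = tab1$table, both_depolarized = tab1$both,
              n = tab1$n)
  if (!is.null(reference)) {
    tab2 <- crosstab_one(reference, ligand_threshold, pip2_threshold)
    out$reference_table <- tab2$table
    cmp <- matrix(c(tab1$both, tab1$n - tab1$both,
                    tab2$both, tab2$n - tab2$both), 2, byrow = TRUE,
                  dimnames = list(c("cohort", "reference"),
                                  c("both_depolarized", "other")))
    out$comparison <- cmp
    out$fisher_p <- fisher_exact(cmp)$p
  }
  out
}

crosstab_one <- function(cohort, lt, pt) {
  need <- c("animal_id", "ligand_index", "pip2_index")
  if (!all(need %in% names(cohort)))
    abort_acq("cohort must have animal_id, ligand_index, pip2_index columns",
              "acquant_bad_param")
  bad <- cohort$animal_id[!is.finite(cohort$ligand_index) |
                          !is.finite(cohort$pip2_index)]
  if (length(bad))
    abort_acq(paste0("unpaired polarity records for animal(s): ",
                     paste(bad, collapse = ", ")), "acquant_unpaired_records")
  lig <- factor(ifelse(cohort$ligand_index > lt, "polarized", "depolarized"),
                levels = c("polarized", "depolarized"))
  pip <- factor(ifelse(cohort$pip2_index > pt, "polarized", "depolarized"),
                levels = c("polarized", "depolarized"))
  tab <- table(ligand = lig, pip2 = pip)
  list(table = tab, both = tab["depolarized", "depolarized"], n = nrow(cohort))
}

#' Quantify AC polarity for one animal end-to-end
#'
#' Convenience wrapper running the full per-animal chain on an attached
#' ligand stack: summed z-projection over the whole stack, AC
#' segmentation seeded at the given centre, background subtraction
#' (median outside the mask), and both polarity indices.
#'
#' @param stack [image_stack()] across the AC.
#' @param center_yx AC nucleus centre, `(y, x)` 0-based pixels.
#' @param ap_orientation Which side is proximal to the nearest VPC
#'   (`"anterior"` or `"posterior"`).
#' @param window_halfwidth Passed to [segment_ac()].
#' @return List: `i_dv`, `i_ap` ([polarity_result]s), `mask`,
#'   `projection`.
#' @export
quantify_ac_polarity <- function(stack, center_yx, ap_orientation = "anterior",
                                 window_halfwidth = 24) {
  proj <- sum_projection(stack)
  mask <- segment_ac(proj, center_yx, window_halfwidth = window_halfwidth)
  proj_bs <- subtract_background(proj, mask$pixels)
  list(i_dv = polarity_index(proj_bs, mask, center_yx, axis = "dv"),
       i_ap = polarity_index(proj_bs, mask, center_yx, axis = "ap",
                             orientation = ap_orientation),
       mask = mask, projection = proj_bs)
}
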