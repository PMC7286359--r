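# ERK kinase-translocation-reporter (KTR) quantification: nuclear
# red/green ratios per VPC, per-animal normalization and the
# highest-in-P6.p call.

#' Nuclear red/green ratio at one VPC
#'
#' Segments the nucleus on the red (H2B) channel --- the activity-neutral
#' channel --- from a summed projection of the five central slices around
#' `focus_z`, and applies the identical mask to both channels' summed
#' projections. MPK-1 activity is read out as the nuclear mean red
#' divided by the nuclear mean green (the KTR reporter leaves the nucleus
#' when phosphorylated, so higher activity means a higher ratio).
#'
#' @param red_stack,green_stack Calibrated, illumination-corrected
#'   [image_stack()]s of the H2B (red) and KTR (green) channels.
#' @param nucleus_centroid `(y, x)` 0-based pixel coordinates of the
#'   nucleus.
#' @param focus_z 0-based focus slice of the nuclear red signal.
#' @param k Slices in the central window (default 5).
#' @param window_halfwidth Otsu window half-width for nucleus
#'   segmentation (default 10 px).
#' @return List: `red_mean`, `green_mean`, `ratio`, `mask`.
#' @export
measure_nuclear_ratio <- function(red_stack, green_stack, nucleus_centroid,
                                  focus_z, k = 5L, window_halfwidth = 10) {
  stopifnot(inherits(red_stack, "image_stack"), inherits(green_stack, "image_stack"))
  zr <- central_slices(red_stack, focus_z, k)
  red_p <- sum_projection(red_stack, zr)
  green_p <- sum_projection(green_stack, zr)
  mask <- segment_ac(red_p, nucleus_centroid, window_halfwidth = window_halfwidth)
  red_mean <- mean(red_p$pixels[mask$pixels])
  green_mean <- mean(green_p$pixels[mask$pixels])
  if (green_mean == 0)
    abort_acq("green nuclear mean is zero: ratio undefined", "acquant_infinite_index")
  list(red_mean = red_mean, green_mean = green_mean,
       ratio = red_mean / green_mean, mask = mask)
}

vpc5 <- paste0("P", 4:8, ".p")

#' Normalize a per-animal biosensor profile
#'
#' Divides each VPC's red/green ratio by the arithmetic mean of the five
#' ratios P4.p-P8.p of the same animal, so normalized values average to 1
#' per animal and are comparable across animals. Normalization is to the
#' five-cell mean rather than to P4.p, since no VPC can be assumed
#' unaffected. P3.p is excluded throughout (it adopts a VPC fate in only
#' about half of all animals).
#'
#' @param ratios Named numeric vector of raw red/green ratios for
#'   `P4.p ... P8.p` (all five present, positive).
#' @return Named numeric vector of normalized ratios (mean 1).
#' @examples
#' normalize_profile(c(P4.p = 1, P5.p = 1, P6.p = 2, P7.p = 1, P8.p = 1))
#' @export
normalize_profile <- function(ratios) {
  if (is.null(names(ratios)) && length(ratios) == 5L) names(ratios) <- vpc5
  missing <- setdiff(vpc5, names(ratios))
  if (length(missing))
    abort_acq(paste0("missing VPC ratio(s): ", paste(missing, collapse = ", ")),
              "acquant_missing_vpc")
  r <- ratios[vpc5]
  if (any(!is.finite(r)) || any(r <= 0))
    abort_acq("ratios must be finite and positive", "acquant_bad_param")
  r / mean(r)
}

#' Is biosensor activity highest in P6.p?
#'
#' TRUE iff P6.p's normalized ratio is the strict maximum over
#' P4.p-P8.p; exact ties are counted as not-highest (conservative) and
#' logged.
#'
#' @param profile Named numeric vector of (normalized or raw) ratios for
#'   P4.p-P8.p.
#' @return Logical scalar.
#' @export
call_highest_p6p <- function(profile) {
  r <- normalize_profile(profile)   # validates completeness; scale-free call
  mx <- max(r)
  if (r["P6.p"] == mx && sum(r == mx) > 1L) {
    message("highest-activity tie involving P6.p: counted as not highest")
    return(FALSE)
  }
  unname(r["P6.p"] == mx)
}

#' Cohort fraction with highest activity in P6.p, with bootstrap CI
#'
#' @param profiles List of per-animal ratio vectors (P4.p-P8.p), or a
#'   logical vector of precomputed calls.
#' @param n_resamples Bootstrap resamples (default 10,000).
#' @param seed RNG seed.
#' @return List: `fraction`, `ci95`, `n`, `bootstrap`.
#' @export
cohort_highest_fraction <- function(profiles, n_resamples = 10000L, seed = 1L) {
  if (length(profiles) < 1L) abort_acq("empty cohort", "acquant_bad_param")
  calls <- if (is.logical(profiles)) profiles
           else vapply(profiles, call_highest_p6p, logical(1))
  bs <- bootstrap_mean(as.numeric(calls), n_resamples = n_resamples, seed = seed)
  list(fraction = mean(calls), ci95 = bs$ci95, n = length(calls), bootstrap = bs)
}

#' Quantify a biosensor animal end-to-end
#'
#' Runs [measure_nuclear_ratio()] at each of the five VPC nuclei,
#' normalizes the profile and makes the highest-in-P6.p call.
#'
#' @param red_stack,green_stack The two channel stacks.
#' @param centroids_px 5 x 2 matrix of `(y, x)` 0-based nucleus centroids
#'   (P4.p-P8.p rows).
#' @param focus_z 0-based focus slice.
#' @param ... Passed to [measure_nuclear_ratio()].
#' @return Data frame (one row per VPC): `vpc`, `red_mean`, `green_mean`,
#'   `ratio`, `normalized_ratio`; attribute `highest_is_p6p`.
#' @export
quantify_biosensor <- function(red_stack, green_stack, centroids_px, focus_z, ...) {
  if (nrow(centroids_px) != 5L)
    abort_acq("need 5 nucleus centroids (P4.p-P8.p)", "acquant_bad_param")
  meas <- lapply(seq_len(5L), function(i)
    measure_nuclear_ratio(red_stack, green_stack, centroids_px[i, ], focus_z, ...))
  ratios <- stats::setNames(vapply(meas, `[[`, numeric(1), "ratio"), vpc5)
  norm <- normalize_profile(ratios)
  out <- data.frame(vpc = vpc5,
                    red_mean = vapply(meas, `[[`, numeric(1), "red_mean"),
                    green_mean = vapply(meas, `[[`, numeric(1), "green_mean"),
                    ratio = unname(ratios), normalized_ratio = unname(norm),
                    stringsAsFactors = FALSE)
  attr(out, "highest_is_p6p") <- call_highest_p6p(ratios)
  out
}
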