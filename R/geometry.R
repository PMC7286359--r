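# Developmental staging, nearest-VPC identification and the AC-to-P6.p
# alignment index R.

#' Developmental stage from gonad length
#'
#' Bins the gonad length (um) into the larval stages used for cohort
#' stratification: early/mid-L2 for 30-70 um, late L2 for 70-110 um and
#' early/mid-L3 for 110-150 um. Bins are half-open, lower-inclusive
#' (70 um is late L2); lengths outside 30-150 um return
#' `"out-of-range"` rather than an error.
#'
#' @param length_um Gonad length in micrometres (> 0), vectorised.
#' @return Character vector of stage labels.
#' @examples
#' stage_from_gonad_length(c(50, 70, 120, 160))
#' @export
stage_from_gonad_length <- function(length_um) {
  if (any(!is.finite(length_um)) || any(length_um <= 0))
    abort_acq("gonad length must be positive", "acquant_bad_param")
  ifelse(length_um < 30, "out-of-range",
  ifelse(length_um < 70, "early/mid-L2",
  ifelse(length_um < 110, "late-L2",
  ifelse(length_um <= 150, "early/mid-L3", "out-of-range"))))
}

euclid <- function(a, b) sqrt(sum((a - b)^2))

#' AC-to-VPC alignment index R
#'
#' R is the distance from the AC to the target VPC (normally P6.p, or
#' the nearest VPC), divided by the distance from the target to its
#' flanking reference VPC --- P5.p when the AC lies anterior of the
#' target, P7.p when posterior (an exact tie uses P5.p and is logged).
#' R = 0 means the AC sits exactly on the target; R = 0.5 puts it at the
#' midpoint of the target-reference segment. Distances are Euclidean in
#' the projection plane, in micrometres, centroid to centroid.
#'
#' @param animal An [annotated_animal()] with the target and both its
#'   neighbours (as required) annotated.
#' @param target_vpc Target VPC label, default `"P6.p"`.
#' @return List of class `alignment_result`: `r_index`, `nearest_vpc`,
#'   `reference_vpc`, `d_ac_vpc` (um), `d_ref` (um), `target_vpc`.
#' @export
alignment_index <- function(animal, target_vpc = "P6.p") {
  stopifnot(inherits(animal, "annotated_animal"))
  vc <- animal$vpc_centroids
  if (is.null(vc) || is.null(animal$ac_centroid))
    abort_acq("animal lacks AC/VPC centroids", "acquant_bad_param")
  if (!target_vpc %in% rownames(vc))
    abort_acq(sprintf("target VPC %s not annotated", target_vpc), "acquant_bad_param")
  ord <- paste0("P", 3:8, ".p")
  k <- match(target_vpc, ord)
  ac <- as.numeric(animal$ac_centroid); tg <- as.numeric(vc[target_vpc, ])
  d_ac <- euclid(ac, tg)
  anterior_side <- ac[2] <= tg[2]   # anterior = decreasing x; tie -> anterior
  if (ac[2] == tg[2])
    message("AC exactly at target x: using the anterior reference VPC")
  ref <- ord[if (anterior_side) k - 1L else k + 1L]
  if (is.na(ref) || !ref %in% rownames(vc))
    abort_acq(sprintf("missing reference neighbour %s of %s on the AC side",
                      if (anterior_side) ord[k - 1L] else ord[k + 1L], target_vpc),
              "acquant_missing_neighbor")
  d_ref <- euclid(tg, as.numeric(vc[ref, ]))
  structure(list(r_index = d_ac / d_ref, nearest_vpc = nearest_vpc(animal),
                 reference_vpc = ref, d_ac_vpc = d_ac, d_ref = d_ref,
                 target_vpc = target_vpc),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment_result> R = %.4g  (AC-%s %.4g um / %s-%s %.4g um; nearest %s)\n",
              x$r_index, x$target_vpc, x$d_ac_vpc, x$target_vpc,
              x$reference_vpc, x$d_ref, x$nearest_vpc))
  invisible(x)
}

#' Classify an alignment index
#'
#' Step classification of R with the two comparisons strict as printed:
#' `aligned` when R <= 0.09, `pre-aligned` when 0.09 < R <= 0.4, and
#' `misaligned` when R > 0.4 (in wild-type animals the AC is always
#' nearest P6.p and R does not exceed 0.4).
#'
#' @param result An `alignment_result` (or a numeric R value).
#' @param misaligned_threshold,unaligned_floor Breakpoints (defaults 0.4
#'   and 0.09).
#' @return `"aligned"`, `"pre-aligned"` or `"misaligned"`.
#' @export
classify_alignment <- function(result, misaligned_threshold = 0.4,
                               unaligned_floor = 0.09) {
  r <- if (inherits(result, "alignment_result")) result$r_index else result
  if (any(!is.finite(r)) || any(r < 0))
    abort_acq("R must be finite and >= 0", "acquant_bad_param")
  ifelse(r > misaligned_threshold, "misaligned",
         ifelse(r > unaligned_floor, "pre-aligned", "aligned"))
}

#' Nearest VPC to the anchor cell
#'
#' Minimal centroid-to-centroid Euclidean distance; an exact tie goes to
#' the more anterior VPC (smaller x) and is logged.
#'
#' @param animal An [annotated_animal()] with at least two VPCs.
#' @return VPC label.
#' @export
nearest_vpc <- function(animal) {
  stopifnot(inherits(animal, "annotated_animal"))
  vc <- animal$vpc_centroids
  if (is.null(vc) || nrow(vc) < 2L)
    abort_acq("need at least two annotated VPCs", "acquant_bad_param")
  d <- sqrt(rowSums(sweep(vc, 2, as.numeric(animal$ac_centroid))^2))
  hits <- which(d == min(d))
  if (length(hits) > 1L) {
    hits <- hits[which.min(vc[hits, 2])]
    message("nearest-VPC tie: choosing the more anterior VPC")
  }
  rownames(vc)[hits]
}

#' Rank correlation between AP polarity and alignment
#'
#' Spearman rank correlation between the P6.p-directed polarity index
#' I_AP and the alignment index R across a cohort; a negative coefficient
#' means stronger VPC-directed polarity in better-aligned animals.
#'
#' @param cohort Data frame with numeric columns `i_ap` and `r_index`
#'   (>= 3 rows).
#' @return List: `rho`, `p`, `n`, `method`.
#' @export
correlate_polarity_alignment <- function(cohort) {
  if (!all(c("i_ap", "r_index") %in% names(cohort)) || nrow(cohort) < 3L)
    abort_acq("need >= 3 paired (i_ap, r_index) records", "acquant_bad_param")
  if (stats::sd(cohort$i_ap) == 0 || stats::sd(cohort$r_index) == 0)
    abort_acq("undefined correlation: constant input", "acquant_degenerate_input")
  ct <- suppressWarnings(stats::cor.test(cohort$i_ap, cohort$r_index,
                                         method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = nrow(cohort),
       method = "spearman")
}

#' Tidy alignment table for a cohort
#'
#' @param animals List of [annotated_animal()].
#' @param target_vpc Passed to [alignment_index()].
#' @return Data frame: animal_id, stage, nearest_vpc, reference_vpc, R,
#'   category.
#' @export
alignment_table <- function(animals, target_vpc = "P6.p") {
  rows <- lapply(animals, function(a) {
    al <- alignment_index(a, target_vpc)
    data.frame(animal_id = a$animal_id,
               stage = if (is.na(a$gonad_length)) NA_character_
                       else stage_from_gonad_length(a$gonad_length),
               nearest_vpc = al$nearest_vpc, reference_vpc = al$reference_vpc,
               r_index = al$r_index, category = classify_alignment(al),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
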