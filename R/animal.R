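#' Per-animal annotation record
#'
#' Bundles one animal's metadata: genotype, gonad length (used for
#' developmental staging), the anchor-cell (AC) centroid, the vulval
#' precursor cell (VPC, P3.p-P8.p) nucleus centroids, the vulval induction
#' count and any attached channel stacks. Centroids are `(y, x)` in
#' micrometres in a common projection-plane frame; under the package axis
#' convention ventral is increasing `y` and anterior is decreasing `x`,
#' so VPC x-coordinates must increase strictly from P3.p to P8.p.
#'
#' @param animal_id Identifier.
#' @param genotype Genotype label (free text, e.g. `"wild-type"`,
#'   `"unc-6(lf)"`).
#' @param gonad_length Gonad length in micrometres (staging proxy).
#' @param ac_centroid Numeric `(y, x)` in um.
#' @param vpc_centroids Numeric matrix with rownames among
#'   `"P3.p" ... "P8.p"` and columns `(y, x)` in um.
#' @param induced_count Induced VPCs for this animal (multiples of 0.5,
#'   0-6), or `NA` if not scored.
#' @param primary_fate_vpc Label of the VPC carrying the primary fate
#'   (`"P5.p"`, `"P6.p"` or `"P7.p"`), or `NA`.
#' @param stacks Named list of [image_stack()] objects or file paths.
#' @param truth Optional list of generator ground truth (simulated animals
#'   only).
#' @return An object of class `annotated_animal`.
#' @export
annotated_animal <- function(animal_id, genotype = "wild-type",
                             gonad_length = NA_real_,
                             ac_centroid = NULL, vpc_centroids = NULL,
                             induced_count = NA_real_,
                             primary_fate_vpc = NA_character_,
                             stacks = list(), truth = list()) {
  if (!is.null(vpc_centroids)) {
    if (!is.matrix(vpc_centroids) || ncol(vpc_centroids) != 2L ||
        is.null(rownames(vpc_centroids)))
      abort_acq("`vpc_centroids` must be a named (y, x) matrix", "acquant_bad_param")
    labs <- rownames(vpc_centroids)
    ok <- paste0("P", 3:8, ".p")
    if (anyDuplicated(labs) || !all(labs %in% ok))
      abort_acq("VPC labels must be unique and among P3.p-P8.p", "acquant_bad_param")
    ord <- ok[ok %in% labs]
    vpc_centroids <- vpc_centroids[ord, , drop = FALSE]
    if (any(diff(vpc_centroids[, 2]) <= 0))
      abort_acq("VPC x-coordinates must increase strictly from anterior (P3.p) to posterior (P8.p)",
                "acquant_bad_param")
  }
  if (!is.na(induced_count)) {
    if (induced_count < 0 || induced_count > 6 ||
        abs(induced_count * 2 - round(induced_count * 2)) > 1e-9)
      abort_acq("`induced_count` must be in [0, 6] in steps of 0.5", "acquant_bad_param")
  }
  structure(
    list(animal_id = as.character(animal_id), genotype = as.character(genotype),
         gonad_length = gonad_length, ac_centroid = ac_centroid,
         vpc_centroids = vpc_centroids, induced_count = induced_count,
         primary_fate_vpc = primary_fate_vpc, stacks = stacks, truth = truth),
    class = "annotated_animal")
}

#' @export
print.annotated_animal <- function(x, ...) {
  cat(sprintf("<annotated_animal> %s  [%s]  gonad %.4g um\n",
              x$animal_id, x$genotype, x$gonad_length))
  if (!is.null(x$vpc_centroids))
    cat("  VPCs:", paste(rownames(x$vpc_centroids), collapse = " "), "\n")
  if (!is.na(x$induced_count))
    cat(sprintf("  induced count: %.1f\n", x$induced_count))
  invisible(x)
}

#' Tidy annotation table for a cohort
#'
#' Flattens a list of [annotated_animal()] records into one row per animal
#' (the annotation sidecar format: identifiers, stage fields, centroids,
#' gonad length, induction fields).
#'
#' @param animals List of `annotated_animal`.
#' @return A data.frame.
#' @export
annotation_table <- function(animals) {
  if (inherits(animals, "annotated_animal")) animals <- list(animals)
  rows <- lapply(animals, function(a) {
    row <- data.frame(animal_id = a$animal_id, genotype = a$genotype,
                      gonad_length_um = a$gonad_length,
                      stage = if (is.na(a$gonad_length)) NA_character_
                              else stage_from_gonad_length(a$gonad_length),
                      ac_y_um = if (is.null(a$ac_centroid)) NA_real_ else a$ac_centroid[1],
                      ac_x_um = if (is.null(a$ac_centroid)) NA_real_ else a$ac_centroid[2],
                      induced_count = a$induced_count,
                      primary_fate_vpc = a$primary_fate_vpc,
                      stringsAsFactors = FALSE)
    if (!is.null(a$vpc_centroids)) {
      for (v in rownames(a$vpc_centroids)) {
        key <- tolower(gsub("\\.", "", v))
        row[[paste0(key, "_y_um")]] <- a$vpc_centroids[v, 1]
        row[[paste0(key, "_x_um")]] <- a$vpc_centroids[v, 2]
      }
    }
    row
  })
  cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) { r[setdiff(cols, names(r))] <- NA; r[cols] })
  do.call(rbind, rows)
}

#' Write / read a cohort annotation table
#'
#' Plain tab-delimited text, one row per animal; the companion
#' `*_truth.tsv` (written by the generators via the `truth` fields) uses
#' the same keys plus the simulation ground truth.
#'
#' @param animals List of [annotated_animal()].
#' @param path Output TSV path.
#' @export
write_annotations <- function(animals, path) {
  utils::write.table(annotation_table(animals), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
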