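# Synthetic-data generators: image stacks, annotated animals and induction
# cohorts with known ground truth. Every generator is a pure function of
# (params, seed): identical inputs give bit-identical output.

#' Parameters for a synthetic anchor-cell stack
#'
#' The simulated AC is an ellipsoid of polarized fluorescence over a flat
#' background. Polarization is a two-compartment step in expected
#' intensity: voxels in the ventral half (y above the centre) carry
#' `rho_dv` times the dorsal intensity, and voxels in the anterior
#' (P6.p-proximal by default orientation) half carry `rho_ap` times the
#' posterior intensity, so the noiseless ventral/dorsal mean ratio is
#' `rho_dv` and the anterior/posterior ratio `rho_ap` --- a step rather
#' than a gradient because the measured indices are two-compartment mean
#' ratios. The radial intensity profile emulates the reporter's cellular
#' localization: full `base_intensity` in a cortical shell
#' (`cortex_thickness` voxels thick) and a dimmer diffuse interior pool
#' (`interior_fraction` of the cortical level); `interior_fraction = 1`
#' gives a uniform solid ellipsoid. The profile is radially symmetric,
#' so compartment mean ratios equal `rho_dv` / `rho_ap` exactly for any
#' profile. Punctae are Gaussian blobs confined to the AC mask, placed
#' uniformly inside the ellipsoid with amplitudes scaled by the local
#' compartment factor so they do not bias the expected ratios. Noise is
#' Poisson on (signal + background), then additive Gaussian read noise.
#'
#' The defaults emulate a deconvolved cortical reporter stack at the
#' scale the pipeline is tested at: a 21 x 64 x 64 voxel crop at
#' 0.13 x 0.1 x 0.1 um, semi-axes of at least 8 voxels (rasterization
#' error on compartment means below 1%), a 3-voxel (~0.3 um) cortical
#' shell of about 200 detected photons per voxel with a 20% diffuse
#' interior, over a background of 20 and read noise of 3.
#'
#' @param shape_zyx Integer `(z, y, x)` volume extent in voxels.
#' @param voxel_size `(z, y, x)` voxel size in um.
#' @param ac_center Ellipsoid centre, `(z, y, x)` in 0-based voxel
#'   coordinates; default the volume centre.
#' @param ac_radii Ellipsoid semi-axes `(z, y, x)` in voxels.
#' @param base_intensity Expected photons per cortical voxel in the
#'   dorsal-posterior compartment.
#' @param rho_dv,rho_ap True ventral/dorsal and anterior/posterior
#'   mean-intensity ratios (> 0).
#' @param cortex_thickness Cortical shell thickness in voxels.
#' @param interior_fraction Diffuse interior intensity as a fraction of
#'   the cortical level (1 = uniform solid ellipsoid).
#' @param n_punctae Number of intracellular punctae.
#' @param puncta_amplitude Peak photon amplitude of one puncta before
#'   compartment scaling.
#' @param puncta_sigma Isotropic Gaussian sigma of a puncta, in voxels.
#' @param background Background photons per voxel (added everywhere).
#' @param gaussian_noise_sd Read-noise standard deviation.
#' @param poisson_noise Apply Poisson shot noise?
#' @param seed Integer seed.
#' @return A validated parameter list of class `ac_stack_params`.
#' @export
ac_stack_params <- function(shape_zyx = c(21L, 64L, 64L),
                            voxel_size = c(0.13, 0.1, 0.1),
                            ac_center = (shape_zyx - 1) / 2,
                            ac_radii = c(8, 11, 11),
                            base_intensity = 200,
                            rho_dv = 1, rho_ap = 1,
                            cortex_thickness = 3, interior_fraction = 0.2,
                            n_punctae = 10L, puncta_amplitude = 60,
                            puncta_sigma = 1.2,
                            background = 20, gaussian_noise_sd = 3,
                            poisson_noise = TRUE, seed = 1L) {
  stopifnot_scalar_num(rho_dv, "rho_dv", positive = TRUE)
  stopifnot_scalar_num(rho_ap, "rho_ap", positive = TRUE)
  stopifnot_scalar_num(base_intensity, "base_intensity", positive = TRUE)
  stopifnot_scalar_num(background, "background", nonneg = TRUE)
  stopifnot_scalar_num(gaussian_noise_sd, "gaussian_noise_sd", nonneg = TRUE)
  if (any(ac_radii <= 0)) abort_acq("ac_radii must be strictly positive", "acquant_bad_param")
  if (n_punctae < 0) abort_acq("n_punctae must be >= 0", "acquant_bad_param")
  stopifnot_scalar_num(cortex_thickness, "cortex_thickness", positive = TRUE)
  if (interior_fraction < 0 || interior_fraction > 1)
    abort_acq("`interior_fraction` must be in [0, 1]", "acquant_bad_param")
  axes <- c("z", "y", "x")
  for (i in 1:3) {
    if (ac_center[i] - ac_radii[i] < 0 || ac_center[i] + ac_radii[i] > shape_zyx[i] - 1)
      abort_acq(sprintf("ellipsoid exceeds the volume along the %s axis", axes[i]),
                "acquant_geometry_error")
  }
  structure(list(shape_zyx = as.integer(shape_zyx), voxel_size = voxel_size,
                 ac_center = ac_center, ac_radii = ac_radii,
                 base_intensity = base_intensity, rho_dv = rho_dv, rho_ap = rho_ap,
                 cortex_thickness = cortex_thickness,
                 interior_fraction = interior_fraction,
                 n_punctae = as.integer(n_punctae),
                 puncta_amplitude = puncta_amplitude, puncta_sigma = puncta_sigma,
                 background = background, gaussian_noise_sd = gaussian_noise_sd,
                 poisson_noise = poisson_noise, seed = as.integer(seed)),
            class = "ac_stack_params")
}

# (z, y, x) coordinate grids in 0-based voxel units for a dim vector d
coord_grids <- function(d) {
  list(z = array(0:(d[1] - 1), d),
       y = array(rep(0:(d[2] - 1), each = d[1]), d),
       x = array(rep(0:(d[3] - 1), each = d[1] * d[2]), d))
}

#' Generate a synthetic anchor-cell stack with ground truth
#'
#' Rasterizes the polarized ellipsoid described by `params` (see
#' [ac_stack_params()]), adds punctae, background and noise, and returns
#' the stack together with the noiseless ground truth: the
#' background-free compartment mean intensities over the rasterized
#' voxel halves and the corresponding polarity ratios, plus the true AC
#' footprint for segmentation benchmarking. Pure function of
#' `(params, seed)`.
#'
#' @param params An [ac_stack_params()] object (or arguments forwarded to
#'   it).
#' @param ... Forwarded to [ac_stack_params()] when `params` is missing.
#' @return List with elements `stack` ([image_stack()]), `ground_truth`
#'   (compartment means, `i_dv`, `i_ap`), `footprint` (logical y-x matrix,
#'   true 2-D AC footprint), `mask3d`, `center_yx` (0-based), and `params`.
#' @examples
#' sim <- generate_ac_stack(ac_stack_params(rho_dv = 1.5, seed = 7))
#' sim$ground_truth$i_dv
#' @export
generate_ac_stack <- function(params = ac_stack_params(...), ...) {
  stopifnot(inherits(params, "ac_stack_params"))
  d <- params$shape_zyx
  g <- coord_grids(d)
  cc <- params$ac_center; rr <- params$ac_radii
  rnorm_ <- sqrt(((g$z - cc[1]) / rr[1])^2 + ((g$y - cc[2]) / rr[2])^2 +
                 ((g$x - cc[3]) / rr[3])^2)
  mask <- rnorm_ <= 1
  # radial localization profile: cortical shell at full intensity, dim
  # diffuse interior; radially symmetric, so it cancels from the
  # compartment mean ratios
  shell <- mask & rnorm_ >= 1 - params$cortex_thickness / mean(rr)
  profile <- array(0, d)
  profile[mask] <- params$interior_fraction
  profile[shell] <- 1
  # two-compartment step: ventral (y > cy) x rho_dv, anterior (x < cx)
  # x rho_ap; voxels exactly on a split plane keep factor 1 and are
  # excluded from the truth halves, mirroring the index computation
  fac <- array(1, d)
  fac[g$y > cc[2]] <- fac[g$y > cc[2]] * params$rho_dv
  fac[g$x < cc[3]] <- fac[g$x < cc[3]] * params$rho_ap
  signal <- params$base_intensity * profile * fac

  noiseless <- with_seed(derive_seed(params$seed, 1L), {
    s <- signal
    if (params$n_punctae > 0) {
      # uniform positions inside the ellipsoid by rejection sampling
      pts <- matrix(NA_real_, 0, 3)
      while (nrow(pts) < params$n_punctae) {
        cand <- cbind(stats::runif(params$n_punctae, -1, 1),
                      stats::runif(params$n_punctae, -1, 1),
                      stats::runif(params$n_punctae, -1, 1))
        keep <- rowSums(cand^2) <= 1
        pts <- rbind(pts, cand[keep, , drop = FALSE])
      }
      pts <- pts[seq_len(params$n_punctae), , drop = FALSE]
      pts <- sweep(sweep(pts, 2, rr, `*`), 2, cc, `+`)
      for (i in seq_len(params$n_punctae)) {
        p <- pts[i, ]
        pol <- (if (p[2] > cc[2]) params$rho_dv else 1) *
               (if (p[3] < cc[3]) params$rho_ap else 1)
        blob <- params$puncta_amplitude * pol *
          exp(-((g$z - p[1])^2 + (g$y - p[2])^2 + (g$x - p[3])^2) /
                (2 * params$puncta_sigma^2))
        s <- s + blob * mask
      }
    }
    s
  })

  vtr <- mask & g$y > cc[2]; dor <- mask & g$y < cc[2]
  ant <- mask & g$x < cc[3]; post <- mask & g$x > cc[3]
  gt <- list(ventral_mean = mean(noiseless[vtr]), dorsal_mean = mean(noiseless[dor]),
             proximal_mean = mean(noiseless[ant]), distal_mean = mean(noiseless[post]))
  gt$i_dv <- gt$ventral_mean / gt$dorsal_mean
  gt$i_ap <- gt$proximal_mean / gt$distal_mean
  gt$rho_dv <- params$rho_dv; gt$rho_ap <- params$rho_ap

  expected <- noiseless + params$background
  out <- with_seed(derive_seed(params$seed, 2L), {
    v <- if (params$poisson_noise) {
      array(stats::rpois(length(expected), expected), d)
    } else expected
    if (params$gaussian_noise_sd > 0)
      v <- v + stats::rnorm(length(v), 0, params$gaussian_noise_sd)
    pmax(v, 0)
  })

  footprint <- apply(mask, c(2, 3), any)
  list(stack = image_stack(out, params$voxel_size, channel = "ligand"),
       ground_truth = gt, footprint = footprint, mask3d = mask,
       center_yx = cc[2:3], params = params)
}

#' Generate an annotated animal with known geometry
#'
#' Lays out the VPC row P3.p-P8.p collinearly along the AP axis with
#' configurable spacing, places the AC dorsally at a configurable offset
#' from P6.p, and (optionally) attaches a synthetic ligand stack from
#' [generate_ac_stack()]. The ground-truth alignment index `R` implied by
#' the constructed geometry is recorded in `$truth`.
#'
#' @param stack_params Optional [ac_stack_params()]; when supplied, a
#'   ligand channel stack is generated with a sub-seed derived from
#'   `seed` and attached as `stacks$ligand`.
#' @param layout_params List overriding any of: `vpc_spacing_um` (default
#'   12), `ac_x_offset_um` (AC anteroposterior offset from P6.p, default
#'   0), `ac_dorsal_offset_um` (default 4), `jitter_sd_um` (Gaussian
#'   jitter on the AC x-offset, default 0), `gonad_length_um` (default
#'   90), `genotype`, `animal_id`.
#' @param seed Integer seed.
#' @return An [annotated_animal()]; `$truth$r_index` holds the true R.
#' @export
generate_animal <- function(stack_params = NULL, layout_params = list(), seed = 1L) {
  lp <- utils::modifyList(
    list(vpc_spacing_um = 12, ac_x_offset_um = 0, ac_dorsal_offset_um = 4,
         jitter_sd_um = 0, gonad_length_um = 90, genotype = "wild-type",
         animal_id = sprintf("sim-%d", seed)),
    layout_params)
  if (lp$vpc_spacing_um <= 0)
    abort_acq("`vpc_spacing_um` must be positive", "acquant_bad_param")
  labs <- paste0("P", 3:8, ".p")
  y_row <- 20
  x_row <- 10 + (0:5) * lp$vpc_spacing_um
  vpc <- cbind(y = rep(y_row, 6), x = x_row)
  rownames(vpc) <- labs
  off <- with_seed(derive_seed(seed, 3L), {
    lp$ac_x_offset_um + if (lp$jitter_sd_um > 0) stats::rnorm(1, 0, lp$jitter_sd_um) else 0
  })
  ac <- c(y = y_row - lp$ac_dorsal_offset_um, x = vpc["P6.p", "x"] + off)
  # ground-truth R by construction: AC-P6.p distance over the P6.p-to-
  # flanking-reference distance (P5.p if the AC sits anterior, else P7.p)
  d_ac <- sqrt(sum((ac - vpc["P6.p", ])^2))
  ref <- if (ac["x"] <= vpc["P6.p", "x"]) "P5.p" else "P7.p"
  r_true <- d_ac / sqrt(sum((vpc["P6.p", ] - vpc[ref, ])^2))
  truth <- list(r_index = r_true, reference_vpc = ref,
                ac_x_offset_um = off)
  stacks <- list()
  if (!is.null(stack_params)) {
    stopifnot(inherits(stack_params, "ac_stack_params"))
    stack_params$seed <- derive_seed(seed, 1L)
    sim <- generate_ac_stack(stack_params)
    stacks$ligand <- sim$stack
    truth$polarity <- sim$ground_truth
    truth$footprint <- sim$footprint
    truth$center_yx <- sim$center_yx
  }
  annotated_animal(animal_id = lp$animal_id, genotype = lp$genotype,
                   gonad_length = lp$gonad_length_um, ac_centroid = ac,
                   vpc_centroids = vpc, stacks = stacks, truth = truth)
}

#' Generate a two-channel biosensor image pair
#'
#' Simulates the ERK kinase-translocation-reporter readout: a row of five
#' VPC nuclei (P4.p-P8.p) imaged in a red nuclear reference channel
#' (H2B, activity-independent) and a green reporter channel whose nuclear
#' intensity falls with MPK-1 activity (nuclear export), so the nuclear
#' red/green mean ratio of nucleus `i` equals `activity[i]` exactly in
#' the noiseless image.
#'
#' @param activity Positive numeric length-5 vector of per-VPC activities
#'   (P4.p-P8.p order); this is the injected nuclear red/green ratio.
#' @param noise List overriding any of `background` (default 5),
#'   `gaussian_noise_sd` (default 2), `poisson_noise` (default TRUE),
#'   `red_amplitude` (default 300 photons in the nucleus).
#' @param seed Integer seed; red and green channels use sub-seeds derived
#'   from it.
#' @return List with `red` and `green` [image_stack()]s, `animal`
#'   ([annotated_animal()] with VPC centroids in um), `focus_z` (0-based
#'   focus slice of the nuclear signal), `nucleus_radius_px`, and
#'   `truth$ratios` (the injected vector, named).
#' @export
generate_biosensor_image <- function(activity,
                                     noise = list(), seed = 1L) {
  labs <- paste0("P", 4:8, ".p")
  if (length(activity) != 5L)
    abort_acq("`activity` must cover P4.p-P8.p (length 5)", "acquant_bad_param")
  if (any(!is.finite(activity)) || any(activity <= 0))
    abort_acq("activities must be strictly positive", "acquant_bad_param")
  np <- utils::modifyList(list(background = 5, gaussian_noise_sd = 2,
                               poisson_noise = TRUE, red_amplitude = 300), noise)
  names(activity) <- labs
  d <- c(11L, 40L, 170L)
  vs <- c(0.13, 0.1, 0.1)
  g <- coord_grids(d)
  cz <- 5; cy <- 20
  cx <- 25 + 30 * (0:4)
  r_yx <- 5; r_z <- 3
  red <- array(0, d); green <- array(0, d)
  for (i in 1:5) {
    nuc <- ((g$z - cz) / r_z)^2 + ((g$y - cy) / r_yx)^2 + ((g$x - cx[i]) / r_yx)^2 <= 1
    red[nuc] <- np$red_amplitude
    green[nuc] <- np$red_amplitude / activity[i]
  }
  apply_noise <- function(img, sub) {
    with_seed(derive_seed(seed, sub), {
      v <- img + np$background
      if (np$poisson_noise) v <- array(stats::rpois(length(v), v), d)
      if (np$gaussian_noise_sd > 0) v <- v + stats::rnorm(length(v), 0, np$gaussian_noise_sd)
      pmax(v, 0)
    })
  }
  red_s <- image_stack(apply_noise(red, 1L), vs, "red")
  green_s <- image_stack(apply_noise(green, 2L), vs, "green")
  vpc <- cbind(y = rep(cy * vs[2], 5), x = cx * vs[3])
  rownames(vpc) <- labs
  animal <- annotated_animal(animal_id = sprintf("ktr-%d", seed),
                             gonad_length = 100,
                             ac_centroid = c(y = cy * vs[2] - 2, x = cx[3] * vs[3]),
                             vpc_centroids = vpc,
                             truth = list(ratios = activity))
  list(red = red_s, green = green_s, animal = animal, focus_z = cz,
       nucleus_radius_px = r_yx,
       centroids_px = cbind(y = rep(cy, 5), x = cx),
       truth = list(ratios = activity))
}

#' Parameters for a simulated induction cohort
#'
#' @param n_animals Number of animals (>= 1).
#' @param fate_pattern_probs Named probabilities over the fate patterns
#'   `wild-type` (induced count 3, primary fate at P6.p), `hyperinduced`
#'   (count > 3), `hypo-induced` (count < 3) and `shifted` (count 3,
#'   primary fate at P5.p or P7.p). Must sum to 1 within 1e-9.
#' @param induced_count_distribution Per-pattern named probability vectors
#'   over induced counts (multiples of 0.5). Defaults put most mass on
#'   mild deviations, the way partially penetrant vulval phenotypes are
#'   scored.
#' @param seed Integer seed.
#' @return Parameter list of class `cohort_params`.
#' @export
cohort_params <- function(n_animals = 50L,
                          fate_pattern_probs = c("wild-type" = 1, "hyperinduced" = 0,
                                                 "hypo-induced" = 0, "shifted" = 0),
                          induced_count_distribution = NULL, seed = 1L) {
  if (n_animals < 1) abort_acq("`n_animals` must be >= 1", "acquant_bad_param")
  pats <- c("wild-type", "hyperinduced", "hypo-induced", "shifted")
  if (is.null(names(fate_pattern_probs)) || !all(names(fate_pattern_probs) %in% pats))
    abort_acq("`fate_pattern_probs` must be named with known fate patterns",
              "acquant_bad_param")
  p <- stats::setNames(numeric(4), pats)
  p[names(fate_pattern_probs)] <- fate_pattern_probs
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
    abort_acq("fate-pattern probabilities must be non-negative and sum to 1 (tol 1e-9)",
              "acquant_bad_param")
  dflt <- list(
    "wild-type"   = c("3" = 1),
    "hyperinduced" = c("3.5" = 0.35, "4" = 0.25, "4.5" = 0.15, "5" = 0.1,
                       "5.5" = 0.1, "6" = 0.05),
    "hypo-induced" = c("2.5" = 0.35, "2" = 0.25, "1.5" = 0.15, "1" = 0.1,
                       "0.5" = 0.1, "0" = 0.05),
    "shifted"     = c("3" = 1))
  icd <- if (is.null(induced_count_distribution)) dflt
         else utils::modifyList(dflt, induced_count_distribution)
  for (pat in names(icd)) {
    w <- icd[[pat]]
    cnts <- as.numeric(names(w))
    if (any(w < 0) || abs(sum(w) - 1) > 1e-9 ||
        any(abs(cnts * 2 - round(cnts * 2)) > 1e-9) || any(cnts < 0 | cnts > 6))
      abort_acq(sprintf("invalid induced-count distribution for pattern '%s'", pat),
                "acquant_bad_param")
  }
  structure(list(n_animals = as.integer(n_animals), fate_pattern_probs = p,
                 induced_count_distribution = icd, seed = as.integer(seed)),
            class = "cohort_params")
}

#' Generate a cohort of animals with scored vulval induction
#'
#' Draws a fate pattern per animal from `fate_pattern_probs`, then an
#' induced-cell count from that pattern's count distribution; `shifted`
#' animals carry their primary fate at P5.p or P7.p (equal odds), all
#' others at P6.p when induced. With all probability on `wild-type`,
#' every animal has induced count exactly 3.
#'
#' @param params A [cohort_params()] object.
#' @return List of [annotated_animal()] with `genotype` set to the fate
#'   pattern and `induced_count` / `primary_fate_vpc` populated.
#' @examples
#' coh <- generate_induction_cohort(cohort_params(n_animals = 5))
#' vulval_index(coh)
#' @export
generate_induction_cohort <- function(params = cohort_params()) {
  stopifnot(inherits(params, "cohort_params"))
  with_seed(params$seed, {
    pats <- sample(names(params$fate_pattern_probs), params$n_animals,
                   replace = TRUE, prob = params$fate_pattern_probs)
    lapply(seq_len(params$n_animals), function(i) {
      w <- params$induced_count_distribution[[pats[i]]]
      cnt <- as.numeric(sample(names(w), 1L, prob = w))
      pf <- if (cnt == 0) NA_character_
            else if (pats[i] == "shifted") sample(c("P5.p", "P7.p"), 1L)
            else "P6.p"
      annotated_animal(animal_id = sprintf("coh%d-%04d", params$seed, i),
                       genotype = pats[i], gonad_length = 90,
                       induced_count = cnt, primary_fate_vpc = pf,
                       truth = list(fate_pattern = pats[i]))
    })
  })
}

#' Write a simulated animal to disk
#'
#' Writes each attached channel stack as a calibrated multi-page TIFF,
#' plus the annotation row and a ground-truth sidecar (same keys plus the
#' generator truth) as tab-delimited text.
#'
#' @param animal An [annotated_animal()] from a generator.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_animal <- function(animal, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ch in names(animal$stacks)) {
    if (inherits(animal$stacks[[ch]], "image_stack"))
      write_stack(animal$stacks[[ch]],
                  file.path(dir, sprintf("%s_%s.tif", animal$animal_id, ch)))
  }
  write_annotations(list(animal),
                    file.path(dir, sprintf("%s_annotation.tsv", animal$animal_id)))
  tr <- animal$truth
  flat <- tr[vapply(tr, function(v) is.numeric(v) || is.character(v), logical(1))]
  flat <- lapply(flat, function(v) paste(v, collapse = ","))
  if (length(flat))
    utils::write.table(data.frame(animal_id = animal$animal_id, as.data.frame(flat)),
                       file.path(dir, sprintf("%s_truth.tsv", animal$animal_id)),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}
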