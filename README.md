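# acquant

Quantification of anchor-cell polarity, AC-to-P6.p alignment, ERK
biosensor activity and vulval induction in *C. elegans*.

During vulval development, the gonadal anchor cell (AC) secretes the
EGF-like ligand LIN-3 toward a row of six vulval precursor cells (VPCs,
P3.p–P8.p). The VPC closest to the AC — normally P6.p — receives the most
ligand, activates the EGFR/RAS/MAPK cascade and adopts the primary vulval
fate. Studies of this system quantify four things from fluorescence image
stacks and scored cohorts, and this package implements all four as a
tested, reusable pipeline driven by a synthetic-data generator (so every
stage is testable without raw microscopy data):

1. **AC polarity indices.** From a summed z-projection across the AC, the
   AC is segmented (Otsu threshold in a window around the nucleus,
   8-connected component, holes filled), background is subtracted (median
   outside the mask), and the cell is split by a line through the nucleus
   centre. The dorso-ventral polarity index is the ratio of half mean
   intensities,

   `I_DV = mean(ventral half) / mean(dorsal half)`,

   so `I_DV > 1` means ventral enrichment (toward the VPCs). The
   analogous `I_AP` uses the halves proximal and distal to the nearest
   VPC. Animals are classified polarized at `I_DV > 1.1` (ligand
   reporter) or `> 1.2` (PIP2 membrane marker).

2. **AC-to-P6.p alignment.** `R = d(AC, P6.p) / d(P6.p, ref)`, where the
   reference VPC is P5.p if the AC lies anterior of P6.p and P7.p
   otherwise. `R ≤ 0.09` counts as aligned, `R > 0.4` as misaligned.
   Animals are staged by gonad length (30–70 µm early/mid-L2, 70–110 µm
   late L2, 110–150 µm early/mid-L3).

3. **ERK biosensor activity.** MPK-1 activity per VPC is the nuclear
   red/green mean-intensity ratio (mCherry::H2B over ERK-nKTR::mClover,
   which exits the nucleus when phosphorylated), measured on summed
   projections of the five central slices, with the nucleus mask derived
   from the red channel only. Ratios are normalized to the P4.p–P8.p mean
   within each animal, and each animal is scored for whether P6.p has the
   strict maximum.

4. **Induction statistics.** The vulval induction index
   `VI = (total induced VPCs) / (animals scored)` is 3 in the wild type;
   per-animal counts `> 3` are hyperinduced, `< 3` hypo-induced.
   Uncertainty comes from bootstrap resampling (10,000 resamples; s.e.m.
   = SD of resample means, 95% CI from the 2.5/97.5 percentiles), and
   comparisons use Welch/Student t, Mann–Whitney (exact by enumeration
   for n₁+n₂ ≤ 12, tie-corrected normal approximation otherwise),
   two-sided variance-F and Fisher's exact tests.

## Worked example

```r
library(acquant)

## a synthetic AC stack with known ventral/dorsal ratio 1.5, quantified
## end to end (projection -> segmentation -> background -> index)
sim <- generate_ac_stack(ac_stack_params(rho_dv = 1.5, seed = 42))
quantify_ac_polarity(sim$stack, sim$center_yx)$i_dv
#> <polarity_result> I_DV = 1.483  (half means 2490 / 1679, areas 180 / 170)

## alignment of an AC displaced 3 um posterior of P6.p
animal <- generate_animal(layout_params = list(ac_x_offset_um = 3), seed = 42)
alignment_index(animal)
#> <alignment_result> R = 0.4167  (AC-P6.p 5 um / P6.p-P7.p 12 um; nearest P6.p)

## induction scoring of a mixed cohort (20% hyperinduced animals)
coh <- generate_induction_cohort(cohort_params(
  n_animals = 60, fate_pattern_probs = c("wild-type" = 0.8, "hyperinduced" = 0.2),
  seed = 42))
vulval_index(coh)
#> [1] 3.375
bootstrap_mean(vapply(coh, function(a) a$induced_count, numeric(1)), seed = 1)
#> <bootstrap_result> mean 3.375, s.e.m. 0.09074, 95% CI [3.208, 3.567] (percentile, 10000 resamples, seed 1)
```

The measured `I_DV` of 1.483 recovers the simulated polarization of 1.5
to within the segmentation's rasterization error; the displaced AC's
`R = 5/12` sits just above the 0.4 misalignment threshold and uses P7.p
as the reference because the AC lies posterior of P6.p; the cohort's VI
of 3.375 exceeds the wild-type value of 3 because a fifth of the animals
are hyperinduced, and the bootstrap CI excludes 3.

A full simulate → quantify → summarise run, with tidy output tables and
a run-metadata file (package version, config hash, seeds), is

```r
run_pipeline(default_config(n_animals = 20, seed = 2, out_dir = "out"))
```

and the same is available from a shell via the thin wrapper
`inst/cli/acquant.R` (subcommands `simulate`, `polarity`, `induction`,
`compare`, `all`).

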