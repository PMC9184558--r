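# poolscreen

Ratiometric analysis of pooled isogenic knockout drug screens.

## The problem

Synthetic-lethal drug screening asks which compounds selectively kill cells
that have lost a particular tumour-suppressor gene. A scalable way to run
such screens is to engineer a panel of isogenic knockout cell lines — each
clone carrying a single CRISPR-disrupted gene and, as a by-product of the
editing, a unique integrated gRNA sequence that doubles as a genetic
barcode — and to co-culture 5–7 lines from one parental background in each
well of a 96-well plate. After compound exposure, a single amplicon PCR
tags every template molecule with a 14-nt unique molecular identifier
(UID), a plate barcode and a well barcode; counting *distinct UIDs* per
gRNA counts surviving cells, not sequencing reads. Because all lines in a
well share the treatment, each line is an internal control for the others:
the readout is **ratiometric**.

`poolscreen` implements the full analysis for this assay class, plus a
generative simulator that stands in for the wet-lab screen, and the
companion classifier used to decide whether a CRISPR clone really is a
knockout.

## The statistics at the core

For line *i* in well *w*, the abundance ratio is
`r_iw = UID_iw / Σ_j UID_jw`. The per-plate Z-score compares a well
against the distribution of the same line's ratios across its plate:

```
z_iw = (r_iw − median_plate(r_i)) / sd_plate(r_i)
```

A (compound, line) observation is a **compound of interest** when it is
statistically significant (`z ≤ −1.5` for well-powered lines, `z ≤ −1.0`
for low-powered ones), biologically significant (inhibition
`1 − r/r_DMSO > 50%`), and the well is not flagged for non-specific
killing (total UIDs less than two-fold the same-plate staurosporine well).
Power status comes from an in-silico down-sampling analysis: each line's
DMSO counts are reduced in 10% steps and the Z-score recomputed; lines
that still reach `z ≤ −1.5` after a 90% reduction on their
lowest-representation quartile of plates are *well powered*. A compound is
a **hit** for a gene when a strict majority of that gene's knockout lines
pass in at least two parental backgrounds.

Knockout validation follows four rules: both alleles carry out-of-frame
indels (`length %% 3 != 0`), no complex allele, intact-site (wild-type)
reads below 1%, and the targeted exon cannot rescue the reading frame by
being skipped (internal exon with length divisible by 3). An RNA-level
rule (`rna_evidence()`) additionally requires ≥15 covering reads with no
wild-type or in-frame-skip evidence.

## Worked example

Simulate a small screen — two backgrounds with 3 and 2 TP53-knockout lines,
pools of six, four 96-well plates, 45 compounds at 1 and 10 µM, 50,000 UIDs
per well — with one planted synthetic-lethal interaction, and run the whole
analysis:

```r
library(poolscreen)

design <- make_synthetic_design()
truth  <- truth_model(effects = tibble::tibble(
  compound_id = "C001", gene = "TP53", kill_fraction = 0.9))

result <- run_pipeline(design, truth = truth, config = run_config(seed = 7))
result
#> <screen_result>
#>   384 wells scored; 20 compound-of-interest observations passed
#>   1 hit(s); DMSO false-positive rate 0.0000% (0/72)

glance(result)
#> # A tibble: 1 × 7
#>   n_wells n_lines n_compounds n_well_powered n_coi_passed n_hits dmso_fpr
#>     <int>   <int>       <int>          <int>        <int>  <int>    <dbl>
#> 1     384      12          45             12           20      1        0

head(dplyr::filter(result$coi, passed), 3)[, c("compound_id", "dose_uM",
                                               "line_id", "z", "inhibition")]
#> # A tibble: 3 × 5
#>   compound_id dose_uM line_id         z inhibition
#> 1 C001              1 RPE1_TP53_1 -5.87      0.805
#> 2 C001              1 RPE1_TP53_2 -5.97      0.817
#> 3 C001              1 RPE1_TP53_3 -6.03      0.823
```

The planted compound C001 is depleted about six plate standard deviations
below the plate median for every TP53 line (z ≈ −6), inhibits their growth
by ~82% relative to the same-plate DMSO wells, and is the screen's only
hit — supported by a strict majority of TP53 lines in both backgrounds,
while the 72 DMSO control evaluations produce no false positives.
`autoplot(result)` draws the z-versus-inhibition scatter; `plot_zcurve()`
and `plot_plate_zscores()` show down-sampling power curves and plate
heatmaps. `run_pipeline(..., out_dir = "out")` writes every stage table as
TSV plus a JSON provenance manifest and a self-contained HTML report.

Raw-read workflows are available too: `emit_fastq()` writes paired FASTQ
with the assay's primer layout (UID + plate barcode + anchor + gRNA /
well barcode + spacer + anchor), and `demux_count()` reverses it with
mismatch-tolerant barcode matching and SafeSeqS-style UID collapsing.
Knockout clones are validated with
`simulate_amplicon_reads() |> genotype_amplicon() |> classify_clone()`.

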