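---
title: "Methods: ratiometric analysis of pooled isogenic knockout screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ratiometric analysis of pooled isogenic knockout screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolscreen)
```

# The assay and its model

The assay screens compounds against pools of isogenic knockout cell lines.
Each engineered line carries one disrupted gene and, at the integration
site, a unique 20-nt gRNA sequence that serves as its genetic barcode.
Five to seven lines sharing a parental background are co-cultured in each
well of a 96-well plate (5,000 cells seeded per well), exposed to a
compound for about three days, and read out by amplicon sequencing in
which every template molecule receives a 14-nt unique molecular identifier
(UID). Distinct UIDs per gRNA count molecules — and hence surviving
cells — rather than reads, suppressing PCR and sequencing duplicates.

The quantitative readout is ratiometric. For line $i$ in well $w$ the
abundance ratio is $r_{iw} = c_{iw} / \sum_j c_{jw}$ with $c$ the
UID counts. Within a plate, the same line's ratios across all 96 wells
form the null distribution against which any one well is judged:

$$ z_{iw} = \frac{r_{iw} - \mathrm{median}_w(r_{iw})}{\mathrm{sd}_w(r_{iw})} $$

This statistic assumes that most wells on a plate do not selectively
deplete any one line, so the plate median is an honest null centre; it is
robust to a minority of active compounds but degrades on plates where many
compounds hit the same line.

## Decision rules

A (compound, line) observation passes when all three of the following
hold; every constant is collected in `run_config()` and overridable:

* **statistical**: $z \le -1.5$ for *well-powered* lines, $z \le -1.0$ for
  *low-powered* ones (see the power analysis below);
* **biological**: inhibition $1 - r_{\text{treated}} / \bar r_{\text{DMSO}}$
  strictly greater than 0.5, with $\bar r_{\text{DMSO}}$ the mean ratio of
  the line over the plate's DMSO wells. Inhibition is floored at zero:
  growth advantages are a different phenotype and are not reported as
  negative inhibition;
* **clean well**: the well's total UID count is at least two-fold the
  same-plate staurosporine well's total (mean over staurosporine wells if
  several); wells below that line indicate generalised cytotoxicity and
  are flagged `nonspecific`.

A compound is a **hit** for a gene when, in at least two parental
backgrounds, a strict majority of that gene's screened knockout lines pass
(1 of 2 is not a majority; a single screened line counts 1/1). A line
passing at either dose counts as passing — the screen doses every compound
at 1 and 10 µM and the calls are deliberately dose-agnostic, since the two
doses are two chances to observe the same interaction. Genes screened in
fewer than two backgrounds are reported `untestable` rather than silently
unhittable.

## Down-sampling power analysis

Whether a line can show a depletion signal depends on how well it is
represented on a plate. For each line and plate, the line's UID count in a
DMSO well is scaled to $\mathrm{round}((1-r)\,c)$ for
$r \in \{0.1, \dots, 1.0\}$, the well total is recomputed, and the scaled
ratio is converted to a Z-score. Two choices matter here:

* **Deterministic scaling** (with seeded binomial thinning behind
  `method = "binomial"`): reproducible and monotone, at the cost of
  ignoring resampling noise.
* **Fixed plate context**: the plate median and SD are those of the
  *unmodified* plate; only the probed well's ratio moves. The alternative
  — re-entering the modified ratio into the median/SD — changes the null
  as the probe deepens and can make the curve non-monotone. With a fixed
  context, $z$ is exactly non-increasing in $r$, which the test suite
  asserts on every fixture.

A line is **well powered** when the 90% reduction still reaches
$z \le -1.5$ on the plate at the 25th percentile of its representation
ranking — plates ranked ascending by the line's mean DMSO abundance ratio,
evaluation index $\lceil 0.25\,n_\text{plates} \rceil$, ties broken by
plate id. "Representation" is defined as the mean DMSO abundance ratio
because DMSO wells are the only wells guaranteed untreated; the probe
reduction (0.9) and the quantile (0.25) are `run_config()` parameters.

## Negative-control false positives

The DMSO false-positive rate applies the compound-of-interest criteria to
every DMSO (well, line) evaluation. Inhibition for a DMSO well is computed
leave-one-out against the other DMSO wells of its plate: compared against
a mean that included itself, a lone DMSO well would sit at inhibition zero
by construction and the evaluation would be vacuous. Plates with a single
DMSO well therefore leave that well's inhibition undefined, and undefined
values never pass any filter (missingness propagates as `NA`, never as 0).

# The synthetic screen generator

`simulate_counts()` is a generative model of the assay, not a fixture: it
defines the study conditions under which the pipeline's operating
characteristics are measured.

* **Effects as kill fractions.** A compound's effect on a knockout line is
  a fraction $e \in [0,1]$ of that line's end-point abundance removed.
  The assay measures end-point abundance after ~72 h, so a one-parameter
  end-point model suffices at desk scale; no birth–death dynamics are
  simulated. Controls are planted the same way: staurosporine kills every
  line at 0.95; the MDM2-inhibitor control kills lines with intact TP53
  (i.e. every knockout except TP53's) at 0.8, reflecting the 5–10×
  differential sensitivity of TP53-wild-type cells.
* **Expected fractions.** With seeding share $n_i$ (equal within a pool),
  baseline fitness $f_i$ (default 1) and kill fraction $e_i$, line $i$'s
  expected fraction is $p_i = n_i f_i (1-e_i) / \sum_j n_j f_j (1-e_j)$.
* **Sequencing.** UID counts are multinomial(depth, $p$), or
  Dirichlet-multinomial with concentration `overdispersion` for noisier
  libraries (`Inf`, the default, recovers the multinomial).
* **Depth scaling.** A well's total draw is scaled by its survival
  fraction: `depth * Σ n f (1-e) / Σ n f`. Library yield tracks surviving
  cell mass; without this, every well would sequence to the same total and
  the staurosporine two-fold filter — which reads out exactly that yield —
  would be meaningless. `depth_scaling = FALSE` restores constant depth.
* **FASTQ emission.** `emit_fastq()` writes paired reads in the assay's
  primer layout: read 1 is `UID(14) + plate barcode + TGTGGAAAGGACGAAACACC
  + gRNA(20)`; read 2 is `well barcode + NN + CGGACTAGCCTTATTTTAACTTGC`.
  The placement of the well barcode at the start of read 2 followed by the
  2-nt random spacer is this package's synthetic dialect (the wet assay
  does not fix read-level orientation); the demultiplexer and emitter own
  it jointly. Per-UID read duplication is geometric on $\{1,2,\dots\}$
  with configurable mean; substitution errors are applied uniformly per
  base; qualities are constant Phred 40.

What the generator does **not** emulate: PCR chimeras, index hopping,
quality-score structure, UID collisions beyond uniform sampling, plate
position effects, or growth interactions between co-cultured lines.
Passing tests therefore demonstrate the pipeline's correctness and its
operating characteristics under clean multinomial (or mildly
overdispersed) sampling — not robustness to every artefact of real
libraries.

Default geometry (`make_synthetic_design()`): two backgrounds, one pool
each of six lines (3 TP53 knockouts + fillers in one background, 2 + fillers
in the other), two replicate plates per background, 45 compounds at 1 and
10 µM (90 wells), 3 DMSO + 1 untreated + 1 staurosporine + 1 nutlin-3a
control wells, 5,000 seeded cells, 50,000 UIDs baseline depth. These
mirror the screen's stated conditions where stated (pool size, seeding,
doses, controls) and are otherwise the package's own choices, fixed once.

# Demultiplexing choices

Barcodes and gRNAs are matched by bounded Hamming distance (defaults:
barcodes 1 mismatch, anchors 2, gRNA 1). Any tie at the minimum distance
rejects the read — ambiguity never assigns. Generated whitelists and
panels enforce pairwise distance ≥ 3 so single-mismatch matching cannot be
ambiguous by construction. UID sequencing errors are *not* clustered: two
UIDs one substitution apart count as two molecules. At 14 nt the UID space
(~2.7 × 10⁸) is sparse at realistic depths, so collisions are negligible,
but at high error rates this choice over-counts; it is documented rather
than hidden behind a heuristic correction. `min_reads_per_uid` (default 1)
filters weakly supported UIDs; raising it can only lower counts, which the
suite asserts as a monotonicity property.

# Knockout-validation classifier

`genotype_amplicon()` aligns each UID-collapsed consensus to the 66–80 bp
reference spanning the predicted cut site and calls alleles as
(kind, length, position) with UID fractions. Numerical choices:

* **Affine-gap global alignment** (Gotoh: match +1, mismatch −1, gap open
  −4, extend −1). Linear gap scoring at comparable weights shreds long
  indels into short gaps separated by coincidental matches — CRISPR
  clones carry deletions up to ~38 bp and insertions up to ~43 bp, which
  must be called as single events. Alignment scores are cross-checked in
  the test suite against `Biostrings::pairwiseAlignment` under the same
  scheme; the aligner itself is this package's own, so the two routes stay
  independent.
* **Left-normalised coordinates**, 0-based: a deletion's position is its
  first deleted base, an insertion sits at the base before the inserted
  sequence, and indels inside repeats are shifted to their leftmost
  equivalent placement, making calls canonical regardless of traceback
  tie-breaks.
* **Substitution-only reads count as wild type**: the targeting site is
  intact for frame purposes. Reads with more than one indel are `complex`.

`classify_clone()` validates a clone only when all four rules pass:
(i) at least two non-wild-type alleles, or a single one at fraction
≥ 0.97 — treated as the same edit on both alleles, which is common in
CRISPR clones and otherwise indistinguishable from allele dropout at the
amplicon level; (ii) every non-wild-type allele is a simple out-of-frame
indel (complex alleles fail conservatively); (iii) wild-type fraction
strictly below 1%; (iv) the targeted exon is not skip-rescuable. Exon-skip
rescue is assessed for single internal exons only: skipping an internal
exon whose length is a multiple of 3 preserves the downstream frame;
first/last coding exons cannot be skipped this way. Multi-exon skips are
out of scope and the report says so via the rule identifier.
`rna_evidence()` is a pure decision rule over pre-tabulated counts
(≥ 15 covering reads, zero wild-type, zero in-frame-skip reads);
producing those counts from RNA-seq alignments is outside the package.

# Problem sizes and determinism

Every stochastic function takes an explicit seed and restores the caller's
RNG state; identical seeds give byte-identical counts, FASTQ and result
bundles, which the suite asserts. Operating characteristics are measured
on 100 seeded replicate screens of the default 4-plate geometry at depth
5 × 10⁴ (planted-hit recovery with one compound at kill fraction 0.9
against TP53, and null-screen specificity), plus 50–100 replicates of a
2-plate geometry for the down-sampling detection summaries — sizes chosen
so a full run of suite plus acceptance script completes in a few minutes
on one CPU while keeping binomial noise on a 100-replicate proportion
near ±3 percentage points.

# Known limitations

* The plate-median null breaks down if many compounds on one plate hit the
  same line; the statistic is the assay's, not a robust-regression
  alternative (no B-score or median polish, by design).
* Z-scores use the sample (n−1) SD by default; population SD is available
  (`sd_mode`), as is leave-one-out plate context (`exclude_self`) since
  the assay description is ambiguous about whether the well under test
  joins its own null. Include-all is the default; on 96 wells the
  difference is small.
* Kill fractions act on expected end-point abundance; cytostatic versus
  cytotoxic mechanisms, dose–response shapes and line–line interactions
  are not modelled, and no IC50 fitting is attempted.
* The detection probabilities reported by the acceptance script are
  properties of the synthetic count distributions; real screens have
  heavier-tailed representation and will sit lower, so only the
  directional comparison (90% versus 50% reduction) transfers.
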