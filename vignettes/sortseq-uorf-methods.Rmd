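---
title: "Methods: sort-seq analysis of uORF coding-variant libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sort-seq analysis of uORF coding-variant libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uorfsort)
```

## The assay and the estimation problem

Upstream open reading frames (uORFs) are short coding sequences in mRNA
transcript leaders that modulate translation of the downstream main ORF,
usually repressing it, occasionally enhancing it. Because scanning
pre-initiation complexes must traverse the uORF region, the *speed* at which
an 80S ribosome translates the uORF — set largely by codon optimality and
inhibitory codon pairs — can determine how strongly the uORF throttles
downstream initiation.

`uorfsort` analyses massively parallel reporter assays of this question. A
library of uORF coding variants is built by degenerate synthesis: a fixed
7-codon reading frame (`ATGAAC`–XXX–XXX–XXX–`TTTTAG`) whose middle three
codons are randomized through an IUPAC pattern such as `MRN`
(M = A/C, R = A/G, N = any base; 16 codons, no stops, hence
16³ = 4,096 coding variants). Every variant is paired with a start-codon-dead
control in which AUG is mutated to AGG, so the variant-specific effect of
*translating* the uORF is the contrast between the two partners. Cells
carrying a dual-fluorescent reporter (YFP controlled by the variant leader,
mCherry as internal control) are flow-sorted on the YFP/mCherry ratio into
`n` bins (8 by default), plasmid DNA is sequenced from each bin, and each
variant's expression is inferred from its read distribution across bins.

## The estimator

Let `CellCount_i` be the number of cells sorted into bin `i`,
`ReadsCount_{v,i}` the perfect-match read count of variant `v` in bin `i`,
and `Y_i` the measured YFP/mCherry ratio of bin `i`. The occupancy of
variant `v` in bin `i` is its read fraction scaled by the bin's share of
sorted cells,

    F[v,i] = (CellCount_i / sum_j CellCount_j) *
             (ReadsCount[v,i] / ReadsCount[total,i]),

and the expression estimate is the bin-weighted average

    Y_v = sum_i ( F[v,i] / sum_j F[v,j] ) * Y_i .

`Y_v` is a convex combination of the bin calibration values, so it always
lies inside `[min Y_i, max Y_i]`; a variant with no reads anywhere is
undefined and flagged rather than guessed. There are no pseudocounts:
zero-read bins contribute zero weight, and a bin with zero total reads
contributes zero occupancy for every variant.

Three per-variant quantities are derived:

* **protein effect** `log2(Y_v^AUG / Y_v^AGG)`;
* **RNA effect** `log2(rna_dna^AUG / rna_dna^AGG)`, where `rna_dna` is
  RNA reads-per-million over unsorted-plasmid DNA reads-per-million
  (transcript abundance corrected for plasmid representation);
* **translation-efficiency effect**, computed as the difference of the two
  (an exact identity, since TE = Y / (RNA/DNA); computing it by subtraction
  keeps the identity exact to the last bit).

Variants with fewer than 20 summed per-bin DNA reads fail QC and are
excluded from effect tables and downstream statistics. The threshold is a
package choice (assays of this kind rarely state one); it is configurable
via `variant_quant(min_reads=)`. When several replicate count sets are
supplied, `combine_replicates()` first verifies that replicate `Y_v`
estimates correlate (warning below r = 0.9), then averages them — the
standard practice for replicated sorts.

## The generative simulator

`simulate_sortseq()` is a first-class model of the experiment, used both to
validate the estimator and to calibrate the statistics. Its structure:

1. **Planted truth** (`generate_truth`). Each AUG variant's true protein
   effect (log2) is `intercept + Σ codon-at-position coefficients +
   Σ ordered-dicodon coefficients + Normal(0, residual_sd)`; its AGG partner
   is 0 by construction. True RNA effects are an intercept plus per-codon
   presence terms. Each codon *triple* draws one baseline expression level
   (log2 SD `base_ratio_sd = 0.15`) shared by the AUG/AGG pair — constructs
   differ in baseline output even without uORF translation, and sharing the
   baseline makes it cancel exactly in the paired contrast. Plasmid
   abundances are log-normal with SD 0.3, the spread expected when a cloned
   library is bottlenecked through on the order of ten colonies per variant
   (CV ≈ 1/√10).
2. **Cells and sorting** (`simulate_cells_and_sort`). Each cell draws a
   variant proportional to plasmid abundance and a log2 YFP/mCherry ratio
   Normal(true mean, `cell_noise_sd = 0.25`) — multiplicative reporter
   noise, the standard sort-seq assumption. Cells are gated into
   equal-count bins by rank; a gate never splits cells with identical
   fluorescence (it moves to the nearest value change), and if *all* cells
   share one value the simulator falls back to a single occupied bin with a
   warning. `Y_i` is the mean linear ratio of the cells in bin `i`,
   standing in for a post-sort bulk fluorometer measurement of the regrown
   bin (a fluorometer reads total YFP over total mCherry, i.e. close to the
   linear mixture mean); regrowth drift is out of scope.
3. **Reads** (`sample_reads`). Per-bin DNA counts are multinomial at the
   configured depth over the bin's cell occupancy; unsorted DNA counts are
   multinomial over abundances; RNA counts over abundance × 2^(RNA effect)
   (RNA is extracted before sorting). `emit_fastq()` can materialize every
   counted read as a 2 × 150 nt pair over a fixed 200-nt amplicon, with an
   optional uniform substitution error rate for negative tests.

The default effect generator plants the qualitative structure such screens
report: a mildly enhancing baseline (intercept +0.3 log2), the rare arginine
codon CGA strongly repressive with the largest coefficient at the first
varied position, a few A/T-rich and arginine codons mildly repressive,
common glutamine/histidine codons mildly enhancing, forward-order-only
inhibitory dicodons, a ~10% mRNA decrease for CGA-containing variants and a
small global mRNA decrease for AUG constructs. The coefficient scale is
anchored so that true effects span roughly 2-fold repression to 2-fold
enhancement, the dynamic range these assays report.

**What the simulator does not emulate:** fluorescence spectral overlap and
compensation, sorter drop-out and doublets, PCR jackpotting (reads are
multinomial given the template pool), regrowth drift between sorting and
bin calibration, and NMD-mediated coupling between uORF translation and
mRNA level beyond the planted RNA coefficients. Passing recovery tests
therefore demonstrate estimator correctness under idealized but structured
noise, not robustness to every artifact of real data.

## Read processing

The amplicon is fixed-length and the counting contract keeps only reads
that match a designed reference perfectly, so a deterministic overlap
merger plus anchored exact matching replaces a general-purpose aligner.
`merge_pairs()` reverse-complements the reverse read, chooses the overlap
maximizing matching bases (≥ 10 nt overlap, ≤ 2 mismatches by default,
mirroring common merger defaults), and takes the higher-quality base at
disagreements with ties to the forward read. `count_perfect_matches()`
locates the 21-nt variant region by exact 12-nt flank anchors, requires the
region (start codon included) to equal a reference exactly, tries both
orientations, and tallies every discard. Random primer-complexity bases
outside the anchors are ignored by construction. The shipped flanks are
synthetic stand-ins of realistic length (86 + 21 + 93 = 200 nt); any fixed
context with unique anchors behaves identically, and real-data users supply
their own flanks.

## Statistics

* **Codon groups** are computed from variant identity (codon at a given
  position, or at any position), never by re-parsing sequences.
* **Presence tests** are Welch two-sample t-tests of codon-containing
  variants against the rest; Welch avoids the equal-variance assumption.
  Degenerate inputs (both groups numerically constant) return p = 1 when
  the means agree and p = 0 otherwise, by convention.
* **Dicodon order tests** compare, for every unordered pair {A, B} of
  distinct codons (alphabetical order defines "forward"), variants with
  (A, B) at an adjacent position pair against variants with (B, A), by
  Welch t-test on the protein effect. Benjamini–Hochberg adjustment is
  applied within each position pair, matching the per-position-pair
  reporting of such analyses; self-pairs have no order and are excluded;
  undersized groups are reported untested with a reason. With a 16-codon
  alphabet this yields 120 pairs per position pair.
* **nTE scoring**: a variant's codon-optimality score is the arithmetic
  mean of per-codon nTE values (tRNA supply relative to codon demand) over
  the three varied positions, correlated with effects by Pearson
  correlation. nTE tables are user-supplied inputs; the package ships only
  a clearly-labelled synthetic table for testing.

## The regression model

`encode_features()` produces indicator designs: codon-by-position (48
columns for a 16-codon, 3-position library; each row sums to 3), codon
presence (16 columns), and amino-acid-by-position. `fit_lasso()` uses
10-fold cross-validation to pick the L1 penalty at the CV-minimum (not the
1-SE rule — the quantity of interest is variance explained, which the
minimum maximizes), refits on all rows at that penalty, and reports the
in-sample R² as the headline with the cross-validated R² alongside (the two
differ by under a point at these problem sizes). Binary indicators are left
unstandardized — they already share a scale — while an optional appended
numeric predictor (e.g. a 5′-leader folding energy computed by any external
tool; no folding is computed here) is z-scored. Importance is the absolute
coefficient, ties broken by column order, making rankings deterministic.
Fold assignment is seeded, so identical inputs and seed reproduce the fit
exactly.

## Numerical choices and degenerate inputs

* Variant enumeration order is AUG-first, then lexicographic by codon
  triple, so joins and diffs are reproducible across modules.
* Stop codons are excluded from variable positions at enumeration (the
  reading frame is defined by the fixed terminal TAG).
* All-zero occupancy rows, zero-DNA transcription ratios, missing AUG/AGG
  partners and missing nTE codons are flagged (NA / omission records), not
  errors; negative counts and invalid IUPAC codes are errors naming the
  offender.
* Equal-count gating uses rank with tie-preserving boundaries; duplicated
  boundaries yield empty bins (calibration value NA, weight zero).

## Validation scale and expected numbers

The test-suite and acceptance problems are sized for a single CPU:
estimator-vs-oracle checks on 100 random count matrices (agreement to
< 1e−12 relative error), boundedness on 1,000 random matrices, end-to-end
recovery on the full 4,096 + controls library with 400,000 sorted cells and
250,000 reads per bin, two replicate sorts averaged (planted-vs-estimated
protein-effect R² ≈ 0.93), an exact FASTQ round trip on the 384-variant
dicodon library, null calibration of the dicodon tests over 200 reduced
(8-codon, 512 + 512 variant) datasets (empirical type-I rate ≈ 0.045 at
α = 0.05), planted-dicodon power over 20 replicates, and lasso recovery of
noiseless and R² = 0.60 planted models over 20 seeds.

## Known limitations

* **Bin censoring.** With 8 bins, variants whose fluorescence distribution
  sits mostly inside a terminal bin are compressed toward that bin's
  calibration value; estimated effects of extreme variants are attenuated
  (regression slope vs truth ≈ 0.85 at the validation scale). This is a
  property of the estimator itself, shared by the real assay; replicate
  correlation does not reveal it because both replicates share the bias.
  Averaging replicate sorts mitigates the independent-noise component only.
* **Perfect-match counting discards information.** Reads with any mismatch
  in the anchored region are dropped rather than error-corrected; at
  realistic error rates this costs depth, not accuracy.
* The lasso reports no coefficient standard errors; rankings are
  descriptive.
* The dicodon test treats variants as exchangeable units; estimated effects
  share a common bin calibration, a dependence the t-test ignores. The null
  calibration above shows the impact is negligible at the validated scale.
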