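# uorfsort

Sort-seq analysis of upstream ORF (uORF) coding-variant reporter libraries.

Upstream open reading frames are short coding sequences in mRNA transcript
leaders that repress — or sometimes enhance — translation of the downstream
main ORF. Whether a given uORF throttles or boosts expression depends in
part on *which codons it contains and where*: rare codons and inhibitory
codon pairs stall the translating ribosome inside the leader. `uorfsort` is
for groups running (or simulating) massively parallel reporter assays that
read out thousands of uORF coding variants at once by FACS sorting a
dual-fluorescent reporter library into bins and sequencing plasmid DNA from
each bin.

The package covers the full computational pipeline:

* **Library design** — enumerate degenerate (IUPAC) codon libraries such as
  `MRN`×3 (4,096 coding variants) with paired AGG start-codon-dead
  controls, translate them, write FASTA/TSV.
* **Simulation** — a generative model of the assay (planted codon/dicodon
  effects → cells → sorting → per-bin sequencing, optional FASTQ) for
  validation and power analysis.
* **Read processing** — paired-end overlap merging and anchored
  perfect-match counting against the designed references.
* **Quantification** — the sort-seq estimator. With `CellCount_i` sorted
  cells and `ReadsCount_{v,i}` reads for variant *v* in bin *i*, and `Y_i`
  the measured YFP/mCherry ratio of bin *i*,

      F_{v,i} = (CellCount_i / Σ_j CellCount_j) · (ReadsCount_{v,i} / ReadsCount_{total,i})
      Y_v     = Σ_i ( F_{v,i} / Σ_j F_{v,j} ) · Y_i

  plus RNA/DNA transcription levels, translation efficiency, and paired
  AUG/AGG effects `log2(Y^AUG / Y^AGG)` at the protein, RNA and TE level.
* **Codon statistics** — per-codon effect distributions, codon-presence
  Welch tests, dicodon order-dependence tests with Benjamini–Hochberg
  adjustment, nTE (codon-optimality) scoring and correlation.
* **Regression modeling** — lasso fits on codon-identity×position indicator
  encodings with 10-fold cross-validated penalty selection, variance
  explained, encoding comparisons and importance rankings.

## Worked example

Simulate a full 4,096-variant MRN library (plus AGG controls) with the
default planted effects, quantify it, and ask the standard questions:

```r
library(uorfsort)

design <- uorf_design()                  # ATGAAC-MRN-MRN-MRN-TTTTAG
lib    <- enumerate_library(design)      # 8,192 constructs (AUG + AGG)

params <- sim_params(n_cells = 100000, depth_dna_per_bin = 100000, seed = 42)
sim    <- simulate_sortseq(lib, default_effect_generator(), params)

quant   <- variant_quant(sim$counts, sim$bin_scheme)
effects <- uorf_effects(quant)
head(effects[, 1:6], 3)
#>   codon1 codon2 codon3 protein_effect  rna_effect   te_effect
#> 1    AAA    AAA    AAA      0.4867690 -0.41024130 0.897010335
#> 2    AAA    AAA    AAC      0.1124995  0.10957043 0.002929056
#> 3    AAA    AAA    AAG      0.2916097 -0.05296371 0.344573398
```

Are CGA-containing uORFs more repressive than the rest?

```r
cga <- presence_test(effects, "CGA")
#> CGA presence: t = -37.6, p = 4.9e-192, mean effect -0.12 vs 0.23
```

CGA variants average a log2 effect of −0.12 against +0.23 for all others —
the planted repression is recovered. Does codon *order* matter for adjacent
pairs (positions 1–2)?

```r
dt <- dicodon_order_tests(effects, "1-2")
sum(dt$tested)                        # 120 unordered codon pairs
head(dt[order(dt$p_adj), c("codon_a", "codon_b", "mean_diff", "p_adj")], 1)
#>     codon_a codon_b  mean_diff        p_adj
#> 116     CGA     CGG -0.3421043 0.0000686847
```

CGA-then-CGG is significantly more repressive than CGG-then-CGA, as
planted. Finally, model the effects from codon identity and position:

```r
fit <- fit_lasso(encode_features(effects), effects$protein_effect, seed = 1)
fit
#> Lasso fit (codon_position encoding): 36 of 48 variables selected
#>   lambda = 0.0003583, in-sample R2 = 0.4853, CV R2 = 0.4745
#>  feature coefficient importance rank
#>   CGA.p1  -0.4547741  0.4547741    1
#>   CGA.p2  -0.3210939  0.3210939    2
#>   CGA.p3  -0.2268830  0.2268830    3
```

CGA at the first varied position is the most predictive feature, with
positional decay — the planted structure. The in-sample R² of ~0.49 at this
reduced depth reflects measurement noise on top of the generative R²; see
the methods vignette (`vignettes/sortseq-uorf-methods.Rmd`) for the model,
its assumptions and its limitations.

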