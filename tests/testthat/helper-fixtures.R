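# Shared fixtures: small libraries and quick simulation settings used across
# test files. Everything is generated in code at test time.

# reduced 8-codon alphabet library (M x R x S = 2 x 2 x 2 codons, no stops)
mrs_library <- function(starts = c("AUG", "AGG")) {
  enumerate_library(uorf_design(c("MRS", "MRS", "MRS"), starts = starts))
}

# tiny 4-codon alphabet library for FASTQ round trips (AAC, AGC, CAC, CGC)
mrc_library <- function(starts = c("AUG", "AGG")) {
  enumerate_library(uorf_design(c("MRC", "MRC", "MRC"), starts = starts))
}

# fast simulation scale for reduced-alphabet datasets
quick_params <- function(seed = 1L) {
  sim_params(n_cells = 25600, depth_dna_per_bin = 20000,
             depth_rna = 50000, depth_dna_unsorted = 50000, seed = seed)
}

# simulate a reduced-alphabet dataset and return truth + estimated effects
quick_sim_effects <- function(gen, seed, lib = mrs_library(),
                              params = quick_params()) {
  set.seed(seed)
  truth <- generate_truth(lib, gen)
  so <- simulate_cells_and_sort(truth, params)
  cs <- sample_reads(so$occupancy, truth, params)
  eff <- uorf_effects(variant_quant(cs, so$bin_scheme))
  list(truth = truth, effects = eff, bin_scheme = so$bin_scheme, counts = cs)
}

# pseudo effect table straight from a library (no simulation), with supplied
# or zero effects -- used by membership/encoding tests
effects_from_library <- function(lib, protein_effect = 0) {
  aug <- lib[lib$start == "AUG", ]
  out <- data.frame(codon1 = aug$codon1, codon2 = aug$codon2,
                    codon3 = aug$codon3,
                    protein_effect = rep_len(protein_effect, nrow(aug)),
                    rna_effect = 0, te_effect = rep_len(protein_effect,
                                                        nrow(aug)),
                    stringsAsFactors = FALSE)
  class(out) <- c("uorf_effects", "data.frame")
  out
}

# independent brute-force oracle for the occupancy / expression formulas:
# plain double loops over the printed definitions
naive_quant <- function(counts, cell_counts, y) {
  nv <- nrow(counts); nb <- ncol(counts)
  F <- matrix(0, nv, nb)
  for (v in seq_len(nv)) {
    for (i in seq_len(nb)) {
      tot <- 0
      for (w in seq_len(nv)) tot <- tot + counts[w, i]
      if (tot > 0)
        F[v, i] <- (cell_counts[i] / sum(cell_counts)) * counts[v, i] / tot
    }
  }
  Y <- rep(NA_real_, nv)
  for (v in seq_len(nv)) {
    s <- sum(F[v, ])
    if (s > 0) {
      acc <- 0
      for (i in seq_len(nb)) acc <- acc + F[v, i] / s * y[i]
      Y[v] <- acc
    }
  }
  list(F = F, Y = Y)
}
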