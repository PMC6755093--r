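test_that("planted truth places coefficients on exactly the right variants", {
  lib <- enumerate_library(uorf_design())

  # all-zero generator: every effect is zero
  tr0 <- generate_truth(lib, effect_generator(), base_ratio_sd = 0)
  expect_true(all(tr0$true_protein_log2fc == 0))
  expect_true(all(tr0$true_rna_log2fc == 0))

  # a single codon-at-position coefficient hits the 256 AUG variants with
  # CGA at position 1 (1 x 16 x 16) and nothing else
  tr1 <- generate_truth(lib, effect_generator(
    codon_position = c("CGA:1" = -1)), base_ratio_sd = 0)
  aug <- tr1$start == "AUG"
  hit <- aug & tr1$codon1 == "CGA"
  expect_equal(sum(hit), 256)
  expect_true(all(tr1$true_protein_log2fc[hit] == -1))
  expect_true(all(tr1$true_protein_log2fc[!hit] == 0))

  # forward-only dicodon coefficient: forward and reverse order differ by it
  tr2 <- generate_truth(lib, effect_generator(
    dicodon = c("CGA>CGG:1" = -1)), base_ratio_sd = 0)
  fwd <- tr2$start == "AUG" & tr2$codon1 == "CGA" & tr2$codon2 == "CGG"
  rev <- tr2$start == "AUG" & tr2$codon1 == "CGG" & tr2$codon2 == "CGA"
  expect_true(all(tr2$true_protein_log2fc[fwd] == -1))
  expect_true(all(tr2$true_protein_log2fc[rev] == 0))

  # AGG partners always have zero planted effect; abundances sum to one
  tr3 <- generate_truth(lib, default_effect_generator(), seed = 5)
  expect_true(all(tr3$true_protein_log2fc[tr3$start == "AGG"] == 0))
  expect_equal(sum(tr3$abundance), 1)

  # coefficients for codons outside the library warn and are ignored
  small <- mrs_library()
  expect_warning(
    trw <- generate_truth(small, effect_generator(
      codon_position = c("TTT:1" = -2)), base_ratio_sd = 0),
    "absent")
  expect_true(all(trw$true_protein_log2fc == 0))
})

test_that("baseline expression is shared within an AUG/AGG pair", {
  lib <- mrs_library()
  tr <- generate_truth(lib, effect_generator(), seed = 3)
  key <- paste(tr$codon1, tr$codon2, tr$codon3)
  aug <- tr[tr$start == "AUG", ]
  agg <- tr[tr$start == "AGG", ]
  m <- match(paste(aug$codon1, aug$codon2, aug$codon3),
             paste(agg$codon1, agg$codon2, agg$codon3))
  expect_equal(aug$true_base_ratio, agg$true_base_ratio[m])
  expect_gt(sd(log2(aug$true_base_ratio)), 0)
})

test_that("sorting conserves cells and separates separable mixtures", {
  # two variants, no noise, two bins: each bin holds one variant exactly
  lib <- data.frame(
    variant_id = c("AUG_AAA_AAA_AAA", "AUG_CCC_CCC_CCC"),
    start = "AUG", codon1 = c("AAA", "CCC"), codon2 = c("AAA", "CCC"),
    codon3 = c("AAA", "CCC"), stringsAsFactors = FALSE)
  tr <- generate_truth(lib, effect_generator(), abundance_dispersion = 0,
                       base_ratio_sd = 0)
  tr$true_protein_log2fc <- c(0, 2)  # ratios 1.0 and 4.0
  p <- sim_params(n_bins = 2, n_cells = 1000, cell_noise_sd = 0,
                  depth_dna_per_bin = 100)
  so <- simulate_cells_and_sort(tr, p, seed = 9)
  expect_equal(sum(so$bin_scheme$cell_count), 1000)
  expect_equal(so$bin_scheme$yfp_mcherry, c(1, 4))
  expect_equal(so$occupancy["AUG_AAA_AAA_AAA", 2], 0)
  expect_equal(so$occupancy["AUG_CCC_CCC_CCC", 1], 0)

  # degenerate case: identical fluorescence everywhere falls back to one bin
  tr1 <- tr[1, ]
  class(tr1) <- class(tr)
  expect_warning(so1 <- simulate_cells_and_sort(tr1, p, seed = 9),
                 "bin 1")
  expect_equal(so1$bin_scheme$cell_count, c(1000, 0))
  expect_equal(so1$bin_scheme$yfp_mcherry[1], 1)

  # realistic scale: per-bin cell counts sum to n_cells
  lib8 <- mrs_library()
  tr8 <- suppressWarnings(
    generate_truth(lib8, default_effect_generator(), seed = 2))
  p8 <- quick_params()
  so8 <- simulate_cells_and_sort(tr8, p8, seed = 2)
  expect_equal(sum(so8$bin_scheme$cell_count), p8$n_cells)
  expect_equal(sum(so8$occupancy), p8$n_cells)
  expect_equal(colSums(so8$occupancy), so8$bin_scheme$cell_count,
               ignore_attr = TRUE)
  # equal-count gating: all bins within one cell-noise draw of equal
  expect_true(all(abs(so8$bin_scheme$cell_count - p8$n_cells / 8) < 50))
  expect_true(all(diff(so8$bin_scheme$yfp_mcherry) > 0))
})

test_that("read sampling respects depths and multinomial moments", {
  lib <- mrs_library()
  tr <- suppressWarnings(generate_truth(lib, default_effect_generator(), seed = 4))
  p <- quick_params()
  so <- simulate_cells_and_sort(tr, p, seed = 4)
  cs <- sample_reads(so$occupancy, tr, p, seed = 4)
  expect_s3_class(cs, "count_set")
  expect_equal(unname(colSums(cs$counts)), rep(p$depth_dna_per_bin, 8))
  expect_equal(sum(cs$dna_unsorted), p$depth_dna_unsorted)
  expect_equal(sum(cs$rna), p$depth_rna)

  # zero depth gives all-zero counts
  p0 <- sim_params(n_cells = 1000, depth_dna_per_bin = 0, depth_rna = 0,
                   depth_dna_unsorted = 0)
  cs0 <- sample_reads(so$occupancy, tr, p0, seed = 1)
  expect_true(all(cs0$counts == 0) && all(cs0$rna == 0))

  # single variant: every read lands on it in every occupied bin
  occ1 <- matrix(c(10L, 0L), 1, 2, dimnames = list("AUG_AAC_AAC_AAC", NULL))
  tr1 <- tr[1, ]; tr1$abundance <- 1
  p1 <- sim_params(n_bins = 2, n_cells = 10, depth_dna_per_bin = 500,
                   depth_rna = 100, depth_dna_unsorted = 100)
  cs1 <- sample_reads(occ1, tr1, p1, seed = 1)
  expect_equal(unname(cs1$counts[1, ]), c(500L, 0L))

  # multinomial moments: empirical mean within 3 standard errors
  occ <- matrix(c(50L, 30L, 10L, 5L, 5L), 5, 1,
                dimnames = list(paste0("AUG_AAC_AAC_AA", c("C", "G", "T", "A", "S")), NULL))
  trm <- data.frame(abundance = rep(0.2, 5), true_rna_log2fc = 0)
  pm <- sim_params(n_bins = 2, n_cells = 100, depth_dna_per_bin = 1000,
                   depth_rna = 0, depth_dna_unsorted = 0)
  reps <- vapply(1:200, function(k)
    sample_reads(cbind(occ, 0L), trm, pm, seed = k)$counts[1, 1], numeric(1))
  p_hat <- 50 / 100
  se <- sqrt(1000 * p_hat * (1 - p_hat) / 200)
  expect_lt(abs(mean(reps) - 1000 * p_hat), 3 * se)
})

test_that("identical parameters and seed give identical simulations", {
  lib <- mrc_library()
  p <- sim_params(n_cells = 2000, depth_dna_per_bin = 1000,
                  depth_rna = 2000, depth_dna_unsorted = 2000, seed = 77)
  s1 <- suppressWarnings(simulate_sortseq(lib, default_effect_generator(), p))
  s2 <- suppressWarnings(simulate_sortseq(lib, default_effect_generator(), p))
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$counts$counts, s2$counts$counts)
  expect_identical(s1$bin_scheme, s2$bin_scheme)
})

test_that("count set TSV round-trips", {
  lib <- mrc_library()
  p <- sim_params(n_cells = 2000, depth_dna_per_bin = 500,
                  depth_rna = 1000, depth_dna_unsorted = 1000, seed = 3)
  sim <- suppressWarnings(simulate_sortseq(lib, default_effect_generator(), p))
  f <- tempfile(fileext = ".tsv")
  write_count_set(sim$counts, f)
  back <- read_count_set(f)
  expect_equal(back$counts, sim$counts$counts)
  expect_equal(back$rna, sim$counts$rna)
  g <- tempfile(fileext = ".tsv")
  write_bin_scheme(sim$bin_scheme, g)
  bs <- read_bin_scheme(g)
  expect_equal(bs$yfp_mcherry, sim$bin_scheme$yfp_mcherry)
  unlink(c(f, g))
})
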