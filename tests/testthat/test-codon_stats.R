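test_that("codon group membership matches inclusion-exclusion counting", {
  lib <- enumerate_library(uorf_design(starts = "AUG"))
  set.seed(1)
  eff <- effects_from_library(lib, protein_effect = rnorm(4096))
  d <- codon_distribution(eff, "CGA")
  # |A u B u C| = 3*16^2 - 3*16 + 1 for one codon of a 16-codon alphabet
  expect_equal(d$n, 3 * 256 - 3 * 16 + 1)
  # positional membership is one column of the design
  expect_equal(codon_distribution(eff, "CGA", position = 1)$n, 256)
  # a codon outside the design has empty membership, not an error
  expect_equal(codon_distribution(eff, "TTT")$n, 0)
  # summaries agree with direct quantiles of the member values
  member <- eff$codon1 == "CGA" | eff$codon2 == "CGA" | eff$codon3 == "CGA"
  expect_equal(d$median, median(eff$protein_effect[member]))
})

test_that("presence test reproduces the hand-computed Welch statistic", {
  # identical groups: t = 0, p = 1
  eff_id <- data.frame(codon1 = c("CGA", "CGA", "CGA", "AAA", "AAA", "AAA"),
                       codon2 = "AAG", codon3 = "AAG",
                       protein_effect = c(1, 2, 3, 1, 2, 3))
  r_id <- presence_test(eff_id, "CGA")
  expect_equal(r_id$t, 0)
  expect_equal(r_id$p_value, 1)

  # textbook Welch formula evaluated independently for (0,0,0.1) vs (1,1,1.1)
  x <- c(0, 0, 0.1); y <- c(1, 1, 1.1)
  s2x <- sum((x - mean(x))^2) / 2; s2y <- sum((y - mean(y))^2) / 2
  se2 <- s2x / 3 + s2y / 3
  t_hand <- (mean(x) - mean(y)) / sqrt(se2)
  df_hand <- se2^2 / ((s2x / 3)^2 / 2 + (s2y / 3)^2 / 2)
  p_hand <- 2 * pt(-abs(t_hand), df_hand)
  eff_w <- data.frame(codon1 = rep(c("CGA", "AAA"), each = 3),
                      codon2 = "AAG", codon3 = "AAG",
                      protein_effect = c(x, y))
  r_w <- presence_test(eff_w, "CGA")
  expect_equal(r_w$t, t_hand, tolerance = 1e-12)
  expect_equal(r_w$p_value, p_hand, tolerance = 1e-12)

  # degenerate variance: equal means give p = 1, unequal give p = 0
  eff_d <- eff_id
  eff_d$protein_effect <- rep(2, 6)
  expect_equal(presence_test(eff_d, "CGA")$p_value, 1)
  eff_d$protein_effect <- rep(c(0, 5), each = 3)
  expect_equal(presence_test(eff_d, "CGA")$p_value, 0)
})

test_that("dicodon order tests cover all pairs symmetrically", {
  lib <- enumerate_library(uorf_design(starts = "AUG"))
  set.seed(2)
  eff <- effects_from_library(lib, protein_effect = rnorm(4096))
  res12 <- dicodon_order_tests(eff, "1-2")
  # the 16-codon alphabet yields exactly 120 unordered pairs
  expect_equal(nrow(res12), choose(16, 2))
  expect_true(all(res12$tested))
  expect_true(all(res12$codon_a < res12$codon_b))
  expect_true(all(res12$p_adj >= res12$p_value - 1e-15))
  # forward groups at positions 1-2 have 16 variants (free third codon)
  expect_true(all(res12$n_fwd == 16) && all(res12$n_rev == 16))

  # shuffling the rows of the effect table changes nothing
  res_shuf <- dicodon_order_tests(eff[sample(nrow(eff)), ], "1-2")
  expect_equal(res12, res_shuf, tolerance = 1e-12)

  # under a pure null, BH leaves (almost) nothing significant
  expect_lt(sum(res12$p_adj < 0.05), 2)
})

test_that("a planted forward-only dicodon effect is found with the right sign", {
  gen <- effect_generator(dicodon = c("AAG>CGG:1" = -1.0), residual_sd = 0.15)
  sim <- quick_sim_effects(gen, seed = 11)
  res <- dicodon_order_tests(sim$effects, "1-2")
  top <- res[which.min(res$p_adj), ]
  expect_equal(c(top$codon_a, top$codon_b), c("AAG", "CGG"))
  expect_lt(top$p_adj, 0.05)
  # forward (AAG then CGG) is repressive relative to reverse
  expect_lt(top$mean_diff, 0)
  # position pair 2-3 is unaffected by a 1-2 planted effect
  res23 <- dicodon_order_tests(sim$effects, "2-3")
  expect_gt(min(res23$p_adj), 0.05)
})

test_that("small groups are skipped with a reason, not dropped silently", {
  eff <- data.frame(codon1 = c("AAA", "AAG", "AAG", "AAA", "AAG", "AAA"),
                    codon2 = c("AAG", "AAA", "AAA", "AAG", "AAA", "AAG"),
                    codon3 = "AAA",
                    protein_effect = rnorm(6))
  # pair {AAA, AAG} tested; groups of size 3 each
  res <- dicodon_order_tests(eff, "1-2", min_n = 2)
  expect_true(res$tested[res$codon_a == "AAA" & res$codon_b == "AAG"])
  res5 <- dicodon_order_tests(eff, "1-2", min_n = 5)
  row <- res5[res5$codon_a == "AAA" & res5$codon_b == "AAG", ]
  expect_false(row$tested)
  expect_match(row$note, "min_n")
})

test_that("nTE scoring and correlation behave as documented", {
  nte <- c(AAA = 0.2, AAC = 0.4, AAG = 0.9)
  x <- data.frame(codon1 = "AAA", codon2 = "AAC", codon3 = "AAG")
  expect_equal(nte_score(x, nte), 0.5, ignore_attr = TRUE)
  # all three codons equal: the score is that value
  x2 <- data.frame(codon1 = "AAC", codon2 = "AAC", codon3 = "AAC")
  expect_equal(nte_score(x2, nte), 0.4, ignore_attr = TRUE)
  # a missing codon flags the variant
  x3 <- data.frame(codon1 = "CGA", codon2 = "AAC", codon3 = "AAG")
  expect_true(is.na(nte_score(x3, nte)))

  # exact linear relation: r = 1, R2 = 1
  lib <- mrs_library(starts = "AUG")
  tab <- synthetic_nte_table()
  nte_all <- setNames(tab$nte, tab$codon)
  eff <- effects_from_library(lib)
  eff$protein_effect <- 2 * nte_score(eff, nte_all)
  ct <- nte_effect_correlation(eff, nte_all)
  expect_equal(ct$r, 1)
  expect_equal(ct$r2, 1)

  # constant nTE across the library is flagged undefined
  nte_const <- setNames(rep(1, nrow(tab)), tab$codon)
  eff$protein_effect <- rnorm(nrow(eff))
  ct2 <- nte_effect_correlation(eff, nte_const)
  expect_false(ct2$defined)

  # simulation with effects driven by nTE recovers a strong correlation
  gen <- effect_generator(
    codon_position = setNames(
      rep(0.8 * (nte_all[sort(unique(lib$codon1))] - 1), 3),
      paste0(rep(sort(unique(lib$codon1)), 3), ":",
             rep(1:3, each = length(unique(lib$codon1))))),
    residual_sd = 0.05)
  sim <- quick_sim_effects(gen, seed = 13)
  ct3 <- nte_effect_correlation(sim$effects, nte_all)
  expect_gt(ct3$r, 0.8)
})

test_that("the shipped synthetic nTE table loads and covers the library", {
  f <- system.file("extdata", "nte_synthetic.tsv", package = "uorfsort")
  expect_true(nzchar(f))
  nte <- read_nte_table(f)
  expect_equal(length(nte), 61)
  lib <- enumerate_library(uorf_design())
  expect_true(all(unique(lib$codon1) %in% names(nte)))
  # CGA is the rarest-decoded codon in the synthetic scale
  expect_equal(names(which.min(nte)), "CGA")
  expect_identical(unname(nte), synthetic_nte_table()$nte)
})
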