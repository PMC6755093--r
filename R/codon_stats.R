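# Codon-level and dicodon-level statistics on paired uORF effect tables.

effect_codons <- function(effects) {
  sort(unique(c(effects$codon1, effects$codon2, effects$codon3)))
}

codon_membership <- function(effects, codon, position = NULL) {
  if (is.null(position)) {
    effects$codon1 == codon | effects$codon2 == codon |
      effects$codon3 == codon
  } else {
    stopifnot(position %in% 1:3)
    effects[[paste0("codon", position)]] == codon
  }
}

#' Distribution of uORF effects for variants containing a codon
#'
#' Summarises the chosen effect column over the variants carrying
#' \code{codon} at any varied position (default) or at one specific
#' position. Membership is computed from the variant's codon identity
#' columns, never by re-parsing sequences.
#'
#' @param effects A \code{uorf_effects} table.
#' @param codon Concrete 3-nt codon.
#' @param position \code{NULL} for any-position membership, or 1..3.
#' @param column Effect column (default \code{"protein_effect"}).
#' @return List with \code{codon}, \code{position}, \code{n}, \code{median},
#'   \code{q1}, \code{q3} and the member \code{values}. Empty membership
#'   gives \code{n = 0} with NA summaries.
#' @export
codon_distribution <- function(effects, codon, position = NULL,
                               column = "protein_effect") {
  stopifnot(column %in% names(effects))
  member <- codon_membership(effects, codon, position)
  vals <- effects[[column]][member]
  if (!length(vals)) {
    return(list(codon = codon, position = position, n = 0L,
                median = NA_real_, q1 = NA_real_, q3 = NA_real_,
                values = numeric()))
  }
  qs <- quantile(vals, c(0.25, 0.5, 0.75), names = FALSE)
  list(codon = codon, position = position, n = length(vals),
       median = qs[2L], q1 = qs[1L], q3 = qs[3L], values = vals)
}

# Welch two-sample t-test robust to degenerate inputs: with (numerically)
# zero variance in both groups, equal means give p = 1 by convention and
# unequal means p = 0.
welch_test <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    stop("both groups need n >= 2")
  res <- tryCatch(t.test(x, y, var.equal = FALSE),
                  error = function(e) NULL)
  if (is.null(res)) {
    if (isTRUE(all.equal(mean(x), mean(y))))
      return(list(statistic = 0, p.value = 1))
    return(list(statistic = sign(mean(x) - mean(y)) * Inf, p.value = 0))
  }
  list(statistic = unname(res$statistic), p.value = res$p.value)
}

#' Test whether codon-containing variants differ from the rest
#'
#' Welch two-sample t-test comparing the chosen effect column between
#' variants containing \code{codon} (at any varied position, or at one
#' position) and all other variants.
#'
#' @inheritParams codon_distribution
#' @return List with \code{t}, \code{p_value}, group sizes and means.
#' @export
presence_test <- function(effects, codon, position = NULL,
                          column = "protein_effect") {
  member <- codon_membership(effects, codon, position)
  x <- effects[[column]][member]
  y <- effects[[column]][!member]
  res <- welch_test(x, y)
  list(codon = codon, t = res$statistic, p_value = res$p.value,
       n_in = length(x), n_out = length(y),
       mean_in = mean(x), mean_out = mean(y))
}

#' Order-dependence tests for all unordered codon pairs
#'
#' For every unordered pair \{A, B\} of distinct codons in the library
#' alphabet (alphabetical order defines the forward direction), variants
#' carrying (A, B) at the chosen adjacent position pair are compared with
#' variants carrying (B, A) by Welch t-test on \code{protein_effect}.
#' P-values are Benjamini-Hochberg adjusted across all pairs tested at that
#' position pair. Self-pairs (A = A) have no order and are excluded; pairs
#' with a group below \code{min_n} are reported untested with a reason.
#'
#' @param effects A \code{uorf_effects} table.
#' @param position_pair \code{"1-2"} (variable codons 1 and 2) or
#'   \code{"2-3"}.
#' @param min_n Minimum group size (default 2).
#' @param column Effect column (default \code{"protein_effect"}).
#' @return data.frame: \code{codon_a}, \code{codon_b} (alphabetical),
#'   \code{position_pair}, \code{n_fwd}, \code{n_rev}, \code{mean_diff}
#'   (forward minus reverse), \code{t}, \code{p_value}, \code{p_adj},
#'   \code{tested}, \code{note}.
#' @export
dicodon_order_tests <- function(effects, position_pair = c("1-2", "2-3"),
                                min_n = 2L, column = "protein_effect") {
  position_pair <- match.arg(position_pair)
  cols <- if (position_pair == "1-2") c("codon1", "codon2") else
    c("codon2", "codon3")
  first <- effects[[cols[1L]]]
  second <- effects[[cols[2L]]]
  codons <- effect_codons(effects)
  if (length(codons) < 2L) stop("need at least two codons in the alphabet")
  pairs <- combn(codons, 2L)  # columns already have codon_a < codon_b

  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1L, k]; b <- pairs[2L, k]
    fwd <- effects[[column]][first == a & second == b]
    rev <- effects[[column]][first == b & second == a]
    if (length(fwd) < min_n || length(rev) < min_n) {
      return(data.frame(codon_a = a, codon_b = b,
                        position_pair = position_pair,
                        n_fwd = length(fwd), n_rev = length(rev),
                        mean_diff = NA_real_, t = NA_real_,
                        p_value = NA_real_, tested = FALSE,
                        note = "group below min_n",
                        stringsAsFactors = FALSE))
    }
    res <- welch_test(fwd, rev)
    data.frame(codon_a = a, codon_b = b, position_pair = position_pair,
               n_fwd = length(fwd), n_rev = length(rev),
               mean_diff = mean(fwd) - mean(rev),
               t = res$statistic, p_value = res$p.value, tested = TRUE,
               note = "", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- NA_real_
  out$p_adj[out$tested] <- p.adjust(out$p_value[out$tested], method = "BH")
  rownames(out) <- NULL
  out
}

#' Read a codon nTE (normalized translation efficiency) table
#'
#' Expects a TSV with columns \code{codon} and \code{nte}. nTE measures
#' codon optimality as tRNA supply relative to codon demand; low values mark
#' rare codons such as CGA in yeast.
#'
#' @param file Path to the TSV.
#' @return Named numeric vector of nTE scores.
#' @export
read_nte_table <- function(file) {
  df <- utils::read.table(file, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stopifnot(all(c("codon", "nte") %in% names(df)), all(df$nte > 0))
  setNames(df$nte, toupper(df$codon))
}

#' Mean nTE score of each variant's varied codons
#'
#' The arithmetic mean of the per-codon nTE scores over the three varied
#' positions. Variants with any codon missing from the table are \code{NA}
#' (flagged, excluded from correlations).
#'
#' @param x A table with \code{codon1..3} columns (library or effects).
#' @param nte Named numeric vector (see \code{\link{read_nte_table}}).
#' @return Numeric vector of mean nTE scores.
#' @export
nte_score <- function(x, nte) {
  stopifnot(all(c("codon1", "codon2", "codon3") %in% names(x)))
  (nte[x$codon1] + nte[x$codon2] + nte[x$codon3]) / 3
}

#' Correlation between variant nTE scores and regulatory effects
#'
#' Pearson correlation between the per-variant mean nTE and the chosen
#' effect column; a positive correlation means optimal-codon uORFs enhance
#' and rare-codon uORFs repress. Zero variance in either vector is flagged
#' undefined rather than an error.
#'
#' @param effects A \code{uorf_effects} table.
#' @param nte Named numeric vector of codon nTE scores.
#' @param column Effect column (default \code{"protein_effect"}).
#' @return List with \code{r}, \code{r2}, \code{p_value}, \code{n},
#'   \code{defined}.
#' @export
nte_effect_correlation <- function(effects, nte, column = "protein_effect") {
  score <- nte_score(effects, nte)
  eff <- effects[[column]]
  keep <- !is.na(score) & !is.na(eff)
  score <- score[keep]; eff <- eff[keep]
  if (length(score) < 3L)
    stop("need at least 3 scored variants")
  if (sd(score) == 0 || sd(eff) == 0)
    return(list(r = NA_real_, r2 = NA_real_, p_value = NA_real_,
                n = length(score), defined = FALSE))
  ct <- cor.test(score, eff, method = "pearson")
  list(r = unname(ct$estimate), r2 = unname(ct$estimate)^2,
       p_value = ct$p.value, n = length(score), defined = TRUE)
}

#' A synthetic codon nTE table for testing and simulation
#'
#' Fixed, made-up optimality scores for all 61 sense codons, shaped like
#' yeast codon-optimality scales: CGA is the rarest-decoded codon, other
#' A/T-rich arginine codons are low, and codons read by abundant tRNAs score
#' above 1. These values are synthetic; analyses of real data should supply
#' a published nTE table instead. A copy ships as
#' \code{inst/extdata/nte_synthetic.tsv}.
#'
#' @return data.frame with columns \code{codon}, \code{nte}.
#' @export
synthetic_nte_table <- function() {
  nte <- c(
    AAA = 0.55, AAC = 1.10, AAG = 1.30, AAT = 0.60,
    ACA = 0.70, ACC = 1.05, ACG = 0.45, ACT = 1.00,
    AGA = 0.85, AGC = 0.55, AGG = 0.40, AGT = 0.50,
    ATA = 0.35, ATC = 1.10, ATG = 1.00, ATT = 1.00,
    CAA = 1.15, CAC = 1.00, CAG = 0.60, CAT = 0.80,
    CCA = 1.00, CCC = 0.45, CCG = 0.30, CCT = 0.70,
    CGA = 0.12, CGC = 0.35, CGG = 0.25, CGT = 0.75,
    CTA = 0.50, CTC = 0.45, CTG = 0.40, CTT = 0.55,
    GAA = 1.20, GAC = 1.00, GAG = 0.65, GAT = 0.85,
    GCA = 0.80, GCC = 0.95, GCG = 0.45, GCT = 1.25,
    GGA = 0.50, GGC = 0.95, GGG = 0.40, GGT = 1.20,
    GTA = 0.55, GTC = 1.00, GTG = 0.90, GTT = 1.15,
    TAC = 1.05, TAT = 0.60, TCA = 0.70, TCC = 1.00,
    TCG = 0.45, TCT = 1.10, TGC = 0.70, TGG = 0.90,
    TGT = 0.75, TTA = 0.80, TTC = 1.10, TTG = 1.20,
    TTT = 0.65
  )
  data.frame(codon = names(nte), nte = unname(nte), stringsAsFactors = FALSE)
}
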