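# The sort-seq expression estimator.
#
# For variant v and bin i the occupancy is
#   F[v, i] = (CellCount_i / sum_j CellCount_j) *
#             (ReadsCount_{v,i} / ReadsCount_{total,i})
# and the estimated reporter level is the bin-weighted average
#   Y_v = sum_i  F[v, i] / sum_j F[v, j] * Y_i,
# a convex combination of the measured per-bin YFP/mCherry ratios Y_i.
# There are no pseudocounts: bins with zero reads contribute zero weight.

#' Cell-count-normalized read occupancy per variant and bin
#'
#' Each variant's read fraction within a bin is scaled by the bin's share of
#' all sorted cells, correcting for the fact that equal sequencing depth is
#' drawn from bins holding different numbers of cells. Bins with zero total
#' reads contribute zero occupancy for every variant.
#'
#' @param cs A \code{\link{count_set}}.
#' @param bins A \code{\link{bin_scheme}} with as many bins as \code{cs} has
#'   bin columns.
#' @return Numeric matrix variant x bin of occupancies \code{F[v, i]}.
#' @export
compute_occupancy <- function(cs, bins) {
  stopifnot(inherits(cs, "count_set"), inherits(bins, "bin_scheme"),
            ncol(cs$counts) == nrow(bins))
  counts <- cs$counts
  if (any(counts < 0)) stop("negative read counts")
  cell_frac <- bins$cell_count / sum(bins$cell_count)
  tot <- colSums(counts)
  read_frac <- sweep(counts, 2L, ifelse(tot > 0, tot, 1), "/")
  read_frac[, tot == 0] <- 0
  sweep(read_frac, 2L, cell_frac, "*")
}

#' Bin-weighted expression estimate per variant
#'
#' The estimated YFP/mCherry level of each variant is the weighted average
#' of the per-bin measured ratios, with weights proportional to the
#' variant's occupancy across bins. Variants with zero occupancy everywhere
#' are returned as \code{NA} (flagged, not an error). Being a convex
#' combination, every defined estimate lies within the range of the bin
#' calibration values.
#'
#' @param occupancy Matrix from \code{\link{compute_occupancy}}.
#' @param bins The \code{\link{bin_scheme}}.
#' @return Named numeric vector of estimates \code{Y_v}.
#' @export
estimate_expression <- function(occupancy, bins) {
  stopifnot(is.matrix(occupancy), ncol(occupancy) == nrow(bins))
  y <- bins$yfp_mcherry
  y[bins$cell_count == 0 | is.na(y)] <- 0  # zero-weight bins cannot poison sums
  tot <- rowSums(occupancy)
  est <- as.vector(occupancy %*% y) / tot
  est[tot == 0] <- NA_real_
  setNames(est, rownames(occupancy))
}

#' Transcription level per variant (RPM RNA / RPM DNA)
#'
#' RNA reads-per-million divided by unsorted plasmid DNA reads-per-million,
#' correcting construct RNA abundance for relative plasmid representation.
#' RPM normalization uses the library-wide totals. Variants with zero DNA
#' reads are undefined (\code{NA}).
#'
#' @param cs A \code{\link{count_set}} with unsorted DNA and RNA counts.
#' @return Named numeric vector of RNA/DNA ratios.
#' @export
transcription_level <- function(cs) {
  stopifnot(inherits(cs, "count_set"))
  tot_dna <- sum(cs$dna_unsorted)
  tot_rna <- sum(cs$rna)
  if (tot_dna <= 0 || tot_rna <= 0)
    stop("unsorted DNA and RNA totals must be positive")
  rpm_dna <- cs$dna_unsorted / tot_dna * 1e6
  rpm_rna <- cs$rna / tot_rna * 1e6
  out <- rpm_rna / rpm_dna
  out[cs$dna_unsorted == 0] <- NA_real_
  setNames(out, rownames(cs$counts))
}

parse_variant_id <- function(ids) {
  parts <- strsplit(ids, "_", fixed = TRUE)
  bad <- lengths(parts) != 4L
  if (any(bad))
    stop("variant ids must have the form START_CODON1_CODON2_CODON3")
  data.frame(start = vapply(parts, `[`, "", 1L),
             codon1 = vapply(parts, `[`, "", 2L),
             codon2 = vapply(parts, `[`, "", 3L),
             codon3 = vapply(parts, `[`, "", 4L),
             stringsAsFactors = FALSE)
}

#' Per-variant quantification table
#'
#' Combines the bin-weighted expression estimate, the RNA/DNA transcription
#' level and the translation efficiency (expression per unit RNA) with a
#' read-support QC flag. Variants with fewer than \code{min_reads} DNA reads
#' across bins, or an undefined estimate, fail QC and are excluded from
#' downstream statistics.
#'
#' @param cs A \code{\link{count_set}}.
#' @param bins A \code{\link{bin_scheme}}.
#' @param min_reads QC threshold on summed per-bin DNA reads (default 20).
#' @return A data.frame of class \code{variant_quant}: \code{variant_id},
#'   \code{start}, \code{codon1..3}, \code{y} (estimated YFP/mCherry),
#'   \code{rna_dna}, \code{te}, \code{reads}, \code{qc_pass}.
#' @export
variant_quant <- function(cs, bins, min_reads = 20L) {
  occ <- compute_occupancy(cs, bins)
  y <- estimate_expression(occ, bins)
  rd <- transcription_level(cs)
  reads <- rowSums(cs$counts)
  ids <- rownames(cs$counts)
  out <- cbind(
    data.frame(variant_id = ids, stringsAsFactors = FALSE),
    parse_variant_id(ids),
    data.frame(y = unname(y), rna_dna = unname(rd), te = unname(y / rd),
               reads = unname(reads),
               qc_pass = unname(reads >= min_reads & !is.na(y) & !is.na(rd) &
                                  rd > 0),
               stringsAsFactors = FALSE)
  )
  rownames(out) <- NULL
  class(out) <- c("variant_quant", "data.frame")
  out
}

#' Average replicate quantifications
#'
#' Verifies that replicate expression estimates are highly correlated on the
#' variants passing QC in all replicates, then averages \code{y},
#' \code{rna_dna} and \code{te} and sums read support. A warning is issued
#' if any replicate pair correlates below \code{min_cor}.
#'
#' @param quants List of \code{variant_quant} tables over the same variants.
#' @param min_cor Minimum acceptable pairwise Pearson correlation of
#'   \code{y} (default 0.9).
#' @return A \code{variant_quant} of replicate means.
#' @export
combine_replicates <- function(quants, min_cor = 0.9) {
  stopifnot(is.list(quants), length(quants) >= 1L)
  if (length(quants) == 1L) return(quants[[1L]])
  ids <- quants[[1L]]$variant_id
  for (q in quants) stopifnot(identical(q$variant_id, ids))
  pass <- Reduce(`&`, lapply(quants, `[[`, "qc_pass"))
  for (i in seq_along(quants)) {
    for (j in seq_len(i - 1L)) {
      r <- cor(quants[[i]]$y[pass], quants[[j]]$y[pass],
               use = "complete.obs")
      if (is.na(r) || r < min_cor)
        warning(sprintf("replicates %d and %d correlate at r = %.3f (< %.2f)",
                        j, i, r, min_cor))
    }
  }
  out <- quants[[1L]]
  for (col in c("y", "rna_dna", "te"))
    out[[col]] <- rowMeans(do.call(cbind, lapply(quants, `[[`, col)))
  out$reads <- Reduce(`+`, lapply(quants, `[[`, "reads"))
  out$qc_pass <- pass
  out
}

#' Paired AUG/AGG uORF regulatory effects
#'
#' For every codon triple with both start-codon versions passing QC, the
#' protein-level effect is \code{log2(Y_AUG / Y_AGG)}, the RNA-level effect
#' \code{log2(rna_dna_AUG / rna_dna_AGG)}, and the translation-efficiency
#' effect their difference (an exact identity, since TE = Y / (RNA/DNA)).
#' Triples missing a QC-passing partner are omitted and recorded in the
#' \code{"omitted"} attribute with the reason.
#'
#' @param quant A \code{variant_quant} containing AUG and AGG rows.
#' @return A data.frame of class \code{uorf_effects}: \code{codon1..3},
#'   \code{protein_effect}, \code{rna_effect}, \code{te_effect},
#'   \code{y_aug}, \code{y_agg}.
#' @export
uorf_effects <- function(quant) {
  stopifnot(inherits(quant, "variant_quant") || is.data.frame(quant))
  aug <- quant[quant$start == "AUG", , drop = FALSE]
  agg <- quant[quant$start == "AGG", , drop = FALSE]
  key_aug <- paste(aug$codon1, aug$codon2, aug$codon3, sep = "_")
  key_agg <- paste(agg$codon1, agg$codon2, agg$codon3, sep = "_")
  m <- match(key_aug, key_agg)

  paired <- !is.na(m)
  a <- aug[paired, , drop = FALSE]
  g <- agg[m[paired], , drop = FALSE]
  ok <- a$qc_pass & g$qc_pass
  reason <- character(nrow(aug))
  reason[!paired] <- "no AGG partner"
  reason[paired][!ok] <- "QC fail in at least one partner"

  a2 <- a[ok, , drop = FALSE]; g2 <- g[ok, , drop = FALSE]
  protein <- log2(a2$y / g2$y)
  rna <- log2(a2$rna_dna / g2$rna_dna)
  out <- data.frame(
    codon1 = a2$codon1, codon2 = a2$codon2, codon3 = a2$codon3,
    protein_effect = protein, rna_effect = rna,
    te_effect = protein - rna,
    y_aug = a2$y, y_agg = g2$y,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  omitted <- data.frame(triple = key_aug[reason != ""],
                        reason = reason[reason != ""],
                        stringsAsFactors = FALSE)
  attr(out, "omitted") <- omitted
  class(out) <- c("uorf_effects", "data.frame")
  out
}

#' Write effect and quantification tables as TSV
#' @param x A \code{variant_quant} or \code{uorf_effects} table.
#' @param file Path.
#' @export
write_effect_table <- function(x, file) {
  utils::write.table(as.data.frame(x), file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
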