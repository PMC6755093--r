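#' Per-variant read counts across sort bins and unsorted samples
#'
#' Container shared by the simulator and the FASTQ counting pipeline, so the
#' quantification step is agnostic to where counts came from.
#'
#' @param counts Integer matrix, variants x bins; rownames are variant ids.
#' @param dna_unsorted Integer vector of unsorted plasmid DNA counts
#'   (same variants).
#' @param rna Integer vector of RNA-seq counts (same variants).
#' @param discarded Optional data.frame of per-sample discard tallies
#'   (columns \code{sample}, \code{unmerged}, \code{unmatched}).
#' @return A list of class \code{count_set}.
#' @export
count_set <- function(counts, dna_unsorted = NULL, rna = NULL,
                      discarded = NULL) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)))
  if (any(counts < 0)) stop("negative read counts are not allowed")
  nv <- nrow(counts)
  if (is.null(dna_unsorted)) dna_unsorted <- setNames(integer(nv), rownames(counts))
  if (is.null(rna)) rna <- setNames(integer(nv), rownames(counts))
  stopifnot(length(dna_unsorted) == nv, length(rna) == nv,
            all(dna_unsorted >= 0), all(rna >= 0))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("bin_", seq_len(ncol(counts)))
  structure(list(counts = counts, dna_unsorted = dna_unsorted, rna = rna,
                 discarded = discarded),
            class = "count_set")
}

#' @export
print.count_set <- function(x, ...) {
  cat("count_set:", nrow(x$counts), "variants x", ncol(x$counts), "bins\n",
      " bin reads:", paste(colSums(x$counts), collapse = " "), "\n",
      " unsorted DNA:", sum(x$dna_unsorted), " RNA:", sum(x$rna), "\n")
  if (!is.null(x$discarded)) {
    cat(" discarded (unmerged/unmatched):",
        sum(x$discarded$unmerged), "/", sum(x$discarded$unmatched), "\n")
  }
  invisible(x)
}

#' Write / read a count set as TSV
#'
#' The TSV has one row per variant: \code{variant_id}, one column per bin,
#' \code{dna_unsorted}, \code{rna}.
#'
#' @param cs A \code{count_set}.
#' @param file Path.
#' @return \code{read_count_set} returns a \code{count_set}.
#' @export
write_count_set <- function(cs, file) {
  stopifnot(inherits(cs, "count_set"))
  df <- data.frame(variant_id = rownames(cs$counts), cs$counts,
                   dna_unsorted = cs$dna_unsorted, rna = cs$rna,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_count_set
#' @export
read_count_set <- function(file) {
  df <- utils::read.table(file, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  bin_cols <- grep("^bin_", names(df), value = TRUE)
  m <- as.matrix(df[, bin_cols, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$variant_id
  count_set(m, dna_unsorted = setNames(as.integer(df$dna_unsorted), df$variant_id),
            rna = setNames(as.integer(df$rna), df$variant_id))
}

#' The sort-bin calibration scheme
#'
#' Holds, per fluorescence bin, the measured YFP/mCherry ratio (the bin
#' calibration value used as the estimator's weight grid) and the number of
#' sorted cells.
#'
#' @param yfp_mcherry Numeric vector of per-bin measured ratios (positive,
#'   increasing with bin order). Empty bins may be NA.
#' @param cell_count Non-negative integer vector of sorted cells per bin.
#' @param check_increasing Verify that ratios increase with bin index.
#' @return A data.frame of class \code{bin_scheme}.
#' @export
bin_scheme <- function(yfp_mcherry, cell_count, check_increasing = TRUE) {
  stopifnot(length(yfp_mcherry) == length(cell_count),
            length(yfp_mcherry) >= 1L, all(cell_count >= 0),
            sum(cell_count) > 0)
  ok <- !is.na(yfp_mcherry)
  if (any(yfp_mcherry[ok] <= 0))
    stop("bin YFP/mCherry ratios must be positive")
  if (check_increasing && any(diff(yfp_mcherry[ok]) <= 0))
    stop("bin YFP/mCherry ratios must be strictly increasing in bin order")
  out <- data.frame(bin = seq_along(yfp_mcherry),
                    yfp_mcherry = yfp_mcherry,
                    cell_count = as.numeric(cell_count))
  class(out) <- c("bin_scheme", "data.frame")
  out
}

#' @rdname bin_scheme
#' @param bs A \code{bin_scheme}.
#' @param file Path.
#' @export
write_bin_scheme <- function(bs, file) {
  utils::write.table(as.data.frame(bs), file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' @rdname bin_scheme
#' @export
read_bin_scheme <- function(file) {
  df <- utils::read.table(file, header = TRUE, sep = "\t")
  bin_scheme(df$yfp_mcherry, df$cell_count, check_increasing = FALSE)
}
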