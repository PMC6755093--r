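# IUPAC nucleotide codes -> concrete base sets
IUPAC_BASES <- c(
  A = "A", C = "C", G = "G", T = "T",
  M = "AC", R = "AG", W = "AT", S = "CG", Y = "CT", K = "GT",
  V = "ACG", H = "ACT", D = "AGT", B = "CGT", N = "ACGT"
)

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Expand a degenerate (IUPAC) codon pattern into concrete codons
#'
#' A degenerate codon is a 3-letter IUPAC string such as \code{"MRN"}
#' (M = A/C, R = A/G, N = any base). Expansion is the Cartesian product of
#' the per-position base sets, returned sorted so that downstream joins and
#' library enumerations are deterministic.
#'
#' @param pattern A single 3-character IUPAC nucleotide string.
#' @return Character vector of distinct concrete codons, lexicographically
#'   sorted. \code{"MRN"} expands to 16 codons; a fully concrete pattern
#'   expands to itself.
#' @examples
#' expand_degenerate("MRN")
#' expand_degenerate("VRT")
#' @export
expand_degenerate <- function(pattern) {
  stopifnot(is.character(pattern), length(pattern) == 1L, !is.na(pattern))
  pattern <- toupper(pattern)
  if (nchar(pattern) != 3L)
    stop("degenerate codon pattern must have exactly 3 characters, got '",
         pattern, "'")
  chars <- strsplit(pattern, "", fixed = TRUE)[[1L]]
  bad <- setdiff(chars, names(IUPAC_BASES))
  if (length(bad))
    stop("invalid IUPAC code '", bad[[1L]], "' in pattern '", pattern, "'")
  sets <- lapply(chars, function(ch) strsplit(IUPAC_BASES[[ch]], "")[[1L]])
  n1 <- length(sets[[1L]]); n2 <- length(sets[[2L]]); n3 <- length(sets[[3L]])
  codons <- paste0(
    rep(sets[[1L]], each = n2 * n3),
    rep(rep(sets[[2L]], each = n3), times = n1),
    rep(sets[[3L]], times = n1 * n2)
  )
  sort(codons)
}

#' Specify a degenerate uORF variant library
#'
#' A design fixes a short uORF reading frame of 7 codons: a 6-nt prefix
#' holding the start codon (\code{ATGAAC} for functional AUG starts,
#' \code{AGGAAC} for the start-codon-dead AGG control), three variable
#' degenerate codons, and the fixed \code{TTTTAG} suffix whose TAG
#' terminates the uORF. Every full variant sequence is 21 nt.
#'
#' @param variable Character vector of 3 IUPAC codon patterns for the
#'   variable positions (uORF codons 3-5), e.g. \code{c("MRN","MRN","MRN")}.
#' @param starts Which start-codon versions to generate: any subset of
#'   \code{c("AUG","AGG")}.
#' @return An object of class \code{uorf_design}.
#' @examples
#' uorf_design()                                 # the 4,096-variant MRN design
#' uorf_design(c("SKR", "SSR", "VRT"))           # the dicodon follow-up design
#' @export
uorf_design <- function(variable = c("MRN", "MRN", "MRN"),
                        starts = c("AUG", "AGG")) {
  stopifnot(is.character(variable), length(variable) == 3L)
  variable <- toupper(variable)
  lapply(variable, expand_degenerate)  # validates patterns
  starts <- toupper(starts)
  if (!length(starts) || !all(starts %in% c("AUG", "AGG")))
    stop("starts must be a non-empty subset of c('AUG', 'AGG')")
  starts <- intersect(c("AUG", "AGG"), starts)  # canonical order: AUG first
  structure(
    list(variable = variable, starts = starts,
         prefix_aug = "ATGAAC", prefix_agg = "AGGAAC", suffix = "TTTTAG"),
    class = "uorf_design"
  )
}

#' @export
print.uorf_design <- function(x, ...) {
  sizes <- vapply(x$variable, function(p)
    length(setdiff(expand_degenerate(p), STOP_CODONS)), integer(1))
  cat("uORF library design:",
      paste0(x$prefix_aug, "-", paste(x$variable, collapse = "-"), "-", x$suffix),
      "\n  starts:", paste(x$starts, collapse = ", "),
      "\n  variants per start:", prod(sizes), "\n")
  invisible(x)
}

translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[codon]
  unname(aa)
}

#' Translate a uORF variant into its encoded peptide
#'
#' AUG-start variants encode a 6-residue peptide: Met-Asn from the fixed
#' prefix, the three variable residues, and Phe from the fixed suffix (the
#' terminal TAG is the stop). AGG variants carry no functional start codon
#' and are returned as \code{NA} (untranslated).
#'
#' @param codons Character vector of 3 concrete codons, or a 3-column
#'   character matrix (one variant per row).
#' @param start \code{"AUG"} or \code{"AGG"}.
#' @return Peptide string(s); \code{NA_character_} for AGG variants.
#' @examples
#' translate_uorf(c("CGA", "CGA", "CGA"))   # "MNRRRF"
#' @export
translate_uorf <- function(codons, start = "AUG") {
  if (is.matrix(codons)) {
    stopifnot(ncol(codons) == 3L)
  } else {
    stopifnot(length(codons) == 3L)
    codons <- matrix(codons, nrow = 1L)
  }
  start <- toupper(start)
  stopifnot(start %in% c("AUG", "AGG"))
  if (start == "AGG") return(rep(NA_character_, nrow(codons)))
  aa <- apply(codons, 2L, translate_codon)
  aa <- matrix(aa, ncol = 3L)
  paste0("MN", aa[, 1L], aa[, 2L], aa[, 3L], "F")
}

#' Enumerate all variants of a library design
#'
#' Expands the three degenerate positions and forms the Cartesian product,
#' one row per (start kind, codon triple). Variable codons that are stop
#' codons are excluded by default, since the uORF reading frame is defined
#' by the fixed terminal TAG. Rows are ordered lexicographically by
#' (start kind with AUG first, codon1, codon2, codon3), so enumeration order
#' is stable across runs and designs.
#'
#' @param design A \code{\link{uorf_design}}.
#' @param drop_stops Exclude stop codons from the variable positions
#'   (default \code{TRUE}).
#' @return A \code{data.frame} of class \code{uorf_library} with columns
#'   \code{variant_id}, \code{start}, \code{codon1..3}, \code{sequence}
#'   (the 21-nt variant region) and \code{peptide} (NA for AGG variants).
#' @examples
#' lib <- enumerate_library(uorf_design(starts = "AUG"))
#' nrow(lib)  # 4096
#' @export
enumerate_library <- function(design, drop_stops = TRUE) {
  stopifnot(inherits(design, "uorf_design"))
  sets <- lapply(design$variable, expand_degenerate)
  if (drop_stops)
    sets <- lapply(sets, function(s) setdiff(s, STOP_CODONS))
  if (any(lengths(sets) == 0L))
    stop("a variable position expands exclusively to stop codons")
  # expand.grid varies its first factor fastest; feeding codon3 first yields
  # lexicographic order in (codon1, codon2, codon3) since each set is sorted
  grid <- expand.grid(codon3 = sets[[3L]], codon2 = sets[[2L]],
                      codon1 = sets[[1L]], stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  pep <- translate_uorf(cbind(grid$codon1, grid$codon2, grid$codon3), "AUG")
  out <- do.call(rbind, lapply(design$starts, function(st) {
    prefix <- if (st == "AUG") design$prefix_aug else design$prefix_agg
    data.frame(
      variant_id = paste(st, grid$codon1, grid$codon2, grid$codon3, sep = "_"),
      start = st,
      codon1 = grid$codon1, codon2 = grid$codon2, codon3 = grid$codon3,
      sequence = paste0(prefix, grid$codon1, grid$codon2, grid$codon3,
                        design$suffix),
      peptide = if (st == "AUG") pep else NA_character_,
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  class(out) <- c("uorf_library", "data.frame")
  out
}

triple_key <- function(x) paste(x$codon1, x$codon2, x$codon3, sep = "_")

#' Variants of one design not producible by another
#'
#' Returns the variants of \code{design_b} whose codon triple cannot be
#' generated by \code{design_a}. This is how a follow-up library (e.g. the
#' SKR-SSR-VRT dicodon library) contributes coding variants additional to
#' an earlier design (e.g. MRN x 3): 384 enumerated triples minus the 16
#' shared with MRN leaves 368.
#'
#' @param design_b,design_a \code{\link{uorf_design}} objects sharing
#'   prefix/suffix template.
#' @return \code{uorf_library} rows of \code{design_b} (its configured
#'   starts) whose triples are absent from \code{design_a}.
#' @export
additional_variants <- function(design_b, design_a) {
  stopifnot(inherits(design_b, "uorf_design"), inherits(design_a, "uorf_design"))
  if (!identical(design_b$suffix, design_a$suffix) ||
      !identical(design_b$prefix_aug, design_a$prefix_aug) ||
      !identical(design_b$prefix_agg, design_a$prefix_agg))
    stop("designs use incompatible prefix/suffix templates")
  lib_b <- enumerate_library(design_b)
  lib_a <- enumerate_library(uorf_design(design_a$variable, starts = "AUG"))
  keep <- !(triple_key(lib_b) %in% triple_key(lib_a))
  out <- lib_b[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("uorf_library", "data.frame")
  out
}

#' Write a variant library to FASTA (and optionally a TSV manifest)
#'
#' One record per variant; the header is the variant id, which encodes the
#' start kind and codon triple (e.g. \code{AUG_CGA_CGA_CGA}). A constant
#' flanking context (e.g. the reporter amplicon around the 21-nt variant
#' region) may be added on either side.
#'
#' @param library A \code{uorf_library}.
#' @param file Output FASTA path.
#' @param flank5,flank3 Constant flanking sequence added 5' / 3' of the
#'   21-nt variant region (default none).
#' @param manifest Optional path for a TSV manifest
#'   (variant_id, sequence, peptide).
#' @return Invisibly, the written sequences as a named character vector.
#' @export
write_library_fasta <- function(library, file, flank5 = "", flank3 = "",
                                manifest = NULL) {
  stopifnot(inherits(library, "uorf_library") || is.data.frame(library))
  seqs <- paste0(flank5, library$sequence, flank3)
  dna <- Biostrings::DNAStringSet(seqs)
  names(dna) <- library$variant_id
  Biostrings::writeXStringSet(dna, filepath = file)
  if (!is.null(manifest)) {
    utils::write.table(
      data.frame(variant_id = library$variant_id, sequence = seqs,
                 peptide = library$peptide, stringsAsFactors = FALSE),
      file = manifest, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(stats::setNames(seqs, library$variant_id))
}
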