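# Paired-end merging and perfect-match counting.
#
# The amplicon is fixed-length and the counting contract keeps only reads
# that match a designed reference perfectly within anchored flanks, so a
# deterministic overlap merger plus exact string matching replaces a
# general-purpose aligner.

qual_ints <- function(q) utf8ToInt(q) - 33L

merge_one <- function(f, rc, fq, rqr, min_overlap, max_mismatch) {
  af <- strsplit(f, "", fixed = TRUE)[[1L]]
  ar <- strsplit(rc, "", fixed = TRUE)[[1L]]
  lf <- length(af); lr <- length(ar)
  best_o <- NA_integer_; best_mm <- NA_integer_; best_matches <- -1L
  o_max <- min(lf, lr)
  if (o_max < min_overlap)
    return(list(merged = FALSE, sequence = NA_character_,
                overlap_len = NA_integer_, mismatches = NA_integer_))
  for (o in seq.int(o_max, min_overlap)) {
    if (o <= best_matches) break  # shorter overlaps cannot beat the best
    mm <- sum(af[(lf - o + 1L):lf] != ar[seq_len(o)])
    if (mm <= max_mismatch) {
      matches <- o - mm
      if (matches > best_matches) {
        best_matches <- matches; best_o <- o; best_mm <- mm
      }
    }
  }
  if (is.na(best_o))
    return(list(merged = FALSE, sequence = NA_character_,
                overlap_len = NA_integer_, mismatches = NA_integer_))
  o <- best_o
  cons <- c(af, if (o < lr) ar[(o + 1L):lr])
  if (best_mm > 0L && !is.null(fq) && !is.null(rqr)) {
    # at disagreements take the higher-quality base; ties go to the forward read
    qf <- qual_ints(fq); qr <- qual_ints(rqr)
    ov <- seq_len(o)
    dis <- ov[af[(lf - o + ov)] != ar[ov]]
    for (p in dis) {
      if (qr[p] > qf[lf - o + p]) cons[lf - o + p] <- ar[p]
    }
  }
  list(merged = TRUE, sequence = paste(cons, collapse = ""),
       overlap_len = o, mismatches = best_mm)
}

#' Merge paired-end reads by overlap consensus
#'
#' The reverse read is reverse-complemented, the overlap length maximizing
#' the number of matching bases (with at most \code{max_mismatch}
#' mismatches and at least \code{min_overlap} overlap) is chosen, and the
#' consensus takes the higher-quality base at disagreements with ties broken
#' toward the forward read. Pairs with no acceptable overlap are reported
#' unmerged, never dropped silently.
#'
#' @param fwd,rev Character vectors of read sequences (reverse reads in
#'   sequencer orientation).
#' @param fwd_qual,rev_qual Optional Phred+33 quality strings.
#' @param min_overlap Minimum acceptable overlap (default 10).
#' @param max_mismatch Maximum mismatches tolerated in the overlap
#'   (default 2).
#' @return data.frame with columns \code{merged}, \code{sequence},
#'   \code{overlap_len}, \code{mismatches}.
#' @export
merge_pairs <- function(fwd, rev, fwd_qual = NULL, rev_qual = NULL,
                        min_overlap = 10L, max_mismatch = 2L) {
  stopifnot(length(fwd) == length(rev))
  if (!length(fwd))
    return(data.frame(merged = logical(), sequence = character(),
                      overlap_len = integer(), mismatches = integer()))
  has_q <- !is.null(fwd_qual) && !is.null(rev_qual)
  key <- if (has_q) paste(fwd, rev, fwd_qual, rev_qual, sep = "\r") else
    paste(fwd, rev, sep = "\r")
  first <- !duplicated(key)
  map <- match(key, key[first])
  fu <- fwd[first]; ru <- rev[first]
  rc <- revcomp(ru)
  # reverse the quality string so it lines up with the reverse-complement
  rqr <- if (has_q) vapply(rev_qual[first], function(q)
    intToUtf8(rev(utf8ToInt(q))), "", USE.NAMES = FALSE) else NULL
  fq <- if (has_q) fwd_qual[first] else NULL
  res <- lapply(seq_along(fu), function(i)
    merge_one(fu[i], rc[i], if (has_q) fq[i] else NULL,
              if (has_q) rqr[i] else NULL, min_overlap, max_mismatch))
  out <- data.frame(
    merged = vapply(res, `[[`, logical(1), "merged"),
    sequence = vapply(res, `[[`, character(1), "sequence"),
    overlap_len = vapply(res, `[[`, integer(1), "overlap_len"),
    mismatches = vapply(res, `[[`, integer(1), "mismatches"),
    stringsAsFactors = FALSE
  )
  out[map, , drop = FALSE]
}

# Match merged reads to library variants by exact anchored lookup.
# Returns integer variant indices (NA = no perfect match).
match_variants <- function(seqs, library, flank5, flank3) {
  la <- left_anchor(flank5)
  ra <- right_anchor(flank3)
  A <- ANCHOR_LEN
  lookup <- seq_len(nrow(library))
  names(lookup) <- library$sequence
  if (anyDuplicated(library$sequence))
    stop("library reference sequences are not unique within the anchored region")

  match_oriented <- function(s) {
    p <- regexpr(la, s, fixed = TRUE)[[1L]]
    if (p < 0L) return(NA_integer_)
    start <- p + A
    region <- substr(s, start, start + 20L)
    if (nchar(region) < 21L) return(NA_integer_)
    if (substr(s, start + 21L, start + 20L + A) != ra) return(NA_integer_)
    v <- lookup[region]
    if (is.na(v)) NA_integer_ else unname(v)
  }

  vapply(seqs, function(s) {
    v <- match_oriented(s)
    if (is.na(v)) v <- match_oriented(revcomp(s))
    v
  }, integer(1), USE.NAMES = FALSE)
}

#' Count perfect matches of merged reads against a variant library
#'
#' A read increments exactly one variant if and only if the 21-nt region
#' located by exact flank anchors equals that variant's reference sequence
#' (start codon included, so AUG and AGG versions are distinguished). Both
#' orientations of each merged read are tried. Reads failing the anchors or
#' carrying any mismatch in the anchored region are discarded and tallied.
#'
#' @param merged_by_sample Named list of character vectors of merged read
#'   sequences, one element per sample (bins, optionally \code{unsorted}
#'   and \code{rna}).
#' @param library The \code{uorf_library} of references.
#' @param flank5,flank3 The constant amplicon flanks.
#' @param unmerged Optional named integer vector of per-sample unmerged-pair
#'   tallies to carry into the discard table.
#' @return A \code{\link{count_set}}; bin columns are the samples named
#'   \code{bin_*}, with \code{unsorted} and \code{rna} mapped to their slots.
#' @export
count_perfect_matches <- function(merged_by_sample, library,
                                  flank5 = uorf_flank5(),
                                  flank3 = uorf_flank3(),
                                  unmerged = NULL) {
  stopifnot(is.list(merged_by_sample), !is.null(names(merged_by_sample)))
  nv <- nrow(library)
  samples <- names(merged_by_sample)
  counts <- matrix(0L, nv, length(samples),
                   dimnames = list(library$variant_id, samples))
  unmatched <- setNames(integer(length(samples)), samples)
  for (s in samples) {
    reads <- merged_by_sample[[s]]
    if (!length(reads)) next
    tab <- table(reads)
    uniq <- names(tab)
    vi <- match_variants(uniq, library, flank5, flank3)
    ok <- !is.na(vi)
    if (any(ok)) {
      agg <- tapply(as.integer(tab)[ok], vi[ok], sum)
      counts[as.integer(names(agg)), s] <- as.integer(agg)
    }
    unmatched[s] <- sum(as.integer(tab)[!ok])
  }
  disc <- data.frame(
    sample = samples,
    unmerged = if (is.null(unmerged)) 0L else as.integer(unmerged[samples]),
    unmatched = as.integer(unmatched),
    stringsAsFactors = FALSE
  )
  bin_cols <- grep("^bin_", samples, value = TRUE)
  count_set(counts[, bin_cols, drop = FALSE],
            dna_unsorted = if ("unsorted" %in% samples)
              counts[, "unsorted"] else NULL,
            rna = if ("rna" %in% samples) counts[, "rna"] else NULL,
            discarded = disc)
}

read_fastq_chr <- function(file) {
  x <- Biostrings::readDNAStringSet(file, format = "fastq",
                                    with.qualities = TRUE)
  list(seq = as.character(x),
       qual = as.character(S4Vectors::mcols(x)$qualities))
}

#' Process a directory of paired FASTQ files into a count set
#'
#' Reads \code{<sample>_R1.fastq[.gz]} / \code{<sample>_R2.fastq[.gz]} file
#' pairs (samples \code{bin_1..bin_n} plus optional \code{unsorted} and
#' \code{rna}), merges each pair by overlap consensus and counts perfect
#' matches against the library.
#'
#' @param dir Directory containing the FASTQ files.
#' @param library The \code{uorf_library}.
#' @param n_bins Number of bin samples expected.
#' @param flank5,flank3 Constant amplicon flanks.
#' @param min_overlap,max_mismatch Merger settings (see
#'   \code{\link{merge_pairs}}).
#' @return A \code{\link{count_set}} with discard tallies.
#' @export
process_fastq_dir <- function(dir, library, n_bins = 8L,
                              flank5 = uorf_flank5(), flank3 = uorf_flank3(),
                              min_overlap = 10L, max_mismatch = 2L) {
  samples <- c(paste0("bin_", seq_len(n_bins)), "unsorted", "rna")
  merged <- list()
  unmerged <- integer()
  for (s in samples) {
    f1 <- Sys.glob(file.path(dir, paste0(s, "_R1.fastq*")))
    f2 <- Sys.glob(file.path(dir, paste0(s, "_R2.fastq*")))
    if (!length(f1) || !length(f2)) {
      if (startsWith(s, "bin_"))
        stop("missing FASTQ pair for sample '", s, "' in ", dir)
      next
    }
    r1 <- read_fastq_chr(f1[[1L]])
    r2 <- read_fastq_chr(f2[[1L]])
    m <- merge_pairs(r1$seq, r2$seq, r1$qual, r2$qual,
                     min_overlap = min_overlap, max_mismatch = max_mismatch)
    merged[[s]] <- m$sequence[m$merged]
    unmerged[s] <- sum(!m$merged)
  }
  count_perfect_matches(merged, library, flank5 = flank5, flank3 = flank3,
                        unmerged = unmerged)
}
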