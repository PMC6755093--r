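# Fixed amplicon context around the 21-nt variant region.
#
# Real sort-seq amplicons carry the transcript-leader context of the host
# gene between the sequencing primers. The constants below are synthetic
# stand-in flanks of comparable length (amplicon = 86 + 21 + 93 = 200 nt so
# that 2 x 150 nt reads merge with a 100-nt overlap); the 5' flank ends in
# the weak-Kozak hexamer TTGTGC seen upstream of natural enhancer uORFs.
# Analyses only ever use the flanks as exact-match anchors, so any fixed
# context with unique anchor sequences behaves identically.

#' Default synthetic 5' flank of the variant region
#' @return A fixed 86-nt sequence.
#' @export
uorf_flank5 <- function() {
  paste0("AAACAAACACACATATTACCCCGGG",
         "ACTTCTAGCATCAGAGTGGTTCAGTAACCAGTCGAATTGACCAACTCGAA",
         "ATCACTTGTGC")
}

#' Default synthetic 3' flank of the variant region
#' @return A fixed 93-nt sequence.
#' @export
uorf_flank3 <- function() {
  paste0("ATTCGAAGGTCTGAATCCTTGAAGACTGTCAACGGTATCCAGTTGATCC",
         "AAGGTCGTGAATTCAAGACCAGTTCTTGAACGGTAAAGATCGAG")
}

# exact-match anchors bracketing the 21-nt variant region
ANCHOR_LEN <- 12L

left_anchor <- function(flank5) {
  n <- nchar(flank5)
  stopifnot(n >= ANCHOR_LEN)
  substr(flank5, n - ANCHOR_LEN + 1L, n)
}

right_anchor <- function(flank3) {
  stopifnot(nchar(flank3) >= ANCHOR_LEN)
  substr(flank3, 1L, ANCHOR_LEN)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
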