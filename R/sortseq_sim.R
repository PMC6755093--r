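#' Parameters of a simulated sort-seq experiment
#'
#' Defaults mirror the scale of a typical yeast reporter sort: 8 fluorescence
#' bins, 100,000 cells deposited per bin (800,000 sorted cells total), a
#' within-variant cell-to-cell noise of 0.25 on the log2 YFP/mCherry ratio
#' (multiplicative reporter noise), and sequencing depths of 250,000 plasmid
#' DNA reads per bin plus 2 million reads each for the unsorted plasmid pool
#' and the pre-sort RNA sample.
#'
#' @param n_bins Number of sort bins (>= 2).
#' @param n_cells Total sorted cells.
#' @param cell_noise_sd Standard deviation of the log2 fluorescence ratio
#'   among cells carrying the same variant.
#' @param depth_dna_per_bin Plasmid DNA-seq reads per bin.
#' @param depth_rna RNA-seq reads from the unsorted culture.
#' @param depth_dna_unsorted Plasmid DNA-seq reads from the unsorted culture.
#' @param plasmid_abundance_dispersion SD of the log-normal plasmid
#'   representation spread across variants (0 = perfectly even library). The
#'   default 0.3 reflects the colony bottleneck of cloned libraries: pooling
#'   on the order of ten colonies per variant gives a relative abundance
#'   spread near 1/sqrt(10).
#' @param seed Integer seed used by \code{\link{simulate_sortseq}}.
#' @return A list of class \code{sim_params}.
#' @export
sim_params <- function(n_bins = 8L,
                       n_cells = 800000L,
                       cell_noise_sd = 0.25,
                       depth_dna_per_bin = 250000L,
                       depth_rna = 2000000L,
                       depth_dna_unsorted = 2000000L,
                       plasmid_abundance_dispersion = 0.3,
                       seed = 1L) {
  stopifnot(n_bins >= 2L, n_cells >= n_bins, cell_noise_sd >= 0,
            depth_dna_per_bin >= 0, depth_rna >= 0, depth_dna_unsorted >= 0,
            plasmid_abundance_dispersion >= 0)
  structure(list(n_bins = as.integer(n_bins), n_cells = as.integer(n_cells),
                 cell_noise_sd = cell_noise_sd,
                 depth_dna_per_bin = as.integer(depth_dna_per_bin),
                 depth_rna = as.integer(depth_rna),
                 depth_dna_unsorted = as.integer(depth_dna_unsorted),
                 plasmid_abundance_dispersion = plasmid_abundance_dispersion,
                 seed = as.integer(seed)),
            class = "sim_params")
}

#' Generative model of codon and dicodon effects
#'
#' Planted truth for the simulator. A variant's true protein-level effect
#' (log2 fold change of reporter output caused by translating the uORF,
#' i.e. AUG vs AGG) is the sum of an intercept, codon-at-position
#' coefficients, ordered-dicodon coefficients and a Normal residual. The
#' true RNA-level effect is an intercept plus per-codon presence terms.
#'
#' Coefficient names use \code{"CGA:1"} for codon CGA at variable position 1,
#' and \code{"CGA>CGG:1"} for the ordered pair CGA-then-CGG at position pair
#' 1 (variable codons 1-2); position pair 2 is variable codons 2-3.
#'
#' @param codon_position Named numeric vector of codon-at-position
#'   coefficients (log2 units).
#' @param dicodon Named numeric vector of ordered dicodon coefficients.
#' @param intercept Baseline log2 effect of translating the uORF.
#' @param residual_sd SD of the variant-specific Normal residual.
#' @param rna_codon Named numeric vector: per-codon any-position presence
#'   effect on the RNA log2 fold change.
#' @param rna_intercept Baseline RNA log2 fold change of AUG variants.
#' @return A list of class \code{effect_generator}.
#' @export
effect_generator <- function(codon_position = numeric(),
                             dicodon = numeric(),
                             intercept = 0,
                             residual_sd = 0,
                             rna_codon = numeric(),
                             rna_intercept = 0) {
  stopifnot(residual_sd >= 0)
  structure(list(codon_position = codon_position, dicodon = dicodon,
                 intercept = intercept, residual_sd = residual_sd,
                 rna_codon = rna_codon, rna_intercept = rna_intercept),
            class = "effect_generator")
}

#' Default planted effects emulating a yeast uORF codon-variant assay
#'
#' The defaults reproduce the qualitative structure reported for natural
#' uORF variant screens: most variants are mild enhancers (positive
#' intercept), the rare arginine codon CGA is strongly repressive with the
#' largest effect at the first variable position, a handful of A/T-rich and
#' arginine codons are mildly repressive, common glutamine/histidine codons
#' mildly enhancing, known inhibitory dicodons act in forward order only,
#' CGA-containing variants lose ~10\% of their mRNA, and AUG variants carry
#' a small global RNA decrease. The coefficient scale is anchored so true
#' protein effects span roughly 2-fold repression to 2-fold enhancement,
#' the dynamic range such assays report.
#'
#' @return An \code{\link{effect_generator}}.
#' @export
default_effect_generator <- function() {
  effect_generator(
    codon_position = c(
      "CGA:1" = -0.50, "CGA:2" = -0.35, "CGA:3" = -0.25,
      "CGT:1" = -0.20, "CGT:2" = -0.12, "CGT:3" = -0.10,
      "AGA:1" = -0.15, "AGA:2" = -0.10, "AGA:3" = -0.08,
      "AAA:1" = -0.12, "AAA:2" = -0.08,
      "AAT:1" = -0.12, "AAT:2" = -0.08,
      "AGT:1" = -0.10,
      "CAA:1" =  0.12, "CAG:1" =  0.12, "CAT:1" = 0.08, "CAC:2" = 0.08
    ),
    dicodon = c(
      "CGA>CGA:1" = -0.25, "CGA>CGG:1" = -0.25, "AGG>CGG:1" = -0.20,
      "CGA>CGA:2" = -0.15
    ),
    intercept = 0.3,
    residual_sd = 0.15,
    rna_codon = c(CGA = -0.16),
    rna_intercept = -0.07
  )
}

parse_cp_names <- function(nm) {
  # "CGA:1" -> codon, position
  parts <- strsplit(nm, ":", fixed = TRUE)
  data.frame(codon = vapply(parts, `[`, "", 1L),
             pos = as.integer(vapply(parts, `[`, "", 2L)),
             stringsAsFactors = FALSE)
}

parse_dc_names <- function(nm) {
  # "CGA>CGG:1" -> first codon, second codon, position pair
  parts <- strsplit(nm, "[>:]")
  data.frame(first = vapply(parts, `[`, "", 1L),
             second = vapply(parts, `[`, "", 2L),
             pos = as.integer(vapply(parts, `[`, "", 3L)),
             stringsAsFactors = FALSE)
}

#' Plant ground-truth effects and plasmid abundances for a library
#'
#' For each AUG variant, the true protein-level log2 effect is the generator
#' sum; the paired AGG control has effect 0 by construction (no uORF is
#' translated). Plasmid abundance weights are log-normal across all
#' constructs and sum to 1. Coefficients naming codons absent from the
#' library are ignored with a warning.
#'
#' @param library A \code{uorf_library} (must contain AUG variants; AGG rows
#'   are the paired controls).
#' @param gen An \code{\link{effect_generator}}.
#' @param abundance_dispersion SD of the log-normal plasmid representation.
#' @param base_ratio Median YFP/mCherry ratio of the AGG reference
#'   constructs.
#' @param base_ratio_sd SD (log2) of the per-triple baseline expression
#'   spread. Constructs differ in baseline output even without uORF
#'   translation (the transcript still carries the codon changes), so each
#'   codon triple draws one baseline shared by its AUG and AGG partners;
#'   sharing makes the baseline cancel exactly in the paired contrast.
#' @param seed Optional integer seed (residuals, baselines and abundances).
#' @return A \code{data.frame} of class \code{uorf_truth}: one row per
#'   library variant with \code{true_protein_log2fc}, \code{true_rna_log2fc},
#'   \code{true_base_ratio} and \code{abundance}.
#' @export
generate_truth <- function(library, gen = default_effect_generator(),
                           abundance_dispersion = 0.3, base_ratio = 1,
                           base_ratio_sd = 0.15, seed = NULL) {
  stopifnot(is.data.frame(library), nrow(library) > 0)
  if (!is.null(seed)) set.seed(seed)
  lib_codons <- unique(c(library$codon1, library$codon2, library$codon3))

  cp <- if (length(gen$codon_position))
    parse_cp_names(names(gen$codon_position)) else NULL
  dc <- if (length(gen$dicodon)) parse_dc_names(names(gen$dicodon)) else NULL
  referenced <- c(cp$codon, dc$first, dc$second, names(gen$rna_codon))
  missing <- setdiff(unique(referenced), lib_codons)
  if (length(missing))
    warning("ignoring coefficients for codon(s) absent from the library: ",
            paste(sort(missing), collapse = ", "))

  eff <- rep(gen$intercept, nrow(library))
  for (k in seq_len(NROW(cp))) {
    if (cp$codon[k] %in% missing) next
    col <- library[[paste0("codon", cp$pos[k])]]
    eff <- eff + gen$codon_position[k] * (col == cp$codon[k])
  }
  for (k in seq_len(NROW(dc))) {
    if (dc$first[k] %in% missing || dc$second[k] %in% missing) next
    a <- library[[paste0("codon", dc$pos[k])]]
    b <- library[[paste0("codon", dc$pos[k] + 1L)]]
    eff <- eff + gen$dicodon[k] * (a == dc$first[k] & b == dc$second[k])
  }
  if (gen$residual_sd > 0) {
    # the residual is a property of the coding variant, shared by nothing:
    # draw one residual per AUG triple
    aug <- library$start == "AUG"
    res <- rnorm(sum(aug), 0, gen$residual_sd)
    eff[aug] <- eff[aug] + res
  }

  rna <- rep(gen$rna_intercept, nrow(library))
  for (cod in setdiff(names(gen$rna_codon), missing)) {
    present <- library$codon1 == cod | library$codon2 == cod |
      library$codon3 == cod
    rna <- rna + gen$rna_codon[[cod]] * present
  }

  agg <- library$start == "AGG"
  eff[agg] <- 0
  rna[agg] <- 0

  triple <- paste(library$codon1, library$codon2, library$codon3, sep = "_")
  uniq <- unique(triple)
  base_log2 <- if (base_ratio_sd > 0)
    rnorm(length(uniq), 0, base_ratio_sd) else numeric(length(uniq))
  base <- base_ratio * 2^base_log2[match(triple, uniq)]

  w <- if (abundance_dispersion > 0)
    exp(rnorm(nrow(library), 0, abundance_dispersion)) else
      rep(1, nrow(library))
  w <- w / sum(w)

  out <- data.frame(
    variant_id = library$variant_id, start = library$start,
    codon1 = library$codon1, codon2 = library$codon2, codon3 = library$codon3,
    true_base_ratio = base,
    true_protein_log2fc = eff,
    true_rna_log2fc = rna,
    abundance = w,
    stringsAsFactors = FALSE
  )
  class(out) <- c("uorf_truth", "data.frame")
  out
}

#' Simulate single cells and FACS sorting into fluorescence bins
#'
#' Each cell draws a variant proportionally to plasmid abundance and a log2
#' YFP/mCherry ratio Normal(true mean, \code{cell_noise_sd}). Cells are
#' gated into \code{n_bins} equal-count bins by rank on the ratio; gate
#' boundaries never split cells with identical fluorescence (the boundary
#' moves to the nearest value change). Each bin's calibration value is the
#' mean linear YFP/mCherry ratio of its cells, standing in for a post-sort
#' plate-reader measurement. If all cells share one fluorescence value,
#' equal-count gating is impossible: all cells are placed in bin 1 with a
#' warning (the documented degenerate fallback).
#'
#' @param truth A \code{uorf_truth} table.
#' @param params A \code{\link{sim_params}}.
#' @param seed Optional integer seed.
#' @return A list with \code{bin_scheme} (data.frame: bin, yfp_mcherry,
#'   cell_count) and \code{occupancy} (integer matrix variant x bin of cell
#'   counts, rownames = variant ids).
#' @export
simulate_cells_and_sort <- function(truth, params, seed = NULL) {
  stopifnot(inherits(truth, "uorf_truth"), inherits(params, "sim_params"))
  if (!is.null(seed)) set.seed(seed)
  nv <- nrow(truth)
  n_cells <- params$n_cells
  n_bins <- params$n_bins

  idx <- sample.int(nv, n_cells, replace = TRUE, prob = truth$abundance)
  mu <- log2(truth$true_base_ratio) + truth$true_protein_log2fc
  lr <- mu[idx]
  if (params$cell_noise_sd > 0)
    lr <- lr + rnorm(n_cells, 0, params$cell_noise_sd)

  o <- order(lr)
  sorted <- lr[o]
  # candidate gate positions: between consecutive distinct values
  change <- which(diff(sorted) > 0)
  bin_sorted <- integer(n_cells)
  if (!length(change)) {
    if (n_bins > 1L)
      warning("all cells share one fluorescence value; ",
              "equal-count gating impossible, all cells placed in bin 1")
    bin_sorted[] <- 1L
  } else {
    targets <- round(seq_len(n_bins - 1L) * n_cells / n_bins)
    bnd <- vapply(targets, function(t) change[which.min(abs(change - t))], 0L)
    sizes <- diff(c(0L, bnd, n_cells))  # duplicated boundaries -> empty bins
    sizes[sizes < 0L] <- 0L
    bin_sorted <- rep(seq_len(n_bins), sizes)[seq_len(n_cells)]
  }
  bins <- integer(n_cells)
  bins[o] <- bin_sorted

  ratio <- 2^lr
  cell_count <- tabulate(bins, nbins = n_bins)
  y <- vapply(seq_len(n_bins), function(i)
    if (cell_count[i] > 0) mean(ratio[bins == i]) else NA_real_, numeric(1))

  occupancy <- matrix(
    tabulate(idx + (bins - 1L) * nv, nbins = nv * n_bins),
    nrow = nv, ncol = n_bins,
    dimnames = list(truth$variant_id, paste0("bin_", seq_len(n_bins))))

  list(
    bin_scheme = bin_scheme(yfp_mcherry = y, cell_count = cell_count,
                            check_increasing = FALSE),
    occupancy = occupancy
  )
}

#' Sample sequencing reads from bin occupancies and plasmid abundances
#'
#' Per-bin plasmid DNA counts are multinomial over each bin's cell
#' occupancy; unsorted DNA counts are multinomial over plasmid abundances;
#' RNA counts are multinomial over abundance x 2^(true RNA log2 fold change)
#' (RNA is extracted before sorting, so sorting never enters).
#'
#' @param occupancy Integer matrix variant x bin (cells per bin).
#' @param truth The \code{uorf_truth} table.
#' @param params A \code{\link{sim_params}}.
#' @param seed Optional integer seed.
#' @return A \code{\link{count_set}}.
#' @export
sample_reads <- function(occupancy, truth, params, seed = NULL) {
  stopifnot(is.matrix(occupancy), inherits(params, "sim_params"))
  if (!is.null(seed)) set.seed(seed)
  nv <- nrow(occupancy)
  n_bins <- ncol(occupancy)
  counts <- matrix(0L, nv, n_bins, dimnames = dimnames(occupancy))
  for (i in seq_len(n_bins)) {
    tot <- sum(occupancy[, i])
    if (tot > 0 && params$depth_dna_per_bin > 0)
      counts[, i] <- as.integer(
        rmultinom(1L, params$depth_dna_per_bin, occupancy[, i]))
  }
  dna_unsorted <- if (params$depth_dna_unsorted > 0)
    as.integer(rmultinom(1L, params$depth_dna_unsorted, truth$abundance)) else
      integer(nv)
  rna_w <- truth$abundance * 2^truth$true_rna_log2fc
  rna <- if (params$depth_rna > 0)
    as.integer(rmultinom(1L, params$depth_rna, rna_w)) else integer(nv)
  count_set(counts,
            dna_unsorted = setNames(dna_unsorted, rownames(occupancy)),
            rna = setNames(rna, rownames(occupancy)))
}

#' Simulate a complete sort-seq experiment
#'
#' Seeds the generator once from \code{params$seed} and chains
#' \code{\link{generate_truth}}, \code{\link{simulate_cells_and_sort}} and
#' \code{\link{sample_reads}}. Identical parameters and seed give identical
#' output.
#'
#' @param library A \code{uorf_library}.
#' @param gen An \code{\link{effect_generator}}.
#' @param params A \code{\link{sim_params}}.
#' @return List with \code{truth}, \code{bin_scheme}, \code{occupancy} and
#'   \code{counts} (a \code{\link{count_set}}).
#' @export
simulate_sortseq <- function(library, gen = default_effect_generator(),
                             params = sim_params()) {
  set.seed(params$seed)
  truth <- generate_truth(library, gen,
                          abundance_dispersion =
                            params$plasmid_abundance_dispersion)
  sorted <- simulate_cells_and_sort(truth, params)
  cs <- sample_reads(sorted$occupancy, truth, params)
  list(truth = truth, bin_scheme = sorted$bin_scheme,
       occupancy = sorted$occupancy, counts = cs)
}

mutate_bases <- function(seqs, rate) {
  if (rate <= 0 || !length(seqs)) return(seqs)
  len <- nchar(seqs[1L])
  n_mut <- rbinom(length(seqs), len, rate)
  hit <- which(n_mut > 0L)
  bases <- c("A", "C", "G", "T")
  for (i in hit) {
    s <- strsplit(seqs[i], "", fixed = TRUE)[[1L]]
    pos <- sample.int(len, n_mut[i])
    for (p in pos) s[p] <- sample(setdiff(bases, s[p]), 1L)
    seqs[i] <- paste(s, collapse = "")
  }
  seqs
}

write_fastq_records <- function(file, ids, seqs, qual) {
  con <- if (grepl("\\.gz$", file)) gzfile(file, "w") else file(file, "w")
  on.exit(close(con))
  rec <- rbind(paste0("@", ids), seqs, "+", qual)
  writeLines(as.vector(rec), con)
}

#' Emit paired FASTQ files for a simulated count set
#'
#' For every counted read a forward/reverse pair is generated from the
#' variant's flanked amplicon (constant high base quality), with optional
#' uniform per-base substitution errors for negative tests. One R1/R2 pair
#' of files is written per bin plus pairs for the unsorted DNA and RNA
#' samples, named \code{bin_<i>_R1.fastq} etc.
#'
#' @param cs A \code{\link{count_set}}.
#' @param library The \code{uorf_library} the counts refer to.
#' @param dir Output directory (created if missing).
#' @param read_len Read length (default 150).
#' @param error_rate Per-base substitution probability (default 0).
#' @param flank5,flank3 Constant amplicon flanks.
#' @param gzip Write gzip-compressed files.
#' @param seed Optional integer seed (errors only).
#' @return Invisibly, a data.frame of written file pairs.
#' @export
emit_fastq <- function(cs, library, dir, read_len = 150L, error_rate = 0,
                       flank5 = uorf_flank5(), flank3 = uorf_flank3(),
                       gzip = FALSE, seed = NULL) {
  stopifnot(inherits(cs, "count_set"))
  if (!is.null(seed)) set.seed(seed)
  amplicon <- paste0(flank5, library$sequence, flank3)
  L <- nchar(amplicon[1L])
  if (read_len > L)
    stop("read_len exceeds amplicon length (", L, " nt)")
  if (2L * read_len - L < 10L)
    stop("read_len too short: merged pairs would overlap by < 10 nt and ",
         "could not cover the variant region")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ext <- if (gzip) ".fastq.gz" else ".fastq"

  fwd_all <- substr(amplicon, 1L, read_len)
  rev_all <- revcomp(substr(amplicon, L - read_len + 1L, L))
  qual <- strrep("I", read_len)

  stopifnot(identical(rownames(cs$counts), library$variant_id))
  samples <- c(setNames(lapply(seq_len(ncol(cs$counts)),
                               function(i) cs$counts[, i]),
                        colnames(cs$counts)),
               list(unsorted = cs$dna_unsorted, rna = cs$rna))
  files <- lapply(names(samples), function(tag) {
    n <- samples[[tag]]
    vi <- rep(seq_along(n), n)
    f1 <- file.path(dir, paste0(tag, "_R1", ext))
    f2 <- file.path(dir, paste0(tag, "_R2", ext))
    ids <- sprintf("%s_%07d", tag, seq_along(vi))
    r1 <- mutate_bases(fwd_all[vi], error_rate)
    r2 <- mutate_bases(rev_all[vi], error_rate)
    write_fastq_records(f1, ids, r1, rep(qual, length(vi)))
    write_fastq_records(f2, ids, r2, rep(qual, length(vi)))
    data.frame(sample = tag, r1 = f1, r2 = f2, reads = length(vi),
               stringsAsFactors = FALSE)
  })
  invisible(do.call(rbind, files))
}
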