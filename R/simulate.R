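# Synthetic DMS experiment: planted fitness effects, selection, and
# amplicon read simulation with known ground truth.

#' Plant per-variant true fitness effects
#'
#' Draws a ground-truth effect map on the same log scale as the estimated
#' mutational cost. Positions are first assigned a tolerance class
#' (tolerant / intermediate / critical) and variant effects are then drawn
#' from class-specific mixtures, so that critical positions carry many
#' strongly deleterious mutations, as observed in saturation scans of
#' essential-pathway proteins. Premature stops are uniformly deleterious
#' except within the last `stop_tail` positions, where truncation is
#' tolerated. Wild-type identity cells are exactly 0.
#'
#' @param library A `VariantLibrary`.
#' @param seed Integer seed.
#' @param p_class Probabilities of the tolerant / intermediate / critical
#'   position classes (default `c(0.6, 0.2, 0.2)`).
#' @param stop_effect Effect of premature stop codons (default -6).
#' @param stop_tail Number of C-terminal positions where stops are neutral
#'   (default 10).
#' @return A `TrueFitnessMap`: positions x 21 matrix of effects (class
#'   attribute `TrueFitnessMap`), with `wt_aa` attached.
#' @export
simulate_true_effects <- function(library, seed = 1L,
                                  p_class = c(0.6, 0.2, 0.2),
                                  stop_effect = -6, stop_tail = 10L) {
  stopifnot(inherits(library, "VariantLibrary"),
            length(p_class) == 3, all(p_class >= 0))
  local_rng(seed)
  pos <- library$positions
  L <- length(pos)
  wt_aa <- strsplit(library$wt_protein, "")[[1]][pos]
  names(wt_aa) <- pos
  eff <- matrix(0, L, 21L, dimnames = list(pos, aa_alphabet()))
  cls <- sample(c("tolerant", "intermediate", "critical"), L,
                replace = TRUE, prob = p_class / sum(p_class))
  n_aa <- 20L  # 19 substitutions + stop per position, stop handled after
  for (i in seq_len(L)) {
    e <- switch(cls[i],
      tolerant = stats::rnorm(n_aa, 0, 0.3),
      intermediate = ifelse(stats::runif(n_aa) < 0.5,
                            stats::rnorm(n_aa, 0, 0.3),
                            stats::rnorm(n_aa, -2.5, 1.0)),
      critical = ifelse(stats::runif(n_aa) < 0.85,
                        stats::rnorm(n_aa, -4.5, 1.0),
                        stats::rnorm(n_aa, -1.0, 0.7)))
    cells <- setdiff(aa_alphabet(), wt_aa[i])
    eff[i, cells] <- e
  }
  tail_pos <- pos > (max(pos) - stop_tail)
  eff[!tail_pos, "*"] <- stop_effect
  eff[tail_pos, "*"] <- 0
  eff[wt_mask(wt_aa, pos)] <- 0
  structure(eff, wt_aa = wt_aa, position_class = stats::setNames(cls, pos),
            class = c("TrueFitnessMap", "matrix", "array"))
}

#' Apply multiplicative selection to a frequency table
#'
#' The selection model is multiplicative in `exp(effect)`: the
#' post-selection frequency of each variant is its pre-selection frequency
#' times `exp(delta_E_true)`, renormalised; the wild type carries
#' `exp(0) = 1`. This model is the exact inverse of the log-ratio fitness
#' estimator, so with exact frequencies the estimator recovers the planted
#' effects identically.
#'
#' @param pre_freqs A `FrequencyTable` (pre-selection).
#' @param truth A `TrueFitnessMap` covering every position of `pre_freqs`.
#' @return A `FrequencyTable` after selection (condition `"selected"`).
#' @export
simulate_selection <- function(pre_freqs, truth) {
  stopifnot(inherits(pre_freqs, "FrequencyTable"),
            inherits(truth, "TrueFitnessMap"))
  pos <- rownames(pre_freqs$cpm)
  if (!all(pos %in% rownames(truth)))
    stop("truth does not cover every variant position in pre_freqs")
  mult <- exp(truth[pos, , drop = FALSE])
  if (any(pre_freqs$cpm[is.na(mult)] > 0))
    stop("variant present in pre_freqs but missing from truth")
  post <- pre_freqs$cpm * mult
  wt_post <- pre_freqs$wt_cpm  # exp(0) = 1
  tot <- sum(post, na.rm = TRUE) + wt_post
  new_frequency_table(cpm = 1e6 * post / tot, wt_cpm = 1e6 * wt_post / tot,
                      wt_aa = pre_freqs$wt_aa, condition = "selected",
                      replicate = pre_freqs$replicate,
                      sublibrary = pre_freqs$sublibrary)
}

# Codon-level species table for one sub-library: every (position, NNS codon)
# with its encoded amino acid and the mutant CDS string.
codon_species <- function(library, range) {
  pos <- seq(range[1], range[2])
  codons <- nns_codons()
  aa <- translate_codons(codons)
  sp <- expand.grid(pos = pos, codon_idx = seq_along(codons),
                    KEEP.OUT.ATTRS = FALSE)
  sp$codon <- codons[sp$codon_idx]
  sp$aa <- aa[sp$codon_idx]
  wt_aa <- strsplit(library$wt_protein, "")[[1]]
  sp$is_wt <- sp$aa == wt_aa[sp$pos]
  amp_start <- 3L * (range[1] - 1L) + 1L
  amplicon <- substr(library$wt_cds, amp_start, 3L * range[2])
  off <- sp$pos - range[1]
  sp$cds <- paste0(substr(rep(amplicon, nrow(sp)), 1L, 3L * off),
                   sp$codon,
                   substr(rep(amplicon, nrow(sp)), 3L * off + 4L,
                          nchar(amplicon)))
  sp
}

# Vectorised substitution errors: pick (read, position) pairs and replace
# with a random different base, processing the r-th error of every read in
# one vectorised round.
apply_substitution_errors <- function(reads, error_rate) {
  if (error_rate <= 0 || length(reads) == 0) return(reads)
  w <- nchar(reads[1])
  n_err <- stats::rbinom(1L, length(reads) * w, error_rate)
  if (n_err == 0) return(reads)
  idx <- sample.int(length(reads), n_err, replace = TRUE)
  pos <- sample.int(w, n_err, replace = TRUE)
  ord <- order(idx)
  idx <- idx[ord]; pos <- pos[ord]
  rank_in_read <- stats::ave(seq_along(idx), idx, FUN = seq_along)
  bases <- c("A", "C", "G", "T")
  for (r in seq_len(max(rank_in_read))) {
    sel <- rank_in_read == r
    i <- idx[sel]; p <- pos[sel]
    old <- substr(reads[i], p, p)
    new <- bases[(match(old, bases) + sample.int(3L, length(i), replace = TRUE) - 1L) %% 4L + 1L]
    reads[i] <- paste0(substr(reads[i], 1L, p - 1L), new,
                       substr(reads[i], p + 1L, w))
  }
  reads
}

#' Simulate merged amplicon reads from a frequency table
#'
#' Draws reads multinomially over the codon-level species of one
#' sub-library (each amino-acid cell's frequency split uniformly over its
#' NNS codons, the wild-type frequency over wild-type-synonymous codons),
#' applies per-base substitution errors, and reverse-complements a random
#' half of the reads so the counting stage must recover orientation.
#' Deterministic under a fixed seed.
#'
#' @param freqs A `FrequencyTable` whose positions cover the sub-library.
#' @param library A `VariantLibrary`.
#' @param sublibrary Index into `library$sublibraries` (default 1).
#' @param depth Reads per amino-acid variant (default 300, matching
#'   several-hundred-fold per-variant coverage typical of saturation scans).
#' @param error_rate Per-base substitution error rate in `[0, 0.01)`.
#' @param seed Integer seed.
#' @param rc_fraction Fraction of reads emitted as reverse complements
#'   (default 0.5).
#' @return A `ReadSet`: list with `reads` (character vector), `condition`,
#'   `replicate`, `sublibrary` (range), `expected_length`, `seed`, and the
#'   drawn per-species `true_counts`.
#' @export
simulate_reads <- function(freqs, library, sublibrary = 1L, depth = 300,
                           error_rate = 1e-3, seed = 1L, rc_fraction = 0.5) {
  stopifnot(inherits(freqs, "FrequencyTable"),
            inherits(library, "VariantLibrary"),
            depth > 0, error_rate >= 0, error_rate < 0.01)
  local_rng(seed)
  range <- library$sublibraries[[sublibrary]]
  pos <- seq(range[1], range[2])
  stopifnot(all(as.character(pos) %in% rownames(freqs$cpm)))
  sp <- codon_species(library, range)

  cell_cpm <- freqs$cpm[cbind(match(as.character(sp$pos), rownames(freqs$cpm)),
                              match(sp$aa, aa_alphabet()))]
  n_codons <- stats::ave(rep(1L, nrow(sp)),
                         paste(sp$pos, sp$aa), FUN = sum)
  p <- ifelse(sp$is_wt, freqs$wt_cpm / sum(sp$is_wt), cell_cpm / n_codons)
  p <- p / sum(p)

  n_variants <- sum(library$variants$pos %in% pos)
  n_reads <- round(depth * n_variants)
  counts <- as.vector(stats::rmultinom(1L, n_reads, p))
  reads <- rep(sp$cds, counts)
  reads <- reads[sample.int(length(reads))]
  reads <- apply_substitution_errors(reads, error_rate)
  if (rc_fraction > 0) {
    flip <- stats::runif(length(reads)) < rc_fraction
    if (any(flip))
      reads[flip] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(reads[flip])))
  }
  structure(list(reads = reads, condition = freqs$condition %||% NA_character_,
                 replicate = freqs$replicate, sublibrary = range,
                 expected_length = 3L * length(pos), seed = seed,
                 true_counts = stats::setNames(counts,
                                               paste0(sp$pos, ":", sp$codon))),
            class = "ReadSet")
}

#' @export
print.ReadSet <- function(x, ...) {
  cat("ReadSet:", length(x$reads), "reads of", x$expected_length, "nt;",
      "sub-library", paste(x$sublibrary, collapse = "-"),
      if (!is.na(x$condition)) paste0("(", x$condition, ")") else "", "\n")
  invisible(x)
}

#' Write a read set as FASTQ
#'
#' Phred+33 with a constant quality of 40 (the simulator does not model
#' quality scores).
#'
#' @param readset A `ReadSet`.
#' @param path Output file (`.gz` allowed).
#' @return The path, invisibly.
#' @export
write_fastq <- function(readset, path) {
  dna <- Biostrings::DNAStringSet(readset$reads)
  names(dna) <- sprintf("read%07d", seq_along(dna))
  qual <- Biostrings::BStringSet(strrep("I", Biostrings::width(dna)))
  Biostrings::writeXStringSet(dna, path, format = "fastq", qualities = qual,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read merged amplicon reads from FASTQ
#'
#' @param path FASTQ file (plain or gzip).
#' @param ... Metadata fields (`condition`, `replicate`, `sublibrary`,
#'   `expected_length`) attached to the returned `ReadSet`.
#' @return A `ReadSet`.
#' @export
read_fastq <- function(path, ...) {
  dna <- Biostrings::readDNAStringSet(path, format = "fastq")
  meta <- list(...)
  structure(list(reads = as.character(unname(dna)),
                 condition = meta$condition %||% NA_character_,
                 replicate = meta$replicate %||% NA_integer_,
                 sublibrary = meta$sublibrary %||% NA,
                 expected_length = meta$expected_length %||% NA_integer_,
                 seed = NA_integer_),
            class = "ReadSet")
}

#' Write wild-type sequences as FASTA
#'
#' @param library A `VariantLibrary`.
#' @param cds_path,protein_path Output files (either may be `NULL`).
#' @return Invisibly, the written paths.
#' @export
write_wt_fasta <- function(library, cds_path = NULL, protein_path = NULL) {
  if (!is.null(cds_path)) {
    x <- Biostrings::DNAStringSet(library$wt_cds)
    names(x) <- "wt_cds"
    Biostrings::writeXStringSet(x, cds_path)
  }
  if (!is.null(protein_path)) {
    x <- Biostrings::AAStringSet(library$wt_protein)
    names(x) <- "wt_protein"
    Biostrings::writeXStringSet(x, protein_path)
  }
  invisible(c(cds_path, protein_path))
}
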