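# Site-saturation NNS library enumeration.

#' Amino-acid alphabet used throughout the package
#'
#' The 20 standard amino acids in alphabetical one-letter order followed by
#' the stop symbol `"*"` (21 symbols). Fitness landscapes, count tables and
#' frequency tables all index their columns by this vector.
#'
#' @return Character vector of length 21.
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "*")
}

#' Enumerate the 32 NNS codons
#'
#' NNS degenerate codons have any base at the first two positions and G or C
#' at the third (4 x 4 x 2 = 32 codons). Together they encode all 20 amino
#' acids plus one stop (TAG).
#'
#' @return Character vector of 32 codons.
#' @export
nns_codons <- function() {
  n <- c("A", "C", "G", "T")
  s <- c("C", "G")
  as.vector(outer(outer(n, n, paste0), s, paste0))
}

# Translate a vector of codons with the standard genetic code.
translate_codons <- function(codons) {
  unname(Biostrings::GENETIC_CODE[codons])
}

#' Build a complete single-mutation NNS variant library
#'
#' Enumerates, for every position in `positions`, the 32 NNS codons and
#' collapses them to the amino-acid level. The variant set is the full
#' 20-symbol (19 amino acids + stop) non-wild-type substitution set at each
#' position; NNS codons synonymous with the wild-type residue are recorded
#' (they contribute wild-type molecules to the pool) but are not variants.
#'
#' @param wt_cds Wild-type coding sequence, a single DNA string with length
#'   divisible by 3 and no internal stop codon.
#' @param positions Integer vector of 1-based codon positions to mutate
#'   (default: all positions).
#' @param sublibraries List of length-2 integer vectors giving inclusive
#'   position ranges that partition `positions`; default splits at
#'   `ceiling(L / 2)`, mirroring amplicon sub-libraries sized for paired-end
#'   sequencing.
#'
#' @return An object of class `VariantLibrary`: a list with `wt_cds`,
#'   `wt_protein`, `positions`, `variants` (data.frame `pos`, `aa`,
#'   `n_codons`), `wt_codon_counts` (per-position count of WT-synonymous NNS
#'   codons) and `sublibraries`.
#' @export
generate_nns_library <- function(wt_cds, positions = NULL, sublibraries = NULL) {
  wt_cds <- toupper(as.character(wt_cds))
  if (grepl("[^ACGT]", wt_cds)) stop("wt_cds contains non-ACGT characters")
  if (nchar(wt_cds) %% 3L != 0L) stop("wt_cds length must be divisible by 3")
  L <- nchar(wt_cds) %/% 3L
  wt_codons <- substring(wt_cds, 3L * seq_len(L) - 2L, 3L * seq_len(L))
  wt_protein <- translate_codons(wt_codons)
  if (any(wt_protein == "*")) stop("wt_cds translation contains an internal stop codon")
  wt_protein <- paste(wt_protein, collapse = "")

  if (is.null(positions)) positions <- seq_len(L)
  positions <- as.integer(positions)
  if (any(positions < 1L | positions > L)) stop("positions outside 1..L")
  if (is.null(sublibraries)) {
    half <- ceiling(L / 2)
    sublibraries <- list(c(1L, half), c(half + 1L, L))
    sublibraries <- Filter(function(r) r[1] <= r[2], sublibraries)
  }
  covered <- sort(unlist(lapply(sublibraries, function(r) seq(r[1], r[2]))))
  if (!identical(covered, sort(unique(positions))))
    stop("sublibrary ranges must partition the position list")

  nns_aa <- translate_codons(nns_codons())  # length 32, all 20 aa + "*"
  wt_aa <- strsplit(wt_protein, "")[[1]]
  per_pos <- lapply(positions, function(i) {
    tab <- table(nns_aa)
    keep <- names(tab) != wt_aa[i]
    data.frame(pos = i, aa = names(tab)[keep],
               n_codons = as.integer(tab[keep]), stringsAsFactors = FALSE)
  })
  variants <- do.call(rbind, per_pos)
  wt_codon_counts <- vapply(positions, function(i) sum(nns_aa == wt_aa[i]), integer(1))
  names(wt_codon_counts) <- positions

  structure(list(wt_cds = wt_cds, wt_protein = wt_protein,
                 positions = positions, variants = variants,
                 wt_codon_counts = wt_codon_counts,
                 sublibraries = sublibraries),
            class = "VariantLibrary")
}

#' @export
print.VariantLibrary <- function(x, ...) {
  cat("VariantLibrary:", nchar(x$wt_protein), "positions,",
      nrow(x$variants), "amino-acid variants,",
      length(x$sublibraries), "sub-libraries\n")
  invisible(x)
}

#' Generate a random stop-free coding sequence
#'
#' Convenience generator for synthetic experiments: a random CDS of `L`
#' codons starting with ATG and containing no stop codon.
#'
#' @param L Number of codons.
#' @param seed Integer seed.
#' @return A DNA string of length `3 * L`.
#' @export
random_cds <- function(L, seed = 1L) {
  stopifnot(L >= 1)
  rng <- local_rng(seed)
  sense <- setdiff(names(Biostrings::GENETIC_CODE),
                   names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE == "*"])
  codons <- c("ATG", sample(sense, L - 1L, replace = TRUE))[seq_len(L)]
  paste(codons, collapse = "")
}
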