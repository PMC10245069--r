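# Variant counting: merged amplicon reads -> per-(position, amino-acid)
# count tables.

#' Length-filter a read set
#'
#' Retains only reads of exactly the expected amplicon length (indels and
#' truncated merges are discarded); the discard tally is carried on the
#' returned object.
#'
#' @param reads A `ReadSet`.
#' @param expected_length Amplicon length in nucleotides; defaults to the
#'   read set's own `expected_length`.
#' @return The filtered `ReadSet` with a `discarded` tally attached.
#' @export
preprocess_reads <- function(reads, expected_length = reads$expected_length) {
  stopifnot(inherits(reads, "ReadSet"), expected_length > 0)
  if (length(reads$reads) == 0) {
    warning("empty read set")
    reads$discarded <- empty_discard_tally()
    return(reads)
  }
  keep <- nchar(reads$reads) == expected_length
  tally <- reads$discarded %||% empty_discard_tally()
  tally["length"] <- tally["length"] + sum(!keep)
  reads$reads <- reads$reads[keep]
  reads$expected_length <- as.integer(expected_length)
  reads$discarded <- tally
  reads
}

# Byte-matrix view of equal-width sequences: width x n raw matrix (one
# column per sequence), for fast vectorised mismatch counting.
seq_bytes <- function(x, width) {
  r <- charToRaw(paste(x, collapse = ""))
  dim(r) <- c(width, length(x))
  r
}

#' Orient reads against the wild-type amplicon and translate
#'
#' Each read is compared to the wild-type amplicon in both orientations;
#' the orientation with the smaller nucleotide Hamming distance is kept and
#' translated (stop codons render as `"*"`). Reads whose two orientations
#' tie are ambiguous and returned as `NA`.
#'
#' @param reads Character vector of reads, all of the amplicon length
#'   (a multiple of 3).
#' @param wt_amplicon Wild-type amplicon (coding strand) of the same length.
#' @param chunk_size Reads per processing chunk (memory control).
#' @return Character vector of amino-acid strings (`NA` for orientation
#'   ties), with attribute `n_ambiguous`.
#' @export
orient_and_translate <- function(reads, wt_amplicon, chunk_size = 25000L) {
  w <- nchar(wt_amplicon)
  stopifnot(w %% 3L == 0L, all(nchar(reads) == w))
  if (length(reads) == 0)
    return(structure(character(0), n_ambiguous = 0L))
  wt_fwd <- charToRaw(wt_amplicon)
  wt_rev <- charToRaw(as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(wt_amplicon))))
  starts <- seq(1L, length(reads), by = chunk_size)
  use_rc <- logical(length(reads))
  tie <- logical(length(reads))
  for (s in starts) {
    i <- s:min(s + chunk_size - 1L, length(reads))
    m <- seq_bytes(reads[i], w)
    mm_fwd <- colSums(m != wt_fwd)
    mm_rev <- colSums(m != wt_rev)
    use_rc[i] <- mm_rev < mm_fwd
    tie[i] <- mm_rev == mm_fwd
  }
  oriented <- reads
  if (any(use_rc))
    oriented[use_rc] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(reads[use_rc])))
  prot <- as.character(Biostrings::translate(
    Biostrings::DNAStringSet(oriented), no.init.codon = TRUE))
  prot[tie] <- NA_character_
  structure(unname(prot), n_ambiguous = sum(tie))
}

#' Count amino-acid variants from translated reads
#'
#' Reads identical to the wild type count toward `wt_count`; reads with
#' exactly one substitution increment the corresponding
#' (position, amino-acid) cell; reads with two or more substitutions are
#' discarded as multi-mutants (the library is single-mutant by
#' construction). Symbols outside the 21-letter alphabet discard the read
#' as ambiguous.
#'
#' @param proteins Character vector of translated reads (`NA` entries are
#'   counted as ambiguous), all the same length as the wild-type segment.
#' @param wt_protein Wild-type amino-acid string for the segment.
#' @param offset 1-based full-length position of the segment's first
#'   residue.
#' @param chunk_size Reads per processing chunk.
#' @param ... Metadata (`condition`, `replicate`, `sublibrary`) stored on
#'   the table.
#' @return A `CountTable` over positions `offset .. offset + L - 1`.
#' @export
count_variants <- function(proteins, wt_protein, offset = 1L,
                           chunk_size = 25000L, ...) {
  L <- nchar(wt_protein)
  wt_chars <- strsplit(wt_protein, "")[[1]]
  positions <- seq(offset, offset + L - 1L)
  counts <- matrix(0L, L, 21L, dimnames = list(positions, aa_alphabet()))
  tally <- empty_discard_tally()
  meta <- list(...)
  n_input <- length(proteins)
  tally["ambiguous"] <- tally["ambiguous"] + sum(is.na(proteins))
  proteins <- proteins[!is.na(proteins)]
  if (length(proteins) > 0 && any(nchar(proteins) != L))
    stop("translated reads must match the wild-type segment length")
  wt_count <- 0L
  alpha <- aa_alphabet()
  alpha_raw <- as.integer(charToRaw(paste(alpha, collapse = "")))
  wt_raw <- charToRaw(wt_protein)
  for (s in seq(1L, max(length(proteins), 1L), by = chunk_size)) {
    if (length(proteins) == 0) break
    i <- s:min(s + chunk_size - 1L, length(proteins))
    m <- seq_bytes(proteins[i], L)           # L x n raw
    mm <- m != wt_raw
    nmm <- colSums(mm)
    wt_count <- wt_count + sum(nmm == 0L)
    single <- which(nmm == 1L)
    if (length(single)) {
      hit <- which(mm[, single, drop = FALSE], arr.ind = TRUE)
      p <- hit[, 1]                          # mutated position in segment
      sym_int <- as.integer(m[cbind(p, single[hit[, 2]])])
      ai <- match(sym_int, alpha_raw)
      ok <- !is.na(ai)
      tally["ambiguous"] <- tally["ambiguous"] + sum(!ok)
      if (any(ok)) {
        inc <- table(factor((ai[ok] - 1L) * L + p[ok],
                            levels = seq_len(21L * L)))
        counts <- counts + matrix(as.integer(inc), L, 21L)
      }
    }
    tally["multi_mutant"] <- tally["multi_mutant"] + sum(nmm >= 2L)
  }
  new_count_table(counts = counts, wt_count = wt_count,
                  wt_aa = stats::setNames(wt_chars, positions),
                  discarded = tally, n_input = n_input,
                  condition = meta$condition %||% NA_character_,
                  replicate = meta$replicate %||% NA_integer_,
                  sublibrary = meta$sublibrary %||% NA_character_)
}

#' Count a read set against a variant library
#'
#' Convenience wrapper running the counting stage end to end for one
#' sub-library read set: length filter, orientation + translation, and
#' variant counting. Discards from all stages are merged into one tally and
#' `n_input` is the original read count, so reads are conserved:
#' `sum(counts) + wt_count + sum(discarded) == n_input`.
#'
#' @param reads A `ReadSet` (its `sublibrary` range selects the wild-type
#'   segment).
#' @param library A `VariantLibrary`.
#' @return A `CountTable`.
#' @export
count_reads <- function(reads, library) {
  stopifnot(inherits(reads, "ReadSet"), inherits(library, "VariantLibrary"))
  range <- reads$sublibrary
  n_input <- length(reads$reads)
  amp <- substr(library$wt_cds, 3L * (range[1] - 1L) + 1L, 3L * range[2])
  reads <- preprocess_reads(reads, nchar(amp))
  prot <- orient_and_translate(reads$reads, amp)
  seg <- substr(library$wt_protein, range[1], range[2])
  tab <- count_variants(prot, seg, offset = range[1],
                        condition = reads$condition,
                        replicate = reads$replicate,
                        sublibrary = paste(range, collapse = "-"))
  tab$discarded <- tab$discarded + reads$discarded
  tab$n_input <- n_input
  tab
}

#' Merge overlapping paired-end reads (naive overlap merger)
#'
#' Convenience plumbing for paired FASTQ input: aligns the reverse
#' complement of read 2 against read 1 at the overlap implied by
#' `amplicon_length` and resolves overlap disagreements in favour of read 1.
#' Pairs whose implied overlap is negative are dropped.
#'
#' @param fwd,rev Character vectors of read-1 and read-2 sequences.
#' @param amplicon_length Expected merged length.
#' @return Character vector of merged reads.
#' @export
merge_read_pairs <- function(fwd, rev, amplicon_length) {
  stopifnot(length(fwd) == length(rev))
  rev_rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(rev)))
  out <- character(0)
  for (i in seq_along(fwd)) {
    n1 <- nchar(fwd[i]); n2 <- nchar(rev_rc[i])
    if (n1 + n2 < amplicon_length) next
    tail_len <- amplicon_length - n1
    merged <- paste0(fwd[i],
                     if (tail_len > 0) substr(rev_rc[i], n2 - tail_len + 1L, n2)
                     else "")
    out <- c(out, merged)
  }
  out
}
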