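# Count and frequency tables: the per-(position, amino-acid) bookkeeping
# shared by the simulator and the counting pipeline.

new_count_table <- function(counts, wt_count, wt_aa, discarded, n_input,
                            condition = NA_character_, replicate = NA_integer_,
                            sublibrary = NA_character_) {
  stopifnot(is.matrix(counts), ncol(counts) == 21L,
            identical(colnames(counts), aa_alphabet()),
            length(wt_aa) == nrow(counts))
  structure(list(counts = counts, wt_count = wt_count, wt_aa = wt_aa,
                 discarded = discarded, n_input = n_input,
                 condition = condition, replicate = replicate,
                 sublibrary = sublibrary),
            class = "CountTable")
}

#' @export
print.CountTable <- function(x, ...) {
  cat("CountTable:", nrow(x$counts), "positions;",
      sum(x$counts), "variant reads; WT", x$wt_count, ";",
      "discarded", sum(x$discarded),
      sprintf("(%s)", paste(names(x$discarded), x$discarded,
                            sep = "=", collapse = ", ")), "\n")
  invisible(x)
}

empty_discard_tally <- function() {
  c(length = 0L, frame = 0L, multi_mutant = 0L, ambiguous = 0L)
}

new_frequency_table <- function(cpm, wt_cpm, wt_aa,
                                condition = NA_character_,
                                replicate = NA_integer_,
                                sublibrary = NA_character_) {
  stopifnot(is.matrix(cpm), ncol(cpm) == 21L,
            identical(colnames(cpm), aa_alphabet()))
  structure(list(cpm = cpm, wt_cpm = wt_cpm, wt_aa = wt_aa,
                 condition = condition, replicate = replicate,
                 sublibrary = sublibrary),
            class = "FrequencyTable")
}

#' @export
print.FrequencyTable <- function(x, ...) {
  cat("FrequencyTable:", nrow(x$cpm), "positions; WT",
      format(x$wt_cpm, digits = 6), "CPM; cells sum to",
      format(sum(x$cpm, na.rm = TRUE) + x$wt_cpm, digits = 9), "CPM\n")
  invisible(x)
}

# Logical mask of wild-type identity cells (structural zeros) of a
# positions x 21 matrix.
wt_mask <- function(wt_aa, positions = names(wt_aa)) {
  m <- matrix(FALSE, length(wt_aa), 21L,
              dimnames = list(positions, aa_alphabet()))
  idx <- cbind(seq_along(wt_aa), match(wt_aa, aa_alphabet()))
  idx <- idx[!is.na(idx[, 2]), , drop = FALSE]
  m[idx] <- TRUE
  m
}

#' Normalise a count table to counts per million
#'
#' Adds `pseudocount` reads to every variant cell and to the wild type, then
#' rescales so that all cells plus the wild type sum to one million.
#' Wild-type identity cells are structural zeros and receive no pseudocount.
#'
#' @param table A `CountTable`.
#' @param pseudocount Reads added to each cell before normalisation
#'   (default 1; 0 reproduces plain CPM and leaves zero cells at zero, which
#'   propagate to `NA` fitness values downstream).
#' @return A `FrequencyTable`.
#' @export
normalize_cpm <- function(table, pseudocount = 1) {
  stopifnot(inherits(table, "CountTable"), pseudocount >= 0)
  if (sum(table$counts) + table$wt_count == 0)
    stop("all-zero count table cannot be normalised")
  mask <- wt_mask(table$wt_aa, rownames(table$counts))
  cnt <- table$counts + pseudocount
  cnt[mask] <- 0
  wt <- table$wt_count + pseudocount
  tot <- sum(cnt) + wt
  new_frequency_table(cpm = 1e6 * cnt / tot, wt_cpm = 1e6 * wt / tot,
                      wt_aa = table$wt_aa, condition = table$condition,
                      replicate = table$replicate,
                      sublibrary = table$sublibrary)
}

#' Expected pre-selection frequencies of an NNS library pool
#'
#' Models an equimolar pool of mutagenised molecules: every (position, NNS
#' codon) species is present at frequency `1 / (32 * n_positions)`. Collapsed
#' to the amino-acid level, each variant cell's frequency is proportional to
#' its NNS codon multiplicity, and wild-type-synonymous codons contribute the
#' wild-type frequency.
#'
#' @param library A `VariantLibrary`.
#' @param positions Optional subset of positions (e.g. one sub-library).
#' @return A `FrequencyTable` on the CPM scale.
#' @export
library_frequencies <- function(library, positions = NULL) {
  stopifnot(inherits(library, "VariantLibrary"))
  if (is.null(positions)) positions <- library$positions
  v <- library$variants[library$variants$pos %in% positions, ]
  npos <- length(positions)
  cpm <- matrix(0, npos, 21L,
                dimnames = list(positions, aa_alphabet()))
  cpm[cbind(match(v$pos, positions), match(v$aa, aa_alphabet()))] <-
    1e6 * v$n_codons / (32 * npos)
  wt_aa <- strsplit(library$wt_protein, "")[[1]][positions]
  names(wt_aa) <- positions
  wt_cpm <- 1e6 * sum(library$wt_codon_counts[as.character(positions)]) /
    (32 * npos)
  new_frequency_table(cpm = cpm, wt_cpm = wt_cpm, wt_aa = wt_aa)
}

# Concatenate tables from sub-libraries counted independently, by position.
#' Concatenate per-sub-library tables by position
#'
#' Sub-libraries are counted and normalised independently; this stacks their
#' rows into one full-length table. Positions must not overlap.
#'
#' @param tables List of `CountTable` or `FrequencyTable` objects.
#' @return An object of the same class spanning all positions.
#' @export
concat_positions <- function(tables) {
  stopifnot(length(tables) >= 1)
  cls <- class(tables[[1]])
  stopifnot(all(vapply(tables, function(t) identical(class(t), cls), logical(1))))
  ord <- order(vapply(tables, function(t)
    min(as.integer(rownames(t[[1]]))), numeric(1)))
  tables <- tables[ord]
  pos <- unlist(lapply(tables, function(t) rownames(t[[1]])))
  if (anyDuplicated(pos)) stop("overlapping positions across sub-libraries")
  if (cls[1] == "CountTable") {
    new_count_table(counts = do.call(rbind, lapply(tables, `[[`, "counts")),
                    wt_count = sum(vapply(tables, `[[`, numeric(1), "wt_count")),
                    wt_aa = unlist(lapply(tables, `[[`, "wt_aa")),
                    discarded = Reduce(`+`, lapply(tables, `[[`, "discarded")),
                    n_input = sum(vapply(tables, `[[`, numeric(1), "n_input")),
                    condition = tables[[1]]$condition,
                    replicate = tables[[1]]$replicate,
                    sublibrary = "all")
  } else {
    k <- length(tables)
    new_frequency_table(cpm = do.call(rbind, lapply(tables, `[[`, "cpm")) / k,
                        wt_cpm = mean(vapply(tables, `[[`, numeric(1), "wt_cpm")),
                        wt_aa = unlist(lapply(tables, `[[`, "wt_aa")),
                        condition = tables[[1]]$condition,
                        replicate = tables[[1]]$replicate,
                        sublibrary = "all")
  }
}

#' Write a count or frequency table as TSV
#'
#' Long format with columns `position`, `aa`, `condition`, `replicate`,
#' `count` and/or `cpm`; wild-type identity cells are omitted and the
#' wild-type totals appear as `aa = "WT"` rows.
#'
#' @param table A `CountTable` or `FrequencyTable`.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_table_tsv <- function(table, path) {
  m <- table[[1]]
  mask <- wt_mask(table$wt_aa, rownames(m))
  df <- data.frame(position = as.integer(rownames(m)[row(m)[!mask]]),
                   aa = colnames(m)[col(m)[!mask]],
                   condition = table$condition, replicate = table$replicate,
                   value = m[!mask])
  wt_row <- data.frame(position = NA_integer_, aa = "WT",
                       condition = table$condition, replicate = table$replicate,
                       value = table[[2]])
  df <- rbind(df[order(df$position, df$aa), ], wt_row)
  names(df)[names(df) == "value"] <-
    if (inherits(table, "CountTable")) "count" else "cpm"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
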