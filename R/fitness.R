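# Fitness landscape: mutational cost from paired selected/unselected
# frequency tables, replicate averaging, and functional-residue selection.

new_landscape <- function(delta_E, wt_aa, replicate = NA_integer_,
                          partial = NULL, log_base = exp(1)) {
  stopifnot(is.matrix(delta_E), ncol(delta_E) == 21L,
            identical(colnames(delta_E), aa_alphabet()))
  structure(list(delta_E = delta_E, wt_aa = wt_aa, replicate = replicate,
                 partial = partial, log_base = log_base),
            class = "FitnessLandscape")
}

#' @export
print.FitnessLandscape <- function(x, ...) {
  v <- mutation_cells(x)
  cat("FitnessLandscape:", nrow(x$delta_E), "positions;",
      sum(!is.na(v)), "scored mutations;",
      "mean", format(mean(v, na.rm = TRUE), digits = 4),
      "sd", format(stats::sd(v[!is.na(v)]), digits = 4), "\n")
  invisible(x)
}

# Vector of the 20 non-WT mutation cells per position (NA where unobserved).
mutation_cells <- function(landscape) {
  m <- landscape$delta_E
  m[wt_mask(landscape$wt_aa, rownames(m))] <- NA
  as.vector(m)
}

#' Compute the mutational-cost landscape from paired conditions
#'
#' For each variant x at position i,
#' `delta_E = log(f_sel / f_unsel) - log(f_WT_sel / f_WT_unsel)`:
#' the log enrichment of the variant across selection relative to the
#' wild-type enrichment. Natural log by default (`log_base` configurable).
#' The score is invariant to uniform rescaling of either condition, and the
#' wild-type cell of every position is exactly 0. Variants with zero
#' frequency in either condition (possible under `pseudocount = 0`) are
#' masked `NA`.
#'
#' @param sel,unsel `FrequencyTable`s for the selected and unselected
#'   conditions, covering the same positions.
#' @param log_base Base of the logarithm (default `exp(1)`).
#' @return A `FitnessLandscape`.
#' @export
compute_fitness <- function(sel, unsel, log_base = exp(1)) {
  stopifnot(inherits(sel, "FrequencyTable"), inherits(unsel, "FrequencyTable"))
  if (!identical(rownames(sel$cpm), rownames(unsel$cpm)))
    stop("selected and unselected tables must cover the same positions")
  if (sel$wt_cpm <= 0 || unsel$wt_cpm <= 0)
    stop("wild-type frequency must be positive in both conditions")
  wt_term <- log(sel$wt_cpm / unsel$wt_cpm)
  d <- log(sel$cpm / unsel$cpm) - wt_term
  d[!is.finite(d)] <- NA
  d[wt_mask(sel$wt_aa, rownames(d))] <- 0
  d <- d / log(log_base)
  new_landscape(d, wt_aa = sel$wt_aa,
                replicate = sel$replicate, log_base = log_base)
}

#' Concatenate landscapes of independently scored sub-libraries
#'
#' @param landscapes List of `FitnessLandscape`s over disjoint positions.
#' @return A `FitnessLandscape` spanning all positions.
#' @export
concat_landscapes <- function(landscapes) {
  stopifnot(length(landscapes) >= 1)
  ord <- order(vapply(landscapes, function(l)
    min(as.integer(rownames(l$delta_E))), numeric(1)))
  landscapes <- landscapes[ord]
  pos <- unlist(lapply(landscapes, function(l) rownames(l$delta_E)))
  if (anyDuplicated(pos)) stop("overlapping positions")
  new_landscape(do.call(rbind, lapply(landscapes, `[[`, "delta_E")),
                wt_aa = unlist(lapply(landscapes, `[[`, "wt_aa")),
                replicate = landscapes[[1]]$replicate,
                log_base = landscapes[[1]]$log_base)
}

#' Average fitness landscapes over biological replicates
#'
#' Cell-wise arithmetic mean over replicates where observed; a cell is `NA`
#' only if it is `NA` in every replicate, and cells observed in only a
#' subset of replicates are flagged in the `partial` matrix.
#'
#' @param landscapes List of congruent `FitnessLandscape`s.
#' @return A `FitnessLandscape` with `replicate = NA` and a logical
#'   `partial` matrix.
#' @export
average_replicates <- function(landscapes) {
  stopifnot(length(landscapes) >= 1)
  ref <- landscapes[[1]]$delta_E
  for (l in landscapes)
    if (!identical(dim(l$delta_E), dim(ref)) ||
        !identical(rownames(l$delta_E), rownames(ref)))
      stop("landscape shape mismatch across replicates")
  arr <- simplify2array(lapply(landscapes, `[[`, "delta_E"))
  n_obs <- apply(!is.na(arr), c(1, 2), sum)
  avg <- apply(arr, c(1, 2), function(v) {
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  })
  partial <- n_obs > 0 & n_obs < length(landscapes)
  new_landscape(avg, wt_aa = landscapes[[1]]$wt_aa, replicate = NA_integer_,
                partial = partial, log_base = landscapes[[1]]$log_base)
}

#' Per-position mean mutational cost
#'
#' Mean over the 20 non-wild-type symbols at each position, skipping `NA`;
#' positions with no observed mutation are `NA`.
#'
#' @param landscape A `FitnessLandscape`.
#' @return Named numeric vector (one value per position).
#' @export
position_summary <- function(landscape) {
  stopifnot(inherits(landscape, "FitnessLandscape"),
            nrow(landscape$delta_E) > 0)
  m <- landscape$delta_E
  m[wt_mask(landscape$wt_aa, rownames(m))] <- NA
  out <- rowMeans(m, na.rm = TRUE)
  out[is.nan(out)] <- NA
  out
}

#' Select functionally important residues
#'
#' Computes the mean `mu` and standard deviation `sigma` of all observed
#' mutation cells of the landscape (stop variants included) and selects the
#' positions at which at least `k` mutations fall more than `m` standard
#' deviations below the mean (`sided = "below"`, the default: the screen
#' detects loss of function) or away from the mean in either direction
#' (`sided = "two_sided"`).
#'
#' @param landscape A `FitnessLandscape` (typically replicate-averaged).
#' @param k Minimum number of qualifying mutations per position (default 5).
#' @param m Standard-deviation multiplier (default 1).
#' @param sided `"below"` or `"two_sided"`.
#' @return A `ResidueSelection`: list with `selected_positions`,
#'   `qualifying` (per-position counts), `mu`, `sigma`, `threshold`, and the
#'   rule parameters.
#' @export
select_functional_residues <- function(landscape, k = 5L, m = 1,
                                       sided = c("below", "two_sided")) {
  sided <- match.arg(sided)
  stopifnot(inherits(landscape, "FitnessLandscape"), k >= 1, m > 0)
  cells <- landscape$delta_E
  cells[wt_mask(landscape$wt_aa, rownames(cells))] <- NA
  v <- cells[!is.na(cells)]
  mu <- mean(v)
  sigma <- stats::sd(v)
  if (!is.finite(sigma) || sigma == 0)
    stop("degenerate landscape: standard deviation of mutation effects is 0")
  qual <- if (sided == "below") cells < (mu - m * sigma)
          else abs(cells - mu) > m * sigma
  n_qual <- rowSums(qual, na.rm = TRUE)
  selected <- as.integer(rownames(cells))[n_qual >= k]
  structure(list(selected_positions = selected,
                 qualifying = stats::setNames(n_qual, rownames(cells)),
                 mu = mu, sigma = sigma,
                 threshold = if (sided == "below") mu - m * sigma else NA_real_,
                 k = as.integer(k), m = m, sided = sided),
            class = "ResidueSelection")
}

#' @export
print.ResidueSelection <- function(x, ...) {
  cat("ResidueSelection:", length(x$selected_positions), "residues",
      sprintf("(k=%d, m=%g, %s; mu=%.4g, sigma=%.4g)\n",
              x$k, x$m, x$sided, x$mu, x$sigma))
  invisible(x)
}

#' Partition selected residues into functional groups
#'
#' Assigns each selected residue to one of four groups by precedence
#' signal peptide > lipid-binding pocket > buried > surface. Selected
#' residues absent from the annotation are reported as `unclassified` with
#' a warning.
#'
#' @param selection A `ResidueSelection`.
#' @param annot List with `signal_peptide` (length-2 range) and integer
#'   vectors `pocket_positions`, `buried_positions`, `surface_positions`.
#' @return List of integer vectors `signal_peptide`, `pocket`, `buried`,
#'   `surface`, `unclassified`, plus a `counts` vector.
#' @export
classify_groups <- function(selection, annot) {
  stopifnot(inherits(selection, "ResidueSelection"))
  sel <- selection$selected_positions
  sp_range <- annot$signal_peptide
  sp <- if (!is.null(sp_range)) sel[sel >= sp_range[1] & sel <= sp_range[2]]
        else integer(0)
  rest <- setdiff(sel, sp)
  pocket <- intersect(rest, annot$pocket_positions %||% integer(0))
  rest <- setdiff(rest, pocket)
  buried <- intersect(rest, annot$buried_positions %||% integer(0))
  rest <- setdiff(rest, buried)
  surface <- intersect(rest, annot$surface_positions %||% integer(0))
  uncl <- setdiff(rest, surface)
  if (length(uncl))
    warning(length(uncl), " selected position(s) not covered by annotation")
  out <- list(signal_peptide = sp, pocket = pocket, buried = buried,
              surface = surface, unclassified = uncl)
  out$counts <- vapply(out, length, integer(1))
  out
}

#' Write a fitness landscape as TSV
#'
#' Long format: `position`, `aa`, `score`; wild-type identity cells are 0
#' and unobserved cells `NA`.
#'
#' @param landscape A `FitnessLandscape`.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_landscape_tsv <- function(landscape, path) {
  m <- landscape$delta_E
  df <- data.frame(position = as.integer(rownames(m)[row(m)]),
                   aa = colnames(m)[col(m)], score = as.vector(m))
  df <- df[order(df$position, match(df$aa, aa_alphabet())), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export scores as a MaveDB-style CSV
#'
#' One row per variant with an `hgvs_pro` protein-variant string
#' (`p.Ala2Gly`-style; stops as `Ter`) and a `score` column.
#'
#' @param landscape A `FitnessLandscape`.
#' @param path Output CSV.
#' @return The path, invisibly.
#' @export
write_mavedb_scores <- function(landscape, path) {
  m <- landscape$delta_E
  mask <- wt_mask(landscape$wt_aa, rownames(m))
  keep <- which(!mask, arr.ind = TRUE)
  pos <- as.integer(rownames(m))[keep[, 1]]
  aa_to <- colnames(m)[keep[, 2]]
  aa_from <- landscape$wt_aa[keep[, 1]]
  df <- data.frame(hgvs_pro = paste0("p.", aa_three(aa_from), pos,
                                     aa_three(aa_to)),
                   score = m[keep])
  df <- df[order(pos, aa_to), ]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

aa_three_map <- c(A = "Ala", C = "Cys", D = "Asp", E = "Glu", F = "Phe",
                  G = "Gly", H = "His", I = "Ile", K = "Lys", L = "Leu",
                  M = "Met", N = "Asn", P = "Pro", Q = "Gln", R = "Arg",
                  S = "Ser", T = "Thr", V = "Val", W = "Trp", Y = "Tyr",
                  "*" = "Ter")
aa_three <- function(x) unname(aa_three_map[x])
aa_one <- function(x) {
  inv <- stats::setNames(names(aa_three_map), aa_three_map)
  unname(inv[x])
}

#' Read a MaveDB-style score CSV into a fitness landscape
#'
#' Parses protein-variant strings of the form `p.Ala2Gly` (stops as `Ter`)
#' with a `score` column, e.g. a deposited score set downloaded from
#' MaveDB. Rows with missing scores become `NA` cells.
#'
#' @param path CSV with columns `hgvs_pro` and `score` (extra columns and
#'   comment lines starting with `#` are ignored).
#' @param L Protein length; defaults to the largest variant position.
#' @return A `FitnessLandscape`.
#' @export
read_mavedb_scores <- function(path, L = NULL) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("hgvs_pro", "score") %in% names(df)))
  m3 <- regmatches(df$hgvs_pro,
                   regexec("^p\\.([A-Za-z]{3})([0-9]+)([A-Za-z]{3}|=)$",
                           df$hgvs_pro))
  ok <- lengths(m3) == 4
  if (!all(ok)) warning(sum(!ok), " unparseable variant string(s) skipped")
  from <- vapply(m3[ok], `[`, character(1), 2)
  pos <- as.integer(vapply(m3[ok], `[`, character(1), 3))
  to <- vapply(m3[ok], `[`, character(1), 4)
  score <- as.numeric(df$score[ok])
  syn <- to == "="
  to[syn] <- from[syn]
  if (is.null(L)) L <- max(pos)
  d <- matrix(NA_real_, L, 21L, dimnames = list(seq_len(L), aa_alphabet()))
  d[cbind(pos, match(aa_one(to), aa_alphabet()))] <- score
  wt_aa <- rep(NA_character_, L)
  wt_aa[pos] <- aa_one(from)
  names(wt_aa) <- seq_len(L)
  mask <- wt_mask(ifelse(is.na(wt_aa), "?", wt_aa), seq_len(L))
  d[mask] <- 0
  new_landscape(d, wt_aa = wt_aa)
}
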