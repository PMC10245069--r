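# Orchestration: a reproducible synthetic DMS run, stage by stage, with a
# machine-readable run report.

#' Default pipeline configuration
#'
#' Study-scale defaults: a 211-codon CDS split into sub-libraries 1-107 and
#' 108-211, two biological replicates, 300x per-variant sequencing depth and
#' a 1e-3 per-base substitution error rate; pseudocount 1, natural log,
#' selection rule k = 5 qualifying mutations beyond m = 1 SD (one-sided,
#' loss of function).
#'
#' @param ... Overrides of any field.
#' @return A named list (`RunConfig`).
#' @export
default_config <- function(...) {
  cfg <- list(seed = 1L, L = 211L, sublib_split = 107L, replicates = 2L,
              depth = 300, error_rate = 1e-3, pseudocount = 1,
              log_base = exp(1), k = 5L, m = 1, sided = "below",
              cutoff = 4.0, out_dir = NULL,
              stages = c("simulate", "count", "fitness", "select"))
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Run the synthetic DMS pipeline
#'
#' Executes the requested stages in dependency order: simulate (NNS
#' library, planted effects, selection, reads for both conditions and every
#' replicate/sub-library), count (length filter, orientation, translation,
#' variant counting), fitness (CPM normalisation and mutational-cost
#' landscapes per replicate, then averaged) and select (functional-residue
#' rule). Outputs, when `out_dir` is set, are stamped with the config hash;
#' the run report records discard tallies, mu, sigma and the selection.
#' Identical config + seed gives identical outputs.
#'
#' @param config List from [default_config()].
#' @return A run report list: `config_hash`, `library`, `truth`,
#'   `landscapes` (per replicate), `landscape` (averaged), `selection`,
#'   `discards`, and per-stage outputs.
#' @export
run_pipeline <- function(config = default_config()) {
  stages <- config$stages
  report <- list(config = config, config_hash = config_hash(config))
  lib <- generate_nns_library(
    random_cds(config$L, seed = config$seed),
    sublibraries = list(c(1L, config$sublib_split),
                        c(config$sublib_split + 1L, config$L)))
  truth <- simulate_true_effects(lib, seed = config$seed + 1L)
  report$library <- lib
  report$truth <- truth

  if ("count" %in% stages || "fitness" %in% stages) {
    counts <- list()
    for (rep_i in seq_len(config$replicates)) {
      for (sl in seq_along(lib$sublibraries)) {
        range <- lib$sublibraries[[sl]]
        pre <- library_frequencies(lib, positions = seq(range[1], range[2]))
        pre$replicate <- rep_i
        post <- simulate_selection(pre, truth)
        seed_base <- config$seed + 1000L * rep_i + 10L * sl
        pre$condition <- "unselected"
        rs_unsel <- simulate_reads(pre, lib, sublibrary = sl,
                                   depth = config$depth,
                                   error_rate = config$error_rate,
                                   seed = seed_base)
        rs_sel <- simulate_reads(post, lib, sublibrary = sl,
                                 depth = config$depth,
                                 error_rate = config$error_rate,
                                 seed = seed_base + 1L)
        counts[[paste(rep_i, sl, "unselected")]] <- count_reads(rs_unsel, lib)
        counts[[paste(rep_i, sl, "selected")]] <- count_reads(rs_sel, lib)
      }
    }
    report$counts <- counts
    report$discards <- Reduce(`+`, lapply(counts, `[[`, "discarded"))
  }

  if ("fitness" %in% stages) {
    landscapes <- list()
    for (rep_i in seq_len(config$replicates)) {
      per_sl <- lapply(seq_along(lib$sublibraries), function(sl) {
        sel <- normalize_cpm(report$counts[[paste(rep_i, sl, "selected")]],
                             pseudocount = config$pseudocount)
        unsel <- normalize_cpm(report$counts[[paste(rep_i, sl, "unselected")]],
                               pseudocount = config$pseudocount)
        compute_fitness(sel, unsel, log_base = config$log_base)
      })
      landscapes[[rep_i]] <- concat_landscapes(per_sl)
      landscapes[[rep_i]]$replicate <- rep_i
    }
    report$landscapes <- landscapes
    report$landscape <- average_replicates(landscapes)
  }

  if ("select" %in% stages) {
    if (is.null(report$landscape)) stop("select stage requires fitness stage")
    report$selection <- select_functional_residues(
      report$landscape, k = config$k, m = config$m, sided = config$sided)
  }

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    stamp <- function(f) file.path(config$out_dir, f)
    if (!is.null(report$landscape)) {
      write_landscape_tsv(report$landscape, stamp("landscape_mean.tsv"))
      write_mavedb_scores(report$landscape, stamp("scores_mavedb.csv"))
      export_heatmap_matrix(report$landscape, stamp("heatmap_matrix.tsv"))
    }
    if (!is.null(report$selection)) {
      sel <- report$selection
      utils::write.table(
        data.frame(position = as.integer(names(sel$qualifying)),
                   qualifying_mutations = sel$qualifying,
                   selected = as.integer(names(sel$qualifying)) %in%
                     sel$selected_positions),
        stamp("selection.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    }
    summary <- list(
      config_hash = report$config_hash,
      discards = as.list(report$discards %||% NULL),
      mu = report$selection$mu %||% NA,
      sigma = report$selection$sigma %||% NA,
      n_selected = length(report$selection$selected_positions %||% integer(0)))
    jsonlite::write_json(summary, stamp("run_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

#' Export a fitness landscape as a heat-map matrix
#'
#' 21 rows (substitutions, alphabet order with stop last) by L columns
#' (positions, N- to C-terminus). Wild-type identity cells are 0; cells
#' with no coverage are written as `"X"`.
#'
#' @param landscape A `FitnessLandscape`.
#' @param path Optional TSV output path.
#' @return The 21 x L numeric matrix (NA for no coverage), invisibly if
#'   written.
#' @export
export_heatmap_matrix <- function(landscape, path = NULL) {
  m <- t(landscape$delta_E)  # 21 x L
  if (!is.null(path)) {
    out <- format(m, digits = 10, trim = TRUE)
    out[is.na(m)] <- "X"
    df <- data.frame(aa = rownames(m), out, check.names = FALSE)
    colnames(df) <- c("aa", colnames(m))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(m))
  }
  m
}

#' Read a heat-map matrix written by [export_heatmap_matrix()]
#'
#' @param path TSV file.
#' @return A 21 x L numeric matrix with `NA` for `"X"` cells.
#' @export
read_heatmap_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, colClasses = "character")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m[m == "X"] <- NA
  storage.mode(m) <- "numeric"
  m
}
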