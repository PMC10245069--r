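#!/usr/bin/env Rscript
# Stage 3: functional-residue selection from the deposited-style score file
# written by stage 2, under both sidedness conventions, and comparison with
# the planted truth.
#
# Reading the scores back through the MaveDB-style CSV exercises the same
# loader a reader would use on a downloaded score set.

library(mlascan)

seed <- 1L
scores_csv <- "results/dms/scores_mavedb.csv"
if (!file.exists(scores_csv))
  stop("run analysis/02_fitness_landscape.R first")

fl <- read_mavedb_scores(scores_csv, L = 211)

for (sided in c("below", "two_sided")) {
  s <- select_functional_residues(fl, k = 5, m = 1, sided = sided)
  cat(sprintf("%-10s selection: %d residues\n", sided,
              length(s$selected_positions)))
}

sel <- select_functional_residues(fl, k = 5, m = 1, sided = "below")

# planted truth is cheap to regenerate (no read simulation involved)
lib <- generate_nns_library(random_cds(211, seed = seed),
                            sublibraries = list(c(1L, 107L), c(108L, 211L)))
truth <- simulate_true_effects(lib, seed = seed + 1L)
critical <- as.integer(names(which(attr(truth, "position_class") == "critical")))

ov <- overlap_with_dms(sel$selected_positions, critical)
cat(sprintf("selected %d residues; %d of %d planted critical positions recovered\n",
            ov$n_fp, ov$n_overlap, ov$n_hits))

writeLines(as.character(sel$selected_positions), "results/dms_hits.txt")
cat("wrote results/dms_hits.txt\n")
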