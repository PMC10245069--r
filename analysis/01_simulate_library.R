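#!/usr/bin/env Rscript
# Stage 1: build the site-saturation NNS library and the planted ground
# truth for the synthetic selection experiment.
#
# The study conditions: a 211-residue protein, every codon mutagenised with
# an NNS codon (32 codons -> 19 aa + stop beyond the wild type at each
# position), split into two amplicon sub-libraries (positions 1-107 and
# 108-211), two biological replicates downstream.

library(mlascan)

dir.create("results", showWarnings = FALSE)
seed <- 1L

lib <- generate_nns_library(random_cds(211, seed = seed),
                            sublibraries = list(c(1L, 107L), c(108L, 211L)))
print(lib)
stopifnot(nrow(lib$variants) == 4220)

truth <- simulate_true_effects(lib, seed = seed + 1L)
cls <- attr(truth, "position_class")
cat("planted position classes:\n")
print(table(cls))

write_wt_fasta(lib, cds_path = "results/wt_cds.fasta",
               protein_path = "results/wt_protein.fasta")

# exemplar read set (down-sampled to 5x so the FASTQ stays small; the full
# 300x sets are regenerated deterministically inside stage 2)
pre <- library_frequencies(lib, positions = 1:107)
rs <- simulate_reads(pre, lib, sublibrary = 1, depth = 5, error_rate = 1e-3,
                     seed = seed + 10L)
write_fastq(rs, "results/example_reads_sub1_5x.fastq.gz")
cat("wrote", length(rs$reads), "example reads for sub-library 1\n")

# ground truth as TSV for downstream comparison
df <- data.frame(position = as.integer(rownames(truth)[row(truth)]),
                 aa = colnames(truth)[col(truth)],
                 true_effect = as.vector(truth))
write.table(df[order(df$position, df$aa), ], "results/true_effects.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("wrote results/true_effects.tsv\n")
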