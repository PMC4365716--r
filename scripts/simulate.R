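#!/usr/bin/env Rscript

# Thin command-line wrapper around the synthetic-data generator: writes a
# linear-scale expression matrix (TSV), a sample sheet, and the ground-truth
# table for a simulated multi-group experiment at the default settings.
#
# Usage: Rscript scripts/simulate.R --seed <int> --n-probes <int> --out <dir>

suppressPackageStartupMessages(library(lineageRank))

args <- commandArgs(trailingOnly = TRUE)
get_arg <- function(flag, default = NULL) {
  i <- which(args == flag)
  if (length(i) == 1L && i < length(args)) args[i + 1L] else default
}
seed <- as.integer(get_arg("--seed", "1"))
n_probes <- as.integer(get_arg("--n-probes", "5000"))
out_dir <- get_arg("--out", "simulated")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

sim <- generate_dataset(simulation_config(n_probes = n_probes), seed = seed)
write_expression_matrix(sim$matrix, file.path(out_dir, "matrix.tsv"))
write_sample_sheet(sim$sheet, file.path(out_dir, "samples.tsv"))
utils::write.table(sim$truth, file.path(out_dir, "truth.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("wrote matrix.tsv, samples.tsv, truth.tsv to", out_dir, "\n")
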