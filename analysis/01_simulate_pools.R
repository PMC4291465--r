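#!/usr/bin/env Rscript
# Simulate the two pooled screens: a chronological-lifespan (quiescence)
# time course sampled at 0/4/8/12/14 weeks and a competitive-growth time
# course sampled at 120-550 minutes, two biological replicates each, with
# known per-mutant ground truth. Writes truth tables, count matrices and
# sample sheets under results/sim/.

suppressPackageStartupMessages(library(barseqls))
out <- "results/sim"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 2026L

for (mode in c("cls", "growth")) {
  cfg <- sim_config(n_genes = 1000, mode = mode, depth = 1e6, seed = seed)
  truth <- simulate_trajectories(cfg)
  cm <- sample_counts(truth)
  write_sim_truth(truth, file.path(out, paste0(mode, "_truth.tsv")))
  write_tag_table(truth$tags, file.path(out, paste0(mode, "_tags.tsv")))
  write_count_matrix(cm, file.path(out, paste0(mode, "_counts.tsv")),
                     file.path(out, paste0(mode, "_samples.tsv")))
  rate_col <- if (mode == "cls") "survival" else "advantage"
  message(sprintf(
    "%s pool: %d mutants (%d tags), %d samples at depth %g; %s range [%.3g, %.3g]",
    mode, cfg$n_genes, nrow(truth$tags), ncol(cm$counts), cfg$depth,
    rate_col, min(truth$genes[[rate_col]]), max(truth$genes[[rate_col]])))
}
message("wrote ", out)
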