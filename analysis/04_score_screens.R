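#!/usr/bin/env Rscript
# Score both simulated screens from the count tables written by
# 01_simulate_pools.R: per-gene lifespan and growth scores, long-lived /
# short-lived calls, agreement with a replicate re-run of the lifespan
# screen, growth-vs-lifespan correlation, and a hypergeometric enrichment
# of the truly long-lived mutants among the calls.

suppressPackageStartupMessages(library(barseqls))
sim <- "results/sim"
if (!dir.exists(sim)) stop("run analysis/01_simulate_pools.R first")
out <- "results/scores"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfgs <- scoring_config()
read_screen <- function(mode) {
  read_count_matrix(file.path(sim, paste0(mode, "_counts.tsv")),
                    file.path(sim, paste0(mode, "_samples.tsv")))
}

ls_scores <- score_genes(read_screen("cls"), cfgs, mode = "lifespan")
write_score_table(ls_scores, file.path(out, "lifespan_scores.tsv"))
sets <- call_sets(ls_scores)
writeLines(sets$long_lived, file.path(out, "long_lived.txt"))
message(sprintf(
  "lifespan: %d scored genes; %d long-lived (score > %.2f), %d flagged short-lived (< %.2f)",
  sum(!is.na(ls_scores$score)), length(sets$long_lived),
  cfgs$long_lived_threshold, length(sets$flagged_short),
  cfgs$short_lived_threshold))

gr_scores <- score_genes(read_screen("growth"), cfgs, mode = "growth")
write_score_table(gr_scores, file.path(out, "growth_scores.tsv"))
message(sprintf("growth: %d scored genes", sum(!is.na(gr_scores$score))))

# an independent technical re-run of the lifespan screen (fresh sampling
# noise over the same truth) plays the role of a confirmatory screen
truth <- simulate_trajectories(sim_config(n_genes = 1000, depth = 1e6,
                                          seed = 2026L))
rerun_truth <- truth
rerun_truth$cfg$seed <- 4052L
rerun <- score_genes(sample_counts(rerun_truth), cfgs, mode = "lifespan")
cmp <- compare_screens(sets$long_lived, call_sets(rerun)$long_lived)
message(sprintf(
  "confirmatory re-run recovers %d of %d long-lived calls (%.0f%%; Jaccard %.2f)",
  cmp$overlap, length(sets$long_lived), 100 * cmp$fraction_of_a, cmp$jaccard))

ct <- correlate_scores(ls_scores, gr_scores)
message(sprintf("growth vs lifespan: r = %.3f (n = %d, P = %.2g) — no coupling between the simulated traits",
                ct$r, ct$n, ct$p))

scored <- ls_scores$gene_id[!is.na(ls_scores$score)]
truly_long <- intersect(truth$genes$gene_id[truth$genes$survival == 1], scored)
enr <- enrichment_test(intersect(sets$long_lived, scored), truly_long, scored)
message(sprintf(
  "never-dying mutants among long-lived calls: %d/%d, %.1f-fold enrichment (P = %.3g)",
  enr$overlap, length(truly_long), enr$fold, enr$p))
message("wrote ", out)
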