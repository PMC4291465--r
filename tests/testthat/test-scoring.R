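# fold-changes, tag weighting, lifespan/growth scores, set operations

# two genes x two tags, one replicate, reference + two aged timepoints
basic_cm <- function(counts, timepoints = c(0, 4, 8), replicates = NULL,
                     unit = "weeks") {
  row_meta <- data.frame(gene_id = rep(c("gA", "gB"), each = 2),
                         tag_kind = rep(c("dn", "up"), 2))
  manual_count_matrix(counts, row_meta, timepoints, unit, replicates)
}

test_that("fold-changes are depth-normalized ratios with read-count filtering", {
  # rows: gA dn, gA up, gB dn, gB up
  counts <- matrix(c(100, 50, 1000, 1000,    # t0
                     9, 100, 1000, 2000,     # t4: gA up doubles, gA dn dies
                     100, 50, 1000, 1000),   # t8
                   nrow = 4,
                   dimnames = list(NULL, c("s0", "s4", "s8")))
  depths <- colSums(counts)
  cm <- basic_cm(counts)
  wfc <- weighted_fold_changes(cm, scoring_config())
  a4 <- wfc[wfc$gene_id == "gA" & wfc$timepoint == 4, ]
  expect_equal(a4$fc_up, (100 / depths["s4"]) / (50 / depths["s0"]),
               ignore_attr = TRUE)
  expect_true(is.na(a4$fc_dn))       # 9 reads < 10 -> excluded
  expect_equal(a4$w_up, 1)           # single valid tag takes all the weight
  a8 <- wfc[wfc$gene_id == "gA" & wfc$timepoint == 8, ]
  expect_equal(a8$fc_up, 1)          # same pool proportion as reference
  expect_equal(a8$fc_combined, 1)
})

test_that("a missing or empty reference sample is an error", {
  counts <- matrix(10, nrow = 4, ncol = 2, dimnames = list(NULL, c("a", "b")))
  row_meta <- data.frame(gene_id = c("gA", "gA", "gB", "gB"),
                         tag_kind = c("dn", "up", "dn", "up"))
  samples <- rbind(sample_meta("a", 1, 4, "weeks", "aged"),
                   sample_meta("b", 1, 8, "weeks", "aged"))
  expect_error(
    weighted_fold_changes(barseqls:::new_count_matrix(counts, row_meta, samples)),
    "reference")
})

test_that("tag weighting follows the read-sum formula and its edge cases", {
  # symmetric counts: equal weights, combined fc is the plain mean
  sym <- weighted_combine(10, 10, 10, 10, fc_up = 2, fc_dn = 4)
  expect_equal(sym$w_up, 0.5)
  expect_equal(sym$fc_combined, 3.0)

  # hand evaluation: w_up = (30+10)/(30+10+10+10) = 2/3
  hand <- weighted_combine(30, 10, 10, 10, fc_up = 3, fc_dn = 1)
  expect_equal(hand$w_up, 2 / 3)
  expect_equal(hand$fc_combined, 7 / 3)

  only_up <- weighted_combine(30, 0, 10, 0, fc_up = 3, fc_dn = NA)
  expect_equal(only_up$w_up, 1)
  expect_equal(only_up$fc_combined, 3)

  neither <- weighted_combine(5, 5, 5, 5, fc_up = NA, fc_dn = NA)
  expect_false(neither$valid)
})

test_that("weights are a partition of unity and the combination is convex", {
  set.seed(8)
  for (i in 1:50) {
    counts <- matrix(rpois(12, 400) + 10L, nrow = 4,
                     dimnames = list(NULL, c("s0", "s4", "s8")))
    cm <- basic_cm(counts)
    wfc <- weighted_fold_changes(cm, scoring_config())
    both <- !is.na(wfc$fc_up) & !is.na(wfc$fc_dn)
    expect_true(all(abs(wfc$w_up[both] + wfc$w_dn[both] - 1) < 1e-12))
    expect_true(all(wfc$w_up[both] >= 0 & wfc$w_up[both] <= 1))
    expect_true(all(wfc$fc_combined[both] >= pmin(wfc$fc_up, wfc$fc_dn)[both] - 1e-12))
    expect_true(all(wfc$fc_combined[both] <= pmax(wfc$fc_up, wfc$fc_dn)[both] + 1e-12))
  }
})

test_that("scores are the replicate-mean of per-replicate timepoint medians", {
  # oracle: brute-force median/mean over the enumerated fc lists
  wfc <- data.frame(
    gene_id = "gA",
    replicate = rep(1:2, each = 3),
    timepoint = rep(c(4, 8, 12), 2),
    fc_up = NA, fc_dn = NA, w_up = NA, w_dn = NA,
    fc_combined = c(1.7, 1.8, 1.9, 1.1, 1.2, 1.3),
    valid = TRUE
  )
  st <- score_from_weighted(wfc, scoring_config(), mode = "lifespan")
  expect_equal(st$score, mean(c(median(c(1.7, 1.8, 1.9)), median(c(1.1, 1.2, 1.3)))))
  expect_equal(st$score, 1.5)
  expect_equal(st$call, "long_lived")  # 1.5 > 1.44
  expect_false(st$single_replicate)

  # one replicate entirely invalid: single-replicate score, flagged
  wfc$valid[4:6] <- FALSE
  st1 <- score_from_weighted(wfc, scoring_config())
  expect_equal(st1$score, 1.8)
  expect_true(st1$single_replicate)

  # nothing valid anywhere: not scored
  wfc$valid <- FALSE
  st0 <- score_from_weighted(wfc, scoring_config())
  expect_true(is.na(st0$score))
  expect_equal(st0$call, "not_scored")
})

test_that("constant pool proportions give score 1 and an intermediate call", {
  counts <- matrix(rep(c(200, 300, 500, 400), 3), nrow = 4,
                   dimnames = list(NULL, c("s0", "s4", "s8")))
  st <- score_genes(basic_cm(counts), scoring_config(), mode = "lifespan")
  expect_equal(st$score, c(1, 1))
  expect_equal(st$call, c("intermediate", "intermediate"))
})

test_that("genes below the read floor at all timepoints are not scored", {
  counts <- matrix(c(9, 9, 500, 400,
                     9, 9, 600, 500,
                     9, 9, 700, 600), nrow = 4,
                   dimnames = list(NULL, c("s0", "s4", "s8")))
  st <- score_genes(basic_cm(counts), scoring_config(), mode = "lifespan")
  expect_equal(st$call[st$gene_id == "gA"], "not_scored")
  expect_false(is.na(st$score[st$gene_id == "gB"]))
})

test_that("calls use strict thresholds and sets come ordered by score", {
  st <- data.frame(gene_id = c("A", "B", "C"), score = c(1.45, 1.44, 0.13))
  class(st) <- c("score_table", "data.frame")
  sets <- call_sets(st, scoring_config())
  expect_equal(sets$long_lived, "A")
  expect_equal(sets$flagged_short, "C")

  empty <- st[0, ]
  sets0 <- call_sets(empty, scoring_config())
  expect_length(sets0$long_lived, 0L)
  expect_length(sets0$flagged_short, 0L)
})

test_that("screen comparison reports overlap, Jaccard, and B-only genes", {
  cmp <- compare_screens(c("x", "y"), c("y", "z"))
  expect_equal(cmp$overlap, 1L)
  expect_equal(cmp$jaccard, 1 / 3)
  expect_equal(cmp$unique_to_b, "z")

  same <- compare_screens(letters[1:5], letters[1:5])
  expect_equal(same$overlap, 5L)
  expect_equal(same$jaccard, 1)

  expect_equal(compare_screens(c("a", "b"), c("c", "d"))$overlap, 0L)
})

test_that("score correlation matches cor.test and enforces the n floor", {
  mk <- function(ids, s) {
    df <- data.frame(gene_id = ids, score = s)
    class(df) <- c("score_table", "data.frame")
    df
  }
  x <- c(0.2, 0.8, 1.1, 1.9, 0.5)
  a <- mk(letters[1:5], x)
  expect_equal(correlate_scores(a, a)$r, 1.0)
  b <- mk(letters[1:5], -x)
  expect_equal(correlate_scores(a, b)$r, -1.0)
  expect_error(correlate_scores(a[1:2, ], a), "fewer than 3")

  set.seed(3)
  g <- mk(letters[1:5], rnorm(5))
  got <- correlate_scores(a, g)
  ct <- cor.test(x, g$score)
  expect_equal(got$r, unname(ct$estimate))
  expect_equal(got$p, ct$p.value)

  filt <- correlate_scores(mk(letters[1:5], c(0.2, 0.8, 1.1, 1.9, 0.5)), g,
                           min_lifespan = 0.4)
  expect_equal(filt$n, 4L)
})

test_that("hypergeometric enrichment matches exact combinatorics", {
  u <- sprintf("g%03d", 1:100)
  sat <- enrichment_test(u, u, u)
  expect_equal(sat$p, 1)
  expect_equal(sat$fold, 1)

  # all 10 hits inside a 10-gene category: P = 1 / C(100, 10)
  res <- enrichment_test(u[1:10], u[1:10], u)
  expect_equal(res$p, 1 / choose(100, 10))
  expect_equal(res$fold, 10)

  none <- enrichment_test(u[1:10], u[11:90], u)
  expect_equal(none$overlap, 0L)
  expect_equal(none$fold, 0)
  expect_gt(none$p, 0.99)

  expect_error(enrichment_test("a", "a", character(0)), "empty universe")
  expect_error(enrichment_test("zz", u[1:5], u), "subsets")
})

test_that("scores ignore sample and gene ordering", {
  cfg <- sim_config(n_genes = 40, depth = 5e4, seed = 13)
  cm <- sample_counts(simulate_trajectories(cfg))
  st <- score_genes(cm, scoring_config())

  perm_s <- sample(ncol(cm$counts))
  perm_g <- sample(nrow(cm$counts))
  cm2 <- barseqls:::new_count_matrix(cm$counts[perm_g, perm_s],
                                     cm$row_meta[perm_g, ],
                                     cm$samples[perm_s, ])
  st2 <- score_genes(cm2, scoring_config())
  expect_equal(st2, st, ignore_attr = TRUE)
})

test_that("normalized-weight scores are invariant to per-sample depth rescaling", {
  cfg <- sim_config(n_genes = 40, depth = 5e4, seed = 29)
  cm <- sample_counts(simulate_trajectories(cfg))
  # clear the read floor so rescaling cannot change which tags are valid
  cm$counts[cm$counts > 0 & cm$counts < 10] <- 0L
  cm <- barseqls:::new_count_matrix(cm$counts, cm$row_meta, cm$samples)
  cfg_n <- scoring_config(weight_mode = "normalized")
  st <- score_genes(cm, cfg_n)

  scaled <- cm$counts
  scaled[, 3] <- scaled[, 3] * 5L
  scaled[, 7] <- scaled[, 7] * 2L
  cm2 <- barseqls:::new_count_matrix(scaled, cm$row_meta, cm$samples)
  st2 <- score_genes(cm2, cfg_n)
  expect_equal(st2$score, st$score, tolerance = 1e-12)
})

test_that("score tables round-trip through TSV", {
  cfg <- sim_config(n_genes = 20, depth = 2e4, seed = 31)
  st <- score_genes(sample_counts(simulate_trajectories(cfg)), scoring_config())
  path <- withr::local_tempfile(fileext = ".tsv")
  write_score_table(st, path)
  back <- read_score_table(path)
  expect_equal(back$gene_id, st$gene_id)
  expect_equal(back$score, st$score, tolerance = 1e-9)
  expect_equal(back$call, st$call)
})
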