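#' Scoring configuration
#'
#' Tunable parameters of the lifespan/growth scoring procedure.
#'
#' @param min_reads Minimum raw reads for a tag at a timepoint (including the
#'   reference) to be used; tag-timepoints below it are excluded (default 10).
#' @param long_lived_threshold Score strictly above which a gene is called
#'   long-lived (default 1.44).
#' @param short_lived_threshold Score strictly below which a gene is flagged
#'   short-lived/sick (default 0.14).
#' @param min_valid_timepoints Minimum valid non-reference timepoints a
#'   replicate must contribute to enter the score (default 1).
#' @param weight_mode `"raw"`: tag weights computed from raw read counts, as
#'   in the printed weighting formula; `"normalized"`: the same formula on
#'   depth-normalized counts, which makes scores exactly invariant to
#'   per-sample depth rescaling.
#' @return A list of class `scoring_config`.
#' @export
scoring_config <- function(min_reads = 10L,
                           long_lived_threshold = 1.44,
                           short_lived_threshold = 0.14,
                           min_valid_timepoints = 1L,
                           weight_mode = c("raw", "normalized")) {
  weight_mode <- match.arg(weight_mode)
  stopifnot(min_reads >= 0, long_lived_threshold > 0, short_lived_threshold > 0,
            min_valid_timepoints >= 1)
  structure(list(min_reads = as.integer(min_reads),
                 long_lived_threshold = long_lived_threshold,
                 short_lived_threshold = short_lived_threshold,
                 min_valid_timepoints = as.integer(min_valid_timepoints),
                 weight_mode = weight_mode),
            class = "scoring_config")
}

# per-gene count matrices for one tag kind (genes x samples; NA where the
# gene has no decoded tag of that kind)
tag_matrix <- function(cm, kind, genes) {
  rows <- cm$row_meta$tag_kind == kind
  m <- matrix(NA_real_, nrow = length(genes), ncol = ncol(cm$counts),
              dimnames = list(genes, colnames(cm$counts)))
  m[match(cm$row_meta$gene_id[rows], genes), ] <- cm$counts[rows, , drop = FALSE]
  m
}

#' Depth-normalized fold-changes and weighted tag combination
#'
#' For every (gene, replicate, non-reference timepoint): each tag's reads
#' are normalized by the sample's matched-read depth and divided by the
#' reference timepoint's normalized value, giving `fc_up`/`fc_dn`. A
#' tag-timepoint is valid only when both its own and its reference raw count
#' reach `min_reads` (an undetected reference makes the ratio undefined).
#' When both tags are valid they are combined as a weighted mean,
#' `w_up = (Up_i + Up_0) / (Up_i + Dn_i + Up_0 + Dn_0)` and
#' `fc_combined = w_up * fc_up + w_dn * fc_dn`; with a single valid tag its
#' weight is 1.
#'
#' @param cm A `count_matrix` whose sample sheet marks one reference sample
#'   per replicate.
#' @param cfg A [scoring_config()].
#' @return data.frame (one row per gene x replicate x non-reference
#'   timepoint): `gene_id`, `replicate`, `timepoint`, `fc_up`, `fc_dn`,
#'   `w_up`, `w_dn`, `fc_combined`, `valid`.
#' @export
weighted_fold_changes <- function(cm, cfg = scoring_config()) {
  stopifnot(inherits(cm, "count_matrix"))
  validate_sample_sheet(cm$samples)
  genes <- sort(unique(cm$row_meta$gene_id))
  U <- tag_matrix(cm, "up", genes)
  D <- tag_matrix(cm, "dn", genes)
  depth <- cm$depth

  out <- list()
  for (r in sort(unique(cm$samples$replicate))) {
    smp <- cm$samples[cm$samples$replicate == r, , drop = FALSE]
    ref_id <- smp$sample_id[smp$role == "reference"]
    if (depth[ref_id] <= 0) stop(sprintf("replicate %s reference sample has zero depth", r))
    aged <- smp[smp$role != "reference", , drop = FALSE]
    for (k in seq_len(nrow(aged))) {
      sid <- aged$sample_id[k]
      res <- combine_tags(U[, sid], D[, sid], U[, ref_id], D[, ref_id],
                          depth[sid], depth[ref_id], cfg)
      out[[length(out) + 1L]] <- data.frame(
        gene_id = genes, replicate = r, timepoint = aged$timepoint[k],
        res, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# vectorized over genes for one (sample, reference) pair
combine_tags <- function(up_i, dn_i, up_0, dn_0, depth_i, depth_0, cfg) {
  valid_up <- !is.na(up_i) & up_i >= cfg$min_reads & !is.na(up_0) & up_0 >= cfg$min_reads
  valid_dn <- !is.na(dn_i) & dn_i >= cfg$min_reads & !is.na(dn_0) & dn_0 >= cfg$min_reads
  fc_up <- ifelse(valid_up, (up_i / depth_i) / (up_0 / depth_0), NA_real_)
  fc_dn <- ifelse(valid_dn, (dn_i / depth_i) / (dn_0 / depth_0), NA_real_)

  if (cfg$weight_mode == "raw") {
    wu_num <- up_i + up_0
    wd_num <- dn_i + dn_0
  } else {
    wu_num <- up_i / depth_i + up_0 / depth_0
    wd_num <- dn_i / depth_i + dn_0 / depth_0
  }
  w_up <- rep(NA_real_, length(up_i))
  both <- valid_up & valid_dn
  w_up[both] <- wu_num[both] / (wu_num[both] + wd_num[both])
  w_up[valid_up & !valid_dn] <- 1
  w_up[!valid_up & valid_dn] <- 0
  w_dn <- 1 - w_up

  fc_combined <- rep(NA_real_, length(up_i))
  fc_combined[both] <- w_up[both] * fc_up[both] + w_dn[both] * fc_dn[both]
  fc_combined[valid_up & !valid_dn] <- fc_up[valid_up & !valid_dn]
  fc_combined[!valid_up & valid_dn] <- fc_dn[!valid_up & valid_dn]

  data.frame(fc_up = fc_up, fc_dn = fc_dn, w_up = w_up, w_dn = w_dn,
             fc_combined = fc_combined, valid = valid_up | valid_dn)
}

#' Weighted combination of one gene's two tags at one timepoint
#'
#' Scalar form of the tag-weighting step, useful for spot checks:
#' `w_up = (Up_i + Up_0) / (Up_i + Dn_i + Up_0 + Dn_0)` (raw-count mode) and
#' `fc_combined = w_up * fc_up + (1 - w_up) * fc_dn`. `NA` fold-changes mark
#' invalid tags; with one valid tag its weight is 1, with none the result is
#' invalid.
#'
#' @param up_i,dn_i,up_0,dn_0 Raw read counts at timepoint i and reference.
#' @param fc_up,fc_dn Fold-changes of the two tags (`NA` = invalid tag).
#' @return One-row data.frame: `w_up`, `w_dn`, `fc_combined`, `valid`.
#' @export
weighted_combine <- function(up_i, dn_i, up_0, dn_0, fc_up, fc_dn) {
  valid_up <- !is.na(fc_up)
  valid_dn <- !is.na(fc_dn)
  if (!valid_up && !valid_dn) {
    return(data.frame(w_up = NA_real_, w_dn = NA_real_,
                      fc_combined = NA_real_, valid = FALSE))
  }
  if (valid_up && valid_dn) {
    w_up <- (up_i + up_0) / (up_i + dn_i + up_0 + dn_0)
  } else if (valid_up) {
    w_up <- 1
  } else {
    w_up <- 0
  }
  fc <- sum(c(w_up * fc_up, (1 - w_up) * fc_dn), na.rm = TRUE)
  data.frame(w_up = w_up, w_dn = 1 - w_up, fc_combined = fc, valid = TRUE)
}

#' Per-gene lifespan or growth scores
#'
#' Within each replicate the median of `fc_combined` over valid
#' non-reference timepoints is taken; the score is the mean of the replicate
#' medians over replicates with at least `min_valid_timepoints` valid
#' timepoints. Genes scorable in only one replicate are scored from it and
#' flagged. Calls use strict inequalities: long-lived when
#' score > `long_lived_threshold`, short-lived flag when
#' score < `short_lived_threshold`.
#'
#' @param cm A `count_matrix`.
#' @param cfg A [scoring_config()].
#' @param mode `"lifespan"` (reference t = 0 wk) or `"growth"` (reference
#'   t = 120 min); label only — the reference sample is whichever the sample
#'   sheet marks.
#' @return data.frame of class `score_table`, ordered by descending score:
#'   `gene_id`, `score`, per-replicate medians `median_rep<r>` and valid
#'   counts `n_valid_rep<r>`, `n_replicates_used`, `single_replicate`,
#'   `call` in {long_lived, short_lived_flag, intermediate, not_scored}.
#' @export
score_genes <- function(cm, cfg = scoring_config(),
                        mode = c("lifespan", "growth")) {
  mode <- match.arg(mode)
  wfc <- weighted_fold_changes(cm, cfg)
  score_from_weighted(wfc, cfg, mode)
}

#' Scores from a precomputed weighted fold-change table
#'
#' @param wfc Output of [weighted_fold_changes()].
#' @param cfg A [scoring_config()].
#' @param mode Score label (see [score_genes()]).
#' @return A `score_table` (see [score_genes()]).
#' @export
score_from_weighted <- function(wfc, cfg = scoring_config(),
                                mode = c("lifespan", "growth")) {
  mode <- match.arg(mode)
  reps <- sort(unique(wfc$replicate))
  genes <- sort(unique(wfc$gene_id))
  med <- matrix(NA_real_, length(genes), length(reps),
                dimnames = list(genes, as.character(reps)))
  nval <- matrix(0L, length(genes), length(reps),
                 dimnames = list(genes, as.character(reps)))
  ok <- wfc$valid & !is.na(wfc$fc_combined)
  for (j in seq_along(reps)) {
    sub <- wfc[ok & wfc$replicate == reps[j], c("gene_id", "fc_combined")]
    if (nrow(sub)) {
      agg_n <- tapply(sub$fc_combined, sub$gene_id, length)
      agg_m <- tapply(sub$fc_combined, sub$gene_id, stats::median)
      nval[names(agg_n), j] <- as.integer(agg_n)
      med[names(agg_m), j] <- agg_m
    }
  }
  use <- nval >= cfg$min_valid_timepoints
  med_use <- ifelse(use, med, NA_real_)
  n_used <- rowSums(use)
  score <- ifelse(n_used > 0, rowMeans(med_use, na.rm = TRUE), NA_real_)

  call <- rep("intermediate", length(genes))
  call[is.na(score)] <- "not_scored"
  call[!is.na(score) & score > cfg$long_lived_threshold] <- "long_lived"
  call[!is.na(score) & score < cfg$short_lived_threshold] <- "short_lived_flag"

  out <- data.frame(gene_id = genes, score = score, stringsAsFactors = FALSE)
  for (j in seq_along(reps)) {
    out[[paste0("median_rep", reps[j])]] <- med[, j]
    out[[paste0("n_valid_rep", reps[j])]] <- nval[, j]
  }
  out$n_replicates_used <- n_used
  out$single_replicate <- n_used == 1L
  out$call <- call
  out <- out[order(-out$score, out$gene_id, na.last = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "mode") <- mode
  attr(out, "config") <- cfg
  class(out) <- c("score_table", "data.frame")
  out
}

#' Long-lived and short-lived gene sets from a score table
#'
#' @param scores A `score_table`.
#' @param cfg A [scoring_config()] providing the thresholds.
#' @return List with `long_lived` and `flagged_short`, each a character
#'   vector of gene ids ordered by descending score.
#' @export
call_sets <- function(scores, cfg = attr(scores, "config") %||% scoring_config()) {
  sc <- scores[!is.na(scores$score), , drop = FALSE]
  sc <- sc[order(-sc$score, sc$gene_id), , drop = FALSE]
  list(
    long_lived = sc$gene_id[sc$score > cfg$long_lived_threshold],
    flagged_short = sc$gene_id[sc$score < cfg$short_lived_threshold]
  )
}

#' Overlap between two screens' hit sets
#'
#' @param set_a,set_b Character vectors of gene ids.
#' @return List: `overlap` (|A intersect B|), `jaccard`, `unique_to_b`,
#'   `fraction_of_a` (overlap / |A|).
#' @export
compare_screens <- function(set_a, set_b) {
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  ov <- length(intersect(set_a, set_b))
  un <- length(union(set_a, set_b))
  list(overlap = ov,
       jaccard = if (un > 0) ov / un else NA_real_,
       unique_to_b = sort(setdiff(set_b, set_a)),
       fraction_of_a = if (length(set_a)) ov / length(set_a) else NA_real_)
}

#' Correlate lifespan and growth scores
#'
#' Pearson correlation over genes scored in both tables (two-sided p from
#' the t approximation with n - 2 df, as in [stats::cor.test()]).
#'
#' @param lifespan,growth `score_table`s.
#' @param min_lifespan Optional floor: keep only genes with lifespan score
#'   strictly greater than this.
#' @return List: `n`, `r`, `p`.
#' @export
correlate_scores <- function(lifespan, growth, min_lifespan = NULL) {
  a <- lifespan[!is.na(lifespan$score), c("gene_id", "score")]
  if (!is.null(min_lifespan)) a <- a[a$score > min_lifespan, , drop = FALSE]
  b <- growth[!is.na(growth$score), c("gene_id", "score")]
  m <- merge(a, b, by = "gene_id", suffixes = c("_ls", "_gr"))
  if (nrow(m) < 3L) stop("fewer than 3 genes with both scores")
  ct <- stats::cor.test(m$score_ls, m$score_gr, method = "pearson")
  list(n = nrow(m), r = unname(ct$estimate), p = ct$p.value)
}

#' Hypergeometric gene-set enrichment
#'
#' One-sided upper-tail test for the observed overlap between a hit set and
#' a functional category within a gene universe, plus fold enrichment
#' (observed / expected overlap).
#'
#' @param hits,category,universe Character vectors of gene ids;
#'   `hits` and `category` must be subsets of `universe`.
#' @return List: `overlap`, `expected`, `fold`, `p`.
#' @export
enrichment_test <- function(hits, category, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe")
  hits <- unique(hits)
  category <- unique(category)
  if (!all(hits %in% universe) || !all(category %in% universe)) {
    stop("hits and category must be subsets of the universe")
  }
  obs <- length(intersect(hits, category))
  expected <- length(hits) * length(category) / length(universe)
  p <- stats::phyper(obs - 1L, length(category),
                     length(universe) - length(category), length(hits),
                     lower.tail = FALSE)
  fold <- if (expected > 0) obs / expected else NA_real_
  list(overlap = obs, expected = expected, fold = fold, p = p)
}

#' Write / read score tables
#'
#' @param scores A `score_table`.
#' @param path TSV path.
#' @return `path` (write) or a `score_table` (read).
#' @export
write_score_table <- function(scores, path) {
  utils::write.table(as.data.frame(scores), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_score_table
#' @param mode Score label to attach on read.
#' @export
read_score_table <- function(path, mode = c("lifespan", "growth")) {
  mode <- match.arg(mode)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  attr(df, "mode") <- mode
  class(df) <- c("score_table", "data.frame")
  df
}
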