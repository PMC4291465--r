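DEFAULT_SPACER <- "GTCGACCTGCAGCGTACGAAGCTTCA"  # 26-nt universal spacer

#' Simulator configuration
#'
#' Ground-truthed generator of pooled-mutant time courses. Defaults emulate
#' the screen design: ~10^3 mutants carrying up/dn tag pairs (presence mix
#' taken from observed decode yields), two biological replicates, five
#' timepoints (0/4/8/12/14 weeks for lifespan; 120/230/340/460/550 minutes
#' for growth), multinomial read sampling at a fixed per-sample depth, and
#' iid per-base substitution error. Initial pool proportions are log-normal
#' with `abundance_sdlog = 0.5` (a robotically pooled library with roughly
#' two-fold colony-to-colony evenness); per-gene weekly survival is a
#' mixture of a Beta-distributed bulk and a long-lived fraction that does
#' not die; growth mode instead draws a per-gene doubling-rate advantage.
#'
#' @param n_genes Number of mutants in the pool.
#' @param mode `"cls"` (quiescence aging) or `"growth"` (competitive
#'   proliferation).
#' @param p_both,p_up_only,p_dn_only Tag-presence mix (normalized
#'   internally); defaults 1871:254:348.
#' @param abundance_meanlog,abundance_sdlog Log-normal initial proportions.
#' @param survival_shape1,survival_shape2 Beta parameters of bulk weekly
#'   survival.
#' @param long_lived_fraction Fraction of genes with survival exactly 1.
#' @param growth_advantage_sd SD of the per-gene doubling-rate advantage
#'   (doublings per minute) in growth mode.
#' @param timepoints,unit Sampling design; defaults depend on `mode`.
#' @param replicates Number of biological replicates.
#' @param depth Matched reads per sample.
#' @param tag_bias_shape Symmetric Beta shape for the per-gene up:dn read
#'   split (larger = more even).
#' @param error_rate Per-base substitution probability in emitted reads
#'   (must be < 0.25).
#' @param reads_per_tag Decode-run reads generated per tag.
#' @param seed Integer seed; all simulator randomness flows from it.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_genes = 1000L,
                       mode = c("cls", "growth"),
                       p_both = 1871, p_up_only = 254, p_dn_only = 348,
                       abundance_meanlog = 0, abundance_sdlog = 0.5,
                       survival_shape1 = 8, survival_shape2 = 2,
                       long_lived_fraction = 0.05,
                       growth_advantage_sd = 8e-4,
                       timepoints = NULL, unit = NULL,
                       replicates = 2L,
                       depth = 1e6,
                       tag_bias_shape = 20,
                       error_rate = 0.001,
                       reads_per_tag = 20L,
                       seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(timepoints)) {
    timepoints <- if (mode == "cls") c(0, 4, 8, 12, 14) else c(120, 230, 340, 460, 550)
  }
  if (is.null(unit)) unit <- if (mode == "cls") "weeks" else "minutes"
  p <- c(p_both, p_up_only, p_dn_only)
  if (any(p < 0) || sum(p) <= 0) stop("invalid tag-presence mix")
  if (depth < 0) stop("depth must be non-negative")
  if (error_rate < 0 || error_rate >= 0.25) stop("error_rate must be in [0, 0.25)")
  if (n_genes < 2) stop("need at least 2 genes")
  structure(list(
    n_genes = as.integer(n_genes), mode = mode,
    p_tags = p / sum(p),
    abundance_meanlog = abundance_meanlog, abundance_sdlog = abundance_sdlog,
    survival_shape1 = survival_shape1, survival_shape2 = survival_shape2,
    long_lived_fraction = long_lived_fraction,
    growth_advantage_sd = growth_advantage_sd,
    timepoints = sort(timepoints), unit = unit,
    replicates = as.integer(replicates), depth = depth,
    tag_bias_shape = tag_bias_shape, error_rate = error_rate,
    reads_per_tag = as.integer(reads_per_tag),
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Simulate ground-truth pool trajectories
#'
#' Survival acts multiplicatively per week and pool proportions are
#' renormalized at every timepoint — Bar-seq measures relative abundance, so
#' `proportion_g(t) = p_g(0) * s_g^t / sum_h p_h(0) * s_h^t`. Growth mode
#' replaces `s_g^t` by `2^(advantage_g * t)`. Deterministic given the seed.
#'
#' @param cfg A [sim_config()].
#' @return List of class `sim_truth`: `genes` (data.frame: `gene_id`,
#'   `has_up`, `has_dn`, `up_fraction`, `p0`, `survival` or `advantage`),
#'   `proportions` (genes x timepoints matrix, columns named by timepoint),
#'   `tags` (a `tag_table` with random distinct barcodes and expected
#'   flanks), `cfg`.
#' @export
simulate_trajectories <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_genes
  gene_id <- sprintf("gene%04d", seq_len(n))

  tag_class <- sample(c("both", "up_only", "dn_only"), n, replace = TRUE,
                      prob = cfg$p_tags)
  has_up <- tag_class != "dn_only"
  has_dn <- tag_class != "up_only"
  up_fraction <- ifelse(
    has_up & has_dn,
    stats::rbeta(n, cfg$tag_bias_shape, cfg$tag_bias_shape),
    ifelse(has_up, 1, 0))

  p0 <- stats::rlnorm(n, cfg$abundance_meanlog, cfg$abundance_sdlog)
  p0 <- p0 / sum(p0)

  tp <- cfg$timepoints
  if (cfg$mode == "cls") {
    survival <- ifelse(stats::runif(n) < cfg$long_lived_fraction, 1,
                       stats::rbeta(n, cfg$survival_shape1, cfg$survival_shape2))
    logf <- outer(log(survival), tp)                  # log s_g^t
    rate <- survival
  } else {
    advantage <- stats::rnorm(n, 0, cfg$growth_advantage_sd)
    logf <- outer(advantage * log(2), tp)             # log 2^(a_g t)
    rate <- advantage
  }
  w <- exp(sweep(logf, 1, log(p0), `+`))
  props <- sweep(w, 2, colSums(w), `/`)
  colnames(props) <- as.character(tp)
  rownames(props) <- gene_id

  # distinct random barcodes and flanks for the decoded-tag table
  # distinct barcode and flank per tag: the two cassette junctions of a gene
  # carry different flanking genomic sequence
  n_tags <- sum(has_up) + sum(has_dn)
  tag_seqs <- unique(random_dna(n_tags * 2L, 20L))[seq_len(n_tags)]
  flanks <- unique(random_dna(n_tags * 2L, 33L))[seq_len(n_tags)]
  tags <- rbind(
    data.frame(gene_id = gene_id[has_up], tag_kind = "up",
               tag_seq = tag_seqs[seq_len(sum(has_up))],
               expected_flank = flanks[seq_len(sum(has_up))],
               stringsAsFactors = FALSE),
    data.frame(gene_id = gene_id[has_dn], tag_kind = "dn",
               tag_seq = tag_seqs[sum(has_up) + seq_len(sum(has_dn))],
               expected_flank = flanks[sum(has_up) + seq_len(sum(has_dn))],
               stringsAsFactors = FALSE)
  )
  tags <- as_tag_table(tags[order(tags$gene_id, tags$tag_kind), , drop = FALSE])

  genes <- data.frame(gene_id = gene_id, has_up = has_up, has_dn = has_dn,
                      up_fraction = up_fraction, p0 = p0,
                      stringsAsFactors = FALSE)
  genes[[if (cfg$mode == "cls") "survival" else "advantage"]] <- rate

  structure(list(genes = genes, proportions = props, tags = tags, cfg = cfg),
            class = "sim_truth")
}

#' Multinomial read counts from a simulated truth
#'
#' Each sample (replicate x timepoint) draws `depth` reads from a
#' multinomial over (gene, tag) cells with probabilities
#' `proportion_g(t) * tag split`. Replicates share the expected trajectory
#' and differ by independent sampling noise. The first timepoint is the
#' reference; sample `r<rep>_t<tp>` gets multiplex index `(sequential)`.
#'
#' @param truth A `sim_truth`.
#' @return A `count_matrix` whose rows cover every simulated tag.
#' @export
sample_counts <- function(truth) {
  cfg <- truth$cfg
  set.seed(cfg$seed + 1L)
  tags <- truth$tags
  gi <- match(tags$gene_id, truth$genes$gene_id)
  split_frac <- ifelse(tags$tag_kind == "up",
                       truth$genes$up_fraction[gi],
                       1 - truth$genes$up_fraction[gi])

  tp <- cfg$timepoints
  samples <- do.call(rbind, lapply(seq_len(cfg$replicates), function(r) {
    do.call(rbind, lapply(seq_along(tp), function(k) {
      sample_meta(sprintf("r%d_t%s", r, tp[k]), r, tp[k], cfg$unit,
                  if (k == 1L) "reference" else "aged",
                  index_id = as.character(((r - 1L) * length(tp) + k - 1L) %% 20L + 1L))
    }))
  }))

  m <- matrix(0L, nrow = nrow(tags), ncol = nrow(samples),
              dimnames = list(NULL, samples$sample_id))
  for (j in seq_len(nrow(samples))) {
    pr <- truth$proportions[gi, as.character(samples$timepoint[j])] * split_frac
    pr <- pr / sum(pr)
    if (cfg$depth > 0) {
      m[, j] <- as.integer(stats::rmultinom(1L, size = cfg$depth, prob = pr))
    }
  }
  new_count_matrix(m, data.frame(gene_id = tags$gene_id,
                                 tag_kind = tags$tag_kind,
                                 stringsAsFactors = FALSE),
                   samples)
}

# sparse per-base substitution: draw the number of erroneous bases per read,
# then mutate only affected reads
mutate_reads <- function(seqs, width, error_rate) {
  if (error_rate <= 0 || length(seqs) == 0L) return(seqs)
  n_err <- stats::rbinom(length(seqs), width, error_rate)
  hit <- which(n_err > 0L)
  for (i in hit) {
    ch <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    pos <- sample.int(width, n_err[i])
    ch[pos] <- vapply(ch[pos], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1L)
    }, character(1))
    seqs[i] <- paste(ch, collapse = "")
  }
  seqs
}

write_fastq <- function(seqs, path, prefix = "read") {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- sprintf("%s%06d", prefix, seq_along(seqs))
  qual <- Biostrings::BStringSet(strrep("I", Biostrings::width(x)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' Emit 50-cycle counting-run FASTQ files from a count matrix
#'
#' Every counted read becomes one 50-nt read: the first 50 nt of the
#' database entry for (gene, tag, sample's multiplex index), with iid
#' substitutions at the configured error rate. One FASTQ per sample,
#' deterministic given the seed.
#'
#' @param cm A `count_matrix` (e.g. from [sample_counts()]).
#' @param db A `barcode_db` covering every counted (gene, tag) at the
#'   samples' indexes.
#' @param cfg A [sim_config()] (for `error_rate` and `seed`).
#' @param dir Output directory.
#' @return Named character vector of FASTQ paths (by sample_id).
#' @export
emit_fastq <- function(cm, db, cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed + 2L)
  ekey <- paste(db$entries$gene_id, db$entries$tag_kind, db$entries$index_id,
                sep = "\r")
  paths <- character(0)
  for (j in seq_len(nrow(cm$samples))) {
    sid <- cm$samples$sample_id[j]
    idx <- cm$samples$index_id[j]
    counts <- cm$counts[, sid]
    nz <- which(counts > 0L)
    pos <- match(paste(cm$row_meta$gene_id[nz], cm$row_meta$tag_kind[nz], idx,
                       sep = "\r"), ekey)
    if (anyNA(pos)) {
      stop("missing database entries for sample ", sid, " at index ", idx)
    }
    reads <- rep(substr(db$entries$seq[pos], 1L, 50L), counts[nz])
    if (length(reads)) reads <- reads[sample.int(length(reads))]
    reads <- mutate_reads(reads, 50L, cfg$error_rate)
    path <- file.path(dir, paste0(sid, ".fastq"))
    write_fastq(reads, path, prefix = paste0(sid, "_"))
    paths[sid] <- path
  }
  paths
}

#' Emit a 101-cycle decode-run FASTQ
#'
#' Each decoded tag yields `reads_per_tag` reads of anatomy 4-nt multiplex
#' index + 18-nt primer + 20-nt barcode + 26-nt universal spacer + 33-nt
#' flanking genomic sequence, with iid substitutions at the configured error
#' rate. Deterministic given the seed.
#'
#' @param tags A `tag_table` with `expected_flank` set.
#' @param cfg A [sim_config()].
#' @param path Output FASTQ path.
#' @param primers Primer set (defaults as in the database builder).
#' @param indexes Multiplex index pool to draw from.
#' @return `path`, invisibly.
#' @export
emit_decode_fastq <- function(tags, cfg, path,
                              primers = default_primer_set(),
                              indexes = default_multiplex_indexes()) {
  tags <- as_tag_table(as.data.frame(tags))
  if (any(is.na(tags$expected_flank) | !nzchar(tags$expected_flank))) {
    stop("every tag needs an expected_flank to emit decode reads")
  }
  set.seed(cfg$seed + 3L)
  n <- nrow(tags) * cfg$reads_per_tag
  if (n == 0L) {
    write_fastq(character(0), path)
    return(invisible(path))
  }
  row <- rep(seq_len(nrow(tags)), each = cfg$reads_per_tag)
  fwd <- ifelse(tags$tag_kind[row] == "up", primers$up_forward, primers$dn_forward)
  reads <- paste0(sample(indexes, n, replace = TRUE), fwd, tags$tag_seq[row],
                  DEFAULT_SPACER, tags$expected_flank[row])
  reads <- reads[sample.int(n)]
  reads <- mutate_reads(reads, 101L, cfg$error_rate)
  write_fastq(reads, path, prefix = "decode_")
  invisible(path)
}

#' Synthetic wild-type CFU viability table
#'
#' Generates plate-count data whose underlying survival follows a smooth
#' sigmoidal decline (midpoint `midpoint_weeks`, late-phase steepness set so
#' viability stays high for ~3 months and falls below 1% by ~6 months),
#' with binomial colony-count noise. This is a synthetic stand-in for a
#' wild-type quiescence viability experiment, not measured data.
#'
#' @param weeks Timepoints in weeks.
#' @param midpoint_weeks Time of 50% survival (default 16.6).
#' @param scale_weeks Sigmoid scale (default 1.6).
#' @param plated Cells plated per timepoint (default 600: three plates of
#'   ~200 cells).
#' @param plating_efficiency Reference plating efficiency (default 0.9).
#' @param replicates Number of replicates.
#' @param seed Integer seed.
#' @return Viability table (`timepoint`, `unit`, `replicate`, `plated`,
#'   `cfu`).
#' @export
simulate_wildtype_cfu <- function(weeks = seq(0, 24, by = 2),
                                  midpoint_weeks = 16.6, scale_weeks = 1.6,
                                  plated = 600L, plating_efficiency = 0.9,
                                  replicates = 2L, seed = 1L) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(replicates), function(r) {
    surv <- 1 / (1 + exp((weeks - midpoint_weeks) / scale_weeks))
    surv <- surv / surv[1]
    cfu <- stats::rbinom(length(weeks), plated,
                         pmin(1, plating_efficiency * surv))
    data.frame(timepoint = weeks, unit = "weeks", replicate = r,
               plated = plated, cfu = cfu)
  }))
}

#' Write the simulated ground truth as TSV
#'
#' @param truth A `sim_truth`.
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_sim_truth <- function(truth, path) {
  df <- cbind(truth$genes,
              as.data.frame(truth$proportions)[match(truth$genes$gene_id,
                                                     rownames(truth$proportions)), ,
                                               drop = FALSE])
  names(df) <- c(names(truth$genes),
                 paste0("prop_t", colnames(truth$proportions)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
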