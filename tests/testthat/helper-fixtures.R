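# shared fixtures and independent oracles

tiny_tag_table <- function(n_genes = 3, both = TRUE, seed = 11) {
  set.seed(seed)
  gene <- sprintf("g%02d", seq_len(n_genes))
  up <- data.frame(gene_id = gene, tag_kind = "up",
                   tag_seq = barseqls:::random_dna(n_genes, 20),
                   expected_flank = barseqls:::random_dna(n_genes, 33),
                   stringsAsFactors = FALSE)
  if (!both) return(as_tag_table(up))
  dn <- data.frame(gene_id = gene, tag_kind = "dn",
                   tag_seq = barseqls:::random_dna(n_genes, 20),
                   expected_flank = barseqls:::random_dna(n_genes, 33),
                   stringsAsFactors = FALSE)
  as_tag_table(rbind(up, dn))
}

# independent brute-force matching oracle: full Hamming scan over the first
# 42 nt of every entry, distance <= 1, unique-minimum wins
oracle_match <- function(read, db_seqs) {
  if (nchar(read) < 42) return("short_read")
  r <- strsplit(substr(read, 1, 42), "")[[1]]
  d <- vapply(db_seqs, function(s) {
    e <- strsplit(substr(s, 1, 42), "")[[1]]
    sum(e != r | e == "N" | r == "N")
  }, numeric(1), USE.NAMES = FALSE)
  cand <- which(d <= 1)
  if (length(cand) == 0) return("no_match")
  dmin <- min(d[cand])
  at_min <- cand[d[cand] == dmin]
  if (length(at_min) == 1) at_min else "ambiguous"
}

substitute_at <- function(seq, pos) {
  ch <- strsplit(seq, "")[[1]]
  for (p in pos) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
  paste(ch, collapse = "")
}

# count matrix built directly from a matrix of counts (rows gene x tag)
manual_count_matrix <- function(counts, row_meta, timepoints, unit = "weeks",
                                replicates = NULL) {
  if (is.null(replicates)) replicates <- rep(1L, length(timepoints))
  samples <- do.call(rbind, Map(function(tp, r, k) {
    sample_meta(colnames(counts)[k], r, tp, unit,
                if (tp == min(timepoints[replicates == r])) "reference" else "aged")
  }, timepoints, replicates, seq_along(timepoints)))
  barseqls:::new_count_matrix(counts, row_meta, samples)
}
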