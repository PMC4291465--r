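# read matching under the one-mismatch / unique-hit rule

make_db <- function(n_genes = 4, seed = 21) {
  build_barcode_db(tiny_tag_table(n_genes, seed = seed),
                   indexes = default_multiplex_indexes()[1:4])
}

test_that("exact and single-mismatch reads match their entry", {
  db <- make_db()
  entry <- db$entries[7, ]
  read <- substr(entry$seq, 1, 50)
  expect_equal(match_read(read, db)$entry$seq, entry$seq)

  mm30 <- substitute_at(read, 30)
  res <- match_read(mm30, db)
  expect_equal(res$status, "match")
  expect_equal(res$entry$seq, entry$seq)
  expect_equal(res$distance, 1L)
})

test_that("two mismatches within 42 bp lose the read; beyond 42 are ignored", {
  db <- make_db()
  read <- substr(db$entries$seq[3], 1, 50)
  expect_equal(match_read(substitute_at(read, c(10, 30)), db)$status, "no_match")
  # positions 43-50 are outside the discriminating window
  res <- match_read(substitute_at(read, c(30, 45, 50)), db)
  expect_equal(res$status, "match")
  expect_equal(res$distance, 1L)
})

test_that("ties are ambiguous but a perfect hit beats a one-mismatch hit", {
  tags <- tiny_tag_table(1, both = FALSE)
  t2 <- as.data.frame(tags)
  t2 <- rbind(t2, within(t2, {
    gene_id <- "g99"
    tag_seq <- substitute_at(tag_seq, 5)  # sister tag at Hamming distance 1
  }))
  db <- build_barcode_db(as_tag_table(t2), indexes = c(`1` = "ACGT"))
  reads <- substr(db$entries$seq, 1, 50)
  # equidistant: mutate the differing tag position to a third base
  pos <- 22 + 5
  ch <- strsplit(reads[1], "")[[1]]
  third <- setdiff(c("A", "C", "G", "T"),
                   c(substr(db$entries$seq[1], pos, pos),
                     substr(db$entries$seq[2], pos, pos)))[1]
  ch[pos] <- third
  expect_equal(match_read(paste(ch, collapse = ""), db)$status, "ambiguous")
  # distance 0 to entry 1, distance 1 to entry 2: unique best hit
  res <- match_read(reads[1], db)
  expect_equal(res$status, "match")
  expect_equal(res$entry$gene_id, db$entries$gene_id[1])
})

test_that("duplicate database sequences make their reads ambiguous", {
  df <- data.frame(gene_id = c("gA", "gB"), tag_kind = "up",
                   tag_seq = "ACGTAACGTACGTACGTACG")
  db <- build_barcode_db(as_tag_table(df), indexes = c(`1` = "AAAA"))
  expect_true(all(db$entries$duplicated_seq))
  expect_equal(match_read(substr(db$entries$seq[1], 1, 50), db)$status,
               "ambiguous")
})

test_that("short reads are flagged and counted as unmatched", {
  db <- make_db()
  expect_equal(match_read(substr(db$entries$seq[1], 1, 41), db)$status,
               "short_read")
})

test_that("matching agrees with the brute-force Hamming oracle on random inputs", {
  set.seed(99)
  for (trial in 1:4) {
    n_genes <- sample(3:10, 1)
    db <- build_barcode_db(tiny_tag_table(n_genes, seed = trial * 7),
                           indexes = default_multiplex_indexes()[1:sample(2:10, 1)])
    base <- substr(db$entries$seq[sample.int(nrow(db$entries), 60, replace = TRUE)], 1, 50)
    reads <- c(
      vapply(base[1:20], function(r) substitute_at(r, sample.int(42, 1)), character(1)),
      vapply(base[21:40], function(r) substitute_at(r, sample.int(50, 2)), character(1)),
      base[41:60],
      barseqls:::random_dna(10, 50)
    )
    got <- match_reads(reads, db)
    want <- lapply(reads, oracle_match, db_seqs = db$entries$seq)
    for (i in seq_along(reads)) {
      w <- want[[i]]
      if (is.character(w)) {
        expect_equal(got$status[i], w, info = sprintf("trial %d read %d", trial, i))
      } else {
        expect_equal(got$hit[i], w, info = sprintf("trial %d read %d", trial, i))
      }
    }
  }
})

test_that("count_sample conserves reads and is order-invariant", {
  tags <- tiny_tag_table(3)
  db <- build_barcode_db(tags, indexes = default_multiplex_indexes()[1:2])
  meta <- sample_meta("s1", 1, 0, "weeks", "reference", "1")

  good <- rep(substr(db$entries$seq[1], 1, 50), 100)
  junk <- barseqls:::random_dna(10, 50)
  fq <- withr::local_tempfile(fileext = ".fastq")
  barseqls:::write_fastq(c(good, junk), fq)
  res <- count_sample(fq, db, meta)
  expect_equal(res$report$matched_unique, 100L)
  expect_equal(res$report$discarded_unmatched, 10L)
  expect_equal(with(res$report, matched_unique + discarded_ambiguous +
                      discarded_unmatched), res$report$total_reads)
  key <- paste(res$counts$gene_id, res$counts$tag_kind)
  expect_equal(res$counts$count[key == paste(db$entries$gene_id[1],
                                             db$entries$tag_kind[1])], 100L)

  fq2 <- withr::local_tempfile(fileext = ".fastq")
  set.seed(1)
  barseqls:::write_fastq(sample(c(good, junk)), fq2)
  res2 <- count_sample(fq2, db, meta)
  expect_equal(res2$counts, res$counts)

  empty <- withr::local_tempfile(fileext = ".fastq")
  barseqls:::write_fastq(character(0), empty)
  expect_warning(res0 <- count_sample(empty, db, meta), "empty")
  expect_true(all(res0$counts$count == 0L))
})

test_that("count matrices assemble with zeros filled and round-trip via TSV", {
  counts1 <- data.frame(gene_id = c("gA", "gB"), tag_kind = "up",
                        count = c(5L, 7L))
  counts2 <- data.frame(gene_id = c("gA", "gC"), tag_kind = c("up", "dn"),
                        count = c(2L, 9L))
  samples <- rbind(sample_meta("s1", 1, 0, "weeks", "reference"),
                   sample_meta("s2", 1, 4, "weeks", "aged"))
  cm <- assemble_count_matrix(list(s1 = counts1, s2 = counts2), samples)
  expect_equal(dim(cm$counts), c(3L, 2L))
  expect_equal(unname(cm$depth), c(12, 11))
  expect_equal(cm$counts[paste(cm$row_meta$gene_id, cm$row_meta$tag_kind) ==
                           "gB up", "s2"][[1]], 0L)

  dup <- samples
  dup$sample_id <- "s1"
  expect_error(assemble_count_matrix(list(s1 = counts1, s1 = counts2), dup),
               "duplicate")

  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_count_matrix(cm, p1, p2)
  back <- read_count_matrix(p1, p2)
  expect_equal(back$counts, cm$counts)
  expect_equal(back$row_meta, cm$row_meta)
  expect_equal(unname(back$depth), unname(cm$depth))
})

test_that("a zero-error simulated FASTQ reproduces the sampled counts exactly", {
  cfg <- sim_config(n_genes = 30, depth = 2000, error_rate = 0, seed = 17)
  truth <- simulate_trajectories(cfg)
  cm <- sample_counts(truth)
  db <- build_barcode_db(truth$tags)
  dir <- withr::local_tempdir()
  fq <- emit_fastq(cm, db, cfg, dir)
  for (sid in cm$samples$sample_id[c(1, 4)]) {
    res <- count_sample(fq[[sid]], db,
                        cm$samples[cm$samples$sample_id == sid, ])
    key <- paste(res$counts$gene_id, res$counts$tag_kind)
    want <- cm$counts[match(key, paste(cm$row_meta$gene_id, cm$row_meta$tag_kind)), sid]
    expect_equal(res$counts$count, unname(want))
    expect_equal(res$report$discarded_unmatched, 0L)
  }
})
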