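#' Read a decoded-tag table
#'
#' Parses a TSV of decoded molecular barcodes, one row per (gene, tag kind):
#' columns `gene_id`, `tag_kind` (`up`/`dn`), `tag_seq` (20-nt barcode) and
#' optionally `expected_flank` (33-nt genomic sequence adjacent to the
#' deletion cassette, used only for decoding). Rows violating the invariants
#' are rejected with row-level diagnostics.
#'
#' @param path Path to a tab-separated file with a header row.
#' @return A data.frame of class `tag_table` with columns `gene_id`,
#'   `tag_kind`, `tag_seq`, `expected_flank` (NA when absent), and a
#'   `single_tag` attribute listing genes with only one decoded tag.
#' @export
read_tag_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  as_tag_table(df)
}

#' Validate a data.frame of decoded tags
#'
#' @param df data.frame with columns `gene_id`, `tag_kind`, `tag_seq` and
#'   optionally `expected_flank`.
#' @return A validated `tag_table` data.frame.
#' @export
as_tag_table <- function(df) {
  required <- c("gene_id", "tag_kind", "tag_seq")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("tag table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!"expected_flank" %in% names(df)) df$expected_flank <- NA_character_
  df <- df[, c("gene_id", "tag_kind", "tag_seq", "expected_flank")]
  df$tag_seq <- toupper(df$tag_seq)
  df$expected_flank <- toupper(df$expected_flank)

  problems <- character(0)
  row_err <- function(i, msg) sprintf("row %d: %s", i, msg)
  for (i in seq_len(nrow(df))) {
    if (is.na(df$gene_id[i]) || !nzchar(df$gene_id[i])) {
      problems <- c(problems, row_err(i, "empty gene_id"))
    }
    if (!df$tag_kind[i] %in% c("up", "dn")) {
      problems <- c(problems, row_err(i, sprintf("tag_kind '%s' not in {up, dn}", df$tag_kind[i])))
    }
    if (is.na(df$tag_seq[i]) || nchar(df$tag_seq[i]) != 20L) {
      problems <- c(problems, row_err(i, sprintf(
        "tag_seq length %d, expected 20", nchar(df$tag_seq[i]))))
    } else if (!is_dna(df$tag_seq[i])) {
      problems <- c(problems, row_err(i, "tag_seq has characters outside A/C/G/T/N"))
    }
    if (!is.na(df$expected_flank[i]) && nzchar(df$expected_flank[i])) {
      if (nchar(df$expected_flank[i]) != 33L) {
        problems <- c(problems, row_err(i, sprintf(
          "expected_flank length %d, expected 33", nchar(df$expected_flank[i]))))
      } else if (!is_dna(df$expected_flank[i])) {
        problems <- c(problems, row_err(i, "expected_flank has characters outside A/C/G/T/N"))
      }
    }
  }
  key <- paste(df$gene_id, df$tag_kind)
  dup <- duplicated(key)
  if (any(dup)) {
    problems <- c(problems, sprintf("duplicate (gene_id, tag_kind): %s",
                                    paste(unique(key[dup]), collapse = ", ")))
  }
  if (length(problems) > 0) {
    stop("invalid tag table:\n  ", paste(problems, collapse = "\n  "))
  }

  tab <- table(df$gene_id)
  attr(df, "single_tag") <- sort(names(tab)[tab == 1L])
  class(df) <- c("tag_table", "data.frame")
  df
}

#' Write a tag table to TSV
#'
#' @param tags A `tag_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tag_table <- function(tags, path) {
  utils::write.table(as.data.frame(tags), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
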