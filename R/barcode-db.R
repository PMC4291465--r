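#' Default multiplex index set
#'
#' Twenty distinct arbitrary 4-mers used as sample-identifying multiplex
#' indexes. The published index sequences were not disclosed, so the set is
#' configurable everywhere; these defaults are pairwise distinct 4-mers.
#'
#' @return Named character vector of twenty 4-nt sequences, names `"1".."20"`.
#' @export
default_multiplex_indexes <- function() {
  idx <- c("ACGT", "TGCA", "GATC", "CTAG", "AACC", "TTGG", "GGAA", "CCTT",
           "AGAG", "TCTC", "GTGT", "CACA", "ATCG", "TAGC", "GCAT", "CGTA",
           "AATG", "TTAC", "GGCT", "CCGA")
  stats::setNames(idx, as.character(seq_along(idx)))
}

#' Default universal primer set
#'
#' The 18-nt forward and 9-nt trailing universal primer segments that flank
#' the 20-nt barcode in each database entry. The forward 18-mers are the
#' tag-proximal portion of the round-1 PCR forward primers (after the 4-nt
#' multiplex index); the trailing 9-mers are the reverse complement of the
#' tag-proximal end of the round-1 reverse primers.
#'
#' @return List with elements `up_forward`, `up_trailing`, `dn_forward`,
#'   `dn_trailing`.
#' @export
default_primer_set <- function() {
  list(
    up_forward = "GAGGCAAGCTAAGATATC",
    up_trailing = "TAAATGCGA",
    dn_forward = "CCAGTGTCGAAAAGTATC",
    dn_trailing = "CCTACGCAA"
  )
}

validate_primer_set <- function(primers) {
  need <- c("up_forward", "up_trailing", "dn_forward", "dn_trailing")
  if (!all(need %in% names(primers))) {
    stop("primer set must name: ", paste(need, collapse = ", "))
  }
  if (nchar(primers$up_forward) != 18L || nchar(primers$dn_forward) != 18L) {
    stop("forward universal primers must be 18 nt")
  }
  if (nchar(primers$up_trailing) != 9L || nchar(primers$dn_trailing) != 9L) {
    stop("trailing universal primers must be 9 nt")
  }
  invisible(primers)
}

#' Build the barcode reference database
#'
#' Expands a decoded-tag table against a multiplex index set: every decoded
#' tag contributes one 51-nt entry per index, laid out as 4-nt multiplex
#' index + 18-nt universal primer + 20-nt tag + 9-nt universal primer (a
#' 50-cycle counting read covers all but the last base). Entries are ordered
#' deterministically by (gene_id, tag_kind, index_id). Duplicate entry
#' sequences (possible with degenerate tags) are retained and flagged; the
#' matcher treats them as ambiguity.
#'
#' @param tags A `tag_table` (see [as_tag_table()]).
#' @param indexes Character vector of distinct 4-nt multiplex indexes; names
#'   become index ids (defaults to `"1".."n"`).
#' @param primers Primer set as from [default_primer_set()].
#' @return An object of class `barcode_db`: list with `entries` (data.frame:
#'   `gene_id`, `tag_kind`, `index_id`, `seq`, `duplicated_seq`),
#'   `index_table`, `primers`.
#' @export
build_barcode_db <- function(tags,
                             indexes = default_multiplex_indexes(),
                             primers = default_primer_set()) {
  tags <- as_tag_table(as.data.frame(tags))
  if (nrow(tags) == 0L) stop("empty tag table")
  if (length(indexes) == 0L) stop("no multiplex indexes supplied")
  if (any(nchar(indexes) != 4L)) stop("multiplex indexes must be 4 nt")
  if (anyDuplicated(indexes)) stop("multiplex indexes must be distinct")
  if (is.null(names(indexes)) || !all(nzchar(names(indexes)))) {
    names(indexes) <- as.character(seq_along(indexes))
  }
  validate_primer_set(primers)

  tags <- tags[order(tags$gene_id, tags$tag_kind), , drop = FALSE]
  grid <- expand.grid(index_pos = seq_along(indexes), tag_row = seq_len(nrow(tags)),
                      KEEP.OUT.ATTRS = FALSE)
  # expand.grid varies its first factor fastest: tag-major, index-minor order
  tag_row <- grid$tag_row
  index_pos <- grid$index_pos
  fwd <- ifelse(tags$tag_kind[tag_row] == "up", primers$up_forward, primers$dn_forward)
  trl <- ifelse(tags$tag_kind[tag_row] == "up", primers$up_trailing, primers$dn_trailing)
  entries <- data.frame(
    gene_id = tags$gene_id[tag_row],
    tag_kind = tags$tag_kind[tag_row],
    index_id = names(indexes)[index_pos],
    seq = paste0(indexes[index_pos], fwd, tags$tag_seq[tag_row], trl),
    stringsAsFactors = FALSE
  )
  stopifnot(all(nchar(entries$seq) == 51L))
  entries$duplicated_seq <- entries$seq %in% entries$seq[duplicated(entries$seq)]

  structure(
    list(entries = entries, index_table = indexes, primers = primers),
    class = "barcode_db"
  )
}

#' @export
print.barcode_db <- function(x, ...) {
  cat(sprintf("barcode_db: %d entries (%d genes, %d indexes)%s\n",
              nrow(x$entries), length(unique(x$entries$gene_id)),
              length(x$index_table),
              if (any(x$entries$duplicated_seq)) {
                sprintf(", %d duplicated sequences", sum(x$entries$duplicated_seq))
              } else ""))
  invisible(x)
}

#' Re-parse a database entry into its segments
#'
#' Inverse of the 4+18+20+9 concatenation used by [build_barcode_db()].
#'
#' @param seq Character vector of 51-nt entry sequences.
#' @return data.frame with columns `index_seq`, `forward_primer`, `tag_seq`,
#'   `trailing_primer`.
#' @export
parse_db_entry <- function(seq) {
  if (any(nchar(seq) != 51L)) stop("database entries must be 51 nt")
  data.frame(
    index_seq = substr(seq, 1L, 4L),
    forward_primer = substr(seq, 5L, 22L),
    tag_seq = substr(seq, 23L, 42L),
    trailing_primer = substr(seq, 43L, 51L),
    stringsAsFactors = FALSE
  )
}

#' Write a barcode database as FASTA
#'
#' Headers encode `gene_id|tag_kind|index_id`; the companion
#' [read_db_fasta()] restores an identical database.
#'
#' @param db A `barcode_db`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_db_fasta <- function(db, path) {
  stopifnot(inherits(db, "barcode_db"))
  seqs <- Biostrings::DNAStringSet(db$entries$seq)
  names(seqs) <- paste(db$entries$gene_id, db$entries$tag_kind,
                       db$entries$index_id, sep = "|")
  idx_line <- paste(sprintf("%s=%s", names(db$index_table), db$index_table),
                    collapse = ",")
  primer_line <- paste(sprintf("%s=%s", names(db$primers), unlist(db$primers)),
                       collapse = ",")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf(";indexes %s", idx_line),
               sprintf(";primers %s", primer_line)), con)
  close(con)
  on.exit(NULL)
  Biostrings::writeXStringSet(seqs, path, append = TRUE, width = 80L)
  invisible(path)
}

#' Read a barcode database written by [write_db_fasta()]
#'
#' @param path FASTA path.
#' @return A `barcode_db`.
#' @export
read_db_fasta <- function(path) {
  header <- readLines(path, n = 2L)
  parse_kv <- function(line, prefix) {
    body <- sub(paste0("^;", prefix, " "), "", line)
    parts <- strsplit(strsplit(body, ",", fixed = TRUE)[[1]], "=", fixed = TRUE)
    stats::setNames(vapply(parts, `[`, character(1), 2L),
                    vapply(parts, `[`, character(1), 1L))
  }
  if (length(header) < 2L || !startsWith(header[1], ";indexes")) {
    stop("not a barcode_db FASTA (missing ;indexes header)")
  }
  indexes <- parse_kv(header[1], "indexes")
  primers <- as.list(parse_kv(header[2], "primers"))
  seqs <- Biostrings::readDNAStringSet(path)
  meta <- strsplit(names(seqs), "|", fixed = TRUE)
  entries <- data.frame(
    gene_id = vapply(meta, `[`, character(1), 1L),
    tag_kind = vapply(meta, `[`, character(1), 2L),
    index_id = vapply(meta, `[`, character(1), 3L),
    seq = as.character(seqs),
    stringsAsFactors = FALSE
  )
  entries$duplicated_seq <- entries$seq %in% entries$seq[duplicated(entries$seq)]
  rownames(entries) <- NULL
  structure(list(entries = entries, index_table = indexes, primers = primers),
            class = "barcode_db")
}
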