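#' Match a single read against the barcode database
#'
#' Candidate entries are those whose first 42 nt (multiplex index + forward
#' primer + tag) lie within Hamming distance 1 of the read's first 42 nt;
#' positions beyond 42 are ignored (the trailing primer is constant and a
#' 50-cycle read does not cover it fully). A read is assigned only when a
#' single entry attains the minimum distance; a distance-0 hit beats
#' distance-1 hits (best-unique semantics), while two or more entries at the
#' minimum distance make the read ambiguous.
#'
#' @param read A DNA string (>= 42 nt for a match to be possible).
#' @param db A `barcode_db`.
#' @return A list with `status` (`"match"`, `"ambiguous"`, `"no_match"`,
#'   `"short_read"`), and for matches `entry` (one-row data.frame) and
#'   `distance`.
#' @export
match_read <- function(read, db) {
  res <- match_reads(read, db)
  status <- res$status
  out <- list(status = status)
  if (status == "match") {
    out$entry <- db$entries[res$hit, , drop = FALSE]
    out$distance <- res$dist
  }
  out
}

#' Vectorized read matching
#'
#' @param reads Character vector of reads.
#' @param db A `barcode_db`.
#' @return data.frame with columns `hit` (row index into `db$entries`, NA if
#'   unassigned), `dist`, `status`.
#' @export
match_reads <- function(reads, db) {
  stopifnot(inherits(db, "barcode_db"))
  if (nrow(db$entries) == 0L) stop("empty barcode database")
  raw <- match_reads_cpp(as.character(reads), db$entries$seq)
  status <- rep("match", length(reads))
  status[raw$hit == 0L] <- "no_match"
  status[raw$hit == -1L] <- "ambiguous"
  status[raw$hit == -2L] <- "short_read"
  data.frame(
    hit = ifelse(raw$hit > 0L, raw$hit, NA_integer_),
    dist = raw$dist,
    status = status,
    stringsAsFactors = FALSE
  )
}

#' Describe one sequencing sample
#'
#' @param sample_id Unique sample label.
#' @param replicate Biological replicate (1 or 2).
#' @param timepoint Numeric timepoint.
#' @param unit `"weeks"` (lifespan) or `"minutes"` (growth).
#' @param role `"reference"` or `"aged"`.
#' @param index_id Multiplex index id used for the sample (optional).
#' @return A one-row data.frame of class `sample_meta`.
#' @export
sample_meta <- function(sample_id, replicate, timepoint, unit, role,
                        index_id = NA_character_) {
  stopifnot(role %in% c("reference", "aged"), unit %in% c("weeks", "minutes"))
  structure(
    data.frame(sample_id = sample_id, replicate = as.integer(replicate),
               timepoint = as.numeric(timepoint), unit = unit, role = role,
               index_id = as.character(index_id), stringsAsFactors = FALSE),
    class = c("sample_meta", "data.frame")
  )
}

validate_sample_sheet <- function(samples) {
  need <- c("sample_id", "replicate", "timepoint", "unit", "role")
  if (!all(need %in% names(samples))) {
    stop("sample sheet needs columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample_id in sample sheet")
  for (r in unique(samples$replicate)) {
    nref <- sum(samples$role == "reference" & samples$replicate == r)
    if (nref != 1L) {
      stop(sprintf("replicate %s has %d reference samples (exactly one required)", r, nref))
    }
  }
  invisible(samples)
}

#' Count barcode reads in one sample
#'
#' Reads a FASTQ file, classifies every read against the database under the
#' one-mismatch unique-hit rule, and aggregates matched reads over multiplex
#' index into per-(gene, tag) counts. Conservation holds by construction:
#' matched + ambiguous + unmatched = total reads (short reads count as
#' unmatched, flagged in the report).
#'
#' @param fastq Path to a FASTQ file (optionally gzipped).
#' @param db A `barcode_db`.
#' @param meta A `sample_meta` row for the sample.
#' @return List with `counts` (data.frame `gene_id`, `tag_kind`, `count`,
#'   zero rows included for all db tags) and `report` (one-row data.frame:
#'   `total_reads`, `matched_unique`, `discarded_ambiguous`,
#'   `discarded_unmatched`, `short_reads`).
#' @export
count_sample <- function(fastq, db, meta) {
  reads <- tryCatch(
    as.character(Biostrings::readDNAStringSet(fastq, format = "fastq")),
    error = function(e) stop("failed to parse FASTQ '", fastq, "': ", conditionMessage(e))
  )
  if (length(reads) == 0L) {
    warning("empty FASTQ: ", fastq)
  }
  res <- if (length(reads)) match_reads(reads, db) else
    data.frame(hit = integer(0), dist = integer(0), status = character(0))

  tag_keys <- unique(db$entries[, c("gene_id", "tag_kind")])
  rownames(tag_keys) <- NULL
  key <- paste(tag_keys$gene_id, tag_keys$tag_kind, sep = "\r")
  hit_key <- paste(db$entries$gene_id[res$hit[!is.na(res$hit)]],
                   db$entries$tag_kind[res$hit[!is.na(res$hit)]], sep = "\r")
  counts <- as.integer(table(factor(hit_key, levels = key)))
  out <- data.frame(tag_keys, count = counts, stringsAsFactors = FALSE)

  report <- data.frame(
    sample_id = meta$sample_id,
    total_reads = length(reads),
    matched_unique = sum(res$status == "match"),
    discarded_ambiguous = sum(res$status == "ambiguous"),
    discarded_unmatched = sum(res$status %in% c("no_match", "short_read")),
    short_reads = sum(res$status == "short_read"),
    stringsAsFactors = FALSE
  )
  stopifnot(report$matched_unique + report$discarded_ambiguous +
              report$discarded_unmatched == report$total_reads)
  list(counts = out, report = report)
}

#' Assemble per-sample counts into a count matrix
#'
#' @param per_sample Named list (by sample_id) of count data.frames as
#'   returned by [count_sample()] (`$counts`), or plain data.frames with
#'   columns `gene_id`, `tag_kind`, `count`.
#' @param samples Sample sheet data.frame (one row per sample; see
#'   [sample_meta()]).
#' @return A `count_matrix`: list with `counts` (integer matrix, one row per
#'   (gene, tag), one column per sample), `row_meta` (`gene_id`, `tag_kind`),
#'   `samples`, `depth` (column sums).
#' @export
assemble_count_matrix <- function(per_sample, samples) {
  validate_sample_sheet(samples)
  if (is.null(names(per_sample)) || !setequal(names(per_sample), samples$sample_id)) {
    stop("per_sample must be a list named by the sample sheet's sample_id values")
  }
  get_counts <- function(x) if (is.data.frame(x)) x else x$counts
  all_keys <- unique(do.call(rbind, lapply(per_sample, function(x) {
    get_counts(x)[, c("gene_id", "tag_kind")]
  })))
  all_keys <- all_keys[order(all_keys$gene_id, all_keys$tag_kind), , drop = FALSE]
  rownames(all_keys) <- NULL
  key <- paste(all_keys$gene_id, all_keys$tag_kind, sep = "\r")

  m <- matrix(0L, nrow = nrow(all_keys), ncol = nrow(samples),
              dimnames = list(NULL, samples$sample_id))
  for (sid in samples$sample_id) {
    cs <- get_counts(per_sample[[sid]])
    pos <- match(paste(cs$gene_id, cs$tag_kind, sep = "\r"), key)
    m[pos, sid] <- as.integer(cs$count)
  }
  new_count_matrix(m, all_keys, samples)
}

new_count_matrix <- function(counts, row_meta, samples) {
  stopifnot(nrow(counts) == nrow(row_meta), ncol(counts) == nrow(samples))
  depth <- colSums(counts)
  empty <- names(depth)[depth == 0]
  if (length(empty)) {
    warning("sample(s) with zero matched reads: ", paste(empty, collapse = ", "))
  }
  structure(list(counts = counts, row_meta = row_meta,
                 samples = as.data.frame(samples), depth = depth),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d tag rows x %d samples; depth %s-%s\n",
              length(unique(x$row_meta$gene_id)), nrow(x$counts),
              ncol(x$counts), format(min(x$depth), big.mark = ","),
              format(max(x$depth), big.mark = ",")))
  invisible(x)
}

#' Write a count matrix (and its sample sheet) to TSV
#'
#' The count table is wide: `gene_id`, `tag_kind`, then one column per
#' sample, mirroring the gene x tag x sample layout of published Bar-seq
#' count tables.
#'
#' @param cm A `count_matrix`.
#' @param path Output TSV for counts.
#' @param samples_path Optional output TSV for the sample sheet.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(cm, path, samples_path = NULL) {
  df <- cbind(cm$row_meta, as.data.frame(cm$counts, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(samples_path)) {
    utils::write.table(cm$samples, samples_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read a count matrix written by [write_count_matrix()]
#'
#' @param path Counts TSV.
#' @param samples Sample sheet data.frame, or path to its TSV.
#' @return A `count_matrix`.
#' @export
read_count_matrix <- function(path, samples) {
  if (is.character(samples)) {
    samples <- utils::read.delim(samples, stringsAsFactors = FALSE)
  }
  validate_sample_sheet(samples)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(samples$sample_id, names(df))
  if (length(missing)) {
    stop("count table lacks sample column(s): ", paste(missing, collapse = ", "))
  }
  m <- as.matrix(df[, samples$sample_id, drop = FALSE])
  storage.mode(m) <- "integer"
  new_count_matrix(m, df[, c("gene_id", "tag_kind")], samples)
}
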