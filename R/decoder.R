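DECODE_SEGMENTS <- c(index = 4L, primer = 18L, barcode = 20L, spacer = 26L,
                     flank = 33L)

#' Segment decode-run reads
#'
#' A 101-cycle decode read has fixed anatomy: 4-nt multiplex index, 18-nt
#' PCR primer, 20-nt barcode, 26-nt universal spacer, 33-nt flanking genomic
#' sequence. Reads shorter than 101 nt are rejected; longer reads are
#' truncated to the first 101 nt.
#'
#' @param raw Character vector of raw read sequences.
#' @return List with `reads` (data.frame: `index`, `primer`, `barcode`,
#'   `spacer`, `flank`) and `n_short` (number of rejected short reads).
#' @export
parse_decode_reads <- function(raw) {
  raw <- as.character(raw)
  short <- nchar(raw) < 101L
  keep <- raw[!short]
  ends <- cumsum(DECODE_SEGMENTS)
  starts <- ends - DECODE_SEGMENTS + 1L
  reads <- as.data.frame(
    lapply(stats::setNames(seq_along(ends), names(DECODE_SEGMENTS)),
           function(i) substr(keep, starts[i], ends[i])),
    stringsAsFactors = FALSE
  )
  list(reads = reads, n_short = sum(short))
}

#' Group decode reads by exact barcode and call flank consensus
#'
#' One cluster per distinct 20-mer barcode (no merging of near-identical
#' barcodes; sequencing-error singletons are handled by the minimum cluster
#' size instead). The flank consensus is the per-position majority base over
#' the cluster's flanks (ties broken alphabetically, deterministically);
#' support is the fraction of reads whose full flank equals the consensus.
#'
#' @param reads data.frame from [parse_decode_reads()]`$reads`.
#' @param min_cluster Minimum reads per retained cluster (default 2).
#' @return data.frame with columns `barcode`, `n_reads`, `flank_consensus`,
#'   `flank_support`, ordered by decreasing `n_reads` then barcode.
#' @export
cluster_by_barcode <- function(reads, min_cluster = 2L) {
  if (nrow(reads) == 0L) {
    return(data.frame(barcode = character(0), n_reads = integer(0),
                      flank_consensus = character(0), flank_support = numeric(0),
                      stringsAsFactors = FALSE))
  }
  groups <- split(reads$flank, reads$barcode)
  clusters <- lapply(names(groups), function(bc) {
    flanks <- groups[[bc]]
    cons <- consensus_seq(flanks)
    data.frame(barcode = bc, n_reads = length(flanks), flank_consensus = cons,
               flank_support = mean(flanks == cons), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, clusters)
  out <- out[out$n_reads >= min_cluster, , drop = FALSE]
  out <- out[order(-out$n_reads, out$barcode), , drop = FALSE]
  rownames(out) <- NULL
  out
}

consensus_seq <- function(seqs) {
  if (length(seqs) == 1L) return(seqs)
  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  paste(apply(mat, 2L, function(col) {
    tab <- table(col)
    names(tab)[which.max(tab)]  # which.max takes the first = alphabetical tie-break
  }), collapse = "")
}

#' Assign barcode clusters to genes via flanking sequence
#'
#' Each cluster's flank consensus is compared (Hamming distance) with every
#' expected flank; the cluster is assigned to the (gene, tag kind) with the
#' unique minimum distance, provided that distance is at most `d_max` and the
#' second-best distance strictly exceeds it. Assigned clusters become decoded
#' tag records whose `tag_seq` is the cluster barcode. Two clusters decoding
#' different barcodes for the same (gene, tag kind) are both kept and the
#' gene is flagged as a conflicting decode.
#'
#' @param clusters data.frame from [cluster_by_barcode()].
#' @param expected `tag_table`-like data.frame with `gene_id`, `tag_kind`,
#'   `expected_flank` (33 nt; its `tag_seq` column, if any, is ignored).
#' @param d_max Maximum accepted flank distance (default 3).
#' @return List with `tags` (a `tag_table` of decoded records; validation is
#'   relaxed to allow conflicts, see `conflicts`), `report` (data.frame:
#'   `assigned`, `ambiguous`, `unassigned`), `conflicts` (character vector of
#'   flagged (gene, tag kind) keys), `unassigned` (the unassigned clusters
#'   with their best distances).
#' @export
assign_clusters <- function(clusters, expected, d_max = 3L) {
  stopifnot(all(c("gene_id", "tag_kind", "expected_flank") %in% names(expected)))
  if (any(nchar(expected$expected_flank) != 33L)) {
    stop("expected flanks must be 33 nt")
  }
  n <- nrow(clusters)
  if (n == 0L) {
    return(list(tags = NULL,
                report = data.frame(assigned = 0L, ambiguous = 0L, unassigned = 0L),
                conflicts = character(0), unassigned = clusters))
  }
  assigned_rows <- vector("list", n)
  status <- character(n)
  best_d <- integer(n)
  for (i in seq_len(n)) {
    d <- hamming(rep(clusters$flank_consensus[i], nrow(expected)),
                 expected$expected_flank)
    dmin <- min(d)
    best_d[i] <- dmin
    at_min <- which(d == dmin)
    if (dmin > d_max) {
      status[i] <- "unassigned"
    } else if (length(at_min) > 1L) {
      status[i] <- "ambiguous"
    } else {
      status[i] <- "assigned"
      assigned_rows[[i]] <- data.frame(
        gene_id = expected$gene_id[at_min],
        tag_kind = expected$tag_kind[at_min],
        tag_seq = clusters$barcode[i],
        expected_flank = expected$expected_flank[at_min],
        n_reads = clusters$n_reads[i],
        flank_distance = dmin,
        stringsAsFactors = FALSE
      )
    }
  }
  tags <- do.call(rbind, assigned_rows[!vapply(assigned_rows, is.null, logical(1))])
  conflicts <- character(0)
  if (!is.null(tags)) {
    key <- paste(tags$gene_id, tags$tag_kind)
    conflicts <- sort(unique(key[duplicated(key)]))
    rownames(tags) <- NULL
  }
  list(
    tags = tags,
    report = data.frame(assigned = sum(status == "assigned"),
                        ambiguous = sum(status == "ambiguous"),
                        unassigned = sum(status == "unassigned")),
    conflicts = conflicts,
    unassigned = cbind(clusters[status != "assigned", , drop = FALSE],
                       best_distance = best_d[status != "assigned"],
                       status = status[status != "assigned"])
  )
}

#' Decode a full decode-run FASTQ
#'
#' Convenience wrapper: parse, cluster, assign. Reads are pooled regardless
#' of multiplex index (single decode pool).
#'
#' @param fastq Path to the decode-run FASTQ.
#' @param expected Expected-flank table (see [assign_clusters()]).
#' @param min_cluster,d_max Tuning parameters (see the component functions).
#' @return As [assign_clusters()], plus `n_short` and `n_clusters`.
#' @export
decode_run <- function(fastq, expected, min_cluster = 2L, d_max = 3L) {
  raw <- as.character(Biostrings::readDNAStringSet(fastq, format = "fastq"))
  parsed <- parse_decode_reads(raw)
  clusters <- cluster_by_barcode(parsed$reads, min_cluster = min_cluster)
  out <- assign_clusters(clusters, expected, d_max = d_max)
  out$n_short <- parsed$n_short
  out$n_clusters <- nrow(clusters)
  out
}
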