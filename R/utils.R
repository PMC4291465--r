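DNA_ALPHABET <- c("A", "C", "G", "T", "N")

#' Hamming distance between equal-length DNA strings
#'
#' Position-wise mismatch count. `N` never matches anything, including `N`:
#' an uncalled base cannot support a match.
#'
#' @param a,b Character vectors of equal-length sequences (recycled to a
#'   common length).
#' @return Integer vector of mismatch counts.
#' @export
hamming <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) return(integer(0))
  n <- max(length(a), length(b))
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  if (any(nchar(a) != nchar(b))) {
    stop("hamming() requires equal-length sequence pairs")
  }
  mapply(function(x, y) {
    cx <- strsplit(x, "", fixed = TRUE)[[1]]
    cy <- strsplit(y, "", fixed = TRUE)[[1]]
    sum(cx != cy | cx == "N" | cy == "N")
  }, a, b, USE.NAMES = FALSE)
}

is_dna <- function(x) {
  grepl("^[ACGTN]*$", x)
}

#' Random DNA sequences
#'
#' @param n Number of sequences.
#' @param len Length of each sequence.
#' @return Character vector of `n` sequences over A/C/G/T.
#' @keywords internal
random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

# iid substitution errors at a per-base rate; substitutions are uniform over
# the three alternative bases
mutate_seqs <- function(seqs, error_rate) {
  if (error_rate <= 0) return(seqs)
  vapply(seqs, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    hit <- stats::runif(length(ch)) < error_rate
    if (any(hit)) {
      ch[hit] <- vapply(ch[hit], function(b) {
        sample(setdiff(c("A", "C", "G", "T"), b), 1L)
      }, character(1))
    }
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
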