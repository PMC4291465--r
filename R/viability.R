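#' Convert CFU plate counts to a relative viability curve
#'
#' Viability at each timepoint is the plating efficiency (colonies per
#' plated cell) relative to the reference (first) timepoint, in percent; the
#' reference is 100% by construction and later values may exceed 100 (e.g. a
#' pool transiently regrowing on nutrients released by dead cells).
#'
#' @param timepoints Numeric timepoints (any consistent unit).
#' @param cfu Colony counts at each timepoint.
#' @param plated_cells Cells plated at each timepoint (scalar or vector).
#' @param replicate Replicate label stored on the curve.
#' @param reference Index of the reference timepoint (default 1).
#' @return data.frame of class `survival_curve`: `timepoint`, `viability`
#'   (percent), `replicate`.
#' @export
cfu_to_viability <- function(timepoints, cfu, plated_cells, replicate = 1L,
                             reference = 1L) {
  stopifnot(length(timepoints) == length(cfu))
  plated_cells <- rep_len(plated_cells, length(cfu))
  if (any(plated_cells <= 0)) stop("plated_cells must be positive")
  if (cfu[reference] <= 0) stop("reference timepoint has no colonies")
  eff <- cfu / plated_cells
  out <- data.frame(timepoint = timepoints,
                    viability = 100 * eff / eff[reference],
                    replicate = replicate)
  class(out) <- c("survival_curve", "data.frame")
  out
}

#' Median chronological lifespan from a viability curve
#'
#' Fits an order-2 polynomial to viability (percent) versus time by least
#' squares — pooling points across replicates when several are present — and
#' returns the smallest root of `fit(t) = 50` inside the observed time
#' range (the first downward crossing of 50% viability).
#'
#' @param curve A `survival_curve` (or any data.frame with `timepoint`,
#'   `viability`).
#' @return List: `median_cls` (time units of the curve), `coefficients`
#'   (intercept, linear, quadratic), `fitted` function of t.
#' @export
median_cls <- function(curve) {
  t <- curve$timepoint
  v <- curve$viability
  if (length(unique(t)) < 3L) stop("need at least 3 distinct timepoints")
  fit <- stats::lm(v ~ t + I(t^2))
  cf <- unname(stats::coef(fit))  # c0 + c1 t + c2 t^2
  # roots of c2 t^2 + c1 t + (c0 - 50) = 0
  roots <- if (abs(cf[3]) < 1e-12 * max(1, abs(cf[2]), abs(cf[1]))) {
    if (abs(cf[2]) < 1e-12) stop("degenerate fit: constant viability")
    (50 - cf[1]) / cf[2]
  } else {
    disc <- cf[2]^2 - 4 * cf[3] * (cf[1] - 50)
    if (disc < 0) numeric(0) else {
      (-cf[2] + c(-1, 1) * sqrt(disc)) / (2 * cf[3])
    }
  }
  eps <- 1e-9 * max(1, diff(range(t)))
  in_range <- roots[roots >= min(t) - eps & roots <= max(t) + eps]
  if (length(in_range) == 0L) stop("no median reached: fitted curve does not cross 50% in range")
  m <- min(in_range)
  list(median_cls = m, coefficients = cf,
       fitted = function(x) cf[1] + cf[2] * x + cf[3] * x^2)
}

#' Read / write viability tables
#'
#' TSV layout: `timepoint`, `unit`, `replicate`, `plated`, `cfu`.
#'
#' @param path TSV path.
#' @return data.frame (read) or `path` (write).
#' @export
read_viability_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("timepoint", "unit", "replicate", "plated", "cfu")
  if (!all(need %in% names(df))) {
    stop("viability table needs columns: ", paste(need, collapse = ", "))
  }
  df
}

#' @rdname read_viability_table
#' @param df Viability data.frame.
#' @export
write_viability_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Viability analysis of a CFU table
#'
#' Converts each replicate's CFU counts to relative viability (reference =
#' earliest timepoint per replicate) and estimates median lifespan from the
#' pooled points.
#'
#' @param df Viability table (see [read_viability_table()]).
#' @return List: `curves` (per-replicate `survival_curve` rows, combined),
#'   `median` (as [median_cls()]).
#' @export
analyze_viability <- function(df) {
  curves <- do.call(rbind, lapply(split(df, df$replicate), function(d) {
    d <- d[order(d$timepoint), , drop = FALSE]
    cfu_to_viability(d$timepoint, d$cfu, d$plated, replicate = d$replicate[1])
  }))
  rownames(curves) <- NULL
  list(curves = curves, median = median_cls(curves))
}
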