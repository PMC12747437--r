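#' Chromatin-tracing trace container
#'
#' A `TraceSet` holds the localizations of `L` genomic loci across `N` traces
#' (one trace = one chromosome copy in one cell), as an `N x L x D` array of
#' coordinates in nanometres with `NA` marking missing localizations. Loci are
#' kept sorted by genomic start (0-based half-open intervals); repeat-imaged
#' copies of a locus carry role `"repeat"` and are listed in `repeat_pairs`
#' together with the initially imaged locus covering the same interval.
#'
#' A localization is all-or-nothing: if any coordinate of a spot is missing
#' the whole spot is treated as missing (partially missing entries are
#' normalized to fully missing on construction). All downstream statistics are
#' pairwise-complete over localized spots.
#'
#' @param positions numeric array `N x L x D` (a matrix is taken as `D = 1`),
#'   coordinates in nm, `NA` = missing. `D` must be 1, 2 or 3.
#' @param locus_table data frame with columns `chrom`, `start`, `end` (bp,
#'   0-based half-open) and `role` (`"initial"` or `"repeat"`); defaults to a
#'   single chromosome at `resolution_bp` spacing, all initial.
#' @param trace_meta data frame with one row per trace: `trace_id`, `cell`,
#'   `allele`, `condition`, `burst_state` (`"none"`, `"initial_burst"` or
#'   `"later_burst"`). Defaults are synthesized.
#' @param repeat_pairs data frame with columns `initial_locus`,
#'   `repeat_locus` (indices into `locus_table`); both loci must cover the
#'   identical genomic interval.
#' @param resolution_bp genomic spacing used for the default `locus_table`.
#' @return an object of class `TraceSet`.
#' @export
trace_set <- function(positions, locus_table = NULL, trace_meta = NULL,
                      repeat_pairs = NULL, resolution_bp = 1000) {
  if (is.matrix(positions)) positions <- array(positions, c(dim(positions), 1L))
  if (!is.array(positions) || length(dim(positions)) != 3L)
    stop("positions must be an N x L x D array")
  dm <- dim(positions)
  N <- dm[1]; L <- dm[2]; D <- dm[3]
  if (N < 1L) stop("need at least one trace")
  if (L < 2L) stop("need at least two loci")
  if (!D %in% 1:3) stop("D must be 1, 2 or 3")
  storage.mode(positions) <- "double"

  # all-or-none missingness per spot
  miss <- is.na(positions[, , 1, drop = FALSE])[, , 1]
  if (D > 1) for (d in 2:D) miss <- miss | is.na(positions[, , d, drop = FALSE])[, , 1]
  for (d in seq_len(D)) {
    pd <- positions[, , d]
    pd[miss] <- NA_real_
    positions[, , d] <- pd
  }
  if (any(is.infinite(positions), na.rm = TRUE))
    stop("non-finite coordinate in positions")

  if (is.null(locus_table)) {
    locus_table <- data.frame(
      chrom = "chr1",
      start = as.numeric(seq_len(L) - 1) * resolution_bp,
      end   = as.numeric(seq_len(L)) * resolution_bp,
      role  = "initial",
      stringsAsFactors = FALSE
    )
  }
  locus_table <- as.data.frame(locus_table)
  if (!all(c("chrom", "start", "end") %in% names(locus_table)))
    stop("locus_table needs chrom, start, end")
  if (is.null(locus_table$role)) locus_table$role <- "initial"
  if (nrow(locus_table) != L) stop("locus_table has ", nrow(locus_table),
                                   " rows but positions has ", L, " loci")
  if (!all(locus_table$role %in% c("initial", "repeat")))
    stop("locus role must be 'initial' or 'repeat'")

  ord <- order(locus_table$chrom, locus_table$start, locus_table$role != "initial")
  if (!identical(ord, seq_len(L))) {
    positions <- positions[, ord, , drop = FALSE]
    locus_table <- locus_table[ord, , drop = FALSE]
    rownames(locus_table) <- NULL
    if (!is.null(repeat_pairs) && nrow(repeat_pairs)) {
      inv <- match(seq_len(L), ord)
      repeat_pairs$initial_locus <- inv[repeat_pairs$initial_locus]
      repeat_pairs$repeat_locus <- inv[repeat_pairs$repeat_locus]
    }
  }
  rownames(locus_table) <- NULL

  if (is.null(repeat_pairs))
    repeat_pairs <- data.frame(initial_locus = integer(), repeat_locus = integer())
  repeat_pairs <- as.data.frame(repeat_pairs)
  if (nrow(repeat_pairs)) {
    a <- repeat_pairs$initial_locus; r <- repeat_pairs$repeat_locus
    if (any(a == r)) stop("repeat pair referencing a single locus")
    same <- locus_table$chrom[a] == locus_table$chrom[r] &
      locus_table$start[a] == locus_table$start[r] &
      locus_table$end[a] == locus_table$end[r]
    if (!all(same)) stop("repeat pair with mismatching genomic intervals")
  }

  if (is.null(trace_meta)) {
    trace_meta <- data.frame(
      trace_id = sprintf("trace_%d", seq_len(N)),
      cell = sprintf("cell_%d", seq_len(N)),
      allele = "1",
      condition = "default",
      burst_state = "none",
      stringsAsFactors = FALSE
    )
  }
  trace_meta <- as.data.frame(trace_meta)
  if (nrow(trace_meta) != N) stop("trace_meta has wrong number of rows")
  if (is.null(trace_meta$burst_state)) trace_meta$burst_state <- "none"
  if (!all(trace_meta$burst_state %in% c("none", "initial_burst", "later_burst")))
    stop("burst_state must be none, initial_burst or later_burst")
  rownames(trace_meta) <- NULL

  structure(list(positions = positions, locus_table = locus_table,
                 trace_meta = trace_meta, repeat_pairs = repeat_pairs),
            class = "TraceSet")
}

#' @export
print.TraceSet <- function(x, ...) {
  dm <- dim(x$positions)
  nrep <- sum(x$locus_table$role == "repeat")
  cat(sprintf("TraceSet: %d traces x %d loci x %dD (nm)\n", dm[1], dm[2], dm[3]))
  if (nrep) cat(sprintf("  %d repeat-imaged loci (%d pairs)\n",
                        nrep, nrow(x$repeat_pairs)))
  eff <- detection_efficiency(x)
  cat(sprintf("  detection efficiency: mean %.3f (range %.3f-%.3f)\n",
              mean(eff), min(eff), max(eff)))
  invisible(x)
}

#' Trace-set dimensions and masks
#'
#' `n_traces`, `n_loci` and `n_dims` return the array dimensions;
#' `localized_mask` the `N x L` logical matrix of localized spots;
#' `detection_efficiency` the per-trace fraction of localized loci;
#' `initial_loci` the indices of initially imaged (non-repeat) loci.
#'
#' @param ts a `TraceSet`.
#' @return see description.
#' @export
n_traces <- function(ts) dim(ts$positions)[1]

#' @rdname n_traces
#' @export
n_loci <- function(ts) dim(ts$positions)[2]

#' @rdname n_traces
#' @export
n_dims <- function(ts) dim(ts$positions)[3]

#' @rdname n_traces
#' @export
localized_mask <- function(ts) !is.na(ts$positions[, , 1, drop = FALSE])[, , 1, drop = TRUE]

#' @rdname n_traces
#' @export
detection_efficiency <- function(ts) rowMeans(localized_mask(ts))

#' @rdname n_traces
#' @export
initial_loci <- function(ts) which(ts$locus_table$role == "initial")

#' Subset a TraceSet by trace
#'
#' @param ts a `TraceSet`.
#' @param keep logical or integer index over traces.
#' @return a `TraceSet` with the selected traces.
#' @export
subset_traces <- function(ts, keep) {
  trace_set(ts$positions[keep, , , drop = FALSE],
            locus_table = ts$locus_table,
            trace_meta = ts$trace_meta[keep, , drop = FALSE],
            repeat_pairs = ts$repeat_pairs)
}

# replace coordinates, keep metadata
set_positions <- function(ts, positions) {
  trace_set(positions, locus_table = ts$locus_table,
            trace_meta = ts$trace_meta, repeat_pairs = ts$repeat_pairs)
}

#' Observed/truth pair for simulation studies
#'
#' Bundles an observed `TraceSet`, the underlying ground truth, and the
#' injected localization noise, with `observed = truth + noise` wherever a
#' spot is localized. Simulators return this so that error-recovery oracles
#' can be computed directly from the stored noise.
#'
#' @param observed,truth `TraceSet`s of identical shape.
#' @param noise numeric array of the same shape as the positions (0/NA where
#'   missing).
#' @return an object of class `GroundTruthPair`.
#' @export
ground_truth_pair <- function(observed, truth, noise) {
  stopifnot(inherits(observed, "TraceSet"), inherits(truth, "TraceSet"))
  if (!identical(dim(observed$positions), dim(truth$positions)))
    stop("observed and truth have different shapes")
  if (!identical(dim(noise), dim(truth$positions)))
    stop("noise has wrong shape")
  resid <- observed$positions - (truth$positions + noise)
  if (any(abs(resid) > 1e-6, na.rm = TRUE))
    stop("observed != truth + noise")
  structure(list(observed = observed, truth = truth, noise = noise),
            class = "GroundTruthPair")
}

#' @export
print.GroundTruthPair <- function(x, ...) {
  cat("GroundTruthPair\n  observed: ")
  print(x$observed)
  cat(sprintf("  injected noise sd: %.2f nm\n", stats::sd(x$noise, na.rm = TRUE)))
  invisible(x)
}
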