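#' Minimum distance to neighboring loci
#'
#' For each localized spot, the Euclidean distance to the localized previous
#' and next genomic neighbor in the same trace is computed and the smaller
#' one taken. A missing immediate neighbor is skipped up to a genomic gap of
#' two positions (i.e. locus `l-1`, else `l-2`); beyond that the neighbor is
#' considered unavailable. Spots with no available neighbor get `NA` (they
#' are flagged, never removed on this basis). Repeat-imaged loci use the
#' genomic neighbors of their initially imaged twin, not the twin itself.
#'
#' The metric is the basis of off-target detection: a genuine localization
#' sits close to its genomic neighbors, whereas an off-target spot is far
#' from both.
#'
#' @param ts a `TraceSet` with loci in genomic order (enforced on
#'   construction).
#' @return numeric `N x L` matrix of distances (nm), `NA` where undefined.
#' @export
min_neighbor_distance <- function(ts) {
  N <- n_traces(ts); L <- n_loci(ts); D <- n_dims(ts)
  pos <- ts$positions
  loc <- localized_mask(ts)
  if (is.null(dim(loc))) loc <- matrix(loc, nrow = N)
  ini <- initial_loci(ts)
  P <- length(ini)

  # chain position of every locus: its own rank for initial loci, the
  # twin's rank for repeat loci
  chain_pos <- match(seq_len(L), ini)
  if (nrow(ts$repeat_pairs)) {
    rp <- ts$repeat_pairs
    chain_pos[rp$repeat_locus] <- match(rp$initial_locus, ini)
  }

  dist_ll <- function(l, m) {
    s <- 0
    for (d in seq_len(D)) s <- s + (pos[, l, d] - pos[, m, d])^2
    sqrt(s)
  }
  # first localized candidate wins (gap 1 preferred over gap 2)
  neighbor_dist <- function(l, cands) {
    out <- rep(NA_real_, N)
    for (m in cands) {
      fill <- is.na(out) & loc[, l] & loc[, m]
      if (any(fill)) out[fill] <- dist_ll(l, m)[fill]
    }
    out
  }

  mnd <- matrix(NA_real_, N, L)
  for (l in seq_len(L)) {
    p <- chain_pos[l]
    if (is.na(p)) next
    ip <- (p - (1:2)); ip <- ip[ip >= 1]
    nx <- (p + (1:2)); nx <- nx[nx <= P]
    prev_c <- ini[ip]; prev_c <- prev_c[prev_c != l]
    next_c <- ini[nx]; next_c <- next_c[next_c != l]
    pd <- if (length(prev_c)) neighbor_dist(l, prev_c) else rep(NA_real_, N)
    nd <- if (length(next_c)) neighbor_dist(l, next_c) else rep(NA_real_, N)
    both_na <- is.na(pd) & is.na(nd)
    mnd[, l] <- pmin(pd, nd, na.rm = TRUE)
    mnd[both_na, l] <- NA_real_
  }
  mnd
}

new_filter_report <- function(metric, removed, reason, threshold,
                              n_before, n_after, detection_efficiency = NULL) {
  structure(list(metric = metric, removed = removed, reason = reason,
                 threshold = threshold, n_before = n_before, n_after = n_after,
                 detection_efficiency = detection_efficiency),
            class = "FilterReport")
}

#' @export
print.FilterReport <- function(x, ...) {
  cat(sprintf("FilterReport (%s): %d -> %d localizations/traces (%d removed)\n",
              x$reason, x$n_before, x$n_after, x$n_before - x$n_after))
  invisible(x)
}

#' Remove off-target localizations
#'
#' Localizations whose [min_neighbor_distance()] exceeds a threshold are set
#' to missing. The threshold is either an absolute distance in nm or (by
#' default) the 0.995 quantile of the pooled metric. Spots with an undefined
#' metric are never removed. As a guard against mis-set units, the filter
#' refuses to remove more than 20% of localizations unless `force = TRUE`.
#'
#' @param ts a `TraceSet`.
#' @param threshold absolute distance threshold in nm (overrides `quantile`).
#' @param quantile pooled-metric quantile in (0.9, 1) used when no absolute
#'   threshold is given; default 0.995.
#' @param force allow removal of more than 20% of localizations.
#' @return `list(traces = <filtered TraceSet>, report = <FilterReport>)`.
#' @export
filter_off_target <- function(ts, threshold = NULL, quantile = 0.995,
                              force = FALSE) {
  if (is.null(threshold)) {
    if (quantile <= 0.9 || quantile >= 1)
      stop("quantile must be in (0.9, 1)")
  } else if (threshold <= 0) {
    stop("threshold must be positive")
  }
  metric <- min_neighbor_distance(ts)
  thr <- threshold %||% stats::quantile(metric, quantile, na.rm = TRUE, names = FALSE)
  removed <- !is.na(metric) & metric > thr
  n_loc <- sum(localized_mask(ts))
  if (sum(removed) > 0.2 * n_loc && !force)
    stop(sprintf("threshold %.1f nm would remove %d of %d localizations (> 20%%); use force = TRUE if intended",
                 thr, sum(removed), n_loc))
  pos <- ts$positions
  for (d in seq_len(n_dims(ts))) {
    pd <- pos[, , d]
    pd[removed] <- NA_real_
    pos[, , d] <- pd
  }
  out <- set_positions(ts, pos)
  report <- new_filter_report(metric, removed, "off_target", thr,
                              n_loc, n_loc - sum(removed))
  list(traces = out, report = report)
}

#' Drop traces with low detection efficiency
#'
#' Detection efficiency is the fraction of a trace's loci that were
#' localized. Traces with efficiency below `min_eff` are dropped; the
#' boundary is inclusive (a trace at exactly `min_eff` is retained). Deep
#' multi-way contact analyses typically require near-complete traces
#' (e.g. `min_eff = 0.95`).
#'
#' @param ts a `TraceSet`.
#' @param min_eff minimum detection efficiency in (0, 1].
#' @return `list(traces = <filtered TraceSet>, report = <FilterReport>)`.
#' @export
filter_by_detection <- function(ts, min_eff = 0.95) {
  if (min_eff <= 0 || min_eff > 1) stop("min_eff must be in (0, 1]")
  eff <- detection_efficiency(ts)
  keep <- eff >= min_eff
  if (!any(keep))
    stop("all traces dropped at min_eff = ", min_eff, "; lower the cutoff")
  report <- new_filter_report(metric = eff, removed = !keep,
                              reason = "low_detection", threshold = min_eff,
                              n_before = length(keep), n_after = sum(keep),
                              detection_efficiency = eff)
  list(traces = subset_traces(ts, keep), report = report)
}
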