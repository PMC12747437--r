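#' Pairwise contact frequencies
#'
#' For chromatin traces, the contact frequency of a locus pair is the
#' proportion of traces in which both loci are localized and their Euclidean
#' distance is at or below a threshold (150 or 200 nm are common choices).
#' Pairs with fewer than `min_n` co-localized traces are masked (`NA`).
#'
#' @param ts a `TraceSet`.
#' @param threshold contact distance threshold in nm (> 0).
#' @param min_n minimum co-localized traces per pair (default 50).
#' @param loci locus indices to include; defaults to the initially imaged
#'   loci.
#' @return an object of class `ContactMap`: `freq` and `count` matrices
#'   (`length(loci)` square, diagonal `NA`), `threshold`, `min_n`, `loci`.
#' @export
contact_frequency <- function(ts, threshold, min_n = 50, loci = NULL) {
  if (threshold <= 0) stop("threshold must be > 0")
  loci <- loci %||% initial_loci(ts)
  P <- length(loci)
  D <- n_dims(ts)
  pos <- ts$positions
  freq <- matrix(NA_real_, P, P)
  count <- matrix(0L, P, P)
  for (a in seq_len(P - 1)) {
    for (b in (a + 1):P) {
      s <- 0
      for (d in seq_len(D)) s <- s + (pos[, loci[a], d] - pos[, loci[b], d])^2
      s <- sqrt(s)
      ok <- !is.na(s)
      count[a, b] <- count[b, a] <- sum(ok)
      if (any(ok)) freq[a, b] <- freq[b, a] <- mean(s[ok] <= threshold)
    }
  }
  freq[count < min_n] <- NA_real_
  diag(freq) <- NA_real_
  structure(list(freq = freq, count = count, threshold = threshold,
                 min_n = min_n, loci = loci),
            class = "ContactMap")
}

#' @export
print.ContactMap <- function(x, ...) {
  cat(sprintf("ContactMap: %d loci, threshold %g nm, %d masked pairs\n",
              nrow(x$freq), x$threshold,
              (sum(is.na(x$freq)) - nrow(x$freq)) / 2))
  invisible(x)
}

#' Multi-way contact frequencies
#'
#' The k-way contact frequency of a locus tuple is the proportion of traces
#' (with all members localized) in which *every* pairwise distance is at or
#' below the threshold. Tuples are usable only when every pair of members
#' has at least `min_n_pairs` co-localized traces (default 1000), the
#' data-sufficiency rule for higher-order contacts.
#'
#' @param ts a `TraceSet`.
#' @param k tuple size, 3 or 4.
#' @param threshold contact distance threshold in nm.
#' @param min_n_pairs minimum co-localized traces for every member pair
#'   (default 1000).
#' @param loci locus indices to include; defaults to initially imaged loci.
#' @return a data frame of class `MultiwayTable`: columns `l1..lk` (indices
#'   into `loci`), `n` (traces with all members localized), `observed`
#'   frequency, `min_pair_count`, `usable`.
#' @export
multiway_contact_frequency <- function(ts, k, threshold, min_n_pairs = 1000,
                                       loci = NULL) {
  if (!k %in% c(3, 4)) stop("k must be 3 or 4")
  if (threshold <= 0) stop("threshold must be > 0")
  loci <- loci %||% initial_loci(ts)
  P <- length(loci)
  if (P < k) stop("fewer loci than k")
  tuples <- t(combn(P, k))
  counts <- multiway_counts_cpp(ts$positions[, loci, , drop = FALSE],
                                c(n_traces(ts), P, n_dims(ts)),
                                tuples, threshold)
  # pair co-localization counts from the localization mask
  loc <- localized_mask(ts)[, loci, drop = FALSE]
  pc <- crossprod(loc * 1)
  mpc <- apply(tuples, 1, function(tp) {
    pr <- combn(tp, 2)
    min(pc[cbind(pr[1, ], pr[2, ])])
  })
  out <- as.data.frame(tuples)
  names(out) <- paste0("l", seq_len(k))
  out$n <- counts[, 1]
  out$observed <- ifelse(counts[, 1] > 0, counts[, 2] / counts[, 1], NA_real_)
  out$min_pair_count <- mpc
  out$usable <- mpc >= min_n_pairs
  attr(out, "threshold") <- threshold
  attr(out, "k") <- k
  attr(out, "loci") <- loci
  class(out) <- c("MultiwayTable", "data.frame")
  out
}

#' Independence baseline for multi-way contacts
#'
#' Expected k-way contact frequency if the pairwise contact events
#' contributed independently: the product of all `choose(k, 2)` pairwise
#' frequencies of the tuple. The excess of the observed k-way frequency over
#' this baseline measures cooperativity. Tuples touching a masked pair get
#' `NA`.
#'
#' @param cm a [contact_frequency()] map.
#' @param k tuple size, 3 or 4.
#' @return data frame with columns `l1..lk` (same tuple order as
#'   [multiway_contact_frequency()] over the same loci) and `expected`.
#' @export
expected_independent_multiway <- function(cm, k) {
  if (!k %in% c(3, 4)) stop("k must be 3 or 4")
  P <- nrow(cm$freq)
  tuples <- t(combn(P, k))
  expected <- apply(tuples, 1, function(tp) {
    pr <- combn(tp, 2)
    prod(cm$freq[cbind(pr[1, ], pr[2, ])])
  })
  out <- as.data.frame(tuples)
  names(out) <- paste0("l", seq_len(k))
  out$expected <- expected
  out
}

pos_array <- function(x) if (inherits(x, "TraceSet")) x$positions else x

# N x L matrix of Euclidean distances between two position arrays
loc_dist <- function(a, b) {
  N <- dim(a)[1]; D <- dim(a)[3]
  s <- 0
  for (d in seq_len(D))
    s <- s + (matrix(a[, , d], nrow = N) - matrix(b[, , d], nrow = N))^2
  sqrt(s)
}

#' Relative localization error after correction
#'
#' With a known ground truth `T`, the per-locus relative error is the mean
#' Euclidean error of the adjusted positions divided by the mean error of
#' the raw observations, `mean(|A - T|) / mean(|O - T|)`: values below 1
#' mean the correction helped; `100 * (1 - ratio)` is the percent
#' improvement. The per-trace variant averages the per-spot ratios
#' `|A_i - T_i| / |O_i - T_i|` over the loci of each trace, skipping spots
#' with `|O - T| < 1e-6` nm.
#'
#' @param adjusted,observed,truth `TraceSet`s or position arrays of
#'   identical shape.
#' @param loci locus indices to include (default: all columns present).
#' @return `relative_error_per_locus`: numeric vector over `loci`;
#'   `relative_error_per_trace`: numeric vector over traces (`NA` with a
#'   warning for traces whose spots were all skipped).
#' @export
relative_error_per_locus <- function(adjusted, observed, truth, loci = NULL) {
  A <- pos_array(adjusted); O <- pos_array(observed); Tt <- pos_array(truth)
  stopifnot(identical(dim(A), dim(O)), identical(dim(O), dim(Tt)))
  loci <- loci %||% seq_len(dim(A)[2])
  ea <- loc_dist(A, Tt)[, loci, drop = FALSE]
  eo <- loc_dist(O, Tt)[, loci, drop = FALSE]
  colMeans(ea, na.rm = TRUE) / colMeans(eo, na.rm = TRUE)
}

#' @rdname relative_error_per_locus
#' @param eps spots with raw error below `eps` nm are skipped in the
#'   per-trace ratios.
#' @export
relative_error_per_trace <- function(adjusted, observed, truth, loci = NULL,
                                     eps = 1e-6) {
  A <- pos_array(adjusted); O <- pos_array(observed); Tt <- pos_array(truth)
  stopifnot(identical(dim(A), dim(O)), identical(dim(O), dim(Tt)))
  loci <- loci %||% seq_len(dim(A)[2])
  ea <- loc_dist(A, Tt)[, loci, drop = FALSE]
  eo <- loc_dist(O, Tt)[, loci, drop = FALSE]
  ratio <- ea / eo
  ratio[!is.na(eo) & eo < eps] <- NA_real_
  out <- rowMeans(ratio, na.rm = TRUE)
  out[is.nan(out)] <- NA_real_
  if (all(is.na(out)))
    warning("all per-trace ratios undefined (raw errors below eps)")
  out
}

#' Difference between two contact maps
#'
#' Elementwise `cm1 - cm2`; masked entries propagate (a pair masked in
#' either map is `NA` in the difference). Typical use: condition contrasts
#' (e.g. transcribing vs silent alleles, or with vs without a boundary
#' element).
#'
#' @param cm1,cm2 [contact_frequency()] maps over the same loci and
#'   threshold.
#' @return signed numeric matrix.
#' @export
contact_map_difference <- function(cm1, cm2) {
  if (!identical(dim(cm1$freq), dim(cm2$freq)))
    stop("contact maps have different shapes")
  if (!isTRUE(all.equal(cm1$threshold, cm2$threshold)))
    stop("contact maps use different thresholds")
  cm1$freq - cm2$freq
}

#' Frobenius distance between two contact maps
#'
#' Root sum of squared differences over the pairs unmasked in both maps;
#' used to score how closely a corrected map recovers a reference map.
#'
#' @param cm1,cm2 [contact_frequency()] maps of identical shape and
#'   threshold.
#' @return non-negative scalar.
#' @export
contact_map_frobenius <- function(cm1, cm2) {
  if (!identical(dim(cm1$freq), dim(cm2$freq)))
    stop("contact maps have different shapes")
  d <- cm1$freq - cm2$freq
  sqrt(sum(d[upper.tri(d)]^2, na.rm = TRUE))
}
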