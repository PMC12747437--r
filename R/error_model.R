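#' Localization-error model
#'
#' Per-locus, per-dimension standard deviations of the localization error, in
#' nm. Loci for which no direct estimate exists carry the shared per-round,
#' per-dimension mean. `provenance` records how the model was obtained:
#' `"estimated_repeats"`, `"worst_case_bound"` or `"user_supplied"`.
#'
#' @param sigma numeric `L x D` matrix of error STDs (nm, finite, >= 0).
#' @param provenance character scalar, see above.
#' @param round_means optional data frame with per-dimension mean sigma for
#'   the initial and repeat imaging rounds.
#' @return an object of class `ErrorModel`.
#' @export
error_model <- function(sigma, provenance = "user_supplied", round_means = NULL) {
  sigma <- as.matrix(sigma)
  if (any(!is.finite(sigma)) || any(sigma < 0))
    stop("sigma must be finite and >= 0")
  if (!provenance %in% c("estimated_repeats", "worst_case_bound", "user_supplied"))
    stop("unknown provenance")
  structure(list(sigma = sigma, provenance = provenance,
                 round_means = round_means),
            class = "ErrorModel")
}

#' @export
print.ErrorModel <- function(x, ...) {
  cat(sprintf("ErrorModel (%s): %d loci x %d dims, mean sigma %.1f nm\n",
              x$provenance, nrow(x$sigma), ncol(x$sigma), mean(x$sigma)))
  if (!is.null(x$round_means)) print(x$round_means)
  invisible(x)
}

# uniform model: one sigma per dimension (recycled scalar allowed)
uniform_error_model <- function(ts, sigma, provenance = "user_supplied") {
  D <- n_dims(ts)
  sigma <- rep(sigma, length.out = D)
  error_model(matrix(sigma, nrow = n_loci(ts), ncol = D, byrow = TRUE),
              provenance = provenance)
}

# pairwise-complete variance of the displacement between two position columns
pair_var <- function(x, y) {
  d <- x - y
  d <- d[!is.na(d)]
  if (length(d) < 2) return(c(v = NA_real_, n = length(d)))
  c(v = var(d), n = length(d))
}

#' Estimate localization error from repeat-imaged loci
#'
#' When a locus is hybridized and imaged twice in the same cell, the two
#' copies share a true position, so per dimension the displacement variance
#' between the initial copy `a` and the repeat copy `r` satisfies
#' `Var(O^a - O^r) = Var(e^a) + Var(e^r)`. A second, independent moment
#' equation separates the two rounds: averaging over third loci `b`,
#' `Var(O^a - O^b) - Var(O^r - O^b) = Var(e^a) - Var(e^r)`, because the true
#' displacement term is common to both. Solving the 2x2 linear system per
#' repeat pair and dimension gives both error variances; negative solutions
#' (possible from sampling noise) are clamped to zero with a warning.
#'
#' @param ts a `TraceSet` with non-empty `repeat_pairs`.
#' @param min_n minimum number of co-localized traces for a displacement
#'   variance to enter the system (default 50); data-poor pairs are skipped
#'   with a warning.
#' @return an `ErrorModel` with provenance `"estimated_repeats"`;
#'   `$round_means` holds the per-dimension mean STD for the initial and
#'   repeat rounds, `$pair_estimates` the per-pair detail.
#' @export
estimate_error_from_repeats <- function(ts, min_n = 50) {
  if (!nrow(ts$repeat_pairs))
    stop("no repeat-imaged locus pairs; use worst_case_error_bound() or a ",
         "user-supplied ErrorModel")
  L <- n_loci(ts); D <- n_dims(ts)
  pos <- ts$positions
  others <- initial_loci(ts)

  est <- list()
  for (p in seq_len(nrow(ts$repeat_pairs))) {
    a <- ts$repeat_pairs$initial_locus[p]
    r <- ts$repeat_pairs$repeat_locus[p]
    for (d in seq_len(D)) {
      s <- pair_var(pos[, a, d], pos[, r, d])
      if (is.na(s["v"]) || s["n"] < min_n) {
        warning(sprintf("repeat pair (%d, %d) skipped in dim %d: only %d co-localized traces",
                        a, r, d, s["n"]))
        next
      }
      diffs <- vapply(setdiff(others, a), function(b) {
        va <- pair_var(pos[, a, d], pos[, b, d])
        vr <- pair_var(pos[, r, d], pos[, b, d])
        if (is.na(va["v"]) || is.na(vr["v"]) || va["n"] < min_n || vr["n"] < min_n)
          return(NA_real_)
        va[["v"]] - vr[["v"]]
      }, numeric(1))
      diffs <- diffs[!is.na(diffs)]
      if (!length(diffs)) {
        warning(sprintf("repeat pair (%d, %d), dim %d: no third locus with >= %d co-localized traces",
                        a, r, d, min_n))
        next
      }
      S <- s[["v"]]          # Var(e_a) + Var(e_r)
      Dm <- mean(diffs)      # Var(e_a) - Var(e_r)
      va <- (S + Dm) / 2
      vr <- (S - Dm) / 2
      if (va < 0 || vr < 0) {
        warning(sprintf("negative variance solution for pair (%d, %d), dim %d; clamped to 0",
                        a, r, d))
        va <- max(va, 0); vr <- max(vr, 0)
      }
      est[[length(est) + 1]] <- data.frame(
        initial_locus = a, repeat_locus = r, dim = d,
        sigma_init = sqrt(va), sigma_rep = sqrt(vr), n = s[["n"]]
      )
    }
  }
  if (!length(est)) stop("no repeat pair had sufficient co-localized traces")
  est <- do.call(rbind, est)

  round_means <- do.call(rbind, lapply(seq_len(D), function(d) {
    e <- est[est$dim == d, ]
    data.frame(dim = d,
               sigma_initial = if (nrow(e)) mean(e$sigma_init) else NA_real_,
               sigma_repeat = if (nrow(e)) mean(e$sigma_rep) else NA_real_)
  }))

  # per-locus sigma: direct estimates where available, round mean elsewhere
  sigma <- matrix(NA_real_, L, D)
  role <- ts$locus_table$role
  for (d in seq_len(D)) {
    sigma[role == "initial", d] <- round_means$sigma_initial[d]
    sigma[role == "repeat", d] <- round_means$sigma_repeat[d]
    e <- est[est$dim == d, ]
    sigma[e$initial_locus, d] <- e$sigma_init
    sigma[e$repeat_locus, d] <- e$sigma_rep
  }
  sigma[is.na(sigma)] <- 0
  em <- error_model(sigma, provenance = "estimated_repeats",
                    round_means = round_means)
  em$pair_estimates <- est
  em
}

#' Worst-case localization-error bound from neighboring loci
#'
#' Without repeat-imaged loci the error cannot be separated from true spatial
#' variation, but it can be bounded: for any locus pair,
#' `Var(O^a - O^b) >= Var(e^a) + Var(e^b)`, so half the smallest displacement
#' variance over genomically adjacent pairs bounds the (homogeneous) error
#' variance from above. The bound is tight when the adjacent loci move
#' together, and an overestimate otherwise.
#'
#' @param ts a `TraceSet` with at least two initially imaged loci.
#' @param min_n minimum co-localized traces per adjacent pair (default 50).
#' @return an `ErrorModel` with provenance `"worst_case_bound"` carrying one
#'   shared sigma per dimension.
#' @export
worst_case_error_bound <- function(ts, min_n = 50) {
  ini <- initial_loci(ts)
  if (length(ini) < 2) stop("need at least two initially imaged loci")
  D <- n_dims(ts)
  pos <- ts$positions
  smax <- numeric(D)
  for (d in seq_len(D)) {
    vs <- vapply(seq_len(length(ini) - 1), function(k) {
      s <- pair_var(pos[, ini[k], d], pos[, ini[k + 1], d])
      if (is.na(s["v"]) || s["n"] < min_n) NA_real_ else s[["v"]]
    }, numeric(1))
    vs <- vs[!is.na(vs)]
    if (!length(vs))
      stop("no adjacent locus pair with >= ", min_n, " co-localized traces")
    smax[d] <- sqrt(min(vs) / 2)
  }
  error_model(matrix(smax, nrow = n_loci(ts), ncol = D, byrow = TRUE),
              provenance = "worst_case_bound")
}

#' Serialize an ErrorModel to JSON
#'
#' @param em an `ErrorModel`.
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_error_model <- function(em, path) {
  jsonlite::write_json(list(sigma = em$sigma, provenance = em$provenance,
                            round_means = em$round_means),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_error_model
#' @export
read_error_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  error_model(x$sigma, provenance = x$provenance,
              round_means = x$round_means)
}
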