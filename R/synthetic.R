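#' Simulation settings for synthetic chromatin traces
#'
#' Describes a Gaussian-chain ensemble standing in for chromatin at a given
#' genomic resolution. Defaults emulate fine (1 kb-scale) tracing data: with
#' a per-axis step STD of 30 nm the mean 3D neighbor distance is about
#' 30*sqrt(3) ~ 52 nm, comfortably below typical 25-100 nm localization
#' errors — the regime where variance-matching correction is most effective.
#'
#' @param L number of loci.
#' @param N number of traces.
#' @param D spatial dimensions (default 3).
#' @param model `"gaussian_chain"` (free chain) or `"confined_chain"`
#'   (each trace rescaled to the ensemble-mean radius of gyration).
#' @param step_sd per-axis STD of the displacement between consecutive loci
#'   (nm, default 30).
#' @param resolution_bp genomic spacing label (default 1000).
#' @param dropout i.i.d. probability that a localization is missing
#'   (default 0).
#' @param seed RNG seed; fixed seed gives identical trace sets.
#' @return an object of class `SimulationSpec`.
#' @export
simulation_spec <- function(L = 100L, N = 500L, D = 3L,
                            model = c("gaussian_chain", "confined_chain"),
                            step_sd = 30, resolution_bp = 1000,
                            dropout = 0, seed = 1L) {
  model <- match.arg(model)
  stopifnot(L >= 2, N >= 1, D %in% 1:3, step_sd > 0,
            dropout >= 0, dropout < 1, resolution_bp > 0)
  structure(list(L = as.integer(L), N = as.integer(N), D = as.integer(D),
                 model = model, step_sd = step_sd,
                 resolution_bp = resolution_bp, dropout = dropout,
                 seed = as.integer(seed)),
            class = "SimulationSpec")
}

#' Generate polymer-like ground-truth traces
#'
#' Each trace is an independent chain: locus 1 at the origin, each following
#' locus displaced by `Normal(0, step_sd)` per axis, so loci `k` apart have
#' displacement variance `k * step_sd^2` per axis. The confined variant
#' rescales every trace to the ensemble-mean radius of gyration. Dropout is
#' applied i.i.d. per localization. The result is returned as a
#' [ground_truth_pair()] with `observed = truth` (no noise yet); inject
#' noise with [add_localization_error()].
#'
#' @param spec a [simulation_spec()].
#' @return a `GroundTruthPair` with zero noise.
#' @export
generate_polymer_traces <- function(spec) {
  stopifnot(inherits(spec, "SimulationSpec"))
  set.seed(spec$seed)
  N <- spec$N; L <- spec$L; D <- spec$D
  pos <- array(0, c(N, L, D))
  for (d in seq_len(D)) {
    steps <- matrix(rnorm(N * (L - 1), 0, spec$step_sd), N, L - 1)
    pos[, 2:L, d] <- t(apply(steps, 1, cumsum))
  }
  if (spec$model == "confined_chain") {
    target_rg2 <- D * spec$step_sd^2 * (L^2 - 1) / (6 * L)
    for (i in seq_len(N)) {
      x <- matrix(pos[i, , ], L, D)
      x <- sweep(x, 2, colMeans(x))
      rg2 <- mean(rowSums(x^2))
      pos[i, , ] <- x * sqrt(target_rg2 / rg2)
    }
  }
  if (spec$dropout > 0) {
    drop <- matrix(runif(N * L) < spec$dropout, N, L)
    for (d in seq_len(D)) {
      pd <- pos[, , d]
      pd[drop] <- NA_real_
      pos[, , d] <- pd
    }
  }
  truth <- trace_set(pos, resolution_bp = spec$resolution_bp)
  ground_truth_pair(truth, truth, array(0, dim(pos)))
}

#' Inject Gaussian localization error
#'
#' Adds `Normal(0, sigma_d)` noise per axis to the truth, storing the
#' injected values, so recovery oracles can compare corrections against the
#' exact noise realization. Missing spots stay missing.
#'
#' @param gt a `GroundTruthPair` (its `truth` component is used).
#' @param sigma error STD in nm; scalar or one value per dimension.
#' @param seed RNG seed.
#' @return a new `GroundTruthPair` with `observed = truth + noise`.
#' @export
add_localization_error <- function(gt, sigma, seed = 1L) {
  stopifnot(inherits(gt, "GroundTruthPair"), all(sigma >= 0))
  dm <- dim(gt$truth$positions)
  D <- dm[3]
  sigma <- rep(sigma, length.out = D)
  set.seed(seed)
  noise <- array(rnorm(prod(dm)), dm)
  for (d in seq_len(D)) noise[, , d] <- noise[, , d] * sigma[d]
  noise[is.na(gt$truth$positions)] <- NA_real_
  obs <- set_positions(gt$truth, gt$truth$positions + noise)
  noise[is.na(noise)] <- 0
  ground_truth_pair(obs, gt$truth, noise)
}

#' Linear genomic interpolation of traces
#'
#' Inserts `factor - 1` equally spaced points on every segment between
#' consecutive loci, emulating a dataset probed at a `factor`-fold finer
#' genomic resolution (e.g. 5 kb data interpolated 5x approximates 1 kb
#' data). Genomic coordinates are interpolated likewise. Segments with a
#' missing endpoint yield missing interpolants; original loci keep their
#' values. Intended for truth-like (noise-free) data: interpolating noisy
#' coordinates interpolates the noise too.
#'
#' @param ts a `TraceSet`.
#' @param factor integer >= 1; 1 is the identity.
#' @return a `TraceSet` with `factor * (L - 1) + 1` loci.
#' @export
interpolate_traces <- function(ts, factor) {
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1) stop("factor must be an integer >= 1")
  if (factor == 1) return(ts)
  N <- n_traces(ts); L <- n_loci(ts); D <- n_dims(ts)
  if (any(ts$locus_table$role != "initial"))
    stop("interpolation expects initial loci only")
  L2 <- factor * (L - 1) + 1
  pos2 <- array(NA_real_, c(N, L2, D))
  start2 <- numeric(L2)
  lt <- ts$locus_table
  for (j in seq_len(L - 1)) {
    w <- (0:(factor - 1)) / factor
    cols <- (j - 1) * factor + seq_len(factor)
    pos2[, cols[1], ] <- ts$positions[, j, ]   # original locus kept as-is
    start2[cols[1]] <- lt$start[j]
    for (m in seq_along(w)[-1]) {
      pos2[, cols[m], ] <- (1 - w[m]) * ts$positions[, j, ] +
        w[m] * ts$positions[, j + 1, ]
      start2[cols[m]] <- (1 - w[m]) * lt$start[j] + w[m] * lt$start[j + 1]
    }
  }
  pos2[, L2, ] <- ts$positions[, L, ]
  start2[L2] <- lt$start[L]
  res2 <- (lt$start[2] - lt$start[1]) / factor
  lt2 <- data.frame(chrom = lt$chrom[1], start = round(start2),
                    end = round(start2 + res2), role = "initial",
                    stringsAsFactors = FALSE)
  trace_set(pos2, locus_table = lt2, trace_meta = ts$trace_meta)
}

#' Simulate repeat imaging of selected loci
#'
#' Re-imaging a locus in the same cell yields a second localization of the
#' same true position with an independent error draw — in real experiments
#' typically a *larger* one, since re-hybridized spots tend to be dimmer.
#' All initially imaged loci receive `Normal(0, sigma_init)` noise; the
#' selected loci are additionally appended as repeat copies with
#' `Normal(0, sigma_rep)` noise and recorded in `repeat_pairs`.
#'
#' @param gt a `GroundTruthPair` (its `truth` is re-imaged).
#' @param loci indices of loci to re-image.
#' @param sigma_init,sigma_rep per-axis error STD (nm) of the initial and
#'   repeat rounds; scalar or one value per dimension.
#' @param seed RNG seed.
#' @return a `GroundTruthPair` whose `observed` trace set contains the
#'   repeat copies and repeat-pair table; `truth` is expanded to match.
#' @export
simulate_repeat_imaging <- function(gt, loci, sigma_init, sigma_rep, seed = 1L) {
  stopifnot(inherits(gt, "GroundTruthPair"))
  truth <- gt$truth
  N <- n_traces(truth); L <- n_loci(truth); D <- n_dims(truth)
  loci <- sort(unique(as.integer(loci)))
  if (any(loci < 1 | loci > L)) stop("repeat locus index out of range")
  sigma_init <- rep(sigma_init, length.out = D)
  sigma_rep <- rep(sigma_rep, length.out = D)

  L2 <- L + length(loci)
  # interleave: each repeat copy directly after its initial locus
  src <- integer(L2); role <- character(L2)
  j <- 1L
  rp_init <- integer(length(loci)); rp_rep <- integer(length(loci)); r <- 1L
  for (l in seq_len(L)) {
    src[j] <- l; role[j] <- "initial"; ini_idx <- j; j <- j + 1L
    if (l %in% loci) {
      src[j] <- l; role[j] <- "repeat"
      rp_init[r] <- ini_idx; rp_rep[r] <- j
      r <- r + 1L; j <- j + 1L
    }
  }
  truth2 <- array(truth$positions[, src, ], c(N, L2, D))
  lt0 <- truth$locus_table
  lt2 <- data.frame(chrom = lt0$chrom[src], start = lt0$start[src],
                    end = lt0$end[src], role = role, stringsAsFactors = FALSE)

  set.seed(seed)
  noise <- array(rnorm(N * L2 * D), c(N, L2, D))
  for (d in seq_len(D)) {
    sd_col <- ifelse(role == "repeat", sigma_rep[d], sigma_init[d])
    noise[, , d] <- sweep(noise[, , d, drop = FALSE][, , 1], 2, sd_col, `*`)
  }
  noise[is.na(truth2)] <- NA_real_

  rp <- data.frame(initial_locus = rp_init, repeat_locus = rp_rep)
  truth_ts <- trace_set(truth2, locus_table = lt2,
                        trace_meta = truth$trace_meta, repeat_pairs = rp)
  obs_ts <- trace_set(truth2 + noise, locus_table = lt2,
                      trace_meta = truth$trace_meta, repeat_pairs = rp)
  noise[is.na(noise)] <- 0
  ground_truth_pair(obs_ts, truth_ts, noise)
}
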