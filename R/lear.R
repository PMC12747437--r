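#' Optimizer configuration for the variance-matching correction
#'
#' Tunables of the stochastic-descent maximization of the goal-variance
#' likelihood. With a fixed `seed` the whole correction run is
#' bit-reproducible; each (locus, dimension, round) gets its own RNG stream
#' derived from `seed` by a fixed counter scheme, so results do not depend on
#' the order in which loci are processed.
#'
#' @param seed master RNG seed (integer).
#' @param sweeps maximum number of sweeps over all traces per locus
#'   (default 200).
#' @param proposal_frac proposal STD as a fraction of the locus error STD
#'   (default 0.5).
#' @param anneal multiplicative decay of the proposal STD per sweep
#'   (default 0.95).
#' @param min_n minimum co-localized traces for a locus pair to constrain
#'   the fit (default 50).
#' @param var_floor smallest admissible goal variance in nm^2 (default 1);
#'   also floors the goal-variance uncertainty at `var_floor / 10`.
#' @param rounds rounds of correction; rounds beyond the first recompute
#'   goal variances against previously adjusted partners (default 1,
#'   i.e. off).
#' @param tol convergence tolerance on the per-datum likelihood gain of a
#'   sweep (default 1e-6).
#' @return an object of class `OptimizerConfig`.
#' @export
optimizer_config <- function(seed = 1L, sweeps = 200L, proposal_frac = 0.5,
                             anneal = 0.95, min_n = 50L, var_floor = 1,
                             rounds = 1L, tol = 1e-6) {
  stopifnot(sweeps >= 1, proposal_frac > 0, anneal > 0, anneal <= 1,
            min_n >= 2, var_floor > 0, rounds >= 1, tol > 0)
  structure(list(seed = as.integer(seed), sweeps = as.integer(sweeps),
                 proposal_frac = proposal_frac, anneal = anneal,
                 min_n = as.integer(min_n), var_floor = var_floor,
                 rounds = as.integer(rounds), tol = tol),
            class = "OptimizerConfig")
}

# deterministic per-(locus, dim, round) seed below 2^31
derive_seed <- function(seed, locus, dim, round) {
  (as.double(seed) * 48271 + locus * 10007 + dim * 700001 + round * 97) %%
    2147483629
}

#' Goal-variance table
#'
#' For every ordered pair of initially imaged loci `(alpha, beta)` and one
#' imaging dimension, computes the pairwise-complete sample size `n`, the
#' empirical displacement variance `Var(O^alpha - O^beta)`, the goal mean
#' `mu = max(Var(O^alpha - O^beta) - sigma_alpha^2, var_floor)` (the
#' empirical variance with the focal locus' error variance removed) and its
#' sampling uncertainty `sd = sqrt((m4 - m2^2) / n)` from the central
#' moments of the differences — the distribution-free standard error of a
#' sample variance, requiring no normality of the true displacements.
#' Entries with `n < min_n` are marked unusable.
#'
#' @param ts a `TraceSet`.
#' @param em an `ErrorModel` covering every locus and dimension.
#' @param dim imaging dimension (1-based).
#' @param min_n minimum co-localized traces (default 50).
#' @param var_floor positive floor for goal variances in nm^2 (default 1);
#'   a warning reports how many entries were floored.
#' @return a data frame of class `GoalVarianceTable` with columns `alpha`,
#'   `beta`, `n`, `emp_var`, `mu`, `sd`, `usable`.
#' @export
compute_goal_variances <- function(ts, em, dim, min_n = 50, var_floor = 1) {
  loci <- initial_loci(ts)
  P <- length(loci)
  if (P < 2) stop("need at least two initially imaged loci")
  if (nrow(em$sigma) != n_loci(ts) || ncol(em$sigma) < dim)
    stop("ErrorModel does not cover every locus/dimension")
  x <- ts$positions[, loci, dim, drop = TRUE]
  if (is.null(dim(x))) x <- matrix(x, ncol = P)

  pairs <- combn(P, 2)
  np <- ncol(pairs)
  n <- integer(np); s2 <- m4 <- se <- numeric(np)
  for (k in seq_len(np)) {
    d <- x[, pairs[1, k]] - x[, pairs[2, k]]
    d <- d[!is.na(d)]
    n[k] <- length(d)
    if (n[k] < 2) { s2[k] <- NA; m4[k] <- NA; se[k] <- NA; next }
    db <- d - mean(d)
    m2 <- mean(db^2)
    s2[k] <- sum(db^2) / (n[k] - 1)
    m4[k] <- mean(db^4)
    se[k] <- sqrt(max((m4[k] - m2^2) / n[k], 0))
  }
  se <- pmax(se, var_floor / 10)

  a <- loci[pairs[1, ]]; b <- loci[pairs[2, ]]
  tab <- data.frame(
    alpha = c(a, b), beta = c(b, a),
    n = c(n, n), emp_var = c(s2, s2),
    mu = c(s2 - em$sigma[a, dim]^2, s2 - em$sigma[b, dim]^2),
    sd = c(se, se)
  )
  floored <- !is.na(tab$mu) & tab$mu < var_floor
  if (any(floored))
    warning(sum(floored), " goal variance(s) below ", var_floor,
            " nm^2 floored (error estimate exceeds empirical variance)")
  tab$mu <- pmax(tab$mu, var_floor)
  tab$usable <- !is.na(tab$emp_var) & tab$n >= min_n
  attr(tab, "dimension") <- dim
  attr(tab, "min_n") <- min_n
  attr(tab, "var_floor") <- var_floor
  class(tab) <- c("GoalVarianceTable", "data.frame")
  tab
}

#' Log-density of a displacement variance at its goal
#'
#' The probability of observing a displacement variance `v` given the goal
#' mean `mu` and uncertainty `sigma` is modelled as normal (the sampling
#' distribution of a sample variance is asymptotically normal by the CLT).
#'
#' @param v observed variance (nm^2).
#' @param mu goal mean (nm^2).
#' @param sigma goal uncertainty (nm^2), strictly positive.
#' @return the log-density, vectorized over the inputs.
#' @export
goal_variance_logdensity <- function(v, mu, sigma) {
  if (any(sigma <= 0)) stop("sigma must be > 0")
  dnorm(v, mean = mu, sd = sigma, log = TRUE)
}

#' Log-likelihood of an adjusted locus column
#'
#' Sums, over every usable partner locus `beta`, the
#' [goal_variance_logdensity()] of `Var(A^alpha - O^beta)` at that pair's
#' goal. Partner positions are the observed ones; variances are
#' pairwise-complete. Adding a constant to `a_alpha` leaves the value
#' unchanged (variances are translation invariant).
#'
#' @param a_alpha adjusted coordinate vector for the focal locus (length
#'   `N`, `NA` where the spot is missing).
#' @param ts the `TraceSet` supplying partner coordinates.
#' @param gvt a `GoalVarianceTable` for the same dimension.
#' @param alpha focal locus index.
#' @param dim imaging dimension; defaults to the table's.
#' @return scalar log-likelihood.
#' @export
locus_log_likelihood <- function(a_alpha, ts, gvt, alpha, dim = attr(gvt, "dimension")) {
  rows <- gvt[gvt$alpha == alpha & gvt$usable, , drop = FALSE]
  if (!nrow(rows)) stop("no usable partner loci for locus ", alpha)
  ll <- 0
  for (k in seq_len(nrow(rows))) {
    d <- a_alpha - ts$positions[, rows$beta[k], dim]
    d <- d[!is.na(d)]
    ll <- ll + goal_variance_logdensity(var(d), rows$mu[k], rows$sd[k])
  }
  ll
}

#' Optimize the corrections of a single locus
#'
#' Greedy stochastic descent: traces are visited in random order; each
#' proposal perturbs one correction by `Normal(0, proposal_frac *
#' sigma_alpha)` and is kept only if the goal-variance log-likelihood
#' improves. The proposal scale is annealed every sweep. The returned
#' corrections are mean-centered over localized spots (the likelihood is
#' translation invariant, so the gauge is fixed by zero-mean corrections,
#' preserving the ensemble centroid). Missing spots get zero correction and
#' are never proposed.
#'
#' @param alpha focal locus index.
#' @param ts a `TraceSet`.
#' @param gvt a `GoalVarianceTable` for the dimension being corrected.
#' @param cfg an [optimizer_config()].
#' @param em the `ErrorModel` (sets the proposal scale).
#' @param dim imaging dimension; defaults to the table's.
#' @return list with `C` (length-`N` corrections, nm), `loglik` (per-sweep
#'   trace, non-decreasing), `sweeps`, `converged`.
#' @export
optimize_locus <- function(alpha, ts, gvt, cfg = optimizer_config(), em,
                           dim = attr(gvt, "dimension")) {
  rows <- gvt[gvt$alpha == alpha & gvt$usable, , drop = FALSE]
  if (!nrow(rows)) stop("no usable partner loci for locus ", alpha)
  o_alpha <- ts$positions[, alpha, dim]
  sigma_alpha <- em$sigma[alpha, dim]
  if (sigma_alpha <= 0) {
    # no error to remove: goal equals the empirical variance, corrections 0
    ll <- locus_log_likelihood(o_alpha, ts, gvt, alpha, dim)
    return(list(C = rep(0, length(o_alpha)), loglik = ll, sweeps = 0L,
                converged = TRUE))
  }
  o_beta <- ts$positions[, rows$beta, dim, drop = TRUE]
  if (is.null(dim(o_beta))) o_beta <- matrix(o_beta, ncol = nrow(rows))
  fit <- optimize_locus_cpp(o_alpha, o_beta, rows$mu, rows$sd,
                            prop_sd = cfg$proposal_frac * sigma_alpha,
                            sweeps = cfg$sweeps, anneal = cfg$anneal,
                            tol = cfg$tol)
  if (!fit$converged)
    warning("locus ", alpha, " dim ", dim, ": sweep cap reached before ",
            "convergence; best-so-far corrections returned")
  C <- fit$C
  ok <- !is.na(o_alpha)
  C[ok] <- C[ok] - mean(C[ok])
  C[!ok] <- 0
  list(C = C, loglik = fit$loglik, sweeps = fit$sweeps,
       converged = fit$converged)
}

#' Run the full localization-error correction
#'
#' For each imaging dimension independently, goal variances are computed
#' from the observed data and every initially imaged locus is optimized
#' against the *observed* positions of its partners — locus runs share no
#' state, so any processing order (or parallel schedule) yields identical
#' results under a fixed seed. Repeat-imaged loci and loci without a usable
#' partner are passed through unadjusted. Optional extra rounds
#' (`cfg$rounds > 1`, off by default) recompute goal variances against the
#' previously adjusted partners.
#'
#' @param ts a `TraceSet` (typically filtered first, see
#'   [filter_off_target()]).
#' @param em an `ErrorModel` covering all loci and dimensions.
#' @param cfg an [optimizer_config()].
#' @return list of class `lear_result`: `adjusted` (`TraceSet` of
#'   `A = O + C`), `corrections` (array like the positions), `diagnostics`
#'   (per dimension: per-locus likelihood summary and the fraction of usable
#'   pairs whose achieved variance lies within 3 goal uncertainties of the
#'   goal), and `config`.
#' @export
run_lear <- function(ts, em, cfg = optimizer_config()) {
  D <- n_dims(ts)
  cur <- ts
  corrections <- array(0, dim(ts$positions))
  diagnostics <- vector("list", D)
  for (round in seq_len(cfg$rounds)) {
    new_pos <- cur$positions
    for (d in seq_len(D)) {
      gvt <- compute_goal_variances(cur, em, d, min_n = cfg$min_n,
                                    var_floor = cfg$var_floor)
      per_locus <- list()
      for (alpha in initial_loci(cur)) {
        usable <- gvt$usable[gvt$alpha == alpha]
        if (!any(usable)) {
          warning("locus ", alpha, " has no usable partner; passed through")
          next
        }
        set.seed(derive_seed(cfg$seed, alpha, d, round))
        fit <- optimize_locus(alpha, cur, gvt, cfg, em, dim = d)
        new_pos[, alpha, d] <- cur$positions[, alpha, d] + fit$C
        corrections[, alpha, d] <- corrections[, alpha, d] + fit$C
        per_locus[[length(per_locus) + 1]] <- data.frame(
          locus = alpha, round = round,
          loglik_initial = fit$loglik[1],
          loglik_final = fit$loglik[length(fit$loglik)],
          sweeps = fit$sweeps, converged = fit$converged,
          n_partners = sum(usable)
        )
      }
      diagnostics[[d]] <- list(
        locus_summary = do.call(rbind, per_locus),
        goal_table = gvt
      )
    }
    cur <- set_positions(cur, new_pos)
  }
  # achieved-vs-goal coverage, per dimension, against the original partners
  for (d in seq_len(D)) {
    gvt <- diagnostics[[d]]$goal_table
    use <- which(gvt$usable)
    within3 <- logical(length(use))
    for (k in seq_along(use)) {
      r <- gvt[use[k], ]
      dd <- cur$positions[, r$alpha, d] - ts$positions[, r$beta, d]
      dd <- dd[!is.na(dd)]
      within3[k] <- abs(var(dd) - r$mu) <= 3 * r$sd
    }
    diagnostics[[d]]$goal_coverage_3sd <- mean(within3)
  }
  structure(list(adjusted = cur, corrections = corrections,
                 diagnostics = diagnostics, config = cfg),
            class = "lear_result")
}

#' @export
print.lear_result <- function(x, ...) {
  D <- length(x$diagnostics)
  cat(sprintf("lear_result: %d traces x %d loci, %d dimension(s)\n",
              n_traces(x$adjusted), n_loci(x$adjusted), D))
  for (d in seq_len(D)) {
    ls <- x$diagnostics[[d]]$locus_summary
    cat(sprintf("  dim %d: %d loci corrected, mean RMS correction %.1f nm, goal coverage (3 sd) %.3f\n",
                d, nrow(ls),
                sqrt(mean(x$corrections[, , d]^2, na.rm = TRUE)),
                x$diagnostics[[d]]$goal_coverage_3sd))
  }
  invisible(x)
}
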