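test_that("contact frequency matches a hand-computed three-trace case", {
  # pair distances 100, 120, 400 nm at threshold 150 -> 2/3
  pos <- array(0, c(3, 2, 3))
  pos[1, 2, 1] <- 100
  pos[2, 2, 1] <- 120
  pos[3, 2, 1] <- 400
  ts <- trace_set(pos)
  cm <- contact_frequency(ts, threshold = 150, min_n = 3)
  expect_equal(cm$freq[1, 2], 2 / 3)
  expect_equal(cm$count[1, 2], 3L)
})

test_that("contact maps equal a brute-force double loop on randomized traces", {
  ts <- add_localization_error(make_chain_gt(L = 9, N = 60, step = 60, seed = 51,
                                             dropout = 0.15),
                               30, seed = 52)$observed
  th <- 120
  cm <- contact_frequency(ts, th, min_n = 10)
  pos <- ts$positions
  for (a in 1:8) for (b in (a + 1):9) {
    d <- sqrt(rowSums((pos[, a, ] - pos[, b, ])^2))
    ok <- !is.na(d)
    ref <- if (sum(ok) >= 10) mean(d[ok] <= th) else NA_real_
    expect_equal(cm$freq[a, b], ref)
    expect_equal(cm$freq[b, a], ref)     # symmetry
  }
  expect_true(all(is.na(diag(cm$freq))))
  expect_true(all(cm$freq >= 0 & cm$freq <= 1, na.rm = TRUE))
})

test_that("contact frequency is monotone in the threshold", {
  ts <- make_chain_gt(L = 8, N = 100, step = 50, seed = 53)$truth
  f1 <- contact_frequency(ts, 100, min_n = 10)$freq
  f2 <- contact_frequency(ts, 200, min_n = 10)$freq
  expect_true(all(f2 - f1 >= 0, na.rm = TRUE))
})

test_that("multi-way frequencies match brute-force enumeration", {
  ts <- add_localization_error(make_chain_gt(L = 6, N = 40, step = 60, seed = 54,
                                             dropout = 0.1),
                               25, seed = 55)$observed
  th <- 150
  mw <- multiway_contact_frequency(ts, k = 3, threshold = th, min_n_pairs = 20)
  pos <- ts$positions
  for (r in seq_len(nrow(mw))) {
    tp <- unlist(mw[r, c("l1", "l2", "l3")])
    ok <- rep(TRUE, 40); all_close <- rep(TRUE, 40)
    for (a in 1:2) for (b in (a + 1):3) {
      d <- sqrt(rowSums((pos[, tp[a], ] - pos[, tp[b], ])^2))
      ok <- ok & !is.na(d)
      all_close <- all_close & !is.na(d) & d <= th
    }
    expect_equal(mw$n[r], sum(ok))
    expect_equal(mw$observed[r], sum(all_close) / sum(ok))
  }
})

test_that("the 1000-distance sufficiency rule gates k-way tuples", {
  pos <- array(rnorm(1100 * 3 * 3, sd = 40), c(1100, 3, 3))
  pos[1:101, 3, ] <- NA                       # pair counts with locus 3: 999
  ts <- trace_set(pos)
  mw <- multiway_contact_frequency(ts, 3, threshold = 150, min_n_pairs = 1000)
  expect_equal(mw$min_pair_count, 999L)
  expect_false(mw$usable)
  mw2 <- multiway_contact_frequency(trace_set(array(rnorm(9900), c(1100, 3, 3))),
                                    3, 150, min_n_pairs = 1000)
  expect_true(mw2$usable)
  expect_error(multiway_contact_frequency(ts, 5, 150), "k must be 3 or 4")
})

test_that("a k-way contact implies each pairwise contact", {
  ts <- make_chain_gt(L = 10, N = 200, step = 40, seed = 56)$truth
  th <- 150
  cm <- contact_frequency(ts, th, min_n = 10)
  mw <- multiway_contact_frequency(ts, 3, th, min_n_pairs = 10)
  pairmin <- apply(mw[, c("l1", "l2", "l3")], 1, function(tp) {
    pr <- combn(tp, 2)
    min(cm$freq[cbind(pr[1, ], pr[2, ])])
  })
  expect_true(all(mw$observed <= pairmin + 1e-12))
})

test_that("independence baseline is the product of the pairwise frequencies", {
  cm <- list(freq = matrix(1, 4, 4), count = matrix(1e4, 4, 4),
             threshold = 150, min_n = 1, loci = 1:4)
  class(cm) <- "ContactMap"
  exp3 <- expected_independent_multiway(cm, 3)
  expect_true(all(exp3$expected == 1))

  cm$freq[] <- 0.1
  exp3 <- expected_independent_multiway(cm, 3)
  expect_equal(unique(exp3$expected), 1e-3)

  cm$freq[1, 2] <- cm$freq[2, 1] <- NA     # masked pair propagates
  exp3 <- expected_independent_multiway(cm, 3)
  expect_true(all(is.na(exp3$expected[exp3$l1 == 1 & exp3$l2 == 2])))
})

test_that("independently placed loci show no cooperativity", {
  # loci drawn i.i.d. per trace: pairwise contacts are near-independent events
  set.seed(57)
  pos <- array(runif(4000 * 5 * 3, 0, 400), c(4000, 5, 3))
  ts <- trace_set(pos)
  th <- 200
  cm <- contact_frequency(ts, th, min_n = 100)
  mw <- multiway_contact_frequency(ts, 3, th, min_n_pairs = 100)
  ex <- expected_independent_multiway(cm, 3)
  expect_equal(mw$observed, ex$expected, tolerance = 0.15)
})

test_that("relative error metrics have their fixed points and hand value", {
  gt <- make_chain_gt(L = 5, N = 30, step = 40, seed = 58)
  noisy <- add_localization_error(gt, 40, seed = 59)
  expect_true(all(relative_error_per_locus(gt$truth, noisy$observed, gt$truth) == 0))
  expect_equal(relative_error_per_locus(noisy$observed, noisy$observed, gt$truth),
               rep(1, 5), ignore_attr = TRUE)

  # one trace, two loci in 1D: |A-T| = 10, 30; |O-T| = 20, 40
  Tt <- array(0, c(1, 2, 1))
  O <- Tt; O[1, 1, 1] <- 20; O[1, 2, 1] <- 40
  A <- Tt; A[1, 1, 1] <- 10; A[1, 2, 1] <- 30
  expect_equal(relative_error_per_trace(A, O, Tt), (0.5 + 0.75) / 2)
  # per-locus variant is the ratio of mean distances
  expect_equal(unname(relative_error_per_locus(A, O, Tt)), c(0.5, 0.75))

  # all spots skipped -> NA with warning
  expect_warning(out <- relative_error_per_trace(Tt, Tt, Tt), "undefined")
  expect_true(all(is.na(out)))
})

test_that("contact map differences subtract elementwise and propagate masks", {
  ts <- random_trace_set(60)
  cm <- contact_frequency(ts, 150, min_n = 2)
  d0 <- contact_map_difference(cm, cm)
  expect_true(all(d0 == 0 | is.na(d0)))

  cm2 <- cm
  cm2$freq[1, 2] <- cm2$freq[2, 1] <- NA
  d <- contact_map_difference(cm, cm2)
  expect_true(is.na(d[1, 2]))

  cm3 <- cm; cm3$threshold <- 200
  expect_error(contact_map_difference(cm, cm3), "threshold")
})

test_that("burst-state stratified maps equal brute-force recomputation", {
  ts <- random_trace_set(61)
  ts$trace_meta$burst_state <- rep(c("initial_burst", "none"),
                                   length.out = n_traces(ts))
  on <- subset_traces(ts, ts$trace_meta$burst_state == "initial_burst")
  off <- subset_traces(ts, ts$trace_meta$burst_state == "none")
  d <- contact_map_difference(contact_frequency(on, 150, min_n = 1),
                              contact_frequency(off, 150, min_n = 1))
  # brute force on one unmasked pair
  pick <- which(!is.na(d), arr.ind = TRUE)[1, ]
  a <- pick[1]; b <- pick[2]
  f <- function(s) {
    pos <- s$positions
    dd <- sqrt(rowSums((pos[, a, , drop = FALSE] - pos[, b, , drop = FALSE])^2))
    mean(dd[!is.na(dd)] <= 150)
  }
  expect_equal(d[a, b], f(on) - f(off))
})
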