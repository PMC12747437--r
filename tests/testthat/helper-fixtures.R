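# in-code fixtures: all test data is generated, nothing is stored on disk

make_chain_gt <- function(L = 10, N = 200, step = 30, seed = 1, dropout = 0) {
  generate_polymer_traces(simulation_spec(L = L, N = N, step_sd = step,
                                          dropout = dropout, seed = seed))
}

# a small noisy TraceSet with dropout and mixed metadata
random_trace_set <- function(seed, with_repeats = FALSE) {
  set.seed(seed)
  N <- sample(3:6, 1)
  L <- sample(4:8, 1)
  gt <- make_chain_gt(L = L, N = N, step = 50, seed = seed, dropout = 0.15)
  if (with_repeats) {
    ts <- simulate_repeat_imaging(gt, loci = c(2L, L - 1L), 30, 60,
                                  seed = seed + 2)$observed
  } else {
    ts <- add_localization_error(gt, 40, seed = seed + 1)$observed
  }
  set.seed(seed + 5)
  ts$trace_meta$burst_state <- sample(c("none", "initial_burst", "later_burst"),
                                      N, replace = TRUE)
  ts$trace_meta$condition <- sample(c("wt", "boundary"), N, replace = TRUE)
  ts
}

expect_traces_equal <- function(a, b, digits = 3) {
  expect_equal(round(a$positions, digits), round(b$positions, digits),
               ignore_attr = TRUE)
  expect_equal(a$locus_table$chrom, b$locus_table$chrom)
  expect_equal(as.numeric(a$locus_table$start), as.numeric(b$locus_table$start))
  expect_equal(as.numeric(a$locus_table$end), as.numeric(b$locus_table$end))
  expect_equal(a$locus_table$role, b$locus_table$role)
  expect_equal(a$trace_meta$trace_id, b$trace_meta$trace_id)
  expect_equal(a$trace_meta$burst_state, b$trace_meta$burst_state)
  expect_equal(a$repeat_pairs$initial_locus, b$repeat_pairs$initial_locus)
  expect_equal(a$repeat_pairs$repeat_locus, b$repeat_pairs$repeat_locus)
}

# uniform error model shortcut used across tests
known_error_model <- function(ts, sigma) {
  error_model(matrix(rep(sigma, length.out = n_dims(ts)),
                     nrow = n_loci(ts), ncol = n_dims(ts), byrow = TRUE),
              provenance = "user_supplied")
}
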