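test_that("Cot dataset simulation is exact at zero noise and seed-deterministic", {
  m <- ref_model()
  d0 <- simulate_cot_dataset(m, n = 25, noise_sd = 0, seed = 1)
  expect_equal(d0$fraction_reassociated, fraction_reassociated(m, d0$cot))
  d1 <- simulate_cot_dataset(m, n = 40, noise_sd = 0.02, seed = 7)
  d2 <- simulate_cot_dataset(m, n = 40, noise_sd = 0.02, seed = 7)
  expect_identical(d1, d2)
  d3 <- simulate_cot_dataset(m, n = 40, noise_sd = 0.02, seed = 8)
  expect_false(identical(d1, d3))
  # noise never pushes fractions outside [0, 1]
  dh <- simulate_cot_dataset(m, n = 200, noise_sd = 0.4, seed = 2)
  expect_true(all(dh$fraction_reassociated >= 0 &
                    dh$fraction_reassociated <= 1))
  expect_error(simulate_cot_dataset(m, cot_grid = c(2, 1)), "increasing")
})

test_that("generators leave the caller's RNG stream untouched", {
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(simulate_cot_dataset(ref_model(), n = 10, seed = 42))
  invisible(simulate_macroarray(100, 10, copies_on_array = 10, seed = 42))
  expect_equal(runif(1), before)
})

test_that("macroarray placement conserves copies and scales with coverage", {
  x <- simulate_macroarray(1000, 300, copies_on_array = 300, seed = 1)
  expect_equal(sum(x$count), 300)
  expect_equal(nrow(x), 1000)
  expect_true(all(simulate_macroarray(500, 0, copies_on_array = 0,
                                      seed = 1)$count == 0))
  # coverage arithmetic: clones * insert / genome scales the copies placed
  y <- simulate_macroarray(17639, 23892, insert_size = 113,
                           genome_size = 9731, seed = 3)
  expect_equal(sum(y$count), round(23892 * 17639 * 0.113 / 9731))
})

test_that("clustered placement inflates the empty-clone count far beyond Holst", {
  N <- 17639; n <- 4898
  ee <- expected_empty(N, n)
  x <- simulate_macroarray(N, n, copies_on_array = n, clustering = 5,
                           seed = 11)
  expect_gt(sum(x$count == 0), ee$mean + 10 * ee$sd)
})

test_that("planted MITE fixtures satisfy the structural definition", {
  fx <- plant_mites(
    data.frame(tir_len = c(12, 10), dr_len = c(3, 5),
               internal_len = c(200, 150)),
    n_sequences = 2, seed = 21
  )
  expect_equal(nrow(fx$truth), 2)
  for (i in seq_len(nrow(fx$truth))) {
    tr <- fx$truth[i, ]
    s <- fx$sequences$sequence[fx$sequences$seq_id == tr$seq_id]
    left <- substring(s, tr$start, tr$start + tr$tir_len - 1)
    right <- substring(s, tr$end - tr$tir_len + 1, tr$end)
    expect_identical(left, tr$tir_seq)
    expect_identical(revcomp(right), left)
    expect_identical(substring(s, tr$start - tr$dr_len, tr$start - 1),
                     substring(s, tr$end + 1, tr$end + tr$dr_len))
    expect_equal(tr$end - tr$start + 1, 2 * tr$tir_len + tr$internal_len)
  }
})

test_that("MITE planting is byte-deterministic and validates bounds", {
  el <- data.frame(tir_len = 10, dr_len = 3, internal_len = 200)
  a <- plant_mites(el, seed = 5)
  b <- plant_mites(el, seed = 5)
  expect_identical(a, b)
  expect_false(identical(a$sequences$sequence,
                         plant_mites(el, seed = 6)$sequences$sequence))
  # zero elements gives pure background and an empty truth table
  none <- plant_mites(el[0, ], seed = 1)
  expect_equal(nrow(none$truth), 0)
  expect_gt(nchar(none$sequences$sequence[1]), 0)
  expect_error(plant_mites(data.frame(tir_len = 8, dr_len = 2,
                                      internal_len = 10)), "100")
})

test_that("FASTA round trip preserves ids and sequences", {
  fx <- plant_mites(data.frame(tir_len = 10, dr_len = 3, internal_len = 150),
                    n_sequences = 2, seed = 9)
  p <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(fx$sequences, p)
  back <- read_fasta(p)
  expect_equal(back, fx$sequences)
})
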