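test_that("a planted element is recovered at its exact coordinates", {
  fx <- plant_mites(data.frame(tir_len = 10, dr_len = 3, internal_len = 200),
                    seed = 42)
  hits <- scan_mites(fx$sequences)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, fx$truth$start)
  expect_equal(hits$end, fx$truth$end)
  expect_equal(hits$tir_len, fx$truth$tir_len)
  expect_equal(hits$dr_len, fx$truth$dr_len)
  expect_identical(hits$tir_seq, fx$truth$tir_seq)
})

test_that("elements below the TIR threshold are not reported", {
  # TIR 7 nt < the 8 nt minimum: the structure exists but must be invisible
  fx <- plant_mites(data.frame(tir_len = 7, dr_len = 3, internal_len = 200),
                    seed = 13, check_bounds = FALSE)
  hits <- scan_mites(fx$sequences)
  expect_false(any(hits$start == fx$truth$start &
                     hits$end == fx$truth$end))
  # same element clears a lowered threshold
  hits7 <- scan_mites(fx$sequences,
                      mite_params(min_tir = 7, min_len = 100))
  expect_true(any(hits7$start == fx$truth$start &
                    hits7$end == fx$truth$end))
})

test_that("sequences without inverted repeats yield an empty result", {
  expect_equal(nrow(scan_mites(strrep("AC", 200))), 0)
  expect_equal(nrow(scan_mites("ACGT")), 0)
  expect_equal(nrow(scan_mites(character(0))), 0)
})

test_that("N bases never seed or extend a match", {
  fx <- plant_mites(data.frame(tir_len = 12, dr_len = 3, internal_len = 180),
                    seed = 77)
  s <- fx$sequences$sequence[1]
  # blank out the left TIR with N: the element must disappear
  masked <- paste0(
    substring(s, 1, fx$truth$start - 1),
    strrep("N", fx$truth$tir_len),
    substring(s, fx$truth$start + fx$truth$tir_len, nchar(s))
  )
  hits <- scan_mites(masked)
  expect_false(any(hits$start == fx$truth$start))
})

test_that("candidates re-validate against the structural definition", {
  set.seed(30)
  for (i in 1:5) {
    fx <- mite_fixture(i)
    hits <- scan_mites(fx$sequences)
    expect_true(all(validate_mites(hits, fx$sequences)))
  }
})

test_that("scanning the reverse complement mirrors the candidate set", {
  for (i in 1:10) {
    fx <- mite_fixture(40 + i)
    s <- fx$sequences$sequence[1]
    L <- nchar(s)
    fwd <- scan_mites(s)
    rev <- scan_mites(revcomp(s))
    expect_setequal(paste(fwd$start, fwd$end),
                    paste(L - rev$end + 1, L - rev$start + 1))
  }
})

test_that("summaries aggregate candidates and group families by TIR", {
  empty <- summarize_mites(scan_mites(strrep("A", 500)))
  expect_equal(empty$n, 0)
  expect_true(is.na(empty$mean_length))

  fx <- plant_mites(
    data.frame(tir_len = c(10, 14), dr_len = c(2, 4),
               internal_len = c(180, 272)),
    n_sequences = 2, seed = 55
  )
  hits <- scan_mites(fx$sequences)
  sm <- summarize_mites(hits)
  expect_equal(sm$n, 2)
  expect_equal(sm$mean_length, mean(c(200, 300)))
  expect_equal(sm$mean_tir_len, 12)
  # distinct TIRs: every candidate is its own family
  expect_equal(sm$n_families, 2)
})

test_that("candidate tables export to TSV and GFF3", {
  fx <- plant_mites(data.frame(tir_len = 11, dr_len = 3, internal_len = 190),
                    seed = 66)
  hits <- scan_mites(fx$sequences)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_mite_tsv(hits, tsv)
  expect_match(readLines(tsv, n = 1), "1-based")
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_mite_gff3(hits, gff)
  back <- rtracklayer::import(gff)
  expect_equal(length(back), nrow(hits))
  expect_equal(GenomicRanges::start(back), hits$start)
  expect_equal(GenomicRanges::end(back), hits$end)
})

test_that("parameter validation rejects impossible bounds", {
  expect_error(mite_params(min_tir = 60, max_tir = 50))
  expect_error(mite_params(min_len = 10))
  expect_error(scan_mites("ACGU"), "ACGTN")
})
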