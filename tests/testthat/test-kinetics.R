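test_that("forward curve matches the closed form at anchor points", {
  # single pure component reaches half its fraction at cot = 1/k
  m1 <- cot_model(data.frame(fraction = 1, rate_k = 1))
  expect_equal(fraction_reassociated(m1, 1), 0.5)
  # cot = 0 returns the foldback offset alone
  m <- ref_model()
  expect_equal(fraction_reassociated(m, 0), 0.0174)
  # frozen value computed term-by-term from the mixture closed form
  expect_equal(fraction_reassociated(m, 4.64), 0.2644464546, tolerance = 1e-9)
})

test_that("forward curve is monotone and bounded on random models", {
  grid <- 10^seq(-4, 6, length.out = 80)
  for (m in random_models(12)) {
    y <- fraction_reassociated(m, grid)
    expect_true(all(diff(y) > 0))
    expect_true(all(y >= m$foldback - 1e-12))
    expect_true(all(y <= 1 - m$unreassociated + 1e-12))
    # each single component reaches half its fraction at its own cot1/2
    for (j in seq_len(nrow(m$components))) {
      mj <- cot_model(data.frame(fraction = 1,
                                 rate_k = m$components$rate_k[j]))
      expect_equal(fraction_reassociated(mj, 1 / m$components$rate_k[j]), 0.5)
    }
  }
})

test_that("cot1/2, repetition frequency and two-decade ranges reproduce the reference table", {
  expect_equal(round(cot_half_observed(0.2157), 2), 4.64)
  expect_equal(round(cot_half_observed(0.000105), 2), 9523.81)
  expect_equal(cot_half_observed(1), 1)

  expect_equal(round(mean_repetition_frequency(0.2157, 0.000105)), 2054)
  expect_equal(round(mean_repetition_frequency(0.00637, 0.000105)), 61)
  expect_equal(mean_repetition_frequency(0.000105, 0.000105), 1)

  expect_equal(tcdr(4.64), tibble::tibble(low = 0.464, high = 46.4))
  expect_equal(repetition_range(61), tibble::tibble(low = 6.1, high = 610))
  expect_equal(repetition_range(2054),
               tibble::tibble(low = 205.4, high = 20540))
  # the window always spans exactly two decades
  set.seed(5)
  ch <- 10^runif(20, -3, 4)
  r <- tcdr(ch)
  expect_equal(r$high / r$low, rep(100, 20))
})

test_that("kinetic complexity matches the calibrated reference values", {
  expect_equal(round(kinetic_complexity(0.4114, 0.00637), 2), 65.56)
  expect_equal(signif(kinetic_complexity(0.0744, 0.000105), 4), 719.3)
  expect_equal(round(calibration_ratio(), 4), 1.0151)
})

test_that("genome-size-fixed slow rate inverts kinetic complexity", {
  # close to the reported 0.000105 of the genome-size-fixed SL component
  expect_equal(fix_slow_rate_from_genome(9731), 1.0432e-4, tolerance = 1e-4)
  expect_equal(fix_slow_rate_from_genome(calibration_ratio()), 1)
  set.seed(11)
  for (g in 10^runif(10, 1, 5)) {
    expect_equal(kinetic_complexity(1, fix_slow_rate_from_genome(g)), g,
                 tolerance = 1e-9)
  }
})

test_that("repetition at a Cot cut-off reproduces the Cot-1 interpretation", {
  expect_equal(trunc(repetition_at_cot(1, 0.000105)), 9523)
  expect_equal(repetition_at_cot(cot_half_observed(0.000105), 0.000105), 1)
  expect_equal(repetition_at_cot(4.64, 0.000105), 2052.5, tolerance = 1e-4)
})

test_that("component table applies the conventional display rounding", {
  tab <- component_table(ref_model())
  expect_equal(tab$component, c("HR", "MR", "SL"))
  expect_equal(tab$mrf, c(2054, 61, 1))
  expect_equal(tab$cot_half, c(4.64, 156.99, 9523.81))
  expect_equal(tab$kncx_mb, c(2.213, 65.56, 719.3))
  expect_equal(tab$copies_low, c(205.4, 6.1, 0.1))
  expect_equal(tab$copies_high, c(20540, 610, 10))
  raw <- component_table(ref_model(), rounded = FALSE)
  expect_equal(raw$mrf[1], 2054.2857, tolerance = 1e-6)
})

test_that("model construction enforces its invariants", {
  expect_error(cot_model(data.frame(fraction = 1.2, rate_k = 1)), "fractions")
  expect_error(cot_model(data.frame(fraction = c(0.5, 0.5),
                                    rate_k = c(1, 1))), "share a rate")
  expect_error(cot_model(data.frame(fraction = 0.5, rate_k = 1),
                         foldback = 0.2, unreassociated = 0.2), "sum to 1")
  expect_error(cot_model(data.frame(fraction = c(0.7, 0.6),
                                    rate_k = c(1, 0.1))), "exceed 1")
  expect_error(fraction_reassociated(ref_model(), -1), ">= 0")
  # components are sorted fastest first and labeled by count
  m <- cot_model(data.frame(fraction = c(0.3, 0.4), rate_k = c(0.01, 10)))
  expect_equal(m$components$rate_k, c(10, 0.01))
  expect_equal(m$components$component, c("C1", "C2"))
})

test_that("JSON serialization round-trips a model exactly", {
  m <- ref_model()
  js <- cot_model_to_json(m)
  m2 <- cot_model_from_json(js)
  expect_identical(m2$components$fraction, m$components$fraction)
  expect_identical(m2$components$rate_k, m$components$rate_k)
  expect_identical(m2$foldback, m$foldback)
  expect_identical(m2$unreassociated, m$unreassociated)
  # and via a file
  p <- withr::local_tempfile(fileext = ".json")
  cot_model_to_json(m, p)
  expect_identical(cot_model_from_json(p)$components$rate_k,
                   m$components$rate_k)
})

test_that("tidy and glance summarize a model", {
  m <- ref_model()
  expect_equal(tidy(m), m$components)
  g <- glance(m)
  expect_equal(g$n_components, 3)
  expect_equal(g$repetitive_fraction, 0.4702 + 0.4114)
})
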