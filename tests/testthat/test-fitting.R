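test_that("noise-free data are recovered to numerical precision", {
  m <- two_component_model()
  d <- simulate_cot_dataset(m, n = 40, cot_range = c(1e-4, 1e4),
                            noise_sd = 0, seed = 1)
  fit <- fit_cot_curve(d, n_components = 2, seed = 1)
  expect_true(fit$converged)
  expect_equal(fit$model$components$fraction, m$components$fraction,
               tolerance = 1e-6)
  expect_equal(fit$model$components$rate_k, m$components$rate_k,
               tolerance = 1e-6)
  expect_equal(fit$model$foldback, m$foldback, tolerance = 1e-6)
})

test_that("noisy data from the reference model are recovered within tolerance", {
  m <- ref_model()
  d <- simulate_cot_dataset(m, n = 60, noise_sd = 0.01, seed = 42)
  fit <- fit_cot_curve(d, n_components = 3, seed = 42)
  expect_true(fit$converged)
  expect_equal(fit$model$components$fraction, m$components$fraction,
               tolerance = 0.12)
  expect_true(all(abs(log10(fit$model$components$rate_k) -
                        log10(m$components$rate_k)) < 0.35))
  # fractions close in absolute terms
  expect_true(all(abs(fit$model$components$fraction -
                        m$components$fraction) < 0.05))
})

test_that("a one-component fit scores strictly worse on two-component data", {
  d <- simulate_cot_dataset(two_component_model(), n = 50,
                            cot_range = c(1e-4, 1e4), noise_sd = 0.01,
                            seed = 4)
  f1 <- fit_cot_curve(d, 1, seed = 4)
  f2 <- fit_cot_curve(d, 2, seed = 4)
  expect_gt(f1$criterion_value, f2$criterion_value)
})

test_that("model selection finds the true component count", {
  d2 <- simulate_cot_dataset(two_component_model(), n = 50,
                             cot_range = c(1e-4, 1e4), noise_sd = 0.01,
                             seed = 8)
  sel2 <- select_cot_model(d2, max_components = 3, seed = 8)
  expect_equal(sel2$n_components, 2)
  expect_equal(nrow(sel2$criterion_table), 3)

  m1 <- cot_model(data.frame(fraction = 0.95, rate_k = 0.05))
  d1 <- simulate_cot_dataset(m1, n = 40, cot_range = c(1e-2, 1e4),
                             noise_sd = 0.01, seed = 9)
  sel1 <- select_cot_model(d1, max_components = 2, seed = 9)
  expect_equal(sel1$n_components, 1)

  # the selected component count does not depend on the seed
  selA <- select_cot_model(d2, max_components = 3, seed = 101)
  selB <- select_cot_model(d2, max_components = 3, seed = 202)
  expect_equal(selA$n_components, selB$n_components)
})

test_that("a fixed slow rate is honored exactly", {
  m <- ref_model()
  d <- simulate_cot_dataset(m, n = 60, noise_sd = 0.01, seed = 15)
  kfix <- fix_slow_rate_from_genome(9731)
  fit <- fit_cot_curve(d, 3, fixed_slow_rate = kfix, seed = 15)
  expect_equal(min(fit$model$components$rate_k), kfix)
})

test_that("a planted gross error is flagged first and removal lowers the objective", {
  m <- two_component_model()
  d <- simulate_cot_dataset(m, n = 50, cot_range = c(1e-4, 1e4),
                            noise_sd = 0.01, seed = 3)
  bad <- 25
  d$fraction_reassociated[bad] <- min(1, d$fraction_reassociated[bad] + 0.3)
  fit <- fit_cot_curve(d, 2, seed = 3)
  out <- detect_outliers(fit, threshold = 3)
  expect_equal(out[1], bad)
  cleaned <- fit_cot_curve(d, 2, seed = 3, outlier_threshold = 3)
  expect_lte(cleaned$sse, fit$sse)
  expect_true(bad %in% cleaned$removed_outliers)
  expect_false(bad %in% cleaned$data$.row)
})

test_that("clean data yield no outliers and infinite threshold is inert", {
  d <- simulate_cot_dataset(two_component_model(), n = 50,
                            cot_range = c(1e-4, 1e4), noise_sd = 0.01,
                            seed = 14)
  fit <- fit_cot_curve(d, 2, seed = 14)
  expect_length(detect_outliers(fit, threshold = 3), 0)
  expect_length(detect_outliers(fit, threshold = Inf), 0)
})

test_that("row order does not influence the fit", {
  d <- simulate_cot_dataset(two_component_model(), n = 50,
                            cot_range = c(1e-4, 1e4), noise_sd = 0.01,
                            seed = 5)
  set.seed(1)
  dp <- d[sample(nrow(d)), ]
  f1 <- fit_cot_curve(d, 2, seed = 5)
  f2 <- fit_cot_curve(dp, 2, seed = 5)
  expect_equal(f1$model$components$rate_k, f2$model$components$rate_k)
  expect_equal(f1$sse, f2$sse)
})

test_that("fitted models always satisfy mixture closure", {
  for (s in 1:5) {
    d <- simulate_cot_dataset(ref_model(), n = 60, noise_sd = 0.02, seed = s)
    fit <- fit_cot_curve(d, 3, seed = s)
    comp <- fit$model$components
    expect_true(all(comp$fraction > 0))
    expect_equal(fit$model$foldback + sum(comp$fraction) +
                   fit$model$unreassociated, 1, tolerance = 1e-9)
    expect_true(all(diff(comp$rate_k) < 0))
  }
})

test_that("insufficient data are rejected up front", {
  d <- simulate_cot_dataset(ref_model(), n = 12, noise_sd = 0, seed = 1)
  expect_error(fit_cot_curve(d, 3, seed = 1), "at least")
})

test_that("broom-style accessors expose the fit", {
  d <- simulate_cot_dataset(two_component_model(), n = 40,
                            cot_range = c(1e-4, 1e4), noise_sd = 0.01,
                            seed = 6)
  fit <- fit_cot_curve(d, 2, seed = 6)
  td <- tidy(fit)
  expect_equal(nrow(td), 2)
  expect_true(all(c("component", "fraction", "rate_k", "cot_half", "mrf")
                  %in% names(td)))
  g <- glance(fit)
  expect_equal(g$n_obs, 40)
  au <- augment(fit)
  expect_equal(au$.resid, fit$residuals)
  expect_s3_class(autoplot(fit), "ggplot")
  crv <- fitted_curve(fit, n = 50)
  expect_equal(nrow(crv), 50)
  expect_true(all(diff(crv$predicted) > 0))
})

test_that("cot data input validation and file reading work", {
  expect_error(as_cot_data(data.frame(cot = c(-1, 2),
                                      fraction_reassociated = c(0.1, 0.2))),
               "> 0")
  expect_error(as_cot_data(data.frame(cot = 1, fraction_reassociated = 1.5)),
               "0, 1")
  ss <- as_cot_data(data.frame(cot = 1, fraction_reassociated = 0.3),
                    single_stranded = TRUE)
  expect_equal(ss$fraction_reassociated, 0.7)
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# renaturation data", "cot\tfraction_reassociated",
               "0.5\t0.1", "5\t0.4"), p)
  d <- read_cot_data(p)
  expect_equal(d$cot, c(0.5, 5))
})
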