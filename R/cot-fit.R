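#' Validate and normalize observed Cot data
#'
#' Accepts a data frame with columns `cot` (M·s, positive) and
#' `fraction_reassociated` (in `[0, 1]`), plus an optional `weight` column of
#' positive reals. Datasets recorded as fraction *single-stranded* (the
#' hydroxyapatite convention) are converted with `single_stranded = TRUE`.
#' Rows are ordered by `(cot, fraction_reassociated)` so all downstream
#' results are invariant to input row order; the original row number is kept
#' in `.row`.
#'
#' @param data A data frame.
#' @param single_stranded Input `fraction_reassociated` column actually holds
#'   the single-stranded fraction; convert via `y = 1 - y`.
#' @return A tibble with `cot`, `fraction_reassociated`, `weight`, `.row`.
#' @export
as_cot_data <- function(data, single_stranded = FALSE) {
  data <- as.data.frame(data)
  stopifnot(all(c("cot", "fraction_reassociated") %in% names(data)))
  cot <- as.numeric(data$cot)
  y <- as.numeric(data$fraction_reassociated)
  if (single_stranded) y <- 1 - y
  if (any(!is.finite(cot)) || any(cot <= 0)) stop("all cot values must be > 0")
  if (any(!is.finite(y)) || any(y < 0) || any(y > 1)) {
    stop("all fractions must lie in [0, 1]")
  }
  w <- if (!is.null(data$weight)) as.numeric(data$weight) else rep(1, length(y))
  if (any(!is.finite(w)) || any(w <= 0)) stop("weights must be positive")
  out <- tibble::tibble(cot = cot, fraction_reassociated = y, weight = w,
                        .row = seq_along(y))
  out[order(out$cot, out$fraction_reassociated), ]
}

#' Read a Cot dataset from a delimited text file
#'
#' Expects header columns `cot` and `fraction_reassociated` (optional
#' `weight`); lines starting with `#` are ignored. `.csv` files are read as
#' comma-separated, anything else as tab-separated.
#'
#' @param path File path.
#' @param ... Passed to [as_cot_data()].
#' @return A validated Cot data tibble.
#' @export
read_cot_data <- function(path, ...) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                          stringsAsFactors = FALSE)
  as_cot_data(df, ...)
}

# ---- internal fitting machinery -------------------------------------------

# Parameter layout: c(foldback, f[1..m], log10 k for the free components).
# When fixed_lk is non-NULL the slowest component's log10 rate is clamped and
# free rates are bounded at least `sep` decades above it.
fit_param_layout <- function(m, fixed_lk = NULL, sep = 0.3) {
  n_free_lk <- if (is.null(fixed_lk)) m else m - 1L
  lk_lower <- if (is.null(fixed_lk)) rep(-8, n_free_lk)
              else rep(fixed_lk + sep, n_free_lk)
  list(
    m = m, n_free_lk = n_free_lk, fixed_lk = fixed_lk,
    lower = c(0, rep(1e-6, m), lk_lower),
    upper = c(0.999, rep(1, m), rep(4, n_free_lk)),
    n_par = 1L + m + n_free_lk
  )
}

fit_unpack <- function(par, layout) {
  m <- layout$m
  fb <- par[1]
  f <- par[1 + seq_len(m)]
  lk <- par[1 + m + seq_len(layout$n_free_lk)]
  if (!is.null(layout$fixed_lk)) lk <- c(lk, layout$fixed_lk)
  list(foldback = fb, fraction = f, rate_k = 10^lk)
}

fit_predict <- function(par, layout, cot) {
  p <- fit_unpack(par, layout)
  kc <- outer(cot, p$rate_k)
  as.vector(p$foldback + (kc / (1 + kc)) %*% p$fraction)
}

fit_residuals <- function(par, layout, cot, y, sqw) {
  r <- sqw * (y - fit_predict(par, layout, cot))
  total <- par[1] + sum(par[1 + seq_len(layout$m)])
  # soft closure penalty: fractions may not exceed the whole genome
  c(r, 1e3 * max(0, total - 1))
}

fit_starts <- function(layout, cot, y, n_starts, seed) {
  m <- layout$m
  lo <- log10(1 / max(cot))
  hi <- log10(1 / min(cot))
  if (!is.null(layout$fixed_lk)) lo <- max(lo, layout$fixed_lk + 0.3)
  base_lk <- seq(lo, hi, length.out = m + 2)[1 + seq_len(m)]
  fb0 <- min(max(min(y), 0), 0.3)
  amp <- max(max(y) - fb0, 0.1)
  with_seed(seed, {
    lapply(seq_len(n_starts), function(r) {
      if (r == 1) {
        lk <- base_lk
        f <- rep(amp * 0.95 / m, m)
        fb <- fb0
      } else {
        span <- max(hi - lo, 1)
        lk <- sort(stats::runif(m, lo, hi))
        if (m > 1 && min(diff(lk)) < 0.3) lk <- base_lk +
            stats::runif(m, -0.4, 0.4) * span / (m + 1)
        sh <- stats::rgamma(m, 1)
        f <- amp * 0.95 * sh / sum(sh)
        fb <- stats::runif(1, 0, max(fb0 * 2, 0.05))
      }
      lk_free <- sort(lk, decreasing = FALSE)
      if (!is.null(layout$fixed_lk)) lk_free <- lk_free[-1][seq_len(layout$n_free_lk)]
      par <- c(fb, pmin(pmax(f, 1e-4), 1), pmin(pmax(lk_free, layout$lower[-(1:(m + 1))]), 4))
      pmin(pmax(par, layout$lower), layout$upper)
    })
  })
}

fit_single <- function(cot, y, sqw, layout, starts) {
  best <- NULL
  for (par0 in starts) {
    ans <- tryCatch(
      minpack.lm::nls.lm(
        par = par0, lower = layout$lower, upper = layout$upper,
        fn = fit_residuals, layout = layout, cot = cot, y = y, sqw = sqw,
        control = minpack.lm::nls.lm.control(maxiter = 300, ftol = 1e-14,
                                             ptol = 1e-14)
      ),
      error = function(e) NULL
    )
    if (is.null(ans)) next
    r <- fit_residuals(ans$par, layout, cot, y, sqw)
    sse <- sum(r[seq_along(cot)]^2)
    conv <- ans$info %in% 1:4
    cand <- list(par = ans$par, sse = sse, converged = conv)
    if (is.null(best) || sse < best$sse - 1e-15 ||
        (abs(sse - best$sse) <= 1e-15 &&
         isTRUE(vec_less(cand$par, best$par)))) {
      best <- cand
    }
  }
  best
}

vec_less <- function(a, b) {
  d <- a - b
  i <- which(abs(d) > 0)[1]
  if (is.na(i)) FALSE else d[i] < 0
}

fit_to_model <- function(par, layout) {
  p <- fit_unpack(par, layout)
  k <- p$rate_k
  # break exact rate ties (collapsed components) so the model stays valid
  while (anyDuplicated(k)) {
    i <- which(duplicated(k))[1]
    k[i] <- k[i] * (1 + 1e-9)
  }
  f <- pmax(p$fraction, 1e-12)
  total <- p$foldback + sum(f)
  if (total > 1) {
    f <- f / total
    fb <- p$foldback / total
  } else {
    fb <- p$foldback
  }
  cot_model(data.frame(fraction = f, rate_k = k), foldback = fb)
}

fit_jacobian <- function(par, layout, cot) {
  eps <- 1e-6
  base <- fit_predict(par, layout, cot)
  J <- matrix(0, length(cot), length(par))
  for (j in seq_along(par)) {
    pj <- par
    h <- eps * max(abs(pj[j]), 1e-3)
    pj[j] <- pj[j] + h
    J[, j] <- (fit_predict(pj, layout, cot) - base) / h
  }
  J
}

# Externally studentized residuals for a nonlinear least-squares fit, using
# the Jacobian-based linear approximation of leverage.
studentized <- function(par, layout, cot, y, sqw) {
  e <- sqw * (y - fit_predict(par, layout, cot))
  J <- sqw * fit_jacobian(par, layout, cot)
  p <- ncol(J)
  n <- length(e)
  if (n - p - 1 <= 0) return(rep(0, n))
  # an (essentially) perfect fit has no outliers; avoid 0/0 studentization
  if (sum(e^2) / (n - p) < 1e-20) return(rep(0, n))
  JtJ <- crossprod(J) + diag(1e-10, p)
  h <- rowSums((J %*% solve(JtJ)) * J)
  h <- pmin(pmax(h, 0), 0.9999)
  sse <- sum(e^2)
  s2i <- (sse - e^2 / (1 - h)) / (n - p - 1)
  s2i <- pmax(s2i, 1e-300)
  e / sqrt(s2i * (1 - h))
}

aicc_score <- function(sse, n, n_par) {
  p <- n_par + 1 # + residual variance
  if (n - p - 1 <= 0) return(Inf)
  n * log(sse / n) + 2 * p + 2 * p * (p + 1) / (n - p - 1)
}

bic_score <- function(sse, n, n_par) {
  p <- n_par + 1
  n * log(sse / n) + p * log(n)
}

# ---- public fitting API ----------------------------------------------------

#' Fit a multi-component Cot model by nonlinear least squares
#'
#' Minimizes the (optionally weighted) sum of squared deviations between
#' observed reassociated fractions and the closed-form mixture curve, with
#' box constraints keeping all fractions non-negative and their total (with
#' foldback) at most 1; whatever the components and foldback do not account
#' for becomes the unreassociated residue. Rates are optimized on the log10
#' scale within `[1e-8, 1e4]` M^-1 s^-1. Optimization uses
#' Levenberg–Marquardt with `n_starts` multi-start initializations (rates on
#' a log grid spanning the reciprocal Cot range of the data, fractions near
#' uniform, jittered); the best sum of squares wins, ties broken by the
#' lexicographically smaller parameter vector. The whole restart schedule is
#' a deterministic function of `seed`.
#'
#' When `outlier_threshold` is set, points whose externally studentized
#' residual exceeds it are removed one at a time (worst first, refitting
#' after each removal) until none exceed the threshold or 10% of the points
#' have been removed.
#'
#' @param data A data frame accepted by [as_cot_data()].
#' @param n_components Number of kinetic components, 1–5.
#' @param fixed_slow_rate Optional rate (M^-1 s^-1) to clamp the slowest
#'   component to, e.g. from [fix_slow_rate_from_genome()] when the genome
#'   size is known independently.
#' @param seed Integer seed governing all restarts.
#' @param n_starts Number of multi-start initializations.
#' @param outlier_threshold Studentized-residual threshold for iterative
#'   outlier removal; `NULL` (default) disables removal.
#' @param single_stranded Passed to [as_cot_data()].
#' @return An object of class `cot_fit`: a list with `model` (the fitted
#'   [cot_model()]), `n_components`, `data` (retained points), `residuals`,
#'   `removed_outliers` (original row numbers of excluded points), `sse`,
#'   `criterion_value` (AICc), `converged`, `seed`, `fixed_slow_rate`.
#' @examples
#' d <- simulate_cot_dataset(taxodium_cot_model(), noise_sd = 0, seed = 1)
#' fit <- fit_cot_curve(d, n_components = 3)
#' tidy(fit)
#' @export
fit_cot_curve <- function(data, n_components, fixed_slow_rate = NULL,
                          seed = 1, n_starts = 25, outlier_threshold = NULL,
                          single_stranded = FALSE) {
  stopifnot(n_components >= 1, n_components <= 5)
  d <- as_cot_data(data, single_stranded = single_stranded)
  if (!is.null(fixed_slow_rate)) stopifnot(fixed_slow_rate > 0)
  fixed_lk <- if (is.null(fixed_slow_rate)) NULL else log10(fixed_slow_rate)
  layout <- fit_param_layout(n_components, fixed_lk)
  if (nrow(d) < 3 * layout$n_par) {
    stop(sprintf("need at least %d points to fit %d component(s), got %d",
                 3 * layout$n_par, n_components, nrow(d)))
  }
  removed <- integer(0)
  keep <- rep(TRUE, nrow(d))
  cap <- floor(0.1 * nrow(d))
  repeat {
    dk <- d[keep, ]
    starts <- fit_starts(layout, dk$cot, dk$fraction_reassociated,
                         n_starts, seed)
    best <- fit_single(dk$cot, dk$fraction_reassociated, sqrt(dk$weight),
                       layout, starts)
    if (is.null(best)) stop("all optimization restarts failed")
    if (is.null(outlier_threshold) || length(removed) >= cap) break
    t_i <- studentized(best$par, layout, dk$cot, dk$fraction_reassociated,
                       sqrt(dk$weight))
    worst <- which.max(abs(t_i))
    if (!length(worst) || abs(t_i[worst]) <= outlier_threshold) break
    removed <- c(removed, dk$.row[worst])
    keep[which(keep)[worst]] <- FALSE
  }
  dk <- d[keep, ]
  model <- fit_to_model(best$par, layout)
  resid <- dk$fraction_reassociated -
    fraction_reassociated(model, dk$cot)
  structure(
    list(
      model = model,
      n_components = n_components,
      data = dk,
      residuals = resid,
      removed_outliers = sort(removed),
      sse = best$sse,
      criterion_value = aicc_score(best$sse, nrow(dk), layout$n_par),
      n_par = layout$n_par,
      converged = best$converged,
      seed = seed,
      fixed_slow_rate = fixed_slow_rate
    ),
    class = "cot_fit"
  )
}

#' @export
print.cot_fit <- function(x, ...) {
  cat(sprintf(
    "<cot_fit> %d component(s), SSE %.4g on %d points (%d outlier(s) removed), AICc %.2f%s\n",
    x$n_components, x$sse, nrow(x$data), length(x$removed_outliers),
    x$criterion_value, if (x$converged) "" else " [NOT CONVERGED]"))
  print(x$model)
  invisible(x)
}

#' Detect outlying Cot observations
#'
#' Iteratively removes the single point with the largest externally
#' studentized residual, refits, and repeats until no residual exceeds
#' `threshold` or 10% of the points have been removed. Studentization uses
#' the Jacobian-based leverage of the nonlinear fit.
#'
#' @param fit A [fit_cot_curve()] result (fitted without outlier removal).
#' @param threshold Studentized-residual threshold (default 3).
#' @return Integer vector of original row numbers flagged as outliers
#'   (empty when the data are clean or `threshold = Inf`).
#' @export
detect_outliers <- function(fit, threshold = 3) {
  stopifnot(inherits(fit, "cot_fit"), threshold > 0)
  if (!is.finite(threshold)) return(integer(0))
  refit <- fit_cot_curve(
    fit$data[, c("cot", "fraction_reassociated", "weight")],
    n_components = fit$n_components,
    fixed_slow_rate = fit$fixed_slow_rate,
    seed = fit$seed, outlier_threshold = threshold
  )
  # refit re-indexes rows 1..n; map back to the original row numbers
  sort(fit$data$.row[refit$removed_outliers])
}

#' Select the number of kinetic components
#'
#' Fits candidate models with 1 to `max_components` components, applies
#' studentized-residual outlier rejection to each, and returns the candidate
#' minimizing the small-sample-corrected information criterion (AICc by
#' default; BIC available). Candidates whose fitted rates collapse (adjacent
#' components closer than 0.3 decades in log10 rate) are excluded from the
#' comparison, as are candidates with too few points for their parameter
#' count. The full candidate table is attached to the returned fit as
#' `$criterion_table`.
#'
#' @inheritParams fit_cot_curve
#' @param max_components Largest candidate component count (≤ 5).
#' @param criterion `"aicc"` (default) or `"bic"`.
#' @param outlier_threshold Studentized-residual threshold applied to every
#'   candidate (default 3); `NULL` disables removal.
#' @return The winning `cot_fit`, with a `criterion_table` element: a tibble
#'   with one row per candidate (`n_components`, `sse`, `criterion`,
#'   `converged`, `collapsed`, `n_removed`, `note`).
#' @examples
#' d <- simulate_cot_dataset(taxodium_cot_model(), noise_sd = 0.01, seed = 7)
#' sel <- select_cot_model(d, max_components = 4, seed = 7)
#' sel$criterion_table
#' @export
select_cot_model <- function(data, max_components = 5,
                             fixed_slow_rate = NULL, seed = 1,
                             n_starts = 25, criterion = c("aicc", "bic"),
                             outlier_threshold = 3,
                             single_stranded = FALSE) {
  criterion <- match.arg(criterion)
  stopifnot(max_components >= 1, max_components <= 5)
  score_fun <- switch(criterion, aicc = aicc_score, bic = bic_score)
  fits <- vector("list", max_components)
  rows <- vector("list", max_components)
  for (m in seq_len(max_components)) {
    ans <- tryCatch(
      fit_cot_curve(data, n_components = m,
                    fixed_slow_rate = fixed_slow_rate, seed = seed,
                    n_starts = n_starts,
                    outlier_threshold = outlier_threshold,
                    single_stranded = single_stranded),
      error = function(e) e
    )
    if (inherits(ans, "error")) {
      rows[[m]] <- tibble::tibble(
        n_components = m, sse = NA_real_, criterion = NA_real_,
        converged = NA, collapsed = NA, n_removed = NA_integer_,
        note = conditionMessage(ans))
      next
    }
    lk <- sort(log10(ans$model$components$rate_k))
    collapsed <- length(lk) > 1 && min(diff(lk)) < 0.3
    sc <- score_fun(ans$sse, nrow(ans$data), ans$n_par)
    ans$criterion_value <- sc
    fits[[m]] <- ans
    rows[[m]] <- tibble::tibble(
      n_components = m, sse = ans$sse, criterion = sc,
      converged = ans$converged, collapsed = collapsed,
      n_removed = length(ans$removed_outliers), note = "")
  }
  tab <- dplyr::bind_rows(rows)
  ok <- which(!is.na(tab$criterion) & !tab$collapsed)
  if (!length(ok)) stop("no candidate component count produced a usable fit")
  win <- ok[which.min(tab$criterion[ok])]
  out <- fits[[win]]
  out$criterion_table <- tab
  out
}

#' @exportS3Method generics::tidy
tidy.cot_fit <- function(x, ...) {
  comp <- x$model$components
  k_sl <- min(comp$rate_k)
  tibble::tibble(
    component = comp$component,
    fraction = comp$fraction,
    rate_k = comp$rate_k,
    cot_half = cot_half_observed(comp$rate_k),
    mrf = mean_repetition_frequency(comp$rate_k, k_sl)
  )
}

#' @exportS3Method generics::glance
glance.cot_fit <- function(x, ...) {
  tibble::tibble(
    n_components = x$n_components,
    foldback = x$model$foldback,
    unreassociated = x$model$unreassociated,
    sse = x$sse,
    criterion_value = x$criterion_value,
    n_obs = nrow(x$data),
    n_removed = length(x$removed_outliers),
    converged = x$converged
  )
}

#' @exportS3Method generics::augment
augment.cot_fit <- function(x, ...) {
  d <- x$data
  d$.fitted <- fraction_reassociated(x$model, d$cot)
  d$.resid <- d$fraction_reassociated - d$.fitted
  d
}

#' Plot a fitted Cot curve over the data
#'
#' @param object A `cot_fit`.
#' @param ... Unused.
#' @return A ggplot object: observed points, fitted mixture curve, and (when
#'   present) removed outliers marked with crosses.
#' @exportS3Method ggplot2::autoplot
autoplot.cot_fit <- function(object, ...) {
  d <- object$data
  rng <- range(d$cot)
  p <- autoplot.cot_model(object$model, cot_range = rng, components = FALSE) +
    ggplot2::geom_point(
      data = d,
      ggplot2::aes(x = .data$cot, y = .data$fraction_reassociated),
      colour = "grey50"
    )
  p
}

#' Predicted curve on a Cot grid, for export alongside a fit report
#'
#' @param fit A `cot_fit`.
#' @param n Number of log-spaced grid points spanning the data range.
#' @return A tibble with `cot` and `predicted`.
#' @export
fitted_curve <- function(fit, n = 200) {
  stopifnot(inherits(fit, "cot_fit"))
  rng <- range(fit$data$cot)
  grid <- 10^seq(log10(rng[1]), log10(rng[2]), length.out = n)
  tibble::tibble(cot = grid,
                 predicted = fraction_reassociated(fit$model, grid))
}
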