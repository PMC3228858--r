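#' Expected empty clones under random repeat placement (Holst urn model)
#'
#' When `n` copies of a repeat element fall independently among `N` arrayed
#' clones, each with probability `p_fall` of landing in a given clone, Holst's
#' occupancy theory gives the number of clones receiving no copy a mean of
#' \deqn{\mu = N e^{-n p}} and standard deviation
#' \deqn{\sigma = \sqrt{n^2 N p^2 / 2}.}
#' With the uniform default `p_fall = 1/N` the standard deviation reduces to
#' `n / sqrt(2N)`.
#'
#' @param n_clones `N`, nuclear-DNA-containing clones on the array.
#' @param n_copies `n`, expected element copies represented on the array.
#' @param p_fall `p`, probability a copy lands in a given clone
#'   (default `1/N`).
#' @return A tibble with columns `mean` and `sd` (clones).
#' @examples
#' expected_empty(17639, 4898) # mean ~13362, sd ~26
#' @export
expected_empty <- function(n_clones, n_copies, p_fall = 1 / n_clones) {
  stopifnot(n_clones > 0, n_copies >= 0)
  if (p_fall <= 0 || p_fall > 1) stop("p_fall must lie in (0, 1]")
  tibble::tibble(
    mean = n_clones * exp(-n_copies * p_fall),
    sd = sqrt(n_copies^2 * n_clones * p_fall^2 / 2)
  )
}

#' Deviation ratio of the observed empty-clone count
#'
#' The headline statistic of the macroarray screen: the observed number of
#' clones lacking hybridization signal divided by the Holst standard
#' deviation (unrounded). Note this divides the observed COUNT itself by the
#' SD, following the original screen's usage; the conventional standardized
#' deviation `(observed - mean) / sd` is returned alongside as `z_score`.
#'
#' @inheritParams expected_empty
#' @param observed_empty Observed count of clones with no signal.
#' @return A tibble with `ratio` (= observed / sd) and `z_score`
#'   (= (observed - mean) / sd).
#' @examples
#' deviation_ratio(17639, 4898, 16751) # ratio ~642
#' @export
deviation_ratio <- function(n_clones, n_copies, observed_empty,
                            p_fall = 1 / n_clones) {
  stopifnot(observed_empty >= 0, observed_empty <= n_clones)
  ee <- expected_empty(n_clones, n_copies, p_fall)
  if (ee$sd <= 0) stop("standard deviation is zero; ratio undefined")
  tibble::tibble(
    ratio = observed_empty / ee$sd,
    z_score = (observed_empty - ee$mean) / ee$sd
  )
}

#' Test whether a repeat element is randomly distributed among clones
#'
#' Under random placement the empty-clone count is approximately normal with
#' the Holst mean and SD; an observed count many SDs from the mean indicates
#' the element is clustered (non-random). The verdict compares the absolute
#' standardized deviation `|observed - mean| / sd` against `ratio_threshold`
#' (default 5, far beyond plausible normal fluctuation).
#'
#' @inheritParams deviation_ratio
#' @param ratio_threshold Standardized-deviation threshold for declaring
#'   non-randomness.
#' @return An object of class `urn_test`: a one-row tibble with columns
#'   `n_clones`, `n_copies`, `p_fall`, `observed_empty`,
#'   `expected_empty_mean`, `expected_empty_sd`, `deviation_ratio`,
#'   `z_score`, `verdict` (`"non_random"` or `"consistent_with_random"`).
#' @examples
#' test_random_distribution(17639, 4898, 16751)
#' @export
test_random_distribution <- function(n_clones, n_copies, observed_empty,
                                     p_fall = 1 / n_clones,
                                     ratio_threshold = 5) {
  stopifnot(ratio_threshold > 0)
  ee <- expected_empty(n_clones, n_copies, p_fall)
  dr <- deviation_ratio(n_clones, n_copies, observed_empty, p_fall)
  out <- tibble::tibble(
    n_clones = n_clones,
    n_copies = n_copies,
    p_fall = p_fall,
    observed_empty = observed_empty,
    expected_empty_mean = ee$mean,
    expected_empty_sd = ee$sd,
    deviation_ratio = dr$ratio,
    z_score = dr$z_score,
    verdict = if (abs(dr$z_score) > ratio_threshold) "non_random"
              else "consistent_with_random"
  )
  class(out) <- c("urn_test", class(out))
  out
}

#' @exportS3Method generics::glance
glance.urn_test <- function(x, ...) {
  tibble::as_tibble(unclass(x))[
    , c("expected_empty_mean", "expected_empty_sd",
        "deviation_ratio", "z_score", "verdict")]
}
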