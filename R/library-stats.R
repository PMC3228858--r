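#' Describe a large-insert (BAC) clone library
#'
#' Bundles the counts and rates needed for library coverage arithmetic:
#' the total number of archived clones, the mean insert size, the false
#' positive rate (vector-only clones with no insert), the organellar
#' (chloroplast) contamination rate, and the 1C genome size of the source
#' organism.
#'
#' @param total_clones Total archived clones.
#' @param mean_insert Mean insert size, kb.
#' @param genome_size 1C genome size, Mb.
#' @param false_positive_rate Proportion of insert-free clones, `[0, 1)`.
#' @param organellar_rate Proportion of chloroplast-contaminated clones,
#'   `[0, 1)`.
#' @param nuclear_clones Optional directly determined count of
#'   nuclear-DNA-containing clones; when given it overrides the rate-based
#'   estimate in [nuclear_clone_count()] (useful when the nuclear count was
#'   established upstream with more precision than the pooled rates carry).
#' @return An object of class `library_profile`.
#' @examples
#' taxodium_bac_library()
#' @export
library_profile <- function(total_clones, mean_insert, genome_size,
                            false_positive_rate = 0, organellar_rate = 0,
                            nuclear_clones = NULL) {
  stopifnot(total_clones > 0, mean_insert > 0, genome_size > 0)
  if (false_positive_rate < 0 || false_positive_rate >= 1 ||
      organellar_rate < 0 || organellar_rate >= 1) {
    stop("rates must lie in [0, 1)")
  }
  if (false_positive_rate + organellar_rate >= 1) {
    stop("contamination rates sum to >= 1")
  }
  if (!is.null(nuclear_clones)) {
    stopifnot(nuclear_clones > 0, nuclear_clones <= total_clones)
  }
  structure(
    list(total_clones = total_clones, mean_insert = mean_insert,
         genome_size = genome_size,
         false_positive_rate = false_positive_rate,
         organellar_rate = organellar_rate,
         nuclear_clones = nuclear_clones),
    class = "library_profile"
  )
}

#' @export
print.library_profile <- function(x, ...) {
  cat(sprintf(
    "<library_profile> %s clones, %.0f kb mean insert, genome %.0f Mb\n",
    format(x$total_clones, big.mark = ","), x$mean_insert, x$genome_size))
  invisible(x)
}

#' The bald cypress BAC library profile
#'
#' The TDD_Ba library: 606,336 archived clones with a 113 kb mean insert for
#' the 9731 Mb bald cypress genome; 580,263 clones were determined to contain
#' nuclear DNA after subtracting false positives (1.8% pooled) and
#' chloroplast contamination (2348 of 92,160 array-screened clones, ~2.5%).
#'
#' @return A [library_profile()].
#' @export
taxodium_bac_library <- function() {
  library_profile(
    total_clones = 606336, mean_insert = 113, genome_size = 9731,
    false_positive_rate = 0.018, organellar_rate = 2348 / 92160,
    nuclear_clones = 580263
  )
}

#' Nuclear clone count and nuclear fraction of a library
#'
#' Subtracts false positive and organellar-contaminated clones from the total.
#' If the profile carries a directly determined `nuclear_clones` count it is
#' used as-is; otherwise the count is `total * (1 - fp_rate - org_rate)`,
#' rounded to the nearest clone.
#'
#' @param profile A [library_profile()].
#' @return A tibble with `total_clones`, `nuclear_clones` and
#'   `nuclear_fraction` (= nuclear / total).
#' @examples
#' nuclear_clone_count(taxodium_bac_library()) # fraction 0.957
#' @export
nuclear_clone_count <- function(profile) {
  stopifnot(inherits(profile, "library_profile"))
  nuc <- profile$nuclear_clones
  if (is.null(nuc)) {
    nuc <- round(profile$total_clones *
                   (1 - profile$false_positive_rate - profile$organellar_rate))
  }
  tibble::tibble(
    total_clones = profile$total_clones,
    nuclear_clones = nuc,
    nuclear_fraction = nuc / profile$total_clones
  )
}

#' Genome-equivalent coverage of a clone set
#'
#' Fold coverage of the genome represented by `n_clones` inserts:
#' `n_clones * mean_insert / genome_size` with kb/Mb conversion handled
#' internally (1 Mb = 1000 kb exactly).
#'
#' @param profile A [library_profile()].
#' @param n_clones Number of (nuclear) clones; defaults to the profile's
#'   nuclear clone count.
#' @return Fold coverage (dimensionless).
#' @examples
#' genome_equivalents(taxodium_bac_library()) # ~6.74
#' @export
genome_equivalents <- function(profile,
                               n_clones = nuclear_clone_count(profile)$nuclear_clones) {
  stopifnot(inherits(profile, "library_profile"), n_clones >= 0)
  n_clones * (profile$mean_insert / 1000) / profile$genome_size
}

#' Probability that a locus is represented in a library
#'
#' Clarke–Carbon formula: `1 - (1 - insert/genome)^n`, the chance a given
#' single-copy genomic sequence appears at least once among `n` random
#' inserts. For insert sizes much smaller than the genome this approaches
#' `1 - exp(-coverage)`.
#'
#' @inheritParams genome_equivalents
#' @return Probability in `[0, 1)`.
#' @examples
#' prob_locus_in_library(taxodium_bac_library()) # ~0.9988
#' @export
prob_locus_in_library <- function(profile,
                                  n_clones = nuclear_clone_count(profile)$nuclear_clones) {
  stopifnot(inherits(profile, "library_profile"), n_clones >= 0)
  frac <- (profile$mean_insert / 1000) / profile$genome_size
  if (frac >= 1) stop("mean insert must be smaller than the genome")
  1 - (1 - frac)^n_clones
}

#' Expected element copies represented on one macroarray
#'
#' Scales a genome-wide copy number by the fold coverage a macroarray's
#' clones provide: an array covering 0.205 genome equivalents should carry
#' `0.205 * copies` copies of the element.
#'
#' @param genome_copies Element copies per 1C genome.
#' @param array_coverage Fold coverage of the array (see
#'   [genome_equivalents()] with the per-array clone count).
#' @return Expected copy count (not rounded).
#' @examples
#' expected_copies_on_array(23892, 0.205) # ~4898
#' @export
expected_copies_on_array <- function(genome_copies, array_coverage) {
  stopifnot(genome_copies >= 0, array_coverage >= 0)
  genome_copies * array_coverage
}

#' Full library accounting report
#'
#' Computes every derived library quantity in one pass: nuclear clone count
#' and fraction, whole-library genome equivalents and Clarke–Carbon
#' representation probability, and (when an array clone count is supplied)
#' per-array nuclear clones and fold coverage. Display rounding follows the
#' conventional presentation: counts to integers, fractions to 3 decimals,
#' fold coverage to 2 decimals (per-array coverage to 3, where the extra
#' digit is meaningful).
#'
#' @param profile A [library_profile()].
#' @param array_clones Clones spotted per macroarray (optional).
#' @param rounded Apply display rounding.
#' @return A one-row tibble.
#' @examples
#' library_report(taxodium_bac_library(), array_clones = 18432)
#' @export
library_report <- function(profile, array_clones = NULL, rounded = TRUE) {
  nuc <- nuclear_clone_count(profile)
  ge <- genome_equivalents(profile, nuc$nuclear_clones)
  pr <- prob_locus_in_library(profile, nuc$nuclear_clones)
  out <- tibble::tibble(
    total_clones = nuc$total_clones,
    nuclear_clones = nuc$nuclear_clones,
    nuclear_fraction = if (rounded) round(nuc$nuclear_fraction, 3) else nuc$nuclear_fraction,
    genome_equivalents = if (rounded) round(ge, 2) else ge,
    prob_locus = if (rounded) round(pr, 4) else pr
  )
  if (!is.null(array_clones)) {
    arr_nuc <- round(array_clones * out$nuclear_fraction)
    cov <- genome_equivalents(profile, arr_nuc)
    out$array_clones <- array_clones
    out$array_nuclear_clones <- arr_nuc
    out$array_coverage <- if (rounded) round(cov, 3) else cov
  }
  out
}
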