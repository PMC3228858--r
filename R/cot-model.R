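#' Construct a multi-component Cot reassociation model
#'
#' A Cot model describes the renaturation kinetics of a genome as a mixture of
#' second-order reassociating sequence classes ("kinetic components"), plus a
#' foldback fraction that reassociates essentially instantaneously (hairpins
#' and other snap-back structures, modeled as a Cot-independent offset) and an
#' unreassociated residue that never renatures over the observed Cot range.
#' Each component `i` occupies a fraction \eqn{f_i} of the genome and renatures
#' with second-order rate constant \eqn{k_i} (M\eqn{^{-1}}s\eqn{^{-1}}), so the
#' fraction of total DNA reassociated at a given Cot value \eqn{c} is
#' \deqn{y(c) = f_{fold} + \sum_i f_i \frac{k_i c}{1 + k_i c}.}
#'
#' Components are stored sorted by rate, fastest first. With exactly three
#' components they are labeled `HR` (highly repetitive), `MR` (moderately
#' repetitive) and `SL` (single/low-copy), the conventional names for the
#' fast, intermediate and slow classes of a plant genome; otherwise they are
#' labeled `C1`...`Cn` (C1 fastest).
#'
#' @param components A data frame with columns `fraction` (proportion of the
#'   genome in each component, each in (0, 1]) and `rate_k` (second-order rate
#'   constant, M^-1 s^-1, all positive and distinct).
#' @param foldback Foldback proportion in `[0, 1)`.
#' @param unreassociated Unreassociated residue in `[0, 1)`. When `NULL`
#'   (default) it is computed as `1 - foldback - sum(fraction)` so the model
#'   always closes to 1. When supplied, the closure identity
#'   `foldback + sum(fraction) + unreassociated == 1` is enforced to
#'   `tolerance`.
#' @param tolerance Numeric tolerance for the closure identity.
#' @return An object of class `cot_model`: a list with elements `components`
#'   (a tibble with `component`, `fraction`, `rate_k`), `foldback` and
#'   `unreassociated`.
#' @examples
#' m <- cot_model(data.frame(fraction = c(0.5, 0.45), rate_k = c(1, 0.01)),
#'                foldback = 0.02)
#' fraction_reassociated(m, c(0.1, 1, 100))
#' @export
cot_model <- function(components, foldback = 0, unreassociated = NULL,
                      tolerance = 1e-6) {
  components <- as.data.frame(components)
  stopifnot(all(c("fraction", "rate_k") %in% names(components)))
  f <- as.numeric(components$fraction)
  k <- as.numeric(components$rate_k)
  if (length(f) < 1) stop("at least one kinetic component is required")
  if (any(!is.finite(f)) || any(f <= 0) || any(f > 1)) {
    stop("component fractions must lie in (0, 1]")
  }
  if (any(!is.finite(k)) || any(k <= 0)) stop("component rates must be positive")
  if (anyDuplicated(k)) stop("no two components may share a rate")
  if (!is.finite(foldback) || foldback < 0 || foldback >= 1) {
    stop("foldback must lie in [0, 1)")
  }
  if (is.null(unreassociated)) {
    unreassociated <- 1 - foldback - sum(f)
    if (unreassociated < -tolerance) {
      stop("foldback + component fractions exceed 1")
    }
    unreassociated <- max(unreassociated, 0)
  } else {
    if (unreassociated < 0 || unreassociated >= 1) {
      stop("unreassociated must lie in [0, 1)")
    }
    total <- foldback + sum(f) + unreassociated
    if (abs(total - 1) > tolerance) {
      stop(sprintf(
        "model fractions must sum to 1 (got %.7f); pass unreassociated = NULL to close the model",
        total
      ))
    }
  }
  ord <- order(k, decreasing = TRUE)
  f <- f[ord]
  k <- k[ord]
  comp <- tibble::tibble(
    component = component_labels(length(k)),
    fraction = f,
    rate_k = k
  )
  structure(
    list(components = comp, foldback = foldback,
         unreassociated = unreassociated),
    class = "cot_model"
  )
}

component_labels <- function(n) {
  if (n == 3) c("HR", "MR", "SL") else paste0("C", seq_len(n))
}

#' @export
print.cot_model <- function(x, ...) {
  cat(sprintf("<cot_model> %d component(s), foldback %.4f, unreassociated %.4f\n",
              nrow(x$components), x$foldback, x$unreassociated))
  print(x$components)
  invisible(x)
}

is_cot_model <- function(x) inherits(x, "cot_model")

#' Reference three-component Cot model for the bald cypress genome
#'
#' The published least-squares fit for bald cypress (*Taxodium distichum* var.
#' *distichum*, 1C = 9731 Mb) resolves the genome into highly repetitive (HR),
#' moderately repetitive (MR) and single/low-copy (SL) components with the
#' fractions and rates returned here, plus a 1.74% foldback fraction. The
#' printed component fractions carry display rounding, so the unreassociated
#' residue is recomputed from closure (0.0266 rather than the displayed
#' 0.0233); the residue enters none of the derived component statistics.
#'
#' @return A [cot_model()] with components HR (f = 0.4702, k = 0.2157),
#'   MR (f = 0.4114, k = 0.00637) and SL (f = 0.0744, k = 0.000105).
#' @examples
#' component_table(taxodium_cot_model())
#' @export
taxodium_cot_model <- function() {
  cot_model(
    data.frame(fraction = c(0.4702, 0.4114, 0.0744),
               rate_k = c(0.2157, 0.00637, 0.000105)),
    foldback = 0.0174
  )
}

#' Genome size of bald cypress (1C, Mb)
#'
#' Flow-cytometric 1C DNA content used throughout the worked examples.
#' @return 9731 (Mb).
#' @export
taxodium_genome_size <- function() 9731

#' Fraction of DNA reassociated at given Cot values
#'
#' Evaluates the closed-form mixture curve
#' \eqn{y(c) = f_{fold} + \sum_i f_i k_i c / (1 + k_i c)}. The curve is
#' strictly increasing in Cot and tends to `1 - unreassociated` as Cot grows.
#'
#' @param model A [cot_model()].
#' @param cot Numeric vector of Cot values (M·s), all `>= 0`.
#' @return Numeric vector of reassociated fractions in `[0, 1]`.
#' @export
fraction_reassociated <- function(model, cot) {
  stopifnot(is_cot_model(model))
  cot <- as.numeric(cot)
  if (any(!is.finite(cot)) || any(cot < 0)) stop("cot values must be >= 0")
  f <- model$components$fraction
  k <- model$components$rate_k
  vapply(cot, function(c0) {
    kc <- k * c0
    model$foldback + sum(f * kc / (1 + kc))
  }, numeric(1))
}

#' Observed Cot1/2 of a kinetic component
#'
#' The Cot value at which half of a pure second-order component has
#' reassociated: the reciprocal of its rate constant.
#'
#' @param rate_k Second-order rate constant(s), M^-1 s^-1, positive.
#' @return Cot1/2 in M·s.
#' @examples
#' cot_half_observed(0.2157) # ~4.64 M·s
#' @export
cot_half_observed <- function(rate_k) {
  rate_k <- as.numeric(rate_k)
  if (any(!is.finite(rate_k)) || any(rate_k <= 0)) stop("rate_k must be > 0")
  1 / rate_k
}

#' Mean repetition frequency of a component
#'
#' Average genome copy number of sequences in a component, estimated by
#' dividing its rate constant by that of the single/low-copy reference
#' component (whose repetition frequency is taken to be 1).
#'
#' @param rate_k Rate constant(s) of the component(s) of interest.
#' @param slow_rate_k Rate constant of the single/low-copy reference.
#' @return Copy number(s), dimensionless.
#' @examples
#' mean_repetition_frequency(0.2157, 0.000105) # ~2054
#' @export
mean_repetition_frequency <- function(rate_k, slow_rate_k) {
  if (!is.finite(slow_rate_k) || slow_rate_k <= 0) {
    stop("slow reference rate must be > 0")
  }
  as.numeric(rate_k) / slow_rate_k
}

#' Two-Cot-decade region of a component
#'
#' For a second-order component, 80% of its sequences reassociate within the
#' two-decade Cot interval centered (in log space) on its Cot1/2: from
#' `0.1 * cot_half` to `10 * cot_half`. Because rate (hence Cot1/2) maps to
#' copy number, the same two-decade spread applies to repetition frequencies
#' (see [repetition_range()]).
#'
#' @param cot_half Observed Cot1/2 value(s), M·s.
#' @return A tibble with columns `low` and `high` (M·s); `high/low` is
#'   always exactly 100.
#' @export
tcdr <- function(cot_half) {
  cot_half <- as.numeric(cot_half)
  if (any(!is.finite(cot_half)) || any(cot_half <= 0)) {
    stop("cot_half must be > 0")
  }
  tibble::tibble(low = 0.1 * cot_half, high = 10 * cot_half)
}

#' Copy-number range covering 80% of a component's sequences
#'
#' The two-Cot-decade region expressed in repetition-frequency space: 80% of
#' sequences in a component with mean repetition frequency `mrf` have copy
#' numbers between `mrf/10` and `10*mrf`.
#'
#' @param mrf Mean repetition frequency value(s).
#' @return A tibble with columns `low` and `high` (copies).
#' @examples
#' repetition_range(61) # 6.1 to 610
#' @export
repetition_range <- function(mrf) {
  mrf <- as.numeric(mrf)
  if (any(!is.finite(mrf)) || any(mrf < 0)) stop("mrf must be >= 0")
  tibble::tibble(low = mrf / 10, high = mrf * 10)
}

#' Calibration standard for kinetic complexity
#'
#' Kinetic complexity and genome-size arithmetic are calibrated against a
#' genome of known sequence complexity and known pure Cot1/2 — conventionally
#' *E. coli* (complexity 4.639e6 bp). The defaults here use a pure Cot1/2 of
#' 4.57 M·s, giving a calibration ratio of 1.0151 Mb per M·s; both fields are
#' configurable for other reaction conditions.
#'
#' @param reference_complexity Sequence complexity of the calibration genome,
#'   base pairs.
#' @param reference_cot_half Pure Cot1/2 of the calibration genome, M·s.
#' @return An object of class `calibration_standard`.
#' @examples
#' calibration_ratio(calibration_standard()) # ~1.0151 Mb per M·s
#' @export
calibration_standard <- function(reference_complexity = 4.639e6,
                                 reference_cot_half = 4.57) {
  if (!is.finite(reference_complexity) || reference_complexity <= 0 ||
      !is.finite(reference_cot_half) || reference_cot_half <= 0) {
    stop("calibration fields must be > 0")
  }
  structure(
    list(reference_complexity = reference_complexity,
         reference_cot_half = reference_cot_half),
    class = "calibration_standard"
  )
}

#' @export
print.calibration_standard <- function(x, ...) {
  cat(sprintf("<calibration_standard> complexity %.4g bp, pure Cot1/2 %.4g M·s (R = %.4f Mb per M·s)\n",
              x$reference_complexity, x$reference_cot_half,
              calibration_ratio(x)))
  invisible(x)
}

#' @rdname calibration_standard
#' @param calib A `calibration_standard`.
#' @return `calibration_ratio()`: Mb of complexity per M·s of pure Cot1/2.
#' @export
calibration_ratio <- function(calib = calibration_standard()) {
  stopifnot(inherits(calib, "calibration_standard"))
  (calib$reference_complexity / 1e6) / calib$reference_cot_half
}

#' Kinetic complexity of a component
#'
#' Estimated unique sequence length (Mb) of a component: its pure Cot1/2
#' (`fraction / rate_k`, the Cot1/2 it would show if studied in isolation)
#' scaled by the calibration genome's complexity-to-Cot1/2 ratio.
#'
#' @param fraction Genome fraction(s) of the component(s).
#' @param rate_k Rate constant(s), M^-1 s^-1.
#' @param calib A [calibration_standard()].
#' @return Kinetic complexity in Mb.
#' @examples
#' kinetic_complexity(0.4114, 0.00637) # ~65.56 Mb
#' @export
kinetic_complexity <- function(fraction, rate_k, calib = calibration_standard()) {
  fraction <- as.numeric(fraction)
  rate_k <- as.numeric(rate_k)
  if (any(!is.finite(fraction)) || any(fraction < 0)) stop("fraction must be >= 0")
  if (any(!is.finite(rate_k)) || any(rate_k <= 0)) stop("rate_k must be > 0")
  (fraction / rate_k) * calibration_ratio(calib)
}

#' Fix the slow-component rate from an independently known genome size
#'
#' When the genome size is known (e.g. from flow cytometry) the rate constant
#' of the single/low-copy component can be fixed rather than fitted: a
#' single-copy sequence class spanning the whole genome would have pure Cot1/2
#' `G / R`, hence rate `R / G`, where `R` is the calibration ratio. This is
#' the algebraic inverse of [kinetic_complexity()]: with the returned rate, a
#' component of fraction `f` has kinetic complexity `f * genome_size`.
#'
#' @param genome_size 1C genome size, Mb.
#' @param calib A [calibration_standard()].
#' @return Rate constant, M^-1 s^-1.
#' @examples
#' fix_slow_rate_from_genome(9731) # ~1.043e-4, rounds to the reported 0.000105
#' @export
fix_slow_rate_from_genome <- function(genome_size, calib = calibration_standard()) {
  if (!is.finite(genome_size) || genome_size <= 0) stop("genome_size must be > 0")
  calibration_ratio(calib) / genome_size
}

#' Mean repetition frequency of sequences at a Cot cut-off
#'
#' In Cot filtration, DNA reassociated by a chosen Cot cut-off is enriched for
#' repeats. A sequence class whose Cot1/2 equals the cut-off has mean
#' repetition frequency `Cot1/2(SL) / cutoff = 1 / (cutoff * k_SL)` relative
#' to the single/low-copy component.
#'
#' @param cot_cutoff Cot cut-off, M·s, `> 0`.
#' @param slow_rate_k Rate constant of the single/low-copy component.
#' @return Copy number (dimensionless).
#' @examples
#' repetition_at_cot(1, 0.000105) # ~9523.8: Cot-1 DNA averages ~9523 copies
#' @export
repetition_at_cot <- function(cot_cutoff, slow_rate_k) {
  cot_cutoff <- as.numeric(cot_cutoff)
  if (any(!is.finite(cot_cutoff)) || any(cot_cutoff <= 0)) {
    stop("cot_cutoff must be > 0")
  }
  cot_half_observed(slow_rate_k) / cot_cutoff
}

#' Per-component genome statistics table
#'
#' Derives, for every component of a Cot model, the columns of the
#' conventional Cot-analysis results table: genome fraction, kinetic
#' complexity (Mb), rate constant, observed Cot1/2 (M·s), mean repetition
#' frequency (MRF, relative to the slowest component), the two-Cot-decade
#' region, and the copy-number range holding 80% of the component's
#' sequences.
#'
#' With `rounded = TRUE` (default) display rounding mirrors the conventional
#' presentation: MRF to the nearest integer, Cot1/2 to 2 decimals, kinetic
#' complexity to 4 significant figures; the 80% copy range is derived from
#' the rounded MRF so printed columns stay mutually consistent.
#'
#' @param model A [cot_model()].
#' @param calib A [calibration_standard()].
#' @param rounded Apply display rounding (see Details).
#' @return A tibble with one row per component: `component`, `fraction`,
#'   `kncx_mb`, `rate_k`, `cot_half`, `mrf`, `tcdr_low`, `tcdr_high`,
#'   `copies_low`, `copies_high`.
#' @examples
#' component_table(taxodium_cot_model())
#' @export
component_table <- function(model, calib = calibration_standard(),
                            rounded = TRUE) {
  stopifnot(is_cot_model(model))
  comp <- model$components
  k_sl <- min(comp$rate_k)
  cot_half <- cot_half_observed(comp$rate_k)
  mrf <- mean_repetition_frequency(comp$rate_k, k_sl)
  kncx <- kinetic_complexity(comp$fraction, comp$rate_k, calib)
  if (rounded) {
    cot_half <- round(cot_half, 2)
    mrf <- round(mrf)
    kncx <- signif(kncx, 4)
  }
  reg <- tcdr(cot_half)
  cop <- repetition_range(mrf)
  tibble::tibble(
    component = comp$component,
    fraction = comp$fraction,
    kncx_mb = kncx,
    rate_k = comp$rate_k,
    cot_half = cot_half,
    mrf = mrf,
    tcdr_low = reg$low,
    tcdr_high = reg$high,
    copies_low = cop$low,
    copies_high = cop$high
  )
}

#' @exportS3Method generics::tidy
tidy.cot_model <- function(x, ...) {
  x$components
}

#' @exportS3Method generics::glance
glance.cot_model <- function(x, ...) {
  tibble::tibble(
    n_components = nrow(x$components),
    foldback = x$foldback,
    unreassociated = x$unreassociated,
    repetitive_fraction = sum(x$components$fraction[
      x$components$rate_k > min(x$components$rate_k)])
  )
}

#' Serialize a Cot model to JSON
#'
#' The document has fields `foldback`, `unreassociated` and `components`
#' (array of `{fraction, k}` objects, fastest first), written at full double
#' precision so that a write/read round trip reproduces the model exactly.
#'
#' @param model A [cot_model()].
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return `path` invisibly when writing to file, else the JSON string.
#' @export
cot_model_to_json <- function(model, path = NULL) {
  stopifnot(is_cot_model(model))
  doc <- list(
    foldback = model$foldback,
    unreassociated = model$unreassociated,
    components = purrr::map2(
      model$components$fraction, model$components$rate_k,
      function(f, k) list(fraction = f, k = k)
    )
  )
  if (is.null(path)) {
    as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = I(17)))
  } else {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17))
    invisible(path)
  }
}

#' @rdname cot_model_to_json
#' @param json A JSON string or path to a JSON file produced by
#'   [cot_model_to_json()].
#' @export
cot_model_from_json <- function(json) {
  doc <- jsonlite::fromJSON(json, simplifyDataFrame = TRUE)
  comp <- as.data.frame(doc$components)
  cot_model(
    data.frame(fraction = comp$fraction, rate_k = comp$k),
    foldback = doc$foldback,
    unreassociated = doc$unreassociated
  )
}

#' Plot a Cot model curve
#'
#' Draws the mixture renaturation curve (and optionally each component's
#' individual profile) over a log-spaced Cot grid, in the conventional
#' orientation: fraction reassociated against log10 Cot.
#'
#' @param object A [cot_model()].
#' @param cot_range Length-2 numeric, Cot limits (M·s).
#' @param components Also draw per-component profiles.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.cot_model <- function(object, cot_range = c(1e-4, 1e5),
                               components = TRUE, ...) {
  grid <- 10^seq(log10(cot_range[1]), log10(cot_range[2]), length.out = 300)
  total <- tibble::tibble(cot = grid,
                          y = fraction_reassociated(object, grid))
  p <- ggplot2::ggplot(total, ggplot2::aes(x = .data$cot, y = .data$y)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Cot (M·s)", y = "Fraction reassociated") +
    ggplot2::theme_minimal()
  if (components) {
    per <- purrr::pmap_dfr(
      object$components,
      function(component, fraction, rate_k) {
        tibble::tibble(component = component, cot = grid,
                       y = fraction * (rate_k * grid) / (1 + rate_k * grid))
      }
    )
    p <- p + ggplot2::geom_line(
      data = per,
      ggplot2::aes(colour = .data$component),
      linetype = "dashed"
    )
  }
  p
}
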