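# Seed hygiene: generators are pure functions of their arguments (seed
# included) and never disturb the caller's RNG stream.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

#' Simulate a noisy Cot dataset from a known model
#'
#' Evaluates the forward renaturation curve on a Cot grid and adds i.i.d.
#' Gaussian noise to the reassociated fractions, clipping to `[0, 1]`. This
#' emulates the scatter of a wet-lab reassociation experiment with a known
#' underlying component mixture, so curve-fitting can be validated by
#' parameter recovery.
#'
#' @param model A [cot_model()].
#' @param n Number of points (ignored when `cot_grid` is given).
#' @param cot_range Length-2 Cot limits, M·s; points are log-spaced.
#' @param cot_grid Optional explicit strictly increasing Cot grid.
#' @param noise_sd Standard deviation of additive Gaussian noise on the
#'   fraction scale (`>= 0`).
#' @param seed Integer seed; identical arguments give identical datasets.
#' @return A tibble with columns `cot` and `fraction_reassociated`.
#' @examples
#' simulate_cot_dataset(taxodium_cot_model(), n = 10, noise_sd = 0, seed = 1)
#' @export
simulate_cot_dataset <- function(model, n = 60, cot_range = c(1e-3, 1e5),
                                 cot_grid = NULL, noise_sd = 0.01, seed = 1) {
  stopifnot(is_cot_model(model), noise_sd >= 0)
  if (is.null(cot_grid)) {
    stopifnot(length(cot_range) == 2, cot_range[1] > 0,
              cot_range[2] > cot_range[1])
    cot_grid <- 10^seq(log10(cot_range[1]), log10(cot_range[2]),
                       length.out = n)
  }
  cot_grid <- as.numeric(cot_grid)
  if (any(diff(cot_grid) <= 0)) stop("cot_grid must be strictly increasing")
  y <- fraction_reassociated(model, cot_grid)
  if (noise_sd > 0) {
    y <- with_seed(seed, y + stats::rnorm(length(y), sd = noise_sd))
  }
  tibble::tibble(cot = cot_grid,
                 fraction_reassociated = pmin(pmax(y, 0), 1))
}

#' Simulate repeat-element placement across an arrayed clone library
#'
#' Models a macroarray hybridization screen: the array's clones collectively
#' cover `n_clones * insert_size / genome_size` genome equivalents, so of the
#' `element_copies` genome-wide copies of an element, about
#' `round(element_copies * coverage)` fall on the array. With
#' `clustering = 0` each copy lands in a clone independently and uniformly
#' (multinomial placement) — the null model of the Holst occupancy test. With
#' `clustering > 0` clone propensities are drawn from a symmetric Dirichlet
#' with concentration `1/clustering`, so copies pile into correlated blocks
#' and the empty-clone count inflates, emulating a physically clustered
#' repeat.
#'
#' @param n_clones Clones on the array.
#' @param element_copies Element copies per 1C genome.
#' @param insert_size Mean insert size, kb.
#' @param genome_size 1C genome size, Mb.
#' @param clustering Dispersion dial `>= 0`; `0` = random placement.
#' @param seed Integer seed.
#' @param copies_on_array Directly specify the number of copies landing on
#'   the array, bypassing the coverage arithmetic (useful for calibration
#'   against closed forms).
#' @return A tibble with `clone_id` and `count`; `sum(count)` equals the
#'   number of copies placed.
#' @examples
#' x <- simulate_macroarray(1000, element_copies = 300, copies_on_array = 300,
#'                          seed = 1)
#' sum(x$count == 0) # compare expected_empty(1000, 300)
#' @export
simulate_macroarray <- function(n_clones, element_copies, insert_size = 113,
                                genome_size = 9731, clustering = 0, seed = 1,
                                copies_on_array = NULL) {
  stopifnot(n_clones > 0, element_copies >= 0, clustering >= 0)
  if (is.null(copies_on_array)) {
    coverage <- n_clones * (insert_size / 1000) / genome_size
    copies_on_array <- round(element_copies * coverage)
  }
  counts <- with_seed(seed, {
    prob <- if (clustering > 0) {
      g <- stats::rgamma(n_clones, shape = 1 / clustering)
      # guard against all-zero draws at extreme clustering
      if (sum(g) == 0) g[sample.int(n_clones, 1)] <- 1
      g / sum(g)
    } else {
      rep(1 / n_clones, n_clones)
    }
    if (copies_on_array > 0) {
      as.integer(stats::rmultinom(1, size = copies_on_array, prob = prob))
    } else {
      integer(n_clones)
    }
  })
  tibble::tibble(clone_id = seq_len(n_clones), count = counts)
}

base_probs <- function(gc) {
  c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
}

random_dna <- function(n, gc = 0.38) {
  if (n <= 0) return("")
  p <- base_probs(gc)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Reverse complement of DNA strings
#'
#' @param x Character vector of DNA sequences (A/C/G/T/N).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

comp_base <- function(x) chartr("ACGTN", "TGCAN", x)

#' Plant MITE-like elements into random background sequences
#'
#' Builds synthetic reads resembling repeat-dense (Cot-filtered) genomic
#' sequence: random-background DNA into which elements with the canonical
#' MITE structure are inserted — a direct repeat (DR), the left terminal
#' inverted repeat (TIR), an internal spacer, the reverse complement of the
#' TIR, and the second copy of the DR. Elements are laid down left to right
#' separated by background spacers of length `spacer[1]`–`spacer[2]` bp.
#'
#' The generator guarantees the truth table is the *maximal* structure a
#' scanner should report: the DR's first two bases differ (so no longer
#' direct repeat spans the planted one by periodicity), the outermost DR
#' bases do not complement each other (so the TIR cannot extend outward into
#' the DRs), and the internal spacer's terminal bases do not complement each
#' other (so the TIR cannot extend inward). Without these guards the planted
#' coordinates would be ambiguous ground truth, not a property of the
#' scanner.
#'
#' @param elements A data frame with columns `tir_len`, `dr_len`,
#'   `internal_len` and optionally `count` (default 1 each); one planted
#'   element per row-count, assigned to sequences round-robin.
#' @param n_sequences Number of sequences to generate.
#' @param gc GC content of background, DR, TIR and internal sequence.
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @param spacer Length-2 integer range for background spacers between and
#'   around elements, bp.
#' @param check_bounds Validate that planted element lengths
#'   (`2*tir_len + internal_len`) lie within the default detectable range
#'   `[100, 1000]` bp; set `FALSE` to plant out-of-bounds elements
#'   deliberately (e.g. for threshold tests).
#' @return A list with `sequences` (tibble: `seq_id`, `sequence`) and
#'   `truth` (tibble: `seq_id`, `start`, `end`, `tir_len`, `dr_len`,
#'   `internal_len`, `tir_seq`, `dr_seq`); coordinates are 1-based inclusive
#'   and delimit the element itself (TIR through TIR, DRs outside).
#' @examples
#' fx <- plant_mites(data.frame(tir_len = 10, dr_len = 3, internal_len = 200))
#' fx$truth
#' @export
plant_mites <- function(elements, n_sequences = 1, gc = 0.38, seed = 1,
                        spacer = c(40, 120), check_bounds = TRUE) {
  elements <- as.data.frame(elements)
  stopifnot(all(c("tir_len", "dr_len", "internal_len") %in% names(elements)))
  if (is.null(elements$count)) elements$count <- rep(1L, nrow(elements))
  elements <- elements[rep(seq_len(nrow(elements)), elements$count),
                       c("tir_len", "dr_len", "internal_len"), drop = FALSE]
  n_elem <- nrow(elements)
  if (n_elem > 0) {
    stopifnot(all(elements$tir_len >= 1), all(elements$dr_len >= 1),
              all(elements$internal_len >= 2))
    if (check_bounds) {
      len <- 2 * elements$tir_len + elements$internal_len
      if (any(len < 100 | len > 1000)) {
        stop("planted element lengths must lie in [100, 1000] bp ",
             "(set check_bounds = FALSE to override)")
      }
    }
  }
  stopifnot(n_sequences >= 1, length(spacer) == 2, spacer[1] >= 2,
            spacer[2] >= spacer[1])
  assign_seq <- if (n_elem > 0) ((seq_len(n_elem) - 1L) %% n_sequences) + 1L
                else integer(0)

  with_seed(seed, {
    seqs <- character(n_sequences)
    truth <- vector("list", n_elem)
    ti <- 0L
    for (s in seq_len(n_sequences)) {
      idx <- which(assign_seq == s)
      parts <- character(0)
      pos <- 0L
      lead <- sample(spacer[1]:spacer[2], 1)
      parts <- c(parts, random_dna(lead, gc))
      pos <- pos + lead
      for (j in idx) {
        tl <- elements$tir_len[j]
        dl <- elements$dr_len[j]
        il <- elements$internal_len[j]
        dr <- make_guarded_dr(dl, gc)
        tir <- random_dna(tl, gc)
        internal <- make_guarded_internal(il, gc)
        unit <- paste0(dr, tir, internal, revcomp(tir), dr)
        start <- pos + dl + 1L
        end <- pos + dl + 2L * tl + il
        ti <- ti + 1L
        truth[[ti]] <- tibble::tibble(
          seq_id = sprintf("seq%03d", s), start = start, end = end,
          tir_len = tl, dr_len = dl, internal_len = il,
          tir_seq = tir, dr_seq = dr
        )
        parts <- c(parts, unit)
        pos <- pos + nchar(unit)
        gap <- sample(spacer[1]:spacer[2], 1)
        parts <- c(parts, random_dna(gap, gc))
        pos <- pos + gap
      }
      seqs[s] <- paste(parts, collapse = "")
    }
    list(
      sequences = tibble::tibble(
        seq_id = sprintf("seq%03d", seq_len(n_sequences)),
        sequence = seqs
      ),
      truth = if (ti > 0) dplyr::bind_rows(truth[seq_len(ti)])
              else tibble::tibble(
                seq_id = character(), start = integer(), end = integer(),
                tir_len = integer(), dr_len = integer(),
                internal_len = integer(), tir_seq = character(),
                dr_seq = character())
    )
  })
}

# DR whose first two bases differ (no periodic extension past the planted DR)
# and whose outermost bases do not complement each other (no outward TIR
# extension through the DRs).
make_guarded_dr <- function(len, gc) {
  repeat {
    dr <- random_dna(len, gc)
    b <- strsplit(dr, "", fixed = TRUE)[[1]]
    if (len >= 2 && b[1] == b[2]) next
    if (b[len] == comp_base(b[1])) next
    return(dr)
  }
}

# Internal spacer whose terminal bases do not complement each other, so the
# TIR cannot extend inward past the planted boundary.
make_guarded_internal <- function(len, gc) {
  repeat {
    x <- random_dna(len, gc)
    b <- strsplit(x, "", fixed = TRUE)[[1]]
    if (b[1] != comp_base(b[len])) return(x)
  }
}

#' Write sequences to a FASTA file
#'
#' @param sequences A tibble with `seq_id` and `sequence` (as produced by
#'   [plant_mites()]), or a named character vector.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  if (is.data.frame(sequences)) {
    x <- Biostrings::DNAStringSet(sequences$sequence)
    names(x) <- sequences$seq_id
  } else {
    x <- Biostrings::DNAStringSet(sequences)
  }
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

#' Read a FASTA file into a tibble
#'
#' @param path FASTA file path.
#' @return A tibble with `seq_id` and `sequence`.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  tibble::tibble(seq_id = sub("\\s.*$", "", names(x)),
                 sequence = unname(as.character(x)))
}
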