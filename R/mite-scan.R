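#' Parameters for MITE scanning
#'
#' Detection bounds for candidate miniature inverted-repeat transposable
#' elements: lengths of the terminal inverted repeats (TIRs), of the flanking
#' target-site duplications (direct repeats, DRs), and of the whole element
#' (TIR through TIR). Defaults follow the conventional screen for short
#' non-autonomous elements in plant genomic reads: TIR 8–50 nt, DR 2–30 nt,
#' element 100–1000 nt, exact TIR matching.
#'
#' @param min_tir,max_tir TIR length bounds, nt.
#' @param min_dr,max_dr DR length bounds, nt.
#' @param min_len,max_len Element length bounds, nt (`min_len >= 2*min_tir`).
#' @param max_tir_mismatches Mismatches tolerated between the left TIR and
#'   the reverse complement of the right TIR (0 = exact).
#' @param require_dr Reject candidates with no flanking DR of at least
#'   `min_dr` nt. Whether genuine elements always retain a detectable
#'   target-site duplication is debatable, so this is a switch.
#' @return An object of class `mite_params`.
#' @export
mite_params <- function(min_tir = 8, max_tir = 50, min_dr = 2, max_dr = 30,
                        min_len = 100, max_len = 1000,
                        max_tir_mismatches = 0, require_dr = TRUE) {
  stopifnot(min_tir >= 1, max_tir >= min_tir, min_dr >= 1, max_dr >= min_dr,
            min_len >= 2 * min_tir, max_len >= min_len,
            max_tir_mismatches >= 0)
  structure(
    list(min_tir = min_tir, max_tir = max_tir, min_dr = min_dr,
         max_dr = max_dr, min_len = min_len, max_len = max_len,
         max_tir_mismatches = max_tir_mismatches, require_dr = require_dr),
    class = "mite_params"
  )
}

#' @export
print.mite_params <- function(x, ...) {
  cat(sprintf(
    "<mite_params> TIR %d-%d nt, DR %d-%d nt, element %d-%d nt, %d TIR mismatch(es), DR %s\n",
    x$min_tir, x$max_tir, x$min_dr, x$max_dr, x$min_len, x$max_len,
    x$max_tir_mismatches, if (x$require_dr) "required" else "optional"))
  invisible(x)
}

empty_candidates <- function() {
  tibble::tibble(
    seq_id = character(), start = integer(), end = integer(),
    length = integer(), tir_len = integer(), dr_len = integer(),
    internal_len = integer(), tir_seq = character(), dr_seq = character()
  )
}

#' Scan sequences for candidate MITEs
#'
#' Seed-and-extend search for the canonical MITE structure: a left TIR whose
#' reverse complement recurs at the element's right end, flanked immediately
#' outside by identical direct repeats. Seeds are exact `min_tir`-mer inverted
#' matches within the allowed element-length window, found through a k-mer
#' hash; each seed pair fixes the element boundaries and the TIR is then
#' extended inward as far as bases keep pairing (up to `max_tir`, spending at
#' most `max_tir_mismatches`). `N` bases never match. Candidates nested
#' inside a larger candidate are dropped, and overlapping candidates are
#' resolved greedily, longest TIR first, then leftmost. Results are reported
#' in ascending start order with 1-based inclusive coordinates.
#'
#' @param sequences A data frame with `seq_id` and `sequence` columns (see
#'   [read_fasta()], [plant_mites()]), or a (optionally named) character
#'   vector of sequences over `{A, C, G, T, N}`.
#' @param params A [mite_params()].
#' @return A tibble of candidates: `seq_id`, `start`, `end`, `length`,
#'   `tir_len`, `dr_len`, `internal_len`, `tir_seq` (left TIR), `dr_seq`
#'   (`NA` when no DR qualifies and `require_dr = FALSE`).
#' @examples
#' fx <- plant_mites(data.frame(tir_len = 12, dr_len = 3, internal_len = 180),
#'                   seed = 42)
#' scan_mites(fx$sequences)
#' @export
scan_mites <- function(sequences, params = mite_params()) {
  stopifnot(inherits(params, "mite_params"))
  if (is.character(sequences)) {
    ids <- names(sequences)
    if (is.null(ids)) ids <- sprintf("seq%03d", seq_along(sequences))
    sequences <- tibble::tibble(seq_id = ids, sequence = sequences)
  }
  stopifnot(all(c("seq_id", "sequence") %in% names(sequences)))
  out <- purrr::map2(sequences$seq_id, sequences$sequence,
                     function(id, s) scan_one_sequence(id, s, params))
  res <- dplyr::bind_rows(c(list(empty_candidates()), out))
  res[order(res$seq_id, res$start, res$end), ]
}

scan_one_sequence <- function(seq_id, seq, params) {
  seq <- toupper(seq)
  if (grepl("[^ACGTN]", seq)) stop("sequence contains non-ACGTN characters")
  L <- nchar(seq)
  if (L < params$min_len) return(empty_candidates())
  k <- params$min_tir
  bases <- strsplit(seq, "", fixed = TRUE)[[1]]
  comp <- strsplit(comp_base(seq), "", fixed = TRUE)[[1]]

  n_pos <- L - k + 1L
  kmers <- substring(seq, 1:n_pos, k:L)
  valid <- !grepl("N", kmers, fixed = TRUE)
  rcseq <- revcomp(seq)
  # reverse complement of the k-mer starting at j reads from the mirrored
  # position on the reverse strand
  rckmers <- substring(rcseq, L - (1:n_pos) - k + 2L, L - (1:n_pos) + 1L)

  idx <- new.env(hash = TRUE, parent = emptyenv())
  for (grp in split(which(valid), kmers[valid])) {
    assign(kmers[grp[1]], grp, envir = idx)
  }

  cand <- list()
  nc <- 0L
  for (a in which(valid)) {
    js <- get0(rckmers[a], envir = idx, ifnotfound = NULL)
    if (is.null(js)) next
    js <- js[js >= a + params$min_len - k & js <= a + params$max_len - k]
    for (j in js) {
      e <- j + k - 1L
      len <- e - a + 1L
      # extend the TIR inward from the fixed outer boundaries
      t <- k
      mm <- 0L
      t_last_match <- k
      while (t < params$max_tir && len - 2L * (t + 1L) >= 0L) {
        lb <- bases[a + t]
        rb <- comp[e - t]
        if (lb != "N" && rb != "N" && lb == rb) {
          t <- t + 1L
          t_last_match <- t
        } else if (mm < params$max_tir_mismatches) {
          mm <- mm + 1L
          t <- t + 1L
        } else break
      }
      t <- t_last_match
      dr <- longest_flanking_dr(seq, a, e, L, params)
      if (params$require_dr && is.na(dr$seq)) next
      nc <- nc + 1L
      cand[[nc]] <- list(start = a, end = e, length = len, tir_len = t,
                         dr_len = dr$len, dr_seq = dr$seq,
                         tir_seq = substring(seq, a, a + t - 1L))
    }
  }
  if (nc == 0L) return(empty_candidates())
  df <- dplyr::bind_rows(lapply(cand[seq_len(nc)], tibble::as_tibble))
  df <- df[!duplicated(df[, c("start", "end")]), ]
  df <- resolve_overlaps(df)
  tibble::tibble(
    seq_id = seq_id, start = df$start, end = df$end, length = df$length,
    tir_len = df$tir_len, dr_len = df$dr_len,
    internal_len = df$length - 2L * df$tir_len,
    tir_seq = df$tir_seq, dr_seq = df$dr_seq
  )
}

# longest identical flanking repeat within [min_dr, max_dr], no N
longest_flanking_dr <- function(seq, a, e, L, params) {
  for (d in seq(params$max_dr, params$min_dr)) {
    if (a - d < 1L || e + d > L) next
    left <- substring(seq, a - d, a - 1L)
    if (grepl("N", left, fixed = TRUE)) next
    if (left == substring(seq, e + 1L, e + d)) {
      return(list(len = d, seq = left))
    }
  }
  list(len = NA_integer_, seq = NA_character_)
}

# One greedy pass resolves both nesting and overlap: longest TIR wins, ties
# go to the longer (outermost) element, then the leftmost. Because inward
# extension gives the outermost member of a nested seed family the longest
# TIR, this keeps exactly the maximal candidate of each family while a
# marginal chance candidate (minimum-length TIR) can never displace a
# better-supported element it happens to span.
resolve_overlaps <- function(df) {
  if (nrow(df) <= 1) return(df)
  o <- order(-df$tir_len, -df$length, df$start, df$end)
  df <- df[o, ]
  taken_start <- integer(0)
  taken_end <- integer(0)
  keep <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    if (!any(df$start[i] <= taken_end & df$end[i] >= taken_start)) {
      keep[i] <- TRUE
      taken_start <- c(taken_start, df$start[i])
      taken_end <- c(taken_end, df$end[i])
    }
  }
  df <- df[keep, ]
  df[order(df$start), ]
}

#' Summarize a set of MITE candidates
#'
#' Counts candidates, averages element/DR/TIR lengths, and groups candidates
#' into families by exact left-TIR sequence identity (elements sharing no
#' TIR are each their own family).
#'
#' @param candidates Output of [scan_mites()].
#' @return A one-row tibble: `n`, `mean_length`, `median_length`,
#'   `mean_dr_len`, `mean_tir_len`, `n_families`. Means are `NA` when no
#'   candidates are present.
#' @export
summarize_mites <- function(candidates) {
  if (nrow(candidates) == 0) {
    return(tibble::tibble(
      n = 0L, mean_length = NA_real_, median_length = NA_real_,
      mean_dr_len = NA_real_, mean_tir_len = NA_real_, n_families = 0L))
  }
  tibble::tibble(
    n = nrow(candidates),
    mean_length = mean(candidates$length),
    median_length = stats::median(candidates$length),
    mean_dr_len = mean(candidates$dr_len, na.rm = TRUE),
    mean_tir_len = mean(candidates$tir_len),
    n_families = length(unique(candidates$tir_seq))
  )
}

#' Re-validate candidates against the structural definition
#'
#' Independent string checks (not reusing the scanner's internals): the left
#' TIR must equal the reverse complement of the right TIR, the flanking DRs
#' must be identical, and the element length must lie within bounds.
#'
#' @param candidates Output of [scan_mites()].
#' @param sequences The scanned sequences (data frame with `seq_id`,
#'   `sequence`).
#' @param params The [mite_params()] used.
#' @return Logical vector, one entry per candidate.
#' @export
validate_mites <- function(candidates, sequences, params = mite_params()) {
  if (nrow(candidates) == 0) return(logical(0))
  seqs <- stats::setNames(sequences$sequence, sequences$seq_id)
  vapply(seq_len(nrow(candidates)), function(i) {
    x <- candidates[i, ]
    s <- toupper(seqs[[x$seq_id]])
    left <- substring(s, x$start, x$start + x$tir_len - 1)
    right <- substring(s, x$end - x$tir_len + 1, x$end)
    ok_tir <- sum(strsplit(left, "")[[1]] !=
                    strsplit(revcomp(right), "")[[1]]) <=
      params$max_tir_mismatches
    ok_len <- x$length >= params$min_len && x$length <= params$max_len &&
      x$length == x$end - x$start + 1
    ok_dr <- if (is.na(x$dr_len)) !params$require_dr else
      substring(s, x$start - x$dr_len, x$start - 1) ==
        substring(s, x$end + 1, x$end + x$dr_len)
    ok_tir && ok_len && ok_dr
  }, logical(1))
}

#' Write MITE candidates to TSV
#'
#' @param candidates Output of [scan_mites()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mite_tsv <- function(candidates, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# MITE candidates; coordinates are 1-based inclusive", con)
  utils::write.table(candidates, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write MITE candidates as a GFF3 track
#'
#' Features of type `MITE` with `tir_len`, `dr_len` and `ID` attributes,
#' 1-based inclusive per the GFF3 standard.
#'
#' @param candidates Output of [scan_mites()].
#' @param path Output path (`.gff3`).
#' @return `path`, invisibly.
#' @export
write_mite_gff3 <- function(candidates, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = if (nrow(candidates)) candidates$seq_id else character(),
    ranges = IRanges::IRanges(start = candidates$start,
                              end = candidates$end),
    strand = "+"
  )
  gr$type <- rep("MITE", nrow(candidates))
  gr$source <- rep("cotkit", nrow(candidates))
  gr$ID <- if (nrow(candidates)) {
    sprintf("MITE_%s_%d", candidates$seq_id, candidates$start)
  } else character()
  gr$tir_len <- candidates$tir_len
  gr$dr_len <- candidates$dr_len
  rtracklayer::export(gr, path, format = "GFF3")
  invisible(path)
}
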