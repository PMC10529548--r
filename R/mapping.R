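#' Build a k-mer index over a reference sequence
#'
#' Desk-scale replacement for an FM-index: exact k-mer seeds anchor candidate
#' placements which are then verified by ungapped mismatch counting. Circular
#' references (mitogenomes) are handled by a wrap-around extension of the
#' reference; alignment starts are reported modulo the reference length.
#'
#' @param ref Reference sequence: a single named character string, or a
#'   one-row tibble with columns `id` and `seq`.
#' @param k Seed length (default 13; minimum 4).
#' @param circular Treat the reference as circular.
#' @return An object of class `kmer_index`.
#' @export
build_index <- function(ref, k = 13L, circular = FALSE) {
  ref <- .as_seq_tbl(ref)
  stopifnot(nrow(ref) == 1L)
  k <- as.integer(k)
  if (k < 4L) abort("k must be >= 4")
  if (k > nchar(ref$seq)) abort("k exceeds reference length")
  structure(
    list(ref_id = ref$id, seq = toupper(ref$seq), k = k, circular = circular),
    class = "kmer_index"
  )
}

#' @export
print.kmer_index <- function(x, ...) {
  cat(sprintf("<kmer_index> ref '%s' (%d bp%s), k = %d\n", x$ref_id,
              nchar(x$seq), if (x$circular) ", circular" else "", x$k))
  invisible(x)
}

#' Look up a k-mer in an index
#'
#' @param index A `kmer_index`.
#' @param kmer Query k-mer (length `index$k`).
#' @return A list with integer vectors `fwd` and `rev`: 0-based reference
#'   positions where the k-mer (resp. its reverse complement) occurs.
#' @export
index_lookup <- function(index, kmer) {
  stopifnot(inherits(index, "kmer_index"), nchar(kmer) == index$k)
  cpp_kmer_positions(index$seq, toupper(kmer))
}

#' Map reads with a mismatch budget
#'
#' Ungapped best-placement mapping on either strand. A read placement is
#' admissible when its mismatch count is within `floor(max_mismatch_frac *
#' read_length)`; `N` counts as a mismatch at every position. Among
#' admissible placements the fewest-mismatch one wins (ties broken
#' deterministically: `+` strand first, then smallest start). Mapping quality
#' encodes placement uniqueness: 60 when no admissible competitor exists,
#' 0 for an exact tie, otherwise `min(60, 30 * (second_best - best))`
#' mismatches of gap — so the conventional quality-30 filter retains reads
#' whose best placement beats all competitors by at least one mismatch.
#'
#' Seeding is provably lossless: the read is split into `budget + 1` blocks,
#' one exact seed per block (pigeonhole), with the seed length reduced (and
#' ultimately an exhaustive scan used) when the blocks are too short.
#'
#' @param reads A reads tibble (`read_id`, `bases`).
#' @param index A `kmer_index` from [build_index()].
#' @param max_mismatch_frac Mismatch budget as a fraction of read length
#'   (default 0.04, the usual strict short-read setting).
#' @param keep_unmapped Keep unmapped reads as rows with `NA` placement.
#' @return An alignment tibble: `read_id`, `ref_id`, `start`, `end` (0-based
#'   half-open), `strand`, `n_mismatch`, `mapq`.
#' @export
map_reads <- function(reads, index, max_mismatch_frac = 0.04,
                      keep_unmapped = FALSE) {
  stopifnot(inherits(index, "kmer_index"))
  res <- cpp_map_reads(index$seq, reads$bases, index$k, max_mismatch_frac,
                       index$circular)
  out <- tibble(
    read_id = reads$read_id,
    ref_id = index$ref_id,
    start = ifelse(res$mapped, res$start, NA_integer_),
    end = ifelse(res$mapped, res$end, NA_integer_),
    strand = ifelse(res$mapped, res$strand, NA_character_),
    n_mismatch = ifelse(res$mapped, res$n_mismatch, NA_integer_),
    mapq = ifelse(res$mapped, res$mapq, NA_integer_)
  )
  if (keep_unmapped) out else out[res$mapped, , drop = FALSE]
}

#' @rdname map_reads
#' @param bases A single read sequence.
#' @export
map_read <- function(bases, index, max_mismatch_frac = 0.04) {
  map_reads(tibble(read_id = "read", bases = bases), index, max_mismatch_frac)
}

#' Filter alignments on mapping quality
#'
#' @param alignments An alignment tibble.
#' @param min_mapq Minimum retained mapping quality (default 30).
#' @return The filtered alignment tibble.
#' @export
filter_mapq <- function(alignments, min_mapq = 30L) {
  alignments[!is.na(alignments$mapq) & alignments$mapq >= min_mapq, ,
             drop = FALSE]
}

#' Remove PCR duplicates
#'
#' Reads sharing an identical placement (`start`, `end`, `strand`) are
#' treated as amplification duplicates of one template molecule; exactly one
#' is retained per placement (highest mapping quality, ties broken by
#' read id). Output is sorted by `start`.
#'
#' @param alignments An alignment tibble on a single reference.
#' @return A deduplicated alignment tibble.
#' @export
remove_duplicates <- function(alignments) {
  if (nrow(alignments) == 0L) return(alignments)
  stopifnot(length(unique(alignments$ref_id)) <= 1L)
  alignments |>
    dplyr::arrange(.data$start, .data$end, .data$strand,
                   dplyr::desc(.data$mapq), .data$read_id) |>
    dplyr::distinct(.data$start, .data$end, .data$strand, .keep_all = TRUE) |>
    dplyr::arrange(.data$start)
}

#' Endogenous-content assessment by stringency sweep
#'
#' Maps a QC'd read set against a candidate endogenous reference at a range
#' of mismatch stringencies, applying the quality filter and duplicate
#' removal at each, and reports the surviving mapped fraction. Tightening the
#' stringency can only shrink the mapped set, so the fractions are
#' monotonically non-increasing; a library dominated by contaminant DNA
#' yields near-zero fractions throughout.
#'
#' @param reads A reads tibble (already trimmed and length-filtered).
#' @param ref Reference sequence (named string or `id`/`seq` tibble).
#' @param stringencies Mismatch-fraction budgets to sweep (default
#'   `c(0.04, 0.01, 0.001)`).
#' @param min_mapq Mapping-quality filter (default 30).
#' @param k Seed length for the index.
#' @param circular Treat the reference as circular.
#' @return A tibble: `stringency`, `n_mapped`, `n_total`, `fraction_mapped`.
#' @export
endogenous_sweep <- function(reads, ref, stringencies = c(0.04, 0.01, 0.001),
                             min_mapq = 30L, k = 13L, circular = FALSE) {
  index <- build_index(ref, k = k, circular = circular)
  n_total <- nrow(reads)
  purrr::map_dfr(stringencies, function(s) {
    n_mapped <- reads |>
      map_reads(index, max_mismatch_frac = s) |>
      filter_mapq(min_mapq) |>
      remove_duplicates() |>
      nrow()
    tibble(stringency = s, n_mapped = n_mapped, n_total = n_total,
           fraction_mapped = if (n_total > 0) n_mapped / n_total else 0)
  })
}
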