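#' Trim adapter sequence from read 3' ends
#'
#' Implements single-end adapter trimming as used for degraded museum
#' libraries: a full internal occurrence of the adapter removes the occurrence
#' and everything 3' of it; otherwise the longest read suffix exactly matching
#' a prefix of the adapter, of length at least `min_overlap`, is removed.
#' A single-base overlap (`min_overlap = 1`) is the default, as is usual for
#' short-fragment libraries where the insert is often shorter than the read.
#'
#' Matching is exact (`max_error_rate = 0`); an error-tolerant mode is exposed
#' but off by default.
#'
#' @param reads A reads tibble (`read_id`, `bases`, optional `qual`).
#' @param adapter Adapter sequence (5' end as it appears at the read 3' end).
#'   Defaults to the Illumina single-end adapter.
#' @param min_overlap Minimum suffix/prefix overlap to trim (default 1).
#' @param max_error_rate Allowed mismatch fraction within the overlap
#'   (default 0, exact matching).
#' @return The reads tibble with trimmed `bases` (and `qual`).
#' @export
trim_adapter <- function(reads, adapter = "AGATCGGAAGAGC", min_overlap = 1L,
                         max_error_rate = 0) {
  stopifnot(nchar(adapter) >= 1L, min_overlap >= 1L, max_error_rate >= 0)
  adapter <- toupper(adapter)
  keep_len <- vapply(reads$bases, .trim_point, integer(1),
                     adapter = adapter, min_overlap = as.integer(min_overlap),
                     max_error_rate = max_error_rate, USE.NAMES = FALSE)
  out <- reads
  out$bases <- substr(reads$bases, 1L, keep_len)
  if ("qual" %in% names(out)) {
    out$qual <- ifelse(is.na(out$qual), out$qual, substr(out$qual, 1L, keep_len))
  }
  out
}

# number of 5' bases kept after adapter removal
.trim_point <- function(bases, adapter, min_overlap, max_error_rate) {
  L <- nchar(bases)
  la <- nchar(adapter)
  if (L == 0L) return(0L)
  ok <- function(a, b) {
    if (max_error_rate == 0) return(a == b)
    n <- nchar(a)
    mm <- sum(utf8ToInt(a) != utf8ToInt(b))
    mm <= floor(max_error_rate * n)
  }
  # full internal occurrence (leftmost)
  if (L >= la) {
    for (p in seq_len(L - la + 1L)) {
      if (ok(substr(bases, p, p + la - 1L), adapter)) return(p - 1L)
    }
  }
  # longest suffix of read == prefix of adapter
  for (ov in seq(min(L, la - 1L), min_overlap)) {
    if (ov < min_overlap) break
    if (ok(substr(bases, L - ov + 1L, L), substr(adapter, 1L, ov))) {
      return(L - ov)
    }
  }
  L
}

#' Discard reads shorter than a minimum length
#'
#' Very short post-trimming fragments are uninformative and map spuriously;
#' the conventional museum-DNA cutoff of 30 bp is the default.
#'
#' @param reads A reads tibble.
#' @param min_len Minimum retained length in bp (default 30).
#' @return The reads tibble restricted to reads of length >= `min_len`,
#'   input order preserved.
#' @export
length_filter <- function(reads, min_len = 30L) {
  stopifnot(min_len >= 1L)
  reads[nchar(reads$bases) >= min_len, , drop = FALSE]
}
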