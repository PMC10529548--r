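#' Consensus-calling configuration
#'
#' The three configurations used across the reconstruction pipeline are a
#' permissive iteration-phase rule (50% majority, any coverage, reference
#' fill at zero depth), a stringent post-convergence rule (90% majority,
#' minimum depth 3, no fill) and a final very stringent rule (85% majority,
#' minimum depth 10, no fill).
#'
#' @param majority_threshold Required modal-base frequency in (0, 1];
#'   comparisons use `>=` (the boundary counts as a call).
#' @param min_depth Minimum read depth for a call.
#' @param fill_with_reference At zero depth, emit the reference base instead
#'   of `N`.
#' @return A `consensus_config` list.
#' @export
consensus_config <- function(majority_threshold = 0.5, min_depth = 1L,
                             fill_with_reference = TRUE) {
  stopifnot(majority_threshold > 0, majority_threshold <= 1, min_depth >= 0)
  structure(list(majority_threshold = majority_threshold,
                 min_depth = as.integer(min_depth),
                 fill_with_reference = isTRUE(fill_with_reference)),
            class = "consensus_config")
}

#' Build a per-position base-count pileup
#'
#' @param alignments An alignment tibble (ungapped placements).
#' @param reads The reads tibble the alignments refer to.
#' @param ref Reference sequence (named string or `id`/`seq` tibble).
#' @param circular Wrap alignments past the reference end (circular
#'   mitogenome).
#' @return A pileup tibble: `ref_id`, `pos` (0-based), `A`, `C`, `G`, `T`,
#'   `depth`. Depth is the sum of the four base counts; `N` read bases are
#'   not counted.
#' @export
build_pileup <- function(alignments, reads, ref, circular = FALSE) {
  ref <- .as_seq_tbl(ref)
  stopifnot(nrow(ref) == 1L)
  L <- nchar(ref$seq)
  aln <- dplyr::inner_join(alignments, reads[, c("read_id", "bases")],
                           by = "read_id")
  counts <- cpp_pileup(L, as.integer(aln$start), aln$strand, aln$bases,
                       circular)
  structure(tibble(
    ref_id = ref$id, pos = 0:(L - 1L),
    A = counts[1, ], C = counts[2, ], G = counts[3, ], T = counts[4, ],
    depth = colSums(counts)
  ), class = c("pileup", class(tibble())))
}

#' Majority-rule consensus call from a pileup
#'
#' Per column: below the minimum depth the call is `N` (or the reference base
#' when depth is exactly zero and reference fill is on); otherwise the modal
#' base is called iff its frequency reaches the majority threshold (`>=`),
#' with ties and sub-threshold columns yielding `N`. No IUPAC ambiguity codes
#' are emitted: downstream alignment treats ambiguity as missing data.
#'
#' @param pileup A pileup tibble from [build_pileup()].
#' @param ref The reference used to build the pileup (for zero-depth fill).
#' @param cfg A [consensus_config()].
#' @return A named character string (the consensus sequence, named by
#'   `ref_id`).
#' @export
call_consensus <- function(pileup, ref, cfg = consensus_config()) {
  ref <- .as_seq_tbl(ref)
  refv <- strsplit(ref$seq, "")[[1]]
  stopifnot(nrow(pileup) == length(refv))
  counts <- rbind(pileup$A, pileup$C, pileup$G, pileup$T)
  depth <- pileup$depth
  bases <- c("A", "C", "G", "T")
  top <- max.col(t(counts), ties.method = "first")
  top_count <- counts[cbind(top, seq_along(depth))]
  tied <- colSums(counts == rep(top_count, each = 4L)) > 1L & top_count > 0L
  call <- rep("N", length(depth))
  callable <- depth >= cfg$min_depth & depth > 0L
  ok <- callable & !tied & (top_count / pmax(depth, 1L)) >= cfg$majority_threshold
  call[ok] <- bases[top[ok]]
  if (cfg$fill_with_reference) {
    call[depth == 0L] <- refv[depth == 0L]
  }
  setNames(paste(call, collapse = ""), ref$id)
}

#' Iterative reference refinement
#'
#' The central museum-genomics reconstruction step: reads are mapped to the
#' current reference with a permissive mismatch budget, a 50% majority-rule
#' consensus (reference-filled at uncovered sites) is called, and the
#' consensus becomes the next mapping reference. Iteration stops when the
#' set of mapped read ids no longer changes ("no new reads were mapped") or
#' after `max_iterations` rounds. The consensus returned is called from the
#' final alignment under the stringent rule (90% majority, depth >= 3, no
#' reference fill), so sites without real read support are `N`.
#'
#' @param reads QC'd reads tibble.
#' @param initial_ref Starting reference (a related species' sequence is
#'   fine; divergent sites are corrected as the consensus converges).
#' @param max_iterations Maximum refinement rounds (default 10).
#' @param iter_cfg Consensus rule used between iterations.
#' @param final_cfg Consensus rule for the returned sequence.
#' @param map_frac Permissive mismatch budget used while iterating
#'   (default 0.10, so reads from a several-percent-divergent source still
#'   seed the first round).
#' @param k Seed length.
#' @param circular Treat the reference as circular.
#' @return A list: `consensus` (named string), `log` (tibble `iteration`,
#'   `n_mapped`, `n_changed`, `converged`), `alignments` (final alignment
#'   tibble), `pileup` (final pileup).
#' @export
iterative_refine <- function(reads, initial_ref, max_iterations = 10L,
                             iter_cfg = consensus_config(0.5, 1L, TRUE),
                             final_cfg = consensus_config(0.9, 3L, FALSE),
                             map_frac = 0.10, k = 13L, circular = FALSE) {
  ref <- .as_seq_tbl(initial_ref)
  stopifnot(nrow(ref) == 1L, nchar(ref$seq) > 0L)
  current <- setNames(toupper(ref$seq), ref$id)
  prev_ids <- NULL
  prev_seq <- current
  log <- vector("list", max_iterations)
  aln <- NULL
  pile <- NULL
  for (it in seq_len(max_iterations)) {
    index <- build_index(current, k = k, circular = circular)
    aln <- map_reads(reads, index, max_mismatch_frac = map_frac)
    if (nrow(aln) == 0L && it == 1L) abort("no seed alignment")
    ids <- sort(aln$read_id)
    converged <- !is.null(prev_ids) && identical(ids, prev_ids)
    pile <- build_pileup(aln, reads, current, circular = circular)
    cons <- call_consensus(pile, current, iter_cfg)
    n_changed <- .n_diff(cons, prev_seq)
    log[[it]] <- tibble(iteration = it, n_mapped = nrow(aln),
                        n_changed = n_changed, converged = converged)
    prev_ids <- ids
    prev_seq <- cons
    current <- setNames(unname(cons), ref$id)
    if (converged) break
  }
  final <- call_consensus(pile, current, final_cfg)
  list(consensus = final, log = dplyr::bind_rows(log[!vapply(log, is.null, TRUE)]),
       alignments = aln, pileup = pile)
}

.n_diff <- function(a, b) {
  av <- strsplit(unname(a), "")[[1]]
  bv <- strsplit(unname(b), "")[[1]]
  if (length(av) != length(bv)) return(NA_integer_)
  sum(av != bv)
}

#' Final stringent consensus call
#'
#' Re-maps all reads against the converged consensus with the strict
#' mismatch budget and calls an 85% majority consensus requiring depth 10,
#' mirroring the final strict re-mapping pass of the reconstruction
#' pipeline. Sites below depth 10 are `N`.
#'
#' @param reads Reads tibble.
#' @param converged_consensus Output consensus of [iterative_refine()].
#' @param cfg Consensus rule (default 85% majority, min depth 10, no fill).
#' @param map_frac Strict mismatch budget (default 0.04).
#' @param k Seed length.
#' @param circular Treat the reference as circular.
#' @return A list: `consensus`, `alignments`, `pileup`.
#' @export
final_stringent_call <- function(reads, converged_consensus,
                                 cfg = consensus_config(0.85, 10L, FALSE),
                                 map_frac = 0.04, k = 13L, circular = FALSE) {
  ref <- .as_seq_tbl(converged_consensus)
  index <- build_index(ref, k = k, circular = circular)
  aln <- map_reads(reads, index, max_mismatch_frac = map_frac)
  pile <- build_pileup(aln, reads, ref, circular = circular)
  cons <- call_consensus(pile, ref, cfg)
  list(consensus = cons, alignments = aln, pileup = pile)
}

#' Extract well-covered regions
#'
#' Maximal runs of consecutive positions at or above a depth threshold, the
#' rule used to decide which parts of a sparse historical alignment are
#' trustworthy (depth >= 3 by default).
#'
#' @param x A pileup tibble or a non-negative numeric depth vector.
#' @param min_depth Depth threshold (default 3).
#' @param min_length Minimum region length to report (default 1).
#' @param ref_id Reference name used when `x` is a bare depth vector.
#' @return A region tibble: `ref_id`, `start`, `end` (0-based half-open),
#'   `mean_depth`.
#' @export
extract_regions <- function(x, min_depth = 3L, min_length = 1L,
                            ref_id = "ref") {
  if (is.data.frame(x)) {
    depth <- x$depth
    ref_id <- if (nrow(x) > 0L) x$ref_id[1] else ref_id
  } else {
    depth <- as.numeric(x)
  }
  stopifnot(all(depth >= 0))
  ok <- depth >= min_depth
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values & r$lengths >= min_length
  if (!any(keep)) {
    return(tibble(ref_id = character(), start = integer(), end = integer(),
                  mean_depth = numeric()))
  }
  tibble(
    ref_id = ref_id,
    start = starts[keep],
    end = ends[keep],
    mean_depth = vapply(which(keep), function(i) {
      mean(depth[(starts[i] + 1L):ends[i]])
    }, numeric(1))
  )
}
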