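#' Read a FASTA file
#'
#' Parses a (possibly multi-record) FASTA file into a tibble of sequences.
#' Record ids are the first whitespace-delimited token of each header line;
#' bases are normalised to upper case. Only the alphabet `A C G T N -` is
#' accepted; anything else is an error naming the offending record and
#' position.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` (character) and `seq` (character).
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">mt a mitogenome", "ACGTN"), fa)
#' read_fasta(fa)
read_fasta <- function(path) {
  stopifnot(is.character(path), length(path) == 1L)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  .validate_fasta_lines(path)
  set <- tryCatch(
    suppressWarnings(Biostrings::readDNAStringSet(path, format = "fasta")),
    error = function(e) {
      abort(paste0("malformed FASTA (", conditionMessage(e), "): ", path))
    }
  )
  if (length(set) == 0L) abort(paste0("empty FASTA file: ", path))
  ids <- vapply(strsplit(names(set), "[ \t]+"), `[[`, character(1), 1L)
  seqs <- toupper(as.character(set))
  .check_alphabet(seqs, ids, alphabet = "ACGTN-")
  tibble(id = unname(ids), seq = unname(seqs))
}

# the backend parser silently drops codes outside its alphabet, so scan the
# raw lines first and name the first offending position
.validate_fasta_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  for (i in seq_along(lines)) {
    if (startsWith(lines[i], ">")) next
    bad <- regexpr("[^ACGTNacgtn-]", lines[i])
    if (bad > 0L) {
      abort(sprintf("illegal character '%s' in FASTA at line %d, position %d",
                    substr(lines[i], bad, bad), i, bad))
    }
  }
  invisible(TRUE)
}

.check_alphabet <- function(seqs, ids, alphabet) {
  pat <- paste0("[^", alphabet, "]")
  for (i in seq_along(seqs)) {
    bad <- regexpr(pat, seqs[i])
    if (bad > 0L) {
      abort(sprintf("illegal character '%s' in record '%s' at position %d",
                    substr(seqs[i], bad, bad), ids[i], bad))
    }
  }
  invisible(TRUE)
}

#' Write sequences to a FASTA file
#'
#' @param seqs A tibble with columns `id` and `seq` (as from [read_fasta()]),
#'   or a named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width in bases.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  seqs <- .as_seq_tbl(seqs)
  set <- Biostrings::BStringSet(setNames(seqs$seq, seqs$id))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

.as_seq_tbl <- function(seqs) {
  if (is.character(seqs)) {
    ids <- names(seqs)
    if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
    seqs <- tibble(id = ids, seq = unname(seqs))
  }
  stopifnot(is.data.frame(seqs), all(c("id", "seq") %in% names(seqs)))
  seqs
}

#' Read a FASTQ file
#'
#' Four-line FASTQ records with Phred+33 qualities. An empty file yields an
#' empty tibble; a record whose quality string differs in length from its
#' bases is an error.
#'
#' @param path Path to a FASTQ file.
#' @return A tibble with columns `read_id`, `bases`, `qual` (Phred+33 string).
#' @export
read_fastq <- function(path) {
  stopifnot(is.character(path), length(path) == 1L)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  info <- file.info(path)
  if (!is.na(info$size) && info$size == 0) {
    return(tibble(read_id = character(), bases = character(),
                  qual = character()))
  }
  .validate_fastq_lines(path)
  set <- tryCatch(
    suppressWarnings(
      Biostrings::readQualityScaledDNAStringSet(path,
                                                quality.scoring = "phred")),
    error = function(e) {
      abort(paste0("malformed FASTQ (", conditionMessage(e), "): ", path))
    }
  )
  ids <- vapply(strsplit(names(set), "[ \t]+"), `[[`, character(1), 1L)
  tibble(
    read_id = unname(ids),
    bases = unname(toupper(as.character(set))),
    qual = unname(as.character(Biostrings::quality(set)))
  )
}

# 4-line record structure and per-record base/quality length agreement
.validate_fastq_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) %% 4L != 0L) {
    abort(paste0("malformed FASTQ (truncated record): ", path))
  }
  for (i in seq(1L, length(lines), by = 4L)) {
    if (!startsWith(lines[i], "@") || !startsWith(lines[i + 2L], "+")) {
      abort(sprintf("malformed FASTQ record at line %d: %s", i, path))
    }
    if (nchar(lines[i + 1L]) != nchar(lines[i + 3L])) {
      abort(sprintf(
        "malformed FASTQ: base/quality length mismatch at line %d (%d vs %d)",
        i, nchar(lines[i + 1L]), nchar(lines[i + 3L])))
    }
  }
  invisible(TRUE)
}

#' Write reads to a FASTQ file
#'
#' @param reads A tibble with columns `read_id`, `bases` and optionally
#'   `qual`; missing qualities are written as Phred 40 (`I`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("read_id", "bases") %in% names(reads)))
  qual <- if ("qual" %in% names(reads)) reads$qual else NA_character_
  n <- nrow(reads)
  if (length(qual) == 1L) qual <- rep(qual, n)
  fill <- is.na(qual)
  qual[fill] <- vapply(nchar(reads$bases)[fill],
                       function(w) strrep("I", w), character(1))
  out <- character(4L * n)
  out[seq(1L, by = 4L, length.out = n)] <- paste0("@", reads$read_id)
  out[seq(2L, by = 4L, length.out = n)] <- reads$bases
  out[seq(3L, by = 4L, length.out = n)] <- "+"
  out[seq(4L, by = 4L, length.out = n)] <- qual
  writeLines(out, path)
  invisible(path)
}

#' Decode Phred+33 quality strings
#'
#' @param qual Character vector of Phred+33 quality strings.
#' @return A list of integer vectors of quality scores.
#' @export
phred_scores <- function(qual) {
  lapply(qual, function(q) as.integer(charToRaw(q)) - 33L)
}

#' Write genomic regions as 3-column BED
#'
#' Regions use 0-based half-open coordinates throughout the package, which is
#' exactly the BED convention, so serialisation is direct. Input order is
#' preserved.
#'
#' @param regions A tibble with columns `ref_id`, `start`, `end` (and
#'   optionally `mean_depth`, ignored here).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  stopifnot(all(c("ref_id", "start", "end") %in% names(regions)))
  if (nrow(regions) > 0 && any(regions$start < 0 | regions$start >= regions$end)) {
    abort("invalid region: need 0 <= start < end")
  }
  lines <- sprintf("%s\t%d\t%d", regions$ref_id,
                   as.integer(regions$start), as.integer(regions$end))
  writeLines(lines, path, sep = "\n")
  if (nrow(regions) == 0L) writeLines(character(), path)
  invisible(path)
}

#' Human-readable region report (1-based inclusive)
#'
#' Internal coordinates are 0-based half-open; printed reports use the
#' 1-based inclusive convention of genome browsers.
#'
#' @param regions A region tibble (`ref_id`, `start`, `end`, `mean_depth`).
#' @return A character vector, one line per region.
#' @export
region_report <- function(regions) {
  sprintf("%s:%d-%d length %d mean depth %.2f",
          regions$ref_id, regions$start + 1L, regions$end,
          regions$end - regions$start,
          if ("mean_depth" %in% names(regions)) regions$mean_depth else NA_real_)
}

#' Read and write Newick trees
#'
#' Thin wrappers around the ape parser that enforce unique tip labels and
#' report malformed input. Round trips preserve topology, labels and branch
#' lengths to 12 significant digits.
#'
#' @param path Path to a Newick file.
#' @return For `read_newick`, an [ape::read.tree()] `phylo` object.
#' @export
read_newick <- function(path) {
  stopifnot(is.character(path), length(path) == 1L)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  .parse_newick(txt, path)
}

.parse_newick <- function(txt, what = "newick string") {
  n_open <- lengths(regmatches(txt, gregexpr("(", txt, fixed = TRUE)))
  n_close <- lengths(regmatches(txt, gregexpr(")", txt, fixed = TRUE)))
  if (n_open != n_close) {
    abort(sprintf("unbalanced parentheses in %s (%d '(' vs %d ')')",
                  what, n_open, n_close))
  }
  tree <- tryCatch(ape::read.tree(text = txt),
                   error = function(e) NULL)
  if (is.null(tree)) abort(paste0("malformed Newick: ", what))
  if (anyDuplicated(tree$tip.label)) {
    abort(paste0("duplicate tip labels: ",
                 paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
                       collapse = ", ")))
  }
  tree
}

#' @rdname read_newick
#' @param tree A `phylo` object.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}

#' Read a specimen-by-character morphology table
#'
#' Expects a header row with columns `specimen_id`, `population`, `sex`, then
#' numeric meristic character columns. Empty cells and `?` are missing data
#' (museum specimens rarely yield every character); missingness is preserved,
#' never coerced to zero. Non-numeric content in a character column is an
#' error naming the cell.
#'
#' @param path Path to a CSV file (RFC-4180, header required).
#' @return A tibble with `population` and `sex` as factors and numeric
#'   character columns.
#' @export
read_morph_csv <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         na = character(), progress = FALSE)
  need <- c("specimen_id", "population", "sex")
  if (!all(need %in% names(raw))) {
    abort(paste0("morphology CSV must have columns: ",
                 paste(need, collapse = ", ")))
  }
  blank <- function(x) trimws(x) %in% c("", "?", "NA")
  out <- raw
  out$sex[blank(out$sex)] <- NA_character_
  out$population[blank(out$population)] <- NA_character_
  char_cols <- setdiff(names(raw), need)
  for (cc in char_cols) {
    x <- raw[[cc]]
    x[blank(x)] <- NA_character_
    num <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(num))
    if (length(bad)) {
      abort(sprintf("non-numeric value '%s' in column '%s', row %d",
                    x[bad[1]], cc, bad[1]))
    }
    out[[cc]] <- num
  }
  out$population <- factor(out$population)
  out$sex <- factor(out$sex)
  out
}
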