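# GTR rate-matrix eigensystem (reversible, so symmetrisable); Q is scaled to
# one expected substitution per unit branch length
.gtr_eigen <- function(exch, pi) {
  Q <- matrix(0, 4, 4)
  pair <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  for (r in seq_len(6)) {
    i <- pair[r, 1]; j <- pair[r, 2]
    Q[i, j] <- exch[r] * pi[j]
    Q[j, i] <- exch[r] * pi[i]
  }
  diag(Q) <- -rowSums(Q)
  scale <- -sum(pi * diag(Q))
  Q <- Q / scale
  sp <- sqrt(pi)
  B <- diag(sp) %*% Q %*% diag(1 / sp)
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  list(U = diag(1 / sp) %*% e$vectors,
       Uinv = t(e$vectors) %*% diag(sp),
       vals = e$values, pi = pi)
}

.gtr_pmat <- function(eig, t) {
  P <- eig$U %*% diag(exp(eig$vals * t)) %*% eig$Uinv
  P[P < 0] <- 0
  P / rowSums(P)
}

# discrete-gamma category rates (mean of each equal-probability class)
.discrete_gamma <- function(shape, m) {
  if (!is.finite(shape)) return(rep(1, m))
  cut <- qgamma(seq(0, 1, length.out = m + 1), shape, rate = shape)
  m * diff(pgamma(cut, shape + 1, rate = shape))
}

#' Concatenate gene alignments into a partitioned matrix
#'
#' Taxa missing from a partition are filled with `N` (missing data), the
#' standard treatment for historical samples from which only some loci could
#' be recovered. Protein-coding genes named in `coding` are pooled and split
#' into three codon-position partitions (`cp1`, `cp2`, `cp3`; the reading
#' frame restarts at each gene boundary); every other gene is its own
#' partition.
#'
#' @param partition_alignments Named list of alignments, each a tibble
#'   (`id`, `seq`) or named character vector of equal-length aligned
#'   sequences (gaps `-` and `N` allowed).
#' @param coding Names of elements holding protein-coding sequence.
#' @return A `partitioned_alignment`: taxa, a taxa-by-columns character
#'   matrix, and a named list of column-index partitions.
#' @export
concatenate <- function(partition_alignments, coding = character()) {
  stopifnot(is.list(partition_alignments),
            !is.null(names(partition_alignments)))
  parts <- lapply(partition_alignments, .as_seq_tbl)
  for (nm in names(parts)) {
    if (anyDuplicated(parts[[nm]]$id)) {
      abort(paste0("duplicate taxon in partition '", nm, "'"))
    }
    w <- nchar(parts[[nm]]$seq)
    if (length(unique(w)) > 1L) {
      abort(paste0("unequal sequence lengths in partition '", nm, "'"))
    }
  }
  taxa <- sort(unique(unlist(lapply(parts, function(p) p$id))))
  blocks <- lapply(names(parts), function(nm) {
    p <- parts[[nm]]
    w <- nchar(p$seq[1])
    m <- matrix("N", length(taxa), w, dimnames = list(taxa, NULL))
    rows <- match(p$id, taxa)
    chars <- strsplit(toupper(p$seq), "")
    for (i in seq_along(rows)) m[rows[i], ] <- chars[[i]]
    m
  })
  widths <- vapply(blocks, ncol, integer(1))
  mat <- do.call(cbind, blocks)
  offsets <- cumsum(c(0L, widths[-length(widths)]))
  names(offsets) <- names(parts)
  partitions <- list()
  cp <- list(cp1 = integer(), cp2 = integer(), cp3 = integer())
  for (i in seq_along(parts)) {
    nm <- names(parts)[i]
    cols <- offsets[[nm]] + seq_len(widths[i])
    if (nm %in% coding) {
      pos <- ((seq_len(widths[i]) - 1L) %% 3L) + 1L
      for (j in 1:3) cp[[j]] <- c(cp[[j]], cols[pos == j])
    } else {
      partitions[[nm]] <- cols
    }
  }
  for (j in 1:3) if (length(cp[[j]])) partitions[[names(cp)[j]]] <- cp[[j]]
  structure(list(taxa = taxa, matrix = mat, partitions = partitions),
            class = "partitioned_alignment")
}

#' @export
print.partitioned_alignment <- function(x, ...) {
  cat(sprintf("<partitioned_alignment> %d taxa x %d columns; partitions: %s\n",
              length(x$taxa), ncol(x$matrix),
              paste(sprintf("%s (%d)", names(x$partitions),
                            lengths(x$partitions)), collapse = ", ")))
  invisible(x)
}

#' Build a one-partition alignment from tip sequences
#'
#' @param seqs A tibble (`id`, `seq`) or named character vector of aligned
#'   sequences.
#' @param name Partition name.
#' @return A `partitioned_alignment`.
#' @export
as_partitioned_alignment <- function(seqs, name = "all") {
  concatenate(setNames(list(seqs), name))
}

# integer state codes for the pruning kernel: ACGT = 0..3, anything else
# (gap, N, ambiguity) = 4 = missing
.state_codes <- function(mat) {
  s <- matrix(4L, nrow(mat), ncol(mat))
  for (b in seq_along(c("A", "C", "G", "T"))) {
    s[mat == c("A", "C", "G", "T")[b]] <- b - 1L
  }
  s
}

.pattern_compress <- function(states) {
  key <- apply(states, 2, paste, collapse = ",")
  u <- !duplicated(key)
  w <- as.numeric(table(factor(key, levels = key[u])))
  list(states = states[, u, drop = FALSE], weights = w)
}

.empirical_freqs <- function(mat, cols) {
  sub <- mat[, cols, drop = FALSE]
  n <- vapply(c("A", "C", "G", "T"), function(b) sum(sub == b), numeric(1))
  n <- n + 1  # pseudocount so no frequency is exactly zero
  unname(n / sum(n))
}

#' Fixed-topology chronogram
#'
#' A rooted tree with node ages (tips at 0, in Mya) and per-branch rate
#' multipliers. Branch length on the substitution scale is
#' `duration * clock_rate * multiplier`.
#'
#' @param tree A rooted binary `phylo`. If `ages` is `NULL` the tree must be
#'   ultrametric and ages are taken from its branch lengths.
#' @param ages Numeric vector of ages for all nodes (ape numbering: tips
#'   `1..n`, then internal), or `NULL`.
#' @param rates Per-edge rate multipliers (recycled; order of `tree$edge`).
#' @param clock_rate Mean clock rate in substitutions/site/Myr.
#' @return A `chronogram` object.
#' @export
chronogram <- function(tree, ages = NULL, rates = 1, clock_rate = 1) {
  stopifnot(inherits(tree, "phylo"))
  n_node <- length(tree$tip.label) + tree$Nnode
  if (is.null(ages)) {
    stopifnot(!is.null(tree$edge.length))
    depth <- ape::node.depth.edgelength(tree)
    ages <- max(depth) - depth
    ages[seq_along(tree$tip.label)] <- 0
  }
  stopifnot(length(ages) == n_node)
  rates <- rep_len(rates, nrow(tree$edge))
  dur <- ages[tree$edge[, 1]] - ages[tree$edge[, 2]]
  if (any(dur < 0)) abort("parent age must exceed child age on every edge")
  structure(list(tree = tree, ages = ages, rates = rates,
                 clock_rate = clock_rate),
            class = "chronogram")
}

#' @export
print.chronogram <- function(x, ...) {
  cat(sprintf("<chronogram> %d tips, root age %.4g, clock rate %.4g\n",
              length(x$tree$tip.label),
              max(x$ages), x$clock_rate))
  invisible(x)
}

#' Partitioned GTR+Gamma(+I) log-likelihood on a chronogram
#'
#' Felsenstein pruning over compressed site patterns; gaps and `N` are
#' missing data (partial likelihood 1 in every state). Rate variation uses
#' four equal-probability discrete-gamma category means; the invariant-site
#' class is a plain zero-rate mixture component with weight `p_inv`.
#'
#' @param aln A `partitioned_alignment`.
#' @param chrono A [chronogram()].
#' @param models Named list of [gtr_params()] per partition; by default each
#'   partition gets equal exchangeabilities, empirical base frequencies, no
#'   rate variation.
#' @return The total log-likelihood (a scalar).
#' @export
log_likelihood <- function(aln, chrono, models = NULL) {
  stopifnot(inherits(aln, "partitioned_alignment"),
            inherits(chrono, "chronogram"))
  prep <- .lik_prep(aln, chrono$tree)
  ll <- .loglik_state(prep, chrono$ages, chrono$clock_rate, chrono$rates,
                      .resolve_models(aln, models))
  if (!is.finite(ll)) abort("non-finite likelihood")
  ll
}

.resolve_models <- function(aln, models) {
  out <- list()
  for (nm in names(aln$partitions)) {
    m <- if (!is.null(models) && !is.null(models[[nm]])) models[[nm]] else
      gtr_params(base_freqs = .empirical_freqs(aln$matrix, aln$partitions[[nm]]))
    out[[nm]] <- m
  }
  out
}

# tree- and data-side precomputation shared by log_likelihood and the MCMC
.lik_prep <- function(aln, tree) {
  post <- ape::reorder.phylo(tree, "postorder")
  # permutation taking per-edge quantities from input order to postorder
  perm <- match(paste(post$edge[, 1], post$edge[, 2]),
                paste(tree$edge[, 1], tree$edge[, 2]))
  idx <- match(post$tip.label, rownames(aln$matrix))
  if (anyNA(idx)) abort("alignment is missing taxa present in the tree")
  states <- .state_codes(aln$matrix[idx, , drop = FALSE])
  pats <- lapply(aln$partitions, function(cols) {
    .pattern_compress(states[, cols, drop = FALSE])
  })
  list(tree = post, edge = post$edge, edge_perm = perm,
       n_tips = length(post$tip.label), patterns = pats)
}

# likelihood at explicit parameter values; `rates` follows the order of the
# input tree's edges and is remapped onto the postorder edge order
.loglik_state <- function(prep, ages, clock_rate, rates, models,
                          eigs = NULL) {
  edge <- prep$edge
  dur <- ages[edge[, 1]] - ages[edge[, 2]]
  brlen <- dur * clock_rate * rates[prep$edge_perm]
  total <- 0
  for (nm in names(prep$patterns)) {
    m <- models[[nm]]
    eig <- if (!is.null(eigs)) eigs[[nm]] else
      .gtr_eigen(m$exchangeabilities, m$base_freqs)
    g <- .discrete_gamma(m$gamma_shape, m$n_gamma_categories)
    pat <- prep$patterns[[nm]]
    total <- total + cpp_pruning_loglik(
      edge, prep$n_tips, pat$states, pat$weights, m$base_freqs,
      eig$U, eig$Uinv, eig$vals, brlen, g,
      rep(1 / length(g), length(g)), m$p_inv)
  }
  total
}
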