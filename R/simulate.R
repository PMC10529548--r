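#' Post-mortem damage model
#'
#' Cytosine deamination in degraded DNA produces apparent C→T substitutions
#' at read 5' ends and G→A at 3' ends, decaying geometrically with distance
#' from the terminus: the C→T probability at 5' offset `i` is
#' `delta5 * decay_lambda^i`. Libraries built with uracil-excision (UDG)
#' treatment have this damage removed enzymatically, so the model is
#' disabled by default; enabling it lets the pipeline's robustness to
#' residual damage be exercised.
#'
#' @param delta5 C→T probability at the first 5' position.
#' @param delta3 G→A probability at the last 3' position.
#' @param decay_lambda Geometric per-position decay rate in (0, 1].
#' @param enabled Apply damage at all.
#' @return A `damage_model` list.
#' @export
damage_model <- function(delta5 = 0.3, delta3 = 0.3, decay_lambda = 0.5,
                         enabled = FALSE) {
  stopifnot(delta5 >= 0, delta5 <= 1, delta3 >= 0, delta3 <= 1,
            decay_lambda > 0, decay_lambda <= 1)
  structure(list(delta5 = delta5, delta3 = delta3,
                 decay_lambda = decay_lambda, enabled = isTRUE(enabled)),
            class = "damage_model")
}

#' Read-simulation configuration
#'
#' Emulates a single-end 75 bp shotgun library from a degraded museum
#' extract: short lognormal fragments (truncated to `[20, 2 * read_len]`),
#' a low endogenous fraction against a contaminant background, and uniform
#' per-base miscalls.
#'
#' @param coverage Mean fold-coverage of the endogenous reference.
#' @param frag_len_mean,frag_len_sd Fragment length mean and SD in bp
#'   (lognormal; defaults 60 and 25, conventional for museum extracts).
#' @param endogenous_fraction Proportion of reads from the target organism.
#' @param contaminant_ref Contaminant reference sequence (named string or
#'   `id`/`seq` tibble); required when `endogenous_fraction < 1`.
#' @param seq_error Per-base miscall probability (default 0.001).
#' @param read_len Read length in bp (default 75, single-end).
#' @param seed Integer seed.
#' @return A `read_sim_config` list.
#' @export
read_sim_config <- function(coverage, frag_len_mean = 60, frag_len_sd = 25,
                            endogenous_fraction = 1, contaminant_ref = NULL,
                            seq_error = 0.001, read_len = 75L, seed = 1L) {
  stopifnot(coverage >= 0, read_len >= 1L,
            endogenous_fraction >= 0, endogenous_fraction <= 1,
            frag_len_mean > 0, frag_len_sd >= 0, seq_error >= 0, seq_error < 1)
  if (endogenous_fraction < 1 && is.null(contaminant_ref)) {
    abort("endogenous_fraction < 1 requires a contaminant_ref")
  }
  structure(list(coverage = coverage, frag_len_mean = frag_len_mean,
                 frag_len_sd = frag_len_sd,
                 endogenous_fraction = endogenous_fraction,
                 contaminant_ref = contaminant_ref, seq_error = seq_error,
                 read_len = as.integer(read_len), seed = as.integer(seed)),
            class = "read_sim_config")
}

#' Simulate a random reference sequence
#'
#' @param length Sequence length in bp.
#' @param gc GC fraction.
#' @param seed Integer seed.
#' @param id Sequence id.
#' @return A named character string.
#' @export
simulate_reference <- function(length, gc = 0.4, seed = 1L, id = "ref") {
  stopifnot(length >= 1, gc >= 0, gc <= 1)
  set.seed(seed)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  setNames(paste(sample(names(p), length, replace = TRUE, prob = p),
                 collapse = ""), id)
}

#' Introduce random substitutions into a sequence
#'
#' Used to manufacture a divergent starting reference (a related species'
#' genome) for refinement experiments.
#'
#' @param seq A named character string.
#' @param divergence Per-site substitution probability.
#' @param seed Integer seed.
#' @return A named character string with `round(divergence * length)` sites
#'   substituted (in expectation).
#' @export
mutate_sequence <- function(seq, divergence, seed = 1L) {
  stopifnot(divergence >= 0, divergence <= 1)
  set.seed(seed)
  v <- strsplit(unname(seq), "")[[1]]
  hit <- which(runif(length(v)) < divergence & v %in% c("A", "C", "G", "T"))
  bases <- c("A", "C", "G", "T")
  for (i in hit) v[i] <- sample(setdiff(bases, v[i]), 1L)
  setNames(paste(v, collapse = ""), names(seq))
}

.revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# vectorised terminal-damage application on read-oriented sequences
.apply_damage <- function(bases, dmg) {
  if (!dmg$enabled || length(bases) == 0L) return(bases)
  L <- nchar(bases)
  # damage beyond the offset where the terminal probability falls under
  # 1e-6 is negligible; a decay of exactly 1 never decays
  maxoff <- if (dmg$decay_lambda >= 1) max(L) else {
    min(max(L), 1L + ceiling(log(1e-6 / max(dmg$delta5, dmg$delta3, 1e-12)) /
                               log(dmg$decay_lambda)))
  }
  for (i in seq_len(maxoff) - 1L) {
    p5 <- dmg$delta5 * dmg$decay_lambda^i
    ch <- substr(bases, i + 1L, i + 1L)
    flip <- ch == "C" & runif(length(bases)) < p5 & i < L
    if (any(flip)) substr(bases[flip], i + 1L, i + 1L) <- "T"
    p3 <- dmg$delta3 * dmg$decay_lambda^i
    pos <- L - i
    ch <- substr(bases, pos, pos)
    flip <- ch == "G" & runif(length(bases)) < p3 & pos >= 1L
    if (any(flip)) {
      bases[flip] <- paste0(substr(bases[flip], 1L, pos[flip] - 1L), "A",
                            substr(bases[flip], pos[flip] + 1L, L[flip]))
    }
  }
  bases
}

.apply_seq_error <- function(bases, rate) {
  if (rate <= 0) return(bases)
  L <- nchar(bases)
  n_err <- rbinom(length(bases), L, rate)
  idx <- which(n_err > 0L)
  alphabet <- c("A", "C", "G", "T")
  for (i in idx) {
    pos <- sample.int(L[i], n_err[i])
    for (p in pos) {
      cur <- substr(bases[i], p, p)
      sub <- sample(setdiff(alphabet, cur), 1L)
      substr(bases[i], p, p) <- sub
    }
  }
  bases
}

# draw fragments from one source sequence until `target_bases` emitted
.draw_fragments <- function(seq, target_bases, cfg) {
  L <- nchar(seq)
  mu <- log(cfg$frag_len_mean^2 /
              sqrt(cfg$frag_len_mean^2 + cfg$frag_len_sd^2))
  sig <- sqrt(log(1 + cfg$frag_len_sd^2 / cfg$frag_len_mean^2))
  lens <- integer(0)
  emitted <- 0
  while (emitted < target_bases) {
    block <- pmin(pmax(round(rlnorm(256L, mu, sig)), 20L), 2L * cfg$read_len)
    block <- pmin(block, L)
    lens <- c(lens, block)
    emitted <- emitted + sum(pmin(block, cfg$read_len))
    if (target_bases <= 0) break
  }
  cum <- cumsum(pmin(lens, cfg$read_len))
  n <- if (target_bases <= 0) 0L else which(cum >= target_bases)[1]
  if (is.na(n)) n <- length(lens)
  lens <- lens[seq_len(n)]
  starts <- floor(runif(n, 0, L - lens + 1))
  strand <- sample(c("+", "-"), n, replace = TRUE)
  frag <- substring(seq, starts + 1L, starts + lens)
  frag[strand == "-"] <- .revcomp_chr(frag[strand == "-"])
  read_len <- pmin(lens, cfg$read_len)
  bases <- substring(frag, 1L, read_len)
  # reference coordinates covered by the emitted (possibly truncated) read
  ref_start <- ifelse(strand == "+", starts, starts + lens - read_len)
  tibble(bases = bases, strand = strand,
         ref_start = as.integer(ref_start),
         ref_end = as.integer(ref_start + read_len))
}

#' Simulate a degraded shotgun library
#'
#' Draws endogenous fragments from `ref` to the configured fold-coverage,
#' adds contaminant fragments to reach the configured endogenous fraction
#' (by read count), applies terminal deamination damage to the endogenous
#' reads when enabled, then uniform sequencing errors to everything. Each
#' read carries truth metadata so realised endogenous fractions and mapping
#' accuracy can be computed exactly.
#'
#' @param ref Endogenous reference (named string or `id`/`seq` tibble).
#' @param cfg A [read_sim_config()].
#' @param dmg A [damage_model()].
#' @return A list: `reads` (tibble `read_id`, `bases`, `qual`) and `truth`
#'   (tibble `read_id`, `source`, `ref_start`, `ref_end`, `strand`).
#' @export
simulate_reads <- function(ref, cfg, dmg = damage_model()) {
  stopifnot(inherits(cfg, "read_sim_config"))
  ref <- .as_seq_tbl(ref)
  set.seed(cfg$seed)
  target <- cfg$coverage * nchar(ref$seq)
  endo <- if (target > 0) .draw_fragments(ref$seq, target, cfg) else
    tibble(bases = character(), strand = character(),
           ref_start = integer(), ref_end = integer())
  endo$bases <- .apply_damage(endo$bases, dmg)
  f <- cfg$endogenous_fraction
  n_cont <- if (f >= 1) 0L else if (f > 0) round(nrow(endo) * (1 - f) / f) else
    round(target / cfg$read_len)
  if (n_cont > 0L) {
    cref <- .as_seq_tbl(cfg$contaminant_ref)
    cont <- .draw_fragments(cref$seq, n_cont * cfg$read_len * 0.999, cfg)
    cont <- cont[seq_len(min(n_cont, nrow(cont))), , drop = FALSE]
  } else {
    cont <- endo[0, , drop = FALSE]
  }
  all <- dplyr::bind_rows(endo, cont)
  all$source <- rep(c("endogenous", "contaminant"), c(nrow(endo), nrow(cont)))
  if (nrow(all) > 0L) {
    all <- all[sample.int(nrow(all)), , drop = FALSE]
    all$bases <- .apply_seq_error(all$bases, cfg$seq_error)
  }
  ids <- sprintf("r%06d", seq_len(nrow(all)))
  list(
    reads = tibble(read_id = ids, bases = all$bases,
                   qual = strrep("I", nchar(all$bases))),
    truth = tibble(read_id = ids, source = all$source,
                   ref_start = all$ref_start, ref_end = all$ref_end,
                   strand = all$strand)
  )
}

#' Simulate clean amplicon reads tiling a reference
#'
#' Emulates sequencing of sheared long-range PCR products: error-free,
#' undamaged reads uniformly tiling each amplicon at a target depth.
#'
#' @param ref Reference sequence (named string or `id`/`seq` tibble).
#' @param amplicon_coords Region tibble (`start`, `end`, 0-based half-open)
#'   of the amplified sections; amplicons may overlap.
#' @param depth Target per-position depth within amplicons.
#' @param read_len Read length (default 75).
#' @param seed Integer seed.
#' @return A reads tibble (`read_id`, `bases`, `qual`).
#' @export
simulate_amplicons <- function(ref, amplicon_coords, depth, read_len = 75L,
                               seed = 1L) {
  stopifnot(depth >= 1)
  ref <- .as_seq_tbl(ref)
  L <- nchar(ref$seq)
  if (any(amplicon_coords$start < 0 | amplicon_coords$end > L)) {
    abort("amplicon outside reference")
  }
  if (any(amplicon_coords$end - amplicon_coords$start < read_len)) {
    abort("amplicon shorter than read length")
  }
  set.seed(seed)
  out <- purrr::pmap_dfr(amplicon_coords[, c("start", "end")],
                         function(start, end) {
    # target is the interior (fully-tileable) depth: read starts live in
    # [start, end - read_len], so scale the read count to that span; two
    # anchor reads pin the amplicon boundaries so coverage never drops to
    # zero at the ends
    n <- max(2L, ceiling(depth * (end - start - read_len + 1) / read_len))
    starts <- c(start, end - read_len,
                floor(runif(n - 2L, start, end - read_len + 1)))
    strand <- sample(c("+", "-"), n, replace = TRUE)
    bases <- substring(ref$seq, starts + 1L, starts + read_len)
    bases[strand == "-"] <- .revcomp_chr(bases[strand == "-"])
    tibble(bases = bases)
  })
  tibble(read_id = sprintf("a%06d", seq_len(nrow(out))), bases = out$bases,
         qual = strrep("I", nchar(out$bases)))
}

#' GTR+Gamma(+I) substitution-model parameters
#'
#' @param exchangeabilities Six GTR exchangeabilities in the order
#'   AC, AG, AT, CG, CT, GT.
#' @param base_freqs Equilibrium base frequencies (A, C, G, T), summing to 1.
#' @param gamma_shape Gamma shape for among-site rate variation; `Inf` means
#'   no rate variation.
#' @param n_gamma_categories Number of discrete gamma categories (default 4).
#' @param p_inv Proportion of invariant sites in `[0, 1)`.
#' @return A `gtr_params` list.
#' @export
gtr_params <- function(exchangeabilities = c(1, 1, 1, 1, 1, 1),
                       base_freqs = c(0.25, 0.25, 0.25, 0.25),
                       gamma_shape = Inf, n_gamma_categories = 4L,
                       p_inv = 0) {
  stopifnot(length(exchangeabilities) == 6L, all(exchangeabilities > 0),
            length(base_freqs) == 4L,
            abs(sum(base_freqs) - 1) < 1e-12, gamma_shape > 0,
            p_inv >= 0, p_inv < 1)
  structure(list(exchangeabilities = exchangeabilities,
                 base_freqs = base_freqs, gamma_shape = gamma_shape,
                 n_gamma_categories = as.integer(n_gamma_categories),
                 p_inv = p_inv),
            class = "gtr_params")
}

#' Evolve a sequence along a tree
#'
#' Simulates the GTR+Gamma(+I) continuous-time Markov chain site by site
#' down a rooted tree whose branch lengths are in expected substitutions per
#' site, producing an aligned tip matrix (no indels).
#'
#' @param root_seq Root sequence (named string or `id`/`seq` tibble).
#' @param tree A rooted `phylo` with non-negative branch lengths.
#' @param model A [gtr_params()].
#' @param seed Integer seed.
#' @return A tibble (`id`, `seq`) of tip sequences, aligned to the root
#'   sequence length.
#' @export
evolve_on_tree <- function(root_seq, tree, model = gtr_params(), seed = 1L) {
  stopifnot(inherits(tree, "phylo"), all(tree$edge.length >= 0))
  ref <- .as_seq_tbl(root_seq)
  set.seed(seed)
  codes <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  root <- unname(codes[strsplit(ref$seq, "")[[1]]])
  n_site <- length(root)
  rates <- .site_rates(model, n_site)
  eig <- .gtr_eigen(model$exchangeabilities, model$base_freqs)
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  seqs <- vector("list", n_node)
  root_node <- n_tip + 1L
  seqs[[root_node]] <- root
  edges <- tree$edge[order(tree$edge[, 1]), , drop = FALSE]  # preorder-ish
  # walk edges so parents are filled before children
  todo <- seq_len(nrow(tree$edge))
  done_nodes <- root_node
  while (length(todo)) {
    ready <- todo[tree$edge[todo, 1] %in% done_nodes]
    for (e in ready) {
      par <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
      seqs[[ch]] <- .evolve_branch(seqs[[par]], tree$edge.length[e] * rates,
                                   eig)
      done_nodes <- c(done_nodes, ch)
    }
    todo <- setdiff(todo, ready)
  }
  bases <- c("A", "C", "G", "T")
  tibble(
    id = tree$tip.label,
    seq = vapply(seq_len(n_tip),
                 function(i) paste(bases[seqs[[i]]], collapse = ""),
                 character(1))
  )
}

# per-site rate multipliers: invariant sites get 0, others a gamma category
.site_rates <- function(model, n_site) {
  inv <- runif(n_site) < model$p_inv
  if (is.finite(model$gamma_shape)) {
    g <- .discrete_gamma(model$gamma_shape, model$n_gamma_categories)
    r <- sample(g, n_site, replace = TRUE)
  } else {
    r <- rep(1, n_site)
  }
  r[inv] <- 0
  r
}

.evolve_branch <- function(parent, t_site, eig) {
  child <- parent
  for (rate in unique(t_site)) {
    if (rate == 0) next
    P <- .gtr_pmat(eig, rate)
    for (b in 1:4) {
      idx <- which(parent == b & t_site == rate)
      if (length(idx)) {
        child[idx] <- sample.int(4L, length(idx), replace = TRUE, prob = P[b, ])
      }
    }
  }
  child
}
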