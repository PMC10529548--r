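# shared fixtures and independent oracles

rc <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

random_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# exhaustive-scan mapping oracle: best placement, mismatch count and the
# same mapq rule, computed over every offset and strand
brute_map <- function(read, ref, frac) {
  refv <- strsplit(ref, "")[[1]]
  L <- nchar(read)
  budget <- floor(frac * L)
  if (L > length(refv)) return(NULL)
  best <- NULL
  second <- Inf
  for (st in c("+", "-")) {
    v <- strsplit(if (st == "+") read else rc(read), "")[[1]]
    for (o in 0:(length(refv) - L)) {
      mm <- sum(refv[o + seq_len(L)] != v | !(refv[o + seq_len(L)] %in%
                                                c("A", "C", "G", "T")))
      if (mm <= budget) {
        if (is.null(best) || mm < best$mm) {
          if (!is.null(best)) second <- min(second, best$mm)
          best <- list(mm = mm, o = o, st = st)
        } else {
          second <- min(second, mm)
        }
      }
    }
  }
  if (is.null(best)) return(NULL)
  mapq <- if (is.infinite(second)) 60 else min(60, 30 * (second - best$mm))
  list(start = best$o, strand = best$st, n_mismatch = best$mm, mapq = mapq)
}

# GTR rate matrix built independently of the package internals
brute_gtr_q <- function(exch, pi) {
  Q <- matrix(0, 4, 4)
  pair <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  for (r in 1:6) {
    Q[pair[r, 1], pair[r, 2]] <- exch[r] * pi[pair[r, 2]]
    Q[pair[r, 2], pair[r, 1]] <- exch[r] * pi[pair[r, 1]]
  }
  diag(Q) <- -rowSums(Q)
  Q / (-sum(pi * diag(Q)))
}

brute_pmat <- function(Q, t) {
  as.matrix(Matrix::expm(Q * t))
}

# likelihood by brute-force summation over all ancestral-state assignments
# (small trees only); states: tips x columns matrix of codes 1..4, NA missing
brute_tree_loglik <- function(tree, states, pi, exch, brlens,
                              rates = 1, cat_weights = 1, p_inv = 0) {
  Q <- brute_gtr_q(exch, pi)
  n_tip <- length(tree$tip.label)
  n_int <- tree$Nnode
  total <- 0
  for (col in seq_len(ncol(states))) {
    mix <- 0
    for (ci in seq_along(rates)) {
      P <- lapply(seq_len(nrow(tree$edge)), function(e) {
        brute_pmat(Q, brlens[e] * rates[ci])
      })
      lik <- 0
      for (assign_idx in seq_len(4^n_int) - 1L) {
        a <- integer(n_int)
        r <- assign_idx
        for (j in seq_len(n_int)) { a[j] <- r %% 4L + 1L; r <- r %/% 4L }
        state_of <- function(nd) {
          if (nd <= n_tip) states[nd, col] else a[nd - n_tip]
        }
        term <- pi[a[1]]  # root = n_tip + 1 is the first internal node
        for (e in seq_len(nrow(tree$edge))) {
          sp <- state_of(tree$edge[e, 1])
          sc <- state_of(tree$edge[e, 2])
          if (is.na(sc)) next  # missing tip: sum over states = 1
          term <- term * P[[e]][sp, sc]
        }
        lik <- lik + term
      }
      mix <- mix + cat_weights[ci] * lik
    }
    site <- (1 - p_inv) * mix
    if (p_inv > 0) {
      obs <- states[, col]
      compat <- vapply(1:4, function(b) all(is.na(obs) | obs == b), logical(1))
      site <- site + p_inv * sum(pi[compat])
    }
    total <- total + log(site)
  }
  total
}

# two-sided Fisher p by explicit enumeration with factorial products
brute_fisher_p <- function(tb) {
  m <- sum(tb[1, ]); n <- sum(tb[2, ]); k <- sum(tb[, 1])
  p_of <- function(a) {
    b <- m - a; c <- k - a; d <- n - k + a
    exp(lgamma(m + 1) - lgamma(a + 1) - lgamma(b + 1) +
          lgamma(n + 1) - lgamma(c + 1) - lgamma(d + 1) -
          (lgamma(m + n + 1) - lgamma(k + 1) - lgamma(m + n - k + 1)))
  }
  support <- max(0, k - n):min(k, m)
  probs <- vapply(support, p_of, numeric(1))
  obs <- p_of(tb[1, 1])
  min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
}

seq_identity <- function(a, b) {
  av <- strsplit(unname(a), "")[[1]]
  bv <- strsplit(unname(b), "")[[1]]
  mean(av == bv)
}

consensus_vs_truth <- function(consensus, truth) {
  cv <- strsplit(unname(consensus), "")[[1]]
  tv <- strsplit(unname(truth), "")[[1]]
  called <- cv != "N"
  list(called_frac = mean(called),
       identity = if (any(called)) mean(cv[called] == tv[called]) else NA)
}
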