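# topological node heights (max edge count to a descendant tip)
.node_heights <- function(tree) {
  n_tip <- length(tree$tip.label)
  h <- numeric(n_tip + tree$Nnode)
  post <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(post$edge))) {
    par <- post$edge[e, 1]; ch <- post$edge[e, 2]
    h[par] <- max(h[par], h[ch] + 1)
  }
  h
}

# initial node ages: topological heights scaled to a sensible root age, then
# calibrated nodes pinned to their prior means with order repaired
.init_ages <- function(tree, calibrations) {
  n_tip <- length(tree$tip.label)
  h <- .node_heights(tree)
  root <- n_tip + 1L
  root_age <- if (length(calibrations)) {
    1.25 * max(vapply(calibrations, `[[`, numeric(1), "mean_age"))
  } else 10
  ages <- h / h[root] * root_age
  cal_nodes <- vapply(calibrations, function(cal) {
    .check_monophyly(tree, cal)
  }, integer(1))
  post <- ape::reorder.phylo(tree, "postorder")
  eps <- root_age * 1e-3
  for (pass in seq_len(50L)) {
    for (i in seq_along(cal_nodes)) {
      ages[cal_nodes[i]] <- calibrations[[i]]$mean_age
    }
    for (e in seq_len(nrow(post$edge))) {
      par <- post$edge[e, 1]; ch <- post$edge[e, 2]
      if (ages[par] <= ages[ch]) ages[par] <- ages[ch] + eps
    }
  }
  ages
}

#' Bayesian node dating by Metropolis-Hastings MCMC on a fixed topology
#'
#' Samples node ages, the mean clock rate, per-branch lognormal rate
#' multipliers, the relaxed-clock standard deviation, the Yule birth rate
#' and (optionally) per-partition substitution-model parameters, under the
#' partitioned GTR+Gamma(+I) likelihood of [log_likelihood()] and the prior
#' of [log_prior()]. The topology never changes; proposals are node-age
#' slides (a coarse uniform draw within the node's age bounds plus a fine
#' Gaussian step matched to the near-fixing calibration scale), a whole-tree
#' age scale, and multiplicative scales for the scalar parameters.
#'
#' @param aln A `partitioned_alignment`.
#' @param topology A rooted binary `phylo` (branch lengths ignored).
#' @param calibrations List of [calibration()] objects.
#' @param n_generations Number of proposals (default 500,000; scale down for
#'   exploratory runs).
#' @param sample_every Thinning interval (default 100).
#' @param seed Integer seed; runs are reproducible.
#' @param models Named list of [gtr_params()] initial values per partition
#'   (default: equal exchangeabilities, empirical frequencies, gamma shape 1
#'   with 4 categories, p_inv 0).
#' @param sample_model Also sample exchangeabilities, gamma shape and p_inv
#'   (default TRUE when any model has rate variation, else FALSE).
#' @param init Optional list of initial values (`clock_rate`, `clock_sd`,
#'   `yule_lambda`, `ages`).
#' @return An `mcmc_trace` tibble, one row per sample, with node-age columns
#'   `age_<node>` keyed by ape node numbers of `topology`.
#' @export
run_mcmc <- function(aln, topology, calibrations = list(),
                     n_generations = 5e5, sample_every = 100L, seed = 1L,
                     models = NULL, sample_model = NULL, init = list()) {
  stopifnot(inherits(aln, "partitioned_alignment"),
            inherits(topology, "phylo"))
  set.seed(seed)
  tree <- topology
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  internal <- (n_tip + 1L):n_node
  root <- n_tip + 1L
  n_edge <- nrow(tree$edge)
  parent_of <- integer(n_node)
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]
  children_of <- split(tree$edge[, 2], tree$edge[, 1])
  edge_of_child <- integer(n_node)
  edge_of_child[tree$edge[, 2]] <- seq_len(n_edge)

  prep <- .lik_prep(aln, tree)
  if (is.null(models)) {
    models <- lapply(aln$partitions, function(cols) {
      gtr_params(base_freqs = .empirical_freqs(aln$matrix, cols),
                 gamma_shape = 1, p_inv = 0)
    })
  }
  models <- .resolve_models(aln, models)
  if (is.null(sample_model)) {
    sample_model <- any(vapply(models, function(m) is.finite(m$gamma_shape),
                               logical(1)))
  }
  part_names <- names(aln$partitions)

  st <- list(
    ages = if (!is.null(init$ages)) init$ages else .init_ages(tree, calibrations),
    clock_rate = if (!is.null(init$clock_rate)) init$clock_rate else 0.01,
    clock_sd = if (!is.null(init$clock_sd)) init$clock_sd else 0.1,
    yule = if (!is.null(init$yule_lambda)) init$yule_lambda else NA_real_,
    mults = rep(1, n_edge),
    models = models
  )
  if (is.na(st$yule)) {
    st$yule <- max(0.01, (n_tip - 1) / sum(st$ages[internal]))
  }
  if (any(st$ages[tree$edge[, 1]] <= st$ages[tree$edge[, 2]])) {
    abort("initial node ages violate parent-child order")
  }

  eigs <- lapply(st$models, function(m) {
    .gtr_eigen(m$exchangeabilities, m$base_freqs)
  })

  cal_nodes <- vapply(calibrations, function(cal) {
    .check_monophyly(tree, cal)
  }, integer(1))
  min_cal_sd <- if (length(calibrations)) {
    min(vapply(calibrations, `[[`, numeric(1), "sd"))
  } else 0.05

  state_prior <- function(s) {
    lp <- (n_tip - 1) * log(s$yule) - s$yule * sum(s$ages[internal])
    for (i in seq_along(cal_nodes)) {
      lp <- lp + dnorm(s$ages[cal_nodes[i]], calibrations[[i]]$mean_age,
                       calibrations[[i]]$sd, log = TRUE)
    }
    lp <- lp + sum(dlnorm(s$mults, -s$clock_sd^2 / 2, s$clock_sd, log = TRUE))
    lp <- lp + dlnorm(s$yule, 0, 2, log = TRUE) +
      dexp(s$clock_sd, 1, log = TRUE) +
      dlnorm(s$clock_rate, 0, 5, log = TRUE)
    if (sample_model) {
      for (m in s$models) {
        if (is.finite(m$gamma_shape)) {
          lp <- lp + dlnorm(m$gamma_shape, 0, 1.5, log = TRUE)
        }
        lp <- lp + sum(dlnorm(m$exchangeabilities[-2], 0, 1.5, log = TRUE))
      }
    }
    lp
  }
  state_lik <- function(s, eg) {
    .loglik_state(prep, s$ages, s$clock_rate, s$mults, s$models, eigs = eg)
  }

  cur_prior <- state_prior(st)
  cur_lik <- state_lik(st, eigs)

  n_samp <- floor(n_generations / sample_every) + 1L
  age_cols <- paste0("age_", internal)
  extra_cols <- c()
  if (sample_model) {
    extra_cols <- c(paste0("shape_", part_names), paste0("pinv_", part_names))
  }
  cols <- c("generation", "posterior", "likelihood", "prior", "clock_rate",
            "clock_sd", "yule_lambda", "rate_mean", age_cols, extra_cols)
  out <- matrix(NA_real_, n_samp, length(cols),
                dimnames = list(NULL, cols))
  record <- function(row, gen, s, lik, prior) {
    vals <- c(gen, lik + prior, lik, prior, s$clock_rate, s$clock_sd,
              s$yule, mean(s$mults), s$ages[internal])
    if (sample_model) {
      vals <- c(vals,
                vapply(s$models, `[[`, numeric(1), "gamma_shape"),
                vapply(s$models, `[[`, numeric(1), "p_inv"))
    }
    out[row, ] <<- vals
  }
  record(1L, 0, st, cur_lik, cur_prior)

  move_names <- c("age_coarse", "age_fine", "tree_scale", "clock_rate",
                  "mult", "clock_sd", "yule", "shape", "pinv", "exch")
  w <- c(28, 16, 3, 10, 20, 5, 5, 0, 0, 0)
  if (sample_model) w[8:10] <- c(4, 4, 5)
  w <- w / sum(w)
  n_acc <- setNames(numeric(length(move_names)), move_names)
  n_try <- n_acc

  row <- 2L
  for (gen in seq_len(n_generations)) {
    mv <- sample.int(length(move_names), 1L, prob = w)
    prop <- st
    log_h <- 0
    lik_changed <- TRUE
    valid <- TRUE
    switch(move_names[mv],
      age_coarse = {
        nd <- internal[sample.int(length(internal), 1L)]
        lo <- max(st$ages[children_of[[as.character(nd)]]])
        if (nd == root) {
          x <- st$ages[nd] - lo
          xp <- x * exp(runif(1, -0.5, 0.5))
          prop$ages[nd] <- lo + xp
          log_h <- log(xp / x)
        } else {
          hi <- st$ages[parent_of[nd]]
          prop$ages[nd] <- runif(1, lo, hi)
        }
      },
      age_fine = {
        nd <- internal[sample.int(length(internal), 1L)]
        lo <- max(st$ages[children_of[[as.character(nd)]]])
        hi <- if (nd == root) Inf else st$ages[parent_of[nd]]
        xp <- st$ages[nd] + rnorm(1, 0, min_cal_sd)
        if (xp <= lo || xp >= hi) valid <- FALSE else prop$ages[nd] <- xp
      },
      tree_scale = {
        f <- exp(runif(1, -0.15, 0.15))
        prop$ages[internal] <- st$ages[internal] * f
        log_h <- length(internal) * log(f)
      },
      clock_rate = {
        f <- exp(runif(1, -0.3, 0.3))
        prop$clock_rate <- st$clock_rate * f
        log_h <- log(f)
      },
      mult = {
        e <- sample.int(n_edge, 1L)
        f <- exp(rnorm(1, 0, 0.3))
        prop$mults[e] <- st$mults[e] * f
        log_h <- log(f)
      },
      clock_sd = {
        f <- exp(runif(1, -0.3, 0.3))
        prop$clock_sd <- st$clock_sd * f
        log_h <- log(f)
        lik_changed <- FALSE
      },
      yule = {
        f <- exp(runif(1, -0.5, 0.5))
        prop$yule <- st$yule * f
        log_h <- log(f)
        lik_changed <- FALSE
      },
      shape = {
        p <- sample.int(length(part_names), 1L)
        m <- st$models[[p]]
        if (!is.finite(m$gamma_shape)) { valid <- FALSE } else {
          f <- exp(runif(1, -0.4, 0.4))
          prop$models[[p]]$gamma_shape <- m$gamma_shape * f
          log_h <- log(f)
        }
      },
      pinv = {
        p <- sample.int(length(part_names), 1L)
        xp <- st$models[[p]]$p_inv + rnorm(1, 0, 0.05)
        if (xp < 0 || xp >= 0.95) valid <- FALSE else
          prop$models[[p]]$p_inv <- xp
      },
      exch = {
        p <- sample.int(length(part_names), 1L)
        i <- sample(c(1L, 3L, 4L, 5L, 6L), 1L)  # A-G exchangeability fixed
        f <- exp(rnorm(1, 0, 0.25))
        prop$models[[p]]$exchangeabilities[i] <-
          st$models[[p]]$exchangeabilities[i] * f
        log_h <- log(f)
      }
    )
    n_try[mv] <- n_try[mv] + 1
    if (valid) {
      prop_eigs <- eigs
      if (move_names[mv] == "exch") {
        p <- which(vapply(seq_along(part_names), function(q) {
          !identical(prop$models[[q]]$exchangeabilities,
                     st$models[[q]]$exchangeabilities)
        }, logical(1)))
        for (q in p) {
          prop_eigs[[q]] <- .gtr_eigen(prop$models[[q]]$exchangeabilities,
                                       prop$models[[q]]$base_freqs)
        }
      }
      prop_prior <- state_prior(prop)
      ok_order <- !any(prop$ages[tree$edge[, 1]] <= prop$ages[tree$edge[, 2]])
      if (is.finite(prop_prior) && ok_order) {
        prop_lik <- if (lik_changed) state_lik(prop, prop_eigs) else cur_lik
        log_a <- (prop_lik + prop_prior) - (cur_lik + cur_prior) + log_h
        if (is.finite(log_a) && log(runif(1)) < log_a) {
          st <- prop; cur_lik <- prop_lik; cur_prior <- prop_prior
          eigs <- prop_eigs
          n_acc[mv] <- n_acc[mv] + 1
        }
      }
    }
    if (gen %% sample_every == 0L) {
      record(row, gen, st, cur_lik, cur_prior)
      row <- row + 1L
    }
  }

  trace <- as_tibble(as.data.frame(out[seq_len(row - 1L), , drop = FALSE]))
  attr(trace, "topology") <- topology
  attr(trace, "calibrations") <- calibrations
  attr(trace, "sample_every") <- sample_every
  attr(trace, "n_generations") <- n_generations
  attr(trace, "acceptance") <- ifelse(n_try > 0, n_acc / n_try, NA_real_)
  class(trace) <- c("mcmc_trace", class(trace))
  trace
}
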