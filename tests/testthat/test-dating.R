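test_that("concatenation pads missing taxa and splits codon positions", {
  set.seed(61)
  taxa <- paste0("t", 1:6)
  mk <- function(ids, w) {
    setNames(vapply(ids, function(i) random_seq(w), character(1)), ids)
  }
  parts <- list(
    `12S` = mk(taxa, 512), `16S` = mk(taxa, 483),
    cytb = mk(taxa[-6], 657), nd4 = mk(taxa[-6], 659)
  )
  aln <- concatenate(parts, coding = c("cytb", "nd4"))
  expect_equal(ncol(aln$matrix), 2311L)
  expect_equal(names(aln$partitions), c("12S", "16S", "cp1", "cp2", "cp3"))
  expect_equal(sum(lengths(aln$partitions)), 2311L)
  expect_equal(anyDuplicated(unlist(aln$partitions)), 0L)
  # the taxon absent from the protein genes is all-N there
  prot_cols <- sort(unlist(aln$partitions[c("cp1", "cp2", "cp3")]))
  expect_true(all(aln$matrix["t6", prot_cols] == "N"))
  expect_false(any(aln$matrix["t1", ] == "N"))

  one <- concatenate(parts["12S"])
  expect_equal(ncol(one$matrix), 512L)
  expect_equal(paste(one$matrix["t1", ], collapse = ""),
               unname(parts$`12S`["t1"]))

  dup <- parts
  dup$`12S` <- c(dup$`12S`, setNames("A", "t1"))
  expect_error(concatenate(dup), "duplicate taxon")
})

test_that("pruning likelihood matches simple closed forms", {
  # identical sequences on a zero-duration tree: logL = sum log pi(base)
  topo <- ape::read.tree(text = "(A:0,B:0);")
  s <- "ACGTAC"
  aln <- as_partitioned_alignment(setNames(c(s, s), c("A", "B")))
  freqs <- c(0.4, 0.3, 0.2, 0.1)
  mod <- gtr_params(base_freqs = freqs)
  ch <- chronogram(topo, ages = c(0, 0, 0), clock_rate = 1)
  ll <- log_likelihood(aln, ch, models = list(all = mod))
  expected <- sum(log(freqs[match(strsplit(s, "")[[1]],
                                  c("A", "C", "G", "T"))]))
  expect_equal(ll, expected, tolerance = 1e-10)

  # JC, 2 taxa, 1 matching column, duration t each side
  t <- 0.07
  alnm <- as_partitioned_alignment(setNames(c("A", "A"), c("A", "B")))
  ch <- chronogram(topo, ages = c(0, 0, t), clock_rate = 1)
  ll <- log_likelihood(alnm, ch, models = list(all = gtr_params()))
  expect_equal(ll, log(1 / 4) + log(1 / 4 + 3 / 4 * exp(-4 * (2 * t) / 3)),
               tolerance = 1e-10)
  # and a mismatching column
  alnx <- as_partitioned_alignment(setNames(c("A", "C"), c("A", "B")))
  ll <- log_likelihood(alnx, ch, models = list(all = gtr_params()))
  expect_equal(ll, log(1 / 4) + log(1 / 4 - 1 / 4 * exp(-4 * (2 * t) / 3)),
               tolerance = 1e-10)
})

test_that("likelihood is invariant to root position (reversibility)", {
  set.seed(62)
  tips <- evolve_on_tree(simulate_reference(200, seed = 63),
                         ape::read.tree(text = "((A:0.1,B:0.2):0.05,(C:0.15,D:0.1):0.1);"),
                         gtr_params(exchangeabilities = c(1, 3, 1, 1, 3, 1),
                                    base_freqs = c(0.3, 0.2, 0.3, 0.2)),
                         seed = 64)
  aln <- as_partitioned_alignment(tips)
  mod <- gtr_params(exchangeabilities = c(1, 3, 1, 1, 3, 1),
                    base_freqs = c(0.3, 0.2, 0.3, 0.2))
  # same unrooted tree, root slid along the central branch
  t1 <- ape::read.tree(text = "((A:0.1,B:0.2):0.05,(C:0.15,D:0.1):0.1);")
  t2 <- ape::read.tree(text = "((A:0.1,B:0.2):0.12,(C:0.15,D:0.1):0.03);")
  ll <- function(tr) {
    # encode branch lengths through per-edge rate multipliers so the
    # chronogram machinery reproduces arbitrary (non-ultrametric) lengths
    ages <- c(0, 0, 0, 0, 1, 0.5, 0.5)
    dur <- ages[tr$edge[, 1]] - ages[tr$edge[, 2]]
    chronogram(tr, ages = ages, rates = tr$edge.length / dur, clock_rate = 1) |>
      log_likelihood(aln, chrono = _, models = list(all = mod))
  }
  expect_equal(ll(t1), ll(t2), tolerance = 1e-8)
})

test_that("pruning equals brute-force summation over ancestral states", {
  set.seed(65)
  freqs <- c(0.35, 0.15, 0.2, 0.3)
  exch <- c(1.2, 2.5, 0.7, 1.1, 3.0, 1)
  codes <- c("A", "C", "G", "T")
  for (n_tip in 3:5) {
    trees <- phangorn::allTrees(n_tip, rooted = TRUE)
    take <- if (length(trees) > 12) {
      sample(seq_along(trees), 12)
    } else {
      seq_along(trees)
    }
    for (j in take) {
      tr <- trees[[j]]  # [[ reattaches the shared tip labels
      tr$edge.length <- runif(nrow(tr$edge), 0.02, 0.5)
      states <- matrix(sample(c(1:4, NA), n_tip * 3, replace = TRUE,
                              prob = c(rep(0.22, 4), 0.12)), n_tip, 3)
      seqs <- apply(states, 1, function(row) {
        paste(ifelse(is.na(row), "N", codes[row]), collapse = "")
      })
      aln <- as_partitioned_alignment(setNames(seqs, tr$tip.label))
      ages <- rep(0, n_tip + tr$Nnode)
      ages[n_tip + 1] <- 1
      # make every internal node age distinct and ordered
      if (tr$Nnode > 1) {
        h <- museomics:::.node_heights(tr)
        ages[(n_tip + 2):(n_tip + tr$Nnode)] <-
          h[(n_tip + 2):(n_tip + tr$Nnode)] / h[n_tip + 1]
      }
      dur <- ages[tr$edge[, 1]] - ages[tr$edge[, 2]]
      mod <- gtr_params(exchangeabilities = exch, base_freqs = freqs,
                        p_inv = 0.15)
      ch <- chronogram(tr, ages = ages, rates = tr$edge.length / dur,
                       clock_rate = 1)
      mine <- log_likelihood(aln, ch, models = list(all = mod))
      # oracle needs branch lengths in the postorder edge order it uses
      oracle <- brute_tree_loglik(tr, states, freqs, exch,
                                  brlens = tr$edge.length, p_inv = 0.15)
      expect_equal(mine, oracle, tolerance = 1e-8)
    }
  }
})

test_that("gamma rate mixing matches an independently discretised oracle", {
  skip_if_not_installed("phangorn")
  set.seed(66)
  tr <- ape::rcoal(6)
  mod <- gtr_params(exchangeabilities = c(1, 2, 1, 1, 2, 1),
                    base_freqs = c(0.3, 0.2, 0.2, 0.3), gamma_shape = 0.45)
  tips <- evolve_on_tree(simulate_reference(400, seed = 67), tr, mod,
                         seed = 68)
  aln <- as_partitioned_alignment(tips)
  ch <- chronogram(tr, clock_rate = 1)
  ll <- log_likelihood(aln, ch, models = list(all = mod))
  m <- t(vapply(strsplit(tips$seq, ""), identity, character(400)))
  rownames(m) <- tips$id
  fit <- phangorn::pml(tr, phangorn::phyDat(m), bf = mod$base_freqs,
                       Q = mod$exchangeabilities, k = 4, shape = 0.45)
  expect_equal(ll, fit$logLik, tolerance = 1e-6)
})

test_that("the prior density matches its closed forms", {
  topo <- ape::read.tree(text = "(A:3,B:3);")
  t <- 3
  ch <- chronogram(topo, ages = c(0, 0, t), rates = 1, clock_rate = 1)
  lambda <- 0.7
  sdc <- 0.2
  lp <- log_prior(ch, list(), yule_birth_rate = lambda, clock_sd = sdc,
                  include_hyperpriors = FALSE)
  expected <- log(lambda) - lambda * t +
    sum(dlnorm(c(1, 1), -sdc^2 / 2, sdc, log = TRUE))
  expect_equal(lp, expected, tolerance = 1e-12)

  # calibration exactly at its mean adds the normal density at the mode
  cal <- list(calibration(c("A", "B"), t, 0.01))
  lp_cal <- log_prior(ch, cal, lambda, sdc, include_hyperpriors = FALSE)
  expect_equal(lp_cal - lp, -log(0.01 * sqrt(2 * pi)), tolerance = 1e-12)

  # with all multipliers at 1, the relaxed-clock term grows as clock_sd
  # shrinks towards the strict-clock limit
  lps <- vapply(c(0.5, 0.2, 0.05, 0.01), function(s) {
    log_prior(ch, list(), lambda, s, include_hyperpriors = FALSE)
  }, numeric(1))
  expect_true(all(diff(lps) > 0))

  # a non-monophyletic calibrated clade is rejected
  topo4 <- ape::read.tree(text = "((A,B),(C,D));")
  ch4 <- chronogram(topo4, ages = c(0, 0, 0, 0, 2, 1, 1), clock_rate = 1)
  expect_error(
    log_prior(ch4, list(calibration(c("A", "C"), 1)), 1, 0.1),
    "not monophyletic")
})

test_that("MCMC is reproducible and recovers the prior on empty data", {
  topo <- ape::read.tree(text = "((A,B),(C,D));")
  alnN <- as_partitioned_alignment(
    setNames(rep(strrep("N", 60), 4), c("A", "B", "C", "D")))
  cal <- list(calibration(c("A", "B"), 10, 0.01))
  tr1 <- run_mcmc(alnN, topo, cal, n_generations = 8000, sample_every = 10,
                  seed = 71, sample_model = FALSE)
  tr2 <- run_mcmc(alnN, topo, cal, n_generations = 8000, sample_every = 10,
                  seed = 71, sample_model = FALSE)
  expect_identical(as.data.frame(tr1), as.data.frame(tr2))

  # with no data the calibrated node's posterior is its Normal(10, 0.01)
  # prior: mean within 3 Monte-Carlo SEs
  ca <- clade_age(tr1, c("A", "B"), burn_in_frac = 0.2)
  mcse <- 0.01 / sqrt(ca$ess)
  expect_lt(abs(ca$mean - 10), 3 * mcse + 1e-4)
  expect_lt(ca$hpd_upper - ca$hpd_lower, 0.06)
})

test_that("trace summaries compute HPD and ESS correctly", {
  set.seed(72)
  x <- rnorm(100000)
  h <- hpd_interval(x)
  expect_lt(abs(h[1] + 1.96), 0.05)
  expect_lt(abs(h[2] - 1.96), 0.05)

  const <- tibble::tibble(generation = 1:100, a = rep(2, 100))
  s <- summarize_trace(const, burn_in_frac = 0)
  expect_equal(s$hpd_upper - s$hpd_lower, 0)
  expect_equal(s$ess, 100)

  phi <- 0.9
  ar <- as.numeric(arima.sim(list(ar = phi), 20000))
  expect_lt(abs(ess(ar) - 20000 * (1 - phi) / (1 + phi)),
            0.2 * 20000 * (1 - phi) / (1 + phi))

  expect_error(summarize_trace(const[1:5, ], burn_in_frac = 0.5),
               "fewer than 10")
})
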