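test_that("chi-squared statistic matches the Pearson formula and stats oracle", {
  expect_equal(chisq_2x2(matrix(c(10, 0, 0, 10), 2))$statistic, 20)
  r <- chisq_2x2(matrix(c(5, 5, 5, 5), 2))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  r <- chisq_2x2(matrix(c(8, 4, 2, 6), 2))
  expect_equal(round(r$statistic, 2), 3.33)

  set.seed(81)
  for (i in 1:10) {
    tb <- matrix(rpois(4, 8) + 1, 2)
    for (corr in c(FALSE, TRUE)) {
      mine <- chisq_2x2(tb, continuity_correction = corr)
      oracle <- suppressWarnings(stats::chisq.test(tb, correct = corr))
      expect_equal(mine$statistic, unname(oracle$statistic), tolerance = 1e-12)
      expect_equal(mine$p_value, oracle$p.value, tolerance = 1e-12)
    }
  }
  expect_error(chisq_2x2(matrix(c(0, 0, 3, 4), 2)), "[Ff]isher")
})

test_that("chi-squared is invariant to transposition and swaps", {
  tb <- matrix(c(8, 4, 2, 6), 2)
  x <- chisq_2x2(tb)$statistic
  expect_equal(chisq_2x2(t(tb))$statistic, x)
  expect_equal(chisq_2x2(tb[2:1, ])$statistic, x)
  expect_equal(chisq_2x2(tb[, 2:1])$statistic, x)
})

test_that("Fisher's exact test equals enumeration", {
  expect_equal(fisher_exact_2x2(matrix(c(3, 0, 0, 3), 2))$p_value, 0.1,
               tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(matrix(c(1, 1, 1, 1), 2))$p_value, 1)

  set.seed(82)
  for (i in 1:30) {
    tb <- matrix(sample(0:8, 4, replace = TRUE), 2)
    if (sum(tb) == 0) next
    mine <- fisher_exact_2x2(tb)$p_value
    expect_equal(mine, brute_fisher_p(tb), tolerance = 1e-10)
    expect_equal(mine, stats::fisher.test(tb)$p.value, tolerance = 1e-7)
  }
})

test_that("Monte-Carlo Fisher agrees with the exact test on r x c tables", {
  tb <- matrix(c(6, 1, 2, 5, 1, 4), 2)
  mc <- fisher_exact_mc(tb, n_sim = 40000, seed = 3)$p_value
  exact <- stats::fisher.test(tb)$p.value
  expect_lt(abs(mc - exact), 0.02)
})

test_that("two-way ANOVA reproduces hand-computed and oracle decompositions", {
  # balanced 2x2 with known cell means: hand-computable Type I SS
  d <- tibble::tibble(
    population = rep(c("SA", "ZW"), each = 4),
    sex = rep(c("F", "F", "M", "M"), 2),
    y = c(10, 12, 14, 16, 7, 9, 11, 13))
  a <- two_way_anova(d, "y")
  n <- 8
  ss_total <- sum((d$y - mean(d$y))^2)
  ss_pop <- 4 * sum((tapply(d$y, d$population, mean) - mean(d$y))^2)
  ss_sex <- 4 * sum((tapply(d$y, d$sex, mean) - mean(d$y))^2)
  cellm <- tapply(d$y, list(d$population, d$sex), mean)
  ss_cells <- 2 * sum((cellm - mean(d$y))^2)
  ss_int <- ss_cells - ss_pop - ss_sex
  ss_res <- ss_total - ss_cells
  expect_equal(a$df, c(1L, 1L, 1L))
  expect_equal(a$statistic,
               c(ss_pop, ss_sex, ss_int) / (ss_res / 4),
               tolerance = 1e-10)

  # every cell mean identical (with residual spread): all F exactly 0
  d0 <- d; d0$y <- rep(c(4, 6), 4)  # each cell holds {4, 6}, mean 5
  d0 <- dplyr::bind_rows(d0, d0)    # two specimens per cell per value
  a0 <- two_way_anova(d0, "y")
  expect_true(all(abs(a0$statistic) < 1e-10))

  # unbalanced data: sequential SS matches anova(lm(...)) exactly
  m <- simulate_morphology(seed = 83)
  mine <- two_way_anova(m, "subcaudals")
  oracle <- anova(lm(subcaudals ~ population * sex, data = m))
  expect_equal(mine$statistic, oracle$`F value`[1:3], tolerance = 1e-10)
  expect_equal(mine$p_value, oracle$`Pr(>F)`[1:3], tolerance = 1e-10)

  # constant second factor degenerates to the one-way analysis
  m$onesex <- factor("F")
  red <- two_way_anova(m, "subcaudals", "population", "onesex")
  ow <- anova(lm(subcaudals ~ population, data = m))
  expect_equal(red$statistic[1], ow$`F value`[1], tolerance = 1e-10)
})

test_that("ANCOVA adjusts for the covariate before testing factors", {
  set.seed(84)
  n <- 120
  d <- tibble::tibble(
    population = rep(c("SA", "ZW"), each = n / 2),
    sex = rep(c("F", "M"), n / 2),
    # populations differ strongly in body size but not in relative tail
    # length: a naive ANOVA on tl sees a population effect, the ANCOVA
    # (covariate first) must absorb it
    svl = rnorm(n, rep(c(700, 550), each = n / 2), 40))
  d$tl <- 0.2 * d$svl + rnorm(n, 0, 3)
  a <- two_way_ancova(d, "tl", "svl")
  naive <- two_way_anova(d, "tl")
  expect_lt(naive$p_value[1], 1e-6)
  expect_gt(a$p_value[a$term == "population"], 0.01)
  expect_lt(a$p_value[a$term == "svl"], 1e-10)

  d2 <- d; d2$svl <- 650
  expect_error(two_way_ancova(d2, "tl", "svl"), "degenerate")

  oracle <- anova(lm(tl ~ svl + population * sex, data = d))
  expect_equal(a$statistic, oracle$`F value`[1:4], tolerance = 1e-6)
})

test_that("a real sex effect on relative tail length is detected reliably", {
  hits <- 0
  for (r in 1:60) {
    m <- simulate_morphology(n_per_group = 50, seed = 8000 + r)
    a <- two_way_ancova(m, "tl", "svl")
    if (a$p_value[a$term == "sex"] < 0.01) hits <- hits + 1
  }
  expect_gte(hits / 60, 0.95)
})

test_that("standardised PCA has the correlation-matrix structure", {
  set.seed(85)
  d <- tibble::tibble(specimen_id = sprintf("s%02d", 1:20),
                      x = rnorm(20, 10, 2))
  d$y <- 3 * d$x - 5  # perfectly correlated pair
  p2 <- pca_standardized(d, characters = c("x", "y"))
  expect_equal(p2$eigenvalues, c(2, 0), tolerance = 1e-10)
  expect_equal(p2$percent_variance[1], 100, tolerance = 1e-10)

  m <- simulate_morphology(n_per_group = 12, seed = 86)
  p <- pca_standardized(m)
  expect_equal(sum(p$eigenvalues), 4, tolerance = 1e-9)
  expect_true(all(diff(p$eigenvalues) <= 1e-12))
  expect_equal(sum(p$percent_variance), 100, tolerance = 1e-9)
  # orthonormal loadings; largest-magnitude loading positive per component
  expect_equal(crossprod(p$vectors), diag(4), tolerance = 1e-10,
               ignore_attr = TRUE)
  for (j in 1:4) {
    expect_gt(p$vectors[which.max(abs(p$vectors[, j])), j], 0)
  }
  # scores: zero mean, variances equal to the eigenvalues
  sc <- as.matrix(p$scores[, paste0("PC", 1:4)])
  expect_equal(colMeans(sc), rep(0, 4), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(apply(sc, 2, var), p$eigenvalues, tolerance = 1e-9,
               ignore_attr = TRUE)
  # eigenvalues agree with the prcomp oracle
  pr <- prcomp(m[, p$characters], scale. = TRUE)
  expect_equal(p$eigenvalues, unname(pr$sdev^2), tolerance = 1e-10)

  # complete-case handling and degenerate input
  m2 <- m
  m2$ventrals[1:3] <- NA
  expect_equal(pca_standardized(m2)$n_used, nrow(m2) - 3L)
  m3 <- m
  m3$ventrals <- 120
  expect_error(pca_standardized(m3), "zero-variance")
})

test_that("tidy, glance, augment and autoplot work on result objects", {
  m <- simulate_morphology(n_per_group = 10, seed = 87)
  p <- pca_standardized(m)
  td <- tidy(p)
  expect_equal(nrow(td), 16L)
  g <- glance(p)
  expect_equal(g$pc1_percent, p$percent_variance[1])
  expect_equal(nrow(augment(p)), p$n_used)
  expect_s3_class(autoplot(p), "ggplot")

  topo <- ape::read.tree(text = "((A,B),(C,D));")
  alnN <- as_partitioned_alignment(
    setNames(rep(strrep("N", 40), 4), c("A", "B", "C", "D")))
  tr <- run_mcmc(alnN, topo, list(calibration(c("A", "B"), 5, 0.01)),
                 n_generations = 2000, sample_every = 10, seed = 88,
                 sample_model = FALSE)
  expect_s3_class(autoplot(tr), "ggplot")
  expect_true("min_ess" %in% names(glance(tr)))
  expect_true(all(c("parameter", "mean") %in% names(tidy(tr))))
})
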