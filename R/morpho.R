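#' Pearson chi-squared test for a 2x2 table
#'
#' The Pearson statistic `sum((O - E)^2 / E)` on 1 degree of freedom, with
#' the Yates continuity correction (subtracting 0.5 from `|O - E|`)
#' available behind a flag (off by default).
#'
#' @param table A 2x2 matrix of counts.
#' @param continuity_correction Apply the Yates correction.
#' @return A `morph_test` tibble: `term`, `df`, `statistic`, `p_value`,
#'   `method`.
#' @export
chisq_2x2 <- function(table, continuity_correction = FALSE) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == 2L), all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    abort("zero row or column margin; use fisher_exact_2x2 instead")
  }
  E <- outer(rowSums(table), colSums(table)) / sum(table)
  d <- abs(table - E)
  if (continuity_correction) d <- pmax(d - 0.5, 0)
  x2 <- sum(d^2 / E)
  .morph_test(term = "population", df = 1L, statistic = x2,
              p_value = pchisq(x2, 1L, lower.tail = FALSE),
              method = if (continuity_correction) {
                "chi-squared (Yates)"
              } else "chi-squared")
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by direct enumeration: with all margins fixed, the sum
#' of hypergeometric probabilities of every table at most as probable as the
#' observed one (with the usual `1 + 1e-7` tolerance on "at most as
#' probable" to absorb floating-point ties).
#'
#' @param table A 2x2 matrix of non-negative counts.
#' @return A `morph_test` tibble.
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == 2L), all(table >= 0))
  m <- sum(table[1, ])     # row-1 margin
  n <- sum(table[2, ])
  k <- sum(table[, 1])     # column-1 margin
  support <- max(0L, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(table[1, 1], m, n, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  .morph_test(term = "population", df = NA_integer_, statistic = NA_real_,
              p_value = min(p, 1), method = "Fisher exact")
}

#' Fisher-style exact test for an r x c table by Monte Carlo
#'
#' For tables larger than 2x2 (multi-level meristic classes) the two-sided
#' p-value is estimated by sampling tables with fixed margins
#' ([stats::r2dtable()]) and comparing their hypergeometric probabilities
#' with the observed table's.
#'
#' @param table An r x c matrix of counts.
#' @param n_sim Number of Monte Carlo tables (default 10,000).
#' @param seed Integer seed.
#' @return A `morph_test` tibble.
#' @export
fisher_exact_mc <- function(table, n_sim = 10000L, seed = 1L) {
  table <- as.matrix(table)
  if (all(dim(table) == 2L)) return(fisher_exact_2x2(table))
  set.seed(seed)
  logp <- function(tb) {
    sum(lgamma(rowSums(tb) + 1)) + sum(lgamma(colSums(tb) + 1)) -
      lgamma(sum(tb) + 1) - sum(lgamma(tb + 1))
  }
  obs <- logp(table)
  sims <- stats::r2dtable(n_sim, rowSums(table), colSums(table))
  hits <- sum(vapply(sims, logp, numeric(1)) <= obs + 1e-7)
  .morph_test(term = "population", df = NA_integer_, statistic = NA_real_,
              p_value = (hits + 1) / (n_sim + 1), method = "Fisher exact (MC)")
}

.morph_test <- function(term, df, statistic, p_value, method) {
  structure(tibble(term = term, df = df, statistic = statistic,
                   p_value = p_value, method = method),
            class = c("morph_test", class(tibble())))
}

# sequential (Type I) sum-of-squares decomposition over a list of nested
# design-matrix blocks, by QR projection
.seq_anova <- function(y, blocks, labels, method) {
  keep <- stats::complete.cases(cbind(y, do.call(cbind, blocks)))
  y <- y[keep]
  blocks <- lapply(blocks, function(b) b[keep, , drop = FALSE])
  n <- length(y)
  rss <- numeric(length(blocks) + 1L)
  rank <- integer(length(blocks) + 1L)
  X <- matrix(1, n, 1)
  fit0 <- stats::lm.fit(X, y)
  rss[1] <- sum(fit0$residuals^2)
  rank[1] <- fit0$rank
  for (i in seq_along(blocks)) {
    X <- cbind(X, blocks[[i]])
    fit <- stats::lm.fit(X, y)
    rss[i + 1L] <- sum(fit$residuals^2)
    rank[i + 1L] <- fit$rank
  }
  df_terms <- diff(rank)
  ss_terms <- -diff(rss)
  df_res <- n - rank[length(rank)]
  if (df_res <= 0) abort("no residual degrees of freedom")
  ms_res <- rss[length(rss)] / df_res
  Fv <- ifelse(df_terms > 0, (ss_terms / df_terms) / ms_res, NA_real_)
  structure(tibble(
    term = labels, df = df_terms, statistic = Fv,
    p_value = pf(Fv, df_terms, df_res, lower.tail = FALSE),
    method = method
  ), class = c("morph_test", class(tibble())), df_residual = df_res)
}

# a constant factor contributes no columns, so its term degenerates to
# df 0 / F NA and the remaining terms reduce to the lower-way analysis
.factor_block <- function(f) {
  f <- droplevels(factor(f))
  if (nlevels(f) < 2L) {
    return(matrix(numeric(0), length(f), 0))
  }
  stats::model.matrix(~f)[, -1, drop = FALSE]
}

.interaction_block <- function(a, b) {
  a <- droplevels(factor(a)); b <- droplevels(factor(b))
  if (nlevels(a) < 2L || nlevels(b) < 2L) {
    return(matrix(numeric(0), length(a), 0))
  }
  stats::model.matrix(~ a:b)[, -1, drop = FALSE]
}

#' Two-way ANOVA with sequential sums of squares
#'
#' Tests a meristic character for population and sex effects and their
#' interaction. Sums of squares are sequential (Type I) in the order
#' `factor_a`, `factor_b`, interaction — the convention of common
#' statistical environments, made explicit here because meristic data sets
#' are rarely balanced. Rows with missing response or factors are dropped
#' listwise. An empty cell in the two-way layout drops the interaction with
#' a warning.
#'
#' @param data A data frame (e.g. a morphology table).
#' @param response Response column name.
#' @param factor_a,factor_b Factor column names (defaults `population`,
#'   `sex`).
#' @return A `morph_test` tibble with rows for `factor_a`, `factor_b` and
#'   the interaction.
#' @export
two_way_anova <- function(data, response, factor_a = "population",
                          factor_b = "sex") {
  y <- data[[response]]
  a <- data[[factor_a]]
  b <- data[[factor_b]]
  keep <- !is.na(y) & !is.na(a) & !is.na(b)
  y <- y[keep]; a <- droplevels(factor(a[keep])); b <- droplevels(factor(b[keep]))
  labels <- c(factor_a, factor_b, paste0(factor_a, ":", factor_b))
  has_empty_cell <- any(table(a, b) == 0L)
  blocks <- list(.factor_block(a), .factor_block(b))
  if (has_empty_cell) {
    warning("empty cell in the two-way layout; interaction omitted")
    labels <- labels[1:2]
  } else {
    blocks <- c(blocks, list(.interaction_block(a, b)))
  }
  .seq_anova(y, blocks, labels, "two-way ANOVA")
}

#' Two-way ANCOVA with a size covariate
#'
#' Linear model `response ~ covariate + factor_a + factor_b + interaction`
#' with sequential sums of squares, covariate first — the standard guard
#' against size confounding in growth-related characters (tail length
#' against snout-vent length).
#'
#' @param data A data frame.
#' @param response Response column name (e.g. `tl`).
#' @param covariate Covariate column name (e.g. `svl`).
#' @param factor_a,factor_b Factor column names.
#' @return A `morph_test` tibble with rows for the covariate, both factors
#'   and the interaction.
#' @export
two_way_ancova <- function(data, response, covariate,
                           factor_a = "population", factor_b = "sex") {
  y <- data[[response]]
  x <- data[[covariate]]
  a <- data[[factor_a]]
  b <- data[[factor_b]]
  keep <- !is.na(y) & !is.na(x) & !is.na(a) & !is.na(b)
  y <- y[keep]; x <- x[keep]
  a <- droplevels(factor(a[keep])); b <- droplevels(factor(b[keep]))
  if (length(unique(x)) < 2L) abort("covariate is degenerate (zero variance)")
  blocks <- list(matrix(x, ncol = 1), .factor_block(a), .factor_block(b),
                 .interaction_block(a, b))
  labels <- c(covariate, factor_a, factor_b,
              paste0(factor_a, ":", factor_b))
  .seq_anova(y, blocks, labels, "two-way ANCOVA")
}

#' PCA of standardised meristic characters
#'
#' Characters are standardised to zero mean and unit (n-1) standard
#' deviation; the eigendecomposition of the covariance of the standardised
#' data (the correlation matrix) gives eigenvalues summing to the number of
#' characters. Specimens missing any selected character are excluded
#' (complete-case). Eigenvector signs are fixed so each component's
#' largest-magnitude loading is positive, making loadings comparable across
#' runs.
#'
#' @param data A morphology table.
#' @param characters Character column names (default the four meristic
#'   characters that separate the two rinkhals populations: midbody rows,
#'   nape rows, ventrals, subcaudals).
#' @param id_cols Columns carried into the score table (default
#'   `specimen_id`, `population`, `sex` where present).
#' @return A `morph_pca` object: `eigenvalues`, `vectors` (characters x
#'   components), `scores` (tibble), `percent_variance`, `n_used`.
#' @export
pca_standardized <- function(data,
                             characters = c("midbody_rows", "nape_rows",
                                            "ventrals", "subcaudals"),
                             id_cols = intersect(
                               c("specimen_id", "population", "sex"),
                               names(data))) {
  stopifnot(all(characters %in% names(data)))
  X <- as.matrix(data[, characters, drop = FALSE])
  cc <- stats::complete.cases(X)
  X <- X[cc, , drop = FALSE]
  if (nrow(X) < 3L) abort("fewer than 3 complete-case specimens")
  sds <- apply(X, 2, sd)
  if (any(sds == 0)) {
    abort(paste0("zero-variance character: ",
                 paste(characters[sds == 0], collapse = ", ")))
  }
  Z <- scale(X, center = TRUE, scale = sds)
  S <- crossprod(Z) / (nrow(Z) - 1)
  e <- eigen(S, symmetric = TRUE)
  V <- e$vectors
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  dimnames(V) <- list(characters, paste0("PC", seq_len(ncol(V))))
  scores <- Z %*% V
  lab <- data[cc, id_cols, drop = FALSE]
  structure(list(
    eigenvalues = pmax(e$values, 0),
    vectors = V,
    scores = dplyr::bind_cols(as_tibble(lab),
                              as_tibble(as.data.frame(scores))),
    percent_variance = pmax(e$values, 0) / sum(pmax(e$values, 0)) * 100,
    characters = characters,
    n_used = nrow(X)
  ), class = "morph_pca")
}

#' @export
print.morph_pca <- function(x, ...) {
  cat(sprintf("<morph_pca> %d specimens, %d characters\n", x$n_used,
              length(x$characters)))
  cat("percent variance:",
      paste(sprintf("%.2f", x$percent_variance), collapse = ", "), "\n")
  invisible(x)
}
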