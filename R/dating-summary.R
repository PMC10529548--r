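#' Shortest (highest-posterior-density) interval of a sample
#'
#' @param x Numeric sample.
#' @param prob Coverage probability (default 0.95).
#' @return Numeric length-2 vector (lower, upper).
#' @export
hpd_interval <- function(x, prob = 0.95) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  if (n == 0L) return(c(NA_real_, NA_real_))
  m <- max(1L, ceiling(prob * n))
  if (m >= n) return(c(x[1], x[n]))
  widths <- x[(m):n] - x[seq_len(n - m + 1L)]
  i <- which.min(widths)
  c(x[i], x[i + m - 1L])
}

#' Effective sample size of an autocorrelated trace
#'
#' `n / (1 + 2 * sum(rho_k))` with the autocorrelation sum truncated at the
#' first non-positive term. A constant trace has ESS `n` by convention.
#'
#' @param x Numeric sample (one MCMC trace column).
#' @return The effective sample size.
#' @export
ess <- function(x) {
  n <- length(x)
  if (n < 2L || sd(x) == 0 || !is.finite(sd(x))) return(as.numeric(n))
  lag_max <- min(n - 1L, 2000L)
  rho <- as.numeric(stats::acf(x, lag.max = lag_max, plot = FALSE,
                               demean = TRUE)$acf)[-1]
  bad <- which(rho <= 0)
  if (length(bad)) rho <- rho[seq_len(bad[1] - 1L)]
  out <- n / (1 + 2 * sum(rho))
  min(max(out, 1), n)
}

#' Summarise an MCMC trace
#'
#' Drops the burn-in fraction, then reports for every sampled parameter the
#' posterior mean, 95% HPD interval and effective sample size.
#'
#' @param trace An `mcmc_trace` tibble (or any tibble with a `generation`
#'   column and numeric parameter columns).
#' @param burn_in_frac Fraction of samples discarded as burn-in
#'   (default 0.10).
#' @return A tibble: `parameter`, `mean`, `hpd_lower`, `hpd_upper`, `ess`.
#' @export
summarize_trace <- function(trace, burn_in_frac = 0.10) {
  stopifnot(burn_in_frac >= 0, burn_in_frac < 1)
  n <- nrow(trace)
  keep <- trace[seq_len(n) > floor(burn_in_frac * n), , drop = FALSE]
  if (nrow(keep) < 10L) abort("fewer than 10 post-burn-in samples")
  pars <- setdiff(names(keep), "generation")
  purrr::map_dfr(pars, function(p) {
    x <- keep[[p]]
    h <- hpd_interval(x)
    tibble(parameter = p, mean = mean(x), hpd_lower = h[1], hpd_upper = h[2],
           ess = ess(x))
  })
}

#' Posterior age summary for a clade
#'
#' Convenience accessor: the posterior mean and 95% HPD of the age of the
#' MRCA of `tips`, from a trace produced by [run_mcmc()].
#'
#' @param trace An `mcmc_trace`.
#' @param tips Tip labels defining the clade.
#' @param burn_in_frac Burn-in fraction (default 0.10).
#' @return A one-row tibble: `node`, `mean`, `hpd_lower`, `hpd_upper`, `ess`.
#' @export
clade_age <- function(trace, tips, burn_in_frac = 0.10) {
  tree <- attr(trace, "topology")
  if (is.null(tree)) abort("trace lacks a topology attribute")
  node <- mrca_node(tree, tips)
  s <- summarize_trace(trace, burn_in_frac)
  s <- s[s$parameter == paste0("age_", node), , drop = FALSE]
  tibble(node = node, mean = s$mean, hpd_lower = s$hpd_lower,
         hpd_upper = s$hpd_upper, ess = s$ess)
}
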