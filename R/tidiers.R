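#' Tidy a morphometric PCA
#'
#' @param x A `morph_pca`.
#' @param ... Unused.
#' @return A tibble of loadings: `character`, `component`, `loading`.
#' @export
tidy.morph_pca <- function(x, ...) {
  as_tibble(as.data.frame(x$vectors), rownames = "character") |>
    tidyr::pivot_longer(-"character", names_to = "component",
                        values_to = "loading")
}

#' @rdname tidy.morph_pca
#' @return For `glance`, a one-row tibble with the specimen count and the
#'   variance shares of the first two components.
#' @export
glance.morph_pca <- function(x, ...) {
  tibble(n_specimens = x$n_used, n_characters = length(x$characters),
         pc1_percent = x$percent_variance[1],
         pc2_percent = x$percent_variance[2])
}

#' @rdname tidy.morph_pca
#' @return For `augment`, the per-specimen score table.
#' @export
augment.morph_pca <- function(x, ...) {
  x$scores
}

#' Tidy an MCMC trace into posterior summaries
#'
#' @param x An `mcmc_trace` from [run_mcmc()].
#' @param burn_in_frac Burn-in fraction (default 0.10).
#' @param ... Unused.
#' @return [summarize_trace()] output.
#' @export
tidy.mcmc_trace <- function(x, burn_in_frac = 0.10, ...) {
  summarize_trace(x, burn_in_frac)
}

#' @rdname tidy.mcmc_trace
#' @return For `glance`, a one-row tibble: generations, samples, minimum
#'   ESS over parameters.
#' @export
glance.mcmc_trace <- function(x, burn_in_frac = 0.10, ...) {
  s <- summarize_trace(x, burn_in_frac)
  tibble(n_generations = attr(x, "n_generations"),
         n_samples = nrow(x),
         min_ess = min(s$ess))
}
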