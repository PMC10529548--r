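#' Ordination plot of a morphometric PCA
#'
#' Specimens in the space of the first two principal components, coloured
#' by population — the standard way to visualise overall phenotypic
#' distinctness free of a priori group assignment.
#'
#' @param object A `morph_pca`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.morph_pca <- function(object, ...) {
  sc <- object$scores
  colour <- if ("population" %in% names(sc)) "population" else NULL
  p <- ggplot2::ggplot(sc, ggplot2::aes(.data$PC1, .data$PC2)) +
    ggplot2::geom_point(
      if (!is.null(colour)) ggplot2::aes(colour = .data$population),
      size = 2) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", object$percent_variance[1]),
      y = sprintf("PC2 (%.1f%%)", object$percent_variance[2])) +
    ggplot2::theme_minimal()
  p
}

#' Depth profile of a pileup
#'
#' @param object A pileup tibble from [build_pileup()].
#' @param min_depth Reference line for the region-extraction threshold.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pileup <- function(object, min_depth = 3, ...) {
  plot_depth(object, min_depth)
}

#' @rdname autoplot.pileup
#' @param pileup A pileup tibble.
#' @export
plot_depth <- function(pileup, min_depth = 3) {
  ggplot2::ggplot(pileup, ggplot2::aes(.data$pos, .data$depth)) +
    ggplot2::geom_area(fill = "grey70") +
    ggplot2::geom_hline(yintercept = min_depth, linetype = 2,
                        colour = "firebrick") +
    ggplot2::labs(x = "position (0-based)", y = "read depth") +
    ggplot2::theme_minimal()
}

#' Stringency-sweep plot of endogenous content
#'
#' @param sweep Output tibble of [endogenous_sweep()].
#' @return A ggplot object.
#' @export
plot_sweep <- function(sweep) {
  ggplot2::ggplot(sweep, ggplot2::aes(factor(.data$stringency),
                                      .data$fraction_mapped)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "allowed mismatch fraction",
                  y = "mapped fraction after filters") +
    ggplot2::theme_minimal()
}

#' Trace plot of sampled MCMC parameters
#'
#' @param object An `mcmc_trace`.
#' @param parameters Columns to show (default the posterior and the root
#'   age).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mcmc_trace <- function(object, parameters = NULL, ...) {
  if (is.null(parameters)) {
    tree <- attr(object, "topology")
    root_col <- if (!is.null(tree)) {
      paste0("age_", length(tree$tip.label) + 1L)
    } else NULL
    parameters <- intersect(c("posterior", root_col), names(object))
  }
  long <- tidyr::pivot_longer(
    as_tibble(object)[, c("generation", parameters), drop = FALSE],
    -"generation", names_to = "parameter", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$generation, .data$value)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::theme_minimal()
}
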