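#' Default group parameters for morphology simulation
#'
#' Published scale-count summaries for the two rinkhals populations (South
#' Africa, `SA`, and Zimbabwe, `ZW`): mean, standard deviation and observed
#' range per meristic character, with ventral and subcaudal counts split by
#' sex (they are sexually dimorphic) and dorsal scale-row counts pooled.
#'
#' @return A tibble: `character`, `population`, `sex` (`NA` = both sexes),
#'   `mean`, `sd`, `min`, `max`.
#' @export
morph_group_defaults <- function() {
  tibble::tribble(
    ~character,      ~population, ~sex, ~mean, ~sd,  ~min, ~max,
    "midbody_rows",  "SA",        NA,   18.6,  0.72, 17,   19,
    "midbody_rows",  "ZW",        NA,   17.8,  0.95, 17,   19,
    "nape_rows",     "SA",        NA,   17.9,  0.99, 17,   19,
    "nape_rows",     "ZW",        NA,   17.0,  0.43, 16,   18,
    "subcaudals",    "SA",        "F",  39.0,  2.6,  35,   40,
    "subcaudals",    "SA",        "M",  40.9,  3.1,  35,   46,
    "subcaudals",    "ZW",        "F",  33.8,  2.3,  30,   37,
    "subcaudals",    "ZW",        "M",  36.3,  1.8,  34,   38,
    "ventrals",      "SA",        "F",  141,   6.5,  129,  148,
    "ventrals",      "SA",        "M",  129,   6.9,  117,  138,
    "ventrals",      "ZW",        "F",  128,   1.6,  126,  130,
    "ventrals",      "ZW",        "M",  122,   1.7,  119,  124
  )
}

#' Simulate a two-population meristic morphology table
#'
#' Draws integer scale counts as rounded normals per population-by-sex
#' group, clamped to the published observed range when one is given.
#' Optionally adds body-size columns (`svl`, snout-vent length, and `tl`,
#' tail length, both mm) with a sexually dimorphic tail-to-body ratio so
#' the ANCOVA workflow can be exercised; the published description reports
#' specimens around 600-1000 mm total length.
#'
#' @param group_params Parameter tibble as in [morph_group_defaults()].
#' @param n_per_group Either a single integer (specimens per population x
#'   sex group) or a tibble (`population`, `sex`, `n`). The default mirrors
#'   the published sample: 6 SA females, 14 SA males, 6 ZW females, 5 ZW
#'   males.
#' @param seed Integer seed.
#' @param lengths Also simulate `svl` and `tl`.
#' @return A morphology tibble: `specimen_id`, `population`, `sex`, one
#'   column per character.
#' @export
simulate_morphology <- function(group_params = morph_group_defaults(),
                                n_per_group = NULL, seed = 1L,
                                lengths = TRUE) {
  stopifnot(all(group_params$sd >= 0))
  set.seed(seed)
  if (is.null(n_per_group)) {
    n_per_group <- tibble(population = c("SA", "SA", "ZW", "ZW"),
                          sex = c("F", "M", "F", "M"), n = c(6L, 14L, 6L, 5L))
  } else if (is.numeric(n_per_group) && length(n_per_group) == 1L) {
    n_per_group <- tidyr::expand_grid(population = unique(group_params$population),
                                      sex = c("F", "M")) |>
      dplyr::mutate(n = as.integer(n_per_group))
  }
  chars <- unique(group_params$character)
  rows <- purrr::pmap_dfr(n_per_group, function(population, sex, n) {
    out <- tibble(population = rep(population, n), sex = rep(sex, n))
    for (ch in chars) {
      gp <- group_params[group_params$character == ch &
                           group_params$population == population &
                           (is.na(group_params$sex) |
                              group_params$sex == sex), , drop = FALSE]
      if (nrow(gp) == 0L) { out[[ch]] <- NA_real_; next }
      gp <- gp[1, ]
      x <- round(rnorm(n, gp$mean, gp$sd))
      if (!is.na(gp$min)) x <- pmax(x, gp$min)
      if (!is.na(gp$max)) x <- pmin(x, gp$max)
      out[[ch]] <- as.numeric(x)
    }
    if (lengths) {
      svl <- round(rnorm(n, 650, 100))
      ratio <- rnorm(n, ifelse(sex == "M", 0.21, 0.19), 0.012)
      out$svl <- pmax(svl, 300)
      out$tl <- round(out$svl * ratio)
    }
    out
  })
  rows$specimen_id <- sprintf("sp%03d", seq_len(nrow(rows)))
  rows$population <- factor(rows$population)
  rows$sex <- factor(rows$sex)
  dplyr::relocate(rows, "specimen_id", "population", "sex")
}
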