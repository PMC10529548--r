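#' Node-age calibration
#'
#' Normal prior on the age of a clade's most recent common ancestor. The
#' conventional near-fixing calibration uses sd 0.01 Myr, which effectively
#' pins the node to the mean while keeping the posterior proper.
#'
#' @param tips Character vector (length >= 2) of tip labels defining the
#'   clade's MRCA.
#' @param mean_age Prior mean age in Mya.
#' @param sd Prior standard deviation in Myr (default 0.01).
#' @return A `calibration` list.
#' @export
calibration <- function(tips, mean_age, sd = 0.01) {
  stopifnot(length(tips) >= 2L, sd > 0, mean_age > 0)
  structure(list(tips = tips, mean_age = mean_age, sd = sd),
            class = "calibration")
}

#' MRCA node of a tip set
#'
#' @param tree A `phylo`.
#' @param tips Tip labels.
#' @return The ape node number of the MRCA.
#' @export
mrca_node <- function(tree, tips) {
  if (length(tips) == length(tree$tip.label)) {
    return(length(tree$tip.label) + 1L)
  }
  ape::getMRCA(tree, tips)
}

# tips descending from each internal node
.clade_tips <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  if (node <= n_tip) return(tree$tip.label[node])
  desc <- ape::prop.part(tree)
  tree$tip.label[desc[[node - n_tip]]]
}

.check_monophyly <- function(tree, cal) {
  node <- mrca_node(tree, cal$tips)
  tips <- .clade_tips(tree, node)
  if (!setequal(tips, cal$tips)) {
    abort(paste0("calibrated clade {", paste(cal$tips, collapse = ","),
                 "} is not monophyletic in the fixed topology"))
  }
  node
}

#' Log prior density of a chronogram under the dating model
#'
#' Sum of: a Yule pure-birth term over internal-node ages, using the
#' normalisation `(n - 1) log(lambda) - lambda * sum(node ages)` (which for
#' a two-tip tree of root age t reduces to `lambda * exp(-lambda t)`);
#' a Normal term per calibration at its MRCA's age; iid lognormal terms for
#' the per-branch rate multipliers, parameterised to have real-space mean 1
#' and log-space sd `clock_sd`; and, optionally, the declared hyperpriors
#' (`yule_birth_rate ~ Lognormal(0, 2)`, `clock_sd ~ Exp(1)`).
#'
#' @param chrono A [chronogram()].
#' @param calibrations List of [calibration()] objects.
#' @param yule_birth_rate Yule birth rate (per Myr).
#' @param clock_sd Relaxed-clock log-space standard deviation.
#' @param include_hyperpriors Add the hyperprior terms.
#' @return The log prior density (a scalar).
#' @export
log_prior <- function(chrono, calibrations = list(), yule_birth_rate = 1,
                      clock_sd = 0.1, include_hyperpriors = TRUE) {
  stopifnot(inherits(chrono, "chronogram"))
  tree <- chrono$tree
  n_tip <- length(tree$tip.label)
  internal <- (n_tip + 1L):(n_tip + tree$Nnode)
  lp <- (n_tip - 1) * log(yule_birth_rate) -
    yule_birth_rate * sum(chrono$ages[internal])
  for (cal in calibrations) {
    node <- .check_monophyly(tree, cal)
    lp <- lp + dnorm(chrono$ages[node], cal$mean_age, cal$sd, log = TRUE)
  }
  if (clock_sd > 0) {
    lp <- lp + sum(dlnorm(chrono$rates, -clock_sd^2 / 2, clock_sd,
                          log = TRUE))
  } else if (any(chrono$rates != 1)) {
    lp <- -Inf
  }
  if (include_hyperpriors) {
    lp <- lp + dlnorm(yule_birth_rate, 0, 2, log = TRUE) +
      dexp(clock_sd, 1, log = TRUE)
  }
  lp
}
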