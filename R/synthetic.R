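#' Synthetic CBE tables with controllable directional structure
#'
#' Generates seeded per-receptor conditional binding efficiencies for the
#' three channels. Each channel's values are drawn from a lognormal
#' distribution whose mean equals the channel level (\code{gcc_bias},
#' \code{nhc_level}, \code{factor_level}) and whose coefficient of variation
#' is \code{noise_cv}; lognormal noise keeps efficiencies nonnegative and
#' mirrors the multiplicative score-times-expression structure of the CBE.
#' With \code{noise_cv = 0} every receptor gets the channel level exactly.
#'
#' @param n_receptors number of receptor types.
#' @param gcc_bias mean of the GCC channel (a multiplier expressing how much
#'   stronger tumour-cell binding is than the other channels).
#' @param nhc_level,factor_level means of the NHC and F channels.
#' @param noise_cv lognormal coefficient of variation (0 = deterministic).
#' @param seed optional integer seed; the caller's RNG state is restored on
#'   exit, so the generator is reproducible without side effects.
#' @return a [cbe_tables()] object.
#' @examples
#' synth_cbe_tables(4, gcc_bias = 2, noise_cv = 0)
#' @export
synth_cbe_tables <- function(n_receptors = 11, gcc_bias = 1, nhc_level = 1,
                             factor_level = 1, noise_cv = 0, seed = NULL) {
  if (n_receptors < 1) stop("n_receptors must be at least 1")
  levels <- c(gcc_bias, nhc_level, factor_level)
  if (any(levels < 0) || noise_cv < 0) {
    stop("channel levels and noise_cv must be nonnegative")
  }
  if (!is.null(seed)) {
    if (!exists(".Random.seed", envir = globalenv())) stats::runif(1)
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  draw <- function(level) {
    if (noise_cv == 0 || level == 0) return(rep(level, n_receptors))
    s2 <- log(1 + noise_cv^2)  # E[lnorm(-s2/2, sqrt(s2))] = 1
    level * stats::rlnorm(n_receptors, meanlog = -s2 / 2, sdlog = sqrt(s2))
  }
  cbe_tables(gcc = draw(gcc_bias), nhc = draw(nhc_level),
             f = draw(factor_level))
}
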