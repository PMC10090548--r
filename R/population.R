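#' Population fractions by predicted direction
#'
#' Sums each configuration's total probability mass into the channel it is
#' classified towards (GCC, NHC, F) or into NNDP when no selective propensity
#' clears the threshold. Also builds the per-(k, k_f) node table used by the
#' network rendering: each cell's absolute mass, its mass split by direction,
#' and within-cell odds ratios per channel.
#'
#' @param pt a [class_probabilities()] result.
#' @return object of class \code{population_summary}: list with
#'   \code{fractions} (named \code{gcc, nhc, f, nndp}, summing to 1),
#'   \code{per_node} data frame, and \code{n}.
#' @export
population_fractions <- function(pt) {
  stopifnot(inherits(pt, "config_probabilities"))
  cfg <- pt$config
  mass <- cfg$p_gcc + cfg$p_nhc + cfg$p_f
  frac_of <- function(dir) sum(mass[cfg$direction == dir])
  fractions <- c(gcc = frac_of("GCC"), nhc = frac_of("NHC"),
                 f = frac_of("F"), nndp = frac_of("NNDP"))
  key <- paste(cfg$k, cfg$k_f, sep = ":")
  cells <- unique(key)
  per_node <- do.call(rbind, lapply(cells, function(cell) {
    sel <- key == cell
    m <- mass[sel]
    dirs <- cfg$direction[sel]
    tot <- sum(m)
    share <- vapply(c("GCC", "NHC", "F", "NNDP"),
                    function(d) sum(m[dirs == d]), numeric(1))
    within <- if (tot > 0) share / tot else rep(NA_real_, 4)
    data.frame(k = cfg$k[sel][1], k_f = cfg$k_f[sel][1], mass = tot,
               frac_gcc = share[1], frac_nhc = share[2], frac_f = share[3],
               frac_nndp = share[4],
               or_gcc = odds_ratio(within[1], mean(within[2:3])),
               or_nhc = odds_ratio(within[2], mean(within[c(1, 3)])),
               or_f = odds_ratio(within[3], mean(within[1:2])),
               stringsAsFactors = FALSE)
  }))
  per_node <- per_node[order(per_node$k, per_node$k_f), ]
  rownames(per_node) <- NULL
  structure(list(fractions = fractions, per_node = per_node, n = pt$n),
            class = "population_summary")
}

#' @export
print.population_summary <- function(x, ...) {
  cat("Population fractions (raw):\n")
  print(round(x$fractions, 4))
  invisible(x)
}

#' Redistribute the NNDP mass equally over the three fates
#'
#' Particles with no net directional preference end up somewhere; absent any
#' information, their mass is split equally among GCC, NHC and F for the
#' headline prediction. Intermediate tables keep the raw NNDP mass.
#'
#' @param x a named fraction vector containing \code{gcc, nhc, f, nndp}, or a
#'   \code{population_summary}.
#' @return same shape as the input with \code{nndp = 0} and each channel
#'   increased by a third of the former NNDP mass.
#' @examples
#' redistribute_nndp(c(gcc = 0.37, nhc = 0, f = 0.60, nndp = 0.03))
#' @export
redistribute_nndp <- function(x) {
  if (inherits(x, "population_summary")) {
    x$fractions <- redistribute_nndp(x$fractions)
    return(x)
  }
  req <- c("gcc", "nhc", "f", "nndp")
  if (!all(req %in% names(x))) {
    stop("fractions must be named with ", paste(req, collapse = ", "))
  }
  share <- x[["nndp"]] / 3
  x[c("gcc", "nhc", "f")] <- x[c("gcc", "nhc", "f")] + share
  x[["nndp"]] <- 0
  x
}

#' Odds ratio of one channel against its mean competitor
#'
#' With \code{f} the fraction of population directed towards the channel of
#' interest and \code{g} the mean fraction of the two competing channels,
#' returns \eqn{[f/(1-f)] / [g/(1-g)]}. Degenerate inputs signal rather than
#' fail: \code{g = 0} with \code{f > 0} gives \code{Inf}, both zero give
#' \code{NaN}, and a fraction of exactly 1 gives \code{Inf}/\code{NaN}
#' through the odds themselves.
#'
#' @param f fraction in favour, in \code{[0, 1]}.
#' @param g mean competing fraction, in \code{[0, 1]}.
#' @return the odds ratio.
#' @examples
#' odds_ratio(0.5, 0.25) # 3
#' @export
odds_ratio <- function(f, g) {
  if (anyNA(c(f, g))) return(NA_real_)
  if (any(c(f, g) < 0) || any(c(f, g) > 1)) {
    stop("fractions must lie in [0, 1]")
  }
  (f / (1 - f)) / (g / (1 - g))
}

#' Odds ratios for all three channels
#'
#' @param fractions named vector with \code{gcc, nhc, f} (raw model
#'   fractions, i.e. mass with selective propensity above threshold).
#' @return named vector \code{c(gcc, nhc, f)} of odds ratios, each channel
#'   against the mean of the other two.
#' @export
channel_odds <- function(fractions) {
  g <- fractions[["gcc"]]; h <- fractions[["nhc"]]; f <- fractions[["f"]]
  c(gcc = odds_ratio(g, mean(c(h, f))),
    nhc = odds_ratio(h, mean(c(g, f))),
    f = odds_ratio(f, mean(c(g, h))))
}

#' Run the model under an experimental culture condition
#'
#' Test culture I contains tumour cells and secreted factors but no normal
#' cells; it is modelled by zeroing the NHC channel before enumeration.
#' Test culture II contains all three and uses the channels as given.
#'
#' @param cbe a [cbe_tables()] object.
#' @param mode \code{"culture_II"} (default) or \code{"culture_I"}.
#' @param threshold direction threshold in degrees.
#' @return a [ccmen_model()] fit.
#' @export
run_culture_mode <- function(cbe, mode = c("culture_II", "culture_I"),
                             threshold = 45) {
  ccmen_model(cbe, mode = match.arg(mode), threshold = threshold)
}
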