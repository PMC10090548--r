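#' Fit the CCMEN directional-preference model
#'
#' The central constructor. Given per-receptor conditional binding
#' efficiencies towards glioblastoma cells (GCC), normal cells (NHC) and
#' secreted factors (F) — supplied directly, or derived from intrinsic
#' binding scores plus an expression table — it exhaustively enumerates all
#' receptor combinations and factor-binding subclasses, assigns
#' BST-proportional probability mass, classifies every configuration by its
#' selective-propensity angles, and aggregates population fractions, odds
#' ratios, conditional expectations, and the break-even point.
#'
#' @param cbe a [cbe_tables()] object, or \code{NULL} to build one from
#'   \code{bs} + \code{expression}. When both are given the precomputed CBE
#'   table takes precedence.
#' @param bs optional [binding_scores()] object.
#' @param expression optional \code{expression_table} (required with
#'   \code{bs}).
#' @param expr_ccmen nanoparticle-side expression table, defaults to
#'   \code{expression} (the particle carries the tumour membrane).
#' @param mode \code{"culture_II"} (GCC + NHC + F, default) or
#'   \code{"culture_I"} (no normal cells; the NHC channel is zeroed before
#'   enumeration).
#' @param threshold selective-propensity decision threshold in degrees.
#' @param pairing factor-channel pairing passed to [build_cbe_tables()].
#' @return object of class \code{ccmen_model} with components
#'   \code{cbe}, \code{probabilities} (the [class_probabilities()] engine
#'   output), \code{distribution} (per-degree mass, [distribution_over_k()]),
#'   \code{bep}, \code{fractions} (raw, with NNDP),
#'   \code{fractions_redistributed}, \code{odds_ratios}, \code{per_node},
#'   and \code{expectations} ([expectation_tables()]).
#' @examples
#' cbe <- synth_cbe_tables(5, gcc_bias = 3, seed = 1)
#' fit <- ccmen_model(cbe)
#' fit
#' coef(fit)
#' @export
ccmen_model <- function(cbe = NULL, bs = NULL, expression = NULL,
                        expr_ccmen = expression,
                        mode = c("culture_II", "culture_I"), threshold = 45,
                        pairing = c("cognate", "max_over_factors")) {
  mode <- match.arg(mode)
  pairing <- match.arg(pairing)
  if (is.null(cbe)) {
    if (is.null(bs) || is.null(expression)) {
      stop("supply either a CBE table or binding scores plus an expression table")
    }
    cbe <- build_cbe_tables(bs, expression, expr_ccmen = expr_ccmen,
                            pairing = pairing)
  } else if (!is.null(bs)) {
    message("both CBE tables and binding scores supplied; using the CBE tables")
  }
  cbe <- validate_cbe(cbe)
  if (mode == "culture_I") cbe <- zero_channel(cbe, "nhc")
  pt <- class_probabilities(cbe, threshold = threshold)
  dist <- distribution_over_k(pt)
  pop <- population_fractions(pt)
  fr <- pop$fractions
  structure(list(call = match.call(), cbe = cbe, n = pt$n, mode = mode,
                 threshold = threshold, probabilities = pt,
                 distribution = dist,
                 bep = break_even_point(dist),
                 fractions = fr,
                 fractions_redistributed = redistribute_nndp(fr),
                 odds_ratios = channel_odds(fr),
                 per_node = pop$per_node,
                 expectations = expectation_tables(pt)),
            class = "ccmen_model")
}

#' @export
print.ccmen_model <- function(x, ...) {
  cfg <- x$probabilities$config
  cat("CCMEN directional-preference model\n")
  cat("  mode: ", x$mode, ", n = ", x$n, " receptors, threshold ",
      x$threshold, " degrees\n", sep = "")
  cat("  ", sum(choose(x$n, seq_len(x$n))), " combinations, ",
      nrow(cfg), " (combination, k_f) pairs\n", sep = "")
  pct <- function(v) paste0(round(100 * v), "%")
  fr <- x$fractions
  rd <- x$fractions_redistributed
  cat("  raw fractions:          GCC ", pct(fr[["gcc"]]), "  NHC ",
      pct(fr[["nhc"]]), "  F ", pct(fr[["f"]]), "  NNDP ",
      pct(fr[["nndp"]]), "\n", sep = "")
  cat("  NNDP redistributed:     GCC ", pct(rd[["gcc"]]), "  NHC ",
      pct(rd[["nhc"]]), "  F ", pct(rd[["f"]]), "\n", sep = "")
  odd <- round(x$odds_ratios, 2)
  cat("  odds ratios:            GCC ", odd[["gcc"]], "  NHC ",
      odd[["nhc"]], "  F ", odd[["f"]], "\n", sep = "")
  cat("  break-even point (BEP): ",
      if (is.na(x$bep)) "none" else x$bep, "\n", sep = "")
  invisible(x)
}

#' @export
coef.ccmen_model <- function(object, redistributed = FALSE, ...) {
  if (redistributed) object$fractions_redistributed else object$fractions
}

#' @export
summary.ccmen_model <- function(object, ...) {
  structure(list(model = object), class = "summary.ccmen_model")
}

#' @export
print.summary.ccmen_model <- function(x, ...) {
  m <- x$model
  print(m)
  cat("\nPer-degree conditional probabilities (CP_k):\n")
  d <- m$distribution
  print(data.frame(k = d$k, cp_gcc = round(d$cp_gcc, 4),
                   cp_nhc = round(d$cp_nhc, 4), cp_f = round(d$cp_f, 4),
                   mass = round(d$p_total, 4)), row.names = FALSE)
  invisible(x)
}

#' Plot the per-degree probability profile of a fitted model
#'
#' Draws the conditional probabilities \eqn{CP_k} of the three channels
#' against the degree of interaction \code{k}, with the absolute per-degree
#' mass as bars and the break-even point marked.
#'
#' @param x a \code{ccmen_model}.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.ccmen_model <- function(x, ...) {
  d <- x$distribution
  graphics::barplot(d$p_total, names.arg = d$k, col = "grey90",
                    border = NA, ylim = c(0, 1),
                    xlab = "degree of interaction k",
                    ylab = "probability")
  at <- seq(0.7, by = 1.2, length.out = nrow(d))
  graphics::matlines(at, cbind(d$cp_gcc, d$cp_nhc, d$cp_f),
                     lty = 1, lwd = 2,
                     col = c("firebrick", "steelblue", "darkgreen"), ...)
  if (!is.na(x$bep)) {
    graphics::abline(v = at[match(x$bep, d$k)], lty = 3)
    graphics::mtext(paste("BEP =", x$bep), side = 3, adj = 1, cex = 0.8)
  }
  graphics::legend("topright", bty = "n", lwd = 2,
                   col = c("firebrick", "steelblue", "darkgreen"),
                   legend = c("CP GCC", "CP NHC", "CP F"))
  invisible(x)
}
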