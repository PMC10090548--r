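#' Probability-weighted expected value
#'
#' Expectation of a discrete variable under (possibly unnormalized)
#' nonnegative weights; weights are renormalized to sum to one within the
#' conditioning cell before averaging.
#'
#' @param values numeric outcomes.
#' @param probs nonnegative weights, same length, not all zero.
#' @return the expectation \eqn{\sum_i p_i x_i}.
#' @examples
#' expected_value(c(4, 8), c(0.25, 0.75)) # 7
#' @export
expected_value <- function(values, probs) {
  if (length(values) != length(probs)) stop("values and probs lengths differ")
  if (anyNA(probs) || any(probs < 0)) stop("probs must be nonnegative")
  s <- sum(probs)
  if (s <= 0) stop("undefined expectation: all probabilities are zero")
  sum(values * probs / s)
}

#' Conditional expectations of binding strength and selective propensity
#'
#' For every channel, degree \code{k} and factor degree \code{k_f}, computes
#' the expectation of the channel binding strength and of the channel
#' selective propensity over the combinations in that (k, k_f) cell, using
#' the cell-renormalized conditional probabilities; also the per-degree
#' overall expectation (over all k_f). Cells with no probability mass are
#' omitted.
#'
#' @param pt a [class_probabilities()] result.
#' @return data frame with columns \code{channel}, \code{k}, \code{k_f}
#'   (\code{NA} for the per-degree overall row), \code{e_bst}, \code{e_sp}
#'   (degrees).
#' @export
expectation_tables <- function(pt) {
  stopifnot(inherits(pt, "config_probabilities"))
  cfg <- pt$config
  rows <- list()
  for (channel in c("GCC", "NHC", "F")) {
    col <- c(GCC = "gcc", NHC = "nhc", F = "f")[[channel]]
    w_all <- cfg[[paste0("p_", col)]]
    bst <- cfg[[paste0("bst_", col)]]
    sp <- cfg[[paste0("sp_", col)]]
    for (k in seq_len(pt$n)) {
      in_k <- cfg$k == k
      for (kf in c(NA, 0:k)) {
        sel <- if (is.na(kf)) in_k else in_k & cfg$k_f == kf
        w <- w_all[sel]
        if (sum(w) <= 0) next
        keep <- w > 0
        rows[[length(rows) + 1L]] <- data.frame(
          channel = channel, k = k, k_f = kf,
          e_bst = expected_value(bst[sel][keep], w[keep]),
          e_sp = expected_value(sp[sel][keep], w[keep]),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Break-even point of a per-degree probability profile
#'
#' The break-even point (BEP) is the smallest degree of interaction \code{k}
#' at which the conditional probability of tumour-cell binding falls below
#' either competing channel, i.e. \eqn{CP_{k,GCC} < \max(CP_{k,NHC},
#' CP_{k,F})}. A larger BEP means the nanoparticle keeps its tumour
#' preference up to higher-order interactions, so BEP serves as a targeting
#' quality scale. When tumour binding never drops below the competition the
#' BEP is undefined (\code{NA}, reported as \code{"none"}).
#'
#' @param dist a data frame with columns \code{k, cp_gcc, cp_nhc, cp_f}
#'   (e.g. from [distribution_over_k()]), or a \code{ccmen_model}.
#' @return integer degree, or \code{NA_integer_} when there is no crossing.
#' @examples
#' d <- data.frame(k = 1:4, cp_gcc = c(.6, .5, .3, .2),
#'                 cp_nhc = .1, cp_f = c(.3, .4, .6, .7))
#' break_even_point(d) # 3
#' @export
break_even_point <- function(dist) {
  if (inherits(dist, "ccmen_model")) dist <- dist$distribution
  req <- c("k", "cp_gcc", "cp_nhc", "cp_f")
  if (!all(req %in% names(dist))) {
    stop("dist must have columns ", paste(req, collapse = ", "))
  }
  dist <- dist[order(dist$k), ]
  comp <- pmax(dist$cp_nhc, dist$cp_f)
  hit <- which(!is.na(dist$cp_gcc) & !is.na(comp) & dist$cp_gcc < comp)
  if (length(hit) == 0L) NA_integer_ else as.integer(dist$k[hit[1L]])
}
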