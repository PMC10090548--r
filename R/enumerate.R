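#' Number of receptor combinations of a given degree
#'
#' How many distinct sets of \code{k} surface proteins can engage
#' simultaneously out of \code{n}: the binomial coefficient
#' \eqn{n! / ((n-k)!\,k!)}.
#'
#' @param n total number of receptor types.
#' @param k degree of interaction, \code{1 <= k <= n}.
#' @return integer count.
#' @examples
#' count_combinations(11, 2) # 55
#' @export
count_combinations <- function(n, k) {
  if (any(k < 1) || any(k > n)) stop("k must satisfy 1 <= k <= n")
  choose(n, k)
}

#' Enumerate all interaction configurations
#'
#' Streams every (combination, factor degree, branch) triple exactly once:
#' a combination of degree \code{k} with \code{k_f < k} factor-bound members
#' appears on both cell branches (GCC and NHC, which are mutually exclusive
#' targets), while the fully factor-bound case \code{k_f = k} is a single
#' F-only configuration, not duplicated per cell branch.
#'
#' @param n number of receptor types.
#' @return data frame with columns \code{comb} (codes joined by "-"),
#'   \code{k}, \code{k_f}, \code{branch} (\code{GCC}/\code{NHC}/
#'   \code{F_only}), ordered by k ascending, combination lexicographic,
#'   k_f ascending.
#' @examples
#' nrow(enumerate_configurations(2)) # 11
#' @export
enumerate_configurations <- function(n) {
  if (n < 1) stop("n must be at least 1")
  parts <- list()
  for (k in seq_len(n)) {
    m <- utils::combn(n, k)
    labels <- apply(m, 2, paste, collapse = "-")
    for (i in seq_along(labels)) {
      kf <- 0:k
      cell <- kf[kf < k]
      parts[[length(parts) + 1L]] <- data.frame(
        comb = labels[i], k = k,
        k_f = c(rep(cell, each = 2L), k),
        branch = c(rep(c("GCC", "NHC"), length(cell)), "F_only"),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

# per-combination channel sums for all degrees (lexicographic within k)
combination_sums <- function(cbe) {
  n <- nrow(cbe)
  parts <- vector("list", n)
  for (k in seq_len(n)) {
    m <- utils::combn(n, k)
    parts[[k]] <- data.frame(
      comb = apply(m, 2, function(j) paste(cbe$code[j], collapse = "-")),
      k = k,
      sum_gcc = colSums(matrix(cbe$gcc[m], nrow = k)),
      sum_nhc = colSums(matrix(cbe$nhc[m], nrow = k)),
      sum_f = colSums(matrix(cbe$f[m], nrow = k)),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Binding-strength vector of one configuration
#'
#' For a combination of degree \code{k} with \code{k_f} factor-bound members,
#' which members bind factors is unobserved; binding strengths are averaged
#' over all \code{C(k, k_f)} equally likely assignments. By exchangeability
#' this closed form holds: the cell channels carry
#' \code{(k - k_f)/k} of the combination's summed cell CBE and the factor
#' channel \code{k_f/k} of its summed factor CBE.
#'
#' @param codes receptor codes in the combination.
#' @param k_f number of factor-bound members, \code{0 <= k_f <= k}.
#' @param cbe a [cbe_tables()] object.
#' @return named numeric \code{c(bst_gcc, bst_nhc, bst_f)}.
#' @export
configuration_bst <- function(codes, k_f, cbe) {
  cbe <- validate_cbe(cbe)
  k <- length(codes)
  if (k_f < 0 || k_f > k) stop("k_f must lie in 0..k")
  i <- match(codes, cbe$code)
  if (anyNA(i)) stop("unknown receptor code(s): ",
                     paste(codes[is.na(i)], collapse = ", "))
  cell <- (k - k_f) / k
  c(bst_gcc = cell * sum(cbe$gcc[i]),
    bst_nhc = cell * sum(cbe$nhc[i]),
    bst_f = k_f / k * sum(cbe$f[i]))
}

#' Enumerate configurations and assign probability mass
#'
#' The core engine. Every receptor combination of degree \code{k} is expanded
#' over factor degrees \code{k_f = 0..k}; each (combination, k_f) gets its
#' binding-strength triple ([configuration_bst()]), its selective-propensity
#' angles and a direction class. Probability mass is proportional to binding
#' strength: each cell branch (GCC, NHC; only defined while \code{k_f < k})
#' weighs in with its branch BST and every configuration with \code{k_f > 0}
#' adds its factor BST as F-channel mass; the global normalizer \code{Z} is
#' the sum of all weights, so absolute probabilities sum to one.
#'
#' @param cbe a [cbe_tables()] object (or data frame with columns
#'   \code{gcc, nhc, f}).
#' @param threshold direction threshold in degrees (default 45).
#' @return object of class \code{config_probabilities}: a list with
#'   \code{config} (one row per (combination, k_f) with BST, propensity,
#'   direction and per-channel absolute \code{p_*} and within-degree
#'   \code{cp_*} probabilities), \code{n}, \code{Z}, \code{threshold} and the
#'   input \code{cbe}. \code{as.data.frame()} flattens it to the long
#'   (combination, k_f, channel) probability table.
#' @export
class_probabilities <- function(cbe, threshold = 45) {
  cbe <- validate_cbe(cbe)
  n <- nrow(cbe)
  cs <- combination_sums(cbe)
  reps <- cs$k + 1L
  cfg <- cs[rep(seq_len(nrow(cs)), reps), , drop = FALSE]
  cfg$k_f <- sequence(reps) - 1L
  rownames(cfg) <- NULL
  cell <- (cfg$k - cfg$k_f) / cfg$k
  cfg$bst_gcc <- cell * cfg$sum_gcc
  cfg$bst_nhc <- cell * cfg$sum_nhc
  cfg$bst_f <- cfg$k_f / cfg$k * cfg$sum_f
  sp <- selective_propensity(as.matrix(cfg[c("bst_gcc", "bst_nhc", "bst_f")]))
  cfg$sp_gcc <- sp[, 1]; cfg$sp_nhc <- sp[, 2]; cfg$sp_f <- sp[, 3]
  cfg$direction <- classify_direction(sp, threshold)
  # branch masking is implicit: bst_gcc/bst_nhc are 0 at k_f = k and bst_f is
  # 0 at k_f = 0, so the BST columns double as channel weights
  z <- sum(cfg$bst_gcc) + sum(cfg$bst_nhc) + sum(cfg$bst_f)
  if (z <= 0) {
    stop("degenerate model: all conditional binding efficiencies are zero")
  }
  cfg$p_gcc <- cfg$bst_gcc / z
  cfg$p_nhc <- cfg$bst_nhc / z
  cfg$p_f <- cfg$bst_f / z
  per_k <- rowsum(cfg$p_gcc + cfg$p_nhc + cfg$p_f, cfg$k)[, 1]
  tot_k <- per_k[as.character(cfg$k)]
  cfg$cp_gcc <- cfg$p_gcc / tot_k
  cfg$cp_nhc <- cfg$p_nhc / tot_k
  cfg$cp_f <- cfg$p_f / tot_k
  cfg$sum_gcc <- cfg$sum_nhc <- cfg$sum_f <- NULL
  structure(list(config = cfg, n = n, Z = z, threshold = threshold,
                 cbe = cbe),
            class = "config_probabilities")
}

#' @export
print.config_probabilities <- function(x, ...) {
  cat("Configuration probabilities: n =", x$n, "receptors,",
      nrow(x$config), "(combination, k_f) pairs, Z =",
      format(x$Z, digits = 6), "\n")
  invisible(x)
}

#' Long probability table
#'
#' @param x a \code{config_probabilities} object.
#' @param row.names,optional,... ignored (S3 signature).
#' @return data frame with one row per (combination, k_f, channel) carrying
#'   the channel BST, absolute probability and within-degree conditional
#'   probability; only structurally possible rows are emitted (cell branches
#'   require \code{k_f < k}, the factor channel \code{k_f > 0}).
#' @export
as.data.frame.config_probabilities <- function(x, row.names = NULL,
                                               optional = FALSE, ...) {
  cfg <- x$config
  mk <- function(channel, keep, col) {
    data.frame(comb = cfg$comb[keep], k = cfg$k[keep], k_f = cfg$k_f[keep],
               channel = channel,
               bst = cfg[[paste0("bst_", col)]][keep],
               p_abs = cfg[[paste0("p_", col)]][keep],
               cp_within_k = cfg[[paste0("cp_", col)]][keep],
               stringsAsFactors = FALSE)
  }
  out <- rbind(mk("GCC", cfg$k_f < cfg$k, "gcc"),
               mk("NHC", cfg$k_f < cfg$k, "nhc"),
               mk("F", cfg$k_f > 0, "f"))
  rownames(out) <- NULL
  out
}

#' Probability mass by degree of interaction
#'
#' Aggregates the engine's absolute mass per degree \code{k} and channel, and
#' the within-degree conditional probabilities \code{CP_k} (each degree's
#' channel shares sum to one).
#'
#' @param pt a [class_probabilities()] result.
#' @return data frame with columns \code{k}, absolute \code{p_gcc, p_nhc,
#'   p_f, p_total}, and conditional \code{cp_gcc, cp_nhc, cp_f}.
#' @export
distribution_over_k <- function(pt) {
  stopifnot(inherits(pt, "config_probabilities"))
  cfg <- pt$config
  agg <- function(col) rowsum(cfg[[col]], cfg$k)[, 1]
  out <- data.frame(k = sort(unique(cfg$k)),
                    p_gcc = agg("p_gcc"), p_nhc = agg("p_nhc"),
                    p_f = agg("p_f"))
  out$p_total <- out$p_gcc + out$p_nhc + out$p_f
  out$cp_gcc <- out$p_gcc / out$p_total
  out$cp_nhc <- out$p_nhc / out$p_total
  out$cp_f <- out$p_f / out$p_total
  rownames(out) <- NULL
  out
}
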