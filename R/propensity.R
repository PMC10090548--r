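#' Selective propensity angles of a binding-strength vector
#'
#' The binding strengths of a configuration towards GCC, NHC and F are read
#' as a vector in a 3-D channel space. For each channel the selective
#' propensity is \eqn{S_p = 90^\circ - \theta}, where \eqn{\theta} is the
#' angle between the BST vector and that channel's axis
#' (\eqn{\cos\theta = BST / \lVert BST \rVert}). \eqn{S_p} therefore grows
#' from 0 (orthogonal pull) to 90 degrees (pure pull along the axis), and
#' because the squared direction cosines sum to 1, at most one channel can
#' exceed 45 degrees.
#'
#' @param bst numeric length-3 vector \code{(gcc, nhc, f)} or a 3-column
#'   matrix of such vectors; all entries nonnegative.
#' @return for a vector input, a named numeric vector
#'   \code{c(sp_gcc, sp_nhc, sp_f)} in degrees; for a matrix, a matrix with
#'   those columns. A zero BST vector yields \code{NA} angles (no defined
#'   direction; classified NNDP downstream).
#' @examples
#' selective_propensity(c(1, 0, 0)) # 90, 0, 0
#' selective_propensity(c(1, 1, 1)) # all 35.26 degrees
#' @export
selective_propensity <- function(bst) {
  vec_in <- !is.matrix(bst)
  b <- if (vec_in) matrix(bst, nrow = 1L) else bst
  if (ncol(b) != 3L) stop("bst must have three channels (gcc, nhc, f)")
  if (anyNA(b) || any(b < 0)) stop("binding strengths must be nonnegative")
  r <- sqrt(rowSums(b^2))
  ratio <- b / r                       # direction cosines; 0/0 -> NaN
  sp <- 90 - acos(pmin(ratio, 1)) * 180 / pi
  sp[r == 0, ] <- NA_real_
  colnames(sp) <- c("sp_gcc", "sp_nhc", "sp_f")
  if (vec_in) sp[1L, ] else sp
}

#' Classify a propensity vector by the 45-degree threshold
#'
#' A configuration is directed towards the unique channel whose selective
#' propensity strictly exceeds the threshold; if none does (including the
#' exact-threshold and zero-vector cases) it has no net directional
#' preference (NNDP).
#'
#' @param sp output of [selective_propensity()] (named vector or matrix).
#' @param threshold decision threshold in degrees, strictly between 0 and 90.
#' @return character vector over \code{"GCC"}, \code{"NHC"}, \code{"F"},
#'   \code{"NNDP"}.
#' @export
classify_direction <- function(sp, threshold = 45) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 90) {
    stop("threshold must be a single angle strictly between 0 and 90 degrees")
  }
  s <- if (is.matrix(sp)) sp else matrix(sp, nrow = 1L)
  if (ncol(s) != 3L) stop("sp must have three channels")
  dir <- rep("NNDP", nrow(s))
  labs <- c("GCC", "NHC", "F")
  for (j in 1:3) {
    hit <- !is.na(s[, j]) & s[, j] > threshold
    dir[hit] <- labs[j]
  }
  dir
}
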