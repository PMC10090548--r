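#' Conditional binding efficiency
#'
#' The conditional binding efficiency (CBE) scales an intrinsic binding score
#' (BS, e.g. from protein-protein docking) by the lower of the two partners'
#' native expression levels and the lower of their fold changes:
#' \deqn{CBE = BS \times \min(NEX_{CCMEN}, NEX_{target}) \times
#'             \min(FC_{CCMEN}, FC_{target})}
#' so an interaction can never be more efficient than its scarcer partner
#' allows. All arguments are vectorized.
#'
#' @param bs intrinsic binding score, nonnegative.
#' @param nex_ccmen,nex_target native expression of the surface protein on
#'   the nanoparticle coat and on the target (cell or factor).
#' @param fc_ccmen,fc_target tumour-vs-normal fold change on each side (use 1
#'   for the normal-cell side, which is the fold-change reference).
#' @return nonnegative numeric vector of CBE values.
#' @examples
#' compute_cbe(2, 3, 5, 2, 1.5) # 2 * 3 * 1.5 = 9
#' @export
compute_cbe <- function(bs, nex_ccmen, nex_target, fc_ccmen, fc_target) {
  args <- list(bs, nex_ccmen, nex_target, fc_ccmen, fc_target)
  if (any(vapply(args, function(a) !is.numeric(a) || anyNA(a) || any(a < 0),
                 logical(1)))) {
    stop("all CBE inputs must be numeric and nonnegative")
  }
  bs * pmin(nex_ccmen, nex_target) * pmin(fc_ccmen, fc_target)
}

#' Intrinsic binding score set
#'
#' Container for docking-derived binding scores: homotypic receptor-receptor
#' scores (\code{bs_cell}, one per receptor, the nanoparticle receptor versus
#' the same receptor on a target cell) and the receptor-by-factor score
#' matrix (\code{bs_factor}, native receptor--factor pairs on the diagonal
#' under row-aligned cognate pairing).
#'
#' @param bs_cell nonnegative numeric vector of length n (receptor code order).
#' @param bs_factor nonnegative n x n matrix, rows = receptor codes,
#'   columns = factor codes.
#' @return object of class \code{binding_scores}.
#' @export
binding_scores <- function(bs_cell, bs_factor) {
  bs_cell <- as.numeric(bs_cell)
  bs_factor <- as.matrix(bs_factor)
  n <- length(bs_cell)
  if (!all(dim(bs_factor) == c(n, n))) {
    stop("bs_factor must be an n x n matrix matching length(bs_cell)")
  }
  if (anyNA(bs_cell) || anyNA(bs_factor) ||
      any(bs_cell < 0) || any(bs_factor < 0)) {
    stop("binding scores must be nonnegative")
  }
  structure(list(bs_cell = bs_cell, bs_factor = bs_factor, n = n),
            class = "binding_scores")
}

#' Read binding scores from long-format CSV
#'
#' Expects columns \code{receptor_code,target_code,channel,score} with
#' \code{channel} either \code{"cell"} (homotypic receptor score; target_code
#' ignored) or \code{"factor"} (receptor-vs-factor score).
#'
#' @param path CSV path.
#' @param n number of receptors; inferred from the maximum code when NULL.
#' @return a \code{binding_scores} object (unlisted entries are 0).
#' @export
read_binding_scores <- function(path, n = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("receptor_code", "target_code", "channel", "score")
  if (!all(req %in% names(df))) {
    stop("binding score file must have columns: ", paste(req, collapse = ", "))
  }
  if (is.null(n)) n <- max(df$receptor_code, df$target_code)
  bs_cell <- numeric(n)
  bs_factor <- matrix(0, n, n)
  cell <- df[df$channel == "cell", ]
  bs_cell[cell$receptor_code] <- cell$score
  fac <- df[df$channel == "factor", ]
  bs_factor[cbind(fac$receptor_code, fac$target_code)] <- fac$score
  binding_scores(bs_cell, bs_factor)
}

#' Per-receptor CBE tables for the three channels
#'
#' Builds the GCC, NHC and F conditional-binding-efficiency channels from
#' intrinsic binding scores and expression tables. The nanoparticle carries
#' the tumour cell's membrane, so by default the CCMEN side uses the same
#' expression table as the tumour side. Channel construction:
#' \itemize{
#'   \item GCC: homotypic receptor score with tumour-side nex and fold change
#'     on both sides.
#'   \item NHC: same homotypic score, but the normal cell is the fold-change
#'     reference, so its fold change is fixed at 1.
#'   \item F: receptor-vs-factor score with the factor's nex/fc on the target
#'     side; the cognate factor by default, or the best factor under
#'     \code{pairing = "max_over_factors"}.
#' }
#'
#' @param bs a [binding_scores()] object.
#' @param expression target-side \code{expression_table} (receptors and
#'   factors).
#' @param expr_ccmen nanoparticle-side expression table; defaults to
#'   \code{expression}.
#' @param pairing \code{"cognate"} (default) restricts the factor channel to
#'   native receptor--factor pairs; \code{"max_over_factors"} takes the
#'   maximum CBE over all factors.
#' @return a [cbe_tables()] object.
#' @export
build_cbe_tables <- function(bs, expression, expr_ccmen = expression,
                             pairing = c("cognate", "max_over_factors")) {
  pairing <- match.arg(pairing)
  if (!inherits(bs, "binding_scores")) stop("bs must be a binding_scores object")
  rec <- expr_side(expression, "receptor")
  fac <- expr_side(expression, "factor")
  recc <- expr_side(expr_ccmen, "receptor")
  n <- bs$n
  if (nrow(rec) != n || nrow(recc) != n || nrow(fac) != n) {
    stop("expression tables and binding scores disagree on receptor count")
  }
  gcc <- compute_cbe(bs$bs_cell, recc$nex, rec$nex, recc$fc, rec$fc)
  nhc <- compute_cbe(bs$bs_cell, recc$nex, rec$nex, recc$fc, rep(1, n))
  cognate <- attr(expression, "cognate") %||% seq_len(n)
  # receptor r against factor j: CCMEN receptor expression vs factor expression
  cbe_rf <- function(r, j) {
    compute_cbe(bs$bs_factor[cbind(r, j)], recc$nex[r], fac$nex[j],
                recc$fc[r], fac$fc[j])
  }
  f <- if (pairing == "cognate") {
    vapply(seq_len(n), function(r) cbe_rf(r, cognate[r]), numeric(1))
  } else {
    vapply(seq_len(n), function(r) max(cbe_rf(rep(r, n), seq_len(n))),
           numeric(1))
  }
  cbe_tables(gcc = gcc, nhc = nhc, f = f)
}

#' Three-channel CBE table
#'
#' One nonnegative conditional binding efficiency per receptor per channel
#' (GCC, NHC, F). This is the sole input the enumeration engine needs.
#'
#' @param gcc,nhc,f nonnegative numeric vectors of equal length (receptor
#'   code order).
#' @param code receptor codes; defaults to 1..n.
#' @return data frame of class \code{cbe_tables} with columns
#'   \code{code, gcc, nhc, f}.
#' @export
cbe_tables <- function(gcc, nhc, f, code = seq_along(gcc)) {
  gcc <- as.numeric(gcc); nhc <- as.numeric(nhc); f <- as.numeric(f)
  n <- length(gcc)
  if (length(nhc) != n || length(f) != n) {
    stop("gcc, nhc and f channels must have the same length")
  }
  if (n < 1L) stop("at least one receptor is required")
  if (anyNA(c(gcc, nhc, f)) || any(c(gcc, nhc, f) < 0)) {
    stop("CBE values must be nonnegative")
  }
  out <- data.frame(code = as.integer(code), gcc = gcc, nhc = nhc, f = f)
  out <- out[order(out$code), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cbe_tables", "data.frame")
  out
}

validate_cbe <- function(cbe) {
  if (!inherits(cbe, "cbe_tables")) {
    if (is.data.frame(cbe) && all(c("gcc", "nhc", "f") %in% names(cbe))) {
      cbe <- cbe_tables(cbe$gcc, cbe$nhc, cbe$f,
                        code = cbe$code %||% seq_len(nrow(cbe)))
    } else {
      stop("cbe must be a cbe_tables object (columns code, gcc, nhc, f)")
    }
  }
  cbe
}

#' Read one CBE channel from file
#'
#' Accepts the single-column per-receptor layout (one CBE per row in code
#' order, header optional) or a full receptor-by-factor matrix, which is
#' reduced to one value per receptor by its cognate diagonal (default) or
#' its row maximum.
#'
#' @param path CSV path.
#' @param n expected number of receptors; checked when supplied.
#' @param pairing matrix reduction rule: \code{"cognate"} (diagonal) or
#'   \code{"max_over_factors"} (row maximum).
#' @return numeric vector of CBE values.
#' @export
read_cbe_channel <- function(path, n = NULL,
                             pairing = c("cognate", "max_over_factors")) {
  pairing <- match.arg(pairing)
  if (!file.exists(path)) stop("CBE file not found: ", path)
  first <- strsplit(readLines(path, n = 1L), ",")[[1]]
  has_header <- anyNA(suppressWarnings(as.numeric(first)))
  df <- utils::read.csv(path, header = has_header)
  m <- as.matrix(df)
  if (!is.numeric(m) || anyNA(m)) stop("CBE file must be fully numeric: ", path)
  vals <- if (ncol(m) == 1L) {
    as.numeric(m)
  } else if (nrow(m) == ncol(m)) {
    if (pairing == "cognate") diag(m) else apply(m, 1, max)
  } else {
    stop("CBE file must be a single column or a square matrix: ", path)
  }
  if (!is.null(n) && length(vals) != n) {
    stop("CBE file ", path, " has ", length(vals), " rows, expected ", n)
  }
  if (any(vals < 0)) stop("CBE values must be nonnegative: ", path)
  vals
}

#' Read the three channel files (cmcc.csv / cmnc.csv / cmf.csv layout)
#'
#' @param path_gcc,path_nhc,path_f per-channel CBE files.
#' @inheritParams read_cbe_channel
#' @return a [cbe_tables()] object.
#' @export
read_cbe_tables <- function(path_gcc, path_nhc, path_f, n = NULL,
                            pairing = c("cognate", "max_over_factors")) {
  pairing <- match.arg(pairing)
  gcc <- read_cbe_channel(path_gcc, n = n, pairing = pairing)
  nhc <- read_cbe_channel(path_nhc, n = length(gcc), pairing = pairing)
  f <- read_cbe_channel(path_f, n = length(gcc), pairing = pairing)
  cbe_tables(gcc = gcc, nhc = nhc, f = f)
}

#' Write one CBE channel as a single-column CSV
#'
#' @param values numeric vector of CBE values.
#' @param path output path.
#' @export
write_cbe_channel <- function(values, path) {
  writeLines(c("cbe", as.character(values)), path)
  invisible(path)
}

#' Write all three channels in the cmcc/cmnc/cmf layout
#'
#' @param cbe a \code{cbe_tables} object.
#' @param dir output directory (created if missing).
#' @return invisibly, the three file paths.
#' @export
write_cbe_tables <- function(cbe, dir) {
  cbe <- validate_cbe(cbe)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("cmcc.csv", "cmnc.csv", "cmf.csv"))
  write_cbe_channel(cbe$gcc, paths[1])
  write_cbe_channel(cbe$nhc, paths[2])
  write_cbe_channel(cbe$f, paths[3])
  invisible(paths)
}

#' Zero out one channel
#'
#' Replaces one channel of a CBE table with zeros and leaves the others
#' untouched. Supplying a zero NHC channel reproduces the test-culture-I
#' condition (tumour cells and factors only, no normal cells present).
#'
#' @param cbe a \code{cbe_tables} object.
#' @param channel one of \code{"gcc"}, \code{"nhc"}, \code{"f"}.
#' @return the modified \code{cbe_tables}.
#' @export
zero_channel <- function(cbe, channel = c("nhc", "gcc", "f")) {
  channel <- match.arg(channel)
  cbe <- validate_cbe(cbe)
  cbe[[channel]] <- rep(0, nrow(cbe))
  cbe
}
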