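#' Read a receptor/factor expression table
#'
#' Loads a comma-separated expression table with one row per gene and columns
#' \code{gene}, \code{role} (\code{"receptor"} or \code{"factor"}),
#' \code{nex} (native expression in the normal tissue, arbitrary units) and
#' \code{fc} (tumour-vs-normal fold change). Optional columns: \code{code}
#' (1..n numeric code within each role; assigned from row order when absent)
#' and \code{rnx} (expression relative to the baseline gene). \code{rnx} is
#' always recomputed from \code{nex}; a supplied \code{rnx} that disagrees
#' with the recomputed value by more than \code{rnx_tol} (relative) triggers a
#' warning, not an error, because published tables are typically rounded at
#' the last digit.
#'
#' @param path path to a delimited text file (comma-separated, header row).
#' @param baseline baseline gene symbol for relative expression; default is
#'   the secreted factor with the minimum \code{nex}.
#' @param rnx_tol relative tolerance before a supplied \code{rnx} column is
#'   flagged as inconsistent.
#' @return an object of class \code{expression_table} (a data frame with
#'   attributes \code{baseline_gene} and \code{cognate}).
#' @seealso [gbm_expression()] for the packaged glioblastoma panel,
#'   [compute_relative_expression()].
#' @export
read_expression_table <- function(path, baseline = NULL, rnx_tol = 0.01) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_expression_table(df, baseline = baseline, rnx_tol = rnx_tol)
}

#' Validate a data frame as an expression table
#'
#' @param df data frame with columns \code{gene}, \code{role}, \code{nex},
#'   \code{fc}; optionally \code{code} and \code{rnx}.
#' @inheritParams read_expression_table
#' @param cognate optional integer vector pairing receptor code \code{i} with
#'   factor code \code{cognate[i]} (a bijection); default is row alignment
#'   (receptor \code{i} pairs with factor \code{i}).
#' @return an \code{expression_table}.
#' @export
as_expression_table <- function(df, baseline = NULL, rnx_tol = 0.01,
                                cognate = NULL) {
  req <- c("gene", "role", "nex", "fc")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0L) {
    stop("expression table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (!all(df$role %in% c("receptor", "factor"))) {
    stop("role must be 'receptor' or 'factor'")
  }
  if (!is.numeric(df$nex) || anyNA(df$nex) || any(df$nex < 0)) {
    stop("nex must be numeric and nonnegative")
  }
  if (!is.numeric(df$fc) || anyNA(df$fc) || any(df$fc <= 0)) {
    stop("fc must be numeric and positive")
  }
  n_rec <- sum(df$role == "receptor")
  n_fac <- sum(df$role == "factor")
  if (n_rec < 1L || n_rec != n_fac) {
    stop("receptor and factor counts must be equal and nonzero (got ",
         n_rec, " receptors, ", n_fac, " factors)")
  }
  if (is.null(df$code)) {
    df$code <- stats::ave(seq_len(nrow(df)), df$role, FUN = seq_along)
  }
  for (role in c("receptor", "factor")) {
    codes <- sort(df$code[df$role == role])
    if (!identical(as.integer(codes), seq_len(n_rec))) {
      stop(role, " codes must be 1..n with no gaps")
    }
  }
  supplied_rnx <- df$rnx
  out <- compute_relative_expression(df, baseline = baseline)
  if (!is.null(supplied_rnx)) {
    rel <- abs(supplied_rnx - out$rnx) / ifelse(out$rnx == 0, 1, out$rnx)
    bad <- which(rel > rnx_tol)
    if (length(bad) > 0L) {
      warning("supplied rnx disagrees with nex/nex(baseline) beyond ",
              rnx_tol * 100, "% for: ",
              paste(out$gene[bad], collapse = ", "))
    }
  }
  if (is.null(cognate)) cognate <- seq_len(n_rec)
  if (!identical(sort(as.integer(cognate)), seq_len(n_rec))) {
    stop("cognate pairing must be a bijection over factor codes 1..n")
  }
  attr(out, "cognate") <- as.integer(cognate)
  out
}

#' Relative expression against a baseline gene
#'
#' Recomputes the \code{rnx} column as \code{nex / nex(baseline)}; the
#' baseline row gets \code{rnx = 1}. The default baseline is the secreted
#' factor with the minimum native expression, the convention used when all
#' levels are reported relative to the least-expressed factor.
#'
#' @param x an \code{expression_table} or a data frame with \code{gene},
#'   \code{role}, \code{nex} columns.
#' @param baseline baseline gene symbol; \code{NULL} picks the minimum-nex
#'   factor (minimum-nex record if there are no factor rows).
#' @return \code{x} with \code{rnx} recomputed and attribute
#'   \code{baseline_gene} set.
#' @examples
#' tab <- gbm_expression()
#' tab <- compute_relative_expression(tab, baseline = "IL-13")
#' tab$rnx[tab$gene == "EGFR"] # 40
#' @export
compute_relative_expression <- function(x, baseline = NULL) {
  if (!is.data.frame(x)) stop("x must be a data frame")
  if (is.null(baseline)) {
    pool <- if (any(x$role == "factor")) x[x$role == "factor", ] else x
    baseline <- pool$gene[which.min(pool$nex)]
  }
  i <- match(baseline, x$gene)
  if (is.na(i)) stop("baseline gene not found in table: ", baseline)
  b <- x$nex[i]
  if (b <= 0) stop("baseline gene '", baseline, "' has nonpositive nex")
  x$rnx <- x$nex / b
  attr(x, "baseline_gene") <- baseline
  class(x) <- unique(c("expression_table", class(x)))
  x
}

#' Packaged glioblastoma receptor/factor expression panel
#'
#' Eleven receptor--factor pairs curated for glioblastoma targeting
#' (PDGFRA/PDGF, TGFB2R/TGF, EGFR/EGF, MetR/HGF, IL4R/IL-4, IL-13R/IL-13,
#' Tfr2/Tf, Kdr/VEGF, FGFR1/FGF2, PLAUR/PLAU, ITGA2B/TNC), with normal-brain
#' native expression (\code{nex}, Human Protein Atlas / GEO derived),
#' expression relative to the IL-13 baseline (\code{rnx}) and
#' glioblastoma-vs-normal fold change (\code{fc}, GEO series GSE147352).
#'
#' @return an \code{expression_table} with 11 receptors and 11 factors,
#'   baseline IL-13, cognate pairing by row alignment.
#' @examples
#' panel <- gbm_expression()
#' subset(panel, gene == "Tfr2")$rnx # 4.5
#' @export
gbm_expression <- function() {
  path <- system.file("extdata", "gbm_expression.csv", package = "ccmen")
  read_expression_table(path, baseline = "IL-13")
}

# role-side accessors, rows ordered by code
expr_side <- function(x, role) {
  s <- x[x$role == role, , drop = FALSE]
  s[order(s$code), , drop = FALSE]
}

#' @export
print.expression_table <- function(x, ...) {
  cat("Expression table: ", sum(x$role == "receptor"), " receptor/factor pairs",
      ", baseline ", attr(x, "baseline_gene") %||% "<unset>", "\n", sep = "")
  print.data.frame(x, ...)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
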