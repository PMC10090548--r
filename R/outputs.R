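#' Write the tabular output families of a fitted model
#'
#' Emits the full CSV family for a fitted [ccmen_model()]:
#' \itemize{
#'   \item \code{BST_k_GCC/NHC/F.csv} — binding strengths per combination
#'     (\code{Prot_comb}, receptor codes joined by \code{"-"}) and factor
#'     degree (\code{BST@kf=N}), one file per degree \code{k}.
#'   \item \code{P_k_GCC/NHC/F.csv} — absolute binding probabilities
#'     (\code{P@kf=N}).
#'   \item \code{SP_k_GCC/NHC/F.csv} — selective propensities in degrees
#'     (\code{Sp_avg}, \code{Sp@kf=N}).
#'   \item \code{BST@k_interactions.csv}, \code{P@K_interactions.csv},
#'     \code{SP@K_interactions.csv} — per-degree totals, rows GCC, NHC, F.
#'   \item \code{EBST_k_*.csv}, \code{ESP_k_*.csv} and their
#'     \code{*_k_interactions.csv} summaries — conditional expected binding
#'     strength and selective propensity per (k, k_f) cell and per degree.
#'   \item \code{summary.json} — headline fractions (raw and
#'     NNDP-redistributed), odds ratios, BEP and the per-degree table at
#'     full precision.
#' }
#' Numeric cells in the CSVs are formatted to a fixed number of significant
#' digits so repeated runs on identical inputs are byte-identical.
#'
#' @param model a fitted \code{ccmen_model}.
#' @param dir output directory (created if missing).
#' @param digits significant digits for CSV cells.
#' @return invisibly, the output directory.
#' @export
write_model_outputs <- function(model, dir, digits = 6) {
  stopifnot(inherits(model, "ccmen_model"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- model$probabilities$config
  n <- model$n
  fmt <- function(x) ifelse(is.na(x), "NA",
                            formatC(x, digits = digits, format = "g"))
  wcsv <- function(df, file) {
    utils::write.csv(df, file.path(dir, file), row.names = FALSE,
                     quote = FALSE)
  }
  fmt_block <- function(m) {
    out <- as.data.frame(matrix(fmt(as.matrix(m)), nrow = nrow(m)),
                         stringsAsFactors = FALSE)
    out
  }
  channels <- c(GCC = "gcc", NHC = "nhc", F = "f")

  # per-degree wide layout: rows = combinations, columns = k_f
  wide <- function(sub, col, k) {
    combs <- unique(sub$comb)
    m <- matrix(NA_real_, length(combs), k + 1L)
    m[cbind(match(sub$comb, combs), sub$k_f + 1L)] <- sub[[col]]
    list(combs = combs, m = m)
  }
  for (k in seq_len(n)) {
    sub <- cfg[cfg$k == k, , drop = FALSE]
    for (ch in names(channels)) {
      co <- channels[[ch]]
      for (fam in c("BST", "P", "SP")) {
        col <- switch(fam, BST = paste0("bst_", co), P = paste0("p_", co),
                      SP = paste0("sp_", co))
        w <- wide(sub, col, k)
        block <- fmt_block(w$m)
        prefix <- switch(fam, BST = "BST@kf=", P = "P@kf=", SP = "Sp@kf=")
        if (fam == "SP") {
          avg <- rowMeans(w$m, na.rm = TRUE)
          df <- cbind(data.frame(Prot_comb = w$combs,
                                 Sp_avg = fmt(avg),
                                 stringsAsFactors = FALSE), block)
          names(df) <- c("Prot_comb", "Sp_avg", paste0(prefix, 0:k))
        } else {
          df <- cbind(data.frame(Prot_comb = w$combs,
                                 stringsAsFactors = FALSE), block)
          names(df) <- c("Prot_comb", paste0(prefix, 0:k))
        }
        wcsv(df, paste0(fam, "_", k, "_", ch, ".csv"))
      }
    }
  }

  # per-degree totals, rows GCC / NHC / F
  interactions <- function(value_fun, file) {
    m <- matrix(unlist(lapply(unname(channels), value_fun)),
                nrow = 3L, byrow = TRUE)
    df <- cbind(data.frame(channel = names(channels),
                           stringsAsFactors = FALSE), fmt_block(m))
    names(df) <- c("channel", paste0("k=", seq_len(n)))
    wcsv(df, file)
  }
  ksum <- function(col) rowsum(cfg[[col]], cfg$k)[, 1]
  interactions(function(co) ksum(paste0("bst_", co)), "BST@k_interactions.csv")
  interactions(function(co) ksum(paste0("p_", co)), "P@K_interactions.csv")
  # propensity of the per-degree total BST vector
  tot <- cbind(ksum("bst_gcc"), ksum("bst_nhc"), ksum("bst_f"))
  sp_tot <- selective_propensity(tot)
  interactions(function(co) sp_tot[, paste0("sp_", co)],
               "SP@K_interactions.csv")

  # conditional expectations
  ex <- model$expectations
  for (ch in names(channels)) {
    sub <- ex[ex$channel == ch, , drop = FALSE]
    for (fam in c("EBST", "ESP")) {
      val <- if (fam == "EBST") sub$e_bst else sub$e_sp
      m <- matrix(NA_real_, n, n + 2L)  # cols: overall, kf = 0..n
      ov <- is.na(sub$k_f)
      if (any(ov)) m[cbind(sub$k[ov], rep(1L, sum(ov)))] <- val[ov]
      if (any(!ov)) m[cbind(sub$k[!ov], sub$k_f[!ov] + 2L)] <- val[!ov]
      df <- cbind(data.frame(k = seq_len(n)), fmt_block(m))
      label <- if (fam == "EBST") "EBST" else "SP"
      names(df) <- c("k", paste0(label, "_Overall"),
                     paste0(label, "@kf=", 0:n))
      wcsv(df, paste0(fam, "_k_", ch, ".csv"))
    }
  }
  overall <- function(ch, field) {
    sub <- ex[ex$channel == ch & is.na(ex$k_f), , drop = FALSE]
    out <- rep(NA_real_, n)
    out[sub$k] <- sub[[field]]
    out
  }
  interactions(function(co) {
    overall(names(channels)[channels == co], "e_bst")
  }, "EBST_k_interactions.csv")
  interactions(function(co) {
    overall(names(channels)[channels == co], "e_sp")
  }, "ESP_k_interactions.csv")

  summ <- list(
    mode = model$mode,
    n = model$n,
    threshold = model$threshold,
    fractions = as.list(model$fractions),
    fractions_redistributed = as.list(model$fractions_redistributed),
    odds_ratios = as.list(model$odds_ratios),
    bep = if (is.na(model$bep)) "none" else model$bep,
    per_k = model$distribution)
  jsonlite::write_json(summ, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(dir)
}

#' Read back a package-written output CSV
#'
#' @param path path to a CSV written by [write_model_outputs()].
#' @return data frame with original (unmangled) column names.
#' @export
read_output_csv <- function(path) {
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Run the full pipeline from input files to the output directory
#'
#' Loads per-channel CBE files (cmcc/cmnc/cmf layout) or binding scores plus
#' an expression table, fits [ccmen_model()], and writes every tabular output
#' family plus \code{summary.json}; optionally renders the diagnostic plots.
#' Precomputed CBE files take precedence when both input styles are given.
#'
#' @param cbe_gcc,cbe_nhc,cbe_f per-channel CBE file paths.
#' @param bs_file long-format binding score file ([read_binding_scores()]).
#' @param expression an \code{expression_table} or a file path for
#'   [read_expression_table()] (required with \code{bs_file}).
#' @param mode \code{"culture_II"} or \code{"culture_I"}.
#' @param threshold direction threshold in degrees.
#' @param pairing factor-channel pairing rule.
#' @param out output directory.
#' @param plots also render the diagnostic plots into \code{out}.
#' @param digits significant digits for CSV cells.
#' @return invisibly, the fitted \code{ccmen_model}.
#' @export
run_pipeline <- function(cbe_gcc = NULL, cbe_nhc = NULL, cbe_f = NULL,
                         bs_file = NULL, expression = NULL,
                         mode = c("culture_II", "culture_I"), threshold = 45,
                         pairing = c("cognate", "max_over_factors"),
                         out, plots = FALSE, digits = 6) {
  mode <- match.arg(mode)
  pairing <- match.arg(pairing)
  have_cbe <- !is.null(cbe_gcc) || !is.null(cbe_nhc) || !is.null(cbe_f)
  if (have_cbe && (is.null(cbe_gcc) || is.null(cbe_nhc) || is.null(cbe_f))) {
    stop("all three CBE channel files are required (gcc, nhc, f)")
  }
  if (have_cbe) {
    if (!is.null(bs_file)) {
      message("both CBE files and binding scores supplied; using the CBE files")
    }
    cbe <- read_cbe_tables(cbe_gcc, cbe_nhc, cbe_f, pairing = pairing)
    model <- ccmen_model(cbe, mode = mode, threshold = threshold)
  } else {
    if (is.null(bs_file) || is.null(expression)) {
      stop("supply either the three CBE files or bs_file plus expression")
    }
    if (is.character(expression)) {
      expression <- read_expression_table(expression)
    }
    bs <- read_binding_scores(bs_file,
                              n = sum(expression$role == "receptor"))
    model <- ccmen_model(bs = bs, expression = expression, mode = mode,
                         threshold = threshold, pairing = pairing)
  }
  write_model_outputs(model, out, digits = digits)
  if (plots) render_plots(model, out)
  invisible(model)
}
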