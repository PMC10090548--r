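#' Render diagnostic plots for a fitted model
#'
#' Best-effort graphical summaries written as PNG files into \code{dir}:
#' \itemize{
#'   \item \code{distribution.png} — per-degree probability profile
#'     ([plot.ccmen_model()]).
#'   \item \code{propensity.png} — selective propensity towards GCC against
#'     F for every (combination, k_f), coloured by direction class, with the
#'     45-degree decision lines.
#'   \item \code{network.png} — class/subclass tree in a Kamada-Kawai
#'     layout (requires the \pkg{igraph} package): root, degree nodes
#'     \code{k}, leaf nodes \code{(k, k_f)}; node area tracks the fractional
#'     population directed towards GCC and leaf labels read "odds ratio /
#'     fraction".
#' }
#' Any rendering failure degrades to a warning; the model itself is never
#' affected.
#'
#' @param model a fitted \code{ccmen_model}.
#' @param dir output directory.
#' @return invisibly, the paths of the files that were written.
#' @export
render_plots <- function(model, dir) {
  stopifnot(inherits(model, "ccmen_model"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  try_png <- function(file, expr) {
    path <- file.path(dir, file)
    ok <- tryCatch({
      grDevices::png(path, width = 900, height = 700)
      on.exit(grDevices::dev.off(), add = TRUE)
      eval.parent(substitute(expr))
      TRUE
    }, error = function(e) {
      warning("plot '", file, "' failed: ", conditionMessage(e))
      FALSE
    })
    if (ok) written <<- c(written, path)
  }

  try_png("distribution.png", plot(model))

  try_png("propensity.png", {
    cfg <- model$probabilities$config
    cols <- c(GCC = "firebrick", NHC = "steelblue", F = "darkgreen",
              NNDP = "grey60")
    graphics::plot(cfg$sp_gcc, cfg$sp_f, col = cols[cfg$direction],
                   pch = 16, cex = 0.7, xlim = c(0, 90), ylim = c(0, 90),
                   xlab = "Sp towards GCC (degrees)",
                   ylab = "Sp towards F (degrees)")
    graphics::abline(h = model$threshold, v = model$threshold, lty = 2,
                     col = "red")
    graphics::legend("topright", bty = "n", pch = 16, col = cols,
                     legend = names(cols))
  })

  try_png("network.png", {
    if (!requireNamespace("igraph", quietly = TRUE)) {
      stop("igraph not available")
    }
    nodes <- model$per_node
    nodes <- nodes[nodes$mass > 0, , drop = FALSE]
    k_lab <- paste0("k=", sort(unique(nodes$k)))
    leaf_lab <- paste0("k=", nodes$k, ",kf=", nodes$k_f)
    edges <- rbind(cbind("CCMEN", k_lab),
                   cbind(paste0("k=", nodes$k), leaf_lab))
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    vn <- igraph::V(g)$name
    size <- numeric(length(vn))
    for (i in seq_along(vn)) {
      if (vn[i] == "CCMEN") {
        size[i] <- sum(nodes$frac_gcc)
      } else if (grepl(",kf=", vn[i])) {
        j <- match(vn[i], leaf_lab)
        size[i] <- nodes$frac_gcc[j]
      } else {
        kk <- as.integer(sub("k=", "", vn[i]))
        size[i] <- sum(nodes$frac_gcc[nodes$k == kk])
      }
    }
    lab <- vn
    leaf_idx <- match(vn, leaf_lab)
    has_leaf <- !is.na(leaf_idx)
    lab[has_leaf] <- sprintf("%.2g/%.2g", nodes$or_gcc[leaf_idx[has_leaf]],
                             nodes$frac_gcc[leaf_idx[has_leaf]])
    igraph::plot.igraph(g, layout = igraph::layout_with_kk(g),
                        vertex.size = 4 + 60 * sqrt(size),
                        vertex.label = lab, vertex.label.cex = 0.7,
                        vertex.color = "lightsteelblue")
  })

  invisible(written)
}
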