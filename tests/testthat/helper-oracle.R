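# Naive full-materialization oracle for the enumeration engine.
# Deliberately independent of the package implementation: factor assignments
# are enumerated explicitly (no closed form), propensity angles use the
# atan2 elevation form instead of arccos of a direction cosine, and all
# aggregation is done with plain loops.

oracle_model <- function(cbe_df, threshold = 45) {
  n <- nrow(cbe_df)
  g <- cbe_df$gcc; h <- cbe_df$nhc; f <- cbe_df$f
  rows <- list()
  for (size in seq_len(n)) {
    for (comb in utils::combn(n, size, simplify = FALSE)) {
      for (kf in 0:size) {
        assigns <- if (kf == 0) list(integer(0)) else
          utils::combn(size, kf, simplify = FALSE)
        avg <- function(fun) mean(vapply(assigns, fun, numeric(1)))
        bg <- avg(function(a) sum(g[comb[setdiff(seq_len(size), a)]]))
        bh <- avg(function(a) sum(h[comb[setdiff(seq_len(size), a)]]))
        bf <- avg(function(a) sum(f[comb[a]]))
        if (bg^2 + bh^2 + bf^2 == 0) {
          sp <- c(NA_real_, NA_real_, NA_real_)
          dir <- "NNDP"
        } else {
          sp <- c(atan2(bg, sqrt(bh^2 + bf^2)),
                  atan2(bh, sqrt(bg^2 + bf^2)),
                  atan2(bf, sqrt(bg^2 + bh^2))) * 180 / pi
          above <- which(sp > threshold)
          dir <- if (length(above) == 1) c("GCC", "NHC", "F")[above] else "NNDP"
        }
        rows[[length(rows) + 1L]] <- data.frame(
          comb = paste(comb, collapse = "-"), k = size, k_f = kf,
          bst_gcc = bg, bst_nhc = bh, bst_f = bf,
          sp_gcc = sp[1], sp_nhc = sp[2], sp_f = sp[3],
          direction = dir, stringsAsFactors = FALSE)
      }
    }
  }
  cfg <- do.call(rbind, rows)
  # branch-level weights: cell branches only while k_f < k, F only if k_f > 0
  w_gcc <- ifelse(cfg$k_f < cfg$k, cfg$bst_gcc, 0)
  w_nhc <- ifelse(cfg$k_f < cfg$k, cfg$bst_nhc, 0)
  w_f <- ifelse(cfg$k_f > 0, cfg$bst_f, 0)
  z <- sum(w_gcc) + sum(w_nhc) + sum(w_f)
  cfg$p_gcc <- w_gcc / z
  cfg$p_nhc <- w_nhc / z
  cfg$p_f <- w_f / z
  dist <- data.frame(k = seq_len(n), p_gcc = NA_real_, p_nhc = NA_real_,
                     p_f = NA_real_)
  for (k in seq_len(n)) {
    sel <- cfg$k == k
    dist$p_gcc[k] <- sum(cfg$p_gcc[sel])
    dist$p_nhc[k] <- sum(cfg$p_nhc[sel])
    dist$p_f[k] <- sum(cfg$p_f[sel])
  }
  tot <- dist$p_gcc + dist$p_nhc + dist$p_f
  dist$cp_gcc <- dist$p_gcc / tot
  dist$cp_nhc <- dist$p_nhc / tot
  dist$cp_f <- dist$p_f / tot
  mass <- cfg$p_gcc + cfg$p_nhc + cfg$p_f
  fractions <- c(gcc = sum(mass[cfg$direction == "GCC"]),
                 nhc = sum(mass[cfg$direction == "NHC"]),
                 f = sum(mass[cfg$direction == "F"]),
                 nndp = sum(mass[cfg$direction == "NNDP"]))
  bep <- NA_integer_
  for (k in seq_len(n)) {
    if (dist$cp_gcc[k] < max(dist$cp_nhc[k], dist$cp_f[k])) {
      bep <- k
      break
    }
  }
  list(config = cfg, Z = z, dist = dist, fractions = fractions, bep = bep)
}

# oracle conditional expectation for one (channel, k, k_f) cell; kf = NA
# means the per-degree overall cell
oracle_expectation <- function(ora, channel, k, kf = NA) {
  cfg <- ora$config
  col <- c(GCC = "gcc", NHC = "nhc", F = "f")[[channel]]
  sel <- cfg$k == k
  if (!is.na(kf)) sel <- sel & cfg$k_f == kf
  w <- cfg[[paste0("p_", col)]][sel]
  if (sum(w) == 0) return(c(e_bst = NA_real_, e_sp = NA_real_))
  b <- cfg[[paste0("bst_", col)]][sel]
  s <- cfg[[paste0("sp_", col)]][sel]
  keep <- w > 0
  c(e_bst = sum(b[keep] * w[keep]) / sum(w[keep]),
    e_sp = sum(s[keep] * w[keep]) / sum(w[keep]))
}

# random nonnegative CBE table for property tests
random_cbe <- function(n, seed) {
  set.seed(seed)
  cbe_tables(gcc = runif(n, 0, 5), nhc = runif(n, 0, 5), f = runif(n, 0, 5))
}
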