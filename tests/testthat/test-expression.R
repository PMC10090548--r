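test_that("packaged panel loads with recomputed relative expression", {
  tab <- gbm_expression()
  expect_s3_class(tab, "expression_table")
  expect_identical(sum(tab$role == "receptor"), 11L)
  expect_identical(sum(tab$role == "factor"), 11L)
  expect_identical(attr(tab, "baseline_gene"), "IL-13")
  expect_equal(tab$rnx[tab$gene == "Tfr2"], 4.5)
  expect_equal(tab$rnx[tab$gene == "EGFR"], 40)
  expect_equal(tab$rnx[tab$gene == "IL-13"], 1)
  expect_equal(tab$fc[tab$gene == "PDGFRA"], 11.1)
  expect_equal(tab$fc[tab$gene == "TNC"], 78.92)
  # cognate pairing is a bijection over codes
  expect_setequal(attr(tab, "cognate"), 1:11)
})

test_that("relative expression follows the ratio definition", {
  df <- data.frame(gene = c("R1", "R2", "F1", "F2"),
                   role = c("receptor", "receptor", "factor", "factor"),
                   nex = c(4, 8, 2, 6), fc = 1)
  tab <- as_expression_table(df)
  # default baseline is the minimum-nex factor (F1, nex 2)
  expect_identical(attr(tab, "baseline_gene"), "F1")
  expect_equal(tab$rnx, c(2, 4, 1, 3))
  # explicit baseline applied to itself gives 1
  tab2 <- compute_relative_expression(tab, baseline = "F2")
  expect_equal(tab2$rnx[tab2$gene == "F2"], 1)
  expect_equal(tab2$rnx, c(4, 8, 2, 6) / 6)
})

test_that("normalization is idempotent and scale invariant", {
  tab <- gbm_expression()
  again <- compute_relative_expression(tab, baseline = "IL-13")
  expect_equal(again$rnx, tab$rnx)
  scaled <- tab
  scaled$nex <- scaled$nex * 37.5
  rescaled <- compute_relative_expression(scaled, baseline = "IL-13")
  expect_equal(rescaled$rnx, tab$rnx)
})

test_that("loader validates schema and values", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(gene = c("R1", "F1"), role = c("receptor", "factor"),
                   nex = c(1, 2), fc = c(1, 1))
  # missing fc column
  utils::write.csv(df[setdiff(names(df), "fc")], path, row.names = FALSE)
  expect_error(read_expression_table(path), "missing column")
  # negative nex
  bad <- df; bad$nex[1] <- -1
  utils::write.csv(bad, path, row.names = FALSE)
  expect_error(read_expression_table(path), "nonnegative")
  # count mismatch
  bad <- rbind(df, data.frame(gene = "R2", role = "receptor", nex = 1, fc = 1))
  utils::write.csv(bad, path, row.names = FALSE)
  expect_error(read_expression_table(path), "counts")
  # minimal well-formed 2x2 file
  ok <- data.frame(gene = c("R1", "R2", "F1", "F2"),
                   role = rep(c("receptor", "factor"), each = 2),
                   nex = c(1, 2, 0.5, 1), fc = c(2, 3, 1, 1))
  utils::write.csv(ok, path, row.names = FALSE)
  tab <- read_expression_table(path)
  expect_equal(sort(tab$code[tab$role == "receptor"]), 1:2)
  # zero baseline is a division error
  zero <- ok; zero$nex[3:4] <- 0
  utils::write.csv(zero, path, row.names = FALSE)
  expect_error(read_expression_table(path), "nonpositive")
  # unknown baseline gene
  expect_error(compute_relative_expression(tab, baseline = "nope"),
               "not found")
})

test_that("inconsistent supplied rnx warns instead of failing", {
  df <- data.frame(gene = c("R1", "F1"), role = c("receptor", "factor"),
                   nex = c(4, 2), rnx = c(2.9, 1), fc = c(1, 1))
  expect_warning(as_expression_table(df), "rnx disagrees")
  df$rnx <- c(2.0001, 1)
  expect_silent(as_expression_table(df))
})

test_that("write/load round-trips the table", {
  tab <- gbm_expression()
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(as.data.frame(tab), path, row.names = FALSE)
  back <- read_expression_table(path, baseline = "IL-13")
  expect_equal(back$nex, tab$nex)
  expect_equal(back$rnx, tab$rnx)
  expect_equal(back$fc, tab$fc)
  expect_identical(back$gene, tab$gene)
})
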