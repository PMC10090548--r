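test_that("population fractions sum the mass of each direction class", {
  # three identical channels: GCC and NHC propensities coincide, so neither
  # cell channel can ever strictly dominate; mass splits between F (factor-
  # heavy subclasses, pure-F vectors at k_f = k) and NNDP (cell-heavy ones,
  # exactly 45 degrees at k_f = 0)
  sym_pt <- class_probabilities(
    cbe_tables(gcc = c(1, 2), nhc = c(1, 2), f = c(1, 2)))
  sym <- population_fractions(sym_pt)
  expect_equal(unname(sym$fractions[c("gcc", "nhc")]), c(0, 0))
  expect_equal(unname(sym$fractions["f"] + sym$fractions["nndp"]), 1)
  cfg <- sym_pt$config
  expect_true(all(cfg$direction[cfg$k_f == 0] == "NNDP"))
  expect_true(all(cfg$direction[cfg$k_f == cfg$k] == "F"))
  # only the GCC channel nonzero: everything is GCC-directed
  gcc_only <- population_fractions(class_probabilities(
    cbe_tables(gcc = c(1, 2), nhc = c(0, 0), f = c(0, 0))))
  expect_equal(unname(gcc_only$fractions["gcc"]), 1)
  # oracle agreement on random tables
  for (n in c(2, 4)) {
    cbe <- random_cbe(n, 500 + n)
    got <- population_fractions(class_probabilities(cbe))
    expect_equal(got$fractions, oracle_model(cbe)$fractions,
                 tolerance = 1e-12)
    expect_equal(sum(got$fractions), 1, tolerance = 1e-9)
  }
})

test_that("NNDP redistribution conserves mass and splits equally", {
  out <- redistribute_nndp(c(gcc = 0.37, nhc = 0, f = 0.60, nndp = 0.03))
  expect_equal(unname(out), c(0.38, 0.01, 0.61, 0))
  expect_equal(sum(out), 1)
  none <- c(gcc = 0.5, nhc = 0.2, f = 0.3, nndp = 0)
  expect_equal(redistribute_nndp(none), none)
  all_nndp <- redistribute_nndp(c(gcc = 0, nhc = 0, f = 0, nndp = 1))
  expect_equal(unname(all_nndp), c(1 / 3, 1 / 3, 1 / 3, 0))
})

test_that("odds ratios follow the mean-competitor definition", {
  expect_equal(odds_ratio(0.5, 0.25), 3)
  expect_equal(odds_ratio(0.4, 0.4), 1)
  expect_identical(odds_ratio(0.5, 0), Inf)
  expect_true(is.nan(odds_ratio(0, 0)))
  expect_error(odds_ratio(1.2, 0.1), "\\[0, 1\\]")
  # hand computation on an n=2 toy
  cbe <- cbe_tables(gcc = c(5, 6), nhc = c(0.1, 0.2), f = c(0.5, 0.4))
  fr <- population_fractions(class_probabilities(cbe))$fractions
  odds <- channel_odds(fr)
  g <- fr[["gcc"]]; h <- fr[["nhc"]]; f <- fr[["f"]]
  expect_equal(unname(odds["gcc"]),
               (g / (1 - g)) / (mean(c(h, f)) / (1 - mean(c(h, f)))))
  expect_equal(unname(odds["f"]),
               (f / (1 - f)) / (mean(c(g, h)) / (1 - mean(c(g, h)))))
})

test_that("culture I equals culture II with a zeroed NHC channel", {
  cbe <- random_cbe(4, 77)
  m1 <- run_culture_mode(cbe, "culture_I")
  expect_equal(unname(m1$fractions["nhc"]), 0)
  m2 <- ccmen_model(zero_channel(cbe, "nhc"), mode = "culture_II")
  expect_equal(m1$fractions, m2$fractions)
  expect_equal(m1$distribution, m2$distribution)
  expect_identical(m1$bep, m2$bep)
  # mass reallocation on a tumour-biased toy agrees with the oracle in both
  # modes: removing the NHC channel strips NHC-branch mass from the
  # cell-heavy (GCC-directed) configurations, so the factor share grows and
  # the GCC fraction does not increase
  toy <- synth_cbe_tables(4, gcc_bias = 3, noise_cv = 0.2, seed = 3)
  m_full <- ccmen_model(toy)
  m_cult1 <- run_culture_mode(toy, "culture_I")
  expect_equal(m_full$fractions, oracle_model(toy)$fractions,
               tolerance = 1e-12)
  expect_equal(m_cult1$fractions,
               oracle_model(zero_channel(toy, "nhc"))$fractions,
               tolerance = 1e-12)
  expect_lte(m_cult1$fractions[["gcc"]], m_full$fractions[["gcc"]] + 1e-12)
})

test_that("scaling the GCC channel up never decreases the GCC fraction", {
  for (seed in 1:5) {
    cbe <- random_cbe(5, 600 + seed)
    base <- ccmen_model(cbe)$fractions[["gcc"]]
    up <- cbe_tables(gcc = cbe$gcc * 2.5, nhc = cbe$nhc, f = cbe$f)
    expect_gte(ccmen_model(up)$fractions[["gcc"]], base - 1e-12)
  }
})

test_that("per-node table conserves mass and feeds the network labels", {
  cbe <- random_cbe(3, 88)
  pop <- population_fractions(class_probabilities(cbe))
  expect_equal(sum(pop$per_node$mass), 1, tolerance = 1e-9)
  expect_equal(sum(pop$per_node$frac_gcc) + sum(pop$per_node$frac_nhc) +
                 sum(pop$per_node$frac_f) + sum(pop$per_node$frac_nndp),
               1, tolerance = 1e-9)
})
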