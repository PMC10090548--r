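test_that("combination counts are binomial coefficients", {
  expect_equal(count_combinations(11, 2), 55)
  expect_equal(count_combinations(11, 11), 1)
  expect_equal(count_combinations(4, 2), 6)
  expect_error(count_combinations(4, 0), "1 <= k <= n")
  expect_error(count_combinations(4, 5), "1 <= k <= n")
})

test_that("configuration enumeration emits every branch exactly once", {
  cfg <- enumerate_configurations(2)
  expect_equal(nrow(cfg), 11)
  # F-only appears once per combination, at k_f = k
  fo <- cfg[cfg$branch == "F_only", ]
  expect_true(all(fo$k_f == fo$k))
  expect_equal(nrow(fo), 3) # {1}, {2}, {1,2}
  # cell branches exist only while k_f < k, in GCC/NHC pairs
  cell <- cfg[cfg$branch != "F_only", ]
  expect_true(all(cell$k_f < cell$k))
  expect_equal(sum(cell$branch == "GCC"), sum(cell$branch == "NHC"))
  expect_equal(nrow(enumerate_configurations(1)), 3)
  # count identity sum_k C(n,k) (2k+1) for several n
  for (n in 2:6) {
    expect_equal(nrow(enumerate_configurations(n)),
                 sum(choose(n, 1:n) * (2 * (1:n) + 1)))
  }
})

test_that("configuration BST equals the mean over explicit factor assignments", {
  cbe <- cbe_tables(gcc = c(2, 4), nhc = c(1, 5), f = c(1, 3))
  # {A,B}, one factor bound: two assignments, hand-enumerated
  b <- configuration_bst(c(1, 2), 1, cbe)
  expect_equal(unname(b), c(mean(c(2, 4)), mean(c(1, 5)), mean(c(1, 3))))
  # no factor bound: full cell sum, zero factor strength
  b0 <- configuration_bst(c(1, 2), 0, cbe)
  expect_equal(unname(b0), c(6, 6, 0))
  # fully factor bound: zero cell strength
  b2 <- configuration_bst(c(1, 2), 2, cbe)
  expect_equal(unname(b2), c(0, 0, 4))
  # random tables against the exhaustive oracle
  for (seed in 1:3) {
    cbe <- random_cbe(5, seed)
    ora <- oracle_model(cbe)
    for (i in sample(nrow(ora$config), 20)) {
      row <- ora$config[i, ]
      codes <- as.integer(strsplit(row$comb, "-")[[1]])
      got <- configuration_bst(codes, row$k_f, cbe)
      expect_equal(unname(got), c(row$bst_gcc, row$bst_nhc, row$bst_f))
    }
  }
})

test_that("engine matches the brute-force oracle on every configuration", {
  for (n in c(2, 4, 6)) {
    cbe <- random_cbe(n, seed = 100 + n)
    pt <- class_probabilities(cbe)
    ora <- oracle_model(cbe)
    cfg <- pt$config
    key <- paste(cfg$comb, cfg$k_f)
    okey <- paste(ora$config$comb, ora$config$k_f)
    expect_setequal(key, okey)
    m <- match(key, okey)
    for (col in c("bst_gcc", "bst_nhc", "bst_f", "p_gcc", "p_nhc", "p_f",
                  "sp_gcc", "sp_nhc", "sp_f")) {
      expect_equal(cfg[[col]], ora$config[[col]][m], tolerance = 1e-12,
                   info = paste(col, "n =", n))
    }
    expect_identical(cfg$direction, ora$config$direction[m])
    expect_equal(pt$Z, ora$Z)
    d <- distribution_over_k(pt)
    expect_equal(d$cp_gcc, ora$dist$cp_gcc, tolerance = 1e-12)
    expect_equal(d$cp_nhc, ora$dist$cp_nhc, tolerance = 1e-12)
    expect_equal(d$cp_f, ora$dist$cp_f, tolerance = 1e-12)
  }
})

test_that("n=2 toy probabilities equal hand-computed weights over Z", {
  cbe <- cbe_tables(gcc = c(2, 4), nhc = c(1, 1), f = c(1, 3))
  pt <- class_probabilities(cbe)
  cfg <- pt$config
  # hand enumeration: singles contribute cbe sums at kf=0 and factor at kf=1;
  # the pair contributes kf=0,1 cell branches and kf=1,2 factor mass
  z_hand <- (2 + 1 + 1) + (4 + 1 + 3) +          # {1}, {2}
    (6 + 2) + (3 + 1) + (2 + 4)                  # {1,2}: kf=0 cell, kf=1 cell, f mass
  expect_equal(pt$Z, z_hand)
  expect_equal(cfg$p_gcc[cfg$comb == "1" & cfg$k_f == 0], 2 / z_hand)
  expect_equal(cfg$p_f[cfg$comb == "2" & cfg$k_f == 1], 3 / z_hand)
  expect_equal(cfg$p_gcc[cfg$comb == "1-2" & cfg$k_f == 1], 3 / z_hand)
  expect_equal(cfg$p_f[cfg$comb == "1-2" & cfg$k_f == 2], 4 / z_hand)
})

test_that("probability normalization and per-degree sums hold", {
  for (seed in 1:5) {
    cbe <- random_cbe(6, seed)
    pt <- class_probabilities(cbe)
    cfg <- pt$config
    expect_equal(sum(cfg$p_gcc + cfg$p_nhc + cfg$p_f), 1, tolerance = 1e-9)
    d <- distribution_over_k(pt)
    expect_equal(d$cp_gcc + d$cp_nhc + d$cp_f, rep(1, 6), tolerance = 1e-9)
    expect_equal(sum(d$p_total), 1, tolerance = 1e-9)
  }
  # single receptor: everything at k = 1
  d1 <- distribution_over_k(class_probabilities(
    cbe_tables(gcc = 2, nhc = 1, f = 1)))
  expect_equal(d1$p_total, 1)
})

test_that("probabilities and angles are invariant to global CBE scaling", {
  cbe <- random_cbe(5, 42)
  scaled <- cbe_tables(gcc = cbe$gcc * 7.3, nhc = cbe$nhc * 7.3,
                       f = cbe$f * 7.3)
  a <- class_probabilities(cbe)
  b <- class_probabilities(scaled)
  for (col in c("p_gcc", "p_nhc", "p_f", "cp_gcc", "cp_nhc", "cp_f",
                "sp_gcc", "sp_nhc", "sp_f")) {
    expect_equal(a$config[[col]], b$config[[col]], tolerance = 1e-12)
  }
  expect_identical(a$config$direction, b$config$direction)
})

test_that("no configuration carries simultaneous GCC and NHC mass", {
  # structural form of mutual exclusivity: the long probability table has at
  # most one cell-branch row per channel per (comb, k_f), and F-only rows
  # carry no cell mass at all
  pt <- class_probabilities(random_cbe(4, 7))
  long <- as.data.frame(pt)
  cell <- long[long$channel %in% c("GCC", "NHC"), ]
  expect_true(all(cell$k_f < cell$k))
  fonly <- pt$config[pt$config$k_f == pt$config$k, ]
  expect_true(all(fonly$p_gcc == 0 & fonly$p_nhc == 0))
})

test_that("zero channels and degenerate input behave as specified", {
  cbe <- random_cbe(3, 9)
  pt <- class_probabilities(zero_channel(cbe, "nhc"))
  expect_true(all(pt$config$p_nhc == 0))
  expect_error(class_probabilities(cbe_tables(gcc = c(0, 0), nhc = c(0, 0),
                                              f = c(0, 0))),
               "degenerate")
})

test_that("full n=11 enumeration is exhaustive and fast", {
  cbe <- synth_cbe_tables(11, gcc_bias = 3, noise_cv = 0.25, seed = 5)
  t0 <- proc.time()[["elapsed"]]
  model <- ccmen_model(cbe)
  elapsed <- proc.time()[["elapsed"]] - t0
  expect_equal(nrow(model$probabilities$config),
               sum(choose(11, 1:11) * (1:11 + 1)))
  expect_equal(nrow(enumerate_configurations(11)),
               sum(choose(11, 1:11) * (2 * (1:11) + 1)))
  expect_equal(sum(model$fractions), 1, tolerance = 1e-9)
  expect_lt(elapsed, 60)
})
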