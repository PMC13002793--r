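test_that("ROR reproduces the worked examples and the null identity", {
  expect_equal(rorStat(contingencyTable(1, 1, 1, 1))$point, 1.0)
  expect_equal(round(rorStat(contingencyTable(4927, 25, 1, 1))$point, 2), 197.08)
  expect_equal(round(rorStat(contingencyTable(522, 25, 1, 1))$point, 2), 20.88)
})

test_that("PRR reproduces the worked example and sits below the ROR", {
  expect_equal(prrStat(contingencyTable(1, 1, 1, 1))$point, 1.0)
  expect_equal(prrStat(contingencyTable(10, 90, 10, 890))$point, 9.0)
  tabs <- random_tables(200, seed = 21, positive = TRUE)
  for (i in seq_len(nrow(tabs))) {
    x <- tabs[i, ]
    r <- rorStat(x)$point; p <- prrStat(x)$point
    if (!is.finite(r) || !is.finite(p)) next
    if (r > 1) expect_gte(r, p - 1e-12)
  }
})

test_that("chi-square uses the Yates correction", {
  expect_equal(chiSquareStat(contingencyTable(1, 1, 1, 1)), 0)
  expect_equal(chiSquareStat(contingencyTable(20, 10, 5, 65)),
               o_chi2_yates(20, 10, 5, 65), tolerance = 1e-12)
})

test_that("Fisher p equals exhaustive hypergeometric enumeration", {
  expect_equal(fisherExactP(contingencyTable(1, 1, 1, 1)), 1.0)
  tabs <- random_tables(100, seed = 22, max_cell = 15)
  for (i in seq_len(nrow(tabs))) {
    x <- tabs[i, ]
    expect_equal(fisherExactP(x), o_fisher_enum(x[1], x[2], x[3], x[4]),
                 tolerance = 1e-9)
  }
  # monotone in association strength at fixed margins
  p_seq <- vapply(0:5, function(a) fisherExactP(c(5 + a, 10 - a, 10 - a, 75 + a)),
                  numeric(1))
  expect_true(all(diff(p_seq) <= 1e-12))
})

test_that("O/E uses exact Poisson (Garwood) bounds", {
  oe <- oeStat(contingencyTable(1, 1, 1, 1))
  expect_equal(oe$point, 1.0)
  z <- oeStat(c(0, 10, 10, 80))
  expect_equal(z$lo, 0)
  tabs <- random_tables(100, seed = 23, positive = TRUE)
  for (i in seq_len(nrow(tabs))) {
    x <- tabs[i, ]
    got <- oeStat(x)
    ref <- o_oe(x[1], x[2], x[3], x[4])
    expect_equal(c(got$point, got$lo, got$hi), unname(ref), tolerance = 1e-9)
  }
})

test_that("BCPNN normal approximation is centred at independence and monotone", {
  # scaled null table: large-N independence limit
  expect_equal(bcpnnNormal(c(1000, 1000, 1000, 1000))$ic, 0, tolerance = 1e-9)
  ics <- vapply(0:10, function(k)
    bcpnnNormal(c(10 + k, 40 - k, 40 - k, 910 + k))$ic, numeric(1))
  expect_true(all(diff(ics) > 0))
})

test_that("BCPNN MCMC is seeded, null-calibrated, and agrees with the normal form", {
  tab <- contingencyTable(50, 100, 100, 1000)
  m1 <- bcpnnMcmc(tab, 5000, seed = 9)
  m2 <- bcpnnMcmc(tab, 5000, seed = 9)
  expect_identical(m1, m2)
  expect_warning(bcpnnMcmc(tab, 500, seed = 1), "noisy")
  # null tables: ic025 below 0
  expect_lt(bcpnnMcmc(c(20, 180, 200, 1800), 5000, seed = 3)$ic025, 0)
  # agreement with the closed form when all cells are large (>= 20):
  # the IC point agrees to 0.1 bits; the 2.5th percentile only converges
  # in the large-count limit because the two variants put different
  # prior mass on the joint cell
  tabs <- list(c(60, 140, 200, 2000), c(90, 210, 150, 2700),
               c(120, 300, 260, 2600))
  for (x in tabs) {
    bn <- bcpnnNormal(x)
    bm <- bcpnnMcmc(x, 20000, seed = 5)
    expect_lt(abs(bn$ic - bm$ic), 0.1)
  }
  big <- c(800, 2200, 3000, 30000)
  bn <- bcpnnNormal(big)
  bm <- bcpnnMcmc(big, 20000, seed = 6)
  expect_lt(abs(bn$ic025 - bm$ic025), 0.1)
})

test_that("threshold flags implement the signal criteria", {
  null_stats <- c(ror = 1, ror_lo = 0.5, ror_hi = 2, prr = 1, prr_lo = 0.5,
                  prr_hi = 2, chi2 = 0, fisher_p = 1, oe = 1, oe_lo = 0.5,
                  oe_hi = 2, ic_norm = 0, ic_norm_025 = -1, ic_mcmc = 0,
                  ic_mcmc_025 = -1, ebgm = 1, eb05 = 0.5)
  expect_false(any(evaluateThresholds(null_stats, a = 10)))
  pos <- null_stats
  pos[c("ror_lo", "prr_lo", "chi2", "prr", "fisher_p", "oe_lo",
        "ic_norm_025", "ic_mcmc_025", "eb05")] <-
    c(1.2, 1.0, 4, 2, 0.01, 1.1, 0.2, 0.2, 2)
  expect_true(all(evaluateThresholds(pos, a = 5)))
  expect_false(evaluateThresholds(pos, a = 2)[["ror"]])  # a >= 3 gate
})

test_that("signalResult flags are reproducible from the stored statistics", {
  tab <- contingencyTable(30, 70, 50, 2000)
  hp <- ebgmFit(c(30, 5, 2, 8, 1), c(3, 5, 2.2, 7.5, 1.1), seed = 2)
  sr <- signalResult(tab, "X", "E", hyper = hp, mcmc_draws = 2000,
                     mcmc_seed = 4)
  expect_identical(signalFlags(sr),
                   evaluateThresholds(signalStats(sr), cellCounts(tab)[["a"]]))
  expect_true(sr@stats[["ror_lo"]] <= sr@stats[["ror"]])
  expect_true(sr@stats[["ror"]] <= sr@stats[["ror_hi"]])
})

test_that("drug-specificity ratio classifies the worked examples", {
  pd <- data.frame(drug_id = c("X", "Y"), ror = c(50, 4),
                   ror_lo = c(2, 0.5), a = c(5, 3))
  d <- drugSpecificity("ev", pd)
  expect_equal(d@ratio, 12.5)
  expect_true(d@is_specific)

  single <- drugSpecificity("ev", data.frame(drug_id = "X", ror = 8,
                                             ror_lo = 2, a = 4))
  expect_true(is.infinite(single@ratio))
  expect_true(single@is_specific)

  weak <- drugSpecificity("ev", data.frame(drug_id = c("X", "Y"),
                                           ror = c(8, 4), ror_lo = c(2, 0.5),
                                           a = c(5, 3)))
  expect_equal(weak@ratio, 2)
  expect_false(weak@is_specific)
})

test_that("zero cells trigger the continuity correction only where specified", {
  r <- rorStat(c(5, 0, 3, 10))
  expect_true(r$corrected)
  expect_equal(r$point, (5.5 * 10.5) / (0.5 * 3.5))
  p <- prrStat(c(5, 5, 0, 10))
  expect_true(p$corrected)
  # Fisher and O/E stay on raw counts
  expect_equal(fisherExactP(c(5, 0, 3, 10)), o_fisher_enum(5, 0, 3, 10),
               tolerance = 1e-9)
})
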