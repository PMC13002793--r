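test_that("generation is deterministic given config and seed", {
  cfg <- srsConfig(n_reports = 500, seed = 81)
  s1 <- generateSrs(cfg)
  s2 <- generateSrs(cfg)
  expect_identical(reportData(s1), reportData(s2))
  expect_identical(groundTruth(s1), groundTruth(s2))
  # a different seed changes the data
  s3 <- generateSrs(srsConfig(n_reports = 500, seed = 82))
  expect_false(identical(reportData(s1), reportData(s3)))
})

test_that("a certain event appears in every report", {
  cfg <- tto_config(100, shape = 1, scale = 5, seed = 83)
  sim <- generateSrs(cfg)
  expect_true(all(vapply(reportData(sim)$events, function(e)
    "immune effector cell-associated neurotoxicity syndrome" %in% e,
    logical(1))))
  expect_true(all(lengths(reportData(sim)$events) >= 1))
})

test_that("the ground-truth ledger recounts match the emitted reports", {
  cfg <- srsConfig(
    n_reports = 5000, seed = 84,
    signals = data.frame(drug = c("talquetamab", "TCE"),
                         pt = c("dry mouth", "infection"),
                         or = c(20, 2)))
  sim <- generateSrs(cfg)
  df <- reportData(sim)
  tr <- groundTruth(sim)
  for (i in seq_len(nrow(tr$signals))) {
    s <- tr$signals[i, ]
    ex <- df$drug_id == s$drug | df$drug_class == s$drug
    ev <- vapply(df$events, function(e) s$pt %in% e, logical(1))
    expect_equal(s$a, sum(ex & ev))
    expect_equal(s$b, sum(ex & !ev))
    expect_equal(s$c, sum(!ex & ev))
    expect_equal(s$d, sum(!ex & !ev))
  }
})

test_that("planted odds ratios and lifts are recovered at scale", {
  icans <- "immune effector cell-associated neurotoxicity syndrome"
  cfg <- srsConfig(
    n_reports = 100000, seed = 85,
    signals = data.frame(drug = c("talquetamab", "blinatumomab"),
                         pt = c("dry mouth", "tumour flare"),
                         or = c(20, 12)),
    cooc = data.frame(pt_a = "cytokine release syndrome", pt_b = icans,
                      lift = 2.71))
  sim <- generateSrs(cfg)
  tr <- groundTruth(sim)
  # realized ORs within 10% of planted values (both planted ORs >= 10)
  expect_true(all(abs(tr$signals$realized_or / tr$signals$planted_or - 1)
                  < 0.10))
  # realized lift within 5% of planted
  expect_true(all(abs(tr$cooc$realized_lift / tr$cooc$planted_lift - 1)
                  < 0.05))
})

test_that("a null configuration centres the ROR on 1", {
  cfg <- srsConfig(n_reports = 50000, seed = 86)
  sim <- generateSrs(cfg)
  df <- reportData(sim)
  pts <- c("pyrexia", "fatigue", "infection", "anaemia", "neutropenia",
           "headache", "hypotension", "hypoxia")
  tabs <- buildAllPairs(df, list(TCE = byClass("TCE")), pts)
  lr <- vapply(seq_len(nrow(tabs)), function(i)
    log(rorStat(unlist(tabs[i, c("a", "b", "c", "d")]))$point), numeric(1))
  expect_lt(mean(abs(lr)), 0.1)
})

test_that("infeasible planted lifts are rejected naming the pair", {
  expect_error(
    srsConfig(cooc = data.frame(pt_a = "cytokine release syndrome",
                                pt_b = "pyrexia", lift = 50)),
    "infeasible lift")
  expect_error(
    srsConfig(cooc = data.frame(pt_a = rep("pyrexia", 2),
                                pt_b = c("fatigue", "infection"),
                                lift = c(2, 2))),
    "disjoint")
})

test_that("planted blocks reach their pairwise lift target", {
  blocks <- list(list(pts = sprintf("genrl event %02d", 1:5),
                      p = 0.04, lift = 3))
  cfg <- srsConfig(n_reports = 50000, seed = 87, blocks = blocks)
  sim <- generateSrs(cfg)
  tr <- groundTruth(sim)
  expect_equal(tr$blocks$mean_realized_lift, 3, tolerance = 0.15)
  expect_error(srsConfig(blocks = list(list(pts = c("pyrexia", "fatigue"),
                                            p = 0.5, lift = 10))),
               "infeasible block")
})

test_that("injected duplicates are exactly undone by deduplication", {
  sim <- generateSrs(srsConfig(n_reports = 100, seed = 88))
  # rate 0 emits one record per report
  raw0 <- injectDuplicates(sim@reports, version_rate = 0, clone_rate = 0)
  expect_equal(nrow(raw0), 100)
  # 10 versioned cases -> 110 raw records, dedup restores 100
  raw <- injectDuplicates(sim@reports, version_rate = 0.1, clone_rate = 0,
                          seed = 89)
  expect_equal(nrow(raw), 110)
  dd <- deduplicate(raw)
  expect_equal(nrow(dd), attr(raw, "expected_survivors"))
  expect_equal(nrow(dd), 100)
  # content clones removed by the content-key step
  raw2 <- injectDuplicates(sim@reports, version_rate = 0, clone_rate = 0.1,
                           seed = 90)
  dd2 <- deduplicate(raw2)
  aud <- attr(dd2, "audit")
  expect_equal(aud$content_removed, 10)
  expect_equal(nrow(dd2), 100)
  # survivors are the original primary ids
  expect_setequal(dd2$primaryid, reportData(sim)$report_id)
})

test_that("Weibull generating shape lies in the fit's CI at the nominal rate", {
  hits <- 0
  n_seeds <- 100
  for (s in seq_len(n_seeds)) {
    sim <- generateSrs(tto_config(2000, shape = 0.63, scale = 5, seed = 9000 + s))
    f <- weibullFit(extractTto(
      sim@reports, "immune effector cell-associated neurotoxicity syndrome"))
    ci <- shapeParam(f)
    if (ci[["lo"]] <= 0.63 && 0.63 <= ci[["hi"]]) hits <- hits + 1
  }
  expect_gte(hits / n_seeds, 0.90)
})

test_that("missingness rates are honoured", {
  cfg <- srsConfig(n_reports = 5000, seed = 91,
                   missingness = c(age = 0.5, sex = 0.2, weight = 0.8,
                                   region = 0, reporter = 0, indication = 0.3,
                                   dates = 0.4))
  df <- reportData(generateSrs(cfg))
  expect_equal(mean(is.na(df$age_years)), 0.5, tolerance = 0.05)
  expect_equal(mean(is.na(df$sex)), 0.2, tolerance = 0.05)
  expect_equal(mean(is.na(df$weight_kg)), 0.8, tolerance = 0.05)
  expect_equal(mean(is.na(df$region)), 0, tolerance = 0.01)
  expect_equal(mean(is.na(df$tto_days)), 0.4, tolerance = 0.05)
})
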