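test_that("identical cohorts compare as null across all variables", {
  set.seed(61)
  events <- replicate(200, list("PT1"))
  rs <- mk_reports("blinatumomab", events,
                   age = sample(20:90, 200, TRUE),
                   sex = sample(c("M", "F"), 200, TRUE),
                   weight = runif(200, 50, 100))
  cmp <- describeAndCompare(rs, rs, variables = c("age_years", "sex",
                                                  "weight_kg"))
  expect_true(all(cmp$p >= 0.99, na.rm = TRUE))
})

test_that("a planted age shift is detected with high power", {
  hits <- 0
  for (s in 1:10) {
    set.seed(600 + s)
    a <- mk_reports("blinatumomab", replicate(2500, list("P")),
                    age = round(rnorm(2500, 60, 15)))
    b <- mk_reports("tisagenlecleucel", replicate(2500, list("P")),
                    age = round(rnorm(2500, 62, 15)))
    cmp <- describeAndCompare(a, b, variables = "age_years")
    if (cmp$p[1] < 0.001) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("percentages use non-missing denominators", {
  a <- mk_reports("blinatumomab", replicate(10, list("P")),
                  sex = c("M", "M", "M", "F", NA, NA, NA, NA, NA, NA))
  b <- mk_reports("tisagenlecleucel", replicate(4, list("P")),
                  sex = c("M", "F", "F", "F"))
  cmp <- describeAndCompare(a, b, variables = "sex")
  m_row <- cmp[cmp$level == "M", ]
  expect_match(m_row$a, "75.00%", fixed = TRUE)  # 3/4 non-missing, not 3/10
  expect_equal(m_row$missing_a, 6)
})

test_that("fatalTrend computes per-year proportions and a two-sided trend p", {
  set.seed(62)
  years <- rep(2015:2019, each = 400)
  fatal <- rbinom(2000, 1, 0.10 + 0.03 * (years - 2015)) == 1
  rs <- mk_reports("blinatumomab", replicate(2000, list("P")),
                   fatal = fatal, year = years)
  ft <- fatalTrend(rs)
  expect_equal(ft$by_year$year, 2015:2019)
  expect_equal(sum(ft$by_year$n), 2000)
  expect_lt(ft$p, 0.01)
  # hand-check one year's proportion
  expect_equal(ft$by_year$prop_fatal[1],
               mean(fatal[years == 2015]))
  # degenerate single year errors
  one <- mk_reports("blinatumomab", replicate(5, list("P")), year = 2020)
  expect_error(fatalTrend(one), "2 years")
})

test_that("univariate odds ratios match brute-force 2x2 computation", {
  set.seed(63)
  n <- 800
  crs <- runif(n) < 0.3
  icans_p <- ifelse(crs, 0.25, 0.10)
  icans <- runif(n) < icans_p
  icans_pt <- "immune effector cell-associated neurotoxicity syndrome"
  events <- lapply(seq_len(n), function(i) {
    e <- "filler"
    if (crs[i]) e <- c(e, "cytokine release syndrome")
    if (icans[i]) e <- c(e, icans_pt)
    e
  })
  rs <- mk_reports("blinatumomab", events, age = sample(30:90, n, TRUE))
  rf <- univariateRisk(rs, "icans")
  row <- rf[rf$factor == "concurrent_crs" & rf$level == "CRS", ]
  a <- sum(crs & icans); b <- sum(crs & !icans)
  c0 <- sum(!crs & icans); d0 <- sum(!crs & !icans)
  expect_equal(row$or, (a * d0) / (b * c0), tolerance = 1e-12)
  # reference rows carry OR 1
  refs <- rf[rf$level == rf$reference, ]
  expect_true(all(refs$or == 1))
})

test_that("a planted CRS-ICANS odds ratio of 3 is recovered", {
  icans_pt <- "immune effector cell-associated neurotoxicity syndrome"
  hits <- 0
  for (s in 1:5) {
    set.seed(640 + s)
    n <- 20000
    crs <- runif(n) < 0.3
    p0 <- 0.08; o0 <- p0 / (1 - p0)
    p1 <- 3 * o0 / (1 + 3 * o0)
    icans <- runif(n) < ifelse(crs, p1, p0)
    events <- lapply(seq_len(n), function(i) {
      e <- "filler"
      if (crs[i]) e <- c(e, "cytokine release syndrome")
      if (icans[i]) e <- c(e, icans_pt)
      e
    })
    rs <- mk_reports("blinatumomab", events)
    rf <- univariateRisk(rs, "icans")
    or <- rf$or[rf$factor == "concurrent_crs" & rf$level == "CRS"]
    if (or >= 2.5 && or <= 3.6) hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("zero-cell levels get a flagged continuity-corrected OR", {
  icans_pt <- "immune effector cell-associated neurotoxicity syndrome"
  events <- c(replicate(30, list(icans_pt)), replicate(30, list("x")))
  rs <- mk_reports("blinatumomab", events,
                   age = c(rep(70, 30), rep(40, 30)))  # all ICANS in >=65
  rf <- univariateRisk(rs, "icans")
  row <- rf[rf$factor == "age" & rf$level == ">=65", ]
  expect_true(row$corrected)
  expect_true(is.finite(row$or))
})

test_that("death-within-ICANS outcome restricts the analysis population", {
  icans_pt <- "immune effector cell-associated neurotoxicity syndrome"
  events <- c(replicate(40, list(icans_pt)), replicate(40, list("x")))
  fatal <- c(rep(c(TRUE, FALSE), 20), rep(FALSE, 40))
  rs <- mk_reports("blinatumomab", events, fatal = fatal,
                   weight = runif(80, 50, 110))
  rf <- univariateRisk(rs, "death_in_icans")
  row <- rf[rf$factor == "weight" & rf$level == ">=80", ]
  # denominators only count ICANS reports
  expect_lte(row$n_exp + row$n_ref, 40)
})
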