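#' Describe and compare two cohorts variable by variable
#'
#' Complete-case comparison: for each variable, reports missing it are
#' excluded from that variable's summary and test (and counted
#' separately). Continuous variables are summarised as median [Q1-Q3] and
#' compared by the two-sided Wilcoxon rank-sum test; categorical variables
#' as n (%) on the non-missing denominator, compared by Pearson's
#' chi-squared test, or Fisher's exact test when any expected cell count
#' is below 5.
#'
#' @param cohort_a,cohort_b \linkS4class{SafetyReportSet}s or data.frames.
#' @param variables character vector of column names to compare (default:
#'   age, sex, weight, region, reporter, indication group, target).
#' @param labels length-2 labels for the cohorts.
#' @return data.frame with one row per variable level: \code{variable},
#'   \code{level}, the two cohorts' summaries, \code{missing_a},
#'   \code{missing_b}, \code{p}, \code{test}.
#' @export
describeAndCompare <- function(cohort_a, cohort_b,
                               variables = c("age_years", "sex", "weight_kg",
                                             "region", "reporter",
                                             "indication_group", "target"),
                               labels = c("A", "B")) {
  da <- if (is(cohort_a, "SafetyReportSet")) cohort_a@reports else cohort_a
  db <- if (is(cohort_b, "SafetyReportSet")) cohort_b@reports else cohort_b
  rows <- list()
  for (v in variables) {
    xa <- da[[v]]; xb <- db[[v]]
    ma <- sum(is.na(xa)); mb <- sum(is.na(xb))
    if (is.numeric(xa)) {
      qa <- stats::quantile(xa, c(0.25, 0.5, 0.75), na.rm = TRUE, type = 7)
      qb <- stats::quantile(xb, c(0.25, 0.5, 0.75), na.rm = TRUE, type = 7)
      ht <- suppressWarnings(stats::wilcox.test(xa, xb, exact = FALSE))
      rows[[length(rows) + 1]] <- data.frame(
        variable = v, level = "median [Q1-Q3]",
        a = sprintf("%.1f [%.1f-%.1f]", qa[2], qa[1], qa[3]),
        b = sprintf("%.1f [%.1f-%.1f]", qb[2], qb[1], qb[3]),
        missing_a = ma, missing_b = mb,
        p = ht$p.value, test = "wilcoxon", stringsAsFactors = FALSE)
    } else {
      lev <- sort(unique(c(xa[!is.na(xa)], xb[!is.na(xb)])))
      if (!length(lev)) next
      ta <- table(factor(xa, levels = lev))
      tb <- table(factor(xb, levels = lev))
      m <- rbind(ta, tb)
      test <- "chisq"
      p <- NA_real_
      if (length(lev) >= 2 && all(rowSums(m) > 0)) {
        exp_cts <- outer(rowSums(m), colSums(m)) / sum(m)
        if (any(exp_cts < 5)) {
          test <- "fisher"
          p <- stats::fisher.test(m, simulate.p.value = sum(m) > 2e4,
                                  B = 1e4)$p.value
        } else {
          p <- suppressWarnings(stats::chisq.test(m, correct = FALSE)$p.value)
        }
      }
      for (l in lev) {
        rows[[length(rows) + 1]] <- data.frame(
          variable = v, level = l,
          a = sprintf("%d (%.2f%%)", ta[[l]], 100 * ta[[l]] / max(sum(ta), 1)),
          b = sprintf("%d (%.2f%%)", tb[[l]], 100 * tb[[l]] / max(sum(tb), 1)),
          missing_a = ma, missing_b = mb,
          p = p, test = test, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "labels") <- labels
  out
}

#' Fatal-outcome proportion by year with Cochran-Armitage trend test
#'
#' Orders reports into a 2 x k (fatal x year) table and tests for a linear
#' trend in the fatal proportion with the Cochran-Armitage statistic using
#' consecutive integer year scores (two-sided p).
#'
#' @param reports a \linkS4class{SafetyReportSet} or its data.frame.
#' @return list with \code{by_year} (data.frame \code{year}, \code{n},
#'   \code{n_fatal}, \code{prop_fatal}), \code{p} and \code{statistic}
#'   (the trend chi-square on 1 df).
#' @export
fatalTrend <- function(reports) {
  df <- if (is(reports, "SafetyReportSet")) reports@reports else reports
  df <- df[!is.na(df$year), , drop = FALSE]
  years <- sort(unique(df$year))
  if (length(years) < 2) stop("trend test needs at least 2 years")
  n <- vapply(years, function(y) sum(df$year == y), numeric(1))
  nf <- vapply(years, function(y) sum(df$fatal[df$year == y]), numeric(1))
  ht <- stats::prop.trend.test(nf, n, score = seq_along(years))
  list(by_year = data.frame(year = years, n = n, n_fatal = nf,
                            prop_fatal = nf / n),
       p = ht$p.value, statistic = unname(ht$statistic))
}

#' Univariate risk-factor analysis
#'
#' For each factor, a 2x2 odds ratio of the outcome for the level against
#' its reference level, with a Woolf (log-scale Wald) 95\% CI and a
#' chi-squared p-value (Fisher's exact when any expected cell is below 5).
#' Zero cells get the +0.5 continuity correction (flagged).
#'
#' The bundled factor definitions follow the usual ICANS risk-factor set:
#' age >= 65 vs < 65; indication group vs Leukaemia; target vs CD19;
#' weight >= 80 kg vs < 80; concurrent CRS (the CRS PT in the same
#' report) vs none.
#'
#' @param reports a \linkS4class{SafetyReportSet} or its data.frame.
#' @param outcome either the string \code{"icans"} (occurrence of the
#'   ICANS PT among all reports) or \code{"death_in_icans"} (fatal outcome
#'   among ICANS reports), or a predicate function over the data.frame.
#' @param factors named list mapping factor name to a function that
#'   returns a factor (first level = reference) from the data.frame;
#'   defaults to the bundled set.
#' @param icans_pt,crs_pt the PT strings used by the bundled definitions.
#' @return data.frame: \code{factor}, \code{level}, \code{reference},
#'   \code{or}, \code{or_lo}, \code{or_hi}, \code{p}, \code{test},
#'   \code{corrected}, cell counts \code{n_exp_out}, \code{n_exp},
#'   \code{n_ref_out}, \code{n_ref}. Reference levels appear with OR 1.
#' @export
univariateRisk <- function(reports, outcome = "icans", factors = NULL,
                           icans_pt = "immune effector cell-associated neurotoxicity syndrome",
                           crs_pt = "cytokine release syndrome") {
  df <- if (is(reports, "SafetyReportSet")) reports@reports else reports
  has_icans <- vapply(df$events, function(e) icans_pt %in% e, logical(1))
  if (is.function(outcome)) {
    y <- outcome(df)
  } else if (outcome == "icans") {
    y <- has_icans
  } else if (outcome == "death_in_icans") {
    df <- df[has_icans, , drop = FALSE]
    y <- df$fatal
  } else stop("unknown outcome definition: ", outcome)
  if (is.null(factors)) {
    factors <- list(
      age = function(d) factor(ifelse(is.na(d$age_years), NA,
                                      ifelse(d$age_years >= 65, ">=65", "<65")),
                               levels = c("<65", ">=65")),
      indication = function(d) factor(d$indication_group,
                                      levels = c("Leukaemia", "Lymphoma",
                                                 "PlasmaCellNeoplasms",
                                                 "SolidTumors", "Unclassified")),
      target = function(d) factor(d$target,
                                  levels = c("CD19", "BCMA", "CD20",
                                             "GPRC5D", "Other")),
      weight = function(d) factor(ifelse(is.na(d$weight_kg), NA,
                                         ifelse(d$weight_kg >= 80, ">=80", "<80")),
                                  levels = c("<80", ">=80")),
      concurrent_crs = function(d) {
        crs <- vapply(d$events, function(e) crs_pt %in% e, logical(1))
        factor(ifelse(crs, "CRS", "none"), levels = c("none", "CRS"))
      }
    )
  }
  rows <- list()
  for (fn in names(factors)) {
    f <- factors[[fn]](df)
    lev <- levels(f)
    ref <- lev[1]
    y_ref <- y[!is.na(f) & f == ref]
    rows[[length(rows) + 1]] <- data.frame(
      factor = fn, level = ref, reference = ref, or = 1,
      or_lo = NA_real_, or_hi = NA_real_, p = NA_real_, test = "",
      corrected = FALSE, n_exp_out = sum(y_ref), n_exp = length(y_ref),
      n_ref_out = sum(y_ref), n_ref = length(y_ref),
      stringsAsFactors = FALSE)
    for (l in lev[-1]) {
      y_l <- y[!is.na(f) & f == l]
      tab <- c(a = sum(y_l), b = length(y_l) - sum(y_l),
               c = sum(y_ref), d = length(y_ref) - sum(y_ref))
      corrected <- any(tab == 0)
      tt <- if (corrected) tab + 0.5 else tab
      or <- (tt[["a"]] * tt[["d"]]) / (tt[["b"]] * tt[["c"]])
      se <- sqrt(sum(1 / tt))
      m <- matrix(tab, 2, 2, byrow = TRUE)
      exp_cts <- outer(rowSums(m), colSums(m)) / max(sum(m), 1)
      if (any(exp_cts < 5) || any(rowSums(m) == 0) || any(colSums(m) == 0)) {
        test <- "fisher"
        p <- tryCatch(stats::fisher.test(m)$p.value, error = function(e) NA_real_)
      } else {
        test <- "chisq"
        p <- suppressWarnings(stats::chisq.test(m, correct = TRUE)$p.value)
      }
      rows[[length(rows) + 1]] <- data.frame(
        factor = fn, level = l, reference = ref, or = or,
        or_lo = exp(log(or) - 1.96 * se), or_hi = exp(log(or) + 1.96 * se),
        p = p, test = test, corrected = corrected,
        n_exp_out = tab[["a"]], n_exp = tab[["a"]] + tab[["b"]],
        n_ref_out = tab[["c"]], n_ref = tab[["c"]] + tab[["d"]],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
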