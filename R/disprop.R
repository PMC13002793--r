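## Eight-algorithm disproportionality suite.
## Zero-cell convention: ROR/PRR point + Wald CI use the Haldane-Anscombe
## +0.5 correction only when a zero cell exists; Fisher, O/E and the
## Bayesian estimators always use the raw counts.

.cells <- function(table) {
  if (is(table, "ContingencyTable")) cellCounts(table)
  else {
    stopifnot(length(table) == 4)
    stats::setNames(as.numeric(table), c("a", "b", "c", "d"))
  }
}

#' Reporting odds ratio
#'
#' Point estimate (a d)/(b c) with a 95\% Wald interval on the log scale,
#' exp(ln ROR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d)).
#'
#' @param table a \linkS4class{ContingencyTable} or numeric (a,b,c,d).
#' @return list with \code{point}, \code{lo}, \code{hi}, \code{corrected}
#'   (TRUE when a zero cell forced the +0.5 correction).
#' @export
rorStat <- function(table) {
  x <- .cells(table)
  corrected <- any(x == 0)
  if (corrected) x <- x + 0.5
  pt <- (x["a"] * x["d"]) / (x["b"] * x["c"])
  se <- sqrt(sum(1 / x))
  list(point = unname(pt),
       lo = unname(exp(log(pt) - 1.96 * se)),
       hi = unname(exp(log(pt) + 1.96 * se)),
       corrected = corrected)
}

#' Proportional reporting ratio
#'
#' Point estimate [a/(a+b)] / [c/(c+d)] with Wald interval
#' exp(ln PRR +/- 1.96 sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d))).
#'
#' @inheritParams rorStat
#' @return list with \code{point}, \code{lo}, \code{hi}, \code{corrected}.
#' @export
prrStat <- function(table) {
  x <- .cells(table)
  corrected <- any(x == 0)
  if (corrected) x <- x + 0.5
  a <- x["a"]; b <- x["b"]; c <- x["c"]; d <- x["d"]
  pt <- (a / (a + b)) / (c / (c + d))
  se <- sqrt(1 / a - 1 / (a + b) + 1 / c - 1 / (c + d))
  list(point = unname(pt),
       lo = unname(exp(log(pt) - 1.96 * se)),
       hi = unname(exp(log(pt) + 1.96 * se)),
       corrected = corrected)
}

#' Yates-corrected Pearson chi-square statistic for the 2x2
#'
#' @inheritParams rorStat
#' @return the continuity-corrected chi-square statistic (NA for a
#'   degenerate margin).
#' @export
chiSquareStat <- function(table) {
  x <- .cells(table)
  m <- matrix(x, 2, 2, byrow = TRUE)
  out <- tryCatch(
    suppressWarnings(unname(stats::chisq.test(m, correct = TRUE)$statistic)),
    error = function(e) NA_real_)
  out
}

#' Two-sided Fisher exact p-value for the 2x2
#'
#' @inheritParams rorStat
#' @return the two-sided hypergeometric p-value.
#' @export
fisherExactP <- function(table) {
  x <- .cells(table)
  m <- matrix(x, 2, 2, byrow = TRUE)
  stats::fisher.test(m)$p.value
}

#' Observed-to-expected ratio with exact Poisson interval
#'
#' O = a, E = (a+b)(a+c)/N; the interval divides the exact (Garwood)
#' Poisson bounds for O by E: lower = qchisq(0.025, 2O)/2 (0 when O = 0),
#' upper = qchisq(0.975, 2(O+1))/2.
#'
#' @inheritParams rorStat
#' @return list with \code{point}, \code{lo}, \code{hi}, \code{expected}.
#' @export
oeStat <- function(table) {
  x <- .cells(table)
  N <- sum(x)
  O <- x[["a"]]
  E <- (x[["a"]] + x[["b"]]) * (x[["a"]] + x[["c"]]) / N
  if (E == 0) return(list(point = NA_real_, lo = NA_real_, hi = NA_real_, expected = 0))
  lo <- if (O == 0) 0 else stats::qchisq(0.025, 2 * O) / 2
  hi <- stats::qchisq(0.975, 2 * (O + 1)) / 2
  list(point = O / E, lo = lo / E, hi = hi / E, expected = E)
}

#' BCPNN information component, normal approximation
#'
#' Closed-form posterior expectation and variance of the information
#' component IC = log2 p11 / (p1. p.1) under the standard BCPNN prior with
#' marginal Beta(1, 1) priors (alpha1 = beta1 = 1, alpha = beta = 2) and a
#' joint prior centred on independence. The decision bound is
#' IC025 = E(IC) - 1.96 sqrt(V(IC)).
#'
#' @inheritParams rorStat
#' @return list with \code{ic} (posterior expectation) and \code{ic025}.
#' @export
bcpnnNormal <- function(table) {
  x <- .cells(table)
  n11 <- x[["a"]]; n1. <- x[["a"]] + x[["b"]]; n.1 <- x[["a"]] + x[["c"]]
  N <- sum(x)
  a1 <- 1; b1 <- 1; al <- 2; be <- 2; g11 <- 1
  g <- g11 * (N + al) * (N + be) / ((n1. + a1) * (n.1 + b1))
  eic <- log2((n11 + g11) * (N + al) * (N + be) /
                ((N + g) * (n1. + a1) * (n.1 + b1)))
  vic <- ((N - n11 + g - g11) / ((n11 + g11) * (1 + N + g)) +
            (N - n1. + al - a1) / ((n1. + a1) * (1 + N + al)) +
            (N - n.1 + be - b1) / ((n.1 + b1) * (1 + N + be))) / log(2)^2
  list(ic = eic, ic025 = eic - 1.96 * sqrt(vic))
}

#' BCPNN information component by Monte Carlo
#'
#' Posterior draws of the 2x2 cell probabilities from
#' Dirichlet((1,1,1,1) + (a,b,c,d)); the IC is computed per draw and
#' summarised by its median and 2.5th percentile. Deterministic under a
#' fixed seed.
#'
#' @inheritParams rorStat
#' @param n_draws number of posterior draws (default 10000; fewer than
#'   1000 triggers a warning).
#' @param seed integer seed for the draws.
#' @return list with \code{ic} (posterior median) and \code{ic025}.
#' @export
bcpnnMcmc <- function(table, n_draws = 10000, seed = 1L) {
  if (n_draws < 1000) warning("n_draws < 1000: IC quantiles will be noisy")
  x <- .cells(table)
  g <- withr_seed(seed, {
    matrix(stats::rgamma(4L * n_draws, shape = rep(x + 1, each = n_draws)),
           nrow = n_draws)
  })
  p <- g / rowSums(g)
  ic <- log2(p[, 1] / ((p[, 1] + p[, 2]) * (p[, 1] + p[, 3])))
  q <- stats::quantile(ic, c(0.5, 0.025), names = FALSE, type = 7)
  list(ic = q[1], ic025 = q[2])
}

# run expr under a local RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Fit the DuMouchel gamma-Poisson shrinker prior
#'
#' Maximises the marginal likelihood of observed pair counts a_i given
#' their expectations E_i under a two-component gamma mixture prior for the
#' relative reporting rate: marginally each a_i is a mixture of two
#' negative binomials. Five hyperparameters are estimated
#' (alpha1, beta1, alpha2, beta2, mixing weight P); optimisation is BFGS on
#' unconstrained transforms with jittered multi-starts to guard against the
#' likelihood ridge this model is known for.
#'
#' @param a integer vector of observed counts.
#' @param E numeric vector of expected counts (same length, positive).
#' @param start numeric(5) starting values
#'   (default DuMouchel's 0.2, 0.1, 2, 4, 1/3).
#' @param n_restarts number of jittered restarts (default 5).
#' @param seed seed for the jitter.
#' @return A \linkS4class{GpsHyperparams}.
#' @export
ebgmFit <- function(a, E, start = c(0.2, 0.1, 2, 4, 1/3),
                    n_restarts = 5, seed = 1L) {
  stopifnot(length(a) == length(E), all(E > 0), all(a >= 0))
  nll <- function(th) {
    a1 <- exp(th[1]); b1 <- exp(th[2]); a2 <- exp(th[3]); b2 <- exp(th[4])
    P <- stats::plogis(th[5])
    # extreme exploratory steps can push dnbinom outside its domain;
    # treat those as very unlikely rather than erroring out of BFGS
    out <- suppressWarnings({
      l1 <- stats::dnbinom(a, size = a1, prob = b1 / (b1 + E), log = TRUE)
      l2 <- stats::dnbinom(a, size = a2, prob = b2 / (b2 + E), log = TRUE)
      m <- pmax(l1, l2)
      -sum(m + log(P * exp(l1 - m) + (1 - P) * exp(l2 - m)))
    })
    if (!is.finite(out)) 1e10 else out
  }
  th0 <- c(log(start[1:4]), stats::qlogis(start[5]))
  starts <- withr_seed(seed, {
    c(list(th0), lapply(seq_len(max(0, n_restarts - 1)), function(i)
      th0 + stats::rnorm(5, 0, 0.5)))
  })
  best <- NULL
  for (s in starts) {
    o <- tryCatch(stats::optim(s, nll, method = "BFGS",
                               control = list(maxit = 500)),
                  error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best)) stop("GPS hyperparameter optimisation failed to converge")
  th <- best$par
  eps <- 1e-9
  new("GpsHyperparams",
      alpha1 = exp(th[1]), beta1 = exp(th[2]),
      alpha2 = exp(th[3]), beta2 = exp(th[4]),
      mix_p = min(max(stats::plogis(th[5]), eps), 1 - eps),
      loglik = -best$value, convergence = as.numeric(best$convergence))
}

#' EBGM and EB05 shrinkage scores
#'
#' Given the fitted prior, the posterior of the relative reporting rate for
#' a pair with count a and expectation E is a two-component gamma mixture.
#' EBGM is the posterior geometric mean 2^E[log2 lambda]; EB05 the 5th
#' posterior percentile, found by numerical inversion of the mixture CDF
#' (bisection via uniroot, tolerance 1e-8).
#'
#' @param table a \linkS4class{ContingencyTable} or numeric (a,b,c,d); or
#'   use \code{a} and \code{E} directly (vectors allowed).
#' @param hyper a \linkS4class{GpsHyperparams}.
#' @param a,E optional explicit count(s) and expectation(s); override
#'   \code{table}.
#' @return list with \code{ebgm} and \code{eb05} (vectors when a/E are).
#' @export
ebgmScore <- function(table = NULL, hyper, a = NULL, E = NULL) {
  if (is.null(a)) {
    x <- .cells(table)
    a <- x[["a"]]
    E <- (x[["a"]] + x[["b"]]) * (x[["a"]] + x[["c"]]) / sum(x)
  }
  a1 <- hyper@alpha1; b1 <- hyper@beta1
  a2 <- hyper@alpha2; b2 <- hyper@beta2; P <- hyper@mix_p
  l1 <- stats::dnbinom(a, size = a1, prob = b1 / (b1 + E), log = TRUE)
  l2 <- stats::dnbinom(a, size = a2, prob = b2 / (b2 + E), log = TRUE)
  m <- pmax(l1, l2)
  Q <- P * exp(l1 - m) / (P * exp(l1 - m) + (1 - P) * exp(l2 - m))
  elog <- Q * (digamma(a1 + a) - log(b1 + E)) +
    (1 - Q) * (digamma(a2 + a) - log(b2 + E))
  ebgm <- exp(elog)
  eb05 <- vapply(seq_along(a), function(i) {
    cdf <- function(x)
      Q[i] * stats::pgamma(x, a1 + a[i], rate = b1 + E[i]) +
      (1 - Q[i]) * stats::pgamma(x, a2 + a[i], rate = b2 + E[i]) - 0.05
    up <- ebgm[i] + 1
    while (cdf(up) < 0) up <- up * 2
    stats::uniroot(cdf, c(0, up), tol = 1e-8)$root
  }, numeric(1))
  list(ebgm = ebgm, eb05 = eb05)
}

#' Evaluate the positive-signal thresholds for all eight algorithms
#'
#' ROR: lower ROR CI bound > 1 and a >= 3. PRR: lower PRR CI bound >= 1 and
#' a >= 3. Chi-square: statistic >= 4, PRR >= 2 and a >= 3. Fisher:
#' p < 0.05. O/E: lower bound > 1. BCPNN (both variants): IC025 > 0.
#' EBGM: EB05 >= 2.
#'
#' @param stats named numeric vector as stored in a
#'   \linkS4class{SignalResult} (see that class).
#' @param a the a cell of the pair's table.
#' @return named logical vector of flags.
#' @export
evaluateThresholds <- function(stats, a) {
  f <- c(
    ror = isTRUE(stats[["ror_lo"]] > 1 && a >= 3),
    prr = isTRUE(stats[["prr_lo"]] >= 1 && a >= 3),
    chi2 = isTRUE(!is.na(stats[["chi2"]]) && stats[["chi2"]] >= 4 &&
                    stats[["prr"]] >= 2 && a >= 3),
    fisher = isTRUE(stats[["fisher_p"]] < 0.05),
    oe = isTRUE(!is.na(stats[["oe_lo"]]) && stats[["oe_lo"]] > 1),
    bcpnn_norm = isTRUE(stats[["ic_norm_025"]] > 0),
    bcpnn_mcmc = isTRUE(stats[["ic_mcmc_025"]] > 0),
    ebgm = isTRUE(stats[["eb05"]] >= 2)
  )
  f
}

#' All eight estimators and flags for one drug-event pair
#'
#' @param table a \linkS4class{ContingencyTable}.
#' @param exposure,event labels for the pair.
#' @param hyper optional \linkS4class{GpsHyperparams}; when NULL the EBGM
#'   scores are NA (they require a prior fitted across a set of pairs).
#' @param mcmc_draws,mcmc_seed forwarded to \code{\link{bcpnnMcmc}}.
#' @return A \linkS4class{SignalResult}.
#' @export
signalResult <- function(table, exposure = "exposure", event = "event",
                         hyper = NULL, mcmc_draws = 10000, mcmc_seed = 1L) {
  r <- rorStat(table); p <- prrStat(table)
  oe <- oeStat(table); bn <- bcpnnNormal(table)
  bm <- bcpnnMcmc(table, mcmc_draws, mcmc_seed)
  if (!is.null(hyper)) {
    eb <- ebgmScore(table, hyper)
  } else eb <- list(ebgm = NA_real_, eb05 = NA_real_)
  s <- c(ror = r$point, ror_lo = r$lo, ror_hi = r$hi,
         prr = p$point, prr_lo = p$lo, prr_hi = p$hi,
         chi2 = chiSquareStat(table), fisher_p = fisherExactP(table),
         oe = oe$point, oe_lo = oe$lo, oe_hi = oe$hi,
         ic_norm = bn$ic, ic_norm_025 = bn$ic025,
         ic_mcmc = bm$ic, ic_mcmc_025 = bm$ic025,
         ebgm = eb$ebgm, eb05 = eb$eb05)
  new("SignalResult", exposure = exposure, event = event, table = table,
      stats = s, flags = evaluateThresholds(s, cellCounts(table)[["a"]]),
      corrected = r$corrected)
}

#' Batch signal detection over exposure x event pairs
#'
#' Builds the 2x2 tables for every pair, fits the gamma-Poisson shrinker
#' prior across all pairs, and returns one row per pair with all eight
#' estimators, intervals and threshold flags.
#'
#' @inheritParams buildAllPairs
#' @param mcmc_draws,seed Monte Carlo settings for the BCPNN MCMC variant
#'   and the GPS multi-start jitter.
#' @return data.frame: pair keys, cells, estimators (\code{ror},
#'   \code{ror_lo}, \code{ror_hi}, ..., \code{ebgm}, \code{eb05}) and
#'   logical flag columns (\code{flag_ror}, ..., \code{flag_ebgm}),
#'   plus \code{corrected}. The fitted \linkS4class{GpsHyperparams} is
#'   attached as attribute \code{"gps"}.
#' @export
signalTable <- function(reports, exposures, events,
                        mcmc_draws = 2000, seed = 1L) {
  tabs <- buildAllPairs(reports, exposures, events)
  E <- (tabs$a + tabs$b) * (tabs$a + tabs$c) / (tabs$a + tabs$b + tabs$c + tabs$d)
  ok <- E > 0
  hyper <- if (sum(ok) >= 2)
    ebgmFit(tabs$a[ok], E[ok], seed = seed) else NULL
  rows <- lapply(seq_len(nrow(tabs)), function(i) {
    tab <- contingencyTable(tabs$a[i], tabs$b[i], tabs$c[i], tabs$d[i])
    sr <- signalResult(tab, tabs$exposure[i], tabs$event[i],
                       hyper = if (ok[i]) hyper else NULL,
                       mcmc_draws = mcmc_draws, mcmc_seed = seed + i)
    st <- as.list(sr@stats)
    fl <- as.list(sr@flags)
    names(fl) <- paste0("flag_", names(fl))
    cbind(tabs[i, , drop = FALSE], as.data.frame(st), as.data.frame(fl),
          corrected = sr@corrected)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "gps") <- hyper
  out
}

#' Drug-specificity ratio for one event across a drug cohort
#'
#' Divides the highest ROR for the event by the second-highest among the
#' cohort's drugs. The pair is a drug-specific signal when the top drug's
#' standard ROR signal criteria hold (lower CI bound > 1, a >= 3), its
#' ROR exceeds 5, and the ratio exceeds 10; an event reported for a single
#' drug has an infinite ratio, which counts as meeting the criterion.
#'
#' @param event the PT analysed.
#' @param per_drug data.frame with one row per cohort drug reporting the
#'   event: columns \code{drug_id}, \code{ror}, \code{ror_lo}, \code{a}.
#' @param ror_min,ratio_min the exploratory thresholds (defaults 5 and 10).
#' @return A \linkS4class{DSRResult}.
#' @export
drugSpecificity <- function(event, per_drug, ror_min = 5, ratio_min = 10) {
  stopifnot(nrow(per_drug) >= 1)
  pd <- per_drug[order(-per_drug$ror, per_drug$drug_id), , drop = FALSE]
  pd$flagged <- pd$ror_lo > 1 & pd$a >= 3
  top <- pd[1, ]
  second <- if (nrow(pd) >= 2) pd$ror[2] else NA_real_
  ratio <- if (is.na(second)) Inf else top$ror / second
  specific <- isTRUE(top$flagged) && top$ror > ror_min &&
    (is.infinite(ratio) || ratio > ratio_min)
  new("DSRResult", event = event,
      per_drug = pd[, c("drug_id", "ror", "a", "flagged")],
      top_drug = top$drug_id, top_ror = top$ror,
      second_ror = second, ratio = ratio, is_specific = specific)
}

#' Class-level signal proportion for an event
#'
#' Fraction of a class's drugs whose drug-event pair is ROR-flagged
#' (lower CI bound > 1 and a >= 3); the per-class summary shown as bubble
#' colour intensity in class-comparison displays.
#'
#' @param signal_table output of \code{\link{signalTable}} with per-drug
#'   exposures.
#' @param event the PT.
#' @param drugs character vector of the class's drug ids.
#' @return proportion in [0, 1].
#' @export
signalProportion <- function(signal_table, event, drugs) {
  sub <- signal_table[signal_table$event == event &
                        signal_table$exposure %in% drugs, ]
  if (!nrow(sub)) return(NA_real_)
  mean(sub$flag_ror)
}
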