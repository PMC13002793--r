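#' Configuration for the synthetic SRS generator
#'
#' Defines the generative model for a synthetic spontaneous-reporting
#' database: drug roster with marketing-share weights, PT vocabulary with
#' base reporting probabilities, planted drug-event odds ratios, planted
#' pairwise co-occurrence lifts, per-(class, PT) Weibull time-to-onset
#' models, a per-year fatality model with PT-set-conditional overrides,
#' per-field missingness and a duplicate-injection rate.
#'
#' Lift planting uses a two-step scheme (anchor PT then partner PT with
#' the conditional probability that makes the population lift equal the
#' target); this is exact in expectation only for disjoint pair lists, so
#' overlapping pairs, or pairs sharing a PT with a planted odds-ratio
#' signal, are rejected at validation. An infeasible lift (implied
#' conditional probability above 1) is a hard error naming the pair.
#'
#' @param n_reports number of reports to generate.
#' @param seed integer seed; identical config + seed gives identical data.
#' @param years calendar years covered (reports spread uniformly).
#' @param drugs data.frame \code{drug_id}, \code{class}, \code{target},
#'   \code{share} (weights, normalised to sum 1).
#' @param pts data.frame \code{pt}, \code{soc}, \code{base_p}.
#' @param signals data.frame \code{drug} (a drug_id, or a class name
#'   \code{"TCE"}/\code{"CART"}), \code{pt}, \code{or} (target odds ratio
#'   vs background).
#' @param cooc data.frame \code{pt_a}, \code{pt_b}, \code{lift}.
#' @param blocks optional list of planted co-occurrence blocks, each a
#'   list with \code{pts} (PT names), \code{p} (common marginal
#'   probability), \code{lift} (common pairwise lift target) and
#'   \code{q} (latent-activation probability, default 0.3). Block members
#'   are driven by a shared latent Bernoulli(q): active reports use a
#'   high per-PT probability h, inactive a low l, with (h, l) solved so
#'   the marginal equals p and every within-block pairwise lift equals
#'   the target; cross-block lifts stay 1. Infeasible targets (h > 1 or
#'   discriminant < 0) are a hard error naming the block.
#' @param tto data.frame \code{class}, \code{pt} (NA = class default),
#'   \code{shape}, \code{scale}; first matching row (in order) assigns a
#'   report's onset model, falling back to shape 1 / scale 7 days.
#' @param fatality list: \code{p_start}, \code{p_end} (per-year fatal
#'   probability linearly interpolated across \code{years}) and optional
#'   \code{conditional} data.frame (\code{pts} = PT set joined by ";",
#'   \code{prob}) applied most-specific-last.
#' @param missingness named rates in [0,1) for \code{age}, \code{sex},
#'   \code{weight}, \code{region}, \code{reporter}, \code{indication},
#'   \code{dates} (therapy/event dates, hence time-to-onset).
#' @param outcome_probs named Bernoulli rates for the non-death outcome
#'   codes (HO, LT, DS, CA, RI); OT fills otherwise-empty outcome sets.
#' @param dup_rate fraction of cases later emitted as version duplicates
#'   by \code{\link{injectDuplicates}}.
#' @return validated config list of class \code{"srs_config"}.
#' @export
srsConfig <- function(n_reports = 10000,
                      seed = 1L,
                      years = 2015:2025,
                      drugs = NULL,
                      pts = mockPtDictionary(),
                      signals = NULL,
                      cooc = NULL,
                      blocks = NULL,
                      tto = NULL,
                      fatality = list(p_start = 0.143, p_end = 0.235),
                      missingness = c(age = 0.44, sex = 0.28, weight = 0.79,
                                      region = 0.01, reporter = 0.02,
                                      indication = 0.29, dates = 0.45),
                      outcome_probs = c(HO = 0.35, LT = 0.10, DS = 0.02,
                                        CA = 0.002, RI = 0.005),
                      dup_rate = 0) {
  if (is.null(drugs)) {
    reg <- defaultRegistry()
    drugs <- reg@drugs[, c("drug_id", "class", "target", "share")]
  }
  stopifnot(n_reports >= 1, length(years) >= 1)
  if (any(drugs$share < 0) || sum(drugs$share) <= 0)
    stop("drug shares must be nonnegative with positive sum")
  drugs$share <- drugs$share / sum(drugs$share)
  if (any(pts$base_p < 0 | pts$base_p > 1)) stop("base_p must be in [0,1]")
  if (anyDuplicated(pts$pt)) stop("duplicate PT in vocabulary")
  if (!is.null(signals)) {
    stopifnot(all(c("drug", "pt", "or") %in% names(signals)))
    if (any(signals$or <= 0)) stop("planted odds ratios must be positive")
    if (!all(signals$pt %in% pts$pt)) stop("signal PT not in vocabulary")
  }
  if (!is.null(cooc)) {
    stopifnot(all(c("pt_a", "pt_b", "lift") %in% names(cooc)))
    if (any(cooc$lift <= 0)) stop("planted lifts must be positive")
    all_pts <- c(cooc$pt_a, cooc$pt_b)
    if (anyDuplicated(all_pts))
      stop("planted co-occurrence pairs must be disjoint")
    if (!all(all_pts %in% pts$pt)) stop("co-occurrence PT not in vocabulary")
    if (!is.null(signals) && any(all_pts %in% signals$pt))
      stop("a planted pair PT also carries a planted odds-ratio signal; ",
           "lift planting would not be exact")
    for (i in seq_len(nrow(cooc))) {
      pa <- pts$base_p[pts$pt == cooc$pt_a[i]]
      pb <- pts$base_p[pts$pt == cooc$pt_b[i]]
      L <- cooc$lift[i]
      if (L * pb > 1 || L * pa > 1)
        stop(sprintf("infeasible lift %.3g for pair (%s, %s): implied conditional probability > 1",
                     L, cooc$pt_a[i], cooc$pt_b[i]))
    }
  }
  if (!is.null(blocks)) {
    blk_pts <- unlist(lapply(blocks, `[[`, "pts"))
    if (anyDuplicated(blk_pts)) stop("block PT lists must be disjoint")
    if (!all(blk_pts %in% pts$pt)) stop("block PT not in vocabulary")
    if (!is.null(cooc) && any(blk_pts %in% c(cooc$pt_a, cooc$pt_b)))
      stop("a block PT also appears in a planted pair")
    if (!is.null(signals) && any(blk_pts %in% signals$pt))
      stop("a block PT also carries a planted odds-ratio signal")
    for (i in seq_along(blocks)) {
      b <- blocks[[i]]
      b$q <- b$q %||% 0.3
      hl <- .blockProbs(b$p, b$lift, b$q)  # errors if infeasible
      blocks[[i]] <- b
    }
  }
  if (is.null(tto)) {
    icans <- "immune effector cell-associated neurotoxicity syndrome"
    tto <- data.frame(
      class = c("TCE", "CART", "TCE", "CART"),
      pt = c(icans, icans, NA, NA),
      shape = c(0.63, 1.0, 0.9, 1.1),
      scale = c(5, 6, 4, 8),
      stringsAsFactors = FALSE)
  }
  if (any(tto$shape <= 0) || any(tto$scale <= 0))
    stop("Weibull shapes and scales must be positive")
  stopifnot(fatality$p_start >= 0, fatality$p_start <= 1,
            fatality$p_end >= 0, fatality$p_end <= 1)
  stopifnot(all(missingness >= 0 & missingness < 1))
  stopifnot(dup_rate >= 0, dup_rate < 1)
  structure(list(n_reports = as.integer(n_reports), seed = as.integer(seed),
                 years = as.integer(years), drugs = drugs, pts = pts,
                 signals = signals, cooc = cooc, blocks = blocks, tto = tto,
                 fatality = fatality, missingness = missingness,
                 outcome_probs = outcome_probs, dup_rate = dup_rate),
            class = "srs_config")
}

# solve the latent-factor (h, l) probabilities for a planted block:
# marginal q h + (1-q) l = p, pairwise lift (q h^2 + (1-q) l^2) / p^2 = L
.blockProbs <- function(p, L, q) {
  disc <- (q - 1 + L * (1 - q)) / q
  if (disc < 0)
    stop(sprintf("infeasible block lift %.3g at q=%.2f", L, q))
  h <- p * (1 + sqrt(disc))
  l <- (p - q * h) / (1 - q)
  if (h > 1 || l < 0)
    stop(sprintf("infeasible block (p=%.3g, lift=%.3g, q=%.2f): member probability outside [0,1]",
                 p, L, q))
  c(h = h, l = l)
}

# per-year fatal probability, linear between the endpoints
.yearFatalProb <- function(fatality, years) {
  if (length(years) == 1) return(stats::setNames(fatality$p_start, years))
  p <- fatality$p_start + (fatality$p_end - fatality$p_start) *
    (seq_along(years) - 1) / (length(years) - 1)
  stats::setNames(p, years)
}

#' Generate a synthetic SRS database with ground truth
#'
#' Draws reports from the generative model in the config: the
#' primary-suspect drug by marketing share, each PT as a Bernoulli with
#' base odds multiplied by the planted odds ratio where one applies,
#' planted co-occurrence pairs by the anchor/partner conditional scheme,
#' day-rounded Weibull onset times from the first matching (class, PT)
#' model, outcomes with the per-year fatality probability (overridden by
#' PT-set conditionals), demographics, and per-field missingness. Every
#' report carries at least one event (empty draws are resampled).
#' Deterministic given config + seed.
#'
#' @param config an \code{\link{srsConfig}}.
#' @return An \linkS4class{SrsSimulation}; its ground-truth ledger holds
#'   the realized 2x2 counts of every planted signal, the realized lift of
#'   every planted pair, and the generating parameter echo.
#' @export
generateSrs <- function(config) {
  stopifnot(inherits(config, "srs_config"))
  n <- config$n_reports
  pts <- config$pts
  K <- nrow(pts)
  withr_seed(config$seed, {
    di <- sample.int(nrow(config$drugs), n, replace = TRUE,
                     prob = config$drugs$share)
    drug_id <- config$drugs$drug_id[di]
    drug_class <- config$drugs$class[di]
    target <- config$drugs$target[di]
    year <- config$years[sample.int(length(config$years), n, replace = TRUE)]

    cooc_pts <- if (!is.null(config$cooc))
      c(config$cooc$pt_a, config$cooc$pt_b) else character(0)
    blk_pts <- unlist(lapply(config$blocks, `[[`, "pts"))
    indep <- which(!(pts$pt %in% c(cooc_pts, blk_pts)))

    # per-(pt, report) success probability for the independent PTs;
    # planted ORs act on the odds of the matching drug's reports
    prob_for <- function(j, idx) {
      p <- rep(pts$base_p[j], length(idx))
      if (!is.null(config$signals)) {
        sig <- config$signals[config$signals$pt == pts$pt[j], , drop = FALSE]
        for (s in seq_len(nrow(sig))) {
          hit <- drug_id[idx] == sig$drug[s] | drug_class[idx] == sig$drug[s]
          if (any(hit)) {
            o <- p[hit] / (1 - p[hit]) * sig$or[s]
            p[hit] <- o / (1 + o)
          }
        }
      }
      p
    }

    draw_events <- function(idx) {
      m <- length(idx)
      M <- matrix(FALSE, m, K)
      for (j in indep)
        M[, j] <- stats::runif(m) < prob_for(j, idx)
      if (!is.null(config$cooc)) {
        for (i in seq_len(nrow(config$cooc))) {
          ja <- match(config$cooc$pt_a[i], pts$pt)
          jb <- match(config$cooc$pt_b[i], pts$pt)
          pa <- pts$base_p[ja]; pb <- pts$base_p[jb]
          L <- config$cooc$lift[i]
          A <- stats::runif(m) < pa
          pb_given <- ifelse(A, L * pb, pb * (1 - L * pa) / (1 - pa))
          M[, ja] <- A
          M[, jb] <- stats::runif(m) < pb_given
        }
      }
      for (b in config$blocks) {
        hl <- .blockProbs(b$p, b$lift, b$q %||% 0.3)
        Z <- stats::runif(m) < (b$q %||% 0.3)
        pr <- ifelse(Z, hl[["h"]], hl[["l"]])
        for (pt in b$pts)
          M[, match(pt, pts$pt)] <- stats::runif(m) < pr
      }
      M
    }

    M <- draw_events(seq_len(n))
    for (iter in 1:100) {
      empty <- which(rowSums(M) == 0)
      if (!length(empty)) break
      M[empty, ] <- draw_events(empty)
    }
    if (any(rowSums(M) == 0))
      stop("could not guarantee >= 1 event per report; raise base probabilities")

    # time-to-onset: first matching (class, pt) rule, day-rounded Weibull
    tto_shape <- rep(1, n); tto_scale <- rep(7, n)
    assigned <- rep(FALSE, n)
    for (r in seq_len(nrow(config$tto))) {
      rule <- config$tto[r, ]
      hit <- !assigned & drug_class == rule$class
      if (!is.na(rule$pt)) hit <- hit & M[, match(rule$pt, pts$pt)]
      tto_shape[hit] <- rule$shape; tto_scale[hit] <- rule$scale
      assigned <- assigned | hit
    }
    tto_days <- floor(stats::rweibull(n, tto_shape, tto_scale))

    # outcomes: fatality by year, overridden by PT-set conditionals
    p_year <- .yearFatalProb(config$fatality, config$years)
    p_fatal <- unname(p_year[as.character(year)])
    cond <- config$fatality$conditional
    if (!is.null(cond)) {
      sets <- strsplit(cond$pts, ";", fixed = TRUE)
      ord <- order(lengths(sets))
      for (i in ord) {
        js <- match(trimws(sets[[i]]), pts$pt)
        if (anyNA(js)) stop("conditional fatality PT not in vocabulary")
        hit <- rowSums(M[, js, drop = FALSE]) == length(js)
        p_fatal[hit] <- cond$prob[i]
      }
    }
    fatal <- stats::runif(n) < p_fatal
    op <- config$outcome_probs
    omat <- vapply(names(op), function(o) stats::runif(n) < op[[o]],
                   logical(n))
    outcomes <- lapply(seq_len(n), function(i) {
      o <- names(op)[omat[i, ]]
      if (fatal[i]) o <- c("DE", o)
      if (!length(o)) o <- "OT"
      o
    })

    # demographics
    age <- round(pmin(pmax(stats::rnorm(n, 60, 20), 1), 99))
    sex <- sample(c("M", "F"), n, replace = TRUE, prob = c(0.55, 0.45))
    weight <- round(stats::rlnorm(n, log(68.8), 0.25), 1)
    region <- sample(c("Americas", "Asia", "Europe", "Oceania", "Africa"),
                     n, replace = TRUE,
                     prob = c(0.574, 0.212, 0.196, 0.015, 0.003))
    reporter <- sample(c("Physician", "Health Professional", "Pharmacist",
                         "Consumer", "Other"), n, replace = TRUE,
                       prob = c(0.524, 0.187, 0.146, 0.095, 0.048))
    ind_tab <- list(
      CD19 = c(Leukaemia = 0.55, Lymphoma = 0.30, Unclassified = 0.15),
      BCMA = c(PlasmaCellNeoplasms = 0.80, Unclassified = 0.20),
      CD20 = c(Lymphoma = 0.80, Unclassified = 0.20),
      GPRC5D = c(PlasmaCellNeoplasms = 0.80, Unclassified = 0.20),
      Other = c(SolidTumors = 0.75, Unclassified = 0.25))
    indication <- character(n)
    for (tg in names(ind_tab)) {
      hit <- which(target == tg)
      w <- ind_tab[[tg]]
      indication[hit] <- sample(names(w), length(hit), replace = TRUE, prob = w)
    }

    ms <- config$missingness
    na_at <- function(x, rate) {
      x[stats::runif(length(x)) < rate] <- NA
      x
    }
    age <- na_at(age, ms[["age"]])
    sex <- na_at(sex, ms[["sex"]])
    weight <- na_at(weight, ms[["weight"]])
    region <- na_at(region, ms[["region"]])
    reporter <- na_at(reporter, ms[["reporter"]])
    indication <- na_at(indication, ms[["indication"]])
    tto_days[stats::runif(n) < ms[["dates"]]] <- NA

    start_dt <- as.Date(sprintf("%d-01-01", year)) +
      sample.int(360, n, replace = TRUE) - 1L
    event_dt <- start_dt + tto_days
    start_dt[is.na(tto_days)] <- NA
    event_dt[is.na(tto_days)] <- NA

    events <- apply(M, 1, function(r) pts$pt[r], simplify = FALSE)

    reports <- data.frame(
      report_id = sprintf("S%08d", seq_len(n)),
      drug_id = drug_id, drug_class = drug_class, target = target,
      fatal = fatal, age_years = as.numeric(age), sex = sex,
      weight_kg = weight, region = region, reporter = reporter,
      indication_group = indication, year = as.integer(year),
      tto_days = as.numeric(tto_days), stringsAsFactors = FALSE)
    reports$events <- events
    reports$outcomes <- outcomes
    reports$start_dt <- start_dt
    reports$event_dt <- event_dt
    reports <- reports[, c(.report_cols, "start_dt", "event_dt")]

    truth <- .groundTruth(reports, M, pts, config)
    set <- new("SafetyReportSet", reports = reports,
               audit = list(generated = n))
    new("SrsSimulation", reports = set, truth = truth, config = unclass(config))
  })
}

# realized planted-parameter ledger, recounted from the emitted reports
.groundTruth <- function(reports, M, pts, config) {
  n <- nrow(reports)
  sig <- NULL
  if (!is.null(config$signals)) {
    rows <- lapply(seq_len(nrow(config$signals)), function(i) {
      s <- config$signals[i, ]
      ex <- reports$drug_id == s$drug | reports$drug_class == s$drug
      ev <- M[, match(s$pt, pts$pt)]
      data.frame(drug = s$drug, pt = s$pt, planted_or = s$or,
                 a = sum(ex & ev), b = sum(ex & !ev),
                 c = sum(!ex & ev), d = sum(!ex & !ev),
                 stringsAsFactors = FALSE)
    })
    sig <- do.call(rbind, rows)
    sig$realized_or <- (sig$a * sig$d) / pmax(sig$b * sig$c, 1e-12)
  }
  co <- NULL
  if (!is.null(config$cooc)) {
    rows <- lapply(seq_len(nrow(config$cooc)), function(i) {
      p <- config$cooc[i, ]
      ha <- M[, match(p$pt_a, pts$pt)]
      hb <- M[, match(p$pt_b, pts$pt)]
      lift <- if (sum(ha) && sum(hb))
        (sum(ha & hb) / n) / ((sum(ha) / n) * (sum(hb) / n)) else 0
      data.frame(pt_a = p$pt_a, pt_b = p$pt_b, planted_lift = p$lift,
                 n_ab = sum(ha & hb), realized_lift = lift,
                 stringsAsFactors = FALSE)
    })
    co <- do.call(rbind, rows)
  }
  blk <- NULL
  if (!is.null(config$blocks)) {
    rows <- lapply(seq_along(config$blocks), function(i) {
      b <- config$blocks[[i]]
      js <- match(b$pts, pts$pt)
      prs <- utils::combn(js, 2)
      lifts <- apply(prs, 2, function(jj) {
        ha <- M[, jj[1]]; hb <- M[, jj[2]]
        if (sum(ha) && sum(hb))
          (sum(ha & hb) / n) / ((sum(ha) / n) * (sum(hb) / n)) else 0
      })
      data.frame(block = i, planted_lift = b$lift,
                 mean_realized_lift = mean(lifts),
                 stringsAsFactors = FALSE)
    })
    blk <- do.call(rbind, rows)
  }
  list(signals = sig, cooc = co, blocks = blk,
       params = list(seed = config$seed, n_reports = n,
                     fatality = config$fatality, tto = config$tto))
}

#' Emit a raw-record view with injected duplicates
#'
#' Converts generated reports to raw FAERS-dialect records and injects
#' (a) version duplicates: a fraction of cases re-emitted under the same
#' case id with a later receipt date and a higher primary id, and
#' (b) content clones: a further fraction re-emitted under a new case id
#' with identical content-key fields. The deduplication protocol should
#' restore exactly the original reports; the expected survivor count is
#' attached as attribute \code{"expected_survivors"}.
#'
#' @param reports a \linkS4class{SafetyReportSet} (or
#'   \linkS4class{SrsSimulation}).
#' @param version_rate fraction of cases given a second version.
#' @param clone_rate fraction of cases given a content clone
#'   (default \code{version_rate / 2}).
#' @param seed integer seed.
#' @return raw-record data.frame (see \code{\link{readQuarter}} for the
#'   schema).
#' @export
injectDuplicates <- function(reports, version_rate, clone_rate = version_rate / 2,
                             seed = 1L) {
  stopifnot(version_rate >= 0, version_rate < 1,
            clone_rate >= 0, clone_rate < 1)
  if (is(reports, "SrsSimulation")) reports <- reports@reports
  raw <- asRawRecords(reports)
  n <- nrow(raw)
  withr_seed(seed, {
    out <- raw
    if (version_rate > 0 && n > 0) {
      idx <- sample.int(n, max(1, round(version_rate * n)))
      dup <- raw[idx, , drop = FALSE]
      dup$primaryid <- paste0(dup$primaryid, "-2")
      dup$fda_dt <- dup$fda_dt + 30
      out <- rbind(out, dup)
    }
    if (clone_rate > 0 && n > 0) {
      idx <- sample.int(n, max(1, round(clone_rate * n)))
      cl <- raw[idx, , drop = FALSE]
      cl$caseid <- paste0("C", cl$caseid)
      cl$primaryid <- paste0("Z", cl$primaryid)  # sorts after the original
      out <- rbind(out, cl)
    }
    rownames(out) <- NULL
    attr(out, "expected_survivors") <- n
    out
  })
}

# SafetyReportSet -> raw FAERS-dialect record view
asRawRecords <- function(reports) {
  df <- if (is(reports, "SafetyReportSet")) reports@reports else reports
  n <- nrow(df)
  fda <- as.Date(sprintf("%d-07-01", df$year))
  raw <- data.frame(
    primaryid = df$report_id,
    caseid = df$report_id,
    fda_dt = fda,
    event_dt = df$event_dt %||% as.Date(rep(NA, n)),
    start_dt = df$start_dt %||% as.Date(rep(NA, n)),
    age = df$age_years, age_cod = ifelse(is.na(df$age_years), "", "YR"),
    sex = df$sex, wt = df$weight_kg,
    wt_cod = ifelse(is.na(df$weight_kg), "", "KG"),
    country = df$region, occp_cod = .reporterToCode(df$reporter),
    indi = .indicationToText(df$indication_group),
    ps_drug = df$drug_id, stringsAsFactors = FALSE)
  raw$drugs <- as.list(df$drug_id)
  raw$pts <- df$events
  raw$outcomes <- df$outcomes
  raw
}

.reporter_codes <- c(Physician = "MD", `Health Professional` = "HP",
                     Pharmacist = "PH", Consumer = "CN", Other = "OT")

.reporterToCode <- function(x) {
  out <- unname(.reporter_codes[x])
  out[is.na(x)] <- NA_character_
  out
}

.codeToReporter <- function(x) {
  inv <- stats::setNames(names(.reporter_codes), .reporter_codes)
  out <- unname(inv[x])
  out
}

.indication_text <- c(Leukaemia = "ACUTE LYMPHOBLASTIC LEUKAEMIA",
                      Lymphoma = "DIFFUSE LARGE B-CELL LYMPHOMA",
                      PlasmaCellNeoplasms = "PLASMA CELL MYELOMA",
                      SolidTumors = "METASTATIC MELANOMA",
                      Unclassified = "PRODUCT USED FOR UNKNOWN INDICATION")

.indicationToText <- function(x) {
  out <- unname(.indication_text[x])
  out[is.na(x)] <- NA_character_
  out
}
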