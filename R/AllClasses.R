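#' @import methods
NULL

#' DrugRegistry: the drug roster for cohort assignment
#'
#' Maps free-text drug names (brand names, synonyms, aliases) to a canonical
#' drug id with its therapeutic class (TCE or CAR-T) and molecular target.
#' Also carries the keyword table used to map free-text indications to the
#' five indication groups.
#'
#' @slot drugs data.frame with columns \code{drug_id}, \code{class}
#'   (\code{"TCE"} or \code{"CART"}), \code{target}, and a list-column
#'   \code{synonyms} of recognised names (matched case-insensitively).
#' @slot indication_keywords data.frame with columns \code{group} and
#'   \code{keyword}; the first keyword (case-insensitive substring) that hits
#'   an indication text assigns its group.
#' @exportClass DrugRegistry
setClass("DrugRegistry", representation(
  drugs = "data.frame",
  indication_keywords = "data.frame"
))

setValidity("DrugRegistry", function(object) {
  d <- object@drugs
  need <- c("drug_id", "class", "target", "synonyms")
  if (!all(need %in% names(d)))
    return(paste("drugs must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(d$drug_id)) return("duplicate drug_id in registry")
  if (!all(d$class %in% c("TCE", "CART")))
    return("class must be 'TCE' or 'CART'")
  syn <- toupper(unlist(d$synonyms))
  if (anyDuplicated(syn))
    return(paste("synonym maps to more than one drug:",
                 paste(unique(syn[duplicated(syn)]), collapse = ", ")))
  TRUE
})

#' SafetyReportSet: a collection of deduplicated safety reports
#'
#' The central container of the package. One row per deduplicated case,
#' with list-columns for the report's preferred-term (PT) events and its
#' outcome codes. Invariants enforced: every report carries at least one
#' event, and \code{fatal} is true exactly when the death outcome
#' (\code{"DE"}) is among the outcomes.
#'
#' @slot reports data.frame with columns \code{report_id}, \code{drug_id},
#'   \code{drug_class}, \code{target}, list-columns \code{events} and
#'   \code{outcomes}, \code{fatal}, \code{age_years}, \code{sex},
#'   \code{weight_kg}, \code{region}, \code{reporter},
#'   \code{indication_group}, \code{year}, \code{tto_days}.
#' @slot audit named list of counts recorded by the processing steps
#'   (rows read, duplicates removed per deduplication step, unresolved
#'   drugs, negative onset intervals suppressed, ...).
#' @exportClass SafetyReportSet
setClass("SafetyReportSet", representation(
  reports = "data.frame",
  audit = "list"
))

.report_cols <- c("report_id", "drug_id", "drug_class", "target", "events",
                  "outcomes", "fatal", "age_years", "sex", "weight_kg",
                  "region", "reporter", "indication_group", "year", "tto_days")

setValidity("SafetyReportSet", function(object) {
  r <- object@reports
  miss <- setdiff(.report_cols, names(r))
  if (length(miss)) return(paste("missing columns:", paste(miss, collapse = ", ")))
  if (nrow(r)) {
    if (anyDuplicated(r$report_id)) return("report_id not unique")
    if (any(lengths(r$events) == 0)) return("every report must have >= 1 event")
    de <- vapply(r$outcomes, function(o) "DE" %in% o, logical(1))
    if (!identical(unname(de), unname(r$fatal)))
      return("fatal flag must equal presence of the DE outcome")
    tto <- r$tto_days
    if (any(!is.na(tto) & tto < 0)) return("tto_days must be nonnegative or NA")
  }
  TRUE
})

#' ContingencyTable: the 2x2 table behind every disproportionality statistic
#'
#' Cell a counts reports matching both the exposure and the event predicate,
#' b exposure-only, c event-only, d neither; N = a+b+c+d.
#'
#' @slot a,b,c,d single nonnegative integer-valued counts.
#' @exportClass ContingencyTable
setClass("ContingencyTable", representation(
  a = "numeric", b = "numeric", c = "numeric", d = "numeric"
))

setValidity("ContingencyTable", function(object) {
  x <- c(object@a, object@b, object@c, object@d)
  if (length(x) != 4 || any(is.na(x))) return("a,b,c,d must be single counts")
  if (any(x < 0) || any(x != floor(x))) return("counts must be nonnegative integers")
  if (sum(x) <= 0) return("N must be > 0")
  TRUE
})

#' SignalResult: all eight disproportionality estimators for one pair
#'
#' @slot exposure,event labels of the pair.
#' @slot table the underlying \linkS4class{ContingencyTable}.
#' @slot stats named numeric vector: \code{ror}, \code{ror_lo}, \code{ror_hi},
#'   \code{prr}, \code{prr_lo}, \code{prr_hi}, \code{chi2}, \code{fisher_p},
#'   \code{oe}, \code{oe_lo}, \code{oe_hi}, \code{ic_norm}, \code{ic_norm_025},
#'   \code{ic_mcmc}, \code{ic_mcmc_025}, \code{ebgm}, \code{eb05}.
#' @slot flags named logical vector, one per algorithm
#'   (\code{ror}, \code{prr}, \code{chi2}, \code{fisher}, \code{oe},
#'   \code{bcpnn_norm}, \code{bcpnn_mcmc}, \code{ebgm}).
#' @slot corrected TRUE when a zero cell forced the Haldane-Anscombe
#'   continuity correction for the ROR/PRR point and interval.
#' @exportClass SignalResult
setClass("SignalResult", representation(
  exposure = "character", event = "character",
  table = "ContingencyTable",
  stats = "numeric", flags = "logical", corrected = "logical"
))

#' GpsHyperparams: the DuMouchel gamma-Poisson shrinker prior
#'
#' Two-component gamma mixture prior for the relative reporting rate,
#' estimated by maximising the negative-binomial mixture marginal likelihood.
#'
#' @slot alpha1,beta1 shape/rate of the first gamma component.
#' @slot alpha2,beta2 shape/rate of the second gamma component.
#' @slot mix_p mixing weight of the first component, in (0,1).
#' @slot loglik marginal log-likelihood at the optimum.
#' @slot convergence optimizer convergence code (0 = converged).
#' @exportClass GpsHyperparams
setClass("GpsHyperparams", representation(
  alpha1 = "numeric", beta1 = "numeric",
  alpha2 = "numeric", beta2 = "numeric",
  mix_p = "numeric", loglik = "numeric", convergence = "numeric"
))

setValidity("GpsHyperparams", function(object) {
  p <- c(object@alpha1, object@beta1, object@alpha2, object@beta2)
  if (any(p <= 0)) return("gamma hyperparameters must be positive")
  if (object@mix_p <= 0 || object@mix_p >= 1) return("mix_p must be in (0,1)")
  TRUE
})

#' DSRResult: drug-specificity analysis for one event
#'
#' Ratio of the highest to the second-highest reporting odds ratio for an
#' event across the drugs of a cohort; an event reported for a single drug
#' has an infinite ratio, which counts as meeting the specificity criterion.
#'
#' @slot event the PT analysed.
#' @slot per_drug data.frame (\code{drug_id}, \code{ror}, \code{a},
#'   \code{flagged}) for each cohort drug reporting the event.
#' @slot top_drug,top_ror the drug with the highest ROR and its value.
#' @slot second_ror second-highest ROR (NA when only one drug reports).
#' @slot ratio top_ror / second_ror (Inf when second is absent).
#' @slot is_specific TRUE when the ROR signal criteria hold for the top drug
#'   together with ROR > 5 and ratio > 10 (infinite counts as met).
#' @exportClass DSRResult
setClass("DSRResult", representation(
  event = "character", per_drug = "data.frame",
  top_drug = "character", top_ror = "numeric",
  second_ror = "numeric", ratio = "numeric", is_specific = "logical"
))

#' WeibullFit: maximum-likelihood Weibull fit of time-to-onset
#'
#' Shape below 1 indicates an early-peaking reporting hazard, shape
#' indistinguishable from 1 a constant rate, shape above 1 a late-peaking
#' (wear-out) pattern.
#'
#' @slot shape,scale MLE point estimates (scale in days).
#' @slot shape_ci,scale_ci 95\% Wald intervals on the log scale.
#' @slot loglik maximised log-likelihood.
#' @slot n number of onset values used.
#' @slot method \code{"interval"} (day-resolution interval-censored
#'   likelihood) or \code{"shift"} (continuous MLE after the half-day
#'   zero shift).
#' @slot pattern \code{"early-peaking"}, \code{"constant-rate"} or
#'   \code{"late-peaking"}, from the position of the shape CI versus 1.
#' @exportClass WeibullFit
setClass("WeibullFit", representation(
  shape = "numeric", scale = "numeric",
  shape_ci = "numeric", scale_ci = "numeric",
  loglik = "numeric", n = "numeric",
  method = "character", pattern = "character"
))

setValidity("WeibullFit", function(object) {
  if (object@shape <= 0 || object@scale <= 0) return("shape and scale must be positive")
  if (length(object@shape_ci) != 2 || length(object@scale_ci) != 2)
    return("CIs must have length 2")
  if (object@shape_ci[1] > object@shape || object@shape_ci[2] < object@shape)
    return("shape CI must bracket the point estimate")
  TRUE
})

#' CoocNetwork: lift-weighted adverse-event co-occurrence network
#'
#' @slot graph the undirected \pkg{igraph} graph; edge weights are lift.
#' @slot nodes data.frame (\code{pt}, \code{n}) of retained PTs and their
#'   report frequency.
#' @slot edges data.frame (\code{pt_a}, \code{pt_b}, \code{n_ab},
#'   \code{lift}) of admitted edges.
#' @slot membership named integer vector: community id per PT.
#' @slot modularity weighted modularity Q of the partition (NA for an
#'   empty graph).
#' @slot hubs data.frame (\code{community}, \code{size}, \code{hub},
#'   \code{centrality}) with the eigenvector-centrality hub per community.
#' @exportClass CoocNetwork
setClass("CoocNetwork", representation(
  graph = "ANY", nodes = "data.frame", edges = "data.frame",
  membership = "integer", modularity = "numeric", hubs = "data.frame"
))

#' SrsSimulation: synthetic SRS database plus its ground truth
#'
#' @slot reports the generated \linkS4class{SafetyReportSet}.
#' @slot truth list with realized 2x2 counts for every planted drug-event
#'   signal, realized lift for every planted pair, and an echo of the
#'   generating parameters.
#' @slot config the \code{srsConfig()} list that produced the data.
#' @exportClass SrsSimulation
setClass("SrsSimulation", representation(
  reports = "SafetyReportSet", truth = "list", config = "list"
))

# ---- show methods -----------------------------------------------------------

setMethod("show", "SafetyReportSet", function(object) {
  r <- object@reports
  cat("SafetyReportSet with", nrow(r), "reports\n")
  if (nrow(r)) {
    cat("  classes: ", paste(sprintf("%s=%d", names(table(r$drug_class)),
                                     table(r$drug_class)), collapse = ", "), "\n")
    cat("  years:   ", paste(range(r$year, na.rm = TRUE), collapse = "-"), "\n")
    cat("  fatal:   ", sprintf("%.1f%%", 100 * mean(r$fatal)), "\n")
  }
  if (length(object@audit))
    cat("  audit:   ", paste(sprintf("%s=%s", names(object@audit),
                                     unlist(object@audit)), collapse = ", "), "\n")
})

setMethod("show", "ContingencyTable", function(object) {
  cat("ContingencyTable (a,b,c,d) = (",
      paste(c(object@a, object@b, object@c, object@d), collapse = ", "),
      "), N =", object@a + object@b + object@c + object@d, "\n")
})

setMethod("show", "SignalResult", function(object) {
  cat("SignalResult:", object@exposure, "~", object@event, "\n")
  s <- object@stats
  cat(sprintf("  ROR %.2f (%.2f-%.2f)  PRR %.2f  chi2 %.2f  Fisher p %.3g\n",
              s["ror"], s["ror_lo"], s["ror_hi"], s["prr"], s["chi2"], s["fisher_p"]))
  cat(sprintf("  O/E %.2f  IC(norm) %.2f [%.2f]  IC(mcmc) %.2f [%.2f]  EBGM %.2f (EB05 %.2f)\n",
              s["oe"], s["ic_norm"], s["ic_norm_025"], s["ic_mcmc"],
              s["ic_mcmc_025"], s["ebgm"], s["eb05"]))
  cat("  flags:", paste(names(object@flags)[object@flags], collapse = ", "), "\n")
})

setMethod("show", "GpsHyperparams", function(object) {
  cat(sprintf("GpsHyperparams: alpha1=%.3f beta1=%.3f alpha2=%.3f beta2=%.3f P=%.3f (loglik %.2f)\n",
              object@alpha1, object@beta1, object@alpha2, object@beta2,
              object@mix_p, object@loglik))
})

setMethod("show", "WeibullFit", function(object) {
  cat(sprintf("WeibullFit (%s, n=%d): shape %.3f (95%% CI %.3f-%.3f), scale %.2f days -> %s\n",
              object@method, as.integer(object@n), object@shape,
              object@shape_ci[1], object@shape_ci[2], object@scale, object@pattern))
})

setMethod("show", "DSRResult", function(object) {
  cat(sprintf("DSRResult '%s': top %s ROR=%.2f, second=%.2f, ratio=%.2f, specific=%s\n",
              object@event, object@top_drug, object@top_ror, object@second_ror,
              object@ratio, object@is_specific))
})

setMethod("show", "CoocNetwork", function(object) {
  cat("CoocNetwork:", nrow(object@nodes), "PTs,", nrow(object@edges),
      "edges,", length(unique(object@membership)), "communities, Q =",
      round(object@modularity, 4), "\n")
})

setMethod("show", "SrsSimulation", function(object) {
  cat("SrsSimulation:", nrow(object@reports@reports), "reports; planted signals:",
      nrow(object@truth$signals %||% data.frame()), "; planted pairs:",
      nrow(object@truth$cooc %||% data.frame()), "\n")
})

`%||%` <- function(a, b) if (is.null(a)) b else a
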