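#' Construct a 2x2 contingency table
#'
#' @param a,b,c,d nonnegative integer counts: a = exposure & event,
#'   b = exposure only, c = event only, d = neither.
#' @return A \linkS4class{ContingencyTable}.
#' @export
contingencyTable <- function(a, b, c, d) {
  new("ContingencyTable", a = as.numeric(a), b = as.numeric(b),
      c = as.numeric(c), d = as.numeric(d))
}

#' Selector helpers for building contingency tables
#'
#' Predicates over the report set used as exposure / event selectors:
#' \code{byDrug}, \code{byClass}, \code{byTarget} match on the resolved
#' primary-suspect drug; \code{byEvent} matches reports carrying a given PT
#' (or any of several PTs). Each returns a function mapping the report
#' data.frame to a logical vector.
#'
#' @param drug_id,class,target,pt the value(s) to match.
#' @return A predicate function.
#' @name selectors
NULL

#' @rdname selectors
#' @export
byDrug <- function(drug_id) {
  force(drug_id)
  function(df) df$drug_id %in% drug_id
}
#' @rdname selectors
#' @export
byClass <- function(class) {
  force(class)
  function(df) df$drug_class %in% class
}
#' @rdname selectors
#' @export
byTarget <- function(target) {
  force(target)
  function(df) df$target %in% target
}
#' @rdname selectors
#' @export
byEvent <- function(pt) {
  force(pt)
  function(df) vapply(df$events, function(e) any(pt %in% e), logical(1))
}

#' Build a 2x2 contingency table from a report set
#'
#' Report-level counting: a report contributes once to cell a when it
#' matches both predicates, however many of its PTs match. The background
#' cells (c, d) are the non-exposed reports in scope, so comparative
#' frameworks (e.g. one therapeutic class against another) are obtained by
#' restricting \code{reports} to the union of the two cohorts first.
#'
#' @param reports a \linkS4class{SafetyReportSet} or its data.frame.
#' @param exposure,event predicate functions over the report data.frame
#'   (see \link{selectors}).
#' @return A \linkS4class{ContingencyTable}. A selector matching nothing
#'   yields a table with a = b = 0 (allowed; a warning is emitted).
#' @export
buildTable <- function(reports, exposure, event) {
  df <- if (is(reports, "SafetyReportSet")) reports@reports else reports
  if (!nrow(df)) stop("empty report set")
  ex <- exposure(df)
  ev <- event(df)
  if (!any(ex)) warning("exposure selector matched no reports")
  tab <- contingencyTable(sum(ex & ev), sum(ex & !ev), sum(!ex & ev), sum(!ex & !ev))
  tab
}

#' Build contingency tables for all exposure x event pairs
#'
#' Batch driver: one table per (exposure, event) pair, computed from a
#' single pass over the report set. Exposures are given as a named list of
#' predicates (or a character vector of drug ids); events as a character
#' vector of PTs.
#'
#' @param reports a \linkS4class{SafetyReportSet} or its data.frame.
#' @param exposures named list of predicates, or character vector of drug
#'   ids (used as both name and \code{byDrug} selector).
#' @param events character vector of PTs.
#' @return data.frame with columns \code{exposure}, \code{event},
#'   \code{a}, \code{b}, \code{c}, \code{d}.
#' @export
buildAllPairs <- function(reports, exposures, events) {
  df <- if (is(reports, "SafetyReportSet")) reports@reports else reports
  if (!nrow(df)) stop("empty report set")
  if (is.character(exposures))
    exposures <- stats::setNames(lapply(exposures, byDrug), exposures)
  if (is.null(names(exposures)) || anyDuplicated(names(exposures)))
    stop("exposures must be uniquely named")
  if (anyDuplicated(events)) stop("duplicate event keys")
  n <- nrow(df)
  # incidence of each event PT across reports, via one unlist pass
  ev_long <- unlist(df$events, use.names = FALSE)
  rep_idx <- rep.int(seq_len(n), lengths(df$events))
  has <- matrix(FALSE, n, length(events), dimnames = list(NULL, events))
  keep <- ev_long %in% events
  if (any(keep))
    has[cbind(rep_idx[keep], match(ev_long[keep], events))] <- TRUE
  out <- vector("list", length(exposures) * length(events))
  k <- 0L
  for (xn in names(exposures)) {
    ex <- exposures[[xn]](df)
    nex <- sum(ex)
    a <- colSums(has[ex, , drop = FALSE])
    cc <- colSums(has[!ex, , drop = FALSE])
    for (j in seq_along(events)) {
      k <- k + 1L
      out[[k]] <- data.frame(exposure = xn, event = events[j],
                             a = a[j], b = nex - a[j],
                             c = cc[j], d = (n - nex) - cc[j],
                             stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
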