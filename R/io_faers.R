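## FAERS-dialect quarterly ASCII ingestion: '$'-delimited files with a
## header row (DEMO/DRUG/REAC/OUTC/THER/INDI), deduplication per the
## multi-step protocol, and cohort assignment against a drug registry.

.fmt_date <- function(d) ifelse(is.na(d), "", format(d, "%Y%m%d"))

.parse_date <- function(x) {
  x <- trimws(x)
  out <- rep(as.Date(NA), length(x))
  ok <- grepl("^[0-9]{8}$", x)
  out[ok] <- as.Date(x[ok], format = "%Y%m%d")
  # partial dates (year or year-month) stay NA at day resolution
  out
}

.read_dollar <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("empty file: ", path)
  header <- lines[1]
  body <- lines[-1]
  dup_hdr <- body == header
  body <- body[!dup_hdr]
  cols <- strsplit(header, "$", fixed = TRUE)[[1]]
  # sentinel keeps trailing empty fields; strsplit would drop them
  parts <- strsplit(paste0(body, "$\r"), "$", fixed = TRUE)
  parts <- lapply(parts, function(p) p[-length(p)])
  bad <- lengths(parts) != length(cols)
  parts <- parts[!bad]
  m <- if (length(parts)) do.call(rbind, parts) else
    matrix(character(0), 0, length(cols))
  df <- as.data.frame(m, stringsAsFactors = FALSE)
  names(df) <- cols
  attr(df, "skipped_headers") <- sum(dup_hdr)
  attr(df, "malformed") <- sum(bad)
  df
}

#' Read a FAERS-dialect quarter into raw report records
#'
#' Reads the '$'-delimited quarterly tables and joins them on
#' \code{primaryid} into one raw record per DEMO row. DEMO, DRUG and REAC
#' are mandatory; OUTC, THER and INDI optional. Duplicate header lines and
#' rows with the wrong field count are skipped and counted (attribute
#' \code{"audit"}); unparseable dates become missing fields, never errors.
#'
#' @param paths either a directory containing \code{DEMO.txt},
#'   \code{DRUG.txt}, ... or a named list/vector of file paths with names
#'   \code{demo}, \code{drug}, \code{reac}, \code{outc}, \code{ther},
#'   \code{indi}.
#' @return raw-record data.frame: \code{primaryid}, \code{caseid},
#'   \code{fda_dt}, \code{event_dt}, \code{start_dt}, \code{age},
#'   \code{age_cod}, \code{sex}, \code{wt}, \code{wt_cod}, \code{country},
#'   \code{occp_cod}, \code{indi}, \code{ps_drug}, list-columns
#'   \code{drugs}, \code{pts}, \code{outcomes}.
#' @export
readQuarter <- function(paths) {
  if (length(paths) == 1 && is.character(paths) && dir.exists(paths)) {
    find1 <- function(stem) {
      hit <- list.files(paths, pattern = paste0("^", stem, "\\.(txt|TXT)$"),
                        ignore.case = TRUE, full.names = TRUE)
      if (length(hit)) hit[1] else NA_character_
    }
    paths <- list(demo = find1("DEMO"), drug = find1("DRUG"),
                  reac = find1("REAC"), outc = find1("OUTC"),
                  ther = find1("THER"), indi = find1("INDI"))
  }
  for (f in c("demo", "drug", "reac"))
    if (is.null(paths[[f]]) || is.na(paths[[f]]) || !file.exists(paths[[f]]))
      stop("mandatory file missing: ", f)
  demo <- .read_dollar(paths$demo)
  drug <- .read_dollar(paths$drug)
  reac <- .read_dollar(paths$reac)
  opt <- function(f) if (!is.null(paths[[f]]) && !is.na(paths[[f]]) &&
                           file.exists(paths[[f]])) .read_dollar(paths[[f]]) else NULL
  outc <- opt("outc"); ther <- opt("ther"); indi <- opt("indi")

  pid <- demo$primaryid
  num <- function(x) suppressWarnings(as.numeric(x))
  grp <- function(tab, val_col) {
    if (is.null(tab) || !nrow(tab)) return(stats::setNames(list(), character(0)))
    split(tab[[val_col]], tab$primaryid)
  }
  drugs_by <- grp(drug, "drugname")
  ps_by <- grp(drug[drug$role_cod == "PS", , drop = FALSE], "drugname")
  pts_by <- grp(reac, "pt")
  outc_by <- grp(outc, "outc_cod")
  ther1 <- if (!is.null(ther) && nrow(ther))
    tapply(ther$start_dt, ther$primaryid, function(x) x[1]) else NULL
  indi1 <- if (!is.null(indi) && nrow(indi))
    tapply(indi$indi_pt, indi$primaryid, function(x) x[1]) else NULL

  pick <- function(by, default) {
    out <- by[pid]
    out[vapply(out, is.null, logical(1))] <- list(default)
    unname(out)
  }
  raw <- data.frame(
    primaryid = pid, caseid = demo$caseid,
    fda_dt = .parse_date(demo$fda_dt),
    event_dt = .parse_date(demo$event_dt),
    start_dt = if (!is.null(ther1)) .parse_date(unname(ther1[pid]))
    else as.Date(rep(NA, length(pid))),
    age = num(demo$age), age_cod = demo$age_cod,
    sex = ifelse(nzchar(trimws(demo$sex)), demo$sex, NA),
    wt = num(demo$wt), wt_cod = demo$wt_cod,
    country = ifelse(nzchar(trimws(demo$occr_country)), demo$occr_country, NA),
    occp_cod = ifelse(nzchar(trimws(demo$occp_cod)), demo$occp_cod, NA),
    indi = if (!is.null(indi1)) {
      v <- unname(indi1[pid])
      ifelse(!is.na(v) & nzchar(trimws(v)), v, NA)
    } else NA_character_,
    stringsAsFactors = FALSE)
  raw$ps_drug <- vapply(pick(ps_by, character(0)), function(x)
    if (length(x)) x[1] else NA_character_, character(1))
  raw$drugs <- pick(drugs_by, character(0))
  raw$pts <- pick(pts_by, character(0))
  raw$outcomes <- pick(outc_by, character(0))
  attr(raw, "audit") <- list(
    demo_rows = nrow(demo),
    skipped_headers = sum(vapply(list(demo, drug, reac), attr,
                                 0, "skipped_headers")),
    malformed = sum(vapply(list(demo, drug, reac), attr, 0, "malformed")))
  raw
}

#' Write reports (or raw records) as FAERS-dialect quarterly files
#'
#' Emits DEMO/DRUG/REAC/OUTC/THER/INDI '$'-delimited files such that
#' \code{readQuarter()} on the output reproduces the records up to field
#' ordering; missing values round-trip as empty fields.
#'
#' @param x a \linkS4class{SafetyReportSet}, \linkS4class{SrsSimulation}
#'   or raw-record data.frame.
#' @param out_dir output directory (created if needed).
#' @return invisible named vector of the file paths written.
#' @export
writeFaersDialect <- function(x, out_dir) {
  if (is(x, "SrsSimulation")) x <- x@reports
  raw <- if (is(x, "SafetyReportSet")) asRawRecords(x) else x
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  na2e <- function(v) ifelse(is.na(v), "", as.character(v))
  wr <- function(df, name) {
    path <- file.path(out_dir, paste0(name, ".txt"))
    lines <- c(paste(names(df), collapse = "$"),
               do.call(paste, c(lapply(df, na2e), sep = "$")))
    writeLines(lines, path)
    path
  }
  demo <- data.frame(primaryid = raw$primaryid, caseid = raw$caseid,
                     fda_dt = .fmt_date(raw$fda_dt),
                     event_dt = .fmt_date(raw$event_dt),
                     age = raw$age, age_cod = raw$age_cod, sex = raw$sex,
                     wt = raw$wt, wt_cod = raw$wt_cod,
                     occr_country = raw$country, occp_cod = raw$occp_cod,
                     stringsAsFactors = FALSE)
  rep_n <- function(col) rep.int(raw$primaryid, lengths(col))
  drug <- data.frame(primaryid = rep_n(raw$drugs),
                     drug_seq = unlist(lapply(lengths(raw$drugs), seq_len)),
                     role_cod = "PS",
                     drugname = unlist(raw$drugs), stringsAsFactors = FALSE)
  reac <- data.frame(primaryid = rep_n(raw$pts),
                     pt = unlist(raw$pts), stringsAsFactors = FALSE)
  outc <- data.frame(primaryid = rep_n(raw$outcomes),
                     outc_cod = unlist(raw$outcomes), stringsAsFactors = FALSE)
  ther <- data.frame(primaryid = raw$primaryid, dsg_drug_seq = 1,
                     start_dt = .fmt_date(raw$start_dt),
                     stringsAsFactors = FALSE)
  indi <- data.frame(primaryid = raw$primaryid, indi_drug_seq = 1,
                     indi_pt = raw$indi, stringsAsFactors = FALSE)
  paths <- c(demo = wr(demo, "DEMO"), drug = wr(drug, "DRUG"),
             reac = wr(reac, "REAC"), outc = wr(outc, "OUTC"),
             ther = wr(ther, "THER"), indi = wr(indi, "INDI"))
  invisible(paths)
}

#' Deduplicate raw report records
#'
#' Three steps, each audited: (1) version selection — per case id keep the
#' record with the latest receipt date (missing dates count as oldest),
#' ties broken by the highest primary id; (2) content duplicates — records
#' identical on the content-key fields collapse to the one with the
#' lexicographically smallest primary id; (3) removal of case ids on the
#' deletion list. Idempotent.
#'
#' @param raw raw-record data.frame (from \code{\link{readQuarter}} or
#'   \code{\link{injectDuplicates}}).
#' @param deletion_list character vector of withdrawn case ids.
#' @param content_key character vector of the fields defining a content
#'   duplicate; the default mirrors common FAERS practice (event date,
#'   age, sex, weight, country, sorted PT set, sorted drug-name set).
#' @return deduplicated raw-record data.frame; attribute \code{"audit"}
#'   holds the number removed at each step.
#' @export
deduplicate <- function(raw, deletion_list = character(0),
                        content_key = c("event_dt", "age", "sex", "wt",
                                        "country", "pts", "drugs")) {
  n0 <- nrow(raw)
  if (!n0) {
    attr(raw, "audit") <- list(input = 0, versions_removed = 0,
                               content_removed = 0, deleted = 0)
    return(raw)
  }
  # (1) latest version per case
  fda_key <- ifelse(is.na(raw$fda_dt), as.Date("1900-01-01"), raw$fda_dt)
  ord <- order(raw$caseid, fda_key, raw$primaryid)
  r1 <- raw[ord, , drop = FALSE]
  keep1 <- !duplicated(r1$caseid, fromLast = TRUE)
  r1 <- r1[keep1, , drop = FALSE]
  n1 <- nrow(r1)
  # (2) content duplicates
  keyof <- function(df) {
    parts <- lapply(content_key, function(k) {
      col <- df[[k]]
      if (is.list(col)) vapply(col, function(v)
        paste(sort(as.character(v)), collapse = "|"), character(1))
      else as.character(col)
    })
    do.call(paste, c(parts, sep = "\r"))
  }
  key <- keyof(r1)
  ord2 <- order(key, r1$primaryid)
  r2 <- r1[ord2, , drop = FALSE]
  keep2 <- !duplicated(key[ord2])
  r2 <- r2[keep2, , drop = FALSE]
  n2 <- nrow(r2)
  # (3) deletion list
  r3 <- r2[!(r2$caseid %in% deletion_list), , drop = FALSE]
  r3 <- r3[order(r3$primaryid), , drop = FALSE]
  rownames(r3) <- NULL
  attr(r3, "audit") <- list(input = n0, versions_removed = n0 - n1,
                            content_removed = n1 - n2,
                            deleted = n2 - nrow(r3))
  r3
}

#' Assign cohort membership and normalise raw records into SafetyReports
#'
#' Keeps only records whose primary-suspect drug resolves in the registry,
#' normalises units (age codes YR/MON/WK/DY/DEC to years, clipped to
#' [0, 120] else missing; weight LBS to kg), maps indication text to its
#' group via the registry keyword table, derives the onset interval
#' (event date minus therapy start date; negative intervals become
#' missing and are audited) and drops invalid records (no events).
#'
#' @param raw deduplicated raw-record data.frame.
#' @param registry a \linkS4class{DrugRegistry}.
#' @return A \linkS4class{SafetyReportSet} with an audit of exclusions.
#' @export
assignCohort <- function(raw, registry) {
  n0 <- nrow(raw)
  drug_id <- resolveDrug(raw$ps_drug, registry)
  resolved <- !is.na(drug_id)
  valid <- lengths(raw$pts) > 0
  keep <- resolved & valid
  r <- raw[keep, , drop = FALSE]
  drug_id <- drug_id[keep]
  d <- registry@drugs
  di <- match(drug_id, d$drug_id)

  age_years <- r$age
  conv <- c(YR = 1, MON = 1 / 12, WK = 1 / 52.1775, DY = 1 / 365.25, DEC = 10)
  cf <- conv[toupper(r$age_cod)]
  age_years <- ifelse(is.na(cf), age_years, age_years * cf)
  age_years[!is.na(age_years) & (age_years < 0 | age_years > 120)] <- NA

  wt <- r$wt
  lbs <- !is.na(r$wt_cod) & toupper(r$wt_cod) %in% c("LBS", "LB")
  wt[lbs] <- wt[lbs] * 0.45359237

  tto <- as.numeric(r$event_dt - r$start_dt)
  neg <- sum(!is.na(tto) & tto < 0)
  tto[!is.na(tto) & tto < 0] <- NA

  outcomes <- r$outcomes
  fatal <- vapply(outcomes, function(o) "DE" %in% o, logical(1))

  reports <- data.frame(
    report_id = r$primaryid,
    drug_id = drug_id,
    drug_class = d$class[di],
    target = d$target[di],
    fatal = fatal,
    age_years = age_years,
    sex = r$sex,
    weight_kg = wt,
    region = r$country,
    reporter = .codeToReporter(r$occp_cod),
    indication_group = mapIndication(r$indi, registry),
    year = as.integer(format(r$fda_dt, "%Y")),
    tto_days = tto,
    stringsAsFactors = FALSE)
  reports$events <- r$pts
  reports$outcomes <- outcomes
  reports$start_dt <- r$start_dt
  reports$event_dt <- r$event_dt
  reports <- reports[, c(.report_cols, "start_dt", "event_dt")]
  rownames(reports) <- NULL
  new("SafetyReportSet", reports = reports,
      audit = c(attr(raw, "audit") %||% list(),
                list(unresolved_drug = sum(!resolved),
                     no_events = sum(resolved & !valid),
                     negative_tto = neg,
                     assigned = nrow(reports))))
}
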