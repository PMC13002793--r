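#' Pipeline configuration
#'
#' Assembles and validates the configuration for the end-to-end driver.
#' Thresholds default to the standard signal-detection values (the eight
#' algorithm thresholds, edge admission at co-occurrence count >= 10 and
#' lift > 2, drug-specificity at ROR > 5 and ratio > 10, BH cutoff 0.05);
#' every default is overridable. Unknown keys are a hard error.
#'
#' @param input either \code{list(mode = "synthetic", config = srsConfig)}
#'   or \code{list(mode = "faers", dir = <quarter dir>, deletion_list =
#'   <chr>)}.
#' @param seed global seed; per-stage child seeds are derived from it
#'   (stage k uses seed * 10 + k).
#' @param out_dir output directory for tables and the run manifest
#'   (NULL = no files written).
#' @param events PTs analysed for signals (default: the AEs of special
#'   interest bundled in the mock dictionary's named terms).
#' @param ae_of_interest PT list for the intersection (UpSet) table.
#' @param thresholds named list overriding \code{min_count},
#'   \code{min_lift}, \code{dsr_ror}, \code{dsr_ratio}, \code{bh_alpha}.
#' @param mcmc_draws Monte Carlo draws for the BCPNN MCMC variant.
#' @param log_level \code{"info"} or \code{"quiet"}.
#' @return validated list of class \code{"pipeline_config"}.
#' @export
pipelineConfig <- function(input = list(mode = "synthetic",
                                        config = srsConfig()),
                           seed = 1L, out_dir = NULL,
                           events = NULL, ae_of_interest = NULL,
                           thresholds = list(), mcmc_draws = 2000,
                           log_level = c("info", "quiet")) {
  log_level <- match.arg(log_level)
  stopifnot(is.list(input), !is.null(input$mode))
  if (!input$mode %in% c("synthetic", "faers"))
    stop("input mode must be 'synthetic' or 'faers'")
  th <- list(min_count = 10, min_lift = 2, dsr_ror = 5, dsr_ratio = 10,
             bh_alpha = 0.05)
  unknown <- setdiff(names(thresholds), names(th))
  if (length(unknown)) stop("unknown threshold key: ",
                            paste(unknown, collapse = ", "))
  th[names(thresholds)] <- thresholds
  if (is.null(events)) {
    icans <- "immune effector cell-associated neurotoxicity syndrome"
    events <- c("cytokine release syndrome", icans, "tumour lysis syndrome",
                "infection", "cytopenia",
                "hemophagocytic lymphohistiocytosis",
                "multiple organ dysfunction syndrome")
  }
  if (is.null(ae_of_interest))
    ae_of_interest <- c("cytokine release syndrome",
                        "immune effector cell-associated neurotoxicity syndrome",
                        "infection")
  structure(list(input = input, seed = as.integer(seed), out_dir = out_dir,
                 events = events, ae_of_interest = ae_of_interest,
                 thresholds = th, mcmc_draws = mcmc_draws,
                 log_level = log_level),
            class = "pipeline_config")
}

.plog <- function(cfg, stage, ...) {
  if (cfg$log_level == "info")
    message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"),
                    stage, paste0(...)))
}

#' Run the full analysis pipeline
#'
#' Stages execute in order: input (synthetic generation or FAERS-dialect
#' ingestion) -> deduplication -> cohort assignment -> contingency +
#' eight-algorithm signal detection (TCE vs background, CAR-T vs
#' background, TCE vs CAR-T, and per-drug) -> drug-specificity ->
#' time-to-onset and Weibull fits -> co-occurrence network -> cohort
#' statistics (comparison table, fatal-outcome trend, univariate risk
#' factors). A stage failure aborts with a stage-tagged error. Given the
#' same inputs and seed the result bundle (and manifest) is identical.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @return list of class \code{"pipeline_result"}: \code{reports},
#'   \code{signals} (per-framework tables), \code{dsr}, \code{tto},
#'   \code{network}, \code{cohort}, and \code{manifest} (seed, stage
#'   counts, package version, threshold echo).
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  stage_seed <- function(k) seed * 10L + k
  th <- config$thresholds
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE))
  }
  counts <- list()

  # -- input + dedup + cohort --------------------------------------------
  reports <- run_stage("input", {
    if (config$input$mode == "synthetic") {
      sim <- generateSrs(config$input$config)
      .plog(config, "input", paste("synthetic reports:", length(sim@reports)))
      sim@reports
    } else {
      raw <- readQuarter(config$input$dir)
      .plog(config, "input", paste("raw records:", nrow(raw)))
      raw <- run_stage("dedup",
                       deduplicate(raw, config$input$deletion_list %||% character(0)))
      run_stage("cohort-assign", assignCohort(raw, config$input$registry %||%
                                                defaultRegistry()))
    }
  })
  counts$reports <- length(reports)
  df <- reports@reports

  # -- signal detection ---------------------------------------------------
  signals <- run_stage("disprop", {
    frameworks <- list(
      tce_vs_background = list(reports = df, exposures = list(TCE = byClass("TCE"))),
      cart_vs_background = list(reports = df, exposures = list(CART = byClass("CART"))),
      tce_vs_cart = list(reports = df[df$drug_class %in% c("TCE", "CART"), ],
                         exposures = list(TCE = byClass("TCE"))))
    out <- lapply(names(frameworks), function(fw) {
      f <- frameworks[[fw]]
      signalTable(f$reports, f$exposures, config$events,
                  mcmc_draws = config$mcmc_draws, seed = stage_seed(4L))
    })
    names(out) <- names(frameworks)
    tce_drugs <- sort(unique(df$drug_id[df$drug_class == "TCE"]))
    out$per_drug <- signalTable(df, tce_drugs, config$events,
                                mcmc_draws = config$mcmc_draws,
                                seed = stage_seed(4L))
    .plog(config, "disprop", paste(length(out), "frameworks"))
    out
  })

  dsr <- run_stage("dsr", {
    pd <- signals$per_drug
    lapply(stats::setNames(config$events, config$events), function(ev) {
      sub <- pd[pd$event == ev & pd$a > 0, ]
      if (!nrow(sub)) return(NULL)
      drugSpecificity(ev, data.frame(drug_id = sub$exposure, ror = sub$ror,
                                     ror_lo = sub$ror_lo, a = sub$a),
                      ror_min = th$dsr_ror, ratio_min = th$dsr_ratio)
    })
  })

  # -- time-to-onset ------------------------------------------------------
  tto <- run_stage("tto", {
    tce <- df[df$drug_class == "TCE", ]
    out <- lapply(stats::setNames(config$events, config$events), function(ev) {
      s <- extractTto(tce, ev, group = ev)
      if (length(s$values) < 10 || length(unique(s$values)) < 2) return(NULL)
      list(sample = s, km = kmCurve(s), weibull = weibullFit(s))
    })
    Filter(Negate(is.null), out)
  })

  # -- network ------------------------------------------------------------
  network <- run_stage("network", {
    tce <- df[df$drug_class == "TCE", ]
    pts <- selectSignificantPts(df, byClass("TCE"), alpha = th$bh_alpha)
    .plog(config, "network", paste(length(pts), "significant PTs"))
    if (length(pts) < 2) NULL
    else coocNetwork(tce, pts, min_count = th$min_count,
                     min_lift = th$min_lift, seed = stage_seed(6L))
  })
  upset <- run_stage("upset", {
    tce <- df[df$drug_class == "TCE", ]
    if (nrow(tce)) upsetTable(tce, config$ae_of_interest) else NULL
  })

  # -- cohort statistics --------------------------------------------------
  cohort <- run_stage("cohort-stats", {
    tce <- df[df$drug_class == "TCE", ]
    cart <- df[df$drug_class == "CART", ]
    cmp <- if (nrow(tce) && nrow(cart))
      describeAndCompare(tce, cart, labels = c("TCE", "CART")) else NULL
    trend <- if (length(unique(tce$year)) >= 2) fatalTrend(tce) else NULL
    risk <- if (nrow(tce)) univariateRisk(tce, "icans") else NULL
    list(comparison = cmp, fatal_trend = trend, risk_icans = risk)
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("tcevigil")),
    seed = seed, counts = counts, thresholds = th,
    events = config$events, input_mode = config$input$mode)

  result <- structure(list(reports = reports, signals = signals, dsr = dsr,
                           tto = tto, network = network, upset = upset,
                           cohort = cohort, manifest = manifest),
                      class = "pipeline_result")
  if (!is.null(config$out_dir)) writePipelineResult(result, config$out_dir)
  result
}

#' Write the pipeline result bundle as delimited text + JSON manifest
#'
#' @param result a \code{pipeline_result}.
#' @param dir output directory (created if needed).
#' @return invisible vector of paths written.
#' @export
writePipelineResult <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wt <- function(df, name) {
    if (is.null(df)) return(invisible(NULL))
    p <- file.path(dir, paste0(name, ".tsv"))
    df2 <- df
    for (j in names(df2)) if (is.list(df2[[j]]))
      df2[[j]] <- vapply(df2[[j]], paste, "", collapse = "|")
    utils::write.table(df2, p, sep = "\t", row.names = FALSE, quote = FALSE)
    paths <<- c(paths, p)
  }
  for (fw in names(result$signals)) wt(result$signals[[fw]],
                                       paste0("signals_", fw))
  dsr_df <- do.call(rbind, lapply(Filter(Negate(is.null), result$dsr),
                                  function(d)
    data.frame(event = d@event, top_drug = d@top_drug, top_ror = d@top_ror,
               second_ror = d@second_ror, ratio = d@ratio,
               is_specific = d@is_specific)))
  wt(dsr_df, "drug_specificity")
  if (!is.null(result$network)) {
    writeNetwork(result$network, file.path(dir, "network"))
    paths <- c(paths, file.path(dir, "network"))
  }
  wt(result$upset, "upset")
  wt(result$cohort$comparison, "cohort_comparison")
  if (!is.null(result$cohort$fatal_trend))
    wt(result$cohort$fatal_trend$by_year, "fatal_trend")
  wt(result$cohort$risk_icans, "risk_factors_icans")
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(result$manifest, mp, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, mp)
  invisible(paths)
}

#' Load a pipeline configuration from a YAML file
#'
#' Schema (version 1): top-level keys \code{seed}, \code{out_dir},
#' \code{mcmc_draws}, \code{log_level}, \code{thresholds} (see
#' \code{\link{pipelineConfig}}), \code{events}, \code{ae_of_interest},
#' and \code{input} with \code{mode: synthetic} plus \code{n_reports}/
#' \code{dup_rate} (forwarded to \code{\link{srsConfig}}) or
#' \code{mode: faers} plus \code{dir} and optional \code{deletion_list}
#' file. Unknown keys are a hard error.
#'
#' @param path YAML file.
#' @return a \code{\link{pipelineConfig}}.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("schema_version", "seed", "out_dir", "mcmc_draws", "log_level",
             "thresholds", "events", "ae_of_interest", "input")
  unknown <- setdiff(names(y), known)
  if (length(unknown)) stop("unknown config key: ",
                            paste(unknown, collapse = ", "))
  input <- y$input %||% list(mode = "synthetic")
  if (identical(input$mode, "synthetic")) {
    sc <- srsConfig(n_reports = input$n_reports %||% 10000,
                    seed = y$seed %||% 1L,
                    dup_rate = input$dup_rate %||% 0)
    input <- list(mode = "synthetic", config = sc)
  } else if (identical(input$mode, "faers")) {
    dl <- if (!is.null(input$deletion_list))
      readLines(input$deletion_list, warn = FALSE) else character(0)
    input <- list(mode = "faers", dir = input$dir, deletion_list = dl)
  } else stop("input mode must be 'synthetic' or 'faers'")
  pipelineConfig(input = input, seed = y$seed %||% 1L,
                 out_dir = y$out_dir,
                 events = y$events, ae_of_interest = y$ae_of_interest,
                 thresholds = y$thresholds %||% list(),
                 mcmc_draws = y$mcmc_draws %||% 2000,
                 log_level = y$log_level %||% "info")
}
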