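#' Build a drug registry
#'
#' @param drugs data.frame with columns \code{drug_id}, \code{class}
#'   (\code{"TCE"}/\code{"CART"}), \code{target} and a list-column
#'   \code{synonyms}. Synonyms are matched case-insensitively; a synonym
#'   mapping to more than one drug is a hard error.
#' @param indication_keywords data.frame with columns \code{group},
#'   \code{keyword}; defaults to the bundled keyword table.
#' @return A \linkS4class{DrugRegistry}.
#' @export
drugRegistry <- function(drugs, indication_keywords = defaultIndicationKeywords()) {
  if (!is.list(drugs$synonyms)) drugs$synonyms <- as.list(drugs$synonyms)
  new("DrugRegistry", drugs = drugs, indication_keywords = indication_keywords)
}

#' The default TCE / CAR-T drug roster
#'
#' Marketed T-cell engagers and CAR-T products with their molecular targets
#' and common brand-name synonyms; \code{share} is the marketing-share
#' weight used by the synthetic generator when sampling the primary-suspect
#' drug of a report.
#'
#' @return A \linkS4class{DrugRegistry}.
#' @export
defaultRegistry <- function() {
  e <- function(id, cls, tgt, share, ...) {
    list(drug_id = id, class = cls, target = tgt, share = share,
         synonyms = list(unique(c(id, ...))))
  }
  rows <- list(
    e("blinatumomab",  "TCE",  "CD19",   0.28, "BLINCYTO"),
    e("teclistamab",   "TCE",  "BCMA",   0.08, "TECVAYLI"),
    e("elranatamab",   "TCE",  "BCMA",   0.06, "ELREXFIO"),
    e("talquetamab",   "TCE",  "GPRC5D", 0.06, "TALVEY"),
    e("mosunetuzumab", "TCE",  "CD20",   0.06, "LUNSUMIO"),
    e("glofitamab",    "TCE",  "CD20",   0.05, "COLUMVI"),
    e("epcoritamab",   "TCE",  "CD20",   0.06, "EPKINLY", "TEPKINLY"),
    e("tarlatamab",    "TCE",  "Other",  0.03, "IMDELLTRA"),
    e("tebentafusp",   "TCE",  "Other",  0.04, "KIMMTRAK"),
    e("tisagenlecleucel",        "CART", "CD19", 0.07, "KYMRIAH"),
    e("axicabtagene ciloleucel", "CART", "CD19", 0.08, "YESCARTA"),
    e("brexucabtagene autoleucel","CART","CD19", 0.03, "TECARTUS"),
    e("lisocabtagene maraleucel","CART", "CD19", 0.04, "BREYANZI"),
    e("idecabtagene vicleucel",  "CART", "BCMA", 0.03, "ABECMA"),
    e("ciltacabtagene autoleucel","CART","BCMA", 0.03, "CARVYKTI")
  )
  drugs <- data.frame(
    drug_id = vapply(rows, `[[`, "", "drug_id"),
    class   = vapply(rows, `[[`, "", "class"),
    target  = vapply(rows, `[[`, "", "target"),
    share   = vapply(rows, `[[`, 0, "share"),
    stringsAsFactors = FALSE
  )
  drugs$synonyms <- lapply(rows, function(r) r$synonyms[[1]])
  drugRegistry(drugs)
}

#' Default indication-to-group keyword table
#'
#' Case-insensitive substrings; the first matching row assigns the group.
#' Unmatched (or missing) indication text maps to \code{"Unclassified"}.
#' @return data.frame with columns \code{group}, \code{keyword}.
#' @export
defaultIndicationKeywords <- function() {
  data.frame(
    group = c(rep("Leukaemia", 4), rep("Lymphoma", 4),
              rep("PlasmaCellNeoplasms", 3), rep("SolidTumors", 5)),
    keyword = c("LEUKAEMIA", "LEUKEMIA", "LYMPHOBLASTIC", "MYELOID",
                "LYMPHOMA", "DLBCL", "FOLLICULAR", "MANTLE CELL",
                "MYELOMA", "PLASMA CELL", "PLASMACYTOMA",
                "MELANOMA", "CARCINOMA", "SMALL CELL LUNG", "UVEAL",
                "SOLID TUMOUR"),
    stringsAsFactors = FALSE
  )
}

#' Read a drug registry from a YAML file
#'
#' Schema: top-level \code{drugs}, a list of entries with \code{drug_id},
#' \code{class} (TCE/CART), \code{target}, optional \code{share} and
#' \code{synonyms} (list); optional top-level \code{indication_keywords},
#' a list of \code{group}/\code{keyword} pairs (defaults to the bundled
#' table). Colliding synonyms are a hard error at load.
#'
#' @param path YAML file.
#' @return A \linkS4class{DrugRegistry}.
#' @export
readDrugRegistry <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$drugs)) stop("registry file must have a 'drugs' key")
  drugs <- data.frame(
    drug_id = vapply(y$drugs, `[[`, "", "drug_id"),
    class = vapply(y$drugs, `[[`, "", "class"),
    target = vapply(y$drugs, `[[`, "", "target"),
    share = vapply(y$drugs, function(d) d$share %||% 1, numeric(1)),
    stringsAsFactors = FALSE)
  drugs$synonyms <- lapply(y$drugs, function(d)
    unique(c(d$drug_id, unlist(d$synonyms))))
  kw <- if (!is.null(y$indication_keywords)) {
    data.frame(
      group = vapply(y$indication_keywords, `[[`, "", "group"),
      keyword = vapply(y$indication_keywords, `[[`, "", "keyword"),
      stringsAsFactors = FALSE)
  } else defaultIndicationKeywords()
  drugRegistry(drugs, kw)
}

#' Resolve a free-text drug name against a registry
#'
#' @param names character vector of drug names.
#' @param registry a \linkS4class{DrugRegistry}.
#' @return character vector of \code{drug_id}, NA where unresolved.
#' @export
resolveDrug <- function(names, registry) {
  map <- synonymMap(registry)
  unname(map[toupper(trimws(names))])
}

synonymMap <- function(registry) {
  d <- registry@drugs
  syn <- lapply(seq_len(nrow(d)), function(i) {
    s <- toupper(d$synonyms[[i]])
    stats::setNames(rep(d$drug_id[i], length(s)), s)
  })
  do.call(c, syn)
}

#' Map indication free text to an indication group
#'
#' @param text character vector of indication text (may be NA).
#' @param registry a \linkS4class{DrugRegistry}.
#' @return character vector of groups; \code{"Unclassified"} for unmatched
#'   non-missing text, NA for missing text.
#' @export
mapIndication <- function(text, registry) {
  kw <- registry@indication_keywords
  up <- toupper(text)
  out <- ifelse(is.na(up), NA_character_, "Unclassified")
  for (i in rev(seq_len(nrow(kw)))) {
    hit <- !is.na(up) & grepl(kw$keyword[i], up, fixed = TRUE)
    out[hit] <- kw$group[i]
  }
  out
}

#' The bundled mock PT/SOC dictionary
#'
#' A stand-in adverse-event vocabulary: ~200 preferred terms (PTs) mapped to
#' the 27 system organ class (SOC) abbreviations used for SOC-level
#' summaries, each with a base reporting probability for the synthetic
#' generator. The key clinical-syndrome PTs (cytokine release syndrome,
#' ICANS, tumour lysis syndrome, infections, cytopenias, ...) are named
#' explicitly; filler terms are systematic. This is a synthetic dictionary:
#' it mirrors the structure of a licensed AE terminology, not its content.
#'
#' @return data.frame with columns \code{pt}, \code{soc}, \code{base_p}.
#' @export
mockPtDictionary <- function() {
  socs <- c("Genrl", "Nerv", "Neopl", "Blood", "Inv", "Gastr", "Resp",
            "Skin", "Metab", "Psych", "Vasc", "Musc", "Card", "Hepat",
            "Renal", "Surg", "Prod", "Immun", "Eye", "SocCi", "Ear",
            "Endo", "Cong", "Repro", "Preg", "Inj&P", "Infec")
  key <- data.frame(
    pt = c("cytokine release syndrome",
           "immune effector cell-associated neurotoxicity syndrome",
           "tumour lysis syndrome", "pyrexia", "death", "fatigue",
           "tremor", "anaemia", "neutropenia", "thrombocytopenia",
           "infection", "bacterial infection", "fungal infection",
           "hemophagocytic lymphohistiocytosis",
           "disseminated intravascular coagulation",
           "multiple organ dysfunction syndrome", "cytopenia",
           "oral toxicity", "nail toxicity", "dry mouth", "dry skin",
           "dysgeusia", "off label use", "tumour flare",
           "leukaemic infiltration extramedullary", "lineage switch leukaemia",
           "central nervous system leukaemia", "hypotension", "hypoxia",
           "headache", "confusional state", "aphasia", "seizure",
           "encephalopathy", "hypogammaglobulinaemia"),
    soc = c("Immun", "Nerv", "Metab", "Genrl", "Genrl", "Genrl",
            "Nerv", "Blood", "Blood", "Blood",
            "Infec", "Infec", "Infec",
            "Blood", "Vasc", "Genrl", "Blood",
            "Gastr", "Skin", "Gastr", "Skin",
            "Nerv", "Inj&P", "Neopl",
            "Neopl", "Neopl", "Neopl", "Vasc", "Resp",
            "Nerv", "Psych", "Nerv", "Nerv", "Nerv", "Immun"),
    base_p = c(0.170, 0.060, 0.030, 0.096, 0.067, 0.080,
               0.030, 0.060, 0.055, 0.045,
               0.080, 0.020, 0.015,
               0.010, 0.006, 0.012, 0.030,
               0.004, 0.004, 0.015, 0.012,
               0.010, 0.040, 0.006,
               0.003, 0.002, 0.003, 0.040, 0.030,
               0.050, 0.020, 0.010, 0.012, 0.015, 0.010),
    stringsAsFactors = FALSE
  )
  n_fill <- 200 - nrow(key)
  fsoc <- rep(socs, length.out = n_fill)
  idx <- stats::ave(seq_len(n_fill), fsoc, FUN = seq_along)
  fill <- data.frame(
    pt = sprintf("%s event %02d", tolower(fsoc), idx),
    soc = fsoc,
    base_p = rep(c(0.020, 0.012, 0.008, 0.005, 0.003), length.out = n_fill),
    stringsAsFactors = FALSE
  )
  rbind(key, fill)
}
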