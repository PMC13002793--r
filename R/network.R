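#' Select the significant PTs for network analysis
#'
#' PTs whose exposure-versus-background Fisher exact p-value, adjusted by
#' Benjamini-Hochberg across all tested PTs, falls below the cutoff.
#'
#' @param reports a \linkS4class{SafetyReportSet} or its data.frame
#'   (full scope: exposure plus background).
#' @param exposure predicate for the exposure cohort (see \link{selectors}).
#' @param pts character vector of PTs to test (default: every PT occurring
#'   in the exposed reports).
#' @param alpha BH-adjusted significance cutoff (default 0.05).
#' @return character vector of retained PTs (with the adjusted p-values as
#'   a named attribute \code{"p_adj"}).
#' @export
selectSignificantPts <- function(reports, exposure, pts = NULL, alpha = 0.05) {
  df <- if (is(reports, "SafetyReportSet")) reports@reports else reports
  ex <- exposure(df)
  if (is.null(pts))
    pts <- sort(unique(unlist(df$events[ex], use.names = FALSE)))
  tabs <- buildAllPairs(df, list(exposure = exposure), pts)
  p <- vapply(seq_len(nrow(tabs)), function(i)
    fisherExactP(c(tabs$a[i], tabs$b[i], tabs$c[i], tabs$d[i])), numeric(1))
  p_adj <- stats::p.adjust(p, method = "BH")
  keep <- p_adj < alpha
  structure(tabs$event[keep], p_adj = stats::setNames(p_adj, tabs$event))
}

#' Lift between two PTs
#'
#' Lift = P(both) / (P(a) P(b)) = N n_ab / (n_a n_b), computed over the
#' report set in scope (by default the exposure cohort's reports only).
#'
#' @param reports a \linkS4class{SafetyReportSet} or its data.frame.
#' @param pt_a,pt_b the two PTs.
#' @return list (\code{pt_a}, \code{pt_b}, \code{n_ab}, \code{lift},
#'   \code{fisher_p}); lift is 0 when the PTs never co-occur.
#' @export
pairLift <- function(reports, pt_a, pt_b) {
  df <- if (is(reports, "SafetyReportSet")) reports@reports else reports
  N <- nrow(df)
  ha <- vapply(df$events, function(e) pt_a %in% e, logical(1))
  hb <- vapply(df$events, function(e) pt_b %in% e, logical(1))
  n_ab <- sum(ha & hb)
  lift <- if (sum(ha) == 0 || sum(hb) == 0) 0
  else (n_ab / N) / ((sum(ha) / N) * (sum(hb) / N))
  p <- fisherExactP(c(n_ab, sum(ha) - n_ab, sum(hb) - n_ab,
                      N - sum(ha) - sum(hb) + n_ab))
  list(pt_a = pt_a, pt_b = pt_b, n_ab = n_ab, lift = lift, fisher_p = p)
}

#' All pairwise co-occurrence edges among a PT list
#'
#' Vectorised cross-product of the report-by-PT incidence matrix; one row
#' per unordered PT pair with the co-report count and lift.
#'
#' @param reports a \linkS4class{SafetyReportSet} or its data.frame.
#' @param pts character vector of PTs.
#' @return data.frame (\code{pt_a}, \code{pt_b}, \code{n_a}, \code{n_b},
#'   \code{n_ab}, \code{lift}).
#' @export
coocEdges <- function(reports, pts) {
  df <- if (is(reports, "SafetyReportSet")) reports@reports else reports
  N <- nrow(df)
  ev_long <- unlist(df$events, use.names = FALSE)
  rep_idx <- rep.int(seq_len(N), lengths(df$events))
  keep <- ev_long %in% pts
  M <- matrix(0L, N, length(pts), dimnames = list(NULL, pts))
  M[cbind(rep_idx[keep], match(ev_long[keep], pts))] <- 1L
  co <- crossprod(M)
  n <- diag(co)
  ij <- which(upper.tri(co), arr.ind = TRUE)
  n_ab <- co[ij]
  lift <- ifelse(n[ij[, 1]] * n[ij[, 2]] > 0,
                 (n_ab / N) / ((n[ij[, 1]] / N) * (n[ij[, 2]] / N)), 0)
  data.frame(pt_a = pts[ij[, 1]], pt_b = pts[ij[, 2]],
             n_a = n[ij[, 1]], n_b = n[ij[, 2]],
             n_ab = n_ab, lift = lift, stringsAsFactors = FALSE)
}

#' Build the lift-weighted co-occurrence graph
#'
#' Admits edges with co-occurrence count >= \code{min_count} and lift
#' strictly greater than \code{min_lift}; edge weight is the lift;
#' isolated nodes are dropped.
#'
#' @param edges data.frame from \code{\link{coocEdges}} (or with columns
#'   \code{pt_a}, \code{pt_b}, \code{n_ab}, \code{lift}).
#' @param min_count minimum co-report count (default 10).
#' @param min_lift lift threshold, strict (default 2).
#' @return an undirected \pkg{igraph} graph with edge attribute
#'   \code{weight} (= lift) and \code{n_ab}.
#' @export
buildGraph <- function(edges, min_count = 10, min_lift = 2) {
  adm <- edges[edges$n_ab >= min_count & edges$lift > min_lift, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    data.frame(from = adm$pt_a, to = adm$pt_b,
               weight = adm$lift, n_ab = adm$n_ab),
    directed = FALSE)
  g
}

#' Louvain community detection
#'
#' Weighted modularity optimisation at resolution 1; node order
#' randomisation is controlled by the seed so runs are reproducible.
#'
#' @param graph an \pkg{igraph} graph with \code{weight} edge attribute.
#' @param seed integer seed.
#' @return list with \code{membership} (named integer vector),
#'   \code{modularity} (Q of the returned partition; NA for an empty
#'   graph) and \code{communities} (the igraph communities object).
#' @export
louvainCommunities <- function(graph, seed = 1L) {
  if (igraph::vcount(graph) == 0)
    return(list(membership = integer(0), modularity = NA_real_,
                communities = NULL))
  cl <- withr_seed(seed, igraph::cluster_louvain(graph, resolution = 1))
  memb <- igraph::membership(cl)
  q <- igraph::modularity(graph, memb,
                          weights = igraph::E(graph)$weight)
  list(membership = stats::setNames(as.integer(memb), names(memb)),
       modularity = q, communities = cl)
}

#' Per-community eigenvector-centrality hubs
#'
#' Within each community, weighted eigenvector centrality is computed on
#' the community's induced subgraph; the hub is the PT with the largest
#' centrality (ties broken lexicographically).
#'
#' @param graph the \pkg{igraph} graph.
#' @param membership named integer vector (PT -> community id).
#' @return list with \code{hubs} (data.frame \code{community}, \code{size},
#'   \code{hub}, \code{centrality}) and \code{centrality} (named vector
#'   over all PTs, scaled to max 1 within each community).
#' @export
communityHubs <- function(graph, membership) {
  cids <- sort(unique(membership))
  cent_all <- numeric(0)
  rows <- lapply(cids, function(cid) {
    vs <- names(membership)[membership == cid]
    sub <- igraph::induced_subgraph(graph, vs)
    if (igraph::vcount(sub) == 1) {
      cent <- stats::setNames(1, vs)
    } else {
      cent <- igraph::eigen_centrality(
        sub, weights = igraph::E(sub)$weight)$vector
    }
    cent_all <<- c(cent_all, cent)
    top <- max(cent)
    cands <- sort(names(cent)[cent >= top - 1e-12])
    data.frame(community = cid, size = length(vs), hub = cands[1],
               centrality = unname(cent[cands[1]]), stringsAsFactors = FALSE)
  })
  list(hubs = do.call(rbind, rows), centrality = cent_all)
}

#' Full co-occurrence network analysis
#'
#' Chains PT selection (optional), pairwise lift computation, graph
#' construction, Louvain communities and per-community hubs into a
#' \linkS4class{CoocNetwork}.
#'
#' @param reports exposure-cohort reports (a \linkS4class{SafetyReportSet}
#'   or data.frame) over which lifts are computed.
#' @param pts PTs to include as candidate nodes.
#' @param min_count,min_lift edge admission thresholds (defaults 10 and 2).
#' @param seed seed for the community detection.
#' @return A \linkS4class{CoocNetwork}.
#' @export
coocNetwork <- function(reports, pts, min_count = 10, min_lift = 2, seed = 1L) {
  df <- if (is(reports, "SafetyReportSet")) reports@reports else reports
  edges <- coocEdges(df, pts)
  g <- buildGraph(edges, min_count, min_lift)
  lv <- louvainCommunities(g, seed)
  hubs <- if (length(lv$membership))
    communityHubs(g, lv$membership)$hubs
  else data.frame(community = integer(0), size = integer(0),
                  hub = character(0), centrality = numeric(0))
  freq <- table(unlist(df$events, use.names = FALSE))
  nodes <- data.frame(pt = names(lv$membership),
                      n = as.integer(freq[names(lv$membership)]),
                      stringsAsFactors = FALSE)
  adm <- edges[edges$n_ab >= min_count & edges$lift > min_lift,
               c("pt_a", "pt_b", "n_ab", "lift")]
  rownames(adm) <- NULL
  new("CoocNetwork", graph = g, nodes = nodes, edges = adm,
      membership = lv$membership, modularity = lv$modularity, hubs = hubs)
}

#' Exact intersection (UpSet-style) table for a set of AEs
#'
#' For every nonempty subset of \code{ae_list}, counts the reports whose
#' intersection with the list is exactly that subset (not cumulative),
#' with the per-subset outcome distribution, fatality proportion and drug
#' target breakdown. Reports carrying none of the listed AEs are excluded.
#'
#' @param reports a \linkS4class{SafetyReportSet} or its data.frame.
#' @param ae_list character vector of AEs of interest (2 to ~6 terms).
#' @return data.frame: \code{subset} (terms joined by " + "), \code{n},
#'   \code{n_fatal}, \code{fatal_prop}, one \code{outc_*} count column per
#'   outcome code seen, one \code{target_*} count column per target.
#' @export
upsetTable <- function(reports, ae_list) {
  df <- if (is(reports, "SafetyReportSet")) reports@reports else reports
  stopifnot(length(ae_list) >= 2)
  inc <- vapply(ae_list, function(p)
    vapply(df$events, function(e) p %in% e, logical(1)),
    logical(nrow(df)))
  inc <- matrix(inc, nrow = nrow(df))
  any_hit <- rowSums(inc) > 0
  key <- apply(inc[any_hit, , drop = FALSE], 1, function(r)
    paste(ae_list[r], collapse = " + "))
  sub_df <- df[any_hit, , drop = FALSE]
  outc_codes <- sort(unique(unlist(sub_df$outcomes, use.names = FALSE)))
  targets <- sort(unique(sub_df$target))
  rows <- lapply(split(seq_along(key), key), function(idx) {
    s <- sub_df[idx, , drop = FALSE]
    oc <- table(factor(unlist(s$outcomes, use.names = FALSE),
                       levels = outc_codes))
    tg <- table(factor(s$target, levels = targets))
    out <- data.frame(subset = key[idx[1]], n = nrow(s),
                      n_fatal = sum(s$fatal),
                      fatal_prop = mean(s$fatal), stringsAsFactors = FALSE)
    for (o in outc_codes) out[[paste0("outc_", o)]] <- as.integer(oc[[o]])
    for (tt in targets) out[[paste0("target_", tt)]] <- as.integer(tg[[tt]])
    out
  })
  res <- do.call(rbind, rows)
  res <- res[order(-res$n), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_in_scope") <- sum(any_hit)
  res
}

#' Export a network as edge list and membership tables
#'
#' @param net a \linkS4class{CoocNetwork}.
#' @param dir output directory (created if needed).
#' @return invisible paths written.
#' @export
writeNetwork <- function(net, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ep <- file.path(dir, "edges.tsv")
  mp <- file.path(dir, "membership.tsv")
  utils::write.table(net@edges, ep, sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(
    data.frame(pt = names(net@membership), community = net@membership),
    mp, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(c(ep, mp))
}
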