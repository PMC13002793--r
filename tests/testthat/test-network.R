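test_that("pairLift reproduces the constructed worked example", {
  # 10,000 reports: 542 with both PTs, 1458 A only, 458 B only
  events <- c(rep(list(c("A", "B")), 542), rep(list("A"), 1458),
              rep(list("B"), 458), rep(list("F"), 7542))
  rs <- mk_reports("blinatumomab", events)
  e <- pairLift(rs, "A", "B")
  expect_equal(e$n_ab, 542)
  expect_equal(round(e$lift, 2), 2.71)
  # symmetry
  e2 <- pairLift(rs, "B", "A")
  expect_equal(e2$lift, e$lift)
  expect_equal(e2$n_ab, e$n_ab)
})

test_that("lift is about 1 for independent PTs and 0 for disjoint ones", {
  set.seed(51)
  n <- 20000
  events <- lapply(seq_len(n), function(i) {
    e <- c(if (runif(1) < 0.2) "A", if (runif(1) < 0.1) "B", "F")
    e
  })
  rs <- mk_reports("blinatumomab", events)
  expect_equal(pairLift(rs, "A", "B")$lift, 1, tolerance = 0.1)
  expect_equal(pairLift(rs, "A", "Z")$lift, 0)
})

test_that("coocEdges agrees with pairLift on every pair", {
  set.seed(52)
  events <- replicate(300, sample(paste0("P", 1:5), sample(1:3, 1)),
                      simplify = FALSE)
  rs <- mk_reports("blinatumomab", events)
  ed <- coocEdges(rs, paste0("P", 1:4))
  for (i in seq_len(nrow(ed))) {
    ref <- pairLift(rs, ed$pt_a[i], ed$pt_b[i])
    expect_equal(ed$n_ab[i], ref$n_ab)
    expect_equal(ed$lift[i], ref$lift, tolerance = 1e-12)
  }
})

test_that("edge admission applies both thresholds strictly", {
  ed <- data.frame(pt_a = paste0("A", 1:6), pt_b = paste0("B", 1:6),
                   n_ab = c(9, 10, 10, 15, 50, 12),
                   lift = c(5, 2.0, 2.1, 1.9, 3, 2.5))
  g <- buildGraph(ed)
  # hand check: rows 3, 5, 6 admitted (n_ab >= 10 AND lift > 2)
  expect_equal(igraph::ecount(g), 3)
  expect_setequal(names(igraph::V(g)),
                  c("A3", "B3", "A5", "B5", "A6", "B6"))
})

test_that("Louvain recovers two cliques with the closed-form modularity", {
  el <- rbind(t(combn(paste0("a", 1:4), 2)), t(combn(paste0("b", 1:4), 2)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = el[, 1], to = el[, 2], weight = 1), directed = FALSE)
  lv <- louvainCommunities(g, seed = 3)
  expect_equal(length(unique(lv$membership)), 2)
  expect_equal(lv$modularity, 0.5, tolerance = 1e-12)  # 2*(6/12 - (12/24)^2)
  # nodes of one clique share a community
  expect_equal(length(unique(lv$membership[paste0("a", 1:4)])), 1)
  # complete uniform graph collapses to one community
  gk <- igraph::make_full_graph(6)
  igraph::E(gk)$weight <- 1
  igraph::V(gk)$name <- paste0("v", 1:6)
  expect_equal(length(unique(louvainCommunities(gk, 1)$membership)), 1)
  # empty graph
  ge <- igraph::make_empty_graph(0, directed = FALSE)
  expect_true(is.na(louvainCommunities(ge, 1)$modularity))
})

test_that("community hubs follow eigenvector centrality with lexicographic ties", {
  # star: hub is the centre
  g <- igraph::graph_from_data_frame(
    data.frame(from = "centre", to = paste0("leaf", 1:5), weight = 1),
    directed = FALSE)
  memb <- stats::setNames(rep(1L, 6), names(igraph::V(g)))
  h <- communityHubs(g, memb)
  expect_equal(h$hubs$hub, "centre")
  # uniform clique: all centralities equal, first PT alphabetically wins
  gk <- igraph::make_full_graph(4)
  igraph::V(gk)$name <- c("delta", "alpha", "charlie", "bravo")
  igraph::E(gk)$weight <- 1
  memb2 <- stats::setNames(rep(1L, 4), igraph::V(gk)$name)
  expect_equal(communityHubs(gk, memb2)$hubs$hub, "alpha")
})

test_that("weighted-path centralities match a dense eigendecomposition", {
  w <- c(1, 5, 2, 4)
  nodes <- paste0("n", 1:5)
  g <- igraph::graph_from_data_frame(
    data.frame(from = nodes[1:4], to = nodes[2:5], weight = w),
    directed = FALSE)
  memb <- stats::setNames(rep(1L, 5), nodes)
  got <- communityHubs(g, memb)
  adj <- matrix(0, 5, 5, dimnames = list(nodes, nodes))
  for (i in 1:4) { adj[i, i + 1] <- w[i]; adj[i + 1, i] <- w[i] }
  ref <- o_eigen_centrality(adj)
  expect_equal(unname(got$centrality[nodes]), unname(ref), tolerance = 1e-8)
})

test_that("upsetTable gives exact subset counts that conserve totals", {
  ae <- c("CRS", "ICANS", "INF")
  events <- list(c("CRS"), c("CRS"), c("CRS", "ICANS"), c("CRS", "ICANS"),
                 c("CRS", "ICANS", "INF"), c("ICANS"), c("X"), c("INF", "X"))
  rs <- mk_reports("blinatumomab", events,
                   fatal = c(FALSE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  ut <- upsetTable(rs, ae)
  expect_equal(sum(ut$n), 7)           # the "X"-only report is excluded
  expect_equal(attr(ut, "n_in_scope"), 7)
  expect_equal(ut$n[ut$subset == "CRS"], 2)
  expect_equal(ut$n[ut$subset == "CRS + ICANS"], 2)
  expect_equal(ut$n[ut$subset == "CRS + ICANS + INF"], 1)
  expect_equal(ut$fatal_prop[ut$subset == "CRS"], 0.5)
  expect_equal(ut$fatal_prop[ut$subset == "CRS + ICANS + INF"], 1)
})

test_that("significant-PT selection controls the null and finds planted signals", {
  # planted: drugA strongly over-reports PT "S"
  set.seed(53)
  n <- 4000
  exposed <- rep(c(TRUE, FALSE), c(1000, 3000))
  events <- lapply(seq_len(n), function(i) {
    e <- "F"
    p_s <- if (exposed[i]) 0.25 else 0.02
    if (runif(1) < p_s) e <- c(e, "S")
    if (runif(1) < 0.05) e <- c(e, "N")   # null PT, same rate in both
    e
  })
  rs <- mk_reports(ifelse(exposed, "blinatumomab", "tisagenlecleucel"), events)
  pts <- selectSignificantPts(rs, byClass("TCE"), pts = c("S", "N"))
  expect_true("S" %in% pts)
  expect_false("N" %in% pts)
})

test_that("planted fatality hierarchy is recovered by the intersection table", {
  icans <- "immune effector cell-associated neurotoxicity syndrome"
  crs <- "cytokine release syndrome"
  cfg <- srsConfig(
    n_reports = 50000, seed = 54,
    fatality = list(p_start = 0.10, p_end = 0.10,
                    conditional = data.frame(
                      pts = c(crs, paste(crs, icans, sep = ";"),
                              paste(crs, icans, "infection", sep = ";")),
                      prob = c(0.15, 0.28, 0.45))))
  sim <- generateSrs(cfg)
  ut <- upsetTable(sim@reports, c(crs, icans, "infection"))
  p1 <- ut$fatal_prop[ut$subset == crs]
  p2 <- ut$fatal_prop[ut$subset == paste(crs, icans, sep = " + ")]
  p3 <- ut$fatal_prop[ut$subset == paste(crs, icans, "infection", sep = " + ")]
  expect_lt(p1, p2)
  expect_lt(p2, p3)
})
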