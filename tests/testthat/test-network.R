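# Connectivity statistics, permutation null, candidate network, modules,
# centrality, core-periphery, meta-nodes. Small-graph behaviour is checked
# against exhaustive/matrix oracles.

line_graph <- function(edges, nodes = NULL) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges[, 1], to = edges[, 2], stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = if (is.null(nodes)) NULL else data.frame(name = nodes))
  igraph::E(g)$confidence <- 0.5
  g
}

test_that("cross and internal connectivity count the defined edge classes", {
  g <- line_graph(rbind(c("a", "b"), c("b", "c"), c("c", "a"), c("c", "d")))
  expect_equal(as.integer(cross_connectivity(g, "a", "b")), 1L)
  expect_equal(as.integer(cross_connectivity(g, "a", "d")), 0L)
  # both endpoints in the intersection count once
  expect_equal(as.integer(cross_connectivity(g, c("a", "b"), c("a", "b", "d"))), 1L)
  expect_equal(as.integer(internal_connectivity(g, c("a", "b", "c"))), 3L)
  expect_equal(as.integer(internal_connectivity(g, c("a", "d"))), 0L)
  expect_error(cross_connectivity(g, "zz", "yy"), "empty")

  set.seed(41)
  for (i in 1:20) {
    rg <- random_small_graph(sample(5:10, 1))
    a <- sample(rg$nodes, sample(1:4, 1))
    b <- sample(rg$nodes, sample(1:4, 1))
    expect_equal(as.integer(cross_connectivity(rg$graph, a, b)),
                 oracle_cross_count(rg$adj, rg$nodes, a, b))
    expect_equal(as.integer(internal_connectivity(rg$graph, a)),
                 oracle_internal_count(rg$adj, rg$nodes, a))
  }
  # larger instance against the matrix oracle
  rg <- random_small_graph(30, 0.2)
  a <- sample(rg$nodes, 8); b <- sample(rg$nodes, 10)
  expect_equal(as.integer(cross_connectivity(rg$graph, a, b)),
               oracle_cross_count(rg$adj, rg$nodes, a, b))
})

test_that("permutation p follows the add-one formula and is seed-reproducible", {
  # a graph whose only edges join A to B: observed beats every null draw
  ab_edges <- expand.grid(a = paste0("a", 1:5), b = paste0("b", 1:5))
  ring <- cbind(paste0("r", 1:30), paste0("r", c(2:30, 1)))
  g <- line_graph(rbind(as.matrix(ab_edges), ring))
  r <- permutation_p(g, paste0("a", 1:5), paste0("b", 1:5),
                     n_perm = 999, seed = 101)
  expect_equal(r$observed, 25L)
  expect_equal(r$empirical_p, 1 / 1000)

  # no cross edges at all: p = 1 (every null >= 0 = observed)
  r0 <- permutation_p(g, c("r1", "r5"), c("r10", "r20"), n_perm = 200, seed = 5)
  expect_equal(r0$observed, 0L)
  expect_equal(r0$empirical_p, 1)

  # bit-for-bit reproducibility under a fixed seed
  r1 <- permutation_p(g, paste0("a", 1:5), paste0("b", 1:5), n_perm = 300, seed = 9)
  r2 <- permutation_p(g, paste0("a", 1:5), paste0("b", 1:5), n_perm = 300, seed = 9)
  expect_identical(r1, r2)
  # the degree-binned sampler runs and respects sizes
  rb <- permutation_p(g, paste0("a", 1:5), paste0("b", 1:5), n_perm = 100,
                      seed = 3, method = "degree_binned")
  expect_equal(rb$observed, 25L)
  expect_true(rb$empirical_p <= 1)
})

test_that("adding a cross edge never decreases the statistic; power grows with excess", {
  set.seed(43)
  for (i in 1:10) {
    rg <- random_small_graph(10, 0.3)
    a <- sample(rg$nodes, 3); b <- setdiff(sample(rg$nodes, 6), a)[1:3]
    base <- as.integer(cross_connectivity(rg$graph, a, b))
    pair <- c(a[1], b[1])
    g2 <- igraph::add_edges(rg$graph, pair)
    expect_gte(as.integer(cross_connectivity(g2, a, b)), base)
  }

  # median empirical p decreases as the planted excess grows
  set.seed(47)
  med_p <- vapply(c(0, 10, 30), function(extra) {
    ps <- vapply(1:8, function(rep) {
      g <- igraph::sample_gnp(120, 0.05)
      igraph::V(g)$name <- paste0("n", 1:120)
      a <- paste0("n", 1:12); b <- paste0("n", 13:30)
      if (extra > 0) {
        new <- matrix(c(sample(a, extra, TRUE), sample(b, extra, TRUE)),
                      nrow = 2, byrow = TRUE)
        g <- igraph::simplify(igraph::add_edges(g, as.vector(new)))
      }
      permutation_p(g, a, b, n_perm = 199, seed = rep)$empirical_p
    }, numeric(1))
    stats::median(ps)
  }, numeric(1))
  expect_true(med_p[3] <= med_p[2])
  expect_true(med_p[3] < med_p[1])
})

test_that("candidate networks cap interactors and are seed-deterministic", {
  # direct edge: no interactors at all
  g1 <- line_graph(rbind(c("c1", "c2"), c("c1", "x"), c("c2", "x")))
  net1 <- build_candidate_network(g1, list(cnv = "c1", snp = "c2"), seed = 1)
  expect_setequal(igraph::V(net1)$name, c("c1", "c2"))
  expect_equal(igraph::ecount(net1), 1L)

  # five common neighbours, no direct edge: exactly 3 kept
  spokes <- rbind(cbind("c1", paste0("m", 1:5)), cbind(paste0("m", 1:5), "c2"))
  g2 <- line_graph(spokes)
  net2 <- build_candidate_network(g2, list(cnv = "c1", snp = "c2"),
                                  max_interactors = 3, seed = 7)
  expect_equal(sum(igraph::V(net2)$type == "interactor"), 3L)
  expect_true(all(igraph::degree(net2)[igraph::V(net2)$type == "interactor"] == 2))

  net2b <- build_candidate_network(g2, list(cnv = "c1", snp = "c2"),
                                   max_interactors = 3, seed = 7)
  expect_true(igraph::identical_graphs(net2, net2b))
  net2c <- build_candidate_network(g2, list(cnv = "c1", snp = "c2"),
                                   max_interactors = 3, seed = 8)
  # another seed may keep different interactors but the same counts/types
  expect_equal(sum(igraph::V(net2c)$type == "interactor"), 3L)
  expect_setequal(igraph::V(net2c)$name[igraph::V(net2c)$type != "interactor"],
                  c("c1", "c2"))

  # unconnected candidates stay as isolates
  g3 <- line_graph(rbind(c("c1", "x"), c("lonely", "y")))
  net3 <- build_candidate_network(g3, list(cnv = c("c1", "lonely")), seed = 1)
  expect_true("lonely" %in% igraph::V(net3)$name)
  expect_equal(igraph::degree(net3)[["lonely"]], 0)
})

test_that("module detection recovers planted structure", {
  # two 5-cliques joined by one edge
  cl <- function(prefix) t(utils::combn(paste0(prefix, 1:5), 2))
  g <- line_graph(rbind(cl("a"), cl("b"), c("a1", "b1")))
  m <- detect_modules(g, seed = 3)
  expect_equal(length(unique(m$membership)), 2L)
  expect_equal(length(unique(m$membership[paste0("a", 1:5)])), 1L)
  expect_equal(length(unique(m$membership[paste0("b", 1:5)])), 1L)
  expect_gte(m$modularity, 0)

  # planted 4-block graph: adjusted agreement >= 0.9 across seeds
  set.seed(53)
  blocks <- rep(1:4, each = 12)
  nodes <- paste0("v", seq_along(blocks))
  pairs <- t(utils::combn(seq_along(blocks), 2))
  p <- ifelse(blocks[pairs[, 1]] == blocks[pairs[, 2]], 0.6, 0.02)
  keep <- stats::runif(nrow(pairs)) < p
  g4 <- line_graph(cbind(nodes[pairs[keep, 1]], nodes[pairs[keep, 2]]), nodes)
  for (s in 1:3) {
    m4 <- detect_modules(g4, seed = s)
    expect_gte(adjusted_rand_index(m4$membership[nodes], blocks), 0.9)
  }
})

test_that("centrality matches the matrix-power betweenness oracle", {
  star <- line_graph(cbind("hub", paste0("s", 1:6)))
  expect_equal(names(which.max(node_centrality(star, "degree"))), "hub")
  expect_equal(names(which.max(node_centrality(star, "betweenness"))), "hub")

  path <- line_graph(rbind(c("a", "b"), c("b", "c")))
  bw <- node_centrality(path, "betweenness")
  expect_equal(bw[["b"]], 1)
  expect_equal(bw[["a"]], 0)

  set.seed(59)
  for (i in 1:10) {
    rg <- random_small_graph(sample(6:10, 1), 0.35)
    expect_equal(unname(node_centrality(rg$graph, "betweenness")),
                 oracle_betweenness(rg$adj), tolerance = 1e-10)
  }
  rg20 <- random_small_graph(20, 0.15)
  expect_equal(unname(node_centrality(rg20$graph, "betweenness")),
               oracle_betweenness(rg20$adj), tolerance = 1e-10)
})

test_that("core-periphery recovers ideal structure and flags unstable fits", {
  # clique of 4 with 4 pendants: the clique is the core
  clique <- t(utils::combn(paste0("k", 1:4), 2))
  pend <- cbind(paste0("k", 1:4), paste0("p", 1:4))
  g <- line_graph(rbind(clique, pend))
  cp <- core_periphery(g, seed = 2)
  expect_setequal(names(cp$labels)[cp$labels == "core"], paste0("k", 1:4))
  expect_gt(cp$fit, 0.5)

  # a cycle has no core: fit near zero, flagged unstable
  cyc <- line_graph(cbind(paste0("c", 1:8), paste0("c", c(2:8, 1))))
  cpc <- core_periphery(cyc, seed = 2)
  expect_lt(cpc$fit, 0.35)
  expect_false(cpc$stable)

  # greedy within 5% of the exhaustive optimum on 50 random graphs (n <= 10)
  set.seed(61)
  for (i in 1:50) {
    rg <- random_small_graph(sample(5:10, 1), stats::runif(1, 0.2, 0.6))
    if (igraph::ecount(rg$graph) == 0) next
    best <- oracle_cp_best_fit(rg$adj)
    got <- core_periphery(rg$graph, restarts = 10, seed = i)$fit
    expect_gte(got, best - 0.05 * max(best, 1e-9) - 1e-9)
  }
})

test_that("meta-node networks conserve edges and match cross-tabulation", {
  cl <- function(prefix) t(utils::combn(paste0(prefix, 1:4), 2))
  g <- line_graph(rbind(cl("a"), cl("b")))
  part <- stats::setNames(rep(1:2, each = 4), c(paste0("a", 1:4), paste0("b", 1:4)))
  meta <- meta_node_network(g, part)
  expect_equal(igraph::vcount(meta), 2L)
  expect_equal(igraph::ecount(meta), 0L)

  set.seed(67)
  for (i in 1:10) {
    rg <- random_small_graph(10, 0.4)
    part <- stats::setNames(sample(1:3, 10, TRUE), rg$nodes)
    meta <- meta_node_network(rg$graph, part)
    el <- igraph::as_edgelist(rg$graph)
    cross <- sum(part[el[, 1]] != part[el[, 2]])
    within <- sum(part[el[, 1]] == part[el[, 2]])
    expect_equal(sum(igraph::E(meta)$weight), cross)
    expect_equal(sum(igraph::V(meta)$within_edges), within)
    expect_equal(sum(igraph::V(meta)$size), 10)
  }
})
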