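# PPI connectivity statistics with permutation nulls, candidate-network
# construction, module detection, centrality, and core-periphery
# classification.
#
# The convergence test: are the proteins encoded by rare-CNV genes (set A)
# and common-variant candidate genes (set B) more interconnected in the
# interactome than random gene sets of the same sizes? Genes absent from
# the PPI universe (non-coding or unmapped) are dropped with a logged
# count before any statistic is computed.

# case-insensitive symbol match returning graph-native node names
map_to_graph <- function(graph, genes) {
  genes <- unique(toupper(genes))
  nm <- igraph::V(graph)$name
  mapped <- nm[toupper(nm) %in% genes]
  attr(mapped, "n_dropped") <- length(genes) - length(mapped)
  mapped
}

#' Direct interactions between two gene sets
#'
#' Counts PPI edges \{u, v\} with u in A-only and v in B-only, plus edges
#' with both endpoints among genes shared by the two sets (counted once).
#' Genes absent from the graph are dropped first; the drop counts are
#' attached as attributes `n_dropped_a` / `n_dropped_b`.
#'
#' @param graph PPI igraph (see [ppi_graph()]).
#' @param set_a,set_b character vectors of gene symbols.
#' @return integer count (with drop-count attributes).
#' @export
cross_connectivity <- function(graph, set_a, set_b) {
  a <- map_to_graph(graph, set_a); b <- map_to_graph(graph, set_b)
  if (!length(a) && !length(b)) stop("both gene sets are empty after mapping into the graph")
  el <- igraph::as_edgelist(graph, names = TRUE)
  n <- cross_edge_count(el, setdiff(a, b), setdiff(b, a), intersect(a, b))
  structure(n, n_dropped_a = attr(a, "n_dropped"), n_dropped_b = attr(b, "n_dropped"))
}

cross_edge_count <- function(el, a_only, b_only, both) {
  u <- el[, 1]; v <- el[, 2]
  sum((u %in% a_only & v %in% b_only) | (u %in% b_only & v %in% a_only) |
        (u %in% both & v %in% both))
}

#' Interactions within one gene set
#'
#' Counts PPI edges with both endpoints in the (mapped) set; used for the
#' pooled-set connectivity test.
#'
#' @inheritParams cross_connectivity
#' @param gene_set character vector of gene symbols.
#' @return integer count (with attribute `n_dropped`).
#' @export
internal_connectivity <- function(graph, gene_set) {
  s <- map_to_graph(graph, gene_set)
  if (!length(s)) stop("gene set is empty after mapping into the graph")
  el <- igraph::as_edgelist(graph, names = TRUE)
  structure(sum(el[, 1] %in% s & el[, 2] %in% s), n_dropped = attr(s, "n_dropped"))
}

#' Permutation test of PPI inter-connectivity
#'
#' Recomputes the connectivity statistic over `n_perm` random gene sets of
#' the same mapped sizes, drawn without replacement from the graph's node
#' universe, and reports the add-one empirical p
#' `(1 + #\{null >= observed\}) / (n_perm + 1)`. With two sets the
#' statistic is [cross_connectivity()] (set overlap structure is preserved
#' in each draw); with one set it is [internal_connectivity()].
#'
#' The default null resamples genes uniformly; `method = "degree_binned"`
#' resamples within degree-decile bins of the observed genes, since
#' connectivity statistics are degree-confounded.
#'
#' @param graph PPI igraph.
#' @param set_a first gene set.
#' @param set_b optional second gene set; omit for the pooled/internal test.
#' @param n_perm number of permutations (default 10,000).
#' @param seed RNG seed (mandatory for reproducibility).
#' @param tail `"geq"` (default, null >= observed) or `"gt"` (strict).
#' @param method `"uniform"` or `"degree_binned"`.
#' @param n_bins degree bins for the binned sampler.
#' @return object of class `connectivity_result`: `observed`, `n_perm`,
#'   `empirical_p`, `null_mean`, `null_sd`, `null_quantiles`, `seed`.
#' @export
permutation_p <- function(graph, set_a, set_b = NULL, n_perm = 10000L,
                          seed = 1L, tail = c("geq", "gt"),
                          method = c("uniform", "degree_binned"),
                          n_bins = 10L) {
  tail <- match.arg(tail); method <- match.arg(method)
  stopifnot(n_perm >= 1)
  nodes <- igraph::V(graph)$name
  n <- length(nodes)
  el <- igraph::as_edgelist(graph, names = FALSE)
  u <- el[, 1]; v <- el[, 2]

  a <- map_to_graph(graph, set_a)
  b <- if (is.null(set_b)) NULL else map_to_graph(graph, set_b)
  pooled <- is.null(b)
  if (pooled) {
    grp_sizes <- c(only_a = length(a))
    if (!length(a)) stop("gene set is empty after mapping into the graph")
  } else {
    if (!length(a) && !length(b)) stop("both gene sets are empty after mapping into the graph")
    grp_sizes <- c(only_a = length(setdiff(a, b)), only_b = length(setdiff(b, a)),
                   both = length(intersect(a, b)))
  }
  if (sum(grp_sizes) > n) stop("combined set size exceeds the graph's node universe")

  idx <- function(genes) match(genes, nodes)
  stat_fun <- function(ia, ib, iboth) {
    in_a <- logical(n); in_b <- logical(n); in_2 <- logical(n)
    in_a[ia] <- TRUE; in_b[ib] <- TRUE; in_2[iboth] <- TRUE
    if (pooled) {
      sum(in_a[u] & in_a[v])
    } else {
      sum((in_a[u] & in_b[v]) | (in_b[u] & in_a[v]) | (in_2[u] & in_2[v]))
    }
  }
  ia0 <- if (pooled) idx(a) else idx(setdiff(a, b))
  ib0 <- if (pooled) integer(0) else idx(setdiff(b, a))
  i20 <- if (pooled) integer(0) else idx(intersect(a, b))
  observed <- stat_fun(ia0, ib0, i20)

  set.seed(seed)
  total <- sum(grp_sizes)
  draw <- if (method == "uniform") {
    function() sample.int(n, total)
  } else {
    deg <- igraph::degree(graph)
    bins <- as.integer(cut(rank(deg, ties.method = "first"),
                           breaks = n_bins, labels = FALSE))
    by_bin <- split(seq_len(n), bins)
    obs_bins <- bins[c(ia0, ib0, i20)]
    pos_by_bin <- split(seq_along(obs_bins), obs_bins)
    function() {
      res <- integer(length(obs_bins))
      for (bn in names(pos_by_bin)) {
        pos <- pos_by_bin[[bn]]
        pool <- by_bin[[bn]]
        res[pos] <- pool[sample.int(length(pool), length(pos))]
      }
      res
    }
  }
  n1 <- grp_sizes[["only_a"]]
  n2 <- if (pooled) 0L else grp_sizes[["only_b"]]
  null_stats <- vapply(seq_len(n_perm), function(i) {
    s <- draw()
    stat_fun(s[seq_len(n1)],
             if (n2) s[n1 + seq_len(n2)] else integer(0),
             if (length(s) > n1 + n2) s[(n1 + n2 + 1L):length(s)] else integer(0))
  }, numeric(1))

  hits <- if (tail == "geq") sum(null_stats >= observed) else sum(null_stats > observed)
  structure(list(observed = observed, n_perm = n_perm,
                 empirical_p = (1 + hits) / (n_perm + 1),
                 null_mean = mean(null_stats), null_sd = stats::sd(null_stats),
                 null_quantiles = stats::quantile(null_stats, c(.5, .95, .99)),
                 tail = tail, method = method, seed = seed,
                 statistic = if (pooled) "internal" else "cross"),
            class = "connectivity_result")
}

#' @export
print.connectivity_result <- function(x, ...) {
  cat(sprintf("PPI %s-connectivity permutation test\n", x$statistic))
  cat(sprintf("  observed connections: %d\n", x$observed))
  cat(sprintf("  null mean (sd): %.2f (%.2f) over %d permutations [%s sampling]\n",
              x$null_mean, x$null_sd, x$n_perm, x$method))
  cat(sprintf("  empirical p: %.4g\n", x$empirical_p))
  invisible(x)
}

#' Build the candidate gene network
#'
#' Nodes are the mapped candidate genes plus bridging interactors. Every
#' direct candidate-candidate interaction is included. For each candidate
#' pair without a direct interaction, their common neighbors in the PPI
#' graph bridge them; when more than `max_interactors` exist for a pair, a
#' random subset of `max_interactors` is kept (seeded, reproducible).
#' Retained interactors keep all their edges to included candidates.
#' Candidates without any connection remain as isolates.
#'
#' @param graph PPI igraph.
#' @param candidates named list `list(cnv = ..., snp = ...)` of symbol
#'   vectors, or a single vector. Genes in both sets are typed
#'   `candidate_cnv` (shared symbols are recorded in the `shared`
#'   attribute).
#' @param max_interactors bridge cap per candidate pair (default 3).
#' @param seed RNG seed for the random cut-off.
#' @return igraph with vertex attributes `type` (`candidate_cnv`,
#'   `candidate_snp`, `interactor`) and graph attributes `seed`, `shared`.
#' @export
build_candidate_network <- function(graph, candidates, max_interactors = 3L,
                                    seed = 1L) {
  if (!is.list(candidates)) candidates <- list(cnv = candidates)
  cnv <- map_to_graph(graph, candidates$cnv %||% character(0))
  snp <- map_to_graph(graph, candidates$snp %||% character(0))
  shared <- intersect(cnv, snp)
  cand <- union(cnv, snp)
  if (!length(cand)) stop("no candidate maps into the graph")
  type <- ifelse(cand %in% cnv, "candidate_cnv", "candidate_snp")

  set.seed(seed)
  sub <- igraph::induced_subgraph(graph, cand)
  direct <- igraph::as_edgelist(sub, names = TRUE)
  has_direct <- new.env(hash = TRUE)
  if (nrow(direct)) {
    for (i in seq_len(nrow(direct))) {
      assign(paste(sort(direct[i, ]), collapse = "\r"), TRUE, envir = has_direct)
    }
  }
  adj <- igraph::adjacent_vertices(graph, cand)
  names(adj) <- cand
  neigh <- lapply(adj, function(x) setdiff(x$name, cand))

  interactors <- character(0)
  if (length(cand) > 1L) {
    pairs <- utils::combn(sort(cand), 2L)
    for (j in seq_len(ncol(pairs))) {
      p1 <- pairs[1, j]; p2 <- pairs[2, j]
      if (!is.null(has_direct[[paste(p1, p2, sep = "\r")]])) next
      common <- intersect(neigh[[p1]], neigh[[p2]])
      if (!length(common)) next
      if (length(common) > max_interactors) {
        common <- sort(common)[sample.int(length(common), max_interactors)]
      }
      interactors <- union(interactors, common)
    }
  }

  edges <- direct
  for (it in interactors) {
    to <- intersect(igraph::neighbors(graph, it)$name, cand)
    if (length(to)) edges <- rbind(edges, cbind(rep(it, length(to)), to))
  }
  all_nodes <- c(cand, interactors)
  net <- igraph::graph_from_data_frame(
    if (is.null(edges) || !nrow(edges)) data.frame(from = character(), to = character())
    else data.frame(from = edges[, 1], to = edges[, 2], stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = all_nodes,
                          type = c(type, rep("interactor", length(interactors))),
                          stringsAsFactors = FALSE))
  net <- igraph::simplify(net)
  net <- igraph::set_graph_attr(net, "seed", seed)
  net <- igraph::set_graph_attr(net, "shared", shared)
  net
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Detect network modules by modularity maximization
#'
#' Multi-level (Louvain) modularity optimization; deterministic under a
#' fixed seed.
#'
#' @param network igraph.
#' @param resolution modularity resolution parameter (default 1).
#' @param seed RNG seed.
#' @return list with `membership` (named integer vector) and `modularity`.
#' @export
detect_modules <- function(network, resolution = 1, seed = 1L) {
  stopifnot(igraph::vcount(network) > 0)
  set.seed(seed)
  cl <- igraph::cluster_louvain(network, resolution = resolution)
  m <- igraph::membership(cl)
  list(membership = stats::setNames(as.integer(m), names(m)),
       modularity = igraph::modularity(network, m))
}

#' Node centrality
#'
#' @param network igraph.
#' @param measure `"degree"` or `"betweenness"` (betweenness is normalized
#'   by the number of ordered node pairs).
#' @return named numeric vector, one score per node.
#' @export
node_centrality <- function(network, measure = c("degree", "betweenness")) {
  measure <- match.arg(measure)
  stopifnot(igraph::vcount(network) > 0)
  if (measure == "degree") {
    igraph::degree(network)
  } else {
    igraph::betweenness(network, normalized = igraph::vcount(network) > 2)
  }
}

# Pearson correlation between the observed adjacency and the ideal
# core-periphery pattern (1 for core-core pairs, 0 otherwise), computed
# from pair counts. core: logical vector; ecc: edges within core; E: total
# edges; n: node count.
cp_fit_from_counts <- function(n_core, ecc, E, n) {
  N <- n * (n - 1) / 2
  sx <- n_core * (n_core - 1) / 2
  num <- N * ecc - sx * E
  den <- sqrt(max(0, N * sx - sx^2)) * sqrt(max(0, N * E - E^2))
  if (den == 0) return(0)
  num / den
}

#' Discrete core-periphery classification
#'
#' Assigns each node a core/periphery label by maximizing the Pearson
#' correlation between the network's adjacency and the ideal pattern in
#' which core-core pairs are connected and all other pairs are not
#' (a discrete Borgatti-Everett-style fit). Optimization is greedy
#' single-label swaps from several seeded restarts; isolates are always
#' periphery. A fit near 0 with restarts disagreeing on the best labeling
#' is flagged unstable.
#'
#' @param network igraph.
#' @param restarts greedy restarts (default 10; first start is
#'   degree-based, the rest random).
#' @param seed RNG seed.
#' @return list: `labels` (named, `"core"`/`"periphery"`), `fit` in
#'   \[-1, 1\], `stable` (logical).
#' @export
core_periphery <- function(network, restarts = 10L, seed = 1L) {
  n <- igraph::vcount(network)
  stopifnot(n > 0)
  nodes <- igraph::V(network)$name
  if (is.null(nodes)) nodes <- as.character(seq_len(n))
  deg <- igraph::degree(network)
  el <- igraph::as_edgelist(network, names = FALSE)
  E <- nrow(el)
  adj <- lapply(seq_len(n), function(i) integer(0))
  if (E) {
    adj <- igraph::as_adj_list(network)
    adj <- lapply(adj, as.integer)
  }
  if (n < 3 || E == 0) {
    return(list(labels = stats::setNames(rep("periphery", n), nodes),
                fit = 0, stable = TRUE))
  }

  set.seed(seed)
  run_greedy <- function(core) {
    core_deg <- vapply(seq_len(n), function(i) sum(core[adj[[i]]]), numeric(1))
    ecc <- sum(vapply(seq_len(E), function(e) core[el[e, 1]] && core[el[e, 2]],
                      logical(1)))
    n_core <- sum(core)
    fit <- cp_fit_from_counts(n_core, ecc, E, n)
    repeat {
      best_gain <- 0; best_i <- 0L
      for (i in seq_len(n)) {
        if (core[i]) {
          f2 <- cp_fit_from_counts(n_core - 1, ecc - core_deg[i], E, n)
        } else {
          f2 <- cp_fit_from_counts(n_core + 1, ecc + core_deg[i], E, n)
        }
        if (f2 - fit > best_gain + 1e-12) { best_gain <- f2 - fit; best_i <- i }
      }
      if (best_i == 0L) break
      i <- best_i
      if (core[i]) {
        n_core <- n_core - 1; ecc <- ecc - core_deg[i]
        core[i] <- FALSE
        for (j in adj[[i]]) core_deg[j] <- core_deg[j] - 1
      } else {
        n_core <- n_core + 1; ecc <- ecc + core_deg[i]
        core[i] <- TRUE
        for (j in adj[[i]]) core_deg[j] <- core_deg[j] + 1
      }
      fit <- fit + best_gain
    }
    list(core = core, fit = fit)
  }

  starts <- c(list(deg > stats::median(deg)),
              lapply(seq_len(max(0L, restarts - 1L)),
                     function(i) stats::runif(n) < 0.3))
  results <- lapply(starts, run_greedy)
  fits <- vapply(results, `[[`, numeric(1), "fit")
  best <- results[[which.max(fits)]]
  top <- results[fits > max(fits) - 1e-9]
  labelings <- unique(lapply(top, function(r) r$core))
  core <- best$core
  core[deg == 0] <- FALSE  # isolates are periphery by definition
  list(labels = stats::setNames(ifelse(core, "core", "periphery"), nodes),
       fit = best$fit,
       stable = length(labelings) == 1L && best$fit > 0.1)
}

#' Module-level (meta-node) network
#'
#' Contracts a partition into one meta-node per module. Meta-edge weight is
#' the number of cross-module edges; each meta-node records its module size
#' and within-module edge count.
#'
#' @param network igraph.
#' @param partition named membership vector covering all nodes (e.g. from
#'   [detect_modules()]).
#' @return igraph of meta-nodes with attributes `size`, `within_edges`
#'   (vertex) and `weight` (edge).
#' @export
meta_node_network <- function(network, partition) {
  nodes <- igraph::V(network)$name
  stopifnot(all(nodes %in% names(partition)))
  mem <- partition[nodes]
  mods <- sort(unique(mem))
  el <- igraph::as_edgelist(network, names = TRUE)
  m1 <- mem[el[, 1]]; m2 <- mem[el[, 2]]
  cross <- m1 != m2
  within_counts <- table(factor(m1[!cross], levels = mods))
  key <- paste(pmin(m1[cross], m2[cross]), pmax(m1[cross], m2[cross]), sep = "\r")
  w <- table(key)
  meta_edges <- if (length(w)) {
    pp <- do.call(rbind, strsplit(names(w), "\r", fixed = TRUE))
    data.frame(from = as.character(pp[, 1]), to = as.character(pp[, 2]),
               weight = as.numeric(w), stringsAsFactors = FALSE)
  } else data.frame(from = character(), to = character(), weight = numeric())
  igraph::graph_from_data_frame(
    meta_edges, directed = FALSE,
    vertices = data.frame(name = as.character(mods),
                          size = as.numeric(table(factor(mem, levels = mods))),
                          within_edges = as.numeric(within_counts),
                          stringsAsFactors = FALSE))
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same nodes;
#' 1 is identical structure, 0 is chance-level.
#'
#' @param x,y label vectors of equal length.
#' @return numeric scalar.
#' @export
adjusted_rand_index <- function(x, y) {
  stopifnot(length(x) == length(y))
  tab <- table(x, y)
  a <- sum(choose(tab, 2))
  b <- sum(choose(rowSums(tab), 2))
  c <- sum(choose(colSums(tab), 2))
  n <- choose(length(x), 2)
  expected <- b * c / n
  maxi <- (b + c) / 2
  if (maxi == expected) return(1)
  (a - expected) / (maxi - expected)
}
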