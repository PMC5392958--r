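# Independent brute-force oracles. Each recomputes a quantity by a
# different route than the implementation (direct enumeration, matrix
# powers, exhaustive labelings) so agreement is evidence, not tautology.

# shared bp between two single intervals, by direct arithmetic on a base grid
oracle_overlap_fraction <- function(q, t) {
  if (q$chrom != t$chrom) return(0)
  shared <- length(intersect(seq(q$start, q$end - 1), seq(t$start, t$end - 1)))
  shared / (q$end - q$start)
}

# quadratic all-pairs privatization scan
oracle_is_private <- function(segments, panel, threshold = 0.5) {
  vapply(seq_len(nrow(segments)), function(i) {
    s <- segments[i, ]
    for (j in seq_len(nrow(panel))) {
      r <- panel[j, ]
      if (r$chrom != s$chrom || r$direction != s$direction) next
      ov <- max(0, min(s$end, r$end) - max(s$start, r$start)) / (s$end - s$start)
      if (ov > threshold) return(FALSE)
    }
    TRUE
  }, logical(1))
}

# upper-tail hypergeometric by direct pmf summation with choose()
oracle_hyper_tail <- function(overlap, n_pathway, n_universe, n_query) {
  ks <- overlap:min(n_pathway, n_query)
  sum(choose(n_pathway, ks) * choose(n_universe - n_pathway, n_query - ks)) /
    choose(n_universe, n_query)
}

# hand-applied Benjamini-Hochberg step-up
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- p[o] * n / seq_len(n)
  for (i in (n - 1):1) if (n > 1) q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1])
  q <- numeric(n)
  q[o] <- pmin(1, q_sorted)
  q
}

# cross/internal connectivity by adjacency-matrix double loop
oracle_cross_count <- function(adj, nodes, a, b) {
  n <- length(nodes)
  cnt <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (!adj[i, j]) next
    u <- nodes[i]; v <- nodes[j]
    a_only <- function(x) x %in% a && !(x %in% b)
    b_only <- function(x) x %in% b && !(x %in% a)
    both <- function(x) x %in% a && x %in% b
    if ((a_only(u) && b_only(v)) || (a_only(v) && b_only(u)) ||
        (both(u) && both(v))) cnt <- cnt + 1
  }
  cnt
}

oracle_internal_count <- function(adj, nodes, s) {
  n <- length(nodes)
  cnt <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (adj[i, j] && nodes[i] %in% s && nodes[j] %in% s) cnt <- cnt + 1
  }
  cnt
}

# normalized betweenness via matrix powers: shortest-path counts are the
# minimal-length walk counts A^d[s,t]
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  pows <- list(diag(n), adj)
  for (k in 2:max(2, n)) pows[[k + 1]] <- pows[[k]] %*% adj
  d <- matrix(Inf, n, n)
  sigma <- matrix(0, n, n)
  for (s in 1:n) for (t in 1:n) {
    if (s == t) { d[s, t] <- 0; sigma[s, t] <- 1; next }
    for (k in 1:n) {
      if (pows[[k + 1]][s, t] > 0) {
        d[s, t] <- k; sigma[s, t] <- pows[[k + 1]][s, t]; break
      }
    }
  }
  bw <- numeric(n)
  for (v in 1:n) {
    for (s in 1:(n - 1)) for (t in (s + 1):n) {
      if (s == v || t == v || !is.finite(d[s, t])) next
      if (is.finite(d[s, v]) && is.finite(d[v, t]) &&
          d[s, v] + d[v, t] == d[s, t]) {
        bw[v] <- bw[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
      }
    }
  }
  if (n > 2) bw / ((n - 1) * (n - 2) / 2) else bw
}

# exhaustive core-periphery fit: try all 2^n labelings, score each by
# Pearson correlation between the vectorized adjacency and ideal pattern
oracle_cp_best_fit <- function(adj) {
  n <- nrow(adj)
  ut <- upper.tri(adj)
  y <- adj[ut]
  best <- -Inf
  for (code in 0:(2^n - 1)) {
    core <- as.logical(bitwAnd(code, 2^(0:(n - 1))))
    ideal <- outer(core, core, "&")[ut] * 1
    if (stats::sd(ideal) == 0 || stats::sd(y) == 0) next
    f <- suppressWarnings(stats::cor(y, ideal))
    if (!is.na(f) && f > best) best <- f
  }
  if (!is.finite(best)) 0 else best
}

# random small undirected igraph with named nodes
random_small_graph <- function(n, p = 0.4) {
  adj <- matrix(0, n, n)
  adj[upper.tri(adj)] <- stats::rbinom(n * (n - 1) / 2, 1, p)
  adj <- adj + t(adj)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::V(g)$name <- paste0("N", seq_len(n))
  list(graph = g, adj = adj, nodes = igraph::V(g)$name)
}

# tiny segment-table builder
seg <- function(chrom, start, end, direction = "DUP", n_probes = 10,
                sample_id = "s1", caller = "c1", state = NA) {
  cnv_segments(rep_len(chrom, length(start)), start, end, direction, n_probes,
               sample_id, caller, state)
}

empty_call_table <- function() {
  cnv_segments(character(0), numeric(0), numeric(0), character(0), numeric(0))
}
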