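# Independent brute-force oracles used to check the graph and statistics
# implementations. These are deliberately naive (explicit enumeration,
# Floyd-Warshall) and never call the code paths they verify.

# adjacency matrix from an edge data.frame over the given node labels
oracle_adjacency <- function(nodes, edges) {
  a <- matrix(0L, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  if (nrow(edges) > 0) {
    i <- match(edges$source, nodes)
    j <- match(edges$target, nodes)
    a[cbind(i, j)] <- 1L
    a[cbind(j, i)] <- 1L
  }
  a
}

# all-pairs shortest paths by Floyd-Warshall
oracle_shortest_paths <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  d[adj == 1] <- 1
  diag(d) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

# connected components from reachability
oracle_components <- function(adj) {
  d <- oracle_shortest_paths(adj)
  n <- nrow(adj)
  comp <- rep(NA_integer_, n)
  k <- 0L
  for (i in seq_len(n)) {
    if (is.na(comp[i])) {
      k <- k + 1L
      comp[is.finite(d[i, ])] <- k
    }
  }
  comp
}

# diameter of the largest connected component (ties broken by first index,
# matching which.max)
oracle_diameter_largest <- function(adj) {
  comp <- oracle_components(adj)
  sizes <- tabulate(comp)
  largest <- which.max(sizes)
  idx <- which(comp == largest)
  if (length(idx) < 2) return(0L)
  d <- oracle_shortest_paths(adj[idx, idx, drop = FALSE])
  as.integer(max(d))
}

# global transitivity by exhaustive triple enumeration:
# 3 * triangles / (triangles * 3 + open wedges)
oracle_transitivity <- function(adj) {
  n <- nrow(adj)
  if (n < 3) return(0)
  triangles <- 0L
  wedges_open <- 0L
  triples <- utils::combn(n, 3)
  for (t in seq_len(ncol(triples))) {
    v <- triples[, t]
    e <- adj[v[1], v[2]] + adj[v[1], v[3]] + adj[v[2], v[3]]
    if (e == 3) triangles <- triangles + 1L
    if (e == 2) wedges_open <- wedges_open + 1L
  }
  closed <- 3L * triangles
  if (closed + wedges_open == 0) return(0)
  closed / (closed + wedges_open)
}

# two-sided Fisher p-value by full enumeration of tables with fixed margins,
# using explicit binomial coefficients (no dhyper)
oracle_fisher <- function(a, b, c, d) {
  m <- a + b
  n <- c + d
  k <- a + c
  total <- m + n
  denom <- choose(total, k)
  support <- max(0, k - n):min(k, m)
  probs <- choose(m, support) * choose(n, k - support) / denom
  p_obs <- choose(m, a) * choose(n, k - a) / denom
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# Erdos-Renyi edge list on n nodes with edge probability p
random_edges <- function(n, p) {
  nodes <- sprintf("n%02d", seq_len(n))
  pairs <- utils::combn(nodes, 2)
  keep <- stats::runif(ncol(pairs)) < p
  data.frame(source = pairs[1, keep], target = pairs[2, keep],
             weight = rep(1L, sum(keep)), stringsAsFactors = FALSE)
}

# wrap an edge list as an interaction_network (nodes = endpoints observed)
as_network <- function(edges, nodes = NULL) {
  structure(list(
    level = "medication",
    nodes = nodes %||% sort(unique(c(edges$source, edges$target))),
    edges = edges,
    self_pairs = 0L,
    unmapped = 0L
  ), class = "interaction_network")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
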