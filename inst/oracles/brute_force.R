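# Naive reference implementations used as independent cross-checks for the
# graph metrics and the Fisher exact test. Deliberately written by explicit
# enumeration (Floyd-Warshall, triple enumeration, binomial coefficients) and
# independent of the package's own code paths.

bf_adjacency <- function(nodes, edges) {
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

bf_shortest_paths <- function(adj) {
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

bf_components <- function(adj) {
  d <- bf_shortest_paths(adj)
  comp <- rep(NA_integer_, nrow(adj))
  k <- 0L
  for (i in seq_len(nrow(adj))) {
    if (is.na(comp[i])) {
      k <- k + 1L
      comp[is.finite(d[i, ])] <- k
    }
  }
  comp
}

bf_diameter_largest <- function(adj) {
  comp <- bf_components(adj)
  idx <- which(comp == which.max(tabulate(comp)))
  if (length(idx) < 2) return(0L)
  as.integer(max(bf_shortest_paths(adj[idx, idx, drop = FALSE])))
}

bf_transitivity <- function(adj) {
  n <- nrow(adj)
  if (n < 3) return(0)
  triangles <- 0L
  open_wedges <- 0L
  triples <- utils::combn(n, 3)
  for (t in seq_len(ncol(triples))) {
    v <- triples[, t]
    e <- adj[v[1], v[2]] + adj[v[1], v[3]] + adj[v[2], v[3]]
    if (e == 3) triangles <- triangles + 1L
    if (e == 2) open_wedges <- open_wedges + 1L
  }
  closed <- 3L * triangles
  if (closed + open_wedges == 0) return(0)
  closed / (closed + open_wedges)
}

bf_fisher <- function(a, b, c, d) {
  m <- a + b
  n <- c + d
  k <- a + c
  denom <- choose(m + n, k)
  support <- max(0, k - n):min(k, m)
  probs <- choose(m, support) * choose(n, k - support) / denom
  p_obs <- choose(m, a) * choose(n, k - a) / denom
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

bf_random_edges <- function(n, p) {
  nodes <- sprintf("n%02d", seq_len(n))
  pairs <- utils::combn(nodes, 2)
  keep <- stats::runif(ncol(pairs)) < p
  data.frame(source = pairs[1, keep], target = pairs[2, keep],
             weight = rep(1L, sum(keep)), stringsAsFactors = FALSE)
}

bf_as_network <- function(edges) {
  structure(list(
    level = "medication",
    nodes = sort(unique(c(edges$source, edges$target))),
    edges = edges,
    self_pairs = 0L,
    unmapped = 0L
  ), class = "interaction_network")
}
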