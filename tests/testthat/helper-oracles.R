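# Independent oracles and fixture builders used across the suite.
# All fixtures are generated in code; oracles deliberately take a different
# computational route than the package implementation they check.

# Random complete weighted network: symmetric, zero diagonal, weights in
# (lo, hi). Uses the ambient RNG stream (seed in the calling test).
rand_network <- function(m, lo = 0.05, hi = 1.95) {
  W <- matrix(0, m, m)
  W[upper.tri(W)] <- stats::runif(m * (m - 1) / 2, lo, hi)
  W <- W + t(W)
  dimnames(W) <- list(paste0("n", 1:m), paste0("n", 1:m))
  W
}

# Is the edge subset (rows of `edges`, columns from/to) a spanning tree of m
# nodes? Checked by component counting.
spans_tree <- function(edges, m) {
  parent <- seq_len(m)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  for (e in seq_len(nrow(edges))) {
    ra <- find(edges[e, 1L]); rb <- find(edges[e, 2L])
    if (ra == rb) return(FALSE)   # cycle
    parent[ra] <- rb
  }
  TRUE                            # m - 1 acyclic edges always span
}

# Exhaustive minimum spanning tree weight: enumerate all C(m(m-1)/2, m-1)
# edge subsets. Feasible for m <= 6.
exhaustive_mst_weight <- function(W) {
  m <- nrow(W)
  ut <- which(upper.tri(W), arr.ind = TRUE)
  weights <- W[upper.tri(W)]
  best <- Inf
  combos <- utils::combn(nrow(ut), m - 1L)
  for (c in seq_len(ncol(combos))) {
    idx <- combos[, c]
    if (spans_tree(ut[idx, , drop = FALSE], m)) {
      best <- min(best, sum(weights[idx]))
    }
  }
  best
}

# Breadth-first-search component count of the graph with edges w <= lam.
bfs_components <- function(W, lam) {
  m <- nrow(W)
  adj <- (W <= lam) & upper.tri(W)
  adj <- adj | t(adj)
  seen <- logical(m)
  comps <- 0L
  for (s in seq_len(m)) {
    if (seen[s]) next
    comps <- comps + 1L
    queue <- s
    seen[s] <- TRUE
    while (length(queue) > 0L) {
      v <- queue[1L]; queue <- queue[-1L]
      nb <- which(adj[v, ] & !seen)
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
  }
  comps
}

# All set partitions of n elements as membership vectors (restricted growth
# strings). Bell(8) = 4140, fine for exhaustive modularity checks.
set_partitions <- function(n) {
  out <- list()
  grow <- function(mem, k) {
    if (length(mem) == n) {
      out[[length(out) + 1L]] <<- mem
      return(invisible())
    }
    for (c in seq_len(k + 1L)) grow(c(mem, c), max(k, c))
  }
  grow(integer(0), 0L)
  out
}

# Newman modularity of a weighted undirected graph (affinity matrix S, zero
# diagonal) under a membership vector.
newman_modularity <- function(S, mem) {
  two_m <- sum(S)
  k <- rowSums(S)
  same <- outer(mem, mem, `==`)
  sum((S - outer(k, k) / two_m) * same) / two_m
}

# Exhaustive maximum modularity over all partitions (m <= 8).
exhaustive_best_modularity <- function(S) {
  max(vapply(set_partitions(nrow(S)), function(mem) newman_modularity(S, mem),
             numeric(1)))
}

# Planted two-community affinity network as a dissimilarity matrix:
# within-community correlation r_in, between-community r_out.
planted_block_network <- function(sizes, r_in = 0.9, r_out = 0) {
  mem <- rep(seq_along(sizes), sizes)
  R <- ifelse(outer(mem, mem, `==`), r_in, r_out)
  W <- 1 - R
  diag(W) <- 0
  attr(W, "planted") <- mem
  W
}

# Small deterministic cohort config for fast pipeline tests.
tiny_config <- function(...) {
  cohort_config(n_carrier = 3L, n_noncarrier = 3L, n_roi = 8L,
                n_timepoints = 40L, seed = 11L, ...)
}
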