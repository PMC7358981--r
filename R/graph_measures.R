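#' All-pairs shortest path lengths
#'
#' Floyd-Warshall over the complete weighted graph, treating the dissimilarity
#' weights directly as edge lengths (no inverse-weight transform: the 1 -
#' Pearson weight is already distance-like). The result has zero diagonal,
#' satisfies `D <= W` entrywise and the triangle inequality.
#'
#' @param net Symmetric non-negative weight matrix with zero diagonal.
#' @return The all-pairs distance matrix.
#' @export
shortest_paths <- function(net) {
  W <- validate_network(net)
  D <- W
  for (k in seq_len(nrow(D))) {
    D <- pmin(D, outer(D[, k], D[k, ], `+`))
  }
  D
}

#' Characteristic path length (CPL)
#'
#' Mean shortest-path length over all ordered pairs of distinct nodes.
#'
#' @param net Symmetric non-negative weight matrix with zero diagonal.
#' @return The CPL scalar.
#' @export
characteristic_path_length <- function(net) {
  D <- shortest_paths(net)
  if (nrow(D) < 2L) stop("need at least 2 nodes", call. = FALSE)
  mean(D[row(D) != col(D)])
}

#' Global efficiency (GC)
#'
#' Mean inverse shortest-path length over all ordered pairs of distinct
#' nodes.
#'
#' @param net Symmetric non-negative weight matrix with zero diagonal.
#' @return The global-efficiency scalar.
#' @export
global_efficiency <- function(net) {
  D <- shortest_paths(net)
  if (nrow(D) < 2L) stop("need at least 2 nodes", call. = FALSE)
  mean(1 / D[row(D) != col(D)])
}

#' Network radius (NR)
#'
#' The minimum nodal eccentricity, where a node's eccentricity is its
#' greatest shortest-path distance to any other node.
#'
#' @param net Symmetric non-negative weight matrix with zero diagonal.
#' @return The radius scalar.
#' @export
network_radius <- function(net) {
  D <- shortest_paths(net)
  if (nrow(D) < 2L) stop("need at least 2 nodes", call. = FALSE)
  min(apply(D, 1L, max))
}

#' Affinity matrix for community and centrality measures
#'
#' Modularity and eigenvector centrality operate on similarities, not
#' distances, so the dissimilarity weights are mapped back to affinities
#' `s_ij = max(0, 1 - W_ij)` - i.e. the Pearson correlation with negative
#' values zeroed (which also keeps the matrix non-negative as required for a
#' Perron-Frobenius leading eigenvector). The diagonal is set to zero.
#'
#' @param net Symmetric non-negative weight matrix with zero diagonal.
#' @return Symmetric non-negative affinity matrix with zero diagonal.
#' @export
affinity_matrix <- function(net) {
  W <- validate_network(net)
  S <- 1 - W
  S[S < 0] <- 0
  diag(S) <- 0
  S
}

#' Modularity of the best Louvain partition
#'
#' Runs Louvain community detection on the affinity graph under
#' `n_restarts` random node orderings and returns the Newman modularity Q of
#' the best partition found. Uses R's RNG stream (seed it, or pass `seed`,
#' for reproducibility).
#'
#' @param net Symmetric non-negative weight matrix with zero diagonal.
#' @param n_restarts Number of restarts with permuted node order (default 10).
#' @param seed Optional seed applied locally (caller's RNG state restored).
#' @return List with `modularity` (best Q) and `membership` (integer
#'   community labels for that partition).
#' @export
modularity_score <- function(net, n_restarts = 10L, seed = NULL) {
  S <- affinity_matrix(net)
  if (all(S == 0)) {
    stop("all-zero affinity matrix: no positive correlations", call. = FALSE)
  }
  m <- nrow(S)
  g <- igraph::graph_from_adjacency_matrix(S, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  with_local_seed(seed, {
    best_q <- -Inf
    best_mem <- NULL
    for (r in seq_len(n_restarts)) {
      perm <- if (r == 1L) seq_len(m) else sample.int(m)
      gp <- igraph::permute(g, perm)
      cl <- igraph::cluster_louvain(gp)
      q <- igraph::modularity(cl)
      if (q > best_q) {
        best_q <- q
        mem <- integer(m)
        mem[seq_len(m)] <- igraph::membership(cl)[perm]
        best_mem <- mem
      }
    }
    list(modularity = best_q, membership = best_mem)
  })
}

#' Eigenvector centrality of the affinity graph
#'
#' Leading eigenvector of the affinity matrix, computed by shifted power
#' iteration (the shift guarantees convergence on bipartite-like graphs),
#' normalised to unit Euclidean norm and non-negative by Perron-Frobenius.
#'
#' @param net Symmetric non-negative weight matrix with zero diagonal.
#' @param tol Convergence tolerance on the max absolute change (default
#'   1e-11).
#' @param max_iter Iteration cap (default 200000, generous because the
#'   spectral gap closes when the network splits into nearly disconnected
#'   communities); exceeding it is an error.
#' @return Numeric vector of centralities (unit L2 norm).
#' @export
eigenvector_centrality <- function(net, tol = 1e-11, max_iter = 200000L) {
  S <- affinity_matrix(net)
  m <- nrow(S)
  A <- S + diag(1, m)
  v <- rep(1 / sqrt(m), m)
  for (it in seq_len(max_iter)) {
    w <- as.vector(A %*% v)
    nw <- sqrt(sum(w^2))
    if (nw == 0) stop("power iteration collapsed to zero", call. = FALSE)
    w <- w / nw
    if (max(abs(w - v)) < tol) {
      names(w) <- rownames(S)
      return(w)
    }
    v <- w
  }
  stop("eigenvector centrality did not converge within ", max_iter,
       " iterations", call. = FALSE)
}

#' Subject-level eigenvector centrality score (EC)
#'
#' The per-subject scalar reduction of eigenvector centrality: the mean of
#' the nodal centralities.
#'
#' @param net Symmetric non-negative weight matrix with zero diagonal.
#' @return The mean nodal centrality.
#' @export
eigenvector_centrality_score <- function(net) {
  mean(eigenvector_centrality(net))
}

#' All seven per-subject network features
#'
#' Computes the two persistent-homology features (SIP, BNP) and the five
#' graph-theoretic measures (CPL, NR, EC, Mod, GC) of one weighted network.
#'
#' @param net Symmetric non-negative weight matrix with zero diagonal.
#' @param n_restarts Louvain restarts for the modularity measure.
#' @param seed Optional local seed for the Louvain restarts.
#' @return Named numeric vector `sip`, `bnp`, `cpl`, `nr`, `ec`, `mod`, `gc`.
#' @export
subject_features <- function(net, n_restarts = 10L, seed = NULL) {
  W <- validate_network(net)
  c(
    sip = compute_sip(W),
    bnp = compute_bnp(W),
    cpl = characteristic_path_length(W),
    nr  = network_radius(W),
    ec  = eigenvector_centrality_score(W),
    mod = modularity_score(W, n_restarts = n_restarts, seed = seed)$modularity,
    gc  = global_efficiency(W)
  )
}

# Canonical feature column order used across the package.
FEATURE_NAMES <- c("sip", "bnp", "cpl", "nr", "ec", "mod", "gc")
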