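# Union-find with path halving; closure-based so the parent vector mutates
# in place. Component count = number of roots, valid under any compression.
new_union_find <- function(n) {
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  union <- function(a, b) {
    ra <- find(a)
    rb <- find(b)
    if (ra == rb) return(FALSE)
    parent[ra] <<- rb
    TRUE
  }
  list(
    find = find,
    union = union,
    n_components = function() sum(parent == seq_along(parent)),
    membership = function() vapply(seq_len(n), find, integer(1))
  )
}

# All i < j node pairs of an m-node complete graph in deterministic Kruskal
# order: by weight, then by (i, j) node position.
sorted_edge_list <- function(W) {
  m <- nrow(W)
  ut <- upper.tri(W)
  i <- row(W)[ut]
  j <- col(W)[ut]
  w <- W[ut]
  ord <- order(w, i, j)
  data.frame(from = i[ord], to = j[ord], weight = w[ord])
}

#' Minimum spanning tree of a weighted network
#'
#' Kruskal's algorithm with union-find over the complete graph defined by the
#' weight matrix. Ties between equal-weight edges are broken by lexicographic
#' node-position order, so the returned tree is deterministic; the total
#' weight (and hence the filtration values and Betti curve) is the same for
#' every minimum spanning tree regardless of tie-breaking.
#'
#' @param net Symmetric non-negative weight matrix with zero diagonal.
#' @return An object of class `spanning_tree`: a list with `edges` (a data
#'   frame `from`, `to`, `weight` with m - 1 rows, in order of inclusion,
#'   i.e. non-decreasing weight), `n_nodes`, `labels` and `total_weight`.
#' @examples
#' W <- matrix(c(0, .1, .5, .1, 0, .2, .5, .2, 0), 3, 3)
#' minimum_spanning_tree(W)$total_weight   # 0.3
#' @export
minimum_spanning_tree <- function(net) {
  W <- validate_network(net)
  m <- nrow(W)
  if (m < 2L) stop("need at least 2 nodes for a spanning tree", call. = FALSE)
  edges <- sorted_edge_list(W)
  uf <- new_union_find(m)
  keep <- logical(nrow(edges))
  taken <- 0L
  for (e in seq_len(nrow(edges))) {
    if (uf$union(edges$from[e], edges$to[e])) {
      keep[e] <- TRUE
      taken <- taken + 1L
      if (taken == m - 1L) break
    }
  }
  tree <- edges[keep, , drop = FALSE]
  rownames(tree) <- NULL
  structure(
    list(edges = tree, n_nodes = m, labels = rownames(W),
         total_weight = sum(tree$weight)),
    class = "spanning_tree"
  )
}

#' @export
print.spanning_tree <- function(x, ...) {
  cat("Minimum spanning tree:", x$n_nodes, "nodes, total weight",
      format(x$total_weight), "\n")
  invisible(x)
}

#' Filtration values of a network
#'
#' The graph filtration for zeroth homology only changes topology at the
#' minimum-spanning-tree weights, so the filtration values are 0 followed by
#' the m - 1 MST edge weights in ascending order (kept as a multiset: exact
#' ties yield repeated values and a Betti step larger than one).
#'
#' @param tree A `spanning_tree`, or a weight matrix (the MST is computed).
#' @return Non-decreasing numeric vector of length m starting at 0.
#' @export
filtration_values <- function(tree) {
  if (!inherits(tree, "spanning_tree")) tree <- minimum_spanning_tree(tree)
  c(0, sort(tree$edges$weight))
}

#' Zeroth Betti number at a threshold
#'
#' Number of connected components of the graph containing exactly the edges
#' whose weight is less than or equal to `lam` (closed threshold, so the
#' count drops exactly at the MST weights). Computed with union-find.
#'
#' @param net Symmetric non-negative weight matrix with zero diagonal.
#' @param lam Threshold, `lam >= 0`.
#' @return Integer component count.
#' @export
betti0_at <- function(net, lam) {
  W <- validate_network(net)
  if (!is.numeric(lam) || length(lam) != 1L || is.na(lam) || lam < 0) {
    stop("`lam` must be a single non-negative number", call. = FALSE)
  }
  m <- nrow(W)
  uf <- new_union_find(m)
  ut <- which(upper.tri(W) & W <= lam, arr.ind = TRUE)
  for (e in seq_len(nrow(ut))) uf$union(ut[e, 1L], ut[e, 2L])
  uf$n_components()
}

#' Betti number curve of the graph filtration
#'
#' Evaluates the zeroth Betti number at each filtration value of the network.
#' For a network with all-positive weights the curve starts at the node count
#' m and decreases (non-strictly) to 1, dropping at each filtration value by
#' the number of MST edges with that exact weight.
#'
#' @param net Symmetric non-negative weight matrix with zero diagonal.
#' @return A data frame of class `filtration_profile` with columns `lambda`
#'   and `betti0` (length m each).
#' @export
betti0_curve <- function(net) {
  W <- validate_network(net)
  lambdas <- filtration_values(minimum_spanning_tree(W))
  betti <- vapply(lambdas, function(l) betti0_at(W, l), integer(1))
  structure(
    data.frame(lambda = lambdas, betti0 = betti),
    class = c("filtration_profile", "data.frame")
  )
}

#' Single-linkage merge structure of the filtration
#'
#' Replays Kruskal's algorithm and records, at each accepted edge, the two
#' components it merges. This is exactly the single-linkage agglomerative
#' clustering of the weight matrix: merge heights are the MST edge weights in
#' ascending order and there are m - 1 events, the last producing one
#' component of size m.
#'
#' @param net Symmetric non-negative weight matrix with zero diagonal.
#' @return An object of class `merge_dendrogram`: list with `events` (each a
#'   list `lambda`, `members_a`, `members_b` of node positions), `n_nodes`
#'   and `labels`.
#' @export
merge_dendrogram <- function(net) {
  W <- validate_network(net)
  m <- nrow(W)
  if (m < 2L) stop("need at least 2 nodes", call. = FALSE)
  edges <- sorted_edge_list(W)
  uf <- new_union_find(m)
  events <- vector("list", m - 1L)
  taken <- 0L
  for (e in seq_len(nrow(edges))) {
    i <- edges$from[e]
    j <- edges$to[e]
    memb <- uf$membership()
    if (memb[i] == memb[j]) next
    events[[taken + 1L]] <- list(
      lambda = edges$weight[e],
      members_a = which(memb == memb[i]),
      members_b = which(memb == memb[j])
    )
    uf$union(i, j)
    taken <- taken + 1L
    if (taken == m - 1L) break
  }
  structure(list(events = events, n_nodes = m, labels = rownames(W)),
            class = "merge_dendrogram")
}

#' @export
print.merge_dendrogram <- function(x, ...) {
  cat("Single-linkage merge dendrogram:", x$n_nodes, "nodes,",
      length(x$events), "merge events\n")
  invisible(x)
}

#' Export a filtration profile or dendrogram as delimited text
#'
#' Profiles are written with columns `(lambda, betti0)`; dendrograms one merge
#' event per line as `(lambda, members_a, members_b)` with comma-separated
#' node labels.
#'
#' @param x A `filtration_profile` or `merge_dendrogram`.
#' @param file Output path.
#' @param sep Field separator (default tab).
#' @return `file`, invisibly.
#' @export
write_filtration <- function(x, file, sep = "\t") {
  if (inherits(x, "merge_dendrogram")) {
    labels <- if (is.null(x$labels)) as.character(seq_len(x$n_nodes)) else x$labels
    rows <- lapply(x$events, function(ev) {
      data.frame(lambda = ev$lambda,
                 members_a = paste(labels[ev$members_a], collapse = ","),
                 members_b = paste(labels[ev$members_b], collapse = ","))
    })
    out <- do.call(rbind, rows)
  } else {
    out <- as.data.frame(x)
  }
  utils::write.table(out, file, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Element-wise mean network of a group of subjects
#'
#' The group-level aggregation rule used for descriptive multiscale plots:
#' the entry-wise mean of the subjects' weight matrices (all of the same
#' dimension and node order).
#'
#' @param nets List of symmetric weight matrices.
#' @return The mean weight matrix.
#' @export
group_mean_network <- function(nets) {
  stopifnot(length(nets) >= 1L)
  mats <- lapply(nets, validate_network)
  dims <- vapply(mats, nrow, integer(1))
  if (length(unique(dims)) != 1L) {
    stop("all networks must have the same dimension", call. = FALSE)
  }
  Reduce(`+`, mats) / length(mats)
}
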