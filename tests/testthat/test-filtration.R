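test_that("MST of the 3-node example picks the two cheapest edges", {
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 0.1
  W[2, 3] <- W[3, 2] <- 0.2
  W[1, 3] <- W[3, 1] <- 0.5
  tree <- minimum_spanning_tree(W)
  expect_equal(nrow(tree$edges), 2L)
  expect_equal(tree$total_weight, 0.3, tolerance = 1e-15)
  expect_equal(sort(tree$edges$weight), c(0.1, 0.2))
  expect_error(minimum_spanning_tree(W[1, 1, drop = FALSE]), "at least 2")
})

test_that("equal-weight graphs give total weight (m-1) * w", {
  W <- matrix(0.7, 4, 4)
  diag(W) <- 0
  expect_equal(minimum_spanning_tree(W)$total_weight, 3 * 0.7)
})

test_that("MST total weight matches exhaustive enumeration and igraph", {
  set.seed(505)
  for (i in 1:25) {
    m <- sample(3:6, 1)
    W <- rand_network(m)
    tree <- minimum_spanning_tree(W)
    expect_equal(tree$total_weight, exhaustive_mst_weight(W),
                 tolerance = 1e-12)
    g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                             weighted = TRUE)
    ig <- igraph::mst(g, weights = igraph::E(g)$weight)
    expect_equal(tree$total_weight, sum(igraph::E(ig)$weight),
                 tolerance = 1e-12)
  }
})

test_that("filtration values are 0 plus the sorted MST weight multiset", {
  set.seed(6)
  W <- rand_network(26)
  lam <- filtration_values(W)
  expect_length(lam, 26L)
  expect_equal(lam[1L], 0)
  expect_true(all(diff(lam) >= 0))
  expect_equal(lam[-1L], sort(minimum_spanning_tree(W)$edges$weight))
})

test_that("betti0 thresholding matches BFS component counts", {
  set.seed(99)
  for (i in 1:30) {
    W <- rand_network(7)
    lam <- stats::runif(1, 0, 2)
    expect_equal(betti0_at(W, lam), bfs_components(W, lam))
  }
  W <- rand_network(26, lo = 0.2)
  expect_equal(betti0_at(W, 0), 26L)
  expect_equal(betti0_at(W, max(W)), 1L)
})

test_that("the Betti curve is a non-increasing step function from m to 1", {
  set.seed(123)
  for (i in 1:100) {
    m <- sample(3:12, 1)
    W <- rand_network(m, lo = 0.05)
    prof <- betti0_curve(W)
    expect_equal(nrow(prof), m)
    expect_equal(prof$betti0[1L], m)
    expect_equal(prof$betti0[m], 1L)
    expect_true(all(diff(prof$betti0) <= 0))
  }
})

test_that("a chain-weighted network steps down one component at a time", {
  # path weights far below all shortcuts: MST is the chain
  W <- matrix(2, 4, 4)
  diag(W) <- 0
  W[1, 2] <- W[2, 1] <- 0.1
  W[2, 3] <- W[3, 2] <- 0.2
  W[3, 4] <- W[4, 3] <- 0.3
  prof <- betti0_curve(W)
  expect_equal(prof$betti0, c(4L, 3L, 2L, 1L))
  expect_equal(prof$lambda, c(0, 0.1, 0.2, 0.3))
})

test_that("tied MST weights produce a Betti step of size two", {
  W <- matrix(2, 4, 4)
  diag(W) <- 0
  W[1, 2] <- W[2, 1] <- 0.1
  W[3, 4] <- W[4, 3] <- 0.1
  W[2, 3] <- W[3, 2] <- 0.5
  lam <- filtration_values(W)
  expect_equal(lam, c(0, 0.1, 0.1, 0.5))
  prof <- betti0_curve(W)
  expect_equal(prof$betti0, c(4L, 2L, 2L, 1L))
})

test_that("the merge dendrogram replays single-linkage clustering", {
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 0.1
  W[2, 3] <- W[3, 2] <- 0.2
  W[1, 3] <- W[3, 1] <- 0.5
  dend <- merge_dendrogram(W)
  expect_length(dend$events, 2L)
  expect_equal(dend$events[[1L]]$lambda, 0.1)
  expect_equal(sort(c(dend$events[[1L]]$members_a,
                      dend$events[[1L]]$members_b)), c(1L, 2L))
  expect_equal(dend$events[[2L]]$lambda, 0.2)

  set.seed(77)
  for (i in 1:10) {
    m <- sample(4:10, 1)
    W <- rand_network(m)
    dend <- merge_dendrogram(W)
    expect_length(dend$events, m - 1L)
    # final event reunites all m nodes
    last <- dend$events[[m - 1L]]
    expect_equal(sort(c(last$members_a, last$members_b)), seq_len(m))
    # merge heights equal hclust single-linkage heights
    hc <- stats::hclust(stats::as.dist(W), method = "single")
    expect_equal(vapply(dend$events, `[[`, numeric(1), "lambda"),
                 sort(hc$height), tolerance = 1e-12)
    # distinct merge values = distinct MST weights
    mst_w <- minimum_spanning_tree(W)$edges$weight
    expect_equal(length(unique(vapply(dend$events, `[[`, numeric(1),
                                      "lambda"))),
                 length(unique(mst_w)))
  }
})

test_that("dendrogram memberships agree with the betti0 partition", {
  set.seed(31)
  W <- rand_network(9)
  dend <- merge_dendrogram(W)
  for (ev in dend$events) {
    # just below the merge height the two sides are separate components;
    # at the height they are joined
    expect_equal(betti0_at(W, ev$lambda),
                 bfs_components(W, ev$lambda))
  }
  lam <- filtration_values(W)
  expect_equal(vapply(lam, function(l) betti0_at(W, l), integer(1)),
               betti0_curve(W)$betti0)
})

test_that("monotone weight transforms preserve the MST edge set and step order", {
  set.seed(404)
  for (i in 1:10) {
    W <- rand_network(8)
    tr <- function(x) x^2 + 0.5 * x          # strictly increasing on [0, 2]
    W2 <- tr(W)
    diag(W2) <- 0
    e1 <- minimum_spanning_tree(W)$edges
    e2 <- minimum_spanning_tree(W2)$edges
    expect_equal(e1[, c("from", "to")], e2[, c("from", "to")])
    expect_equal(betti0_curve(W)$betti0, betti0_curve(W2)$betti0)
  }
})

test_that("group mean networks are element-wise means", {
  set.seed(8)
  nets <- replicate(3, rand_network(5), simplify = FALSE)
  M <- group_mean_network(nets)
  expect_equal(M[2, 3], mean(c(nets[[1]][2, 3], nets[[2]][2, 3],
                               nets[[3]][2, 3])))
  expect_error(group_mean_network(list(rand_network(4), rand_network(5))),
               "same dimension")
})
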