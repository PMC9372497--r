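test_that("degree centrality has its closed-form values on canonical graphs", {
  star <- graph_from_edges(4, list(c(1, 2), c(1, 3), c(1, 4)))
  expect_equal(nodalDegreeCentrality(star, "n01"), 1)
  expect_equal(nodalDegreeCentrality(star, "n02"), 1 / 3)

  complete <- graph_from_edges(5, combn(5, 2, c, simplify = FALSE))
  expect_equal(nodalDegreeCentrality(complete, "n03"), 1)
  expect_equal(subsetMeanDegreeCentrality(complete, c("n01", "n02", "n04")), 1)

  empty <- graph_from_edges(4, list())
  expect_equal(nodalDegreeCentrality(empty, "n02"), 0)
  expect_equal(subsetMeanDegreeCentrality(empty, c("n01", "n03")), 0)

  expect_error(nodalDegreeCentrality(star, "missing"), "not in graph")
  expect_error(subsetMeanDegreeCentrality(star, "n01"), "at least 2")
})

test_that("clustering and efficiency match closed forms on tiny graphs", {
  tri <- graph_from_edges(3, list(c(1, 2), c(2, 3), c(1, 3)))
  expect_equal(clusteringCoefficient(tri, c("n01", "n02", "n03")), 1)
  expect_equal(globalEfficiency(tri, c("n01", "n02", "n03")), 1)

  path <- graph_from_edges(3, list(c(1, 2), c(2, 3)))
  expect_equal(clusteringCoefficient(path, "n02"), 0)
  expect_equal(globalEfficiency(path, c("n01", "n02", "n03")),
               mean(c(1, 1 / 2, 1)))
})

test_that("metrics agree with brute-force oracles on random graphs", {
  set.seed(33)
  for (rep in 1:25) {
    n <- sample(4:9, 1)
    g <- random_graph(n, runif(1, 0.2, 0.7))
    A <- g@adjacency
    v <- sample(n, 1)
    expect_equal(nodalDegreeCentrality(g, g@nodes[v]),
                 oracle_degree_centrality(A, v))
    expect_equal(clusteringCoefficient(g, g@nodes[v]),
                 oracle_local_clustering(A, v))
    sub <- sort(sample(n, sample(2:n, 1)))
    expect_equal(subsetMeanDegreeCentrality(g, g@nodes[sub]),
                 oracle_mean_induced_dc(A, sub))
    expect_equal(clusteringCoefficient(g, g@nodes[sub]),
                 oracle_mean_clustering(A[sub, sub, drop = FALSE]))
    expect_equal(globalEfficiency(g, g@nodes[sub]),
                 oracle_global_efficiency(A[sub, sub, drop = FALSE]))
  }
})

test_that("metrics agree with igraph as an independent library cross-check", {
  set.seed(91)
  for (rep in 1:15) {
    n <- sample(5:12, 1)
    g <- random_graph(n, runif(1, 0.15, 0.8))
    ig <- igraph::graph_from_adjacency_matrix(g@adjacency * 1,
                                              mode = "undirected")
    sub <- g@nodes
    expect_equal(clusteringCoefficient(g, sub),
                 mean(igraph::transitivity(ig, type = "local",
                                           isolates = "zero")),
                 tolerance = 1e-12)
    d <- igraph::distances(ig)
    inv <- 1 / d[row(d) != col(d)]
    inv[!is.finite(inv)] <- 0
    expect_equal(globalEfficiency(g, sub), mean(inv), tolerance = 1e-12)
    expect_equal(subsetMeanDegreeCentrality(g, sub),
                 mean(igraph::degree(ig)) / (n - 1), tolerance = 1e-12)
  }
})

test_that("metrics are invariant under node relabeling", {
  set.seed(41)
  for (rep in 1:10) {
    n <- 7
    g <- random_graph(n)
    perm <- sample(n)
    gp <- BinaryGraph(g@nodes, g@adjacency[perm, perm])
    sub <- sample(n, 4)
    # permuting labels, then asking for the same *relabelled* nodes,
    # gives the same values
    expect_equal(subsetMeanDegreeCentrality(g, g@nodes[sub]),
                 subsetMeanDegreeCentrality(gp, gp@nodes[match(sub, perm)]))
    expect_equal(globalEfficiency(g, g@nodes[sub]),
                 globalEfficiency(gp, gp@nodes[match(sub, perm)]))
  }
})

test_that("adding an edge never decreases degree centrality", {
  set.seed(55)
  for (rep in 1:10) {
    n <- 6
    g <- random_graph(n, 0.3)
    A <- g@adjacency
    off <- which(!A & upper.tri(A), arr.ind = TRUE)
    if (nrow(off) == 0) next
    e <- off[sample(nrow(off), 1), ]
    A2 <- A; A2[e[1], e[2]] <- A2[e[2], e[1]] <- TRUE
    g2 <- BinaryGraph(g@nodes, A2)
    for (v in g@nodes)
      expect_gte(nodalDegreeCentrality(g2, v), nodalDegreeCentrality(g, v))
  }
})

test_that("thresholdGraph composes fdrEdges with the sign rule", {
  s <- small_sim(seed = 13, nSubjects = 2L, nRois = 10L, nTime = 30L,
                 instanceSizes = c(3L, 3L, 2L, 2L))
  for (mode in c("positive", "absolute")) {
    g <- thresholdGraph(s$stack, 1, 2, q = 0.05, mode = mode)
    mask <- fdrEdges(pvalMatrix(s$stack, 1, 2), 0.05)
    if (mode == "positive") mask <- mask & (connMatrix(s$stack, 1, 2) > 0)
    mask <- mask & t(mask)
    diag(mask) <- FALSE
    expect_identical(unname(g@adjacency), unname(mask))
    expect_identical(g@nodes, roiKeys(s$stack))
  }
  # degenerate slices: all-significant and all-null
  pnull <- matrix(1, 4, 4); diag(pnull) <- 0
  rfull <- matrix(0.9, 4, 4); diag(rfull) <- 1
  expect_false(any(fdrEdges(pnull, 0.05)))
  psig <- matrix(1e-10, 4, 4); diag(psig) <- 0
  expect_true(all(fdrEdges(psig, 0.05)[upper.tri(psig)]))
})

test_that("graphProperty dispatches on subset size and scope", {
  g <- graph_from_edges(5, list(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(1, 5),
                                c(1, 3)))
  # single node -> nodal value on the full graph
  expect_equal(graphProperty(g, "n01"), nodalDegreeCentrality(g, "n01"))
  # multi-node induced (default) vs full-graph scope
  sub <- c("n01", "n02", "n03")
  expect_equal(graphProperty(g, sub), subsetMeanDegreeCentrality(g, sub))
  i <- match(sub, g@nodes)
  expect_equal(graphProperty(g, sub, scope = "full"),
               mean(rowSums(g@adjacency[i, ])) / 4)
  expect_equal(graphProperty(g, sub, metric = "clustering"),
               clusteringCoefficient(g, sub))
  expect_equal(graphProperty(g, sub, metric = "efficiency"),
               globalEfficiency(g, sub))
  expect_error(graphProperty(g, sub, metric = "clustering", scope = "full"),
               "only defined for the degree metric")
})
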