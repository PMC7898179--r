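test_that("MST total length equals the exhaustive spanning-tree minimum", {
  set.seed(15)
  z <- named_matrix(rnorm(24), 4, samples = paste0("s", 1:6))
  tree <- build_mst(z)
  d <- as.matrix(dist(t(z)))
  expect_equal(tree$total_length, min_spanning_length(d), tolerance = 1e-10)
  expect_equal(igraph::ecount(tree$graph), 5)       # |E| = n - 1
  expect_true(igraph::is_connected(tree$graph))
})

test_that("MST handles collinear points, duplicates, and permutations", {
  # 3 collinear points form a path
  z <- named_matrix(c(0, 1, 5), 1, samples = c("a", "b", "c"))
  tree <- build_mst(z)
  expect_equal(sort(unname(igraph::degree(tree$graph))), c(1, 1, 2))
  expect_equal(tree$total_length, 5)

  # duplicated sample yields a zero-length edge
  z2 <- named_matrix(c(0, 0, 3), 1, samples = c("a", "a2", "b"))
  tree2 <- build_mst(z2)
  expect_true(any(igraph::E(tree2$graph)$length == 0))
  expect_equal(tree2$total_length, 3)

  # total length is invariant under sample permutation
  set.seed(29)
  z3 <- named_matrix(rnorm(40), 5, samples = paste0("s", 1:8))
  perm <- sample(8)
  expect_equal(build_mst(z3)$total_length,
               build_mst(z3[, perm])$total_length, tolerance = 1e-12)
})

test_that("tree distances match a breadth-first oracle and add along paths", {
  set.seed(47)
  z <- named_matrix(rnorm(35), 5, samples = paste0("s", 1:7))
  tree <- build_mst(z)
  # BFS oracle for hop distance
  adj <- igraph::as_adj_list(tree$graph)
  names(adj) <- tree$samples
  bfs_hops <- function(from, to) {
    seen <- setNames(rep(NA_integer_, 7), tree$samples)
    seen[from] <- 0L
    queue <- from
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (nb in tree$samples[as.integer(adj[[v]])]) {
        if (is.na(seen[nb])) { seen[nb] <- seen[v] + 1L; queue <- c(queue, nb) }
      }
    }
    seen[to]
  }
  for (a in tree$samples) for (b in tree$samples) {
    expect_equal(tree_distance(tree, a, b, "edges"), unname(bfs_hops(a, b)))
  }
  # path additivity of the length metric along the unique path
  path <- igraph::shortest_paths(tree$graph, "s1", "s5")$vpath[[1]]
  ids <- tree$samples[as.integer(path)]
  if (length(ids) > 2) {
    total <- sum(sapply(seq_len(length(ids) - 1), function(i)
      tree_distance(tree, ids[i], ids[i + 1], "length")))
    expect_equal(tree_distance(tree, "s1", "s5", "length"), total,
                 tolerance = 1e-12)
  }
  # adjacent nodes are 1 hop apart
  e1 <- igraph::ends(tree$graph, 1)
  expect_equal(tree_distance(tree, e1[1], e1[2], "edges"), 1)
  expect_error(tree_distance(tree, "s1", "nope"), "unknown node")
})

test_that("path-graph endpoints sit n-1 hops apart", {
  z <- named_matrix(c(1, 2, 3, 4, 5), 1, samples = paste0("s", 1:5))
  tree <- build_mst(z)
  expect_equal(tree_distance(tree, "s1", "s5", "edges"), 4)
})

test_that("branch classification separates terminal from transitional states", {
  # path graph with state blocks A-B-C: B is the through-state
  z <- named_matrix(c(1, 2, 3, 10, 11, 12, 20, 21, 22), 1,
                    samples = paste0("s", 1:9))
  states <- setNames(rep(c("A", "B", "C"), each = 3), paste0("s", 1:9))
  tree <- build_mst(z, states = states)
  calls <- classify_branches(tree)
  expect_equal(calls$call[calls$state == "A"], "terminal")
  expect_equal(calls$call[calls$state == "C"], "terminal")
  expect_equal(calls$call[calls$state == "B"], "transitional")

  # star of state-pure arms around a hub state
  z2 <- named_matrix(c(0, 5, 6, -5, -6, 0.2, 0, 0, 0, 0, 5, 6), 2,
                     samples = paste0("s", 1:6))
  states2 <- setNames(c("H", "X", "X", "Y", "Y", "H"), paste0("s", 1:6))
  tree2 <- build_mst(z2, states = states2)
  calls2 <- classify_branches(tree2)
  expect_true(all(calls2$call[calls2$state %in% c("X", "Y")] == "terminal"))

  # singleton state: terminal by convention, flagged
  states3 <- setNames(c("A", "A", "A", "B", "B", "B", "C", "C", "S"),
                      paste0("s", 1:9))
  calls3 <- classify_branches(tree, states = states3)
  expect_equal(calls3$call[calls3$state == "S"], "terminal")
  expect_true(calls3$flagged[calls3$state == "S"])
})

test_that("middle states of planted trajectories classify as transitional", {
  set.seed(53)
  hits <- 0
  n_rep <- 100
  for (rep in seq_len(n_rep)) {
    centers <- c(0, 4, 8, 12)                # linear state ordering
    n_per <- 8
    z <- t(sapply(1:3, function(d)
      rnorm(4 * n_per, rep(centers, each = n_per), 0.5)))
    colnames(z) <- paste0("s", seq_len(4 * n_per))
    rownames(z) <- paste0("g", 1:3)
    states <- setNames(rep(paste0("st", 1:4), each = n_per), colnames(z))
    calls <- classify_branches(build_mst(z, states = states))
    mid <- calls$call[calls$state %in% c("st2", "st3")]
    hits <- hits + all(mid == "transitional")
  }
  expect_gte(hits / n_rep, 0.9)
})

test_that("ellipsoid volumes match the closed form for known covariances", {
  set.seed(88)
  n <- 500
  x <- matrix(rnorm(3 * n), n, 3)           # isotropic unit Gaussian
  z <- t(x)
  colnames(z) <- paste0("s", seq_len(n))
  rownames(z) <- paste0("g", 1:3)
  groups <- setNames(rep("iso", n), colnames(z))
  es <- pca_ellipsoids(z, groups, n_pc = 3, radius_sd = 2)
  v_closed <- 4 / 3 * pi * 2^3
  expect_lt(abs(es$groups$iso$volume - v_closed) / v_closed, 0.15)

  # identical groups: volume ratio ~ 1; scaled group: ratio tracks the scale
  set.seed(89)
  y <- matrix(rnorm(3 * 2 * n), 2 * n, 3)
  y[(n + 1):(2 * n), ] <- y[(n + 1):(2 * n), ] * 0.5  # variance x 0.25 per axis
  zz <- t(y); colnames(zz) <- paste0("s", seq_len(2 * n))
  rownames(zz) <- paste0("g", 1:3)
  grp <- setNames(rep(c("broad", "tight"), each = n), colnames(zz))
  es2 <- pca_ellipsoids(zz, grp, n_pc = 3, radius_sd = 2)
  ratio <- es2$groups$tight$volume / es2$groups$broad$volume
  expect_lt(abs(ratio - 0.125) / 0.125, 0.25)

  # nested groups: the tight group lies inside the broad ellipsoid at at
  # least the nominal coverage of radius_sd = 2
  expect_gte(es2$containment["tight", "broad"], 0.95)
  # PCs are orthonormal
  expect_equal(crossprod(es2$loadings), diag(3), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("degenerate group covariance yields zero volume, flagged", {
  z <- named_matrix(c(1, 2, 3, 4, 5, 6, 7, 8,
                      2, 4, 6, 8, 10, 12, 14, 16,
                      0, 0, 0, 0, 1, 1, 1, 1), 3,
                    samples = paste0("s", 1:8))
  groups <- setNames(rep("only", 8), colnames(z))
  es <- pca_ellipsoids(z, groups, n_pc = 3)
  expect_true(es$groups$only$degenerate)
  expect_equal(es$groups$only$volume, 0)
})
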