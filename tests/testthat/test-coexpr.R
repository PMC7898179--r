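test_that("correlate_all matches the scalar formula and flags tiny overlaps", {
  set.seed(23)
  m <- named_matrix(abs(rnorm(50, 3)), 5)     # 5 genes x 10 samples
  e <- toy_expr(m)
  cc <- correlate_all(e, min_pairs = 2)
  pearson <- function(a, b) {
    am <- a - mean(a); bm <- b - mean(b)
    sum(am * bm) / sqrt(sum(am^2) * sum(bm^2))
  }
  for (i in 1:5) for (j in 1:5) {
    if (i == j) next
    r <- pearson(m[i, ], m[j, ])
    expect_equal(cc$r[i, j], r, tolerance = 1e-12)
    tt <- r * sqrt(8 / (1 - r^2))
    expect_equal(cc$p[i, j], 2 * pt(abs(tt), 8, lower.tail = FALSE),
                 tolerance = 1e-12)
  }

  # a perfectly correlated pair: r = 1, p ~ 0
  m2 <- named_matrix(c(1:6, 2 * (1:6) + 1, 6:1), 3)
  cc2 <- correlate_all(toy_expr(m2), min_pairs = 2)
  expect_equal(cc2$r["g1", "g2"], 1)
  expect_lt(cc2$p["g1", "g2"], 1e-12)

  # pairwise-detected mode drops pairs below min_pairs
  m3 <- named_matrix(c(0, 0, 0, 0, 1, 2,  1, 2, 3, 4, 5, 6), 2)
  cc3 <- correlate_all(toy_expr(m3), min_pairs = 8, pairwise_detected = TRUE)
  expect_true(is.na(cc3$r["g1", "g2"]))
})

test_that("correlation p values are uniform under independence", {
  set.seed(61)
  n <- 30
  m <- named_matrix(rnorm(2000 * n, 5), 2000)
  m <- pmax(m, 0)
  cc <- suppressWarnings(correlate_all(toy_expr(m), min_pairs = 8))
  # take 1000 disjoint pairs to keep them independent
  ps <- sapply(seq_len(1000), function(k) cc$p[2 * k - 1, 2 * k])
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("qvalues reproduces the BH hand computation", {
  expect_equal(qvalues(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(qvalues(rep(1, 5)), rep(1, 5))
  expect_equal(qvalues(0.2), 0.2)           # single test: q = p
  # matrix form adjusts the upper triangle once and mirrors it
  p <- matrix(c(NA, 0.01, 0.02, 0.01, NA, 0.03, 0.02, 0.03, NA), 3)
  q <- qvalues(p)
  expect_true(isSymmetric(q))
  expect_equal(q[1, 2], p.adjust(c(0.01, 0.02, 0.03), "BH")[1])
})

test_that("build_network keeps exactly the sub-threshold edges", {
  set.seed(3)
  m <- named_matrix(abs(rnorm(60, 3)), 6)
  cc <- correlate_all(toy_expr(m), min_pairs = 2)
  net <- build_network(cc, q_cut = 0.5)
  # oracle: recompute q on the upper triangle and filter row by row
  qs <- p.adjust(cc$p[upper.tri(cc$p)], "BH")
  idx <- which(upper.tri(cc$p), arr.ind = TRUE)
  expected <- sum(qs < 0.5, na.rm = TRUE)
  expect_equal(nrow(net$edges), expected)
  expect_true(all(net$edges$q < 0.5))
  expect_true(all(net$edges$gene_i < net$edges$gene_j))
  # no q below an impossible cutoff -> empty edge list, nodes retained
  net0 <- build_network(cc, q_cut = 1e-12)
  expect_equal(nrow(net0$edges), 0)
  expect_equal(net0$nodes, rownames(m))
  expect_equal(net0$isolated, rownames(m))
})

test_that("edge count is monotone non-decreasing in the q cutoff", {
  set.seed(44)
  m <- named_matrix(abs(rnorm(80, 3)), 8)
  cc <- correlate_all(toy_expr(m), min_pairs = 2)
  counts <- sapply(c(1e-4, 1e-2, 0.1, 0.5, 1), function(q)
    nrow(build_network(cc, q_cut = q)$edges))
  expect_true(all(diff(counts) >= 0))
})

test_that("a planted two-block structure is recovered", {
  set.seed(10)
  n <- 40
  block <- function(k, rho) {
    shared <- rnorm(n)
    t(sapply(seq_len(k), function(i) sqrt(rho) * shared + sqrt(1 - rho) * rnorm(n)))
  }
  m <- rbind(block(5, 0.8), block(5, 0.8)) + 5
  rownames(m) <- paste0("g", 1:10); colnames(m) <- paste0("s", 1:n)
  e <- toy_expr(pmax(m, 0))
  net <- build_network(correlate_all(e, min_pairs = 8), q_cut = 1e-3)
  within <- function(a, b) (a <= 5) == (b <= 5)
  gi <- as.integer(sub("g", "", net$edges$gene_i))
  gj <- as.integer(sub("g", "", net$edges$gene_j))
  n_within <- sum(within(gi, gj))
  n_cross <- sum(!within(gi, gj))
  expect_gte(n_within / 20, 0.9)      # 2 * choose(5,2) = 20 within-block pairs
  expect_lte(n_cross / 25, 0.04)      # 25 cross-block pairs
})

test_that("edge set algebra matches exhaustive enumeration", {
  mk <- function(edges, nodes = paste0("g", 1:5), cond = "c") {
    df <- data.frame(gene_i = edges[, 1], gene_j = edges[, 2],
                     r = 0.9, p = 1e-6, q = 1e-6, sign = 1,
                     stringsAsFactors = FALSE)
    structure(list(condition = cond, edges = df, nodes = nodes,
                   isolated = setdiff(nodes, unlist(edges)), q_cut = 1e-3),
              class = "coexpr_network")
  }
  n1 <- mk(cbind(c("g1", "g1", "g2"), c("g2", "g3", "g3")), cond = "a")
  n2 <- mk(cbind(c("g1", "g2", "g4"), c("g2", "g3", "g5")), cond = "b")
  n3 <- mk(cbind(c("g1", "g3"), c("g2", "g4")), cond = "c")
  alg <- edge_set_algebra(list(a = n1, b = n2, c = n3))
  # brute force over the 5 distinct edges
  expect_equal(nrow(alg$shared_core), 1)      # g1-g2 in all three
  expect_equal(paste(alg$shared_core$gene_i, alg$shared_core$gene_j), "g1 g2")
  expect_equal(paste(alg$unique$a$gene_i, alg$unique$a$gene_j), "g1 g3")
  expect_setequal(paste(alg$unique$b$gene_i, alg$unique$b$gene_j), "g4 g5")
  expect_setequal(paste(alg$unique$c$gene_i, alg$unique$c$gene_j), "g3 g4")
  expect_equal(alg$summary$unique_fraction, c(1/3, 1/3, 1/2))

  # identical networks have no unique edges; disjoint ones are fully unique
  alg_same <- edge_set_algebra(list(x = n1, y = n1))
  expect_equal(alg_same$summary$n_unique, c(0, 0))
  n_disj <- mk(cbind("g4", "g5"), cond = "d")
  alg_disj <- edge_set_algebra(list(a = n1, d = n_disj))
  expect_equal(alg_disj$summary$unique_fraction, c(1, 1))

  # mismatched panels error
  n_bad <- mk(cbind("g1", "g2"), nodes = paste0("g", 1:4))
  expect_error(edge_set_algebra(list(n1, n_bad)), "different gene panels")
})

test_that("hub ranking is degree-first with documented tie handling", {
  # star on 6 nodes: center degree 5, rank 1
  star <- data.frame(gene_i = "g1", gene_j = paste0("g", 2:6),
                     r = 0.9, p = 1e-6, q = 1e-6, sign = 1)
  net <- structure(list(condition = "c", edges = star,
                        nodes = paste0("g", 1:6), isolated = character(0),
                        q_cut = 1e-3), class = "coexpr_network")
  h <- hub_rank(net, top_k = 5)
  expect_equal(h$gene[1], "g1")
  expect_equal(h$degree[1], 5)
  expect_equal(h$rank[1], 1)
  expect_true(all(h$rank[h$gene != "g1"] == 2))   # all leaves tie at rank 2
  expect_equal(attr(h, "top_k")[1], "g1")

  # exhaustive degree count on a toy network
  set.seed(2)
  m <- named_matrix(abs(rnorm(80, 3)), 8)
  netr <- build_network(correlate_all(toy_expr(m), min_pairs = 2), q_cut = 0.8)
  h2 <- hub_rank(netr)
  for (g in netr$nodes) {
    expect_equal(h2$degree[h2$gene == g],
                 sum(netr$edges$gene_i == g) + sum(netr$edges$gene_j == g))
  }
  expect_true(all(diff(h2$degree) <= 0))

  # empty network: every gene rank 1 at degree 0
  net0 <- build_network(correlate_all(toy_expr(m), min_pairs = 2), q_cut = 1e-15)
  h0 <- hub_rank(net0)
  expect_true(all(h0$degree == 0) && all(h0$rank == 1))
})

test_that("false edges under a global null respect the q_cut bound", {
  set.seed(71)
  m <- named_matrix(abs(rnorm(30 * 25, 4)), 30)   # 30 independent genes
  q_cut <- 0.05
  false_edges <- nrow(build_network(correlate_all(toy_expr(m), min_pairs = 8),
                                    q_cut = q_cut)$edges)
  m_tests <- choose(30, 2)
  expect_lte(false_edges, qbinom(0.999, m_tests, q_cut) + 1)
})
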