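#' Minimum spanning tree over inter-sample Euclidean distances
#'
#' Builds the MST of the complete graph on samples with Euclidean edge
#' lengths computed from a gene x sample matrix (typically Z scores).
#' Tie-breaking is deterministic: edges are supplied in lexicographic
#' sample-id order, which igraph's MST respects, so identical inputs give
#' identical trees.
#'
#' @param z gene x sample numeric matrix (e.g. a `z_matrix`).
#' @param states optional named state labels for the samples.
#' @param meta optional sample metadata (condition labels attached to
#'   nodes).
#' @return a `sample_tree`: list with `graph` (igraph, edge attribute
#'   `length`), `samples`, `states`, `conditions`, `total_length`.
#' @export
build_mst <- function(z, states = NULL, meta = NULL) {
  if (ncol(z) < 2) stop("need at least 2 samples")
  ids <- colnames(z)
  if (is.null(ids)) ids <- paste0("S", seq_len(ncol(z)))
  d <- as.matrix(stats::dist(t(z)))
  g <- igraph::graph_from_adjacency_matrix(d, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  # dist() of duplicated samples gives 0, which graph_from_adjacency_matrix
  # would drop as a non-edge; re-add zero-length edges explicitly
  zero_pairs <- which(d == 0 & upper.tri(d), arr.ind = TRUE)
  if (nrow(zero_pairs)) {
    for (k in seq_len(nrow(zero_pairs))) {
      g <- igraph::add_edges(g, c(zero_pairs[k, 1], zero_pairs[k, 2]),
                             weight = 0)
    }
  }
  mst <- igraph::mst(g, weights = igraph::E(g)$weight)
  igraph::E(mst)$length <- igraph::E(mst)$weight
  cond <- if (!is.null(meta)) {
    meta <- as.data.frame(meta)
    stats::setNames(meta$condition[match(ids, meta$sample_id)], ids)
  } else NULL
  structure(list(graph = mst, samples = ids,
                 states = if (!is.null(states)) states[ids] else NULL,
                 conditions = cond,
                 total_length = sum(igraph::E(mst)$length)),
            class = "sample_tree")
}

#' @export
print.sample_tree <- function(x, ...) {
  cat(sprintf("sample_tree: %d nodes, %d edges, total length %.4g\n",
              length(x$samples), igraph::ecount(x$graph), x$total_length))
  invisible(x)
}

#' Distance between two samples along the tree
#'
#' The path between two nodes of a tree is unique; `metric = "edges"` counts
#' hops along it, `metric = "length"` sums the Euclidean edge lengths.
#'
#' @param tree a `sample_tree`.
#' @param a,b sample ids.
#' @param metric `"edges"` or `"length"`.
#' @return a single distance.
#' @export
tree_distance <- function(tree, a, b, metric = c("edges", "length")) {
  metric <- match.arg(metric)
  stopifnot(inherits(tree, "sample_tree"))
  for (v in c(a, b)) if (!v %in% tree$samples) stop("unknown node: ", v)
  w <- if (metric == "length") igraph::E(tree$graph)$length else NA
  as.numeric(igraph::distances(tree$graph, v = a, to = b, weights = w))
}

#' Classify states as terminal or transitional on the tree
#'
#' A node is a "through node" when it lies on the tree path between two
#' other states: deleting it leaves two or more components that contain
#' other-state nodes. A state is called terminal when at least `threshold`
#' of its nodes are not through nodes (they sit on leaf-side subtrees, so
#' removing them cannot disconnect the remaining states); otherwise it is
#' transitional. Singleton states are terminal by convention and flagged.
#'
#' @param tree a `sample_tree` with state labels (or pass `states`).
#' @param states optional named state labels overriding the tree's.
#' @param threshold fraction of qualifying nodes needed for a terminal call
#'   (default 0.7).
#' @return data.frame: state, n, fraction_terminal_like, call, flagged.
#' @export
classify_branches <- function(tree, states = NULL, threshold = 0.7) {
  stopifnot(inherits(tree, "sample_tree"))
  st <- if (!is.null(states)) states[tree$samples] else tree$states
  if (is.null(st)) stop("no state labels available")
  if (anyNA(st)) stop("states must cover every node")
  g <- tree$graph
  deg <- igraph::degree(g)
  qualifies <- vapply(seq_along(tree$samples), function(i) {
    if (deg[i] <= 1) return(TRUE)
    sub <- igraph::delete_vertices(g, i)
    comp <- igraph::components(sub)$membership
    st_rest <- st[-i]
    other <- tapply(st_rest != st[i], comp, any)
    sum(other) <= 1
  }, logical(1))
  out <- do.call(rbind, lapply(sort(unique(st)), function(s) {
    idx <- which(st == s)
    frac <- mean(qualifies[idx])
    singleton <- length(idx) == 1
    data.frame(state = s, n = length(idx),
               fraction_terminal_like = frac,
               call = if (singleton || frac >= threshold) "terminal" else "transitional",
               flagged = singleton, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' PCA group ellipsoids in expression space
#'
#' Projects all samples jointly onto the first `n_pc` principal components
#' (sign convention: the largest-magnitude loading of each PC is positive),
#' then summarises each group by its covariance ellipsoid at `radius_sd`
#' standard deviations: centroid, semi-axis lengths
#' `radius_sd * sqrt(eigenvalue)`, and volume
#' `pi^(d/2)/gamma(d/2+1) * prod(semi_axes)` (for d = 3 the familiar
#' `(4/3) pi r1 r2 r3`). Cross-group containment is the fraction of one
#' group's points with Mahalanobis distance (in PC space, w.r.t. the other
#' group's ellipsoid) at most `radius_sd`.
#'
#' @param z gene x sample matrix (samples are projected).
#' @param groups named group labels per sample.
#' @param n_pc number of components (default 3).
#' @param radius_sd ellipsoid radius in SD units (default 2).
#' @return an `ellipsoid_summary`: list with `scores`, `loadings`,
#'   `groups` (per-group centroid, eigenvalues, axes, volume, flag), and
#'   `containment` (matrix: fraction of row group's points inside column
#'   group's ellipsoid).
#' @export
pca_ellipsoids <- function(z, groups, n_pc = 3, radius_sd = 2) {
  x <- t(z)
  groups <- groups[rownames(x)]
  if (anyNA(groups)) stop("groups must cover every sample")
  tab <- table(groups)
  if (any(tab < n_pc + 1)) stop("every group needs >= n_pc + 1 samples")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  n_pc <- min(n_pc, ncol(pc$rotation))
  rot <- pc$rotation[, seq_len(n_pc), drop = FALSE]
  flip <- apply(rot, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  rot <- sweep(rot, 2, flip, "*")
  scores <- sweep(pc$x[, seq_len(n_pc), drop = FALSE], 2, flip, "*")
  unit_ball <- pi^(n_pc / 2) / gamma(n_pc / 2 + 1)
  grp <- lapply(names(tab), function(gname) {
    s <- scores[groups == gname, , drop = FALSE]
    centroid <- colMeans(s)
    cv <- stats::cov(s)
    ev <- eigen(cv, symmetric = TRUE)
    lambda <- pmax(ev$values, 0)
    axes <- radius_sd * sqrt(lambda)
    degenerate <- any(lambda < .Machine$double.eps)
    list(group = gname, n = nrow(s), centroid = centroid, cov = cv,
         eigenvalues = lambda, axes = axes,
         volume = if (degenerate) 0 else unit_ball * prod(axes),
         degenerate = degenerate)
  })
  names(grp) <- names(tab)
  contain <- matrix(NA_real_, length(grp), length(grp),
                    dimnames = list(names(grp), names(grp)))
  for (gi in names(grp)) for (gj in names(grp)) {
    if (grp[[gj]]$degenerate) next
    s <- scores[groups == gi, , drop = FALSE]
    md2 <- stats::mahalanobis(s, grp[[gj]]$centroid, grp[[gj]]$cov)
    contain[gi, gj] <- mean(md2 <= radius_sd^2)
  }
  structure(list(scores = scores, loadings = rot, radius_sd = radius_sd,
                 groups = grp, containment = contain),
            class = "ellipsoid_summary")
}

#' @export
print.ellipsoid_summary <- function(x, ...) {
  for (g in x$groups)
    cat(sprintf("%s: n = %d, volume = %.4g%s\n", g$group, g$n, g$volume,
                if (g$degenerate) " (degenerate)" else ""))
  invisible(x)
}
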