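#' Pearson correlation distance between samples or genes
#'
#' Computes `d = 1 - r` over the chosen axis, giving distances in `[0, 2]`
#' with 0 on the diagonal. Items with zero variance carry no correlation
#' signal; their distance to every other item is set to the maximum (2),
#' with a warning naming them, so they fall out as singleton branches
#' rather than aborting the clustering.
#'
#' @param x numeric matrix (e.g. a `z_matrix` or binned matrix).
#' @param axis `"samples"` (columns, default) or `"genes"` (rows).
#' @return symmetric distance matrix with item names.
#' @export
correlation_distance <- function(x, axis = c("samples", "genes")) {
  axis <- match.arg(axis)
  m <- if (axis == "samples") x else t(x)
  if (ncol(m) < 2) stop("need at least 2 items")
  sds <- apply(m, 2, stats::sd)
  flat <- sds == 0 | is.na(sds)
  r <- suppressWarnings(stats::cor(m))
  d <- 1 - r
  if (any(flat)) {
    warning("zero-variance item(s) set to maximum distance: ",
            paste(colnames(m)[flat], collapse = ", "))
    d[flat, ] <- 2
    d[, flat] <- 2
  }
  diag(d) <- 0
  d[d < 0] <- 0           # guard tiny negative rounding of 1 - r
  d
}

#' Average-linkage hierarchical clustering
#'
#' Thin wrapper around [stats::hclust()] (UPGMA) that validates the distance
#' matrix and returns the standard merge tree.
#'
#' @param dist_mat symmetric distance matrix (or a `dist`).
#' @param linkage linkage criterion; only `"average"` is offered, matching
#'   the clustering convention used throughout the package.
#' @return an `hclust` object.
#' @export
cluster_tree <- function(dist_mat, linkage = "average") {
  if (!inherits(dist_mat, "dist")) {
    if (!is.matrix(dist_mat) || !isSymmetric(unname(dist_mat), tol = 1e-10))
      stop("distance matrix must be symmetric")
    dist_mat <- stats::as.dist(dist_mat)
  }
  stats::hclust(dist_mat, method = linkage)
}

#' Parsimonious flat cut of a dendrogram
#'
#' Scans candidate cut heights (the midpoints between consecutive distinct
#' merge heights) and selects, among cuts whose clusters all contain at
#' least `min_size` members and whose cluster count lies in `k_range`, the
#' cut with the largest number of clusters. If several heights yield that
#' count the highest such height is used (the most margin before the next
#' merge). When no cut is feasible the whole tree is returned as a single
#' cluster with a warning.
#'
#' Cluster labels are letters assigned in order of decreasing cluster size
#' ("A" largest), giving stable names across runs.
#'
#' @param tree an `hclust` object.
#' @param min_size minimum cluster size (default 5).
#' @param k_range integer interval of admissible cluster counts.
#' @return named character vector of cluster labels, one per leaf, with
#'   attributes `k`, `cut_height`.
#' @export
cut_parsimonious <- function(tree, min_size = 5, k_range = c(2, 12)) {
  stopifnot(inherits(tree, "hclust"), min_size >= 1)
  n <- length(tree$order)
  k_range <- c(max(1L, k_range[1]), min(n, k_range[2]))
  hts <- sort(unique(tree$height))
  cands <- if (length(hts) > 1) (hts[-1] + hts[-length(hts)]) / 2 else numeric(0)
  cands <- c(cands, max(hts) + 1)   # the k = 1 cut is always available
  best <- NULL
  for (h in cands) {
    lab <- stats::cutree(tree, h = h)
    k <- length(unique(lab))
    sizes <- table(lab)
    if (k >= k_range[1] && k <= k_range[2] && all(sizes >= min_size)) {
      if (is.null(best) || k > best$k || (k == best$k && h > best$h))
        best <- list(lab = lab, k = k, h = h)
    }
  }
  if (is.null(best)) {
    warning("no feasible cut in k_range with min_size; returning k = 1")
    best <- list(lab = stats::setNames(rep(1L, n), tree$labels), k = 1L,
                 h = max(hts) + 1)
  }
  labels_by_size <- names(sort(table(best$lab), decreasing = TRUE))
  letters_pool <- make.unique(rep(LETTERS, length.out = best$k), sep = "")
  remap <- stats::setNames(letters_pool[seq_len(best$k)], labels_by_size)
  out <- remap[as.character(best$lab)]
  names(out) <- names(best$lab)
  attr(out, "k") <- best$k
  attr(out, "cut_height") <- best$h
  out
}

#' Discover sample states and gene modules by hierarchical clustering
#'
#' Runs the full correlation-distance / average-linkage / parsimonious-cut
#' pipeline on both axes of an expression-derived matrix.
#'
#' @param x numeric gene x sample matrix (quartile bins or Z scores).
#' @param min_size,k_range passed to [cut_parsimonious()] for the sample
#'   axis.
#' @param gene_min_size,gene_k_range same for the gene axis.
#' @return a `state_partition`: list with `states` (sample labels),
#'   `modules` (gene labels), the two `hclust` trees, and cut heights.
#' @export
discover_states <- function(x, min_size = 5, k_range = c(2, 12),
                            gene_min_size = 3, gene_k_range = c(2, 10)) {
  sd_tree <- cluster_tree(correlation_distance(x, "samples"))
  gd_tree <- cluster_tree(correlation_distance(x, "genes"))
  states <- cut_parsimonious(sd_tree, min_size, k_range)
  modules <- cut_parsimonious(gd_tree, gene_min_size, gene_k_range)
  structure(list(states = states, modules = modules,
                 sample_tree = sd_tree, gene_tree = gd_tree,
                 cut_heights = c(samples = attr(states, "cut_height"),
                                 genes = attr(modules, "cut_height"))),
            class = "state_partition")
}

#' @export
print.state_partition <- function(x, ...) {
  cat(sprintf("state_partition: %d samples in %d states; %d genes in %d modules\n",
              length(x$states), length(unique(x$states)),
              length(x$modules), length(unique(x$modules))))
  print(table(states = x$states))
  invisible(x)
}

#' Heatmap-ready export with per-state composition
#'
#' Orders rows and columns by dendrogram leaf order and computes, for each
#' state, the exact proportion of samples per condition and per side (the
#' pie-chart annotations of a state heatmap).
#'
#' @param partition a `state_partition` from [discover_states()].
#' @param x the matrix that was clustered (bins or Z scores).
#' @param meta sample metadata with `sample_id`, `condition`, `side`.
#' @return list with `matrix` (reordered), `row_order`, `col_order`,
#'   `states` (in column order), and `composition` (data.frame of state,
#'   group type, group, proportion, n).
#' @export
compose_heatmap <- function(partition, x, meta) {
  stopifnot(inherits(partition, "state_partition"))
  col_order <- partition$sample_tree$labels[partition$sample_tree$order]
  row_order <- partition$gene_tree$labels[partition$gene_tree$order]
  m <- x[row_order, col_order, drop = FALSE]
  meta <- as.data.frame(meta)
  meta <- meta[match(col_order, meta$sample_id), , drop = FALSE]
  st <- partition$states[col_order]
  comp <- do.call(rbind, lapply(unique(st), function(s) {
    idx <- st == s
    rows <- list()
    for (what in c("condition", "side")) {
      tab <- table(factor(meta[[what]][idx]))
      rows[[what]] <- data.frame(state = s, stratum = what,
                                 group = names(tab),
                                 n = as.integer(tab),
                                 proportion = as.numeric(tab) / sum(idx),
                                 stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  }))
  rownames(comp) <- NULL
  list(matrix = m, row_order = row_order, col_order = col_order,
       states = st, composition = comp)
}

#' Adjusted Rand index between two partitions
#'
#' Closed-form ARI from the contingency table; used to score recovery of
#' planted states on synthetic data.
#'
#' @param a,b label vectors of equal length.
#' @return ARI in `[-1, 1]` (1 = identical partitions).
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
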