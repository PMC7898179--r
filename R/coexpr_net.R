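#' All-pairs Pearson correlation with p values
#'
#' Correlates every gene pair within one condition's samples on the
#' LOD-relative expression scale. By default censored zeros are kept (the
#' values live on the relative-to-LOD scale where 0 is meaningful);
#' `pairwise_detected = TRUE` instead uses only samples where both genes
#' were detected. Pairs with fewer than `min_pairs` jointly informative
#' samples are returned as `NA`, which guards against spurious perfect
#' correlations in tiny groups.
#'
#' @param expr an `expr_matrix` already subset to one condition.
#' @param min_pairs minimum informative samples per pair (default 8).
#' @param pairwise_detected restrict each pair to jointly detected samples.
#' @return list of gene x gene matrices `r`, `p` (two-sided), `n`.
#' @export
correlate_all <- function(expr, min_pairs = 8, pairwise_detected = FALSE) {
  stopifnot(inherits(expr, "expr_matrix"))
  x <- t(expr$values)
  if (pairwise_detected) {
    xd <- x
    xd[!t(expr$detected)] <- NA
    r <- suppressWarnings(stats::cor(xd, use = "pairwise.complete.obs"))
    n <- crossprod(!is.na(xd))
  } else {
    r <- suppressWarnings(stats::cor(x))
    n <- matrix(nrow(x), ncol(x), ncol(x))
  }
  dimnames(n) <- dimnames(r)
  low <- n < min_pairs
  r[low] <- NA
  # zero-variance genes give NA correlations already (cor warns, we suppress)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  p[is.na(r)] <- NA
  diag(r) <- 1; diag(p) <- NA
  list(r = r, p = p, n = n)
}

#' Benjamini-Hochberg q values for a p-value table
#'
#' Adjusts the upper triangle of a symmetric p matrix (each pair counted
#' once) and mirrors the result back, or adjusts a plain vector.
#'
#' @param p symmetric matrix or numeric vector of p values in `[0, 1]`.
#' @return object of the same shape holding BH-adjusted q values.
#' @export
qvalues <- function(p) {
  if (is.matrix(p)) {
    ut <- upper.tri(p)
    q <- p
    q[ut] <- stats::p.adjust(p[ut], method = "BH")
    q[lower.tri(q)] <- t(q)[lower.tri(q)]
    return(q)
  }
  stats::p.adjust(p, method = "BH")
}

#' Build a thresholded signed co-expression network
#'
#' Keeps gene pairs with `q < q_cut` as edges; the edge sign is the sign of
#' the correlation. Genes with no surviving edge remain in the node set,
#' flagged isolated.
#'
#' @param cors output of [correlate_all()].
#' @param q_cut q-value cutoff (default `1e-3`).
#' @param condition label stored on the network.
#' @return a `coexpr_network`: list with `edges` (data.frame gene_i, gene_j
#'   with `gene_i < gene_j`, r, p, q, sign), `nodes`, `isolated`,
#'   `q_cut`.
#' @export
build_network <- function(cors, q_cut = 1e-3, condition = "all") {
  q <- qvalues(cors$p)
  ut <- which(upper.tri(q), arr.ind = TRUE)
  keep <- !is.na(q[ut]) & q[ut] < q_cut
  idx <- ut[keep, , drop = FALSE]
  genes <- rownames(cors$r)
  gi <- genes[idx[, 1]]; gj <- genes[idx[, 2]]
  swap <- gi > gj
  tmp <- gi[swap]; gi[swap] <- gj[swap]; gj[swap] <- tmp
  edges <- data.frame(gene_i = gi, gene_j = gj,
                      r = cors$r[idx], p = cors$p[idx], q = q[idx],
                      sign = sign(cors$r[idx]), stringsAsFactors = FALSE)
  edges <- edges[order(edges$gene_i, edges$gene_j), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(condition = condition, edges = edges, nodes = genes,
                 isolated = setdiff(genes, union(edges$gene_i, edges$gene_j)),
                 q_cut = q_cut),
            class = "coexpr_network")
}

#' @export
print.coexpr_network <- function(x, ...) {
  cat(sprintf("coexpr_network [%s]: %d nodes, %d edges (q < %g), %d isolated\n",
              x$condition, length(x$nodes), nrow(x$edges), x$q_cut,
              length(x$isolated)))
  invisible(x)
}

edge_keys <- function(net) paste(net$edges$gene_i, net$edges$gene_j, sep = "\r")

#' Unique and shared edges across condition networks
#'
#' @param networks named list of `coexpr_network`s on the same gene panel.
#' @return list with per-condition `unique` edge data.frames, the
#'   `shared_core` present in every network, and a `summary` data.frame of
#'   edge counts and uniqueness fractions.
#' @export
edge_set_algebra <- function(networks) {
  if (length(networks) < 2) stop("need >= 2 networks")
  panels <- lapply(networks, `[[`, "nodes")
  if (!all(vapply(panels[-1], identical, logical(1), y = panels[[1]])))
    stop("networks built on different gene panels")
  if (is.null(names(networks)))
    names(networks) <- vapply(networks, `[[`, character(1), "condition")
  keys <- lapply(networks, edge_keys)
  core <- Reduce(intersect, keys)
  uniq <- lapply(seq_along(networks), function(i) {
    others <- unique(unlist(keys[-i]))
    networks[[i]]$edges[!(keys[[i]] %in% others), , drop = FALSE]
  })
  names(uniq) <- names(networks)
  summary <- data.frame(
    condition = names(networks),
    n_edges = vapply(keys, length, integer(1)),
    n_unique = vapply(uniq, nrow, integer(1)),
    stringsAsFactors = FALSE)
  summary$unique_fraction <- ifelse(summary$n_edges > 0,
                                    summary$n_unique / summary$n_edges, NA)
  core_df <- networks[[1]]$edges[keys[[1]] %in% core, , drop = FALSE]
  list(unique = uniq, shared_core = core_df, summary = summary)
}

#' Degree-ranked hub genes
#'
#' Ranks every panel gene by network degree; ties are broken by the summed
#' absolute correlation of incident edges, then lexicographically. In an
#' empty network all genes tie at degree 0 and share rank 1.
#'
#' @param net a `coexpr_network`.
#' @param top_k optionally also return the top-k membership set.
#' @return data.frame (gene, degree, strength, rank); attribute `top_k`
#'   holds the membership set when requested.
#' @export
hub_rank <- function(net, top_k = NULL) {
  deg <- stats::setNames(rep(0L, length(net$nodes)), net$nodes)
  str <- stats::setNames(rep(0, length(net$nodes)), net$nodes)
  if (nrow(net$edges)) {
    tab <- table(c(net$edges$gene_i, net$edges$gene_j))
    deg[names(tab)] <- as.integer(tab)
    for (i in seq_len(nrow(net$edges))) {
      a <- abs(net$edges$r[i])
      str[net$edges$gene_i[i]] <- str[net$edges$gene_i[i]] + a
      str[net$edges$gene_j[i]] <- str[net$edges$gene_j[i]] + a
    }
  }
  ord <- order(-deg, -str, names(deg))
  df <- data.frame(gene = names(deg)[ord], degree = unname(deg[ord]),
                   strength = unname(str[ord]), stringsAsFactors = FALSE)
  # competition ranking: equal (degree, strength) share the lowest rank
  key <- paste(df$degree, signif(df$strength, 12))
  first_pos <- which(!duplicated(key))
  df$rank <- first_pos[match(key, key[first_pos])]
  if (!is.null(top_k)) attr(df, "top_k") <- df$gene[seq_len(min(top_k, nrow(df)))]
  df
}
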