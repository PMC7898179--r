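#' miRNA count container (NanoString-style)
#'
#' @param counts non-negative integer matrix, probes x samples.
#' @param is_negctrl logical vector flagging negative-control probe rows.
#' @param groups per-sample group labels (e.g. control / LAD / RIPC+LAD).
#' @return a `mirna_counts` list.
#' @export
mirna_counts <- function(counts, is_negctrl, groups) {
  stopifnot(is.matrix(counts), length(is_negctrl) == nrow(counts),
            length(groups) == ncol(counts))
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (!any(is_negctrl)) stop("need at least one negative-control probe")
  structure(list(counts = counts, is_negctrl = as.logical(is_negctrl),
                 groups = as.character(groups)),
            class = "mirna_counts")
}

#' Background-thresholded miRNA detection
#'
#' A probe is detected when its mean count across samples strictly exceeds
#' the negative-control background: the mean of the negative-control probes'
#' per-probe means plus `k_sd` of their standard deviation.
#'
#' @param x a `mirna_counts`.
#' @param k_sd background SD multiplier (default 2).
#' @return character vector of detected probe ids; attributes `threshold`,
#'   `probe_means`.
#' @export
detect_mirna <- function(x, k_sd = 2) {
  stopifnot(inherits(x, "mirna_counts"))
  pm <- rowMeans(x$counts)
  neg <- pm[x$is_negctrl]
  thr <- mean(neg) + k_sd * stats::sd(neg)
  if (is.na(thr)) thr <- mean(neg)   # a single negative control has no SD
  det <- names(pm)[!x$is_negctrl & pm > thr]
  attr(det, "threshold") <- thr
  attr(det, "probe_means") <- pm
  det
}

#' Total-count normalisation and log2 transform
#'
#' Scales each sample by the total count over non-control probes (to the
#' mean library size) and returns `log2(x + 1)`.
#'
#' @param x a `mirna_counts`.
#' @return probes x samples matrix of normalised log2 counts.
#' @export
normalize_mirna <- function(x) {
  stopifnot(inherits(x, "mirna_counts"))
  tot <- colSums(x$counts[!x$is_negctrl, , drop = FALSE])
  if (any(tot == 0)) stop("sample with zero total counts")
  scaled <- sweep(x$counts, 2, mean(tot) / tot, "*")
  log2(scaled + 1)
}

# All distinct arrangements of a label multiset (for the exact permutation
# null). Returns a matrix with one arrangement per row.
multiset_permutations <- function(labels) {
  labels <- as.character(labels)
  rec <- function(remaining) {
    if (length(remaining) == 0) return(matrix(character(0), 1, 0))
    out <- list()
    for (u in unique(remaining)) {
      rest <- remaining[-match(u, remaining)]
      sub <- rec(rest)
      out[[length(out) + 1]] <- cbind(u, sub, deparse.level = 0)
    }
    do.call(rbind, out)
  }
  rec(labels)
}

#' Template matching of group-level expression patterns
#'
#' Scores each probe by the Pearson correlation between its per-sample
#' values and the per-sample expansion of a group-level template (the
#' default encodes "dysregulated by injury, normalised by preconditioning":
#' control = 0, LAD = 1, RIPC+LAD = 0). Matching is sign-agnostic: the
#' statistic is `|r|`, so up- and down-dysregulation both match. p values
#' come from a permutation null over group labels: exhaustive enumeration of
#' all distinct label arrangements when there are at most `exact_limit`,
#' otherwise `n_perm` Monte Carlo draws under `seed`.
#'
#' @param norm normalised probes x samples matrix (see [normalize_mirna()]).
#' @param groups per-sample group labels.
#' @param template named numeric vector, one value per group.
#' @param n_perm Monte Carlo permutations (default 10000).
#' @param seed RNG seed for the Monte Carlo null.
#' @param exact_limit enumerate exactly when the number of distinct label
#'   arrangements is at most this (default 5000).
#' @return data.frame (`template_match`): probe, score (signed r),
#'   abs_score, p_value, fold_change (linear LAD/control fold from log2
#'   group-mean difference, signed by direction), mean_abundance.
#' @export
template_match <- function(norm, groups, template = c(control = 0, LAD = 1, RIPC_LAD = 0),
                           n_perm = 10000, seed = 42, exact_limit = 5000) {
  groups <- as.character(groups)
  if (!all(groups %in% names(template)))
    stop("template must name every group; missing: ",
         paste(setdiff(unique(groups), names(template)), collapse = ", "))
  if (any(table(groups) < 2)) stop("need >= 2 samples per group")
  t_obs <- as.numeric(template[groups])
  score_against <- function(tv) {
    tv <- tv - mean(tv)
    denom_t <- sqrt(sum(tv^2))
    xc <- norm - rowMeans(norm)
    denom_x <- sqrt(rowSums(xc^2))
    s <- as.numeric(xc %*% tv) / (denom_x * denom_t)
    s[denom_x == 0] <- 0
    s
  }
  obs <- score_against(t_obs)
  n_distinct <- exp(lfactorial(length(groups)) -
                      sum(lfactorial(table(t_obs))))
  if (round(n_distinct) <= exact_limit) {
    perms <- multiset_permutations(as.character(t_obs))
    scores <- sapply(seq_len(nrow(perms)), function(i)
      abs(score_against(as.numeric(perms[i, ]))))
    scores <- matrix(scores, nrow = nrow(norm))
    p <- rowMeans(scores >= abs(obs) - 1e-12)
  } else {
    exceed <- rep(0, nrow(norm))
    with_seed(seed, {
      for (b in seq_len(n_perm)) {
        sb <- abs(score_against(sample(t_obs)))
        exceed <- exceed + (sb >= abs(obs) - 1e-12)
      }
    })
    p <- (1 + exceed) / (n_perm + 1)
  }
  zero_var <- apply(norm, 1, function(v) stats::sd(v) == 0)
  p[zero_var] <- 1
  # fold change between the template's extreme groups (injury vs control)
  g_hi <- names(template)[which.max(template)]
  g_lo <- names(template)[which.min(template)]
  m_hi <- rowMeans(norm[, groups == g_hi, drop = FALSE])
  m_lo <- rowMeans(norm[, groups == g_lo, drop = FALSE])
  lfc <- m_hi - m_lo
  fold <- ifelse(lfc >= 0, 2^lfc, -(2^(-lfc)))
  out <- data.frame(probe = rownames(norm), score = obs, abs_score = abs(obs),
                    p_value = p, log2_fold = lfc, fold_change = fold,
                    mean_abundance = rowMeans(norm),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("template_match", class(out))
  out
}

#' Prioritise candidate miRNAs
#'
#' Candidates must be detected, match the template at `p <= p_cut`, change
#' at least `fold_cut`-fold between injury and control (either direction),
#' and sit at or above the `abundance_quantile` of detected-probe abundance.
#' Output is sorted by p value.
#'
#' @param matches a `template_match` data.frame.
#' @param detected character vector from [detect_mirna()].
#' @param p_cut p-value cutoff (default 0.05).
#' @param fold_cut minimum linear fold change (default 2).
#' @param abundance_quantile abundance floor as a quantile of detected
#'   probes (default 0.25).
#' @return subset of `matches` rows forming the candidate list.
#' @export
prioritize <- function(matches, detected, p_cut = 0.05, fold_cut = 2,
                       abundance_quantile = 0.25) {
  m <- matches[matches$probe %in% detected, , drop = FALSE]
  if (nrow(m) == 0) return(m)
  ab_floor <- stats::quantile(m$mean_abundance, abundance_quantile, names = FALSE)
  keep <- m$p_value <= p_cut & abs(m$fold_change) >= fold_cut &
    m$mean_abundance >= ab_floor
  out <- m[keep, , drop = FALSE]
  out[order(out$p_value), , drop = FALSE]
}

#' Consensus-filtered miRNA target network
#'
#' Builds the bipartite miRNA -> gene network from a precomputed
#' target-prediction hit table: an edge requires a consensus hit (more than
#' one prediction algorithm flags the pair) and a target gene present in the
#' supplied expressed-gene list. Candidate miRNAs absent from the hit table
#' are retained as isolated nodes with a warning.
#'
#' @param candidates character vector of candidate miRNA ids (e.g.
#'   `prioritize(...)$probe`).
#' @param hits data.frame with columns `mirna`, `gene` and one logical/0-1
#'   column per prediction algorithm.
#' @param expressed_genes character vector of genes robustly expressed in
#'   the tissue.
#' @param category_map optional named vector gene -> functional category.
#' @param algorithms columns of `hits` holding per-algorithm flags; default
#'   every column except `mirna`/`gene`.
#' @return list with `edges` (mirna, gene, n_algorithms, category),
#'   `nodes_mirna`, `nodes_gene`, and `graph` (igraph bipartite).
#' @export
target_network <- function(candidates, hits, expressed_genes,
                           category_map = NULL, algorithms = NULL) {
  if (length(expressed_genes) == 0) stop("expressed-gene list is empty")
  hits <- as.data.frame(hits)
  if (!all(c("mirna", "gene") %in% names(hits)))
    stop("hit table needs `mirna` and `gene` columns")
  if (is.null(algorithms)) algorithms <- setdiff(names(hits), c("mirna", "gene"))
  if (length(algorithms) < 2) stop("need hit flags for >= 2 algorithms")
  flags <- sapply(hits[algorithms], function(col) as.logical(col) %in% TRUE)
  flags <- matrix(flags, nrow = nrow(hits))
  n_alg <- rowSums(flags)
  absent <- setdiff(candidates, hits$mirna)
  if (length(absent))
    warning("candidate(s) absent from hit table: ", paste(absent, collapse = ", "))
  keep <- hits$mirna %in% candidates & n_alg >= 2 & hits$gene %in% expressed_genes
  edges <- data.frame(mirna = hits$mirna[keep], gene = hits$gene[keep],
                      n_algorithms = n_alg[keep], stringsAsFactors = FALSE)
  edges$category <- if (!is.null(category_map))
    unname(category_map[edges$gene]) else NA_character_
  g <- igraph::make_empty_graph(directed = FALSE)
  nodes <- c(unique(candidates), setdiff(unique(edges$gene), candidates))
  g <- igraph::add_vertices(g, length(nodes), name = nodes,
                            type = nodes %in% candidates)
  if (nrow(edges))
    g <- igraph::add_edges(g, rbind(match(edges$mirna, nodes),
                                    match(edges$gene, nodes)))
  list(edges = edges, nodes_mirna = unique(candidates),
       nodes_gene = unique(edges$gene), graph = g)
}
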