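#' Region-ligand-receptor connectivity prior
#'
#' The prior is plain data: a table with one row per input (a brain region
#' projecting onto the nucleus, the ligand it releases, and the receptor
#' genes that read that ligand) or output (an effector signal and the
#' synthesis/marker genes that produce it). It ships as an editable TSV and
#' can be replaced wholesale by the user.
#'
#' @param df data.frame with columns `kind` ("in"/"out"),
#'   `region_or_signal`, `ligand` (may be `""` for outputs), `genes`
#'   (semicolon-separated gene ids), `grouped` (logical: the region entry is
#'   an unresolvable group of regions).
#' @param panel optional character vector of assayed genes; prior genes not
#'   in the panel are flagged (`missing_genes` column) with a warning, not
#'   dropped.
#' @return validated data.frame of class `connectivity_prior` with list
#'   columns `gene_list` and `missing_genes`.
#' @export
connectivity_prior <- function(df, panel = NULL) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  required <- c("kind", "region_or_signal", "ligand", "genes", "grouped")
  miss <- setdiff(required, names(df))
  if (length(miss)) stop("prior lacks column(s): ", paste(miss, collapse = ", "))
  if (!all(df$kind %in% c("in", "out"))) stop("`kind` must be 'in' or 'out'")
  if (any(!nzchar(df$region_or_signal))) stop("empty region/signal label")
  df$grouped <- as.logical(df$grouped)
  df$gene_list <- lapply(strsplit(df$genes, ";", fixed = TRUE), trimws)
  if (any(lengths(df$gene_list) == 0)) stop("prior row with no genes")
  df$missing_genes <- lapply(df$gene_list, function(g) character(0))
  if (!is.null(panel)) {
    df$missing_genes <- lapply(df$gene_list, setdiff, y = panel)
    n_miss <- sum(lengths(df$missing_genes) > 0)
    if (n_miss > 0)
      warning(n_miss, " prior row(s) name gene(s) absent from the panel; flagged")
  }
  class(df) <- c("connectivity_prior", class(df))
  df
}

#' Load a connectivity prior from TSV
#'
#' @param path TSV with columns kind, region_or_signal, ligand, genes
#'   (semicolon list), grouped.
#' @param panel optional assay panel for validation (see
#'   [connectivity_prior()]).
#' @return a `connectivity_prior`.
#' @export
load_prior <- function(path, panel = NULL) {
  if (!file.exists(path)) stop("prior file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "\"",
                          colClasses = c(grouped = "logical"))
  connectivity_prior(df, panel)
}

#' Write a connectivity prior to TSV
#' @param prior a `connectivity_prior`.
#' @param path output path.
#' @export
write_prior <- function(prior, path) {
  cols <- c("kind", "region_or_signal", "ligand", "genes", "grouped")
  utils::write.table(as.data.frame(prior)[, cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-state input-output signal-processing map
#'
#' For each sample state, every input edge (region -> state, via a ligand)
#' is weighted by the mean LOD-relative expression of its receptor genes:
#' the mean over the state's samples of the per-sample mean over the mapped
#' genes. Output signals are weighted the same way from their synthesis
#' genes. An edge is emitted only if at least one contributing gene is
#' detected in at least `min_detect_frac` of the state's samples; an edge
#' whose genes all sit below the LOD in a state is absent from that state's
#' map.
#'
#' @param expr an `expr_matrix`.
#' @param states named state-label vector covering the samples (e.g.
#'   `partition$states`).
#' @param prior a `connectivity_prior`.
#' @param min_detect_frac detection-fraction floor for emitting an edge
#'   (default 0.1).
#' @return an `io_map`: data.frame with state, kind, region_or_signal,
#'   ligand, grouped, weight, detect_frac; attribute `prior_digest`
#'   identifies the prior it was built from.
#' @export
build_map <- function(expr, states, prior, min_detect_frac = 0.1) {
  stopifnot(inherits(expr, "expr_matrix"), inherits(prior, "connectivity_prior"))
  ids <- colnames(expr$values)
  if (!all(ids %in% names(states))) stop("states must cover every sample")
  states <- states[ids]
  edges <- list()
  for (s in sort(unique(states))) {
    cols <- which(states == s)
    if (length(cols) == 0) stop("state with 0 samples: ", s)
    for (i in seq_len(nrow(prior))) {
      genes <- intersect(prior$gene_list[[i]], rownames(expr$values))
      if (length(genes) == 0) next
      sub <- expr$values[genes, cols, drop = FALSE]
      det <- expr$detected[genes, cols, drop = FALSE]
      gene_frac <- rowMeans(det)
      if (max(gene_frac) < min_detect_frac) next
      weight <- mean(colMeans(sub))
      edges[[length(edges) + 1]] <- data.frame(
        state = s, kind = prior$kind[i],
        region_or_signal = prior$region_or_signal[i],
        ligand = prior$ligand[i], grouped = prior$grouped[i],
        weight = weight, detect_frac = mean(gene_frac),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(edges)) do.call(rbind, edges) else
    data.frame(state = character(0), kind = character(0),
               region_or_signal = character(0), ligand = character(0),
               grouped = logical(0), weight = numeric(0),
               detect_frac = numeric(0))
  attr(out, "prior_digest") <- prior_digest(prior)
  attr(out, "min_detect_frac") <- min_detect_frac
  class(out) <- c("io_map", class(out))
  out
}

prior_digest <- function(prior) {
  paste(prior$kind, prior$region_or_signal, prior$ligand, prior$genes,
        collapse = "|")
}

#' Classify differential edges between two input-output maps
#'
#' Compares edge weights between a baseline map and a comparison map built
#' on the same prior. An edge is `increasing` when the comparison weight
#' exceeds baseline by more than `rel_threshold` (relative), `decreasing`
#' when it falls below by more than `rel_threshold`, else `unchanged`.
#' Edges pruned from one map are treated as weight 0, so appearance or
#' disappearance of a signal registers as increasing/decreasing. The
#' classification is scale-free: rescaling all expression leaves classes
#' unchanged.
#'
#' Optionally, an empirical permutation null for each edge's weight change
#' is computed by shuffling which samples belong to which condition within
#' the pooled data (requires the two expression matrices and state labels).
#'
#' @param map_a baseline `io_map`.
#' @param map_b comparison `io_map`.
#' @param rel_threshold relative change needed to call an edge
#'   increasing/decreasing (default 0.25).
#' @param expr_a,expr_b,states_a,states_b,prior optional inputs enabling the
#'   permutation test.
#' @param n_perm permutation replicates (default 1000).
#' @param seed RNG seed for permutations.
#' @return data.frame with edge keys, `weight_a`, `weight_b`, `delta`,
#'   `class`, and `p_perm` when permutations were requested.
#' @export
differential_map <- function(map_a, map_b, rel_threshold = 0.25,
                             expr_a = NULL, expr_b = NULL,
                             states_a = NULL, states_b = NULL, prior = NULL,
                             n_perm = 1000, seed = 7) {
  if (!identical(attr(map_a, "prior_digest"), attr(map_b, "prior_digest")))
    stop("maps were built from different priors")
  cols <- c("state", "kind", "region_or_signal", "ligand")
  key <- function(m) do.call(paste, c(unclass(m)[cols], sep = "\r"))
  edges <- unique(rbind(as.data.frame(map_a)[cols], as.data.frame(map_b)[cols]))
  wa <- map_a$weight[match(key(edges), key(map_a))]
  wb <- map_b$weight[match(key(edges), key(map_b))]
  wa[is.na(wa)] <- 0; wb[is.na(wb)] <- 0
  cls <- ifelse(wb > wa * (1 + rel_threshold), "increasing",
         ifelse(wb < wa * (1 - rel_threshold), "decreasing", "unchanged"))
  out <- data.frame(edges, weight_a = wa, weight_b = wb,
                    delta = wb - wa, class = cls,
                    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(expr_a) && !is.null(expr_b)) {
    stopifnot(!is.null(states_a), !is.null(states_b), !is.null(prior))
    out$p_perm <- perm_edge_pvalues(out, expr_a, expr_b, states_a, states_b,
                                    prior, attr(map_a, "min_detect_frac"),
                                    n_perm, seed)
  }
  out[order(out$state, out$kind, out$region_or_signal), ]
}

# Permutation null for |weight_b - weight_a|: pool the two cohorts' samples
# within each state and reshuffle the condition assignment.
perm_edge_pvalues <- function(diff_df, expr_a, expr_b, states_a, states_b,
                              prior, min_detect_frac, n_perm, seed) {
  if (is.null(min_detect_frac)) min_detect_frac <- 0.1
  genes <- rownames(expr_a$values)
  va <- expr_a$values; vb <- expr_b$values
  da <- expr_a$detected; db <- expr_b$detected
  v <- cbind(va, vb); d <- cbind(da, db)
  n_a <- ncol(va)
  st <- c(states_a[colnames(va)], states_b[colnames(vb)])
  obs <- abs(diff_df$delta)
  exceed <- numeric(nrow(diff_df))
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      idx_a <- sort(sample(ncol(v), n_a))
      is_a <- seq_len(ncol(v)) %in% idx_a
      wgt <- function(sel) {
        sapply(seq_len(nrow(diff_df)), function(i) {
          g <- intersect(prior$gene_list[[match(
            paste(diff_df$kind[i], diff_df$region_or_signal[i], diff_df$ligand[i]),
            paste(prior$kind, prior$region_or_signal, prior$ligand))]],
            genes)
          cols <- which(sel & st == diff_df$state[i])
          if (length(g) == 0 || length(cols) == 0) return(0)
          det <- d[g, cols, drop = FALSE]
          if (max(rowMeans(det)) < min_detect_frac) return(0)
          mean(colMeans(v[g, cols, drop = FALSE]))
        })
      }
      delta_b <- wgt(!is_a) - wgt(is_a)
      exceed <- exceed + (abs(delta_b) >= obs - 1e-12)
    }
  })
  (1 + exceed) / (n_perm + 1)
}
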