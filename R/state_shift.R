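#' State distribution across conditions (optionally by side)
#'
#' @param states named character vector of sample state labels.
#' @param meta sample metadata (`sample_id`, `condition`, `side`).
#' @param stratify_by_side compute separate tables per side.
#' @return list with `counts` (state x condition table, or a list of them
#'   per side) and `proportions` (columns sum to 1; zero-count cells kept).
#' @export
state_distribution <- function(states, meta, stratify_by_side = FALSE) {
  meta <- as.data.frame(meta)
  meta <- meta[match(names(states), meta$sample_id), , drop = FALSE]
  one <- function(idx) {
    tab <- table(state = factor(states[idx]),
                 condition = factor(meta$condition[idx]))
    prop <- sweep(tab, 2, pmax(colSums(tab), 1), "/")
    list(counts = tab, proportions = prop)
  }
  if (!stratify_by_side) return(one(seq_along(states)))
  sides <- sort(unique(meta$side))
  out <- lapply(sides, function(s) one(which(meta$side == s)))
  names(out) <- sides
  out
}

#' Chi-square test of state redistribution between conditions
#'
#' Tests homogeneity of a state x condition contingency table. When any
#' expected cell count falls below 5 the asymptotic chi-square reference is
#' unreliable, so a Monte Carlo p value is computed instead (fixed seed for
#' reproducibility). Standardized residuals indicate which states drive the
#' shift.
#'
#' @param tab contingency table or matrix (>= 2 rows, >= 2 columns).
#' @param n_sim Monte Carlo replicates used when expected counts are small.
#' @param seed seed for the Monte Carlo p value.
#' @return list (`shift_result`): `statistic`, `p_value`, `df`, `residuals`
#'   (standardized), `method`, and the input table.
#' @export
shift_test <- function(tab, n_sim = 2000, seed = 171) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2 || ncol(tab) < 2) stop("need a table with >= 2 rows and columns")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("degenerate table: zero row or column margin")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  simulate <- any(expected < 5)
  res <- with_seed(seed, suppressWarnings(
    stats::chisq.test(tab, correct = FALSE,
                      simulate.p.value = simulate, B = n_sim)))
  structure(list(statistic = unname(res$statistic),
                 p_value = res$p.value,
                 df = if (simulate) NA_real_ else unname(res$parameter),
                 residuals = res$stdres,
                 method = if (simulate) "chi-square (Monte Carlo p)" else "chi-square",
                 table = tab),
            class = "shift_result")
}

#' @export
print.shift_result <- function(x, ...) {
  cat(sprintf("%s: X-squared = %.4g, p = %.4g\n", x$method, x$statistic, x$p_value))
  invisible(x)
}

#' One-way ANOVA of a gene's expression across conditions
#'
#' F test on LOD-relative expression (-dCt). Censored zeros are part of the
#' expression scale and are included by default; `detected_only = TRUE`
#' restricts to samples where the gene was detected.
#'
#' @param expr an `expr_matrix`.
#' @param gene gene id.
#' @param condition_labels optional per-sample condition vector; defaults to
#'   the metadata `condition` column.
#' @param detected_only drop censored samples before testing.
#' @return list with `F`, `p_value`, `df`, group means and n.
#' @export
gene_condition_anova <- function(expr, gene, condition_labels = NULL,
                                 detected_only = FALSE) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (!gene %in% rownames(expr$values)) stop("gene not in panel: ", gene)
  y <- expr$values[gene, ]
  g <- if (is.null(condition_labels)) expr$sample_meta$condition else condition_labels
  g <- factor(as.character(g))
  keep <- if (detected_only) expr$detected[gene, ] else rep(TRUE, length(y))
  y <- y[keep]; g <- droplevels(g[keep])
  if (nlevels(g) < 2) stop("need >= 2 condition groups")
  if (any(table(g) < 2)) stop("need >= 2 samples per group")
  grand <- mean(y)
  means <- tapply(y, g, mean)
  ns <- tapply(y, g, length)
  ss_between <- sum(ns * (means - grand)^2)
  ss_within <- sum((y - means[g])^2)
  df1 <- nlevels(g) - 1
  df2 <- length(y) - nlevels(g)
  if (ss_between < .Machine$double.eps^0.5 && ss_within < .Machine$double.eps^0.5) {
    f <- 0; p <- 1           # all values identical
  } else if (ss_within == 0) {
    f <- Inf; p <- 0
  } else {
    f <- (ss_between / df1) / (ss_within / df2)
    p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  }
  list(F = f, p_value = p, df = c(df1, df2),
       group_means = means, group_n = ns)
}

#' Condition effects within a marker-positive sample subset
#'
#' Restricts to samples where `marker_gene` was detected (e.g. the Fos+
#' immediate-early-gene subset) and tests every gene for a condition effect
#' with [gene_condition_anova()], correcting across genes by
#' Benjamini-Hochberg.
#'
#' @param expr an `expr_matrix`.
#' @param marker_gene gene whose detection defines the subset.
#' @param condition_labels optional; defaults to metadata conditions.
#' @param detected_only passed through to the per-gene ANOVA.
#' @return list with `samples` (subset ids) and `results` (data.frame:
#'   gene, F, p, q), sorted by p.
#' @export
marker_subset <- function(expr, marker_gene, condition_labels = NULL,
                          detected_only = FALSE) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (!marker_gene %in% rownames(expr$values))
    stop("marker gene not in panel: ", marker_gene)
  in_sub <- expr$detected[marker_gene, ]
  if (!any(in_sub)) stop("marker gene detected in no sample")
  sub <- expr
  sub$values <- expr$values[, in_sub, drop = FALSE]
  sub$detected <- expr$detected[, in_sub, drop = FALSE]
  sub$sample_meta <- expr$sample_meta[in_sub, , drop = FALSE]
  labs <- if (is.null(condition_labels)) NULL else condition_labels[in_sub]
  res <- lapply(rownames(sub$values), function(g) {
    a <- tryCatch(gene_condition_anova(sub, g, labs, detected_only),
                  error = function(e) NULL)
    if (is.null(a)) return(NULL)
    data.frame(gene = g, F = a$F, p = a$p_value, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (is.null(res)) stop("no testable gene within subset")
  res$q <- stats::p.adjust(res$p, method = "BH")
  res <- res[order(res$p), ]
  rownames(res) <- NULL
  list(samples = colnames(sub$values), results = res)
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so seeded internals do not
#' perturb user-level random streams.
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the expression's value.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
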