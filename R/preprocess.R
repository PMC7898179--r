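#' Censored expression relative to the limit of detection
#'
#' Converts raw Ct values into the non-negative expression scale used
#' throughout the package: `expr = lod_ct - Ct` for detected reactions
#' (a -dCt relative to the limit of detection), and 0 for reactions at or
#' below the LOD. Detected reactions whose Ct is at or beyond `lod_ct` are
#' reclassified as not detected, so `values == 0` exactly when
#' `detected == FALSE`.
#'
#' @param ct a [ct_matrix()].
#' @param lod_ct positive Ct cycle treated as the limit of detection
#'   (default 28, a common microfluidic qPCR ceiling).
#' @return An object of class `expr_matrix`: list with `values` (gene x
#'   sample, >= 0), `detected` (logical mask), `lod_ct`, and the sample
#'   metadata carried over from `ct`.
#' @export
to_expression <- function(ct, lod_ct = 28) {
  stopifnot(inherits(ct, "ct_matrix"))
  if (!is.numeric(lod_ct) || length(lod_ct) != 1 || lod_ct <= 0)
    stop("`lod_ct` must be a single positive number")
  detected <- !is.na(ct$values) & ct$values < lod_ct
  values <- ifelse(detected, lod_ct - ct$values, 0)
  dimnames(values) <- dimnames(ct$values)
  structure(
    list(values = values, detected = detected, lod_ct = lod_ct,
         sample_meta = ct$sample_meta),
    class = "expr_matrix"
  )
}

#' Construct an expression matrix directly from -dCt values
#'
#' Convenience constructor for simulated or pre-censored data already on the
#' expression-relative-to-LOD scale (0 means at/below LOD).
#'
#' @param values non-negative gene x sample matrix.
#' @param sample_meta per-sample metadata (see [ct_matrix()]); optional.
#' @param lod_ct the LOD cycle the values are relative to.
#' @param detected optional logical mask; defaults to `values > 0`.
#' @return an `expr_matrix`.
#' @export
expr_matrix <- function(values, sample_meta = NULL, lod_ct = 28, detected = NULL) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (any(values < 0)) stop("expression values must be >= 0")
  if (is.null(detected)) detected <- values > 0
  if (any(values[!detected] != 0)) stop("undetected entries must be 0")
  if (is.null(sample_meta)) {
    sample_meta <- data.frame(sample_id = colnames(values),
                              condition = "unknown", side = "left",
                              unit_type = "single", pool_size = 1L,
                              stringsAsFactors = FALSE)
  }
  structure(list(values = values, detected = detected, lod_ct = lod_ct,
                 sample_meta = as.data.frame(sample_meta)),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples, LOD Ct = %g, %.1f%% detected\n",
              nrow(x$values), ncol(x$values), x$lod_ct, 100 * mean(x$detected)))
  invisible(x)
}

#' Quartile-bin detected expression per gene
#'
#' For each gene, detected values are split at the 25/50/75 percentiles of
#' that gene's detected values into bins 1-4 (right-closed intervals, so a
#' value equal to a boundary falls in the lower bin); below-LOD entries get
#' bin 0. A gene whose detected values are all equal collapses to bin 1.
#'
#' @param expr an `expr_matrix`.
#' @return integer matrix of bins in 0..4 with the input's dimnames,
#'   class `binned_matrix`.
#' @export
quartile_bin <- function(expr) {
  stopifnot(inherits(expr, "expr_matrix"))
  bins <- matrix(0L, nrow(expr$values), ncol(expr$values),
                 dimnames = dimnames(expr$values))
  for (g in seq_len(nrow(expr$values))) {
    det <- expr$detected[g, ]
    if (!any(det)) next
    v <- expr$values[g, det]
    qs <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    bins[g, det] <- 1L + (v > qs[1]) + (v > qs[2]) + (v > qs[3])
  }
  class(bins) <- c("binned_matrix", class(bins))
  bins
}

#' Per-gene Z scores of LOD-relative expression
#'
#' Standardises each gene's -dCt values to mean 0, SD 1 using the population
#' (divide by n) standard deviation. Zero-variance genes map to all-zero
#' rows. Censored (below-LOD) zeros are included by default, matching
#' heatmaps drawn over all samples; with `include_censored = FALSE` censored
#' entries are excluded from the mean/SD and returned as `NA`.
#'
#' @param expr an `expr_matrix`.
#' @param include_censored include below-LOD zeros in the standardisation
#'   (default TRUE).
#' @return numeric gene x sample matrix of Z scores, class `z_matrix`.
#' @export
zscore <- function(expr, include_censored = TRUE) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (ncol(expr$values) < 2) stop("need at least 2 samples")
  z <- matrix(0, nrow(expr$values), ncol(expr$values),
              dimnames = dimnames(expr$values))
  for (g in seq_len(nrow(expr$values))) {
    x <- expr$values[g, ]
    keep <- if (include_censored) rep(TRUE, length(x)) else expr$detected[g, ]
    if (!include_censored) z[g, !keep] <- NA
    if (sum(keep) == 0) next
    xk <- x[keep]
    mu <- mean(xk)
    sd_pop <- sqrt(mean((xk - mu)^2))
    z[g, keep] <- if (sd_pop > 0) (xk - mu) / sd_pop else 0
  }
  class(z) <- c("z_matrix", class(z))
  z
}

#' Fraction of samples detected per gene within groups
#'
#' @param expr an `expr_matrix`.
#' @param grouping named character/factor vector mapping each sample id to a
#'   group label; every sample column must be covered.
#' @return gene x group matrix of fractions in `[0, 1]`.
#' @export
detection_fraction <- function(expr, grouping) {
  stopifnot(inherits(expr, "expr_matrix"))
  ids <- colnames(expr$values)
  if (is.null(names(grouping))) {
    if (length(grouping) != length(ids))
      stop("unnamed `grouping` must have one entry per sample")
    names(grouping) <- ids
  }
  missing <- setdiff(ids, names(grouping))
  if (length(missing))
    stop("sample(s) not assigned to a group: ", paste(missing, collapse = ", "))
  grp <- factor(as.character(grouping[ids]))
  if (any(table(grp) == 0)) stop("empty group")
  out <- sapply(levels(grp), function(lev) {
    rowMeans(expr$detected[, grp == lev, drop = FALSE])
  })
  out <- matrix(out, nrow = nrow(expr$values),
                dimnames = list(rownames(expr$values), levels(grp)))
  out
}
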