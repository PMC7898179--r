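#' Single cell-scale qPCR Ct matrix with sample metadata
#'
#' A `ct_matrix` couples a gene x sample matrix of raw qPCR cycle-threshold
#' (Ct) values with per-sample metadata. Reactions that never crossed the
#' fluorescence threshold ("not detected") are stored as `NA`. Lower Ct means
#' higher expression; all numeric Ct values must be positive.
#'
#' @param values numeric matrix, genes in rows, samples in columns. `NA`
#'   marks a not-detected reaction.
#' @param sample_meta data.frame with one row per sample and columns
#'   `sample_id`, `condition`, `side` (`"left"`/`"right"`), and optionally
#'   `unit_type` (`"single"`/`"pool"`) and `pool_size` (integer >= 1).
#'   Samples are matched to matrix columns by `sample_id`.
#'
#' @return An object of class `ct_matrix`: a list with elements `values`
#'   (the Ct matrix), `gene_ids`, and `sample_meta`.
#' @export
ct_matrix <- function(values, sample_meta) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix (genes x samples)")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene row names and sample column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene identifiers: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample identifiers: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  sample_meta <- as.data.frame(sample_meta)
  required <- c("sample_id", "condition", "side")
  missing_cols <- setdiff(required, names(sample_meta))
  if (length(missing_cols))
    stop("sample metadata lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(sample_meta$sample_id))
    stop("duplicate sample identifiers in metadata")
  absent <- setdiff(colnames(values), sample_meta$sample_id)
  if (length(absent))
    stop("sample(s) missing from metadata: ", paste(absent, collapse = ", "))
  sample_meta <- sample_meta[match(colnames(values), sample_meta$sample_id), , drop = FALSE]
  rownames(sample_meta) <- NULL
  if (!all(sample_meta$side %in% c("left", "right")))
    stop("`side` must be 'left' or 'right'")
  if (is.null(sample_meta$unit_type)) sample_meta$unit_type <- "single"
  if (is.null(sample_meta$pool_size)) sample_meta$pool_size <- 1L
  if (any(sample_meta$pool_size < 1)) stop("`pool_size` must be >= 1")
  if (any(values <= 0, na.rm = TRUE)) stop("all Ct values must be positive")
  structure(
    list(values = values, gene_ids = rownames(values), sample_meta = sample_meta),
    class = "ct_matrix"
  )
}

#' @export
print.ct_matrix <- function(x, ...) {
  nd <- mean(is.na(x$values))
  cat(sprintf("ct_matrix: %d genes x %d samples (%.1f%% not detected)\n",
              nrow(x$values), ncol(x$values), 100 * nd))
  cat("conditions:", paste(names(table(x$sample_meta$condition)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.ct_matrix <- function(x) dim(x$values)

#' Load a Ct table and sample metadata from delimited text
#'
#' Reads a gene x sample Ct matrix and a metadata table, normalising the
#' various "not detected" encodings (empty cells, `ND`, `NA`, and Ct values
#' at or above a configured ceiling such as the 999 emitted by microfluidic
#' qPCR instruments) to `NA`.
#'
#' @param path path to the delimited Ct table; first column gene ids,
#'   remaining columns samples.
#' @param meta_path path to the delimited metadata table (columns
#'   `sample_id`, `condition`, `side`, optionally `unit_type`, `pool_size`).
#' @param sep field separator for both files (default tab).
#' @param nd_ceiling Ct values at or above this ceiling are treated as not
#'   detected (default 40 cycles).
#' @param nd_strings character values interpreted as not detected.
#' @return a [ct_matrix()].
#' @export
load_ct_table <- function(path, meta_path, sep = "\t", nd_ceiling = 40,
                          nd_strings = c("", "ND", "NA", "N/A", "999")) {
  if (!file.exists(path)) stop("Ct table not found: ", path)
  if (!file.exists(meta_path)) stop("metadata table not found: ", meta_path)
  raw <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           colClasses = "character", quote = "\"",
                           stringsAsFactors = FALSE)
  genes <- raw[[1]]
  mat <- as.matrix(raw[, -1, drop = FALSE])
  mat[trimws(mat) %in% nd_strings] <- NA
  values <- suppressWarnings(matrix(as.numeric(mat), nrow = nrow(mat),
                                    dimnames = list(genes, colnames(mat))))
  values[!is.na(values) & values >= nd_ceiling] <- NA
  meta <- utils::read.table(meta_path, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE)
  ct_matrix(values, meta)
}

#' Write a matrix as a TSV with a leading id column
#' @param x matrix with dimnames
#' @param path output path
#' @param id_name header for the row-id column
#' @export
write_matrix_tsv <- function(x, path, id_name = "gene_id") {
  df <- data.frame(rownames(x), x, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- id_name
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
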