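# Small fixtures built in code.

toy_meta <- function(ids, condition = "naive", side = "left") {
  data.frame(sample_id = ids,
             condition = rep_len(condition, length(ids)),
             side = rep_len(side, length(ids)),
             unit_type = "single", pool_size = 1L,
             stringsAsFactors = FALSE)
}

toy_ct <- function(values, condition = "naive", side = "left") {
  ct_matrix(values, toy_meta(colnames(values), condition, side))
}

# expr_matrix straight from a -dCt value matrix
toy_expr <- function(values, condition = "naive", side = "left") {
  expr_matrix(values, toy_meta(colnames(values), condition, side))
}

# row-major: `data` lists each gene's values in turn
named_matrix <- function(data, nr, genes = NULL, samples = NULL) {
  m <- matrix(data, nrow = nr, byrow = TRUE)
  rownames(m) <- genes %||% paste0("g", seq_len(nrow(m)))
  colnames(m) <- samples %||% paste0("s", seq_len(ncol(m)))
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Write a Ct table + metadata pair to temp files; returns the two paths.
write_ct_fixture <- function(values, meta, sep = "\t") {
  p1 <- tempfile(fileext = ".tsv"); p2 <- tempfile(fileext = ".tsv")
  df <- data.frame(gene_id = rownames(values), values, check.names = FALSE)
  write.table(df, p1, sep = sep, quote = FALSE, row.names = FALSE)
  write.table(meta, p2, sep = sep, quote = FALSE, row.names = FALSE)
  c(ct = p1, meta = p2)
}
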