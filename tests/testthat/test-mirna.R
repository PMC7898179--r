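toy_counts <- function(counts, n_neg = 2, groups = NULL) {
  n <- nrow(counts) - n_neg
  if (is.null(groups)) groups <- rep(c("control", "LAD", "RIPC_LAD"),
                                     length.out = ncol(counts))
  mirna_counts(counts, c(rep(FALSE, n), rep(TRUE, n_neg)), groups)
}

test_that("detection thresholds on negative-control background, strictly", {
  cts <- matrix(0L, 5, 6, dimnames = list(
    c("m1", "m2", "m3", "NEG1", "NEG2"), paste0("s", 1:6)))
  x <- toy_counts(cts)
  expect_length(detect_mirna(x), 0)      # all zero counts: nothing detected

  cts2 <- cts
  cts2["NEG1", ] <- 5L; cts2["NEG2", ] <- 5L       # bg mean 5, sd 0
  thr <- 5
  cts2["m1", ] <- 100L
  cts2["m2", ] <- 5L                               # exactly at threshold
  x2 <- toy_counts(cts2)
  det <- detect_mirna(x2)
  expect_true("m1" %in% det)
  expect_false("m2" %in% det)                      # strict >
  expect_equal(attr(det, "threshold"), thr)

  # monotone: raising k_sd never adds detections
  d1 <- detect_mirna(x2, k_sd = 1)
  d3 <- detect_mirna(x2, k_sd = 3)
  expect_true(all(d3 %in% d1))

  expect_error(mirna_counts(cts[1:3, ], rep(FALSE, 3), rep("a", 6)),
               "negative-control")
})

test_that("template scores are exact for a perfect match and zero-variance safe", {
  groups <- rep(c("control", "LAD", "RIPC_LAD"), each = 2)
  tmpl <- c(control = 0, LAD = 1, RIPC_LAD = 0)
  norm <- rbind(perfect = c(0, 0, 1, 1, 0, 0),
                flat = rep(2, 6))
  colnames(norm) <- paste0("s", 1:6)
  tm <- template_match(norm, groups, tmpl)
  expect_equal(tm$score[tm$probe == "perfect"], 1)
  expect_equal(tm$score[tm$probe == "flat"], 0)
  expect_equal(tm$p_value[tm$probe == "flat"], 1)
})

test_that("permutation p values equal exhaustive enumeration on a toy fixture", {
  # 3 groups x 2 samples: 90 distinct label arrangements, which collapse to
  # 15 distinct template-value arrangements (6 labelings each, so the two
  # enumerations induce the same null distribution)
  groups <- rep(c("control", "LAD", "RIPC_LAD"), each = 2)
  tmpl <- c(control = 0, LAD = 1, RIPC_LAD = 0)
  set.seed(101)
  norm <- matrix(rnorm(4 * 6, 8), 4, dimnames = list(paste0("m", 1:4),
                                                     paste0("s", 1:6)))
  tm <- template_match(norm, groups, tmpl)    # small: exact path
  # independent oracle: enumerate permutations of sample indices directly
  perms <- NULL
  idx <- 1:6
  all_perm <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in all_perm(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    out
  }
  t_exp <- as.numeric(tmpl[groups])
  seen <- new.env()
  scores_by_probe <- vector("list", 4)
  for (p in all_perm(idx)) {
    key <- paste(t_exp[p], collapse = ",")
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    for (g in 1:4)
      scores_by_probe[[g]] <- c(scores_by_probe[[g]],
                                abs(cor(norm[g, ], t_exp[p])))
  }
  expect_length(scores_by_probe[[1]], 15)
  for (g in 1:4) {
    obs <- abs(cor(norm[g, ], t_exp))
    p_exact <- mean(scores_by_probe[[g]] >= obs - 1e-12)
    expect_equal(tm$p_value[g], p_exact, tolerance = 1e-12)
  }
})

test_that("prioritisation output is a detected subset honouring every filter", {
  spec <- synth_spec(seed = 77)
  sim <- generate_mirna(spec)
  det <- detect_mirna(sim$counts)
  norm <- normalize_mirna(sim$counts)
  tm <- template_match(norm, sim$counts$groups, n_perm = 200, seed = 5)
  cand <- prioritize(tm, det)
  expect_true(all(cand$probe %in% det))            # subset of detections
  expect_true(all(cand$p_value <= 0.05))
  expect_true(all(abs(cand$fold_change) >= 2))
  expect_true(all(sim$truth$planted %in% cand$probe))
  expect_true(all(diff(cand$p_value) >= 0))        # sorted by p
  # impossible fold cutoff empties the list
  expect_equal(nrow(prioritize(tm, det, fold_cut = Inf)), 0)
  # no detections -> empty
  expect_equal(nrow(prioritize(tm, character(0))), 0)
})

test_that("target_network applies the consensus and expression filters", {
  hits <- data.frame(
    mirna = c("miR-1", "miR-1", "miR-1", "miR-2"),
    gene = c("Gad1", "Chat", "Oxtr", "Gad1"),
    mirwalk = c(TRUE, TRUE, TRUE, TRUE),
    rna22 = c(TRUE, FALSE, TRUE, TRUE),
    miranda = FALSE, targetscan = FALSE,
    stringsAsFactors = FALSE)
  expressed <- c("Gad1", "Chat")      # Oxtr not expressed
  net <- target_network(c("miR-1"), hits, expressed)
  # consensus (>1 algorithm) and expression filters leave one edge
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$gene, "Gad1")
  expect_equal(net$edges$n_algorithms, 2)

  expect_error(target_network("miR-1", hits, character(0)), "empty")
  expect_warning(target_network(c("miR-1", "miR-9"), hits, expressed),
                 "miR-9")

  # row-by-row oracle on a random hit table
  set.seed(31)
  big <- data.frame(
    mirna = sample(paste0("miR-", 1:5), 60, TRUE),
    gene = sample(paste0("g", 1:12), 60, TRUE),
    a1 = sample(c(TRUE, FALSE), 60, TRUE), a2 = sample(c(TRUE, FALSE), 60, TRUE),
    a3 = sample(c(TRUE, FALSE), 60, TRUE), a4 = sample(c(TRUE, FALSE), 60, TRUE))
  big <- big[!duplicated(big[1:2]), ]
  expressed2 <- paste0("g", 1:8)
  cands <- c("miR-1", "miR-2", "miR-3")
  net2 <- suppressWarnings(target_network(cands, big, expressed2))
  for (i in seq_len(nrow(big))) {
    should <- big$mirna[i] %in% cands &&
      sum(big$a1[i], big$a2[i], big$a3[i], big$a4[i]) >= 2 &&
      big$gene[i] %in% expressed2
    has <- any(net2$edges$mirna == big$mirna[i] & net2$edges$gene == big$gene[i])
    expect_equal(has, should)
  }
  # category annotation travels onto edges
  cm <- setNames(rep("ion channel", 12), paste0("g", 1:12))
  net3 <- suppressWarnings(target_network(cands, big, expressed2, category_map = cm))
  if (nrow(net3$edges)) expect_true(all(net3$edges$category == "ion channel"))
})

test_that("template-match p values are uniform under a permuted null", {
  spec <- synth_spec(n_probes = 300, n_expressed = 300, n_planted = 0, seed = 303)
  sim <- generate_mirna(spec)
  norm <- normalize_mirna(sim$counts)
  norm <- norm[!sim$counts$is_negctrl, ]
  tm <- template_match(norm, sim$counts$groups, n_perm = 400, seed = 8)
  # permutation p values are discrete, hence tied; the KS distance itself
  # is still the right calibration summary
  expect_gt(suppressWarnings(ks.test(tm$p_value, "punif")$p.value), 0.01)
})
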