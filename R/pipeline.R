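#' Default pipeline configuration
#'
#' @return named list of every recognised configuration key with defaults.
#' @export
default_config <- function() {
  list(
    out_dir = "iostates_run",
    seed = 1L,
    ct_path = NULL, meta_path = NULL, prior_path = NULL,
    lod_ct = 28, nd_ceiling = 40,
    min_size = 5, k_min = 2, k_max = 12,
    min_detect_frac = 0.1, rel_threshold = 0.25,
    q_cut = 1e-3, min_pairs = 8,
    mirna_n_perm = 2000, mirna_p_cut = 0.05, mirna_fold_cut = 2,
    baseline_condition = NULL, comparison_condition = NULL
  )
}

read_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  base <- default_config()
  unknown <- setdiff(names(config), names(base))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  base[names(config)] <- config
  base
}

pipeline_stages <- c("simulate", "preprocess", "states", "shift", "iomap",
                     "network", "landscape", "mirna")

#' Run the analysis pipeline
#'
#' Chains the package's stages with a single configuration, writing TSV/JSON
#' artifacts and a manifest (parameters, output file hashes, package
#' version) into `out_dir`. With `stages = "all"` the full dependency chain
#' runs; a single later stage fails with an error naming the missing
#' upstream stage. When no `ct_path` is configured the `simulate` stage
#' supplies synthetic inputs.
#'
#' @param config named list or path to a YAML config file; unknown keys are
#'   rejected. See [default_config()].
#' @param stages `"all"` or a subset of
#'   `c("simulate","preprocess","states","shift","iomap","network","landscape","mirna")`.
#' @return (invisibly) a list of in-memory stage results plus the manifest.
#' @export
run_pipeline <- function(config = list(), stages = "all") {
  cfg <- read_config(config)
  if (identical(stages, "all")) stages <- pipeline_stages
  bad <- setdiff(stages, pipeline_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  if (!is.null(cfg$ct_path)) stages <- setdiff(stages, "simulate")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  env <- new.env(parent = emptyenv())
  artifacts <- character(0)
  note <- function(path) artifacts <<- c(artifacts, path)
  need <- function(obj, from) {
    if (!exists(obj, env)) stop("missing upstream artifact `", obj,
                                "`: run stage '", from, "' first")
    get(obj, env)
  }

  for (stage in pipeline_stages[pipeline_stages %in% stages]) {
    message("stage: ", stage)
    switch(stage,
      simulate = {
        spec <- synth_spec(seed = cfg$seed)
        env$sim <- generate_qpcr(spec)
        env$ct <- env$sim$ct
        env$mirna_sim <- generate_mirna(spec)
        p <- file.path(cfg$out_dir, "truth_states.tsv")
        utils::write.table(data.frame(sample_id = names(env$sim$truth$states),
                                      state = env$sim$truth$states),
                           p, sep = "\t", quote = FALSE, row.names = FALSE)
        note(p)
      },
      preprocess = {
        if (!exists("ct", env)) {
          if (is.null(cfg$ct_path))
            stop("missing upstream artifact `ct`: run stage 'simulate' first",
                 " or set ct_path/meta_path")
          env$ct <- load_ct_table(cfg$ct_path, cfg$meta_path,
                                  nd_ceiling = cfg$nd_ceiling)
        }
        env$expr <- to_expression(env$ct, cfg$lod_ct)
        env$bins <- quartile_bin(env$expr)
        env$z <- zscore(env$expr)
        note(write_matrix_tsv(env$expr$values,
                              file.path(cfg$out_dir, "expression.tsv")))
        note(write_matrix_tsv(env$bins, file.path(cfg$out_dir, "bins.tsv")))
        note(write_matrix_tsv(env$z, file.path(cfg$out_dir, "zscores.tsv")))
      },
      states = {
        expr <- need("expr", "preprocess")
        env$partition <- discover_states(unclass(env$z),
                                         min_size = cfg$min_size,
                                         k_range = c(cfg$k_min, cfg$k_max))
        hm <- compose_heatmap(env$partition, env$bins, expr$sample_meta)
        p <- file.path(cfg$out_dir, "states.tsv")
        utils::write.table(data.frame(sample_id = names(env$partition$states),
                                      state = env$partition$states),
                           p, sep = "\t", quote = FALSE, row.names = FALSE)
        note(p)
        p <- file.path(cfg$out_dir, "state_composition.tsv")
        utils::write.table(hm$composition, p, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        note(p)
      },
      shift = {
        part <- need("partition", "states")
        expr <- need("expr", "preprocess")
        dist <- state_distribution(part$states, expr$sample_meta)
        env$shift <- if (all(dim(dist$counts) >= 2))
          shift_test(dist$counts, seed = cfg$seed) else NULL
        p <- file.path(cfg$out_dir, "state_distribution.tsv")
        utils::write.table(as.data.frame.matrix(dist$proportions), p,
                           sep = "\t", quote = FALSE)
        note(p)
        if (!is.null(env$shift)) {
          p <- file.path(cfg$out_dir, "shift_test.json")
          jsonlite::write_json(list(statistic = env$shift$statistic,
                                    p_value = env$shift$p_value,
                                    method = env$shift$method),
                               p, auto_unbox = TRUE, digits = NA)
          note(p)
        }
      },
      iomap = {
        part <- need("partition", "states")
        expr <- need("expr", "preprocess")
        prior <- if (!is.null(cfg$prior_path))
          load_prior(cfg$prior_path, rownames(expr$values))
        else suppressWarnings(default_prior(rownames(expr$values)))
        env$iomap <- build_map(expr, part$states, prior,
                               min_detect_frac = cfg$min_detect_frac)
        p <- file.path(cfg$out_dir, "io_map.tsv")
        utils::write.table(as.data.frame(env$iomap), p, sep = "\t",
                           quote = FALSE, row.names = FALSE)
        note(p)
        conds <- unique(expr$sample_meta$condition)
        base_c <- cfg$baseline_condition %||% conds[1]
        comp_c <- cfg$comparison_condition %||% conds[length(conds)]
        if (base_c != comp_c) {
          sub <- function(cc) {
            keep <- expr$sample_meta$condition == cc
            e <- expr
            e$values <- expr$values[, keep, drop = FALSE]
            e$detected <- expr$detected[, keep, drop = FALSE]
            e$sample_meta <- expr$sample_meta[keep, , drop = FALSE]
            e
          }
          st <- part$states
          keep_state <- function(e) st[colnames(e$values)]
          ea <- sub(base_c); eb <- sub(comp_c)
          common <- intersect(unique(keep_state(ea)), unique(keep_state(eb)))
          if (length(common)) {
            filt <- function(e) {
              k <- keep_state(e) %in% common
              e$values <- e$values[, k, drop = FALSE]
              e$detected <- e$detected[, k, drop = FALSE]
              e$sample_meta <- e$sample_meta[k, , drop = FALSE]
              e
            }
            ea <- filt(ea); eb <- filt(eb)
            ma <- build_map(ea, st, prior, cfg$min_detect_frac)
            mb <- build_map(eb, st, prior, cfg$min_detect_frac)
            env$diffmap <- differential_map(ma, mb, cfg$rel_threshold)
            p <- file.path(cfg$out_dir, "io_map_differential.tsv")
            utils::write.table(env$diffmap, p, sep = "\t", quote = FALSE,
                               row.names = FALSE)
            note(p)
          }
        }
      },
      network = {
        expr <- need("expr", "preprocess")
        conds <- unique(expr$sample_meta$condition)
        nets <- lapply(conds, function(cc) {
          keep <- expr$sample_meta$condition == cc
          e <- expr
          e$values <- expr$values[, keep, drop = FALSE]
          e$detected <- expr$detected[, keep, drop = FALSE]
          e$sample_meta <- expr$sample_meta[keep, , drop = FALSE]
          build_network(correlate_all(e, min_pairs = cfg$min_pairs),
                        q_cut = cfg$q_cut, condition = cc)
        })
        names(nets) <- conds
        env$networks <- nets
        for (cc in conds) {
          p <- file.path(cfg$out_dir, paste0("network_", cc, ".tsv"))
          utils::write.table(nets[[cc]]$edges, p, sep = "\t", quote = FALSE,
                             row.names = FALSE)
          note(p)
        }
        if (length(nets) >= 2) {
          alg <- edge_set_algebra(nets)
          p <- file.path(cfg$out_dir, "network_summary.tsv")
          utils::write.table(alg$summary, p, sep = "\t", quote = FALSE,
                             row.names = FALSE)
          note(p)
        }
        hubs <- do.call(rbind, lapply(conds, function(cc) {
          h <- hub_rank(nets[[cc]], top_k = 5)
          cbind(condition = cc, utils::head(h, 10))
        }))
        p <- file.path(cfg$out_dir, "hub_genes.tsv")
        utils::write.table(hubs, p, sep = "\t", quote = FALSE, row.names = FALSE)
        note(p)
      },
      landscape = {
        part <- need("partition", "states")
        expr <- need("expr", "preprocess")
        tree <- build_mst(unclass(env$z), states = part$states,
                          meta = expr$sample_meta)
        env$tree <- tree
        env$branches <- classify_branches(tree)
        p <- file.path(cfg$out_dir, "branch_classes.tsv")
        utils::write.table(env$branches, p, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        note(p)
        groups <- stats::setNames(expr$sample_meta$condition,
                                  expr$sample_meta$sample_id)
        env$ellipsoids <- tryCatch(
          pca_ellipsoids(unclass(env$z), groups),
          error = function(e) NULL)
        if (!is.null(env$ellipsoids)) {
          p <- file.path(cfg$out_dir, "ellipsoids.json")
          jsonlite::write_json(
            lapply(env$ellipsoids$groups, function(g)
              list(group = g$group, n = g$n, volume = g$volume,
                   axes = g$axes)),
            p, auto_unbox = TRUE, digits = NA)
          note(p)
        }
      },
      mirna = {
        sim <- need("mirna_sim", "simulate")
        counts <- sim$counts
        det <- detect_mirna(counts)
        norm <- normalize_mirna(counts)
        tm <- template_match(norm, counts$groups, n_perm = cfg$mirna_n_perm,
                             seed = cfg$seed)
        env$mirna_candidates <- prioritize(tm, det, p_cut = cfg$mirna_p_cut,
                                           fold_cut = cfg$mirna_fold_cut)
        p <- file.path(cfg$out_dir, "mirna_candidates.tsv")
        utils::write.table(env$mirna_candidates, p, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        note(p)
      }
    )
  }

  manifest <- list(
    package = "iostates",
    version = as.character(utils::packageVersion("iostates")),
    stages = stages,
    config = cfg[!vapply(cfg, is.null, logical(1))],
    outputs = lapply(stats::setNames(artifacts, basename(artifacts)),
                     function(p) unname(tools::md5sum(p)))
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(as.list(env), list(manifest = manifest)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
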