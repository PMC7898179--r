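#' Default region-ligand-receptor connectivity prior
#'
#' Ships the input-output scaffold used by the state maps: brain regions
#' projecting onto the vagal motor nucleus with the neuropeptide/transmitter
#' each delivers and the receptor genes that read it, plus the effector
#' output signals with their synthesis/marker genes. The dopamine, GABA and
#' norepinephrine inputs cannot be attributed to a single region and are
#' carried by one grouped NTS/AP/CVLM/LC entry each. The table is data, not
#' code: edit the TSV written by [write_prior()] and reload with
#' [load_prior()] to change the scaffold.
#'
#' @param panel optional assay panel to validate against.
#' @return a `connectivity_prior`.
#' @export
default_prior <- function(panel = NULL) {
  rows <- rbind(
    c("in",  "PVN",            "oxytocin",            "Oxtr",                      FALSE),
    c("in",  "PVN",            "vasopressin",         "Avpr1a;Avpr1b",             FALSE),
    c("in",  "PVN",            "natriuretic peptide", "Npr1;Npr2;Npr3",            FALSE),
    c("in",  "RPa",            "serotonin",           "Htr2a;Htr3a;Htr3b;Htr6",    FALSE),
    c("in",  "RPa",            "TRH",                 "Trhr",                      FALSE),
    c("in",  "CeA",            "somatostatin",        "Sstr2;Sstr3",               FALSE),
    c("in",  "CeA",            "CRH",                 "Crhr1;Crhr2",               FALSE),
    c("in",  "BST",            "CRH",                 "Crhr1;Crhr2",               FALSE),
    c("in",  "LHA",            "orexin",              "Hcrtr1;Hcrtr2",             FALSE),
    c("in",  "TMN",            "histamine",           "Hrh1;Hrh3",                 FALSE),
    c("in",  "NTS/AP/CVLM/LC", "dopamine",            "Drd1;Drd2;Drd4",            TRUE),
    c("in",  "NTS/AP/CVLM/LC", "GABA",                "Gabra1;Gabra2;Gabrb1;Gabbr1", TRUE),
    c("in",  "NTS/AP/CVLM/LC", "norepinephrine",      "Adra1a;Adra2a;Adrb1",       TRUE),
    c("out", "ACh",            "",                    "Chat;Ache",                 FALSE),
    c("out", "Dopa",           "",                    "Th;Ddc",                    FALSE),
    c("out", "NE",             "",                    "Th;Ddc;Dbh",                FALSE),
    c("out", "Epi",            "",                    "Th;Ddc;Dbh;Pnmt",           FALSE),
    c("out", "GABA",           "",                    "Gad1;Gad2",                 FALSE),
    c("out", "ANP",            "",                    "Nppa",                      FALSE),
    c("out", "tachykinins",    "",                    "Tac1",                      FALSE),
    c("out", "somatostatin",   "",                    "Sst",                       FALSE),
    c("out", "CCK",            "",                    "Cck",                       FALSE),
    c("out", "CART",           "",                    "Cartpt",                    FALSE),
    c("out", "galanin",        "",                    "Gal",                       FALSE),
    c("out", "follistatin-like 1", "",                "Fstl1",                     FALSE)
  )
  df <- data.frame(kind = rows[, 1], region_or_signal = rows[, 2],
                   ligand = rows[, 3], genes = rows[, 4],
                   grouped = as.logical(rows[, 5]), stringsAsFactors = FALSE)
  connectivity_prior(df, panel)
}

prior_panel_genes <- function(prior = default_prior()) {
  unique(unlist(prior$gene_list))
}

#' Specification for the synthetic qPCR / miRNA generator
#'
#' Defines the study conditions the generator emulates. Defaults mirror the
#' scale of a homeostatic single cell-scale dataset: ~180 samples x 170
#' genes, six planted neuronal states whose mixture varies by condition and
#' side, gene programs elevated per state, and a logistic detection model
#' coupling dropout to the program mean (low-expression genes drop out
#' more). The miRNA block emulates a digital-counting experiment: ~400
#' probes, three groups, a planted injury-dysregulated /
#' preconditioning-normalised candidate set, negative-binomial counts, and
#' negative-control probes at background.
#'
#' @param n_genes number of assayed genes (default 170).
#' @param k_states number of planted states (default 6).
#' @param samples_per_cell samples per condition x side cell (default 30;
#'   3 conditions x 2 sides x 30 = 180 samples).
#' @param conditions condition labels.
#' @param mixtures optional matrix (condition-side cells x states) of state
#'   proportions; rows named `condition.side`. Default: a skewed base
#'   mixture with condition- and side-specific shifts.
#' @param mu_base baseline program mean on the -dCt scale (default 3).
#' @param mu_delta elevation of a state's own module (default 6).
#' @param sigma Gaussian noise SD for detected reactions (default 1).
#' @param detect_tau,detect_scale logistic detection parameters:
#'   `P(detect) = 1 / (1 + exp(-(mu - tau)/scale))` (defaults 1.5 and 1).
#' @param lod_ct limit-of-detection cycle (default 28).
#' @param program_means optional explicit genes x states matrix of program
#'   means overriding the module construction.
#' @param n_probes,n_negctrl,mirna_group_size miRNA block dimensions
#'   (defaults 400 probes, 8 negative controls, 5 samples/group).
#' @param n_expressed probes planted above background (default 150).
#' @param n_planted planted template-following candidates (default 3).
#' @param planted_fold linear fold change of planted candidates in the
#'   injury group (default 4).
#' @param nb_size negative-binomial size (inverse dispersion, default 10).
#' @param background_mu background count level (default 5).
#' @param seed mandatory RNG seed.
#' @return a `synth_spec` list.
#' @export
synth_spec <- function(n_genes = 170, k_states = 6, samples_per_cell = 30,
                       conditions = c("naive", "sham", "RIPC"),
                       mixtures = NULL,
                       mu_base = 3, mu_delta = 6, sigma = 1,
                       detect_tau = 1.5, detect_scale = 1, lod_ct = 28,
                       program_means = NULL,
                       n_probes = 400, n_negctrl = 8, mirna_group_size = 5,
                       n_expressed = 150, n_planted = 3, planted_fold = 4,
                       nb_size = 10, background_mu = 5, seed) {
  if (missing(seed) || is.null(seed)) stop("`seed` is mandatory")
  if (sigma <= 0) stop("`sigma` must be > 0")
  cells <- as.vector(outer(conditions, c("left", "right"), paste, sep = "."))
  if (is.null(mixtures)) {
    base <- (k_states:1)
    base <- base / sum(base)
    mixtures <- matrix(rep(base, each = length(cells)), nrow = length(cells),
                       dimnames = list(cells, paste0("state", seq_len(k_states))))
    # condition/side-specific redistribution, echoing perturbation-driven
    # state shifts (last condition, right side: first state down, last two up)
    if (length(cells) >= 2 && k_states >= 3) {
      shift_row <- cells[length(cells)]
      m <- mixtures[shift_row, ]
      moved <- m[1] * 0.6
      m[1] <- m[1] - moved
      m[k_states] <- m[k_states] + moved / 2
      m[k_states - 1] <- m[k_states - 1] + moved / 2
      mixtures[shift_row, ] <- m
    }
  }
  if (!all(abs(rowSums(mixtures) - 1) < 1e-8))
    stop("mixture proportions must sum to 1 per condition-side cell")
  n_samples <- samples_per_cell * length(cells)
  if (k_states > n_samples) stop("infeasible spec: more states than samples")
  structure(list(
    n_genes = n_genes, k_states = k_states,
    samples_per_cell = samples_per_cell, conditions = conditions,
    cells = cells, mixtures = mixtures,
    mu_base = mu_base, mu_delta = mu_delta, sigma = sigma,
    detect_tau = detect_tau, detect_scale = detect_scale, lod_ct = lod_ct,
    program_means = program_means,
    n_probes = n_probes, n_negctrl = n_negctrl,
    mirna_group_size = mirna_group_size, n_expressed = n_expressed,
    n_planted = n_planted, planted_fold = planted_fold,
    nb_size = nb_size, background_mu = background_mu, seed = seed
  ), class = "synth_spec")
}

synth_panel <- function(spec) {
  named <- prior_panel_genes()
  extra <- c("Fos", "Gapdh", "Actb", "Hcn2", "Kcnn4", "Grin2a",
             "Cacna1b", "Cacna1c", "Cacna1d", "Rgs2", "Rgs3", "Pax4a", "Cebpd")
  panel <- unique(c(named, extra))
  if (length(panel) < spec$n_genes)
    panel <- c(panel, sprintf("G%03d", seq_len(spec$n_genes - length(panel))))
  panel[seq_len(spec$n_genes)]
}

#' Generate a synthetic Ct matrix with planted states
#'
#' Draws each sample's state from its condition-side mixture, builds program
#' means per gene module, adds Gaussian noise, converts to Ct as
#' `lod_ct - expression`, and censors reactions through the logistic
#' detection model (plus natural censoring at the LOD when the realised
#' expression is non-positive). Reproducible: the same spec (same seed)
#' yields identical output.
#'
#' @param spec a [synth_spec()].
#' @return list with `ct` (a [ct_matrix()]) and `truth` (states, modules,
#'   detection probabilities, program means).
#' @export
generate_qpcr <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  with_seed(spec$seed, {
    panel <- synth_panel(spec)
    modules <- rep(seq_len(spec$k_states), length.out = spec$n_genes)
    names(modules) <- panel
    mu <- spec$program_means
    if (is.null(mu)) {
      mu <- matrix(spec$mu_base, spec$n_genes, spec$k_states,
                   dimnames = list(panel, paste0("state", seq_len(spec$k_states))))
      for (g in seq_len(spec$n_genes)) mu[g, modules[g]] <- spec$mu_base + spec$mu_delta
    } else {
      panel <- rownames(mu)
      modules <- rep(seq_len(spec$k_states), length.out = nrow(mu))
      names(modules) <- panel
    }
    n <- spec$samples_per_cell * length(spec$cells)
    cell_of <- rep(spec$cells, each = spec$samples_per_cell)
    states <- integer(n)
    for (i in seq_len(n))
      states[i] <- sample.int(spec$k_states, 1, prob = spec$mixtures[cell_of[i], ])
    ids <- sprintf("S%03d", seq_len(n))
    cond_side <- do.call(rbind, strsplit(cell_of, ".", fixed = TRUE))
    meta <- data.frame(sample_id = ids, condition = cond_side[, 1],
                       side = cond_side[, 2], unit_type = "single",
                       pool_size = 1L, stringsAsFactors = FALSE)
    mu_mat <- mu[, states, drop = FALSE]          # genes x samples
    p_det <- 1 / (1 + exp(-(mu_mat - spec$detect_tau) / spec$detect_scale))
    detected <- matrix(stats::runif(length(p_det)) < p_det, nrow(mu_mat))
    valu <- mu_mat + matrix(stats::rnorm(length(mu_mat), sd = spec$sigma),
                            nrow(mu_mat))
    ct_vals <- spec$lod_ct - valu
    ct_vals[!detected | ct_vals >= spec$lod_ct] <- NA
    ct_vals[!is.na(ct_vals) & ct_vals <= 0] <- 0.01   # Ct must stay positive
    dimnames(ct_vals) <- list(panel, ids)
    names(states) <- ids
    list(ct = ct_matrix(ct_vals, meta),
         truth = list(states = states, modules = modules,
                      detect_prob = structure(p_det, dimnames = dimnames(ct_vals)),
                      program_means = mu))
  })
}

#' Generate synthetic miRNA counts with a planted rescue pattern
#'
#' Negative-binomial counts for `n_probes` probes over three groups
#' (control, LAD, RIPC_LAD). `n_expressed` probes receive log-uniform base
#' abundances above background; the first `n_planted` of them follow the
#' injury-dysregulated / preconditioning-normalised pattern (control = base,
#' LAD = base x fold, RIPC_LAD = base), alternating up and down
#' dysregulation. Remaining probes and the negative controls sit at
#' background.
#'
#' @param spec a [synth_spec()].
#' @return list with `counts` (a [mirna_counts()]) and `truth` (planted
#'   candidate ids, expressed probe ids, per-probe group means).
#' @export
generate_mirna <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  with_seed(spec$seed + 1L, {
    groups <- rep(c("control", "LAD", "RIPC_LAD"), each = spec$mirna_group_size)
    n_col <- length(groups)
    probes <- sprintf("miR-%03d", seq_len(spec$n_probes))
    negs <- sprintf("NEG-%02d", seq_len(spec$n_negctrl))
    base <- rep(spec$background_mu * 0.8, spec$n_probes)
    expressed <- probes[seq_len(spec$n_expressed)]
    base[seq_len(spec$n_expressed)] <-
      exp(stats::runif(spec$n_expressed, log(30), log(2000)))
    # planted candidates sit in the upper abundance range: the candidate
    # selection rule itself conditions on overall abundance
    base[seq_len(spec$n_planted)] <-
      exp(stats::runif(spec$n_planted, log(300), log(2000)))
    mu <- matrix(base, spec$n_probes, n_col)
    planted <- probes[seq_len(spec$n_planted)]
    for (j in seq_len(spec$n_planted)) {
      f <- if (j %% 2 == 1) spec$planted_fold else 1 / spec$planted_fold
      mu[j, groups == "LAD"] <- base[j] * f
    }
    mu_all <- rbind(mu, matrix(spec$background_mu, spec$n_negctrl, n_col))
    dimnames(mu_all) <- list(c(probes, negs), sprintf("M%02d", seq_len(n_col)))
    counts <- matrix(stats::rnbinom(length(mu_all), mu = mu_all,
                                    size = spec$nb_size),
                     nrow(mu_all),
                     dimnames = list(c(probes, negs),
                                     sprintf("M%02d", seq_len(n_col))))
    list(counts = mirna_counts(counts, c(rep(FALSE, spec$n_probes),
                                         rep(TRUE, spec$n_negctrl)), groups),
         truth = list(planted = planted, expressed = expressed,
                      group_means = mu_all))
  })
}
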