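---
title: "Methods: censored qPCR expression, neuronal states, and input-output maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: censored qPCR expression, neuronal states, and input-output maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`iostates` analyses single cell-scale RT-qPCR panels (tens to hundreds of
neurons by one to two hundred targeted genes) together with a companion
digital-counting miRNA assay. This vignette is the package's account of the
models it fits, the parameters that matter, the numerical conventions it
fixes, and what validation on synthetic data does and does not establish.

## Censored expression relative to the limit of detection

A qPCR reaction either crosses the fluorescence threshold at cycle Ct or
never crosses it. The package treats the second case as *censored at the
limit of detection* (LOD), not as missing: the biology it encodes — the
transcript is absent or too rare to amplify — is informative. Expression is

\[ x_{gs} = \max(0,\; \mathrm{Ct}_{\mathrm{LOD}} - \mathrm{Ct}_{gs}), \]

a −ΔCt relative to the LOD, so one unit is one PCR cycle (≈ one doubling)
and 0 means at-or-below detection. `lod_ct` defaults to 28 cycles, a common
ceiling for microfluidic qPCR chemistry; it is a free parameter of
`to_expression()` and every downstream quantity inherits it. Detected
reactions at or beyond the ceiling are reclassified as censored, which
makes `values == 0 ⇔ detected == FALSE` an invariant.

Three derived matrices feed the rest of the pipeline:

* **Quartile bins** (0–4): per gene, detected values are split at that
  gene's 25/50/75 percentiles (type-7 quantiles, right-closed intervals:
  a value equal to a boundary falls in the lower bin). A gene whose
  detected values are all equal collapses to bin 1; an undetected gene is
  all 0. Binning is invariant under any strictly increasing per-gene
  transform, which makes the downstream clustering robust to scale.
* **Z scores**: per-gene standardisation of −ΔCt using the *population*
  (divide-by-n) SD, zero-variance genes mapping to zero rows. Censored
  zeros are included by default — heatmaps and distances are drawn over
  all samples, and dropping the zeros would overstate the expression of
  sparsely detected genes. `include_censored = FALSE` excludes them (they
  return as `NA`) for sensitivity analyses.
* **Detection fractions**: per gene and sample group, the exact fraction
  of samples above LOD. Group-size-weighted fractions reconstruct the
  overall fraction exactly (a tested identity).

The package deliberately does no efficiency correction, standard-curve
quantification, or housekeeping ΔΔCt normalisation; an optional
housekeeping pre-step was considered and left out because the LOD-relative
scale is the object of interest and the assay panels involved carry no
validated reference set.

## State discovery

Samples (and, independently, genes) are clustered by average-linkage
(UPGMA) agglomeration of the Pearson correlation distance
\(d = 1 - r \in [0, 2]\). Items with zero variance carry no correlation
signal; they are pushed to the maximum distance 2 with a warning so they
fall out as singleton branches instead of aborting the run. For the
homeostatic-style analysis the quartile-binned matrix is the natural input
(bins are what the heatmap shows); for perturbation analyses the Z matrix
is. Both are accepted; `discover_states()` takes whatever matrix you give
it. The same distance/linkage convention is applied to both analyses, with
the caveat that cluster counts on real data can shift under alternatives.

The flat cut is *parsimonious*: candidate heights are the midpoints
between consecutive distinct merge heights (plus one above the root), and
among cuts whose clusters all reach `min_size` (default 5 samples — a
state you cannot summarise is not a state) with a cluster count inside
`k_range` (default 2–12), the cut with the **largest** k wins; among
heights giving that k the highest is used, leaving the most margin before
the next merge. If nothing is feasible the tree is returned whole (k = 1)
with a warning. State labels are letters in decreasing size order, so
labels are stable across runs of the same input; the pipeline from
distance to labels contains no randomness.

## State shifts

Redistribution of states across conditions is tested with a chi-square
test of homogeneity on the state × condition table,
switching to a Monte Carlo p value (2000 draws, fixed seed, exposed)
whenever any expected cell falls below 5. Standardized residuals say which
states drive a shift. Per-gene condition effects use one-way ANOVA on
−ΔCt with censored zeros included, mirroring the expression scale of the
summaries; `detected_only = TRUE` restricts to detected samples. The
degenerate all-identical case returns F = 0, p = 1; zero within-group
variance with distinct means returns the p → 0 limit. Marker-positive
subset analysis (`marker_subset()`) reruns the ANOVA inside the subset of
samples where a marker gene (e.g. an immediate-early gene) is detected and
corrects across genes by Benjamini–Hochberg. Left/right sides are pooled
by default with a stratification flag, and no animal-level nesting is
modelled (sample→animal maps are usually unavailable at this scale).

## Input-output maps

The connectivity prior is data, not code: a TSV of input rows
(brain region, its ligand, the receptor genes that read it) and output
rows (effector signal, synthesis/marker genes). The shipped default
(`default_prior()`, also at `inst/extdata/connectivity_prior.tsv`) encodes
the hypothalamic/brainstem afferents of the vagal motor nucleus — PVN,
RPa, CeA, BST, LHA, TMN, and a *grouped* NTS/AP/CVLM/LC entry for the
dopamine, GABA and norepinephrine inputs that cannot be attributed to a
single region — and the ACh/monoamine/GABA/peptide outputs. Prior genes
absent from an assay panel are flagged, never silently dropped.

Edge thickness in a state map is proportional to receptor expression; the
aggregation behind that proportionality is a choice the package makes
explicit and isolates in one function: the weight of an edge in a state is
the mean over the state's samples of the per-sample mean of the mapped
genes' −ΔCt, and an edge is emitted only when at least one contributing
gene is detected in ≥ `min_detect_frac` (default 0.1) of the state's
samples — below-LOD signals are absent from the map. Mean-of-means keeps
the weight on the −ΔCt scale, makes state-size-weighted weights decompose
exactly into the pooled weight, and is linear: rescaling expression
rescales weights.

Differential maps compare two cohorts edge by edge:
increasing if \(w_b > w_a (1 + \theta)\), decreasing if
\(w_b < w_a(1 - \theta)\), else unchanged, with \(\theta\) =
`rel_threshold` = 0.25 by default. The threshold is relative, so the
classification is scale-free; 0.25 was chosen as a change comfortably
above qPCR replicate noise while still sensitive, and it is configurable.
Edges pruned from one map enter at weight 0 so appearing/disappearing
signals classify as increasing/decreasing. An optional empirical null
(shuffle which samples belong to which cohort, recompute the weight delta,
1000 draws by default, fixed seed) attaches a permutation p value per
edge.

## Co-expression networks

Per condition, all gene pairs get a Pearson r on −ΔCt (censored zeros
included by default, for the same reason as the Z scores; a
pairwise-detected mode exists because the right choice is genuinely open)
and a two-sided p from the t transform \(t = r\sqrt{(n-2)/(1-r^2)}\).
Pairs with fewer than `min_pairs` (default 8) informative samples are
dropped — below that, a couple of coincident detections can fabricate a
perfect correlation. Pearson r is invariant under per-gene affine
transforms, so correlating Z scores or raw −ΔCt gives identical networks.
q values are Benjamini–Hochberg over all pairs tested within the
condition (the simplest defensible reading of a "q value"; Storey's
estimator is a noted alternative, not the default), and edges require
q < `q_cut` = 10⁻³. Unique and shared edge sets across condition networks
are exact set algebra on canonically ordered pairs; hub ranking is by
degree with ties broken by summed |r| then lexicographically (an empty
network leaves every gene tied at rank 1, degree 0).

## Phenotype landscape

The minimum spanning tree over pairwise Euclidean distances in Z space is
the landscape scaffold. Edges enter the MST in lexicographic sample order,
so ties break deterministically; duplicated samples yield zero-length
edges rather than errors. Tree distances come in both flavours — hop
counts and summed Euclidean lengths — because "distance along the tree"
is ambiguous in general use and both are cheap.

Terminal versus transitional states are defined topologically. A node is
a *through node* when deleting it separates two or more other states
(≥ 2 of the resulting components contain other-state nodes); it sits on a
path between phenotypes. A state is **terminal** when at least 70% of its
nodes are *not* through nodes — they hang on leaf-side subtrees whose
removal cannot disconnect the remaining states — and **transitional**
otherwise. The 70% tolerance (configurable) lets a state with a few
stragglers inside another branch still call terminal. This is a sharper
criterion than neighbour-purity: a three-node end block of a path graph is
correctly terminal even though its boundary node touches the next state.
Singleton states are terminal by convention and flagged.

PCA ellipsoids summarise cohort expression spaces: PCA on all samples
jointly (sign convention: each PC's largest-magnitude loading is
positive), per-group covariance of the first `n_pc` = 3 PC scores,
semi-axes \(r\sqrt{\lambda_i}\) at `radius_sd` = 2 SD (a conventional
~95%-coverage radius; the figure convention is not standardised, so it is
a parameter), volume \(\pi^{d/2}/\Gamma(d/2+1)\prod_i r\sqrt{\lambda_i}\),
and cross-group containment as the fraction of one group's points with
Mahalanobis distance ≤ `radius_sd` in the other group's ellipsoid — a
testable restatement of "cohort A's expression space lies within
cohort B's". Degenerate covariances give volume 0, flagged.

## miRNA template analysis

Detection follows the digital-counting convention: a probe is detected
when its mean count strictly exceeds the negative-control background mean
plus `k_sd` = 2 background SDs (background statistics over the control
probes' per-probe means; with a single control probe the SD term drops
out). Counts are normalised by per-sample totals over non-control probes
and log2(x+1)-transformed; both steps are isolated and swappable since
platform conventions vary.

Template matching scores each probe by the Pearson correlation between
its per-sample profile and the per-sample expansion of a group-level
template, by default (control = 0, injury = 1, preconditioned-injury = 0):
dysregulated by injury, normalised by preconditioning. Matching is
sign-agnostic (|r|) because dysregulation goes both ways. The p value is
a label-permutation test: exact enumeration of all distinct template-value
arrangements when there are at most 5000 (each value arrangement
corresponds to an equal number of group-label permutations, so the two
enumerations induce the same null), otherwise Monte Carlo with an add-one
correction and a fixed seed. Zero-variance profiles get score 0, p 1.

Candidates must be detected, match at p ≤ `p_cut`, move at least
`fold_cut` = 2-fold between injury and control (fold change is the
difference of log2 group means reported as a signed linear fold), and sit
at or above the `abundance_quantile` = 0.25 of detected-probe abundance.
The target network is then a pure filter: consensus hits (> 1 prediction
algorithm) from candidate miRNAs to genes on a user-supplied
expressed-gene list, annotated by functional category. No prediction
service is queried; the hit table is precomputed input.

## The synthetic generator

`synth_spec()` fixes the study conditions the package validates against:
170 genes × 180 samples (30 per condition × side cell over three
conditions), six planted states whose mixture is skewed and shifts in one
condition-side cell (last state-pair up, first state down — the shape of a
perturbation-driven redistribution), gene programs with baseline 3 and
elevation +6 −ΔCt units (SD 1) on each state's own module, and dropout
coupled to the program mean through a logistic detection model
\(P(\mathrm{detect}) = 1/(1+e^{-(\mu-\tau)/s})\) with τ = 1.5, s = 1
(≈ 18% censoring at baseline, ≈ 0 when elevated) — low-expression genes
drop out more, as in real detection-fraction profiles. Ct is written back
as `lod_ct − value` so the generator's output exercises the same loaders
and censoring path as real data. The miRNA block plants ~150 of 400
probes above a negative-binomial background (size 10, background mean 5),
three of them following the injury/rescue template at fold 4 with
alternating direction, in three groups of five samples. Planted
candidates draw their abundance from the upper part of the expressed
range because the prioritisation rule itself conditions on abundance — a
planted "candidate" below the abundance floor would contradict its truth
label. All draws are reproducible from the mandatory seed.

What the generator does **not** emulate: amplification chemistry and
primer efficiency differences, spatial capture artifacts, animal-level
nesting, doublets/contamination, batch effects, and correlated dropout
beyond the mean-coupled logistic. Passing the synthetic recovery tests
therefore shows the algorithms are correct and well calibrated under
clean planted structure — not that real tissue will yield six states or
three candidate miRNAs.

## Problem sizes and runtime choices

The validation suite uses: 180 × 170 for state recovery (single run,
fixed seed), 500 null simulations each for the shift-test and
template-match calibrations, 200 seeded generator runs for candidate
recovery, 500 samples for the ellipsoid closed-form check, and ≤ 10-item
fixtures wherever a brute-force oracle (exhaustive spanning trees via
Prüfer sequences, exhaustive label permutations, scalar formula loops) is
the comparator. These sizes keep the whole suite around two minutes on a
single core while leaving the Monte Carlo bounds meaningful.

## Known limitations

* The IO-map aggregation (mean-of-means with a detection floor) is one
  defensible reading of "edge thickness proportional to receptor
  expression"; it is isolated in `build_map()` precisely so it can be
  revised.
* BH q values control FDR under independence/PRDS; strongly dependent
  gene pairs in small cohorts can locally exceed the nominal rate.
* The parsimonious cut maximises the cluster count under a size floor; on
  data with nested substructure it can split one planted state (observed
  in roughly one synthetic run in twenty), which lowers ARI only
  marginally but changes k.
* Chi-square shift tests treat samples as exchangeable units; if multiple
  samples derive from one animal the p values are anti-conservative.
* Template matching with few samples per group has a coarse permutation
  grid; with 2 samples per group the smallest achievable p is 1/15.
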