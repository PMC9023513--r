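# End-to-end benchmark runners on synthetic cohorts. These wire the whole
# pipeline together (simulate -> learn -> model -> score -> evaluate) and
# back both the validation suite and scripts/acceptance.R.

#' Planted-module network recovery benchmark
#'
#' Simulates one cohort with a planted co-perturbation module, learns the
#' disease-specific network, and measures planted-edge recall (fraction of
#' module node pairs recovered as edges) and precision (fraction of
#' recovered edges that are module pairs).
#'
#' @param seed Integer seed driving both the generator and the learner.
#' @param spec A [cohort_spec()]; its seed is overridden by `seed`.
#' @return One-row tibble: `seed`, `recall`, `precision`, `n_edges`.
#' @export
run_recovery_benchmark <- function(seed, spec = cohort_spec()) {
  spec$seed <- as.integer(seed)
  co <- make_cohort(spec)
  net <- suppressWarnings(learn_disease_network(
    cohort_profiles(co, "disease"), cohort_profiles(co, "reference"),
    network_config(seed = seed)))
  truth <- apply(t(combn(lex_sort(spec$module_nodes), 2)), 1, paste,
                 collapse = "\r")
  got <- paste(net$edges$node_a, net$edges$node_b, sep = "\r")
  tibble::tibble(seed = seed,
                 recall = mean(truth %in% got),
                 precision = if (length(got) > 0) mean(got %in% truth)
                             else NA_real_,
                 n_edges = length(got))
}

#' Multi-disease diagnostic ranking benchmark
#'
#' Simulates `n_diseases` cohorts with disjoint planted modules plus a
#' shared reference cohort, learns one disease-specific network per
#' disease, builds disease models (module, CTDdm reference null, Brown
#' calibration), scores every sample against every model, and evaluates
#' the ranking: top-1/top-3/in-DD fractions over disease samples and the
#' median differential-diagnosis length over reference samples.
#'
#' @param seed Integer seed.
#' @param n_diseases Number of modeled diseases. Default 5.
#' @param template [cohort_spec()] template (namespace size, cohort sizes,
#'   effect size).
#' @param config A [network_config()]; its seed is overridden by `seed`.
#' @return List with `evaluation` (see [evaluate_cohort()]), `models`,
#'   `reports`, and `summary` (one-row tibble with `seed`, `top1`, `top3`,
#'   `in_dd`, `reference_dd_median`).
#' @export
run_ranking_benchmark <- function(seed, n_diseases = 5,
                                  template = cohort_spec(n_metabolites = 40),
                                  config = network_config()) {
  template$seed <- as.integer(seed)
  config$seed <- as.integer(seed)
  bm <- make_multidisease_benchmark(n_diseases, 0, template)

  models <- lapply(names(bm$diseases), function(lab) {
    net <- suppressWarnings(learn_disease_network(
      bm$diseases[[lab]], bm$reference, config, condition_label = lab))
    build_disease_model(net, bm$diseases[[lab]], bm$reference, lab, config)
  })
  names(models) <- names(bm$diseases)

  universe <- unique(unlist(lapply(models, function(m) m$network$nodes)))
  all_profiles <- Reduce(bind_samples, bm$diseases, bm$reference)
  reports <- list()
  for (sid in bm$metadata$sample_id) {
    ps <- extract_perturbations(all_profiles, sid, universe,
                                config$z_threshold, config$max_set_size)
    if (length(ps$nodes) == 0) next
    scores <- score_sample_panel(ps, models)
    if (!any(scores$scoreable)) next
    reports[[sid]] <- rank_and_dd(scores, n_models = length(models),
                                  alpha = config$alpha,
                                  bonferroni = config$bonferroni)
  }
  ev <- evaluate_cohort(reports, bm$truth)
  list(evaluation = ev, models = models, reports = reports,
       summary = tibble::tibble(seed = seed,
                                top1 = ev$summary$top1,
                                top3 = ev$summary$top3,
                                in_dd = ev$summary$in_dd,
                                reference_dd_median =
                                  ev$summary$reference_dd_median))
}

#' Cohort-geometry benchmark (distance matrix, MDS, cluster purity)
#'
#' Simulates three disease cohorts with distinct planted modules and a
#' shared reference, learns one network from all disease samples pooled
#' against the reference, computes the pairwise CTDncd distance matrix of
#' the disease samples, embeds it by classical MDS, and reports the
#' k-means cluster purity against the true cohort labels.
#'
#' @param seed Integer seed.
#' @param n_per_cohort Disease samples per cohort. Default 12.
#' @param template [cohort_spec()] template.
#' @return List with `purity`, `coords`, `labels`, `distance_matrix`,
#'   `mds_reembedding_error` (max deviation when re-embedding a Euclidean
#'   distance matrix of the embedded coordinates), and one-row `summary`.
#' @export
run_geometry_benchmark <- function(seed, n_per_cohort = 12,
                                   template = cohort_spec(n_metabolites = 40)) {
  template$seed <- as.integer(seed)
  template$n_disease <- n_per_cohort
  bm <- make_multidisease_benchmark(3, 0, template)
  config <- network_config(seed = seed)

  pooled <- Reduce(bind_samples, bm$diseases)
  net <- suppressWarnings(learn_disease_network(pooled, bm$reference,
                                                config,
                                                condition_label = "pooled"))
  sets <- list()
  labels <- character()
  for (lab in names(bm$diseases)) {
    pm <- bm$diseases[[lab]]
    for (sid in sample_ids(pm)) {
      ps <- extract_perturbations(pm, sid, net$nodes, config$z_threshold,
                                  config$max_set_size)
      if (length(intersect(ps$nodes, net$nodes)) == 0) next
      sets[[sid]] <- ps
      labels <- c(labels, lab)
    }
  }
  dmat <- pairwise_distance_matrix(net, sets)
  coords <- mds_embed(dmat, dims = 2)
  purity <- kmeans_purity(coords, labels, k = 3, seed = seed)

  # isometry check: a Euclidean matrix re-embeds exactly
  X <- as.matrix(coords[, c("MDS1", "MDS2")])
  D <- as.matrix(stats::dist(X))
  re <- mds_embed(D, dims = 2)
  err <- max(abs(as.matrix(stats::dist(as.matrix(re[, c("MDS1", "MDS2")]))) -
                   D))
  list(purity = as.numeric(purity), coords = coords, labels = labels,
       distance_matrix = dmat, mds_reembedding_error = err,
       summary = tibble::tibble(seed = seed, purity = as.numeric(purity),
                                mds_reembedding_error = err,
                                n_samples = length(sets)))
}

#' Treatment-confounder censoring benchmark
#'
#' Emulates the treatment-confounding scenario: half of disease A's cohort
#' is under a treatment whose overlay module overlaps disease B's module,
#' so B patients spuriously match A's model. The benchmark learns A's
#' (confounded) network, identifies the main treatment module from a
#' treatment-specific network (treated contrasted against untreated A
#' patients, so the disease module has no between-arm shift and only
#' treatment structure survives the pruning), drops module nodes that are
#' recurrently perturbed in untreated patients (disease, not treatment,
#' signal), censors the remainder from A's network, and measures the count
#' of false HITs of B patients against A's model and the top-1 accuracy of
#' A patients, before and after censoring.
#'
#' @param seed Integer seed.
#' @param n_metabolites Namespace size. Default 40.
#' @return One-row tibble: `seed`, `false_hits_before`, `false_hits_after`,
#'   `top1_before`, `top1_after`, `treatment_module_size`.
#' @export
run_treatment_benchmark <- function(seed, n_metabolites = 40) {
  mets <- sprintf("met%03d", seq_len(n_metabolites))
  module_a <- mets[1:6]
  module_b <- mets[10:15]
  overlay <- mets[c(10:12, 20)]   # overlaps B's module
  config <- network_config(seed = seed)

  spec_a <- cohort_spec(
    n_metabolites = n_metabolites, n_disease = 40, n_reference = 40,
    module_nodes = module_a, disease_label = "diseaseA",
    treatment_overlay = list(nodes = overlay, effect = 3,
                             fraction_treated = 0.5),
    seed = child_seed(seed, 11L))
  co_a <- make_cohort(spec_a)
  spec_b <- cohort_spec(
    n_metabolites = n_metabolites, n_disease = 20, n_reference = 1,
    module_nodes = module_b, disease_label = "diseaseB",
    seed = child_seed(seed, 12L))
  co_b <- make_cohort(spec_b)

  reference <- cohort_profiles(co_a, "reference")
  d_a <- cohort_profiles(co_a, "disease")
  d_b <- cohort_profiles(co_b, "disease")
  treated_ids <- co_a$metadata$sample_id[co_a$metadata$treatment_flags ==
                                           "treatment"]
  treated <- select_samples(d_a, treated_ids)
  untreated <- select_samples(d_a, setdiff(sample_ids(d_a), treated_ids))

  net_a <- suppressWarnings(learn_disease_network(
    d_a, reference, config, condition_label = "diseaseA"))
  net_b <- suppressWarnings(learn_disease_network(
    d_b, reference, config, condition_label = "diseaseB"))
  model_b <- build_disease_model(net_b, d_b, reference, "diseaseB", config)

  # treatment-specific network: treated contrasted against the untreated
  # patients with the same disease, so the disease module carries no
  # between-arm shift and only treatment structure survives the pruning
  tnet <- suppressWarnings(learn_treatment_network(
    treated, untreated, untreated, config, condition_label = "treatment"))
  tmodule <- main_disease_module(tnet, treated, "treatment", config)
  # treatment-related = recurrently perturbed under treatment but not in
  # untreated patients with the same disease; keeps disease perturbations
  # out of the censoring set
  unt_z <- untreated$z[intersect(tmodule$nodes, rownames(untreated$z)), ,
                       drop = FALSE]
  recur_unt <- rowMeans(abs(unt_z) >= config$z_threshold, na.rm = TRUE) > 0.5
  censor <- setdiff(tmodule$nodes, names(recur_unt)[recur_unt])
  if (length(censor) > 0) {
    tmodule <- disease_module("treatment", censor, "algorithm1_surrogate")
  }

  score_cohort <- function(model_a) {
    models <- list(diseaseA = model_a, diseaseB = model_b)
    universe <- unique(c(model_a$network$nodes, net_b$nodes))
    false_hits <- 0L
    top1 <- 0L
    for (sid in sample_ids(d_b)) {
      ps <- extract_perturbations(d_b, sid, universe, config$z_threshold,
                                  config$max_set_size)
      sc <- score_sample(ps, model_a)
      if (isTRUE(sc$scoreable) && classify_hit(sc$p_combined) == "HIT") {
        false_hits <- false_hits + 1L
      }
    }
    for (sid in sample_ids(d_a)) {
      ps <- extract_perturbations(d_a, sid, universe, config$z_threshold,
                                  config$max_set_size)
      scores <- score_sample_panel(ps, models)
      if (!any(scores$scoreable)) next
      rep <- rank_and_dd(scores, n_models = 2, alpha = config$alpha,
                         bonferroni = config$bonferroni)
      if (rep$disease_label[rep$rank == 1] == "diseaseA") top1 <- top1 + 1L
    }
    c(false_hits = false_hits, top1 = top1 / ncol(d_a$z))
  }

  model_a <- build_disease_model(net_a, d_a, reference, "diseaseA", config)
  before <- score_cohort(model_a)

  net_a_censored <- prune_nodes(net_a, tmodule$nodes)
  model_a2 <- build_disease_model(net_a_censored, d_a, reference,
                                  "diseaseA", config)
  after <- score_cohort(model_a2)

  tibble::tibble(seed = seed,
                 false_hits_before = before[["false_hits"]],
                 false_hits_after = after[["false_hits"]],
                 top1_before = before[["top1"]],
                 top1_after = after[["top1"]],
                 treatment_module_size = length(tmodule$nodes))
}
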