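#' Configuration for network learning and scoring
#'
#' Bundles every tunable threshold of the pipeline with its default:
#' presence filter fraction (0.5, strict), perturbation |z| threshold
#' (2 SD), perturbation-set cap (30 nodes), StARS settings (20 subsamples,
#' instability 0.1, 30-penalty path down to 1% of lambda_max), surrogate
#' augmentation (off), and diagnosis thresholds (alpha 0.05, Bonferroni
#' on).
#'
#' @param min_frac Presence-filter fraction (strict `>`).
#' @param z_threshold Perturbation |z| cutoff, in reference SD units.
#' @param max_set_size Perturbation-set cap.
#' @param n_subsamples,instability_threshold StARS settings.
#' @param n_lambda,lambda_min_ratio Penalty-path settings.
#' @param n_surrogates Number of surrogate disease profiles to append
#'   (bootstrap + noise); 0 disables.
#' @param surrogate_noise_sd Noise SD for surrogates.
#' @param alpha,bonferroni Differential-diagnosis threshold settings.
#' @param seed Integer seed for every stochastic step.
#' @return A named list of class `ctdnet_config`.
#' @export
network_config <- function(min_frac = 0.5, z_threshold = 2, max_set_size = 30,
                           n_subsamples = 20, instability_threshold = 0.1,
                           n_lambda = 30, lambda_min_ratio = 0.1,
                           n_surrogates = 0, surrogate_noise_sd = 0.1,
                           alpha = 0.05, bonferroni = TRUE, seed = 1L) {
  stopifnot(min_frac >= 0, min_frac < 1, z_threshold > 0, max_set_size >= 1,
            n_subsamples >= 2, instability_threshold >= 0,
            instability_threshold <= 0.5, n_lambda >= 2,
            lambda_min_ratio > 0, lambda_min_ratio < 1,
            n_surrogates >= 0, surrogate_noise_sd >= 0,
            alpha > 0, alpha <= 1)
  structure(list(min_frac = min_frac, z_threshold = z_threshold,
                 max_set_size = max_set_size, n_subsamples = n_subsamples,
                 instability_threshold = instability_threshold,
                 n_lambda = n_lambda, lambda_min_ratio = lambda_min_ratio,
                 n_surrogates = n_surrogates,
                 surrogate_noise_sd = surrogate_noise_sd,
                 alpha = alpha, bonferroni = bonferroni,
                 seed = as.integer(seed)),
            class = "ctdnet_config")
}

# glasso + StARS on a samples x metabolites matrix; returns network + stars
fit_condition_network <- function(X, label, config, seed) {
  lambdas <- lambda_path(X, config$n_lambda, config$lambda_min_ratio)
  sel <- stars_select(X, lambdas, n_subsamples = config$n_subsamples,
                      instability_threshold = config$instability_threshold,
                      seed = seed)
  theta <- glasso_fit(X, sel$selected_lambda)
  net <- to_partial_correlation(theta, provenance = list(
    condition_label = label,
    lambda_selected = sel$selected_lambda,
    stars_all_unstable = sel$all_unstable,
    stars_seed = sel$seed,
    n_samples = nrow(X)))
  list(network = net, stars = sel)
}

#' Learn a disease-specific co-perturbation network
#'
#' Implements the discriminative-latent-structure pipeline: (1) presence
#' filter (metabolites observed in > `min_frac` of both cohorts; binary
#' analytes are excluded from learning since they carry no z-scores),
#' (2) minimum-z imputation of remaining missing cells against the control
#' cohort, (3) graphical lasso with StARS penalty selection on the pooled
#' disease+control samples, (4) the same on control samples alone,
#' (5) partial-correlation edge weights for both, (6) differential pruning
#' of the pooled network against the control network. Pooling disease and
#' control samples makes the disease state a hidden variable, so edges
#' surviving the pruning capture disease-specific co-perturbation.
#'
#' @param disease_profiles,control_profiles `profile_matrix` cohorts.
#'   At least 3 samples each are required; fewer than 5 disease or 25
#'   control samples triggers a warning (network stability suffers below
#'   those sizes).
#' @param config A [network_config()].
#' @param condition_label Label stored in provenance.
#' @return A disease-specific [copnet()]. Provenance records both selected
#'   penalties, cohort sizes, the seed, and surrogate counts; the StARS
#'   objects are attached as attribute `"stars"`.
#' @export
learn_disease_network <- function(disease_profiles, control_profiles,
                                  config = network_config(),
                                  condition_label = "disease") {
  n_d <- ncol(disease_profiles$z)
  n_c <- ncol(control_profiles$z)
  if (n_d < 3 || n_c < 3) {
    stopf("need at least 3 samples per condition (got %d disease, %d control)",
          n_d, n_c)
  }
  if (n_d < 5) warnf("only %d disease profiles; at least 5 are recommended", n_d)
  if (n_c < 25) warnf("only %d control profiles; at least 25 are recommended", n_c)

  n_surr <- 0L
  if (config$n_surrogates > 0) {
    surr <- make_surrogates(disease_profiles, config$n_surrogates,
                            noise_sd = config$surrogate_noise_sd,
                            seed = child_seed(config$seed, 97L))
    disease_profiles <- bind_samples(disease_profiles, surr$profiles)
    n_surr <- config$n_surrogates
  }

  kept <- filter_by_presence(disease_profiles, control_profiles,
                             config$min_frac)
  kept <- setdiff(kept, union(disease_profiles$binary_analytes,
                              control_profiles$binary_analytes))
  if (length(kept) < 2) stopf("fewer than 2 metabolites pass the presence filter")

  ref <- control_profiles
  dz <- impute_missing(subset_metabolites(disease_profiles, kept), ref)
  cz <- impute_missing(subset_metabolites(control_profiles, kept), ref)

  pooled <- rbind(t(dz$z), t(cz$z))[, kept, drop = FALSE]
  control <- t(cz$z)[, kept, drop = FALSE]

  fit_dc <- fit_condition_network(pooled, paste0(condition_label, "+control"),
                                  config, child_seed(config$seed, 1L))
  fit_c <- fit_condition_network(control, "control", config,
                                 child_seed(config$seed, 2L))
  net <- differential_prune(fit_dc$network, fit_c$network)
  net$provenance <- c(net$provenance[setdiff(names(net$provenance),
                                             "condition_label")],
                      list(condition_label = condition_label,
                           lambda_control = fit_c$stars$selected_lambda,
                           n_samples_disease = n_d,
                           n_samples_control = n_c,
                           n_surrogates = n_surr,
                           seed = config$seed))
  attr(net, "stars") <- list(pooled = fit_dc$stars, control = fit_c$stars)
  net
}

#' Learn a treatment-specific co-perturbation network
#'
#' Mirrors the disease pipeline for treatment confounders: network 1 is
#' learned from treated patients pooled with a contrast cohort (patients
#' with related diseases not on the treatment), network 2 from untreated
#' patients with the same disease, and edges found in both are pruned from
#' network 1. The surviving edges capture treatment-driven, not
#' disease-driven, co-perturbation.
#'
#' @param treated Profiles of patients on the treatment.
#' @param contrast Profiles the treated cohort is contrasted against.
#' @param untreated_same_disease Profiles of untreated patients with the
#'   same disease.
#' @param config A [network_config()].
#' @param condition_label Provenance label.
#' @return A treatment-specific [copnet()].
#' @export
learn_treatment_network <- function(treated, contrast,
                                    untreated_same_disease,
                                    config = network_config(),
                                    condition_label = "treatment") {
  if (ncol(contrast$z) == 0) stopf("empty contrast cohort")
  net <- learn_disease_network(treated, contrast, config,
                               condition_label = condition_label)
  if (ncol(untreated_same_disease$z) < 3) {
    stopf("need at least 3 untreated samples, got %d",
          ncol(untreated_same_disease$z))
  }
  kept <- intersect(net$nodes, rownames(untreated_same_disease$z))
  un <- impute_missing(subset_metabolites(untreated_same_disease, kept),
                       untreated_same_disease)
  fit_u <- fit_condition_network(t(un$z)[, kept, drop = FALSE],
                                 "untreated", config,
                                 child_seed(config$seed, 3L))
  out <- differential_prune(net, fit_u$network)
  out$provenance$lambda_untreated <- fit_u$stars$selected_lambda
  out
}

subset_metabolites <- function(pm, ids) {
  profile_matrix(pm$z[ids, , drop = FALSE],
                 intersect(pm$binary_analytes, ids))
}
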