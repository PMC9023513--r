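#' Specification of a synthetic metabolomics cohort
#'
#' Describes a cohort with a planted co-perturbation module: reference
#' samples are independent standard normal per metabolite (that is what a
#' z-score is under health), disease samples share a latent factor over the
#' module nodes plus a mean |z| shift, so the module is both perturbed and
#' co-perturbed — the structure a Gaussian graphical model can recover.
#' Defaults mirror a small clinical cohort: 30 metabolites, 20 disease and
#' 40 reference samples, a 6-node module shifted by 3 reference SDs with
#' within-module latent correlation 0.8, and 5% missingness.
#'
#' @param n_metabolites Number of z-scored metabolites.
#' @param n_disease,n_reference Cohort sizes.
#' @param module_nodes Metabolite ids of the planted module (defaults to
#'   the first 6).
#' @param effect_size Mean |z| shift of module nodes in disease samples
#'   (reference SD units). Default 3.
#' @param module_correlation Within-module latent correlation in [0, 1).
#'   Default 0.8.
#' @param missing_rate Uniform missingness rate in [0, 1). Default 0.05.
#' @param treatment_overlay Optional list with `nodes`, `effect`,
#'   `fraction_treated` (and optionally `correlation`): a second latent
#'   module overlaid on the treated fraction of disease samples.
#' @param binary_analytes Optional tibble/list with `id`, `prob_disease`,
#'   `prob_reference`: presence-flag analytes appended to the matrix.
#' @param disease_label Diagnosis label for the disease samples.
#' @param seed Integer seed; all randomness flows from it.
#' @return A `cohort_spec`.
#' @export
cohort_spec <- function(n_metabolites = 30, n_disease = 20,
                        n_reference = 40, module_nodes = NULL,
                        effect_size = 3, module_correlation = 0.8,
                        missing_rate = 0.05, treatment_overlay = NULL,
                        binary_analytes = NULL, disease_label = "disease",
                        seed = 1L) {
  mets <- sprintf("met%03d", seq_len(n_metabolites))
  if (is.null(module_nodes)) module_nodes <- mets[seq_len(min(6, n_metabolites))]
  if (!all(module_nodes %in% mets)) {
    stopf("module node outside the metabolite namespace (met001..met%03d)",
          n_metabolites)
  }
  stopifnot(n_disease >= 1, n_reference >= 1, effect_size >= 0,
            module_correlation >= 0, module_correlation < 1,
            missing_rate >= 0, missing_rate < 1)
  if (!is.null(treatment_overlay)) {
    stopifnot(all(treatment_overlay$nodes %in% mets),
              treatment_overlay$fraction_treated >= 0,
              treatment_overlay$fraction_treated <= 1)
    treatment_overlay$correlation <- treatment_overlay$correlation %||% 0.8
  }
  if (!is.null(binary_analytes)) {
    binary_analytes <- tibble::as_tibble(binary_analytes)
    stopifnot(all(c("id", "prob_disease") %in% names(binary_analytes)))
    if (is.null(binary_analytes$prob_reference)) {
      binary_analytes$prob_reference <- 0.02
    }
  }
  structure(list(n_metabolites = n_metabolites, n_disease = n_disease,
                 n_reference = n_reference, metabolites = mets,
                 module_nodes = module_nodes, effect_size = effect_size,
                 module_correlation = module_correlation,
                 missing_rate = missing_rate,
                 treatment_overlay = treatment_overlay,
                 binary_analytes = binary_analytes,
                 disease_label = disease_label, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("<cohort_spec> %d metabolites, %d disease + %d reference, module of %d at %.1f SD (seed %d)\n",
              x$n_metabolites, x$n_disease, x$n_reference,
              length(x$module_nodes), x$effect_size, x$seed))
  invisible(x)
}

# disease-sample z-block for a module: shared latent factor + mean shift
draw_disease_block <- function(mets, module, n, effect, rho) {
  z <- matrix(rnorm(length(mets) * n), length(mets), n,
              dimnames = list(mets, NULL))
  if (length(module) > 0 && n > 0) {
    lat <- rnorm(n)
    eps <- z[module, , drop = FALSE]
    z[module, ] <- sqrt(1 - rho) * eps +
      matrix(sqrt(rho) * lat, length(module), n, byrow = TRUE) + effect
  }
  z
}

#' Generate a synthetic cohort
#'
#' Draws the cohort described by a [cohort_spec()]: reference samples
#' standard normal, disease samples with the planted latent-factor module,
#' optional treatment overlay on a treated fraction, optional binary
#' analytes, and uniform missingness that never removes more than half of
#' any module node's disease observations (so the presence filter cannot
#' drop the planted structure). Byte-identical output for identical seeds.
#'
#' @param spec A [cohort_spec()].
#' @return List with `profiles` (a [profile_matrix()] holding disease then
#'   reference columns) and `metadata` (tibble: `sample_id`, `role`,
#'   `diagnosis_label`, `treatment_flags`, `age_group`).
#' @export
make_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    mets <- spec$metabolites
    d_ids <- sprintf("%s_d%02d", spec$disease_label, seq_len(spec$n_disease))
    r_ids <- sprintf("ref%03d", seq_len(spec$n_reference))

    zd <- draw_disease_block(mets, spec$module_nodes, spec$n_disease,
                             spec$effect_size, spec$module_correlation)
    colnames(zd) <- d_ids
    zr <- matrix(rnorm(length(mets) * spec$n_reference), length(mets),
                 spec$n_reference, dimnames = list(mets, r_ids))

    treated <- character()
    ov <- spec$treatment_overlay
    if (!is.null(ov) && ov$fraction_treated > 0) {
      n_tr <- round(ov$fraction_treated * spec$n_disease)
      treated <- d_ids[seq_len(n_tr)]
      if (n_tr > 0) {
        lat <- rnorm(n_tr)
        add <- matrix(sqrt(ov$correlation) * lat, length(ov$nodes), n_tr,
                      byrow = TRUE) +
          sqrt(1 - ov$correlation) *
            matrix(rnorm(length(ov$nodes) * n_tr), length(ov$nodes), n_tr) +
          ov$effect
        zd[ov$nodes, treated] <- zd[ov$nodes, treated] + add
      }
    }

    z <- cbind(zd, zr)

    binary_ids <- character()
    if (!is.null(spec$binary_analytes)) {
      ba <- spec$binary_analytes
      binary_ids <- ba$id
      bz <- matrix(0, nrow(ba), ncol(z),
                   dimnames = list(ba$id, colnames(z)))
      for (i in seq_len(nrow(ba))) {
        bz[i, d_ids] <- as.numeric(runif(length(d_ids)) < ba$prob_disease[i])
        bz[i, r_ids] <- as.numeric(runif(length(r_ids)) < ba$prob_reference[i])
      }
      z <- rbind(z, bz)
    }

    if (spec$missing_rate > 0) {
      mask <- matrix(runif(length(z)) < spec$missing_rate, nrow(z), ncol(z),
                     dimnames = dimnames(z))
      # planted module must stay observable in strictly > 50% of disease
      # samples, or the presence filter could drop the planted structure
      cap <- max(ceiling(spec$n_disease / 2) - 1, 0)
      for (m in spec$module_nodes) {
        hit <- which(mask[m, d_ids])
        if (length(hit) > cap) mask[m, d_ids[hit[-seq_len(cap)]]] <- FALSE
      }
      z[mask] <- NA_real_
    }

    metadata <- tibble::tibble(
      sample_id = c(d_ids, r_ids),
      role = rep(c("disease", "reference"),
                 c(spec$n_disease, spec$n_reference)),
      diagnosis_label = rep(c(spec$disease_label, NA_character_),
                            c(spec$n_disease, spec$n_reference)),
      treatment_flags = ifelse(c(d_ids, r_ids) %in% treated,
                               "treatment", ""),
      age_group = NA_character_)

    list(profiles = profile_matrix(z, binary_ids), metadata = metadata)
  })
}

#' Split a generated cohort by sample role
#'
#' @param cohort Output of [make_cohort()].
#' @param role `"disease"`, `"reference"` or `"surrogate"`.
#' @return A `profile_matrix` with the matching samples.
#' @export
cohort_profiles <- function(cohort, role) {
  ids <- cohort$metadata$sample_id[cohort$metadata$role == role]
  select_samples(cohort$profiles, ids)
}

#' Generate a labeled multi-disease benchmark
#'
#' Builds `n_diseases` disease cohorts with distinct planted modules and a
#' single shared reference cohort. Module node sets are laid out along the
#' metabolite namespace so that adjacent diseases share exactly
#' `round(overlap_fraction * module_size)` nodes; `overlap_fraction = 0`
#' gives disjoint modules.
#'
#' @param n_diseases Number of diseases (>= 2).
#' @param overlap_fraction Pairwise module overlap fraction in [0, 1).
#' @param template A [cohort_spec()] providing every other parameter; its
#'   `module_nodes` length sets the module size and its seed drives all
#'   randomness.
#' @return List with `reference` (`profile_matrix`), `diseases` (named
#'   list of `profile_matrix`), `modules` (named list of node-id vectors),
#'   `metadata` (all samples), and `truth` (tibble `sample_id`,
#'   `diagnosis_label`).
#' @export
make_multidisease_benchmark <- function(n_diseases, overlap_fraction = 0,
                                        template = cohort_spec()) {
  stopifnot(n_diseases >= 2, overlap_fraction >= 0, overlap_fraction < 1)
  m <- length(template$module_nodes)
  o <- round(overlap_fraction * m)
  stride <- m - o
  span <- (n_diseases - 1) * stride + m
  if (span > template$n_metabolites) {
    stopf("overlap %.2f infeasible: %d modules of %d need %d metabolites, have %d",
          overlap_fraction, n_diseases, m, span, template$n_metabolites)
  }
  mets <- template$metabolites
  labels <- sprintf("disease%02d", seq_len(n_diseases))
  modules <- stats::setNames(lapply(seq_len(n_diseases), function(i) {
    mets[seq((i - 1) * stride + 1, (i - 1) * stride + m)]
  }), labels)

  ref_spec <- cohort_spec(
    n_metabolites = template$n_metabolites, n_disease = 1,
    n_reference = template$n_reference,
    module_nodes = template$module_nodes, effect_size = 0,
    module_correlation = 0, missing_rate = template$missing_rate,
    seed = child_seed(template$seed, 0L))
  reference <- cohort_profiles(make_cohort(ref_spec), "reference")

  cohorts <- lapply(seq_len(n_diseases), function(i) {
    sp <- cohort_spec(
      n_metabolites = template$n_metabolites,
      n_disease = template$n_disease, n_reference = 1,
      module_nodes = modules[[i]], effect_size = template$effect_size,
      module_correlation = template$module_correlation,
      missing_rate = template$missing_rate, disease_label = labels[i],
      seed = child_seed(template$seed, i))
    make_cohort(sp)
  })
  diseases <- stats::setNames(lapply(cohorts, cohort_profiles, "disease"),
                              labels)
  md <- dplyr::bind_rows(
    lapply(cohorts, function(co) {
      co$metadata[co$metadata$role == "disease", ]
    }))
  md <- dplyr::bind_rows(md, tibble::tibble(
    sample_id = sample_ids(reference), role = "reference",
    diagnosis_label = NA_character_, treatment_flags = "",
    age_group = NA_character_))
  truth <- tibble::tibble(sample_id = md$sample_id,
                          diagnosis_label = md$diagnosis_label)
  list(reference = reference, diseases = diseases, modules = modules,
       metadata = md, truth = truth)
}

#' Generate surrogate profiles by bootstrap and noise
#'
#' Surrogate disease profiles stabilize network learning for very small
#' cohorts: columns are resampled with replacement and perturbed with
#' additive Gaussian noise (binary analyte rows are resampled but not
#' noised).
#'
#' @param profiles Source `profile_matrix` (>= 1 sample).
#' @param n Number of surrogates (> 0).
#' @param noise_sd Additive noise SD. Default 0.1.
#' @param seed Integer seed.
#' @param resample Bootstrap the source columns (`TRUE`, default) or copy
#'   them in order (`FALSE`, requires `n <=` number of source samples).
#' @return List with `profiles` (surrogate `profile_matrix`, samples named
#'   `surr001..`) and `metadata` (role `"surrogate"`).
#' @export
make_surrogates <- function(profiles, n, noise_sd = 0.1, seed = 1L,
                            resample = TRUE) {
  if (n <= 0) stopf("n must be positive")
  n_src <- ncol(profiles$z)
  if (n_src < 1) stopf("need at least one source profile")
  if (!resample && n > n_src) stopf("n exceeds source size with resample = FALSE")
  with_seed(seed, {
    idx <- if (resample) sample.int(n_src, n, replace = TRUE) else seq_len(n)
    z <- profiles$z[, idx, drop = FALSE]
    if (noise_sd > 0) {
      noise <- matrix(rnorm(length(z), sd = noise_sd), nrow(z), ncol(z))
      noise[rownames(z) %in% profiles$binary_analytes, ] <- 0
      z <- z + noise
    }
    ids <- sprintf("surr%03d", seq_len(n))
    colnames(z) <- ids
    list(profiles = profile_matrix(z, profiles$binary_analytes),
         metadata = tibble::tibble(sample_id = ids, role = "surrogate",
                                   diagnosis_label = NA_character_,
                                   treatment_flags = "",
                                   age_group = NA_character_))
  })
}
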