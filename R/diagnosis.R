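#' Disease models: the unit of diagnostic ranking
#'
#' A disease model bundles a disease-specific co-perturbation network, its
#' main disease module, the null distribution of CTDdm distances measured
#' on reference (healthy) samples, and the per-reference (p_ctd, p_dm)
#' score table used to calibrate Brown's combined p-value.
#'
#' @param disease_label Disease name.
#' @param network A [copnet()].
#' @param module A `disease_module` over `network`'s nodes.
#' @param reference_dm_null Numeric vector of CTDdm distances of reference
#'   samples to the module.
#' @param reference_score_table Tibble with columns `p_ctd`, `p_dm` per
#'   reference sample (used for the Brown covariance estimate).
#' @return A `disease_model`.
#' @export
disease_model <- function(disease_label, network, module,
                          reference_dm_null = numeric(),
                          reference_score_table = NULL) {
  if (!all(module$nodes %in% network$nodes)) {
    stopf("module nodes missing from the network")
  }
  structure(list(disease_label = disease_label, network = network,
                 module = module, reference_dm_null = reference_dm_null,
                 reference_score_table = reference_score_table),
            class = "disease_model")
}

#' @export
print.disease_model <- function(x, ...) {
  cat(sprintf("<disease_model> %s: %d nodes, %d edges, module of %d, %d reference scores\n",
              x$disease_label, length(x$network$nodes), n_edges(x$network),
              length(x$module$nodes), length(x$reference_dm_null)))
  invisible(x)
}

#' Build a disease model from cohorts
#'
#' Learns nothing itself: takes an already-learned network, extracts the
#' main disease module from the disease cohort, then scores every
#' reference sample against the model to populate the CTDdm null
#' distribution and the (p_ctd, p_dm) calibration table (each reference's
#' p_dm is computed leave-one-out against the remaining references).
#' Reference samples whose perturbation sets miss the network are skipped.
#'
#' @param network A disease-specific [copnet()].
#' @param disease_profiles,reference_profiles `profile_matrix` cohorts.
#' @param disease_label Disease name.
#' @param config A [network_config()].
#' @return A [disease_model()].
#' @export
build_disease_model <- function(network, disease_profiles,
                                reference_profiles,
                                disease_label = "disease",
                                config = network_config()) {
  module <- main_disease_module(network, disease_profiles, disease_label,
                                config)
  universe <- union(network$nodes, reference_profiles$binary_analytes)
  sets <- lapply(sample_ids(reference_profiles), function(sid) {
    extract_perturbations(reference_profiles, sid, universe,
                          config$z_threshold, config$max_set_size)
  })
  ok <- vapply(sets, function(s) {
    length(intersect(s$nodes, network$nodes)) > 0
  }, logical(1))
  sets <- sets[ok]
  dm <- vapply(sets, function(s) {
    as.numeric(ctd_dm(network, s, module))
  }, numeric(1))
  p_ctd <- vapply(sets, function(s) ctd_pvalue(network, s)$p_value,
                  numeric(1))
  p_dm <- vapply(seq_along(dm), function(i) {
    if (length(dm) > 1) empirical_percentile(dm[i], dm[-i]) else 1
  }, numeric(1))
  tbl <- tibble::tibble(sample_id = vapply(sets, `[[`, "", "sample_id"),
                        p_ctd = p_ctd, d_dm = dm, p_dm = p_dm)
  disease_model(disease_label, network, module, reference_dm_null = dm,
                reference_score_table = tbl)
}

#' Brown's combined p-value for correlated tests
#'
#' Fisher's statistic `T = -2 * sum(log p_i)` is referred to a scaled
#' chi-square whose first two moments match `T` under dependence:
#' `E[T] = 2k`, `Var[T] = 4k + 2 * sum_{i<j} cov(-2 log p_i, -2 log p_j)`,
#' `f = 2 E^2 / Var`, `c = Var / (2E)`, `p = P(chi^2_f > T / c)`. With no
#' covariance (or a single p-value) this reduces to Fisher's method (the
#' identity for k = 1).
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @param covariance Optional k x k covariance matrix of the
#'   `-2 * log(p)` statistics (off-diagonal entries are used); `NULL` means
#'   independence (Fisher).
#' @return Combined p-value in (0, 1].
#' @export
brown_combine <- function(p_values, covariance = NULL) {
  k <- length(p_values)
  if (k == 0) stopf("no p-values to combine")
  if (any(p_values <= 0)) {
    stopf("p-value of 0 is not combinable; use the smallest representable positive value")
  }
  if (any(p_values > 1)) stopf("p-values must lie in (0, 1]")
  tstat <- -2 * sum(log(p_values))
  e <- 2 * k
  v <- 4 * k
  if (!is.null(covariance) && k > 1) {
    cv <- as.matrix(covariance)
    if (!all(dim(cv) == k)) stopf("covariance must be %d x %d", k, k)
    v <- v + 2 * sum(cv[upper.tri(cv)])
    v <- max(v, 1e-8)
  }
  f <- 2 * e^2 / v
  cc <- v / (2 * e)
  pchisq(tstat / cc, df = f, lower.tail = FALSE)
}

# Brown covariance of (-2 log p_ctd, -2 log p_dm) from a model's reference
# score table; NULL (Fisher fallback) below 10 reference scores.
brown_covariance <- function(model) {
  tbl <- model$reference_score_table
  if (is.null(tbl) || nrow(tbl) < 10) return(NULL)
  q <- cbind(-2 * log(pmax(tbl$p_ctd, 1e-300)),
             -2 * log(pmax(tbl$p_dm, 1e-300)))
  cov(q)
}

#' Score one sample against one disease model
#'
#' Computes the three network-quantified predictors: `p_ctd`, the CTD
#' connectedness p-value of the sample's perturbation set in the disease
#' network (optimal-subset p); `d_dm`, the CTDdm distance to the main
#' disease module, converted to the left-tail percentile `p_dm` against
#' the model's reference null; and `p_combined`, Brown's combination of
#' `p_ctd` and `p_dm` calibrated on the model's reference score table
#' (Fisher when fewer than 10 reference scores exist).
#'
#' @param sample A `perturbation_set`.
#' @param model A [disease_model()].
#' @param threshold Diffusion truncation mass.
#' @return One-row tibble: `sample_id`, `disease_label`, `p_ctd`, `d_dm`,
#'   `p_dm`, `p_combined`, `scoreable`, and `detected_module` (list column
#'   holding the optimal subset with the sample's z-values).
#' @export
score_sample <- function(sample, model, threshold = 1e-4) {
  overlap <- intersect(as_node_set(sample), model$network$nodes)
  if (length(overlap) == 0 || length(model$reference_dm_null) == 0) {
    return(tibble::tibble(
      sample_id = sample$sample_id, disease_label = model$disease_label,
      p_ctd = NA_real_, d_dm = NA_real_, p_dm = NA_real_,
      p_combined = NA_real_, scoreable = FALSE,
      detected_module = list(tibble::tibble(node = character(),
                                            z = numeric()))))
  }
  res <- ctd_pvalue(model$network, sample, threshold)
  d <- as.numeric(ctd_dm(model$network, sample, model$module, threshold))
  p_dm <- empirical_percentile(d, model$reference_dm_null)
  p_comb <- brown_combine(c(res$p_value, p_dm), brown_covariance(model))
  zv <- sample$z_values[res$optimal_subset]
  tibble::tibble(
    sample_id = sample$sample_id, disease_label = model$disease_label,
    p_ctd = res$p_value, d_dm = d, p_dm = p_dm, p_combined = p_comb,
    scoreable = TRUE,
    detected_module = list(tibble::tibble(node = res$optimal_subset,
                                          z = unname(zv))))
}

#' Score one sample against a panel of disease models
#'
#' @param sample A `perturbation_set`.
#' @param models List of [disease_model()]s.
#' @param threshold Diffusion truncation mass.
#' @return Tibble with one row per model (see [score_sample()]).
#' @export
score_sample_panel <- function(sample, models, threshold = 1e-4) {
  dplyr::bind_rows(lapply(models, function(m) {
    score_sample(sample, m, threshold)
  }))
}

#' Rank diseases and build the differential-diagnosis list
#'
#' Ranks scoreable diseases by ascending combined p-value (ties broken by
#' disease label) and flags the differential diagnosis (DD) list: diseases
#' whose combined p-value clears `alpha / n_models` (Bonferroni) or plain
#' `alpha`. Each disease also receives a HIT / BORDERLINE / NONE call
#' (see [classify_hit()]).
#'
#' @param scores Tibble of per-disease scores for one sample
#'   ([score_sample_panel()] output).
#' @param n_models Number of disease models tested (Bonferroni divisor).
#' @param alpha Significance level. Default 0.05.
#' @param bonferroni Apply the Bonferroni correction to DD membership.
#'   Default `TRUE`.
#' @return A `diagnosis_report`: tibble of ranked scoreable diseases with
#'   `rank`, `in_dd` and `hit_call` columns; attributes `dd_threshold`,
#'   `n_models`, `unscoreable` (labels of skipped diseases).
#' @export
rank_and_dd <- function(scores, n_models = nrow(scores), alpha = 0.05,
                        bonferroni = TRUE) {
  if (nrow(scores) == 0) stopf("no scores to rank")
  scoreable <- scores[scores$scoreable, , drop = FALSE]
  if (nrow(scoreable) == 0) stopf("no scoreable disease for this sample")
  thr <- if (bonferroni) alpha / n_models else alpha
  out <- scoreable |>
    dplyr::arrange(.data$p_combined, .data$disease_label) |>
    dplyr::mutate(rank = dplyr::row_number(),
                  in_dd = .data$p_combined < thr,
                  hit_call = classify_hit(.data$p_combined))
  structure(out, class = c("diagnosis_report", class(out)),
            dd_threshold = thr, n_models = n_models,
            unscoreable = scores$disease_label[!scores$scoreable])
}

#' HIT / BORDERLINE calls from a combined network p-value
#'
#' `p < 0.05` is a HIT (functional evidence supporting pathogenicity),
#' `0.05 <= p < 0.15` a BORDERLINE hit, anything else NONE. Vectorized.
#'
#' @param p_combined Combined p-value(s) in (0, 1].
#' @return Character vector of `"HIT"`, `"BORDERLINE"`, `"NONE"`.
#' @export
classify_hit <- function(p_combined) {
  dplyr::case_when(p_combined < 0.05 ~ "HIT",
                   p_combined < 0.15 ~ "BORDERLINE",
                   TRUE ~ "NONE")
}

#' Classify variant evidence from pathogenicity and zygosity counts
#'
#' Assigns an individual, for one disease gene under autosomal recessive
#' inheritance, to one of five classes: 1 (disease case: >= 2 heterozygous
#' pathogenic or >= 1 homozygous pathogenic), 2 (at least a carrier: 1
#' heterozygous pathogenic and >= 1 heterozygous VUS), 3 (uncertain: >= 1
#' homozygous VUS or >= 2 heterozygous VUS), 4 (potential carrier: exactly
#' 1 heterozygous VUS), 5 (control: all variants benign). Rules are
#' evaluated in that order; anything else is `"unclassified"`.
#'
#' @param n_het_pathogenic,n_hom_pathogenic,n_het_vus,n_hom_vus Counts of
#'   variants by ACMG class and zygosity.
#' @param all_benign `TRUE` when every observed variant is benign.
#' @return Class label: `"1"`..`"5"` or `"unclassified"`.
#' @export
classify_variant_evidence <- function(n_het_pathogenic, n_hom_pathogenic,
                                      n_het_vus, n_hom_vus,
                                      all_benign = FALSE) {
  stopifnot(n_het_pathogenic >= 0, n_hom_pathogenic >= 0,
            n_het_vus >= 0, n_hom_vus >= 0)
  if (n_het_pathogenic >= 2 || n_hom_pathogenic >= 1) return("1")
  if (n_het_pathogenic == 1 && n_het_vus >= 1) return("2")
  if (n_hom_vus >= 1 || n_het_vus >= 2) return("3")
  if (n_het_vus == 1) return("4")
  if (isTRUE(all_benign)) return("5")
  "unclassified"
}

#' Cohort-level accuracy metrics of the diagnostic ranking
#'
#' Given per-sample score tables for a labeled cohort, computes the
#' top-1 / top-3 / in-DD fractions over disease samples, the distribution
#' of DD lengths (median, 5th and 95th percentiles), per-disease
#' sensitivity / specificity / accuracy from HIT calls, and, separately,
#' the median DD length over reference samples (a specificity proxy:
#' healthy samples should match nothing).
#'
#' @param reports Named list of `diagnosis_report`s (one per sample).
#' @param truth Tibble with `sample_id` and `diagnosis_label`
#'   (`NA`/`"reference"` for reference samples).
#' @return List with `summary` (one-row tibble), `per_disease` (tibble),
#'   and `dd_lengths` (per-sample tibble).
#' @export
evaluate_cohort <- function(reports, truth) {
  stopifnot(length(reports) > 0)
  ids <- names(reports)
  truth_of <- stats::setNames(truth$diagnosis_label, truth$sample_id)
  rows <- dplyr::bind_rows(lapply(ids, function(sid) {
    r <- reports[[sid]]
    lab <- truth_of[[sid]] %||% NA_character_
    is_ref <- is.na(lab) || lab == "reference"
    hit_rank <- if (!is_ref && lab %in% r$disease_label) {
      r$rank[r$disease_label == lab]
    } else NA_integer_
    in_dd <- if (!is_ref && lab %in% r$disease_label) {
      r$in_dd[r$disease_label == lab]
    } else NA
    tibble::tibble(sample_id = sid, truth = lab, is_reference = is_ref,
                   truth_rank = hit_rank, truth_in_dd = in_dd,
                   dd_length = sum(r$in_dd),
                   modeled = is_ref || lab %in% r$disease_label)
  }))
  skipped <- rows$sample_id[!rows$modeled]
  if (length(skipped) > 0) {
    warnf("skipping %d sample(s) whose diagnosis is not modeled: %s",
          length(skipped), paste(head(skipped, 3), collapse = ", "))
  }
  dis <- rows[!rows$is_reference & rows$modeled, , drop = FALSE]
  ref <- rows[rows$is_reference, , drop = FALSE]
  summary <- tibble::tibble(
    n_disease_samples = nrow(dis),
    n_reference_samples = nrow(ref),
    top1 = if (nrow(dis) > 0) mean(dis$truth_rank == 1) else NA_real_,
    top3 = if (nrow(dis) > 0) mean(dis$truth_rank <= 3) else NA_real_,
    in_dd = if (nrow(dis) > 0) mean(dis$truth_in_dd) else NA_real_,
    dd_length_median = if (nrow(dis) > 0) median(dis$dd_length) else NA_real_,
    dd_length_q05 = if (nrow(dis) > 0)
      unname(quantile(dis$dd_length, 0.05)) else NA_real_,
    dd_length_q95 = if (nrow(dis) > 0)
      unname(quantile(dis$dd_length, 0.95)) else NA_real_,
    reference_dd_median = if (nrow(ref) > 0) median(ref$dd_length) else NA_real_
  )
  diseases <- lex_sort(unique(unlist(lapply(reports, function(r) {
    r$disease_label
  }))))
  per_disease <- dplyr::bind_rows(lapply(diseases, function(dl) {
    calls <- vapply(ids, function(sid) {
      r <- reports[[sid]]
      if (dl %in% r$disease_label) r$hit_call[r$disease_label == dl] else NA_character_
    }, character(1))
    is_case <- !is.na(truth_of[ids]) & truth_of[ids] == dl
    pred_pos <- !is.na(calls) & calls == "HIT"
    usable <- !is.na(calls) & rows$modeled
    tp <- sum(pred_pos & is_case & usable)
    fn <- sum(!pred_pos & is_case & usable)
    fp <- sum(pred_pos & !is_case & usable)
    tn <- sum(!pred_pos & !is_case & usable)
    tibble::tibble(disease_label = dl, tp = tp, fn = fn, fp = fp, tn = tn,
                   sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
                   specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
                   accuracy = if (tp + fn + fp + tn > 0)
                     (tp + tn) / (tp + fn + fp + tn) else NA_real_)
  }))
  list(summary = summary, per_disease = per_disease, dd_lengths = rows)
}

#' @export
glance.diagnosis_report <- function(x, ...) {
  tibble::tibble(n_ranked = nrow(x),
                 dd_length = sum(x$in_dd),
                 dd_threshold = attr(x, "dd_threshold"),
                 n_models = attr(x, "n_models"),
                 top_disease = x$disease_label[x$rank == 1],
                 top_p_combined = x$p_combined[x$rank == 1])
}

#' Write/read a diagnosis report
#'
#' The TSV carries one row per (sample, disease) with the scores, rank, DD
#' membership and HIT call; a JSON sidecar (`<path>.json`) holds the
#' detected modules with their sample z-values and the DD threshold.
#'
#' @param report A `diagnosis_report`.
#' @param path TSV path.
#' @export
write_diagnosis_report <- function(report, path) {
  flat <- dplyr::select(as_tibble(report), -"detected_module")
  readr::write_tsv(flat, path, progress = FALSE)
  detail <- list(
    dd_threshold = attr(report, "dd_threshold"),
    n_models = attr(report, "n_models"),
    unscoreable = as.list(attr(report, "unscoreable") %||% character()),
    detected_modules = stats::setNames(
      lapply(seq_len(nrow(report)), function(i) {
        m <- report$detected_module[[i]]
        list(nodes = as.list(m$node), z = as.list(m$z))
      }), report$disease_label))
  jsonlite::write_json(detail, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_diagnosis_report
#' @export
read_diagnosis_report <- function(path) {
  flat <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    disease_label = readr::col_character(),
    scoreable = readr::col_logical(), in_dd = readr::col_logical(),
    hit_call = readr::col_character(), rank = readr::col_integer(),
    .default = readr::col_double()), progress = FALSE)
  detail <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = FALSE)
  flat$detected_module <- lapply(flat$disease_label, function(dl) {
    m <- detail$detected_modules[[dl]]
    tibble::tibble(node = unlist(m$nodes) %||% character(),
                   z = unlist(m$z) %||% numeric())
  })
  structure(flat, class = c("diagnosis_report", class(flat)),
            dd_threshold = detail$dd_threshold,
            n_models = detail$n_models,
            unscoreable = unlist(detail$unscoreable) %||% character())
}
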