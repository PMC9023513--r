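#' Joint information content of two node sets
#'
#' `I(S1, S2)` is the information content of the union encoding: both sets
#' are compressed together by a single adaptive walk, so sets occupying the
#' same network neighbourhood cost barely more together than alone.
#'
#' @param network A [copnet()].
#' @param s1,s2 Node sets (character vectors or `perturbation_set`s).
#' @param threshold Diffusion truncation mass.
#' @return Bits (numeric scalar).
#' @export
joint_information <- function(network, s1, s2, threshold = 1e-4) {
  u <- union(intersect(as_node_set(s1), network$nodes),
             intersect(as_node_set(s2), network$nodes))
  if (length(u) == 0) stopf("both sets empty after network intersection")
  information_content(network, u, threshold)$bits
}

#' CTDncd: normalized compression distance between two node sets
#'
#' `CTDncd(S1, S2) = max(I(S1,S2) - I(S1), I(S1,S2) - I(S2)) /
#' max(I(S1), I(S2))`, with `I` the adaptive-walk information content and
#' `I(S1,S2)` the union encoding. Identical sets are at distance 0; sets in
#' distal network regions approach 1. The value is clipped to [0, 1]; the
#' pre-clip value and the three information terms are attached as
#' attributes (`pre_clip`, `i1`, `i2`, `i12`).
#'
#' @inheritParams joint_information
#' @return Numeric distance in [0, 1].
#' @export
ctd_ncd <- function(network, s1, s2, threshold = 1e-4) {
  n1 <- intersect(as_node_set(s1), network$nodes)
  n2 <- intersect(as_node_set(s2), network$nodes)
  if (length(n1) == 0 || length(n2) == 0) {
    stopf("empty node set after network intersection")
  }
  i1 <- information_content(network, n1, threshold)$bits
  i2 <- information_content(network, n2, threshold)$bits
  i12 <- if (setequal(n1, n2)) i1 else {
    information_content(network, union(n1, n2), threshold)$bits
  }
  raw <- max(i12 - i1, i12 - i2) / max(i1, i2)
  structure(min(1, max(0, raw)), pre_clip = raw, i1 = i1, i2 = i2, i12 = i12)
}

#' Main disease module of a network
#'
#' The representative, highly connected perturbed subset characterizing a
#' disease: (i) candidate nodes are the network nodes perturbed
#' (|z| >= `z_threshold`, or binary presence) in strictly more than half of
#' the disease cohort; (ii) the CTD optimal subset of the candidates is the
#' module. If no candidate recurs in enough samples, the fallback is the
#' top 10 network nodes by median |z| across the cohort.
#'
#' @param network A [copnet()].
#' @param disease_profiles `profile_matrix` of the disease cohort (>= 2
#'   samples).
#' @param disease_label Label stored in the module.
#' @param config A [network_config()] (supplies `z_threshold`).
#' @return A `disease_module`: `disease_label`, `nodes`, `source`
#'   (`"algorithm1_surrogate"` or `"user_supplied"`).
#' @export
main_disease_module <- function(network, disease_profiles,
                                disease_label = "disease",
                                config = network_config()) {
  if (ncol(disease_profiles$z) < 2) stopf("need at least 2 disease profiles")
  meas <- intersect(network$nodes, rownames(disease_profiles$z))
  if (length(meas) == 0) stopf("no network nodes measured in the cohort")
  z <- disease_profiles$z[meas, , drop = FALSE]
  is_bin <- meas %in% disease_profiles$binary_analytes
  pert <- abs(z) >= config$z_threshold
  pert[is_bin, ] <- !is.na(z[is_bin, , drop = FALSE]) &
    z[is_bin, , drop = FALSE] == 1
  pert[is.na(pert)] <- FALSE
  recur <- rowMeans(pert) > 0.5
  candidates <- meas[recur]
  if (length(candidates) > 0) {
    module <- ctd_pvalue(network, candidates)$optimal_subset
  } else {
    med <- apply(abs(z), 1, median, na.rm = TRUE)
    med[is.na(med)] <- 0
    ord <- order(-med, meas, method = "radix")
    module <- lex_sort(meas[ord][seq_len(min(10, length(meas)))])
  }
  disease_module(disease_label, module, source = "algorithm1_surrogate")
}

#' @rdname main_disease_module
#' @param nodes Module node ids (for user-supplied modules).
#' @param source Module provenance tag.
#' @export
disease_module <- function(disease_label, nodes, source = "user_supplied") {
  nodes <- lex_sort(unique(as.character(nodes)))
  if (length(nodes) == 0) stopf("empty disease module")
  structure(list(disease_label = disease_label, nodes = nodes,
                 source = source),
            class = "disease_module")
}

#' @export
print.disease_module <- function(x, ...) {
  cat(sprintf("<disease_module> %s: %d nodes (%s)\n", x$disease_label,
              length(x$nodes), x$source))
  invisible(x)
}

#' Read/write a disease module as JSON
#'
#' @param module A `disease_module`.
#' @param path JSON path.
#' @export
write_disease_module <- function(module, path) {
  jsonlite::write_json(list(disease_label = module$disease_label,
                            nodes = as.list(module$nodes),
                            source = module$source),
                       path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_disease_module
#' @export
read_disease_module <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  disease_module(m$disease_label, m$nodes, m$source)
}

#' CTDdm: distance between a patient and a disease state
#'
#' The CTDncd distance between an individual's perturbation set and the
#' main disease module of a disease-specific network.
#'
#' @param network A [copnet()].
#' @param patient_set The patient's `perturbation_set` (or node ids).
#' @param module A `disease_module`.
#' @param threshold Diffusion truncation mass.
#' @return Numeric distance in [0, 1] (attributes as [ctd_ncd()]).
#' @export
ctd_dm <- function(network, patient_set, module, threshold = 1e-4) {
  nodes <- if (inherits(module, "disease_module")) module$nodes else
    as_node_set(module)
  ctd_ncd(network, patient_set, nodes, threshold)
}

#' Add-one empirical left-tail percentile
#'
#' Position of a distance within a reference distribution:
#' `(#{reference <= value} + 1) / (n + 1)`. Used to convert a CTDdm
#' distance into the left-tail p-value `p_dm` (small distance =
#' disease-like = small p).
#'
#' @param value Observed distance.
#' @param reference_values Nonempty numeric vector of reference distances.
#' @return Fraction in (0, 1].
#' @export
empirical_percentile <- function(value, reference_values) {
  if (length(reference_values) == 0) stopf("empty reference distribution")
  (sum(reference_values <= value) + 1) / (length(reference_values) + 1)
}

#' Pairwise CTDncd distance matrix
#'
#' @param network A [copnet()].
#' @param sets List of `perturbation_set`s (or node-id vectors); names or
#'   sample ids label the rows.
#' @param threshold Diffusion truncation mass.
#' @return A `dist_matrix`: list with `ids` and the symmetric matrix `d`
#'   (zero diagonal; each pair computed once).
#' @export
pairwise_distance_matrix <- function(network, sets, threshold = 1e-4) {
  if (length(sets) < 2) stopf("need at least 2 sets")
  ids <- names(sets) %||% vapply(sets, function(s) {
    if (inherits(s, "perturbation_set")) s$sample_id else NA_character_
  }, character(1))
  if (anyNA(ids) || is.null(ids)) ids <- sprintf("S%03d", seq_along(sets))
  for (i in seq_along(sets)) {
    if (length(intersect(as_node_set(sets[[i]]), network$nodes)) == 0) {
      stopf("sample %s has no nodes in the network", ids[i])
    }
  }
  m <- length(sets)
  nodes <- lapply(sets, function(s) {
    lex_sort(intersect(as_node_set(s), network$nodes))
  })
  # marginal encodings computed once per sample, unions once per pair
  marg <- vapply(nodes, function(s) {
    information_content(network, s, threshold)$bits
  }, numeric(1))
  d <- matrix(0, m, m, dimnames = list(ids, ids))
  for (i in seq_len(m - 1)) {
    for (j in seq(i + 1, m)) {
      if (setequal(nodes[[i]], nodes[[j]])) next
      i12 <- information_content(network, union(nodes[[i]], nodes[[j]]),
                                 threshold)$bits
      raw <- max(i12 - marg[i], i12 - marg[j]) / max(marg[i], marg[j])
      v <- min(1, max(0, raw))
      d[i, j] <- v
      d[j, i] <- v
    }
  }
  structure(list(ids = ids, d = d), class = "dist_matrix")
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat(sprintf("<dist_matrix> %d samples\n", length(x$ids)))
  invisible(x)
}

#' @export
tidy.dist_matrix <- function(x, ...) {
  as.data.frame.table(x$d, responseName = "distance") |>
    tibble::as_tibble() |>
    dplyr::rename(sample_a = "Var1", sample_b = "Var2") |>
    dplyr::mutate(dplyr::across(c("sample_a", "sample_b"), as.character))
}

#' Read/write a distance matrix as square TSV
#'
#' @param x A `dist_matrix`.
#' @param path TSV path (header row of ids, first column id).
#' @export
write_distance_matrix <- function(x, path) {
  out <- cbind(sample_id = x$ids,
               as.data.frame(format(x$d, digits = 17, trim = TRUE,
                                    scientific = FALSE)))
  colnames(out) <- c("sample_id", x$ids)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(), .default = readr::col_double()),
    progress = FALSE)
  d <- as.matrix(tbl[, -1])
  dimnames(d) <- list(tbl$sample_id, colnames(tbl)[-1])
  structure(list(ids = tbl$sample_id, d = d), class = "dist_matrix")
}
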