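#' Z-scored metabolomics profile matrices
#'
#' A `profile_matrix` holds a metabolites x samples matrix of z-scores
#' (analyte abundance in reference-population standard deviations), a
#' missingness mask, and the set of binary-presence analytes. Binary
#' analytes (e.g. argininosuccinate, which cannot be z-scored because it is
#' absent from normal reference blood) carry 0/1 presence flags instead of
#' z-scores.
#'
#' @param z Numeric matrix, metabolites in rows (rownames = metabolite ids),
#'   samples in columns (colnames = sample ids). `NA` marks a missing
#'   measurement.
#' @param binary_analytes Character vector of metabolite ids whose rows are
#'   0/1 presence flags.
#' @return An object of class `profile_matrix`.
#' @export
profile_matrix <- function(z, binary_analytes = character()) {
  if (!is.matrix(z) || !is.numeric(z)) stopf("`z` must be a numeric matrix")
  if (nrow(z) > 0 && is.null(rownames(z))) {
    stopf("`z` needs metabolite rownames")
  }
  if (ncol(z) > 0 && is.null(colnames(z))) {
    stopf("`z` needs sample colnames")
  }
  if (is.null(rownames(z))) rownames(z) <- character(0)
  if (is.null(colnames(z))) colnames(z) <- character(0)
  if (anyDuplicated(rownames(z))) {
    stopf("duplicate metabolite id: %s",
          rownames(z)[duplicated(rownames(z))][1])
  }
  if (anyDuplicated(colnames(z))) {
    stopf("duplicate sample id: %s", colnames(z)[duplicated(colnames(z))][1])
  }
  bad <- setdiff(binary_analytes, rownames(z))
  if (length(bad) > 0) stopf("unknown binary analyte: %s", bad[1])
  for (b in binary_analytes) {
    v <- z[b, ]
    v <- v[!is.na(v)]
    if (length(v) > 0 && !all(v %in% c(0, 1))) {
      stopf("binary analyte %s has values outside {0,1}", b)
    }
  }
  structure(list(z = z, binary_analytes = binary_analytes),
            class = "profile_matrix")
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat(sprintf("<profile_matrix> %d metabolites x %d samples (%d binary, %.1f%% missing)\n",
              nrow(x$z), ncol(x$z), length(x$binary_analytes),
              100 * mean(is.na(x$z))))
  invisible(x)
}

#' @rdname profile_matrix
#' @param x A `profile_matrix`.
#' @export
metabolite_ids <- function(x) rownames(x$z)

#' @rdname profile_matrix
#' @export
sample_ids <- function(x) colnames(x$z)

#' @rdname profile_matrix
#' @export
missing_mask <- function(x) is.na(x$z)

#' @rdname profile_matrix
#' @export
n_samples <- function(x) ncol(x$z)

#' Subset the samples of a profile matrix
#'
#' @param x A `profile_matrix`.
#' @param samples Character vector of sample ids (order preserved).
#' @return A `profile_matrix` restricted to `samples`.
#' @export
select_samples <- function(x, samples) {
  missing <- setdiff(samples, colnames(x$z))
  if (length(missing) > 0) stopf("unknown sample id: %s", missing[1])
  profile_matrix(x$z[, samples, drop = FALSE], x$binary_analytes)
}

#' Combine two profile matrices sample-wise
#'
#' Both matrices must cover the same metabolites; columns are concatenated.
#'
#' @param a,b `profile_matrix` objects over the same metabolite namespace.
#' @return A `profile_matrix` with the samples of `a` followed by `b`.
#' @export
bind_samples <- function(a, b) {
  if (!identical(rownames(a$z), rownames(b$z))) {
    b_z <- b$z[rownames(a$z), , drop = FALSE]
  } else {
    b_z <- b$z
  }
  profile_matrix(cbind(a$z, b_z),
                 union(a$binary_analytes, b$binary_analytes))
}

#' Read a z-scored profile matrix (and optional sample metadata)
#'
#' The profile file is TSV or CSV (decided by extension): a header row of
#' sample ids, first column the metabolite id, blank or `NA` cells are
#' missing measurements. Metadata is a TSV with columns `sample_id`,
#' `role` (`disease`, `reference` or `surrogate`), `diagnosis_label`,
#' `treatment_flags` (semicolon-joined) and optionally `age_group`.
#'
#' @param path Path to the profile table.
#' @param metadata_path Optional path to the sample metadata TSV.
#' @param binary_analytes Character vector of metabolite ids to treat as
#'   0/1 presence flags.
#' @return A `profile_matrix`; if `metadata_path` is given, a list with
#'   elements `profiles` and `metadata` (a tibble).
#' @export
read_profiles <- function(path, metadata_path = NULL,
                          binary_analytes = character()) {
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tbl <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE,
    na = character())
  if (nrow(tbl) == 0 || ncol(tbl) < 2) stopf("no metabolites in %s", path)
  ids <- tbl[[1]]
  if (anyDuplicated(ids)) {
    stopf("duplicate metabolite id: %s", ids[duplicated(ids)][1])
  }
  cells <- as.matrix(tbl[, -1, drop = FALSE])
  cells[cells == "" | cells == "NA"] <- NA_character_
  suppressWarnings(num <- array(as.numeric(cells), dim = dim(cells)))
  bad <- which(is.na(num) & !is.na(cells), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stopf("non-numeric cell '%s' at row %d (metabolite %s), column %d (sample %s)",
          cells[bad[1, 1], bad[1, 2]], bad[1, 1], ids[bad[1, 1]],
          bad[1, 2], colnames(tbl)[-1][bad[1, 2]])
  }
  dimnames(num) <- list(ids, colnames(tbl)[-1])
  pm <- profile_matrix(num, binary_analytes)
  if (is.null(metadata_path)) return(pm)
  list(profiles = pm, metadata = read_sample_metadata(metadata_path))
}

#' Write a profile matrix to TSV/CSV
#'
#' Missing cells are written as empty fields; finite values round-trip
#' bit-identically through [read_profiles()] (full double precision).
#'
#' @param x A `profile_matrix`.
#' @param path Output path; `.csv` selects comma separation, anything else
#'   tab separation.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(x, path) {
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  chr <- array(NA_character_, dim = dim(x$z))
  ok <- !is.na(x$z)
  chr[ok] <- format(x$z[ok], digits = 17, trim = TRUE, scientific = FALSE)
  chr[is.na(x$z)] <- ""
  out <- cbind(metabolite = rownames(x$z), as.data.frame(chr))
  colnames(out) <- c("metabolite", colnames(x$z))
  readr::write_delim(out, path, delim = delim, na = "", progress = FALSE)
  invisible(path)
}

#' @rdname read_profiles
#' @export
read_sample_metadata <- function(metadata_path) {
  md <- readr::read_tsv(metadata_path, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  req <- c("sample_id", "role")
  miss <- setdiff(req, names(md))
  if (length(miss) > 0) stopf("metadata lacks column %s", miss[1])
  if (!"diagnosis_label" %in% names(md)) md$diagnosis_label <- NA_character_
  if (!"treatment_flags" %in% names(md)) md$treatment_flags <- ""
  if (!"age_group" %in% names(md)) md$age_group <- NA_character_
  validate_sample_metadata(tibble::as_tibble(md))
}

#' @rdname read_profiles
#' @param metadata Sample metadata tibble.
#' @export
write_sample_metadata <- function(metadata, metadata_path) {
  readr::write_tsv(metadata, metadata_path, na = "", progress = FALSE)
  invisible(metadata_path)
}

validate_sample_metadata <- function(md) {
  ok_roles <- c("disease", "reference", "surrogate")
  bad <- setdiff(unique(md$role), ok_roles)
  if (length(bad) > 0) stopf("unknown role '%s'", bad[1])
  no_label <- md$role == "disease" &
    (is.na(md$diagnosis_label) | md$diagnosis_label == "")
  if (any(no_label)) {
    stopf("disease sample %s lacks a diagnosis_label",
          md$sample_id[no_label][1])
  }
  md
}

#' Presence filter for network learning
#'
#' Keeps the metabolites observed (non-missing) in strictly more than
#' `min_frac` of reference samples AND strictly more than `min_frac` of
#' disease samples. Only metabolites present in both matrices are
#' considered.
#'
#' @param disease,reference `profile_matrix` cohorts sharing a metabolite
#'   namespace.
#' @param min_frac Fraction of samples that must carry an observation
#'   (strict inequality). Default 0.5.
#' @return Character vector of retained metabolite ids (input row order).
#' @export
filter_by_presence <- function(disease, reference, min_frac = 0.5) {
  if (ncol(disease$z) == 0) stopf("empty disease cohort")
  if (ncol(reference$z) == 0) stopf("empty reference cohort")
  shared <- intersect(rownames(disease$z), rownames(reference$z))
  frac_d <- rowMeans(!is.na(disease$z[shared, , drop = FALSE]))
  frac_r <- rowMeans(!is.na(reference$z[shared, , drop = FALSE]))
  shared[frac_d > min_frac & frac_r > min_frac]
}

#' Minimum-z imputation of missing measurements
#'
#' Each missing z-score is replaced by the minimum observed z-score of that
#' analyte across the reference cohort (missing binary analytes become 0,
#' i.e. absent). Observed cells are untouched, so the operation is
#' idempotent.
#'
#' @param m `profile_matrix` to impute.
#' @param reference Reference cohort supplying the per-analyte minima
#'   (may be `m` itself).
#' @return The imputed `profile_matrix`.
#' @export
impute_missing <- function(m, reference) {
  need <- rownames(m$z)[rowSums(is.na(m$z)) > 0]
  if (length(need) == 0) return(m)
  z <- m$z
  nonbin <- setdiff(need, m$binary_analytes)
  if (length(nonbin) > 0) {
    ref_rows <- intersect(nonbin, rownames(reference$z))
    n_obs <- rowSums(!is.na(reference$z[ref_rows, , drop = FALSE]))
    missing_ref <- union(setdiff(nonbin, rownames(reference$z)),
                         ref_rows[n_obs == 0])
    if (length(missing_ref) > 0) {
      stopf("no reference observations for analyte(s): %s",
            paste(missing_ref, collapse = ", "))
    }
    mins <- apply(reference$z[nonbin, , drop = FALSE], 1, min, na.rm = TRUE)
    for (a in nonbin) {
      z[a, is.na(z[a, ])] <- mins[[a]]
    }
  }
  for (a in intersect(need, m$binary_analytes)) {
    z[a, is.na(z[a, ])] <- 0
  }
  profile_matrix(z, m$binary_analytes)
}

#' Extract a sample's perturbation set
#'
#' Collects the metabolites of one sample whose |z| meets the abnormality
#' threshold (conventionally 2 reference standard deviations), restricted to
#' the node universe of the network the set will be scored against. Binary
#' analytes present in the sample (value 1) always qualify and rank above
#' any z-scored analyte. If more than `max_set_size` qualify, the
#' `max_set_size` largest by |z| are kept (ties broken by metabolite id).
#'
#' @param profiles A `profile_matrix`.
#' @param sample_id Sample (column) to extract.
#' @param node_universe Character vector of admissible metabolite ids
#'   (normally the nodes of a co-perturbation network plus binary analytes).
#' @param z_threshold Minimum |z| to call a perturbation. Default 2.
#' @param max_set_size Cap on the set size. Default 30.
#' @return A `perturbation_set`: list with `sample_id`, `nodes` (sorted
#'   ids) and `z_values` (named numeric).
#' @export
extract_perturbations <- function(profiles, sample_id, node_universe,
                                  z_threshold = 2, max_set_size = 30) {
  if (length(node_universe) == 0) stopf("empty node universe")
  if (!sample_id %in% colnames(profiles$z)) {
    stopf("unknown sample id: %s", sample_id)
  }
  v <- profiles$z[, sample_id]
  cand <- intersect(rownames(profiles$z), node_universe)
  is_bin <- cand %in% profiles$binary_analytes
  val <- v[cand]
  keep <- !is.na(val) &
    ((is_bin & val == 1) | (!is_bin & abs(val) >= z_threshold))
  nodes <- cand[keep]
  rank_mag <- ifelse(nodes %in% profiles$binary_analytes, Inf,
                     abs(val[nodes]))
  if (length(nodes) > max_set_size) {
    ord <- order(-rank_mag, nodes, method = "radix")
    nodes <- nodes[ord][seq_len(max_set_size)]
  }
  nodes <- lex_sort(nodes)
  structure(list(sample_id = sample_id, nodes = nodes,
                 z_values = v[nodes]),
            class = "perturbation_set")
}

#' @export
print.perturbation_set <- function(x, ...) {
  cat(sprintf("<perturbation_set> sample %s: %d nodes\n", x$sample_id,
              length(x$nodes)))
  invisible(x)
}

# Coerce character vectors / perturbation sets to a plain node id vector.
as_node_set <- function(s) {
  if (inherits(s, "perturbation_set")) s$nodes else as.character(s)
}
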