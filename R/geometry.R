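#' Classical multidimensional scaling of a distance matrix
#'
#' Torgerson MDS: the squared distances are double-centered
#' (`B = -1/2 * J D^2 J`), the top `dims` eigenpairs give the coordinates
#' `V * sqrt(lambda)` (negative eigenvalues truncated at zero). The
#' embedding is deterministic; the sign of each axis is fixed so that its
#' largest-magnitude loading is positive.
#'
#' @param d A `dist_matrix` (see [pairwise_distance_matrix()]) or a
#'   symmetric numeric matrix.
#' @param dims Number of embedding dimensions (< number of samples).
#'   Default 2.
#' @return A tibble with `sample_id` and columns `MDS1..MDSk`; the
#'   eigenvalues are attached as attribute `"eigenvalues"`.
#' @export
mds_embed <- function(d, dims = 2) {
  if (inherits(d, "dist_matrix")) {
    ids <- d$ids
    D <- d$d
  } else {
    D <- as.matrix(d)
    ids <- rownames(D) %||% sprintf("S%03d", seq_len(nrow(D)))
  }
  n <- nrow(D)
  if (dims >= n) stopf("dims must be smaller than the number of samples")
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (D^2) %*% J
  B <- (B + t(B)) / 2
  eg <- eigen(B, symmetric = TRUE)
  lam <- pmax(eg$values[seq_len(dims)], 0)
  coords <- eg$vectors[, seq_len(dims), drop = FALSE] %*%
    diag(sqrt(lam), dims)
  for (k in seq_len(dims)) {
    i <- which.max(abs(coords[, k]))
    if (coords[i, k] < 0) coords[, k] <- -coords[, k]
  }
  colnames(coords) <- paste0("MDS", seq_len(dims))
  out <- tibble::tibble(sample_id = ids, !!!as.data.frame(coords))
  attr(out, "eigenvalues") <- eg$values
  out
}

coords_matrix <- function(coords) {
  if (is.matrix(coords)) return(coords)
  m <- as.matrix(coords[, grep("^MDS", names(coords)), drop = FALSE])
  rownames(m) <- coords$sample_id
  m
}

#' K-means cluster purity of an embedding
#'
#' Runs k-means with `n_init` seeded restarts on the embedding coordinates
#' and reports cluster purity: each cluster votes for its majority class,
#' and purity is the fraction of samples matching their cluster's majority
#' class, `(1/N) * sum_c max_k |c ∩ k|`.
#'
#' @param coords Embedding tibble from [mds_embed()] (or a numeric
#'   matrix).
#' @param true_labels Class label per sample.
#' @param k Number of clusters (<= number of samples).
#' @param seed Integer seed for the restarts.
#' @param n_init Number of random restarts. Default 50.
#' @return Purity in (0, 1]; the k-means fit is attached as attribute
#'   `"kmeans"`.
#' @export
kmeans_purity <- function(coords, true_labels, k, seed = 1L, n_init = 50) {
  X <- coords_matrix(coords)
  if (k > nrow(X)) stopf("k = %d exceeds the number of samples (%d)", k, nrow(X))
  if (length(true_labels) != nrow(X)) stopf("one label per sample required")
  km <- with_seed(seed, kmeans(X, centers = k, nstart = n_init))
  purity <- sum(tapply(seq_along(true_labels), km$cluster, function(i) {
    max(table(true_labels[i]))
  })) / length(true_labels)
  structure(purity, kmeans = km)
}

#' Euclidean distance between two group centroids in an embedding
#'
#' @param coords Embedding tibble or coordinate matrix.
#' @param labels Group label per sample.
#' @param group_a,group_b The two groups to compare.
#' @return Euclidean distance between the group mean coordinates.
#' @export
centroid_distance <- function(coords, labels, group_a, group_b) {
  X <- coords_matrix(coords)
  for (g in c(group_a, group_b)) {
    if (!g %in% labels) stopf("unknown label: %s", g)
  }
  ca <- colMeans(X[labels == group_a, , drop = FALSE])
  cb <- colMeans(X[labels == group_b, , drop = FALSE])
  sqrt(sum((ca - cb)^2))
}

#' Plot an MDS embedding
#'
#' @param object Embedding tibble from [mds_embed()].
#' @param labels Optional class label per sample (colours the points).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_embedding <- function(object, labels = NULL, ...) {
  d <- object
  if (!is.null(labels)) d$label <- labels
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$MDS1, .data$MDS2))
  if (is.null(labels)) {
    p <- p + ggplot2::geom_point()
  } else {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$label)) +
      ggplot2::labs(colour = NULL)
  }
  p + ggplot2::coord_equal() + ggplot2::theme_minimal()
}
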