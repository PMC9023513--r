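#' Co-perturbation networks
#'
#' An undirected weighted graph over metabolites. Edge weights are partial
#' correlations (the correlation of two metabolites conditioned on all
#' others), so they live in [-1, 1]. Edges are stored canonically with
#' `node_a < node_b`; nodes are kept in lexicographic order for
#' deterministic downstream walks.
#'
#' @param nodes Character vector of metabolite ids.
#' @param edges Tibble/data frame with columns `node_a`, `node_b`,
#'   `weight`; may be empty.
#' @param provenance Named list of free-form provenance (condition label,
#'   selected lambdas, cohort sizes, seed, ...).
#' @return An object of class `copnet`.
#' @export
copnet <- function(nodes, edges = NULL, provenance = list()) {
  nodes <- lex_sort(unique(as.character(nodes)))
  if (is.null(edges) || nrow(edges) == 0) {
    edges <- tibble::tibble(node_a = character(), node_b = character(),
                            weight = numeric())
  } else {
    edges <- tibble::as_tibble(edges[, c("node_a", "node_b", "weight")])
    if (any(edges$node_a == edges$node_b)) stopf("self-edge not allowed")
    bad <- setdiff(c(edges$node_a, edges$node_b), nodes)
    if (length(bad) > 0) stopf("edge endpoint not in node set: %s", bad[1])
    if (any(abs(edges$weight) > 1 + 1e-9)) {
      stopf("edge weight outside [-1, 1]")
    }
    edges$weight <- pmin(1, pmax(-1, edges$weight))
    flip <- edges$node_a > edges$node_b
    tmp <- edges$node_a[flip]
    edges$node_a[flip] <- edges$node_b[flip]
    edges$node_b[flip] <- tmp
    edges <- dplyr::arrange(edges, .data$node_a, .data$node_b)
    key <- paste(edges$node_a, edges$node_b)
    if (anyDuplicated(key)) stopf("duplicate edge: %s", key[duplicated(key)][1])
  }
  structure(list(nodes = nodes, edges = edges, provenance = provenance),
            class = "copnet")
}

#' @export
print.copnet <- function(x, ...) {
  cat(sprintf("<copnet> %d nodes, %d edges", length(x$nodes), nrow(x$edges)))
  if (!is.null(x$provenance$condition_label)) {
    cat(sprintf(" [%s]", x$provenance$condition_label))
  }
  cat("\n")
  invisible(x)
}

#' @rdname copnet
#' @param x A `copnet`.
#' @export
n_edges <- function(x) nrow(x$edges)

edge_keys <- function(net) paste(net$edges$node_a, net$edges$node_b, sep = "\r")

#' Dense signed adjacency matrix of a network
#'
#' @param net A `copnet`.
#' @return Symmetric numeric matrix (nodes in lexicographic order).
#' @export
adjacency_matrix <- function(net) {
  n <- length(net$nodes)
  W <- matrix(0, n, n, dimnames = list(net$nodes, net$nodes))
  if (nrow(net$edges) > 0) {
    ia <- match(net$edges$node_a, net$nodes)
    ib <- match(net$edges$node_b, net$nodes)
    W[cbind(ia, ib)] <- net$edges$weight
    W[cbind(ib, ia)] <- net$edges$weight
  }
  W
}

#' Convert a precision matrix to a partial-correlation network
#'
#' The partial correlation of metabolites i and j given all others is
#' `-theta_ij / sqrt(theta_ii * theta_jj)`. Edges are created wherever the
#' precision entry is numerically nonzero (|theta_ij| > 1e-12).
#'
#' @param theta A `precision_matrix` (see [glasso_fit()]).
#' @param provenance Provenance list carried into the network.
#' @return A [copnet()].
#' @export
to_partial_correlation <- function(theta, provenance = list()) {
  th <- theta$theta
  d <- diag(th)
  if (any(d <= 0)) stopf("non-positive diagonal in precision matrix")
  ids <- theta$metabolite_ids
  p <- length(ids)
  idx <- which(upper.tri(th) & abs(th) > 1e-12, arr.ind = TRUE)
  if (nrow(idx) > 0) {
    w <- -th[idx] / sqrt(d[idx[, 1]] * d[idx[, 2]])
    edges <- tibble::tibble(node_a = ids[idx[, 1]], node_b = ids[idx[, 2]],
                            weight = w)
  } else {
    edges <- NULL
  }
  copnet(ids, edges, provenance)
}

#' Differential pruning of a network against a background network
#'
#' Removes from `target` every edge whose node pair also occurs in
#' `background`, regardless of weight sign or magnitude. This is how a
#' disease-specific network is obtained from the disease+control network
#' and the control-only network: shared (constitutive) co-perturbations are
#' stripped, leaving disease-state structure.
#'
#' @param target,background `copnet` objects over a shared node namespace.
#' @return A `copnet` with `target`'s nodes and the surviving edges.
#' @export
differential_prune <- function(target, background) {
  keep <- !(edge_keys(target) %in% edge_keys(background))
  prov <- target$provenance
  prov$pruned_against <- background$provenance$condition_label %||% "background"
  prov$n_edges_pruned <- sum(!keep)
  copnet(target$nodes, target$edges[keep, , drop = FALSE], prov)
}

#' Remove nodes (and incident edges) from a network
#'
#' Used to censor treatment-related metabolites from a disease-specific
#' network. Removing absent nodes is a no-op.
#'
#' @param network A `copnet`.
#' @param nodes_to_remove Character vector of node ids.
#' @return The induced subgraph on the remaining nodes.
#' @export
prune_nodes <- function(network, nodes_to_remove) {
  nodes_to_remove <- as_node_set(nodes_to_remove)
  keep_nodes <- setdiff(network$nodes, nodes_to_remove)
  keep <- !(network$edges$node_a %in% nodes_to_remove) &
    !(network$edges$node_b %in% nodes_to_remove)
  prov <- network$provenance
  prov$nodes_censored <- union(prov$nodes_censored,
                               intersect(network$nodes, nodes_to_remove))
  copnet(keep_nodes, network$edges[keep, , drop = FALSE], prov)
}

#' Connected components of a network
#'
#' @param network A `copnet`.
#' @return Integer vector of component labels named by node id; component 1
#'   is the largest (ties broken by smallest member id).
#' @export
graph_components <- function(network) {
  n <- length(network$nodes)
  comp <- integer(n)
  names(comp) <- network$nodes
  W <- adjacency_matrix(network) != 0
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      cur <- cur + 1L
      queue <- i
      comp[i] <- cur
      while (length(queue) > 0) {
        v <- queue[1]
        queue <- queue[-1]
        nb <- which(W[v, ] & comp == 0L)
        comp[nb] <- cur
        queue <- c(queue, nb)
      }
    }
  }
  sizes <- table(comp)
  relabel <- order(-as.integer(sizes), as.integer(names(sizes)))
  match(comp, as.integer(names(sizes))[relabel]) |>
    stats::setNames(network$nodes)
}

#' Read/write co-perturbation networks
#'
#' Networks are serialized as a TSV edge list (`node_a`, `node_b`,
#' `weight`) plus a JSON sidecar (`<path>.json`) holding the node list and
#' provenance. The loader accepts the edge list alone, in which case the
#' node set is implied by the edge endpoints.
#'
#' @param net A `copnet`.
#' @param path Path of the edge-list TSV.
#' @return `write_network()` returns `path` invisibly; `read_network()`
#'   returns a `copnet`.
#' @export
write_network <- function(net, path) {
  edges <- net$edges
  edges$weight <- format(edges$weight, digits = 17, trim = TRUE,
                         scientific = FALSE)
  readr::write_tsv(edges, path, progress = FALSE)
  sidecar <- list(nodes = as.list(net$nodes), provenance = net$provenance)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  edges <- readr::read_tsv(path, col_types = "ccd", progress = FALSE)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    nodes <- as.character(meta$nodes)
    prov <- if (is.null(meta$provenance)) list() else as.list(meta$provenance)
  } else {
    nodes <- union(edges$node_a, edges$node_b)
    prov <- list()
  }
  copnet(nodes, edges, prov)
}

#' @export
tidy.copnet <- function(x, ...) x$edges

#' @export
glance.copnet <- function(x, ...) {
  n <- length(x$nodes)
  tibble::tibble(
    n_nodes = n,
    n_edges = nrow(x$edges),
    density = if (n > 1) nrow(x$edges) / choose(n, 2) else 0,
    condition_label = x$provenance$condition_label %||% NA_character_,
    lambda_selected = x$provenance$lambda_selected %||% NA_real_
  )
}

#' Plot a co-perturbation network
#'
#' Circular layout; edge colour encodes the sign and opacity the magnitude
#' of the partial correlation.
#'
#' @param object A `copnet`.
#' @param label_nodes Draw node labels. Default `TRUE`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.copnet <- function(object, label_nodes = TRUE, ...) {
  n <- length(object$nodes)
  ang <- 2 * pi * (seq_len(n) - 1) / max(n, 1)
  pos <- tibble::tibble(node = object$nodes, x = cos(ang), y = sin(ang))
  ed <- object$edges |>
    dplyr::left_join(pos, by = c(node_a = "node")) |>
    dplyr::rename(xa = "x", ya = "y") |>
    dplyr::left_join(pos, by = c(node_b = "node")) |>
    dplyr::rename(xb = "x", yb = "y")
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = ed,
      ggplot2::aes(x = .data$xa, y = .data$ya, xend = .data$xb,
                   yend = .data$yb, colour = .data$weight > 0,
                   alpha = abs(.data$weight))) +
    ggplot2::geom_point(data = pos, ggplot2::aes(.data$x, .data$y),
                        size = 2) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#b2182b",
                                            `FALSE` = "#2166ac"),
                                 guide = "none") +
    ggplot2::scale_alpha(range = c(0.2, 1), guide = "none") +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
  if (label_nodes) {
    p <- p + ggplot2::geom_text(
      data = pos, ggplot2::aes(.data$x * 1.12, .data$y * 1.12,
                               label = .data$node), size = 2.7)
  }
  p
}
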