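#' Probability diffusion over a co-perturbation network
#'
#' One unit of probability mass per anchor node spreads recursively to
#' unvisited neighbours, split proportionally to |edge weight| (the sign of
#' a partial correlation does not matter for connectedness). A node
#' receiving mass keeps all of it when the mass falls below `threshold` or
#' it has no unvisited neighbours to pass it to; otherwise it keeps half
#' and forwards half. The recursion therefore always terminates and the
#' returned scores sum to at most the number of anchors.
#'
#' @param network A [copnet()].
#' @param anchors Node ids the mass starts from (must be in the network and
#'   in `visited`).
#' @param visited Node ids excluded from receiving mass (defaults to the
#'   anchors themselves).
#' @param threshold Truncation mass. Default 1e-4.
#' @return Named numeric vector of positive diffusion scores over the
#'   unvisited nodes reached; empty when the anchors are isolated.
#' @export
diffuse <- function(network, anchors, visited = anchors, threshold = 1e-4) {
  anchors <- as_node_set(anchors)
  visited <- union(as_node_set(visited), anchors)
  bad <- setdiff(anchors, network$nodes)
  if (length(bad) > 0) stopf("anchor not in network: %s", bad[1])
  W <- abs(adjacency_matrix(network))
  vis <- network$nodes %in% visited
  sc <- .ctd_diffuse_cpp(W, match(anchors, network$nodes) - 1L, vis,
                         threshold)
  names(sc) <- network$nodes
  sc[sc > 0]
}

#' Adaptive walk encoding of a node set
#'
#' Starting from `start`, nodes are ranked one at a time: at each step the
#' unranked node with the highest diffusion score (anchored on every member
#' of `s` found so far, ties broken by node id) is appended; every
#' appended member of `s` joins the anchor set. The walk stops once all
#' reachable members of `s` are ranked; members the diffusion never reaches
#' are appended in id order and reported as unreachable.
#'
#' @param network A [copnet()].
#' @param s The node set being encoded (character vector or
#'   `perturbation_set`), intersected with the network's nodes.
#' @param start A member of `s` to start from.
#' @param threshold Diffusion truncation mass.
#' @return A `walk_ranking`: `start_node`, `ranking` (node ids),
#'   `found_positions` (1-based positions after the start at which members
#'   of `s` were found by diffusion), and `unreachable` members.
#' @export
adaptive_walk <- function(network, s, start, threshold = 1e-4) {
  s <- intersect(as_node_set(s), network$nodes)
  if (!start %in% s) stopf("start node %s not in the encoded set", start)
  W <- abs(adjacency_matrix(network))
  in_set <- network$nodes %in% s
  res <- .ctd_walk_cpp(W, in_set, match(start, network$nodes) - 1L,
                       threshold)
  structure(list(start_node = start,
                 ranking = network$nodes[res$ranking + 1L],
                 found_positions = as.integer(res$found_pos),
                 unreachable = network$nodes[res$unreachable + 1L]),
            class = "walk_ranking")
}

#' @export
print.walk_ranking <- function(x, ...) {
  cat(sprintf("<walk_ranking> start %s, %d ranked, found at {%s}%s\n",
              x$start_node, length(x$ranking),
              paste(x$found_positions, collapse = ","),
              if (length(x$unreachable) > 0)
                sprintf(", %d unreachable", length(x$unreachable)) else ""))
  invisible(x)
}

# encoding length of the full set for one walk:
#   log2(n) start pointer + position of the last diffusion-found member
#   + log2(n) per unreachable member (fixed-length fallback)
walk_encoding_bits <- function(walk, n) {
  last <- if (length(walk$found_positions) > 0) max(walk$found_positions) else 0L
  log2(n) + last + length(walk$unreachable) * log2(n)
}

#' Information content of a node set in a network
#'
#' The encoding length, in bits, of the most compressible adaptive-walk
#' description of `s`: for each start node the cost is `log2(n)` (a pointer
#' to the start) plus the rank position of the last member found by the
#' walk, plus `log2(n)` for each unreachable member; the information
#' content `I(S)` is the minimum over start nodes. A singleton always costs
#' exactly `log2(n)`; a k-clique found consecutively costs
#' `log2(n) + (k - 1)`.
#'
#' @inheritParams adaptive_walk
#' @return List with `bits` (I(S)) and `best_walk` (the minimizing
#'   `walk_ranking`; earliest start in id order on ties).
#' @export
information_content <- function(network, s, threshold = 1e-4) {
  s <- lex_sort(intersect(as_node_set(s), network$nodes))
  if (length(s) == 0) stopf("empty node set")
  n <- length(network$nodes)
  best <- NULL
  best_bits <- Inf
  for (w in all_walks(network, s, threshold)) {
    b <- walk_encoding_bits(w, n)
    if (b < best_bits) {
      best_bits <- b
      best <- w
    }
  }
  list(bits = best_bits, best_walk = best)
}

# one adaptive walk per start node of s, sharing the graph construction
all_walks <- function(network, s, threshold = 1e-4) {
  W <- abs(adjacency_matrix(network))
  in_set <- network$nodes %in% s
  res <- .ctd_walks_cpp(W, in_set, match(s, network$nodes) - 1L, threshold)
  lapply(seq_along(s), function(k) {
    r <- res[[k]]
    structure(list(start_node = s[k],
                   ranking = network$nodes[r$ranking + 1L],
                   found_positions = as.integer(r$found_pos),
                   unreachable = network$nodes[r$unreachable + 1L]),
              class = "walk_ranking")
  })
}

#' CTD connectedness p-value of a node set
#'
#' Scores how tightly a perturbation set clusters in the network. Every
#' adaptive walk from every start node yields nested candidate subsets
#' (the start plus the first m diffusion-found members); each candidate of
#' size j saves `j*log2(n) - (log2(n) + pos)` bits relative to the
#' fixed-length code that names each of its j nodes with `log2(n)` bits,
#' where `pos` is the rank position of its last member. The optimal subset
#' maximizes bits saved (ties: larger subset, then lexicographic node
#' order), and `p = 2^(-bits_saved)` bounds the fraction of equally sized
#' subsets that could compress this well; highly connected sets earn small
#' p-values with no permutation testing.
#'
#' @inheritParams adaptive_walk
#' @return A `ctd_result`: `input_set`, `optimal_subset`, `encoding_bits`
#'   and `fixed_bits` for the optimal subset, `bits_saved`, `p_value`
#'   (optimal subset), plus `information_bits` = I(S) of the whole set and
#'   the corresponding `p_value_full`.
#' @export
ctd_pvalue <- function(network, s, threshold = 1e-4) {
  input <- lex_sort(intersect(as_node_set(s), network$nodes))
  if (length(input) == 0) stopf("no scoreable nodes: set does not intersect the network")
  n <- length(network$nodes)
  best <- list(bits_saved = -Inf, size = 0L, subset = character(),
               encoding_bits = NA_real_)
  full_bits <- Inf
  for (w in all_walks(network, input, threshold)) {
    v <- w$start_node
    full_bits <- min(full_bits, walk_encoding_bits(w, n))
    members <- w$ranking[w$found_positions + 1L]
    # prefix of the start alone: 0 bits saved, p = 1 baseline
    prefixes_pos <- c(0L, w$found_positions)
    for (m in seq_along(prefixes_pos)) {
      pos <- prefixes_pos[m]
      subset <- c(v, if (m > 1) members[seq_len(m - 1L)])
      saved <- (m - 1L) * log2(n) - pos
      better <- saved > best$bits_saved + 1e-12 ||
        (abs(saved - best$bits_saved) <= 1e-12 &&
           (m > best$size ||
              (m == best$size &&
                 paste(lex_sort(subset), collapse = "\r") <
                   paste(lex_sort(best$subset), collapse = "\r"))))
      if (better) {
        best <- list(bits_saved = saved, size = m,
                     subset = lex_sort(subset),
                     encoding_bits = log2(n) + pos)
      }
    }
  }
  structure(list(
    input_set = input,
    optimal_subset = best$subset,
    encoding_bits = best$encoding_bits,
    fixed_bits = best$size * log2(n),
    bits_saved = best$bits_saved,
    p_value = min(1, 2^(-best$bits_saved)),
    information_bits = full_bits,
    p_value_full = min(1, 2^(-(length(input) * log2(n) - full_bits))),
    n_network_nodes = n
  ), class = "ctd_result")
}

#' @export
print.ctd_result <- function(x, ...) {
  cat(sprintf("<ctd_result> |S| = %d, optimal subset %d nodes, %.2f bits saved, p = %.3g\n",
              length(x$input_set), length(x$optimal_subset), x$bits_saved,
              x$p_value))
  invisible(x)
}

#' @export
tidy.ctd_result <- function(x, ...) {
  tibble::tibble(node = x$input_set,
                 in_optimal_subset = x$input_set %in% x$optimal_subset)
}

#' @export
glance.ctd_result <- function(x, ...) {
  tibble::tibble(n_input = length(x$input_set),
                 n_optimal = length(x$optimal_subset),
                 encoding_bits = x$encoding_bits,
                 fixed_bits = x$fixed_bits,
                 bits_saved = x$bits_saved,
                 p_value = x$p_value,
                 information_bits = x$information_bits,
                 p_value_full = x$p_value_full,
                 n_network_nodes = x$n_network_nodes)
}
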