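# Shared fixtures and independent oracles for the test suite.

# ---- graph fixtures -------------------------------------------------------

# n-node network from an edge data frame given as index pairs
fixture_net <- function(n, a, b, w, prefix = "n") {
  nodes <- sprintf("%s%02d", prefix, seq_len(n))
  copnet(nodes, tibble::tibble(node_a = nodes[a], node_b = nodes[b],
                               weight = w))
}

# 16 nodes: a 4-clique (n01..n04) plus a disjoint path n05-...-n16
fixture_clique16 <- function() {
  cl <- t(combn(1:4, 2))
  fixture_net(16, c(cl[, 1], 5:15), c(cl[, 2], 6:16),
              c(rep(0.5, nrow(cl)), rep(0.3, 11)))
}

# weighted 6-node path with uneven weights
fixture_path6 <- function() {
  fixture_net(6, 1:5, 2:6, c(0.9, 0.2, 0.7, 0.4, 0.6))
}

# deterministic random graph: Erdos-Renyi support, uniform weights
fixture_random_net <- function(n, p_edge, seed, prefix = "n") {
  set.seed(seed)
  pairs <- t(combn(seq_len(n), 2))
  keep <- runif(nrow(pairs)) < p_edge
  w <- round(runif(sum(keep), 0.1, 1), 3) * sample(c(-1, 1), sum(keep), TRUE)
  fixture_net(n, pairs[keep, 1], pairs[keep, 2], w, prefix)
}

# ---- independent CTD oracles (plain R, recursive, mirror the definition) --

oracle_diffuse <- function(net, anchors, visited = anchors,
                           threshold = 1e-4) {
  W <- abs(adjacency_matrix(net))
  nodes <- net$nodes
  vis <- nodes %in% union(visited, anchors)
  score <- stats::setNames(numeric(length(nodes)), nodes)
  unvisited_nb <- function(i) which(W[i, ] > 0 & !vis)
  receive <- function(i, m) {
    nb <- unvisited_nb(i)
    if (m < threshold || length(nb) == 0) {
      score[nodes[i]] <<- score[nodes[i]] + m
      return(invisible())
    }
    score[nodes[i]] <<- score[nodes[i]] + m / 2
    tot <- sum(W[i, nb])
    for (j in nb) receive(j, (m / 2) * W[i, j] / tot)
  }
  for (a in anchors) {
    i <- match(a, nodes)
    nb <- unvisited_nb(i)
    if (length(nb) == 0) next
    tot <- sum(W[i, nb])
    for (j in nb) receive(j, W[i, j] / tot)
  }
  score[score > 0]
}

oracle_walk <- function(net, s, start, threshold = 1e-4) {
  s <- intersect(s, net$nodes)
  ranking <- start
  anchors <- start
  found_pos <- integer()
  repeat {
    if (length(intersect(s, ranking)) == length(s)) break
    sc <- oracle_diffuse(net, anchors, ranking, threshold)
    if (length(sc) == 0) break
    # argmax with ties to the lexicographically smallest node id
    best <- names(sc)[order(-sc, names(sc), method = "radix")][1]
    ranking <- c(ranking, best)
    if (best %in% s) {
      anchors <- c(anchors, best)
      found_pos <- c(found_pos, length(ranking) - 1L)
    }
  }
  unreachable <- sort(setdiff(s, ranking), method = "radix")
  list(ranking = c(ranking, unreachable), found_positions = found_pos,
       unreachable = unreachable)
}

oracle_information <- function(net, s, threshold = 1e-4) {
  s <- sort(intersect(s, net$nodes), method = "radix")
  n <- length(net$nodes)
  min(vapply(s, function(v) {
    w <- oracle_walk(net, s, v, threshold)
    last <- if (length(w$found_positions) > 0) max(w$found_positions) else 0
    log2(n) + last + length(w$unreachable) * log2(n)
  }, numeric(1)))
}

# maximum bits saved over all walk prefixes (start + first m found members)
oracle_bits_saved <- function(net, s, threshold = 1e-4) {
  s <- sort(intersect(s, net$nodes), method = "radix")
  n <- length(net$nodes)
  best <- 0
  for (v in s) {
    w <- oracle_walk(net, s, v, threshold)
    pos <- c(0L, w$found_positions)
    for (m in seq_along(pos)) {
      best <- max(best, (m - 1) * log2(n) - pos[m])
    }
  }
  best
}

# ---- tiny cohort builders -------------------------------------------------

tiny_profiles <- function(z, binary = character()) {
  profile_matrix(z, binary)
}

# named matrix shorthand
zmat <- function(values, mets, samples) {
  matrix(values, length(mets), length(samples),
         dimnames = list(mets, samples))
}
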