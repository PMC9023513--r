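test_that("diffusion obeys its contracts on canonical graphs", {
  star <- copnet(c("c", "l1", "l2", "l3"),
                 tibble::tibble(node_a = "c", node_b = c("l1", "l2", "l3"),
                                weight = 1))
  sc <- diffuse(star, "c")
  expect_equal(unname(sc[c("l1", "l2", "l3")]), rep(1 / 3, 3))

  iso <- copnet(c("a", "b"), tibble::tibble(node_a = "a", node_b = "b",
                                            weight = 0.5))
  lonely <- copnet(c("a", "b", "x"),
                   tibble::tibble(node_a = "a", node_b = "b", weight = 0.5))
  expect_length(diffuse(lonely, "x"), 0)
  expect_error(diffuse(iso, "ghost"), "anchor")

  # total mass never exceeds the anchor count
  net <- fixture_random_net(12, 0.4, 13)
  sc2 <- diffuse(net, net$nodes[1:3])
  expect_lte(sum(sc2), 3 + 1e-9)
})

test_that("diffusion matches an independent recursive oracle on weighted paths and random graphs", {
  p6 <- fixture_path6()
  sc <- diffuse(p6, "n02")
  osc <- oracle_diffuse(p6, "n02")
  expect_equal(sc[order(names(sc))], osc[order(names(osc))], tolerance = 1e-12)

  for (seed in c(19, 23)) {
    net <- fixture_random_net(10, 0.35, seed)
    anchors <- net$nodes[c(2, 5)]
    visited <- net$nodes[c(2, 5, 8)]
    a <- diffuse(net, anchors, visited)
    b <- oracle_diffuse(net, anchors, visited)
    expect_equal(a[order(names(a))], b[order(names(b))], tolerance = 1e-12)
  }
})

test_that("adaptive walk ranks cliques consecutively and handles singletons", {
  net16 <- fixture_clique16()
  w <- adaptive_walk(net16, c("n01", "n02", "n03"), "n01")
  expect_identical(w$ranking[1], "n01")
  expect_identical(w$found_positions, c(1L, 2L))

  ws <- adaptive_walk(net16, "n05", "n05")
  expect_identical(ws$ranking[1], "n05")
  expect_length(ws$found_positions, 0)

  expect_error(adaptive_walk(net16, c("n01", "n02"), "n16"), "start")
})

test_that("adaptive walk replays the step-by-step oracle on random graphs", {
  for (seed in c(29, 31, 37)) {
    net <- fixture_random_net(10, 0.3, seed)
    set.seed(seed + 1)
    s <- sample(net$nodes, 4)
    for (v in s) {
      got <- adaptive_walk(net, s, v)
      want <- oracle_walk(net, s, v)
      expect_identical(got$ranking, want$ranking)
      expect_identical(got$found_positions, want$found_positions)
      expect_identical(got$unreachable, want$unreachable)
    }
  }
})

test_that("information content hits the singleton and clique closed forms", {
  net16 <- fixture_clique16()
  expect_equal(information_content(net16, "n09")$bits, log2(16))
  expect_equal(information_content(net16, c("n01", "n02", "n03", "n04"))$bits,
               log2(16) + 3)
  expect_error(information_content(net16, character()), "empty")

  # unreachable members degrade to the fixed-length code
  two_comp <- fixture_net(8, c(1, 5), c(2, 6), c(1, 1))
  bits <- information_content(two_comp, c("n01", "n02", "n05"))$bits
  # best walk starts in one component, the other member costs log2(8)
  expect_equal(bits, log2(8) + 1 + log2(8))
})

test_that("information content equals exhaustive oracle over all size-3 subsets of a 10-node graph", {
  net <- fixture_random_net(10, 0.35, 43)
  subsets <- combn(net$nodes, 3)
  for (k in seq_len(ncol(subsets))) {
    s <- subsets[, k]
    expect_equal(information_content(net, s)$bits, oracle_information(net, s),
                 tolerance = 1e-12, label = paste(s, collapse = ","))
  }
})

test_that("ctd p-values: singleton p = 1, cliques beat scattered sets, errors on no overlap", {
  net16 <- fixture_clique16()
  r1 <- ctd_pvalue(net16, "n03")
  expect_equal(r1$bits_saved, 0)
  expect_equal(r1$p_value, 1)

  rc <- ctd_pvalue(net16, c("n01", "n02", "n03", "n04"))
  expect_identical(rc$optimal_subset, c("n01", "n02", "n03", "n04"))
  expect_equal(rc$bits_saved, 3 * log2(16) - 3)
  expect_equal(rc$p_value, 2^-(3 * log2(16) - 3))

  rs <- ctd_pvalue(net16, c("n01", "n06", "n09", "n13"))
  expect_lt(rc$p_value, rs$p_value)

  expect_error(ctd_pvalue(net16, "zz"), "no scoreable")

  # p = 1 on an edgeless network for any set
  bare <- copnet(sprintf("x%d", 1:6))
  expect_equal(ctd_pvalue(bare, c("x1", "x2", "x3"))$p_value, 1)
})

test_that("ctd scoring is deterministic and p stays in (0, 1]", {
  net <- fixture_random_net(12, 0.3, 47)
  s <- net$nodes[c(1, 4, 7, 10)]
  a <- ctd_pvalue(net, s)
  b <- ctd_pvalue(net, s)
  expect_identical(a, b)
  for (k in 2:5) {
    set.seed(k)
    s2 <- sample(net$nodes, k)
    p <- ctd_pvalue(net, s2)$p_value
    expect_gt(p, 0)
    expect_lte(p, 1)
  }
})

test_that("the union bound #{S: bits_saved >= b} <= n^k * 2^(-b) holds exhaustively", {
  # the decodable-code guarantee: at most 2^(k log2 n - b) node sets can
  # save b bits, since each is identified by its (start, walk-bitstring)
  # encoding of k log2 n - b bits
  for (seed in c(53, 101)) {
    net <- fixture_random_net(10, 0.3, seed)
    n <- length(net$nodes)
    for (k in c(3, 4)) {
      subsets <- combn(net$nodes, k)
      saved <- vapply(seq_len(ncol(subsets)), function(i) {
        ctd_pvalue(net, subsets[, i])$bits_saved
      }, numeric(1))
      for (b in unique(saved)) {
        expect_lte(sum(saved >= b - 1e-9) / n^k, 2^(-b) + 1e-12,
                   label = sprintf("seed %d k %d bound at b = %.3f",
                                   seed, k, b))
      }
    }
  }
})

test_that("adding an edge inside the set never increases its information content", {
  base <- fixture_net(10, c(1, 2, 5, 6, 8), c(2, 3, 6, 7, 9),
                      c(0.5, 0.5, 0.4, 0.4, 0.3))
  s <- c("n01", "n03", "n05")
  before <- information_content(base, s)$bits
  plus <- copnet(base$nodes,
                 dplyr::bind_rows(base$edges,
                                  tibble::tibble(node_a = "n01",
                                                 node_b = "n03",
                                                 weight = 0.6)))
  after <- information_content(plus, s)$bits
  expect_lte(after, before + 1e-9)
})
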