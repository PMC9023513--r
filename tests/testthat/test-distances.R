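test_that("joint information is the union encoding", {
  net <- fixture_clique16()
  s1 <- c("n01", "n02")
  s2 <- c("n03", "n04")
  expect_equal(joint_information(net, s1, s1),
               information_content(net, s1)$bits)
  expect_equal(joint_information(net, s1, s2),
               information_content(net, union(s1, s2))$bits)
  # disjoint singletons cost at least one start pointer
  expect_gte(joint_information(net, "n01", "n09"), log2(16))
  expect_error(joint_information(net, "zz", "yy"), "empty")
})

test_that("ctd_ncd: identity, symmetry, range, and same-module < distal (Fig-2C-style geometry)", {
  net <- fixture_clique16()
  expect_equal(as.numeric(ctd_ncd(net, c("n01", "n02"), c("n01", "n02"))), 0)

  # symmetry, exactly, over random pairs
  set.seed(61)
  rnet <- fixture_random_net(12, 0.35, 67)
  for (i in 1:25) {
    s1 <- sample(rnet$nodes, sample(2:4, 1))
    s2 <- sample(rnet$nodes, sample(2:4, 1))
    d12 <- ctd_ncd(rnet, s1, s2)
    d21 <- ctd_ncd(rnet, s2, s1)
    expect_identical(as.numeric(d12), as.numeric(d21))
    expect_gte(as.numeric(d12), 0)
    expect_lte(as.numeric(d12), 1)
  }

  # two sets inside one 5-clique vs. sets in distal components
  cl <- t(combn(1:5, 2))
  big <- fixture_net(14, c(cl[, 1], 6:13), c(cl[, 2], 7:14),
                     c(rep(0.6, nrow(cl)), rep(0.4, 8)))
  near <- ctd_ncd(big, c("n01", "n02", "n03"), c("n03", "n04", "n05"))
  far <- ctd_ncd(big, c("n01", "n02", "n03"), c("n12", "n13", "n14"))
  expect_lt(as.numeric(near), as.numeric(far))
})

test_that("main disease module recovers recurrent perturbations and falls back gracefully", {
  net <- fixture_clique16()
  # all samples perturb the clique; noise elsewhere below recurrence
  set.seed(71)
  z <- zmat(rnorm(16 * 6, 0, 0.5), net$nodes, sprintf("d%d", 1:6))
  z[c("n01", "n02", "n03", "n04"), ] <- 3
  mod <- main_disease_module(copnet(net$nodes, net$edges),
                             tiny_profiles(z), "demo")
  expect_identical(mod$nodes, c("n01", "n02", "n03", "n04"))
  expect_identical(mod$source, "algorithm1_surrogate")

  # single shared perturbed node -> singleton module
  z2 <- zmat(0, net$nodes, sprintf("d%d", 1:4))
  z2["n07", ] <- 4
  mod2 <- main_disease_module(net, tiny_profiles(z2), "demo")
  expect_identical(mod2$nodes, "n07")

  # nothing recurrent -> top-10 by median |z| fallback, still inside network
  z3 <- zmat(rnorm(16 * 4, 0, 0.2), net$nodes, sprintf("d%d", 1:4))
  mod3 <- main_disease_module(net, tiny_profiles(z3), "demo")
  expect_length(mod3$nodes, 10)
  expect_true(all(mod3$nodes %in% net$nodes))

  expect_error(main_disease_module(net, tiny_profiles(z[, 1, drop = FALSE])),
               "2 disease")
})

test_that("ctd_dm is the set-module ncd distance", {
  net <- fixture_clique16()
  mod <- disease_module("demo", c("n01", "n02", "n03"))
  ps <- structure(list(sample_id = "s", nodes = c("n01", "n02", "n03"),
                       z_values = c(n01 = 3, n02 = 3, n03 = 3)),
                  class = "perturbation_set")
  expect_equal(as.numeric(ctd_dm(net, ps, mod)), 0)
  # distal patient set is near-maximally far
  far <- ctd_dm(net, c("n12", "n13", "n14"), mod)
  expect_gte(attr(far, "pre_clip"), 0.8)
  # symmetric in the two node sets
  expect_equal(as.numeric(far),
               as.numeric(ctd_ncd(net, mod$nodes, c("n12", "n13", "n14"))))
})

test_that("empirical percentile implements the add-one left-tail rule", {
  expect_equal(empirical_percentile(0.1, rep(0.5, 24)), 1 / 25)
  expect_equal(empirical_percentile(0.9, rep(0.5, 24)), 1)
  set.seed(81)
  ref <- runif(99)
  v <- median(ref)
  expect_equal(empirical_percentile(v, ref),
               (sum(ref <= v) + 1) / 100)
  expect_error(empirical_percentile(0.5, numeric()), "empty")
})

test_that("pairwise distance matrix is symmetric, zero-diagonal, and matches per-pair recomputation", {
  net <- fixture_clique16()
  mk <- function(id, nodes) structure(
    list(sample_id = id, nodes = nodes,
         z_values = stats::setNames(rep(3, length(nodes)), nodes)),
    class = "perturbation_set")
  sets <- list(mk("a", c("n01", "n02")), mk("b", c("n03", "n04")),
               mk("c", c("n08", "n09")))
  dm <- pairwise_distance_matrix(net, sets)
  expect_identical(dm$ids, c("a", "b", "c"))
  expect_equal(unname(diag(dm$d)), rep(0, 3))
  expect_identical(dm$d, t(dm$d))
  for (i in 1:2) for (j in (i + 1):3) {
    expect_equal(dm$d[i, j],
                 as.numeric(ctd_ncd(net, sets[[i]], sets[[j]])))
  }

  # identical sets give the zero matrix
  same <- list(mk("a", c("n01", "n02")), mk("b", c("n01", "n02")),
               mk("c", c("n01", "n02")))
  expect_equal(max(pairwise_distance_matrix(net, same)$d), 0)

  bad <- list(mk("a", c("n01")), structure(
    list(sample_id = "ghost", nodes = "zz", z_values = c(zz = 3)),
    class = "perturbation_set"))
  expect_error(pairwise_distance_matrix(net, bad), "ghost")

  # TSV round-trip
  dir <- withr::local_tempdir()
  f <- file.path(dir, "d.tsv")
  write_distance_matrix(dm, f)
  back <- read_distance_matrix(f)
  expect_equal(back$d, dm$d)
})

test_that("classical MDS reproduces Euclidean geometry", {
  # equilateral unit triangle
  D3 <- matrix(1, 3, 3) - diag(3)
  rownames(D3) <- colnames(D3) <- c("a", "b", "c")
  co <- mds_embed(D3, 2)
  X <- as.matrix(co[, c("MDS1", "MDS2")])
  expect_equal(as.numeric(dist(X)), rep(1, 3), tolerance = 1e-6)

  # collinear points stay one-dimensional
  x <- c(0, 1, 2, 3.5)
  D4 <- as.matrix(dist(x))
  co4 <- mds_embed(D4, 2)
  ev <- attr(co4, "eigenvalues")
  expect_lt(abs(ev[2]), 1e-9)

  # random 10-point cloud: distances reproduced to 1e-8
  set.seed(91)
  P <- matrix(rnorm(20), 10, 2)
  D10 <- as.matrix(dist(P))
  co10 <- mds_embed(D10, 2)
  X10 <- as.matrix(co10[, c("MDS1", "MDS2")])
  expect_lt(max(abs(as.matrix(dist(X10)) - D10)), 1e-8)

  # deterministic sign convention: largest loading positive
  expect_gte(max(X10[, 1]), abs(min(X10[, 1])))

  # degenerate all-zero distances embed at the origin without error
  co0 <- mds_embed(matrix(0, 4, 4), 2)
  expect_equal(max(abs(as.matrix(co0[, -1]))), 0)
  expect_error(mds_embed(D3, 3), "dims")
})

test_that("k-means purity and centroid distances follow their formulas", {
  coords <- rbind(c(0, 0), c(0.1, 0), c(5, 5), c(5.1, 5), c(5, 5.1),
                  c(0.2, 0.1))
  rownames(coords) <- sprintf("s%d", 1:6)
  labels <- c("A", "A", "B", "B", "B", "B")
  pur <- kmeans_purity(coords, labels, k = 2, seed = 1)
  expect_equal(as.numeric(pur), (2 + 3) / 6)

  sep <- c("A", "A", "B", "B", "B", "A")
  expect_equal(as.numeric(kmeans_purity(coords, sep, k = 2, seed = 1)), 1)
  expect_error(kmeans_purity(coords, labels, k = 9, seed = 1), "exceeds")

  expect_equal(centroid_distance(rbind(c(0, 0), c(3, 4)), c("a", "b"),
                                 "a", "b"), 5)
  expect_equal(centroid_distance(coords, rep("x", 6), "x", "x"), 0)
  set.seed(95)
  C <- matrix(rnorm(24), 12, 2)
  lb <- rep(c("g1", "g2"), each = 6)
  oracle <- sqrt(sum((colMeans(C[1:6, ]) - colMeans(C[7:12, ]))^2))
  expect_equal(centroid_distance(C, lb, "g1", "g2"), oracle)
  expect_error(centroid_distance(C, lb, "g1", "nope"), "unknown")
})
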