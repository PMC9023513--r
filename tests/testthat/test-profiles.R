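test_that("read_profiles parses tables, missing cells, and errors precisely", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "profiles.tsv")
  writeLines(c("metabolite\ts1\ts2",
               "alanine\t1.5\t-0.2",
               "citrulline\t\t2.25",
               "ornithine\t0\t0.125"), p)
  pm <- read_profiles(p)
  expect_equal(dim(pm$z), c(3, 2))
  expect_equal(sum(missing_mask(pm)), 1)
  expect_true(is.na(pm$z["citrulline", "s1"]))
  expect_equal(pm$z["citrulline", "s2"], 2.25)

  writeLines(c("metabolite\ts1", "alanine\t1", "alanine\t2"),
             file.path(dir, "dup.tsv"))
  expect_error(read_profiles(file.path(dir, "dup.tsv")), "alanine")

  writeLines(c("metabolite\ts1", "alanine\tbogus"),
             file.path(dir, "bad.tsv"))
  expect_error(read_profiles(file.path(dir, "bad.tsv")), "bogus.*alanine|alanine.*bogus")

  writeLines("metabolite\ts1", file.path(dir, "empty.tsv"))
  expect_error(read_profiles(file.path(dir, "empty.tsv")), "no metabolites")
})

test_that("write/read round-trips a random matrix with missingness bit-identically", {
  set.seed(11)
  mets <- sprintf("met%03d", 1:50)
  samp <- sprintf("s%02d", 1:20)
  z <- zmat(rnorm(1000), mets, samp)
  z[sample(1000, 100)] <- NA
  pm <- profile_matrix(z)
  dir <- withr::local_tempdir()
  for (ext in c("tsv", "csv")) {
    f <- file.path(dir, paste0("rt.", ext))
    write_profiles(pm, f)
    back <- read_profiles(f)
    expect_identical(back$z, pm$z)
  }

  md <- tibble::tibble(sample_id = samp, role = "reference",
                       diagnosis_label = NA_character_,
                       treatment_flags = "", age_group = NA_character_)
  mf <- file.path(dir, "md.tsv")
  write_sample_metadata(md, mf)
  both <- read_profiles(file.path(dir, "rt.tsv"), mf)
  expect_identical(both$metadata$sample_id, samp)
})

test_that("presence filter applies the strict >50% rule in both cohorts", {
  mets <- c("kept", "ref_only", "dis_only", "border")
  # 5 reference, 5 disease samples; "border" observed in exactly 50%
  zr <- zmat(1, mets, sprintf("r%d", 1:5))
  zd <- zmat(1, mets, sprintf("d%d", 1:5))
  zd["ref_only", ] <- NA                              # 0% in disease
  zr["dis_only", ] <- NA
  zr["border", 1:2] <- NA; zd["border", 1:3] <- NA    # 60% ref, 40% disease
  keep <- filter_by_presence(tiny_profiles(zd), tiny_profiles(zr))
  expect_identical(keep, "kept")

  # exactly 50% observed must be excluded (strict inequality)
  zr2 <- zmat(1, "m", sprintf("r%d", 1:4)); zr2[1, 1:2] <- NA
  zd2 <- zmat(1, "m", sprintf("d%d", 1:4))
  expect_identical(filter_by_presence(tiny_profiles(zd2), tiny_profiles(zr2)),
                   character(0))

  expect_error(filter_by_presence(tiny_profiles(zd[, 0, drop = FALSE]),
                                  tiny_profiles(zr)), "empty")
})

test_that("presence filter matches brute-force counting on a random fixture", {
  set.seed(21)
  mets <- sprintf("m%02d", 1:20)
  zr <- zmat(rnorm(20 * 8), mets, sprintf("r%d", 1:8))
  zd <- zmat(rnorm(20 * 6), mets, sprintf("d%d", 1:6))
  zr[runif(160) < 0.4] <- NA
  zd[runif(120) < 0.4] <- NA
  keep <- filter_by_presence(tiny_profiles(zd), tiny_profiles(zr), 0.5)
  brute <- mets[vapply(mets, function(m) {
    sum(!is.na(zr[m, ])) / 8 > 0.5 && sum(!is.na(zd[m, ])) / 6 > 0.5
  }, logical(1))]
  expect_identical(keep, brute)

  # order-invariance under sample permutation
  perm <- sample(8)
  keep2 <- filter_by_presence(tiny_profiles(zd),
                              tiny_profiles(zr[, perm]), 0.5)
  expect_identical(keep2, keep)
})

test_that("minimum-z imputation fills with per-analyte reference minima", {
  zr <- zmat(c(-1.2, 0.3, 2.0, 0.5, 0.1, 0.4), c("a", "b"), sprintf("r%d", 1:3))
  zd <- zmat(c(NA, 1, 2, NA), c("a", "b"), c("d1", "d2"))
  out <- impute_missing(tiny_profiles(zd), tiny_profiles(zr))
  expect_equal(out$z["a", "d1"], -1.2)
  expect_equal(out$z["b", "d2"], 0.3)
  expect_equal(out$z["b", "d1"], 1)  # observed cells untouched

  # no missing cells: identity; and idempotence
  expect_identical(impute_missing(out, tiny_profiles(zr))$z, out$z)

  # binary analytes are imputed to 0 (absent)
  zb <- zmat(c(NA, 1), "argininosuccinate", c("d1", "d2"))
  outb <- impute_missing(tiny_profiles(zb, "argininosuccinate"),
                         tiny_profiles(zr))
  expect_equal(outb$z["argininosuccinate", "d1"], 0)

  # zero reference observations must error and name the analyte
  zr_gap <- zr; zr_gap["a", ] <- NA
  expect_error(impute_missing(tiny_profiles(zd), tiny_profiles(zr_gap)), "a")
})

test_that("imputed cells equal brute-force reference minima on a random fixture", {
  set.seed(31)
  mets <- sprintf("m%02d", 1:30)
  zr <- zmat(rnorm(30 * 15), mets, sprintf("r%d", 1:15))
  zd <- zmat(rnorm(30 * 15), mets, sprintf("d%d", 1:15))
  zd[runif(450) < 0.2] <- NA
  zr[runif(450) < 0.1] <- NA
  out <- impute_missing(tiny_profiles(zd), tiny_profiles(zr))
  for (m in mets) {
    for (s in which(is.na(zd[m, ]))) {
      expect_equal(out$z[m, s], min(zr[m, ], na.rm = TRUE))
    }
  }
  expect_false(anyNA(out$z))
})

test_that("perturbation extraction thresholds, caps, and always includes present binaries", {
  z <- zmat(c(2.5, -0.5, -3.1, 1), c("A", "B", "C", "asa"), "s1")
  pm <- tiny_profiles(z, "asa")
  ps <- extract_perturbations(pm, "s1", c("A", "B", "C", "asa"))
  expect_setequal(ps$nodes, c("A", "C", "asa"))

  # binary absent (0) does not qualify
  z0 <- z; z0["asa", ] <- 0
  ps0 <- extract_perturbations(tiny_profiles(z0, "asa"), "s1",
                               c("A", "B", "C", "asa"))
  expect_setequal(ps0$nodes, c("A", "C"))

  # cap keeps the largest |z|, verified against a sort oracle
  set.seed(41)
  mets <- sprintf("m%02d", 1:40)
  zz <- zmat(sample(c(-1, 1), 40, TRUE) * runif(40, 2, 8), mets, "s1")
  psc <- extract_perturbations(tiny_profiles(zz), "s1", mets,
                               z_threshold = 2, max_set_size = 30)
  expect_length(psc$nodes, 30)
  oracle <- mets[order(-abs(zz[, 1]), mets)][1:30]
  expect_setequal(psc$nodes, oracle)

  # monotone in the threshold (before capping)
  lo <- extract_perturbations(tiny_profiles(zz), "s1", mets, 1.5, 40)
  hi <- extract_perturbations(tiny_profiles(zz), "s1", mets, 3, 40)
  expect_true(all(hi$nodes %in% lo$nodes))

  # empty result is allowed
  znone <- zmat(0.1, "A", "s1")
  expect_length(extract_perturbations(tiny_profiles(znone), "s1", "A")$nodes, 0)
})
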