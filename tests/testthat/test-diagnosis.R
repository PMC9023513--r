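test_that("Brown's method reduces to Fisher without covariance and handles the correlated limit", {
  # k = 1 identity
  expect_equal(brown_combine(0.03), 0.03)

  # two independent p = 0.05: Fisher chi-square with 4 df
  expect_equal(brown_combine(c(0.05, 0.05)),
               pchisq(-2 * log(0.05 * 0.05), df = 4, lower.tail = FALSE))
  expect_equal(brown_combine(c(0.05, 0.05)), 0.0175, tolerance = 1e-2)

  # zero covariance equals Fisher to 1e-10 on a grid
  grid <- c(0.01, 0.05, 0.1, 0.25, 0.5, 0.9)
  for (p1 in grid) for (p2 in grid) {
    expect_equal(brown_combine(c(p1, p2), matrix(0, 2, 2)),
                 pchisq(-2 * log(p1 * p2), df = 4, lower.tail = FALSE),
                 tolerance = 1e-10)
  }

  # perfectly correlated duplicate: cov(-2logp) = 4 recovers the single p
  for (p in grid) {
    expect_equal(brown_combine(c(p, p), matrix(4, 2, 2)), p,
                 tolerance = 1e-10)
  }

  expect_error(brown_combine(c(0, 0.5)), "0")
  expect_error(brown_combine(c(0.5, 1.5)), "0, 1")
})

test_that("ranking and DD threshold follow Bonferroni and alpha monotonicity", {
  mk_scores <- function(p) tibble::tibble(
    sample_id = "s", disease_label = sprintf("dis%02d", seq_along(p)),
    p_ctd = p, d_dm = 0.5, p_dm = p, p_combined = p, scoreable = TRUE,
    detected_module = replicate(length(p),
                                tibble::tibble(node = character(),
                                               z = numeric()),
                                simplify = FALSE))
  r <- rank_and_dd(mk_scores(c(0.001, 0.5, 0.002)), n_models = 16)
  expect_equal(attr(r, "dd_threshold"), 0.05 / 16)
  expect_identical(r$disease_label[1], "dis01")
  expect_identical(r$rank, 1:3)
  expect_equal(sum(r$in_dd), 2)  # 0.001 and 0.002 < 0.003125

  # all p = 1 -> empty DD
  r1 <- rank_and_dd(mk_scores(rep(1, 4)), n_models = 4)
  expect_equal(sum(r1$in_dd), 0)
  # deterministic tie-break by label
  expect_identical(r1$disease_label, sprintf("dis%02d", 1:4))

  # DD membership is monotone in alpha
  set.seed(101)
  ps <- runif(8, 0, 0.2)
  dd_at <- function(a) sum(rank_and_dd(mk_scores(ps), n_models = 8,
                                       alpha = a)$in_dd)
  sizes <- vapply(c(0.01, 0.05, 0.2, 0.8), dd_at, numeric(1))
  expect_true(all(diff(sizes) >= 0))

  # without bonferroni the threshold is alpha itself
  rnb <- rank_and_dd(mk_scores(c(0.04, 0.5)), n_models = 16,
                     bonferroni = FALSE)
  expect_equal(attr(rnb, "dd_threshold"), 0.05)
  expect_equal(sum(rnb$in_dd), 1)
})

test_that("HIT classification uses the 0.05 and 0.15 boundaries", {
  expect_identical(classify_hit(0.004), "HIT")
  expect_identical(classify_hit(0.10), "BORDERLINE")
  expect_identical(classify_hit(0.5), "NONE")
  # boundary cases: 0.05 is BORDERLINE (HIT is strict <), 0.15 is NONE
  expect_identical(classify_hit(c(0.049999, 0.05, 0.149999, 0.15)),
                   c("HIT", "BORDERLINE", "BORDERLINE", "NONE"))
})

test_that("variant evidence classes follow the ordered zygosity rules", {
  expect_identical(classify_variant_evidence(0, 1, 0, 0), "1")
  expect_identical(classify_variant_evidence(2, 0, 0, 0), "1")
  expect_identical(classify_variant_evidence(1, 0, 1, 0), "2")
  expect_identical(classify_variant_evidence(0, 0, 2, 0), "3")
  expect_identical(classify_variant_evidence(0, 0, 0, 1), "3")
  expect_identical(classify_variant_evidence(0, 0, 1, 0), "4")
  expect_identical(classify_variant_evidence(0, 0, 0, 0, all_benign = TRUE),
                   "5")
  expect_identical(classify_variant_evidence(0, 0, 0, 0), "unclassified")
  # rule order: hom pathogenic dominates even with VUS present
  expect_identical(classify_variant_evidence(0, 1, 3, 1), "1")
  expect_error(classify_variant_evidence(-1, 0, 0, 0))
})

test_that("cohort evaluation counts ranks, DD lengths, and HIT confusion correctly", {
  mk_report <- function(sid, p, labels) {
    scores <- tibble::tibble(
      sample_id = sid, disease_label = labels, p_ctd = p, d_dm = 0.5,
      p_dm = p, p_combined = p, scoreable = TRUE,
      detected_module = replicate(length(p),
                                  tibble::tibble(node = character(),
                                                 z = numeric()),
                                  simplify = FALSE))
    rank_and_dd(scores, n_models = length(p), alpha = 0.05,
                bonferroni = FALSE)
  }
  labels <- c("dA", "dB", "dC")
  reports <- list(
    s1 = mk_report("s1", c(0.001, 0.2, 0.9), labels),   # dA rank 1, in DD
    s2 = mk_report("s2", c(0.03, 0.01, 0.9), labels),   # dA rank 2
    s3 = mk_report("s3", c(0.2, 0.3, 0.4), labels),     # truth dC at rank 3
    r1 = mk_report("r1", c(0.9, 0.8, 0.7), labels))     # reference sample
  truth <- tibble::tibble(sample_id = c("s1", "s2", "s3", "r1"),
                          diagnosis_label = c("dA", "dA", "dC", NA))
  ev <- evaluate_cohort(reports, truth)
  # ranks of truth: s1 -> 1, s2 -> 2, s3 (dC) -> 3
  expect_equal(ev$summary$top1, 1 / 3)
  expect_equal(ev$summary$top3, 1)
  expect_equal(ev$summary$in_dd, 2 / 3)   # s1 (0.001) and s2 (0.03) clear 0.05
  expect_equal(ev$summary$reference_dd_median, 0)
  # per-disease confusion for dA: s1 HIT case, s2 HIT case, s3/r1 not cases
  pa <- ev$per_disease[ev$per_disease$disease_label == "dA", ]
  expect_equal(pa$tp, 2)   # s1 and s2 both HIT their true disease
  expect_equal(pa$fp, 0)   # s3 (0.2) and r1 (0.9) are NONE for dA
  expect_equal(pa$sensitivity, 1)
  expect_equal(pa$specificity, 1)

  # unknown diagnosis triggers a warning and is skipped
  truth_bad <- truth
  truth_bad$diagnosis_label[3] <- "unmodeled"
  expect_warning(evaluate_cohort(reports, truth_bad), "unmodeled|not modeled")
})
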