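test_that("fisher_exact_2x2 matches direct hypergeometric enumeration", {
  # (2,1;1,3): all tables with margins (3,4 | 3,4), enumerated literally
  n1 <- 3; n2 <- 4; m1 <- 3
  k <- 0:3
  probs <- choose(n1, k) * choose(n2, m1 - k) / choose(n1 + n2, m1)
  obs <- probs[k == 2]
  expected <- sum(probs[probs <= obs * (1 + 1e-7)])
  expect_equal(fisher_exact_2x2(contingency_table(2, 1, 1, 3)), expected)
  # perfectly balanced table
  expect_equal(fisher_exact_2x2(contingency_table(5, 5, 5, 5)), 1)
  # degenerate symptom margin
  expect_warning(p <- fisher_exact_2x2(contingency_table(0, 5, 0, 5)), "degenerate")
  expect_equal(p, 1)
})

test_that("fisher_exact_2x2 agrees with fisher.test across a table sweep", {
  # exhaustive for group sizes up to 8
  for (n1 in c(3, 5, 8)) for (n2 in c(4, 8)) {
    for (a in 0:n1) for (cc in 0:n2) {
      if (a + cc == 0 || (n1 - a) + (n2 - cc) == 0) next
      got <- fisher_exact_2x2(contingency_table(a, n1 - a, cc, n2 - cc))
      ref <- stats::fisher.test(matrix(c(a, n1 - a, cc, n2 - cc), 2, byrow = TRUE))$p.value
      expect_equal(got, min(ref, 1), tolerance = 1e-12)
    }
  }
  # random tables with total n <= 60
  set.seed(8)
  for (i in 1:200) {
    n1 <- sample(2:30, 1); n2 <- sample(2:30, 1)
    a <- sample(0:n1, 1); cc <- sample(0:n2, 1)
    if (a + cc == 0 || (n1 - a) + (n2 - cc) == 0) next
    got <- fisher_exact_2x2(contingency_table(a, n1 - a, cc, n2 - cc))
    ref <- stats::fisher.test(matrix(c(a, n1 - a, cc, n2 - cc), 2, byrow = TRUE))$p.value
    expect_equal(got, min(ref, 1), tolerance = 1e-12)
  }
})

test_that("odds_ratio_cmle maximizes the conditional likelihood", {
  # symmetric table
  expect_equal(odds_ratio_cmle(contingency_table(5, 5, 5, 5)), 1)
  # grid + golden-section oracle on a non-boundary table (case orientation)
  expect_equal(odds_ratio_cmle(contingency_table(3, 5, 4, 2),
                               orientation = "case_vs_comparator"),
               cmle_grid_oracle(3, 5, 4, 2), tolerance = 1e-6)
  # score equation: conditional expectation at the estimate equals the
  # observed cell, for random non-boundary tables
  set.seed(21)
  for (i in 1:30) {
    n1 <- sample(4:25, 1); n2 <- sample(4:25, 1)
    a <- sample(1:(n1 - 1), 1); cc <- sample(1:(n2 - 1), 1)
    psi <- odds_ratio_cmle(contingency_table(a, n1 - a, cc, n2 - cc),
                           orientation = "case_vs_comparator")
    if (!is.finite(psi) || psi == 0) next
    expect_equal(cond_expectation(a, n1 - a, cc, n2 - cc, psi), a,
                 tolerance = 1e-6)
  }
})

test_that("cMLE handles orientation, transposition and boundaries", {
  tab <- contingency_table(7, 41, 26, 26)
  psi_comp <- odds_ratio_cmle(tab)
  psi_case <- odds_ratio_cmle(tab, orientation = "case_vs_comparator")
  expect_equal(psi_comp, 1 / psi_case)
  # swapping the two groups inverts the ratio and keeps p unchanged
  swapped <- contingency_table(26, 26, 7, 41)
  expect_equal(odds_ratio_cmle(swapped), psi_case, tolerance = 1e-8)
  expect_equal(fisher_exact_2x2(swapped), fisher_exact_2x2(tab), tolerance = 1e-12)
  # zero cells sit on the likelihood boundary
  expect_equal(odds_ratio_cmle(contingency_table(9, 39, 0, 52)), 0)
  expect_equal(odds_ratio_cmle(contingency_table(0, 48, 9, 43)), Inf)
  expect_warning(psi <- odds_ratio_cmle(contingency_table(0, 5, 0, 5)), "degenerate")
  expect_true(is.nan(psi))
  # Haldane auxiliary estimate is always finite
  expect_true(is.finite(odds_ratio_haldane(contingency_table(9, 39, 0, 52))))
})

test_that("holm_adjust implements the step-down correction", {
  expect_equal(holm_adjust(0.03), 0.03)
  expect_equal(holm_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(holm_adjust(c(0.6, 0.7, 0.8)), c(1, 1, 1))
  expect_identical(holm_adjust(numeric(0)), numeric(0))
  set.seed(4)
  p <- runif(12)
  perm <- sample(12)
  expect_equal(holm_adjust(p)[perm], holm_adjust(p[perm]))
  expect_true(all(holm_adjust(p) >= p))
})

test_that("screen_cohort flags the published strong indicators at scale", {
  co <- generate_cohort(default_study_config(size_multiplier = 50,
                                             dependence = 0, seed = 31))
  scr <- screen_cohort(co)
  expect_s3_class(scr, "sit_screening")
  expect_true(all(c("splenomegaly", "hepatomegaly", "thrombocytopenia_bleeding",
                    "mixed_dyslipidemia_low_hdl") %in%
                  scr$symptom_id[scr$candidate]))
  expect_true(all(scr$p_holm >= scr$p_raw, na.rm = TRUE))
  # layout: organ systems in table order, descending case prevalence inside
  expect_equal(rle(scr$organ_system)$values,
               c("neurological", "visceral", "skeletal", "other"))
  for (g in unique(scr$organ_system))
    expect_true(!is.unsorted(rev(scr$case_present[scr$organ_system == g])))
})

test_that("screening handles equal prevalence and untestable symptoms", {
  prev <- rbind(case = c(0.4, 0.4, 0, 0), control = c(0.4, 0.4, 0, 0),
                non_case = c(0.4, 0.4, 0, 0))
  colnames(prev) <- mini_catalog()$symptom_id
  co <- generate_cohort(mini_config(n = c(case = 3000, control = 3000, non_case = 5),
                                    prev = prev, seed = 37))
  d <- co$data
  d$ataxia <- NA_integer_    # wholly unknown symptom
  scr <- screen_cohort(cohort(d, co$catalog))
  expect_false(scr$candidate[scr$symptom_id == "splenomegaly"])
  expect_false(scr$testable[scr$symptom_id == "ataxia"])
  expect_true(is.na(scr$p_holm[scr$symptom_id == "ataxia"]))
})
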