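# A tool around a hand-built model with known coefficients.
manual_tool <- function(cutoff = 0.5) {
  vars <- c("hepatosplenomegaly", "thrombocytopenia_bleeding",
            "interstitial_lung_disease", "mixed_dyslipidemia_low_hdl")
  fit <- structure(list(
    spec = model_spec(vars),
    classes = c("case", "control", "non_case"), reference_class = "non_case",
    coefficients = matrix(c(-2, 2, 1.5, 2.5, 1,
                            -1, 1, 0.2, -0.5, 0.3), nrow = 2, byrow = TRUE,
                          dimnames = list(c("case", "control"),
                                          c("(intercept)", vars))),
    converged = TRUE, iterations = 0L, train_log_likelihood = NA_real_,
    loglik_trace = numeric(0), n_used = 0L, n_excluded = 0L),
    class = "asmd_multinom")
  sit_model(fit, cutoff = cutoff)
}

seeded_tool <- function() {
  co <- generate_cohort(default_study_config(seed = 1))
  co <- merge_hepatosplenomegaly(co)
  fit <- fit_multinomial(co, model_spec(c("hepatosplenomegaly",
                                          "thrombocytopenia_bleeding",
                                          "interstitial_lung_disease",
                                          "mixed_dyslipidemia_low_hdl")))
  list(tool = sit_model(fit), cohort = co)
}

test_that("the prerequisite gate never emits probabilities", {
  tool <- manual_tool()
  grid <- expand.grid(thrombocytopenia_bleeding = 0:1,
                      interstitial_lung_disease = 0:1,
                      mixed_dyslipidemia_low_hdl = 0:1)
  for (i in seq_len(nrow(grid))) {
    res <- sit_score(tool, c(hepatosplenomegaly = 0, unlist(grid[i, ])))
    expect_true(res$gated)
    expect_true(is.na(res$probability_case))
    expect_true(is.na(res$probability_control))
    expect_true(is.na(res$probability_non_case))
  }
})

test_that("scoring validates its input pattern", {
  tool <- manual_tool()
  expect_error(sit_score(tool, c(hepatosplenomegaly = 1)),
               "thrombocytopenia_bleeding")
  expect_error(sit_score(tool, c(hepatosplenomegaly = 1,
                                 thrombocytopenia_bleeding = 2,
                                 interstitial_lung_disease = 0,
                                 mixed_dyslipidemia_low_hdl = 0)),
               "thrombocytopenia_bleeding")
  expect_error(sit_model(manual_tool()$model,
                         prerequisite = "thrombocytopenia_bleeding",
                         inputs = c("thrombocytopenia_bleeding",
                                    "interstitial_lung_disease")),
               "prerequisite")
})

test_that("an all-zero model scores one third everywhere", {
  tool <- manual_tool()
  tool$model$coefficients[] <- 0
  res <- sit_score(tool, c(hepatosplenomegaly = 1, thrombocytopenia_bleeding = 0,
                           interstitial_lung_disease = 0,
                           mixed_dyslipidemia_low_hdl = 0))
  expect_false(res$gated)
  expect_equal(res$probability_case, 1/3)
})

test_that("the probability table enumerates patterns consistently with scoring", {
  tool <- manual_tool()
  tab <- probability_table(tool)
  expect_equal(nrow(tab), 8L)
  expect_equal(tab$probability_case + tab$probability_control +
                 tab$probability_non_case, rep(1, 8), tolerance = 1e-12)
  for (i in seq_len(nrow(tab))) {
    res <- sit_score(tool, c(stats::setNames(1, tool$prerequisite),
                             unlist(tab[i, tool$inputs])))
    expect_identical(res$probability_case, tab$probability_case[i])
  }
  # scoring is a pure function
  pat <- c(hepatosplenomegaly = 1, thrombocytopenia_bleeding = 1,
           interstitial_lung_disease = 0, mixed_dyslipidemia_low_hdl = 1)
  expect_identical(sit_score(tool, pat), sit_score(tool, pat))
})

test_that("the seeded study fit shows the documented probability ordering", {
  st <- seeded_tool()
  base <- c(hepatosplenomegaly = 1, thrombocytopenia_bleeding = 0,
            mixed_dyslipidemia_low_hdl = 1)
  with_ild <- sit_score(st$tool, c(base, interstitial_lung_disease = 1))
  without_ild <- sit_score(st$tool, c(base, interstitial_lung_disease = 0))
  expect_gt(with_ild$probability_case, without_ild$probability_case)
  # all symptoms present maximizes the case probability over the table
  tab <- probability_table(st$tool)
  expect_equal(which.max(tab$probability_case), nrow(tab))
})

test_that("derive_cutoff is the median case score over gated-in cases", {
  st <- seeded_tool()
  tool <- derive_cutoff(st$tool, st$cohort)
  d <- st$cohort$data
  vars <- c(st$tool$prerequisite, st$tool$inputs)
  cases <- d[d$group == "case", vars]
  cases <- cases[stats::complete.cases(cases) & cases[[st$tool$prerequisite]] == 1, ]
  scores <- vapply(seq_len(nrow(cases)), function(i)
    sit_score(st$tool, unlist(cases[i, ]))$probability_case, numeric(1))
  expect_equal(tool$cutoff, stats::median(scores))
  expect_gt(tool$cutoff, 0); expect_lt(tool$cutoff, 1)
  # constant scores give that constant; a 3-score set gives its middle value
  tool3 <- manual_tool()
  d3 <- tiny_cohort_df()[rep(1, 3), ]
  d3$patient_id <- c("a", "b", "c")
  d3$splenomegaly <- NULL; d3$hepatomegaly <- NULL
  d3$hepatosplenomegaly <- 1L
  d3$thrombocytopenia_bleeding <- c(0L, 1L, 0L)
  d3$interstitial_lung_disease <- c(0L, 0L, 1L)
  d3$mixed_dyslipidemia_low_hdl <- 0L
  cat3 <- symptom_catalog(data.frame(
    symptom_id = c("hepatosplenomegaly", "thrombocytopenia_bleeding",
                   "interstitial_lung_disease", "mixed_dyslipidemia_low_hdl"),
    display_name = c("HSM", "Thrombocytopenia", "ILD", "Dyslipidemia"),
    organ_system = "visceral", stringsAsFactors = FALSE))
  co3 <- cohort(d3, cat3)
  derived <- derive_cutoff(tool3, co3)
  expected <- sort(vapply(seq_len(3), function(i)
    sit_score(tool3, unlist(d3[i, cat3$symptom_id]))$probability_case, numeric(1)))[2]
  expect_equal(derived$cutoff, expected)
  # no gated-in case -> error
  d3$hepatosplenomegaly <- 0L
  expect_error(derive_cutoff(tool3, cohort(d3, cat3)), "prerequisite")
})
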