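# Hand-built model with known coefficients (reference class non_case).
manual_model <- function(coefs, variables) {
  structure(list(
    spec = model_spec(variables),
    classes = c("case", "control", "non_case"), reference_class = "non_case",
    coefficients = matrix(coefs, nrow = 2, byrow = TRUE,
                          dimnames = list(c("case", "control"),
                                          c("(intercept)", variables))),
    converged = TRUE, iterations = 0L, train_log_likelihood = NA_real_,
    loglik_trace = numeric(0), n_used = 0L, n_excluded = 0L),
    class = "asmd_multinom")
}

test_that("intercept-only fit reproduces class frequencies", {
  co <- generate_cohort(mini_config(n = c(case = 40, control = 40, non_case = 40),
                                    seed = 2))
  f <- fit_multinomial(co, model_spec(character(0)))
  expect_equal(unname(predict_proba(f, c())), rep(1/3, 3), tolerance = 1e-7)
  co2 <- generate_cohort(mini_config(n = c(case = 10, control = 30, non_case = 60),
                                     seed = 2))
  f2 <- fit_multinomial(co2, model_spec(character(0)))
  expect_equal(unname(predict_proba(f2, c())), c(0.1, 0.3, 0.6), tolerance = 1e-7)
})

test_that("predict_proba equals direct softmax arithmetic", {
  m <- manual_model(c(0.5, 1.2, -0.7,  -0.3, 0.4, 0.9), c("ataxia", "splenomegaly"))
  p <- predict_proba(m, c(ataxia = 1, splenomegaly = 0))
  e_case <- exp(0.5 + 1.2); e_ctrl <- exp(-0.3 + 0.4); den <- e_case + e_ctrl + 1
  expect_equal(unname(p), c(e_case / den, e_ctrl / den, 1 / den))
  expect_equal(sum(p), 1, tolerance = 1e-12)
  # uniform when all coefficients vanish
  m0 <- manual_model(rep(0, 6), c("ataxia", "splenomegaly"))
  expect_equal(unname(predict_proba(m0, c(ataxia = 1, splenomegaly = 1))),
               rep(1/3, 3))
  # softmax limit at a huge intercept
  mInf <- manual_model(c(50, 0, 0,  0, 0, 0), c("ataxia", "splenomegaly"))
  expect_gte(predict_proba(mInf, c(ataxia = 0, splenomegaly = 0))["case"],
             1 - 1e-20)
  expect_error(predict_proba(m, c(ataxia = 1)), "splenomegaly")
})

test_that("separated data stay finite under ridge and the trace is monotone", {
  d <- tiny_cohort_df()[rep(1:3, each = 20), ]
  d$patient_id <- sprintf("p%03d", 1:60)
  d$splenomegaly <- as.integer(d$group == "case")   # perfect separator
  d$hepatomegaly <- 0L
  f <- fit_multinomial(cohort(d), model_spec("splenomegaly"))
  expect_true(f$converged)
  expect_true(all(is.finite(coef(f))))
  expect_true(all(diff(f$loglik_trace) >= -1e-8))
})

test_that("slopes are recovered within 3 SE from simulated data", {
  # truth: two binary predictors, known coefficient matrix
  B <- matrix(c(-1.0, 1.5, -0.8,
                -0.5, 0.6,  0.9), nrow = 2, byrow = TRUE)
  n <- 20000
  set.seed(77)
  x1 <- rbinom(n, 1, 0.5); x2 <- rbinom(n, 1, 0.4)
  eta <- cbind(1, x1, x2) %*% t(B)
  den <- 1 + rowSums(exp(eta))
  P <- cbind(exp(eta), 1) / den
  y <- vapply(seq_len(n), function(i) sample(3L, 1L, prob = P[i, ]), integer(1))
  d <- data.frame(patient_id = sprintf("s%05d", 1:n),
                  group = c("case", "control", "non_case")[y],
                  subtype = "none", sex = "male",
                  age_onset_years = 1, age_current_years = 2,
                  splenomegaly = x1, hepatomegaly = x2,
                  stringsAsFactors = FALSE)
  d$subtype[d$group == "case"] <- "B"
  f <- fit_multinomial(cohort(d, mini_catalog()),
                       model_spec(c("splenomegaly", "hepatomegaly"),
                                  ridge_penalty = 1e-6))
  # SE from the expected information at the true parameters
  pats <- cbind(1, c(0, 1, 0, 1), c(0, 0, 1, 1))
  w <- c((1 - 0.5) * (1 - 0.4), 0.5 * (1 - 0.4), (1 - 0.5) * 0.4, 0.5 * 0.4)
  I <- matrix(0, 6, 6)
  for (r in 1:4) {
    etaR <- pats[r, ] %*% t(B)
    pR <- exp(etaR) / (1 + sum(exp(etaR)))
    W <- diag(as.vector(pR)) - t(pR) %*% pR
    I <- I + n * w[r] * kronecker(W, tcrossprod(pats[r, ]))
  }
  se <- sqrt(diag(solve(I)))
  est <- as.vector(t(coef(f)))       # class-major, matching kronecker order
  truth <- as.vector(t(B))
  expect_true(all(abs(est - truth) < 3 * se))
})

test_that("fit agrees with an independent multinomial fitter", {
  skip_if_not_installed("nnet")
  co <- generate_cohort(mini_config(seed = 41))
  f <- fit_multinomial(co, model_spec(c("splenomegaly", "ataxia"),
                                      ridge_penalty = 1e-10, tolerance = 1e-10))
  m <- nnet::multinom(factor(group, levels = c("non_case", "case", "control")) ~
                        splenomegaly + ataxia,
                      data = co$data, trace = FALSE, maxit = 1000, reltol = 1e-14)
  expect_equal(unname(coef(f)[c("case", "control"), ]),
               unname(stats::coef(m)[c("case", "control"), ]), tolerance = 1e-4)
})

test_that("reference-class relabeling leaves probabilities unchanged", {
  co <- generate_cohort(mini_config(seed = 43))
  pat <- c(splenomegaly = 1, ataxia = 0)
  p_ref <- lapply(c("non_case", "case", "control"), function(r)
    predict_proba(fit_multinomial(co, model_spec(c("splenomegaly", "ataxia"),
                                                 reference_class = r,
                                                 ridge_penalty = 1e-8)), pat))
  expect_equal(p_ref[[1]], p_ref[[2]], tolerance = 1e-6)
  expect_equal(p_ref[[1]], p_ref[[3]], tolerance = 1e-6)
  # at the default ridge the penalty breaks exact invariance only mildly
  p_def <- lapply(c("non_case", "case"), function(r)
    predict_proba(fit_multinomial(co, model_spec(c("splenomegaly", "ataxia"),
                                                 reference_class = r)), pat))
  expect_equal(p_def[[1]], p_def[[2]], tolerance = 1e-2)
})

test_that("unknown predictor values are excluded and counted", {
  d <- tiny_cohort_df()[rep(1:3, each = 10), ]
  d$patient_id <- sprintf("p%03d", 1:30)
  d$hepatomegaly <- rep(c(1L, 0L, 0L), each = 10)
  d$hepatomegaly[c(1, 5, 9)] <- NA
  f <- fit_multinomial(cohort(d), model_spec("hepatomegaly"))
  expect_equal(f$n_excluded, 3L)
  expect_equal(f$n_used, 27L)
  expect_error(fit_multinomial(cohort(d[d$group == "case", ]),
                               model_spec("hepatomegaly")), "two groups")
})

test_that("models survive JSON serialization bit-for-bit", {
  co <- generate_cohort(mini_config(seed = 47))
  f <- fit_multinomial(co, model_spec(c("splenomegaly", "hepatomegaly", "ataxia")))
  path <- withr::local_tempfile(fileext = ".json")
  save_model(f, path)
  g <- load_model(path)
  expect_identical(coef(g), coef(f))
  # re-evaluation on all 8 patterns
  pats <- expand.grid(splenomegaly = 0:1, hepatomegaly = 0:1, ataxia = 0:1)
  expect_identical(predict(g, pats), predict(f, pats))
  # truncated and mis-versioned files are rejected
  txt <- readLines(path)
  writeLines(txt[1:5], path)
  expect_error(load_model(path), "model")
  jsonlite::write_json(list(schema_version = "other/9"), path, auto_unbox = TRUE)
  expect_error(load_model(path), "schema")
})

test_that("probability outputs are simplex-valued for any finite model", {
  set.seed(51)
  for (i in 1:20) {
    m <- manual_model(rnorm(6, sd = 5), c("ataxia", "splenomegaly"))
    p <- predict_proba(m, c(ataxia = rbinom(1, 1, 0.5),
                            splenomegaly = rbinom(1, 1, 0.5)))
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(p > 0))
  }
})
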