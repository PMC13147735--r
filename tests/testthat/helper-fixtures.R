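# Shared fixtures and independent oracles, all built in code.

# Minimal three-patient cohort data frame (one per group).
tiny_cohort_df <- function() {
  data.frame(
    patient_id = c("p1", "p2", "p3"),
    group = c("case", "control", "non_case"),
    subtype = c("B", "none", "none"),
    sex = c("male", "female", "male"),
    age_onset_years = c(2.5, 10, NA),
    age_current_years = c(6, 12, 40),
    splenomegaly = c(1L, 1L, 0L),
    hepatomegaly = c(1L, 0L, NA),
    stringsAsFactors = FALSE)
}

# Small generator config over a reduced catalog; moderate prevalences in
# every group so fits are never separated.
mini_catalog <- function() {
  symptom_catalog(data.frame(
    symptom_id = c("splenomegaly", "hepatomegaly", "ataxia", "family_history_asmd"),
    display_name = c("Splenomegaly", "Hepatomegaly", "Ataxia", "Family history"),
    organ_system = c("visceral", "visceral", "neurological", "other"),
    stringsAsFactors = FALSE))
}

mini_config <- function(n = c(case = 60, control = 60, non_case = 60),
                        prev = NULL, dependence = 0, seed = 42) {
  cat <- mini_catalog()
  if (is.null(prev)) {
    prev <- rbind(case = c(0.8, 0.6, 0.3, 0.2),
                  control = c(0.5, 0.4, 0.5, 0.0),
                  non_case = c(0.1, 0.2, 0.1, 0.0))
    colnames(prev) <- cat$symptom_id
  }
  generator_config(
    group_sizes = n, prevalence = prev, dependence = dependence,
    age_params = list(
      case = list(onset_mean = 8, onset_sd = 5, current_mean = 20, current_sd = 8),
      control = list(onset_mean = 12, onset_sd = 6, current_mean = 25, current_sd = 8),
      non_case = list(onset_mean = 20, onset_sd = 8, current_mean = 35, current_sd = 10)),
    sex_male_rate = c(case = 0.5, control = 0.5, non_case = 0.5),
    seed = seed, catalog = cat)
}

# Candidate variables for the stability selection: published-count symptoms
# with computed cases-vs-controls Fisher p < 0.001, hepatomegaly and
# splenomegaly replaced by the merged variable.
study_candidates <- function() {
  sc <- study_symptom_counts()
  sc <- sc[sc$symptom_id != "family_history_asmd", ]
  p <- vapply(seq_len(nrow(sc)), function(i)
    fisher_exact_2x2(contingency_table(sc$cases[i], 48L - sc$cases[i],
                                       sc$controls[i], 52L - sc$controls[i])),
    numeric(1))
  cand <- sc$symptom_id[p < 0.001]
  c("hepatosplenomegaly", setdiff(cand, c("hepatomegaly", "splenomegaly")))
}

# Cohort whose per-symptom case/control counts equal the published table
# exactly (symptom columns filled independently; screening is per-symptom
# so the joint pattern is irrelevant).
published_counts_cohort <- function() {
  sc <- study_symptom_counts()
  n_case <- 48L; n_control <- 52L; n_non <- 808L
  fill <- function(count, n) c(rep(1L, count), rep(0L, n - count))
  d <- data.frame(
    patient_id = sprintf("p%03d", seq_len(n_case + n_control + n_non)),
    group = rep(c("case", "control", "non_case"), c(n_case, n_control, n_non)),
    subtype = "none", sex = "male",
    age_onset_years = 10, age_current_years = 20,
    stringsAsFactors = FALSE)
  d$subtype[d$group == "case"] <- "B"
  for (i in seq_len(nrow(sc)))
    d[[sc$symptom_id[i]]] <- c(fill(sc$cases[i], n_case),
                               fill(sc$controls[i], n_control),
                               fill(sc$non_cases[i], n_non))
  cohort(d)
}

# Independent cMLE oracle: golden-section refinement of a log-spaced grid
# maximization of the conditional noncentral hypergeometric likelihood
# (case-exposure orientation ad/bc).
cmle_grid_oracle <- function(a, b, c, d) {
  m1 <- a + c; n1 <- a + b; n2 <- c + d
  k <- max(0, m1 - n2):min(m1, n1)
  loglik <- function(logpsi)
    (lchoose(n1, a) + lchoose(n2, c) + a * logpsi) -
      max(w <- lchoose(n1, k) + lchoose(n2, m1 - k) + k * logpsi) -
      log(sum(exp(w - max(w))))
  grid <- seq(-15, 15, length.out = 400)
  i <- which.max(vapply(grid, loglik, numeric(1)))
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  exp(stats::optimize(loglik, c(lo, hi), maximum = TRUE, tol = 1e-12)$maximum)
}

# Independent AUC oracle: all-pairs concordance with half-weight ties.
auc_pairs_oracle <- function(case_scores, comp_scores) {
  tot <- 0
  for (s in case_scores)
    tot <- tot + sum(s > comp_scores) + 0.5 * sum(s == comp_scores)
  tot / (length(case_scores) * length(comp_scores))
}

# Conditional expectation of the cases-present cell of a 2x2 table at a
# given odds ratio (case-exposure orientation); independent of the package
# internals.
cond_expectation <- function(a, b, c, d, psi) {
  m1 <- a + c; n1 <- a + b; n2 <- c + d
  k <- max(0, m1 - n2):min(m1, n1)
  w <- lchoose(n1, k) + lchoose(n2, m1 - k) + k * log(psi)
  w <- exp(w - max(w))
  sum(k * w) / sum(w)
}

# Published cases-vs-controls 2x2 table for one symptom.
study_table <- function(symptom) {
  sc <- study_symptom_counts()
  i <- match(symptom, sc$symptom_id)
  contingency_table(sc$cases[i], 48L - sc$cases[i],
                    sc$controls[i], 52L - sc$controls[i])
}

# Score frame for metric/ROC tests: cases then comparators.
scores_df <- function(case, comp, comparator = "control") {
  data.frame(probability_case = c(case, comp),
             group = rep(c("case", comparator), c(length(case), length(comp))),
             stringsAsFactors = FALSE)
}
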