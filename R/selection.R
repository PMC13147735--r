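# EPV-capped best-subset stability selection over repeated stratified
# train/test splits, plus the random-forest importance cross-check.

#' Maximum model size under an events-per-variable rule
#'
#' With `n_events` outcome events and a required minimum of `epv` events
#' per predictor, at most `floor(n_events / epv)` variables are admissible
#' (48 cases at 10 EPV allow four).
#'
#' @param n_events number of events (here: ASMD cases).
#' @param epv required events per variable (default 10).
#' @return Integer cap on model size.
#' @export
max_subset_size_from_epv <- function(n_events, epv = 10) {
  stopifnot(n_events >= 0, epv >= 1)
  if (n_events < epv)
    stop("no admissible model: ", n_events, " events < ", epv, " events per variable")
  as.integer(floor(n_events / epv))
}

#' Merge hepatomegaly and splenomegaly into one variable
#'
#' Adds a `hepatosplenomegaly` column (and catalog entry, visceral). Under
#' the default `"and"` rule the merged variable is present only when both
#' organs are enlarged, `unknown` when one is unknown and the conjunction is
#' undecidable; the `"or"` rule marks it present when either is. Source
#' columns are retained.
#'
#' @param x an `asmd_cohort` whose catalog contains both source symptoms.
#' @param rule `"and"` (default) or `"or"`.
#' @return A new `asmd_cohort`.
#' @export
merge_hepatosplenomegaly <- function(x, rule = c("and", "or")) {
  stopifnot(inherits(x, "asmd_cohort"))
  rule <- match.arg(rule)
  if ("hepatosplenomegaly" %in% x$catalog$symptom_id)
    stop("variable 'hepatosplenomegaly' already exists")
  if (!all(c("hepatomegaly", "splenomegaly") %in% x$catalog$symptom_id))
    stop("catalog lacks hepatomegaly and/or splenomegaly")
  h <- x$data$hepatomegaly; s <- x$data$splenomegaly
  v <- rep(NA_integer_, length(h))
  if (rule == "and") {
    v[!is.na(h) & !is.na(s) & h == 1L & s == 1L] <- 1L
    v[(!is.na(h) & h == 0L) | (!is.na(s) & s == 0L)] <- 0L   # one absent decides
  } else {
    v[(!is.na(h) & h == 1L) | (!is.na(s) & s == 1L)] <- 1L
    v[!is.na(h) & !is.na(s) & h == 0L & s == 0L] <- 0L
  }
  cat2 <- symptom_catalog(rbind(as.data.frame(x$catalog),
                                data.frame(symptom_id = "hepatosplenomegaly",
                                           display_name = "Hepatosplenomegaly",
                                           organ_system = "visceral")))
  d <- x$data
  d$hepatosplenomegaly <- v
  cohort(d, cat2)
}

#' Stability-selection configuration
#'
#' @param candidate_variables symptom_ids entering the subset search.
#' @param repetitions number of random train/test splits (default 1000;
#'   desk-scale runs typically use 100).
#' @param train_fraction fraction of each group assigned to training
#'   (default 0.70, stratified by group).
#' @param epv events-per-variable floor (default 10).
#' @param max_subset_size cap on subset size, or `"auto"` to derive it from
#'   the cohort's case count via [max_subset_size_from_epv()].
#' @param criterion per-repetition winner criterion: held-out
#'   `"test_accuracy"` (default) or `"test_deviance"`. Ties favor the
#'   smaller subset, then lexicographic order.
#' @param frequency_threshold occurrence-frequency cutoff for the final
#'   variable set (default 0.70: keep variables winning in more than 70%
#'   of repetitions).
#' @param seed integer seed.
#' @param ridge_penalty,tolerance passed to the per-subset model fits.
#' @return An object of class `selection_config`.
#' @export
selection_config <- function(candidate_variables, repetitions = 1000L,
                             train_fraction = 0.70, epv = 10L,
                             max_subset_size = "auto",
                             criterion = c("test_accuracy", "test_deviance"),
                             frequency_threshold = 0.70, seed = 1L,
                             ridge_penalty = 1e-2, tolerance = 1e-6) {
  stopifnot(length(candidate_variables) >= 1, !anyDuplicated(candidate_variables),
            repetitions >= 1, train_fraction > 0, train_fraction < 1,
            epv >= 1, frequency_threshold > 0, frequency_threshold < 1)
  if (!identical(max_subset_size, "auto"))
    stopifnot(max_subset_size >= 1)
  structure(list(candidate_variables = as.character(candidate_variables),
                 repetitions = as.integer(repetitions),
                 train_fraction = train_fraction, epv = as.integer(epv),
                 max_subset_size = max_subset_size,
                 criterion = match.arg(criterion),
                 frequency_threshold = frequency_threshold,
                 seed = as.integer(seed), ridge_penalty = ridge_penalty,
                 tolerance = tolerance),
            class = "selection_config")
}

#' Best-subset stability selection
#'
#' For each repetition: a stratified-by-group random split at
#' `train_fraction`; every non-empty candidate subset up to the size cap is
#' fitted on the training part ([fit_multinomial()] objective) and scored
#' on the held-out part; the winning subset is recorded. Variables are then
#' ranked by the fraction of repetitions whose winner contains them, and
#' the final set keeps those above `frequency_threshold`. The enumeration
#' is exact (no heuristic search); ties break toward parsimony and then
#' lexicographic subset order, so results are invariant to candidate
#' ordering.
#'
#' @param x an `asmd_cohort` containing all three groups.
#' @param config a [selection_config()].
#' @return An object of class `sit_selection`: list with `per_rep_winners`,
#'   `criterion_values`, `occurrence_frequency`, `final_set`, `config`,
#'   `n_redrawn`.
#' @export
best_subset_select <- function(x, config) {
  stopifnot(inherits(x, "asmd_cohort"), inherits(config, "selection_config"))
  cand <- config$candidate_variables
  bad <- setdiff(cand, x$catalog$symptom_id)
  if (length(bad)) stop("candidates not in catalog: ", paste(bad, collapse = ", "))
  d <- x$data
  V <- as.matrix(d[, cand, drop = FALSE])
  keep <- stats::complete.cases(V)
  d <- d[keep, , drop = FALSE]; V <- V[keep, , drop = FALSE]
  gc <- table(factor(d$group, levels = .groups))
  if (any(gc == 0)) stop("cohort must contain all three groups")
  m <- if (identical(config$max_subset_size, "auto"))
    min(max_subset_size_from_epv(gc[["case"]], config$epv), length(cand))
  else min(config$max_subset_size, length(cand))
  subsets <- unlist(lapply(seq_len(m), function(k)
    utils::combn(seq_along(cand), k, simplify = FALSE)), recursive = FALSE)
  if (length(subsets) > 50000)
    stop("subset enumeration too large (", length(subsets),
         " subsets); reduce candidates or max_subset_size")
  # canonical tie-break order: size, then lexicographic by sorted names
  subset_key <- vapply(subsets, function(s) paste(sort(cand[s]), collapse = ","), "")
  tie_order <- order(lengths(subsets), subset_key)
  classes <- c("case", "control", "non_case")
  y <- match(d$group, classes)
  grp_idx <- split(seq_len(nrow(d)), d$group)
  maximize <- config$criterion == "test_accuracy"
  set.seed(config$seed)
  winners <- vector("list", config$repetitions)
  crit_vals <- numeric(config$repetitions)
  n_redrawn <- 0L
  for (rep_i in seq_len(config$repetitions)) {
    repeat {
      tr <- unlist(lapply(grp_idx, function(ix)
        sample(ix, max(1L, floor(config$train_fraction * length(ix))))),
        use.names = FALSE)
      if (length(unique(y[tr])) == 3L && length(unique(y[-tr])) >= 2L) break
      n_redrawn <- n_redrawn + 1L
    }
    n_te <- length(y) - length(tr)
    # one aggregation over the full candidate set per split; each subset
    # then collapses the distinct patterns rather than rescanning patients
    agg_tr <- .aggregate_patterns(V[tr, , drop = FALSE], y[tr], 3L)
    agg_te <- .aggregate_patterns(V[-tr, , drop = FALSE], y[-tr], 3L)
    Vtr_pat <- agg_tr$X[, -1, drop = FALSE]
    Vte_pat <- agg_te$X[, -1, drop = FALSE]
    vals <- vapply(subsets, function(s) {
      agg <- .collapse_patterns(Vtr_pat, agg_tr$N, s)
      fit <- .multinom_newton(agg$X, agg$N, config$ridge_penalty,
                              tol = config$tolerance, maxit = 50L)
      te <- .collapse_patterns(Vte_pat, agg_te$N, s)
      eta <- te$X %*% fit$B
      mm <- .rowmax0(eta)
      dd <- exp(-mm) + rowSums(exp(eta - mm))
      P <- cbind(exp(eta - mm), exp(-mm)) / dd
      if (maximize) {
        pred <- max.col(P, ties.method = "first")
        sum(te$N[cbind(seq_len(nrow(P)), pred)]) / n_te
      } else -sum(te$N * log(pmax(P, 1e-300))) * 2
    }, numeric(1))
    score <- if (maximize) vals else -vals
    best <- tie_order[which.max(score[tie_order])]
    winners[[rep_i]] <- sort(cand[subsets[[best]]])
    crit_vals[rep_i] <- vals[best]
  }
  freq <- vapply(cand, function(v)
    mean(vapply(winners, function(w) v %in% w, logical(1))), numeric(1))
  final_set <- names(freq)[freq > config$frequency_threshold]
  structure(list(per_rep_winners = winners, criterion_values = crit_vals,
                 occurrence_frequency = freq, final_set = final_set,
                 max_subset_size = m, config = config, n_redrawn = n_redrawn),
            class = "sit_selection")
}

#' @export
print.sit_selection <- function(x, ...) {
  cat(sprintf("Best-subset stability selection: %d repetitions, %d candidates, size cap %d\n",
              x$config$repetitions, length(x$config$candidate_variables),
              x$max_subset_size))
  f <- sort(x$occurrence_frequency, decreasing = TRUE)
  for (v in names(f))
    cat(sprintf("  %-42s %5.1f%%%s\n", v, 100 * f[v],
                if (v %in% x$final_set) "  *" else ""))
  cat(sprintf("Final set (> %.0f%%): %s\n", 100 * x$config$frequency_threshold,
              paste(x$final_set, collapse = ", ")))
  invisible(x)
}

#' Random-forest variable importance
#'
#' Cross-check for the best-subset search: repeated random-forest fits of
#' group on the candidate variables, averaging the mean decrease in
#' impurity (Gini) per variable over repetitions, ranked descending.
#'
#' @param x an `asmd_cohort`.
#' @param candidates symptom_ids to rank.
#' @param repetitions number of forest fits to average (default 100).
#' @param seed integer seed.
#' @param ntree trees per forest.
#' @return data.frame with `symptom_id` and `importance`, sorted
#'   descending.
#' @export
forest_importance <- function(x, candidates, repetitions = 100L, seed = 1L,
                              ntree = 200L) {
  stopifnot(inherits(x, "asmd_cohort"), length(candidates) >= 1)
  d <- x$data
  V <- as.data.frame(d[, candidates, drop = FALSE])
  keep <- stats::complete.cases(V)
  V <- V[keep, , drop = FALSE]
  yy <- factor(d$group[keep], levels = .groups)
  set.seed(seed)
  acc <- stats::setNames(numeric(length(candidates)), candidates)
  n_ok <- 0L
  for (i in seq_len(repetitions)) {
    fit <- tryCatch(randomForest::randomForest(x = V, y = yy, ntree = ntree),
                    error = function(e) NULL)
    if (is.null(fit)) next
    imp <- fit$importance[, "MeanDecreaseGini"]
    acc <- acc + imp[candidates]
    n_ok <- n_ok + 1L
  }
  if (!n_ok) stop("all forest fits failed")
  out <- data.frame(symptom_id = candidates, importance = unname(acc / n_ok),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$importance), , drop = FALSE]
  rownames(out) <- NULL
  out
}
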