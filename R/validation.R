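# Internal validation: fixed-cutoff classification metrics, ROC/AUC with
# the midrank tie convention, and stratified bootstrap with percentile
# confidence intervals.

.contrasts <- c("case_vs_control", "case_vs_non_case")

.contrast_comparator <- function(contrast) {
  switch(contrast, case_vs_control = "control", case_vs_non_case = "non_case",
         stop("unknown contrast: ", contrast))
}

#' Fixed-cutoff classification metrics for one contrast
#'
#' Within the two groups of the contrast: sensitivity is the fraction of
#' cases scoring at or above the cutoff, specificity the fraction of the
#' comparator group scoring below it, accuracy the overall correct
#' fraction.
#'
#' @param scores data.frame with columns `probability_case` and `group`.
#' @param contrast `"case_vs_control"` or `"case_vs_non_case"`.
#' @param cutoff probability cutoff (default 0.50).
#' @return Named numeric vector `c(accuracy, sensitivity, specificity)`.
#' @export
classification_metrics <- function(scores, contrast = "case_vs_control",
                                   cutoff = 0.50) {
  comp <- .contrast_comparator(contrast)
  s_case <- scores$probability_case[scores$group == "case"]
  s_comp <- scores$probability_case[scores$group == comp]
  if (!length(s_case) || !length(s_comp))
    stop("both classes of the contrast must be present")
  sens <- mean(s_case >= cutoff)
  spec <- mean(s_comp < cutoff)
  acc <- (sum(s_case >= cutoff) + sum(s_comp < cutoff)) /
    (length(s_case) + length(s_comp))
  c(accuracy = acc, sensitivity = sens, specificity = spec)
}

#' ROC curve and AUC for one contrast
#'
#' Thresholds at the unique score values; the AUC is computed by the
#' trapezoidal rule, which with this construction equals the normalized
#' rank-sum (Mann-Whitney) statistic: ties between a case and a comparator
#' count one half.
#'
#' @inheritParams classification_metrics
#' @return List of class `sit_roc`: `points` (data.frame `threshold`,
#'   `fpr`, `tpr`, from (0,0) to (1,1)) and `auc`.
#' @export
roc_curve <- function(scores, contrast = "case_vs_control") {
  comp <- .contrast_comparator(contrast)
  s_case <- scores$probability_case[scores$group == "case"]
  s_comp <- scores$probability_case[scores$group == comp]
  if (!length(s_case) || !length(s_comp))
    stop("both classes of the contrast must be present")
  th <- sort(unique(c(s_case, s_comp)), decreasing = TRUE)
  tpr <- vapply(th, function(t) mean(s_case >= t), numeric(1))
  fpr <- vapply(th, function(t) mean(s_comp >= t), numeric(1))
  pts <- data.frame(threshold = c(Inf, th), fpr = c(0, fpr), tpr = c(0, tpr))
  if (pts$fpr[nrow(pts)] != 1 || pts$tpr[nrow(pts)] != 1)
    pts <- rbind(pts, data.frame(threshold = -Inf, fpr = 1, tpr = 1))
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
  structure(list(points = pts, auc = auc, contrast = contrast), class = "sit_roc")
}

#' @export
print.sit_roc <- function(x, ...) {
  cat(sprintf("ROC (%s): %d operating points, AUC = %.4f\n",
              x$contrast, nrow(x$points), x$auc))
  invisible(x)
}

#' @export
plot.sit_roc <- function(x, ...) {
  graphics::plot(x$points$fpr, x$points$tpr, type = "l",
                 xlab = "1 - specificity", ylab = "sensitivity",
                 main = sprintf("%s (AUC = %.3f)", x$contrast, x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Validation configuration
#'
#' @param bootstrap_reps number of bootstrap repetitions (default 1000;
#'   desk-scale runs typically use 100).
#' @param ci_level percentile confidence level (default 0.95).
#' @param contrasts which one-vs-one contrasts to evaluate.
#' @param seed integer seed.
#' @return An object of class `validation_config`.
#' @export
validation_config <- function(bootstrap_reps = 1000L, ci_level = 0.95,
                              contrasts = .contrasts, seed = 1L) {
  stopifnot(bootstrap_reps >= 1, ci_level > 0, ci_level < 1,
            all(contrasts %in% .contrasts))
  structure(list(bootstrap_reps = as.integer(bootstrap_reps),
                 ci_level = ci_level, contrasts = contrasts,
                 seed = as.integer(seed)),
            class = "validation_config")
}

# Tool probabilities for every complete-case patient (ungated: validation
# scores the underlying model on each patient's actual symptom values).
.cohort_scores <- function(model, cohort) {
  vars <- model$spec$variables
  d <- cohort$data
  keep <- stats::complete.cases(d[, vars, drop = FALSE])
  d <- d[keep, , drop = FALSE]
  P <- predict(model, d)
  data.frame(probability_case = P[, "case"], group = d$group,
             stringsAsFactors = FALSE)
}

#' Bootstrap internal validation of a suspicion-index tool
#'
#' Each repetition resamples patients with replacement stratified by group,
#' refits the tool's multinomial model on a stratified 70% training part of
#' the resample, and evaluates accuracy, sensitivity, specificity (at the
#' tool's cutoff) and AUC on the held-out 30% for every requested contrast.
#' Point estimates come from the model refitted to the full cohort;
#' confidence bounds are percentile order statistics of the bootstrap
#' distribution.
#'
#' @param x a [sit_model()].
#' @param cohort an `asmd_cohort`.
#' @param config a [validation_config()].
#' @param train_fraction within-resample training fraction (default 0.70).
#' @return An object of class `sit_validation`: per contrast a list with
#'   `estimate` (accuracy/sensitivity/specificity/auc), matching `lower`
#'   and `upper` percentile bounds, `roc` (full-cohort ROC) and the matrix
#'   of bootstrap replicates.
#' @export
bootstrap_validate <- function(x, cohort, config = validation_config(),
                               train_fraction = 0.70) {
  stopifnot(inherits(x, "sit_model"), inherits(cohort, "asmd_cohort"),
            inherits(config, "validation_config"))
  vars <- x$model$spec$variables
  d <- cohort$data
  keep <- stats::complete.cases(d[, vars, drop = FALSE])
  d <- d[keep, , drop = FALSE]
  spec <- x$model$spec
  refit_scores <- function(dd, tr) {
    fit <- fit_multinomial(cohort(dd[tr, , drop = FALSE], cohort$catalog), spec)
    te <- dd[-tr, , drop = FALSE]
    P <- predict(fit, te)
    data.frame(probability_case = P[, "case"], group = te$group,
               stringsAsFactors = FALSE)
  }
  grp_idx <- split(seq_len(nrow(d)), d$group)
  set.seed(config$seed)
  metric_names <- c("accuracy", "sensitivity", "specificity", "auc")
  reps <- lapply(config$contrasts, function(ct)
    matrix(NA_real_, config$bootstrap_reps, 4,
           dimnames = list(NULL, metric_names)))
  names(reps) <- config$contrasts
  n_redrawn <- 0L
  for (b in seq_len(config$bootstrap_reps)) {
    repeat {
      boot <- unlist(lapply(grp_idx, function(ix)
        sample(ix, length(ix), replace = TRUE)), use.names = FALSE)
      dd <- d[boot, , drop = FALSE]
      dd$patient_id <- sprintf("b%07d", seq_len(nrow(dd)))
      tr <- unlist(lapply(split(seq_len(nrow(dd)), dd$group), function(ix)
        sample(ix, max(1L, floor(train_fraction * length(ix))))), use.names = FALSE)
      if (length(unique(dd$group[tr])) == 3L &&
          length(unique(dd$group[-tr])) >= 2L) break
      n_redrawn <- n_redrawn + 1L
    }
    sc <- suppressWarnings(refit_scores(dd, tr))
    for (ct in config$contrasts) {
      comp <- .contrast_comparator(ct)
      if (!any(sc$group == "case") || !any(sc$group == comp)) next
      m <- classification_metrics(sc, ct, x$cutoff)
      reps[[ct]][b, ] <- c(m, roc_curve(sc, ct)$auc)
    }
  }
  full <- .cohort_scores(x$model, cohort)
  alpha <- (1 - config$ci_level) / 2
  out <- lapply(config$contrasts, function(ct) {
    m <- classification_metrics(full, ct, x$cutoff)
    roc <- roc_curve(full, ct)
    est <- c(m, auc = roc$auc)
    R <- reps[[ct]]
    lower <- apply(R, 2, stats::quantile, probs = alpha, na.rm = TRUE, names = FALSE)
    upper <- apply(R, 2, stats::quantile, probs = 1 - alpha, na.rm = TRUE, names = FALSE)
    list(estimate = est, lower = stats::setNames(lower, metric_names),
         upper = stats::setNames(upper, metric_names), roc = roc, replicates = R)
  })
  names(out) <- config$contrasts
  structure(list(contrasts = out, config = config, cutoff = x$cutoff,
                 n_redrawn = n_redrawn),
            class = "sit_validation")
}

#' @export
print.sit_validation <- function(x, ...) {
  cat(sprintf("Bootstrap internal validation: %d repetitions, cutoff %.3f, %.0f%% percentile CIs\n",
              x$config$bootstrap_reps, x$cutoff, 100 * x$config$ci_level))
  for (ct in names(x$contrasts)) {
    r <- x$contrasts[[ct]]
    cat(" ", ct, "\n")
    for (mname in names(r$estimate))
      cat(sprintf("    %-12s %.3f  [%.3f, %.3f]\n", mname,
                  r$estimate[mname], r$lower[mname], r$upper[mname]))
  }
  invisible(x)
}

#' @export
plot.sit_validation <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, length(x$contrasts)))
  on.exit(graphics::par(op))
  for (ct in names(x$contrasts)) plot(x$contrasts[[ct]]$roc, ...)
  invisible(x)
}
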