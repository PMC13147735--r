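# The suspicion-index calculator: prerequisite gate, 0/1 symptom inputs,
# ASMD probability, full pattern table, risk cutoff.

#' Construct a suspicion-index tool
#'
#' Wraps a fitted multinomial risk model into the deployed-tool semantics:
#' hepatosplenomegaly acts as a prerequisite gate (patients without it are
#' never scored; it enters the model as a predictor fixed at 1 during
#' scoring), the remaining variables are 0/1 inputs, and a probability
#' cutoff flags high risk.
#'
#' @param model an `asmd_multinom` whose variables are exactly
#'   `{prerequisite} U inputs`.
#' @param prerequisite symptom_id of the gate (default
#'   `hepatosplenomegaly`).
#' @param inputs ordered symptom_ids of the tool's 0/1 questions; default
#'   the development study's three
#'   (thrombocytopenia with bleeding, interstitial lung disease, mixed
#'   dyslipidemia with low HDL-C).
#' @param cutoff high-risk probability cutoff in (0,1); default 0.50, the
#'   study's median case score. See [derive_cutoff()].
#' @return An object of class `sit_model`.
#' @export
sit_model <- function(model, prerequisite = "hepatosplenomegaly",
                      inputs = c("thrombocytopenia_bleeding",
                                 "interstitial_lung_disease",
                                 "mixed_dyslipidemia_low_hdl"),
                      cutoff = 0.50) {
  stopifnot(inherits(model, "asmd_multinom"), cutoff > 0, cutoff < 1)
  if (prerequisite %in% inputs) stop("prerequisite must not be among inputs")
  if (!setequal(model$spec$variables, c(prerequisite, inputs)))
    stop("model variables must be exactly the prerequisite plus the inputs")
  structure(list(prerequisite = prerequisite, inputs = inputs,
                 model = model, cutoff = cutoff),
            class = "sit_model")
}

#' @export
print.sit_model <- function(x, ...) {
  cat("ASMD suspicion-index tool\n")
  cat("  prerequisite:", x$prerequisite, "\n")
  cat("  inputs:      ", paste(x$inputs, collapse = ", "), "\n")
  cat(sprintf("  high-risk cutoff: P(case) >= %.3f\n", x$cutoff))
  invisible(x)
}

#' Score one symptom pattern with the suspicion-index tool
#'
#' If the prerequisite is absent the tool declines (`gated = TRUE`) and no
#' probability is emitted. Otherwise the result carries the multinomial
#' probabilities of being a case, a control (another lysosomal storage
#' disorder) or a non-case, plus a high-risk flag.
#'
#' @param x a [sit_model()].
#' @param pattern named vector/list with 0/1 entries for the prerequisite
#'   and every input.
#' @return An object of class `sit_result`: list with `gated`,
#'   `probability_case`, `probability_control`, `probability_non_case`,
#'   `high_risk`, `pattern`.
#' @export
sit_score <- function(x, pattern) {
  stopifnot(inherits(x, "sit_model"))
  pattern <- unlist(pattern)
  need <- c(x$prerequisite, x$inputs)
  miss <- setdiff(need, names(pattern))
  if (length(miss)) stop("pattern lacks field(s): ", paste(miss, collapse = ", "))
  v <- pattern[need]
  bad <- !v %in% c(0, 1)
  if (any(bad)) stop("non-binary entry for field(s): ",
                     paste(need[bad], collapse = ", "))
  if (v[[x$prerequisite]] == 0)
    return(structure(list(gated = TRUE, probability_case = NA_real_,
                          probability_control = NA_real_,
                          probability_non_case = NA_real_,
                          high_risk = NA, pattern = v), class = "sit_result"))
  p <- predict_proba(x$model, v)
  structure(list(gated = FALSE,
                 probability_case = unname(p["case"]),
                 probability_control = unname(p["control"]),
                 probability_non_case = unname(p["non_case"]),
                 high_risk = unname(p["case"] >= x$cutoff),
                 pattern = v),
            class = "sit_result")
}

#' @export
print.sit_result <- function(x, ...) {
  if (x$gated) {
    cat("Tool declined: prerequisite absent (no probability emitted)\n")
  } else {
    cat(sprintf("P(ASMD case) = %.2f%%  [control %.2f%%, non-case %.2f%%]  %s\n",
                100 * x$probability_case, 100 * x$probability_control,
                100 * x$probability_non_case,
                if (x$high_risk) "HIGH RISK" else "below cutoff"))
  }
  invisible(x)
}

#' @export
predict.sit_model <- function(object, newdata, ...) {
  if (inherits(newdata, "asmd_cohort")) newdata <- newdata$data
  predict(object$model, newdata, ...)
}

#' Full probability table over all input patterns
#'
#' Enumerates the `2^k` combinations of the k inputs (prerequisite fixed
#' present) in canonical binary order and tabulates the three class
#' probabilities for each.
#'
#' @param x a [sit_model()].
#' @return data.frame with one 0/1 column per input plus `probability_case`,
#'   `probability_control`, `probability_non_case`, `high_risk`.
#' @export
probability_table <- function(x) {
  stopifnot(inherits(x, "sit_model"))
  k <- length(x$inputs)
  grid <- expand.grid(rep(list(0:1), k), KEEP.OUT.ATTRS = FALSE)
  names(grid) <- x$inputs
  grid <- grid[do.call(order, grid), , drop = FALSE]
  rownames(grid) <- NULL
  res <- lapply(seq_len(nrow(grid)), function(i) {
    pat <- c(stats::setNames(1, x$prerequisite), unlist(grid[i, , drop = FALSE]))
    sit_score(x, pat)
  })
  grid$probability_case <- vapply(res, `[[`, numeric(1), "probability_case")
  grid$probability_control <- vapply(res, `[[`, numeric(1), "probability_control")
  grid$probability_non_case <- vapply(res, `[[`, numeric(1), "probability_non_case")
  grid$high_risk <- vapply(res, `[[`, logical(1), "high_risk")
  grid
}

#' Derive the high-risk cutoff from a cohort
#'
#' The cutoff is the median tool probability of being a case over the
#' cohort's cases that pass the prerequisite gate (the development study
#' reports a median case score of 50%).
#'
#' @param x a [sit_model()].
#' @param cohort an `asmd_cohort` with at least one gated-in case.
#' @return The updated `sit_model` with `cutoff` set; the numeric cutoff is
#'   attached as attribute `"cutoff"`.
#' @export
derive_cutoff <- function(x, cohort) {
  stopifnot(inherits(x, "sit_model"), inherits(cohort, "asmd_cohort"))
  d <- cohort$data
  need <- c(x$prerequisite, x$inputs)
  cases <- d[d$group == "case", need, drop = FALSE]
  cases <- cases[stats::complete.cases(cases) & cases[[x$prerequisite]] == 1L, ,
                 drop = FALSE]
  if (!nrow(cases)) stop("no cases pass the prerequisite gate")
  p_case <- vapply(seq_len(nrow(cases)), function(i)
    sit_score(x, unlist(cases[i, , drop = FALSE]))$probability_case, numeric(1))
  x$cutoff <- stats::median(p_case)
  attr(x, "cutoff") <- x$cutoff
  x
}
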