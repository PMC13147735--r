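# Per-symptom exact-test screening: two-sided Fisher exact p-values,
# conditional-MLE odds ratios, Holm correction, candidate selection.

#' Construct a 2x2 symptom-by-group contingency table
#'
#' Fixed orientation: `a`/`b` are cases with the symptom present/absent,
#' `c`/`d` the comparator group (controls by default) present/absent.
#'
#' @param a,b,c,d non-negative integer cell counts; both rows must be
#'   non-empty (`a + b > 0`, `c + d > 0`).
#' @return An object of class `contingency_2x2`.
#' @export
contingency_table <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("cell counts must be non-negative integers")
  if (a + b <= 0 || c + d <= 0) stop("each group must contain at least one patient")
  counts <- as.integer(counts)
  structure(list(a = counts[1], b = counts[2], c = counts[3], d = counts[4]),
            class = "contingency_2x2")
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, byrow = TRUE,
              dimnames = list(c("cases", "comparator"), c("present", "absent")))
  print(m)
  invisible(x)
}

# Hypergeometric support and log-probabilities for tables sharing the
# margins of `tab`, indexed by the cases-present cell.
.hyper_support <- function(tab) {
  m1 <- tab$a + tab$c          # symptom present margin
  n1 <- tab$a + tab$b          # cases margin
  n2 <- tab$c + tab$d          # comparator margin
  k <- max(0L, m1 - n2):min(m1, n1)
  list(k = k, logp = stats::dhyper(k, n1, n2, m1, log = TRUE))
}

#' Two-sided Fisher exact p-value for a 2x2 table
#'
#' Point-probability method: the sum of central-hypergeometric
#' probabilities, over all tables with the observed margins, that do not
#' exceed the observed table's probability (within relative slack 1e-7
#' to absorb floating error). A degenerate symptom margin (`a + c = 0` or
#' `b + d = 0`) yields p = 1 with a warning.
#'
#' @param tab a [contingency_table()].
#' @return p-value in `(0, 1]`.
#' @export
fisher_exact_2x2 <- function(tab) {
  stopifnot(inherits(tab, "contingency_2x2"))
  if (tab$a + tab$c == 0L || tab$b + tab$d == 0L) {
    warning("degenerate symptom margin; p = 1")
    return(1)
  }
  h <- .hyper_support(tab)
  obs <- h$logp[match(tab$a, h$k)]
  min(1, sum(exp(h$logp[h$logp <= obs + log(1 + 1e-7)])))
}

# Conditional (noncentral hypergeometric) expectation of the cases-present
# cell at log-odds-ratio theta, computed stably on the log scale.
.cond_moment <- function(h, theta) {
  w <- h$logp + h$k * theta
  w <- exp(w - max(w))
  sum(h$k * w) / sum(w)
}

#' Conditional maximum-likelihood odds ratio for a 2x2 table
#'
#' The odds ratio maximizing Fisher's noncentral hypergeometric likelihood
#' given all margins, found by root-finding on the conditional score
#' equation (expected cases-present cell = observed). Orientation follows
#' the development study's reporting convention: the returned value is
#' (odds of the symptom among the comparator group) / (odds among cases) —
#' the reverse of the conventional case-exposure odds ratio, so
#' case-enriched symptoms get values below 1. Boundary tables (the observed
#' cell at the edge of its support) return 0 or `Inf` exactly.
#'
#' @param tab a [contingency_table()].
#' @param orientation `"comparator_vs_case"` (default, the study's printed
#'   direction) or `"case_vs_comparator"` (its reciprocal).
#' @return Non-negative number, possibly 0 or `Inf`; `NaN` with a warning
#'   when a symptom margin is degenerate (odds ratio undefined).
#' @export
odds_ratio_cmle <- function(tab, orientation = c("comparator_vs_case", "case_vs_comparator")) {
  stopifnot(inherits(tab, "contingency_2x2"))
  orientation <- match.arg(orientation)
  if (tab$a + tab$c == 0L || tab$b + tab$d == 0L) {
    warning("degenerate symptom margin; odds ratio undefined")
    return(NaN)
  }
  h <- .hyper_support(tab)
  # psi_case below is the conventional case-exposure direction (ad/bc)
  psi_case <- if (length(h$k) == 1L) 1 else if (tab$a == min(h$k)) 0 else if (tab$a == max(h$k)) Inf else {
    f <- function(theta) .cond_moment(h, theta) - tab$a
    lim <- 35
    while (f(-lim) > 0 || f(lim) < 0) lim <- lim * 2
    exp(stats::uniroot(f, c(-lim, lim), tol = 1e-12)$root)
  }
  if (orientation == "comparator_vs_case") 1 / psi_case else psi_case
}

#' Haldane-Anscombe corrected sample odds ratio
#'
#' Auxiliary finite estimate for boundary tables: 0.5 is added to every
#' cell. Same orientation convention as [odds_ratio_cmle()].
#'
#' @inheritParams odds_ratio_cmle
#' @return Positive finite number.
#' @export
odds_ratio_haldane <- function(tab, orientation = c("comparator_vs_case", "case_vs_comparator")) {
  stopifnot(inherits(tab, "contingency_2x2"))
  orientation <- match.arg(orientation)
  psi_case <- ((tab$a + 0.5) * (tab$d + 0.5)) / ((tab$b + 0.5) * (tab$c + 0.5))
  if (orientation == "comparator_vs_case") 1 / psi_case else psi_case
}

#' Holm (Bonferroni-Holm) step-down multiplicity adjustment
#'
#' Thin wrapper over `stats::p.adjust(method = "holm")`, kept as the
#' package's single entry point for familywise-error correction.
#'
#' @param p numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values in the original order.
#' @export
holm_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "holm")
}

#' Screening configuration
#'
#' @param alpha two-sided significance level for reporting (default 0.05).
#' @param candidate_threshold p-value threshold below which a symptom
#'   becomes a model candidate. The development study states `p < 0.001` in
#'   its methods and `p < 0.01` in its results; the default follows the
#'   methods value.
#' @param comparator `"controls"` (default; the published per-symptom
#'   p-values and odds ratios correspond to the cases-vs-controls contrast)
#'   or `"non_cases"`.
#' @param use_adjusted_for_threshold apply the candidate threshold to the
#'   Holm-adjusted p instead of the raw p (default `FALSE`).
#' @return An object of class `screening_config`.
#' @export
screening_config <- function(alpha = 0.05, candidate_threshold = 0.001,
                             comparator = c("controls", "non_cases"),
                             use_adjusted_for_threshold = FALSE) {
  stopifnot(alpha > 0, alpha < 1, candidate_threshold > 0, candidate_threshold < 1)
  structure(list(alpha = alpha, candidate_threshold = candidate_threshold,
                 comparator = match.arg(comparator),
                 use_adjusted_for_threshold = isTRUE(use_adjusted_for_threshold)),
            class = "screening_config")
}

#' Screen every catalog symptom between cases and a comparator group
#'
#' For each symptom: pairwise-complete 2x2 table (patients with an unknown
#' entry excluded from that symptom's denominators), two-sided Fisher exact
#' p, Holm-adjusted p over the testable family, conditional-MLE odds ratio
#' (comparator/case orientation) and a candidate flag. Results are ordered
#' by organ system and then by descending case prevalence, mirroring the
#' study's summary-table layout.
#'
#' @param x an `asmd_cohort` with non-empty case and comparator groups.
#' @param config a [screening_config()].
#' @return data.frame of class `sit_screening` with one row per symptom:
#'   `symptom_id`, `organ_system`, `case_present`, `case_known`,
#'   `comp_present`, `comp_known`, `case_pct`, `comp_pct`, `p_raw`,
#'   `p_holm`, `or_cmle`, `or_haldane`, `testable`, `candidate`.
#' @export
screen_cohort <- function(x, config = screening_config()) {
  stopifnot(inherits(x, "asmd_cohort"), inherits(config, "screening_config"))
  comp_group <- if (config$comparator == "controls") "control" else "non_case"
  dc <- x$data[x$data$group == "case", , drop = FALSE]
  dm <- x$data[x$data$group == comp_group, , drop = FALSE]
  if (!nrow(dc) || !nrow(dm)) stop("both comparison groups must be non-empty")
  cat <- x$catalog
  n <- nrow(cat)
  out <- data.frame(symptom_id = cat$symptom_id, organ_system = cat$organ_system,
                    case_present = NA_integer_, case_known = NA_integer_,
                    comp_present = NA_integer_, comp_known = NA_integer_,
                    case_pct = NA_real_, comp_pct = NA_real_,
                    p_raw = NA_real_, p_holm = NA_real_,
                    or_cmle = NA_real_, or_haldane = NA_real_,
                    testable = FALSE, candidate = FALSE, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    vc <- dc[[cat$symptom_id[i]]]; vm <- dm[[cat$symptom_id[i]]]
    a <- sum(vc == 1L, na.rm = TRUE); ka <- sum(!is.na(vc))
    cc <- sum(vm == 1L, na.rm = TRUE); km <- sum(!is.na(vm))
    out$case_present[i] <- a; out$case_known[i] <- ka
    out$comp_present[i] <- cc; out$comp_known[i] <- km
    out$case_pct[i] <- 100 * a / ka; out$comp_pct[i] <- 100 * cc / km
    if (ka > 0 && km > 0) {
      out$testable[i] <- TRUE
      tab <- contingency_table(a, ka - a, cc, km - cc)
      out$p_raw[i] <- suppressWarnings(fisher_exact_2x2(tab))
      out$or_cmle[i] <- suppressWarnings(odds_ratio_cmle(tab))
      out$or_haldane[i] <- odds_ratio_haldane(tab)
    }
  }
  # untestable symptoms are excluded from the Holm family
  out$p_holm[out$testable] <- holm_adjust(out$p_raw[out$testable])
  p_for_threshold <- if (config$use_adjusted_for_threshold) out$p_holm else out$p_raw
  out$candidate <- out$testable & !is.na(p_for_threshold) &
    p_for_threshold < config$candidate_threshold
  ord <- order(factor(out$organ_system,
                      levels = c("neurological", "visceral", "skeletal", "other")),
               -out$case_present)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "config") <- config
  class(out) <- c("sit_screening", "data.frame")
  out
}

#' @export
print.sit_screening <- function(x, digits = 3, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("Exact-test screening, cases vs %s (candidate threshold p < %g%s)\n",
              cfg$comparator, cfg$candidate_threshold,
              if (cfg$use_adjusted_for_threshold) ", Holm-adjusted" else ""))
  show <- data.frame(symptom = x$symptom_id,
                     cases = sprintf("%d (%.0f%%)", x$case_present, x$case_pct),
                     comparator = sprintf("%d (%.0f%%)", x$comp_present, x$comp_pct),
                     p = signif(x$p_raw, digits), p_holm = signif(x$p_holm, digits),
                     OR = signif(x$or_cmle, digits),
                     candidate = ifelse(x$candidate, "*", ""))
  print(show, row.names = FALSE)
  invisible(x)
}
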