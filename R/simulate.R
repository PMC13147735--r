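# Seeded synthetic-cohort generator: three groups, per-group symptom
# prevalences, optional within-patient dependence via a shared latent factor.

#' Construct a synthetic-cohort generator configuration
#'
#' The generator draws, per patient, a standard-normal latent severity z and
#' then each symptom independently from
#' `Bernoulli(plogis(alpha_gj + dependence * z))`, where the intercept
#' `alpha_gj` is recalibrated by 1-D numerical integration so that the
#' marginal prevalence stays at the configured `p_gj` for any dependence.
#' `dependence = 0` gives exactly independent symptoms.
#'
#' @param group_sizes named positive integer vector over
#'   `case`, `control`, `non_case`.
#' @param prevalence numeric matrix of symptom prevalences in `[0,1]`;
#'   rows named by group, columns by catalog `symptom_id`.
#' @param dependence non-negative latent-factor loading (log-odds shift per
#'   unit z); 0 = independent symptoms.
#' @param age_params per-group list of `onset_mean`, `onset_sd`,
#'   `current_mean`, `current_sd` in years (normal, truncated at 0, with
#'   onset <= current enforced by resampling).
#' @param sex_male_rate named probability vector per group.
#' @param family_history_rate named probability vector per group; overrides
#'   the `family_history_asmd` column of `prevalence`.
#' @param subtype_probs probabilities for ASMD subtypes `A`, `AB`, `B`
#'   assigned to cases.
#' @param seed integer root seed; per-group substreams are derived from it
#'   so changing one group size does not perturb the others.
#' @param catalog a [symptom_catalog()].
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(group_sizes, prevalence, dependence = 0,
                             age_params, sex_male_rate,
                             family_history_rate = NULL,
                             subtype_probs = c(A = 1/3, AB = 1/3, B = 1/3),
                             seed = 1L, catalog = default_catalog()) {
  stopifnot(all(.groups %in% names(group_sizes)),
            all(group_sizes[.groups] >= 1),
            is.matrix(prevalence),
            all(.groups %in% rownames(prevalence)),
            dependence >= 0)
  prevalence <- prevalence[.groups, , drop = FALSE]
  extra <- setdiff(colnames(prevalence), catalog$symptom_id)
  if (length(extra)) stop("prevalence for unknown symptoms: ", paste(extra, collapse = ", "))
  for (s in setdiff(catalog$symptom_id, colnames(prevalence))) {
    prevalence <- cbind(prevalence, 0)
    colnames(prevalence)[ncol(prevalence)] <- s
  }
  prevalence <- prevalence[, catalog$symptom_id, drop = FALSE]
  if (any(prevalence < 0 | prevalence > 1)) stop("prevalences must lie in [0,1]")
  if (!is.null(family_history_rate))
    prevalence[names(family_history_rate), "family_history_asmd"] <-
      family_history_rate
  for (g in .groups) {
    a <- age_params[[g]]
    stopifnot(all(c("onset_mean", "onset_sd", "current_mean", "current_sd") %in% names(a)),
              a$onset_sd >= 0, a$current_sd >= 0)
  }
  stopifnot(all(sex_male_rate[.groups] >= 0 & sex_male_rate[.groups] <= 1),
            length(subtype_probs) == 3, all(subtype_probs >= 0), sum(subtype_probs) > 0)
  structure(list(group_sizes = vapply(.groups, function(g) as.integer(group_sizes[[g]]),
                                      integer(1)),
                 prevalence = prevalence, dependence = dependence,
                 age_params = age_params[.groups],
                 sex_male_rate = vapply(.groups, function(g) sex_male_rate[[g]], numeric(1)),
                 subtype_probs = subtype_probs / sum(subtype_probs),
                 seed = as.integer(seed), catalog = catalog),
            class = "generator_config")
}

#' Default configuration emulating the ASMD development study
#'
#' Group sizes 48 / 52 / 808; per-group symptom prevalences equal to the
#' published per-group counts over group size ([study_symptom_counts()]);
#' demographics (sex split, onset/current age means and SDs, family-history
#' rates) matching the published summary table. The default latent-factor
#' loading of 1 reproduces, qualitatively, the observed within-patient
#' co-occurrence of visceral signs (isolated hepatomegaly without
#' splenomegaly being rare); set `dependence = 0` for exactly independent
#' symptoms.
#'
#' @param size_multiplier integer factor applied to all three group sizes
#'   (e.g. 10 for a 480/520/8080 cohort).
#' @param dependence latent-factor loading, default 1.
#' @param seed root seed.
#' @return A [generator_config()].
#' @export
default_study_config <- function(size_multiplier = 1, dependence = 1, seed = 1L) {
  counts <- study_symptom_counts()
  sizes <- study_group_sizes()
  prev <- rbind(case = counts$cases / sizes["case"],
                control = counts$controls / sizes["control"],
                non_case = counts$non_cases / sizes["non_case"])
  colnames(prev) <- counts$symptom_id
  generator_config(
    group_sizes = sizes * as.integer(size_multiplier),
    prevalence = prev,
    dependence = dependence,
    age_params = list(
      case     = list(onset_mean = 8.6,  onset_sd = 12.7, current_mean = 20.4, current_sd = 15.9),
      control  = list(onset_mean = 11.6, onset_sd = 10.9, current_mean = 22.9, current_sd = 14.8),
      non_case = list(onset_mean = 34.9, onset_sd = 19.3, current_mean = 14.0, current_sd = 5.4)),
    sex_male_rate = c(case = 26/48, control = 24/52, non_case = 520/808),
    family_history_rate = c(case = 10/48, control = 0, non_case = 0),
    seed = seed)
}

# Intercept calibration: find alpha with E_z[plogis(alpha + lambda z)] = p.
# Monotone in alpha, so a uniroot on a widening bracket always succeeds.
.calibrate_intercept <- function(p, lambda) {
  if (p <= 0) return(-Inf)
  if (p >= 1) return(Inf)
  if (lambda == 0) return(stats::qlogis(p))
  marg <- function(alpha)
    stats::integrate(function(z) stats::plogis(alpha + lambda * z) * stats::dnorm(z),
                     -Inf, Inf, rel.tol = 1e-10)$value
  f <- function(alpha) marg(alpha) - p
  lo <- stats::qlogis(p) - 5 * lambda - 5
  hi <- stats::qlogis(p) + 5 * lambda + 5
  stats::uniroot(f, c(lo, hi), tol = 1e-10, extendInt = "upX")$root
}

.substream_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + index * 104729) %% 2147483629L)
}

.rtnorm_pos <- function(n, mean, sd) {
  if (sd == 0) return(rep(max(mean, 0), n))
  x <- stats::rnorm(n, mean, sd)
  for (i in 1:100) {
    bad <- x < 0
    if (!any(bad)) break
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  x[x < 0] <- 0
  x
}

#' Generate a synthetic cohort
#'
#' Deterministic given the configuration's seed: the same configuration
#' always yields an identical cohort.
#'
#' @param config a [generator_config()].
#' @return An `asmd_cohort`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  cat <- config$catalog
  lambda <- config$dependence
  alphas <- if (lambda > 0)
    apply(config$prevalence, c(1, 2), .calibrate_intercept, lambda = lambda)
  parts <- vector("list", length(.groups))
  for (gi in seq_along(.groups)) {
    g <- .groups[gi]
    n <- config$group_sizes[[g]]
    set.seed(.substream_seed(config$seed, gi))
    z <- stats::rnorm(n)
    sym <- matrix(NA_integer_, n, nrow(cat), dimnames = list(NULL, cat$symptom_id))
    for (j in seq_len(nrow(cat))) {
      p <- config$prevalence[g, j]
      prob <- if (lambda == 0 || p <= 0 || p >= 1) rep(p, n)
              else stats::plogis(alphas[g, j] + lambda * z)
      sym[, j] <- stats::rbinom(n, 1L, prob)
    }
    ap <- config$age_params[[g]]
    onset <- .rtnorm_pos(n, ap$onset_mean, ap$onset_sd)
    current <- .rtnorm_pos(n, ap$current_mean, ap$current_sd)
    # onset precedes current age; resample offending pairs, then clamp
    for (i in 1:100) {
      bad <- onset > current
      if (!any(bad)) break
      onset[bad] <- .rtnorm_pos(sum(bad), ap$onset_mean, ap$onset_sd)
      current[bad] <- .rtnorm_pos(sum(bad), ap$current_mean, ap$current_sd)
    }
    onset <- pmin(onset, current)
    sex <- ifelse(stats::runif(n) < config$sex_male_rate[[g]], "male", "female")
    subtype <- if (g == "case")
      sample(c("A", "AB", "B"), n, replace = TRUE, prob = config$subtype_probs)
    else rep("none", n)
    parts[[gi]] <- data.frame(
      patient_id = sprintf("%s_%04d", g, seq_len(n)), group = g,
      subtype = subtype, sex = sex,
      age_onset_years = round(onset, 1), age_current_years = round(current, 1),
      sym, stringsAsFactors = FALSE)
  }
  cohort(do.call(rbind, parts), cat)
}

#' Per-group symptom prevalence table
#'
#' Counts of `present` over non-`unknown` entries, per group and symptom.
#' A symptom with no known entries in a group gets count 0, denominator 0
#' and proportion `NaN`.
#'
#' @param x an `asmd_cohort` with at least one patient.
#' @return data.frame with columns `group`, `symptom_id`, `n_present`,
#'   `n_known`, `proportion`.
#' @export
prevalence_table <- function(x) {
  stopifnot(inherits(x, "asmd_cohort"))
  if (!nrow(x$data)) stop("cohort is empty")
  out <- expand.grid(group = .groups, symptom_id = x$catalog$symptom_id,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$n_present <- NA_integer_; out$n_known <- NA_integer_
  for (i in seq_len(nrow(out))) {
    v <- x$data[[out$symptom_id[i]]][x$data$group == out$group[i]]
    out$n_present[i] <- sum(v == 1L, na.rm = TRUE)
    out$n_known[i] <- sum(!is.na(v))
  }
  out$proportion <- out$n_present / out$n_known
  out
}

#' Read / write a generator configuration
#'
#' Configurations serialize to JSON (or YAML when the file extension is
#' `.yaml`/`.yml` and the yaml package is installed).
#'
#' @param path file path.
#' @param config a [generator_config()].
#' @name generator_config_io
#' @return `read_generator_config` returns a [generator_config()];
#'   `write_generator_config` returns `path` invisibly.
NULL

.config_to_list <- function(config) {
  list(group_sizes = as.list(config$group_sizes),
       prevalence = stats::setNames(
         lapply(.groups, function(g) as.list(config$prevalence[g, ])), .groups),
       dependence = config$dependence,
       age_params = config$age_params,
       sex_male_rate = as.list(config$sex_male_rate),
       subtype_probs = stats::setNames(as.list(config$subtype_probs), c("A", "AB", "B")),
       seed = config$seed)
}

#' @rdname generator_config_io
#' @export
write_generator_config <- function(config, path) {
  stopifnot(inherits(config, "generator_config"))
  x <- .config_to_list(config)
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) stop("yaml package not installed")
    yaml::write_yaml(x, path)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  }
  invisible(path)
}

#' @rdname generator_config_io
#' @export
read_generator_config <- function(path, catalog = default_catalog()) {
  x <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) stop("yaml package not installed")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  prev <- do.call(rbind, lapply(.groups, function(g) unlist(x$prevalence[[g]])))
  rownames(prev) <- .groups
  generator_config(group_sizes = unlist(x$group_sizes),
                   prevalence = prev, dependence = x$dependence,
                   age_params = x$age_params,
                   sex_male_rate = unlist(x$sex_male_rate),
                   subtype_probs = unlist(x$subtype_probs),
                   seed = x$seed, catalog = catalog)
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf("Synthetic cohort generator: n = %s; dependence = %g; seed = %d\n",
              paste(sprintf("%s %d", .groups, x$group_sizes), collapse = ", "),
              x$dependence, x$seed))
  invisible(x)
}
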