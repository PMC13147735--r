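# Cohort container, delimited-text I/O and descriptive statistics.

.groups <- c("case", "control", "non_case")
.subtypes <- c("A", "AB", "B", "none")

#' Construct a patient cohort
#'
#' A cohort holds one row per patient: identifier, group (`case` = confirmed
#' ASMD, `control` = phenotypically similar lysosomal-disease patient,
#' `non_case` = confirmed not ASMD), ASMD subtype, sex, ages and one 0/1/NA
#' column per catalog symptom (NA codes an `unknown` chart entry, which is
#' deliberately distinct from `absent`).
#'
#' @param data data.frame with columns `patient_id`, `group`, `subtype`,
#'   `sex`, `age_onset_years`, `age_current_years` and one column per
#'   catalog `symptom_id` holding 0, 1 or NA.
#' @param catalog a [symptom_catalog()]; defaults to [default_catalog()].
#' @return An object of class `asmd_cohort`.
#' @export
cohort <- function(data, catalog = default_catalog()) {
  stopifnot(is.data.frame(data))
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  base_cols <- c("patient_id", "group", "subtype", "sex",
                 "age_onset_years", "age_current_years")
  miss <- setdiff(base_cols, names(data))
  if (length(miss)) stop("missing cohort columns: ", paste(miss, collapse = ", "))
  extra <- setdiff(names(data), c(base_cols, catalog$symptom_id))
  if (length(extra))
    stop("unrecognized symptom columns: ", paste(extra, collapse = ", "))
  if (nrow(data)) {
    data$patient_id <- as.character(data$patient_id)
    if (anyDuplicated(data$patient_id))
      stop("duplicate patient_id: ",
           paste(unique(data$patient_id[duplicated(data$patient_id)]), collapse = ", "))
    bad <- !data$group %in% .groups
    if (any(bad)) stop("group label outside {case, control, non_case}: ",
                       paste(unique(data$group[bad]), collapse = ", "))
    data$subtype[is.na(data$subtype) | data$subtype == ""] <- "none"
    bad <- !data$subtype %in% .subtypes
    if (any(bad)) stop("unknown subtype: ", paste(unique(data$subtype[bad]), collapse = ", "))
    if (any(data$subtype != "none" & data$group != "case"))
      stop("subtype may differ from 'none' only for cases")
    bad <- !is.na(data$sex) & !data$sex %in% c("male", "female")
    if (any(bad)) stop("unknown sex: ", paste(unique(data$sex[bad]), collapse = ", "))
    for (col in c("age_onset_years", "age_current_years")) {
      data[[col]] <- as.numeric(data[[col]])
      if (any(data[[col]] < 0, na.rm = TRUE)) stop("negative ", col)
    }
  }
  for (s in intersect(catalog$symptom_id, names(data))) {
    v <- data[[s]]
    if (!all(is.na(v) | v %in% c(0, 1)))
      stop("symptom column '", s, "' must be coded 0/1/NA")
    data[[s]] <- as.integer(v)
  }
  # symptoms absent from the file are wholly unknown
  for (s in setdiff(catalog$symptom_id, names(data)))
    data[[s]] <- rep(NA_integer_, nrow(data))
  data <- data[, c(base_cols, catalog$symptom_id), drop = FALSE]
  rownames(data) <- NULL
  structure(list(data = data, catalog = catalog), class = "asmd_cohort")
}

#' Number of patients per group
#' @param x an `asmd_cohort`.
#' @return Named integer vector over `case`, `control`, `non_case`.
#' @export
group_counts <- function(x) {
  stopifnot(inherits(x, "asmd_cohort"))
  tab <- table(factor(x$data$group, levels = .groups))
  stats::setNames(as.integer(tab), .groups)
}

#' @export
print.asmd_cohort <- function(x, ...) {
  gc <- group_counts(x)
  cat(sprintf("ASMD cohort: %d patients (%d cases, %d controls, %d non-cases); %d catalog symptoms\n",
              nrow(x$data), gc["case"], gc["control"], gc["non_case"], nrow(x$catalog)))
  invisible(x)
}

#' Read a cohort from a delimited text file
#'
#' Expects UTF-8 CSV with header
#' `patient_id,group,subtype,sex,age_onset_years,age_current_years,<symptom_id>...`;
#' symptoms coded 1 (present), 0 (absent), empty (unknown). Unrecognized
#' symptom columns are rejected rather than silently dropped.
#'
#' @param path file path.
#' @param catalog a [symptom_catalog()].
#' @return An `asmd_cohort`.
#' @export
read_cohort <- function(path, catalog = default_catalog()) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                         na.strings = character())
  base_cols <- c("patient_id", "group", "subtype", "sex",
                 "age_onset_years", "age_current_years")
  miss <- setdiff(base_cols, names(raw))
  if (length(miss)) stop("file lacks required columns: ", paste(miss, collapse = ", "))
  for (col in c("age_onset_years", "age_current_years")) {
    v <- trimws(raw[[col]])
    v[v == ""] <- NA
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(num))
    if (length(bad)) stop("malformed ", col, " at data line ", bad[1], ": '", v[bad[1]], "'")
    raw[[col]] <- num
  }
  for (s in intersect(names(raw), catalog$symptom_id)) {
    v <- trimws(raw[[s]])
    v[v == ""] <- NA
    bad <- which(!is.na(v) & !v %in% c("0", "1"))
    if (length(bad)) stop("malformed symptom value for '", s, "' at data line ",
                          bad[1], ": '", v[bad[1]], "'")
    raw[[s]] <- as.integer(v)
  }
  raw$sex[trimws(raw$sex) == ""] <- NA
  cohort(raw, catalog)
}

#' Write a cohort to a delimited text file
#'
#' Inverse of [read_cohort()]: `present` is written as 1, `absent` as 0 and
#' `unknown` as an empty field.
#'
#' @param x an `asmd_cohort`.
#' @param path destination file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(x, path) {
  stopifnot(inherits(x, "asmd_cohort"))
  utils::write.csv(x$data, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' Descriptive cohort summary
#'
#' Per-group demographics: n, sex counts and percents, seven-number age
#' summaries (min, first quartile, median, mean, SD, third quartile, max)
#' over non-missing values, and family-history counts. Percentages are
#' printed to 0 decimals; the returned values keep full precision.
#'
#' @param x an `asmd_cohort` with at least one patient.
#' @return An object of class `cohort_summary`: a list with one entry per
#'   group plus `all`, each holding `n`, `sex`, `age_onset`, `age_current`
#'   and `family_history`.
#' @export
describe_cohort <- function(x) {
  stopifnot(inherits(x, "asmd_cohort"))
  if (!nrow(x$data)) stop("cohort is empty")
  num_summary <- function(v) {
    n_missing <- sum(is.na(v))
    v <- v[!is.na(v)]
    if (!length(v))
      return(list(n = 0L, n_missing = n_missing, min = NA_real_, q1 = NA_real_,
                  median = NA_real_, mean = NA_real_, sd = NA_real_,
                  q3 = NA_real_, max = NA_real_))
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    list(n = length(v), n_missing = n_missing, min = min(v), q1 = q[1],
         median = q[2], mean = mean(v), sd = stats::sd(v), q3 = q[3], max = max(v))
  }
  one_group <- function(d) {
    sex <- table(factor(d$sex, levels = c("male", "female")))
    fh <- d$family_history_asmd
    list(n = nrow(d),
         sex = list(male = as.integer(sex["male"]), female = as.integer(sex["female"]),
                    male_pct = 100 * as.integer(sex["male"]) / max(nrow(d), 1L),
                    female_pct = 100 * as.integer(sex["female"]) / max(nrow(d), 1L)),
         age_onset = num_summary(d$age_onset_years),
         age_current = num_summary(d$age_current_years),
         family_history = list(n = sum(fh == 1L, na.rm = TRUE),
                               unknown = sum(is.na(fh))))
  }
  out <- lapply(.groups, function(g) one_group(x$data[x$data$group == g, , drop = FALSE]))
  names(out) <- .groups
  out$all <- one_group(x$data)
  structure(out, class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  fmt_age <- function(a) {
    if (!a$n) return("--")
    sprintf("%.1f (%.1f)", a$mean, a$sd)
  }
  cat(sprintf("%-12s %6s %14s %20s %20s %8s\n",
              "group", "n", "male n (%)", "onset age m (SD)", "current age m (SD)", "famhist"))
  for (g in c(.groups, "all")) {
    s <- x[[g]]
    cat(sprintf("%-12s %6d %8d (%.0f%%) %20s %20s %8d\n",
                g, s$n, s$sex$male, s$sex$male_pct,
                fmt_age(s$age_onset), fmt_age(s$age_current), s$family_history$n))
  }
  invisible(x)
}
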