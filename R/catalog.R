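# Symptom catalog: the canonical symptom list used across the package.

#' Construct a symptom catalog
#'
#' A symptom catalog is an ordered table of symptom identifiers, display
#' names and organ systems. It fixes the join keys used by cohort files,
#' the screening engine and the risk model.
#'
#' @param entries data.frame with columns `symptom_id` (unique
#'   lower_snake_case tokens), `display_name` and `organ_system` (one of
#'   `"neurological"`, `"visceral"`, `"skeletal"`, `"other"`).
#' @return An object of class `symptom_catalog` (a validated data.frame).
#' @seealso [default_catalog()] for the packaged ASMD catalog.
#' @export
symptom_catalog <- function(entries) {
  stopifnot(is.data.frame(entries),
            all(c("symptom_id", "display_name", "organ_system") %in% names(entries)))
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  if (anyDuplicated(entries$symptom_id))
    stop("duplicate symptom_id in catalog: ",
         paste(unique(entries$symptom_id[duplicated(entries$symptom_id)]), collapse = ", "))
  ok <- entries$organ_system %in% c("neurological", "visceral", "skeletal", "other")
  if (!all(ok))
    stop("unknown organ_system: ", paste(unique(entries$organ_system[!ok]), collapse = ", "))
  if (!all(grepl("^[a-z][a-z0-9_]*$", entries$symptom_id)))
    stop("symptom_id must be a lower_snake_case token")
  rownames(entries) <- NULL
  structure(entries, class = c("symptom_catalog", "data.frame"))
}

#' The default ASMD symptom catalog
#'
#' The 27 chart-review symptoms observed in more than 5% of ASMD cases,
#' grouped by organ system (10 neurological, 14 visceral, 3 skeletal),
#' plus a first/second-degree ASMD family-history indicator. These
#' identifiers are the canonical column names of cohort files.
#'
#' @return A `symptom_catalog` with 28 entries.
#' @export
default_catalog <- function() {
  e <- rbind(
    c("learning_disability",          "Learning disability",                               "neurological"),
    c("muscular_hypotonia",           "Muscular hypotonia",                                "neurological"),
    c("peripheral_neuropathy",        "Peripheral neuropathy",                             "neurological"),
    c("loss_of_deep_tendon_reflexes", "Loss of deep tendon reflexes",                      "neurological"),
    c("macular_halo",                 "Macular halo",                                      "neurological"),
    c("loss_of_skills",               "Loss of skills",                                    "neurological"),
    c("ocular_cherry_red_spot",       "Ocular cherry red spot",                            "neurological"),
    c("ataxia",                       "Ataxia",                                            "neurological"),
    c("psychiatric_symptoms",         "Psychiatric symptoms",                              "neurological"),
    c("dysphagia",                    "Dysphagia",                                         "neurological"),
    c("splenomegaly",                 "Splenomegaly",                                      "visceral"),
    c("hepatomegaly",                 "Hepatomegaly",                                      "visceral"),
    c("interstitial_lung_disease",    "Interstitial lung disease",                         "visceral"),
    c("thrombocytopenia_bleeding",    "Thrombocytopenia (with bleeding tendencies)",       "visceral"),
    c("mixed_dyslipidemia_low_hdl",   "Mixed dyslipidemia with low HDL-C",                 "visceral"),
    c("recurrent_respiratory_tract_infections", "Recurrent respiratory tract infections",  "visceral"),
    c("abnormal_liver_function_test", "Abnormal liver function test",                      "visceral"),
    c("diarrhea",                     "Diarrhea",                                          "visceral"),
    c("cholestatic_jaundice",         "Cholestatic jaundice",                              "visceral"),
    c("portal_hypertension",          "Portal hypertension",                               "visceral"),
    c("aspiration_pneumonia",         "Aspiration pneumonia",                              "visceral"),
    c("liver_fibrosis",               "Liver fibrosis",                                    "visceral"),
    c("feeding_difficulties",         "Feeding difficulties",                              "visceral"),
    c("cardiac_valve_disease",        "Cardiac valve disease",                             "visceral"),
    c("growth_retardation_childhood", "Growth retardation in childhood",                   "skeletal"),
    c("reduced_bone_density",         "Reduced bone density (with pathologic fractures)",  "skeletal"),
    c("bone_and_joint_pain",          "Bone and joint pain",                               "skeletal"),
    c("family_history_asmd",          "ASMD family history (first/second degree)",         "other")
  )
  symptom_catalog(data.frame(symptom_id = e[, 1], display_name = e[, 2],
                             organ_system = e[, 3], stringsAsFactors = FALSE))
}

#' @export
print.symptom_catalog <- function(x, ...) {
  cat("Symptom catalog:", nrow(x), "entries\n")
  tab <- table(factor(x$organ_system,
                      levels = c("neurological", "visceral", "skeletal", "other")))
  cat(paste(sprintf("  %s: %d", names(tab), as.integer(tab)), collapse = "\n"), "\n")
  invisible(x)
}

#' Published per-group symptom counts of the ASMD development study
#'
#' Symptom counts among 48 ASMD cases, 52 controls (phenotypically similar
#' lysosomal-disease patients) and 808 non-cases, as reported by the chart
#' review that the packaged defaults emulate. These counts drive the default
#' synthetic-cohort prevalences and can be screened directly as 2x2 tables.
#'
#' @return data.frame with columns `symptom_id`, `organ_system`, `cases`,
#'   `controls`, `non_cases` (counts of patients with the symptom present;
#'   group sizes 48 / 52 / 808).
#' @export
study_symptom_counts <- function() {
  cat <- default_catalog()
  counts <- matrix(c(
    # cases, controls, non_cases
    19, 13,   0,   # learning_disability
    10, 15,   0,   # muscular_hypotonia
    10,  3,   1,   # peripheral_neuropathy
     9,  5,   0,   # loss_of_deep_tendon_reflexes
     9,  0,   0,   # macular_halo
     8, 17,   0,   # loss_of_skills
     8,  0,   0,   # ocular_cherry_red_spot
     7, 26,   0,   # ataxia
     7, 10,   0,   # psychiatric_symptoms
     5, 26,   1,   # dysphagia
    48, 37,   3,   # splenomegaly
    44, 29,   3,   # hepatomegaly
    32,  3,   0,   # interstitial_lung_disease
    27,  2,   4,   # thrombocytopenia_bleeding
    24,  6, 806,   # mixed_dyslipidemia_low_hdl
    18,  0,   0,   # recurrent_respiratory_tract_infections
    15,  0,   0,   # abnormal_liver_function_test
    15,  5,   0,   # diarrhea
    14,  2,   0,   # cholestatic_jaundice
    12,  0,   0,   # portal_hypertension
    11,  1,   0,   # aspiration_pneumonia
    11,  1,   1,   # liver_fibrosis
     6, 24,   0,   # feeding_difficulties
     3,  2,   0,   # cardiac_valve_disease
    24,  9,   0,   # growth_retardation_childhood
    13,  2,   0,   # reduced_bone_density
    10,  3,   4,   # bone_and_joint_pain
    10,  0,   0    # family_history_asmd
  ), ncol = 3, byrow = TRUE)
  data.frame(symptom_id = cat$symptom_id,
             organ_system = cat$organ_system,
             cases = counts[, 1], controls = counts[, 2], non_cases = counts[, 3],
             stringsAsFactors = FALSE)
}

#' Group sizes of the development study
#' @return Named integer vector `c(case = 48, control = 52, non_case = 808)`.
#' @export
study_group_sizes <- function() {
  c(case = 48L, control = 52L, non_case = 808L)
}
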