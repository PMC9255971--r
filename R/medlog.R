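#' Medication-log ingestion and polypharmacy quantification
#'
#' A cohort couples a patient covariate table with a normalized medication log.
#' Regular medications (prescription, over-the-counter, complementary) drive the
#' polypharmacy count; cancer treatments and supportive-care drugs are kept in
#' the log but never contribute to it.
#'
#' @name medlog
NULL

MED_CATEGORIES <- c("prescription", "otc", "complementary")
KPS_BANDS <- c("20-60", "70-80", "90-100")

# tokens stripped from recorded names before matching: dose numbers, units and
# routes. Conservative by design; unknown tokens are left alone.
DOSE_TOKENS <- c(
  "mg", "mcg", "ug", "g", "gram", "grams", "ml", "mls", "iu", "meq", "units",
  "unit", "tablet", "tablets", "tab", "tabs", "capsule", "capsules", "cap",
  "caps", "cream", "ointment", "patch", "patches", "solution", "suspension",
  "syrup", "drops", "spray", "inhaler", "oral", "topical", "po", "iv", "sc",
  "subcutaneous", "daily", "bid", "tid", "qid", "prn", "er", "xr", "sr", "xl",
  "hcl", "sodium", "potassium"
)

#' Normalize a recorded medication name
#'
#' Lowercases, trims, and removes dose/route tokens (e.g. "Metformin 500 mg
#' tablet" becomes "metformin"). Tokens are dropped only when they are pure
#' numbers, numbers glued to a unit ("500mg"), or members of a conservative
#' blacklist; anything else passes through unchanged.
#'
#' @param x character vector of recorded names.
#' @return character vector of normalized names.
#' @examples
#' normalize_name("Metformin 500 mg tablet")
#' @export
normalize_name <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x <- gsub("[,;/()]+", " ", x)
  vapply(strsplit(x, "\\s+"), function(tok) {
    tok <- tok[nzchar(tok)]
    drop <- grepl("^[0-9.]+$", tok) |
      grepl("^[0-9.]+(mg|mcg|ug|g|ml|iu|meq|%)$", tok) |
      tok %in% DOSE_TOKENS
    paste(tok[!drop], collapse = " ")
  }, character(1))
}

#' Read a medication log
#'
#' Expects UTF-8 CSV with a header and columns `patient_id`, `drug_name`,
#' `category`, `is_cancer_treatment`, `is_supportive_care`.
#'
#' @param path path to the CSV file.
#' @return data.frame with columns `patient_id`, `raw_name`, `generic_name`
#'   (normalized), `category`, `is_cancer_treatment`, `is_supportive_care`.
#' @export
read_medication_log <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  assert_cols(df, c("patient_id", "drug_name", "category",
                    "is_cancer_treatment", "is_supportive_care"),
              "medication log")
  medication_log(
    patient_id = df$patient_id,
    raw_name = df$drug_name,
    category = df$category,
    is_cancer_treatment = df$is_cancer_treatment,
    is_supportive_care = df$is_supportive_care
  )
}

#' Construct a medication log from vectors
#'
#' @param patient_id patient identifiers (coerced to character).
#' @param raw_name medication names as recorded.
#' @param category one of `"prescription"`, `"otc"`, `"complementary"` per
#'   record.
#' @param is_cancer_treatment,is_supportive_care logical flags; flagged records
#'   never count toward the regular-medication total.
#' @return a normalized medication-log data.frame.
#' @export
medication_log <- function(patient_id, raw_name,
                           category = "prescription",
                           is_cancer_treatment = FALSE,
                           is_supportive_care = FALSE) {
  n <- length(raw_name)
  df <- data.frame(
    patient_id = as.character(patient_id),
    raw_name = as.character(raw_name),
    category = rep_len(as.character(category), n),
    is_cancer_treatment = rep_len(as.logical(is_cancer_treatment), n),
    is_supportive_care = rep_len(as.logical(is_supportive_care), n),
    stringsAsFactors = FALSE
  )
  bad <- !df$category %in% MED_CATEGORIES
  if (any(bad)) {
    stop_("unknown medication category: ",
          paste(unique(df$category[bad]), collapse = ", "))
  }
  df$generic_name <- normalize_name(df$raw_name)
  df[c("patient_id", "raw_name", "generic_name", "category",
       "is_cancer_treatment", "is_supportive_care")]
}

#' Map brand names to generics and collapse duplicates
#'
#' Applies a brand-to-generic synonym map (identity for unmapped names), drops
#' records whose name is empty after normalization (with a warning), and keeps
#' the first record per (patient, generic) pair. Row order is otherwise stable,
#' so the operation is idempotent.
#'
#' @param meds medication-log data.frame (see [medication_log()]).
#' @param synonyms either a two-column data.frame (`brand`, `generic`) or a
#'   named character vector `c(brand = generic)`; names are matched after
#'   normalization.
#' @return deduplicated medication-log data.frame.
#' @export
normalize_and_dedupe <- function(meds, synonyms = NULL) {
  assert_cols(meds, c("patient_id", "generic_name"), "medication log")
  map <- character(0)
  if (is.data.frame(synonyms)) {
    assert_cols(synonyms, c("brand", "generic"), "synonym map")
    map <- stats::setNames(tolower(synonyms$generic), tolower(synonyms$brand))
  } else if (!is.null(synonyms)) {
    map <- stats::setNames(tolower(synonyms), tolower(names(synonyms)))
  }

  empty <- !nzchar(meds$generic_name)
  if (any(empty)) {
    warning(sum(empty), " record(s) with empty medication name rejected",
            call. = FALSE)
    meds <- meds[!empty, , drop = FALSE]
  }
  hit <- meds$generic_name %in% names(map)
  meds$generic_name[hit] <- unname(map[meds$generic_name[hit]])

  key <- paste(meds$patient_id, meds$generic_name, sep = "\r")
  meds <- meds[!duplicated(key), , drop = FALSE]
  rownames(meds) <- NULL
  meds
}

#' Assemble a cohort
#'
#' @param patients data.frame with one row per patient: `patient_id`,
#'   `age_years` (must be >= 70), optional covariate columns (`gender`, `race`,
#'   `education`, `income`, `marital_status`, `cancer_type`, `stage`,
#'   `treatment_line`, `life_expectancy`, `kps`) and logical geriatric
#'   assessment flags (`ga_function`, `ga_physical`, `ga_comorbidity`,
#'   `ga_cognition`, `ga_social`, `ga_psychological`, `ga_nutrition`).
#' @param meds normalized, deduplicated medication-log data.frame; every
#'   `patient_id` must appear in `patients`.
#' @return an object of class `med_cohort`.
#' @export
med_cohort <- function(patients, meds) {
  assert_cols(patients, c("patient_id", "age_years"), "patient table")
  patients$patient_id <- as.character(patients$patient_id)
  if (anyDuplicated(patients$patient_id)) {
    stop_("duplicate patient_id in patient table")
  }
  if (any(patients$age_years < 70, na.rm = TRUE)) {
    stop_("cohort is restricted to age >= 70 years")
  }
  if ("kps" %in% names(patients)) {
    bad <- !(is.na(patients$kps) | patients$kps %in% KPS_BANDS)
    if (any(bad)) {
      stop_("kps must be one of ", paste(KPS_BANDS, collapse = ", "))
    }
  }
  orphans <- setdiff(unique(meds$patient_id), patients$patient_id)
  if (length(orphans) > 0) {
    stop_("medication records for unknown patient(s): ",
          paste(utils::head(orphans, 5), collapse = ", "))
  }
  structure(list(patients = patients, meds = meds), class = "med_cohort")
}

#' @export
print.med_cohort <- function(x, ...) {
  cat("med_cohort:", nrow(x$patients), "patients,",
      nrow(x$meds), "medication records\n")
  counts <- regular_med_count(x)
  cat("  regular medications per patient: median",
      stats::median(counts$n_regular),
      sprintf("(range %d-%d)\n", min(counts$n_regular), max(counts$n_regular)))
  invisible(x)
}

is_regular <- function(meds) {
  !meds$is_cancer_treatment & !meds$is_supportive_care
}

#' Regular medications per patient
#'
#' Counts each patient's regular medications, excluding records flagged as
#' cancer treatment or supportive care. Patients with no medication records
#' count zero.
#'
#' @param cohort a `med_cohort`.
#' @return data.frame with columns `patient_id` and `n_regular`, one row per
#'   cohort patient, in patient-table order.
#' @export
regular_med_count <- function(cohort) {
  stopifnot(inherits(cohort, "med_cohort"))
  reg <- cohort$meds[is_regular(cohort$meds), , drop = FALSE]
  tab <- table(factor(reg$patient_id, levels = cohort$patients$patient_id))
  data.frame(patient_id = cohort$patients$patient_id,
             n_regular = as.integer(tab),
             stringsAsFactors = FALSE)
}

#' Classify a medication count as polypharmacy
#'
#' @param count nonnegative integer vector of regular-medication counts.
#' @param threshold_poly polypharmacy cutoff (default >= 5 medications).
#' @param threshold_excessive excessive-polypharmacy cutoff (default >= 10).
#' @return factor with levels `none`, `polypharmacy`, `excessive`. Excessive
#'   counts also satisfy the polypharmacy definition wherever prevalence is
#'   tallied.
#' @examples
#' polypharmacy_class(c(0, 4, 5, 9, 10, 24))
#' @export
polypharmacy_class <- function(count, threshold_poly = 5,
                               threshold_excessive = 10) {
  if (any(count < 0)) stop_("medication count cannot be negative")
  cls <- ifelse(count >= threshold_excessive, "excessive",
                ifelse(count >= threshold_poly, "polypharmacy", "none"))
  factor(cls, levels = c("none", "polypharmacy", "excessive"))
}

#' Cohort-level medication summary
#'
#' @param cohort a `med_cohort`.
#' @param threshold_poly,threshold_excessive polypharmacy cutoffs (counts of
#'   regular medications).
#' @return list of class `cohort_summary`: `n_patients`, `n_med_occurrences`
#'   (regular occurrences), `n_distinct_generics`, `median_meds`, `range_meds`,
#'   `pct_polypharmacy`, `pct_excessive_polypharmacy`,
#'   `pct_nonprescription_of_total` (OTC + complementary share of regular
#'   occurrences). Percentages are reported to one decimal, half-up.
#' @export
cohort_summary <- function(cohort, threshold_poly = 5,
                           threshold_excessive = 10) {
  stopifnot(inherits(cohort, "med_cohort"))
  n <- nrow(cohort$patients)
  if (n == 0) stop_("empty cohort")
  counts <- regular_med_count(cohort)$n_regular
  reg <- cohort$meds[is_regular(cohort$meds), , drop = FALSE]
  nonrx <- sum(reg$category %in% c("otc", "complementary"))
  structure(list(
    n_patients = n,
    n_med_occurrences = nrow(reg),
    n_distinct_generics = length(unique(reg$generic_name)),
    median_meds = stats::median(counts),
    range_meds = range(counts),
    pct_polypharmacy = pct(sum(counts >= threshold_poly), n),
    pct_excessive_polypharmacy = pct(sum(counts >= threshold_excessive), n),
    pct_nonprescription_of_total = pct(nonrx, max(nrow(reg), 1L))
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf(
    paste0("cohort of %d patients: %d occurrences of %d distinct regular ",
           "medications\n  median %s per patient (range %d-%d)\n",
           "  polypharmacy %.1f%%, excessive polypharmacy %.1f%%, ",
           "nonprescription share %.1f%%\n"),
    x$n_patients, x$n_med_occurrences, x$n_distinct_generics,
    format(x$median_meds), x$range_meds[1], x$range_meds[2],
    x$pct_polypharmacy, x$pct_excessive_polypharmacy,
    x$pct_nonprescription_of_total))
  invisible(x)
}
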