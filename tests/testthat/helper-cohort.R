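# small hand-built cohorts used across test files

tiny_patients <- function(ids, age = 75, ...) {
  df <- data.frame(patient_id = ids, age_years = rep_len(age, length(ids)),
                   stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  df
}

# cohort of two patients with known medications and ATC classes
demo_cohort <- function() {
  meds <- medication_log(
    patient_id = c("p1", "p1", "p1", "p1", "p2", "p2"),
    raw_name = c("omeprazole", "lorazepam", "ibuprofen", "carboplatin",
                 "atorvastatin", "diphenhydramine"),
    category = c("otc", "prescription", "otc", "prescription",
                 "prescription", "otc"),
    is_cancer_treatment = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE),
    is_supportive_care = FALSE
  )
  patients <- tiny_patients(c("p1", "p2"),
                            ga_function = c(TRUE, FALSE),
                            ga_comorbidity = c(TRUE, FALSE))
  med_cohort(patients, normalize_and_dedupe(meds))
}

extdata <- function(file) {
  system.file("extdata", file, package = "polyrx", mustWork = TRUE)
}
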