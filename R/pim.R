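#' Potentially inappropriate medication (PIM) screening
#'
#' A declarative rules engine in the style of the 2019 Beers criteria and the
#' STOPP criteria. Rules are data, not code: each rule names its source
#' catalog, a set of drug targets (ATC prefixes and/or generic names) and
#' optional conjunctive patient predicates. The packaged ruleset is a
#' representative machine-readable subset of both catalogs, not a complete
#' transcription.
#'
#' @name pim
NULL

PIM_SOURCES <- c("BEERS2019", "STOPP")

#' Load a PIM ruleset
#'
#' @param path JSON array of rule objects with fields `rule_id`, `source`
#'   (`"BEERS2019"` or `"STOPP"`), `targets` (object with optional `atc` and
#'   `generic` arrays; at least one target required), optional `predicates`
#'   (object with any of `min_age`, `covariate` (name/value map),
#'   `co_medication_atc`, `ga_flag`) and optional `rationale`.
#' @return list of class `pim_ruleset`.
#' @export
load_ruleset <- function(path) {
  rules <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (length(rules) == 0) {
    warning("empty PIM ruleset", call. = FALSE)
  }
  rules <- lapply(rules, validate_rule)
  ids <- vapply(rules, `[[`, character(1), "rule_id")
  if (anyDuplicated(ids)) {
    stop_("duplicate rule_id: ", paste(unique(ids[duplicated(ids)]),
                                       collapse = ", "))
  }
  structure(rules, class = "pim_ruleset")
}

validate_rule <- function(rule) {
  id <- rule$rule_id %||% "<missing rule_id>"
  if (is.null(rule$rule_id)) stop_("rule without rule_id")
  if (is.null(rule$source) || !rule$source %in% PIM_SOURCES) {
    stop_("rule ", id, ": source must be one of ",
          paste(PIM_SOURCES, collapse = ", "))
  }
  atc <- toupper(unlist(rule$targets$atc))
  generic <- normalize_name(unlist(rule$targets$generic))
  if (length(atc) + length(generic) == 0) {
    stop_("rule ", id, ": empty targets")
  }
  list(
    rule_id = as.character(rule$rule_id),
    source = rule$source,
    targets = list(atc = atc, generic = generic),
    predicates = rule$predicates %||% list(),
    rationale = rule$rationale %||% ""
  )
}

# A medication matches a rule if its generic name is targeted or its primary
# ATC code starts with a targeted prefix. Unclassified medications can still
# match generic-name targets.
match_targets <- function(rule, generic, atc_code) {
  hit <- generic %in% rule$targets$generic
  for (prefix in rule$targets$atc) {
    hit <- hit | (!is.na(atc_code) & startsWith(atc_code, prefix))
  }
  hit
}

# Conjunctive patient predicates; a predicate on a missing (NA/absent)
# covariate fails closed. Returns list(ok=, missing=) so callers can log.
eval_predicates <- function(pred, patient, patient_meds) {
  missing <- character(0)
  ok <- TRUE
  if (!is.null(pred$min_age)) {
    age <- patient$age_years
    if (is.na(age)) { missing <- c(missing, "age_years"); ok <- FALSE }
    else ok <- ok && age >= pred$min_age
  }
  if (ok && !is.null(pred$covariate)) {
    for (nm in names(pred$covariate)) {
      val <- if (nm %in% names(patient)) patient[[nm]] else NA
      if (is.na(val)) { missing <- c(missing, nm); ok <- FALSE; break }
      if (val != pred$covariate[[nm]]) { ok <- FALSE; break }
    }
  }
  if (ok && !is.null(pred$ga_flag)) {
    col <- paste0("ga_", pred$ga_flag)
    val <- if (col %in% names(patient)) patient[[col]] else NA
    if (is.na(val)) { missing <- c(missing, col); ok <- FALSE }
    else ok <- ok && isTRUE(val)
  }
  if (ok && !is.null(pred$co_medication_atc)) {
    codes <- patient_meds$atc_code
    ok <- any(!is.na(codes) & startsWith(codes, pred$co_medication_atc))
  }
  list(ok = ok, missing = missing)
}

#' Screen one patient against a PIM ruleset
#'
#' Emits one flag per (rule, matching regular medication) where all the rule's
#' predicates hold, ordered by (rule_id, generic_name). Predicates referencing
#' a missing covariate fail closed and the miss is reported via a message.
#'
#' @param patient one-row data.frame from the cohort patient table.
#' @param patient_meds that patient's annotated regular medications (rows of
#'   `classify_cohort()$annotated`).
#' @param rules a `pim_ruleset`.
#' @return data.frame of flags: `patient_id`, `rule_id`, `source`,
#'   `generic_name`, `category`.
#' @export
screen_patient <- function(patient, patient_meds, rules) {
  stopifnot(inherits(rules, "pim_ruleset"), nrow(patient) == 1)
  flags <- lapply(rules, function(rule) {
    hit <- match_targets(rule, patient_meds$generic_name,
                         patient_meds$atc_code)
    if (!any(hit)) return(NULL)
    pr <- eval_predicates(rule$predicates, patient, patient_meds)
    if (length(pr$missing) > 0) {
      message("rule ", rule$rule_id, ": missing covariate(s) ",
              paste(pr$missing, collapse = ", "), " for patient ",
              patient$patient_id, "; predicate fails closed")
    }
    if (!pr$ok) return(NULL)
    data.frame(patient_id = patient$patient_id,
               rule_id = rule$rule_id,
               source = rule$source,
               generic_name = patient_meds$generic_name[hit],
               category = patient_meds$category[hit],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(flags, list(empty_flags())))
  out <- out[order(out$rule_id, out$generic_name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_flags <- function() {
  data.frame(patient_id = character(0), rule_id = character(0),
             source = character(0), generic_name = character(0),
             category = character(0), stringsAsFactors = FALSE)
}

#' Screen a whole cohort
#'
#' @param cohort a `med_cohort`.
#' @param rules a `pim_ruleset`.
#' @param annotation an `atc_annotation` from [classify_cohort()].
#' @return data.frame of flags across all patients, ordered by
#'   (patient table order, rule_id, generic_name).
#' @export
screen_cohort <- function(cohort, rules, annotation) {
  stopifnot(inherits(cohort, "med_cohort"),
            inherits(annotation, "atc_annotation"))
  ann <- annotation$annotated
  out <- lapply(seq_len(nrow(cohort$patients)), function(i) {
    patient <- cohort$patients[i, , drop = FALSE]
    pm <- ann[ann$patient_id == patient$patient_id, , drop = FALSE]
    screen_patient(patient, pm, rules)
  })
  out <- do.call(rbind, c(out, list(empty_flags())))
  rownames(out) <- NULL
  out
}

#' PIM prevalence by source and overall
#'
#' Prevalence is patient-level: a patient counts once per source regardless of
#' how many flags they accrue, and once toward the union. The nonprescription
#' share is flag-level, by source: the fraction of a source's flags whose
#' medication is OTC or complementary.
#'
#' @param cohort a `med_cohort`.
#' @param flags flag data.frame from [screen_cohort()].
#' @return list of class `pim_prevalence`: `n_patients`, `pct_beers`,
#'   `pct_stopp`, `pct_union`, `per_patient` (data.frame `patient_id`,
#'   `n_flags`, `any_pim`), `pct_nonrx_flags` (named by source), and
#'   `class_share` (data.frame of flag share and patient share per rule).
#' @export
pim_prevalence <- function(cohort, flags) {
  stopifnot(inherits(cohort, "med_cohort"))
  n <- nrow(cohort$patients)
  if (n == 0) stop_("empty cohort")
  ids <- cohort$patients$patient_id
  flagged_by <- function(src) unique(flags$patient_id[flags$source == src])
  beers <- flagged_by("BEERS2019")
  stopp <- flagged_by("STOPP")
  nonrx_share <- function(src) {
    f <- flags[flags$source == src, , drop = FALSE]
    if (nrow(f) == 0) return(NA_real_)
    pct(sum(f$category %in% c("otc", "complementary")), nrow(f))
  }
  per_patient <- data.frame(
    patient_id = ids,
    n_flags = as.integer(table(factor(flags$patient_id, levels = ids))),
    stringsAsFactors = FALSE
  )
  per_patient$any_pim <- per_patient$n_flags > 0
  class_share <- if (nrow(flags) > 0) {
    sp <- split(flags, flags$rule_id)
    data.frame(
      rule_id = names(sp),
      source = vapply(sp, function(f) f$source[1], character(1)),
      pct_of_flags = vapply(sp, function(f) pct(nrow(f), nrow(flags)),
                            numeric(1)),
      pct_of_patients = vapply(sp, function(f)
        pct(length(unique(f$patient_id)), n), numeric(1)),
      stringsAsFactors = FALSE, row.names = NULL
    )
  } else {
    data.frame(rule_id = character(0), source = character(0),
               pct_of_flags = numeric(0), pct_of_patients = numeric(0))
  }
  structure(list(
    n_patients = n,
    pct_beers = pct(length(beers), n),
    pct_stopp = pct(length(stopp), n),
    pct_union = pct(length(union(beers, stopp)), n),
    per_patient = per_patient,
    pct_nonrx_flags = c(BEERS2019 = nonrx_share("BEERS2019"),
                        STOPP = nonrx_share("STOPP")),
    class_share = class_share
  ), class = "pim_prevalence")
}

#' @export
print.pim_prevalence <- function(x, ...) {
  cat(sprintf(
    paste0("PIM prevalence over %d patients:\n  Beers %.1f%%  STOPP %.1f%%  ",
           "either %.1f%%\n  nonprescription share of flags: Beers %s%%, ",
           "STOPP %s%%\n"),
    x$n_patients, x$pct_beers, x$pct_stopp, x$pct_union,
    format(x$pct_nonrx_flags[["BEERS2019"]]),
    format(x$pct_nonrx_flags[["STOPP"]])))
  invisible(x)
}
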