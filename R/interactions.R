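#' Drug-drug and drug-cancer-treatment interaction detection
#'
#' Interactions are looked up in a pluggable knowledge base of unordered drug
#' pairs graded C (monitor therapy), D (consider therapy modification) or X
#' (avoid combination); D and X are "major". DDI are pairs of two regular
#' medications; DCI cross the regular / cancer-treatment boundary.
#' Supportive-care medications take part in neither. Matching is by generic
#' name — interaction severity is substance-specific, so ATC classes enter only
#' at network aggregation.
#'
#' @name interactions
NULL

SEVERITIES <- c("C", "D", "X") # ascending severity

canonical_pair <- function(a, b) {
  swap <- a > b
  list(a = ifelse(swap, b, a), b = ifelse(swap, a, b))
}

#' Load an interaction knowledge base
#'
#' Pairs are canonicalized to lexicographic order; a pair listed more than once
#' keeps its maximum severity (X > D > C) and the merge is reported.
#'
#' @param path CSV with columns `drug_a`, `drug_b`, `severity`.
#' @return data.frame of class `interaction_kb` with canonical `drug_a` <
#'   `drug_b` and `severity`.
#' @export
load_interaction_kb <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  assert_cols(df, c("drug_a", "drug_b", "severity"), "interaction KB")
  interaction_kb(df$drug_a, df$drug_b, df$severity)
}

#' Construct an interaction knowledge base from vectors
#'
#' @param drug_a,drug_b generic names (normalized on entry; order irrelevant).
#' @param severity one of `"C"`, `"D"`, `"X"` per pair.
#' @return data.frame of class `interaction_kb`.
#' @export
interaction_kb <- function(drug_a, drug_b, severity) {
  severity <- toupper(trimws(severity))
  bad <- !severity %in% SEVERITIES
  if (any(bad)) {
    stop_("unknown interaction severity: ",
          paste(unique(severity[bad]), collapse = ", "),
          " (must be C, D or X)")
  }
  p <- canonical_pair(normalize_name(drug_a), normalize_name(drug_b))
  if (any(p$a == p$b)) stop_("interaction pair with identical drugs")
  df <- data.frame(drug_a = p$a, drug_b = p$b, severity = severity,
                   stringsAsFactors = FALSE)
  key <- paste(df$drug_a, df$drug_b, sep = "\r")
  if (anyDuplicated(key)) {
    rank <- match(df$severity, SEVERITIES)
    keep <- unlist(lapply(split(seq_len(nrow(df)), key), function(i) {
      i[which.max(rank[i])]
    }), use.names = FALSE)
    n_dup <- nrow(df) - length(keep)
    df <- df[sort(keep), , drop = FALSE]
    message(n_dup, " duplicate pair(s) merged, keeping maximum severity")
  }
  rownames(df) <- NULL
  class(df) <- c("interaction_kb", "data.frame")
  df
}

kb_lookup <- function(kb, a, b) {
  p <- canonical_pair(a, b)
  idx <- match(paste(p$a, p$b, sep = "\r"),
               paste(kb$drug_a, kb$drug_b, sep = "\r"))
  kb$severity[idx]
}

detection_frame <- function(patient_id, a, b, severity, kind) {
  p <- canonical_pair(a, b)
  data.frame(patient_id = patient_id, drug_a = p$a, drug_b = p$b,
             severity = severity, kind = kind,
             major = severity %in% c("D", "X"),
             stringsAsFactors = FALSE)
}

empty_detections <- function() {
  detection_frame(character(0), character(0), character(0),
                  character(0), character(0))
}

patient_meds_split <- function(meds) {
  list(
    regular = unique(meds$generic_name[is_regular(meds)]),
    cancer = unique(meds$generic_name[meds$is_cancer_treatment &
                                        !meds$is_supportive_care])
  )
}

#' Potential drug-drug interactions for one patient
#'
#' Looks up every unordered pair of the patient's distinct regular medications
#' once; cancer-treatment and supportive-care records are excluded from both
#' sides.
#'
#' @param meds one patient's medication-log rows (normalized, deduplicated).
#' @param kb an `interaction_kb`.
#' @return data.frame `patient_id`, `drug_a`, `drug_b`, `severity`,
#'   `kind = "DDI"`, `major`.
#' @export
find_ddi <- function(meds, kb) {
  stopifnot(inherits(kb, "interaction_kb"))
  pid <- unique(meds$patient_id)
  if (length(pid) > 1) stop_("find_ddi expects one patient's records")
  drugs <- sort(patient_meds_split(meds)$regular)
  if (length(drugs) < 2) return(empty_detections())
  pairs <- utils::combn(drugs, 2)
  sev <- kb_lookup(kb, pairs[1, ], pairs[2, ])
  hit <- !is.na(sev)
  detection_frame(rep(pid, sum(hit)), pairs[1, hit], pairs[2, hit],
                  sev[hit], rep("DDI", sum(hit)))
}

#' Potential drug-cancer-treatment interactions for one patient
#'
#' Looks up pairs across the regular x cancer-treatment boundary only; pairs
#' among cancer drugs themselves are never emitted and supportive-care drugs
#' are excluded entirely.
#'
#' @inheritParams find_ddi
#' @return data.frame as [find_ddi()], with `kind = "DCI"`.
#' @export
find_dci <- function(meds, kb) {
  stopifnot(inherits(kb, "interaction_kb"))
  pid <- unique(meds$patient_id)
  if (length(pid) > 1) stop_("find_dci expects one patient's records")
  sp <- patient_meds_split(meds)
  if (length(sp$regular) == 0 || length(sp$cancer) == 0) {
    return(empty_detections())
  }
  grid <- expand.grid(reg = sp$regular, ca = sp$cancer,
                      stringsAsFactors = FALSE)
  grid <- grid[grid$reg != grid$ca, , drop = FALSE]
  sev <- kb_lookup(kb, grid$reg, grid$ca)
  hit <- !is.na(sev)
  out <- detection_frame(rep(pid, sum(hit)), grid$reg[hit], grid$ca[hit],
                         sev[hit], rep("DCI", sum(hit)))
  out <- out[order(out$drug_a, out$drug_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect all interactions across a cohort
#'
#' One detection per (patient, canonical pair, kind); a pair occurring in k
#' patients contributes k occurrences to downstream aggregation.
#'
#' @param cohort a `med_cohort`.
#' @param kb an `interaction_kb`.
#' @return data.frame of detections across patients.
#' @export
detect_interactions <- function(cohort, kb) {
  stopifnot(inherits(cohort, "med_cohort"))
  out <- lapply(split(cohort$meds, cohort$meds$patient_id), function(m) {
    rbind(find_ddi(m, kb), find_dci(m, kb))
  })
  out <- do.call(rbind, c(out, list(empty_detections())))
  rownames(out) <- NULL
  out
}

#' Cohort-level interaction summary
#'
#' @param cohort a `med_cohort`.
#' @param detections detections from [detect_interactions()]; computed from
#'   `kb` if omitted.
#' @param kb an `interaction_kb`, used when `detections` is missing.
#' @return list of class `interaction_summary`: totals by severity and kind,
#'   and patient-level percentages (over the full cohort) with at least one
#'   DDI / major DDI / DCI / major DCI and by severity category.
#' @export
interaction_summary <- function(cohort, detections = NULL, kb = NULL) {
  stopifnot(inherits(cohort, "med_cohort"))
  n <- nrow(cohort$patients)
  if (n == 0) stop_("empty cohort")
  if (is.null(detections)) {
    if (is.null(kb)) stop_("provide detections or a knowledge base")
    detections <- detect_interactions(cohort, kb)
  }
  ddi <- detections[detections$kind == "DDI", , drop = FALSE]
  dci <- detections[detections$kind == "DCI", , drop = FALSE]
  pct_with <- function(d) pct(length(unique(d$patient_id)), n)
  sev_tab <- function(d) {
    vapply(SEVERITIES, function(s) sum(d$severity == s), integer(1))
  }
  structure(list(
    n_patients = n,
    n_ddi = nrow(ddi),
    n_dci = nrow(dci),
    ddi_by_severity = sev_tab(ddi),
    dci_by_severity = sev_tab(dci),
    pct_any_ddi = pct_with(ddi),
    pct_major_ddi = pct_with(ddi[ddi$major, , drop = FALSE]),
    pct_any_dci = pct_with(dci),
    pct_major_dci = pct_with(dci[dci$major, , drop = FALSE]),
    pct_ddi_by_severity = vapply(SEVERITIES, function(s)
      pct_with(ddi[ddi$severity == s, , drop = FALSE]), numeric(1))
  ), class = "interaction_summary")
}

#' @export
print.interaction_summary <- function(x, ...) {
  cat(sprintf(
    paste0("%d potential DDI (C/D/X = %d/%d/%d), %d potential DCI over %d ",
           "patients\n  >=1 DDI: %.1f%%  >=1 major DDI: %.1f%%  >=1 DCI: ",
           "%.1f%%  >=1 major DCI: %.1f%%\n"),
    x$n_ddi, x$ddi_by_severity[["C"]], x$ddi_by_severity[["D"]],
    x$ddi_by_severity[["X"]], x$n_dci, x$n_patients,
    x$pct_any_ddi, x$pct_major_ddi, x$pct_any_dci, x$pct_major_dci))
  invisible(x)
}
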