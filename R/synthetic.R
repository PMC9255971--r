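#' Synthetic cohort, formulary, ruleset and knowledge-base generator
#'
#' The raw study data are not deposited, so the package ships a seeded
#' generator that emulates the cohort the analysis assumes: ~718 patients aged
#' >= 70, a median of 5 regular medications per patient (counts clamped to
#' 0-24), roughly a 73/27 prescription/nonprescription occurrence split, and a
#' C/D/X interaction severity mix of about 86/12/2. Known effects are planted
#' so the pipeline's estimators can be scored against a truth ledger: a
#' comorbidity-to-polypharmacy prevalence odds ratio, and per-additional-
#' medication log-odds of a major drug-drug (ln 1.39) and drug-cancer-treatment
#' (ln 1.12) interaction injected through a Bernoulli logistic link.
#'
#' @name synthetic
NULL

# run code under a seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# drug-class templates: full ATC codes are built as <code5><2 digits>, names as
# <syllable><suffix>. Categories follow how the class is typically obtained.
SYN_CLASSES <- data.frame(
  code5 = c("C10AA", "C09AA", "C09CA", "C07AB", "C03CA", "C03AA", "A10BA",
            "A10BB", "A02BC", "A02BA", "N05BA", "N06AB", "N02BE", "M01AE",
            "R06AA", "B01AA", "B01AC", "A11GA", "A11CC", "A12AA", "B03BA",
            "H03AA", "L01XA", "L01BC", "A04AA"),
  suffix = c("statin", "pril", "sartan", "olol", "semide", "thiazide",
             "formin", "ride", "prazole", "tidine", "azepam", "oxetine",
             "cetamol", "profen", "dramine", "arin", "grel", "scorbate",
             "calcif", "calcium", "cobalamin", "thyrox", "platin", "rabine",
             "setron"),
  category = c("prescription", "prescription", "prescription", "prescription",
               "prescription", "prescription", "prescription", "prescription",
               "otc", "otc", "prescription", "prescription", "otc", "otc",
               "otc", "prescription", "otc", "complementary", "complementary",
               "otc", "otc", "prescription", "prescription", "prescription",
               "prescription"),
  role = c(rep("regular", 22), "cancer", "cancer", "supportive"),
  stringsAsFactors = FALSE
)

SYN_SYLLABLES <- c("bal", "cor", "dex", "fen", "gal", "hex", "jun", "kel",
                   "lam", "mor", "nev", "pol", "quin", "ras", "sul", "tav",
                   "vex", "wil", "xan", "zor")

#' Configuration for the synthetic generator
#'
#' Medication counts are negative-binomial (size `nb_size`), clamped to
#' `[0, max_meds]`, with the group means solved numerically so that
#' P(count >= 5) equals `p_poly_baseline` for comorbidity-unimpaired patients
#' and the planted odds ratio times those odds for impaired ones. The logistic
#' intercepts for the planted interaction outcomes are solved so the marginal
#' outcome rates match `p_major_ddi` / `p_major_dci` under the theoretical
#' count distribution.
#'
#' @param n_patients cohort size (default 718).
#' @param seed mandatory integer seed; the same seed and config reproduce the
#'   cohort exactly.
#' @param nb_size negative-binomial size (dispersion) parameter.
#' @param p_poly_baseline P(>= 5 regular medications) among patients without
#'   comorbidity impairment.
#' @param max_meds clamp for per-patient regular medication counts.
#' @param category_mix occurrence probabilities over prescription / otc /
#'   complementary (must sum to 1).
#' @param severity_mix knowledge-base severity probabilities over C / D / X
#'   (must sum to 1).
#' @param covariate_prevalences named list of category probability vectors for
#'   the patient covariates; defaults follow the published cohort marginals.
#' @param planted_effects named list: `comorbidity_poly_or`,
#'   `major_ddi_or_per_med`, `major_dci_or_per_med`, `p_major_ddi`,
#'   `p_major_dci`.
#' @param drugs_per_class synthetic generics generated per drug class.
#' @param n_kb_pairs interaction-KB size.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_patients = 718,
                             seed,
                             nb_size = 25,
                             p_poly_baseline = 0.40,
                             max_meds = 24,
                             category_mix = c(prescription = 0.733,
                                              otc = 0.200,
                                              complementary = 0.067),
                             severity_mix = c(C = 0.86, D = 0.12, X = 0.02),
                             covariate_prevalences = NULL,
                             planted_effects = list(
                               comorbidity_poly_or = 3.4,
                               major_ddi_or_per_med = 1.39,
                               major_dci_or_per_med = 1.12,
                               p_major_ddi = 0.247,
                               p_major_dci = 0.054),
                             drugs_per_class = 6,
                             n_kb_pairs = 120) {
  if (missing(seed) || is.null(seed)) stop_("a seed is mandatory")
  if (n_patients < 1) stop_("n_patients must be >= 1")
  check_mix <- function(x, what) {
    if (any(x < 0) || any(x > 1) || abs(sum(x) - 1) > 1e-6) {
      stop_(what, " must be probabilities summing to 1")
    }
  }
  check_mix(category_mix, "category_mix")
  check_mix(severity_mix, "severity_mix")
  prev <- covariate_prevalences %||% list(
    gender = c(male = 0.564, female = 0.436),
    race = c(white = 0.875, black = 0.072, others = 0.053),
    education = c(less_than_hs = 0.155, high_school = 0.341,
                  college_or_above = 0.504),
    income = c(le_50k = 0.517, gt_50k = 0.265, declined = 0.218),
    marital_status = c(single = 0.024, married = 0.627, separated = 0.349),
    cancer_type = c(gastrointestinal = 0.343, genitourinary = 0.152,
                    gynecological = 0.060, breast = 0.078, lung = 0.251,
                    lymphoma = 0.064, others = 0.052),
    stage = c(III = 0.125, IV = 0.875),
    treatment_line = c(first = 0.70, second_or_later = 0.30),
    life_expectancy = c(le_12mo = 0.335, gt_12mo = 0.665),
    kps = c(`20-60` = 0.130, `70-80` = 0.529, `90-100` = 0.341),
    ga_function = 0.575, ga_physical = 0.930, ga_comorbidity = 0.675,
    ga_cognition = 0.450, ga_social = 0.350, ga_psychological = 0.290,
    ga_nutrition = 0.600
  )
  for (nm in c("gender", "race", "education", "income", "marital_status",
               "cancer_type", "stage", "treatment_line", "life_expectancy",
               "kps")) {
    check_mix(prev[[nm]], nm)
  }

  # group means so that P(NB >= 5) hits each group's polypharmacy probability
  p0 <- p_poly_baseline
  p1 <- stats::plogis(stats::qlogis(p0) +
                        log(planted_effects$comorbidity_poly_or))
  solve_mu <- function(target) {
    stats::uniroot(function(mu) {
      1 - stats::pnbinom(4, size = nb_size, mu = mu) - target
    }, c(0.05, 60))$root
  }
  mu0 <- solve_mu(p0)
  mu1 <- solve_mu(p1)

  # theoretical clamped count distribution (comorbidity mixture)
  p_com <- prev$ga_comorbidity
  count_support <- 0:max_meds
  dmix <- p_com * stats::dnbinom(count_support, size = nb_size, mu = mu1) +
    (1 - p_com) * stats::dnbinom(count_support, size = nb_size, mu = mu0)
  dmix[length(dmix)] <- dmix[length(dmix)] +
    p_com * (1 - stats::pnbinom(max_meds, size = nb_size, mu = mu1)) +
    (1 - p_com) * (1 - stats::pnbinom(max_meds, size = nb_size, mu = mu0))
  solve_alpha <- function(log_or, target) {
    stats::uniroot(function(alpha) {
      sum(dmix * stats::plogis(alpha + log_or * count_support)) - target
    }, c(-30, 10))$root
  }
  alpha_ddi <- solve_alpha(log(planted_effects$major_ddi_or_per_med),
                           planted_effects$p_major_ddi)
  alpha_dci <- solve_alpha(log(planted_effects$major_dci_or_per_med),
                           planted_effects$p_major_dci)

  structure(list(
    n_patients = as.integer(n_patients),
    seed = as.integer(seed),
    nb_size = nb_size,
    mu_unimpaired = mu0,
    mu_impaired = mu1,
    p_poly_baseline = p0,
    max_meds = as.integer(max_meds),
    category_mix = category_mix,
    severity_mix = severity_mix,
    covariate_prevalences = prev,
    planted_effects = planted_effects,
    alpha_major_ddi = alpha_ddi,
    alpha_major_dci = alpha_dci,
    drugs_per_class = as.integer(drugs_per_class),
    n_kb_pairs = as.integer(n_kb_pairs)
  ), class = "synthetic_config")
}

#' Generate a synthetic formulary, interaction KB and PIM ruleset
#'
#' The three fixtures are internally consistent: every KB drug and every rule
#' target resolves against the formulary. Drug names are synthetic
#' (class-typical suffixes with generated stems); KB pairs are sampled among
#' regular drugs plus a share of regular-cancer pairs, severities drawn from
#' the configured mix with the maximum kept on duplicate pairs.
#'
#' @param config a `synthetic_config`.
#' @return list of class `synthetic_fixtures`: `formulary` (a `formulary`),
#'   `kb` (an `interaction_kb`), `rules` (a `pim_ruleset`), `drugs` (the
#'   per-drug table with `generic_name`, `atc_code`, `category`, `role`).
#' @export
generate_formulary <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, {
    k <- config$drugs_per_class
    drugs <- do.call(rbind, lapply(seq_len(nrow(SYN_CLASSES)), function(i) {
      cl <- SYN_CLASSES[i, ]
      syl <- SYN_SYLLABLES[(seq_len(k) + (i - 1L)) %% length(SYN_SYLLABLES) + 1L]
      data.frame(
        generic_name = paste0(syl, cl$suffix),
        atc_code = paste0(cl$code5, sprintf("%02d", seq_len(k))),
        category = cl$category,
        role = cl$role,
        stringsAsFactors = FALSE
      )
    }))
    stopifnot(!anyDuplicated(drugs$generic_name))
    fml <- formulary(drugs$generic_name, as.list(drugs$atc_code))

    regular <- drugs$generic_name[drugs$role == "regular"]
    cancer <- drugs$generic_name[drugs$role == "cancer"]
    n_dci <- round(0.15 * config$n_kb_pairs)
    n_ddi <- config$n_kb_pairs - n_dci
    # oversample then keep the first n unique canonical pairs
    draw_pairs <- function(pool_a, pool_b, n) {
      a <- sample(pool_a, 4 * n, replace = TRUE)
      b <- sample(pool_b, 4 * n, replace = TRUE)
      ok <- a != b
      p <- canonical_pair(a[ok], b[ok])
      key <- paste(p$a, p$b, sep = "\r")
      keep <- !duplicated(key)
      utils::head(data.frame(drug_a = p$a[keep], drug_b = p$b[keep],
                             stringsAsFactors = FALSE), n)
    }
    pairs <- rbind(draw_pairs(regular, regular, n_ddi),
                   draw_pairs(regular, cancer, n_dci))
    sev <- sample(names(config$severity_mix), nrow(pairs), replace = TRUE,
                  prob = config$severity_mix)
    kb <- interaction_kb(pairs$drug_a, pairs$drug_b, sev)

    rules <- synthetic_ruleset()
    structure(list(formulary = fml, kb = kb, rules = rules, drugs = drugs),
              class = "synthetic_fixtures")
  })
}

# rule templates over the classes the generator emits; targets are ATC
# prefixes, so they resolve against any formulary built from SYN_CLASSES
synthetic_ruleset <- function() {
  mk <- function(rule_id, source, atc, generic = NULL, predicates = NULL,
                 rationale = "") {
    list(rule_id = rule_id, source = source,
         targets = list(atc = atc, generic = generic),
         predicates = predicates, rationale = rationale)
  }
  rules <- list(
    mk("BEERS-PPI", "BEERS2019", "A02BC",
       rationale = "proton pump inhibitor, avoid prolonged use"),
    mk("BEERS-BZD", "BEERS2019", "N05BA",
       rationale = "benzodiazepine, fall and cognition risk"),
    mk("BEERS-NSAID", "BEERS2019", "M01AE",
       rationale = "chronic NSAID, GI bleeding risk"),
    mk("BEERS-FGA", "BEERS2019", "R06AA",
       rationale = "first-generation antihistamine, anticholinergic"),
    mk("BEERS-SSRI-FALLS", "BEERS2019", "N06AB",
       predicates = list(ga_flag = "function"),
       rationale = "SSRI with impaired function, fall risk"),
    mk("STOPP-FGA", "STOPP", "R06AA",
       rationale = "first-generation antihistamine"),
    mk("STOPP-BB-DM", "STOPP", "C07AB",
       predicates = list(co_medication_atc = "A10B"),
       rationale = "beta-blocker with antidiabetic co-medication"),
    mk("STOPP-BZD", "STOPP", "N05BA",
       rationale = "benzodiazepine > 4 weeks"),
    mk("STOPP-NSAID", "STOPP", "M01AE",
       predicates = list(ga_flag = "comorbidity"),
       rationale = "NSAID with significant comorbidity")
  )
  structure(lapply(rules, validate_rule), class = "pim_ruleset")
}

#' Generate a synthetic cohort with a planted-truth ledger
#'
#' @param config a `synthetic_config`.
#' @param fixtures optional `synthetic_fixtures`; regenerated from the config
#'   when omitted.
#' @return list of class `synthetic_cohort`: `cohort` (a `med_cohort` whose
#'   patient table carries the planted binary outcomes `planted_major_ddi`,
#'   `planted_major_dci`), `truth` (the planted-truth ledger) and `fixtures`.
#' @export
generate_cohort <- function(config, fixtures = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  fixtures <- fixtures %||% generate_formulary(config)
  drugs <- fixtures$drugs
  n <- config$n_patients
  prev <- config$covariate_prevalences

  with_seed((config$seed + 1000003L) %% .Machine$integer.max, {
    draw_cat <- function(p) sample(names(p), n, replace = TRUE, prob = p)
    patients <- data.frame(
      patient_id = sprintf("P%05d", seq_len(n)),
      age_years = pmin(70L + stats::rpois(n, 7.2), 96L),
      gender = draw_cat(prev$gender),
      race = draw_cat(prev$race),
      education = draw_cat(prev$education),
      income = draw_cat(prev$income),
      marital_status = draw_cat(prev$marital_status),
      cancer_type = draw_cat(prev$cancer_type),
      stage = draw_cat(prev$stage),
      treatment_line = draw_cat(prev$treatment_line),
      life_expectancy = draw_cat(prev$life_expectancy),
      kps = draw_cat(prev$kps),
      stringsAsFactors = FALSE
    )
    for (flag in c("ga_function", "ga_physical", "ga_comorbidity",
                   "ga_cognition", "ga_social", "ga_psychological",
                   "ga_nutrition")) {
      patients[[flag]] <- stats::runif(n) < prev[[flag]]
    }

    mu <- ifelse(patients$ga_comorbidity, config$mu_impaired,
                 config$mu_unimpaired)
    n_meds <- pmin(stats::rnbinom(n, size = config$nb_size, mu = mu),
                   config$max_meds)

    # regular medications: category by mix, then a drug uniform within the
    # category's pool, distinct within patient
    reg_pool <- drugs[drugs$role == "regular", , drop = FALSE]
    w <- config$category_mix[reg_pool$category] /
      as.vector(table(reg_pool$category)[reg_pool$category])
    reg_picks <- lapply(n_meds, function(k) {
      if (k == 0) integer(0) else sample(seq_len(nrow(reg_pool)), k, prob = w)
    })
    reg_idx <- unlist(reg_picks)

    # cancer regimen (1-3 drugs) and supportive care (0-2)
    ca_pool <- drugs$generic_name[drugs$role == "cancer"]
    sc_pool <- drugs$generic_name[drugs$role == "supportive"]
    ca_n <- sample(1:3, n, replace = TRUE)
    sc_n <- stats::rbinom(n, min(2, length(sc_pool)), 0.5)
    ca_picks <- lapply(ca_n, function(k) sample(ca_pool, k))
    sc_picks <- lapply(sc_n, function(k) sample(sc_pool, k))

    pid <- patients$patient_id
    meds <- medication_log(
      patient_id = c(rep(pid, lengths(reg_picks)),
                     rep(pid, ca_n), rep(pid, sc_n)),
      raw_name = c(reg_pool$generic_name[reg_idx],
                   unlist(ca_picks), unlist(sc_picks)),
      category = c(reg_pool$category[reg_idx],
                   rep("prescription", sum(ca_n) + sum(sc_n))),
      is_cancer_treatment = c(rep(FALSE, length(reg_idx)),
                              rep(TRUE, sum(ca_n)), rep(FALSE, sum(sc_n))),
      is_supportive_care = c(rep(FALSE, length(reg_idx) + sum(ca_n)),
                             rep(TRUE, sum(sc_n)))
    )
    meds <- normalize_and_dedupe(meds)

    # planted interaction outcomes through the logistic link on the count
    eff <- config$planted_effects
    patients$planted_major_ddi <- stats::runif(n) < stats::plogis(
      config$alpha_major_ddi + log(eff$major_ddi_or_per_med) * n_meds)
    patients$planted_major_dci <- stats::runif(n) < stats::plogis(
      config$alpha_major_dci + log(eff$major_dci_or_per_med) * n_meds)

    truth <- list(
      seed = config$seed,
      n_patients = n,
      comorbidity_poly_or = eff$comorbidity_poly_or,
      major_ddi_or_per_med = eff$major_ddi_or_per_med,
      major_dci_or_per_med = eff$major_dci_or_per_med,
      alpha_major_ddi = config$alpha_major_ddi,
      alpha_major_dci = config$alpha_major_dci,
      nb_size = config$nb_size,
      mu_unimpaired = config$mu_unimpaired,
      mu_impaired = config$mu_impaired,
      category_mix = as.list(config$category_mix),
      severity_mix = as.list(config$severity_mix)
    )
    structure(list(
      cohort = med_cohort(patients, meds),
      truth = truth,
      fixtures = fixtures
    ), class = "synthetic_cohort")
  })
}

#' Write the planted-truth ledger as JSON
#' @param truth the `truth` element of a `synthetic_cohort`.
#' @param path output path.
#' @export
write_planted_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
}
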