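rules_path <- function() extdata("pim_rules.json")

test_that("packaged ruleset loads and covers the headline PIM classes", {
  rules <- load_ruleset(rules_path())
  expect_gte(length(rules), 4)
  atc_targets <- unlist(lapply(rules, function(r) r$targets$atc))
  for (cls in c("A02BC", "N05BA", "M01AE", "R06AA")) {
    expect_true(any(startsWith(atc_targets, cls) | startsWith(cls, atc_targets)),
                label = paste("class", cls, "targeted"))
  }
  expect_setequal(unique(vapply(rules, `[[`, character(1), "source")),
                  c("BEERS2019", "STOPP"))
})

test_that("ruleset schema errors are specific", {
  bad_dup <- tempfile(fileext = ".json")
  writeLines('[{"rule_id":"R1","source":"STOPP","targets":{"atc":["A02BC"]}},
               {"rule_id":"R1","source":"STOPP","targets":{"atc":["N05BA"]}}]',
             bad_dup)
  expect_error(load_ruleset(bad_dup), "duplicate rule_id")

  bad_src <- tempfile(fileext = ".json")
  writeLines('[{"rule_id":"R1","source":"PRISCUS","targets":{"atc":["A02BC"]}}]',
             bad_src)
  expect_error(load_ruleset(bad_src), "source")

  bad_tgt <- tempfile(fileext = ".json")
  writeLines('[{"rule_id":"R1","source":"STOPP","targets":{}}]', bad_tgt)
  expect_error(load_ruleset(bad_tgt), "empty targets")

  empty <- tempfile(fileext = ".json")
  writeLines("[]", empty)
  expect_warning(rs <- load_ruleset(empty), "empty")
  expect_length(rs, 0)
})

test_that("a rule with both ATC and generic targets matches either", {
  f <- tempfile(fileext = ".json")
  writeLines(paste0('[{"rule_id":"R1","source":"BEERS2019",',
                    '"targets":{"atc":["A02BC"],"generic":["ranitidine"]}}]'),
             f)
  rules <- load_ruleset(f)
  fml <- formulary(c("omeprazole", "ranitidine", "aspirin"),
                   list("A02BC01", "A02BA02", "B01AC06"))
  meds <- normalize_and_dedupe(medication_log(
    rep("p1", 3), c("omeprazole", "ranitidine", "aspirin")))
  co <- med_cohort(tiny_patients("p1"), meds)
  flags <- screen_cohort(co, rules, classify_cohort(co, fml))
  expect_setequal(flags$generic_name, c("omeprazole", "ranitidine"))
})

test_that("screening flags match a hand evaluation of the fixture rules", {
  rules <- load_ruleset(rules_path())
  fml <- read_formulary(extdata("formulary.csv"))
  co <- demo_cohort()
  ann <- classify_cohort(co, fml)
  flags <- screen_cohort(co, rules, ann)
  # patient p1 (function-impaired, comorbidity-impaired) is on omeprazole
  # (A02BC01), lorazepam (N05BA06), ibuprofen (M01AE01):
  # Beers: PPI, BZD, NSAID; STOPP: PPI-LONG, BZD-LONG, NSAID-COMORB
  p1 <- flags[flags$patient_id == "p1", ]
  expect_setequal(p1$rule_id[p1$source == "BEERS2019"],
                  c("BEERS-PPI", "BEERS-BZD", "BEERS-NSAID"))
  expect_setequal(p1$rule_id[p1$source == "STOPP"],
                  c("STOPP-PPI-LONG", "STOPP-BZD-LONG", "STOPP-NSAID-COMORB"))
  # p2 is on atorvastatin + diphenhydramine: first-generation antihistamine
  # flags only
  p2 <- flags[flags$patient_id == "p2", ]
  expect_setequal(p2$rule_id, c("BEERS-FG-ANTIHIST", "STOPP-FG-ANTIHIST"))
  # deterministic order within patient
  expect_equal(p1$rule_id, sort(p1$rule_id))
  # cancer treatment (carboplatin) never flagged
  expect_false("carboplatin" %in% flags$generic_name)
})

test_that("predicates fail closed on missing covariates, with a log message", {
  f <- tempfile(fileext = ".json")
  writeLines(paste0('[{"rule_id":"R1","source":"STOPP",',
                    '"targets":{"atc":["M01AE"]},',
                    '"predicates":{"ga_flag":"comorbidity"}}]'), f)
  rules <- load_ruleset(f)
  fml <- formulary("ibuprofen", list("M01AE01"))
  meds <- normalize_and_dedupe(medication_log("p1", "ibuprofen"))
  co <- med_cohort(tiny_patients("p1"), meds) # no ga_comorbidity column
  expect_message(
    flags <- screen_cohort(co, rules, classify_cohort(co, fml)),
    "fails closed")
  expect_equal(nrow(flags), 0)
})

test_that("co-medication predicates require the interacting class", {
  rules <- load_ruleset(rules_path())
  fml <- read_formulary(extdata("formulary.csv"))
  # metoprolol alone: no STOPP-BB-DM flag; with metformin (A10B): flagged
  co1 <- med_cohort(tiny_patients("p1"),
                    normalize_and_dedupe(medication_log("p1", "metoprolol")))
  f1 <- screen_cohort(co1, rules, classify_cohort(co1, fml))
  expect_false("STOPP-BB-DM" %in% f1$rule_id)
  co2 <- med_cohort(
    tiny_patients("p1"),
    normalize_and_dedupe(medication_log(c("p1", "p1"),
                                        c("metoprolol", "metformin"))))
  f2 <- screen_cohort(co2, rules, classify_cohort(co2, fml))
  expect_true("STOPP-BB-DM" %in% f2$rule_id)
})

test_that("prevalence counts patients once per source; union dominates", {
  rules <- load_ruleset(rules_path())
  fml <- read_formulary(extdata("formulary.csv"))
  co <- demo_cohort()
  flags <- screen_cohort(co, rules, classify_cohort(co, fml))
  prev <- pim_prevalence(co, flags)
  # both patients flagged by both sources -> 100% each and union
  expect_equal(prev$pct_beers, 100)
  expect_equal(prev$pct_stopp, 100)
  expect_gte(prev$pct_union, max(prev$pct_beers, prev$pct_stopp))
  # brute-force recount oracle
  expect_equal(prev$pct_union,
               round_half_up(100 * length(unique(flags$patient_id)) /
                               nrow(co$patients), 1))
  # p1's flagged PPI/NSAID are OTC records
  beers_flags <- flags[flags$source == "BEERS2019", ]
  expect_equal(prev$pct_nonrx_flags[["BEERS2019"]],
               round_half_up(100 * sum(beers_flags$category %in%
                                         c("otc", "complementary")) /
                               nrow(beers_flags), 1))
})

test_that("adding a rule never decreases any patient's flag count", {
  fml <- read_formulary(extdata("formulary.csv"))
  co <- demo_cohort()
  ann <- classify_cohort(co, fml)
  rules_all <- load_ruleset(rules_path())
  for (k in c(3, 6, length(rules_all))) {
    sub <- structure(rules_all[seq_len(k - 1)], class = "pim_ruleset")
    full <- structure(rules_all[seq_len(k)], class = "pim_ruleset")
    n_sub <- table(factor(screen_cohort(co, sub, ann)$patient_id,
                          levels = co$patients$patient_id))
    n_full <- table(factor(screen_cohort(co, full, ann)$patient_id,
                           levels = co$patients$patient_id))
    expect_true(all(as.integer(n_full) >= as.integer(n_sub)))
  }
})

test_that("no targeted drug means no flags; empty cohort errors", {
  rules <- load_ruleset(rules_path())
  fml <- read_formulary(extdata("formulary.csv"))
  co <- med_cohort(tiny_patients("p1"),
                   normalize_and_dedupe(medication_log("p1", "levothyroxine")))
  flags <- screen_cohort(co, rules, classify_cohort(co, fml))
  expect_equal(nrow(flags), 0)
  prev <- pim_prevalence(co, flags)
  expect_equal(prev$pct_union, 0)
})
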