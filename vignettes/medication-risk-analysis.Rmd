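---
title: "Methods: medication-risk analysis in older adults with cancer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: medication-risk analysis in older adults with cancer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The analysis and its assumptions

`polyrx` analyses per-patient medication logs from cohorts of adults aged 70
or older with advanced cancer who are starting systemic treatment. The unit of
observation is the *medication occurrence*: one (patient, generic drug)
exposure, classified as prescription, OTC or complementary. Three structural
assumptions run through every module:

1. **Regular vs cancer-related.** Cancer therapies and supportive-care drugs
   live in the same log but are flagged, and they never contribute to the
   regular-medication count, PIM screening, or the regular side of interaction
   detection. Supportive-care drugs take part in no interaction analysis at
   all; cancer drugs appear only on the cancer side of drug–cancer-treatment
   (DCI) lookups.
2. **Name-level identity.** Records are normalized to lowercase generic names
   (brand names mapped through a synonym table, dose/route tokens stripped
   conservatively), and a duplicate is the same (patient, generic) pair —
   different doses of one generic collapse to one record. As-needed (PRN) and
   scheduled medications count equally: the log represents what the patient
   actually received in the recent window, so a schedule field is accepted
   but ignored for counting.
3. **Patient-level prevalence.** All headline percentages are patients meeting
   a definition over the full cohort n, not occurrence shares, except where a
   share of occurrences or of flags is explicitly named.

Polypharmacy is ≥ 5 regular medications and excessive polypharmacy ≥ 10; both
thresholds are arguments, not constants, because the literature uses cut-offs
from 3 to 10. An excessive-polypharmacy patient also satisfies the
polypharmacy definition wherever prevalence is tallied, so
`pct_excessive ≤ pct_polypharmacy` is an invariant.

## ATC classification

Full WHO ATC codes are seven characters in five nested levels with prefix
widths 1, 3, 4, 5 and 7. The analysis uses levels 1–3. A formulary table maps
each generic to one or more codes with a designated primary code; tallies and
network node assignment use the primary code only, so each occurrence lands in
exactly one subgroup and nothing is double-counted. The full code list is
retained on the formulary entry for inspection. Occurrences missing from the
formulary go to an *unclassified report*: they are excluded from class tallies
but still count toward the medication totals, giving the conservation law
`sum(level-2 tallies) + unclassified = total regular occurrences`. Combination
products are not given special handling — a combination name that is not in
the formulary simply appears in the unclassified report, which is the honest
place for it given that tallying conventions for combinations vary.

## The PIM rules engine

Rules are data: each has a source catalog (`BEERS2019` or `STOPP`), a
nonempty target set (ATC prefixes and/or generic names, matched as a union),
optional conjunctive predicates (minimum age, a required covariate value, a
required co-medication ATC prefix, a required geriatric-assessment impairment
flag) and a free-text rationale. The packaged ruleset
(`inst/extdata/pim_rules.json`, 25 rules) is a *representative
machine-readable subset* reconstructed from the drug classes these catalogs
are known for — proton pump inhibitors, benzodiazepines, NSAIDs,
first-generation antihistamines, tricyclics, sulfonylureas and so on. It does
not claim completeness of either catalog; full transcription is a licensing
and curation problem outside this package's scope, and users with access to
the complete criteria can supply their own JSON.

Two evaluation decisions matter. A predicate that references a covariate the
patient record lacks **fails closed** (no flag) and the miss is logged — the
alternative, flagging on missing data, would inflate prevalence invisibly.
And a medication matching several rules of one source yields several flags,
but the patient counts once per source toward prevalence, since the reported
quantity is "patients with ≥ 1 PIM". Because class-share percentages have two
defensible denominators (flags vs patients), `pim_prevalence()` reports both,
labelled `pct_of_flags` and `pct_of_patients`.

## Interaction detection

The knowledge base is a pluggable CSV of unordered generic-name pairs graded
C / D / X; pairs are canonicalized to lexicographic order at load and a
duplicated pair keeps its maximum severity (X > D > C). Matching is by generic
name, not ATC class, because interaction severity is substance-specific; ATC
enters only at aggregation. Severities other than C, D, X are rejected at
load — the milder categories of commercial interaction databases are
deliberately unrepresentable here. One detection is emitted per (patient,
canonical pair, kind), so a pair occurring in k patients contributes k
occurrences downstream; whether a cohort-level count of "potential DDIs"
should deduplicate pairs across patients is a reporting convention, and this
package consistently uses the patient-level sum.

## Networks and their metrics

A network is built from detections at the medication level or any ATC rollup
level 1–3. The node universe is the labels that actually interact, not the
whole formulary — a density denominator over all observed subgroups would
shrink density by counting isolated nodes that carry no risk information. At
rollup levels a detection whose two drugs share a class becomes a *self-pair
tally* (not a self-loop edge), and a detection involving an unclassified drug
goes to an *unmapped tally*; edge weights plus both tallies always equal the
number of input detections.

- **Density** is `2E / (N(N−1))`, defined as 0 for fewer than two nodes.
- **Diameter** is the longest shortest path within the largest connected
  component. Medication-level networks routinely split into disconnected
  sub-networks, where the all-pairs diameter would be infinite;
  per-component diameters are reported alongside.
- **Triadic closure** is implemented as global transitivity — three times the
  triangle count over the number of connected triples — which is the closest
  formalization of "the chance that two nodes connected to a third are
  themselves connected". Mean local clustering, the other common reading of
  that phrase, is reported as a secondary statistic
  (`mean_local_clustering`).

Chord-diagram export returns the symmetric pairwise occurrence matrix with
sorted labels and zero diagonal, zeroing pairs below `min_count` — published
chord diagrams conventionally hide subgroup pairs below an occurrence
threshold (the pipeline defaults to 20 for all interactions and 3 for major
ones).

## Statistics

For a 2×2 table (a, b, c, d) = (exposed with outcome, exposed without,
referent with, referent without), the prevalence odds ratio is the
cross-product `ad/bc` with the Woolf interval
`exp(ln POR ± z·√(1/a+1/b+1/c+1/d))`, z = 1.959964 for 95%. A zero cell
triggers the Haldane–Anscombe correction (0.5 added to all four cells) and the
result is tagged `continuity_corrected`; an all-zero margin is an error, not a
number. Fisher's exact test uses the probability-mass convention for the
two-sided p-value — the hypergeometric probabilities of all tables (margins
fixed) no more probable than the observed one are summed, with a 1e-7 relative
tolerance guarding floating-point ties; conventions differ across software, so
this one is stated. Chi-square is the Pearson statistic with no continuity
correction. The two-sample t-test defaults to Welch's unequal-variance form
with a pooled-variance option, since "independent t-test" underdetermines the
variant; two identical constant samples return p = 1 with a message rather
than erroring.

The odds ratio per additional medication comes from a univariate logistic
regression fitted by iteratively reweighted least squares, iterating until the
relative log-likelihood change is below 1e-10 (at most 100 iterations), with a
Wald interval from the observed information. Complete separation is reported
as an error instead of a silently diverging slope (diagnostics: divergent
coefficient or all fitted probabilities pinned at 0/1). A univariate fit is
used because the per-medication odds increase is most interpretable
unadjusted; users wanting adjusted models can feed the same columns to
`glm()`. Significance language follows two-sided α = 0.05.

Association tables drop patients with a missing value of the variable under
test (complete-case per variable). This is why a minority of published table
rows are not exactly recomputable from their printed cells: with a handful of
patients missing per covariate, printed marginals and cross-products can
disagree in the second decimal. The packaged
`inst/extdata/printed_por_rows.csv` stores the printed cells with a
`reproduces` flag; regression tests assert exact two-decimal agreement on the
21 of 40 rows whose cells are internally consistent and take no side on the
rest. Similarly, when a source reports two slightly different cohort means in
different places, the package just computes the mean of the data it is given.

## The synthetic generator: what it emulates, and what it does not

`synthetic_config()` encodes the study conditions: 718 patients aged ≥ 70
(ages 70 + Poisson(7.2), capped at 96), regular-medication counts from a
negative binomial clamped to 0–24, occurrence categories mixed
73.3/20/6.7 prescription/OTC/complementary (26.7% nonprescription), a C/D/X
knowledge-base severity mix of 86/12/2, and covariate marginals matching the
published cohort (KPS bands 13/52.9/34.1%, life expectancy ≤ 12 months in
33.5%, comorbidity impairment 67.5%, and so on; geriatric-assessment domains
without a published marginal use plausible mid-range values).

Effects are planted analytically, not tuned:

- **Comorbidity → polypharmacy.** The baseline P(≥ 5 medications) for
  comorbidity-unimpaired patients is 0.40; the impaired group's probability is
  `plogis(qlogis(0.40) + log(3.4))`, planting a prevalence odds ratio of 3.4.
  The two negative-binomial means are solved numerically (uniroot on the CDF)
  from those probabilities with dispersion size 25. Size 25 keeps the count
  distribution concentrated enough that the theoretical mixture median is 5
  (a sample of 718 has a ≈ 99.6% chance of hitting it exactly); the cost is a
  lighter right tail than real cohorts show — generated maxima run in the
  mid-teens rather than the low twenties, and excessive-polypharmacy
  prevalence is correspondingly lower. The clamp at 24 is therefore a
  guardrail, rarely binding.
- **Per-medication interaction odds.** Binary major-DDI and major-DCI
  outcomes are drawn from `plogis(α + log(OR)·count)` with OR 1.39 and 1.12;
  each α is solved so the marginal outcome rate is 0.247 and 0.054 under the
  theoretical count distribution. These planted outcomes live on the patient
  table (`planted_major_ddi`, `planted_major_dci`) alongside — deliberately
  not derived from — the knowledge-base detections, so estimator recovery can
  be scored against exact truth.

Everything is seeded: the fixture trio (formulary/KB/ruleset) consumes the
config seed and the cohort a fixed offset of it, so identical seed and config
reproduce the cohort bit for bit while a shared fixture set can serve many
replicate cohorts.

What the generator does **not** emulate: the joint covariate distribution
beyond the published marginals (covariates other than comorbidity are drawn
independently), realistic co-prescription correlation structure (drugs are
sampled per occurrence-category weights, not by indication), dose or duration,
and a knowledge base dense enough to reproduce cohort-level interaction
headcounts — the packaged and generated KBs are representative subsets, so
synthetic DDI prevalence is well below the published cohort's. Consequently,
passing recovery tests demonstrate that the estimators are correct and
calibrated, not that the generator reproduces every published headline number;
the numbers that *are* directly recomputable (printed-count percentages and
internally consistent table rows) are recomputed from the printed inputs
instead.

## Problem sizes and numerical choices in the test suite

The suite checks graph metrics against exhaustive oracles (Floyd–Warshall
shortest paths, full triple enumeration) on random graphs of 2–15 nodes across
edge densities 0.15–0.9; Fisher's exact test against full
binomial-coefficient enumeration for table totals up to 40; t-test null
calibration with 1000 two-sample draws at n = 25; and logistic recovery of the
planted OR 1.39 as 95%-CI coverage over 200 replicate cohorts of n = 718
(required ≥ 90%). These sizes keep each property readable and exhaustive where
exhaustiveness is the point. Reporting rounds half away from zero — one
decimal for percentages, two for odds ratios and intervals, matching how such
tables are conventionally printed — while module outputs keep full precision;
`round_half_up()` exists because base R rounds to even.

## Known limitations

- The PIM rulesets and interaction KB are curated subsets; prevalence computed
  with them on real data will undercount relative to the complete catalogs.
- Dose-, duration- and indication-conditional criteria are out of scope, as
  are START (under-prescribing) criteria and pharmacokinetic modelling.
- Network metrics are the three descriptive ones (density, diameter, triadic
  closure); no centrality or statistical network models.
- No multivariable adjustment and no multiple-testing correction in the
  association layer; every test is a planned bivariate comparison.
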