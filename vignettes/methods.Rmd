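---
title: "CohortCube: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CohortCube: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CohortCube)
```

CohortCube models a federated EHR-learning network at desk scale: each
"site" turns a bulk-FHIR export into a de-identified, text-free set of
study tables, evaluates a computable phenotype, and publishes only a
suppressed aggregate count matrix; a coordinating step sums those matrices
into a network matrix from which epidemiological measures are computed.
This vignette records the model, the tunable parameters, and the design
decisions taken where more than one defensible choice existed.

## The count model

Let $S = (v_1, \dots, v_n)$ be the ordered study variables, each with a
finite set of discrete levels. For every subset $T \subseteq S$ and every
observed level combination on $T$, the aggregate matrix stores the number
of cohort units (patients or encounters) matching that partial assignment.
The empty subset contributes the *null-set row*, whose count is the total
cohort size. There are $2^n$ subset shapes; level combinations never
observed in the cohort are omitted, so the stored matrix is sparse
relative to the full cross-product. Internally the cube is computed by
explicit subset enumeration with grouped counting (data.table), which is
equivalent to a SQL `CUBE` aggregation; an independent brute-force
enumeration oracle backs this equivalence in the test suite. A
configurable cap (`nMax = 10` variables) turns the exponential growth into
a hard error rather than a surprise.

Useful consequences that the tests exercise as invariants:

* every cell count is bounded by the null-set count (monotone anti-chain);
* summing one variable's levels inside any fixed context reproduces the
  context's own row (marginal consistency, pre-suppression);
* the cube of an empty cohort is a single null-set row of zero.

## Suppression and federation

Cells with fewer than `threshold` units (default 10) are **removed
entirely** — no masking token, no rounding — and the applied threshold is
recorded in the matrix metadata. The threshold applies uniformly,
including to the null-set row: a cohort smaller than the threshold
suppresses to an empty matrix with a logged refusal. Whether the total
row deserves an exemption is genuinely arguable; uniform treatment was
chosen because a sub-threshold cohort total is itself a small cell, and
the refusal is visible rather than silent.

Merging is cellwise addition over the union of assignments, with absent
cells contributing zero. Inputs must agree on the variable list, the study
period, and the suppression threshold. The merged result is re-suppressed
at that same threshold, because a merged cell assembled from a few small
site cells can otherwise fall below the disclosure floor. Two consequences
are accepted and documented rather than corrected:

* **Undercounting.** A cell suppressed at one site contributes nothing to
  the network sum, so merged counts can undercount the true network total.
  This is the price of suppress-then-share; sites never transmit
  sub-threshold counts, so the coordinator cannot recover them.
* **Asymmetry with pooling.** Cells suppressed everywhere vanish from the
  network matrix even if their pooled count would clear the threshold.

Merge is commutative and associative modulo metadata ordering, which the
tests check on random fixtures.

## Analytics from counts alone

A 2×2 exposure-by-outcome table is extracted by marginal subtraction:
$a$ = joint cell, $b$ = exposure marginal − $a$, $c$ = outcome marginal −
$a$, $d$ = total − $a$ − $b$ − $c$. Measures follow their classical
closed forms: OR $= ad/bc$ with a log-scale Wald 95% interval, RR
$= \frac{a/(a+b)}{c/(c+d)}$, conditional probability $a/(a+b)$,
prevalence = level marginal / null-set count, and the 2×2 chi-square
$N(ad-bc)^2 / [(a+b)(c+d)(a+c)(b+d)]$ with 1 df (Yates correction
available, off by default). A zero cell in OR/RR triggers the
Haldane–Anscombe 0.5 correction, reported with a `corrected` flag rather
than silently.

**Absent-cell policy.** In a matrix that was never suppressed, an absent
cell is an exact zero — the sparse representation omits zeros by
construction — and is used as such. In a suppressed matrix an absent cell
is destroyed information, and every measure that needs one raises an
explicit incomputable error. Imputation is never attempted: in an
aggregate-only federation a missing cell is information, not a zero. The
monthly trend series applies the same rule per month and additionally
enumerates the study period from the matrix metadata so that months whose
every cell was suppressed can still be listed as omitted.

## Computable phenotypes

A study specification is a case definition (inclusion and exclusion
criterion trees over three primitives: code-in-value-set on the condition,
symptom or medication table; numeric threshold on the observation table;
combined with any-of / all-of), an ordered list of study variables, a
study period in whole months, and a counting unit. Evaluation is strictly
in-period: only events attached to encounters whose month falls inside the
period can influence case status or any variable, which the tests verify
by perturbation. For patient-level counting, a patient is a case if any
in-period encounter qualifies, and the reference encounter for age and
month variables is the first in-period encounter.

The shipped hypertension definition reads: systolic ≥ 140 mm Hg **or**
diastolic ≥ 90 mm Hg, both comparators inclusive. The source measure
this mirrors treats either arm at its critical value as uncontrolled, so
the inclusive-OR reading was adopted; integer boundary sweeps in the
acceptance suite pin 140 and 90 as the minimal case-positive readings. A
medication-in-value-set exclusion hook exists but ships with no
authoritative code list, hence an empty exclusion.

Age at encounter is computed from birth year and encounter month only,
because de-identification truncates all dates to month precision; the
error is at most one year, uniform across the cohort. Comparison cohorts,
when requested, are simply all in-period non-cases — propensity-score
matching is out of scope.

## Note-text symptom extraction

The production systems this package emulates run learned clinical NLP;
CohortCube substitutes a deterministic, configurable two-stage rule
pipeline with the same contract (structured, text-free symptom records per
note):

* **Dictionary matching**: case-insensitive surface-form matches at word
  boundaries ("cough" never fires inside "coughing"), longest match wins,
  non-overlapping, ordered by span start. The shipped dictionary maps five
  respiratory symptoms to ICD-10-CM codes with 2–3 surface forms each; the
  same codes serve as the coded-data value sets, so NLP-derived and
  ICD-derived flags are directly comparable.
* **Negation**: NegEx-style. A mention is negated iff a pre-cue ("no",
  "denies", "without", "negative for", ...) occurs within a five-token
  window before it, or a post-cue ("ruled out", "unlikely") within the
  window after it, with scope cut by sentence boundaries and conjunction
  terminators ("but", "however"). Five tokens is the conventional NegEx
  scope; both the cue lists and the window are configuration, not code.
  Polarity is binary — hedged mentions ("possible fever") count as
  affirmed, since no uncertain class is defined downstream.

Only affirmed mentions become records, carrying concept code, encounter
reference and document month; no span text, offsets or note text survive
into the output. Notes are consumed inside the site ETL stage and never
reach the de-identification boundary at all.

## De-identification

Field handling is **allow-list**: every field not named by a rule is
dropped, which fails safe for fields the rules never anticipated. Actions
are keep, drop, generalize-date-to-month, and pseudonymize. The codebook
is a keyed one-way construction — HMAC-SHA256 over the identifier,
rendered as 24 lowercase letters — rather than a stored lookup table, so
determinism (joins survive, re-runs reproduce) comes without a PHI-bearing
mapping file; the only retained state is a collision-detection cache. The
a–z output alphabet means no digit-bearing source identifier can resurface
as a substring of a pseudonym. Record ids are keyed as `Type/id`, matching
how references are written, so `Patient/123` in an Encounter's subject and
the Patient record's own id map to the same pseudonym. Dates are truncated
to month, matching the month granularity of every downstream display;
date *shifting* was considered and rejected as unnecessary once nothing
finer than month survives. The generator caps ages at 89 so the special
handling of very old ages never arises.

## The synthetic generator

The generator emulates exactly what the pipeline needs to be testable with
known ground truth: a multi-site bulk-FHIR export with per-patient disease
status, per-patient true symptom sets, per-encounter notes containing
affirmed mentions of true symptoms and negated mentions of absent ones,
ICD-coded conditions at a configurable (lower) sensitivity, two
blood-pressure observations per encounter drawn from hypertensive/normal
strata, and occasional antihypertensive medication requests. Its defaults
are the study conditions the package is exercised under: 5 sites, disease
prevalence 0.3, note-mention sensitivity 0.9, ICD coding sensitivity 0.5,
negated-mention rate 0.2, a 12-month window (2021-01 to 2021-12, chosen so
a 10,000-patient network yields monthly denominators of several hundred),
hypertensive stratum N(150, 10)/N(95, 8) vs normal N(118, 8)/N(75, 6)
mm Hg, and 1 + Poisson(0.3) encounters per patient. Because note-mention
sensitivity exceeds coding sensitivity, text-derived symptom detection
outperforms coded detection *in expectation by construction* — the
pipeline is expected to reproduce that ordering from the aggregate matrix,
and does.

What it does **not** model, deliberately: disease progression,
comorbidity structure, care pathways, seasonal encounter intensity
(months are uniform unless the window is changed), coding noise
(false-positive ICD codes), misspelled or out-of-dictionary symptom
mentions, and hedged language. Passing tests therefore demonstrate that
the pipeline's mechanics are correct under its stated assumptions — not
that the shipped dictionary or cue lists would reach any particular
accuracy on real clinical prose.

A fixed seed makes the NDJSON output byte-identical across runs; the
ground truth is written as separate CSVs and is never fed to the pipeline.

## Numerical and degenerate-input policies

* Cube of an empty cohort: one null-set row, count 0.
* Suppression of a cohort below threshold: empty matrix plus a logged
  refusal, never a masked total.
* Continuous (non-integer double) variable columns: hard error directing
  the user to bin.
* Mixed suppression thresholds at merge: error; the semantics of a mixed
  merge are undefined.
* Matrix CSV serialization: an empty cell means "variable not in this
  row's subset"; empty-string levels are therefore rejected at write time.
* Canonical row order (subset size, then variable names, then levels)
  makes serialized matrices byte-stable for diffing.
* Pseudonymization of the empty string, and codebook secrets under 16
  characters, are errors.

## Problem sizes

The test suite validates the cube against brute-force enumeration on 200
random cohorts of up to 1,000 rows and 6 variables, and runs the full
five-site pipeline at 10,000 patients for parameter recovery (prevalence
within three binomial standard errors of the generating 0.3; aggregate
crosstab odds ratio exactly equal to the line-level odds ratio when no
required cell is suppressed) and for the NLP-vs-ICD monthly comparison
(every month with denominator ≥ 200). These sizes were chosen as the
smallest at which the binomial tolerances are meaningfully tight.

## Known limitations

* The negation rules are intentionally simple; scope termination handles
  conjunctions and sentence ends but not, e.g., pseudo-negation ("no
  increase in cough").
* Suppress-then-merge undercounts, as discussed above; the package
  documents rather than corrects this, since correcting it would require
  transmitting sub-threshold information.
* Value-set matching is by code string only; code-system labels are
  carried but not enforced during matching.
* The medication table is flattened but the shipped studies do not use it
  beyond the exclusion hook.
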