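---
title: "Methods: rule-based detection of shoulder injury related to vaccine administration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rule-based detection of shoulder injury related to vaccine administration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sirvanlp)
```

## The problem

Shoulder injury related to vaccine administration (SIRVA) — shoulder pain
and limited range of motion after an intramuscular vaccine injected into
the upper arm — has no dedicated diagnosis code, occurs on the order of 1
per 10,000 vaccinations, and shares its presenting symptoms with some of
the most common musculoskeletal complaints in primary care. Finding cases
in an EHR therefore requires reading free-text clinical notes, and doing
that manually across tens of thousands of presumptive records is
impractical. `sirvanlp` implements a fully rule-based pipeline that (1)
narrows a vaccinated population to presumptive cases using structured
diagnosis codes, (2) reads each patient's notes for anatomic, temporal and
causal statements about the shoulder problem, and (3) classifies each
vaccination event as a definite, probable, possible or negative case with
a per-criterion audit trail. Because real EHR data cannot ship with the
package, a grammar-based synthetic generator produces populations with
exact ground truth for every behavior the pipeline must discriminate.

## Case definition

A vaccination event (day 0 = vaccination date) is a positive case only if
all five criteria hold:

* **c1 — injury**: a non-negated, non-resolved shoulder symptom or
  diagnosis is documented in the shoulder region (pain, stiffness,
  weakness, limited range of motion; bursitis, tendinopathy, rotator cuff
  lesions, ...).
* **c2 — laterality**: that injury is on the same side as the injection
  (bilateral counts by default; unknown laterality fails).
* **c3 — onset**: some documented onset falls within days 0–7. When notes
  offer several candidate onsets, *any* one inside the window satisfies
  the criterion (a deliberate max-sensitivity rule, because onset
  documentation degrades with distance from the event).
* **c4 — causality**: vaccination is documented as a cause, and no
  non-vaccination cause (accident, work, other medical condition,
  exercise, daily activity) is documented non-negated. An explicitly
  *unknown* cause does not disqualify.
* **c5 — duration**: evidence that the problem outlasted 30 days — an
  extracted duration > 30 days, a qualifying note dated after day 30, or
  a laterality-matched shoulder code during days 31–180.

Positive cases are then graded by three weak-evidence indicators: **w1**
the vaccination cause was found only by cross-sentence search; **w2**
every vaccination attribution comes from a note dated at most 30 days
post-vaccination; **w3** the vaccine named in the note normalizes to a
different product than the vaccination file records. Zero indicators give
*definite*, exactly one *probable*, two or more *possible*. The mapping is
pure (`verdict_from_criteria()`) and exhaustively tested over all 2^8 flag
combinations.

Note that for a patient who survives the cohort funnel, the structured
arm of c5 is satisfied by construction (the funnel itself requires a
matched code in days 31–180); c5 can still fail when classification is
applied to evidence assembled outside the funnel, and the tests exercise
that path directly.

## Indexing and context

Notes are indexed in four passes. *Sections* are detected from header
lines (a known header or capitalized word ending in ":", or an all-caps
line); sections tile the note and text before the first header is
`UNLABELED`. *Sentences* split on sentence-final punctuation and on
newlines followed by a capitalized token or bullet, protecting a
configurable abbreviation list ("Dr.", "hx.") and decimals; clinical notes
often lack final periods, so the newline rule matters. *Tokens* preserve
intra-token `/`, `-` and apostrophes so shorthand like "s/p", "b/l" and
"x-ray" stays whole; offsets are 0-based half-open against the source
text, which makes every annotation verbatim-recoverable. *Concept
matching* is greedy longest-match left-to-right over a precompiled
variant table: a multiword entry ("rotator cuff tear") suppresses its
parts, and when two classes share a surface ("since" is both a causal
trigger and a temporal cue) one mention per class is emitted for the same
span. Bare "L"/"R" laterality abbreviations match case-sensitively and
only adjacent to a body-location mention, to avoid false hits inside
ordinary text.

Context is applied NegEx-style: pre-cues ("denies", "no", "without") flag
clinical-finding mentions forward within the sentence up to a termination
cue ("but", "however") or a 5-word window (configurable); post-cues
("ruled out") flag backward; uncertainty ("possible", "likely") and
hypothetical cues ("return if") set their own flags the same way. Scope
never crosses a sentence boundary, and the operation is idempotent
because flags are recomputed from scratch. Negated and hypothetical
mentions never ground a finding; uncertain mentions do, since hedged
attributions ("suspect rotator cuff irritation from vaccination") are
exactly the statements the method must capture.

## Relation search

The extraction layer is a distance-constrained relation search
(`search_relations()`). A query is an ordered or unordered list of items
— semantic classes or nested sub-queries, to depth 3 — with three
constraints: consecutive groundings (in document order) may have at most
`max_intervening_words` word tokens between them, the whole match may
cover at most `max_sentence_span` consecutive sentences, and by default
may not cross a section boundary. Groundings are pairwise non-overlapping;
for ordered queries document order must follow item order; unordered
matches are deduplicated by grounding set. The default cross-sentence
window is 4 sentences / 50 intervening words, generalized from the
method's canonical cross-sentence query, and both values are
configuration knobs.

The engine is a depth-first search with positional pruning; unordered
queries run the ordered search over item permutations. Its specification
is operationalized by a second, deliberately naive implementation —
`search_relations_bruteforce()`, an `expand.grid` enumeration that applies
the constraints literally — and the two are required to agree on
hundreds of randomized small notes under randomized windows. This
dual-route check is what makes the cheaper engine trustworthy.

### From matches to findings

*Anatomic*: each injury mention takes the nearest laterality and
body-location mention within its sentence and an 8-word window; distance
ties prefer the preceding mention (English modifier order — the method
itself gives no tie rule, so this is a package choice). "b/l" and
"bilateral" normalize to bilateral.

*Temporal*: expressions in the injury's sentence are normalized against
the note date with fixed conversions (week = 7 d, month = 30 d, year =
365 d — calendar conventions the source method leaves unstated, recorded
in the configuration); "since last Thursday" resolves to the most recent
such weekday strictly before the note date; dates missing a year take the
year placing them nearest the note date (ties resolve to the earlier
year). Duration phrases imply onset = note date − duration.
Vaccination-anchored phrasings ("started the day she got a flu shot",
"since immunizations") yield day offsets directly. A sentence describing
the symptom as past ("in past ... lasting a few days") marks its findings
resolved, which removes them from the injury and duration criteria. If
the injury's own sentence has no expression, expression-bearing sentences
without their own injury mention inside the cross-sentence window are
consulted.

*Causal*: one query per (injury class × cause class): the injury plus a
nested ordered (trigger, cause) pair, searched over the full
cross-sentence window so intra-sentence matches fall out of the same
query with `scope = "intra_sentence"`. Unknown-cause statements
("insidious onset") need no trigger. Two anatomic guards shape the
output. First, findings anchor only to injuries with shoulder-region
anatomy (a shoulder diagnosis, or a symptom whose attached location is in
the configured shoulder region): a bare "pain" echo in a later sentence
does not become an intra-sentence attachment when the documented
complaint is the located injury in an earlier sentence — this is what
makes the canonical two-sentence example ("...left arm pain. States
experiencing pain × 1 month s/p flu vaccine.") come out as exactly one
cross-sentence vaccination finding, while the raw relation search, and
its brute-force oracle, correctly see both groundings. Second, with
`strict_anatomy` (default on) a cross-sentence match is dropped when the
cause's own sentence carries an injury located outside the shoulder
region; the cause belongs to that local injury (a fall that "worsened her
back pain" must not explain the shoulder). This guard goes slightly
beyond the source method, which reports exactly this confusion as an
error mode; it is a documented improvement and a toggle.

## Cohort selection

The structured funnel keeps intramuscular arm injections at a facility
for members aged ≥ 3 with membership covering ±180 days; requires a
laterality-matched shoulder code in days 0–180, a clean 180-day lookback
and a matched code in days 31–180 (dropping transient local reactions);
and applies the day-0 rules (at least two time-ordered encounters, the
first free of shoulder codes and not before the vaccination, a later
urgent-care/ED/virtual visit) to events coded on day 0. All day windows
are inclusive, computed as pure calendar-day offsets. Every excluded
record carries exactly its first failing reason, so funnel counts are
reproducible. The four training-subpopulation criteria (no external-cause
group-D code in ±180 d, no day-0 code, a code in days 1–30, codes on ≥ 2
distinct dates in days 31–180) are a separate, composable stage. The
shipped code list is a documented, editable stand-in built from public
ICD-10-CM structure (M75.*, M25.51*, M25.61*, S43.*, S46.*), with
laterality decoded from the final digit (1 right, 2 left, 3 bilateral);
the original study's code list is not public.

## Lexicons

All matching is driven by editable JSON lexicons over 18 semantic
classes. The shipped default reconstructs the vocabulary from phrasing
attested in the clinical literature on this adverse event — including 79
causal trigger terms ("because", "due to", "s/p", "status post",
"related to", "after", ...) and cause terms for the six non-vaccination
cause types ("fall", "auto accident", "lifting", "vacuuming", "overuse",
"side sleeping", "sports", ...). It is a behavioral default, not a
reproduction of any proprietary list. `expand_variants()` adds bounded
rule-based morphology (plural/singular, -ed/-ing) and, at edit distance
1, single-character deletion typos, never generating forms shorter than
four characters; embedding-based synonym discovery is out of scope.
Vaccine names normalize through a small product table (flu/influenza,
tdap, zoster/shingles, pneumococcal, ...) so a note/file mismatch is
detected at the product level, and generic words ("vaccine", "shot")
never mismatch.

## The synthetic generator

`generate_population()` emits, per patient: a vaccination record with arm
laterality, membership spanning the window, encounter and diagnosis
streams, and notes from scenario templates. Eleven scenarios cover the
decision space: `definite`, one scenario per weak criterion
(`probable_w1/w2/w3`), `possible` (two weak criteria), five negative
constructions (onset outside the window, a competing cause, fully negated
causes, a laterality mismatch between note and vaccination file, and a
short-duration course that also fails the cohort's 31–180-day code
requirement) and a `non_case_control` with no shoulder codes. Template
pools include clinical phrasings with known correct readings ("L shoulder
pain that started the day she got a flu shot", "Reports having R shoulder
pain for last 2 months", "Denies any injury or trauma") plus paraphrases;
gold spans are recorded at generation time and are verbatim-recoverable
by construction. Index dates are drawn across a 2016–2017 vaccination
period, arms and ages are randomized, and output is byte-identical for a
fixed seed. `inject_distractors()` appends irrelevant sentences
(hypothetical advice, resolved past symptoms in other joints) without
shifting existing spans.

What the generator does **not** emulate — and therefore what a passing
end-to-end suite does not establish about real notes: spelling noise and
OCR artifacts, copy-forwarded and templated note structure, conflicting
documentation between notes, misattributed laterality in the source
record, and free narrative syntax beyond the template grammars. On
grammar-pure populations the pipeline is required to recover 100% of
verdicts and every cohort exclusion reason; with distractors the suite
asserts a high floor rather than perfection. Positive-case prevalence in
the default mixes is far above the real-world rate by design — desk-scale
tests of a 1/10,000 event would otherwise contain no positives.

## Evaluation statistics

`compute_metrics()` reports sensitivity, specificity, PPV and NPV from a
2×2 table; `compute_confirmation_rate()` reports a confirmed/identified
proportion. Intervals are exact Clopper–Pearson by default (Wilson
optionally), computed from beta quantiles and cross-checked in the tests
against a direct binomial tail search; percentages round half-up at one
decimal to match clinical reporting style. Zero-denominator metrics are
reported as undefined rather than erroring. Published validation figures
for this method quote a 39.6% lower bound for 4/4 and 95.2% for 96/96
where exact Clopper–Pearson yields 39.8% and 96.2%; the package reports
the exact values and leaves the discrepancy (an unstated interval method
in the source) documented rather than imitated.

## Problem sizes and numerical choices

The default test and acceptance runs use 605-patient populations (55 per
scenario), 500 randomized oracle-equivalence checks, 2,000 replicates
for interval-coverage simulation, and the full 256-combination verdict
enumeration — sizes chosen so the whole suite exercises every code path
in about a minute on one core. Determinism is absolute for fixed seeds:
no step depends on iteration order of hashed structures, ties in nearest-
mention selection and year inference have stated resolutions, and
`apply_context()` recomputes flags rather than accumulating them.

## Known limitations

Section and sentence detection are heuristic; unusual header styles will
fold text into neighboring sections. Temporal normalization covers the
expression families enumerated above, not free-form narrative time.
Cross-sentence temporal fallback can still attach an unrelated date when
the window contains only expression-bearing distractor sentences — the
error mode the source method documents. Coreference ("it started then")
is out of scope, as are machine-learned relation classification and any
probabilistic scoring above the rule layer.
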