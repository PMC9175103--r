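# sirvanlp

Rule-based clinical text mining for **shoulder injury related to vaccine
administration (SIRVA)** in electronic health records.

SIRVA — shoulder pain and limited range of motion after an intramuscular
vaccine injected into the upper arm — has no dedicated ICD-10-CM code and
occurs on the order of 1 per 10,000 vaccinations, while shoulder pain in
general is among the most common musculoskeletal complaints. Finding
cases therefore means reading free-text notes for a large presumptive
population. `sirvanlp` is for vaccine-safety and pharmacoepidemiology
researchers who need that reading automated, auditable and reproducible.

## What it does

1. **Cohort selection** over structured tables (vaccinations, encounters,
   diagnoses, membership): intramuscular arm injections, age ≥ 3,
   membership covering ±180 days of the index date (day 0); a
   laterality-matched shoulder code in days 0–180 with a clean 180-day
   lookback and a matched code in days 31–180; time-ordered day-0
   encounter rules. Every exclusion carries its first failing reason.
2. **Note indexing**: section detection, sentence segmentation,
   tokenization that preserves clinical shorthand ("s/p", "b/l"),
   longest-match lexicon concept matching, and NegEx-style
   negation/uncertainty/hypothetical scoping with sentence-bounded cue
   windows.
3. **Relation extraction**: a distance-based search over ordered/nested
   item patterns with word- and sentence-distance constraints (default
   cross-sentence window: 4 sentences / 50 intervening words), distilled
   into anatomic (laterality, body location), temporal (onset, duration,
   resolution; week = 7 d, month = 30 d, year = 365 d) and causal
   findings across 7 cause types (vaccination, accident, work, other
   medical condition, exercise, daily activity, unknown). A brute-force
   enumerator ships as an independent oracle for the search engine.
4. **Case classification** per vaccination event. Positive iff all five
   criteria hold — c1 injury confirmed, c2 same-side laterality, c3 onset
   in days 0–7, c4 vaccination cause and no competing cause, c5 duration
   > 30 days — then graded by three weak-evidence criteria (w1
   cross-sentence-only causality, w2 attribution only ≤ 30 days
   post-vaccination, w3 vaccine-name mismatch with the vaccination file):

   verdict = **negative** if any c-criterion fails, else **definite** /
   **probable** / **possible** for 0 / 1 / ≥ 2 weak criteria.
5. **Synthetic EHR generation** (11 labeled scenarios, exact gold spans)
   and **evaluation statistics** (sensitivity/specificity/PPV/NPV and
   confirmation rates with exact Clopper–Pearson 95% CIs, half-up
   rounding to one decimal).

## Worked example

The canonical hard case is a cause stated in a different sentence than
the complaint:

```r
library(sirvanlp)
note <- clinical_note("n1", "pt1", "2017-02-10T10:00:00", paste0(
  "HPI: Patient requesting an appointment for evaluation for left arm pain. ",
  "States experiencing pain x 1 month s/p flu vaccine."))
ix <- index_note(note)
ix
#> <indexed_note> n1 - 1 sections, 2 sentences, 23 tokens, 10 mentions

extract_causal(ix)
#>   mention_id  cause_type trigger cause_entry          scope vaccine_name
#> 1          6 vaccination  trg007      vax001 cross_sentence  flu vaccine

extract_temporal(ix, index_date = as.Date("2017-01-05"))
#>   mention_id expression onset_date onset_offset duration_days resolved
#> 1          7  x 1 month 2017-01-11            6            30    FALSE
```

The vaccination cause is found with `scope = "cross_sentence"` (weak
criterion w1), anchored to the anatomically grounded "left arm pain" in
the first sentence; "x 1 month" yields a 30-day duration and an onset 6
days after the vaccination (inside the 0–7-day window, criterion c3).

End to end, on a synthetic population with known truth:

```r
pop <- generate_population(list(scenario_spec("definite", 5),
                                scenario_spec("probable_w1", 5),
                                scenario_spec("negative_negated", 5)),
                           seed = 42)
res <- run_pipeline(pop$vaccinations, pop$encounters, pop$diagnoses,
                    pop$membership, pop$notes)
table(res$cases$verdict)
#> definite negative probable
#>        5        5        5

evaluate_against_truth(res, pop$truth)$accuracy
#> [1] 1
```

Evaluation arithmetic prints the way clinical validation tables do:

```r
compute_confirmation_rate(278, 291)
#> 95.5% (278/291; 95% CI 92.5%-97.6%, clopper_pearson)

compute_metrics(list(tp = 4, fp = 0, tn = 96, fn = 0))
#> sensitivity 100.0% (4/4; 95% CI 39.8%-100.0%, clopper_pearson)
#> specificity 100.0% (96/96; 95% CI 96.2%-100.0%, clopper_pearson)
#> ppv         100.0% (4/4; 95% CI 39.8%-100.0%, clopper_pearson)
#> npv         100.0% (96/96; 95% CI 96.2%-100.0%, clopper_pearson)
```

A thin command-line front end lives at `inst/cli/sirva.R`
(`simulate` / `run` / `evaluate` subcommands over the same functions).

## Documentation

The methods vignette (`vignettes/sirva-nlp-methods.Rmd`) describes the
case definition, the relation-search semantics, the temporal calculus,
every tunable parameter with its default and rationale, what the
synthetic generator does and does not emulate, and known limitations.
Lexicons (`inst/extdata/lexicon_default.json`), the shoulder-code list
and the default query set are editable, documented reconstructions — not
reproductions of any proprietary resource.
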