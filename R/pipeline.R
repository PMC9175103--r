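# End-to-end orchestration: cohort -> index -> extract -> classify, with
# Table-style summary reporting and evaluation against ground truth.

#' Run the full case-finding pipeline
#'
#' Applies the cohort funnel to the structured tables, then indexes every
#' note of each included patient within the ascertainment window, extracts
#' anatomic/temporal/causal findings, aggregates them per vaccination event
#' and classifies each event. Deterministic: identical inputs give
#' identical outputs.
#'
#' @param vaccinations,encounters,diagnoses,membership structured tables
#' @param notes list of [clinical_note()] objects
#' @param lexicon concept lexicon (default shipped)
#' @param code_list shoulder-code list
#' @param config pipeline configuration
#' @return list: `cohort` (events + funnel), `cases` (one row per included
#'   event: verdict and per-criterion flags), `summary` (NLP component
#'   counts), `evidence` (named list of `patient_evidence` for audit)
#' @export
run_pipeline <- function(vaccinations, encounters, diagnoses, membership,
                         notes, lexicon = default_lexicon(),
                         code_list = default_code_list(),
                         config = default_config()) {
  cohort <- run_cohort(vaccinations, encounters, diagnoses, membership,
                       code_list, config = config)
  ev <- cohort$events
  included <- ev[ev$decision == "included", , drop = FALSE]
  cl <- compile_lexicon(lexicon)
  d <- classify_diagnoses(diagnoses, code_list)
  notes_by_patient <- split(notes,
                            vapply(notes, `[[`, character(1), "patient_id"))
  rows <- list(); evidence_out <- list()
  for (i in seq_len(nrow(included))) {
    pid <- included$patient_id[i]
    idx_date <- included$index_date[i]
    event <- index_event(pid, idx_date, included$arm[i],
                         normalize_vaccine_name(included$vaccine_name[i],
                                                config),
                         admin_time = included$admin_datetime[i])
    pnotes <- notes_by_patient[[pid]] %||% list()
    pnotes <- Filter(function(nt) {
      off <- as.integer(as.Date(nt$note_datetime) - idx_date)
      off >= 0L && off <= config$ascertainment_days
    }, pnotes)
    findings <- lapply(pnotes, function(nt)
      extract_findings(index_note(nt, cl, config), idx_date, config))
    di <- d[d$patient_id == pid & !is.na(d$group), , drop = FALSE]
    ct <- if (nrow(di)) data.frame(date = di$date,
                                   laterality = di$code_laterality,
                                   stringsAsFactors = FALSE) else NULL
    evd <- aggregate_findings(event, findings, ct, config)
    cls <- classify_case(evd, config)
    evidence_out[[pid]] <- evd
    note_ids <- vapply(pnotes, `[[`, character(1), "note_id")
    rows[[length(rows) + 1L]] <- data.frame(
      patient_id = pid, index_date = format(idx_date),
      verdict = cls$verdict,
      c1 = cls$case_def$c1, c2 = cls$case_def$c2, c3 = cls$case_def$c3,
      c4 = cls$case_def$c4, c5 = cls$case_def$c5,
      w1 = cls$weak$w1, w2 = cls$weak$w2, w3 = cls$weak$w3,
      n_notes = length(pnotes),
      note_ids = paste(note_ids, collapse = ";"),
      stringsAsFactors = FALSE)
  }
  cases <- if (length(rows)) do.call(rbind, rows) else
    data.frame(patient_id = character(), index_date = character(),
               verdict = character(), c1 = logical(), c2 = logical(),
               c3 = logical(), c4 = logical(), c5 = logical(),
               w1 = logical(), w2 = logical(), w3 = logical(),
               n_notes = integer(), note_ids = character(),
               stringsAsFactors = FALSE)
  list(cohort = cohort, cases = cases,
       summary = summarize_nlp(cases, evidence_out, config),
       evidence = evidence_out)
}

#' Summarize NLP component results
#'
#' Counts (and percentages of the injury-identified denominator) of:
#' shoulder injury identified, laterality identified and mismatched, cause
#' identified including and excluding unknown, onset identified, symptom
#' duration beyond 30 days, and SIRVA verdict counts.
#'
#' @param cases case table from [run_pipeline()]
#' @param evidence named list of `patient_evidence`
#' @param config pipeline configuration
#' @return data frame `measure`, `n`, `pct` (of injury-identified)
#' @export
summarize_nlp <- function(cases, evidence, config = default_config()) {
  n_inj <- n_lat <- n_mis <- n_cause <- n_cause_known <- 0L
  n_onset <- n_dur <- 0L
  for (evd in evidence) {
    a <- evd$anatomic; tmp <- evd$temporal; cs <- evd$causal
    inj <- c1_rows(evd, config)
    has_inj <- !is.null(a) && nrow(inj) > 0
    if (!has_inj) next
    n_inj <- n_inj + 1L
    lat_known <- inj$laterality != "unknown"
    if (any(lat_known)) {
      n_lat <- n_lat + 1L
      arm <- evd$event$arm
      if (!any(inj$laterality[lat_known] == arm |
                 inj$laterality[lat_known] == "bilateral"))
        n_mis <- n_mis + 1L
    }
    if (!is.null(cs) && nrow(cs)) {
      n_cause <- n_cause + 1L
      if (any(cs$cause_type != "unknown")) n_cause_known <- n_cause_known + 1L
    }
    if (!is.null(tmp) && nrow(tmp) && any(!is.na(tmp$onset_offset)))
      n_onset <- n_onset + 1L
    dur <- (!is.null(tmp) && nrow(tmp) &&
              any(!tmp$resolved & !is.na(tmp$duration_days) &
                    tmp$duration_days > config$min_duration_days)) ||
      any(as.integer(inj$note_date - evd$event$index_date) >
            config$min_duration_days)
    if (dur) n_dur <- n_dur + 1L
  }
  vc <- table(factor(cases$verdict,
                     levels = c("definite", "probable", "possible",
                                "negative")))
  pct <- function(x) if (n_inj > 0) round_half_up(100 * x / n_inj) else NA
  data.frame(
    measure = c("shoulder_injury_identified", "laterality_identified",
                "laterality_mismatch", "cause_identified_incl_unknown",
                "cause_identified_excl_unknown", "onset_identified",
                "duration_gt_30d", "sirva_definite", "sirva_probable",
                "sirva_possible", "negative"),
    n = c(n_inj, n_lat, n_mis, n_cause, n_cause_known, n_onset, n_dur,
          as.integer(vc[["definite"]]), as.integer(vc[["probable"]]),
          as.integer(vc[["possible"]]), as.integer(vc[["negative"]])),
    pct = c(100, pct(n_lat), pct(n_mis), pct(n_cause), pct(n_cause_known),
            pct(n_onset), pct(n_dur), NA, NA, NA, NA),
    stringsAsFactors = FALSE)
}

#' Evaluate pipeline verdicts against ground truth
#'
#' Joins the case table (plus cohort exclusions, which count as negative)
#' with the generator's truth labels and computes verdict accuracy and the
#' positive-vs-negative confusion counts.
#'
#' @param result output of [run_pipeline()]
#' @param truth truth table from [generate_population()]
#' @return list: `merged` (per-patient comparison), `accuracy` (fraction of
#'   patients whose verdict matches), `counts` (tp/fp/tn/fn for
#'   any-positive vs negative), `cohort_ok` (fraction of patients whose
#'   cohort decision matches expectation)
#' @export
evaluate_against_truth <- function(result, truth) {
  ev <- result$cohort$events
  verd <- setNames(result$cases$verdict, result$cases$patient_id)
  got_verdict <- vapply(truth$patient_id, function(p) {
    v <- verd[p]
    if (is.na(v)) "negative" else unname(v)
  }, character(1))
  got_cohort <- vapply(truth$patient_id, function(p) {
    row <- ev[ev$patient_id == p, ]
    if (!nrow(row)) return("missing")
    if (row$decision[1] == "included") "included" else row$exclusion_reason[1]
  }, character(1))
  merged <- data.frame(truth,
                       got_verdict = got_verdict,
                       got_cohort = got_cohort,
                       stringsAsFactors = FALSE)
  pos <- c("definite", "probable", "possible")
  tp <- sum(merged$expected_verdict %in% pos & merged$got_verdict %in% pos)
  fn <- sum(merged$expected_verdict %in% pos & !(merged$got_verdict %in% pos))
  fp <- sum(!(merged$expected_verdict %in% pos) & merged$got_verdict %in% pos)
  tn <- sum(!(merged$expected_verdict %in% pos) &
              !(merged$got_verdict %in% pos))
  list(merged = merged,
       accuracy = mean(merged$got_verdict == merged$expected_verdict),
       counts = list(tp = tp, fp = fp, tn = tn, fn = fn),
       cohort_ok = mean(merged$got_cohort == merged$expected_cohort))
}
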