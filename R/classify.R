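# Patient-level case classification: aggregate per-note findings for one
# vaccination event and apply the 5-criterion case definition plus the 3
# weak-evidence criteria to emit definite/probable/possible/negative.

#' Construct a vaccination index event
#'
#' @param patient_id patient identifier
#' @param index_date vaccination date (day 0)
#' @param arm injection arm: `"left"`, `"right"` or `"unknown"`
#' @param vaccine_product normalized product family recorded in the
#'   vaccination file (e.g. `"influenza"`)
#' @param admin_time optional administration time-of-day (POSIXct)
#' @return an `index_event`
#' @export
index_event <- function(patient_id, index_date, arm,
                        vaccine_product = NA_character_,
                        admin_time = NULL) {
  structure(list(patient_id = as.character(patient_id),
                 index_date = as_date(index_date), arm = arm,
                 vaccine_product = vaccine_product,
                 admin_time = admin_time),
            class = "index_event")
}

#' Aggregate per-note findings into patient evidence
#'
#' Unions findings across all notes dated within the ascertainment window
#' (days 0-180 after the index date). Everything is retained — including
#' findings whose laterality contradicts the vaccination arm — so the audit
#' trail is complete; contradictions matter only at evaluation time.
#'
#' @param event an [index_event()]
#' @param findings_list list of per-note finding sets from
#'   [extract_findings()]
#' @param code_timeline optional data frame of structured diagnosis codes
#'   for the patient: columns `date`, `laterality`
#' @param config pipeline configuration
#' @return a `patient_evidence` object
#' @export
aggregate_findings <- function(event, findings_list,
                               code_timeline = NULL,
                               config = default_config()) {
  window_ok <- function(d) {
    off <- as.integer(as_date(d) - event$index_date)
    off >= 0L & off <= config$ascertainment_days
  }
  bind <- function(part) {
    dfs <- lapply(findings_list, `[[`, part)
    dfs <- dfs[vapply(dfs, function(d) !is.null(d) && nrow(d) > 0, logical(1))]
    if (!length(dfs)) return(NULL)
    df <- do.call(rbind, dfs)
    df <- df[window_ok(df$note_date), , drop = FALSE]
    rownames(df) <- NULL
    df
  }
  ct <- code_timeline
  if (!is.null(ct) && nrow(ct)) {
    ct$day <- as.integer(as_date(ct$date) - event$index_date)
  }
  structure(list(event = event, anatomic = bind("anatomic"),
                 temporal = bind("temporal"), causal = bind("causal"),
                 code_timeline = ct),
            class = "patient_evidence")
}

# rows of `anatomic` that can establish the injury criterion: shoulder
# region and not resolved
c1_rows <- function(ev, config) {
  a <- ev$anatomic
  if (is.null(a) || !nrow(a))
    return(data.frame(mention_id = integer(), entry_id = character(),
                      class = character(), sentence_index = integer(),
                      laterality = character(), body_location = character(),
                      resolved = logical(), note_id = character(),
                      note_date = as.Date(character()),
                      stringsAsFactors = FALSE))
  region <- a$class == "shoulder_diagnosis" |
    (!is.na(a$body_location) & a$body_location %in% config$shoulder_region)
  a[region & !a$resolved, , drop = FALSE]
}

#' Evaluate the five-criterion case definition
#'
#' * c1 — a non-negated, non-resolved shoulder symptom/diagnosis finding in
#'   the shoulder region exists.
#' * c2 — such a finding's laterality equals the vaccination arm (bilateral
#'   counts when configured; unknown fails).
#' * c3 — any candidate onset falls within days 0-7 of vaccination
#'   (max-sensitivity rule: one qualifying onset among many suffices).
#' * c4 — a vaccination cause was found and no non-negated cause of type
#'   accident/work/other-medical/exercise/daily-activity was (unknown does
#'   not disqualify).
#' * c5 — duration evidence beyond 30 days: an extracted duration > 30
#'   days, a qualifying finding in a note dated > 30 days post-index, or a
#'   matched-laterality diagnosis code in days 31-180.
#'
#' @param evidence a `patient_evidence`
#' @param config pipeline configuration
#' @return list of logicals `c1`..`c5` plus `support` (finding indices per
#'   criterion)
#' @export
evaluate_case_definition <- function(evidence, config = default_config()) {
  ev <- evidence
  arm <- ev$event$arm
  inj <- c1_rows(ev, config)
  c1 <- nrow(inj) > 0
  lat_ok <- if (isTRUE(config$bilateral_matches_arm))
    inj$laterality == arm | inj$laterality == "bilateral"
  else inj$laterality == arm
  c2 <- c1 && any(lat_ok)
  tmp <- ev$temporal
  onset_ok <- if (is.null(tmp) || !nrow(tmp)) logical(0) else
    !tmp$resolved & !is.na(tmp$onset_offset) &
    tmp$onset_offset >= 0L & tmp$onset_offset <= config$onset_window_days
  c3 <- any(onset_ok)
  cs <- ev$causal
  has_vac <- !is.null(cs) && nrow(cs) > 0 && any(cs$cause_type == "vaccination")
  has_other <- !is.null(cs) && nrow(cs) > 0 &&
    any(cs$cause_type %in% NONVACCINE_CAUSE_TYPES)
  c4 <- has_vac && !has_other
  dur_nlp <- !is.null(tmp) && nrow(tmp) > 0 &&
    any(!tmp$resolved & !is.na(tmp$duration_days) &
          tmp$duration_days > config$min_duration_days)
  late_note <- nrow(inj) > 0 &&
    any(as.integer(inj$note_date - ev$event$index_date) >
          config$min_duration_days)
  ct <- ev$code_timeline
  late_code <- !is.null(ct) && nrow(ct) > 0 &&
    any(ct$day >= config$min_duration_days + 1L &
          ct$day <= config$ascertainment_days &
          (ct$laterality == arm |
             (isTRUE(config$bilateral_matches_arm) &
                ct$laterality == "bilateral")))
  c5 <- dur_nlp || late_note || late_code
  list(c1 = c1, c2 = isTRUE(c2), c3 = c3, c4 = c4, c5 = c5,
       support = list(
         c1 = inj$mention_id, c2 = inj$mention_id[lat_ok],
         c3 = if (length(onset_ok)) which(onset_ok) else integer(),
         c4 = if (has_vac) which(cs$cause_type == "vaccination") else integer(),
         c5 = character()))
}

#' Evaluate the three weak-evidence criteria
#'
#' Only meaningful when a vaccination cause exists (otherwise all three are
#' `FALSE`):
#' * w1 — every vaccination cause was found only by cross-sentence search.
#' * w2 — every vaccination cause comes from a note dated at most 30 days
#'   after vaccination (no later attribution exists).
#' * w3 — some vaccination cause names a vaccine that normalizes to a
#'   product different from the vaccination file's record (a generic or
#'   absent name never mismatches).
#'
#' @param evidence a `patient_evidence`
#' @param config pipeline configuration
#' @return list of logicals `w1`, `w2`, `w3`
#' @export
evaluate_weak_evidence <- function(evidence, config = default_config()) {
  cs <- evidence$causal
  vac <- if (is.null(cs) || !nrow(cs)) cs else
    cs[cs$cause_type == "vaccination", , drop = FALSE]
  if (is.null(vac) || !nrow(vac))
    return(list(w1 = FALSE, w2 = FALSE, w3 = FALSE))
  w1 <- all(vac$scope == "cross_sentence")
  days <- as.integer(as_date(vac$note_date) - evidence$event$index_date)
  w2 <- all(days <= config$late_attribution_days)
  named <- normalize_vaccine_name(vac$vaccine_name, config)
  file_prod <- evidence$event$vaccine_product
  w3 <- !is.na(file_prod) && any(!is.na(named) & named != file_prod)
  list(w1 = w1, w2 = w2, w3 = isTRUE(w3))
}

#' Verdict from criterion flags
#'
#' The classification rule in its pure form: negative unless all five
#' case-definition criteria hold; otherwise the count of weak-evidence
#' criteria met maps 0 to definite, 1 to probable, and 2 or more to
#' possible.
#'
#' @param case_def list/logical vector of the five case-definition flags
#' @param weak list/logical vector of the three weak-evidence flags
#' @return one of `"definite"`, `"probable"`, `"possible"`, `"negative"`
#' @export
verdict_from_criteria <- function(case_def, weak) {
  cd <- unlist(case_def[c("c1", "c2", "c3", "c4", "c5")])
  if (!all(cd)) return("negative")
  k <- sum(unlist(weak[c("w1", "w2", "w3")]))
  if (k == 0L) "definite" else if (k == 1L) "probable" else "possible"
}

#' Classify one vaccination event
#'
#' @param evidence a `patient_evidence`
#' @param config pipeline configuration
#' @return a `case_classification`: `verdict`, `case_def`, `weak`
#' @export
classify_case <- function(evidence, config = default_config()) {
  cd <- evaluate_case_definition(evidence, config)
  wk <- if (cd$c4) evaluate_weak_evidence(evidence, config)
        else list(w1 = FALSE, w2 = FALSE, w3 = FALSE)
  structure(list(verdict = verdict_from_criteria(cd, wk),
                 case_def = cd, weak = wk,
                 patient_id = evidence$event$patient_id,
                 index_date = evidence$event$index_date),
            class = "case_classification")
}

#' @export
print.case_classification <- function(x, ...) {
  cat("<case_classification>", x$patient_id, "->", x$verdict, "\n")
  cat("  case definition:",
      paste(sprintf("%s=%s", c("c1", "c2", "c3", "c4", "c5"),
                    unlist(x$case_def[c("c1", "c2", "c3", "c4", "c5")])),
            collapse = " "), "\n")
  cat("  weak evidence:  ",
      paste(sprintf("%s=%s", c("w1", "w2", "w3"),
                    unlist(x$weak)), collapse = " "), "\n")
  invisible(x)
}
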