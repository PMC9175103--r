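# Synthetic EHR generator: grammar-based populations (structured tables +
# clinical notes + token-level ground truth) covering every scenario the
# pipeline must discriminate. Templates are slot-filled from the default
# lexicon, so gold labels are exact by construction.

SCENARIO_LABELS <- c("definite", "probable_w1", "probable_w2", "probable_w3",
                     "possible", "negative_no_onset", "negative_other_cause",
                     "negative_negated", "negative_laterality",
                     "negative_short_duration", "non_case_control")

#' Scenario specification
#' @param scenario_id one of the supported scenario labels
#' @param n number of patients to generate
#' @return a `scenario_spec` list
#' @export
scenario_spec <- function(scenario_id, n) {
  if (!scenario_id %in% SCENARIO_LABELS)
    stop("unknown scenario label: ", scenario_id)
  structure(list(scenario_id = scenario_id, n = as.integer(n)),
            class = "scenario_spec")
}

#' All scenario labels
#' @return character vector of the 11 supported scenario labels
#' @export
scenario_labels <- function() SCENARIO_LABELS

opposite_arm <- function(arm) if (arm == "left") "right" else "left"

cap1 <- function(x) paste0(toupper(substr(x, 1, 1)), substr(x, 2, nchar(x)))

# Templates. Each returns list(day_offset, text, gold = named character
# vector class -> phrase, expected = list(...)). `ctx` carries patient_id,
# arm, index_date, file_product.
scenario_note_template <- function(scenario, ctx) {
  lat <- lat_note <- if (scenario == "negative_laterality")
    opposite_arm(ctx$arm) else ctx$arm
  Lat <- cap1(lat)
  Abbr <- toupper(substr(lat, 1, 1))
  variant <- switch(scenario,
    definite = sample(1:3, 1), probable_w1 = sample(1:3, 1),
    probable_w2 = sample(1:2, 1), probable_w3 = sample(1:2, 1),
    possible = sample(1:2, 1), 1L)
  tail1 <- sample(c("Symptoms are ongoing.", "Symptoms persist."), 1)
  t <- switch(scenario,
    definite = switch(variant,
      list(day = 40L,
           text = sprintf(paste0("HPI: Patient reports %s shoulder pain that",
                                 " began 2 days after flu vaccine. %s"),
                          lat, tail1),
           gold = c(laterality = lat, body_location = "shoulder",
                    shoulder_symptom = "pain", causal_trigger = "after",
                    vaccine = "flu vaccine"),
           onset = 2L, causes = "vaccination"),
      list(day = 40L,
           text = sprintf(paste0("HPI: %s shoulder pain that started the day",
                                 " she got a flu shot and has continued",
                                 " since. %s"), Abbr, tail1),
           gold = c(laterality = Abbr, body_location = "shoulder",
                    shoulder_symptom = "pain", causal_trigger = "she got",
                    vaccine = "flu shot"),
           onset = 0L, causes = "vaccination"),
      list(day = 40L,
           text = sprintf(paste0("HPI: %s shoulder pain and neck stiffness",
                                 " since immunizations. %s"), Lat, tail1),
           gold = c(laterality = Lat, body_location = "shoulder",
                    shoulder_symptom = "pain", causal_trigger = "since",
                    vaccine = "immunizations"),
           onset = 0L, causes = "vaccination")),
    probable_w1 = switch(variant,
      list(day = 40L,
           text = sprintf(paste0("HPI: Patient requesting evaluation for %s",
                                 " arm pain for the past 5 weeks. States",
                                 " symptoms started s/p flu vaccine."), lat),
           gold = c(laterality = lat, body_location = "arm",
                    shoulder_symptom = "pain", causal_trigger = "s/p",
                    vaccine = "flu vaccine"),
           onset = 5L, causes = "vaccination"),
      list(day = 35L,
           text = sprintf(paste0("HPI: Patient requesting an appointment for",
                                 " evaluation for %s arm pain. States",
                                 " experiencing pain x 1 month s/p flu",
                                 " vaccine."), lat),
           gold = c(laterality = lat, body_location = "arm",
                    shoulder_symptom = "pain", causal_trigger = "s/p",
                    vaccine = "flu vaccine"),
           onset = 5L, causes = "vaccination"),
      list(day = 62L,
           text = sprintf(paste0("HPI: Reports having %s shoulder pain for",
                                 " last 2 months. Thought related to vaccine",
                                 " she received in %s arm."), Abbr, Abbr),
           gold = c(laterality = Abbr, body_location = "shoulder",
                    shoulder_symptom = "pain", causal_trigger = "related to",
                    vaccine = "vaccine"),
           onset = 2L, causes = "vaccination")),
    probable_w2 = switch(variant,
      list(day = 12L,
           text = sprintf(paste0("HPI: Patient reports %s shoulder pain x 1",
                                 " week after flu vaccine. Will continue",
                                 " conservative care."), lat),
           gold = c(laterality = lat, body_location = "shoulder",
                    shoulder_symptom = "pain", causal_trigger = "after",
                    vaccine = "flu vaccine"),
           onset = 5L, causes = "vaccination"),
      list(day = 10L,
           text = sprintf(paste0("HPI: States %s shoulder pain since flu",
                                 " shot. Improving with conservative",
                                 " care."), lat),
           gold = c(laterality = lat, body_location = "shoulder",
                    shoulder_symptom = "pain", causal_trigger = "since",
                    vaccine = "flu shot"),
           onset = 0L, causes = "vaccination")),
    probable_w3 = switch(variant,
      list(day = 40L,
           text = sprintf(paste0("HPI: Patient reports %s shoulder pain that",
                                 " began 2 days after flu shot. %s"),
                          lat, tail1),
           gold = c(laterality = lat, body_location = "shoulder",
                    shoulder_symptom = "pain", causal_trigger = "after",
                    vaccine = "flu shot"),
           onset = 2L, causes = "vaccination"),
      list(day = 40L,
           text = sprintf(paste0("HPI: Patient reports %s shoulder pain that",
                                 " began 2 days after flu vaccine. %s"),
                          lat, tail1),
           gold = c(laterality = lat, body_location = "shoulder",
                    shoulder_symptom = "pain", causal_trigger = "after",
                    vaccine = "flu vaccine"),
           onset = 2L, causes = "vaccination")),
    possible = switch(variant,
      list(day = 20L,
           text = sprintf(paste0("HPI: Patient requesting evaluation for %s",
                                 " arm pain for the past 2 weeks. States",
                                 " symptoms started s/p flu vaccine."), lat),
           gold = c(laterality = lat, body_location = "arm",
                    shoulder_symptom = "pain", causal_trigger = "s/p",
                    vaccine = "flu vaccine"),
           onset = 6L, causes = "vaccination"),
      list(day = 40L,
           text = sprintf(paste0("HPI: Patient requesting evaluation for %s",
                                 " arm pain for the past 5 weeks. States",
                                 " symptoms started s/p flu shot."), lat),
           gold = c(laterality = lat, body_location = "arm",
                    shoulder_symptom = "pain", causal_trigger = "s/p",
                    vaccine = "flu shot"),
           onset = 5L, causes = "vaccination")),
    negative_no_onset =
      list(day = 60L,
           text = sprintf(paste0("HPI: Patient reports %s shoulder pain for",
                                 " the past 2 weeks after flu vaccine. %s"),
                          lat, tail1),
           gold = c(laterality = lat, body_location = "shoulder",
                    shoulder_symptom = "pain", causal_trigger = "after",
                    vaccine = "flu vaccine"),
           onset = 46L, causes = "vaccination"),
    negative_other_cause =
      list(day = 40L,
           text = sprintf(paste0("HPI: Patient reports %s shoulder pain that",
                                 " began 2 days after flu vaccine. Reports",
                                 " the shoulder pain worsened after lifting",
                                 " heavy boxes."), lat),
           gold = c(laterality = lat, body_location = "shoulder",
                    shoulder_symptom = "pain", causal_trigger = "after",
                    vaccine = "flu vaccine",
                    cause_daily_activity = "lifting"),
           onset = 2L, causes = "vaccination,daily_activity"),
    negative_negated =
      list(day = 40L,
           text = sprintf(paste0("HPI: Patient reports %s shoulder pain for",
                                 " the past 6 weeks. Denies any injury or",
                                 " trauma."), lat),
           gold = c(laterality = lat, body_location = "shoulder",
                    shoulder_symptom = "pain", negation_cue = "Denies",
                    cause_accident = "injury"),
           onset = -2L, causes = ""),
    negative_laterality =
      list(day = 40L,
           text = sprintf(paste0("HPI: Patient reports %s shoulder pain that",
                                 " began 2 days after flu vaccine. %s"),
                          lat_note, tail1),
           gold = c(laterality = lat_note, body_location = "shoulder",
                    shoulder_symptom = "pain", causal_trigger = "after",
                    vaccine = "flu vaccine"),
           onset = 2L, causes = "vaccination"),
    negative_short_duration =
      list(day = 14L,
           text = sprintf(paste0("HPI: Patient reports %s shoulder pain x 1",
                                 " week after flu vaccine. Will continue",
                                 " conservative care."), lat),
           gold = c(laterality = lat, body_location = "shoulder",
                    shoulder_symptom = "pain", causal_trigger = "after",
                    vaccine = "flu vaccine"),
           onset = 7L, causes = "vaccination"),
    non_case_control =
      list(day = 30L,
           text = paste0("HPI: Patient seen for upper respiratory",
                         " infection. Symptoms improving with rest."),
           gold = character(),
           onset = NA_integer_, causes = ""))
  t
}

scenario_expectation <- function(scenario) {
  switch(scenario,
    definite = list(verdict = "definite", cohort = "included",
                    w = c(FALSE, FALSE, FALSE)),
    probable_w1 = list(verdict = "probable", cohort = "included",
                       w = c(TRUE, FALSE, FALSE)),
    probable_w2 = list(verdict = "probable", cohort = "included",
                       w = c(FALSE, TRUE, FALSE)),
    probable_w3 = list(verdict = "probable", cohort = "included",
                       w = c(FALSE, FALSE, TRUE)),
    possible = list(verdict = "possible", cohort = "included",
                    w = NA),
    negative_no_onset = list(verdict = "negative", cohort = "included",
                             w = c(FALSE, FALSE, FALSE)),
    negative_other_cause = list(verdict = "negative", cohort = "included",
                                w = c(FALSE, FALSE, FALSE)),
    negative_negated = list(verdict = "negative", cohort = "included",
                            w = c(FALSE, FALSE, FALSE)),
    negative_laterality = list(verdict = "negative", cohort = "included",
                               w = c(FALSE, FALSE, FALSE)),
    negative_short_duration = list(verdict = "negative",
                                   cohort = "no_31_180_code",
                                   w = c(FALSE, FALSE, FALSE)),
    non_case_control = list(verdict = "negative", cohort = "no_shoulder_code",
                            w = c(FALSE, FALSE, FALSE)))
}

# shoulder code with the laterality digit of the given side
shoulder_code_for <- function(arm, group = "A") {
  digit <- if (arm == "right") "1" else "2"
  prefix <- switch(group, A = "M75.4", C = "M25.51", D = "S43.40")
  paste0(prefix, digit)
}

#' Generate one synthetic clinical note
#'
#' Samples a template for the scenario (phrasing pools include literal
#' clinical-note sentences with known correct interpretations) and records
#' gold annotations whose spans are verbatim-recoverable from the text.
#' Uses the current RNG stream; seed via `set.seed()` or
#' [generate_population()].
#'
#' @param scenario scenario label
#' @param ctx patient context: list with `patient_id`, `arm`, `index_date`,
#'   `file_product`, `note_seq`
#' @return list: `note` (a [clinical_note()]), `gold` (data frame of spans),
#'   `day_offset`, `onset`, `causes`
#' @export
generate_note <- function(scenario, ctx) {
  t <- scenario_note_template(scenario, ctx)
  note_id <- sprintf("%s-N%d", ctx$patient_id, ctx$note_seq %||% 1L)
  nd <- ctx$index_date + t$day
  note <- clinical_note(note_id, ctx$patient_id,
                        as.POSIXct(paste(format(nd), "10:00:00"), tz = "UTC"),
                        t$text)
  gold <- data.frame(patient_id = character(), note_id = character(),
                     class = character(), phrase = character(),
                     start = integer(), end = integer(),
                     stringsAsFactors = FALSE)
  for (k in seq_along(t$gold)) {
    phrase <- t$gold[[k]]
    pos <- regexpr(phrase, t$text, fixed = TRUE)
    if (pos == -1) next
    gold <- rbind(gold, data.frame(
      patient_id = ctx$patient_id, note_id = note_id,
      class = names(t$gold)[k], phrase = phrase,
      start = as.integer(pos - 1L),
      end = as.integer(pos - 1L + attr(pos, "match.length")),
      stringsAsFactors = FALSE))
  }
  list(note = note, gold = gold, day_offset = t$day, onset = t$onset,
       causes = t$causes)
}

#' Generate a synthetic population
#'
#' For each scenario patient: a vaccination record (influenza product,
#' except the vaccine-mismatch scenarios, which record zoster while the
#' note says "flu"), membership covering the full ascertainment window,
#' encounter and diagnosis streams built to satisfy — or violate, per
#' scenario — the cohort rules, and 1-2 notes from the template grammar.
#' Byte-identical output for a fixed seed.
#'
#' @param specs list of [scenario_spec()] objects (or a named integer
#'   vector scenario -> n)
#' @param seed RNG seed
#' @param out_dir optional directory; when given, writes vaccinations.csv,
#'   encounters.csv, diagnoses.csv, membership.csv, notes.jsonl,
#'   truth.jsonl and gold_spans.csv
#' @return list: `vaccinations`, `encounters`, `diagnoses`, `membership`
#'   (data frames), `notes` (list of [clinical_note()]), `truth`, `gold`
#' @export
generate_population <- function(specs, seed = 1L, out_dir = NULL) {
  if (is.numeric(specs) && !is.null(names(specs)))
    specs <- mapply(scenario_spec, names(specs), specs, SIMPLIFY = FALSE)
  for (sp in specs)
    if (!inherits(sp, "scenario_spec"))
      stop("specs must be scenario_spec objects")
  set.seed(as.integer(seed))
  vac <- enc <- dx <- mem <- truth <- list()
  notes <- list(); gold <- list()
  pid_n <- 0L
  for (sp in specs) {
    for (k in seq_len(sp$n)) {
      pid_n <- pid_n + 1L
      pid <- sprintf("P%05d", pid_n)
      scenario <- sp$scenario_id
      arm <- sample(c("left", "right"), 1)
      index_date <- as.Date("2016-06-01") + sample(0:390, 1)
      age <- sample(18:85, 1)
      dob <- index_date - as.integer(age * 365.25)
      file_vaccine <- if (scenario == "probable_w3") "zoster" else "influenza"
      ctx <- list(patient_id = pid, arm = arm, index_date = index_date,
                  file_product = file_vaccine, note_seq = 1L)
      gn <- generate_note(scenario, ctx)
      # the possible variant with a mismatching name records zoster on file
      if (scenario == "possible" &&
          any(gn$gold$phrase == "flu shot" & gn$gold$class == "vaccine"))
        file_vaccine <- "zoster"
      vac[[pid]] <- data.frame(
        patient_id = pid,
        admin_datetime = paste(format(index_date), "09:00:00"),
        vaccine_name = file_vaccine, route = "IM", site_laterality = arm,
        setting = "facility", patient_dob = format(dob),
        stringsAsFactors = FALSE)
      mem[[pid]] <- data.frame(
        patient_id = pid, start_date = format(index_date - 200L),
        end_date = format(index_date + 200L), stringsAsFactors = FALSE)
      code_days <- switch(scenario,
        negative_short_duration = c(5L, 10L),
        non_case_control = integer(),
        c(5L, 40L, 90L))
      ei <- 0L
      # day-0 vaccination visit (no shoulder code)
      ei <- ei + 1L
      enc[[paste0(pid, ei)]] <- data.frame(
        encounter_id = sprintf("%s-E%d", pid, ei), patient_id = pid,
        datetime = paste(format(index_date), "09:30:00"), type = "office",
        stringsAsFactors = FALSE)
      for (dday in code_days) {
        ei <- ei + 1L
        eid <- sprintf("%s-E%d", pid, ei)
        enc[[paste0(pid, ei)]] <- data.frame(
          encounter_id = eid, patient_id = pid,
          datetime = paste(format(index_date + dday), "10:00:00"),
          type = "office", stringsAsFactors = FALSE)
        dx[[paste0(pid, ei)]] <- data.frame(
          patient_id = pid, date = format(index_date + dday),
          icd10cm_code = shoulder_code_for(arm),
          encounter_id = eid, stringsAsFactors = FALSE)
      }
      if (scenario == "non_case_control") {
        ei <- ei + 1L
        eid <- sprintf("%s-E%d", pid, ei)
        enc[[paste0(pid, ei)]] <- data.frame(
          encounter_id = eid, patient_id = pid,
          datetime = paste(format(index_date + 30L), "10:00:00"),
          type = "office", stringsAsFactors = FALSE)
        dx[[paste0(pid, ei)]] <- data.frame(
          patient_id = pid, date = format(index_date + 30L),
          icd10cm_code = "J06.9", encounter_id = eid,
          stringsAsFactors = FALSE)
      }
      notes[[length(notes) + 1L]] <- gn$note
      gold[[length(gold) + 1L]] <- gn$gold
      # some patients get a second, neutral note
      if (stats::runif(1) < 0.4) {
        nd2 <- index_date + sample(100:150, 1)
        notes[[length(notes) + 1L]] <- clinical_note(
          sprintf("%s-N2", pid), pid,
          as.POSIXct(paste(format(nd2), "11:00:00"), tz = "UTC"),
          paste0("Progress note: Routine follow-up. Medication list",
                 " reviewed. No acute complaints."))
      }
      ex <- scenario_expectation(scenario)
      truth[[pid]] <- data.frame(
        patient_id = pid, scenario = scenario,
        expected_verdict = ex$verdict, expected_cohort = ex$cohort,
        expected_w1 = if (all(is.na(ex$w))) NA else ex$w[1],
        expected_w2 = if (all(is.na(ex$w))) NA else ex$w[2],
        expected_w3 = if (all(is.na(ex$w))) NA else ex$w[3],
        expected_onset = gn$onset, expected_causes = gn$causes,
        arm = arm, index_date = format(index_date),
        stringsAsFactors = FALSE)
    }
  }
  pop <- list(
    vaccinations = do.call(rbind, c(vac, list(make.row.names = FALSE))),
    encounters = do.call(rbind, c(enc, list(make.row.names = FALSE))),
    diagnoses = if (length(dx))
      do.call(rbind, c(dx, list(make.row.names = FALSE))) else
      data.frame(patient_id = character(), date = character(),
                 icd10cm_code = character(), encounter_id = character(),
                 stringsAsFactors = FALSE),
    membership = do.call(rbind, c(mem, list(make.row.names = FALSE))),
    notes = notes,
    truth = do.call(rbind, c(truth, list(make.row.names = FALSE))),
    gold = do.call(rbind, c(gold, list(make.row.names = FALSE))))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(pop$vaccinations, file.path(out_dir, "vaccinations.csv"),
                     row.names = FALSE)
    utils::write.csv(pop$encounters, file.path(out_dir, "encounters.csv"),
                     row.names = FALSE)
    utils::write.csv(pop$diagnoses, file.path(out_dir, "diagnoses.csv"),
                     row.names = FALSE)
    utils::write.csv(pop$membership, file.path(out_dir, "membership.csv"),
                     row.names = FALSE)
    write_notes_jsonl(pop$notes, file.path(out_dir, "notes.jsonl"))
    con <- file(file.path(out_dir, "truth.jsonl"), "w")
    for (i in seq_len(nrow(pop$truth)))
      writeLines(jsonlite::toJSON(as.list(pop$truth[i, ]),
                                  auto_unbox = TRUE, na = "null"), con)
    close(con)
    utils::write.csv(pop$gold, file.path(out_dir, "gold_spans.csv"),
                     row.names = FALSE)
  }
  pop
}

DISTRACTOR_POOL <- c(
  "Return if pain worsens.",
  "Reported knee pain in the past which has since resolved.",
  "Medication list reviewed and reconciled.",
  "Discussed sleep hygiene and stress management.",
  "Denies fever or chills.")

#' Inject distractor sentences into notes
#'
#' Appends irrelevant sentences — other body parts, resolved past symptoms,
#' hypothetical advice ("return if pain worsens") — to a fraction of notes.
#' Appending never shifts existing gold spans. Deterministic for a fixed
#' seed; rate 0 is the identity.
#'
#' @param notes list of [clinical_note()] objects
#' @param rate fraction of notes receiving distractors, in `[0, 1]`
#' @param seed RNG seed
#' @return the notes list with modified texts
#' @export
inject_distractors <- function(notes, rate, seed = 1L) {
  stopifnot(rate >= 0, rate <= 1)
  if (rate == 0) return(notes)
  set.seed(as.integer(seed))
  lapply(notes, function(nt) {
    if (stats::runif(1) < rate) {
      extra <- sample(DISTRACTOR_POOL, sample(1:2, 1))
      nt$text <- paste(c(nt$text, extra), collapse = " ")
    }
    nt
  })
}
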