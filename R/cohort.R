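# Structured-data cohort funnel: eligible vaccinations -> presumptive
# shoulder-injury cases -> training/validation subpopulation, with one
# first-failing exclusion reason per excluded record.

#' Default shoulder diagnosis-code list
#'
#' A documented, editable stand-in organized into four groups: A — shoulder
#' disorder diagnoses reported in the SIRVA literature (rotator cuff and
#' related lesions, M75), B — other shoulder disorder diagnoses (M25.61,
#' M24.81), C — shoulder symptom codes (pain in shoulder, M25.51), D —
#' shoulder injury codes from the external-cause chapter (S43, S46).
#' Laterality is decoded from the final digit of the code's numeric part
#' per ICD-10-CM convention: 1 right, 2 left, 3 bilateral, otherwise none.
#'
#' @return data frame `code_prefix`, `group`
#' @export
default_code_list <- function() {
  path <- system.file("extdata", "code_list_default.csv",
                      package = "sirvanlp")
  if (!nzchar(path)) path <- file.path("inst", "extdata",
                                       "code_list_default.csv")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Decode laterality from an ICD-10-CM style code
#' @param code character vector of diagnosis codes
#' @return character vector: `"right"`, `"left"`, `"bilateral"` or `"none"`
#' @export
decode_code_laterality <- function(code) {
  digits <- gsub("[^0-9]", "", code)
  last <- substr(digits, nchar(digits), nchar(digits))
  ifelse(last == "1", "right",
         ifelse(last == "2", "left",
                ifelse(last == "3", "bilateral", "none")))
}

# annotate diagnoses with group + laterality from the code list
classify_diagnoses <- function(diagnoses, code_list = default_code_list()) {
  d <- diagnoses
  d$group <- NA_character_
  ord <- order(-nchar(code_list$code_prefix))
  for (i in ord) {
    hit <- startsWith(d$icd10cm_code, code_list$code_prefix[i]) &
      is.na(d$group)
    d$group[hit] <- code_list$group[i]
  }
  if (is.null(d$code_laterality))
    d$code_laterality <- decode_code_laterality(d$icd10cm_code)
  d$date <- as_date(d$date)
  d
}

#' Select eligible vaccinations
#'
#' Keeps intramuscular arm injections given at a facility to members aged
#' at least `min_age_years` at the index date, with continuous membership
#' covering 180 days before and after. Every record gets a decision and, if
#' excluded, its first-failing reason.
#'
#' @param vaccinations data frame: `patient_id`, `admin_datetime`,
#'   `vaccine_name`, `route`, `site_laterality`, `setting`, `patient_dob`
#' @param memberships data frame: `patient_id`, `start_date`, `end_date`
#' @param min_age_years minimum age at index (default 3)
#' @param config pipeline configuration
#' @return data frame of index events with `decision`/`exclusion_reason`
#' @export
select_eligible_vaccinations <- function(vaccinations, memberships,
                                         min_age_years = 3,
                                         config = default_config()) {
  v <- vaccinations
  v$admin_datetime <- as.POSIXct(v$admin_datetime, tz = "UTC")
  v$index_date <- as.Date(v$admin_datetime)
  v$arm <- lc(as.character(v$site_laterality))
  v$decision <- "included"
  v$exclusion_reason <- NA_character_
  w <- as.integer(config$ascertainment_days)
  fail <- function(cond, reason) {
    hit <- cond & v$decision == "included"
    v$decision[hit] <<- "excluded"
    v$exclusion_reason[hit] <<- reason
  }
  fail(!grepl("^(im|intramuscular)$", lc(v$route)), "route")
  fail(!lc(as.character(v$setting)) %in% c("facility", "true", "1"),
       "setting")
  fail(!v$arm %in% c("left", "right"), "no_laterality")
  age <- as.numeric(v$index_date - as_date(v$patient_dob)) / 365.25
  fail(age < min_age_years, "age")
  cov <- vapply(seq_len(nrow(v)), function(i) {
    mi <- memberships[memberships$patient_id == v$patient_id[i], ]
    if (!nrow(mi)) return(FALSE)
    any(as_date(mi$start_date) <= v$index_date[i] - w &
          as_date(mi$end_date) >= v$index_date[i] + w)
  }, logical(1))
  fail(!cov, "membership")
  v
}

#' Identify presumptive shoulder-injury cases
#'
#' Among eligible vaccinations: requires a laterality-matched shoulder code
#' within days 0-180 after the index date, no shoulder code in the 180 days
#' before, and a laterality-matched code during days 31-180 (to exclude
#' transient local reactions). Day windows are inclusive.
#'
#' @param events output of [select_eligible_vaccinations()]
#' @param diagnoses diagnosis table (`patient_id`, `date`, `icd10cm_code`,
#'   `encounter_id`)
#' @param code_list shoulder-code list (default [default_code_list()])
#' @param config pipeline configuration
#' @return the events with updated decisions
#' @export
identify_presumptive_injury <- function(events, diagnoses,
                                        code_list = default_code_list(),
                                        config = default_config()) {
  d <- classify_diagnoses(diagnoses, code_list)
  w <- as.integer(config$ascertainment_days)
  for (i in seq_len(nrow(events))) {
    if (events$decision[i] != "included") next
    di <- d[d$patient_id == events$patient_id[i] & !is.na(d$group), ]
    day <- as.integer(di$date - events$index_date[i])
    lat_match <- di$code_laterality == events$arm[i] | di$code_laterality == "bilateral"
    if (any(day >= -w & day <= -1L)) {
      events$decision[i] <- "excluded"
      events$exclusion_reason[i] <- "prior_shoulder"
    } else if (!any(day >= 0L & day <= w & lat_match)) {
      events$decision[i] <- "excluded"
      events$exclusion_reason[i] <- "no_shoulder_code"
    } else if (!any(day >= 31L & day <= w & lat_match)) {
      events$decision[i] <- "excluded"
      events$exclusion_reason[i] <- "no_31_180_code"
    }
  }
  events
}

#' Apply the day-0 inclusion rules to one event
#'
#' Events whose first shoulder code falls on day 0 represent possible
#' preexisting conditions. They survive only when there were at least two
#' encounters on day 0 ordered by timestamp, the first carries no shoulder
#' code and did not occur before the vaccination, and a later encounter is
#' an urgent-care, emergency or virtual visit.
#'
#' @param event one row of the events table (data frame of one row)
#' @param encounters encounter table (`encounter_id`, `patient_id`,
#'   `datetime`, `type`)
#' @param diagnoses diagnosis table
#' @param code_list shoulder-code list
#' @return list `decision`, `exclusion_reason`
#' @export
apply_day0_rules <- function(event, encounters, diagnoses,
                             code_list = default_code_list()) {
  d <- classify_diagnoses(diagnoses, code_list)
  day0 <- encounters[encounters$patient_id == event$patient_id &
                       as.Date(as.POSIXct(encounters$datetime, tz = "UTC")) ==
                       event$index_date, , drop = FALSE]
  if (!nrow(day0))
    return(list(decision = "excluded", exclusion_reason = "single_day0_encounter"))
  ts <- as.POSIXct(day0$datetime, tz = "UTC")
  if (anyNA(ts))
    return(list(decision = "excluded", exclusion_reason = "unordered_day0"))
  day0 <- day0[order(ts), , drop = FALSE]
  if (nrow(day0) < 2L)
    return(list(decision = "excluded", exclusion_reason = "single_day0_encounter"))
  first <- day0[1, ]
  shoulder_enc <- d$encounter_id[!is.na(d$group) &
                                   d$patient_id == event$patient_id]
  if (first$encounter_id %in% shoulder_enc)
    return(list(decision = "excluded",
                exclusion_reason = "first_day0_shoulder_code"))
  if (!is.null(event$admin_datetime) &&
      as.POSIXct(first$datetime, tz = "UTC") <
        as.POSIXct(event$admin_datetime, tz = "UTC"))
    return(list(decision = "excluded",
                exclusion_reason = "first_day0_before_vaccination"))
  later <- day0[-1, , drop = FALSE]
  if (!any(lc(later$type) %in% c("urgent_care", "emergency", "virtual")))
    return(list(decision = "excluded",
                exclusion_reason = "no_day0_urgent_virtual"))
  list(decision = "included", exclusion_reason = NA_character_)
}

#' Apply the training/validation subpopulation criteria
#'
#' Four additional criteria, in order: (1) no external shoulder injury
#' (group D) code within 180 days before or after vaccination, (2) no
#' shoulder code on day 0, (3) a shoulder code during days 1-30, (4)
#' shoulder codes on at least 2 different dates during days 31-180.
#'
#' @param events presumptive events table
#' @param diagnoses diagnosis table
#' @param code_list shoulder-code list
#' @param config pipeline configuration
#' @return the events with updated decisions
#' @export
apply_subpopulation_criteria <- function(events, diagnoses,
                                         code_list = default_code_list(),
                                         config = default_config()) {
  d <- classify_diagnoses(diagnoses, code_list)
  w <- as.integer(config$ascertainment_days)
  for (i in seq_len(nrow(events))) {
    if (events$decision[i] != "included") next
    di <- d[d$patient_id == events$patient_id[i] & !is.na(d$group), ]
    day <- as.integer(di$date - events$index_date[i])
    inw <- day >= -w & day <= w
    if (any(inw & di$group == "D")) {
      events$decision[i] <- "excluded"
      events$exclusion_reason[i] <- "external_injury"
    } else if (any(day == 0L)) {
      events$decision[i] <- "excluded"
      events$exclusion_reason[i] <- "day0_code"
    } else if (!any(day >= 1L & day <= 30L)) {
      events$decision[i] <- "excluded"
      events$exclusion_reason[i] <- "no_1_30_code"
    } else if (length(unique(di$date[day >= 31L & day <= w])) < 2L) {
      events$decision[i] <- "excluded"
      events$exclusion_reason[i] <- "single_31_180_date"
    }
  }
  events
}

#' Run the full cohort funnel
#'
#' Eligibility, presumptive-injury and day-0 stages in order, recording the
#' first failing reason per record, plus a per-stage flow table.
#'
#' @param vaccinations,encounters,diagnoses,memberships the four structured
#'   tables
#' @param code_list shoulder-code list
#' @param min_age_years minimum age at index
#' @param config pipeline configuration
#' @return list: `events` (decision table) and `funnel` (stage counts)
#' @export
run_cohort <- function(vaccinations, encounters, diagnoses, memberships,
                       code_list = default_code_list(), min_age_years = 3,
                       config = default_config()) {
  ev <- select_eligible_vaccinations(vaccinations, memberships,
                                     min_age_years, config)
  n0 <- nrow(ev)
  n1 <- sum(ev$decision == "included")
  ev <- identify_presumptive_injury(ev, diagnoses, code_list, config)
  n2 <- sum(ev$decision == "included")
  # day-0 rules apply only to events whose shoulder coding includes day 0
  d <- classify_diagnoses(diagnoses, code_list)
  for (i in seq_len(nrow(ev))) {
    if (ev$decision[i] != "included") next
    di <- d[d$patient_id == ev$patient_id[i] & !is.na(d$group), ]
    if (!any(as.integer(di$date - ev$index_date[i]) == 0L)) next
    r <- apply_day0_rules(ev[i, ], encounters, diagnoses, code_list)
    ev$decision[i] <- r$decision
    ev$exclusion_reason[i] <- r$exclusion_reason
  }
  n3 <- sum(ev$decision == "included")
  funnel <- data.frame(
    stage = c("all_vaccinations", "eligible", "presumptive", "after_day0_rules"),
    n = c(n0, n1, n2, n3), stringsAsFactors = FALSE)
  list(events = ev, funnel = funnel)
}
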