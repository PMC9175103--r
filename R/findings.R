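# Finding extraction: anatomic (laterality/body location), temporal
# (onset/duration/resolution) and causal (7 cause types) findings for
# shoulder-injury mentions in one indexed note.

INJURY_CLASSES <- c("shoulder_symptom", "shoulder_diagnosis")

CAUSE_TYPE_OF <- c(vaccine = "vaccination", cause_accident = "accident",
                   cause_work = "work",
                   cause_medical_condition = "other_medical_condition",
                   cause_exercise = "exercise",
                   cause_daily_activity = "daily_activity",
                   cause_unknown = "unknown")

NONVACCINE_CAUSE_TYPES <- c("accident", "work", "other_medical_condition",
                            "exercise", "daily_activity")

normalize_laterality <- function(surface) {
  s <- lc(surface)
  if (s %in% c("left", "lt", "l")) "left"
  else if (s %in% c("right", "rt", "r")) "right"
  else if (s %in% c("bilateral", "b/l", "bl", "both", "b/l shoulders"))
    "bilateral"
  else "unknown"
}

injury_rows <- function(indexed) {
  men <- indexed$mentions
  which(men$class %in% INJURY_CLASSES & !men$negated & !men$hypothetical)
}

RESOLVED_RE <- paste0(
  "\\b(in (the )?past|previously|used to|no longer|resolved|went away|",
  "has since resolved|history of)\\b")

# per-mention resolution flag: the sentence describes the symptom as past
resolved_flags <- function(indexed) {
  men <- indexed$mentions
  out <- logical(nrow(men))
  if (!nrow(men)) return(out)
  for (i in seq_len(nrow(men))) {
    s <- men$sentence_index[i]
    row <- indexed$sentences[indexed$sentences$index == s, ]
    stext <- span_text(indexed$note$text, row$start, row$end)
    out[i] <- grepl(RESOLVED_RE, stext, ignore.case = TRUE)
  }
  out
}

#' Extract anatomic findings
#'
#' For each non-negated, non-hypothetical shoulder symptom/diagnosis
#' mention, attaches the nearest laterality and body-location mention within
#' the same sentence and the configured word window (default 8). Distance
#' ties prefer the mention preceding the injury (English modifier order).
#' "b/l"/"bilateral" normalize to bilateral; nothing in range gives
#' `"unknown"`.
#'
#' @param indexed an `indexed_note`
#' @param config pipeline configuration
#' @return data frame: `mention_id` (row in `indexed$mentions`),
#'   `entry_id`, `class`, `sentence_index`, `laterality`, `body_location`,
#'   `resolved`
#' @export
extract_anatomic <- function(indexed, config = default_config()) {
  men <- indexed$mentions
  inj <- injury_rows(indexed)
  res <- resolved_flags(indexed)
  nearest <- function(i, cls) {
    cand <- which(men$class == cls & men$sentence_index == men$sentence_index[i])
    cand <- setdiff(cand, i)
    if (!length(cand)) return(NA_integer_)
    dist <- vapply(cand, function(j) {
      if (men$tok_from[j] > men$tok_to[i])
        words_between(indexed$tokens, men$tok_to[i], men$tok_from[j])
      else if (men$tok_to[j] < men$tok_from[i])
        words_between(indexed$tokens, men$tok_to[j], men$tok_from[i])
      else 0L
    }, integer(1))
    ok <- dist <= config$anatomic_window
    if (!any(ok)) return(NA_integer_)
    cand <- cand[ok]; dist <- dist[ok]
    precedes <- men$tok_from[cand] < men$tok_from[i]
    cand[order(dist, !precedes, cand)][1]
  }
  out <- lapply(inj, function(i) {
    li <- nearest(i, "laterality")
    bi <- nearest(i, "body_location")
    data.frame(
      mention_id = i, entry_id = men$entry_id[i], class = men$class[i],
      sentence_index = men$sentence_index[i],
      laterality = if (is.na(li)) "unknown" else
        normalize_laterality(span_text(indexed$note$text, men$start[li],
                                       men$end[li])),
      body_location = if (is.na(bi)) NA_character_ else
        lc(span_text(indexed$note$text, men$start[bi], men$end[bi])),
      resolved = res[i], stringsAsFactors = FALSE)
  })
  if (!length(out))
    return(data.frame(mention_id = integer(), entry_id = character(),
                      class = character(), sentence_index = integer(),
                      laterality = character(), body_location = character(),
                      resolved = logical(), stringsAsFactors = FALSE))
  r <- do.call(rbind, out); rownames(r) <- NULL; r
}

# vaccination-anchored onset offsets stated directly against the shot
# ("started the day she got a flu shot", "began 2 days after flu vaccine",
# "since immunizations") -> day offset from the vaccination
scan_vaccination_onset <- function(text) {
  offs <- integer()
  if (grepl(paste0("\\b(started|began|starting|since)\\b[^.]{0,40}",
                   "\\bday\\b[^.]{0,30}\\b(vaccin\\w*|immuniz\\w*|shot)"),
            text, ignore.case = TRUE, perl = TRUE))
    offs <- c(offs, 0L)
  if (grepl(paste0("\\bsince\\b\\s+(his|her|their)?\\s*\\w*\\s*",
                   "(vaccin\\w*|immuniz\\w*|shot)\\b"),
            text, ignore.case = TRUE, perl = TRUE))
    offs <- c(offs, 0L)
  g <- re1(paste0("\\b(?:started|began)\\s+", NUM_RE,
                  "\\s+days?\\s+after\\b[^.]{0,40}",
                  "\\b(?:vaccin\\w*|immuniz\\w*|shot)"), text)
  if (!is.null(g)) {
    n <- parse_count(g[2])
    if (!is.na(n)) offs <- c(offs, n)
  }
  unique(offs)
}

#' Extract temporal findings
#'
#' For each non-negated, non-hypothetical injury mention, normalizes the
#' temporal expressions in its sentence (falling back to expression-bearing
#' sentences without their own injury mention inside the cross-sentence
#' window); onset offsets are counted in days from `index_date`.
#' Vaccination-anchored phrasings ("started the day she got a flu shot")
#' yield offsets directly. A sentence describing the symptom as past sets
#' `resolved = TRUE` on its findings.
#'
#' @param indexed an `indexed_note`
#' @param index_date vaccination date (day 0)
#' @param config pipeline configuration
#' @return data frame: `mention_id`, `expression`, `onset_date`,
#'   `onset_offset`, `duration_days`, `resolved`
#' @export
extract_temporal <- function(indexed, index_date,
                             config = default_config()) {
  index_date <- as_date(index_date)
  note_date <- as_date(as.Date(indexed$note$note_datetime))
  men <- indexed$mentions
  res <- resolved_flags(indexed)
  empty <- data.frame(mention_id = integer(), expression = character(),
                      onset_date = as.Date(character()),
                      onset_offset = integer(), duration_days = integer(),
                      resolved = logical(), stringsAsFactors = FALSE)
  inj <- injury_rows(indexed)
  if (!length(inj)) return(empty)
  sent_text <- function(s) {
    row <- indexed$sentences[indexed$sentences$index == s, ]
    span_text(indexed$note$text, row$start, row$end)
  }
  inj_sents <- unique(men$sentence_index[injury_rows(indexed)])
  out <- list()
  for (i in inj) {
    s <- men$sentence_index[i]
    stext <- sent_text(s)
    tf <- scan_temporal(stext, note_date, config)
    voffs <- scan_vaccination_onset(stext)
    if (!nrow(tf) && !length(voffs)) {
      # cross-sentence fallback: expression-bearing sentences in the window
      # that hold no injury mention of their own
      win <- setdiff(max(0L, s - config$cross_sentence_span + 1L):
                       (s + config$cross_sentence_span - 1L), s)
      win <- win[win %in% indexed$sentences$index & !(win %in% inj_sents)]
      for (s2 in win) {
        tf2 <- scan_temporal(sent_text(s2), note_date, config)
        v2 <- scan_vaccination_onset(sent_text(s2))
        if (nrow(tf2)) tf <- rbind(tf, tf2)
        voffs <- c(voffs, v2)
      }
    }
    if (nrow(tf)) {
      for (r in seq_len(nrow(tf))) {
        onset <- tf$onset_date[r]
        out[[length(out) + 1L]] <- data.frame(
          mention_id = i, expression = tf$expression[r], onset_date = onset,
          onset_offset = if (is.na(onset)) NA_integer_ else
            as.integer(onset - index_date),
          duration_days = tf$duration_days[r], resolved = res[i],
          stringsAsFactors = FALSE)
      }
    }
    for (v in unique(voffs)) {
      out[[length(out) + 1L]] <- data.frame(
        mention_id = i, expression = "vaccination-anchored onset",
        onset_date = index_date + v, onset_offset = as.integer(v),
        duration_days = NA_integer_, resolved = res[i],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty)
  r <- unique(do.call(rbind, out)); rownames(r) <- NULL; r
}

#' Default causal relation queries
#'
#' One cross-sentence query per (injury class, cause class) pair: the injury
#' mention and a nested ordered (trigger, cause) pair, searched over the
#' configured window (default 4 sentences / 50 words). Unknown-cause
#' statements need no trigger.
#'
#' @param config pipeline configuration
#' @return list of [relation_query()] objects
#' @export
default_causal_queries <- function(config = default_config()) {
  qs <- list()
  for (icls in INJURY_CLASSES) {
    for (ccls in setdiff(CAUSE_CLASSES, "cause_unknown")) {
      nested <- relation_query(
        paste0("pair_", ccls), list("causal_trigger", ccls),
        ordered = TRUE, max_sentence_span = 1L,
        max_intervening_words = config$nested_cause_words,
        require_same_section = config$require_same_section)
      qs[[length(qs) + 1L]] <- relation_query(
        paste0("causal_", icls, "_", ccls), list(icls, nested),
        ordered = FALSE, max_sentence_span = config$cross_sentence_span,
        max_intervening_words = config$cross_sentence_words,
        require_same_section = config$require_same_section)
    }
    qs[[length(qs) + 1L]] <- relation_query(
      paste0("causal_", icls, "_cause_unknown"),
      list(icls, "cause_unknown"),
      ordered = FALSE, max_sentence_span = 1L,
      max_intervening_words = config$cross_sentence_words,
      require_same_section = config$require_same_section)
  }
  qs
}

#' Extract causal findings
#'
#' Runs the causal relation-query set and distills each match into a
#' `CausalFinding` row: the cause type of the grounded cause mention, the
#' trigger used, intra- vs cross-sentence scope, and the vaccine name when a
#' specific vaccine term grounded the match. Negated causes yield nothing.
#' Findings anchor only to injury mentions with shoulder-region anatomy (a
#' shoulder diagnosis, or a symptom whose attached body location is in the
#' shoulder region); with `strict_anatomy`, a cross-sentence match is
#' dropped when the cause's own sentence carries an injury mention located
#' outside the shoulder region — the cause belongs to that local injury.
#'
#' @param indexed an `indexed_note`
#' @param config pipeline configuration
#' @param queries causal query set (default [default_causal_queries()])
#' @return data frame: `mention_id` (injury), `cause_type`, `trigger`,
#'   `cause_entry`, `scope`, `vaccine_name`
#' @export
extract_causal <- function(indexed, config = default_config(),
                           queries = default_causal_queries(config)) {
  men <- indexed$mentions
  empty <- data.frame(mention_id = integer(), cause_type = character(),
                      trigger = character(), cause_entry = character(),
                      scope = character(), vaccine_name = character(),
                      stringsAsFactors = FALSE)
  if (!nrow(men)) return(empty)
  anat <- extract_anatomic(indexed, config)
  region_ok <- function(mid) {
    row <- anat[anat$mention_id == mid, ]
    if (!nrow(row)) return(FALSE)
    if (row$class[1] == "shoulder_diagnosis") return(TRUE)
    !is.na(row$body_location[1]) &&
      row$body_location[1] %in% config$shoulder_region
  }
  region_bad <- function(mid) {
    row <- anat[anat$mention_id == mid, ]
    nrow(row) > 0 && !is.na(row$body_location[1]) &&
      !(row$body_location[1] %in% config$shoulder_region)
  }
  out <- list()
  for (q in queries) {
    for (m in search_relations(indexed, q, config)) {
      leaves <- m$leaves
      cls <- men$class[leaves]
      inj_leaf <- leaves[cls %in% INJURY_CLASSES][1]
      cause_leaf <- leaves[cls %in% CAUSE_CLASSES][1]
      if (is.na(inj_leaf) || is.na(cause_leaf)) next
      if (!region_ok(inj_leaf)) next
      trig_leaf <- leaves[cls == "causal_trigger"]
      if (isTRUE(config$strict_anatomy) && m$scope == "cross_sentence") {
        cause_sent <- men$sentence_index[cause_leaf]
        local_inj <- injury_rows(indexed)
        local_inj <- local_inj[men$sentence_index[local_inj] == cause_sent]
        if (any(vapply(local_inj, region_bad, logical(1)))) next
      }
      vac_name <- NA_character_
      if (men$class[cause_leaf] == "vaccine")
        vac_name <- lc(span_text(indexed$note$text, men$start[cause_leaf],
                                 men$end[cause_leaf]))
      out[[length(out) + 1L]] <- data.frame(
        mention_id = inj_leaf,
        cause_type = unname(CAUSE_TYPE_OF[men$class[cause_leaf]]),
        trigger = if (length(trig_leaf)) men$entry_id[trig_leaf[1]] else
          NA_character_,
        cause_entry = men$entry_id[cause_leaf],
        scope = m$scope, vaccine_name = vac_name,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty)
  r <- unique(do.call(rbind, out)); rownames(r) <- NULL; r
}

#' Extract all findings for one note
#'
#' Convenience wrapper returning anatomic, temporal and causal findings
#' tagged with the note id and date.
#'
#' @param indexed an `indexed_note`
#' @param index_date vaccination date (day 0)
#' @param config pipeline configuration
#' @return list of data frames `anatomic`, `temporal`, `causal`
#' @export
extract_findings <- function(indexed, index_date,
                             config = default_config()) {
  note_id <- indexed$note$note_id
  note_date <- as.Date(indexed$note$note_datetime)
  tag <- function(df) {
    if (nrow(df)) { df$note_id <- note_id; df$note_date <- note_date }
    else { df$note_id <- character(); df$note_date <- as.Date(character()) }
    df
  }
  list(anatomic = tag(extract_anatomic(indexed, config)),
       temporal = tag(extract_temporal(indexed, index_date, config)),
       causal = tag(extract_causal(indexed, config)))
}
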