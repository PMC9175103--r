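# Shared fixtures: a compact lexicon for focused matcher tests, quick note
# builders, and helpers for comparing relation-match sets.

mini_lexicon <- function(extra = list()) {
  entries <- c(list(
    lexicon_entry("sym1", "shoulder_symptom", "pain"),
    lexicon_entry("sym2", "shoulder_symptom", "stiffness"),
    lexicon_entry("dx1", "shoulder_diagnosis", "rotator cuff tear"),
    lexicon_entry("dx2", "shoulder_diagnosis", "bursitis"),
    lexicon_entry("loc1", "body_location", "shoulder",
                  variants = "shoulders"),
    lexicon_entry("loc2", "body_location", "arm"),
    lexicon_entry("loc3", "body_location", "back"),
    lexicon_entry("lat1", "laterality", "left", variants = "lt"),
    lexicon_entry("lat2", "laterality", "right", variants = "rt"),
    lexicon_entry("lat3", "laterality", "bilateral", variants = "b/l"),
    lexicon_entry("vax1", "vaccine", "flu vaccine",
                  variants = c("flu shot", "influenza")),
    lexicon_entry("acc1", "cause_accident", "fall", variants = "fell"),
    lexicon_entry("acc2", "cause_accident", "injury"),
    lexicon_entry("acc3", "cause_accident", "trauma"),
    lexicon_entry("dly1", "cause_daily_activity", "vacuuming"),
    lexicon_entry("wrk1", "cause_work", "work injury"),
    lexicon_entry("med1", "cause_medical_condition", "arthritis"),
    lexicon_entry("exr1", "cause_exercise", "sports"),
    lexicon_entry("unk1", "cause_unknown", "insidious onset"),
    lexicon_entry("trg1", "causal_trigger", "s/p"),
    lexicon_entry("trg2", "causal_trigger", "after"),
    lexicon_entry("trg3", "causal_trigger", "due to"),
    lexicon_entry("tmp1", "temporal_cue", "for"),
    lexicon_entry("neg1", "negation_cue", "denies"),
    lexicon_entry("neg2", "negation_cue", "no"),
    lexicon_entry("unc1", "uncertainty_cue", "possible"),
    lexicon_entry("hyp1", "hypothetical_cue", "return if"),
    lexicon_entry("trm1", "termination_cue", "but"),
    lexicon_entry("sec1", "section_header", "hpi")), extra)
  new_lexicon(entries, version = "test")
}

note_of <- function(text, date = "2017-03-10T10:00:00", id = "n1",
                    pid = "p1") {
  clinical_note(id, pid, date, text)
}

index_text <- function(text, lexicon = default_lexicon(), ...) {
  index_note(note_of(text, ...), lexicon)
}

# order-insensitive signature of a relation-match set
match_signature <- function(matches) {
  sort(vapply(matches, function(m) paste(m$key, m$scope), character(1)))
}

# small scenario mix for quick end-to-end tests
small_specs <- function(n = 3) lapply(scenario_labels(), scenario_spec, n = n)
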