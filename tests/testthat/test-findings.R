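test_that("anatomic extraction attaches nearest laterality and location", {
  f <- extract_anatomic(index_text("Patient has persistent pain in his left arm."))
  expect_equal(nrow(f), 1L)
  expect_equal(f$laterality, "left")
  expect_equal(f$body_location, "arm")
  f2 <- extract_anatomic(index_text("Reports shoulder pain."))
  expect_equal(f2$laterality, "unknown")
  expect_equal(f2$body_location, "shoulder")
  # no laterality and no location in range
  f3 <- extract_anatomic(index_text("Reports pain."))
  expect_equal(f3$laterality, "unknown")
  expect_true(is.na(f3$body_location))
})

test_that("bilateral shorthand normalizes to bilateral", {
  # chronic-pain enumeration ending in b/l shoulders
  f <- extract_anatomic(index_text(
    "She has chronic pain\u2014neck, low back, B/L shoulders."))
  expect_true(any(f$laterality == "bilateral"))
})

test_that("negated and hypothetical symptom mentions yield no findings", {
  expect_equal(nrow(extract_anatomic(index_text("No pain in left arm."))), 0L)
  expect_equal(nrow(extract_anatomic(index_text("Return if pain worsens."))),
               0L)
})

test_that("temporal findings derive onset and duration from the note date", {
  # note on day 62 relative to a 2017-01-01 vaccination
  ix <- index_text("Reports having R shoulder pain for last 2 months.",
                   date = "2017-03-04T10:00:00")
  f <- extract_temporal(ix, as.Date("2017-01-01"))
  expect_equal(f$duration_days, 60L)
  expect_equal(f$onset_date, as.Date("2017-03-04") - 60)
  expect_equal(f$onset_offset, 2L)
  expect_false(any(f$resolved))
  # no expression, no finding
  expect_equal(nrow(extract_temporal(index_text("Left shoulder pain."),
                                     as.Date("2017-01-01"))), 0L)
})

test_that("past-tense resolution marks the finding resolved", {
  ix <- index_text(paste0(
    "States in past pain would travel to left shoulder causing numbness ",
    "to left arm and lasting a few days but today denies any numbness."))
  f <- extract_temporal(ix, as.Date("2017-01-01"))
  expect_gte(nrow(f), 1L)
  expect_true(all(f$resolved))
  # numbness after "denies" is negated, so it anchors nothing
  m <- ix$mentions
  numb <- m[m$class == "shoulder_symptom" & m$start > 90, ]
  expect_true(all(numb$negated))
})

test_that("vaccination-anchored phrasings yield day-offset onsets", {
  ix <- index_text("L shoulder pain that started the day she got a flu shot.",
                   date = "2017-02-10T09:00:00")
  f <- extract_temporal(ix, as.Date("2017-01-01"))
  expect_true(0L %in% f$onset_offset)
  ix2 <- index_text("Right shoulder pain and neck stiffness since immunizations.",
                    date = "2017-02-10T09:00:00")
  f2 <- extract_temporal(ix2, as.Date("2017-01-01"))
  expect_true(0L %in% f2$onset_offset)
})

test_that("causal extraction classifies the seven cause types", {
  # vaccination, cross-sentence, with vaccine name
  ix <- index_text(paste0(
    "Patient requesting an appointment for evaluation for left arm pain. ",
    "States experiencing pain x 1 month s/p flu vaccine."))
  f <- extract_causal(ix)
  expect_equal(nrow(f), 1L)
  expect_equal(f$cause_type, "vaccination")
  expect_equal(f$scope, "cross_sentence")
  expect_equal(f$vaccine_name, "flu vaccine")
  # daily activity, intra-sentence
  f2 <- extract_causal(index_text(
    "Complains of left shoulder pain that started 3 weeks ago after vacuuming."))
  expect_true(any(f2$cause_type == "daily_activity" &
                    f2$scope == "intra_sentence"))
  # unknown cause without a trigger
  f3 <- extract_causal(index_text(
    "Insidious onset of left shoulder pain."))
  expect_true(any(f3$cause_type == "unknown"))
})

test_that("negated causes yield no causal findings", {
  expect_equal(nrow(extract_causal(index_text(
    "Left shoulder pain. Denies any injury."))), 0L)
  expect_equal(nrow(extract_causal(index_text(
    "Left shoulder pain today. No injury or trauma."))), 0L)
})

test_that("a cause bound to a non-shoulder injury is not attributed across sentences", {
  # the fall explains the back pain in its own sentence, not the shoulder
  f <- extract_causal(index_text(paste0(
    "Left shoulder pain for two months. ",
    "Back pain due to a fall last week.")))
  expect_false(any(f$cause_type == "accident"))
  # the literal chronic-pain enumeration likewise yields no shoulder cause
  f2 <- extract_causal(index_text(paste0(
    "She has chronic pain\u2014neck, low back, B/L shoulders. ",
    "She has fibromyalgia and also fell a few weeks ago which worsened ",
    "her back pain.")))
  expect_false(any(f2$cause_type == "accident"))
  # without the competing local injury the cross-sentence attribution holds
  f3 <- extract_causal(index_text(paste0(
    "Left shoulder pain for two months. ",
    "Symptoms began due to a fall last week.")))
  expect_true(any(f3$cause_type == "accident" & f3$scope == "cross_sentence"))
})

test_that("vaccination cause appears iff a vaccine mention grounds it", {
  pop <- generate_population(list(scenario_spec("definite", 3),
                                  scenario_spec("negative_negated", 3)),
                             seed = 17)
  lex <- compile_lexicon(default_lexicon())
  for (nt in pop$notes) {
    ix <- index_note(nt, lex)
    f <- extract_causal(ix)
    if (!nrow(f)) next
    vac <- f[f$cause_type == "vaccination", ]
    if (nrow(vac))
      expect_true(all(ix$mentions$class[match(vac$cause_entry,
                                              ix$mentions$entry_id)] ==
                        "vaccine"))
  }
})
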