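# Evidence builders: construct patient_evidence objects directly so the
# classifier logic is exercised independently of text extraction.

ev_event <- function(arm = "left", product = "influenza",
                     index = as.Date("2017-01-01")) {
  index_event("p1", index, arm, product)
}

anat_row <- function(lat = "left", loc = "shoulder", day = 40L,
                     resolved = FALSE, class = "shoulder_symptom",
                     mid = 1L) {
  data.frame(mention_id = mid, entry_id = "sym1", class = class,
             sentence_index = 0L, laterality = lat, body_location = loc,
             resolved = resolved, note_id = "n1",
             note_date = as.Date("2017-01-01") + day,
             stringsAsFactors = FALSE)
}

temp_row <- function(offset, duration = NA_integer_, day = 40L,
                     resolved = FALSE) {
  data.frame(mention_id = 1L, expression = "fixture",
             onset_date = as.Date("2017-01-01") + offset,
             onset_offset = as.integer(offset),
             duration_days = as.integer(duration), resolved = resolved,
             note_id = "n1", note_date = as.Date("2017-01-01") + day,
             stringsAsFactors = FALSE)
}

causal_row <- function(type = "vaccination", scope = "intra_sentence",
                       day = 40L, name = "flu vaccine") {
  data.frame(mention_id = 1L, cause_type = type, trigger = "trg1",
             cause_entry = "vax1", scope = scope, vaccine_name = name,
             note_id = "n1", note_date = as.Date("2017-01-01") + day,
             stringsAsFactors = FALSE)
}

build_evidence <- function(anatomic = NULL, temporal = NULL, causal = NULL,
                           arm = "left", product = "influenza",
                           codes = NULL) {
  structure(list(event = ev_event(arm, product), anatomic = anatomic,
                 temporal = temporal, causal = causal,
                 code_timeline = codes),
            class = "patient_evidence")
}

full_codes <- data.frame(date = as.Date("2017-01-01") + c(5L, 40L, 90L),
                         laterality = "left", day = c(5L, 40L, 90L),
                         stringsAsFactors = FALSE)

test_that("a textbook positive meets all five case-definition criteria", {
  ev <- build_evidence(anat_row(), temp_row(2, duration = 60),
                       causal_row(), codes = full_codes)
  cd <- evaluate_case_definition(ev)
  expect_true(all(unlist(cd[c("c1", "c2", "c3", "c4", "c5")])))
  expect_equal(classify_case(ev)$verdict, "definite")
})

test_that("a competing non-vaccination cause fails the causality criterion", {
  ev <- build_evidence(anat_row(), temp_row(2, 60),
                       rbind(causal_row(), causal_row(type = "accident")),
                       codes = full_codes)
  cd <- evaluate_case_definition(ev)
  expect_false(cd$c4)
  expect_equal(classify_case(ev)$verdict, "negative")
  # an unknown cause does not disqualify
  ev2 <- build_evidence(anat_row(), temp_row(2, 60),
                        rbind(causal_row(), causal_row(type = "unknown")),
                        codes = full_codes)
  expect_true(evaluate_case_definition(ev2)$c4)
})

test_that("any onset inside the window satisfies the onset criterion", {
  ev <- build_evidence(anat_row(), rbind(temp_row(3), temp_row(45)),
                       causal_row(), codes = full_codes)
  expect_true(evaluate_case_definition(ev)$c3)
  ev2 <- build_evidence(anat_row(), temp_row(45), causal_row(),
                        codes = full_codes)
  expect_false(evaluate_case_definition(ev2)$c3)
})

test_that("laterality matching honors arm, bilateral and unknown", {
  mk <- function(lat) build_evidence(anat_row(lat = lat), temp_row(2, 60),
                                     causal_row(), codes = full_codes)
  expect_true(evaluate_case_definition(mk("left"))$c2)
  expect_false(evaluate_case_definition(mk("right"))$c2)
  expect_true(evaluate_case_definition(mk("bilateral"))$c2)
  expect_false(evaluate_case_definition(mk("unknown"))$c2)
  cfg <- default_config(); cfg$bilateral_matches_arm <- FALSE
  expect_false(evaluate_case_definition(mk("bilateral"), cfg)$c2)
})

test_that("duration evidence comes from NLP duration, late notes or codes", {
  # only the structured codes persist past day 30
  ev <- build_evidence(anat_row(day = 12L), temp_row(5, 7, day = 12L),
                       causal_row(day = 12L), codes = full_codes)
  expect_true(evaluate_case_definition(ev)$c5)
  # nothing persists
  short_codes <- full_codes[full_codes$day <= 10, ]
  ev2 <- build_evidence(anat_row(day = 12L), temp_row(5, 7, day = 12L),
                        causal_row(day = 12L), codes = short_codes)
  expect_false(evaluate_case_definition(ev2)$c5)
  # NLP duration alone suffices
  ev3 <- build_evidence(anat_row(day = 12L), temp_row(5, 45, day = 12L),
                        causal_row(day = 12L), codes = short_codes)
  expect_true(evaluate_case_definition(ev3)$c5)
  # a resolved symptom's duration does not count
  ev4 <- build_evidence(anat_row(day = 12L, resolved = TRUE),
                        temp_row(5, 45, day = 12L, resolved = TRUE),
                        causal_row(day = 12L), codes = short_codes)
  expect_false(evaluate_case_definition(ev4)$c1)
  expect_false(evaluate_case_definition(ev4)$c5)
})

test_that("weak-evidence criteria follow scope, timing and vaccine identity", {
  base <- list(anat_row(), temp_row(2, 60))
  # cross-sentence only, in an early note -> w1+w2 -> possible
  ev <- build_evidence(base[[1]], base[[2]],
                       causal_row(scope = "cross_sentence", day = 20L),
                       codes = full_codes)
  wk <- evaluate_weak_evidence(ev)
  expect_true(wk$w1); expect_true(wk$w2); expect_false(wk$w3)
  expect_equal(classify_case(ev)$verdict, "possible")
  # intra-sentence, late, matching -> definite
  ev2 <- build_evidence(base[[1]], base[[2]], causal_row(day = 40L),
                        codes = full_codes)
  expect_equal(unlist(evaluate_weak_evidence(ev2)), c(w1 = FALSE,
                                                      w2 = FALSE,
                                                      w3 = FALSE))
  expect_equal(classify_case(ev2)$verdict, "definite")
  # note says flu, file says zoster -> mismatch
  ev3 <- build_evidence(base[[1]], base[[2]],
                        causal_row(day = 40L, name = "flu shot"),
                        product = "zoster", codes = full_codes)
  expect_true(evaluate_weak_evidence(ev3)$w3)
  expect_equal(classify_case(ev3)$verdict, "probable")
  # a generic name never mismatches
  ev4 <- build_evidence(base[[1]], base[[2]],
                        causal_row(day = 40L, name = "vaccine"),
                        product = "zoster", codes = full_codes)
  expect_false(evaluate_weak_evidence(ev4)$w3)
  # a later intra-sentence attribution clears w1 and w2
  ev5 <- build_evidence(base[[1]], base[[2]],
                        rbind(causal_row(scope = "cross_sentence", day = 20L),
                              causal_row(day = 40L)),
                        codes = full_codes)
  wk5 <- evaluate_weak_evidence(ev5)
  expect_false(wk5$w1); expect_false(wk5$w2)
})

test_that("no vaccination cause means all weak criteria are false", {
  ev <- build_evidence(anat_row(), temp_row(2, 60),
                       causal_row(type = "accident"), codes = full_codes)
  expect_equal(unlist(evaluate_weak_evidence(ev)),
               c(w1 = FALSE, w2 = FALSE, w3 = FALSE))
})

test_that("verdicts over all criterion combinations match the rule", {
  # independent oracle: re-derive the verdict from first principles for
  # each of the 2^8 flag combinations
  for (mask in 0:255) {
    bits <- as.logical(bitwAnd(mask, 2^(0:7)) > 0)
    cd <- setNames(as.list(bits[1:5]), c("c1", "c2", "c3", "c4", "c5"))
    wk <- setNames(as.list(bits[6:8]), c("w1", "w2", "w3"))
    expected <- if (!(bits[1] && bits[2] && bits[3] && bits[4] && bits[5]))
      "negative"
    else {
      nweak <- bits[6] + bits[7] + bits[8]
      if (nweak == 0) "definite" else if (nweak == 1) "probable"
      else "possible"
    }
    expect_identical(verdict_from_criteria(cd, wk), expected)
  }
})

test_that("turning on one more weak criterion never upgrades the verdict", {
  rank <- c(definite = 3, probable = 2, possible = 1, negative = 0)
  cd <- list(c1 = TRUE, c2 = TRUE, c3 = TRUE, c4 = TRUE, c5 = TRUE)
  for (mask in 0:7) {
    w <- as.logical(bitwAnd(mask, 2^(0:2)) > 0)
    base <- verdict_from_criteria(cd, list(w1 = w[1], w2 = w[2], w3 = w[3]))
    for (j in 1:3) {
      if (w[j]) next
      w2 <- w; w2[j] <- TRUE
      up <- verdict_from_criteria(cd, list(w1 = w2[1], w2 = w2[2],
                                           w3 = w2[3]))
      expect_lte(rank[up], rank[base])
    }
  }
})

test_that("aggregation unions findings and keeps conflicting laterality", {
  f1 <- list(anatomic = anat_row(lat = "left"), temporal = temp_row(2, 60),
             causal = causal_row())
  f2 <- list(anatomic = anat_row(lat = "right", mid = 2L),
             temporal = NULL, causal = NULL)
  ev <- aggregate_findings(ev_event(), list(f1, f2), full_codes)
  expect_equal(nrow(ev$anatomic), 2L)
  expect_setequal(ev$anatomic$laterality, c("left", "right"))
  # findings outside the ascertainment window are dropped
  late <- list(anatomic = anat_row(day = 300L), temporal = NULL,
               causal = NULL)
  ev2 <- aggregate_findings(ev_event(), list(late), full_codes)
  expect_equal(nrow(ev2$anatomic), 0L)
  # empty evidence classifies negative
  ev3 <- aggregate_findings(ev_event(), list(), NULL)
  expect_equal(classify_case(ev3)$verdict, "negative")
})

test_that("adding a negated-only note never changes a verdict", {
  pop <- generate_population(list(scenario_spec("definite", 2),
                                  scenario_spec("probable_w2", 2),
                                  scenario_spec("negative_negated", 2)),
                             seed = 23)
  res1 <- run_pipeline(pop$vaccinations, pop$encounters, pop$diagnoses,
                       pop$membership, pop$notes)
  extra <- lapply(unique(pop$truth$patient_id), function(p) {
    idx <- as.Date(pop$truth$index_date[pop$truth$patient_id == p][1])
    clinical_note(paste0(p, "-NEG"), p,
                  as.POSIXct(paste(format(idx + 70), "10:00:00"),
                             tz = "UTC"),
                  "Denies any injury or trauma. No numbness or weakness.")
  })
  res2 <- run_pipeline(pop$vaccinations, pop$encounters, pop$diagnoses,
                       pop$membership, c(pop$notes, extra))
  v1 <- setNames(res1$cases$verdict, res1$cases$patient_id)
  v2 <- setNames(res2$cases$verdict, res2$cases$patient_id)
  expect_identical(v1, v2[names(v1)])
})
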