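test_that("section detection labels headers and tiles the note", {
  s <- detect_sections("HPI: pain.\nPAST MEDICAL HISTORY: diabetes.")
  expect_equal(s$label, c("hpi", "past medical history"))
  expect_equal(s$start[1], 0L)
  expect_equal(s$start[2], s$end[1])
  s2 <- detect_sections("just some text with no headers at all")
  expect_equal(s2$label, "UNLABELED")
  s3 <- detect_sections("Plan:\nPlan:\n")
  expect_equal(s3$label, c("plan", "plan"))
  expect_equal(s3$start[1], 0L)
  expect_equal(s3$start[2], s3$end[1])
  expect_equal(s3$end[2], nchar("Plan:\nPlan:\n"))
  # text before the first header is UNLABELED
  s4 <- detect_sections("note intro line\nASSESSMENT: doing well")
  expect_equal(s4$label, c("UNLABELED", "assessment"))
})

test_that("sentence segmentation protects clinical abbreviations", {
  txt <- "States experiencing pain x 1 month s/p flu vaccine."
  expect_equal(nrow(segment_sentences(txt)), 1L)
  expect_equal(nrow(segment_sentences("Pain for 2 weeks. Denies trauma.")),
               2L)
  expect_equal(nrow(segment_sentences("")), 0L)
  expect_equal(nrow(segment_sentences("   ")), 0L)
  # abbreviation and decimal guards
  expect_equal(nrow(segment_sentences("Seen by Dr. Smith today.")), 1L)
  expect_equal(nrow(segment_sentences("Dose was 2.5 mg daily.")), 1L)
  # newline followed by a capitalized token starts a sentence
  expect_equal(nrow(segment_sentences("pain in arm\nDenies trauma")), 2L)
})

test_that("tokenization preserves clinical shorthand with exact offsets", {
  t1 <- tokenize("left arm pain x 1 month")
  expect_equal(nrow(t1), 6L)
  expect_true(all(t1$is_word))
  t2 <- tokenize("s/p flu vaccine")
  expect_equal(nrow(t2), 3L)
  expect_equal(t2$surface[1], "s/p")
  expect_equal(nrow(tokenize("")), 0L)
  # offsets slice back to the surfaces
  txt <- "b/l shoulders hurt; x-ray negative."
  tt <- tokenize(txt)
  expect_equal(substring(txt, tt$start + 1, tt$end), tt$surface)
  expect_true("x-ray" %in% tt$surface)
  expect_false(tt$is_word[tt$surface == ";"])
})

test_that("index_note composes the full stack deterministically", {
  ix <- index_text("Patient has persistent pain in his left arm.")
  got <- ix$mentions[ix$mentions$class %in%
                       c("shoulder_symptom", "laterality", "body_location"), ]
  expect_setequal(got$class,
                  c("shoulder_symptom", "laterality", "body_location"))
  expect_false(any(got$negated | got$uncertain | got$hypothetical))
  # empty note
  ix0 <- index_text("")
  expect_equal(nrow(ix0$sentences), 0L)
  expect_equal(nrow(ix0$mentions), 0L)
  # sentence spans nest in sections; token spans nest in sentences
  ix2 <- index_text("HPI: Left shoulder pain. Denies trauma.\nPLAN: rest.")
  for (j in seq_len(nrow(ix2$sentences))) {
    sec <- ix2$sections[ix2$sections$label ==
                          ix2$sentences$section_label[j], ]
    expect_true(any(ix2$sentences$start[j] >= sec$start &
                      ix2$sentences$end[j] <= sec$end))
  }
  tok <- ix2$tokens
  sen <- ix2$sentences
  expect_true(all(tok$start >= sen$start[match(tok$sentence_index,
                                               sen$index)]))
  expect_true(all(tok$end <= sen$end[match(tok$sentence_index, sen$index)]))
})

test_that("indexing a note batch twice is byte-identical", {
  set.seed(21)
  specs <- list(scenario_spec("definite", 4),
                scenario_spec("negative_negated", 4))
  pop <- generate_population(specs, seed = 5)
  ser <- function() {
    cl <- compile_lexicon(default_lexicon())
    paste(vapply(pop$notes, function(nt) {
      ix <- index_note(nt, cl)
      jsonlite::toJSON(list(ix$sections, ix$sentences, ix$mentions))
    }, character(1)), collapse = "\n")
  }
  expect_identical(ser(), ser())
})

test_that("mention surfaces recover a lexicon variant via their spans", {
  lex <- default_lexicon()
  variants_of <- new.env()
  for (e in lex$entries)
    assign(e$entry_id, lc(c(e$canonical, e$variants)), envir = variants_of)
  pop <- generate_population(list(scenario_spec("definite", 3),
                                  scenario_spec("probable_w1", 3)), seed = 3)
  for (nt in pop$notes) {
    ix <- index_note(nt, lex)
    m <- ix$mentions
    for (i in seq_len(nrow(m))) {
      surf <- lc(substr(nt$text, m$start[i] + 1, m$end[i]))
      expect_true(surf %in% get(m$entry_id[i], envir = variants_of))
    }
  }
})

test_that("NegEx scoping flags targets forward within the sentence", {
  ix <- index_text("Denies any injury.")
  inj <- ix$mentions[ix$mentions$class == "cause_accident", ]
  expect_true(all(inj$negated))
  ix2 <- index_text("No injury or trauma.")
  inj2 <- ix2$mentions[ix2$mentions$class == "cause_accident", ]
  expect_equal(nrow(inj2), 2L)
  expect_true(all(inj2$negated))
})

test_that("cue scope never crosses a sentence boundary", {
  ix <- index_text("Patient denies trauma. Reports a fall last week.")
  m <- ix$mentions
  expect_true(m$negated[m$class == "cause_accident" &
                          m$sentence_index == 0])
  expect_false(any(m$negated[m$sentence_index == 1]))
})

test_that("a termination cue blocks the negation scope", {
  ix <- index_text("No injury but reports pain today.")
  m <- ix$mentions
  expect_true(all(m$negated[m$class == "cause_accident"]))
  expect_false(any(m$negated[m$class == "shoulder_symptom"]))
})

test_that("uncertainty and hypothetical cues set their own flags", {
  m <- index_text("Possible bursitis of the shoulder.")$mentions
  expect_true(all(m$uncertain[m$class == "shoulder_diagnosis"]))
  expect_false(any(m$negated))
  m2 <- index_text("Return if pain worsens.")$mentions
  expect_true(all(m2$hypothetical[m2$class == "shoulder_symptom"]))
})

test_that("apply_context is idempotent", {
  ix <- index_text("Denies any injury or trauma but reports pain.")
  again <- apply_context(ix)
  expect_identical(ix$mentions, again$mentions)
})

test_that("notes round-trip through JSON-lines", {
  notes <- list(note_of("Left arm pain.", id = "a", pid = "p1"),
                note_of("", id = "b", pid = "p2"))
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_notes_jsonl(notes, path)
  back <- read_notes_jsonl(path)
  expect_equal(length(back), 2L)
  expect_equal(back[[1]]$text, notes[[1]]$text)
  expect_equal(back[[2]]$note_id, "b")
})
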