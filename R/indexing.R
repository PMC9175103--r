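# Note indexing: section detection, sentence segmentation, tokenization,
# concept matching and NegEx-style context scoping. All character offsets
# are 0-based, half-open.

#' Construct a clinical note record
#'
#' @param note_id,patient_id opaque identifiers
#' @param note_datetime note creation date-time (ISO-8601 string or
#'   POSIXct/Date)
#' @param text free text (may be empty)
#' @return a `clinical_note` list
#' @export
clinical_note <- function(note_id, patient_id, note_datetime, text) {
  dt <- if (inherits(note_datetime, c("POSIXct", "Date"))) note_datetime
        else as.POSIXct(note_datetime, tz = "UTC",
                        tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                                       "%Y-%m-%d"))
  if (is.na(dt)) stop("note ", note_id, ": unparseable note_datetime")
  structure(list(note_id = as.character(note_id),
                 patient_id = as.character(patient_id),
                 note_datetime = dt, text = as.character(text)),
            class = "clinical_note")
}

# Core tokenizer: alphanumeric runs, keeping intra-token "/", "-" and "'"
# so clinical shorthand ("s/p", "b/l", "x-ray") stays whole; any other
# non-space character is its own token.
tokenize_text <- function(text) {
  if (is.na(text) || !nzchar(text))
    return(data.frame(surface = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  pat <- "[A-Za-z0-9]+(?:['/-][A-Za-z0-9]+)*|[^A-Za-z0-9[:space:]]"
  m <- gregexpr(pat, text, perl = TRUE)[[1]]
  if (m[1] == -1)
    return(data.frame(surface = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  len <- attr(m, "match.length")
  data.frame(surface = substring(text, m, m + len - 1L),
             start = as.integer(m - 1L), end = as.integer(m + len - 1L),
             stringsAsFactors = FALSE)
}

#' Tokenize text into word and punctuation tokens
#'
#' Whitespace/punctuation tokenization that preserves intra-token "/", "-"
#' and apostrophes so clinical shorthand ("s/p", "b/l", "x-ray") survives as
#' single tokens. Offsets are exact against the source text (0-based,
#' half-open).
#'
#' @param text character scalar
#' @return data frame with columns `surface`, `start`, `end`, `is_word`
#' @export
tokenize <- function(text) {
  toks <- tokenize_text(text)
  toks$is_word <- grepl("^[A-Za-z0-9]", toks$surface)
  toks
}

#' Detect note sections
#'
#' A section starts at each header line — a line whose leading text ends in
#' ":" and is either a known header (the `section_header` lexicon class),
#' all-caps, or a single capitalized word — or an all-caps line without a
#' colon. Each section runs to the next header or end of text; text before
#' the first header is labeled `"UNLABELED"`. Sections tile the note.
#'
#' @param text note text
#' @param headers lexicon supplying `section_header` entries (default
#'   shipped lexicon)
#' @return data frame `label`, `start`, `end`
#' @export
detect_sections <- function(text, headers = default_lexicon()) {
  n <- nchar(text)
  empty <- data.frame(label = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
  if (n == 0L) return(rbind(empty,
    data.frame(label = "UNLABELED", start = 0L, end = 0L,
               stringsAsFactors = FALSE))[0, ])
  known <- lc(unlist(lapply(lexicon_entries(headers, "section_header"),
                            function(e) c(e$canonical, e$variants))))
  # line starts
  nl <- c(0L, gregexpr("\n", text, fixed = TRUE)[[1]])
  if (length(nl) > 1L || nl[1] != -1) {
    starts <- if (identical(nl, c(0L, -1L))) 0L else c(0L, nl[-1])
  } else starts <- 0L
  starts <- unique(as.integer(starts))
  hdr_start <- integer(); hdr_label <- character()
  for (s in starts) {
    lend <- regexpr("\n", substr(text, s + 1L, n), fixed = TRUE)
    le <- if (lend == -1) n else s + as.integer(lend) - 1L
    line <- span_text(text, s, le)
    if (!nzchar(trimws(line))) next
    cm <- regexpr("^\\s*([A-Za-z][A-Za-z0-9 /&-]{0,60}):", line, perl = TRUE)
    lab <- NA_character_
    if (cm != -1) {
      pre <- sub(":.*$", "", trimws(sub("\\s*$", "", regmatches(line, cm))))
      pre <- trimws(pre)
      ok <- lc(pre) %in% known ||
        (pre == toupper(pre) && grepl("[A-Z]", pre)) ||
        (!grepl("\\s", pre) && grepl("^[A-Z]", pre) && nchar(pre) <= 15)
      if (ok) lab <- lc(pre)
    } else if (grepl("^[A-Z][A-Z /&-]*$", trimws(line)) &&
               nchar(trimws(line)) >= 3) {
      lab <- lc(trimws(line))
    }
    if (!is.na(lab)) { hdr_start <- c(hdr_start, s); hdr_label <- c(hdr_label, lab) }
  }
  if (!length(hdr_start))
    return(data.frame(label = "UNLABELED", start = 0L, end = n,
                      stringsAsFactors = FALSE))
  secs <- empty
  if (hdr_start[1] > 0L)
    secs <- rbind(secs, data.frame(label = "UNLABELED", start = 0L,
                                   end = hdr_start[1], stringsAsFactors = FALSE))
  ends <- c(hdr_start[-1], n)
  secs <- rbind(secs, data.frame(label = hdr_label, start = hdr_start,
                                 end = ends, stringsAsFactors = FALSE))
  rownames(secs) <- NULL
  secs
}

#' Segment a section of text into sentences
#'
#' Splits on sentence-final punctuation (`.`, `!`, `?`) followed by
#' whitespace, and on a newline followed by a capitalized token or bullet.
#' A period after a configured abbreviation ("Dr.", "hx.") or inside a
#' decimal number never splits. Clinical notes often lack final periods, so
#' the newline rule carries much of the load.
#'
#' @param text full note text
#' @param start,end 0-based half-open section bounds (default: all of text)
#' @param abbrev abbreviation list protected from splitting (lowercase,
#'   without the trailing period)
#' @return data frame `start`, `end` of trimmed sentence spans, in order
#' @export
segment_sentences <- function(text, start = 0L, end = nchar(text),
                              abbrev = default_config()$sentence_abbrev) {
  s <- span_text(text, start, end)
  n <- nchar(s)
  if (!nzchar(trimws(s)))
    return(data.frame(start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  chars <- strsplit(s, "")[[1]]
  breaks <- integer()  # position AFTER which a new sentence begins (1-based)
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch %in% c(".", "!", "?")) {
      nxt <- if (i < n) chars[i + 1L] else " "
      if (grepl("[[:space:]]", nxt) || i == n) {
        # protect decimals (digit.digit handled by nxt check) and abbrevs
        prev_word <- sub(".*?([A-Za-z/]+)$", "\\1",
                         substr(s, max(1L, i - 12L), i - 1L))
        if (!(lc(prev_word) %in% abbrev)) breaks <- c(breaks, i)
      }
    } else if (ch == "\n") {
      rest <- substr(s, i + 1L, n)
      nxt_char <- sub("^[ \t\n]*", "", rest)
      if (nzchar(nxt_char)) {
        c1 <- substr(nxt_char, 1L, 1L)
        if (grepl("[A-Z]", c1) || c1 %in% c("-", "*", "•"))
          breaks <- c(breaks, i)
      }
    }
    i <- i + 1L
  }
  cuts <- unique(c(0L, breaks, n))
  cuts <- sort(cuts)
  out <- list(); k <- 0L
  for (j in seq_len(length(cuts) - 1L)) {
    a <- cuts[j]; b <- cuts[j + 1L]
    piece <- substr(s, a + 1L, b)
    lead <- nchar(piece) - nchar(sub("^[[:space:]]+", "", piece))
    trail <- nchar(piece) - nchar(sub("[[:space:]]+$", "", piece))
    a2 <- a + lead; b2 <- b - trail
    if (b2 > a2) {
      k <- k + 1L
      out[[k]] <- data.frame(start = start + a2, end = start + b2,
                             stringsAsFactors = FALSE)
    }
  }
  if (!k) return(data.frame(start = integer(), end = integer(),
                            stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Index a clinical note
#'
#' Composes section detection, sentence segmentation, tokenization, concept
#' matching and context scoping into an `indexed_note`: the substrate for
#' relation search. Deterministic for fixed inputs.
#'
#' @param note a [clinical_note()]
#' @param lexicon a `sirva_lexicon` (or a precompiled one from
#'   `compile_lexicon`); also supplies section headers and context cues
#' @param config pipeline configuration
#' @return an `indexed_note`: list of `note`, `sections`, `sentences`
#'   (`index`, `start`, `end`, `section_label`), `tokens` (with
#'   `sentence_index`, `word_ordinal`) and `mentions`
#' @export
index_note <- function(note, lexicon = default_lexicon(),
                       config = default_config()) {
  text <- note$text
  if (!is.character(text) || length(text) != 1L || is.na(text))
    stop("note ", note$note_id, ": text is not decodable character data")
  lex <- if (inherits(lexicon, "compiled_lexicon")) lexicon$source else lexicon
  cl <- if (inherits(lexicon, "compiled_lexicon")) lexicon
        else compile_lexicon(lexicon)
  sections <- detect_sections(text, lex %||% default_lexicon())
  sent_list <- list()
  for (i in seq_len(nrow(sections))) {
    ss <- segment_sentences(text, sections$start[i], sections$end[i],
                            config$sentence_abbrev)
    if (nrow(ss)) {
      ss$section_label <- sections$label[i]
      sent_list[[length(sent_list) + 1L]] <- ss
    }
  }
  sentences <- if (length(sent_list)) do.call(rbind, sent_list) else
    data.frame(start = integer(), end = integer(),
               section_label = character(), stringsAsFactors = FALSE)
  sentences <- sentences[order(sentences$start), , drop = FALSE]
  sentences$index <- seq_len(nrow(sentences)) - 1L
  rownames(sentences) <- NULL

  tokens <- tokenize(text)
  if (nrow(tokens)) {
    si <- rep(NA_integer_, nrow(tokens))
    for (j in seq_len(nrow(sentences))) {
      inside <- tokens$start >= sentences$start[j] &
        tokens$end <= sentences$end[j]
      si[inside] <- sentences$index[j]
    }
    tokens$sentence_index <- si
    tokens <- tokens[!is.na(tokens$sentence_index), , drop = FALSE]
    rownames(tokens) <- NULL
    tokens$word_ordinal <- cumsum(tokens$is_word) - 1L
    tokens$word_ordinal[!tokens$is_word] <- NA_integer_
  } else {
    tokens$sentence_index <- integer()
    tokens$word_ordinal <- integer()
  }
  mentions <- match_concepts(tokens, cl)
  idx <- structure(list(note = note, sections = sections,
                        sentences = sentences, tokens = tokens,
                        mentions = mentions),
                   class = "indexed_note")
  apply_context(idx, config = config)
}

#' @export
print.indexed_note <- function(x, ...) {
  cat("<indexed_note>", x$note$note_id, "-", nrow(x$sections), "sections,",
      nrow(x$sentences), "sentences,", nrow(x$tokens), "tokens,",
      nrow(x$mentions), "mentions\n")
  invisible(x)
}

# classes whose mentions receive context flags
FINDING_CLASSES <- c("shoulder_symptom", "shoulder_diagnosis", "vaccine",
                     "cause_accident", "cause_work",
                     "cause_medical_condition", "cause_exercise",
                     "cause_daily_activity", "cause_unknown")

#' Apply NegEx-style context flags to an indexed note
#'
#' Pre-cues ("denies", "no", "without") flag clinical-finding mentions
#' forward within the same sentence, up to a termination cue ("but",
#' "however") or the configured word window; post-cues ("ruled out") flag
#' backward. Uncertainty cues ("possible", "likely") and hypothetical cues
#' ("if", "return if") set their flags the same way. Scope never crosses a
#' sentence boundary. Idempotent: flags are recomputed from scratch.
#'
#' @param indexed an `indexed_note` with mentions attached
#' @param cues lexicon providing cue entries; defaults to the cues already
#'   matched in the note's mentions
#' @param config pipeline configuration (`negation_window`)
#' @return the `indexed_note` with `negated`/`uncertain`/`hypothetical`
#'   flags set on its mentions
#' @export
apply_context <- function(indexed, cues = NULL, config = default_config()) {
  men <- indexed$mentions
  if (!nrow(men)) return(indexed)
  men$negated <- FALSE; men$uncertain <- FALSE; men$hypothetical <- FALSE
  cue_map <- c(negation_cue = "negated", uncertainty_cue = "uncertain",
               hypothetical_cue = "hypothetical")
  term_rows <- which(men$class == "termination_cue")
  targets <- which(men$class %in% FINDING_CLASSES)
  for (ci in which(men$class %in% names(cue_map))) {
    flag <- cue_map[[men$class[ci]]]
    dir <- men$direction[ci] %||% "pre"
    for (ti in targets) {
      if (men$sentence_index[ti] != men$sentence_index[ci]) next
      if (dir == "pre") {
        if (men$tok_from[ti] <= men$tok_to[ci]) next
        between <- seq_len(nrow(indexed$tokens)) > men$tok_to[ci] &
          seq_len(nrow(indexed$tokens)) < men$tok_from[ti]
      } else {
        if (men$tok_to[ti] >= men$tok_from[ci]) next
        between <- seq_len(nrow(indexed$tokens)) > men$tok_to[ti] &
          seq_len(nrow(indexed$tokens)) < men$tok_from[ci]
      }
      gap <- sum(indexed$tokens$is_word[between], na.rm = TRUE)
      if (gap > config$negation_window) next
      # a termination cue between cue and target blocks the scope
      blocked <- FALSE
      for (tr in term_rows) {
        lo <- if (dir == "pre") men$tok_to[ci] else men$tok_to[ti]
        hi <- if (dir == "pre") men$tok_from[ti] else men$tok_from[ci]
        if (men$tok_from[tr] > lo && men$tok_to[tr] < hi) { blocked <- TRUE; break }
      }
      if (blocked) next
      men[[flag]][ti] <- TRUE
    }
  }
  indexed$mentions <- men
  indexed
}

#' Read clinical notes from a JSON-lines file
#'
#' One object per line: `{note_id, patient_id, note_datetime, text}`.
#'
#' @param path file path
#' @return list of [clinical_note()] objects
#' @export
read_notes_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(l) {
    o <- jsonlite::fromJSON(l, simplifyVector = TRUE)
    clinical_note(o$note_id, o$patient_id, o$note_datetime, o$text)
  })
}

#' Write clinical notes to a JSON-lines file
#' @param notes list of [clinical_note()] objects
#' @param path output path
#' @return `path`, invisibly
#' @export
write_notes_jsonl <- function(notes, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (nt in notes) {
    writeLines(jsonlite::toJSON(list(
      note_id = nt$note_id, patient_id = nt$patient_id,
      note_datetime = format(nt$note_datetime, "%Y-%m-%dT%H:%M:%S"),
      text = nt$text), auto_unbox = TRUE), con)
  }
  invisible(path)
}
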