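# Terminology: lexicon containers, validation, variant expansion and
# longest-match concept matching over tokenized note text.

SEMANTIC_CLASSES <- c(
  "shoulder_symptom", "shoulder_diagnosis", "body_location", "laterality",
  "vaccine", "cause_accident", "cause_work", "cause_medical_condition",
  "cause_exercise", "cause_daily_activity", "cause_unknown",
  "causal_trigger", "temporal_cue", "negation_cue", "uncertainty_cue",
  "hypothetical_cue", "termination_cue", "section_header")

# The seven cause types: six cause_* classes plus `vaccine`.
CAUSE_CLASSES <- c("vaccine", "cause_accident", "cause_work",
                   "cause_medical_condition", "cause_exercise",
                   "cause_daily_activity", "cause_unknown")

#' Semantic classes recognized by the concept matcher
#' @return character vector of the closed class enumeration
#' @export
semantic_classes <- function() SEMANTIC_CLASSES

#' Construct a lexicon entry
#'
#' @param entry_id unique identifier
#' @param class one of [semantic_classes()]
#' @param canonical canonical surface form (non-empty)
#' @param variants additional surface forms (unique, non-empty)
#' @param match_policy `"case_insensitive"` (default) or
#'   `"exact_token_sequence"` for forms like the bare "L"/"R" laterality
#'   abbreviations that must match case-sensitively
#' @param direction for context-cue classes: `"pre"` cues scope forward,
#'   `"post"` cues scope backward over preceding mentions
#' @return a `lexicon_entry` list
#' @export
lexicon_entry <- function(entry_id, class, canonical, variants = character(),
                          match_policy = "case_insensitive",
                          direction = "pre") {
  stopifnot(is.character(entry_id), nzchar(entry_id))
  if (!class %in% SEMANTIC_CLASSES)
    stop("unknown semantic class: ", class)
  if (!is.character(canonical) || !nzchar(canonical))
    stop("entry ", entry_id, ": canonical form must be non-empty")
  variants <- as.character(variants)
  if (any(!nzchar(variants)))
    stop("entry ", entry_id, ": empty variant not allowed")
  if (anyDuplicated(variants))
    stop("entry ", entry_id, ": duplicate variants within entry")
  if (!match_policy %in% c("case_insensitive", "exact_token_sequence"))
    stop("entry ", entry_id, ": unknown match_policy ", match_policy)
  structure(list(entry_id = entry_id, class = class, canonical = canonical,
                 variants = variants, match_policy = match_policy,
                 direction = direction),
            class = "lexicon_entry")
}

#' Construct and validate a lexicon
#'
#' @param entries list of [lexicon_entry()] objects
#' @param version free-text version tag
#' @return a `sirva_lexicon` object
#' @export
new_lexicon <- function(entries, version = "0") {
  ids <- vapply(entries, `[[`, character(1), "entry_id")
  if (anyDuplicated(ids))
    stop("duplicate entry_id: ", ids[duplicated(ids)][1])
  # no surface form may be claimed by two entries of the same class
  for (cls in unique(vapply(entries, `[[`, character(1), "class"))) {
    es <- entries[vapply(entries, function(e) e$class == cls, logical(1))]
    surf <- lapply(es, function(e) unique(lc(c(e$canonical, e$variants))))
    flat <- unlist(surf)
    dup <- unique(flat[duplicated(flat)])
    if (length(dup)) {
      owners <- vapply(es, function(e)
        any(dup[1] %in% lc(c(e$canonical, e$variants))), logical(1))
      ids2 <- vapply(es[owners], `[[`, character(1), "entry_id")
      stop("surface form '", dup[1], "' duplicated in class ", cls,
           " across entries ", paste(ids2, collapse = ", "))
    }
  }
  structure(list(entries = entries, version = version),
            class = "sirva_lexicon")
}

#' @export
print.sirva_lexicon <- function(x, ...) {
  cls <- vapply(x$entries, `[[`, character(1), "class")
  cat("<sirva_lexicon> version", x$version, "-", length(x$entries),
      "entries across", length(unique(cls)), "classes\n")
  print(table(cls))
  invisible(x)
}

#' Entries of one semantic class
#' @param lexicon a `sirva_lexicon`
#' @param class semantic class name
#' @return list of entries
#' @export
lexicon_entries <- function(lexicon, class) {
  lexicon$entries[vapply(lexicon$entries, function(e) e$class == class,
                         logical(1))]
}

#' Load a lexicon from its JSON file format
#'
#' The file is a JSON array of objects `{id, class, canonical, variants[],
#' match_policy, direction}`; `match_policy` and `direction` are optional.
#' Validation rejects unknown classes, empty forms, and any surface form
#' claimed by two entries of the same class.
#'
#' @param path path to the JSON lexicon
#' @param version version tag recorded on the lexicon (defaults to a
#'   `version` attribute in the file when present)
#' @return a `sirva_lexicon`
#' @export
load_lexicon <- function(path, version = NULL) {
  if (!file.exists(path)) stop("lexicon file not found: ", path)
  raw <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e)
                    stop("failed to parse lexicon file ", path, ": ",
                         conditionMessage(e), call. = FALSE))
  if (!is.null(raw$entries)) {
    version <- version %||% raw$version
    raw <- raw$entries
  }
  entries <- lapply(raw, function(o) {
    if (is.null(o$id) || is.null(o$class) || is.null(o$canonical))
      stop("lexicon entry missing required field (id/class/canonical)")
    lexicon_entry(o$id, o$class, o$canonical,
                  vapply(o$variants %||% list(), identity, character(1)),
                  o$match_policy %||% "case_insensitive",
                  o$direction %||% "pre")
  })
  new_lexicon(entries, version = version %||% "0")
}

#' Serialize a lexicon to its JSON file format
#' @param lexicon a `sirva_lexicon`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_lexicon <- function(lexicon, path) {
  obj <- list(
    version = lexicon$version,
    entries = lapply(lexicon$entries, function(e)
      list(id = e$entry_id, class = e$class, canonical = e$canonical,
           variants = as.list(e$variants), match_policy = e$match_policy,
           direction = e$direction)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

.lexicon_cache <- new.env(parent = emptyenv())

#' The shipped default lexicon
#'
#' An editable reconstruction of the terminologies the pipeline needs:
#' shoulder symptoms and diagnoses, body locations, laterality, vaccine
#' names, the six non-vaccination cause classes, 70+ causal trigger terms,
#' temporal cues, context cues and section headers. It is a documented
#' default, not a reproduction of any proprietary word list.
#'
#' @return a `sirva_lexicon`
#' @export
default_lexicon <- function() {
  if (is.null(.lexicon_cache$default)) {
    path <- system.file("extdata", "lexicon_default.json",
                        package = "sirvanlp")
    if (!nzchar(path)) path <- file.path("inst", "extdata",
                                         "lexicon_default.json")
    .lexicon_cache$default <- load_lexicon(path)
  }
  .lexicon_cache$default
}

#' Rule-based variant expansion for one entry
#'
#' Adds morphological variants (plural/singular, -ed/-ing) for single-word
#' alphabetic forms, and, at `max_edit_distance = 1`, single-character
#' deletion typos. Forms shorter than 4 characters are never used as a stem
#' and never generated, so short tokens like "flu" pass through unchanged.
#'
#' @param entry a [lexicon_entry()]
#' @param max_edit_distance 0 (morphology only) or 1 (adds deletion typos)
#' @return the entry with its variant list extended
#' @export
expand_variants <- function(entry, max_edit_distance = 0) {
  stopifnot(max_edit_distance %in% c(0L, 1L))
  base <- unique(c(entry$canonical, entry$variants))
  stems <- base[grepl("^[A-Za-z]+$", base) & nchar(base) >= 4]
  gen <- character()
  for (w in stems) {
    wl <- lc(w)
    # plural
    if (grepl("[^aeiou]y$", wl)) gen <- c(gen, sub("y$", "ies", wl))
    else if (grepl("(s|x|z|ch|sh)$", wl)) gen <- c(gen, paste0(wl, "es"))
    else if (!grepl("s$", wl)) gen <- c(gen, paste0(wl, "s"))
    # singular back-forms
    if (grepl("ies$", wl)) gen <- c(gen, sub("ies$", "y", wl))
    else if (grepl("(ses|xes|zes|ches|shes)$", wl)) gen <- c(gen, sub("es$", "", wl))
    else if (grepl("[^su]s$", wl)) gen <- c(gen, sub("s$", "", wl))
    # verbal suffixes
    if (grepl("e$", wl)) gen <- c(gen, paste0(wl, "d"),
                                  paste0(sub("e$", "", wl), "ing"))
    else gen <- c(gen, paste0(wl, "ed"), paste0(wl, "ing"))
    if (max_edit_distance >= 1L) {
      dels <- vapply(seq_len(nchar(wl)), function(i)
        paste0(substr(wl, 1, i - 1), substr(wl, i + 1, nchar(wl))),
        character(1))
      gen <- c(gen, dels)
    }
  }
  gen <- unique(gen[nchar(gen) >= 4])
  gen <- setdiff(gen, lc(base))
  entry$variants <- unique(c(entry$variants, gen))
  entry
}

#' Precompile a lexicon for batch matching
#'
#' Expands every entry into a token-sequence match table (one row per
#' surface form, lowercased unless the entry is exact-match) indexed by
#' first token. [index_note()] and [match_concepts()] accept the compiled
#' form directly; precompiling once before indexing a note batch avoids
#' recompiling per note.
#'
#' @param lexicon a `sirva_lexicon`
#' @return a `compiled_lexicon`
#' @export
compile_lexicon <- function(lexicon) {
  rows <- list()
  k <- 0L
  for (e in lexicon$entries) {
    for (v in unique(c(e$canonical, e$variants))) {
      toks <- tokenize_text(v)$surface
      if (!length(toks)) next
      exact <- identical(e$match_policy, "exact_token_sequence")
      k <- k + 1L
      rows[[k]] <- list(entry_id = e$entry_id, class = e$class,
                        toks = if (exact) toks else lc(toks),
                        n = length(toks), exact = exact,
                        direction = e$direction)
    }
  }
  first <- vapply(rows, function(r) r$toks[1], character(1))
  structure(list(rows = rows, by_first = split(seq_along(rows), first),
                 source = lexicon),
            class = "compiled_lexicon")
}

#' Match lexicon concepts over a token sequence
#'
#' Longest-match, left-to-right: at each token position the longest matching
#' surface form wins and matching resumes after it, so a multiword entry
#' ("rotator cuff tear") suppresses its parts. When several classes share
#' the same longest surface form (e.g. "since" as both causal trigger and
#' temporal cue), one mention per class is returned for that span. A
#' single-letter laterality abbreviation matched under the exact policy is
#' kept only when adjacent to a body-location mention.
#'
#' @param tokens token data frame from [tokenize()] (columns `surface`,
#'   `start`, `end`, `sentence_index`, `is_word`, `word_ordinal`)
#' @param lexicon a `sirva_lexicon` or precompiled lexicon
#' @return a data frame of mentions: `entry_id`, `class`, `start`, `end`,
#'   `sentence_index`, `tok_from`, `tok_to`, and logical context flags
#'   `negated`, `uncertain`, `hypothetical` (all `FALSE` here)
#' @export
match_concepts <- function(tokens, lexicon) {
  cl <- if (inherits(lexicon, "compiled_lexicon")) lexicon
        else compile_lexicon(lexicon)
  n <- nrow(tokens)
  out <- list(); m <- 0L
  if (n > 0L) {
    surf_lc <- lc(tokens$surface)
    i <- 1L
    while (i <= n) {
      cand_ids <- c(cl$by_first[[surf_lc[i]]], cl$by_first[[tokens$surface[i]]])
      best_len <- 0L; best <- list()
      for (ri in unique(cand_ids)) {
        r <- cl$rows[[ri]]
        j <- i + r$n - 1L
        if (j > n) next
        if (tokens$sentence_index[j] != tokens$sentence_index[i]) next
        seg <- if (r$exact) tokens$surface[i:j] else surf_lc[i:j]
        if (!identical(unname(seg), unname(r$toks))) next
        if (r$n > best_len) { best_len <- r$n; best <- list(r) }
        else if (r$n == best_len) best <- c(best, list(r))
      }
      if (best_len > 0L) {
        j <- i + best_len - 1L
        seen_cls <- character()
        for (r in best) {
          if (r$class %in% seen_cls) next
          seen_cls <- c(seen_cls, r$class)
          m <- m + 1L
          out[[m]] <- data.frame(
            entry_id = r$entry_id, class = r$class,
            start = tokens$start[i], end = tokens$end[j],
            sentence_index = tokens$sentence_index[i],
            tok_from = i, tok_to = j, direction = r$direction,
            stringsAsFactors = FALSE)
        }
        i <- j + 1L
      } else i <- i + 1L
    }
  }
  mentions <- if (m) do.call(rbind, out) else
    data.frame(entry_id = character(), class = character(),
               start = integer(), end = integer(),
               sentence_index = integer(), tok_from = integer(),
               tok_to = integer(), direction = character(),
               stringsAsFactors = FALSE)
  # single-letter exact laterality must sit next to a body location
  if (nrow(mentions)) {
    short_lat <- mentions$class == "laterality" &
      (mentions$end - mentions$start) == 1L
    if (any(short_lat)) {
      keep <- !short_lat
      body_toks <- unlist(mapply(
        function(a, b) a:b,
        mentions$tok_from[mentions$class == "body_location"],
        mentions$tok_to[mentions$class == "body_location"],
        SIMPLIFY = FALSE))
      for (r in which(short_lat)) {
        if ((mentions$tok_from[r] - 1L) %in% body_toks ||
            (mentions$tok_to[r] + 1L) %in% body_toks)
          keep[r] <- TRUE
      }
      mentions <- mentions[keep, , drop = FALSE]
      rownames(mentions) <- NULL
    }
  }
  mentions$negated <- logical(nrow(mentions))
  mentions$uncertain <- logical(nrow(mentions))
  mentions$hypothetical <- logical(nrow(mentions))
  mentions
}
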