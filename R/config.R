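#' Default pipeline configuration
#'
#' Central knobs for the indexing, relation-search, extraction and
#' classification stages. All windows are counted in the unit named by the
#' parameter; day offsets are calendar days from the vaccination index date
#' (day 0).
#'
#' @details
#' * `cross_sentence_span` / `cross_sentence_words` — the cross-sentence
#'   relation search covers at most this many consecutive sentences, with at
#'   most this many word tokens between consecutive matched items (defaults
#'   4 sentences / 50 words).
#' * `negation_window` — NegEx-style cue scope: number of word tokens after
#'   (or before, for backward cues) the cue that a context flag reaches,
#'   within the sentence.
#' * `anatomic_window` — max word-token distance between an injury mention
#'   and the laterality/body-location mention attached to it.
#' * `month_days` / `year_days` — calendar conversions used when normalizing
#'   duration expressions ("2 months" = 60 days).
#' * `strict_anatomy` — when TRUE, a cross-sentence causal match is dropped
#'   if the sentence holding the cause contains its own injury mention whose
#'   body location is outside the shoulder region (the cause is taken to
#'   attach to that local injury instead).
#' * `bilateral_matches_arm` — whether a bilateral injury statement
#'   satisfies the same-arm criterion.
#' * `require_same_section` — whether cross-sentence relation search may
#'   cross section boundaries.
#' * `onset_window_days` — symptom onset must fall within `[0, 7]` days of
#'   vaccination for the case definition.
#' * `min_duration_days` — symptoms must persist beyond this many days
#'   post-vaccination (30).
#' * `late_attribution_days` — a vaccination-cause statement found only in
#'   notes dated at most this many days post-vaccination (30) counts as weak
#'   evidence.
#'
#' @return a named list of configuration values
#' @export
default_config <- function() {
  list(
    cross_sentence_span   = 4L,
    cross_sentence_words  = 50L,
    nested_cause_words    = 2L,
    negation_window       = 5L,
    anatomic_window       = 8L,
    month_days            = 30L,
    year_days             = 365L,
    strict_anatomy        = TRUE,
    bilateral_matches_arm = TRUE,
    require_same_section  = TRUE,
    onset_window_days     = 7L,
    min_duration_days     = 30L,
    late_attribution_days = 30L,
    ascertainment_days    = 180L,
    shoulder_region       = c("shoulder", "shoulders", "arm", "arms",
                              "upper arm", "deltoid", "rotator cuff",
                              "humerus", "ac joint", "glenohumeral joint"),
    sentence_abbrev       = c("dr", "mr", "mrs", "ms", "hx", "fx", "rx",
                              "tx", "pt", "approx", "vs", "no", "eg", "ie",
                              "etc", "wk", "mo", "yr"),
    vaccine_products      = c(
      "flu" = "influenza", "flu shot" = "influenza",
      "flu vaccine" = "influenza", "influenza" = "influenza",
      "tdap" = "tdap", "td" = "tdap", "tetanus" = "tdap",
      "zoster" = "zoster", "shingles" = "zoster", "shingrix" = "zoster",
      "zostavax" = "zoster",
      "pneumococcal" = "pneumococcal", "pneumonia" = "pneumococcal",
      "prevnar" = "pneumococcal", "pneumovax" = "pneumococcal",
      "hepatitis a" = "hepatitis_a", "hepatitis b" = "hepatitis_b",
      "hpv" = "hpv", "gardasil" = "hpv",
      "mmr" = "mmr", "meningococcal" = "meningococcal")
  )
}

#' Normalize a free-text vaccine mention to a product family
#'
#' Maps note phrasings ("flu shot", "shingrix") onto structured-file product
#' names so that a note/file mismatch can be detected. Generic words
#' ("vaccine", "shot", "immunization") normalize to `NA`: they name no
#' specific product, so they can never mismatch.
#'
#' @param name character vector of vaccine phrases
#' @param config pipeline configuration (for the product table)
#' @return character vector of product families, `NA` where generic/unknown
#' @export
normalize_vaccine_name <- function(name, config = default_config()) {
  tab <- config$vaccine_products
  out <- rep(NA_character_, length(name))
  x <- lc(trimws(name))
  for (i in seq_along(x)) {
    if (is.na(x[i]) || !nzchar(x[i])) next
    if (!is.na(tab[x[i]])) { out[i] <- unname(tab[x[i]]); next }
    # fall back to the longest product key contained in the phrase
    keys <- names(tab)[order(-nchar(names(tab)))]
    hit <- keys[vapply(keys, function(k)
      grepl(paste0("\\b", k, "\\b"), x[i], fixed = FALSE), logical(1))]
    if (length(hit)) out[i] <- unname(tab[hit[1]])
  }
  out
}
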