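# Temporal expression normalization: maps phrases like "for 2 months",
# "since last Thursday", "3 weeks ago" or partial dates onto an onset date
# and/or a duration in days, anchored on the note creation date.

NUMBER_WORDS <- c(a = 1, an = 1, one = 1, two = 2, three = 3, four = 4,
                  five = 5, six = 6, seven = 7, eight = 8, nine = 9,
                  ten = 10, eleven = 11, twelve = 12,
                  couple = 2, few = 3, several = 3)

parse_count <- function(w) {
  w <- lc(trimws(w))
  w <- sub("^a\\s+", "", w)
  w <- sub("\\s+of$", "", w)
  if (grepl("^[0-9]+$", w)) return(as.integer(w))
  v <- NUMBER_WORDS[w]
  if (is.na(v)) NA_integer_ else as.integer(v)
}

unit_days <- function(u, config = default_config()) {
  u <- lc(trimws(u))
  if (grepl("^(d|day|days)$", u)) return(1L)
  if (grepl("^(w|wk|wks|week|weeks)$", u)) return(7L)
  if (grepl("^(mo|mos|month|months)$", u)) return(as.integer(config$month_days))
  if (grepl("^(y|yr|yrs|year|years)$", u)) return(as.integer(config$year_days))
  NA_integer_
}

WEEKDAYS <- c(sunday = 0L, monday = 1L, tuesday = 2L, wednesday = 3L,
              thursday = 4L, friday = 5L, saturday = 6L)
MONTHS <- c(january = 1, february = 2, march = 3, april = 4, may = 5,
            june = 6, july = 7, august = 8, september = 9, october = 10,
            november = 11, december = 12, jan = 1, feb = 2, mar = 3,
            apr = 4, jun = 6, jul = 7, aug = 8, sep = 9, sept = 9,
            oct = 10, nov = 11, dec = 12)

UNIT_RE <- "(d|day|days|w|wk|wks|week|weeks|mo|mos|month|months|y|yr|yrs|year|years)"
NUM_RE <- paste0(
  "((?:a\\s+)?(?:few|couple(?:\\s+of)?|several)|[0-9]+|an?|one|two|three|",
  "four|five|six|seven|eight|nine|ten|eleven|twelve)")

re1 <- function(pattern, x) {
  m <- regexec(pattern, x, ignore.case = TRUE, perl = TRUE)
  g <- regmatches(x, m)[[1]]
  if (!length(g)) NULL else g
}

# year placing (month, day) nearest to anchor; ties -> earlier year
nearest_year_date <- function(month, day, anchor) {
  cand <- suppressWarnings(as.Date(sprintf("%d-%02d-%02d",
    (as.integer(format(anchor, "%Y")) - 1L):(as.integer(format(anchor, "%Y")) + 1L),
    month, day)))
  cand <- cand[!is.na(cand)]
  if (!length(cand)) return(as.Date(NA))
  d <- abs(as.integer(cand - anchor))
  cand[order(d, cand)][1]
}

#' Normalize a temporal expression against a note date
#'
#' Conversions: week = 7 days, month = 30 days, year = 365 days
#' (configurable). "since last Thursday" resolves to the most recent such
#' weekday strictly before the note date; a "month day" date without a year
#' takes the year placing it nearest the note date (ties resolve to the
#' earlier year); "yesterday" is the day before the note date. Duration
#' phrases ("for 2 months") also imply onset = note date - duration. Pure:
#' the same (expression, note_date) always gives the same output.
#'
#' @param expression the matched temporal phrase
#' @param note_date note creation date (`Date` or parseable string)
#' @param config pipeline configuration (calendar conversions)
#' @return list with `onset_date` (`Date` or `NULL`) and `duration_days`
#'   (integer or `NULL`); both `NULL` when the expression is unparseable
#' @export
normalize_temporal <- function(expression, note_date,
                               config = default_config()) {
  nd <- as_date(note_date)
  x <- trimws(expression)
  none <- list(onset_date = NULL, duration_days = NULL)

  # duration anchored by for/over/lasting/x or last/past
  g <- re1(paste0("(?:for|over|lasting|x|\u00d7)\\s+(?:the\\s+)?",
                  "(?:last\\s+|past\\s+)?", NUM_RE, "\\s*", UNIT_RE,
                  "\\b"), x)
  if (is.null(g))
    g <- re1(paste0("(?:the\\s+)?(?:last|past)\\s+", NUM_RE, "\\s*",
                    UNIT_RE, "\\b"), x)
  if (!is.null(g)) {
    n <- parse_count(g[2]); u <- unit_days(g[3], config)
    if (!is.na(n) && !is.na(u)) {
      dur <- n * u
      return(list(onset_date = nd - dur, duration_days = as.integer(dur)))
    }
  }

  g <- re1(paste0("\\b", NUM_RE, "\\s*", UNIT_RE, "\\s+ago\\b"), x)
  if (!is.null(g)) {
    n <- parse_count(g[2]); u <- unit_days(g[3], config)
    if (!is.na(n) && !is.na(u))
      return(list(onset_date = nd - n * u, duration_days = NULL))
  }

  g <- re1(paste0("\\bsince\\s+(?:last\\s+)?(",
                  paste(names(WEEKDAYS), collapse = "|"), ")\\b"), x)
  if (!is.null(g)) {
    wd <- unname(WEEKDAYS[lc(g[2])])
    delta <- (as.POSIXlt(nd)$wday - wd) %% 7L
    if (delta == 0L) delta <- 7L
    return(list(onset_date = nd - delta, duration_days = NULL))
  }

  if (grepl("\\b(since\\s+)?yesterday\\b", x, ignore.case = TRUE))
    return(list(onset_date = nd - 1L, duration_days = NULL))
  if (grepl("\\btoday\\b", x, ignore.case = TRUE))
    return(list(onset_date = nd, duration_days = NULL))

  # month-name dates, year optional
  g <- re1(paste0("\\b(", paste(names(MONTHS), collapse = "|"),
                  ")\\.?\\s+([0-9]{1,2})(?:\\s*,?\\s*([0-9]{4}))?\\b"), x)
  if (!is.null(g)) {
    mo <- MONTHS[lc(g[2])]; dy <- as.integer(g[3])
    if (length(g) >= 4 && nzchar(g[4])) {
      d <- suppressWarnings(as.Date(sprintf("%s-%02d-%02d", g[4], mo, dy)))
      if (!is.na(d)) return(list(onset_date = d, duration_days = NULL))
    } else {
      d <- nearest_year_date(mo, dy, nd)
      if (!is.na(d)) return(list(onset_date = d, duration_days = NULL))
    }
  }

  # numeric dates m/d or m/d/y
  g <- re1("\\b([0-9]{1,2})/([0-9]{1,2})(?:/([0-9]{2,4}))?\\b", x)
  if (!is.null(g)) {
    mo <- as.integer(g[2]); dy <- as.integer(g[3])
    if (mo >= 1 && mo <= 12 && dy >= 1 && dy <= 31) {
      if (length(g) >= 4 && nzchar(g[4])) {
        yr <- as.integer(g[4]); if (yr < 100) yr <- yr + 2000L
        d <- suppressWarnings(as.Date(sprintf("%d-%02d-%02d", yr, mo, dy)))
        if (!is.na(d)) return(list(onset_date = d, duration_days = NULL))
      } else {
        d <- nearest_year_date(mo, dy, nd)
        if (!is.na(d)) return(list(onset_date = d, duration_days = NULL))
      }
    }
  }
  none
}

# All temporal phrases in a piece of text, with their normalizations.
# Returns a data frame (possibly empty): expression, onset_date,
# duration_days.
scan_temporal <- function(text, note_date, config = default_config()) {
  pats <- c(
    paste0("(?:for|over|lasting|x|\u00d7)\\s+(?:the\\s+)?(?:last\\s+|past\\s+)?",
           NUM_RE, "\\s*", UNIT_RE, "\\b"),
    paste0("(?:the\\s+)?(?:last|past)\\s+", NUM_RE, "\\s*", UNIT_RE, "\\b"),
    paste0("\\b", NUM_RE, "\\s*", UNIT_RE, "\\s+ago\\b"),
    paste0("\\bsince\\s+(?:last\\s+)?(?:",
           paste(names(WEEKDAYS), collapse = "|"), ")\\b"),
    "\\bsince\\s+yesterday\\b|\\byesterday\\b|\\btoday\\b",
    paste0("\\b(?:", paste(names(MONTHS), collapse = "|"),
           ")\\.?\\s+[0-9]{1,2}(?:\\s*,?\\s*[0-9]{4})?\\b"),
    "\\b[0-9]{1,2}/[0-9]{1,2}(?:/[0-9]{2,4})?\\b")
  hits <- list()
  for (p in pats) {
    m <- gregexpr(p, text, ignore.case = TRUE, perl = TRUE)[[1]]
    if (m[1] == -1) next
    len <- attr(m, "match.length")
    for (k in seq_along(m))
      hits[[length(hits) + 1L]] <- c(as.integer(m[k]),
                                     as.integer(m[k] + len[k] - 1L))
  }
  if (!length(hits))
    return(data.frame(expression = character(),
                      onset_date = as.Date(character()),
                      duration_days = integer(), stringsAsFactors = FALSE))
  # drop hits nested inside an earlier, longer hit (e.g. the bare "2 weeks"
  # inside "for the past 2 weeks")
  spans <- do.call(rbind, hits)
  keep <- rep(TRUE, nrow(spans))
  for (i in seq_len(nrow(spans))) {
    for (j in seq_len(nrow(spans))) {
      if (i == j || !keep[i]) next
      if (spans[j, 1] <= spans[i, 1] && spans[j, 2] >= spans[i, 2] &&
          (spans[j, 2] - spans[j, 1]) > (spans[i, 2] - spans[i, 1]))
        keep[i] <- FALSE
    }
  }
  spans <- spans[keep, , drop = FALSE]
  spans <- unique(spans)
  out <- list()
  for (i in seq_len(nrow(spans))) {
    expr <- substr(text, spans[i, 1], spans[i, 2])
    nr <- normalize_temporal(expr, note_date, config)
    if (is.null(nr$onset_date) && is.null(nr$duration_days)) next
    out[[length(out) + 1L]] <- data.frame(
      expression = expr,
      onset_date = if (is.null(nr$onset_date)) as.Date(NA) else nr$onset_date,
      duration_days = if (is.null(nr$duration_days)) NA_integer_ else
        as.integer(nr$duration_days),
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(expression = character(),
                      onset_date = as.Date(character()),
                      duration_days = integer(), stringsAsFactors = FALSE))
  res <- unique(do.call(rbind, out))
  rownames(res) <- NULL
  res
}
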