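# Distance-constrained, ordered/nested relation search over indexed notes,
# plus an exhaustive brute-force enumerator used as an independent oracle.
#
# Match semantics: every item of a query grounds to a concept mention (or,
# for a nested item, to a match of the inner query). Groundings are pairwise
# non-overlapping in token span; sorted by position, consecutive groundings
# have at most `max_intervening_words` word tokens strictly between them;
# the whole match covers at most `max_sentence_span` consecutive sentences
# (and one section when `require_same_section`). For ordered queries the
# document order of the groundings must follow item order. Mentions flagged
# negated or hypothetical are never eligible groundings.

#' Construct a relation query
#'
#' @param query_id identifier
#' @param items ordered list; each element is a semantic-class name
#'   (character) or a nested `relation_query` (nesting to depth 3)
#' @param ordered must groundings follow item order in the text?
#' @param max_sentence_span number of consecutive sentences the whole match
#'   may cover (1 = intra-sentence)
#' @param max_intervening_words word tokens allowed between consecutive
#'   matched items
#' @param require_same_section whether the match must stay in one section
#' @return a `relation_query`
#' @export
relation_query <- function(query_id, items, ordered = TRUE,
                           max_sentence_span = 1L,
                           max_intervening_words = 50L,
                           require_same_section = TRUE) {
  q <- structure(list(query_id = query_id, items = items, ordered = ordered,
                      max_sentence_span = as.integer(max_sentence_span),
                      max_intervening_words = as.integer(max_intervening_words),
                      require_same_section = require_same_section),
                 class = "relation_query")
  validate_query(q)
  q
}

query_depth <- function(q) {
  if (!inherits(q, "relation_query")) return(0L)
  1L + max(c(0L, vapply(q$items, query_depth, integer(1))))
}

validate_query <- function(q) {
  if (!length(q$items)) stop("query ", q$query_id, ": no items")
  if (q$max_sentence_span < 1L)
    stop("query ", q$query_id, ": max_sentence_span must be >= 1")
  if (q$max_intervening_words < 0L)
    stop("query ", q$query_id, ": max_intervening_words must be >= 0")
  for (it in q$items) {
    if (is.character(it)) {
      if (!it %in% SEMANTIC_CLASSES)
        stop("query ", q$query_id, ": unknown class '", it, "'")
    } else if (!inherits(it, "relation_query")) {
      stop("query ", q$query_id, ": item must be a class name or nested query")
    }
  }
  if (query_depth(q) > 3L)
    stop("query ", q$query_id, ": nesting depth > 3 not supported")
  invisible(q)
}

# A grounding extent: token range, sentence range, and the set of leaf
# mention row indices it consumes.
leaf_extent <- function(men, i) {
  list(tok_from = men$tok_from[i], tok_to = men$tok_to[i],
       s_first = men$sentence_index[i], s_last = men$sentence_index[i],
       leaves = i)
}

match_extent <- function(m) {
  list(tok_from = m$tok_from, tok_to = m$tok_to,
       s_first = m$sentence_window[1], s_last = m$sentence_window[2],
       leaves = m$leaves)
}

eligible_mentions <- function(indexed, class) {
  men <- indexed$mentions
  which(men$class == class & !men$negated & !men$hypothetical)
}

words_between <- function(tokens, a_tok_to, b_tok_from) {
  if (b_tok_from <= a_tok_to + 1L) return(0L)
  idx <- (a_tok_to + 1L):(b_tok_from - 1L)
  sum(tokens$is_word[idx])
}

section_of_sentence <- function(indexed, s) {
  indexed$sentences$section_label[match(s, indexed$sentences$index)]
}

# candidate extents per item (list of lists)
item_candidates <- function(indexed, q, config) {
  lapply(q$items, function(it) {
    if (is.character(it)) {
      lapply(eligible_mentions(indexed, it),
             function(i) leaf_extent(indexed$mentions, i))
    } else {
      lapply(search_relations(indexed, it, config), match_extent)
    }
  })
}

check_sequence <- function(indexed, q, seq_ext) {
  toks <- indexed$tokens
  # pairwise leaf disjointness
  leaves <- unlist(lapply(seq_ext, `[[`, "leaves"))
  if (anyDuplicated(leaves)) return(FALSE)
  ord <- order(vapply(seq_ext, `[[`, integer(1), "tok_from"),
               vapply(seq_ext, `[[`, integer(1), "tok_to"))
  sorted <- seq_ext[ord]
  for (k in seq_len(length(sorted) - 1L)) {
    a <- sorted[[k]]; b <- sorted[[k + 1L]]
    if (b$tok_from <= a$tok_to) return(FALSE)  # token overlap
    if (words_between(toks, a$tok_to, b$tok_from) > q$max_intervening_words)
      return(FALSE)
  }
  s_first <- min(vapply(seq_ext, `[[`, integer(1), "s_first"))
  s_last <- max(vapply(seq_ext, `[[`, integer(1), "s_last"))
  if (s_last - s_first + 1L > q$max_sentence_span) return(FALSE)
  if (isTRUE(q$require_same_section)) {
    secs <- unique(section_of_sentence(indexed, s_first:s_last))
    if (length(secs) > 1L) return(FALSE)
  }
  if (q$ordered && !identical(ord, seq_along(seq_ext))) return(FALSE)
  TRUE
}

build_match <- function(q, seq_ext) {
  leaves <- sort(unlist(lapply(seq_ext, `[[`, "leaves")))
  s_first <- min(vapply(seq_ext, `[[`, integer(1), "s_first"))
  s_last <- max(vapply(seq_ext, `[[`, integer(1), "s_last"))
  structure(list(
    query_id = q$query_id,
    groundings = seq_ext,
    tok_from = min(vapply(seq_ext, `[[`, integer(1), "tok_from")),
    tok_to = max(vapply(seq_ext, `[[`, integer(1), "tok_to")),
    sentence_window = c(s_first, s_last),
    scope = if (s_first == s_last) "intra_sentence" else "cross_sentence",
    leaves = leaves,
    key = paste(leaves, collapse = ",")), class = "relation_match")
}

match_key <- function(q, seq_ext) {
  ids <- lapply(seq_ext, `[[`, "leaves")
  if (q$ordered)
    paste(vapply(ids, paste, character(1), collapse = "."), collapse = "|")
  else paste(sort(vapply(ids, paste, character(1), collapse = ".")),
             collapse = "|")
}

#' Search an indexed note for relation matches
#'
#' Ordered depth-first search with positional pruning; unordered queries are
#' run as ordered searches over every item permutation and deduplicated by
#' grounding set. Returns every distinct grounding satisfying the query
#' constraints (see the match semantics described in the package docs).
#'
#' @param indexed an `indexed_note`
#' @param query a [relation_query()]
#' @param config pipeline configuration
#' @return list of `relation_match` objects
#' @export
search_relations <- function(indexed, query, config = default_config()) {
  validate_query(query)
  cands <- item_candidates(indexed, query, config)
  if (any(vapply(cands, length, integer(1)) == 0L)) return(list())
  n_items <- length(query$items)
  results <- list(); seen <- character()

  run_ordered <- function(perm) {
    # DFS over items in `perm` order, requiring document order
    dfs <- function(pos, chosen, last_ext) {
      if (pos > n_items) {
        if (check_sequence(indexed, query, chosen)) {
          k <- match_key(query, chosen)
          if (!k %in% seen) {
            seen <<- c(seen, k)
            results[[length(results) + 1L]] <<- build_match(query, chosen)
          }
        }
        return(invisible())
      }
      for (ext in cands[[perm[pos]]]) {
        if (!is.null(last_ext)) {
          if (ext$tok_from <= last_ext$tok_to) next
          if (words_between(indexed$tokens, last_ext$tok_to, ext$tok_from) >
              query$max_intervening_words) next
        }
        dfs(pos + 1L, c(chosen, list(ext)), ext)
      }
    }
    dfs(1L, list(), NULL)
  }

  if (query$ordered) {
    run_ordered(seq_len(n_items))
  } else {
    perms <- permutations_of(n_items)
    for (p in perms) run_ordered(p)
  }
  results
}

permutations_of <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (rest in permutations_of(n - 1L)) {
      tail <- seq_len(n)[-i][rest]
      out[[length(out) + 1L]] <- c(i, tail)
    }
  }
  out
}

#' Brute-force relation search (test oracle)
#'
#' Enumerates every tuple of candidate groundings with `expand.grid` and
#' applies the match constraints literally. Reference implementation for
#' equivalence testing only; refuses notes with more than 50 mentions.
#'
#' @inheritParams search_relations
#' @return list of `relation_match` objects
#' @export
search_relations_bruteforce <- function(indexed, query,
                                        config = default_config()) {
  validate_query(query)
  if (nrow(indexed$mentions) > 50L)
    stop("brute-force oracle refuses notes with > 50 mentions")
  cands <- lapply(query$items, function(it) {
    if (is.character(it)) {
      lapply(eligible_mentions(indexed, it),
             function(i) leaf_extent(indexed$mentions, i))
    } else {
      lapply(search_relations_bruteforce(indexed, it, config), match_extent)
    }
  })
  if (any(vapply(cands, length, integer(1)) == 0L)) return(list())
  grid <- expand.grid(lapply(cands, seq_along))
  results <- list(); seen <- character()
  for (r in seq_len(nrow(grid))) {
    seq_ext <- lapply(seq_along(cands),
                      function(k) cands[[k]][[grid[r, k]]])
    if (!check_sequence(indexed, query, seq_ext)) next
    k <- match_key(query, seq_ext)
    if (k %in% seen) next
    seen <- c(seen, k)
    results[[length(results) + 1L]] <- build_match(query, seq_ext)
  }
  results
}

#' Load relation queries from a JSON file
#'
#' Array of objects `{query_id, ordered, max_sentence_span,
#' max_intervening_words, require_same_section, items: [...]}` where an item
#' is a class-name string or a nested query object.
#'
#' @param path JSON file
#' @return list of [relation_query()] objects
#' @export
load_queries <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  parse_q <- function(o) {
    items <- lapply(o$items, function(it)
      if (is.character(it)) it else parse_q(it))
    relation_query(o$query_id %||% "anon", items,
                   ordered = isTRUE(o$ordered),
                   max_sentence_span = o$max_sentence_span %||% 1L,
                   max_intervening_words = o$max_intervening_words %||% 50L,
                   require_same_section = !isFALSE(o$require_same_section))
  }
  lapply(raw, parse_q)
}

#' Write relation queries to a JSON file
#' @param queries list of [relation_query()] objects
#' @param path output path
#' @return `path`, invisibly
#' @export
write_queries <- function(queries, path) {
  unparse_q <- function(q) {
    list(query_id = q$query_id, ordered = q$ordered,
         max_sentence_span = q$max_sentence_span,
         max_intervening_words = q$max_intervening_words,
         require_same_section = q$require_same_section,
         items = lapply(q$items, function(it)
           if (is.character(it)) it else unparse_q(it)))
  }
  jsonlite::write_json(lapply(queries, unparse_q), path,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
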