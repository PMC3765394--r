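# Event-level matching: indicator codes by exact token membership, keywords
# by case-insensitive substring search irrespective of word boundaries.
# Negation is deliberately NOT handled: "no evidence of synovitis" counts as
# a synovitis mention, and the generator makes that over-count measurable.

#' Case-insensitive substring search for a keyword group
#'
#' A text matches iff some term of the group occurs as a contiguous character
#' sequence anywhere in the lower-cased text — no tokenisation, word-boundary
#' or negation handling ("tenosynovitis" matches the term "synovitis").
#' Multi-word terms must match including their internal spaces.
#'
#' @param text Character vector of free-text strings (may be empty strings).
#' @param spec A [keyword_spec()].
#' @return List with `matched` (logical, one per text) and `matched_terms`
#'   (list of character vectors of the terms found in each text).
#' @export
search_text <- function(text, spec) {
  stopifnot(inherits(spec, "keyword_spec"))
  low <- tolower(text)
  hits <- vapply(spec$terms, function(tm) grepl(tm, low, fixed = TRUE),
                 logical(length(text)))
  hits <- matrix(hits, nrow = length(text),
                 dimnames = list(NULL, spec$terms))
  list(matched = rowSums(hits) > 0,
       matched_terms = apply(hits, 1L, function(r) spec$terms[r],
                             simplify = FALSE))
}

#' Count whitespace-delimited words
#'
#' @param text Character vector.
#' @return Integer vector: number of maximal whitespace-delimited tokens
#'   (0 for empty or all-whitespace strings).
#' @export
word_count <- function(text) {
  trimmed <- trimws(text)
  n <- lengths(strsplit(trimmed, "\\s+"))
  n[!nzchar(trimmed)] <- 0L
  as.integer(n)
}

#' Match events against code lists and keyword lists
#'
#' Produces a code hit for every event whose Read code belongs to an
#' indicator group (any record table counts) and a keyword hit for every
#' (event, keyword group) whose free text matches; one event can contribute
#' to several groups and to both channels at once. Each keyword hit records
#' the terms found, the word count of the text, and the associated Read code.
#'
#' @param events Events data.frame; an `effective_date` column is used when
#'   present (as produced by [window_events()]) and computed otherwise.
#' @param code_specs Named list of [code_spec()]s (indicator groups; an
#'   `ra_diagnosis` entry is ignored here).
#' @param keyword_specs Named list of [keyword_spec()]s.
#' @return List with `code_hits` and `keyword_hits` data.frames.
#' @export
match_events <- function(events, code_specs, keyword_specs) {
  eff <- if ("effective_date" %in% names(events)) events$effective_date
         else effective_date(events)

  code_hits <- lapply(intersect(indicator_groups(), names(code_specs)),
                      function(g) {
    sel <- events$read_code %in% code_specs[[g]]$codes
    data.frame(patient_id = events$patient_id[sel],
               event_id = events$event_id[sel],
               group_name = rep(g, sum(sel)),
               read_code = events$read_code[sel],
               record_table = events$record_table[sel],
               effective_date = eff[sel],
               stringsAsFactors = FALSE)
  })
  code_hits <- do.call(rbind, c(code_hits, list(empty_code_hits())))

  low <- tolower(events$free_text)
  wc <- word_count(events$free_text)
  keyword_hits <- lapply(names(keyword_specs), function(g) {
    terms <- keyword_specs[[g]]$terms
    per_term <- lapply(terms, function(tm) grepl(tm, low, fixed = TRUE))
    any_hit <- Reduce(`|`, per_term)
    sel <- which(any_hit)
    if (!length(sel)) return(NULL)
    found <- vapply(sel, function(i) {
      paste(terms[vapply(per_term, `[`, logical(1), i)], collapse = ";")
    }, character(1))
    data.frame(patient_id = events$patient_id[sel],
               event_id = events$event_id[sel],
               group_name = rep(g, length(sel)),
               matched_terms = found,
               associated_read_code = events$read_code[sel],
               record_table = events$record_table[sel],
               effective_date = eff[sel],
               word_count = wc[sel],
               stringsAsFactors = FALSE)
  })
  keyword_hits <- do.call(rbind, c(keyword_hits, list(empty_keyword_hits())))
  rownames(code_hits) <- rownames(keyword_hits) <- NULL
  list(code_hits = code_hits, keyword_hits = keyword_hits)
}

empty_code_hits <- function() {
  data.frame(patient_id = character(), event_id = character(),
             group_name = character(), read_code = character(),
             record_table = character(),
             effective_date = as.Date(character()), stringsAsFactors = FALSE)
}

empty_keyword_hits <- function() {
  data.frame(patient_id = character(), event_id = character(),
             group_name = character(), matched_terms = character(),
             associated_read_code = character(), record_table = character(),
             effective_date = as.Date(character()), word_count = integer(),
             stringsAsFactors = FALSE)
}

#' Collapse event-level hits to per-patient flags and first dates
#'
#' For every cohort patient and every indicator/keyword group: a flag for
#' whether any hit occurred and the earliest effective date among that
#' group's hits. Callers restrict `code_hits` to the analysis window and
#' `keyword_hits` to the search window before collapsing.
#'
#' @param code_hits,keyword_hits Hit data.frames from [match_events()].
#' @param cohort Cohort data.frame from [identify_cases()].
#' @return Flags data.frame: one row per cohort patient with `patient_id`,
#'   `gender`, `index_date`, a logical column per group, a `first_<group>`
#'   date column per group, and the two multiplicity counts
#'   `n_indicator_groups_present` / `n_keyword_groups_present`.
#' @export
collapse_to_patient <- function(code_hits, keyword_hits, cohort) {
  flags <- data.frame(patient_id = cohort$patient_id,
                      gender = cohort$gender,
                      index_date = cohort$index_date,
                      stringsAsFactors = FALSE)
  hits <- rbind(
    code_hits[c("patient_id", "group_name", "effective_date")],
    keyword_hits[c("patient_id", "group_name", "effective_date")])
  for (g in all_groups()) {
    sub <- hits[hits$group_name == g, , drop = FALSE]
    first <- tapply(sub$effective_date, sub$patient_id, min)
    hit <- match(flags$patient_id, names(first))
    date <- as.Date(rep(NA, nrow(flags)))
    date[!is.na(hit)] <- as.Date(first[hit[!is.na(hit)]],
                                 origin = "1970-01-01")
    flags[[g]] <- !is.na(date)
    flags[[paste0("first_", g)]] <- date
  }
  flags$n_indicator_groups_present <-
    as.integer(rowSums(as.matrix(flags[indicator_groups()])))
  flags$n_keyword_groups_present <-
    as.integer(rowSums(as.matrix(flags[keyword_groups()])))
  flags
}
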