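#' Group vocabulary
#'
#' The pipeline tracks six indicator code groups (facets of early rheumatoid
#' arthritis presentation recorded as Read codes) and four keyword groups
#' (free-text search concepts). The special group `ra_diagnosis` holds the RA
#' diagnostic codes that define the index date and is never an indicator.
#'
#' @return Character vector of group names.
#' @export
indicator_groups <- function() {
  c("inflammatory_arthritis_dx", "synovitis", "rhf_test",
    "dmard", "rheum_referral", "joint_sign_symptom")
}

#' @rdname indicator_groups
#' @export
keyword_groups <- function() {
  c("kw_rheumatoid_arthritis", "kw_positive_rhf",
    "kw_inflammatory_arthritis", "kw_synovitis")
}

#' @rdname indicator_groups
#' @export
all_groups <- function() c(indicator_groups(), keyword_groups())

# Record tables of the source database schema. Labels outside this set are
# accepted on read and folded into "other"; matching is table-agnostic.
record_tables <- function() c("clinical", "referral", "test", "therapy", "other")

# Topic pairings used for the code-vs-keyword crosstab: coded channel on the
# left, free-text channel on the right. RhF is asymmetric by design: any test
# code counts, but only positive results are searched for in text.
crosstab_topics <- function() {
  list(
    inflammatory_arthritis = c(code = "inflammatory_arthritis_dx",
                               keyword = "kw_inflammatory_arthritis"),
    synovitis              = c(code = "synovitis", keyword = "kw_synovitis"),
    rhf_test               = c(code = "rhf_test", keyword = "kw_positive_rhf")
  )
}

#' Construct a code or keyword specification
#'
#' A `code_spec` is a named set of Read codes treated as opaque exact-match
#' tokens (no hierarchy expansion). A `keyword_spec` is a named list of
#' case-insensitive search strings; terms are canonicalised to lower case and
#' deduplicated.
#'
#' @param group_name One of [indicator_groups()], `"ra_diagnosis"` (codes
#'   only), or [keyword_groups()] (keywords only).
#' @param codes,terms Character vector of Read codes / search terms.
#' @return A classed list with elements `group_name` and `codes`/`terms`.
#' @export
code_spec <- function(group_name, codes) {
  stopifnot(is.character(group_name), length(group_name) == 1L)
  if (!group_name %in% c(indicator_groups(), "ra_diagnosis")) {
    stop("unknown code group '", group_name, "'; permitted: ",
         paste(c(indicator_groups(), "ra_diagnosis"), collapse = ", "))
  }
  codes <- as.character(codes)
  if (length(codes) == 0L || any(!nzchar(codes))) {
    stop("code group '", group_name, "' must contain non-empty codes")
  }
  if (anyDuplicated(codes)) {
    warning("duplicate codes in group '", group_name, "' deduplicated")
    codes <- unique(codes)
  }
  structure(list(group_name = group_name, codes = codes), class = "code_spec")
}

#' @rdname code_spec
#' @export
keyword_spec <- function(group_name, terms) {
  stopifnot(is.character(group_name), length(group_name) == 1L)
  if (!group_name %in% keyword_groups()) {
    stop("unknown keyword group '", group_name, "'; permitted: ",
         paste(keyword_groups(), collapse = ", "))
  }
  terms <- tolower(as.character(terms))
  terms <- terms[nzchar(trimws(terms))]
  if (length(terms) == 0L) stop("keyword group '", group_name, "' is empty")
  if (anyDuplicated(terms)) {
    warning("duplicate terms in group '", group_name,
            "' deduplicated after lower-casing")
    terms <- unique(terms)
  }
  structure(list(group_name = group_name, terms = terms),
            class = "keyword_spec")
}

#' @export
print.code_spec <- function(x, ...) {
  cat("<code_spec> ", x$group_name, ": ", length(x$codes), " codes\n", sep = "")
  invisible(x)
}

#' @export
print.keyword_spec <- function(x, ...) {
  cat("<keyword_spec> ", x$group_name, ": ",
      paste(x$terms, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Shipped default code lists and keyword lists
#'
#' Paths to the representative code lists and keyword lists installed with the
#' package. These are working defaults covering the published examples per
#' group; real studies supply their own directories in the same layout
#' (`codelists/<group>.csv` with columns `read_code,description`;
#' `keywords/<group>.txt`, one term per line).
#'
#' @return Directory path.
#' @export
default_codelist_dir <- function() {
  system.file("extdata", "codelists", package = "ratext", mustWork = TRUE)
}

#' @rdname default_codelist_dir
#' @export
default_keyword_dir <- function() {
  system.file("extdata", "keywords", package = "ratext", mustWork = TRUE)
}
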