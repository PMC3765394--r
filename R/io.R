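# Flat-file dialect: RFC-4180 CSV with header row, ISO-8601 dates, empty
# string = absent. Free text is quoted so embedded commas/quotes survive a
# round trip byte-for-byte.

patient_cols <- c("patient_id", "gender", "year_of_birth", "registration_date",
                  "uts_date", "transfer_out_date", "last_collection_date")
event_cols <- c("event_id", "patient_id", "record_table", "event_date",
                "system_date", "read_code", "free_text")

read_raw_csv <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, colClasses = "character",
                        na.strings = character(0), check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("file ", path, " lacks required columns: ",
         paste(missing, collapse = ", "))
  }
  df[required]
}

# Parse an ISO-8601 date column; "" means absent. `row_offset` converts a data
# row index into the file line number reported in errors (header = line 1).
parse_date_col <- function(x, col, required = FALSE, file = "") {
  out <- rep(as.Date(NA), length(x))
  blank <- !nzchar(x)
  if (required && any(blank)) {
    stop("missing ", col, " in ", file, " at row ", which(blank)[1] + 1L)
  }
  idx <- which(!blank)
  if (length(idx)) {
    ok <- grepl("^\\d{4}-\\d{2}-\\d{2}$", x[idx])
    d <- suppressWarnings(as.Date(x[idx], format = "%Y-%m-%d"))
    bad <- !ok | is.na(d)
    if (any(bad)) {
      stop("malformed ", col, " '", x[idx][bad][1], "' in ", file,
           " at row ", idx[bad][1] + 1L)
    }
    out[idx] <- d
  }
  out
}

parse_gender <- function(x, file = "") {
  key <- c(m = "male", male = "male", f = "female", female = "female")
  g <- unname(key[tolower(x)])
  if (anyNA(g)) {
    bad <- which(is.na(g))[1]
    stop("unknown gender token '", x[bad], "' in ", file, " at row ", bad + 1L)
  }
  g
}

#' Read and write patient demographics
#'
#' `patients.csv` carries one row per patient: `patient_id`, `gender`
#' (male/female, `M`/`F` accepted), `year_of_birth`, and the four dates that
#' bound valid observation — `registration_date`, `uts_date` (practice
#' up-to-standard date), `transfer_out_date` (may be absent) and
#' `last_collection_date`. Malformed rows are hard errors naming the file
#' line; no row is ever silently dropped.
#'
#' @param path CSV file path.
#' @return A data.frame with parsed `Date` columns and canonical gender.
#' @export
read_patients <- function(path) {
  df <- read_raw_csv(path, patient_cols)
  if (nrow(df) == 0L) return(empty_patients())
  if (anyDuplicated(df$patient_id)) {
    stop("duplicate patient_id in ", path, ": ",
         df$patient_id[duplicated(df$patient_id)][1])
  }
  yob <- suppressWarnings(as.integer(df$year_of_birth))
  if (anyNA(yob)) {
    stop("malformed year_of_birth in ", path, " at row ",
         which(is.na(yob))[1] + 1L)
  }
  out <- data.frame(
    patient_id = df$patient_id,
    gender = parse_gender(df$gender, path),
    year_of_birth = yob,
    registration_date = parse_date_col(df$registration_date,
                                       "registration_date", TRUE, path),
    uts_date = parse_date_col(df$uts_date, "uts_date", TRUE, path),
    transfer_out_date = parse_date_col(df$transfer_out_date,
                                       "transfer_out_date", FALSE, path),
    last_collection_date = parse_date_col(df$last_collection_date,
                                          "last_collection_date", TRUE, path),
    stringsAsFactors = FALSE
  )
  out
}

empty_patients <- function() {
  data.frame(patient_id = character(), gender = character(),
             year_of_birth = integer(),
             registration_date = as.Date(character()),
             uts_date = as.Date(character()),
             transfer_out_date = as.Date(character()),
             last_collection_date = as.Date(character()),
             stringsAsFactors = FALSE)
}

#' @rdname read_patients
#' @param patients Data.frame as returned by `read_patients()`.
#' @export
write_patients <- function(patients, path) {
  df <- patients[patient_cols]
  for (col in grep("_date$", patient_cols, value = TRUE)) {
    df[[col]] <- ifelse(is.na(df[[col]]), "", format(df[[col]], "%Y-%m-%d"))
  }
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read and write clinical events
#'
#' `events.csv` carries one coded entry per row: `event_id`, `patient_id`,
#' `record_table` (clinical/referral/test/therapy; anything else folds into
#' `other`), `event_date` (may be absent — the system date stands in
#' downstream), `system_date` (record creation, always required),
#' `read_code` (opaque token, required) and `free_text` (possibly empty,
#' preserved byte-for-byte including commas and quotes).
#'
#' @param path CSV file path.
#' @return Data.frame of events.
#' @export
read_events <- function(path) {
  df <- read_raw_csv(path, event_cols)
  if (nrow(df) == 0L) return(empty_events())
  if (anyDuplicated(df$event_id)) {
    stop("duplicate event_id in ", path, ": ",
         df$event_id[duplicated(df$event_id)][1])
  }
  if (any(!nzchar(df$read_code))) {
    stop("empty read_code in ", path, " at row ",
         which(!nzchar(df$read_code))[1] + 1L)
  }
  rt <- tolower(df$record_table)
  rt[!rt %in% record_tables()] <- "other"
  data.frame(
    event_id = df$event_id,
    patient_id = df$patient_id,
    record_table = rt,
    event_date = parse_date_col(df$event_date, "event_date", FALSE, path),
    system_date = parse_date_col(df$system_date, "system_date", TRUE, path),
    read_code = df$read_code,
    free_text = df$free_text,
    stringsAsFactors = FALSE
  )
}

empty_events <- function() {
  data.frame(event_id = character(), patient_id = character(),
             record_table = character(),
             event_date = as.Date(character()),
             system_date = as.Date(character()),
             read_code = character(), free_text = character(),
             stringsAsFactors = FALSE)
}

#' @rdname read_events
#' @param events Data.frame as returned by `read_events()`.
#' @export
write_events <- function(events, path) {
  df <- events[event_cols]
  for (col in c("event_date", "system_date")) {
    df[[col]] <- ifelse(is.na(df[[col]]), "", format(df[[col]], "%Y-%m-%d"))
  }
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read code lists and keyword lists
#'
#' `read_codelists()` expects one `<group>.csv` per group (columns
#' `read_code,description`) for the six indicator groups plus `ra_diagnosis`;
#' `read_keywords()` expects one `<group>.txt` per keyword group with one
#' search term per line. Terms are lower-cased on load; duplicates are
#' deduplicated with a warning; a file whose stem is not a permitted group
#' name, or a missing group file, is an error.
#'
#' @param dir Directory holding the group files.
#' @param require_all Require every permitted group to be present (default).
#' @return Named list of [code_spec()] / [keyword_spec()] objects.
#' @export
read_codelists <- function(dir, require_all = TRUE) {
  permitted <- c(indicator_groups(), "ra_diagnosis")
  files <- list.files(dir, pattern = "\\.csv$")
  stems <- sub("\\.csv$", "", files)
  unknown <- setdiff(stems, permitted)
  if (length(unknown)) {
    stop("unknown code list file(s) ", paste(unknown, collapse = ", "),
         " in ", dir, "; permitted names: ", paste(permitted, collapse = ", "))
  }
  if (require_all && length(setdiff(permitted, stems))) {
    stop("missing code list file(s) for group(s): ",
         paste(setdiff(permitted, stems), collapse = ", "), " in ", dir)
  }
  specs <- lapply(stems, function(g) {
    df <- read_raw_csv(file.path(dir, paste0(g, ".csv")), "read_code")
    code_spec(g, df$read_code)
  })
  names(specs) <- stems
  check_ra_disjoint(specs)
  specs[intersect(c(permitted), stems)]
}

check_ra_disjoint <- function(specs) {
  if (!"ra_diagnosis" %in% names(specs)) return(invisible(NULL))
  ra <- specs$ra_diagnosis$codes
  for (g in intersect(indicator_groups(), names(specs))) {
    overlap <- intersect(ra, specs[[g]]$codes)
    if (length(overlap)) {
      stop("ra_diagnosis codes must be disjoint from indicator groups; '",
           overlap[1], "' also appears in ", g)
    }
  }
  invisible(NULL)
}

#' @rdname read_codelists
#' @export
read_keywords <- function(dir, require_all = TRUE) {
  permitted <- keyword_groups()
  files <- list.files(dir, pattern = "\\.txt$")
  stems <- sub("\\.txt$", "", files)
  unknown <- setdiff(stems, permitted)
  if (length(unknown)) {
    stop("unknown keyword file(s) ", paste(unknown, collapse = ", "),
         " in ", dir, "; permitted names: ", paste(permitted, collapse = ", "))
  }
  if (require_all && length(setdiff(permitted, stems))) {
    stop("missing keyword file(s) for group(s): ",
         paste(setdiff(permitted, stems), collapse = ", "), " in ", dir)
  }
  specs <- lapply(stems, function(g) {
    lines <- readLines(file.path(dir, paste0(g, ".txt")), warn = FALSE)
    keyword_spec(g, lines)
  })
  names(specs) <- stems
  specs[intersect(permitted, stems)]
}
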