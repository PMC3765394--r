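# Fixture builders, all programmatic.

make_patients <- function(n = 1, patient_id = sprintf("p%03d", seq_len(n)),
                          gender = rep("female", n),
                          year_of_birth = rep(1950L, n),
                          registration_date = as.Date("2001-01-01"),
                          uts_date = as.Date("2000-01-01"),
                          transfer_out_date = as.Date(NA),
                          last_collection_date = as.Date("2010-12-31")) {
  data.frame(patient_id = patient_id, gender = gender,
             year_of_birth = year_of_birth,
             registration_date = registration_date, uts_date = uts_date,
             transfer_out_date = transfer_out_date,
             last_collection_date = last_collection_date,
             stringsAsFactors = FALSE)
}

make_events <- function(patient_id, read_code, event_date,
                        system_date = as.Date(event_date),
                        free_text = "", record_table = "clinical",
                        event_id = NULL) {
  n <- max(length(patient_id), length(read_code), length(event_date))
  df <- data.frame(
    event_id = if (is.null(event_id)) sprintf("e%03d", seq_len(n))
               else event_id,
    patient_id = rep_len(patient_id, n),
    record_table = rep_len(record_table, n),
    event_date = rep_len(as.Date(event_date), n),
    system_date = rep_len(as.Date(system_date), n),
    read_code = rep_len(read_code, n),
    free_text = rep_len(free_text, n),
    stringsAsFactors = FALSE)
  df
}

# Flags table straight from a membership matrix (rows = patients, columns =
# any subset of group names); first dates default to 10 days before index for
# every set flag.
make_flags <- function(gender, membership = NULL,
                       index_date = as.Date("2006-06-01"),
                       first_offset = 10L) {
  n <- length(gender)
  flags <- data.frame(patient_id = sprintf("p%05d", seq_len(n)),
                      gender = gender,
                      index_date = rep_len(as.Date(index_date), n),
                      stringsAsFactors = FALSE)
  for (g in all_groups()) {
    on <- if (!is.null(membership) && g %in% colnames(membership)) {
      membership[, g]
    } else rep(FALSE, n)
    flags[[g]] <- on
    d <- flags$index_date - first_offset
    d[!on] <- NA
    flags[[paste0("first_", g)]] <- d
  }
  flags$n_indicator_groups_present <-
    as.integer(rowSums(as.matrix(flags[indicator_groups()])))
  flags$n_keyword_groups_present <-
    as.integer(rowSums(as.matrix(flags[keyword_groups()])))
  flags
}

# Membership matrix helper: a logical column with `k` of the first rows TRUE.
first_k <- function(n, k) c(rep(TRUE, k), rep(FALSE, n - k))

default_specs <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- list(codes = read_codelists(default_codelist_dir()),
                     keywords = read_keywords(default_keyword_dir()))
    }
    cache
  }
})

# One shared full-scale simulated run for the acceptance and invariant
# checks; built on first use. The seed is fixed at 42.
shared_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- simulate_cohort(sim_config(seed = 42))
      res <- run_pipeline(sim$patients, sim$events)
      cache <<- list(sim = sim, res = res)
    }
    cache
  }
})
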