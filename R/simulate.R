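# Synthetic GPRD-like record generator. Defaults are calibrated to the
# published cohort: 2,007 men and 4,380 women with a first coded RA diagnosis
# in 2005-2008, per-group occurrence probabilities equal to the published
# pooled prevalences, and first-occurrence intervals (days before the index
# code) drawn from a discretised log-normal fitted to the published median and
# IQR per group.

default_occurrence <- function() {
  n <- 6387
  c(inflammatory_arthritis_dx = 706 / n,
    synovitis                 = 179 / n,
    rhf_test                  = 3511 / n,
    dmard                     = 2034 / n,
    rheum_referral            = 2453 / n,
    joint_sign_symptom        = 3234 / n,
    kw_rheumatoid_arthritis   = 1852 / n,
    kw_positive_rhf           = 2944 / n,
    kw_inflammatory_arthritis = 1168 / n,
    kw_synovitis              = 1168 / n)
}

default_intervals <- function() {
  list(                                      # c(median, q1, q3) in days
    inflammatory_arthritis_dx = c(71, 18, 164),
    synovitis                 = c(78, 26, 180),
    rhf_test                  = c(46, 7, 147),
    dmard                     = c(62, 0, 320),
    rheum_referral            = c(69, 12, 190),
    joint_sign_symptom        = c(133, 52, 254),
    kw_rheumatoid_arthritis   = c(32, 0, 122),
    kw_positive_rhf           = c(48, 7, 147),
    kw_inflammatory_arthritis = c(78.5, 21, 184),
    kw_synovitis              = c(57, 7, 160))
}

# Administrative / communication codes carrying keyword-bearing text, with
# frequency weights shaped like the published ranking (specialist letters and
# rheumatology-clinic codes dominate). Deliberately disjoint from every
# indicator code list so the coded and textual channels stay independent in
# simulation.
default_assoc_codes <- function() {
  c("9N36.00" = 2576,   # letter from specialist
    "8HTB.00" = 1979,   # seen in rheumatology clinic
    "9N35.00" = 770,    # incoming mail NOS
    "8B3R.00" = 482,    # patient reviewed
    "8CB..00" = 345,    # had a chat to patient
    "9N33.00" = 253,    # incoming mail
    "1B1..00" = 239,    # history / symptoms
    "9N4q.00" = 215,    # seen by rheumatologist
    "9N3A.00" = 208,    # communication from specialist
    "8CA..00" = 191,    # advice to patient
    "9D11.00" = 186,    # MED3 - doctor's statement
    "8H9..00" = 169,    # telephone encounter
    "1J...00" = 67,     # suspected condition
    "9N31.00" = 34,     # letter from consultant
    "2....00" = 21)     # examination of patient
}

# Snippet skeletons the keyword is spliced into: clinic-letter style and terse
# consultation style. None may contain a search term of any keyword group on
# its own (enforced by tests).
snippet_templates <- function() {
  c("dear doctor, thank you for referring this patient. impression: %s.",
    "seen in clinic today. evidence of %s on examination.",
    "letter received: findings consistent with %s.",
    "? %s - for review in 2 weeks.",
    "bloods discussed with patient. %s noted.",
    "clinic letter scanned. diagnosis %s.",
    "discussed with patient: likely %s.",
    "examination today shows %s affecting both hands.",
    "hospital letter: %s confirmed by consultant.",
    "tel call - results suggest %s.",
    "%s - commenced treatment as per specialist letter.",
    "follow up of %s, symptoms improving.",
    "dear colleague, many thanks for your letter regarding this patient with %s.",
    "plan: refer to rheumatology, query %s.",
    "reports early morning stiffness, ? %s.",
    "%s")
}

# Negating or third-party skeletons: the term is present but does not apply
# to the patient. A naive substring search still counts these.
negation_templates <- function() {
  c("no evidence of %s",
    "mother had a %s",
    "no %s on examination today",
    "no sign of %s",
    "father treated for %s")
}

distractor_texts <- function() {
  c("bp 128/82 advised diet and exercise",
    "medication review completed no changes",
    "dear colleague thank you for seeing this patient in your clinic",
    "seen today feels well repeat bloods in 4 weeks",
    "telephone advice given re analgesia",
    "sick note issued for two weeks",
    "blood sample taken fasting",
    "knee pain improving continue physio",
    "chest clear no wheeze heart sounds normal",
    "discussed smoking cessation leaflet given",
    "results reviewed and filed no action",
    "patient did not attend appointment rebooked")
}

#' Configuration for the synthetic-record generator
#'
#' Defaults reproduce the published study conditions: 2,007 men and 4,380
#' women (6,387 patients) with an index RA code uniform over 2005--2008,
#' age-at-index quartiles 51/62/72 (men) and 49/60/71 (women), per-group
#' occurrence probabilities equal to the published pooled prevalences, and
#' log-normal first-occurrence intervals fitted to the published medians and
#' IQRs, truncated to the year before the index code.
#'
#' @param n_men,n_women Cohort sizes by gender.
#' @param study_start,study_end Bounds on the index date.
#' @param age_quartiles List with `male` and `female` elements, each the three
#'   age-at-index quartiles (years, strictly increasing).
#' @param age_range Minimum and maximum age at index; the minimum of 30
#'   matches the cohort inclusion rule.
#' @param occurrence Named probabilities, one per indicator and keyword group,
#'   that a patient carries at least one matching event.
#' @param intervals Named list of `c(median, q1, q3)` days-before-index per
#'   group.
#' @param assoc_code_weights Named frequency weights for the Read codes
#'   attached to keyword-bearing text.
#' @param negated_mention_rate Fraction of keyword snippets wrapped in a
#'   negating / third-party template (still matched by a naive search).
#' @param text_suppression_rate Fraction of free-text strings replaced by the
#'   empty string, emulating GP-withheld text.
#' @param missing_event_date_rate Fraction of non-index events whose event
#'   date is absent (the system date stands in downstream).
#' @param distractor_event_rate Mean number of keyword-free events per patient.
#' @param extra_hit_rate Mean number of repeat events per flagged
#'   patient-group beyond the first occurrence.
#' @param seed Integer seed; identical configs give byte-identical output.
#' @return A classed list of settings.
#' @export
sim_config <- function(n_men = 2007, n_women = 4380,
                       study_start = as.Date("2005-01-01"),
                       study_end = as.Date("2008-12-31"),
                       age_quartiles = list(male = c(51, 62, 72),
                                            female = c(49, 60, 71)),
                       age_range = c(30, 95),
                       occurrence = default_occurrence(),
                       intervals = default_intervals(),
                       assoc_code_weights = default_assoc_codes(),
                       negated_mention_rate = 0.05,
                       text_suppression_rate = 0.02,
                       missing_event_date_rate = 0.001,
                       distractor_event_rate = 8,
                       extra_hit_rate = 0.5,
                       seed = 1L) {
  cfg <- list(n_men = as.integer(n_men), n_women = as.integer(n_women),
              study_start = as.Date(study_start),
              study_end = as.Date(study_end),
              age_quartiles = age_quartiles, age_range = age_range,
              occurrence = occurrence, intervals = intervals,
              assoc_code_weights = assoc_code_weights,
              negated_mention_rate = negated_mention_rate,
              text_suppression_rate = text_suppression_rate,
              missing_event_date_rate = missing_event_date_rate,
              distractor_event_rate = distractor_event_rate,
              extra_hit_rate = extra_hit_rate,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_men < 0 || cfg$n_women < 0) stop("cohort sizes must be >= 0")
  missing <- setdiff(all_groups(), names(cfg$occurrence))
  if (length(missing)) {
    stop("occurrence probabilities missing for: ",
         paste(missing, collapse = ", "))
  }
  probs <- c(cfg$occurrence, cfg$negated_mention_rate,
             cfg$text_suppression_rate, cfg$missing_event_date_rate)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  for (g in names(cfg$intervals)) {
    iv <- cfg$intervals[[g]]
    if (iv[1] < 0) stop("interval median for ", g, " must be >= 0")
    if (!(iv[2] <= iv[1] && iv[1] <= iv[3])) {
      stop("impossible quartile ordering for interval of ", g)
    }
  }
  for (g in c("male", "female")) {
    q <- cfg$age_quartiles[[g]]
    if (is.null(q) || length(q) != 3L || any(diff(q) <= 0) ||
        q[1] <= cfg$age_range[1] || q[3] >= cfg$age_range[2]) {
      stop("impossible quartile ordering for ", g, " ages")
    }
  }
  if (cfg$study_end < cfg$study_start) stop("study_end before study_start")
  invisible(cfg)
}

# Fit a log-normal to (median, q1, q3) on the log scale, then re-solve the
# log-median so that after truncation to [0, 365] days the distribution still
# has the target median (plain moment matching would bias wide groups by tens
# of days once the upper tail is cut).
fit_interval_dist <- function(median, q1, q3) {
  stopifnot(median > 0, q3 >= median)
  z75 <- stats::qnorm(0.75)
  sigma <- if (q1 > 0) (log(q3) - log(q1)) / (2 * z75)
           else (log(q3) - log(median)) / z75
  sigma <- max(sigma, 0.05)
  upper <- 365.49                      # rounds to at most 365 whole days
  h <- function(mu) {
    stats::qlnorm(0.5 * stats::plnorm(upper, mu, sigma), mu, sigma) - median
  }
  mu <- stats::uniroot(h, lower = log(median) - 1e-9,
                       upper = log(upper) + 4 * sigma + 1)$root
  list(mu = mu, sigma = sigma)
}

# Inverse-CDF sampling from the truncated distribution, rounded to whole days.
sample_interval_days <- function(n, median, q1, q3) {
  if (n == 0L) return(integer(0))
  fit <- fit_interval_dist(median, q1, q3)
  u <- stats::runif(n) * stats::plnorm(365.49, fit$mu, fit$sigma)
  pmin(365L, as.integer(round(stats::qlnorm(u, fit$mu, fit$sigma))))
}

# Two-piece piecewise-linear quantile function through the three printed age
# quartiles; the published source gives no distributional family.
sample_age <- function(n, quartiles, range) {
  if (n == 0L) return(integer(0))
  anchors <- c(range[1], quartiles, range[2])
  as.integer(round(stats::approx(c(0, 0.25, 0.5, 0.75, 1), anchors,
                                 xout = stats::runif(n))$y))
}

#' Wrap a keyword term in a negating or third-party phrase
#'
#' Used by the generator to inject mentions a naive substring search cannot
#' tell apart from affirmative ones (e.g. "no evidence of synovitis",
#' "mother had a polyarthropathy"). Draws from the current RNG stream.
#'
#' @param term Non-empty keyword term.
#' @return A text string containing `term` preceded by a negating phrase.
#' @export
negate_snippet <- function(term) {
  if (!is.character(term) || length(term) != 1L || !nzchar(term)) {
    stop("term must be a single non-empty string")
  }
  sprintf(sample(negation_templates(), 1L), term)
}

with_preserved_rng <- function(code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  force(code)
}

#' Generate a synthetic GPRD-like dataset with known ground truth
#'
#' Every patient gets exactly one RA diagnostic code at an index date uniform
#' in the study window, observation dates guaranteed to cover the year before
#' and 14 days after it, and, per indicator/keyword group `g`, at least one
#' matching event with probability `occurrence[g]`, first occurring
#' `offset` days before index with `offset` drawn from the configured
#' truncated log-normal. Keyword events carry free text built from a snippet
#' template with one group term spliced in, attached to an
#' administrative/communication code drawn from `assoc_code_weights`.
#' Distractor events, negated mentions, suppressed text and missing event
#' dates are injected at the configured rates. Deterministic given the config
#' (including its seed).
#'
#' @param config A [sim_config()].
#' @param codelists,keywords Optional spec lists; default to the shipped
#'   lists.
#' @return List with `patients`, `events`, `truth` (per patient x group:
#'   intended flag and first-occurrence offset), `truth_events` (per injected
#'   keyword snippet: negated/suppressed flags) and the `config`.
#' @export
simulate_cohort <- function(config = sim_config(), codelists = NULL,
                            keywords = NULL) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  if (is.null(codelists)) codelists <- read_codelists(default_codelist_dir())
  if (is.null(keywords)) keywords <- read_keywords(default_keyword_dir())
  with_preserved_rng({
    set.seed(config$seed)
    simulate_cohort_impl(config, codelists, keywords)
  })
}

simulate_cohort_impl <- function(config, codelists, keywords) {
  n <- config$n_men + config$n_women
  if (n == 0L) {
    return(list(patients = empty_patients(), events = empty_events(),
                truth = data.frame(patient_id = character(),
                                   group_name = character(),
                                   occurred = logical(),
                                   first_offset_days = integer(),
                                   stringsAsFactors = FALSE),
                truth_events = data.frame(event_id = character(),
                                          patient_id = character(),
                                          group_name = character(),
                                          negated = logical(),
                                          suppressed = logical(),
                                          stringsAsFactors = FALSE),
                config = config))
  }
  gender <- rep(c("male", "female"), c(config$n_men, config$n_women))
  patient_id <- sprintf("p%06d", seq_len(n))
  span <- as.integer(config$study_end - config$study_start)
  index <- config$study_start +
    if (n) sample.int(span + 1L, n, replace = TRUE) - 1L else integer(0)
  age <- integer(n)
  for (g in c("male", "female")) {
    sel <- gender == g
    age[sel] <- sample_age(sum(sel), config$age_quartiles[[g]],
                           config$age_range)
  }
  yob <- as.integer(format(index, "%Y")) - age
  registration <- index - 365L - sample(0:2500, n, replace = TRUE)
  uts <- index - 365L - sample(0:2500, n, replace = TRUE)
  last_collection <- index + 14L + sample(0:600, n, replace = TRUE)
  transfer <- as.Date(rep(NA, n))
  has_transfer <- stats::runif(n) < 0.08
  transfer[has_transfer] <- index[has_transfer] + 14L +
    sample(0:200, sum(has_transfer), replace = TRUE)

  patients <- data.frame(
    patient_id = patient_id, gender = gender, year_of_birth = yob,
    registration_date = registration, uts_date = uts,
    transfer_out_date = transfer, last_collection_date = last_collection,
    stringsAsFactors = FALSE)

  ev <- list()
  truth <- list()
  truth_kw <- list()

  # index RA code, one per patient
  ev$ra <- data.frame(
    patient_id = patient_id, record_table = "clinical", date = index,
    read_code = if (n) sample(codelists$ra_diagnosis$codes, n, replace = TRUE)
                else character(0),
    free_text = character(n), kw_group = NA_character_, negated = FALSE,
    stringsAsFactors = FALSE)

  table_for <- c(inflammatory_arthritis_dx = "clinical", synovitis = "clinical",
                 rhf_test = "test", dmard = "therapy",
                 rheum_referral = "referral", joint_sign_symptom = "clinical")

  for (g in all_groups()) {
    occ <- stats::runif(n) < config$occurrence[[g]]
    m <- sum(occ)
    iv <- config$intervals[[g]]
    off <- sample_interval_days(m, iv[1], iv[2], iv[3])
    first <- index[occ] - off
    extra <- stats::rpois(m, config$extra_hit_rate)
    reps <- 1L + extra
    pid <- rep(patient_id[occ], reps)
    dates <- rep(first, reps)
    later <- sequence(reps) > 1L             # repeats after first occurrence
    if (any(later)) {
      gap <- rep(off, reps)[later]
      dates[later] <- rep(index[occ], reps)[later] -
        as.integer(floor(stats::runif(sum(later)) * (gap + 1L)))
    }
    tot <- length(pid)
    truth[[g]] <- data.frame(
      patient_id = patient_id, group_name = g, occurred = occ,
      first_offset_days = NA_integer_, stringsAsFactors = FALSE)
    truth[[g]]$first_offset_days[occ] <- off
    if (tot == 0L) next
    if (g %in% indicator_groups()) {
      ev[[g]] <- data.frame(
        patient_id = pid, record_table = table_for[[g]], date = dates,
        read_code = sample(codelists[[g]]$codes, tot, replace = TRUE),
        free_text = character(tot), kw_group = NA_character_, negated = FALSE,
        stringsAsFactors = FALSE)
    } else {
      term <- sample(keywords[[g]]$terms, tot, replace = TRUE)
      neg <- stats::runif(tot) < config$negated_mention_rate
      text <- character(tot)
      if (any(!neg)) {
        text[!neg] <- sprintf(sample(snippet_templates(), sum(!neg),
                                     replace = TRUE), term[!neg])
      }
      if (any(neg)) {
        text[neg] <- sprintf(sample(negation_templates(), sum(neg),
                                    replace = TRUE), term[neg])
      }
      shout <- stats::runif(tot) < 0.08      # exercise case-insensitivity
      text[shout] <- toupper(text[shout])
      w <- config$assoc_code_weights
      ev[[g]] <- data.frame(
        patient_id = pid,
        record_table = sample(c("clinical", "other", "referral"), tot,
                              replace = TRUE, prob = c(0.6, 0.3, 0.1)),
        date = dates,
        read_code = sample(names(w), tot, replace = TRUE, prob = w),
        free_text = text, kw_group = g, negated = neg,
        stringsAsFactors = FALSE)
    }
  }

  # keyword-free distractor events inside the window
  kd <- stats::rpois(n, config$distractor_event_rate)
  if (sum(kd)) {
    pid <- rep(patient_id, kd)
    dates <- rep(index, kd) - sample(-14:365, sum(kd), replace = TRUE)
    txt <- sample(c(distractor_texts(), rep("", length(distractor_texts()))),
                  sum(kd), replace = TRUE)
    ev$distractor <- data.frame(
      patient_id = pid,
      record_table = sample(record_tables(), sum(kd), replace = TRUE),
      date = dates,
      read_code = sample(names(config$assoc_code_weights), sum(kd),
                         replace = TRUE),
      free_text = txt, kw_group = NA_character_, negated = FALSE,
      stringsAsFactors = FALSE)
  }

  # a few events before the observation start, to be discarded downstream
  pre <- which(stats::runif(n) < 0.02)
  if (length(pre)) {
    ev$preobs <- data.frame(
      patient_id = patient_id[pre], record_table = "clinical",
      date = registration[pre] - sample(30:300, length(pre), replace = TRUE),
      read_code = sample(names(config$assoc_code_weights), length(pre),
                         replace = TRUE),
      free_text = "", kw_group = NA_character_, negated = FALSE,
      stringsAsFactors = FALSE)
  }

  events <- do.call(rbind, ev)
  is_index <- rep(FALSE, nrow(events))
  is_index[seq_len(n)] <- TRUE               # ev$ra rows come first

  event_date <- events$date
  drop_date <- stats::runif(nrow(events)) < config$missing_event_date_rate &
    !is_index
  event_date[drop_date] <- NA
  lag <- sample(0:2, nrow(events), replace = TRUE, prob = c(0.7, 0.2, 0.1))
  system_date <- events$date + lag

  suppress <- nzchar(events$free_text) &
    stats::runif(nrow(events)) < config$text_suppression_rate
  events$free_text[suppress] <- ""

  ord <- order(events$patient_id, events$date,
               events$read_code, method = "radix")
  out <- data.frame(
    event_id = sprintf("e%07d", seq_along(ord)),
    patient_id = events$patient_id[ord],
    record_table = events$record_table[ord],
    event_date = event_date[ord],
    system_date = system_date[ord],
    read_code = events$read_code[ord],
    free_text = events$free_text[ord],
    stringsAsFactors = FALSE)

  kw_rows <- which(!is.na(events$kw_group[ord]))
  truth_events <- data.frame(
    event_id = out$event_id[kw_rows],
    patient_id = out$patient_id[kw_rows],
    group_name = events$kw_group[ord][kw_rows],
    negated = events$negated[ord][kw_rows],
    suppressed = suppress[ord][kw_rows],
    stringsAsFactors = FALSE)

  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  list(patients = patients, events = out, truth = truth,
       truth_events = truth_events, config = config)
}
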