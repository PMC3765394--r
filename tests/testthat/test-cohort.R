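test_that("effective date prefers the event date, falls back to system date", {
  ev <- make_events(rep("p1", 3), "N040.00",
                    c("2006-05-01", NA, "2006-05-03"),
                    system_date = "2006-05-03")
  expect_equal(effective_date(ev),
               as.Date(c("2006-05-01", "2006-05-03", "2006-05-03")))
})

test_that("observation bounds follow the max/min date rules", {
  p <- make_patients(3,
                     registration_date = as.Date(c("2001-01-01", "2001-01-01",
                                                   "2009-06-01")),
                     uts_date = as.Date("2003-06-01"),
                     transfer_out_date = as.Date(c(NA, "2007-01-01", NA)),
                     last_collection_date = as.Date("2009-01-01"))
  b <- observation_bounds(p)
  expect_equal(b$obs_start[1], as.Date("2003-06-01"))
  expect_equal(b$obs_end[1], as.Date("2009-01-01"))
  expect_equal(b$obs_end[2], as.Date("2007-01-01"))   # left practice first
  expect_false(b$usable[3])                           # reg after last collection
})

test_that("case identification applies study period, age and window rules", {
  p <- make_patients(5, year_of_birth = c(1950L, 1950L, 1977L, 1950L, 1950L))
  p$registration_date[4] <- as.Date("2006-01-01")     # window not covered
  ra <- code_spec("ra_diagnosis", "N040.00")
  ev <- make_events(c("p001", "p002", "p003", "p004", "p005"), "N040.00",
                    c("2006-06-01", "2004-12-31", "2006-06-01", "2006-06-01",
                      "2006-06-01"))
  cohort <- identify_cases(p, ev, ra, "2005-01-01", "2008-12-31")
  excl <- attr(cohort, "exclusions")
  expect_setequal(cohort$patient_id, c("p001", "p005"))
  expect_equal(excl$reason[excl$patient_id == "p002"],
               "index_before_study_start")
  expect_equal(excl$reason[excl$patient_id == "p003"], "under_30")  # age 29
  expect_equal(excl$reason[excl$patient_id == "p004"], "window_not_covered")
  expect_equal(cohort$age_at_index[1], 56L)
  expect_equal(cohort$window_start[1], as.Date("2006-06-01") - 365)
  expect_equal(cohort$window_end[1], as.Date("2006-06-01") + 14)
})

test_that("exclusion reasons partition the excluded patients", {
  sim <- simulate_cohort(sim_config(n_men = 40, n_women = 60, seed = 9))
  p <- sim$patients
  p$year_of_birth[1:5] <- 1990L                        # force under_30
  p$registration_date[6:10] <- as.Date("2009-01-01")
  cohort <- identify_cases(p, sim$events,
                           default_specs()$codes$ra_diagnosis,
                           "2005-01-01", "2008-12-31")
  excl <- attr(cohort, "exclusions")
  expect_equal(nrow(cohort) + nrow(excl), nrow(p))
  expect_false(anyDuplicated(excl$patient_id) > 0)
  expect_false(anyNA(excl$reason))
})

test_that("synthetic cohorts are retained exactly by identification", {
  sim <- simulate_cohort(sim_config(n_men = 80, n_women = 120, seed = 10))
  cohort <- identify_cases(sim$patients, sim$events,
                           default_specs()$codes$ra_diagnosis,
                           "2005-01-01", "2008-12-31")
  expect_setequal(cohort$patient_id, sim$patients$patient_id)
  expect_equal(nrow(attr(cohort, "exclusions")), 0L)
})

test_that("an early DMARD extends the search window but not the analysis window", {
  p <- make_patients(1, patient_id = "p1")
  dmard <- code_spec("dmard", "dh11.00")
  ra <- code_spec("ra_diagnosis", "N040.00")
  idx <- as.Date("2006-06-01")
  ev <- make_events("p1", c("N040.00", "dh11.00", "9N36.00", "9N36.00"),
                    c(idx, idx - 400, idx - 380, idx + 15))
  cohort <- identify_cases(p, ev, ra, "2005-01-01", "2008-12-31")
  win <- window_events(cohort, ev, dmard, character(0))
  expect_equal(win$cohort$search_start, idx - 400)
  # analysis window keeps only the index event (others at -400, -380, +15)
  expect_setequal(win$analysis$event_id, "e001")
  expect_setequal(win$search$event_id, c("e001", "e002", "e003"))
})

test_that("events outside observation bounds are always discarded", {
  p <- make_patients(1, patient_id = "p1",
                     registration_date = as.Date("2001-01-01"),
                     uts_date = as.Date("2004-01-01"))
  ra <- code_spec("ra_diagnosis", "N040.00")
  dmard <- code_spec("dmard", "dh11.00")
  idx <- as.Date("2006-06-01")
  ev <- make_events("p1", c("N040.00", "dh11.00", "dh11.00"),
                    c(idx, as.Date("2003-06-01"), idx - 400))
  cohort <- identify_cases(p, ev, ra, "2005-01-01", "2008-12-31")
  win <- window_events(cohort, ev, dmard, character(0))
  # the 2003 DMARD is before the up-to-standard date: discarded, and it must
  # not drag the search window back either
  expect_equal(win$cohort$search_start, idx - 400)
  expect_false("e002" %in% win$search$event_id)
})

test_that("analysis events are a subset of search events", {
  sim <- simulate_cohort(sim_config(n_men = 60, n_women = 60, seed = 12))
  codes <- default_specs()$codes
  cohort <- identify_cases(sim$patients, sim$events, codes$ra_diagnosis,
                           "2005-01-01", "2008-12-31")
  win <- window_events(cohort, sim$events, codes$dmard,
                       c(codes$inflammatory_arthritis_dx$codes,
                         codes$synovitis$codes))
  expect_true(all(win$analysis$event_id %in% win$search$event_id))
  expect_true(all(win$cohort$search_start <= win$cohort$window_start))
})
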