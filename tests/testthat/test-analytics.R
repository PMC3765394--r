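test_that("prevalence rows report counts, percents and a 2x2 chi-squared", {
  n_men <- 2007
  n_women <- 4380
  mem <- cbind(inflammatory_arthritis_dx = c(first_k(n_men, 237),
                                             first_k(n_women, 469)))
  flags <- make_flags(rep(c("male", "female"), c(n_men, n_women)), mem)
  tab <- prevalence_table(flags)
  row <- tab[tab$group_name == "inflammatory_arthritis_dx", ]
  expect_equal(row$men_n, 237)
  expect_equal(row$men_pct, 11.8)
  expect_equal(row$women_pct, 10.7)
  expect_equal(row$total_n, 706)
  expect_equal(row$chi_squared_stat,
               chisq_closed(237, 2007 - 237, 469, 4380 - 469),
               tolerance = 1e-12)
  expect_equal(row$p_bonferroni, min(1, row$p_value * 10))
})

test_that("equal proportions give statistic 0 and p 1", {
  mem <- cbind(dmard = rep(c(TRUE, FALSE), 50))
  flags <- make_flags(rep(c("male", "female"), each = 50), mem)
  tab <- prevalence_table(flags)
  row <- tab[tab$group_name == "dmard", ]
  expect_equal(row$chi_squared_stat, 0)
  expect_equal(row$p_value, 1)
  # a group nobody carries is also no evidence of association
  expect_equal(tab$p_value[tab$group_name == "synovitis"], 1)
})

test_that("chi-squared matches the 2x2 closed form on random tables", {
  set.seed(77)
  for (i in 1:50) {
    a <- sample(1:40, 1); b <- sample(1:40, 1)
    c_ <- sample(1:40, 1); d <- sample(1:40, 1)
    flag <- c(rep(TRUE, a), rep(FALSE, b), rep(TRUE, c_), rep(FALSE, d))
    gender <- rep(c("male", "female"), c(a + b, c_ + d))
    flags <- make_flags(gender, cbind(rhf_test = flag))
    got <- prevalence_table(flags)
    got <- got$chi_squared_stat[got$group_name == "rhf_test"]
    expect_equal(got, chisq_closed(a, b, c_, d), tolerance = 1e-9)
  }
})

test_that("keyword multiplicity bins by number of keyword groups", {
  km <- matrix(FALSE, 5, 4, dimnames = list(NULL, keyword_groups()))
  km[2, 1] <- TRUE
  km[3, 2] <- TRUE
  km[4, c(1, 4)] <- TRUE
  km[5, 1:4] <- TRUE                      # multiplicities (0,1,1,2,4)
  flags <- make_flags(rep("female", 5), km)
  out <- keyword_multiplicity(flags)
  expect_equal(out$n, c(2L, 1L, 1L))
  flags0 <- make_flags(rep("female", 5))
  expect_equal(keyword_multiplicity(flags0)$n, c(0L, 0L, 0L))
})

test_that("interval quartiles use the inverse-ECDF convention", {
  idx <- as.Date("2006-06-01")
  flags <- make_flags(rep("male", 3), cbind(synovitis = rep(TRUE, 3)),
                      index_date = idx)
  flags$first_synovitis <- idx - c(0L, 37L, 121L)
  tab <- interval_table(flags)
  row <- tab[tab$group_name == "synovitis", ]
  expect_equal(row$men_median, 37)
  expect_equal(row$men_q1, 0)
  expect_equal(row$men_q3, 121)
  expect_true(is.na(row$mann_whitney_p))   # no women: test skipped
})

test_that("first occurrences after the index date count for prevalence but not intervals", {
  idx <- as.Date("2006-06-01")
  flags <- make_flags(rep("male", 2), cbind(synovitis = c(TRUE, TRUE)),
                      index_date = idx)
  flags$first_synovitis <- c(idx - 5L, idx + 3L)
  tab <- interval_table(flags)
  expect_equal(tab[tab$group_name == "synovitis", "men_n"], 1L)
  prev <- suppressWarnings(prevalence_table(flags))  # all-male fixture
  expect_equal(prev$men_n[prev$group_name == "synovitis"], 2L)
})

test_that("identical interval multisets across genders give p = 1", {
  idx <- as.Date("2006-06-01")
  flags <- make_flags(rep(c("male", "female"), each = 3),
                      cbind(rhf_test = rep(TRUE, 6)), index_date = idx)
  flags$first_rhf_test <- rep(idx - c(3L, 8L, 21L), 2)
  tab <- interval_table(flags)
  expect_equal(tab$mann_whitney_p[tab$group_name == "rhf_test"], 1)
})

test_that("small untied samples get the exact Mann-Whitney p", {
  idx <- as.Date("2006-06-01")
  flags <- make_flags(rep(c("male", "female"), each = 3),
                      cbind(dmard = rep(TRUE, 6)), index_date = idx)
  flags$first_dmard <- idx - c(1L, 2L, 3L, 4L, 5L, 6L)
  tab <- interval_table(flags)
  expect_equal(tab$mann_whitney_p[tab$group_name == "dmard"], 0.1)
})

test_that("Mann-Whitney agrees with exhaustive enumeration on small samples", {
  set.seed(55)
  for (m in 1:4) {
    for (n in 1:4) {
      z <- sample(1000, m + n)
      p_impl <- ratext:::mann_whitney(z[1:m], z[(m + 1):(m + n)])
      p_enum <- mw_enum_p(z[1:m], z[(m + 1):(m + n)])
      expect_equal(p_impl, p_enum, tolerance = 1e-12,
                   label = sprintf("m=%d n=%d", m, n))
    }
  }
})

test_that("code ranking keeps per-group top-20, ranks the union, breaks ties by code", {
  kh <- data.frame(
    patient_id = "p", event_id = "e",
    group_name = c(rep("kw_synovitis", 4), rep("kw_positive_rhf", 2)),
    matched_terms = "t",
    associated_read_code = c("A", "A", "A", "B", "C", "C"),
    record_table = "clinical", effective_date = as.Date("2006-01-01"),
    word_count = 1L, stringsAsFactors = FALSE)
  out <- rank_codes(kh)
  expect_equal(out$read_code, c("A", "C", "B"))
  expect_equal(out$overall_rank, 1:3)
  expect_equal(out$rank_kw_synovitis, c(1L, NA, 2L))
  expect_equal(out$rank_kw_positive_rhf, c(NA, 1L, NA))

  # ties break lexicographically
  kh2 <- kh
  kh2$associated_read_code <- c("B", "B", "A", "A", "A", "B")
  out2 <- rank_codes(kh2)
  expect_equal(out2$read_code, c("A", "B"))
  expect_equal(out2$rank_kw_synovitis, c(1L, 2L))     # 2 vs 2 within group

  # top_n truncation
  kh3 <- data.frame(
    patient_id = "p", event_id = "e", group_name = "kw_synovitis",
    matched_terms = "t",
    associated_read_code = rep(sprintf("c%02d", 1:5), times = 5:1),
    record_table = "clinical", effective_date = as.Date("2006-01-01"),
    word_count = 1L, stringsAsFactors = FALSE)
  out3 <- rank_codes(kh3, top_n = 3)
  expect_equal(out3$read_code, c("c01", "c02", "c03"))
})

test_that("crosstab assigns each patient to exactly one cell per topic", {
  n_men <- 2007
  counts <- c(neither = 1483, code_only = 146, keyword_only = 287, both = 91)
  code <- c(rep(FALSE, 1483), rep(TRUE, 146), rep(FALSE, 287), rep(TRUE, 91))
  kw <- c(rep(FALSE, 1483), rep(FALSE, 146), rep(TRUE, 287), rep(TRUE, 91))
  flags <- make_flags(rep("male", n_men),
                      cbind(inflammatory_arthritis_dx = code,
                            kw_inflammatory_arthritis = kw))
  out <- crosstab_table(flags)
  row <- out[out$topic == "inflammatory_arthritis" & out$gender == "male", ]
  expect_equal(row$neither_pct, 73.9)
  expect_equal(row$code_only_pct, 7.3)
  expect_equal(row$keyword_only_pct, 14.3)
  expect_equal(row$both_pct, 4.5)
  expect_equal(row$neither_n + row$code_only_n + row$keyword_only_n +
                 row$both_n, row$denominator)
  # all-false flags put everyone in 'neither'
  empty <- crosstab_table(make_flags(rep("male", 10)))
  expect_true(all(empty$neither_pct[empty$gender == "male"] == 100))
})

test_that("combination thresholds and anchored rows count as labelled", {
  mem <- matrix(FALSE, 1, 10,
                dimnames = list(NULL, all_groups()))
  mem[1, c("kw_rheumatoid_arthritis", "dmard", "rhf_test")] <- TRUE
  flags <- make_flags("male", mem)
  out <- combination_table(flags)
  get_n <- function(lbl) out$n[out$label == lbl]
  expect_equal(get_n("RA keyword and 2 or more codes"), 1L)
  expect_equal(get_n("DMARD and 1 or more keyword"), 1L)
  expect_equal(get_n("DMARD and 2 or more codes"), 0L)   # anchor excluded
  expect_equal(get_n("RA keyword and 1 or more other keywords"), 0L)
  expect_equal(get_n("1 or more codes and 1 or more keyword"), 1L)

  solo <- make_flags("male", matrix(c(TRUE), 1, 1,
                                    dimnames = list(NULL,
                                                    "kw_rheumatoid_arthritis")))
  out2 <- combination_table(solo)
  expect_equal(out2$n[out2$label == "1 or more codes or keyword"], 1L)
  expect_true(all(out2$n[grepl("^DMARD", out2$label)] == 0L))
})
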