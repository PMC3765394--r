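# Result tables: gender-split prevalence with chi-squared tests, interval
# statistics with Mann-Whitney tests and Bonferroni correction, the ranking
# of codes associated with keyword-bearing text, code-vs-keyword crosstabs,
# and combination counts for probabilistic case definition.

pct1 <- function(n, den) round(100 * n / den, 1)

# Quartiles by inverse of the empirical distribution function with averaging
# at discontinuities (quantile type 2), so small integer-day samples keep
# their attained values (e.g. {0, 37, 121} -> IQR [0, 121]).
quartiles <- function(x) stats::quantile(x, c(0.25, 0.5, 0.75), type = 2,
                                         names = FALSE)

# Pearson chi-squared on the 2x2 gender-by-flag table, no continuity
# correction. Degenerate margins (a flag constant across the cohort, or an
# empty gender) carry no evidence of association: statistic 0, p 1.
chisq_gender_flag <- function(flag, is_male) {
  tab <- rbind(c(sum(flag & is_male), sum(!flag & is_male)),
               c(sum(flag & !is_male), sum(!flag & !is_male)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(list(statistic = 0, p = 1))
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), p = unname(ct$p.value))
}

# Two-sided Mann-Whitney U comparing two samples: exact null distribution for
# small untied samples, otherwise the normal approximation with tie
# correction (no continuity correction).
mann_whitney <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) return(NA_real_)
  if (all(c(x, y) == c(x, y)[1])) return(1)
  has_ties <- anyDuplicated(c(x, y)) > 0
  exact <- !has_ties && length(x) <= 50 && length(y) <= 50
  stats::wilcox.test(x, y, exact = exact, correct = FALSE)$p.value
}

#' Prevalence of indicator and keyword groups by gender
#'
#' One row per indicator and keyword group: flagged patient counts and
#' percentages in men and women, the Pearson chi-squared statistic for the
#' 2x2 gender-by-flag table (no continuity correction), and raw plus
#' Bonferroni-corrected p-values.
#'
#' @param flags Flags data.frame from [collapse_to_patient()].
#' @param family_size Bonferroni multiplier; defaults to the 10 group
#'   comparisons made (6 indicator + 4 keyword groups).
#' @return Data.frame of prevalence rows (percentages to 1 d.p.).
#' @export
prevalence_table <- function(flags, family_size = 10) {
  if (nrow(flags) == 0L) {
    warning("empty cohort: no prevalence rows")
    return(data.frame(group_name = character()))
  }
  is_male <- flags$gender == "male"
  n_men <- sum(is_male)
  n_women <- sum(!is_male)
  if (n_men == 0L || n_women == 0L) {
    warning("a gender denominator is zero; its percentages are NA and ",
            "gender comparisons are skipped")
  }
  rows <- lapply(all_groups(), function(g) {
    f <- flags[[g]]
    test <- chisq_gender_flag(f, is_male)
    data.frame(
      group_name = g,
      men_n = sum(f & is_male),
      men_pct = if (n_men) pct1(sum(f & is_male), n_men) else NA_real_,
      women_n = sum(f & !is_male),
      women_pct = if (n_women) pct1(sum(f & !is_male), n_women) else NA_real_,
      total_n = sum(f),
      total_pct = pct1(sum(f), nrow(flags)),
      chi_squared_stat = if (n_men && n_women) test$statistic else NA_real_,
      p_value = if (n_men && n_women) test$p else NA_real_,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, out$p_value * family_size)
  out
}

#' Keyword multiplicity counts
#'
#' How many patients carry exactly one, exactly two, and three or more of the
#' four keyword groups (patients with none appear in no bin).
#'
#' @param flags Flags data.frame.
#' @return Data.frame with rows `1`, `2`, `3+`: count and percent of cohort.
#' @export
keyword_multiplicity <- function(flags) {
  k <- flags$n_keyword_groups_present
  n <- c(sum(k == 1L), sum(k == 2L), sum(k >= 3L))
  data.frame(n_keyword_groups = c("1", "2", "3+"), n = n,
             percent = pct1(n, max(nrow(flags), 1L)),
             stringsAsFactors = FALSE)
}

#' Interval from first marker occurrence to the RA index code
#'
#' Per group and gender: median and quartiles of the interval in whole days
#' between the first occurrence and the index date, restricted to first
#' occurrences on or before the index date; genders compared by a two-sided
#' Mann-Whitney U test with Bonferroni correction.
#'
#' @param flags Flags data.frame (carries `index_date`).
#' @param family_size Bonferroni multiplier (default 10).
#' @return Data.frame of interval rows.
#' @export
interval_table <- function(flags, family_size = 10) {
  is_male <- flags$gender == "male"
  rows <- lapply(all_groups(), function(g) {
    d <- flags[[paste0("first_", g)]]
    iv <- as.integer(flags$index_date - d)
    ok <- !is.na(iv) & iv >= 0
    men <- iv[ok & is_male]
    women <- iv[ok & !is_male]
    qm <- if (length(men)) quartiles(men) else rep(NA_real_, 3)
    qw <- if (length(women)) quartiles(women) else rep(NA_real_, 3)
    data.frame(
      group_name = g,
      men_n = length(men), men_median = qm[2], men_q1 = qm[1], men_q3 = qm[3],
      women_n = length(women), women_median = qw[2], women_q1 = qw[1],
      women_q3 = qw[3],
      mann_whitney_p = mann_whitney(men, women),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, out$mann_whitney_p * family_size)
  out
}

#' Rank Read codes associated with keyword-bearing text
#'
#' Within each keyword group, codes are ranked by how often they carry a
#' matching text string and the top `top_n` kept; the union of those codes is
#' then ranked overall by total frequency across all keyword hits. Ties break
#' by code string, ascending. Per-group ranks are reported only where the
#' code is in that group's top `top_n` (blank cells elsewhere).
#'
#' @param keyword_hits Keyword-hit data.frame from [match_events()].
#' @param top_n Codes kept per group (default 20).
#' @return Data.frame: `read_code`, total `frequency`, `overall_rank`, and
#'   one `rank_<group>` column per keyword group.
#' @export
rank_codes <- function(keyword_hits, top_n = 20) {
  groups <- keyword_groups()
  per_group <- lapply(groups, function(g) {
    sub <- keyword_hits[keyword_hits$group_name == g, , drop = FALSE]
    if (!nrow(sub)) return(NULL)
    freq <- table(sub$associated_read_code)
    df <- data.frame(read_code = names(freq), n = as.integer(freq),
                     stringsAsFactors = FALSE)
    df <- df[order(-df$n, df$read_code), , drop = FALSE]
    df <- utils::head(df, top_n)
    df$rank <- seq_len(nrow(df))
    df
  })
  names(per_group) <- groups
  union_codes <- unique(unlist(lapply(per_group, function(d) d$read_code)))
  if (!length(union_codes)) {
    out <- data.frame(read_code = character(), frequency = integer(),
                      overall_rank = integer(), stringsAsFactors = FALSE)
    for (g in groups) out[[paste0("rank_", g)]] <- integer()
    return(out)
  }
  total <- table(keyword_hits$associated_read_code)
  out <- data.frame(read_code = union_codes,
                    frequency = as.integer(total[union_codes]),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$frequency, out$read_code), , drop = FALSE]
  out$overall_rank <- seq_len(nrow(out))
  for (g in groups) {
    d <- per_group[[g]]
    out[[paste0("rank_", g)]] <-
      if (is.null(d)) NA_integer_ else d$rank[match(out$read_code,
                                                    d$read_code)]
  }
  rownames(out) <- NULL
  out
}

#' Cross-tabulate coded against textual evidence per topic
#'
#' For the three topics with both a coded and a textual channel
#' (inflammatory arthritis, synovitis, rheumatoid-factor test), each patient
#' falls in exactly one cell of {neither, code only, keyword only, both} per
#' topic, split by gender. "Keyword only" measures information available in
#' free text with no corresponding code.
#'
#' @param flags Flags data.frame.
#' @return Data.frame: one row per topic x gender with the four cell counts
#'   and percentages (summing to the gender denominator).
#' @export
crosstab_table <- function(flags) {
  rows <- list()
  for (topic in names(crosstab_topics())) {
    pair <- crosstab_topics()[[topic]]
    code <- flags[[pair[["code"]]]]
    kw <- flags[[pair[["keyword"]]]]
    for (g in c("male", "female")) {
      sel <- flags$gender == g
      den <- sum(sel)
      n <- c(neither = sum(sel & !code & !kw),
             code_only = sum(sel & code & !kw),
             keyword_only = sum(sel & !code & kw),
             both = sum(sel & code & kw))
      rows[[paste(topic, g)]] <- data.frame(
        topic = topic, gender = g, denominator = den,
        neither_n = n[["neither"]], neither_pct = pct1(n[["neither"]], den),
        code_only_n = n[["code_only"]],
        code_only_pct = pct1(n[["code_only"]], den),
        keyword_only_n = n[["keyword_only"]],
        keyword_only_pct = pct1(n[["keyword_only"]], den),
        both_n = n[["both"]], both_pct = pct1(n[["both"]], den),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Combination counts for probabilistic case definition
#'
#' Counts of patients meeting threshold combinations of indicator code groups
#' and keyword groups: plain thresholds, cross-conditions, and rows anchored
#' on the RA keyword or on a DMARD prescription. Anchored rows exclude the
#' anchor group itself from the companion count ("other"/"additional"
#' markers).
#'
#' @param flags Flags data.frame.
#' @return Data.frame with `label`, `n`, `percent` (of cohort, 1 d.p.).
#' @export
combination_table <- function(flags) {
  nc <- flags$n_indicator_groups_present
  nk <- flags$n_keyword_groups_present
  ra <- flags$kw_rheumatoid_arthritis
  dm <- flags$dmard
  den <- max(nrow(flags), 1L)
  defs <- list(
    "1 or more codes" = nc >= 1,
    "2 or more codes" = nc >= 2,
    "3 or more codes" = nc >= 3,
    "1 or more codes or keyword" = nc + nk >= 1,
    "2 or more codes or keyword" = nc + nk >= 2,
    "3 or more codes or keyword" = nc + nk >= 3,
    "1 or more codes and 1 or more keyword" = nc >= 1 & nk >= 1,
    "1 or more codes and 2 or more keywords" = nc >= 1 & nk >= 2,
    "2 or more codes and 1 or more keyword" = nc >= 2 & nk >= 1,
    "RA keyword and 1 or more codes" = ra & nc >= 1,
    "RA keyword and 2 or more codes" = ra & nc >= 2,
    "RA keyword and 3 or more codes" = ra & nc >= 3,
    "RA keyword and 1 or more other keywords" = ra & nk - 1 >= 1,
    "RA keyword and 2 or more other keywords" = ra & nk - 1 >= 2,
    "RA keyword and 3 other keywords" = ra & nk - 1 >= 3,
    "RA keyword and 1 or more codes or keywords" = ra & nc + nk - 1 >= 1,
    "RA keyword and 2 or more codes or keywords" = ra & nc + nk - 1 >= 2,
    "RA keyword and 3 or more codes or keywords" = ra & nc + nk - 1 >= 3,
    "DMARD and 1 or more codes" = dm & nc - 1 >= 1,
    "DMARD and 2 or more codes" = dm & nc - 1 >= 2,
    "DMARD and 3 or more codes" = dm & nc - 1 >= 3,
    "DMARD and 1 or more keyword" = dm & nk >= 1,
    "DMARD and 2 or more keywords" = dm & nk >= 2,
    "DMARD and 3 keywords" = dm & nk >= 3,
    "DMARD and 1 or more codes or keywords" = dm & nc - 1 + nk >= 1,
    "DMARD and 2 or more codes or keywords" = dm & nc - 1 + nk >= 2,
    "DMARD and 3 or more codes or keywords" = dm & nc - 1 + nk >= 3)
  n <- vapply(defs, sum, integer(1))
  data.frame(label = names(defs), n = unname(n),
             percent = pct1(unname(n), den), stringsAsFactors = FALSE)
}
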