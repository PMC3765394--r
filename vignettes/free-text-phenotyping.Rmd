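---
title: "Quantifying diagnostic information hidden in primary-care free text"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying diagnostic information hidden in primary-care free text}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ratext)
```

## The problem

UK primary-care research databases (GPRD/CPRD-style extracts) record each
clinical event as a Read code plus, optionally, free text — a qualifier, a
consultation note, or a letter from a hospital specialist pasted into the
record. Most epidemiological work uses only the codes. For a condition like
rheumatoid arthritis (RA), which is not covered by pay-for-performance coding
rules and is often diagnosed in secondary care, diagnostic suspicions can
live in the text for weeks or months before (or instead of) a diagnostic
code. Case definitions built on codes alone may therefore miss or wrongly
date cases.

`ratext` implements a two-channel audit of this problem around each
patient's *index date* (their first RA diagnostic code):

* a **coded channel**: six indicator Read-code groups (inflammatory-arthritis
  diagnosis, synovitis, rheumatoid-factor test, DMARD prescription,
  rheumatology referral, joint signs/symptoms), matched as opaque exact
  tokens against explicit code lists, in any record table;
* a **textual channel**: four keyword groups (RA, positive rheumatoid
  factor, inflammatory arthritis, synovitis), matched as case-insensitive
  substrings anywhere in the free text, irrespective of word boundaries.

The outputs are the five result tables of such a study: prevalence of each
marker by gender with chi-squared comparisons; the interval from first
marker to index code (median/IQR, Mann–Whitney gender comparison,
Bonferroni-corrected); the ranking of Read codes attached to
keyword-bearing text; a per-topic crosstab of coded versus textual evidence
(whose *keyword only* cell is the "hidden information" estimate); and
combination counts usable for probabilistic case definition.

## Cohort and windows

A patient enters the cohort iff their first RA code falls inside the study
period (default 2005-01-01 to 2008-12-31), no RA code predates the study
start, they are at least 30 at index (age = index year − year of birth;
full birth dates are not modelled in these extracts), and their valid
observation — from the later of registration and the practice up-to-standard
date, to the earlier of transfer-out and last collection — covers the whole
window from one year before to 14 days after the index code. Events missing
an event date use the record-creation (system) date instead; events outside
the observation bounds are always discarded.

Code matching and all timing analyses use the *analysis window*
`[index − 365, index + 14]`. Keyword scanning uses a *search window* that
additionally extends back to the first DMARD prescription or first specific
marker code (we take "specific marker" to mean the inflammatory-arthritis
diagnosis and synovitis lists, the RA-specific diagnostic indicators; the
choice only widens text scanning, never the tabulated windows). Interval
statistics use only first occurrences on or before the index date, which is
why every reported IQR has a non-negative lower bound; occurrences in the
14-day tail still count toward prevalence. The `prevalence_window`
switch of `run_pipeline()` drops that tail for sensitivity analyses.

## Matching semantics, deliberately naive

Keyword matching is an exact, case-insensitive substring scan: "synovitis"
matches inside "tenosynovitis", and multi-word terms must occur verbatim
including internal spaces (variants and misspellings belong in the keyword
lists, not in the matcher). There is no negation or context handling — "no
evidence of synovitis" is a hit. This is a feature of the method being
audited, not an oversight: keyword searching is what can be run without
access to raw text for manual review, and its over-counting is one of the
quantities of interest. The synthetic generator therefore *injects* negated
and third-party mentions at a configurable rate so the over-count is
measurable against ground truth, and the package makes no attempt to correct
it.

## The synthetic generator

The real extracts behind studies of this kind are confidential, so the
package ships a generator whose defaults *are* the study conditions:

* 2,007 men and 4,380 women; index dates uniform over 2005–2008;
* age at index drawn from a piecewise-linear quantile function through the
  printed quartiles (51/62/72 men, 49/60/71 women) on [30, 95] — no
  distributional family is published, so the simplest curve through the
  known quartiles is used;
* per-group occurrence probabilities equal to the published pooled
  prevalences (e.g. 0.183 for the inflammatory-arthritis keyword group);
* first-occurrence offsets (days before index) from a log-normal fitted on
  the log scale to the published median and IQR, truncated to [0, 365] by
  inverse-CDF sampling and rounded to whole days. Because truncation pulls
  the median of a wide distribution down by tens of days, the log-median is
  re-solved so the *truncated* distribution keeps the target median; only
  skewness, not a distributional family, is published, so the log-normal is
  a calibration convenience;
* keyword events carry text built from ~20 snippet skeletons (clinic-letter
  and terse consultation styles) with one group term spliced in, attached to
  an administrative/communication code drawn from weights shaped like the
  published ranking (specialist letters dominate). The shipped weight pool
  is kept disjoint from every indicator list so the two channels stay
  independent in simulation — in real data they are not, which is exactly
  what the crosstab measures there;
* noise: 5% of keyword snippets negated/third-party, 2% of free text
  suppressed (emulating GP-withheld text; the published rate is unknown but
  described as small for letters), 0.1% of event dates missing, a mean of 8
  keyword-free distractor events per patient, and occasional events before
  the observation start that the windowing must discard.

What the generator does **not** emulate: realistic clinical language,
practice-level clustering of suppression, coding-style differences between
practices, or any dependence between the coded and textual channels. Tests
passing on synthetic data therefore validate the *pipeline arithmetic and
windowing logic* under known truth; they say nothing about keyword-list
sensitivity on real text.

## Numerical choices

* **Quartiles**: inverse-ECDF with averaging (type 2), so small integer-day
  samples report attained values ({0, 37, 121} gives IQR [0, 121]); at the
  published sample sizes the convention is immaterial.
* **Chi-squared**: Pearson on the 2×2 gender-by-flag table, no continuity
  correction; degenerate margins (a flag nobody or everybody carries, or a
  single-gender cohort) are reported as "no evidence of association"
  (statistic 0, p 1) rather than NaN, with single-gender cohorts also
  warned about.
* **Mann–Whitney**: exact null distribution for untied samples up to 50 per
  arm, otherwise normal approximation with tie correction and no continuity
  correction; two-sided throughout.
* **Bonferroni**: family size 10 (6 indicator + 4 keyword comparisons) by
  default, overridable.
* **Ranking ties**: frequency descending, then code string ascending — the
  published tables show ties, with no stated rule.
* **Anchored combination rows** ("RA keyword and ...", "DMARD and ...")
  exclude the anchor group from its companion count, reading "additional
  markers" literally; rows labelled "3 keywords" are implemented as
  thresholds (≥ 3) like their siblings.

## Problem sizes in the tests

The unit and property tests run on generated cohorts of 10–400 patients;
the calibration-recovery checks run one full-scale cohort (6,387 patients,
~86,000 events, about a second to generate and analyse), asserting every
group prevalence within three binomial standard errors of its configured
probability and every recovered median interval within ±10 days of its
target. A fixed generator seed (42) keeps those checks reproducible.

## Worked example

```{r example, eval = FALSE}
sim <- simulate_cohort(sim_config(seed = 42))
res <- run_pipeline(sim$patients, sim$events)
subset(res$tables$prevalence, group_name == "kw_inflammatory_arthritis")
subset(res$tables$crosstab, topic == "synovitis" & gender == "female")
```

The *keyword only* percentage in the synovitis crosstab row is the
proportion of women whose records mention synovitis in text with no
synovitis code — the "hidden" information this package exists to quantify.

## Limitations

The keyword and code lists shipped under `inst/extdata` are representative
defaults built from the published examples, not the full study lists (which
run to hundreds of entries); real analyses should supply their own
directories in the same layout. Keyword prevalence estimated by this method
is an over-count in the presence of negation and an under-count in the
presence of suppressed or scanned-PDF text; the package measures, and does
not correct, both effects. No control (non-RA) cohort comparison is
implemented, so predictive values of the markers cannot be estimated here.
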