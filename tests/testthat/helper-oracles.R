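# Independent oracles kept deliberately naive.

# Brute-force case-insensitive substring scan: compares every window of
# length nchar(term) against the term.
brute_substring <- function(text, term) {
  text <- tolower(text)
  term <- tolower(term)
  nt <- nchar(text)
  nm <- nchar(term)
  if (nm == 0L || nm > nt) return(FALSE)
  for (i in seq_len(nt - nm + 1L)) {
    if (substr(text, i, i + nm - 1L) == term) return(TRUE)
  }
  FALSE
}

# Exact two-sided Mann-Whitney p by full enumeration of all ways to assign
# the pooled (untied) values to the first sample.
mw_enum_p <- function(x, y) {
  z <- c(x, y)
  stopifnot(!anyDuplicated(z))
  m <- length(x)
  u_of <- function(xs, ys) sum(outer(xs, ys, ">"))
  u_obs <- u_of(x, y)
  splits <- utils::combn(length(z), m)
  u_all <- apply(splits, 2, function(idx) u_of(z[idx], z[-idx]))
  p <- 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs))
  min(1, p)
}

# Closed-form Pearson chi-squared for a 2x2 table.
chisq_closed <- function(a, b, c, d) {
  n <- a + b + c + d
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}
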