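# Independent brute-force oracles used across the statistical tests.
# These deliberately share no code with the package implementations.

# All tables with the given row/column margins (2 columns), as a list of
# matrices, found by recursion over the first-column entries.
enumerate_margin_tables <- function(row_margins, col_margins) {
  stopifnot(length(col_margins) == 2, sum(row_margins) == sum(col_margins))
  out <- list()
  recurse <- function(i, remaining, acc) {
    if (i > length(row_margins)) {
      if (remaining == 0) {
        out[[length(out) + 1]] <<- cbind(acc, row_margins - acc)
      }
      return(invisible())
    }
    lo <- max(0, remaining - sum(row_margins[-seq_len(i)]))
    hi <- min(row_margins[i], remaining)
    if (hi < lo) return(invisible())
    for (x in lo:hi) recurse(i + 1, remaining - x, c(acc, x))
  }
  recurse(1, col_margins[1], integer(0))
  out
}

# Multivariate hypergeometric probability of a table given its margins,
# via binomial coefficients (a different formula than the package's).
margin_table_prob <- function(tab) {
  r <- rowSums(tab)
  n <- sum(tab)
  exp(sum(lchoose(r, tab[, 1])) - lchoose(n, sum(tab[, 1])))
}

pearson_x2 <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}

# Exact two-sided Fisher p by probability ordering, via full enumeration.
oracle_fisher_p <- function(tab) {
  tabs <- enumerate_margin_tables(rowSums(tab), colSums(tab))
  probs <- vapply(tabs, margin_table_prob, numeric(1))
  obs <- margin_table_prob(tab)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Exact null tail probability of the Pearson X2 statistic (the quantity
# the Monte Carlo chi-squared test estimates), via full enumeration.
oracle_chi2_p <- function(tab) {
  tabs <- enumerate_margin_tables(rowSums(tab), colSums(tab))
  probs <- vapply(tabs, margin_table_prob, numeric(1))
  stats <- vapply(tabs, pearson_x2, numeric(1))
  sum(probs[stats >= pearson_x2(tab) - 1e-9])
}

# All 2x2 count tables with positive margins and total <= max_total.
all_small_2x2 <- function(max_total) {
  out <- list()
  for (n in 2:max_total) {
    for (a in 0:n) for (b in 0:(n - a)) for (cc in 0:(n - a - b)) {
      d <- n - a - b - cc
      tab <- matrix(c(a, cc, b, d), 2)
      if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) {
        out[[length(out) + 1]] <- tab
      }
    }
  }
  out
}

# Minimal pileup row builder for hand-constructed calling fixtures.
pileup_rows <- function(animal, replicate, position, ref, event, alt, depth) {
  tibble::tibble(
    animal = animal, replicate = as.integer(replicate),
    position = as.integer(position), ref = ref, event = event,
    alt_reads = as.integer(alt), depth = as.integer(depth)
  )
}

# Both replicates of a single-animal pileup in which each listed event has
# the stated deviant proportion (identical in both replicates).
two_rep_pileup <- function(animal, position, ref, event, prop1,
                           prop2 = prop1, depth = 1e5) {
  dplyr::bind_rows(
    pileup_rows(animal, 1L, position, ref, event, round(prop1 * depth), depth),
    pileup_rows(animal, 2L, position, ref, event, round(prop2 * depth), depth)
  )
}

noise_free_config <- function(...) {
  sim_config(
    substitution_error_rate = 0, indel_error_rate_base = 0,
    indel_error_replicate_sdlog = 0, recovery_rate = 1,
    exact_counts = TRUE, ...
  )
}
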