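chi2_stat <- function(tab) {
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - expected)^2 / expected)
}

check_table <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("contingency table must hold non-negative integer counts")
  }
  if (any(colSums(tab) == 0)) stop("zero column margin")
  storage.mode(tab) <- "double"
  tab
}

# log multivariate hypergeometric probability of a table given its margins
log_table_prob <- function(tab) {
  sum(lfactorial(rowSums(tab))) + sum(lfactorial(colSums(tab))) -
    lfactorial(sum(tab)) - sum(lfactorial(tab))
}

#' Monte Carlo chi-squared test of spectrum homogeneity
#'
#' Compares groups over arbitrarily many categories — typically
#' (position, class) cells, where asymptotic chi-squared theory fails —
#' by referring the Pearson X2 statistic to its null distribution over
#' tables with both margins fixed. Null tables are sampled by Patefield's
#' algorithm (multivariate hypergeometric allocation of mutations to
#' groups) and the p-value uses the add-one estimator
#' (1 + #{X2_sim >= X2_obs}) / (1 + n_sim), which can never be zero.
#'
#' @param tab Matrix of counts, categories x groups; all-zero rows are
#'   dropped.
#' @param n_sim Number of simulated null tables.
#' @param seed Optional seed for reproducibility (caller RNG state is
#'   restored).
#' @return List: statistic, p_value, n_sim, seed.
#' @export
monte_carlo_chi2 <- function(tab, n_sim = 1e5, seed = NULL) {
  tab <- check_table(tab)
  tab <- tab[rowSums(tab) > 0, , drop = FALSE]
  if (nrow(tab) < 2) stop("need at least two non-empty categories")
  obs <- chi2_stat(tab)
  sims <- with_seed_(seed, r2dtable(n_sim, rowSums(tab), colSums(tab)))
  stat_sim <- vapply(sims, chi2_stat, numeric(1))
  p <- (1 + sum(stat_sim >= obs - 1e-9)) / (1 + n_sim)
  list(statistic = obs, p_value = p, n_sim = n_sim, seed = seed)
}

#' Exact / Monte Carlo Fisher test on a type spectrum
#'
#' Tests homogeneity of a k-class x 2-group spectrum. 2x2 tables always
#' use the exact hypergeometric computation; larger tables with at most
#' `exact_max_classes` non-empty classes and total count at most
#' `exact_max_total` use the exact Freeman-Halton computation; the rest
#' use a Monte Carlo estimate of the exact p with both margins
#' fixed, scoring a simulated table as extreme when its hypergeometric
#' probability does not exceed the observed table's. Two-sided throughout
#' (probability-ordering convention).
#'
#' @param tab Matrix of counts, classes x groups.
#' @param n_sim Simulations for the Monte Carlo path.
#' @param seed Optional seed for the Monte Carlo path.
#' @param exact_max_classes,exact_max_total Size bounds for the exact
#'   path.
#' @return List: p_value, method ("exact" or "monte_carlo"), n_sim, seed.
#' @export
fisher_type_spectrum <- function(tab, n_sim = 1e5, seed = NULL,
                                 exact_max_classes = 5L,
                                 exact_max_total = 200L) {
  tab <- check_table(tab)
  tab <- tab[rowSums(tab) > 0, , drop = FALSE]
  if (nrow(tab) < 2) {
    return(list(p_value = 1, method = "degenerate", n_sim = 0L, seed = seed))
  }
  exact_2x2 <- nrow(tab) == 2 && ncol(tab) == 2 && exact_max_classes >= 2
  if (exact_2x2 || (nrow(tab) <= exact_max_classes && sum(tab) <= exact_max_total)) {
    p <- stats::fisher.test(tab, workspace = 2e7)$p.value
    return(list(p_value = min(1, p), method = "exact", n_sim = 0L, seed = seed))
  }
  obs <- log_table_prob(tab)
  sims <- with_seed_(seed, r2dtable(n_sim, rowSums(tab), colSums(tab)))
  lp <- vapply(sims, log_table_prob, numeric(1))
  p <- (1 + sum(lp <= obs + 1e-7)) / (1 + n_sim)
  list(p_value = p, method = "monte_carlo", n_sim = n_sim, seed = seed)
}

#' Per-class 2x2 Fisher screening with Bonferroni adjustment
#'
#' For each mutation class, builds the 2x2 sub-table of that class
#' against all other classes pooled, per group, and applies a two-sided
#' Fisher's exact test. The significance level is Bonferroni-adjusted by
#' the number of classes tested (classes absent from both groups are
#' skipped and do not count).
#'
#' @param counts Tibble (group, class, count) or matrix classes x 2
#'   groups.
#' @param alpha Family-wise level before adjustment (default 0.05).
#' @return Tibble: class, the four sub-table cells, odds_ratio, p_value,
#'   adjusted_alpha, significant.
#' @export
per_type_subtables <- function(counts, alpha = 0.05) {
  if (is.data.frame(counts)) {
    m <- tapply(counts$count, list(counts$class, counts$group), sum, default = 0L)
  } else {
    m <- as.matrix(counts)
  }
  if (ncol(m) != 2) stop("per-type screening compares exactly two groups")
  tested <- rownames(m)[rowSums(m) > 0]
  skipped <- setdiff(rownames(m), tested)
  if (length(skipped)) {
    message("class(es) absent in both groups skipped: ",
            paste(skipped, collapse = ", "))
  }
  k <- length(tested)
  tot <- colSums(m)
  res <- lapply(tested, function(cl) {
    sub <- rbind(m[cl, ], tot - m[cl, ])
    ft <- stats::fisher.test(sub)
    tibble::tibble(
      class = cl,
      count_1 = sub[1, 1], other_1 = sub[2, 1],
      count_2 = sub[1, 2], other_2 = sub[2, 2],
      odds_ratio = unname(ft$estimate),
      p_value = ft$p.value
    )
  })
  out <- dplyr::bind_rows(res)
  out$adjusted_alpha <- alpha / k
  out$significant <- out$p_value < out$adjusted_alpha
  out
}

#' Induced mutation spectrum, corrected for background and burden
#'
#' Puts two conditions (e.g. two tissues) on a common footing by removing
#' the background spectrum and the difference in overall mutant
#' frequency: the induced frequency of class c is
#' MF_treated x p_treated(c) - MF_control x p_control(c). Negative values
#' (classes where treatment did not raise the frequency) are clipped to 0
#' with a warning unless `clip = FALSE`. Induced proportions renormalize
#' the induced frequencies to sum to 1.
#'
#' @param control,treated Lists with `proportions` (named by class) and
#'   `mf`.
#' @param clip Clip negative induced frequencies at zero (default TRUE).
#' @return Tibble: class, induced_frequency, induced_proportion.
#' @export
induced_spectrum <- function(control, treated, clip = TRUE) {
  classes <- union(names(treated$proportions), names(control$proportions))
  pt <- treated$proportions[classes]
  pc <- control$proportions[classes]
  pt[is.na(pt)] <- 0
  pc[is.na(pc)] <- 0
  f <- treated$mf * pt - control$mf * pc
  if (all(f <= 0)) stop("no induced signal: treated spectrum does not exceed background")
  if (clip && any(f < 0)) {
    warning(sum(f < 0), " class(es) with negative induced frequency clipped to 0")
    f <- pmax(f, 0)
  }
  if (sum(f) <= 0) stop("induced frequencies sum to <= 0")
  tibble::tibble(
    class = classes,
    induced_frequency = unname(f),
    induced_proportion = unname(f / sum(f))
  )
}
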