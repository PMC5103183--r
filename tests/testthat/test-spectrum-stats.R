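test_that("exact Fisher path reproduces full-enumeration probabilities on small tables", {
  for (tab in all_small_2x2(7)) {
    expect_equal(
      fisher_type_spectrum(tab)$p_value, oracle_fisher_p(tab),
      tolerance = 1e-7
    )
  }
  set.seed(21)
  for (i in 1:10) {
    repeat {
      tab <- matrix(rpois(6, 3), 3)
      if (sum(tab) <= 30 && all(colSums(tab) > 0) && sum(rowSums(tab) > 0) >= 2) break
    }
    expect_equal(
      fisher_type_spectrum(tab)$p_value, oracle_fisher_p(tab),
      tolerance = 1e-7
    )
  }
})

test_that("Monte Carlo paths converge to their enumeration oracles", {
  set.seed(31)
  tabs <- c(
    list(matrix(c(5, 9, 6, 4), 2), matrix(c(10, 3, 2, 11), 2)),
    lapply(1:4, function(i) matrix(rpois(6, 4) + 1, 3))
  )
  for (tab in tabs) {
    n_sim <- 20000
    # chi-squared extremeness
    p_true <- oracle_chi2_p(tab)
    p_mc <- monte_carlo_chi2(tab, n_sim = n_sim, seed = 17)$p_value
    se <- sqrt(p_true * (1 - p_true) / n_sim)
    expect_lt(abs(p_mc - p_true), 4 * se + 2 / n_sim)
    # probability-ordering extremeness (forced Monte Carlo Fisher)
    p_true <- oracle_fisher_p(tab)
    p_mc <- fisher_type_spectrum(
      tab, n_sim = n_sim, seed = 17, exact_max_classes = 0
    )$p_value
    expect_identical(
      fisher_type_spectrum(tab, n_sim = n_sim, seed = 17,
                           exact_max_classes = 0)$method,
      "monte_carlo"
    )
    se <- sqrt(p_true * (1 - p_true) / n_sim)
    expect_lt(abs(p_mc - p_true), 4 * se + 2 / n_sim)
  }
})

test_that("Monte Carlo tests are seed-reproducible, add-one bounded, and preserve RNG state", {
  tab <- matrix(c(8, 2, 3, 9), 2)
  a <- monte_carlo_chi2(tab, n_sim = 5000, seed = 99)
  b <- monte_carlo_chi2(tab, n_sim = 5000, seed = 99)
  expect_identical(a$p_value, b$p_value)
  expect_gt(a$p_value, 0)
  expect_lte(a$p_value, 1)
  # extreme observed table: p floored by the add-one estimator, never 0
  extreme <- matrix(c(30, 0, 0, 30), 2)
  expect_gte(monte_carlo_chi2(extreme, n_sim = 1000, seed = 1)$p_value, 1 / 1001)

  set.seed(123)
  before <- .Random.seed
  invisible(monte_carlo_chi2(tab, n_sim = 100, seed = 7))
  expect_identical(.Random.seed, before)
})

test_that("degenerate and invalid tables are handled explicitly", {
  expect_equal(
    fisher_type_spectrum(matrix(c(5, 0, 7, 0), 2))$p_value, 1
  )
  expect_identical(
    fisher_type_spectrum(matrix(c(5, 0, 7, 0), 2))$method, "degenerate"
  )
  expect_error(monte_carlo_chi2(matrix(c(0, 0, 3, 4), 2)), "column margin")
  expect_error(monte_carlo_chi2(matrix(c(1.5, 2, 3, 4), 2)), "integer")
  # identical columns: null case
  expect_gt(monte_carlo_chi2(matrix(c(5, 9, 5, 9), 2), 2000, seed = 3)$p_value, 0.9)
  expect_equal(fisher_type_spectrum(matrix(c(5, 9, 5, 9), 2))$p_value, 1)
})

test_that("per-type screening matches a hypergeometric tail-sum oracle", {
  counts <- tibble::tibble(
    group = rep(c("a", "b"), each = 3),
    class = rep(c("G:C>A:T", "G:C>T:A", "deletion"), 2),
    count = c(8L, 3L, 2L, 2L, 9L, 3L)
  )
  res <- per_type_subtables(counts, alpha = 0.05)
  expect_equal(res$adjusted_alpha, rep(0.05 / 3, 3))
  for (i in seq_len(nrow(res))) {
    sub <- matrix(
      c(res$count_1[i], res$other_1[i], res$count_2[i], res$other_2[i]), 2
    )
    # oracle: enumerate the one free cell, sum hypergeometric probabilities
    # of tables no more probable than the observed one
    r <- rowSums(sub)
    cc <- colSums(sub)
    xs <- max(0, cc[1] - r[2]):min(r[1], cc[1])
    probs <- dhyper(xs, r[1], r[2], cc[1])
    obs <- dhyper(sub[1, 1], r[1], r[2], cc[1])
    expect_equal(res$p_value[i], sum(probs[probs <= obs * (1 + 1e-7)]),
                 tolerance = 1e-9)
  }
  # identical composition: never significant
  same <- tibble::tibble(
    group = rep(c("a", "b"), each = 2),
    class = rep(c("G:C>A:T", "deletion"), 2),
    count = c(10L, 5L, 20L, 10L)
  )
  expect_false(any(per_type_subtables(same)$significant))
  # a class absent everywhere is skipped and does not inflate k
  with_zero <- dplyr::bind_rows(
    same,
    tibble::tibble(group = c("a", "b"), class = "A:T>C:G", count = 0L)
  )
  expect_message(res0 <- per_type_subtables(with_zero), "skipped")
  expect_equal(res0$adjusted_alpha, rep(0.05 / 2, 2))
})

test_that("family-wise error of the screened comparison stays at the nominal level", {
  # null: both groups draw classes from the same spectrum, sizes as in the
  # case study (130 and 296 classified mutations)
  p <- sim_config()$spectrum_weights
  set.seed(2024)
  n_rep <- 400
  rejections <- vapply(seq_len(n_rep), function(i) {
    a <- as.integer(rmultinom(1, 130, p))
    b <- as.integer(rmultinom(1, 296, p))
    counts <- tibble::tibble(
      group = rep(c("a", "b"), each = length(p)),
      class = rep(names(p), 2),
      count = c(a, b)
    )
    any(suppressMessages(per_type_subtables(counts))$significant)
  }, logical(1))
  # binomial 95% upper bound on a true 5% rate at 400 replicates is ~0.074
  expect_lt(mean(rejections), 0.075)
})

test_that("induced spectra remove background and renormalize", {
  ctrl <- list(
    proportions = c("G:C>A:T" = 0.6, "G:C>T:A" = 0.3, deletion = 0.1),
    mf = 0
  )
  trt <- list(
    proportions = c("G:C>A:T" = 0.2, "G:C>T:A" = 0.5, deletion = 0.3),
    mf = 1e-4
  )
  out <- induced_spectrum(ctrl, trt)
  expect_equal(
    setNames(out$induced_proportion, out$class)[names(trt$proportions)],
    trt$proportions
  )  # zero background: induced spectrum equals the treated spectrum

  expect_error(induced_spectrum(trt, trt), "no induced signal")

  # two tissues constructed to share per-class induced frequencies have
  # identical induced proportions despite different backgrounds
  f <- c("G:C>A:T" = 2e-5, "G:C>T:A" = 6e-5, deletion = 2e-5)
  bg1 <- c("G:C>A:T" = 3e-5, "G:C>T:A" = 1e-5, deletion = 1e-5)
  bg2 <- c("G:C>A:T" = 0.5e-5, "G:C>T:A" = 1.5e-5, deletion = 1e-5)
  t1 <- list(proportions = (bg1 + f) / sum(bg1 + f), mf = sum(bg1 + f))
  t2 <- list(proportions = (bg2 + f) / sum(bg2 + f), mf = sum(bg2 + f))
  c1 <- list(proportions = bg1 / sum(bg1), mf = sum(bg1))
  c2 <- list(proportions = bg2 / sum(bg2), mf = sum(bg2))
  i1 <- induced_spectrum(c1, t1)
  i2 <- induced_spectrum(c2, t2)
  expect_equal(i1$induced_proportion, i2$induced_proportion, tolerance = 1e-9)
  expect_equal(
    setNames(i1$induced_proportion, i1$class),
    f / sum(f),
    tolerance = 1e-9
  )

  # clipping warns and keeps proportions normalized
  trt_neg <- list(
    proportions = c("G:C>A:T" = 0.05, "G:C>T:A" = 0.65, deletion = 0.3),
    mf = 5e-5
  )
  ctrl_pos <- list(
    proportions = c("G:C>A:T" = 0.9, "G:C>T:A" = 0.05, deletion = 0.05),
    mf = 4e-5
  )
  expect_warning(out <- induced_spectrum(ctrl_pos, trt_neg), "clipped")
  expect_equal(sum(out$induced_proportion), 1)
  expect_true(all(out$induced_frequency >= 0))
})
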