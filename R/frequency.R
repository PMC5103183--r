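#' Clonally corrected mutant frequency
#'
#' The plaque assay counts every recovered mutant, including clonal copies
#' of one premeiotic event, so the raw mutant frequency (mutant plaques /
#' total pfu) overstates the number of independent events. The correction
#' scales MF by the fraction of mutants that are independent:
#' corrected = MF x (1 - clonality).
#'
#' @param mf Raw mutant frequency (proportion; vectorized).
#' @param clonality Clonality as a proportion in `[0, 1)`.
#' @return Corrected mutant frequency, same scale as `mf`.
#' @examples
#' corrected_mf(1.6e-5, 0.568) * 1e5  # ~0.7
#' @export
corrected_mf <- function(mf, clonality) {
  if (any(is.na(clonality)) || any(clonality < 0) || any(clonality >= 1)) {
    stop("clonality must lie in [0, 1)")
  }
  mf * (1 - clonality)
}

#' Group summaries and fold changes of mutant frequency
#'
#' Group means are unweighted across animals and SDs are sample (n-1)
#' statistics, matching how transgenic-rodent assay results are
#' conventionally tabulated. Fold changes divide the treated group mean by
#' the control mean, for raw and corrected MF.
#'
#' @param summaries Tibble with columns animal, group, mf and clonality
#'   (proportions); corrected MF is computed internally.
#' @param control Label of the control group (default the first level).
#' @return List with `animals` (per-animal corrected MF added), `groups`
#'   (per-group mean/SD of raw and corrected MF and mean clonality) and
#'   `fold_change` (one row per non-control group).
#' @export
group_stats <- function(summaries, control = NULL) {
  need <- c("animal", "group", "mf", "clonality")
  missing <- setdiff(need, names(summaries))
  if (length(missing)) {
    stop("summaries missing column(s): ", paste(missing, collapse = ", "))
  }
  x <- summaries
  x$corrected_mf <- corrected_mf(x$mf, x$clonality)
  groups <- dplyr::summarise(
    dplyr::group_by(x, .data$group),
    n = dplyr::n(),
    mean_mf = mean(.data$mf),
    sd_mf = stats::sd(.data$mf),
    mean_corrected_mf = mean(.data$corrected_mf),
    sd_corrected_mf = stats::sd(.data$corrected_mf),
    mean_clonality = mean(.data$clonality),
    .groups = "drop"
  )
  if (any(groups$n < 2)) {
    warning("group(s) with a single animal: SD undefined there")
  }
  if (is.null(control)) control <- groups$group[1]
  if (!control %in% groups$group) stop("control group '", control, "' not found")
  ctrl <- groups[groups$group == control, ]
  treated <- groups[groups$group != control, ]
  fold <- tibble::tibble(
    group = treated$group,
    fold_change_mf = treated$mean_mf / ctrl$mean_mf,
    fold_change_corrected_mf = treated$mean_corrected_mf / ctrl$mean_corrected_mf
  )
  list(animals = x, groups = groups, fold_change = fold)
}

#' Overdispersion-adjusted binomial test of mutant frequency
#'
#' Fits a logistic regression of per-animal (mutant, non-mutant) plaque
#' counts on treatment group, then adjusts for overdispersion in the
#' quasi-likelihood sense: the dispersion is the Pearson statistic over
#' the residual degrees of freedom, standard errors are scaled by its
#' square root, and the two-sided p-value uses the t distribution on the
#' residual df. `force_dispersion = 1` recovers the ordinary binomial
#' fit's scaling (inference still t-based).
#'
#' @param summaries Tibble with columns group, mutant_plaques, total_pfu
#'   (one row per animal).
#' @param control Control group label (reference level; default first).
#' @param force_dispersion Optional fixed dispersion instead of the
#'   Pearson estimate.
#' @return List: coefficient (log odds ratio for the treated group),
#'   se, dispersion, df, p_value, separated flag, and the underlying glm
#'   fit.
#' @export
mf_test <- function(summaries, control = NULL, force_dispersion = NULL) {
  need <- c("group", "mutant_plaques", "total_pfu")
  missing <- setdiff(need, names(summaries))
  if (length(missing)) {
    stop("summaries missing column(s): ", paste(missing, collapse = ", "))
  }
  x <- summaries
  levels <- unique(x$group)
  if (length(levels) != 2) stop("mf_test() compares exactly two groups")
  if (is.null(control)) control <- levels[1]
  x$group <- stats::relevel(factor(x$group, levels = levels), ref = control)
  zero_group <- tapply(x$mutant_plaques, x$group, sum) == 0
  separated <- any(zero_group)
  if (separated) {
    warning("a group has zero mutant plaques: fit is separated, p unreliable")
  }
  fit <- stats::glm(
    cbind(mutant_plaques, total_pfu - mutant_plaques) ~ group,
    family = stats::binomial(), data = x
  )
  df <- fit$df.residual
  dispersion <- if (!is.null(force_dispersion)) {
    force_dispersion
  } else {
    sum(stats::residuals(fit, type = "pearson")^2) / df
  }
  coefs <- summary(fit)$coefficients
  beta <- coefs[2, "Estimate"]
  se <- coefs[2, "Std. Error"] * sqrt(dispersion)
  tval <- beta / se
  p <- 2 * stats::pt(-abs(tval), df)
  list(
    coefficient = unname(beta), se = unname(se), dispersion = dispersion,
    df = df, statistic = unname(tval), p_value = unname(p),
    separated = separated, fit = fit
  )
}
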