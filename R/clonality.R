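#' Estimate clone counts for passed mutation calls
#'
#' The raw clone estimate divides the average corrected deviant proportion
#' across the two technical replicates by the mutation-calling threshold:
#' a mutation carried by k of the N pooled plaques has expected corrected
#' proportion k/N and threshold 1/N, so the ratio estimates k. Because
#' quantification is imprecise near the limit of detection, the estimate
#' is adjusted by a pluggable limit-of-detection/linear rule: raw
#' estimates at or below `lod_bound` count as a single clone; above it,
#' the linear map `slope * raw + intercept` is rounded half-up and floored
#' at 1.
#'
#' When template recovery from the pooled plaques is incomplete, every
#' raw estimate is inflated by the same per-animal factor (plaques pooled
#' / plaques contributing template), because the denominator of the
#' deviant proportion shrinks while the calling threshold keeps the full
#' plaque count. `calibrate = TRUE` rescales per animal by the smallest
#' raw estimate — the singleton cluster, which defines the proportion
#' contributed by one plaque copy — before applying the rule. With
#' complete recovery the scale is ~1 and the calibrated rule reduces to
#' the default one.
#'
#' @param calls Calls tibble from [call_mutations()]; every row must have
#'   `passed == TRUE`.
#' @param lod_bound Raw-estimate bound below which a single clone is
#'   assumed (default 1.5).
#' @param slope,intercept Linear adjustment applied above the bound
#'   (defaults 1 and 0: plain rounding).
#' @param calibrate Rescale per animal by the singleton cluster (see
#'   Details); default FALSE.
#' @return The calls with `raw_clone_estimate` and integer `clone_count`.
#' @export
estimate_clones <- function(calls, lod_bound = 1.5, slope = 1, intercept = 0,
                            calibrate = FALSE) {
  if (nrow(calls) && !all(calls$passed)) {
    stop("estimate_clones() expects passed calls only; filter on `passed` first")
  }
  raw <- (calls$corrected_p1 + calls$corrected_p2) / 2 / calls$threshold
  scale <- rep(1, nrow(calls))
  if (calibrate && nrow(calls)) {
    per_animal <- tapply(raw, calls$animal, min)
    scale <- pmax(as.numeric(per_animal[calls$animal]), 1)
  }
  lin <- slope * raw / scale + intercept
  adjusted <- as.integer(ifelse(
    raw <= lod_bound * scale, 1L, pmax(1L, as.integer(floor(lin + 0.5)))
  ))
  calls$raw_clone_estimate <- raw
  calls$clone_count <- adjusted
  calls
}

#' Collapse calls to independent mutations
#'
#' Mutations recovered more than once per animal are taken to descend from
#' a single premeiotic event by clonal expansion: one record is kept per
#' distinct (animal, position, event), with clone counts summed across any
#' duplicate rows. Clones never span animals.
#'
#' @param estimates Calls with clone counts (from [estimate_clones()]), or
#'   any tibble with animal, position, ref, event and optionally
#'   clone_count / group columns.
#' @return Tibble of independent mutation records (one per animal x
#'   position x event) carrying `class` and `clone_count`.
#' @export
collapse_independent <- function(estimates) {
  x <- estimates
  if (!"clone_count" %in% names(x)) x$clone_count <- 1L
  keys <- c("animal", "position", "ref", "event")
  if ("group" %in% names(x)) keys <- c("animal", "group", "position", "ref", "event")
  out <- dplyr::summarise(
    dplyr::group_by(x, dplyr::across(dplyr::all_of(keys))),
    clone_count = sum(.data$clone_count), .groups = "drop"
  )
  out$class <- classify_mutation(out$ref, out$event)
  dplyr::arrange(out, .data$animal, .data$position, .data$event)
}

#' Per-animal clonality from independent mutation records
#'
#' Clonality is the fraction of identified mutants that are clonal copies:
#' 1 - n_independent / n_identified, where n_identified sums the adjusted
#' clone counts. Animals passed in `animals` but absent from the records
#' (no passed calls) get NA clonality — undefined, not zero.
#'
#' @param records Independent mutation records from
#'   [collapse_independent()].
#' @param animals Optional character vector of animals to report (adds NA
#'   rows for animals without calls).
#' @return Tibble: animal, n_independent, n_identified, clonality.
#' @export
animal_clonality <- function(records, animals = NULL) {
  out <- dplyr::summarise(
    dplyr::group_by(records, .data$animal),
    n_independent = dplyr::n(),
    n_identified = sum(.data$clone_count),
    clonality = 1 - .data$n_independent / .data$n_identified,
    .groups = "drop"
  )
  if (!is.null(animals)) {
    missing <- setdiff(animals, out$animal)
    if (length(missing)) {
      out <- dplyr::bind_rows(
        out,
        tibble::tibble(
          animal = missing, n_independent = NA_integer_,
          n_identified = NA_integer_, clonality = NA_real_
        )
      )
    }
    out <- out[match(animals, out$animal), ]
  }
  out
}
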