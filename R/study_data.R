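#' Bundled case study: mutant frequency and clonality per animal
#'
#' Plaque-assay mutant frequencies and NGS-derived clonality for the
#' bundled case study: 11 MutaMouse males (6 vehicle control, 5 dosed with
#' 100 mg/kg/day benzo(a)pyrene by gavage for 28 days), lacZ recovered
#' from cauda epididymis sperm sampled 42 days after exposure. The
#' `corrected_mf_printed_1e5` column carries the clonally corrected MF as
#' originally tabulated (1 decimal), for cross-checking
#' [corrected_mf()].
#'
#' @return Tibble: animal, group ("control"/"bap"), mf_1e5 (raw MF on the
#'   conventional x 1e-5 scale), clonality (proportion),
#'   corrected_mf_printed_1e5.
#' @export
study_mf_table <- function() {
  tibble::tibble(
    animal = as.character(1:11),
    group = rep(c("control", "bap"), c(6L, 5L)),
    mf_1e5 = c(1.6, 4.6, 4.7, 2.5, 3.3, 6.7, 13.4, 13.3, 11.2, 9.2, 18.4),
    clonality = c(56.8, 14.3, 58.5, 40.6, 26.8, 49.0,
                  27.8, 35.2, 17.2, 4.8, 39.1) / 100,
    corrected_mf_printed_1e5 = c(0.7, 3.9, 2.0, 1.5, 2.4, 3.4,
                                 9.7, 8.6, 9.3, 8.8, 11.2)
  )
}

#' Bundled case study: independent mutation counts per class
#'
#' Class counts of independent lacZ mutations in the bundled case study,
#' for sperm (the study tissue) and for bone marrow of similarly exposed
#' animals (the somatic comparator).
#'
#' @param tissue "sperm" or "bone_marrow".
#' @return Tibble: group, class, count.
#' @export
study_spectrum_counts <- function(tissue = c("sperm", "bone_marrow")) {
  tissue <- match.arg(tissue)
  subs <- MUTATION_CLASSES
  counts <- switch(tissue,
    sperm = list(
      control = c(75L, 28L, 11L, 1L, 1L, 0L, 3L, 11L),
      bap = c(39L, 117L, 27L, 4L, 9L, 1L, 13L, 86L)
    ),
    bone_marrow = list(
      control = c(45L, 47L, 13L, 6L, 5L, 8L, 3L, 17L),
      bap = c(111L, 345L, 129L, 3L, 25L, 10L, 27L, 152L)
    )
  )
  tibble::tibble(
    group = rep(c("control", "bap"), each = length(subs)),
    class = rep(subs, 2L),
    count = c(counts$control, counts$bap)
  )
}

#' Bundled case study: sequence-context counts of all mutations
#'
#' Per-group counts of independent mutations at A:T vs G:C basepairs and
#' at CpG / homopolymer contexts (the `n_total` column is the tabulated
#' header count of independent mutations, which for sperm controls
#' exceeds the classified A:T + G:C sum by one large deletion excluded
#' from the spectrum).
#'
#' @param tissue "sperm" or "bone_marrow".
#' @return Tibble: group, n_total, at, gc, cpg, homopolymer.
#' @export
study_context_counts <- function(tissue = c("sperm", "bone_marrow")) {
  tissue <- match.arg(tissue)
  switch(tissue,
    sperm = tibble::tibble(
      group = c("control", "bap"),
      n_total = c(131L, 296L),
      at = c(5L, 54L), gc = c(125L, 242L),
      cpg = c(60L, 168L), homopolymer = c(27L, 71L)
    ),
    bone_marrow = tibble::tibble(
      group = c("control", "bap"),
      n_total = c(144L, 802L),
      at = c(27L, 108L), gc = c(117L, 694L),
      cpg = c(69L, 470L), homopolymer = c(31L, 156L)
    )
  )
}

#' Bundled case study: sequencing and recovery totals
#'
#' @return List: input mutant plaques pooled for sequencing, mutants
#'   recovered from the alignment, independent mutations after clonal
#'   collapse (total and per group), and wildtype titre plaques sequenced.
#' @export
study_sequencing_totals <- function() {
  list(
    input_plaques = 1591L,
    recovered_mutants = 1117L,
    recovered_control = 393L,
    recovered_bap = 724L,
    independent_total = 427L,
    independent_control = 131L,
    independent_bap = 296L,
    wildtype_plaques = 200L
  )
}

#' Bundled case study: group mutant frequencies
#'
#' @return Named list of per-group mutant frequencies (proportions):
#'   sperm control/BaP and bone marrow BaP.
#' @export
study_group_mfs <- function() {
  list(
    sperm = c(control = 3.9e-5, bap = 13.1e-5),
    bone_marrow = c(bap = 701.7e-5)
  )
}

#' Bundled case study: CpG and dipyrimidine baselines for spontaneous
#' G:C to A:T transitions
#'
#' Counts used to test whether spontaneous G:C>A:T transitions in sperm
#' are enriched at CpG dinucleotides or at dipyrimidine sites relative to
#' the lacZ sequence composition. The two baselines tabulate slightly
#' different G:C totals (1754 vs 1737), as originally reported.
#'
#' @return List of two 2x2 matrices (`cpg`, `dipyrimidine`): row 1 =
#'   spontaneous transitions in/out of context, row 2 = lacZ G:C basepairs
#'   in/out of context.
#' @export
study_context_baselines <- function() {
  list(
    cpg = matrix(
      c(37, 38, 985, 1754 - 985), nrow = 2, byrow = TRUE,
      dimnames = list(c("transitions", "lacZ_GC"), c("in_context", "out"))
    ),
    dipyrimidine = matrix(
      c(61, 14, 1235, 1737 - 1235), nrow = 2, byrow = TRUE,
      dimnames = list(c("transitions", "lacZ_GC"), c("in_context", "out"))
    )
  )
}
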