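#' Annotate mutation records with sequence context
#'
#' Adds the context flags used in transgenic-rodent spectrum analysis:
#' \describe{
#'   \item{at_gc}{the reference basepair is G:C (else A:T).}
#'   \item{cpg}{the mutated position, or a position within `cpg_radius` of
#'     it, participates in a 5'-CG-3' dinucleotide. The default radius of 1
#'     implements "at or adjacent to a CpG"; radius 0 is strict
#'     membership.}
#'   \item{homopolymer}{the position is inside, or within
#'     `homopolymer_adjacency` bases of, a run of at least
#'     `homopolymer_min` identical bases.}
#'   \item{dipyrimidine}{the pyrimidine of the mutated basepair has a
#'     same-strand pyrimidine neighbour. For a pyrimidine reference base
#'     this checks the top strand; for a purine it checks the bottom
#'     strand, i.e. whether a neighbouring top-strand base is a purine.}
#' }
#' Positions at the sequence edge use whatever neighbours exist.
#'
#' @param records Mutation records (animal, position, ref, event, class).
#' @param reference A `tgr_reference`.
#' @param cpg_radius Neighbourhood radius for the CpG flag (default 1).
#' @param homopolymer_min Minimum run length called a homopolymer
#'   (default 3).
#' @param homopolymer_adjacency Bases of adjacency around a run
#'   (default 1).
#' @return `records` with logical columns at_gc, cpg, homopolymer,
#'   dipyrimidine.
#' @export
annotate_context <- function(records, reference, cpg_radius = 1L,
                             homopolymer_min = 3L, homopolymer_adjacency = 1L) {
  bases <- ref_bases(reference)
  L <- length(bases)
  if (any(records$position < 1 | records$position > L)) {
    stop("record position outside the reference")
  }
  # per-position CpG participation, then dilate by the radius
  is_c <- bases == "C"
  is_g <- bases == "G"
  cg_left <- is_c & c(is_g[-1], FALSE)          # C of a CG
  cg_right <- is_g & c(FALSE, is_c[-L])         # G of a CG
  cpg_part <- cg_left | cg_right
  cpg_near <- dilate_mask(cpg_part, cpg_radius)
  hp <- homopolymer_mask(bases, homopolymer_min, homopolymer_adjacency)

  pos <- records$position
  ref <- bases[pos]
  left <- ifelse(pos > 1, bases[pmax(pos - 1, 1)], NA)
  right <- ifelse(pos < L, bases[pmin(pos + 1, L)], NA)
  is_pyr <- ref %in% c("C", "T")
  # purine reference: the basepair's pyrimidine sits on the bottom strand,
  # whose neighbours are pyrimidines exactly where the top strand is purine
  neigh_pyr <- function(n, pyr) {
    !is.na(n) & ifelse(pyr, n %in% c("C", "T"), n %in% c("A", "G"))
  }
  dipy <- neigh_pyr(left, is_pyr) | neigh_pyr(right, is_pyr)

  records$at_gc <- ref %in% c("G", "C")
  records$cpg <- cpg_near[pos]
  records$homopolymer <- hp[pos]
  records$dipyrimidine <- dipy
  records
}

dilate_mask <- function(mask, radius) {
  if (radius <= 0 || !any(mask)) return(mask)
  idx <- which(mask)
  near <- unique(as.vector(outer(idx, -radius:radius, "+")))
  near <- near[near >= 1 & near <= length(mask)]
  out <- mask
  out[near] <- TRUE
  out
}

#' Find mutation hotspots per group
#'
#' A position is a hotspot in a dose group when independent mutations
#' occur there in more than one animal of that group; repeated mutations
#' within one animal count once.
#'
#' @param records Independent mutation records with animal, group,
#'   position.
#' @param min_animals Minimum distinct animals (default 2).
#' @return Tibble: group, position, n_animals, n_mutations.
#' @export
find_hotspots <- function(records, min_animals = 2L) {
  out <- dplyr::summarise(
    dplyr::group_by(records, .data$group, .data$position),
    n_animals = dplyr::n_distinct(.data$animal),
    n_mutations = dplyr::n(),
    .groups = "drop"
  )
  dplyr::arrange(
    out[out$n_animals >= min_animals, ], .data$group, .data$position
  )
}

#' Coding consequence of a mutation
#'
#' Substitutions inside the reading frame are translated before and after
#' the change with the standard genetic code: stop gain is "nonsense", a
#' preserved amino acid "silent", anything else "missense". Indels (all
#' 1-2 bp here) shift the frame: "frameshift". Positions outside the ORF
#' are "intergenic".
#'
#' @param records Mutation records (position, ref, event).
#' @param reference A `tgr_reference` whose `orf_start` anchors frame 0;
#'   the ORF is taken to run to the last complete codon.
#' @return `records` with a `consequence` column.
#' @export
call_consequence <- function(records, reference) {
  bases <- ref_bases(reference)
  code <- Biostrings::GENETIC_CODE
  orf_start <- reference$orf_start
  n_codons <- (length(bases) - orf_start + 1L) %/% 3L
  orf_end <- orf_start + 3L * n_codons - 1L
  kind <- event_kind(records$event)
  n <- nrow(records)
  out <- character(n)
  for (i in seq_len(n)) {
    pos <- records$position[i]
    if (pos < orf_start || pos > orf_end) {
      out[i] <- "intergenic"
    } else if (kind[i] != "substitution") {
      out[i] <- "frameshift"
    } else {
      off <- pos - orf_start
      c0 <- orf_start + 3L * (off %/% 3L)
      codon <- bases[c0:(c0 + 2L)]
      mutated <- codon
      mutated[off %% 3L + 1L] <- records$event[i]
      aa0 <- code[[paste(codon, collapse = "")]]
      aa1 <- code[[paste(mutated, collapse = "")]]
      out[i] <- if (aa1 == "*" && aa0 != "*") {
        "nonsense"
      } else if (aa1 == aa0) {
        "silent"
      } else {
        "missense"
      }
    }
  }
  records$consequence <- out
  records
}

#' Build a mutation spectrum table from independent records
#'
#' Counts and within-group proportions of the eight mutation classes.
#' When per-group mutant frequencies are supplied, an MF-weighted value
#' per class (proportion x group MF) is added, putting groups with
#' different mutational burdens on a common frequency scale.
#'
#' @param records Independent mutation records with group and class.
#' @param group_mfs Optional named vector of group mutant frequencies.
#' @return Spectrum tibble: group, class, count, proportion (and
#'   `weighted_mf` when MFs are given), complete over all classes.
#' @export
build_spectrum <- function(records, group_mfs = NULL) {
  counts <- dplyr::count(records, .data$group, .data$class, name = "count")
  counts <- spectrum_from_counts(counts)
  if (!is.null(group_mfs)) {
    missing <- setdiff(unique(counts$group), names(group_mfs))
    if (length(missing)) {
      stop("group_mfs missing for: ", paste(missing, collapse = ", "))
    }
    counts$weighted_mf <- counts$proportion * group_mfs[counts$group]
  }
  counts
}

#' Spectrum proportions from pre-tabulated class counts
#'
#' @param counts Tibble with group, class, count (classes may be
#'   incomplete; missing classes get zero counts).
#' @return Tibble with counts completed over [MUTATION_CLASSES] and
#'   within-group proportions.
#' @export
spectrum_from_counts <- function(counts) {
  if (!all(counts$class %in% MUTATION_CLASSES)) {
    stop("unknown class label(s): ",
         paste(setdiff(counts$class, MUTATION_CLASSES), collapse = ", "))
  }
  full <- tidyr::complete(
    counts,
    group = unique(counts$group),
    class = MUTATION_CLASSES,
    fill = list(count = 0L)
  )
  full <- dplyr::mutate(
    dplyr::group_by(full, .data$group),
    proportion = {
      tot <- sum(.data$count)
      if (tot == 0) {
        warning("group with zero mutations: proportions undefined")
        rep(NA_real_, dplyr::n())
      } else {
        .data$count / tot
      }
    }
  )
  full <- dplyr::ungroup(full)
  full$class <- factor(full$class, levels = MUTATION_CLASSES)
  dplyr::arrange(full, .data$group, .data$class)
}

#' Summarise sequence context per group
#'
#' Tabulates, per group, the counts and proportions of mutations at G:C
#' vs A:T basepairs and the fractions at CpG, homopolymer and
#' dipyrimidine contexts. Proportions are over classified records (the
#' A:T + G:C total).
#'
#' @param records Annotated records from [annotate_context()].
#' @return Tibble, one row per group.
#' @export
context_summary <- function(records) {
  dplyr::summarise(
    dplyr::group_by(records, .data$group),
    n = dplyr::n(),
    n_gc = sum(.data$at_gc),
    n_at = sum(!.data$at_gc),
    prop_gc = .data$n_gc / (.data$n_gc + .data$n_at),
    prop_at = .data$n_at / (.data$n_gc + .data$n_at),
    n_cpg = sum(.data$cpg),
    prop_cpg = mean(.data$cpg),
    n_homopolymer = sum(.data$homopolymer),
    prop_homopolymer = mean(.data$homopolymer),
    n_dipyrimidine = sum(.data$dipyrimidine),
    prop_dipyrimidine = mean(.data$dipyrimidine),
    .groups = "drop"
  )
}
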