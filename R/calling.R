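#' Estimate the false mutation proportion from wildtype pileups
#'
#' Wildtype (titre) plaques carry no true mutations, so any deviant reads
#' there measure PCR and sequencing error. The false mutation proportion
#' (FMP) for a (position, event) is the pooled deviant read count divided
#' by the pooled depth across all supplied wildtype samples. The maximum
#' FMP over substitution events is retained: indel events whose FMP
#' exceeds it are later discarded, which suppresses the homopolymer indel
#' errors characteristic of semiconductor sequencing.
#'
#' @param wildtype_pileup Pileup tibble of one or more wildtype samples
#'   (any number of animal/replicate combinations; all are pooled).
#' @return An `fmp_model`: list with `fmp` (tibble position, event, fmp)
#'   and `max_substitution_fmp`.
#' @export
estimate_fmp <- function(wildtype_pileup) {
  x <- validate_pileup(wildtype_pileup)
  if (nrow(x) == 0) stop("need at least one wildtype pileup row")
  depth_tbl <- dplyr::summarise(
    dplyr::group_by(
      dplyr::distinct(
        x, .data$animal, .data$replicate, .data$position, .data$depth
      ),
      .data$position
    ),
    pooled_depth = sum(.data$depth), .groups = "drop"
  )
  ev <- x[x$event != ".", ]
  alt_tbl <- dplyr::summarise(
    dplyr::group_by(ev, .data$position, .data$event),
    pooled_alt = sum(.data$alt_reads), .groups = "drop"
  )
  alt_tbl <- dplyr::left_join(alt_tbl, depth_tbl, by = "position")
  zero_depth <- is.na(alt_tbl$pooled_depth) | alt_tbl$pooled_depth == 0
  if (any(zero_depth)) {
    warning(
      "zero pooled depth at ", sum(zero_depth),
      " (position, event) pair(s); FMP treated as 0 there"
    )
  }
  alt_tbl$fmp <- ifelse(zero_depth, 0, alt_tbl$pooled_alt / alt_tbl$pooled_depth)
  subs <- alt_tbl$fmp[event_kind(alt_tbl$event) == "substitution"]
  structure(
    list(
      fmp = alt_tbl[, c("position", "event", "fmp")],
      max_substitution_fmp = if (length(subs)) max(subs) else 0
    ),
    class = "fmp_model"
  )
}

#' @export
print.fmp_model <- function(x, ...) {
  cat(
    "<fmp_model> ", nrow(x$fmp), " (position, event) estimates; ",
    "max substitution FMP = ", signif(x$max_substitution_fmp, 4), "\n",
    sep = ""
  )
  invisible(x)
}

fmp_lookup <- function(fmp_model, position, event) {
  key <- paste(position, event)
  idx <- match(key, paste(fmp_model$fmp$position, fmp_model$fmp$event))
  out <- fmp_model$fmp$fmp[idx]
  out[is.na(out)] <- 0
  out
}

#' Call mutations from duplicate pileups
#'
#' For every candidate (position, event) observed in either technical
#' replicate of an animal, the raw deviant proportion is corrected by
#' subtracting the false mutation proportion (clipped at 0). A mutation is
#' called when the corrected proportion reaches the mutation-calling
#' threshold, 1 / number of plaques pooled for that animal, in BOTH
#' replicates. Indel events whose FMP exceeds the highest substitution FMP
#' are discarded before thresholding; candidate indels longer than
#' `max_indel_length` are likewise dropped.
#'
#' @param pileup Pileup tibble covering both replicates of one or more
#'   animals.
#' @param fmp_model An [estimate_fmp()] model.
#' @param n_plaques Named vector or tibble (animal, n_sequenced or
#'   n_plaques) giving the plaques pooled per animal.
#' @param max_indel_length Longest indel considered (default 2 bp; larger
#'   structural events are outside the calling model).
#' @return Tibble of candidate calls: animal, position, ref, event,
#'   corrected proportions in both replicates, threshold and `passed`.
#' @export
call_mutations <- function(pileup, fmp_model, n_plaques, max_indel_length = 2L) {
  x <- validate_pileup(pileup)
  if (!inherits(fmp_model, "fmp_model")) stop("fmp_model must come from estimate_fmp()")
  np <- normalize_n_plaques(n_plaques)
  animals <- unique(x$animal)
  missing <- setdiff(animals, names(np))
  if (length(missing)) {
    stop("n_plaques missing for animal(s): ", paste(missing, collapse = ", "))
  }
  for (a in animals) {
    reps <- sort(unique(x$replicate[x$animal == a]))
    if (!identical(reps, c(1L, 2L))) {
      stop("animal ", a, " must have replicates 1 and 2")
    }
  }

  depth_tbl <- dplyr::distinct(
    x, .data$animal, .data$replicate, .data$position, .data$depth
  )
  ev <- x[x$event != "." & x$alt_reads > 0, ]
  if (nrow(ev) == 0) {
    return(empty_calls())
  }
  wide <- tidyr::pivot_wider(
    ev[, c("animal", "position", "ref", "event", "replicate", "alt_reads")],
    names_from = "replicate", values_from = "alt_reads",
    names_prefix = "alt_", values_fill = 0L
  )
  if (!"alt_1" %in% names(wide)) wide$alt_1 <- 0L
  if (!"alt_2" %in% names(wide)) wide$alt_2 <- 0L
  d1 <- depth_tbl[depth_tbl$replicate == 1L, c("animal", "position", "depth")]
  d2 <- depth_tbl[depth_tbl$replicate == 2L, c("animal", "position", "depth")]
  wide <- dplyr::left_join(wide, d1, by = c("animal", "position"))
  wide <- dplyr::left_join(
    wide, d2, by = c("animal", "position"), suffix = c("_1", "_2")
  )
  raw1 <- ifelse(
    is.na(wide$depth_1) | wide$depth_1 == 0, 0, wide$alt_1 / wide$depth_1
  )
  raw2 <- ifelse(
    is.na(wide$depth_2) | wide$depth_2 == 0, 0, wide$alt_2 / wide$depth_2
  )
  fmp <- fmp_lookup(fmp_model, wide$position, wide$event)
  kind <- event_kind(wide$event)
  indel_len <- ifelse(
    kind %in% c("insertion", "deletion"), nchar(wide$event) - 1L, 0L
  )
  keep <- !(kind %in% c("insertion", "deletion") &
              (fmp > fmp_model$max_substitution_fmp | indel_len > max_indel_length))
  out <- tibble::tibble(
    animal = wide$animal,
    position = wide$position,
    ref = wide$ref,
    event = wide$event,
    raw_p1 = raw1,
    raw_p2 = raw2,
    fmp = fmp,
    corrected_p1 = pmax(0, raw1 - fmp),
    corrected_p2 = pmax(0, raw2 - fmp),
    threshold = unname(1 / np[wide$animal])
  )[keep, ]
  eps <- 1e-12
  out$passed <- out$corrected_p1 >= out$threshold - eps &
    out$corrected_p2 >= out$threshold - eps
  dplyr::arrange(out, .data$animal, .data$position, .data$event)
}

empty_calls <- function() {
  tibble::tibble(
    animal = character(), position = integer(), ref = character(),
    event = character(), raw_p1 = numeric(), raw_p2 = numeric(),
    fmp = numeric(), corrected_p1 = numeric(), corrected_p2 = numeric(),
    threshold = numeric(), passed = logical()
  )
}

normalize_n_plaques <- function(n_plaques) {
  if (is.data.frame(n_plaques)) {
    col <- intersect(c("n_sequenced", "n_plaques"), names(n_plaques))[1]
    if (is.na(col) || !"animal" %in% names(n_plaques)) {
      stop("n_plaques table needs columns animal and n_sequenced (or n_plaques)")
    }
    np <- stats::setNames(n_plaques[[col]], n_plaques$animal)
  } else {
    np <- n_plaques
  }
  if (is.null(names(np))) stop("n_plaques must be named by animal")
  if (any(np < 1)) stop("n_plaques must be >= 1")
  np
}
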