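#' Read a reference transgene sequence from FASTA
#'
#' The reference is the sequence of the recovered transgene (lacZ in the
#' MutaMouse assay). Coordinates everywhere in this package are 1-based,
#' fully closed, on the transgene strand.
#'
#' @param path Path to a single-record FASTA file.
#' @param orf_start 1-based position of the first base of the reading frame
#'   (default 1).
#' @return A `tgr_reference` object: list with `id`, `seq` (uppercase
#'   character scalar) and `orf_start`.
#' @export
read_reference <- function(path, orf_start = 1L) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0) stop("no sequence records in ", path)
  if (length(set) > 1) stop("expected a single record, found ", length(set))
  seq <- toupper(as.character(set[[1]]))
  new_reference(seq, id = names(set)[1], orf_start = orf_start)
}

#' Construct a reference object from a sequence string
#'
#' @param seq Character scalar over A/C/G/T (case-insensitive).
#' @param id Sequence identifier.
#' @param orf_start 1-based start of the reading frame.
#' @return A `tgr_reference` object.
#' @export
new_reference <- function(seq, id = "reference", orf_start = 1L) {
  seq <- toupper(seq)
  bad <- gregexpr("[^ACGT]", seq)[[1]]
  if (bad[1] != -1) {
    stop(
      "non-ACGT character(s) at position(s): ",
      paste(utils::head(bad, 5), collapse = ", ")
    )
  }
  if (nchar(seq) < 3) stop("reference must be at least 3 bases long")
  structure(
    list(id = id, seq = seq, orf_start = as.integer(orf_start)),
    class = "tgr_reference"
  )
}

#' @export
print.tgr_reference <- function(x, ...) {
  cat(
    "<tgr_reference> ", x$id, ": ", nchar(x$seq), " bp, ORF from ",
    x$orf_start, "\n", sep = ""
  )
  invisible(x)
}

#' @export
length.tgr_reference <- function(x) nchar(x$seq)

#' Reference bases as a character vector
#' @param reference A `tgr_reference`.
#' @return Character vector of single bases.
#' @export
ref_bases <- function(reference) {
  strsplit(reference$seq, "", fixed = TRUE)[[1]]
}

#' Write a reference to FASTA
#' @param reference A `tgr_reference`.
#' @param path Output path.
#' @export
write_reference <- function(reference, path) {
  x <- Biostrings::DNAStringSet(reference$seq)
  names(x) <- reference$id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

pileup_cols <- c("animal", "replicate", "position", "ref", "event",
                 "alt_reads", "depth")

#' Read a per-replicate pileup count table
#'
#' The pileup TSV carries, per pooled plaque sample and technical
#' replicate, the reads supporting each alternate event at each reference
#' position, with the total read depth at that position. Rows with event
#' "." anchor the depth at positions with no deviant reads.
#'
#' @param path TSV with columns animal, replicate, position, ref, event,
#'   alt_reads, depth.
#' @param reference Optional `tgr_reference`; when supplied, positions and
#'   the ref column are validated against it.
#' @return A validated tibble of pileup rows.
#' @export
read_pileup <- function(path, reference = NULL) {
  x <- readr::read_tsv(
    path, na = ".",
    col_types = readr::cols(
      animal = readr::col_character(),
      replicate = readr::col_integer(),
      position = readr::col_integer(),
      ref = readr::col_character(),
      event = readr::col_character(),
      alt_reads = readr::col_integer(),
      depth = readr::col_integer()
    )
  )
  x$event[is.na(x$event)] <- "."
  validate_pileup(x, reference)
}

#' Validate a pileup tibble
#'
#' @param x Tibble with the pileup columns.
#' @param reference Optional `tgr_reference` for coordinate/ref checks.
#' @return The validated tibble (invisibly unchanged).
#' @export
validate_pileup <- function(x, reference = NULL) {
  missing <- setdiff(pileup_cols, names(x))
  if (length(missing)) {
    stop("pileup is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (!all(x$replicate %in% c(1L, 2L))) {
    stop("replicate must be 1 or 2")
  }
  if (any(x$alt_reads > x$depth)) {
    bad <- which(x$alt_reads > x$depth)[1]
    stop("alt_reads exceeds depth (first offending row: ", bad, ")")
  }
  if (any(x$alt_reads < 0) || any(x$depth < 0)) stop("negative counts")
  if (any(x$position < 1)) stop("positions must be 1-based (>= 1)")
  event_kind(x$event)  # errors on malformed events
  if (!is.null(reference)) {
    L <- length(reference)
    if (any(x$position > L)) stop("position beyond reference length ", L)
    rb <- ref_bases(reference)[x$position]
    bad <- which(!is.na(x$ref) & x$ref != rb)
    if (length(bad)) {
      stop(
        "ref column disagrees with reference at row(s): ",
        paste(utils::head(bad, 5), collapse = ", ")
      )
    }
  }
  x
}

#' Write a pileup tibble to TSV
#' @param x Pileup tibble.
#' @param path Output path.
#' @export
write_pileup <- function(x, path) {
  readr::write_tsv(x[, pileup_cols], path)
  invisible(path)
}

mutation_cols <- c("animal", "group", "position", "ref", "event", "class")

#' Read a table of independent mutations
#'
#' Ingests tables shaped like published per-mutation supplements: one row
#' per independent mutation with animal, group, position, reference base,
#' event and (optionally) a stated class and clone count. The class is
#' recomputed from ref/event; a stated class that disagrees raises a
#' warning naming the row.
#'
#' @param path TSV with columns animal, group, position, ref, event and
#'   optionally class, clone_count.
#' @param reference Optional `tgr_reference` for validation.
#' @return Tibble of mutation records with a recomputed `class` column.
#' @export
read_mutation_table <- function(path, reference = NULL) {
  x <- readr::read_tsv(path, na = ".", col_types = readr::cols())
  need <- c("animal", "group", "position", "ref", "event")
  missing <- setdiff(need, names(x))
  if (length(missing)) {
    stop("mutation table is missing column(s): ", paste(missing, collapse = ", "))
  }
  x$position <- as.integer(x$position)
  if (any(x$position < 1)) stop("positions must be 1-based (>= 1)")
  if (!is.null(reference)) {
    if (any(x$position > length(reference))) {
      stop("position beyond reference length ", length(reference))
    }
    rb <- ref_bases(reference)[x$position]
    if (any(x$ref != rb)) {
      stop(
        "ref column disagrees with reference at row(s): ",
        paste(utils::head(which(x$ref != rb), 5), collapse = ", ")
      )
    }
  }
  computed <- classify_mutation(x$ref, x$event)
  if ("class" %in% names(x)) {
    bad <- which(!is.na(x$class) & x$class != computed)
    if (length(bad)) {
      warning(
        "stated class disagrees with ref/event at row(s): ",
        paste(utils::head(bad, 5), collapse = ", "),
        " (recomputed class used)"
      )
    }
  }
  x$class <- computed
  if (!"clone_count" %in% names(x)) x$clone_count <- 1L
  first <- c("animal", "group", "position", "ref", "event", "class", "clone_count")
  x <- x[, c(first, setdiff(names(x), first))]
  tibble::as_tibble(x)
}

#' Write independent mutation records to TSV
#' @param x Mutation record tibble.
#' @param path Output path.
#' @export
write_mutation_table <- function(x, path) {
  keep <- intersect(c(mutation_cols, "clone_count"), names(x))
  readr::write_tsv(x[, keep], path)
  invisible(path)
}

#' Read per-animal plaque-assay counts
#'
#' @param path TSV with columns animal, group, mutant_plaques, total_pfu,
#'   n_sequenced (plaques pooled for sequencing).
#' @return Validated tibble; animals with total_pfu below 125,000 (the
#'   assay's minimum scored count) are flagged in `low_pfu`.
#' @export
read_plaque_counts <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols())
  need <- c("animal", "group", "mutant_plaques", "total_pfu", "n_sequenced")
  missing <- setdiff(need, names(x))
  if (length(missing)) {
    stop("plaque count table is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (any(x$n_sequenced < 1)) stop("n_sequenced must be >= 1")
  x$low_pfu <- x$total_pfu < 125000
  tibble::as_tibble(x)
}
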