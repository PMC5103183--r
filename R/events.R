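#' Mutation classes used throughout the pipeline
#'
#' Substitutions are reported by the reference basepair, normalized so the
#' purine (G or A) names the pair: both G>T and C>A are "G:C>T:A". Small
#' insertions and deletions (1-2 bp) form the remaining two classes.
#'
#' @format Character vector of the eight class labels.
#' @export
MUTATION_CLASSES <- c(
  "G:C>A:T", "G:C>T:A", "G:C>C:G",
  "A:T>G:C", "A:T>T:A", "A:T>C:G",
  "insertion", "deletion"
)

BASES <- c("A", "C", "G", "T")

complement_base <- function(x) chartr("ACGT", "TGCA", x)

#' Kind of an alternate event
#'
#' Events are encoded as strings: a single base ("T") is a substitution to
#' that base, "+XY" an insertion of XY after the anchor base, "-XY" a
#' deletion of XY starting at the anchor position, and "." a depth-anchor
#' row carrying no deviant reads.
#'
#' @param event Character vector of event strings.
#' @return Character vector: "substitution", "insertion", "deletion" or
#'   "none".
#' @export
event_kind <- function(event) {
  kind <- rep(NA_character_, length(event))
  kind[grepl("^[ACGT]$", event)] <- "substitution"
  kind[grepl("^\\+[ACGT]{1,2}$", event)] <- "insertion"
  kind[grepl("^-[ACGT]{1,2}$", event)] <- "deletion"
  kind[event == "."] <- "none"
  if (anyNA(kind)) {
    bad <- unique(event[is.na(kind)])
    stop("malformed event string(s): ", paste(utils::head(bad, 5), collapse = ", "))
  }
  kind
}

#' Classify a mutation into its basepair-normalized class
#'
#' Substitutions are complement-normalized so that the purine member (G or
#' A) of the reference basepair names the class; e.g. a C>A change is
#' reported as G:C>T:A. Indels are classified by sign regardless of length.
#'
#' @param ref_base Reference base at the mutated position ("A","C","G","T").
#' @param event Event string (see [event_kind()]).
#' @return Character vector of class labels from [MUTATION_CLASSES].
#' @examples
#' classify_mutation("G", "T")  # "G:C>T:A"
#' classify_mutation("C", "A")  # "G:C>T:A" (complement-normalized)
#' @export
classify_mutation <- function(ref_base, event) {
  n <- max(length(ref_base), length(event))
  ref_base <- rep_len(toupper(ref_base), n)
  event <- rep_len(event, n)
  if (!all(ref_base %in% BASES)) stop("ref_base must be one of A, C, G, T")
  kind <- event_kind(event)
  if (any(kind == "none")) stop("cannot classify a '.' depth-anchor row")
  out <- character(n)
  out[kind == "insertion"] <- "insertion"
  out[kind == "deletion"] <- "deletion"
  is_sub <- kind == "substitution"
  if (any(is_sub)) {
    ref <- ref_base[is_sub]
    alt <- event[is_sub]
    if (any(ref == alt)) stop("substitution event equals the reference base")
    flip <- ref %in% c("C", "T")
    ref[flip] <- complement_base(ref[flip])
    alt[flip] <- complement_base(alt[flip])
    out[is_sub] <- paste0(
      ref, ":", complement_base(ref), ">", alt, ":", complement_base(alt)
    )
  }
  stopifnot(all(out %in% MUTATION_CLASSES))
  out
}

# Evaluate `expr` under `seed`, restoring the caller's RNG state afterwards.
with_seed_ <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
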