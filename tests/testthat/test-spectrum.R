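test_that("all 12 substitutions classify to the purine-normalized pair", {
  # brute-force oracle: complement pyrimidine references, then label
  comp <- function(b) c(A = "T", C = "G", G = "C", T = "A")[[b]]
  for (ref in c("A", "C", "G", "T")) {
    for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
      r <- ref
      a <- alt
      if (r %in% c("C", "T")) {
        r <- comp(r)
        a <- comp(a)
      }
      want <- paste0(r, ":", comp(r), ">", a, ":", comp(a))
      expect_identical(classify_mutation(ref, alt), want)
      # strand symmetry: the complementary observation gives the same class
      expect_identical(classify_mutation(comp(ref), comp(alt)), want)
    }
  }
  expect_identical(classify_mutation("G", "T"), "G:C>T:A")
  expect_identical(classify_mutation("C", "A"), "G:C>T:A")
  expect_identical(classify_mutation("T", "G"), "A:T>C:G")
  expect_identical(classify_mutation(c("A", "C"), c("+G", "-CA")),
                   c("insertion", "deletion"))
  expect_error(classify_mutation("G", "G"), "equals the reference")
  expect_error(classify_mutation("G", "Z"), "malformed")
})

recs_at <- function(seq, positions) {
  ref <- new_reference(seq)
  b <- ref_bases(ref)
  alt <- ifelse(b[positions] == "A", "G", "A")
  list(ref = ref, records = tibble::tibble(
    animal = "x", group = "g", position = as.integer(positions),
    ref = b[positions], event = alt,
    class = classify_mutation(b[positions], alt)
  ))
}

test_that("context flags follow the CpG / homopolymer / dipyrimidine conventions", {
  # C of a CG dinucleotide
  x <- recs_at("ACGT", 2)
  expect_true(annotate_context(x$records, x$ref)$cpg)
  expect_true(annotate_context(x$records, x$ref)$at_gc)
  # adjacent to a CG still flags at the default radius, not at radius 0
  x <- recs_at("TACGT", 1)
  expect_false(annotate_context(x$records, x$ref)$cpg)
  x <- recs_at("TACGT", 2)
  expect_true(annotate_context(x$records, x$ref)$cpg)
  expect_false(annotate_context(x$records, x$ref, cpg_radius = 0)$cpg)

  # position adjacent to an AAA run counts as homopolymer context
  x <- recs_at("AAAGT", 4)
  expect_true(annotate_context(x$records, x$ref)$homopolymer)
  x <- recs_at("AAAGT", 5)
  expect_false(annotate_context(x$records, x$ref)$homopolymer)
  x <- recs_at("AAGGT", 1)
  expect_false(annotate_context(x$records, x$ref)$homopolymer)  # run of 2

  # C at position 3 of AGCTA has a T neighbour: dipyrimidine
  x <- recs_at("AGCTA", 3)
  expect_true(annotate_context(x$records, x$ref)$dipyrimidine)
  # G at position 2: bottom-strand C has neighbours T (from A) and G (from C)
  x <- recs_at("AGCTA", 2)
  expect_true(annotate_context(x$records, x$ref)$dipyrimidine)
  # isolated pyrimidine between purines
  x <- recs_at("ACGAT", 2)
  expect_false(annotate_context(x$records, x$ref)$dipyrimidine)
})

test_that("dipyrimidine flags match a two-strand enumeration oracle", {
  set.seed(11)
  comp <- function(b) chartr("ACGT", "TGCA", b)
  for (rep in 1:10) {
    seq <- paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE), collapse = "")
    x <- recs_at(seq, 1:40)
    got <- annotate_context(x$records, x$ref)$dipyrimidine
    b <- ref_bases(x$ref)
    bottom <- comp(b)  # bottom-strand base under each top-strand position
    want <- vapply(1:40, function(i) {
      neigh <- c(i - 1, i + 1)
      neigh <- neigh[neigh >= 1 & neigh <= 40]
      if (b[i] %in% c("C", "T")) {
        any(b[neigh] %in% c("C", "T"))
      } else {
        any(bottom[neigh] %in% c("C", "T"))
      }
    }, logical(1))
    expect_identical(got, want)
  }
})

test_that("context flags are invariant under reverse complementation", {
  set.seed(12)
  comp_rev <- function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }
  for (rep in 1:5) {
    L <- 30
    seq <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    fwd <- recs_at(seq, 1:L)
    rev <- recs_at(comp_rev(seq), L:1)  # mirrored positions
    a <- annotate_context(fwd$records, fwd$ref)
    b <- annotate_context(rev$records, rev$ref)
    for (flag in c("at_gc", "cpg", "homopolymer", "dipyrimidine")) {
      expect_identical(a[[flag]], b[[flag]])
    }
  }
})

test_that("hotspots require independent mutations in more than one animal", {
  rec <- tibble::tibble(
    animal = c("a1", "a2", "a3", "a3", "a1"),
    group = c("g", "g", "g", "g", "h"),
    position = c(50L, 50L, 60L, 60L, 50L),
    ref = "G", event = "T"
  )
  hs <- find_hotspots(rec)
  expect_equal(nrow(hs), 1)
  expect_equal(hs$position, 50L)       # two animals of group g
  expect_equal(hs$n_animals, 2L)
  # twice in one animal is not a hotspot; a single animal in group h neither

  # planted recurrence: exactly 7 hotspot positions
  set.seed(5)
  hot_pos <- sort(sample(1:500, 7))
  planted <- dplyr::bind_rows(
    tibble::tibble(animal = "a1", group = "g", position = hot_pos),
    tibble::tibble(animal = "a2", group = "g", position = hot_pos),
    tibble::tibble(animal = "a1", group = "g", position = 501:540)
  )
  planted$ref <- "G"
  planted$event <- "T"
  expect_equal(find_hotspots(planted)$position, hot_pos)
})

test_that("codon consequences match translation of the mutated sequence", {
  # CAA -> TAA is a canonical stop gain; GGC -> GGT third-position silent
  ref <- new_reference("ATGCAAGGC")
  recs <- tibble::tibble(
    animal = "x", position = c(4L, 9L), ref = c("C", "C"), event = c("T", "T")
  )
  out <- call_consequence(recs, ref)
  expect_identical(out$consequence, c("nonsense", "silent"))

  # all nine single-base changes of a codon, against a translation oracle
  ref <- new_reference("ATGTGGAAA")  # codon 2 = TGG (Trp)
  b <- ref_bases(ref)
  for (off in 0:2) {
    pos <- 4L + off
    for (alt in setdiff(c("A", "C", "G", "T"), b[pos])) {
      got <- call_consequence(
        tibble::tibble(animal = "x", position = pos, ref = b[pos], event = alt),
        ref
      )$consequence
      mutated <- b
      mutated[pos] <- alt
      aa0 <- as.character(Biostrings::translate(
        Biostrings::DNAString(paste(b, collapse = ""))
      ))
      aa1 <- as.character(Biostrings::translate(
        Biostrings::DNAString(paste(mutated, collapse = ""))
      ))
      want <- if (substr(aa1, 2, 2) == "*") {
        "nonsense"
      } else if (aa0 == aa1) "silent" else "missense"
      expect_identical(got, want)
    }
  }

  # indels shift the frame; positions outside the ORF are intergenic
  ref <- new_reference("TTATGCAA", orf_start = 3L)
  out <- call_consequence(
    tibble::tibble(
      animal = "x", position = c(1L, 4L, 6L),
      ref = c("T", "T", "C"), event = c("C", "-T", "+A")
    ),
    ref
  )
  expect_identical(out$consequence, c("intergenic", "frameshift", "frameshift"))
})

test_that("spectrum tables carry counts, proportions and optional MF weighting", {
  counts <- study_spectrum_counts("sperm")
  sp <- spectrum_from_counts(counts)
  expect_equal(sum(sp$proportion[sp$group == "bap"]), 1)
  expect_equal(
    sp$proportion[sp$group == "bap" & sp$class == "deletion"],
    86 / 296
  )
  rec <- tibble::tibble(
    animal = "a", group = "g", position = 1L, ref = "G", event = "T",
    class = "G:C>T:A"
  )
  sp1 <- build_spectrum(rec)
  expect_equal(sp1$proportion[sp1$class == "G:C>T:A"], 1)
  expect_equal(sum(sp1$count), 1L)

  spw <- build_spectrum(rec, group_mfs = c(g = 0))
  expect_true(all(spw$weighted_mf == 0))
  expect_error(build_spectrum(rec, group_mfs = c(other = 1e-5)), "missing")
})

test_that("context summaries use classified records as the denominator", {
  ref <- new_reference("ATGGGCCCAAATTT")
  rec <- recs_at("ATGGGCCCAAATTT", c(4, 5, 9, 12))$records
  rec <- annotate_context(rec, ref)
  cs <- context_summary(rec)
  expect_equal(cs$n_gc + cs$n_at, cs$n)
  expect_equal(cs$prop_gc, 0.5)
})
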