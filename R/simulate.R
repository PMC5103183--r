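#' Configuration for the plaque-pool simulator
#'
#' The defaults emulate the scale of a MutaMouse lacZ NGS experiment: ~144
#' mutant plaques pooled per animal, duplicate technical replicates, and
#' ~2700-fold sequencing depth per pooled lacZ copy. The error model is
#' Ion-Torrent-like: substitution error dominates at non-repeat positions
#' while indel error is strongly elevated at homopolymer runs.
#'
#' @param reference_length Reference length in bp (divisible by 3).
#' @param gc_fraction Target G+C fraction of the reference.
#' @param n_animals_per_group Animals simulated per call.
#' @param plaques_per_animal Mutant plaques pooled per animal.
#' @param depth_per_copy Sequencing depth per pooled lacZ copy; total depth
#'   at a position is `depth_per_copy * plaques_per_animal`.
#' @param clonality_target Per-animal clonality (1 - independent/identified)
#'   the clone-size distribution is tuned to; must be < 1. With partial
#'   recovery the clone-size parameter is calibrated so the *recovered*
#'   pool hits this clonality in expectation.
#' @param mutations_per_animal Independent mutations drawn per animal
#'   before recovery; at the default recovery rate ~39 per animal survive,
#'   the per-animal scale of the assay this simulator emulates.
#' @param recovery_rate Probability that a pooled plaque contributes
#'   template to the sequencing library (default 0.702, the recovered /
#'   input mutant ratio of the emulated assay). Mutations whose copies are
#'   all lost never reach the pileup and are absent from the truth table;
#'   surviving mutations are enriched relative to the 1/plaques calling
#'   threshold, which is what makes that threshold conservative. Set to 1
#'   for the idealized complete-recovery pool.
#' @param spectrum_weights Named probability vector over
#'   [MUTATION_CLASSES] summing to 1.
#' @param substitution_error_rate Mean deviant-read proportion per
#'   (position, alternate base) per replicate from PCR/sequencing error.
#'   Site-specific rates are drawn once per run from a Gamma distribution
#'   with this mean and shape `substitution_error_shape`, and are shared
#'   between the wildtype and mutant pools (error is sequence-context
#'   driven), which is what makes subtractive FMP correction effective.
#' @param substitution_error_shape Gamma shape of the site-to-site
#'   substitution rate distribution (default 0.3: a heavy tail, so the
#'   maximum substitution FMP is driven by a few error-prone sites).
#' @param indel_error_rate_base Mean indel error rate at non-homopolymer
#'   positions.
#' @param indel_error_homopolymer_multiplier Multiplier (>= 1) applied to
#'   the indel error rate within or adjacent to homopolymer runs (>= 3
#'   identical bases).
#' @param indel_error_replicate_sdlog Log-sd of the mean-preserving
#'   lognormal jitter applied to each site's indel error rate
#'   independently in every library replicate (default 0.3). Homopolymer
#'   slippage is unstable between amplifications, so wildtype FMP
#'   under-corrects it; the resulting unstable events are what the indel
#'   FMP filter removes.
#' @param mf True mutant frequency used to draw plaque-assay counts.
#' @param total_pfu Total plaque-forming units scored per animal.
#' @param exact_counts Emit expected read counts (round(depth x
#'   proportion)) instead of binomial draws (default FALSE). This is the
#'   noise-free limit: binomial sampling at any depth leaves a mutation
#'   whose expected proportion sits exactly at the calling threshold with
#'   only even odds of clearing it.
#' @param error_seed Seed of the site-specific error landscape. The
#'   landscape is a property of the platform and sequence context, so
#'   configs sharing this seed (the default) see identical per-site error
#'   rates — which is what lets wildtype-estimated FMP correct the mutant
#'   pools of every group in the same experiment. Change it to emulate a
#'   different sequencing run.
#' @param seed Integer seed; the same seed reproduces the simulation
#'   bit-identically.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(reference_length = 3000L,
                       gc_fraction = 0.57,
                       n_animals_per_group = 5L,
                       plaques_per_animal = 144L,
                       depth_per_copy = 2700L,
                       clonality_target = 0.3,
                       mutations_per_animal = 50L,
                       recovery_rate = 0.702,
                       spectrum_weights = NULL,
                       substitution_error_rate = 2e-3,
                       substitution_error_shape = 0.3,
                       indel_error_rate_base = 5e-4,
                       indel_error_homopolymer_multiplier = 20,
                       indel_error_replicate_sdlog = 0.3,
                       mf = 13.1e-5,
                       total_pfu = 3e5,
                       exact_counts = FALSE,
                       error_seed = 104729L,
                       seed = 1L) {
  if (is.null(spectrum_weights)) {
    counts <- study_spectrum_counts("sperm")
    bap <- counts[counts$group == "bap", ]
    spectrum_weights <- stats::setNames(bap$count / sum(bap$count), bap$class)
  }
  cfg <- list(
    reference_length = as.integer(reference_length),
    gc_fraction = gc_fraction,
    n_animals_per_group = as.integer(n_animals_per_group),
    plaques_per_animal = as.integer(plaques_per_animal),
    depth_per_copy = as.integer(depth_per_copy),
    clonality_target = clonality_target,
    mutations_per_animal = as.integer(mutations_per_animal),
    recovery_rate = recovery_rate,
    spectrum_weights = spectrum_weights,
    substitution_error_rate = substitution_error_rate,
    substitution_error_shape = substitution_error_shape,
    indel_error_rate_base = indel_error_rate_base,
    indel_error_homopolymer_multiplier = indel_error_homopolymer_multiplier,
    indel_error_replicate_sdlog = indel_error_replicate_sdlog,
    mf = mf,
    total_pfu = total_pfu,
    exact_counts = isTRUE(exact_counts),
    error_seed = as.integer(error_seed),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  w <- cfg$spectrum_weights
  if (is.null(names(w)) || !all(names(w) %in% MUTATION_CLASSES)) {
    stop("spectrum_weights must be named by mutation class")
  }
  if (abs(sum(w) - 1) > 1e-9) stop("spectrum_weights must sum to 1")
  rates <- c(
    cfg$gc_fraction, cfg$clonality_target, cfg$substitution_error_rate,
    cfg$indel_error_rate_base
  )
  if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0, 1]")
  if (cfg$indel_error_homopolymer_multiplier < 1) {
    stop("indel_error_homopolymer_multiplier must be >= 1")
  }
  if (cfg$recovery_rate <= 0 || cfg$recovery_rate > 1) {
    stop("recovery_rate must lie in (0, 1]")
  }
  counts <- c(
    cfg$reference_length, cfg$n_animals_per_group, cfg$plaques_per_animal,
    cfg$depth_per_copy, cfg$mutations_per_animal
  )
  if (any(counts < 1)) stop("counts must be positive")
  if (cfg$clonality_target >= 1) {
    stop("clonality_target must be < 1: a finite plaque pool cannot realize full clonality")
  }
  structure(cfg, class = "sim_config")
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Generate a synthetic reference ORF
#'
#' Produces a stand-in for the lacZ transgene: a sequence of the requested
#' length and G+C content that starts with ATG and contains no in-frame
#' internal stop codon, so codon-consequence calls are well defined. The
#' G+C count is fixed exactly (up to the forced start codon) and frame-0
#' stop codons are repaired by permuting the bases within the offending
#' codon, which preserves base composition.
#'
#' @param length Sequence length in bp; must be >= 3 and divisible by 3.
#' @param gc_fraction Target G+C fraction in `[0, 1]`.
#' @param seed Integer seed (same seed, same sequence).
#' @return A `tgr_reference` with ORF starting at position 1.
#' @export
generate_reference <- function(length, gc_fraction = 0.57, seed = 1L) {
  length <- as.integer(length)
  if (length < 3L || length %% 3L != 0L) {
    stop("length must be >= 3 and divisible by 3 (got ", length, ")")
  }
  if (gc_fraction < 0 || gc_fraction > 1) stop("gc_fraction must be in [0, 1]")
  if (length == 3L) {
    return(new_reference("ATG", id = "synthetic_orf"))
  }
  bases <- with_seed_(seed, {
    n_rest <- length - 3L
    k_gc <- max(0L, min(n_rest, as.integer(round(gc_fraction * length)) - 1L))
    rest <- c(
      ifelse(stats::runif(k_gc) < 0.5, "G", "C"),
      ifelse(stats::runif(n_rest - k_gc) < 0.5, "A", "T")
    )
    rest <- sample(rest, n_rest)
    b <- c("A", "T", "G", rest)
    # repair in-frame stop codons by permuting within the codon
    perms <- rbind(
      c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1)
    )
    for (i in seq(4L, length - 2L, by = 3L)) {
      codon <- b[i:(i + 2L)]
      if (paste(codon, collapse = "") %in% STOP_CODONS) {
        for (p in seq_len(nrow(perms))) {
          cand <- codon[perms[p, ]]
          if (!paste(cand, collapse = "") %in% STOP_CODONS) {
            b[i:(i + 2L)] <- cand
            break
          }
        }
      }
    }
    b
  })
  new_reference(paste(bases, collapse = ""), id = "synthetic_orf")
}

# Positions inside, or within `adjacency` bases of, a run of >= min_run
# identical bases. Shared by the simulator's error model and the spectrum
# module's context annotation.
homopolymer_mask <- function(bases, min_run = 3L, adjacency = 1L) {
  r <- rle(bases)
  in_run <- inverse.rle(list(lengths = r$lengths, values = r$lengths >= min_run))
  if (adjacency > 0 && any(in_run)) {
    idx <- which(in_run)
    near <- unique(as.vector(outer(idx, -adjacency:adjacency, "+")))
    near <- near[near >= 1 & near <= length(bases)]
    in_run[near] <- TRUE
  }
  in_run
}

# Map a substitution class + reference base to the alternate base.
substitution_alt <- function(class, ref) {
  # class like "G:C>T:A"; the purine row of the class applied to the purine
  # strand, complemented when ref is the pyrimidine member.
  from <- substr(class, 1, 1)
  to <- substr(class, 5, 5)
  ifelse(ref == from, to, complement_base(to))
}

draw_clone_counts <- function(m, clonality, plaques, recovery_rate = 1) {
  if (m > plaques) {
    stop("more independent mutations (", m, ") than plaques (", plaques, ")")
  }
  # Zero-truncated geometric clone sizes: P(k) = (1-q) q^(k-1), mean
  # 1/(1-q). Binomial thinning at recovery rate rho maps ZTG(q) survivors
  # back to ZTG(q~) with q~ = q * rho / (1 - q * (1 - rho)), and the
  # recovered pool's expected clonality equals q~; solving q~ = target
  # gives the calibration below, so the *recovered* clonality hits the
  # target regardless of rho (q = target when rho = 1).
  s <- 1 - recovery_rate
  q <- clonality / (1 - (1 - clonality) * s)
  k <- 1L + stats::rgeom(m, prob = 1 - q)
  # respect the plaque budget: trim the largest clones
  while (sum(k) > plaques) {
    i <- which.max(k)
    k[i] <- max(1L, k[i] - (sum(k) - plaques))
  }
  k
}

#' Simulate pooled mutant-plaque sequencing for one treatment group
#'
#' For each animal: draws independent mutations with classes following
#' `spectrum_weights` (each placed at a base consistent with its class),
#' expands each to a clone count from a zero-truncated geometric
#' distribution tuned to `clonality_target`, then emits two technical
#' replicate pileups. Each pooled plaque contributes template to the
#' library independently with probability `recovery_rate`; a mutation
#' surviving with k' copies among M contributing plaques has expected
#' deviant proportion k'/M in both replicates (equal to clone_count/N
#' exactly when recovery is complete), with binomial sampling noise at
#' depth `depth_per_copy * M` and additive PCR/sequencing error events
#' (indel error multiplied at homopolymer runs). Mutations losing every
#' copy are absent from both the pileup and the truth table. Plaque-assay
#' counts are drawn from the configured true mutant frequency.
#'
#' @param config A [sim_config()].
#' @param reference A `tgr_reference` (e.g. from [generate_reference()]).
#' @param group Group label attached to the simulated animals.
#' @return List with `truth` (one row per recovered independent mutation:
#'   animal, position, ref, event, class, clone_count = surviving copies),
#'   `pileup` (long tibble, both replicates of every animal), and
#'   `plaques` (per-animal counts: mutant_plaques, total_pfu,
#'   n_sequenced).
#' @export
simulate_pools <- function(config, reference, group = "treated") {
  stopifnot(inherits(config, "sim_config"), inherits(reference, "tgr_reference"))
  bases <- ref_bases(reference)
  L <- length(bases)
  gc_sites <- which(bases %in% c("G", "C"))
  at_sites <- which(bases %in% c("A", "T"))
  profile <- error_profile(config, reference)
  N <- config$plaques_per_animal
  rho <- config$recovery_rate

  with_seed_(config$seed, {
    truth <- list()
    pileups <- list()
    plaques <- list()
    for (a in seq_len(config$n_animals_per_group)) {
      animal <- sprintf("%s_%02d", group, a)
      m <- config$mutations_per_animal
      cls <- sample(
        names(config$spectrum_weights), m,
        replace = TRUE, prob = config$spectrum_weights
      )
      is_gc <- grepl("^G:C", cls)
      is_at <- grepl("^A:T", cls)
      is_indel <- cls %in% c("insertion", "deletion")
      pos <- integer(m)
      if (sum(is_gc) > length(gc_sites) || sum(is_at) > length(at_sites)) {
        stop("reference too short for the requested mutation load")
      }
      pos[is_gc] <- sample(gc_sites, sum(is_gc))
      pos[is_at] <- sample(at_sites, sum(is_at))
      free <- setdiff(seq_len(L), pos[!is_indel])
      pos[is_indel] <- sample(free, sum(is_indel))
      ref <- bases[pos]
      event <- character(m)
      event[is_gc | is_at] <- substitution_alt(cls[is_gc | is_at], ref[is_gc | is_at])
      event[cls == "insertion"] <- paste0("+", ref[cls == "insertion"])
      event[cls == "deletion"] <- paste0("-", ref[cls == "deletion"])
      k <- draw_clone_counts(m, config$clonality_target, N, rho)
      # plaque-template recovery: thin each clone, count the pool size
      k_surv <- stats::rbinom(m, k, rho)
      m_pool <- sum(k_surv) + stats::rbinom(1L, N - sum(k), rho)
      if (m_pool < 1) stop("no plaque template recovered; raise recovery_rate")
      keep <- k_surv >= 1L
      truth[[animal]] <- tibble::tibble(
        animal = animal, group = group, position = pos[keep],
        ref = ref[keep], event = event[keep], class = cls[keep],
        clone_count = k_surv[keep]
      )
      depth <- config$depth_per_copy * m_pool
      for (r in 1:2) {
        pileups[[paste(animal, r)]] <- simulate_replicate(
          animal, r, bases, profile, pos[keep], event[keep], k_surv[keep],
          m_pool, depth, config
        )
      }
      mut <- stats::rbinom(1, as.integer(config$total_pfu), config$mf)
      plaques[[animal]] <- tibble::tibble(
        animal = animal, group = group, mutant_plaques = mut,
        total_pfu = as.integer(config$total_pfu), n_sequenced = N
      )
    }
    list(
      truth = dplyr::bind_rows(truth),
      pileup = dplyr::bind_rows(pileups),
      plaques = dplyr::bind_rows(plaques)
    )
  })
}

# Per-run error profile: site-specific mean error rates, fixed for a
# given config seed and reference so the wildtype and mutant pools see
# the same error landscape (FMP subtraction then cancels its mean).
error_profile <- function(config, reference) {
  bases <- ref_bases(reference)
  L <- length(bases)
  hp <- homopolymer_mask(bases)
  idx <- match(bases, BASES)
  with_seed_(config$error_seed, {
    sub_rates <- if (config$substitution_error_rate > 0) {
      stats::rgamma(
        3L * L, shape = config$substitution_error_shape,
        rate = config$substitution_error_shape / config$substitution_error_rate
      )
    } else {
      numeric(3L * L)
    }
    site_indel <- config$indel_error_rate_base *
      ifelse(hp, config$indel_error_homopolymer_multiplier, 1)
    list(
      sub_events = c(
        BASES[idx %% 4 + 1], BASES[(idx + 1) %% 4 + 1], BASES[(idx + 2) %% 4 + 1]
      ),
      sub_positions = rep(seq_len(L), 3L),
      sub_rates = pmin(sub_rates, 0.5),
      del_rates = site_indel,
      ins_rates = site_indel
    )
  })
}

# One technical replicate: true signal + independent error events per
# position, aggregated to pileup rows with a "." depth anchor per position.
simulate_replicate <- function(animal, replicate, bases, profile, pos, event,
                               k, n_pool, depth, config) {
  L <- length(bases)
  draw <- if (config$exact_counts) {
    function(n, size, prob) as.integer(round(size * prob))
  } else {
    stats::rbinom
  }
  rows <- list()
  if (any(profile$sub_rates > 0)) {
    rows$sub_err <- tibble::tibble(
      position = profile$sub_positions,
      event = profile$sub_events,
      alt_reads = draw(3L * L, depth, profile$sub_rates)
    )
  }
  if (config$indel_error_rate_base > 0) {
    sdlog <- config$indel_error_replicate_sdlog
    jitter <- function(rates) {
      if (sdlog <= 0) return(rates)
      rates * stats::rlnorm(length(rates), -sdlog^2 / 2, sdlog)
    }
    rows$del_err <- tibble::tibble(
      position = seq_len(L), event = paste0("-", bases),
      alt_reads = draw(L, depth, pmin(1, jitter(profile$del_rates)))
    )
    rows$ins_err <- tibble::tibble(
      position = seq_len(L), event = paste0("+", bases),
      alt_reads = draw(L, depth, pmin(1, jitter(profile$ins_rates)))
    )
  }
  rows$signal <- tibble::tibble(
    position = pos, event = event,
    alt_reads = draw(length(pos), depth, k / n_pool)
  )
  x <- dplyr::bind_rows(rows)
  x <- dplyr::summarise(
    dplyr::group_by(x, .data$position, .data$event),
    alt_reads = sum(.data$alt_reads), .groups = "drop"
  )
  x <- x[x$alt_reads > 0, ]
  anchors <- tibble::tibble(
    position = seq_len(L), event = ".", alt_reads = 0L
  )
  x <- dplyr::bind_rows(x, anchors)
  x <- dplyr::arrange(x, .data$position, .data$event)
  tibble::tibble(
    animal = animal, replicate = as.integer(replicate),
    position = x$position, ref = bases[x$position], event = x$event,
    alt_reads = as.integer(pmin(x$alt_reads, depth)), depth = depth
  )
}

#' Simulate wildtype (titre-plaque) pileups carrying only error
#'
#' Wildtype plaques carry no mutations, so their pileups estimate the
#' false mutation proportion of the PCR/sequencing process under the same
#' error model as the mutant pools.
#'
#' @param config A [sim_config()].
#' @param reference A `tgr_reference`.
#' @param n_plaques Number of pooled wildtype plaques (default 200, the
#'   scale at which titre plaques are typically sequenced).
#' @param seed Seed; defaults to `config$seed + 1` so wildtype noise is
#'   independent of the mutant pools.
#' @return Pileup tibble (two replicates of one "wildtype" sample).
#' @export
simulate_wildtype <- function(config, reference, n_plaques = 200L,
                              seed = config$seed + 1L) {
  bases <- ref_bases(reference)
  profile <- error_profile(config, reference)
  depth <- config$depth_per_copy * n_plaques
  with_seed_(seed, {
    dplyr::bind_rows(lapply(1:2, function(r) {
      simulate_replicate(
        "wildtype", r, bases, profile,
        pos = integer(0), event = character(0), k = integer(0),
        n_pool = n_plaques, depth = depth, config = config
      )
    }))
  })
}

#' Realized clonality of a simulation truth table
#'
#' @param truth Truth tibble from [simulate_pools()].
#' @return Tibble with animal, n_independent, n_identified and clonality
#'   (1 - independent/identified).
#' @export
truth_clonality <- function(truth) {
  dplyr::summarise(
    dplyr::group_by(truth, .data$animal),
    n_independent = dplyr::n(),
    n_identified = sum(.data$clone_count),
    clonality = 1 - .data$n_independent / .data$n_identified,
    .groups = "drop"
  )
}
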