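#!/usr/bin/env Rscript

# Step 1: simulate a full study's raw material with known ground truth.
#
# Generates a synthetic lacZ-like reference ORF (57% G+C, as the real
# transgene) and two treatment groups of plaque pools: a control group
# drawn from the spontaneous sperm spectrum and an exposed group drawn
# from the benzo(a)pyrene-induced spectrum, at the study's scale (144
# plaques pooled per animal, duplicate replicates, ~2700x depth per
# recovered copy, ~70% template recovery). Also simulates the wildtype
# titre plaques used downstream to estimate PCR/sequencing error.

suppressPackageStartupMessages({
  library(tgrspectra)
  library(dplyr)
  library(readr)
})

dir.create("results/sim", showWarnings = FALSE, recursive = TRUE)
# raw pileups are bulky and fully regenerable: they live under scratch/
dir.create("scratch/sim", showWarnings = FALSE, recursive = TRUE)

ref <- generate_reference(3000, gc_fraction = 0.57, seed = 2016)
write_reference(ref, "results/sim/reference.fa")

weights_for <- function(group) {
  counts <- study_spectrum_counts("sperm")
  x <- counts[counts$group == group, ]
  setNames(x$count / sum(x$count), x$class)
}

# group-level conditions mirror the case study: spontaneous ~41% clonality
# and MF 3.9e-5 in controls; induced ~25% clonality and MF 13.1e-5, with
# more mutations per animal
cfg_control <- sim_config(
  reference_length = 3000, n_animals_per_group = 6,
  clonality_target = 0.41, mutations_per_animal = 30,
  spectrum_weights = weights_for("control"), mf = 3.9e-5, seed = 101
)
cfg_bap <- sim_config(
  reference_length = 3000, n_animals_per_group = 5,
  clonality_target = 0.25, mutations_per_animal = 70,
  spectrum_weights = weights_for("bap"), mf = 13.1e-5, seed = 202
)

sim_control <- simulate_pools(cfg_control, ref, group = "control")
sim_bap <- simulate_pools(cfg_bap, ref, group = "bap")
wildtype <- simulate_wildtype(cfg_control, ref)

truth <- bind_rows(sim_control$truth, sim_bap$truth)
pileup <- bind_rows(sim_control$pileup, sim_bap$pileup)
plaques <- bind_rows(sim_control$plaques, sim_bap$plaques)

write_tsv(truth, "results/sim/truth.tsv")
write_pileup(pileup, "scratch/sim/pileup.tsv")
write_pileup(wildtype, "scratch/sim/wildtype_pileup.tsv")
write_tsv(plaques, "results/sim/plaques.tsv")

cl <- truth_clonality(truth)
message(sprintf(
  "simulated %d animals, %d recovered independent mutations (mean clonality control %.2f, exposed %.2f)",
  nrow(plaques), nrow(truth),
  mean(cl$clonality[grepl("^control", cl$animal)]),
  mean(cl$clonality[grepl("^bap", cl$animal)])
))
message("wrote reference.fa, truth.tsv, plaques.tsv under results/sim/; pileups under scratch/sim/")
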