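test_that("generated references are valid ORFs with the requested composition", {
  cases <- list(
    list(len = 3000L, gc = 0.57, seed = 1L),
    list(len = 600L, gc = 0.40, seed = 2L),
    list(len = 300L, gc = 0.80, seed = 5L)
  )
  for (cs in cases) {
    ref <- generate_reference(cs$len, cs$gc, cs$seed)
    b <- ref_bases(ref)
    expect_length(b, cs$len)
    expect_identical(paste(b[1:3], collapse = ""), "ATG")
    codons <- vapply(
      seq(1, cs$len - 2, by = 3),
      function(i) paste(b[i:(i + 2)], collapse = ""), character(1)
    )
    expect_false(any(codons[-1] %in% c("TAA", "TAG", "TGA")))
    expect_lt(abs(mean(b %in% c("G", "C")) - cs$gc), 0.05)
  }
})

test_that("reference generation handles boundary cases and rejects bad lengths", {
  expect_identical(generate_reference(3, 0.5, 99)$seq, "ATG")
  b <- ref_bases(generate_reference(300, 0, 7))
  expect_true(all(b[-3] %in% c("A", "T")))  # only the forced ATG carries a G
  expect_error(generate_reference(100, 0.5, 1), "divisible")
  expect_error(generate_reference(2, 0.5, 1), "divisible|>= 3")
  expect_identical(
    generate_reference(300, 0.57, 4)$seq,
    generate_reference(300, 0.57, 4)$seq
  )
  expect_false(
    identical(generate_reference(300, 0.57, 4)$seq,
              generate_reference(300, 0.57, 5)$seq)
  )
})

test_that("noise-free pools carry deviant proportions k/N in both replicates", {
  ref <- generate_reference(300, 0.5, seed = 2)
  cfg <- noise_free_config(
    reference_length = 300, n_animals_per_group = 1, plaques_per_animal = 50,
    depth_per_copy = 20000, clonality_target = 0.4, mutations_per_animal = 8,
    seed = 21
  )
  sim <- simulate_pools(cfg, ref, group = "g")
  ev <- sim$pileup[sim$pileup$event != ".", ]
  # only true mutations produce deviant reads
  expect_setequal(
    paste(ev$position, ev$event),
    paste(sim$truth$position, sim$truth$event)
  )
  for (r in 1:2) {
    evr <- ev[ev$replicate == r, ]
    idx <- match(paste(evr$position, evr$event),
                 paste(sim$truth$position, sim$truth$event))
    expected <- sim$truth$clone_count[idx] / 50
    expect_true(all(abs(evr$alt_reads / evr$depth - expected) < 4 * sqrt(expected / evr$depth) + 1e-9))
  }
})

test_that("zero clonality target yields single-copy mutations only", {
  ref <- generate_reference(300, 0.5, seed = 2)
  cfg <- noise_free_config(
    reference_length = 300, n_animals_per_group = 2, plaques_per_animal = 100,
    clonality_target = 0, mutations_per_animal = 10, seed = 3
  )
  sim <- simulate_pools(cfg, ref)
  expect_true(all(sim$truth$clone_count == 1L))
  expect_true(all(truth_clonality(sim$truth)$clonality == 0))
})

test_that("simulated class counts follow the configured spectrum (multinomial bounds)", {
  ref <- generate_reference(1200, 0.57, seed = 8)
  w <- sim_config()$spectrum_weights  # the case study's exposed-group spectrum
  cfg <- noise_free_config(
    reference_length = 1200, n_animals_per_group = 8, plaques_per_animal = 100,
    clonality_target = 0, mutations_per_animal = 37,  # 8 x 37 = 296 draws
    spectrum_weights = w, seed = 13
  )
  sim <- simulate_pools(cfg, ref)
  n <- nrow(sim$truth)
  expect_equal(n, 296L)
  obs <- table(factor(sim$truth$class, levels = names(w)))
  for (cl in names(w)) {
    mu <- n * w[[cl]]
    sigma <- sqrt(n * w[[cl]] * (1 - w[[cl]]))
    expect_lt(abs(obs[[cl]] - mu), 3 * sigma + 1e-9)
  }
})

test_that("simulation is seed-reproducible and replicates share truth but not noise", {
  ref <- generate_reference(300, 0.5, seed = 2)
  cfg <- sim_config(
    reference_length = 300, n_animals_per_group = 1, plaques_per_animal = 100,
    mutations_per_animal = 10, seed = 77
  )
  a <- simulate_pools(cfg, ref)
  b <- simulate_pools(cfg, ref)
  expect_identical(a$truth, b$truth)
  expect_identical(a$pileup, b$pileup)
  r1 <- a$pileup[a$pileup$replicate == 1 & a$pileup$event != ".", ]
  r2 <- a$pileup[a$pileup$replicate == 2 & a$pileup$event != ".", ]
  expect_false(identical(r1$alt_reads, r2$alt_reads))
})

test_that("mutation placement respects class/base compatibility and the plaque budget", {
  ref <- generate_reference(600, 0.57, seed = 2)
  for (s in 1:5) {
    cfg <- sim_config(
      reference_length = 600, n_animals_per_group = 2, plaques_per_animal = 120,
      clonality_target = 0.5, mutations_per_animal = 30, seed = s
    )
    sim <- simulate_pools(cfg, ref)
    tr <- sim$truth
    gc_cls <- grepl("^G:C", tr$class)
    at_cls <- grepl("^A:T", tr$class)
    expect_true(all(tr$ref[gc_cls] %in% c("G", "C")))
    expect_true(all(tr$ref[at_cls] %in% c("A", "T")))
    budget <- tapply(tr$clone_count, tr$animal, sum)
    expect_true(all(budget <= 120))
  }
})

test_that("realized clonality tracks the target across seeds", {
  ref <- generate_reference(300, 0.5, seed = 2)
  for (target in c(0.15, 0.4)) {
    cl <- vapply(1:20, function(s) {
      cfg <- sim_config(
        reference_length = 300, n_animals_per_group = 1,
        plaques_per_animal = 144, clonality_target = target,
        mutations_per_animal = 30, indel_error_rate_base = 0,
        substitution_error_rate = 0, seed = 1000 + s
      )
      mean(truth_clonality(simulate_pools(cfg, ref)$truth)$clonality)
    }, numeric(1))
    expect_lt(abs(mean(cl) - target), 0.05)
  }
})

test_that("impossible clonality or mutation loads are rejected", {
  expect_error(sim_config(clonality_target = 1), "clonality_target")
  expect_error(
    sim_config(clonality_target = 1, plaques_per_animal = 1),
    "clonality_target"
  )
  ref <- generate_reference(300, 0.5, seed = 2)
  cfg <- noise_free_config(
    reference_length = 300, n_animals_per_group = 1, plaques_per_animal = 10,
    mutations_per_animal = 20, seed = 1
  )
  expect_error(simulate_pools(cfg, ref), "more independent mutations")
  expect_error(sim_config(spectrum_weights = c("G:C>A:T" = 0.5)), "sum to 1")
  expect_error(sim_config(gc_fraction = 1.2), "rates")
})
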