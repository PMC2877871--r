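test_that("background generation is seeded, sized and composed correctly", {
  expect_equal(generate_background(0, seed = 1)$sequence, "")
  a <- generate_background(500, seed = 10)
  b <- generate_background(500, seed = 10)
  expect_identical(a$sequence, b$sequence)
  expect_false(identical(a$sequence,
                         generate_background(500, seed = 11)$sequence))

  skewed <- generate_background(20000,
                                base_probabilities = c(A = 0.7, C = 0.1,
                                                       G = 0.1, T = 0.1),
                                seed = 2)
  comp <- table(strsplit(skewed$sequence, "")[[1]]) / 20000
  expect_lt(abs(comp[["A"]] - 0.7), 0.02)
})

test_that("clean backgrounds contain no motif instances", {
  m <- compile_motif()
  rec <- generate_background(50000, seed = 4, motif = m,
                             clean_background = TRUE)
  expect_equal(nrow(scan_sequence(rec, m)), 0L)
})

test_that("cleaning fails loudly when the alphabet cannot escape the motif", {
  m <- compile_motif("AAA", "AAA", 3)
  expect_error(
    generate_background(100, base_probabilities = c(A = 1, C = 0, G = 0, T = 0),
                        seed = 1, motif = m, clean_background = TRUE,
                        max_passes = 10),
    "could not remove")
})

test_that("raw background hit count matches the analytic expectation", {
  m <- compile_motif()
  rec <- generate_background(1e6, seed = 123, motif = m,
                             clean_background = FALSE)
  n <- nrow(scan_sequence(rec, m))
  expected <- expected_count(1e6, mode = "exact_positions")$expected
  # site counts are approximately Poisson in the rare-site regime
  expect_lt(abs(n - expected), 3 * sqrt(expected))
})

test_that("plant_motifs writes sites that the scanner recovers", {
  m <- compile_motif()
  bg <- generate_background(680, seed = 6, motif = m, clean_background = TRUE)
  planted <- plant_motifs(bg, data.frame(position = 86, spacer_length = 3), m)
  h <- scan_sequence(planted, m)
  expect_equal(h$start, 86L)
  expect_equal(h$end, 95L)

  expect_error(plant_motifs(bg, data.frame(position = 679, spacer_length = 3),
                            m),
               "outside")
  expect_error(plant_motifs(bg, data.frame(position = c(86, 90),
                                           spacer_length = c(3, 3)), m),
               "overlap")

  # the bundled three-site geometry yields exactly 3 hits on clean background
  ds <- simulate_dataset(vvl_like_config(seed = 8))
  h3 <- scan_sequence(ds$root, m)
  expect_equal(nrow(h3), 3L)
  expect_equal(h3$start, c(86L, 219L, 508L))
  expect_equal(h3$spacer_length, c(3L, 4L, 3L))

  # explicit spacer text is honored
  p2 <- plant_motifs(bg, data.frame(position = 10, spacer_length = 4,
                                    spacer_text = "ACGT"), m)
  expect_equal(substr(p2$sequence, 11, 20), "TTCACGTGAA")
})

test_that("zero-rate evolution returns identical, ungapped members", {
  ds <- simulate_dataset(vvl_like_config(seed = 12, substitution_rate = 0))
  expect_equal(length(ds$ortho$species), 10L)
  expect_equal(ds$ortho$focal_species, "melanogaster")
  for (sp in ds$ortho$species) {
    expect_identical(ds$ortho$aligned[[sp]], ds$root$sequence)
  }
})

test_that("evolution is deterministic per seed and respects protection", {
  cfg <- vvl_like_config(seed = 33, substitution_rate = 0.3)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$ortho$aligned, d2$ortho$aligned)

  # protected intervals are copied verbatim into every species
  prot <- statsites:::protected_mask(cfg$length, cfg$protected_intervals)
  rootc <- strsplit(d1$root$sequence, "")[[1]]
  for (sp in d1$ortho$species) {
    spc <- strsplit(d1$ortho$aligned[[sp]], "")[[1]]
    expect_identical(spc[prot], rootc[prot])
  }
})

test_that("substitution fraction matches the nominal rate", {
  rate <- 0.1
  n_seeds <- 200
  fracs <- numeric(0)
  set.seed(5)
  seeds <- sample.int(.Machine$integer.max, n_seeds)
  for (s in seeds) {
    cfg <- vvl_like_config(seed = s, substitution_rate = rate)
    ds <- simulate_dataset(cfg)
    prot <- statsites:::protected_mask(cfg$length, cfg$protected_intervals)
    rootc <- strsplit(ds$root$sequence, "")[[1]]
    sp <- ds$ortho$species[2]
    spc <- strsplit(ds$ortho$aligned[[sp]], "")[[1]]
    fracs <- c(fracs, mean(spc[!prot] != rootc[!prot]))
  }
  n_unprotected <- 680 - sum(statsites:::protected_mask(
    680, vvl_like_config()$protected_intervals))
  se <- sqrt(rate * (1 - rate) / (n_seeds * n_unprotected))
  expect_lt(abs(mean(fracs) - rate), 3 * se)
})

test_that("indels produce a valid alignment with invariant protected slices", {
  cfg <- simulation_config(seed = 44, substitution_rate = 0.1,
                           indel_rate = 0.02, indel_max_len = 4)
  ds <- simulate_dataset(cfg)
  o <- ds$ortho
  expect_equal(length(unique(nchar(o$aligned))), 1L)  # not ragged
  expect_gt(o$column_count, 680)                       # insertions opened columns

  # gapless protected slices identical across species: locate the protected
  # intervals through each species' column map
  focal_cols <- statsites:::gapless_to_column(o$aligned[[o$focal_species]])
  for (iv in cfg$protected_intervals) {
    cols <- focal_cols[(iv[1] + 1):iv[2]]             # root columns of interval
    for (sp in o$species) {
      spc <- strsplit(o$aligned[[sp]], "")[[1]]
      expect_identical(paste(spc[cols + 1], collapse = ""),
                       substr(ds$root$sequence, iv[1] + 1, iv[2]))
    }
  }
  # round-trip: evolve output satisfies ortholog_set invariants by re-construction
  expect_s3_class(ortholog_set(o$aligned, o$focal_species), "ortholog_set")
})

test_that("power experiment hits the limiting cases", {
  cfg <- vvl_like_config()
  res0 <- power_experiment(0, n_replicates = 5, config = cfg, seed = 2)
  expect_equal(res0$sensitivity, 1.0)
  expect_equal(res0$decoy_conserved_rate, 1.0)   # nothing diverges

  res1 <- power_experiment(1.0, n_replicates = 10, config = cfg, seed = 2)
  expect_equal(res1$sensitivity, 1.0)            # protected sites survive
  expect_equal(res1$decoy_conserved_rate, 0.0)   # flanks always destroyed

  # sensitivity of unprotected sites decreases with rate; run a small grid
  res <- power_experiment(c(0, 0.3), n_replicates = 10, config = cfg, seed = 3)
  expect_true(all(diff(res$decoy_conserved_rate) <= 0))
  expect_equal(res$n_protected, c(20L, 20L))
  expect_equal(res$n_decoy, c(10L, 10L))
})
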