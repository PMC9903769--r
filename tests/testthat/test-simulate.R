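test_that("simulation spec validates its invariants", {
  expect_s3_class(simulation_spec(), "simulation_spec")
  expect_error(simulation_spec(n_groups = 1), "n_groups")
  expect_error(simulation_spec(n_genomes = 10, n_redundant_pairs = 6),
               "n_redundant_pairs")
  expect_error(simulation_spec(env_shift = c(sst = 1)), "seven")
})

test_that("generated genomes respect declared ranges and planted redundancy", {
  spec <- simulation_spec(n_genomes = 20, n_redundant_pairs = 3, rng_seed = 2)
  sim <- simulate_genomes(spec)
  expect_equal(nrow(sim$genomes), 20)
  expect_true(all(sim$genomes$length >= 1e7 & sim$genomes$length <= 1.3e9))
  expect_true(all(sim$genomes$completion >= 5 & sim$genomes$completion <= 95))
  red <- sim$pairs$ani > 98 & sim$pairs$aligned_fraction_smaller > 0.25
  expect_gte(sum(red), 3)
  # planted pairs are the only above-threshold pairs and they are disjoint
  expect_equal(sum(red), 3)
  expect_equal(length(unique(c(sim$pairs$genome_a[red],
                               sim$pairs$genome_b[red]))), 6)
  # zero planted pairs -> everything below threshold
  sim0 <- simulate_genomes(simulation_spec(n_genomes = 15,
                                           n_redundant_pairs = 0))
  expect_true(all(sim0$pairs$ani < 98))
})

test_that("generators are pure functions of the seed", {
  s1 <- simulation_spec(n_stations = 10, grid_resolution = 10, rng_seed = 7)
  s2 <- simulation_spec(n_stations = 10, grid_resolution = 10, rng_seed = 8)
  b1 <- simulate_bundle(s1)
  b1b <- simulate_bundle(s1)
  b2 <- simulate_bundle(s2)
  expect_identical(b1, b1b)
  expect_false(identical(b1$genomes, b2$genomes))
  expect_false(identical(b1$recruitment, b2$recruitment))
})

test_that("marker functions occur more often in their planted group", {
  spec <- simulation_spec(n_genomes = 120, group_effect_size = 3, rng_seed = 6)
  gen <- simulate_genomes(spec)
  sim <- simulate_annotations(spec, gen$genomes, gen$truth$group_label)
  counts <- sim$truth$counts
  labels <- sim$truth$group_labels[rownames(counts)]
  for (g in names(sim$truth$marker_functions)) {
    mk <- sim$truth$marker_functions[[g]]
    inside <- mean(counts[labels == g, mk])
    outside <- mean(counts[labels != g, mk])
    expect_gt(inside, outside + 1)  # effect size 3 over base 1
  }
})

test_that("retrotransposon-like functions exceed the cap in the largest genome", {
  spec <- simulation_spec(n_genomes = 25, rng_seed = 3)
  gen <- simulate_genomes(spec)
  sim <- simulate_annotations(spec, gen$genomes, gen$truth$group_label)
  biggest <- gen$genomes$genome_id[which.max(gen$genomes$length)]
  m <- build_occurrence_matrix(sim$annotations, gen$genomes)
  expect_true(all(m[biggest, sim$truth$retro_functions] > 500))
  expect_true(all(sim$function_meta$is_retrotransposon ==
                    (sim$function_meta$og_id %in% sim$truth$retro_functions)))
})

test_that("null annotation simulation carries no planted signal", {
  spec <- simulation_spec(n_genomes = 80, group_effect_size = 0, rng_seed = 10)
  gen <- simulate_genomes(spec)
  sim <- simulate_annotations(spec, gen$genomes, gen$truth$group_label)
  counts <- sim$truth$counts
  labels <- sim$truth$group_labels[rownames(counts)]
  mk <- unlist(sim$truth$marker_functions, use.names = FALSE)
  # marker means indistinguishable between groups at effect 0
  grand <- mean(counts[, mk])
  for (g in unique(labels)) {
    expect_lt(abs(mean(counts[labels == g, mk]) - grand), 0.5)
  }
})

test_that("recruitment breadth stays in range and tracks planted niches", {
  spec <- simulation_spec(n_genomes = 15, n_stations = 12,
                          grid_resolution = 10, rng_seed = 4)
  env <- simulate_environment(spec)
  gen <- simulate_genomes(spec)
  rec <- simulate_recruitment(spec, gen$genomes, env$stations)
  expect_true(all(rec$recruitment$breadth >= 0 & rec$recruitment$breadth <= 1))
  expect_true(all(rec$recruitment$recruited_reads >= 0))
  # inside-niche samples sit above, outside below, the 0.25 threshold
  station <- setNames(rec$metagenomes$station_id, rec$metagenomes$metagenome_id)
  inside <- rec$truth$detection[cbind(rec$recruitment$genome_id,
                                      unname(station[rec$recruitment$metagenome_id]))]
  expect_true(all(rec$recruitment$breadth[inside] > 0.25))
  expect_true(all(rec$recruitment$breadth[!inside] < 0.25))
})

test_that("environmental grids shift only where the spec says", {
  spec0 <- simulation_spec(grid_resolution = 10,
                           env_shift = c(sst = 0, salinity = 0, silicate = 0,
                                         nitrate = 0, phosphate = 0, iron = 0,
                                         si_no3 = 0))
  e0 <- simulate_environment(spec0)
  expect_identical(e0$grid1, e0$grid2)
  spec1 <- simulation_spec(grid_resolution = 10)
  e1 <- simulate_environment(spec1)
  expect_true(all(e1$grid2$sst - e1$grid1$sst == 2))
  for (p in setdiff(magscape:::ENV_PARAMS, "sst")) {
    expect_identical(e1$grid2[[p]], e1$grid1[[p]])
  }
  # stations are ocean cells with complete environments
  expect_true(all(e1$grid1$ocean[e1$station_cells]))
  expect_false(any(is.na(e1$stations[magscape:::ENV_PARAMS])))
})

test_that("grid cell areas are positive and shrink toward the poles", {
  lat <- seq(-89.5, 89.5, by = 1)
  a <- cell_area_km2(lat)
  expect_true(all(a > 0))
  north <- a[lat > 0]
  expect_true(all(diff(north) < 0))  # decreasing poleward
  expect_equal(a, rev(a))            # hemispheric symmetry
})
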