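test_that("zero rates reproduce the ancestor in every lineage", {
  cfg <- sim_config(seed = 81, population_size = 15, n_ancestral_spacers = 12,
                    gain_rate = 0, loss_rate = 0, mutation_rate = 0,
                    trailer_repeat_degeneracy = 0, fragmentation_prob = 0)
  sim <- simulate_population(cfg)
  anc <- sim$truth$ancestor
  for (i in seq_len(nrow(sim$arrays))) {
    expect_identical(sim$arrays$spacers[[i]], anc$spacers)
    expect_identical(sim$arrays$repeats[[i]], anc$repeats)
  }
  res <- run_pipeline(sim$arrays, min_group_report = 10)
  expect_equal(nrow(res$groups), 1)
  expect_equal(nrow(res$cluster_map$clusters), cfg$n_ancestral_spacers)
  cg <- res$graphs[["1"]]
  expect_equal(length(cg$blocks), 1)
})

test_that("the same seed reproduces the simulation exactly", {
  cfg <- sim_config(seed = 82, population_size = 10, gain_rate = 0.5,
                    loss_rate = 0.3, mutation_rate = 0.01)
  a <- simulate_population(cfg)
  b <- simulate_population(cfg)
  expect_identical(a$arrays, b$arrays)
  expect_identical(a$truth$novel_spacers, b$truth$novel_spacers)
})

test_that("replaying the event history reproduces every emitted array", {
  for (seed in c(83, 84, 85)) {
    sim <- simulate_population(sim_config(
      seed = seed, population_size = 12, n_ancestral_spacers = 8,
      gain_rate = 0.6, loss_rate = 0.4, mutation_rate = 0.01,
      randomize_strand = seed == 85))
    for (i in seq_len(nrow(sim$arrays))) {
      r <- replay_array(sim$truth, sim$arrays$array_id[[i]])
      expect_identical(r$spacers, sim$arrays$spacers[[i]])
      expect_identical(r$repeats, sim$arrays$repeats[[i]])
    }
  }
})

test_that("losses never touch a protected trailer", {
  sim <- simulate_population(sim_config(seed = 86, population_size = 40,
                                        n_ancestral_spacers = 6,
                                        gain_rate = 0, loss_rate = 1.5,
                                        mutation_rate = 0,
                                        protect_trailer = TRUE))
  last_labels <- vapply(sim$truth$arrays, function(e) {
    e$labels[[length(e$labels)]]
  }, integer(1))
  expect_true(all(last_labels == sim$truth$true_anchor_label))
})

test_that("with losses only, the sink block holds the ancestral trailer", {
  sim <- simulate_population(sim_config(seed = 87, population_size = 30,
                                        n_ancestral_spacers = 10,
                                        gain_rate = 0, loss_rate = 0.8,
                                        mutation_rate = 0))
  cg <- compress(build_spacer_graph(truth_labeled(sim)))
  sink_labels <- unlist(cg$blocks[cg$sinks])
  expect_true(sim$truth$true_anchor_label %in% sink_labels)
})

test_that("fragmentation clears flags and keeps arrays non-empty", {
  base <- simulate_population(sim_config(seed = 88, population_size = 1,
                                         n_ancestral_spacers = 10,
                                         gain_rate = 0, loss_rate = 0,
                                         mutation_rate = 0))$arrays
  unchanged <- fragment_reads(base, 0, seed = 1)
  expect_identical(unchanged, base)

  for (seed in 1:200) {
    fr <- fragment_reads(base, 1, seed = seed)
    n <- length(fr$spacers[[1]])
    expect_gte(n, 1)
    expect_lte(n, 9)
    expect_false(fr$left_complete[[1]])
    expect_false(fr$right_complete[[1]])
    expect_equal(length(fr$repeats[[1]]), n + 1)
  }
})

test_that("truncated ends drop out of trailer-conservation eligibility", {
  sim <- simulate_population(sim_config(seed = 89, population_size = 20,
                                        n_ancestral_spacers = 8,
                                        gain_rate = 0.3, loss_rate = 0.1,
                                        mutation_rate = 0))
  fr <- fragment_reads(sim$arrays, 0.5, seed = 90)
  lab <- truth_labeled(list(arrays = fr, truth = sim$truth))
  tr <- trailer_conservation(lab, "as_given")
  expect_equal(tr$n_eligible, sum(fr$right_complete))
  expect_equal(tr$conservation, 1.0)  # protected trailer among complete ends
})

test_that("plant_protospacers records exact truth and respects n_plants = 0", {
  spacers <- tibble::tibble(spacer_id = c("s1", "s2"),
                            sequence = replicate(2, random_dna_str(30)))
  reads <- random_reads(5, 600, seed = 91)
  same <- plant_protospacers(reads, spacers, n_plants = 0, seed = 92)
  expect_identical(same$reads, reads)
  expect_equal(nrow(same$truth), 0)

  planted <- plant_protospacers(reads, spacers, n_plants = 10, seed = 93)
  expect_equal(nrow(planted$truth), 10)
  for (i in seq_len(nrow(planted$truth))) {
    t <- planted$truth[i, ]
    got <- substr(planted$reads$sequence[[match(t$read_id, planted$reads$read_id)]],
                  t$start + 1, t$end)
    want <- spacers$sequence[[match(t$spacer_id, spacers$spacer_id)]]
    if (t$strand == "-") want <- rc_oracle(want)
    expect_identical(got, want)
  }
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(mutation_rate = 2))
  expect_error(sim_config(n_ancestral_spacers = 0))
  expect_error(sim_config(trailer_repeat_degeneracy = 99, repeat_length = 30))
})
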