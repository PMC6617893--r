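# the four-spacer worked example: arrays (a,b,c,d) and (a,d) with a=1 etc.
fig_example <- function() {
  lab_tbl(c(1, 2, 3, 4), c(1, 4))
}

test_that("a single array yields a simple chain graph", {
  g <- build_spacer_graph(lab_tbl(c(1, 2, 3, 4)))
  expect_equal(length(g$nodes), 4)
  expect_equal(nrow(g$edges), 3)
  expect_equal(g$edges$from, c(1, 2, 3))
  expect_equal(g$edges$to, c(2, 3, 4))
  expect_true(all(g$edges$support == 1))
})

test_that("a spacer-sharing array adds a bypass edge", {
  g <- build_spacer_graph(fig_example())
  expect_equal(length(g$nodes), 4)
  expect_equal(nrow(g$edges), 4)
  expect_true(any(g$edges$from == 1 & g$edges$to == 4))
})

test_that("repeated adjacencies accumulate support", {
  g <- build_spacer_graph(lab_tbl(c(1, 2), c(1, 2)))
  expect_equal(length(g$nodes), 2)
  expect_equal(nrow(g$edges), 1)
  expect_equal(g$edges$support, 2L)
})

test_that("compression reproduces the worked example: 3 blocks, 3 edges", {
  cg <- compress(build_spacer_graph(fig_example()))
  expect_equal(length(cg$blocks), 3)
  expect_equal(nrow(cg$edges), 3)
  expect_true(list(c(2L, 3L)) %in% cg$blocks)  # b,c collapse
  labs <- vapply(cg$blocks, function(b) paste(b, collapse = "-"), character(1))
  b_a <- which(labs == "1"); b_bc <- which(labs == "2-3"); b_d <- which(labs == "4")
  got <- paste(cg$edges$from, cg$edges$to)
  expect_setequal(got, paste(c(b_a, b_bc, b_a), c(b_bc, b_d, b_d)))
  # terminals: a is the lone source, d the lone sink
  term <- classify_terminals(cg)
  expect_equal(term$sources, b_a)
  expect_equal(term$sinks, b_d)
})

test_that("an isolated chain collapses to one block and no edges", {
  cg <- compress(build_spacer_graph(lab_tbl(c(1, 2, 3, 4))))
  expect_equal(length(cg$blocks), 1)
  expect_equal(cg$blocks[[1]], 1:4)
  expect_equal(nrow(cg$edges), 0)
  # a lone block is both source and sink
  expect_equal(classify_terminals(cg), list(sources = 1L, sinks = 1L))
})

test_that("strict contraction also reproduces the worked example", {
  cg <- compress(build_spacer_graph(fig_example()), strict = TRUE)
  expect_equal(length(cg$blocks), 3)
  expect_equal(nrow(cg$edges), 3)
})

test_that("compression reaches a fixed point (idempotence)", {
  set.seed(41)
  for (rep in 1:25) {
    sim <- simulate_population(sim_config(
      seed = 400 + rep, population_size = sample(5:15, 1),
      n_ancestral_spacers = sample(5:12, 1),
      gain_rate = runif(1, 0, 0.8), loss_rate = runif(1, 0, 0.4),
      mutation_rate = 0))
    lab <- truth_labeled(sim)
    cg <- compress(build_spacer_graph(lab))
    deg_in <- tabulate(cg$edges$to, length(cg$blocks))
    deg_out <- tabulate(cg$edges$from, length(cg$blocks))
    if (nrow(cg$edges) > 0) {
      rev_key <- paste(cg$edges$to, cg$edges$from)
      pinned_lab <- spacergraphs:::unmergeable_labels(cg$arrays)
      pinned <- vapply(cg$blocks, function(b) any(b %in% pinned_lab),
                       logical(1))
      contractible <- cg$edges$from != cg$edges$to &
        deg_out[cg$edges$from] == 1 & deg_in[cg$edges$to] == 1 &
        !pinned[cg$edges$from] & !pinned[cg$edges$to] &
        !(paste(cg$edges$from, cg$edges$to) %in% rev_key)
      expect_false(any(contractible))
    }
  }
})

test_that("every array is recoverable from its walk; conservation laws hold", {
  set.seed(42)
  for (rep in 1:25) {
    sim <- simulate_population(sim_config(
      seed = 420 + rep, population_size = sample(5:15, 1),
      n_ancestral_spacers = sample(5:12, 1),
      gain_rate = runif(1, 0, 0.8), loss_rate = runif(1, 0, 0.4),
      mutation_rate = 0, fragmentation_prob = 0))
    lab <- truth_labeled(sim)
    if (rep %% 3 == 0) {
      fr <- fragment_reads(sim$arrays, 0.3, seed = rep)
      lab <- truth_labeled(list(arrays = fr, truth = sim$truth),
                           fragmented = TRUE)
    }
    g <- build_spacer_graph(lab)
    # edge-support conservation before compression
    expect_equal(sum(g$edges$support), sum(lengths(lab$labels) - 1))
    cg <- compress(g)
    # node conservation
    expect_equal(sum(lengths(cg$blocks)), length(unique(unlist(lab$labels))))
    # path preservation
    for (aid in lab$array_id) {
      want <- lab$labels[[match(aid, lab$array_id)]]
      expect_identical(walk_labels(cg, aid), as.integer(want))
    }
  }
})

test_that("dominant path follows frequency, then length, then label order", {
  # 5 arrays of one organization vs 2 of another
  lab <- lab_tbl(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3), c(1, 2, 3), c(1, 2, 3),
                 c(1, 3), c(1, 3))
  cg <- compress(build_spacer_graph(lab))
  expect_identical(walk_path_labels(cg, cg$dominant_path, c(1, 2, 3)), TRUE)

  # all identical: the single walk
  cg2 <- compress(build_spacer_graph(lab_tbl(c(5, 6), c(5, 6))))
  expect_equal(length(cg2$dominant_path), 1)

  # 3 vs 3 tie: the longer (7-label) organization wins
  long <- as.list(rep(list(1:7), 3))
  short <- as.list(rep(list(c(1, 9, 7)), 3))
  lab3 <- do.call(lab_tbl, c(long, short))
  cg3 <- compress(build_spacer_graph(lab3))
  dom_labels <- unlist(cg3$blocks[cg3$dominant_path])
  expect_equal(length(dom_labels), 7)
})

test_that("duplicated labels within an array stay unmerged and walkable", {
  lab <- lab_tbl(c(1, 2, 1, 3), c(1, 2, 1, 3))
  cg <- compress(build_spacer_graph(lab))
  expect_identical(walk_labels(cg, "a01"), c(1L, 2L, 1L, 3L))
  expect_true(list(1L) %in% cg$blocks)  # label 1 pinned to a singleton
})

test_that("block partition is invariant to array input order", {
  set.seed(43)
  sim <- simulate_population(sim_config(seed = 777, population_size = 12,
                                        n_ancestral_spacers = 8,
                                        gain_rate = 0.5, loss_rate = 0.2,
                                        mutation_rate = 0))
  lab <- truth_labeled(sim)
  cg1 <- compress(build_spacer_graph(lab))
  for (i in 1:5) {
    cg2 <- compress(build_spacer_graph(lab[sample(nrow(lab)), ]))
    expect_identical(cg1$blocks, cg2$blocks)
    expect_identical(cg1$edges, cg2$edges)
  }
})

test_that("simulated leader gains land in source blocks", {
  set.seed(44)
  sim <- simulate_population(sim_config(seed = 900, population_size = 50,
                                        n_ancestral_spacers = 10,
                                        gain_rate = 0.3, loss_rate = 0,
                                        mutation_rate = 0))
  gained <- sim$truth$novel_spacers$label
  if (length(gained) > 0) {
    cg <- compress(build_spacer_graph(truth_labeled(sim)))
    src_labels <- unlist(cg$blocks[cg$sources])
    expect_true(all(gained %in% src_labels))
  }
})
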