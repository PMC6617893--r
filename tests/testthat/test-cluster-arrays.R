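test_that("arrays sharing labels group together, others stay apart", {
  groups <- cluster_arrays(lab_tbl(c(1, 2, 3), c(3, 4), c(5, 6)))
  expect_equal(nrow(groups), 2)
  expect_equal(groups$reference_array_id[[1]], "a01")  # most spacers founds
  expect_setequal(groups$member_array_ids[[1]], c("a01", "a02"))
  expect_setequal(groups$member_array_ids[[2]], "a03")
})

test_that("a single array forms a singleton group; empty input empty output", {
  one <- cluster_arrays(lab_tbl(c(7, 8)))
  expect_equal(nrow(one), 1)
  expect_equal(one$member_count, 1)
  none <- cluster_arrays(tibble::tibble(array_id = character(),
                                        labels = list()))
  expect_equal(nrow(none), 0)
})

test_that("transitive sharing chains into one group", {
  groups <- cluster_arrays(lab_tbl(c(1, 2), c(2, 3), c(3, 4)))
  expect_equal(nrow(groups), 1)
  expect_equal(groups$member_count, 3)
})

test_that("reference-only mode does not chain transitively", {
  # a02 shares with reference a01; a03 shares only with a02
  groups <- cluster_arrays(lab_tbl(c(1, 2), c(2, 3), c(3, 4)),
                           transitive = FALSE)
  expect_equal(nrow(groups), 2)
  expect_setequal(groups$member_array_ids[[1]], c("a01", "a02"))
})

test_that("groups partition the arrays and close under sharing", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(3:10, 1)
    labels <- lapply(seq_len(n), function(i) {
      sample.int(6, sample(1:4, 1))
    })
    tbl <- tibble::tibble(array_id = sprintf("a%02d", seq_len(n)),
                          labels = labels)
    groups <- cluster_arrays(tbl)
    members <- unlist(groups$member_array_ids)
    expect_setequal(members, tbl$array_id)        # partition
    expect_equal(length(members), n)              # no array twice
    # sharing invariant: every member of a multi-array group shares at
    # least one label with another member of the same group
    for (k in seq_len(nrow(groups))) {
      mem <- groups$member_array_ids[[k]]
      if (length(mem) < 2) next
      for (a in mem) {
        others <- unique(unlist(labels[match(setdiff(mem, a), tbl$array_id)]))
        mine <- labels[[match(a, tbl$array_id)]]
        expect_gt(length(intersect(mine, others)), 0)
      }
    }
  }
})

test_that("greedy grouping matches the naive oracle and refines components", {
  set.seed(32)
  for (rep in 1:60) {
    n <- sample(2:10, 1)
    labels <- lapply(seq_len(n), function(i) sample.int(6, sample(1:4, 1)))
    ids <- sprintf("a%02d", seq_len(n))
    got <- tidy(cluster_arrays(tibble::tibble(array_id = ids,
                                              labels = labels)))
    got_p <- stats::setNames(got$group_id, got$array_id)
    want <- greedy_groups_oracle(ids, labels)
    expect_true(same_partition(got_p, want), info = paste("rep", rep))

    comp <- components_oracle(ids, labels)
    # every greedy group sits inside one connected component
    for (g in unique(got_p)) {
      expect_equal(length(unique(comp[names(got_p)[got_p == g]])), 1)
    }
  }
})

test_that("zero-label arrays are rejected", {
  expect_error(
    cluster_arrays(tibble::tibble(array_id = "a", labels = list(integer()))),
    "zero"
  )
})

test_that("group_summary counts sizes as reported", {
  g <- tibble::tibble(group_id = 1:4,
                      reference_array_id = letters[1:4],
                      member_array_ids = list(letters[1:12], "b", "c", c("d", "e", "f")),
                      member_count = c(12L, 1L, 1L, 3L))
  expect_equal(group_summary(g, 10),
               tibble::tibble(n_groups = 4L, n_singletons = 2L,
                              n_at_least_min = 1L))
  empty <- cluster_arrays(tibble::tibble(array_id = character(),
                                         labels = list()))
  expect_equal(group_summary(empty, 10)$n_groups, 0L)
  expect_error(group_summary(g, 0), "min_size")
})

test_that("group sizes match the simulator's ground truth", {
  sizes <- c(12, 5, 1, 1, 8)
  sims <- lapply(seq_along(sizes), function(i) {
    simulate_population(sim_config(seed = 100 + i, population_size = sizes[i],
                                   n_ancestral_spacers = 6,
                                   gain_rate = 0.2, loss_rate = 0.1))
  })
  # separate ancestors -> disjoint random spacers -> groups recover the sims
  arrays <- dplyr::bind_rows(lapply(seq_along(sims), function(i) {
    a <- sims[[i]]$arrays
    a$array_id <- paste0("p", i, "_", a$array_id)
    a
  }))
  res <- run_pipeline(arrays, min_group_report = 5)
  expect_equal(sort(res$groups$member_count), sort(as.integer(sizes)))
  expect_equal(group_summary(res$groups, 5),
               tibble::tibble(n_groups = 5L, n_singletons = 2L,
                              n_at_least_min = 3L))
})
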