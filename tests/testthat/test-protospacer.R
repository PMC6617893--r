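plant_at <- function(read_seq, spacer, pos, strand = "+") {
  s <- if (strand == "+") spacer else rc_oracle(spacer)
  substr(read_seq, pos + 1, pos + nchar(s)) <- s
  read_seq
}

test_that("a verbatim planted spacer is found exactly once at full identity", {
  set.seed(71)
  spacer <- random_dna_str(30)
  read <- plant_at(random_dna_str(2000), spacer, 100)
  hits <- find_protospacers(
    tibble::tibble(spacer_cluster_id = "c1", sequence = spacer),
    tibble::tibble(read_id = "r1", sequence = read))
  fwd <- hits[hits$strand == "+", ]
  expect_equal(nrow(fwd), 1)
  expect_equal(fwd$start, 100L)
  expect_equal(fwd$end, 130L)
  expect_equal(fwd$identity, 1.0)
  expect_false(fwd$excluded)
})

test_that("hits inside declared CRISPR intervals are flagged, not dropped", {
  set.seed(72)
  spacer <- random_dna_str(30)
  read <- plant_at(random_dna_str(1000), spacer, 500)
  hits <- find_protospacers(
    tibble::tibble(spacer_cluster_id = "c1", sequence = spacer),
    tibble::tibble(read_id = "r1", sequence = read),
    crispr_intervals = tibble::tibble(read_id = "r1", start = 400L, end = 600L))
  expect_true(all(hits$excluded))
  expect_true(all(hits$exclusion_reason == "in_crispr_region"))
  expect_equal(invader_read_set(hits), character())
})

test_that("reverse-complement plants with mismatches are recovered on -", {
  set.seed(73)
  spacer <- random_dna_str(30)
  mutated <- mutate_dna_str(spacer, 2)
  # plant the reverse complement of a 2-substitution copy mid-read
  read <- plant_at(random_dna_str(800), mutated, 300, strand = "-")
  hits <- find_protospacers(
    tibble::tibble(spacer_cluster_id = "c1", sequence = spacer),
    tibble::tibble(read_id = "r1", sequence = read))
  minus <- hits[hits$strand == "-", ]
  expect_gte(nrow(minus), 1)
  expect_gte(minus$identity[[1]], 28 / 30)
})

test_that("exact plants are always recovered over random placements (both strands)", {
  set.seed(74)
  spacers <- tibble::tibble(spacer_cluster_id = sprintf("c%02d", 1:10),
                            sequence = replicate(10, random_dna_str(30)))
  reads <- random_reads(20, 1500, seed = 74)
  planted <- plant_protospacers(reads, spacers, n_plants = 150,
                                error_rate = 0, seed = 75)
  hits <- find_protospacers(spacers, planted$reads)
  key_h <- paste(hits$read_id, hits$start, hits$end, hits$strand)
  key_t <- paste(planted$truth$read_id, planted$truth$start,
                 planted$truth$end, planted$truth$strand)
  expect_true(all(key_t %in% key_h))
  recovered <- hits[key_h %in% key_t, ]
  expect_true(all(recovered$identity == 1))
})

test_that("no reported non-excluded hit overlaps a CRISPR interval", {
  set.seed(76)
  spacers <- tibble::tibble(spacer_cluster_id = sprintf("c%02d", 1:5),
                            sequence = replicate(5, random_dna_str(30)))
  reads <- random_reads(10, 1200, seed = 76)
  planted <- plant_protospacers(reads, spacers, n_plants = 40, seed = 77)
  iv <- tibble::tibble(read_id = reads$read_id,
                       start = 0L, end = 400L)
  hits <- find_protospacers(spacers, planted$reads, crispr_intervals = iv)
  kept <- hits[!hits$excluded, ]
  for (i in seq_len(nrow(kept))) {
    ov <- iv$read_id == kept$read_id[[i]] &
      iv$start < kept$end[[i]] & kept$start[[i]] < iv$end
    expect_false(any(ov))
  }
  # and plants inside the region were found but excluded
  inside <- planted$truth[planted$truth$start < 400, ]
  if (nrow(inside) > 0) {
    key_h <- paste(hits$read_id[hits$excluded], hits$start[hits$excluded])
    expect_true(all(paste(inside$read_id, inside$start) %in% key_h))
  }
})

test_that("spacers shorter than the seed fall back to exhaustive scanning", {
  set.seed(78)
  spacer <- random_dna_str(8)
  read <- plant_at(paste(rep("AC", 200), collapse = ""), spacer, 77)
  hits <- find_protospacers(
    tibble::tibble(spacer_cluster_id = "tiny", sequence = spacer),
    tibble::tibble(read_id = "r1", sequence = read), k = 12)
  expect_true(any(hits$start == 77 & hits$identity == 1))
})

test_that("invader reads are those with at least one non-excluded hit", {
  hits <- tibble::tibble(
    spacer_cluster_id = c("c1", "c1", "c2"),
    read_id = c("r1", "r2", "r2"),
    start = c(0L, 5L, 9L), end = c(30L, 35L, 39L),
    strand = "+", identity = 1, coverage = 1,
    excluded = c(FALSE, TRUE, TRUE),
    exclusion_reason = c("none", "in_crispr_region", "in_crispr_region"))
  expect_equal(invader_read_set(hits), "r1")
  expect_equal(invader_read_set(hits[0, ]), character())
})

test_that("interval read ids absent from the reads raise a warning", {
  set.seed(79)
  spacer <- random_dna_str(30)
  read <- plant_at(random_dna_str(500), spacer, 100)
  expect_warning(
    find_protospacers(
      tibble::tibble(spacer_cluster_id = "c1", sequence = spacer),
      tibble::tibble(read_id = "r1", sequence = read),
      crispr_intervals = tibble::tibble(read_id = "ghost", start = 0L,
                                        end = 10L)),
    "absent")
})
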