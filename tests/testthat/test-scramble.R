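# SCRaMbLE simulation semantics, replay determinism, the segment-level
# SV caller, and coverage-based copy-number estimation.

test_that("segment maps partition designs and reconstruct them exactly", {
  # zero sites: one segment spanning everything
  plain <- strrep("ACGTT", 100)
  m0 <- build_segment_map(plain, topology = "circular")
  expect_length(m0$ids, 1)
  expect_identical(reconstruct_segments(m0), plain)

  # circular design with n sites has exactly n segments
  for (n in c(3, 8, 20)) {
    circ <- random_lox_circle(n, seg_len = 120, seed = n)
    m <- build_segment_map(circ, topology = "circular")
    expect_length(m$ids, n)
    expect_length(m$site_positions, n)
    expect_true(is_rotation_of(reconstruct_segments(m), circ))
  }

  # reconstruction oracle over random edited designs
  for (seed in c(5, 6, 7)) {
    d <- make_edited_design(seed, n_fragments = 3,
                            size_range = c(1100, 3000))
    m <- build_segment_map(d)
    expect_equal(length(m$ids), sum(d$features$type == "loxPsym"))
    expect_true(is_rotation_of(reconstruct_segments(m), d$sequence))
  }
})

test_that("event semantics: INV preserves, DEL shrinks, DUP grows", {
  m <- build_segment_map(random_lox_circle(10, seed = 2),
                         topology = "circular")
  base_len <- nchar(reconstruct_segments(m))

  none <- simulate_scramble(m, n_events = 0, seed = 1)
  expect_identical(none$sequence, reconstruct_segments(m))
  expect_length(none$events, 0)

  for (seed in 1:20) {
    inv <- simulate_scramble(m, n_events = 1,
                             type_probs = c(DEL = 0, INV = 1, DUP = 0),
                             seed = seed)
    expect_equal(nchar(inv$sequence), base_len)
    expect_length(inv$state, 10)
    expect_identical(sort(abs(inv$state)), 1:10)
    # one contiguous orientation run flipped
    flipped <- which(inv$state < 0)
    expect_true(length(flipped) >= 1 && all(diff(flipped) == 1))

    del <- simulate_scramble(m, n_events = 1,
                             type_probs = c(DEL = 1, INV = 0, DUP = 0),
                             seed = seed)
    expect_lt(nchar(del$sequence), base_len)
    expect_lt(length(del$state), 10)
    # essential (origin-spanning) segment always survives
    expect_true(10 %in% abs(del$state))

    dup <- simulate_scramble(m, n_events = 1,
                             type_probs = c(DEL = 0, INV = 0, DUP = 1),
                             seed = seed)
    expect_gt(nchar(dup$sequence), base_len)
    expect_gt(length(dup$state), 10)
  }
})

test_that("the truth log replays to the scrambled sequence byte-identically", {
  m <- build_segment_map(random_lox_circle(15, seed = 9),
                         topology = "circular")
  for (seed in 1:50) {
    sc <- simulate_scramble(m, n_events = 1 + seed %% 3, seed = 3000 + seed)
    rp <- replay_scramble(m, sc$events)
    expect_identical(rp$state, sc$state)
    expect_identical(rp$sequence, sc$sequence)
    # determinism: same seed, same outcome
    sc2 <- simulate_scramble(m, n_events = 1 + seed %% 3, seed = 3000 + seed)
    expect_identical(sc2$sequence, sc$sequence)
  }
})

test_that("the caller returns an empty report for an unscrambled genome", {
  m <- build_segment_map(random_lox_circle(12, seed = 4),
                         topology = "circular")
  rep <- call_structural_variants(m, reconstruct_segments(m))
  expect_equal(nrow(rep$events), 0)
  expect_true(all(rep$copy_number == 1))
  expect_true(all(rep$orientation == "+"))
  expect_true(rep$consistent)
  expect_equal(rep$n_unmatched, 0)
})

test_that("single-event genomes are classified exactly (all three types)", {
  m <- build_segment_map(random_lox_circle(20, seed = 8),
                         topology = "circular")
  for (seed in 1:100) {
    sc <- simulate_scramble(m, n_events = 1,
                            type_probs = c(DEL = 1, INV = 1, DUP = 1) / 3,
                            seed = 5000 + seed)
    rep <- call_structural_variants(m, sc)
    expect_identical(event_descriptors(rep), event_descriptors(sc))
  }
})

test_that("an inverted vs deleted intergenic span is labelled INV vs DEL", {
  # two clones differing at the same pair of sites: one carries the
  # spanned region inverted, the other carries it deleted
  m <- build_segment_map(random_lox_circle(10, seed = 13),
                         topology = "circular")
  inv_state <- m$ids; inv_state[4:5] <- -rev(inv_state[4:5])
  del_state <- m$ids[-(4:5)]
  rep_inv <- call_structural_variants(m, reconstruct_segments(m, inv_state))
  rep_del <- call_structural_variants(m, reconstruct_segments(m, del_state))
  expect_identical(rep_inv$events$type, "INV")
  expect_equal(c(rep_inv$events$first_seg, rep_inv$events$last_seg), c(4, 5))
  expect_identical(rep_del$events$type, "DEL")
  expect_equal(c(rep_del$events$first_seg, rep_del$events$last_seg), c(4, 5))
})

test_that("copy-number estimation follows the coverage ratio definition", {
  cov <- data.frame(contig = c("chrA", "chrB", "small", "EL"),
                    length = c(5e5, 3e5, 5e4, 2.1e5),
                    mean_depth = c(30, 30, 99, 30))
  expect_equal(estimate_copy_number(cov, "EL"), 1)       # small contig ignored
  cov$mean_depth[4] <- 60
  expect_equal(estimate_copy_number(cov, "EL"), 2)
  # the element contig itself never enters the genome mean
  cov2 <- data.frame(contig = c("chrA", "EL"), length = c(5e5, 2.5e5),
                     mean_depth = c(30, 90))
  expect_equal(estimate_copy_number(cov2, "EL"), 3)
  expect_error(estimate_copy_number(cov, "nope"), "not present")
  expect_error(estimate_copy_number(
    data.frame(contig = "EL", length = 2.1e5, mean_depth = 30), "EL"),
    "no genome contig")
})
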