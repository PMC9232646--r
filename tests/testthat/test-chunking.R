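# Chunking, assembly planning, junction primers, in-silico HR assembly
# and generic region replacement.

make_circle <- function(seed, n_fragments = 5, size_range = c(2000, 12000)) {
  frags <- generate_pan_fragments(fragment_spec(
    n_fragments = n_fragments, size_range = size_range, seed = seed))
  insert_loxpsym(recode_stop_codons(
    concatenate_fragments(frags, synthetic_backbone(seed = seed + 500))))
}

test_that("a 30 kb design divides into 3 chunks sharing exact 200 bp overhangs", {
  d <- make_circle(21, n_fragments = 3, size_range = c(8000, 9500))
  expect_gt(design_length(d), 25000)
  ch <- chunk_design(d, target_size = 10000, overlap = 200)
  expect_equal(length(ch), round(design_length(d) / 10000))
  seqs <- chunk_sequences(ch)
  n <- length(seqs)
  for (i in seq_len(n)) {
    j <- if (i < n) i + 1 else 1
    expect_identical(substring(seqs[i], nchar(seqs[i]) - 199),
                     substr(seqs[j], 1, 200))
    expect_identical(ch[[i]]$right_overhang, ch[[j]]$left_overhang)
  }
  # overlap windows are unique and restriction-free
  for (c_ in ch) {
    for (w in c(c_$left_overhang, c_$right_overhang)) {
      expect_equal(neochrom:::count_occurrences(d$sequence, w,
                                                circular = TRUE), 1)
      expect_false(grepl("GTTTAAAC", w, fixed = TRUE))
      expect_false(grepl("GCGGCCGC", w, fixed = TRUE))
    }
  }
  # concatenating left_overhang + body over all chunks tiles the circle
  tiled <- paste(vapply(ch, function(c_) paste0(c_$left_overhang, c_$body),
                        character(1)), collapse = "")
  expect_true(is_rotation_of(tiled, d$sequence))
})

test_that("chunking and HR assembly round-trip random circular designs", {
  for (seed in c(101, 202, 303)) {
    d <- make_circle(seed)
    ch <- chunk_design(d)
    asm <- simulate_hr_assembly(ch)
    expect_identical(attr(asm, "topology"), "circular")
    expect_true(is_rotation_of(as.character(asm), d$sequence))
    expect_equal(nchar(asm),
                 sum(nchar(chunk_sequences(ch))) - 200 * length(ch))
  }
})

test_that("HR assembly joins on exact overlaps and reports failures", {
  a <- paste(sample(c("A", "C", "G", "T"), 1000, TRUE), collapse = "")
  b <- paste(sample(c("A", "C", "G", "T"), 800, TRUE), collapse = "")
  shared <- substring(a, 801)  # last 200 bp of a
  b <- paste0(shared, b)
  out <- simulate_hr_assembly(c(a, b), overlap = 200, circularize = FALSE)
  expect_equal(nchar(out), 1000 + 1000 - 200)
  expect_identical(as.character(out), paste0(a, substring(b, 201)))

  # one mismatch in the overlap breaks the join, with termini named
  b_bad <- b
  substr(b_bad, 100, 100) <- if (substr(b_bad, 100, 100) == "A") "C" else "A"
  expect_error(simulate_hr_assembly(c(a, b_bad), overlap = 200,
                                    circularize = FALSE), "unjoined")
  # an overlap matching two partners is ambiguous
  expect_error(simulate_hr_assembly(c(a, b, b), overlap = 200,
                                    circularize = FALSE), "ambiguous")
})

test_that("assembly plans follow the opening schedule and alternate markers", {
  fake_chunks <- vector("list", 21)
  plan <- plan_assembly(fake_chunks)
  expect_identical(plan$chunk_rounds[[1]], 1:2)
  expect_identical(plan$chunk_rounds[[2]], 3:5)
  expect_identical(plan$rounds$marker[1:2], c("URA3", "LEU2"))
  expect_identical(plan$final_swap$replacement, "BFP")
  expect_identical(plan$final_swap$marker,
                   plan$rounds$marker[nrow(plan$rounds)])
  expect_error(plan_assembly(fake_chunks, per_round_max = 5), "1 and 4")
  expect_error(plan_assembly(fake_chunks, per_round_max = 0), "1 and 4")

  # exhaustive validity over all chunk counts 1..30
  for (n in 1:30) {
    p <- plan_assembly(vector("list", n))
    expect_true(isTRUE(validate_assembly_plan(p, n)))
    # brute-force re-check of the invariants, independent of the validator
    covered <- unlist(p$chunk_rounds)
    expect_identical(sort(covered), covered)
    expect_identical(as.integer(covered), seq_len(n))
    expect_true(all(lengths(p$chunk_rounds) >= 1 &
                    lengths(p$chunk_rounds) <= 4))
    m <- p$rounds$marker
    if (length(m) > 1) expect_true(all(m[-1] != m[-length(m)]))
  }
})

test_that("nearest-neighbor Tm matches an independent brute-force summation", {
  set.seed(77)
  for (i in 1:50) {
    len <- sample(18:25, 1)
    primer <- paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = "")
    expect_equal(tm_nearest_neighbor(primer), oracle_tm(primer),
                 tolerance = 1e-8)
  }
  # sanity: a GC-rich primer melts hotter than an AT-rich one
  expect_gt(tm_nearest_neighbor(strrep("GC", 10)),
            tm_nearest_neighbor(strrep("AT", 10)))
})

test_that("junction primers span their boundary, hit Tm bounds and are unique", {
  d <- make_circle(55)
  ch <- chunk_design(d)
  pr <- design_junction_primers(d, ch)
  expect_equal(nrow(pr), length(ch))  # circular: one pair per junction
  len <- design_length(d)
  for (i in seq_len(nrow(pr))) {
    row <- pr[i, ]
    expect_true(row$tm_forward >= 58 && row$tm_forward <= 62)
    expect_true(row$tm_reverse >= 58 && row$tm_reverse <= 62)
    expect_true(row$product_length >= 400 && row$product_length <= 1000)
    # amplicon interval contains the boundary coordinate
    expect_true(((row$boundary - row$fwd_start) %% len) < row$product_length)
    # each primer occurs exactly once in the design
    expect_equal(neochrom:::count_occurrences(d$sequence, row$forward,
                                              circular = TRUE), 1)
    expect_equal(neochrom:::count_occurrences(d$sequence, row$reverse,
                                              circular = TRUE), 1)
  }
})

test_that("replace_region performs swaps, insertions and deletions with feature care", {
  d <- make_circle(99, n_fragments = 3, size_range = c(1500, 4000))
  len0 <- design_length(d)

  # marker swap changes length by the payload difference
  marker <- d$features[d$features$type == "marker", ][1, ]
  cassette <- strrep("ACGGT", 60)
  d2 <- replace_region(d, marker$id, cassette,
                       feature = list(id = "BFP", type = "cassette"))
  expect_equal(design_length(d2),
               len0 + nchar(cassette) - (marker$end - marker$start))
  expect_true("BFP" %in% d2$features$id)
  # flanking sequence unchanged
  expect_identical(substr(d2$sequence, marker$start - 49, marker$start),
                   substr(d$sequence, marker$start - 49, marker$start))

  # pure insertion between two ORFs leaves both ORF sequences intact
  orfs <- d$features[d$features$type == "ORF", ]
  orfs <- orfs[order(orfs$start), ]
  gap_at <- neochrom:::find_intergenic_locus(d, orfs$end[1] + 10)
  ars <- strrep("TTTAT", 40)
  d3 <- replace_region(d, c(gap_at, gap_at), ars,
                       feature = list(id = "ARS_extra", type = "ARS"))
  expect_equal(design_length(d3), len0 + nchar(ars))
  orf_seq <- function(des, row)
    substr(des$sequence, row$start + 1, row$end)
  for (i in seq_len(nrow(orfs))) {
    after <- d3$features[d3$features$id == orfs$id[i], ]
    expect_identical(orf_seq(d3, after), orf_seq(d, orfs[i, ]))
  }

  # pure deletion of a feature-free 5 bp window
  free5 <- Find(function(p)
    !any(d$features$start < p + 5 & p < d$features$end),
    seq(0, design_length(d) - 5))
  d4 <- replace_region(d, c(free5, free5 + 5), "")
  expect_equal(design_length(d4), len0 - 5)

  # overlapping an ORF without override is an error
  orf1 <- orfs[1, ]
  expect_error(replace_region(d, c(orf1$start + 1, orf1$start + 10), ""),
               "overlaps ORF")
  expect_identical(replay_edit_log(d3), d3$sequence)
})
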