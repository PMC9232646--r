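# Synthetic-data generators: spec validation, construction guarantees,
# determinism, and distributional correctness.

test_that("fragment generation respects sizes, ORF structure and GC target", {
  spec <- fragment_spec(n_fragments = 17, size_range = c(1100, 60300),
                        seed = 42)
  frags <- generate_pan_fragments(spec)
  expect_length(frags, 17)
  lens <- vapply(frags, function(f) nchar(f$sequence), integer(1))
  expect_true(all(lens >= 1100 & lens <= 60300))

  # ORF construction guarantees on every fragment
  for (f in frags) {
    expect_gt(nrow(f$orfs), 0)
    for (i in seq_len(nrow(f$orfs))) {
      o <- f$orfs[i, ]
      w <- o$end - o$start
      expect_true(w %% 3 == 0 && w >= 6)
      cds <- substr(f$sequence, o$start + 1, o$end)
      if (o$strand == "-")
        cds <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(cds)))
      expect_identical(substr(cds, 1, 3), "ATG")
      expect_true(substr(cds, w - 2, w) %in% c("TAA", "TAG", "TGA"))
      expect_true(o$confidence %in% c("high", "low"))
    }
  }

  # generated fragments are free of the scrubbed motifs
  all_seq <- paste(vapply(frags, function(f) f$sequence, character(1)),
                   collapse = "")
  for (m in c(loxpsym_site(), restriction_sites()))
    expect_false(grepl(m, all_seq, fixed = TRUE))
})

test_that("realized GC tracks the target on a large sample", {
  spec <- fragment_spec(n_fragments = 5, size_range = c(20000, 30000),
                        gc_target = 0.38, seed = 7)
  frags <- generate_pan_fragments(spec)
  all_seq <- paste(vapply(frags, function(f) f$sequence, character(1)),
                   collapse = "")
  expect_gte(nchar(all_seq), 100000)
  gc <- lengths(regmatches(all_seq, gregexpr("[GC]", all_seq))) / nchar(all_seq)
  expect_lt(abs(gc - 0.38), 0.02)
})

test_that("generators are deterministic and reject invalid specs", {
  s <- fragment_spec(n_fragments = 3, size_range = c(1100, 3000), seed = 5)
  f1 <- generate_pan_fragments(s)
  f2 <- generate_pan_fragments(s)
  expect_identical(f1, f2)
  expect_error(fragment_spec(size_range = c(100, 500)), "300")
  expect_error(fragment_spec(orf_density = 0), "orf_density")
  expect_error(fragment_spec(gc_target = 1.2), "gc_target")
  tiny <- fragment_spec(size_range = c(300, 400))
  tiny$size_range <- c(100L, 180L)  # below the fragment_spec() floor
  expect_error(generate_pan_fragments(tiny), "host one ORF")

  p1 <- generate_passaging_counts(passaging_spec(seed = 9))
  p2 <- generate_passaging_counts(passaging_spec(seed = 9))
  expect_identical(p1, p2)
  b1 <- generate_biolog_experiment(plate_spec(seed = 9))
  b2 <- generate_biolog_experiment(plate_spec(seed = 9))
  expect_identical(b1, b2)
  # truth retention
  expect_s3_class(attr(p1, "truth"), "passaging_spec")
  expect_s3_class(attr(generate_pan_fragments(s), "truth"), "fragment_spec")
})

test_that("passaging counts follow the binomial retention model", {
  det0 <- generate_passaging_counts(passaging_spec(p_loss = 0, seed = 1))
  expect_true(all(det0$resistant == det0$total))
  det1 <- generate_passaging_counts(passaging_spec(p_loss = 1, seed = 1))
  expect_true(all(det1$resistant == 0))

  # expected count at the published retention level
  p <- 0.019; g <- 25; n <- 96
  draws <- vapply(1:100, function(s) {
    x <- generate_passaging_counts(passaging_spec(
      p_loss = p, generations = c(25), n_colonies = n, replicates = 1,
      seed = s))
    x$resistant[1]
  }, numeric(1))
  expect_equal((1 - p)^g * n, 59.4, tolerance = 0.01)
  band <- qbinom(c(0.005, 0.995), n, (1 - p)^g)
  expect_true(mean(draws) >= band[1] && mean(draws) <= band[2])

  # chi-square goodness of fit over 1000 draws
  p <- 0.1; g <- 5; n <- 20
  draws <- vapply(1:1000, function(s) {
    generate_passaging_counts(passaging_spec(
      p_loss = p, generations = c(5), n_colonies = n, replicates = 1,
      seed = 20000 + s))$resistant[1]
  }, numeric(1))
  probs <- dbinom(0:n, n, (1 - p)^g)
  obs <- tabulate(draws + 1, nbins = n + 1)
  keep <- probs * 1000 >= 5
  chi <- sum((obs[keep] - 1000 * probs[keep])^2 / (1000 * probs[keep]))
  expect_lt(chi, qchisq(0.99, sum(keep) - 1))
})

test_that("kinetic plates carry planted effects and valid controls", {
  sp <- plate_spec(n_wells = 24, effect_map = c(B01 = 2),
                   control_wells = list(negative = "A01", positive = "A02"),
                   blank_wells = "A03", noise_cv = 0, seed = 3)
  ex <- generate_biolog_experiment(sp)
  a <- function(df, w) max_curve_height(df$value[df$well == w])
  # no-effect wells: identical plateaus across strains
  expect_equal(log2(a(ex$test, "B05") / a(ex$reference, "B05")), 0)
  # planted two-fold effect
  expect_equal(log2(a(ex$test, "B01") / a(ex$reference, "B01")), 1)
  # blank stays below negative + 50 on both plates
  expect_lt(a(ex$test, "A03"), a(ex$test, "A01") + 50)
  expect_lt(a(ex$reference, "A03"), a(ex$reference, "A01") + 50)
  # monotone mean trend without noise
  b05 <- ex$test$value[ex$test$well == "B05"]
  expect_true(all(diff(b05) >= 0))
  expect_error(plate_spec(control_wells = list(negative = "A01")),
               "positive")
  expect_error(plate_spec(noise_cv = -1), "noise_cv")
})

test_that("coverage profiles plant the requested depth ratio", {
  cs <- coverage_spec(true_ratio = 1, noise = "none", seed = 1)
  cov <- generate_coverage_profile(cs)
  expect_equal(estimate_copy_number(cov, "PGNC"), 1)
  cs2 <- coverage_spec(true_ratio = 2, noise = "none", seed = 1)
  expect_equal(estimate_copy_number(generate_coverage_profile(cs2), "PGNC"), 2)
  expect_error(coverage_spec(element_name = "nope"), "element_name")
  expect_error(coverage_spec(true_ratio = 0), "true_ratio")
})
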