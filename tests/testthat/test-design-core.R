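# Design construction and the Sc2.0-style edits: descending-size
# concatenation, terminal stop recoding, loxPsym placement geometry,
# synonymous watermarks, and whole-design validation.

plain_frag <- function(id, len, base = "ACGT") {
  pan_fragment(id, strtrim(strrep(base, ceiling(len / nchar(base))), len))
}

test_that("fragments concatenate in descending size order with id tie-break", {
  bb <- synthetic_backbone(seed = 1)
  f3 <- plain_frag("f3", 3000); f10 <- plain_frag("f10", 10000)
  f5 <- plain_frag("f5", 5000)
  d <- concatenate_fragments(list(f3, f10, f5), bb)
  expect_identical(d$topology, "circular")
  expect_equal(design_length(d), 18000 + nchar(bb$sequence))
  expect_identical(d$sequence,
                   paste0(f10$sequence, f5$sequence, f3$sequence, bb$sequence))

  # equal lengths: deterministic tie-break by id
  fa <- plain_frag("a", 1000, "AACGT"); fb <- plain_frag("b", 1000, "TTGCA")
  d2 <- concatenate_fragments(list(fb, fa), bb)
  expect_identical(substr(d2$sequence, 1, 1000), fa$sequence)

  # single fragment: design = fragment + backbone
  d3 <- concatenate_fragments(list(f3), bb)
  expect_identical(d3$sequence, paste0(f3$sequence, bb$sequence))

  expect_error(concatenate_fragments(list(), bb), "empty")
  expect_error(concatenate_fragments(list(f3, f3), bb), "duplicate")
})

test_that("terminal TAG stops are recoded to TAA, TAA/TGA untouched", {
  bb <- synthetic_backbone(seed = 1)
  mk <- function(orf, strand) {
    fwd <- if (strand == "+") orf
           else as.character(Biostrings::reverseComplement(
             Biostrings::DNAString(orf)))
    manual_fragment("f1", paste0("ACGTACGTACGT", fwd, "ACGTACGTACGT"),
                    12, 12 + nchar(orf), strand)
  }
  for (strand in c("+", "-")) {
    d <- recode_stop_codons(concatenate_fragments(
      list(mk("ATGAAATAG", strand)), bb))
    orf <- d$features[d$features$type == "ORF", ][1, ]
    cds <- substr(d$sequence, orf$start + 1, orf$end)
    if (strand == "-")
      cds <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(cds)))
    expect_identical(cds, "ATGAAATAA")
    expect_length(d$edit_log, 1)
  }
  # TAA and TGA terminal codons are left alone
  for (stop in c("TAA", "TGA")) {
    d <- concatenate_fragments(list(mk(paste0("ATGAAA", stop), "+")), bb)
    before <- d$sequence
    d <- recode_stop_codons(d)
    expect_identical(d$sequence, before)
    expect_length(d$edit_log, 0)
  }
})

test_that("loxPsym insertion lands 3 bp after the stop in ORF orientation", {
  # plus-strand ORF ending at position 9 in a 60-nt design
  seq60 <- paste0("ATGAAATAG", strtrim(strrep("CGTA", 13), 51))
  d <- neochrom:::new_design("t", "circular", seq60,
    neochrom:::feature_row("o1", "ORF", 0, 9, "+", "high"))
  d <- insert_loxpsym(recode_stop_codons(d))
  expect_equal(design_length(d), 94)
  expect_identical(substr(d$sequence, 13, 46), loxpsym_site())
  lox <- d$features[d$features$type == "loxPsym", ]
  expect_equal(c(lox$start, lox$end), c(12, 46))

  # minus-strand ORF starting (leftmost) at position 40: insertion point 37
  orf_fwd <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString("ATGAAATAG")))
  seq100 <- paste0(strtrim(strrep("CGTA", 10), 40), orf_fwd,
                   strtrim(strrep("GACT", 13), 51))
  d2 <- neochrom:::new_design("t2", "circular", seq100,
    neochrom:::feature_row("o1", "ORF", 40, 49, "-", "high"))
  d2 <- insert_loxpsym(recode_stop_codons(d2))
  expect_equal(design_length(d2), 134)
  lox2 <- d2$features[d2$features$type == "loxPsym", ]
  expect_equal(c(lox2$start, lox2$end), c(37, 71))
  orf2 <- d2$features[d2$features$type == "ORF", ]
  # exactly 3 bp between the site and the (shifted) stop codon
  expect_equal(orf2$start - lox2$end, 3)

  # collision with another feature is skipped and reported
  d3 <- neochrom:::new_design("t3", "circular", seq60,
    rbind(neochrom:::feature_row("o1", "ORF", 0, 9, "+", "high"),
          neochrom:::feature_row("blocker", "marker", 10, 20, "+")))
  d3 <- insert_loxpsym(recode_stop_codons(d3))
  expect_equal(sum(d3$features$type == "loxPsym"), 0)
  expect_true("o1" %in% d3$skipped_loxpsym)
})

test_that("watermarks round-trip payloads and never change the protein", {
  set.seed(31)
  for (i in 1:25) {
    d <- make_edited_design(seed = 400 + i, n_fragments = 2,
                            size_range = c(1100, 2500), n_watermarks = 2,
                            payload_bits = sample(1:10, 1))
    payloads <- attr(d, "wm_payloads")
    for (oid in names(payloads))
      expect_identical(decode_watermark(d, oid), payloads[[oid]])
    expect_true(all_checks_pass(validate_design(d)))
  }
  # unwatermarked ORF decodes to the empty payload
  d <- make_edited_design(seed = 1, n_watermarks = 1)
  orfs <- d$features[d$features$type == "ORF", ]
  bare <- setdiff(orfs$id, names(attr(d, "wm_payloads")))[1]
  expect_identical(decode_watermark(d, bare), "")
})

test_that("a watermark window without degenerate codons is an error", {
  bb <- synthetic_backbone(seed = 1)
  # interior entirely tryptophan codons: no synonyms anywhere
  orf <- paste0("ATG", strrep("TGG", 25), "TAA")
  f <- manual_fragment("f1", paste0("ACGTACGTACGT", orf, "ACGTACGTACGT"),
                       12, 12 + nchar(orf))
  d <- recode_stop_codons(concatenate_fragments(list(f), bb))
  expect_error(embed_watermarks(d, f$orfs$id[1], "1"),
               "zero degenerate codons")
})

test_that("the full edit chain preserves every ORF translation and obeys length accounting", {
  for (seed in 1:10) {
    frags <- generate_pan_fragments(fragment_spec(
      n_fragments = 3, size_range = c(1100, 3000), seed = 600 + seed))
    bb <- synthetic_backbone(seed = seed)
    d0 <- concatenate_fragments(frags, bb)
    before <- vapply(seq_len(nrow(d0$features)), function(i) {
      row <- d0$features[i, ]
      if (row$type != "ORF") return(NA_character_)
      cds <- substr(d0$sequence, row$start + 1, row$end)
      if (row$strand == "-")
        cds <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(cds)))
      as.character(Biostrings::translate(Biostrings::DNAString(cds)))
    }, character(1))
    names(before) <- d0$features$id

    d <- recode_stop_codons(d0)
    orfs <- d$features[d$features$type == "ORF", ]
    eligible <- orfs$id[(orfs$end - orfs$start) / 3 >= 24]
    if (length(eligible) > 0)
      d <- embed_watermarks(d, eligible,
                            rep("10110", length(eligible)))
    d <- insert_loxpsym(d)

    n_sites <- sum(d$features$type == "loxPsym")
    expect_equal(design_length(d), design_length(d0) + 34 * n_sites)

    orfs_after <- d$features[d$features$type == "ORF", ]
    for (i in seq_len(nrow(orfs_after))) {
      row <- orfs_after[i, ]
      cds <- substr(d$sequence, row$start + 1, row$end)
      if (row$strand == "-")
        cds <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(cds)))
      tr <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
      # recoding may change the stop codon but never the protein
      expect_identical(substr(tr, 1, nchar(tr) - 1),
                       substr(before[[row$id]], 1,
                              nchar(before[[row$id]]) - 1))
    }
    expect_identical(replay_edit_log(d), d$sequence)
  }
})

test_that("validation passes fresh designs and flags planted restriction sites", {
  bb <- synthetic_backbone(seed = 2)
  frags <- generate_pan_fragments(fragment_spec(
    n_fragments = 2, size_range = c(1100, 2000), seed = 3))
  d <- concatenate_fragments(frags, bb)
  v <- validate_design(d)
  expect_true(all_checks_pass(v))
  expect_match(v$detail[v$check == "summary"], "loxPsym=0")

  # plant a PmeI site in an intergenic stretch
  d2 <- replace_region(d, c(5, 5), "GTTTAAAC")
  v2 <- validate_design(d2)
  expect_false(v2$pass[v2$check == "restriction_free"])
  # loxPsym self-symmetry holds for the configured site
  expect_true(v2$pass[v2$check == "loxpsym_self_symmetric"])
})
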