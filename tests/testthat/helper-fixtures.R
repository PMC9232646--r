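# Shared fixtures and independently coded oracles.

# small fragment set -> fully edited design (recode + watermarks + loxPsym)
make_edited_design <- function(seed, n_fragments = 4L,
                               size_range = c(1100L, 4000L),
                               n_watermarks = 2L, payload_bits = 6L) {
  frags <- generate_pan_fragments(fragment_spec(
    n_fragments = n_fragments, size_range = size_range, seed = seed))
  bb <- synthetic_backbone(seed = seed + 1L)
  d <- recode_stop_codons(concatenate_fragments(frags, bb))
  orfs <- d$features[d$features$type == "ORF", ]
  eligible <- orfs$id[(orfs$end - orfs$start) / 3 >= 24]
  wm <- head(eligible, n_watermarks)
  payloads <- withr::with_seed(seed + 2L, vapply(seq_along(wm), function(i)
    paste(sample(0:1, payload_bits, replace = TRUE), collapse = ""),
    character(1)))
  if (length(wm) > 0) d <- embed_watermarks(d, wm, payloads)
  d <- insert_loxpsym(d)
  attr(d, "wm_payloads") <- stats::setNames(payloads, wm)
  d
}

# hand-built fragment with one ORF, for coordinate-exact cases
manual_fragment <- function(id, sequence, orf_start, orf_end, strand = "+",
                            confidence = "high") {
  pan_fragment(id, sequence,
               data.frame(id = paste0(id, "_orf"), start = orf_start,
                          end = orf_end, strand = strand,
                          confidence = confidence,
                          product = NA_character_,
                          stringsAsFactors = FALSE))
}

# random circular sequence interleaving n unique segments with loxPsym
random_lox_circle <- function(n_segs, seg_len = 300L, seed = 1L) {
  withr::with_seed(seed, {
    segs <- replicate(n_segs, paste(sample(c("A", "C", "G", "T"), seg_len,
                                           replace = TRUE), collapse = ""))
    paste(vapply(segs, function(s) paste0(loxpsym_site(), s), character(1)),
          collapse = "")
  })
}

# --- independent brute-force nearest-neighbor Tm oracle --------------------
# Coded separately from the package implementation: explicit per-step
# summation over an independently transcribed SantaLucia (1998) table.
oracle_tm <- function(primer, na_molar = 0.05, conc = 5e-7) {
  dH <- list(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2, CA = -8.5,
             TG = -8.5, GT = -8.4, AC = -8.4, CT = -7.8, AG = -7.8,
             GA = -8.2, TC = -8.2, CG = -10.6, GC = -9.8, GG = -8.0,
             CC = -8.0)
  dS <- list(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3, CA = -22.7,
             TG = -22.7, GT = -22.4, AC = -22.4, CT = -21.0, AG = -21.0,
             GA = -22.2, TC = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
             CC = -19.9)
  b <- strsplit(primer, "")[[1]]
  h <- 0; s <- 0
  for (i in seq_len(length(b) - 1)) {
    key <- paste0(b[i], b[i + 1])
    h <- h + dH[[key]]
    s <- s + dS[[key]]
  }
  for (term in c(b[1], b[length(b)])) {
    if (term %in% c("G", "C")) { h <- h + 0.1; s <- s - 2.8 }
    else { h <- h + 2.3; s <- s + 4.1 }
  }
  s <- s + 0.368 * (length(b) - 1) * log(na_molar)
  h * 1000 / (s + 1.987 * log(conc / 4)) - 273.15
}

# --- brute-force phenotype-microarray rule oracle ---------------------------
# Literal re-application of the classification rules on plateau heights.
oracle_biolog <- function(a_test, a_ref, roles, delta = 50, pos_min = 100,
                          threshold = 1) {
  neg <- names(roles)[roles == "negative"]
  pos <- names(roles)[roles == "positive"]
  plate_fail <- a_test[[pos]] < pos_min || a_ref[[pos]] < pos_min
  wells <- names(roles)[roles == "compound"]
  out <- character(length(wells)); names(out) <- wells
  for (w in wells) {
    if (plate_fail || a_test[[w]] < a_test[[neg]] + delta ||
        a_ref[[w]] < a_ref[[neg]] + delta) { out[[w]] <- "excluded"; next }
    lr <- log2(a_test[[w]] / a_ref[[w]])
    out[[w]] <- if (lr >= threshold) "increased"
                else if (lr <= -threshold) "decreased" else "unchanged"
  }
  out
}

# build a tidy plate data frame from plateau heights (constant series)
plate_from_heights <- function(a, roles, npts = 5L) {
  do.call(rbind, lapply(names(roles), function(w)
    data.frame(well = w, role = roles[[w]],
               compound = if (roles[[w]] == "compound") paste0("c_", w)
                          else NA_character_,
               time = seq_len(npts), value = a[[w]],
               stringsAsFactors = FALSE)))
}
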