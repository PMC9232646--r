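# Neo-chromosome design container and construction.
#
# A design is an S3 list: name, topology ("circular"/"linear"), sequence
# (uppercase forward strand), a features data.frame (0-based half-open
# coordinates), a watermark registry, an ordered edit log, and the
# pre-edit (concatenated) sequence the edit log replays from.

#' Construct an annotated pan-genome fragment
#'
#' A fragment is a piece of donor DNA carrying zero or more annotated
#' ORFs; fragments are the building blocks a neo-chromosome design is
#' concatenated from.
#'
#' @param id Unique fragment identifier.
#' @param sequence Uppercase DNA string (A/C/G/T).
#' @param orfs `data.frame` with columns `id`, `start`, `end` (0-based,
#'   half-open), `strand` (`"+"`/`"-"`), `confidence` (`"high"`/`"low"`)
#'   and optionally `product`. May have zero rows.
#' @param source_label Free-text provenance label.
#'
#' @return An object of class `pan_fragment`.
#' @export
pan_fragment <- function(id, sequence, orfs = empty_orf_table(),
                         source_label = "") {
  sequence <- toupper(sequence)
  stopifnot_dna(sequence, paste0("fragment ", id, " sequence"))
  orfs <- as.data.frame(orfs, stringsAsFactors = FALSE)
  if (!"product" %in% names(orfs)) orfs$product <- NA_character_
  need <- c("id", "start", "end", "strand", "confidence")
  if (!all(need %in% names(orfs)))
    stop("orfs must have columns ", paste(need, collapse = ", "))
  for (i in seq_len(nrow(orfs))) {
    check_orf_annotation(orfs$start[i], orfs$end[i], orfs$strand[i],
                         sequence, orfs$id[i])
  }
  structure(list(id = as.character(id), source_label = source_label,
                 sequence = sequence, orfs = orfs),
            class = "pan_fragment")
}

empty_orf_table <- function() {
  data.frame(id = character(), start = integer(), end = integer(),
             strand = character(), confidence = character(),
             product = character(), stringsAsFactors = FALSE)
}

# ORF annotation invariants: in-bounds, length divisible by 3 and >= 6,
# starts with ATG and ends with a stop on its own strand. Violations are
# raised (construction-time) — downstream editing assumes them.
check_orf_annotation <- function(start, end, strand, sequence, id) {
  len <- nchar(sequence)
  if (start < 0 || end > len || end <= start)
    stop("ORF ", id, " out of bounds [", start, ", ", end, ") on length ", len)
  w <- end - start
  if (w %% 3 != 0 || w < 6)
    stop("ORF ", id, " length ", w, " not a positive multiple of 3 (>= 6)")
  cds <- subseq0(sequence, start, end)
  if (identical(strand, "-")) cds <- revcomp(cds)
  if (substr(cds, 1, 3) != "ATG")
    stop("ORF ", id, " does not start with ATG on strand ", strand)
  last <- substr(cds, w - 2, w)
  if (!last %in% STOP_CODONS)
    stop("ORF ", id, " does not end with a stop codon (found ", last, ")")
  invisible(TRUE)
}

#' @export
print.pan_fragment <- function(x, ...) {
  cat(sprintf("<pan_fragment %s: %d bp, %d ORF(s)>\n",
              x$id, nchar(x$sequence), nrow(x$orfs)))
  invisible(x)
}

empty_feature_table <- function() {
  data.frame(id = character(), type = character(), start = integer(),
             end = integer(), strand = character(),
             confidence = character(), product = character(),
             stringsAsFactors = FALSE)
}

feature_row <- function(id, type, start, end, strand = "+",
                        confidence = NA_character_, product = NA_character_) {
  data.frame(id = id, type = type, start = as.integer(start),
             end = as.integer(end), strand = strand,
             confidence = confidence, product = product,
             stringsAsFactors = FALSE)
}

new_design <- function(name, topology, sequence, features,
                       initial_sequence = sequence) {
  structure(list(name = name, topology = topology, sequence = sequence,
                 features = features, watermarks = list(),
                 edit_log = list(), issues = character(),
                 initial_sequence = initial_sequence),
            class = "neochrom_design")
}

#' Concatenate fragments into a circular neo-chromosome design
#'
#' Fragments are ordered by decreasing length (ties broken by fragment
#' id) and joined into a single molecule, after which the vector
#' backbone is appended and the topology set to circular. ORF
#' annotations are lifted to design coordinates and the edit log is
#' initialized (empty: the concatenated molecule is the replay origin).
#'
#' @param fragments Non-empty list of [pan_fragment()] objects with
#'   unique ids.
#' @param backbone A `pan_fragment` carrying the centromere/marker
#'   backbone; its extra features (see [synthetic_backbone()]) are
#'   retained.
#' @param name Design name.
#'
#' @return A `neochrom_design` object.
#' @export
concatenate_fragments <- function(fragments, backbone, name = "design") {
  if (length(fragments) == 0L) stop("empty fragment list")
  ids <- vapply(fragments, function(f) f$id, character(1))
  if (anyDuplicated(ids)) stop("duplicate fragment ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  lens <- vapply(fragments, function(f) nchar(f$sequence), integer(1))
  ord <- order(-lens, ids)
  fragments <- fragments[ord]

  feats <- empty_feature_table()
  seqs <- character(length(fragments))
  offset <- 0L
  for (i in seq_along(fragments)) {
    f <- fragments[[i]]
    seqs[i] <- f$sequence
    if (nrow(f$orfs) > 0) {
      o <- f$orfs
      feats <- rbind(feats, feature_row(o$id, "ORF", o$start + offset,
                                        o$end + offset, o$strand,
                                        o$confidence, o$product))
    }
    offset <- offset + nchar(f$sequence)
  }
  # backbone features: ORFs plus any annotated landmark features
  bfeats <- attr(backbone, "features")
  feats <- rbind(feats,
                 feature_row(backbone$id, "backbone", offset,
                             offset + nchar(backbone$sequence), "+"))
  if (!is.null(bfeats) && nrow(bfeats) > 0) {
    feats <- rbind(feats, feature_row(bfeats$id, bfeats$type,
                                      bfeats$start + offset,
                                      bfeats$end + offset, bfeats$strand))
  }
  if (nrow(backbone$orfs) > 0) {
    o <- backbone$orfs
    feats <- rbind(feats, feature_row(o$id, "ORF", o$start + offset,
                                      o$end + offset, o$strand,
                                      o$confidence, o$product))
  }
  seq <- paste0(paste(seqs, collapse = ""), backbone$sequence)
  rownames(feats) <- NULL
  new_design(name, "circular", seq, feats)
}

#' Synthetic centromeric backbone
#'
#' Generates a synthetic stand-in for a p416-style centromeric vector
#' backbone: random sequence carrying annotated CEN, ARS and
#' dominant-marker features. The real vector sequence is not modeled;
#' this object only has to provide the landmark features assembly and
#' SCRaMbLE simulation anchor on.
#'
#' @param length_bp Total backbone length (default 5500).
#' @param seed Integer seed.
#' @return A `pan_fragment` with a `features` attribute (CEN, ARS,
#'   marker intervals).
#' @export
synthetic_backbone <- function(length_bp = 5500L, seed = 1L) {
  seqs <- with_seed(seed, random_dna(length_bp, gc = 0.40))
  seqs <- scrub_motifs(seqs, forbidden_motifs(), orfs = empty_orf_table(),
                       seed = derive_seed(seed, 1))
  f <- pan_fragment("backbone", seqs, source_label = "synthetic p416-style backbone")
  attr(f, "features") <- data.frame(
    id = c("CEN", "ARS", "natR"),
    type = c("CEN", "ARS", "marker"),
    start = c(100L, 300L, 1200L),
    end = c(218L, 500L, 2000L),
    strand = "+", stringsAsFactors = FALSE)
  f
}

#' @export
print.neochrom_design <- function(x, ...) {
  cat(sprintf("<neochrom_design %s: %s, %d bp, %d feature(s), %d edit(s)>\n",
              x$name, x$topology, nchar(x$sequence), nrow(x$features),
              length(x$edit_log)))
  invisible(x)
}

#' @export
summary.neochrom_design <- function(object, ...) {
  tab <- table(object$features$type)
  cat(sprintf("Design %s (%s), %d bp\n", object$name, object$topology,
              nchar(object$sequence)))
  for (t in names(tab)) cat(sprintf("  %-12s %d\n", t, tab[[t]]))
  cat(sprintf("  edits logged: %d\n", length(object$edit_log)))
  invisible(object)
}

#' Design length in base pairs
#' @param design A `neochrom_design`.
#' @return Integer length.
#' @export
design_length <- function(design) nchar(design$sequence)

# ---- edit application and replay ------------------------------------------

# Apply a splice edit: replace `removed` (verified to match) at 0-based
# position `pos` with `inserted`; shift downstream features; log the edit.
apply_edit <- function(design, pos, removed, inserted, op, detail = "") {
  seqs <- design$sequence
  n_rm <- nchar(removed)
  if (n_rm > 0 && subseq0(seqs, pos, pos + n_rm) != removed)
    stop("edit '", op, "' at ", pos, ": sequence does not match expected text")
  before_len <- nchar(seqs)
  design$sequence <- paste0(subseq0(seqs, 0L, pos), inserted,
                            subseq0(seqs, pos + n_rm, nchar(seqs)))
  delta <- nchar(inserted) - n_rm
  if (delta != 0L && nrow(design$features) > 0) {
    f <- design$features
    # features fully downstream shift; features containing the edited
    # interval stretch by delta; features inside a removed span are the
    # caller's responsibility to drop.
    shift_start <- f$start >= pos + n_rm
    # strict containment: features merely abutting the edit keep their width
    span <- f$start < pos + max(n_rm, 1L) & f$end > pos &
            f$start <= pos & f$end >= pos + n_rm
    f$start[shift_start] <- f$start[shift_start] + delta
    f$end[shift_start | span] <- f$end[shift_start | span] + delta
    design$features <- f
  }
  design$edit_log[[length(design$edit_log) + 1L]] <-
    list(op = op, pos = pos, removed = removed, inserted = inserted,
         before_len = before_len, after_len = nchar(design$sequence),
         detail = detail)
  design
}

#' Replay a design's edit log
#'
#' Reapplies every logged edit to the design's stored pre-edit
#' (concatenated) sequence and returns the reconstructed sequence. Used
#' by [validate_design()] to prove the edit log fully accounts for the
#' current sequence.
#'
#' @param design A `neochrom_design`.
#' @return The replayed sequence string.
#' @export
replay_edit_log <- function(design) {
  s <- design$initial_sequence
  for (e in design$edit_log) {
    n_rm <- nchar(e$removed)
    if (n_rm > 0 && subseq0(s, e$pos, e$pos + n_rm) != e$removed)
      stop("edit log replay failed at op '", e$op, "' pos ", e$pos)
    s <- paste0(subseq0(s, 0L, e$pos), e$inserted,
                subseq0(s, e$pos + n_rm, nchar(s)))
  }
  s
}

# forward-strand interval of an ORF's coding sequence; strand-aware read
orf_cds <- function(design, row) {
  cds <- subseq0(design$sequence, row$start, row$end)
  if (row$strand == "-") cds <- revcomp(cds) else cds
}

design_orfs <- function(design) {
  design$features[design$features$type == "ORF", , drop = FALSE]
}
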