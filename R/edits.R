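# Sc2.0-style design edits: terminal stop-codon recoding, symmetric
# loxPsym insertion, synonymous-codon watermarks, and generic region
# replacement. Editing order is enforced: recode -> watermark -> loxPsym.

#' Recode terminal TAG stop codons to TAA
#'
#' For every annotated ORF whose terminal codon (on its own strand) is
#' TAG, substitutes TAA. TAA and TGA terminal codons, and all internal
#' codons, are untouched, so ORF length and translation are unchanged.
#' ORFs whose terminal codon is not a stop are skipped and reported in
#' the design's issue list (surfaced by [validate_design()]).
#'
#' @param design A `neochrom_design`.
#' @return The edited design with one logged edit per recoded ORF.
#' @export
recode_stop_codons <- function(design) {
  orfs <- design_orfs(design)
  if (nrow(orfs) == 0L) stop("design has no ORF features")
  for (i in seq_len(nrow(orfs))) {
    row <- orfs[i, ]
    if (row$strand == "+") {
      pos <- row$end - 3L
      cod <- subseq0(design$sequence, pos, row$end)
      if (!cod %in% STOP_CODONS) {
        design$issues <- c(design$issues,
          sprintf("ORF %s terminal codon %s is not a stop; skipped", row$id, cod))
        next
      }
      if (cod == "TAG")
        design <- apply_edit(design, pos, "TAG", "TAA", "recode_stop", row$id)
    } else {
      pos <- row$start
      fwd <- subseq0(design$sequence, pos, pos + 3L)
      cod <- revcomp(fwd)
      if (!cod %in% STOP_CODONS) {
        design$issues <- c(design$issues,
          sprintf("ORF %s terminal codon %s is not a stop; skipped", row$id, cod))
        next
      }
      if (cod == "TAG")
        design <- apply_edit(design, pos, "CTA", "TTA", "recode_stop", row$id)
    }
  }
  design$recoded <- TRUE
  design
}

#' Insert loxPsym sites 3 bp downstream of selected ORF stop codons
#'
#' Inserts the 34-bp symmetric loxPsym site exactly 3 bp after the stop
#' codon of each selected ORF, in the ORF's own orientation (for a
#' minus-strand ORF the site goes on the lower-coordinate side).
#' Insertions are applied in descending coordinate order so earlier
#' coordinates remain valid; all downstream features are shifted. ORFs
#' whose insertion point falls inside another feature are skipped and
#' reported (or raise an error when `on_collision = "error"`).
#'
#' @param design A recoded `neochrom_design` (see
#'   [recode_stop_codons()]; ordering is enforced).
#' @param orf_ids Explicit character vector of ORF ids, or `NULL` for
#'   the default rule: all high-confidence ORFs.
#' @param site The loxPsym sequence (default [loxpsym_site()]).
#' @param on_collision `"skip"` (default) or `"error"`.
#' @return The edited design; skipped ORF ids are recorded in
#'   `design$skipped_loxpsym`.
#' @export
insert_loxpsym <- function(design, orf_ids = NULL, site = loxpsym_site(),
                           on_collision = c("skip", "error")) {
  on_collision <- match.arg(on_collision)
  if (!isTRUE(design$recoded))
    stop("stop codons must be recoded before loxPsym insertion")
  if (revcomp(site) != site)
    stop("loxPsym site must be its own reverse complement")
  orfs <- design_orfs(design)
  if (is.null(orf_ids)) {
    orf_ids <- orfs$id[!is.na(orfs$confidence) & orfs$confidence == "high"]
  }
  sel <- orfs[orfs$id %in% orf_ids, , drop = FALSE]
  len <- design_length(design)
  pts <- integer(0); pids <- character(0); skipped <- character(0)
  for (i in seq_len(nrow(sel))) {
    row <- sel[i, ]
    p <- if (row$strand == "+") row$end + 3L else row$start - 3L
    if (design$topology == "circular") p <- p %% len
    if (p < 0L || p > len) { skipped <- c(skipped, row$id); next }
    hit <- design$features$start < p & p < design$features$end
    if (any(hit)) {
      if (on_collision == "error")
        stop("loxPsym insertion point for ORF ", row$id,
             " falls inside feature ", design$features$id[hit][1L])
      skipped <- c(skipped, row$id)
      next
    }
    pts <- c(pts, p); pids <- c(pids, row$id)
  }
  ord <- order(pts, decreasing = TRUE)
  pts <- pts[ord]; pids <- pids[ord]
  for (k in seq_along(pts)) {
    design <- apply_edit(design, pts[k], "", site, "insert_loxpsym", pids[k])
    design$features <- rbind(design$features,
      feature_row(paste0("loxPsym_", pids[k]), "loxPsym", pts[k],
                  pts[k] + nchar(site), "+"))
  }
  design$features <- design$features[order(design$features$start), ]
  rownames(design$features) <- NULL
  design$skipped_loxpsym <- c(design$skipped_loxpsym, skipped)
  if (length(skipped))
    design$issues <- c(design$issues,
      sprintf("loxPsym insertion skipped for %d ORF(s): %s", length(skipped),
              paste(skipped, collapse = ", ")))
  design
}

# ---- watermarks ------------------------------------------------------------

# Shared embed/decode walk over the watermark window. Each codon with at
# least one synonym encodes one payload bit: bit 0 keeps the original
# codon, bit 1 swaps to the synonym at maximal Hamming distance (ties ->
# lexicographically smallest). A position is unusable (and consumes no
# bit) when the swap would create a loxPsym/PmeI/NotI occurrence in its
# local context; the decoder reproduces the same usability decisions by
# replaying the walk with original codons on the right and already-final
# codons on the left, so embed/decode stay symmetric.
wm_walk <- function(orig, left_flank, right_flank, motifs,
                    payload_bits = NULL, observed = NULL) {
  n <- length(orig)
  final <- orig
  bits_out <- integer(0)
  used <- 0L
  skipped <- integer(0)
  for (i in seq_len(n)) {
    partner <- watermark_partner(orig[i])
    if (is.na(partner)) next
    left <- paste0(left_flank, paste(final[seq_len(i - 1L)], collapse = ""))
    right <- paste0(paste(orig[seq_len(n - i) + i], collapse = ""), right_flank)
    ctx <- paste0(left, partner, right)
    cod_at <- nchar(left)  # 0-based start of candidate codon in ctx
    clash <- FALSE
    for (m in motifs) {
      for (p in find_all(ctx, m)) {
        if (p < cod_at + 3L && p + nchar(m) > cod_at) { clash <- TRUE; break }
      }
      if (clash) break
    }
    if (clash) { skipped <- c(skipped, i); next }
    if (!is.null(payload_bits)) {           # embed
      if (used >= length(payload_bits)) next
      used <- used + 1L
      bit <- payload_bits[used]
      if (bit == 1L) final[i] <- partner
    } else {                                # decode
      cur <- observed[i]
      bit <- if (cur == partner && cur != orig[i]) 1L
             else if (cur == orig[i]) 0L else NA_integer_
      bits_out <- c(bits_out, bit)
      final[i] <- cur
    }
  }
  list(final = final, bits = bits_out, used = used, skipped = skipped)
}

parse_payload <- function(payload) {
  if (is.numeric(payload)) payload <- paste(as.integer(payload), collapse = "")
  if (!grepl("^[01]*$", payload)) stop("payload must be a bit string of 0/1")
  as.integer(strsplit(payload, "")[[1L]])
}

wm_window_interval <- function(row, window_start, window_len) {
  if (row$strand == "+") {
    a <- row$start + (window_start - 1L) * 3L
    c(a, a + window_len * 3L)
  } else {
    b <- row$end - (window_start - 1L) * 3L
    c(b - window_len * 3L, b)
  }
}

#' Embed synonymous-codon watermarks in ORFs
#'
#' Encodes one payload bit per degenerate codon inside a window of the
#' ORF (default: 12 codons starting at codon 10), using only synonymous
#' substitutions under the standard nuclear genetic code, so every ORF
#' translation is unchanged. Substitutions that would create a new
#' loxPsym, PmeI or NotI occurrence are skipped (position reported) and
#' the bit moves to the next degenerate codon.
#'
#' @param design A `neochrom_design`.
#' @param orf_ids Character vector of ORF ids to watermark.
#' @param payloads Character vector of bit strings (`"0"`/`"1"`), one
#'   per ORF.
#' @param window_start 1-based codon index of the window start.
#' @param window_len Window length in codons.
#' @return The edited design; per-ORF watermark records (original and
#'   recoded codons, payload) are stored in `design$watermarks`.
#' @export
embed_watermarks <- function(design, orf_ids, payloads,
                             window_start = 10L, window_len = 12L) {
  stopifnot(length(orf_ids) == length(payloads))
  motifs <- forbidden_motifs()
  orfs <- design_orfs(design)
  for (k in seq_along(orf_ids)) {
    oid <- orf_ids[[k]]
    row <- orfs[orfs$id == oid, , drop = FALSE]
    if (nrow(row) != 1L) stop("no unique ORF feature with id ", oid)
    row <- row[1, ]
    n_codons <- (row$end - row$start) %/% 3L
    if (window_start - 1L + window_len > n_codons - 1L)
      stop("ORF ", oid, " too short to host watermark window (",
           n_codons, " codons incl. stop)")
    cds <- orf_cds(design, row)
    codons <- split_codons(cds)
    widx <- seq(window_start, window_start + window_len - 1L)
    orig <- codons[widx]
    if (all(is.na(vapply(orig, watermark_partner, character(1)))))
      stop("watermark window of ORF ", oid, " has zero degenerate codons")
    bits <- parse_payload(payloads[[k]])
    left_flank <- paste(codons[seq_len(window_start - 1L)], collapse = "")
    right_flank <- paste(codons[seq(window_start + window_len, n_codons)],
                         collapse = "")
    res <- wm_walk(orig, left_flank, right_flank, motifs, payload_bits = bits)
    if (res$used < length(bits))
      stop("watermark window of ORF ", oid, " holds only ", res$used,
           " bit(s); payload has ", length(bits))
    iv <- wm_window_interval(row, window_start, window_len)
    new_win <- paste(res$final, collapse = "")
    fwd_new <- if (row$strand == "+") new_win else revcomp(new_win)
    fwd_old <- subseq0(design$sequence, iv[1], iv[2])
    if (fwd_old != fwd_new)
      design <- apply_edit(design, iv[1], fwd_old, fwd_new, "watermark", oid)
    design$features <- rbind(design$features,
      feature_row(paste0("wm_", oid), "watermark", iv[1], iv[2], row$strand))
    design$watermarks[[oid]] <- list(
      orf_id = oid, codon_window = c(first_codon = window_start,
                                     n_codons = window_len),
      payload = paste(bits, collapse = ""), n_bits = length(bits),
      original_codons = orig, recoded_codons = res$final,
      skipped_positions = res$skipped,
      original_translation = translate_dna(cds))
  }
  design$features <- design$features[order(design$features$start), ]
  rownames(design$features) <- NULL
  design
}

#' Decode a watermark payload from a design
#'
#' Recovers the embedded bit string by replaying the watermark walk:
#' degenerate window codons equal to the recorded original decode as 0,
#' those equal to the maximal-distance synonym decode as 1.
#'
#' @param design A `neochrom_design`.
#' @param orf_id ORF id to decode.
#' @return The payload bit string; `""` (empty payload) when the ORF
#'   carries no watermark.
#' @export
decode_watermark <- function(design, orf_id) {
  wm <- design$watermarks[[orf_id]]
  if (is.null(wm)) return("")
  orfs <- design_orfs(design)
  row <- orfs[orfs$id == orf_id, , drop = FALSE][1, ]
  ws <- wm$codon_window[[1]]; wl <- wm$codon_window[[2]]
  cds <- orf_cds(design, row)
  codons <- split_codons(cds)
  n_codons <- length(codons)
  observed <- codons[seq(ws, ws + wl - 1L)]
  left_flank <- paste(codons[seq_len(ws - 1L)], collapse = "")
  right_flank <- paste(codons[seq(ws + wl, n_codons)], collapse = "")
  # right context must be the ORIGINAL window codons, as at embed time
  res <- wm_walk(wm$original_codons, left_flank, right_flank,
                 forbidden_motifs(), observed = observed)
  if (anyNA(res$bits))
    warning("watermark of ORF ", orf_id,
            " contains codons matching neither original nor partner")
  bits <- res$bits[!is.na(res$bits)]
  # positions beyond the encoded payload were left at the original codon
  bits <- utils::head(bits, wm$n_bits)
  paste(bits, collapse = "")
}

#' Replace, insert or delete a region of a design
#'
#' Generic sequence edit used for marker swaps (e.g. replacing a
#' remaining auxotrophic marker with a fluorescent-protein cassette),
#' cassette excision, and landmark insertion (e.g. adding an ARS
#' between two ORFs). A zero-length target is a pure insertion; an
#' empty payload is a pure deletion. Downstream feature coordinates are
#' updated and the edit is logged.
#'
#' @param design A `neochrom_design`.
#' @param target Either a length-2 numeric `c(start, end)` (0-based,
#'   half-open; `start == end` for insertion) or a feature id whose
#'   span is replaced.
#' @param payload Replacement DNA (may be `""`).
#' @param allow_orf_overlap Permit edits overlapping ORF features.
#' @param feature Optional `list(id =, type =)` to annotate the payload
#'   span as a new feature.
#' @return The edited design.
#' @export
replace_region <- function(design, target, payload = "",
                           allow_orf_overlap = FALSE, feature = NULL) {
  if (is.character(target) && length(target) == 1L) {
    row <- design$features[design$features$id == target, , drop = FALSE]
    if (nrow(row) != 1L) stop("no unique feature with id ", target)
    iv <- c(row$start[1], row$end[1])
    # the target feature itself is consumed by the edit
    design$features <- design$features[design$features$id != target, ,
                                       drop = FALSE]
  } else {
    iv <- as.integer(target)
  }
  if (length(iv) != 2L || iv[1] > iv[2] || iv[1] < 0 ||
      iv[2] > design_length(design))
    stop("target interval out of bounds")
  if (nchar(payload) > 0) stopifnot_dna(toupper(payload), "payload")
  payload <- toupper(payload)
  f <- design$features
  # strict overlap; for zero-width targets: the insertion point inside
  overlaps <- f$start < iv[2] & f$end > iv[1]
  if (iv[1] == iv[2]) overlaps <- f$start < iv[1] & f$end > iv[1]
  spanning <- f$start <= iv[1] & f$end >= iv[2] & overlaps
  if (any(overlaps & f$type == "ORF") && !allow_orf_overlap)
    stop("target overlaps ORF feature(s): ",
         paste(f$id[overlaps & f$type == "ORF"], collapse = ", "),
         " (set allow_orf_overlap = TRUE to override)")
  affected <- overlaps & !spanning
  if (any(affected)) {
    design$issues <- c(design$issues,
      sprintf("replace_region removed feature(s): %s",
              paste(f$id[affected], collapse = ", ")))
    design$features <- f[!affected, , drop = FALSE]
  }
  removed <- subseq0(design$sequence, iv[1], iv[2])
  design <- apply_edit(design, iv[1], removed, payload, "replace_region",
                       sprintf("[%d,%d)", iv[1], iv[2]))
  if (!is.null(feature) && nchar(payload) > 0) {
    design$features <- rbind(design$features,
      feature_row(feature$id, feature$type, iv[1], iv[1] + nchar(payload),
                  "+"))
    design$features <- design$features[order(design$features$start), ]
    rownames(design$features) <- NULL
  }
  design
}
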