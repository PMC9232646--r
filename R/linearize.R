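# Telomerator-style linearization: open a circular design at a chosen
# locus and seed telomeres at the new ends. The cut/induction chemistry
# is not modeled; linearization is a deterministic sequence transform.

#' Linearize a circular design at a locus
#'
#' Rotates the circular sequence to open at `locus`, optionally excises
#' a counter-selectable cassette feature first (modeling loss of the
#' URA3 marker selected on 5-FOA), and appends telomere seed repeats at
#' both new ends ((CA)n on the left end, (TG)n on the right, matching
#' telomeric strand orientation). All features are retained with
#' remapped coordinates. Variants cut at different loci differ only in
#' gene arrangement relative to the new telomeres: stripping the seeds
#' and rotating recovers the circular parent exactly (see
#' [recircularize()]).
#'
#' @param design A circular `neochrom_design`.
#' @param locus 0-based cut position.
#' @param cassette Optional feature id to excise before cutting.
#' @param seed_unit Telomere seed repeat unit (default `"TG"`).
#' @param seed_copies Repeat copies per end (default 30).
#' @param allow_in_feature Permit a locus inside an annotated feature.
#' @return A `linear_variant` (subclass of `neochrom_design`) with
#'   fields `parent`, `cut_locus` and `telomere_seed`.
#' @export
linearize_at <- function(design, locus, cassette = NULL,
                         seed_unit = "TG", seed_copies = 30L,
                         allow_in_feature = FALSE) {
  if (design$topology != "circular") stop("design must be circular")
  locus <- as.integer(locus %% design_length(design))
  if (!is.null(cassette)) {
    row <- design$features[design$features$id == cassette, , drop = FALSE]
    if (nrow(row) != 1L) stop("no unique cassette feature with id ", cassette)
    if (locus > row$start[1] && locus < row$end[1])
      stop("locus lies inside the cassette being excised")
    design <- replace_region(design, cassette, "")
    # locus was given in pre-excision coordinates
    if (locus >= row$end[1]) locus <- locus - (row$end[1] - row$start[1])
  }
  len <- design_length(design)
  f <- design$features
  inside <- f$start < locus & locus < f$end
  if (any(inside) && !allow_in_feature)
    stop("locus ", locus, " lies inside feature ",
         f$id[inside][1L], " (set allow_in_feature = TRUE to override)")
  rotated <- rotate_seq(design$sequence, locus)
  f$end <- (f$end - locus) %% len
  f$start <- (f$start - locus) %% len
  f$end[f$end == 0L] <- len  # features abutting the cut keep full width
  seed <- strrep(seed_unit, seed_copies)
  sl <- nchar(seed)
  f$start <- f$start + sl
  f$end <- f$end + sl
  out_seq <- paste0(revcomp(seed), rotated, seed)
  f <- rbind(feature_row("telomere_seed_L", "telomere-seed", 0L, sl, "-"),
             f,
             feature_row("telomere_seed_R", "telomere-seed", sl + len,
                         sl + len + sl, "+"))
  rownames(f) <- NULL
  out <- new_design(paste0(design$name, "_lin", locus), "linear", out_seq, f)
  out$parent <- design$name
  out$cut_locus <- locus
  out$telomere_seed <- list(unit = seed_unit, copies = as.integer(seed_copies))
  class(out) <- c("linear_variant", class(out))
  out
}

#' Strip telomere seeds from a linear variant
#'
#' @param variant A `linear_variant`.
#' @return The rotated core sequence (circular parent opened at the cut
#'   locus).
#' @export
strip_telomere_seeds <- function(variant) {
  stopifnot(inherits(variant, "linear_variant"))
  sl <- nchar(strrep(variant$telomere_seed$unit, variant$telomere_seed$copies))
  subseq0(variant$sequence, sl, nchar(variant$sequence) - sl)
}

#' Re-circularize a linear variant
#'
#' Joins the seed-stripped ends and rotates back to the parent origin;
#' for an unedited variant this reproduces the circular parent sequence
#' byte-identically.
#'
#' @param variant A `linear_variant`.
#' @return The reconstructed circular sequence string.
#' @export
recircularize <- function(variant) {
  core <- strip_telomere_seeds(variant)
  rotate_seq(core, (nchar(core) - variant$cut_locus) %% nchar(core))
}
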