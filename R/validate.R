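# Design validation: every constraint the design phase must satisfy,
# collected into one deterministic report.

#' Validate a neo-chromosome design
#'
#' Runs the full battery of design checks and returns a report rather
#' than raising: sequence alphabet; feature bounds; terminal stop
#' codons (TAA/TGA only once recoding has been applied, any stop
#' before); loxPsym feature sequences and self-reverse-complementarity;
#' translation preservation against recorded watermark originals;
#' absence of PmeI/NotI recognition sites; byte-identical edit-log
#' replay; and summary counts.
#'
#' @param design A `neochrom_design`.
#' @return A `data.frame` of class `neochrom_validation` with columns
#'   `check`, `pass`, `detail`.
#' @export
validate_design <- function(design) {
  checks <- list()
  add <- function(check, pass, detail = "") {
    checks[[length(checks) + 1L]] <<- data.frame(
      check = check, pass = pass, detail = detail, stringsAsFactors = FALSE)
  }
  len <- design_length(design)
  seqs <- design$sequence

  add("alphabet", !grepl("[^ACGT]", seqs),
      if (grepl("[^ACGT]", seqs)) "non-ACGT characters present" else "")

  f <- design$features
  oob <- f$start < 0 | f$end > len | f$end <= f$start
  add("feature_bounds", !any(oob),
      if (any(oob)) paste("out of bounds:", paste(f$id[oob], collapse = ", "))
      else sprintf("%d features within %d bp", nrow(f), len))

  orfs <- design_orfs(design)
  allowed <- if (isTRUE(design$recoded)) c("TAA", "TGA") else STOP_CODONS
  bad_stop <- character(0)
  for (i in seq_len(nrow(orfs))) {
    cds <- orf_cds(design, orfs[i, ])
    w <- nchar(cds)
    if (!substr(cds, w - 2, w) %in% allowed) bad_stop <- c(bad_stop, orfs$id[i])
  }
  add("orf_terminal_stops", length(bad_stop) == 0L,
      if (length(bad_stop)) paste("offending ORFs:",
                                  paste(bad_stop, collapse = ", "))
      else sprintf("%d ORFs end in {%s}", nrow(orfs),
                   paste(allowed, collapse = ",")))

  site <- loxpsym_site()
  add("loxpsym_self_symmetric", revcomp(site) == site, site)
  lox <- f[f$type == "loxPsym", , drop = FALSE]
  lox_ok <- vapply(seq_len(nrow(lox)), function(i)
    subseq0(seqs, lox$start[i], lox$end[i]) == site, logical(1))
  add("loxpsym_sequences", all(lox_ok),
      sprintf("%d/%d sites match the configured sequence",
              sum(lox_ok), nrow(lox)))
  ovl <- FALSE
  if (nrow(lox) > 1L) {
    o <- lox[order(lox$start), ]
    ovl <- any(o$start[-1] < o$end[-nrow(o)])
  }
  add("loxpsym_nonoverlapping", !ovl, sprintf("%d sites", nrow(lox)))

  wm_ok <- TRUE; wm_bad <- character(0)
  for (oid in names(design$watermarks)) {
    row <- orfs[orfs$id == oid, , drop = FALSE]
    if (nrow(row) != 1L) { wm_ok <- FALSE; wm_bad <- c(wm_bad, oid); next }
    tr <- translate_dna(orf_cds(design, row[1, ]))
    if (tr != design$watermarks[[oid]]$original_translation) {
      wm_ok <- FALSE; wm_bad <- c(wm_bad, oid)
    }
  }
  add("translations_preserved", wm_ok,
      if (!wm_ok) paste("changed:", paste(wm_bad, collapse = ", "))
      else sprintf("%d watermarked ORFs checked", length(design$watermarks)))

  # independent substring search for restriction sites (circular aware)
  rs <- restriction_sites()
  n_sites <- sum(vapply(rs, function(p)
    length(if (design$topology == "circular") find_all_circ(seqs, p)
           else find_all(seqs, p)), integer(1)))
  add("restriction_free", n_sites == 0L,
      sprintf("%d PmeI/NotI occurrence(s)", n_sites))

  replay_ok <- tryCatch(identical(replay_edit_log(design), seqs),
                        error = function(e) FALSE)
  add("edit_log_replay", replay_ok,
      sprintf("%d edit(s)", length(design$edit_log)))

  add("no_loading_issues", length(design$issues) == 0L,
      paste(design$issues, collapse = "; "))

  add("summary", TRUE,
      sprintf("length=%d bp; ORFs=%d; loxPsym=%d; watermarks=%d",
              len, nrow(orfs), nrow(lox), length(design$watermarks)))

  out <- do.call(rbind, checks)
  class(out) <- c("neochrom_validation", "data.frame")
  out
}

#' @export
print.neochrom_validation <- function(x, ...) {
  for (i in seq_len(nrow(x))) {
    cat(sprintf("[%s] %-24s %s\n", if (x$pass[i]) "ok" else "FAIL",
                x$check[i], x$detail[i]))
  }
  invisible(x)
}

#' Did every validation check pass?
#' @param report A `neochrom_validation` report.
#' @return Logical scalar.
#' @export
all_checks_pass <- function(report) all(report$pass)
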