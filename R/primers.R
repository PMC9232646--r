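# Junction-confirmation primer design with nearest-neighbor melting
# temperatures.

# SantaLucia (1998) unified nearest-neighbor parameters.
# dH in kcal/mol, dS in cal/(mol K), 5'->3' dinucleotide steps.
.nn_dh <- c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4,
            CT = -7.8, GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0,
            TT = -7.9, TG = -8.5, AC = -8.4, AG = -7.8, TC = -8.2,
            CC = -8.0)
.nn_ds <- c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
            CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
            TT = -22.2, TG = -22.7, AC = -22.4, AG = -21.0, TC = -22.2,
            CC = -19.9)

#' Nearest-neighbor melting temperature
#'
#' Duplex melting temperature of a primer against its perfect
#' complement under the unified nearest-neighbor thermodynamic model
#' (dinucleotide stacking enthalpies/entropies plus terminal
#' initiation terms), with entropic monovalent-salt correction
#' `0.368 * (N - 1) * ln[Na+]` and the non-self-complementary
#' two-state formula `Tm = dH / (dS + R ln(C/4))`.
#'
#' @param primer Primer sequence (A/C/G/T).
#' @param na_molar Monovalent cation concentration (default 0.05 M).
#' @param primer_molar Total strand concentration (default 5e-7 M).
#' @return Melting temperature in degrees Celsius.
#' @export
tm_nearest_neighbor <- function(primer, na_molar = 0.05,
                                primer_molar = 5e-7) {
  stopifnot_dna(primer, "primer")
  n <- nchar(primer)
  if (n < 8L) stop("primer too short for a meaningful Tm")
  steps <- substring(primer, seq_len(n - 1L), seq_len(n - 1L) + 1L)
  dh <- sum(.nn_dh[steps])
  ds <- sum(.nn_ds[steps])
  for (term in c(substr(primer, 1L, 1L), substr(primer, n, n))) {
    if (term %in% c("G", "C")) { dh <- dh + 0.1; ds <- ds - 2.8 }
    else { dh <- dh + 2.3; ds <- ds + 4.1 }
  }
  ds <- ds + 0.368 * (n - 1L) * log(na_molar)
  dh * 1000 / (ds + 1.987 * log(primer_molar / 4)) - 273.15
}

#' Design junction-confirmation primer pairs
#'
#' For every junction between adjacent chunks (including the closing
#' junction of a circular design) searches for a forward/reverse primer
#' pair whose amplicon spans the junction boundary, with primer length,
#' nearest-neighbor melting temperature and product length inside the
#' configured bounds, and with each primer occurring exactly once in
#' the design (forward or reverse complement, verified by exact
#' search).
#'
#' @param design The `neochrom_design` the chunks came from.
#' @param chunks The `chunk_set` from [chunk_design()].
#' @param primer_len Length bounds, default `c(18, 25)` nt.
#' @param tm_range Acceptable melting temperatures, default
#'   `c(58, 62)` degrees Celsius.
#' @param product_range Amplicon length bounds, default `c(400, 1000)`.
#' @return A `data.frame` of class `primer_set`: one row per junction
#'   with primers, 0-based positions, Tm values and product length.
#' @export
design_junction_primers <- function(design, chunks,
                                    primer_len = c(18L, 25L),
                                    tm_range = c(58, 62),
                                    product_range = c(400L, 1000L)) {
  seqs <- design$sequence
  len <- design_length(design)
  circular <- design$topology == "circular"
  bs <- attr(chunks, "boundaries")
  junctions <- if (circular) bs else bs[-1L]
  overlap <- attr(chunks, "overlap")
  find_primer <- function(b, side) {
    # search outward so the amplicon stays within product_range
    offsets <- seq(product_range[1] %/% 2L,
                   (product_range[2] - overlap) %/% 2L - max(primer_len))
    for (off in offsets) {
      for (plen in seq(primer_len[1], primer_len[2])) {
        if (side == "fwd") {
          s <- (b - off) %% len
          cand <- subseq_circ(seqs, s, s + plen)
        } else {
          e <- (b + overlap + off) %% len
          cand <- revcomp(subseq_circ(seqs, e - plen, e))
        }
        tm <- tm_nearest_neighbor(cand)
        if (tm < tm_range[1] || tm > tm_range[2]) next
        if (count_occurrences(seqs, cand, circular = circular) != 1L) next
        return(list(primer = cand, pos = if (side == "fwd") (b - off) %% len
                                         else (b + overlap + off) %% len,
                    tm = tm))
      }
    }
    NULL
  }
  out <- lapply(seq_along(junctions), function(i) {
    b <- junctions[i]
    fwd <- find_primer(b, "fwd")
    rev <- find_primer(b, "rev")
    if (is.null(fwd) || is.null(rev))
      stop("no unique primer satisfying the constraints near junction ", i,
           " (boundary ", b, ")")
    prod_len <- (rev$pos - fwd$pos) %% len
    data.frame(junction_index = i, boundary = b,
               forward = fwd$primer, reverse = rev$primer,
               fwd_start = fwd$pos, rev_end = rev$pos,
               tm_forward = fwd$tm, tm_reverse = rev$tm,
               product_length = prod_len, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  class(out) <- c("primer_set", "data.frame")
  out
}
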