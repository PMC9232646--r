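# Internal sequence helpers shared across modules. All coordinates in this
# package are 0-based, half-open, on the forward strand; circular positions
# are normalized modulo the sequence length.

#' Canonical 34-bp loxPsym site
#'
#' The symmetric Cre recombinase recognition site used throughout the
#' package. It is its own reverse complement, which is what makes
#' recombination between two sites orientation-independent.
#'
#' @return A 34-character DNA string.
#' @export
loxpsym_site <- function() "ATAACTTCGTATAATGTACATTATACGAAGTTAT"

#' Restriction sites flanking synthesis chunks
#'
#' PmeI (GTTTAAAC) and NotI (GCGGCCGC) recognition sequences; both are
#' palindromic, so a forward-strand search finds every occurrence.
#'
#' @return Named character vector with elements `PmeI` and `NotI`.
#' @export
restriction_sites <- function() c(PmeI = "GTTTAAAC", NotI = "GCGGCCGC")

# Motifs that must never be created by synonymous recoding.
forbidden_motifs <- function(loxpsym = loxpsym_site()) {
  unname(c(loxpsym, restriction_sites()))
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

translate_dna <- function(x) {
  as.character(Biostrings::translate(Biostrings::DNAString(x),
                                     no.init.codon = TRUE))
}

# substring with 0-based half-open coordinates
subseq0 <- function(s, start, end) {
  if (end <= start) return("")
  substr(s, start + 1L, end)
}

# circular substring: start in [0, len), end may exceed len (wraps once)
subseq_circ <- function(s, start, end) {
  len <- nchar(s)
  width <- end - start
  start <- start %% len
  if (start + width <= len) return(subseq0(s, start, start + width))
  paste0(subseq0(s, start, len), subseq0(s, 0L, start + width - len))
}

# rotate so that position k becomes position 0
rotate_seq <- function(s, k) {
  len <- nchar(s)
  k <- k %% len
  if (k == 0) return(s)
  paste0(subseq0(s, k, len), subseq0(s, 0L, k))
}

# all 0-based start positions of fixed pattern in subject
find_all <- function(subject, pattern) {
  hits <- gregexpr(pattern, subject, fixed = TRUE)[[1L]]
  if (hits[1L] == -1L) return(integer(0))
  as.integer(hits) - 1L
}

# occurrences of pattern in a circular sequence (starts in [0, len))
find_all_circ <- function(subject, pattern) {
  len <- nchar(subject)
  ext <- paste0(subject, subseq0(subject, 0L, min(nchar(pattern) - 1L, len)))
  hits <- find_all(ext, pattern)
  sort(unique(hits[hits < len]))
}

# count forward + reverse-complement occurrences (circular aware)
count_occurrences <- function(subject, pattern, circular = FALSE) {
  finder <- if (circular) find_all_circ else find_all
  n <- length(finder(subject, pattern))
  rc <- revcomp(pattern)
  if (rc != pattern) n <- n + length(finder(subject, rc))
  n
}

stopifnot_dna <- function(x, what = "sequence") {
  if (!is.character(x) || length(x) != 1L || nchar(x) == 0L)
    stop(what, " must be a single non-empty string", call. = FALSE)
  if (grepl("[^ACGT]", x))
    stop(what, " contains characters outside A/C/G/T", call. = FALSE)
  invisible(x)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

# Derive a per-component substream seed from one top-level seed. Documented
# derivation: seed + 10007 * offset, folded into the 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 10007 * offset) %% 2147483647)
}

# ---- codon machinery -------------------------------------------------------

.neochrom_cache <- new.env(parent = emptyenv())

codon_synonyms <- function() {
  if (!is.null(.neochrom_cache$syn)) return(.neochrom_cache$syn)
  gc <- Biostrings::GENETIC_CODE
  syn <- lapply(names(gc), function(cod) {
    others <- names(gc)[gc == gc[[cod]] & names(gc) != cod]
    sort(others)
  })
  names(syn) <- names(gc)
  .neochrom_cache$syn <- syn
  syn
}

codon_hamming <- function(a, b) {
  sum(strsplit(a, "")[[1L]] != strsplit(b, "")[[1L]])
}

# Synonym at maximal nucleotide Hamming distance; ties broken by
# lexicographically smallest codon. NA when the codon has no synonym.
watermark_partner <- function(codon) {
  if (!is.null(.neochrom_cache$partner[[codon]]))
    return(.neochrom_cache$partner[[codon]])
  syn <- codon_synonyms()[[codon]]
  res <- if (length(syn) == 0L) NA_character_ else {
    d <- vapply(syn, codon_hamming, integer(1), a = codon)
    cand <- sort(syn[d == max(d)])
    cand[[1L]]
  }
  if (is.null(.neochrom_cache$partner)) .neochrom_cache$partner <- list()
  .neochrom_cache$partner[[codon]] <- res
  res
}

split_codons <- function(cds) {
  n <- nchar(cds)
  stopifnot(n %% 3 == 0)
  substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
}

STOP_CODONS <- c("TAA", "TAG", "TGA")
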