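# Division of a design into synthesis chunks with homology overhangs,
# alternating-marker assembly planning, and in-silico homologous
# recombination assembly.

#' Divide a design into synthesis chunks
#'
#' Places chunk boundaries at roughly even spacing (one per
#' `target_size` bp) and then searches locally for boundaries whose
#' `overlap`-bp homology window is unique genome-wide (forward and
#' reverse complement) and free of PmeI/NotI sites. Adjacent chunks
#' share the boundary window exactly: the right overhang of chunk *i*
#' is the left overhang of chunk *i + 1*, which is what lets the chunks
#' reassemble in vivo by homologous recombination.
#'
#' @param design A `neochrom_design` (longer than `target_size`).
#' @param target_size Target chunk size in bp (default 10000, i.e.
#'   ~10-kb synthesis units).
#' @param overlap Homology overhang length in bp (default 200).
#' @param search_bp Maximum boundary shift during the local search
#'   (default 1000 = +/-10% of the default spacing).
#' @return A `chunk_set`: list of `synthesis_chunk` objects (fields
#'   `index`, `start`, `body`, `left_overhang`, `right_overhang`,
#'   `flank_sites`) with the boundary vector, overlap and design
#'   metadata as attributes.
#' @export
chunk_design <- function(design, target_size = 10000L, overlap = 200L,
                         search_bp = 1000L) {
  len <- design_length(design)
  if (len <= target_size)
    stop("design (", len, " bp) is not longer than target_size")
  seqs <- design$sequence
  circular <- design$topology == "circular"
  n <- max(2L, round(len / target_size))
  rs <- restriction_sites()
  admissible <- function(b) {
    w <- subseq_circ(seqs, b, b + overlap)
    if (any(vapply(rs, function(p) grepl(p, w, fixed = TRUE), logical(1))))
      return(FALSE)
    count_occurrences(seqs, w, circular = circular) == 1L
  }
  place <- function(ideal) {
    for (off in c(0L, as.vector(rbind(seq_len(search_bp), -seq_len(search_bp))))) {
      b <- (ideal + off) %% len
      if (admissible(b)) return(b)
    }
    stop("no admissible chunk boundary within ", search_bp,
         " bp of position ", ideal)
  }
  ideals <- round((seq_len(n) - 1L) * len / n)
  bs <- if (circular) vapply(ideals, place, numeric(1))
        else c(0L, vapply(ideals[-1], place, numeric(1)))
  bs <- as.integer(sort(bs %% len))
  if (anyDuplicated(bs)) stop("chunk boundaries collided; reduce chunk count")
  chunks <- vector("list", n)
  for (i in seq_len(n)) {
    b <- bs[i]
    nb <- if (i < n) bs[i + 1L] else if (circular) bs[1L] + len else len
    left <- subseq_circ(seqs, b, b + overlap)
    right <- if (i == n && !circular) ""
             else subseq_circ(seqs, nb, nb + overlap)
    body <- subseq_circ(seqs, b + overlap, nb)
    chunks[[i]] <- structure(
      list(index = i, start = b, body = body, left_overhang = left,
           right_overhang = right,
           flank_sites = c(left = unname(rs["PmeI"]),
                           right = unname(rs["NotI"]))),
      class = "synthesis_chunk")
  }
  structure(chunks, class = "chunk_set", boundaries = bs, overlap = overlap,
            design_name = design$name, design_length = len,
            topology = design$topology)
}

#' Chunk sequences
#'
#' @param chunks A `chunk_set`.
#' @param with_flanks Prepend/append the PmeI/NotI release sites used
#'   to excise each chunk from its carrier vector.
#' @return Character vector of chunk sequences (overhangs included).
#' @export
chunk_sequences <- function(chunks, with_flanks = FALSE) {
  vapply(chunks, function(ch) {
    s <- paste0(ch$left_overhang, ch$body, ch$right_overhang)
    if (with_flanks) paste0(ch$flank_sites[["left"]], s,
                            ch$flank_sites[["right"]]) else s
  }, character(1))
}

#' @export
print.chunk_set <- function(x, ...) {
  cat(sprintf("<chunk_set: %d chunks of design %s (%d bp, overlap %d bp)>\n",
              length(x), attr(x, "design_name"), attr(x, "design_length"),
              attr(x, "overlap")))
  invisible(x)
}

#' Are two sequences identical up to circular rotation?
#'
#' @param a,b DNA strings.
#' @return Logical scalar.
#' @export
is_rotation_of <- function(a, b) {
  nchar(a) == nchar(b) && grepl(a, paste0(b, b), fixed = TRUE)
}

#' Plan an iterative alternating-marker assembly
#'
#' Groups chunks into sequential transformation rounds: the opening
#' rounds take 2 then 3 chunks (the schedule the first two in vivo
#' rounds of the published assembly used), subsequent rounds take
#' `per_round_max`; a URA3/LEU2 auxotrophic marker strictly alternates
#' between rounds, and a terminal swap replaces the last marker with a
#' fluorescent-protein (BFP) cassette.
#'
#' @param chunks A `chunk_set` (or anything with a length).
#' @param per_round_max Maximum chunks per round, between 1 and 4.
#' @param first_marker `"URA3"` or `"LEU2"`.
#' @param opening Chunk counts of the first rounds (default `c(2, 3)`).
#' @param final_cassette Replacement for the last marker.
#' @return An `assembly_plan`: `rounds` data.frame (round, marker,
#'   chunk index ranges), `chunk_rounds` list, `final_swap`.
#' @export
plan_assembly <- function(chunks, per_round_max = 4L,
                          first_marker = c("URA3", "LEU2"),
                          opening = c(2L, 3L), final_cassette = "BFP") {
  first_marker <- match.arg(first_marker)
  n <- length(chunks)
  if (n < 1L) stop("need at least one chunk")
  if (per_round_max < 1L || per_round_max > 4L)
    stop("per_round_max must be between 1 and 4")
  opening <- pmin(opening, per_round_max)
  sizes <- integer(0)
  left <- n
  for (o in opening) {
    if (left == 0L) break
    take <- min(o, left)
    sizes <- c(sizes, take); left <- left - take
  }
  while (left > 0L) {
    take <- min(per_round_max, left)
    sizes <- c(sizes, take); left <- left - take
  }
  markers <- c("URA3", "LEU2")
  if (first_marker == "LEU2") markers <- rev(markers)
  idx_end <- cumsum(sizes)
  idx_start <- c(1L, utils::head(idx_end, -1L) + 1L)
  rounds <- data.frame(
    round = seq_along(sizes),
    marker = markers[(seq_along(sizes) - 1L) %% 2L + 1L],
    first_chunk = idx_start, last_chunk = idx_end,
    stringsAsFactors = FALSE)
  plan <- structure(list(
    rounds = rounds,
    chunk_rounds = lapply(seq_along(sizes),
                          function(i) seq(idx_start[i], idx_end[i])),
    final_swap = list(marker = rounds$marker[nrow(rounds)],
                      replacement = final_cassette)),
    class = "assembly_plan", n_chunks = n)
  stopifnot(validate_assembly_plan(plan, n))
  plan
}

#' Check assembly-plan invariants
#'
#' Every chunk appears in exactly one round and in order, rounds carry
#' 1-4 chunks, and markers strictly alternate.
#'
#' @param plan An `assembly_plan`.
#' @param n_chunks Total chunk count the plan must cover.
#' @return `TRUE`, or `FALSE` with a `"why"` attribute.
#' @export
validate_assembly_plan <- function(plan, n_chunks) {
  fail <- function(msg) structure(FALSE, why = msg)
  got <- unlist(plan$chunk_rounds)
  if (!identical(as.integer(got), seq_len(n_chunks)))
    return(fail("chunks not covered exactly once in order"))
  sz <- lengths(plan$chunk_rounds)
  if (any(sz < 1L | sz > 4L)) return(fail("round size outside 1-4"))
  m <- plan$rounds$marker
  if (length(m) > 1L && any(m[-1] == m[-length(m)]))
    return(fail("markers do not alternate"))
  if (!all(m %in% c("URA3", "LEU2"))) return(fail("unknown marker"))
  TRUE
}

#' @export
print.assembly_plan <- function(x, ...) {
  for (i in seq_len(nrow(x$rounds))) {
    r <- x$rounds[i, ]
    cat(sprintf("round %d: chunks %d-%d + %s\n", r$round, r$first_chunk,
                r$last_chunk, r$marker))
  }
  cat(sprintf("final swap: %s -> %s\n", x$final_swap$marker,
              x$final_swap$replacement))
  invisible(x)
}

#' Simulate assembly by homologous recombination
#'
#' Joins linear pieces wherever the terminal window of the configured
#' overlap length of one piece exactly matches the leading window of
#' another, mimicking in vivo recombination across shared homology.
#' The joined length obeys sum(lengths) - overlap * n_joins exactly.
#'
#' @param pieces Character vector of sequences, or a `chunk_set`.
#' @param overlap Homology window length (taken from the `chunk_set`
#'   when one is supplied).
#' @param circularize Require closure of the last piece onto the first
#'   and return a circular molecule.
#' @return The assembled sequence string, with attributes `topology`
#'   and `piece_order`.
#' @export
simulate_hr_assembly <- function(pieces, overlap = 200L, circularize = TRUE) {
  if (inherits(pieces, "chunk_set")) {
    overlap <- attr(pieces, "overlap")
    pieces <- chunk_sequences(pieces)
  }
  n <- length(pieces)
  if (n < 2L) stop("need at least two pieces")
  if (any(nchar(pieces) <= overlap)) stop("every piece must exceed the overlap")
  lefts <- substr(pieces, 1L, overlap)
  rights <- substring(pieces, nchar(pieces) - overlap + 1L)
  nxt <- integer(n)
  for (i in seq_len(n)) {
    match_j <- setdiff(which(lefts == rights[i]), integer(0))
    if (length(match_j) > 1L)
      stop("ambiguous join: right terminus of piece ", i, " matches pieces ",
           paste(match_j, collapse = ", "))
    nxt[i] <- if (length(match_j) == 1L) match_j else NA_integer_
  }
  if (anyDuplicated(stats::na.omit(nxt)))
    stop("ambiguous join: one left terminus matched by several pieces")
  if (circularize) {
    if (anyNA(nxt)) {
      loose <- which(is.na(nxt))
      stop("unjoined termini: right end(s) of piece(s) ",
           paste(loose, collapse = ", "), " match no partner")
    }
    order_ <- integer(n); order_[1L] <- 1L; cur <- 1L
    for (k in seq_len(n - 1L)) {
      cur <- nxt[cur]
      if (cur == 1L) stop("pieces form more than one circle")
      order_[k + 1L] <- cur
    }
    if (nxt[cur] != 1L) stop("pieces do not close into a single circle")
    merged <- pieces[order_[1L]]
    for (k in order_[-1L]) merged <- paste0(merged, substring(pieces[k], overlap + 1L))
    merged <- substr(merged, 1L, nchar(merged) - overlap)
    stopifnot(nchar(merged) == sum(nchar(pieces)) - overlap * n)
    structure(merged, topology = "circular", piece_order = order_)
  } else {
    starts <- setdiff(seq_len(n), nxt[!is.na(nxt)])
    if (length(starts) != 1L)
      stop("unjoined termini: pieces ", paste(starts, collapse = ", "),
           " all lack a left-side partner")
    order_ <- starts; cur <- starts
    while (!is.na(nxt[cur])) { cur <- nxt[cur]; order_ <- c(order_, cur) }
    if (length(order_) != n) {
      loose <- setdiff(seq_len(n), order_)
      stop("unjoined termini: piece(s) ", paste(loose, collapse = ", "),
           " not reachable from the chain")
    }
    merged <- pieces[order_[1L]]
    for (k in order_[-1L]) merged <- paste0(merged, substring(pieces[k], overlap + 1L))
    stopifnot(nchar(merged) == sum(nchar(pieces)) - overlap * (n - 1L))
    structure(merged, topology = "linear", piece_order = order_)
  }
}
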