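# SCRaMbLE: Cre/loxPsym recombination simulation on the segment-level
# (signed permutation) representation, a structural-variant caller that
# works from segment content, and coverage-based copy-number estimation.

#' Build the loxPsym-delimited segment map of a design
#'
#' Segments are the maximal loxPsym-free intervals between consecutive
#' sites; on a circle with n sites there are exactly n segments (the
#' last wraps the origin). Interleaving the segments with the site
#' sequence reconstructs the source exactly (up to rotation for
#' circular designs; see [reconstruct_segments()]).
#'
#' @param design A `neochrom_design` (or a raw sequence string plus
#'   `topology`).
#' @param site The loxPsym sequence.
#' @param topology Used only when `design` is a bare string.
#' @return A `segment_map`: ids, segment sequences, site positions,
#'   topology.
#' @export
build_segment_map <- function(design, site = loxpsym_site(),
                              topology = c("circular", "linear")) {
  if (inherits(design, "neochrom_design")) {
    seqs <- design$sequence; topology <- design$topology
  } else {
    seqs <- design; topology <- match.arg(topology)
  }
  if (revcomp(site) != site) stop("site must be self-reverse-complementary")
  len <- nchar(seqs)
  pts <- if (topology == "circular") find_all_circ(seqs, site)
         else find_all(seqs, site)
  w <- nchar(site)
  if (length(pts) == 0L) {
    segs <- seqs
  } else if (topology == "circular") {
    nxt <- c(pts[-1L], pts[1L] + len)
    segs <- vapply(seq_along(pts), function(i)
      subseq_circ(seqs, pts[i] + w, nxt[i]), character(1))
  } else {
    bounds <- c(0L, pts, len)
    segs <- character(length(pts) + 1L)
    segs[1L] <- subseq0(seqs, 0L, pts[1L])
    for (i in seq_along(pts)) {
      e <- if (i < length(pts)) pts[i + 1L] else len
      segs[i + 1L] <- subseq0(seqs, pts[i] + w, e)
    }
  }
  structure(list(ids = seq_along(segs), seqs = segs, site = site,
                 site_positions = pts, topology = topology,
                 source_length = len),
            class = "segment_map")
}

#' @export
print.segment_map <- function(x, ...) {
  cat(sprintf("<segment_map: %d segment(s), %d loxPsym site(s), %s>\n",
              length(x$ids), length(x$site_positions), x$topology))
  invisible(x)
}

#' Rebuild a sequence from a segment map and a signed permutation
#'
#' @param map A `segment_map`.
#' @param state Signed integer vector of segment ids (negative =
#'   reverse complement); default the identity.
#' @return Sequence string. For a circular map the result starts at the
#'   first site (a rotation of the source); with zero sites it is the
#'   source itself.
#' @export
reconstruct_segments <- function(map, state = NULL) {
  if (is.null(state)) state <- map$ids
  if (length(map$site_positions) == 0L) return(map$seqs[[1L]])
  piece <- function(s) {
    seg <- map$seqs[[abs(s)]]
    if (s < 0L) revcomp(seg) else seg
  }
  if (map$topology == "circular") {
    paste(vapply(state, function(s) paste0(map$site, piece(s)), character(1)),
          collapse = "")
  } else {
    paste0(piece(state[1L]),
           paste(vapply(state[-1L], function(s) paste0(map$site, piece(s)),
                        character(1)), collapse = ""))
  }
}

# deterministic DEL arc choice: delete the arc without essential
# segments; both arcs essential -> NULL (caller resamples)
del_arc <- function(state, a, b, essential) {
  m <- length(state)
  arc1 <- seq(a, b - 1L)
  arc2 <- setdiff(seq_len(m), arc1)
  ess1 <- any(abs(state[arc1]) %in% essential)
  ess2 <- any(abs(state[arc2]) %in% essential)
  if (ess1 && ess2) return(NULL)
  if (ess1) arc2 else arc1
}

apply_scramble_event <- function(state, type, a, b, essential) {
  span <- seq(a, b - 1L)
  if (type == "INV") {
    state[span] <- -rev(state[span])
    list(state = state, segments = sort(abs(state[span])))
  } else if (type == "DEL") {
    arc <- del_arc(state, a, b, essential)
    if (is.null(arc)) return(NULL)
    removed <- state[arc]
    list(state = state[-arc], segments = sort(abs(removed)))
  } else if (type == "DUP") {
    list(state = append(state, state[span], after = b - 1L),
         segments = sort(abs(state[span])))
  } else stop("unknown event type ", type)
}

#' Simulate SCRaMbLE recombination
#'
#' Applies a sequence of Cre-mediated events between randomly chosen
#' loxPsym site pairs on the segment representation of a circular
#' design: INV reverse-complements the spanned arc (site and segment
#' counts unchanged), DEL excises one arc together with its interior
#' sites plus one boundary site (never the arc holding an essential
#' segment), DUP tandem-duplicates the arc plus one site. The truth
#' event log is returned and is replayable ([replay_scramble()]).
#'
#' @param design A `neochrom_design` or a prebuilt `segment_map`.
#' @param n_events Fixed event count, or `NULL` to draw
#'   `Poisson(rate)`.
#' @param rate Poisson mean when `n_events` is `NULL` (default 2).
#' @param type_probs Event-type probabilities (default DEL 0.45, INV
#'   0.45, DUP 0.10).
#' @param essential Segment ids that must survive every deletion;
#'   default the origin-spanning segment (which carries the
#'   centromeric backbone in designs built by this package).
#' @param seed Integer seed.
#' @param max_retries Resampling budget for deletions blocked by
#'   essential segments.
#' @return A `scramble_result`: scrambled `sequence`, signed `state`,
#'   truth `events` list, the `map`, `essential`, `seed`.
#' @export
simulate_scramble <- function(design, n_events = NULL, rate = 2,
                              type_probs = c(DEL = 0.45, INV = 0.45,
                                             DUP = 0.10),
                              essential = NULL, seed = 1L,
                              max_retries = 20L) {
  map <- if (inherits(design, "segment_map")) design
         else build_segment_map(design)
  if (map$topology != "circular")
    stop("SCRaMbLE simulation requires a circular design")
  m0 <- length(map$ids)
  if (is.null(essential)) essential <- m0
  out <- with_seed(seed, {
    if (is.null(n_events)) n_events <- stats::rpois(1L, rate)
    state <- map$ids
    events <- list()
    for (k in seq_len(n_events)) {
      m <- length(state)
      if (m < 2L) stop("SCRaMbLE event requested with fewer than 2 sites")
      for (try in seq_len(max_retries + 1L)) {
        type <- sample(names(type_probs), 1L, prob = type_probs)
        pr <- sort(sample.int(m, 2L))
        res <- apply_scramble_event(state, type, pr[1L], pr[2L], essential)
        if (!is.null(res)) break
        if (try > max_retries)
          stop("could not sample a deletion preserving essential segments")
      }
      events[[k]] <- list(order = k, type = type, a = pr[1L], b = pr[2L],
                          n_sites = m, segments = res$segments)
      state <- res$state
    }
    list(state = state, events = events)
  })
  structure(list(sequence = reconstruct_segments(map, out$state),
                 state = out$state, events = out$events, map = map,
                 essential = essential, seed = seed),
            class = "scramble_result")
}

#' @export
print.scramble_result <- function(x, ...) {
  cat(sprintf("<scramble_result: %d event(s), %d segment(s), %d bp>\n",
              length(x$events), length(x$state), nchar(x$sequence)))
  invisible(x)
}

#' Replay a truth event log
#'
#' Reapplies the logged events to the identity state of the map; the
#' result must match the simulated outcome byte-identically.
#'
#' @param map A `segment_map`.
#' @param events Truth event list from [simulate_scramble()].
#' @param essential Essential segment ids used during simulation.
#' @return List with `state` and `sequence`.
#' @export
replay_scramble <- function(map, events, essential = length(map$ids)) {
  state <- map$ids
  for (e in events) {
    res <- apply_scramble_event(state, e$type, e$a, e$b, essential)
    if (is.null(res)) stop("replay failed: blocked deletion at event ", e$order)
    state <- res$state
  }
  list(state = state, sequence = reconstruct_segments(map, state))
}

#' Call structural variants from segment content
#'
#' Locates loxPsym sites in an observed (rearranged) sequence, matches
#' each inter-site segment to the original map by exact full-length
#' sequence identity (with orientation), canonicalizes the rotation of
#' the resulting signed permutation on an anchor segment, and
#' classifies differences from the identity: missing id runs as
#' deletions, negative-orientation runs as inversions, multiplicity
#' > 1 runs as duplications. Unmatched segments set a report-level
#' flag rather than raising.
#'
#' @param map The original `segment_map`.
#' @param observed Observed sequence string, `scramble_result`, or
#'   `neochrom_design`.
#' @param anchor Segment id used to fix rotation/orientation (default
#'   the origin-spanning segment).
#' @return An `sv_report`: canonical signed `state`, per-segment
#'   `copy_number` and `orientation`, `events` data frame (`type`,
#'   `first_seg`, `last_seg`), `n_unmatched`, `consistent` flag.
#' @export
call_structural_variants <- function(map, observed,
                                     anchor = length(map$ids)) {
  if (inherits(observed, "scramble_result")) observed <- observed$sequence
  if (inherits(observed, "neochrom_design")) observed <- observed$sequence
  obs_map <- build_segment_map(observed, site = map$site,
                               topology = map$topology)
  lookup <- stats::setNames(map$ids, map$seqs)
  state <- integer(length(obs_map$seqs))
  for (i in seq_along(obs_map$seqs)) {
    s <- obs_map$seqs[[i]]
    id <- lookup[s]
    if (!is.na(id)) { state[i] <- id; next }
    id <- lookup[revcomp(s)]
    state[i] <- if (!is.na(id)) -id else NA_integer_
  }
  n_unmatched <- sum(is.na(state))
  # canonical rotation/orientation on the anchor segment
  ap <- which(!is.na(state) & abs(state) == anchor)
  if (length(ap) > 0L) {
    if (state[ap[1L]] < 0L) {
      state <- -rev(state)
      ap <- which(!is.na(state) & abs(state) == anchor)
    }
    p <- ap[1L]
    if (p > 1L) state <- state[c(seq(p, length(state)), seq_len(p - 1L))]
  }
  n <- length(map$ids)
  ids_abs <- abs(state[!is.na(state)])
  copy_number <- tabulate(ids_abs, nbins = n)
  orientation <- vapply(seq_len(n), function(id) {
    occ <- state[!is.na(state) & abs(state) == id]
    if (length(occ) == 0L) "absent"
    else if (all(occ > 0L)) "+"
    else if (all(occ < 0L)) "-"
    else "mixed"
  }, character(1))

  events <- NULL
  consistent <- FALSE
  # preferred path: decompose the signed permutation into an explaining
  # event set (deletions + inversions) by breakpoint-guided search
  if (n_unmatched == 0L && all(copy_number <= 1L) &&
      length(state) >= 1L && state[1L] == anchor) {
    sol <- decompose_events(state[-1L], n, copy_number)
    if (!is.null(sol)) { events <- sol; consistent <- TRUE }
  }
  if (is.null(events)) {
    # fallback: run-based classification (also handles duplications)
    events <- list()
    for (r in id_runs(which(copy_number == 0L)))
      events[[length(events) + 1L]] <- data.frame(type = "DEL",
                                                  first_seg = r[1], last_seg = r[2])
    for (r in id_runs(which(copy_number > 1L)))
      events[[length(events) + 1L]] <- data.frame(type = "DUP",
                                                  first_seg = r[1], last_seg = r[2])
    neg <- unique(abs(state[!is.na(state) & state < 0L]))
    for (r in id_runs(neg))
      events[[length(events) + 1L]] <- data.frame(type = "INV",
                                                  first_seg = r[1], last_seg = r[2])
    events <- if (length(events)) do.call(rbind, events)
              else data.frame(type = character(), first_seg = integer(),
                              last_seg = integer())
    predicted <- predict_state(n, events)
    consistent <- n_unmatched == 0L &&
      identical(unname(predicted), unname(state))
  }
  structure(list(state = state, copy_number = copy_number,
                 orientation = orientation, events = events,
                 n_unmatched = n_unmatched, consistent = consistent),
            class = "sv_report")
}

# maximal runs of consecutive ids
id_runs <- function(idx) {
  if (length(idx) == 0L) return(NULL)
  idx <- sort(unique(idx))
  brk <- c(0L, which(diff(idx) > 1L), length(idx))
  lapply(seq_len(length(brk) - 1L), function(k)
    c(idx[brk[k] + 1L], idx[brk[k + 1L]]))
}

# Decompose a signed permutation (anchor removed; word over surviving
# ids of 1..n-1) into deletions of missing id runs plus up to
# `max_inv` inversions whose boundaries sit on breakpoints. Iterative
# deepening; returns the event data frame of one minimal explanation
# (deterministic choice under tied depth), or NULL.
decompose_events <- function(w, n, copy_number, max_inv = 3L) {
  missing <- which(copy_number == 0L)
  gap_ok <- function(lo, hi) {       # ids strictly between lo and hi missing
    if (hi - lo <= 1L) return(TRUE)
    all(seq(lo + 1L, hi - 1L) %in% missing)
  }
  adj_ok <- function(x, y) {
    if (x > 0L && y > 0L) return(y > x && gap_ok(x, y))
    if (x < 0L && y < 0L) return(-x > -y && gap_ok(-y, -x))
    FALSE
  }
  # gap indices 0..len(w); gap i sits between w[i] and w[i+1], with the
  # anchor acting as id 0 on the left and id n on the right
  breakpoints <- function(w) {
    len <- length(w)
    vals_l <- c(0L, w)          # value left of each gap (0 = anchor out)
    vals_r <- c(w, n)           # value right of each gap
    bad <- !vapply(seq_len(len + 1L), function(i) {
      x <- vals_l[i]; y <- vals_r[i]
      if (i == 1L) return(y > 0L && gap_ok(0L, y))
      if (i == len + 1L) return(x > 0L && gap_ok(x, n))
      adj_ok(x, y)
    }, logical(1))
    which(bad) - 1L
  }
  sorted_ok <- function(w) length(breakpoints(w)) == 0L
  found <- NULL
  dfs <- function(w, ops, depth_left) {
    if (!is.null(found)) return()
    if (sorted_ok(w)) { found <<- ops; return() }
    if (depth_left == 0L) return()
    bps <- breakpoints(w)
    if (length(bps) > 2L * depth_left + 2L) return()
    if (length(bps) < 2L) return()
    for (ii in seq_len(length(bps) - 1L)) {
      for (jj in seq(ii + 1L, length(bps))) {
        a <- bps[ii]; b <- bps[jj]
        span <- seq(a + 1L, b)
        w2 <- w
        w2[span] <- -rev(w[span])
        ids <- sort(abs(w[span]))
        dfs(w2, c(ops, list(c(min(ids), max(ids)))), depth_left - 1L)
        if (!is.null(found)) return()
      }
    }
  }
  for (d in 0:max_inv) {
    dfs(w, list(), d)
    if (!is.null(found)) break
  }
  if (is.null(found)) return(NULL)
  events <- list()
  for (r in id_runs(missing))
    events[[length(events) + 1L]] <- data.frame(type = "DEL",
                                                first_seg = r[1], last_seg = r[2])
  for (op in found)
    events[[length(events) + 1L]] <- data.frame(type = "INV",
                                                first_seg = op[1], last_seg = op[2])
  if (length(events)) do.call(rbind, events)
  else data.frame(type = character(), first_seg = integer(),
                  last_seg = integer())
}

# apply called events to the identity permutation (DEL, then DUP, then
# INV over id ranges); used as an internal consistency check
predict_state <- function(n, events) {
  state <- seq_len(n)
  for (i in seq_len(nrow(events))) {
    e <- events[i, ]
    span <- which(abs(state) >= e$first_seg & abs(state) <= e$last_seg)
    if (length(span) == 0L && e$type != "DEL") next
    if (e$type == "DEL") {
      state <- state[!(abs(state) >= e$first_seg & abs(state) <= e$last_seg)]
    } else if (e$type == "DUP") {
      state <- append(state, state[span], after = max(span))
    } else if (e$type == "INV") {
      if (all(diff(span) == 1L)) state[span] <- -rev(state[span])
    }
  }
  # rotate so the anchor (n) leads, matching the caller's canonical form
  p <- which(abs(state) == n)
  if (length(p) == 1L && p != 1L)
    state <- state[c(seq(p, length(state)), seq_len(p - 1L))]
  state
}

#' @export
print.sv_report <- function(x, ...) {
  cat(sprintf("<sv_report: %d event(s), %d unmatched segment(s)%s>\n",
              nrow(x$events), x$n_unmatched,
              if (x$consistent) ", consistent" else ", UNEXPLAINED differences"))
  if (nrow(x$events)) print(x$events)
  invisible(x)
}

#' Canonical event descriptors of a truth log or SV report
#'
#' Reduces either a truth event log (from [simulate_scramble()]) or a
#' called `sv_report` to a sorted set of `"TYPE:first-last"` strings
#' over original segment ids, so simulated and recovered event sets can
#' be compared directly.
#'
#' @param x A `scramble_result` or `sv_report`.
#' @return Sorted character vector of descriptors.
#' @export
event_descriptors <- function(x) {
  if (inherits(x, "scramble_result")) {
    out <- vapply(x$events, function(e)
      sprintf("%s:%d-%d", e$type, min(e$segments), max(e$segments)),
      character(1))
  } else if (inherits(x, "sv_report")) {
    out <- vapply(seq_len(nrow(x$events)), function(i)
      sprintf("%s:%d-%d", x$events$type[i], x$events$first_seg[i],
              x$events$last_seg[i]), character(1))
  } else stop("unsupported object")
  sort(out)
}

#' Estimate element copy number from per-contig coverage
#'
#' Returns the ratio of the element contig's mean depth to the mean
#' depth of all genome contigs longer than `min_contig` (the element
#' itself excluded), so an element gain gives a ratio above 1.
#'
#' @param coverage A `coverage_table` data frame (contig, length,
#'   mean_depth).
#' @param element_name Element contig name.
#' @param min_contig Minimum genome contig length (default 200000 bp).
#' @return Numeric ratio.
#' @export
estimate_copy_number <- function(coverage, element_name,
                                 min_contig = 200000) {
  if (!element_name %in% coverage$contig)
    stop("element ", element_name, " not present in coverage table")
  el <- coverage$mean_depth[coverage$contig == element_name]
  gen <- coverage$mean_depth[coverage$contig != element_name &
                             coverage$length > min_contig]
  if (length(gen) == 0L)
    stop("no genome contig longer than ", min_contig, " bp")
  unname(el[1] / mean(gen))
}
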