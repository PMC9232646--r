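# Seeded synthetic-data generators for every input the pipeline
# consumes. Each generator returns its ground-truth parameters alongside
# the data (as the "truth" attribute), and identical specs + seeds give
# byte-identical output. One top-level seed can feed all generators via
# derive_seed(seed, offset) with offsets documented at the call sites.

#' Specification for synthetic pan-genome fragments
#'
#' Defaults emulate the donor material of a pan-genome neo-chromosome:
#' 17 fragments spanning 1.1-60.3 kb with well-formed ORFs at roughly
#' the density of the published design and yeast-like GC content.
#'
#' @param n_fragments Number of fragments (default 17).
#' @param size_range `c(min_bp, max_bp)`; `min_bp` must be >= 300.
#' @param orf_density ORFs per kb (> 0).
#' @param gc_target GC fraction in (0, 1).
#' @param seed Integer seed.
#' @return A `fragment_spec` list.
#' @export
fragment_spec <- function(n_fragments = 17L, size_range = c(1100L, 60300L),
                          orf_density = 0.4, gc_target = 0.40, seed = 1L) {
  if (n_fragments < 1L) stop("n_fragments must be >= 1")
  if (size_range[1] < 300L) stop("size_range min must be >= 300 bp")
  if (size_range[2] < size_range[1]) stop("size_range must be increasing")
  if (orf_density <= 0) stop("orf_density must be > 0")
  if (gc_target <= 0 || gc_target >= 1) stop("gc_target must be in (0, 1)")
  structure(list(n_fragments = as.integer(n_fragments),
                 size_range = as.integer(size_range),
                 orf_density = orf_density, gc_target = gc_target,
                 seed = as.integer(seed)),
            class = "fragment_spec")
}

random_dna <- function(n, gc) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

non_stop_codons <- function() {
  all3 <- names(Biostrings::GENETIC_CODE)
  setdiff(all3, STOP_CODONS)
}

# random ORF of len_bp (multiple of 3): ATG + non-stop codons + stop.
# Codons are weighted by the product of base probabilities at the GC
# target so coding regions do not drag composition toward 50% GC.
random_orf_seq <- function(len_bp, gc = 0.5) {
  n_mid <- len_bp %/% 3L - 2L
  cods <- non_stop_codons()
  p_base <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  w <- vapply(cods, function(cc)
    prod(p_base[strsplit(cc, "")[[1L]]]), numeric(1))
  paste0("ATG",
         paste(sample(cods, n_mid, replace = TRUE, prob = w), collapse = ""),
         sample(STOP_CODONS, 1L))
}

# Remove every occurrence of the given motifs: inside ORFs by synonymous
# codon recoding, elsewhere by a single-base change. Deterministic given
# the RNG state; bounded iteration.
scrub_motifs <- function(sequence, motifs, orfs, seed = NULL) {
  if (!is.null(seed)) return(with_seed(seed, scrub_motifs(sequence, motifs, orfs)))
  for (pass in 1:200) {
    hit <- NULL
    for (m in motifs) {
      pos <- find_all(sequence, m)
      rc <- revcomp(m)
      if (rc != m) pos <- c(pos, find_all(sequence, rc))
      if (length(pos)) { hit <- c(min(pos), nchar(m)); break }
    }
    if (is.null(hit)) return(sequence)
    p <- hit[1]; L <- hit[2]
    fixed <- FALSE
    for (i in seq_len(nrow(orfs))) {
      o <- orfs[i, ]
      if (o$start >= p + L || o$end <= p) next
      n_cod <- (o$end - o$start) %/% 3L
      for (j in 2:(n_cod - 1L)) {   # never touch start or stop codon
        iv <- if (o$strand == "+") c(o$start + 3L * (j - 1L), o$start + 3L * j)
              else c(o$end - 3L * j, o$end - 3L * (j - 1L))
        if (iv[1] >= p + L || iv[2] <= p) next
        fwd <- subseq0(sequence, iv[1], iv[2])
        cod <- if (o$strand == "+") fwd else revcomp(fwd)
        for (alt in codon_synonyms()[[cod]]) {
          new_fwd <- if (o$strand == "+") alt else revcomp(alt)
          cand <- paste0(subseq0(sequence, 0L, iv[1]), new_fwd,
                         subseq0(sequence, iv[2], nchar(sequence)))
          # the swap must actually destroy this occurrence
          if (!p %in% c(find_all(cand, m), find_all(cand, revcomp(m)))) {
            sequence <- cand
            fixed <- TRUE
            break
          }
        }
        if (fixed) break
      }
      if (fixed) break
    }
    if (!fixed) {
      # mutate a base of the occurrence that lies outside every ORF
      cand_pos <- seq(p, p + L - 1L)
      if (nrow(orfs) > 0) {
        in_orf <- vapply(cand_pos, function(q)
          any(orfs$start <= q & q < orfs$end), logical(1))
        cand_pos <- cand_pos[!in_orf]
      }
      if (length(cand_pos) == 0L)
        stop("motif occurrence at ", p, " cannot be scrubbed synonymously")
      m_at <- cand_pos[ceiling(length(cand_pos) / 2)]
      old <- subseq0(sequence, m_at, m_at + 1L)
      new <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
      sequence <- paste0(subseq0(sequence, 0L, m_at), new,
                         subseq0(sequence, m_at + 1L, nchar(sequence)))
    }
  }
  stop("motif scrubbing did not converge")
}

#' Generate annotated synthetic pan-genome fragments
#'
#' Fragment sizes are drawn log-uniformly over `size_range` (matching
#' the strong small-fragment skew of natural pan-genome material);
#' background composition is i.i.d. at `gc_target`, and non-overlapping
#' ORFs (ATG start, non-stop interior, random stop, random strand) are
#' planted at `orf_density`, ~80% flagged high-confidence. PmeI, NotI
#' and loxPsym motifs are scrubbed (synonymous recoding inside ORFs)
#' so generated fragments are synthesis-ready.
#'
#' @param spec A [fragment_spec()].
#' @return List of [pan_fragment()] objects; ground truth in
#'   `attr(, "truth")`.
#' @export
generate_pan_fragments <- function(spec) {
  stopifnot(inherits(spec, "fragment_spec"))
  min_orf <- 150L
  if (spec$size_range[2] < min_orf + 50L)
    stop("size_range too small to host one ORF (need max_bp >= ",
         min_orf + 50L, ")")
  frags <- with_seed(spec$seed, {
    sizes <- round(exp(stats::runif(spec$n_fragments,
                                    log(spec$size_range[1]),
                                    log(spec$size_range[2]))))
    sizes <- pmin(pmax(sizes, spec$size_range[1]), spec$size_range[2])
    lapply(seq_len(spec$n_fragments), function(i) {
      size <- sizes[i]
      seqs <- random_dna(size, spec$gc_target)
      n_orfs <- max(1L, round(spec$orf_density * size / 1000))
      orfs <- empty_orf_table()
      occupied <- matrix(numeric(0), ncol = 2)
      margin <- 45L   # leaves room for downstream loxPsym insertion
      tries <- 0L
      while (nrow(orfs) < n_orfs && tries < n_orfs * 60L) {
        tries <- tries + 1L
        olen <- 3L * sample(seq(min_orf %/% 3L, 500L), 1L)
        if (olen + 2L * margin > size) next
        start <- sample.int(size - olen - 2L * margin, 1L) + margin - 1L
        end <- start + olen
        if (nrow(orfs) > 0 &&
            any(orfs$start - margin < end & orfs$end + margin > start)) next
        oseq <- random_orf_seq(olen, gc = spec$gc_target)
        strand <- sample(c("+", "-"), 1L)
        fwd <- if (strand == "+") oseq else revcomp(oseq)
        seqs <- paste0(subseq0(seqs, 0L, start), fwd,
                       subseq0(seqs, end, nchar(seqs)))
        orfs <- rbind(orfs, data.frame(
          id = sprintf("f%02d_orf%d", i, nrow(orfs) + 1L),
          start = start, end = end, strand = strand,
          confidence = if (stats::runif(1) < 0.8) "high" else "low",
          product = NA_character_, stringsAsFactors = FALSE))
      }
      orfs <- orfs[order(orfs$start), ]
      seqs <- scrub_motifs(seqs, forbidden_motifs(), orfs)
      pan_fragment(sprintf("frag_%02d", i), seqs, orfs,
                   source_label = "synthetic pan-genome fragment")
    })
  })
  attr(frags, "truth") <- spec
  frags
}

# ---- kinetic plates --------------------------------------------------------

well_names <- function(n) {
  rows <- LETTERS[seq_len(ceiling(n / 12))]
  grid <- as.vector(t(outer(rows, sprintf("%02d", 1:12), paste0)))
  grid[seq_len(n)]
}

#' Specification for a paired phenotype-microarray experiment
#'
#' @param n_wells Wells per plate (default 96).
#' @param effect_map Named numeric vector, well -> true fold-change of
#'   the test-strain plateau relative to the reference strain. Wells
#'   not named default to 1 (no effect).
#' @param noise_cv Multiplicative (lognormal) noise CV, >= 0.
#' @param control_wells `list(negative =, positive =)` well names.
#' @param blank_wells Wells carrying no respiration signal.
#' @param timepoints Number of kinetic readings.
#' @param t_max Final time in hours.
#' @param seed Integer seed.
#' @return A `plate_spec` list.
#' @export
plate_spec <- function(n_wells = 96L, effect_map = NULL, noise_cv = 0.05,
                       control_wells = list(negative = "A01",
                                            positive = "A02"),
                       blank_wells = character(), timepoints = 25L,
                       t_max = 48, seed = 1L) {
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  if (is.null(control_wells$negative) || is.null(control_wells$positive))
    stop("both a negative and a positive control well must be designated")
  wells <- well_names(n_wells)
  roles <- rep("compound", n_wells); names(roles) <- wells
  roles[control_wells$negative] <- "negative"
  roles[control_wells$positive] <- "positive"
  roles[blank_wells] <- "blank"
  if (anyNA(names(roles))) stop("control/blank wells outside the plate")
  if (sum(roles == "negative") != 1L || sum(roles == "positive") != 1L)
    stop("every well must have exactly one role; need exactly one ",
         "negative and one positive control")
  eff <- stats::setNames(rep(1, n_wells), wells)
  if (!is.null(effect_map)) {
    if (is.null(names(effect_map))) stop("effect_map must be named by well")
    bad <- setdiff(names(effect_map), wells[roles == "compound"])
    if (length(bad)) stop("effect_map names are not compound wells: ",
                          paste(bad, collapse = ", "))
    eff[names(effect_map)] <- effect_map
  }
  structure(list(n_wells = as.integer(n_wells), wells = wells,
                 roles = roles, effects = eff, noise_cv = noise_cv,
                 timepoints = as.integer(timepoints), t_max = t_max,
                 seed = as.integer(seed)),
            class = "plate_spec")
}

logistic_curve <- function(times, plateau, k = 0.35, t0 = 16) {
  plateau / (1 + exp(-k * (times - t0)))
}

#' Generate a paired kinetic plate experiment (test vs reference strain)
#'
#' Every well holds a logistic mean respiration curve with
#' multiplicative lognormal noise. Compound wells with planted effect
#' `f` have a test-strain plateau of `f` times the reference plateau
#' (200 units); the negative control plateaus at 10 units, the positive
#' at 250, blanks at 4. Truth labels are retained.
#'
#' @param spec A [plate_spec()].
#' @return List of class `biolog_experiment` with tidy data frames
#'   `test` and `reference` (columns well, role, compound, time, value)
#'   and a `truth` list.
#' @export
generate_biolog_experiment <- function(spec) {
  stopifnot(inherits(spec, "plate_spec"))
  times <- seq(0, spec$t_max, length.out = spec$timepoints)
  sdlog <- sqrt(log(1 + spec$noise_cv^2))
  base_ref <- 200
  plateau_for <- function(role, effect, strain) {
    switch(role,
           negative = 10, positive = 250, blank = 4,
           compound = if (strain == "test") effect * base_ref else base_ref)
  }
  make_plate <- function(strain) {
    do.call(rbind, lapply(spec$wells, function(w) {
      role <- spec$roles[[w]]
      mu <- logistic_curve(times, plateau_for(role, spec$effects[[w]], strain))
      noise <- if (sdlog > 0)
        exp(stats::rnorm(length(times), -sdlog^2 / 2, sdlog)) else 1
      data.frame(well = w, role = role,
                 compound = if (role == "compound") paste0("cmpd_", w)
                            else NA_character_,
                 time = times, value = mu * noise,
                 stringsAsFactors = FALSE)
    }))
  }
  out <- with_seed(spec$seed,
                   list(test = make_plate("test"),
                        reference = make_plate("reference")))
  out$truth <- list(effects = spec$effects, roles = spec$roles)
  class(out) <- "biolog_experiment"
  out
}

# ---- passaging / stability -------------------------------------------------

#' Specification for a serial-passaging stability experiment
#'
#' The default per-generation loss probability 0.0191 corresponds to
#' 61.7% retention after 25 generations under the geometric loss model
#' (the stability the circular neo-chromosome showed).
#'
#' @param p_loss Per-generation loss probability in `[0, 1]`.
#' @param generations Strictly increasing sampling timepoints.
#' @param n_colonies Colonies plated per replicate (default 96).
#' @param replicates Independent biological replicates (default 3).
#' @param seed Integer seed.
#' @return A `passaging_spec` list.
#' @export
passaging_spec <- function(p_loss = 0.0191, generations = c(25L, 50L),
                           n_colonies = 96L, replicates = 3L, seed = 1L) {
  if (p_loss < 0 || p_loss > 1) stop("p_loss must be in [0, 1]")
  if (any(diff(generations) <= 0) || any(generations <= 0))
    stop("generations must be strictly increasing and positive")
  if (n_colonies < 1L) stop("n_colonies must be >= 1")
  structure(list(p_loss = p_loss, generations = as.integer(generations),
                 n_colonies = as.integer(n_colonies),
                 replicates = as.integer(replicates),
                 seed = as.integer(seed)),
            class = "passaging_spec")
}

#' Generate colony counts from serial passaging under geometric loss
#'
#' Per replicate and sampled generation `g`, the number of
#' marker-retaining (resistant) colonies is drawn from
#' `Binomial(n_colonies, (1 - p_loss)^g)`.
#'
#' @param spec A [passaging_spec()].
#' @return A `stability_experiment` data frame (replicate, generation,
#'   resistant, total); ground truth in `attr(, "truth")`.
#' @export
generate_passaging_counts <- function(spec) {
  stopifnot(inherits(spec, "passaging_spec"))
  out <- with_seed(spec$seed, {
    grid <- expand.grid(replicate = seq_len(spec$replicates),
                        generation = spec$generations)
    grid <- grid[order(grid$replicate, grid$generation), ]
    grid$resistant <- stats::rbinom(nrow(grid), spec$n_colonies,
                                    (1 - spec$p_loss)^grid$generation)
    grid$total <- spec$n_colonies
    rownames(grid) <- NULL
    grid
  })
  attr(out, "truth") <- spec
  class(out) <- c("stability_experiment", "data.frame")
  out
}

# ---- coverage --------------------------------------------------------------

#' Chromosome-scale default contig lengths
#'
#' Sixteen contigs at the lengths of the *S. cerevisiae* chromosomes
#' plus one episomal element contig.
#'
#' @param element_name Name of the element contig.
#' @param element_length Element contig length in bp.
#' @return Named integer vector of contig lengths.
#' @export
default_contig_lengths <- function(element_name = "PGNC",
                                   element_length = 211409L) {
  chr <- c(230218L, 813184L, 316620L, 1531933L, 576874L, 270161L,
           1090940L, 562643L, 439888L, 745751L, 666816L, 1078177L,
           924431L, 784333L, 1091291L, 948066L)
  names(chr) <- sprintf("chr%02d", seq_along(chr))
  out <- c(chr, stats::setNames(as.integer(element_length), element_name))
  out
}

#' Specification for a per-contig coverage profile
#'
#' @param contig_lengths Named vector contig -> length (bp), including
#'   the element contig.
#' @param element_name Element contig identifier.
#' @param true_ratio True element:genome depth ratio (> 0).
#' @param mean_depth Genome-wide mean depth (> 0).
#' @param noise `"poisson"` (read-count sampling) or `"none"`.
#' @param seed Integer seed.
#' @return A `coverage_spec` list.
#' @export
coverage_spec <- function(contig_lengths = default_contig_lengths(),
                          element_name = "PGNC", true_ratio = 1,
                          mean_depth = 30, noise = c("poisson", "none"),
                          seed = 1L) {
  noise <- match.arg(noise)
  if (!element_name %in% names(contig_lengths))
    stop("element_name must be present in contig_lengths")
  if (any(contig_lengths <= 0)) stop("contig lengths must be > 0")
  if (true_ratio <= 0 || mean_depth <= 0)
    stop("true_ratio and mean_depth must be > 0")
  structure(list(contig_lengths = contig_lengths,
                 element_name = element_name, true_ratio = true_ratio,
                 mean_depth = mean_depth, noise = noise,
                 seed = as.integer(seed)),
            class = "coverage_spec")
}

#' Generate a per-contig coverage table with a planted copy-number ratio
#'
#' Genome contigs receive `mean_depth`; the element contig receives
#' `true_ratio * mean_depth`. Under `"poisson"` noise the per-contig
#' mean depth is a Poisson total read-base count divided by contig
#' length.
#'
#' @param spec A [coverage_spec()].
#' @return A `coverage_table` data frame (contig, length, mean_depth);
#'   ground truth in `attr(, "truth")`.
#' @export
generate_coverage_profile <- function(spec) {
  stopifnot(inherits(spec, "coverage_spec"))
  out <- with_seed(spec$seed, {
    contig <- names(spec$contig_lengths)
    len <- as.numeric(spec$contig_lengths)
    lambda <- ifelse(contig == spec$element_name,
                     spec$mean_depth * spec$true_ratio, spec$mean_depth)
    depth <- if (spec$noise == "poisson")
      stats::rpois(length(len), lambda * len) / len else lambda
    data.frame(contig = contig, length = len, mean_depth = depth,
               stringsAsFactors = FALSE)
  })
  attr(out, "truth") <- spec
  class(out) <- c("coverage_table", "data.frame")
  out
}
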