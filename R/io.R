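# Readers/writers for the interchange formats (FASTA + GFF3 + JSON
# sidecar for designs; tidy TSV for plates, stability counts and
# coverage) and the umbrella pipeline driver. GFF3 is written/parsed
# through rtracklayer; its 1-based inclusive coordinates are converted
# to the internal 0-based half-open convention at this boundary.

#' Write a design as FASTA + GFF3 (+ JSON metadata sidecar)
#'
#' @param design A `neochrom_design`.
#' @param fasta,gff Output paths.
#' @param meta Path of the JSON sidecar holding topology, edit log,
#'   watermark records and the pre-edit sequence (default
#'   `<gff>.meta.json`).
#' @return Invisibly, the three paths.
#' @export
write_design <- function(design, fasta, gff,
                         meta = paste0(gff, ".meta.json")) {
  dss <- Biostrings::DNAStringSet(stats::setNames(design$sequence,
                                                  design$name))
  Biostrings::writeXStringSet(dss, fasta)
  f <- design$features
  len <- design_length(design)
  gr <- GenomicRanges::GRanges(
    seqnames = design$name,
    ranges = IRanges::IRanges(start = c(1L, f$start + 1L),
                              end = c(len, f$end)),
    strand = c("*", f$strand))
  S4Vectors::mcols(gr)$type <- c("region", f$type)
  S4Vectors::mcols(gr)$ID <- c(design$name, f$id)
  S4Vectors::mcols(gr)$confidence <- c(NA_character_, f$confidence)
  S4Vectors::mcols(gr)$product <- c(NA_character_, f$product)
  S4Vectors::mcols(gr)$Is_circular <-
    c(if (design$topology == "circular") "true" else "false",
      rep(NA_character_, nrow(f)))
  rtracklayer::export(gr, gff, format = "gff3")
  jsonlite::write_json(
    list(name = design$name, topology = design$topology,
         recoded = isTRUE(design$recoded),
         issues = design$issues,
         skipped_loxpsym = design$skipped_loxpsym,
         edit_log = design$edit_log,
         watermarks = design$watermarks,
         initial_sequence = design$initial_sequence),
    meta, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(fasta = fasta, gff = gff, meta = meta))
}

#' Read a design from FASTA + GFF3 (+ JSON metadata sidecar)
#'
#' Lowercase sequence is normalized to uppercase; circularity is taken
#' from the metadata sidecar or, failing that, the GFF3 region
#' feature's `Is_circular` attribute; coordinate or alphabet problems
#' raise distinct named errors. The design is validated on load.
#'
#' @param fasta,gff Input paths.
#' @param meta JSON sidecar path; `NULL` to read a bare FASTA/GFF3
#'   pair.
#' @return A `neochrom_design`.
#' @export
read_design <- function(fasta, gff, meta = paste0(gff, ".meta.json")) {
  dss <- Biostrings::readDNAStringSet(fasta)
  if (length(dss) != 1L) stop("expected exactly one FASTA record")
  seqs <- toupper(as.character(dss[[1L]]))
  name <- strsplit(names(dss)[1L], "\\s+")[[1L]][1L]
  if (grepl("[^ACGT]", seqs))
    stop("illegal characters in sequence of ", name)
  gr <- rtracklayer::import(gff, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  is_region <- mc$type == "region"
  meta_data <- NULL
  if (!is.null(meta) && file.exists(meta))
    meta_data <- jsonlite::read_json(meta, simplifyVector = FALSE)
  topology <- if (!is.null(meta_data)) meta_data$topology
    else if (any(is_region) && !is.null(mc$Is_circular)) {
      if (identical(mc$Is_circular[is_region][1L], "true")) "circular"
      else "linear"
    } else stop("missing topology: no metadata sidecar and no ",
                "Is_circular region attribute")
  keep <- !is_region
  starts <- BiocGenerics::start(gr)[keep] - 1L
  ends <- BiocGenerics::end(gr)[keep]
  strands <- as.character(BiocGenerics::strand(gr))[keep]
  strands[!strands %in% c("+", "-")] <- "+"
  get_col <- function(col, default = NA_character_) {
    if (col %in% names(mc)) as.character(mc[[col]])[keep]
    else rep(default, sum(keep))
  }
  feats <- data.frame(id = get_col("ID"), type = get_col("type"),
                      start = as.integer(starts), end = as.integer(ends),
                      strand = strands, confidence = get_col("confidence"),
                      product = get_col("product"),
                      stringsAsFactors = FALSE)
  len <- nchar(seqs)
  bad <- feats$start < 0 | feats$end > len
  if (topology == "linear" && any(bad))
    stop("feature coordinates out of bounds: ",
         paste(feats$id[bad], collapse = ", "))
  design <- new_design(name, topology, seqs, feats)
  if (!is.null(meta_data)) {
    design$recoded <- isTRUE(meta_data$recoded)
    design$issues <- as.character(unlist(meta_data$issues))
    design$skipped_loxpsym <- as.character(unlist(meta_data$skipped_loxpsym))
    design$edit_log <- lapply(meta_data$edit_log, function(e) {
      e$pos <- as.integer(e$pos); e
    })
    design$watermarks <- lapply(meta_data$watermarks, function(w) {
      w$original_codons <- as.character(unlist(w$original_codons))
      w$recoded_codons <- as.character(unlist(w$recoded_codons))
      w$codon_window <- as.integer(unlist(w$codon_window))
      w$n_bits <- as.integer(w$n_bits)
      w$skipped_positions <- as.integer(unlist(w$skipped_positions))
      w
    })
    if (!is.null(meta_data$initial_sequence))
      design$initial_sequence <- meta_data$initial_sequence
  }
  design
}

#' Write/read tidy TSV tables
#'
#' Thin wrappers fixing the dialect (tab separator, header, no quoting,
#' no row names) used for plate kinetics, stability counts, coverage
#' tables, plans and primer sets.
#'
#' @param x A data frame.
#' @param path File path.
#' @return `read_tsv()` returns a data frame; `write_tsv()` the path,
#'   invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}

#' Export chunks as multi-FASTA and BED
#'
#' FASTA headers annotate the overhang length and flanking release
#' sites; the BED file gives each chunk's interval on the design
#' (0-based, half-open; a chunk wrapping the circular origin is split
#' into two BED rows).
#'
#' @param chunks A `chunk_set`.
#' @param fasta,bed Output paths.
#' @return Invisibly, the two paths.
#' @export
write_chunks <- function(chunks, fasta, bed) {
  seqs <- chunk_sequences(chunks)
  names(seqs) <- vapply(chunks, function(ch)
    sprintf("chunk_%02d overhang=%d flanks=%s/%s", ch$index,
            nchar(ch$left_overhang), ch$flank_sites[["left"]],
            ch$flank_sites[["right"]]), character(1))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), fasta)
  len <- attr(chunks, "design_length")
  name <- attr(chunks, "design_name")
  bs <- attr(chunks, "boundaries")
  rows <- list()
  for (i in seq_along(chunks)) {
    s <- bs[i]
    e <- if (i < length(bs)) bs[i + 1L] else bs[1L] + len
    lab <- sprintf("chunk_%02d", i)
    if (e <= len) rows[[length(rows) + 1L]] <- data.frame(
      chrom = name, start = s, end = e, name = lab)
    else {
      rows[[length(rows) + 1L]] <- data.frame(chrom = name, start = s,
                                              end = len, name = lab)
      rows[[length(rows) + 1L]] <- data.frame(chrom = name, start = 0L,
                                              end = e - len, name = lab)
    }
  }
  utils::write.table(do.call(rbind, rows), bed, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(c(fasta = fasta, bed = bed))
}

# first position at/after `near` that is not inside any feature
find_intergenic_locus <- function(design, near) {
  len <- design_length(design)
  f <- design$features
  for (off in 0:(len - 1L)) {
    p <- (near + off) %% len
    if (!any(f$start < p & p < f$end)) return(p)
  }
  stop("no intergenic position found")
}

pipeline_defaults <- function() {
  list(seed = 1L, out_dir = NULL,
       n_fragments = 17L, size_range = c(1100L, 60300L),
       orf_density = 0.4, gc_target = 0.40,
       n_watermarks = 36L, payload_bits = 8L,
       chunk_target = 10000L, chunk_overlap = 200L, per_round_max = 4L,
       do_primers = FALSE, n_linear_variants = 0L,
       scramble_events = 2L, coverage_ratio = 1.5,
       biolog_increased = 9L, biolog_decreased = 8L, noise_cv = 0.05,
       p_loss = 0.0191, generations = c(25L, 50L), growth_rate = 0.53)
}

#' Run the full design/build/test pipeline on synthetic inputs
#'
#' Executes design (fragment generation, concatenation, stop-codon
#' recoding, watermarks, loxPsym insertion, validation), chunking,
#' assembly planning, in-silico reassembly check, optional
#' linearization and junction primers, SCRaMbLE simulation with SV
#' calling, copy-number estimation, and the phenotype statistics, all
#' seeded from the single config seed (per-stage substreams via
#' documented offsets). When `out_dir` is set, artifacts are written
#' and their MD5 checksums recorded, so rerunning an identical config
#' reproduces identical checksums.
#'
#' @param config Named list overriding the defaults (unknown keys are
#'   rejected), or a path to a YAML file of the same shape.
#' @return A `neochrom_pipeline` list of stage results, key numbers
#'   and file checksums.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  if (cfg$chunk_overlap >= cfg$chunk_target)
    stop("chunk_overlap must be smaller than chunk_target")
  seed <- as.integer(cfg$seed)

  frags <- generate_pan_fragments(fragment_spec(
    n_fragments = cfg$n_fragments, size_range = cfg$size_range,
    orf_density = cfg$orf_density, gc_target = cfg$gc_target,
    seed = derive_seed(seed, 1)))
  backbone <- synthetic_backbone(seed = derive_seed(seed, 2))
  design <- concatenate_fragments(frags, backbone, name = "neochrom")
  design <- recode_stop_codons(design)

  orfs <- design_orfs(design)
  eligible <- orfs$id[(orfs$end - orfs$start) / 3 >= 24]
  wm_ids <- utils::head(eligible, cfg$n_watermarks)
  payloads <- with_seed(derive_seed(seed, 3), vapply(seq_along(wm_ids),
    function(i) paste(sample(0:1, cfg$payload_bits, replace = TRUE),
                      collapse = ""), character(1)))
  design <- embed_watermarks(design, wm_ids, payloads)
  design <- insert_loxpsym(design)
  validation <- validate_design(design)

  chunks <- chunk_design(design, target_size = cfg$chunk_target,
                         overlap = cfg$chunk_overlap)
  plan <- plan_assembly(chunks, per_round_max = cfg$per_round_max)
  assembled <- simulate_hr_assembly(chunks)
  roundtrip_ok <- is_rotation_of(as.character(assembled), design$sequence)
  if (!roundtrip_ok) stop("stage assembly-check failed: chunk round trip ",
                          "did not reproduce the design")
  primers <- if (isTRUE(cfg$do_primers))
    design_junction_primers(design, chunks) else NULL

  variants <- list()
  if (cfg$n_linear_variants > 0L) {
    len <- design_length(design)
    for (i in seq_len(cfg$n_linear_variants)) {
      locus <- find_intergenic_locus(design, round(i * len /
                                                   (cfg$n_linear_variants + 1)))
      variants[[i]] <- linearize_at(design, locus)
    }
  }

  map <- build_segment_map(design)
  scramble <- simulate_scramble(map, n_events = cfg$scramble_events,
                                seed = derive_seed(seed, 4))
  sv <- call_structural_variants(map, scramble)
  coverage <- generate_coverage_profile(coverage_spec(
    true_ratio = cfg$coverage_ratio, seed = derive_seed(seed, 5)))
  copy_number <- estimate_copy_number(coverage, "PGNC")

  pspec <- plate_spec(seed = derive_seed(seed, 6), noise_cv = cfg$noise_cv)
  cw <- pspec$wells[pspec$roles == "compound"]
  eff <- c(stats::setNames(rep(2.5, cfg$biolog_increased),
                           cw[seq_len(cfg$biolog_increased)]),
           stats::setNames(rep(0.4, cfg$biolog_decreased),
                           cw[cfg$biolog_increased + seq_len(cfg$biolog_decreased)]))
  biolog <- generate_biolog_experiment(plate_spec(
    effect_map = eff, noise_cv = cfg$noise_cv,
    seed = derive_seed(seed, 6)))
  classification <- biolog_classify(biolog$test, biolog$reference)

  passaging <- generate_passaging_counts(passaging_spec(
    p_loss = cfg$p_loss, generations = cfg$generations,
    seed = derive_seed(seed, 7)))
  retention <- retention_stats(passaging)
  g1 <- retention$per_generation$generation[1L]
  loss_rate <- estimate_loss_rate(
    retention$per_generation$mean_pct[1L] / 100, g1)

  growth <- simulate_growth_curve(r = cfg$growth_rate,
                                  seed = derive_seed(seed, 8))
  mu_max <- max_specific_growth_rate(growth$time, growth$od)

  checksums <- NULL
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(...) file.path(cfg$out_dir, ...)
    write_design(design, p("design.fasta"), p("design.gff3"))
    write_chunks(chunks, p("chunks.fasta"), p("chunks.bed"))
    write_tsv(plan$rounds, p("assembly_plan.tsv"))
    if (!is.null(primers)) write_tsv(primers, p("junction_primers.tsv"))
    write_tsv(coverage, p("coverage.tsv"))
    write_tsv(classification, p("biolog_classification.tsv"))
    write_tsv(passaging, p("passaging_counts.tsv"))
    writeLines(scramble$sequence, p("scrambled.txt"))
    files <- list.files(cfg$out_dir, full.names = TRUE)
    checksums <- tools::md5sum(files)
    names(checksums) <- basename(names(checksums))
  }

  structure(list(design = design, validation = validation, chunks = chunks,
                 plan = plan, primers = primers, variants = variants,
                 scramble = scramble, sv_report = sv,
                 copy_number = copy_number,
                 classification = classification, retention = retention,
                 loss_rate = loss_rate, mu_max = mu_max,
                 roundtrip_ok = roundtrip_ok, checksums = checksums,
                 config = cfg),
            class = "neochrom_pipeline")
}

#' Simulate an OD growth curve with logistic kinetics
#'
#' Logistic growth `x(t) = K x0 e^{rt} / (K + x0 (e^{rt} - 1))` with
#' optional multiplicative lognormal noise; the early phase is
#' exponential at rate `r`, so [max_specific_growth_rate()] should
#' recover `r`.
#'
#' @param times Sampling times in hours.
#' @param r Specific growth rate (1/h), default 0.53.
#' @param x0 Inoculum OD.
#' @param K Carrying capacity OD.
#' @param noise_cv Multiplicative noise CV (0 = noiseless).
#' @param seed Integer seed (used only when `noise_cv > 0`).
#' @return Data frame with `time` and `od`.
#' @export
simulate_growth_curve <- function(times = seq(0, 24, by = 0.25), r = 0.53,
                                  x0 = 0.025, K = 2, noise_cv = 0,
                                  seed = 1L) {
  mu <- K * x0 * exp(r * times) / (K + x0 * (exp(r * times) - 1))
  od <- if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    with_seed(seed, mu * exp(stats::rnorm(length(mu), -sdlog^2 / 2, sdlog)))
  } else mu
  data.frame(time = times, od = od)
}

#' @export
print.neochrom_pipeline <- function(x, ...) {
  cat("neochrom pipeline run\n")
  cat(sprintf("  design: %d bp, %d loxPsym site(s), validation %s\n",
              design_length(x$design),
              sum(x$design$features$type == "loxPsym"),
              if (all_checks_pass(x$validation)) "passed" else "FAILED"))
  cat(sprintf("  chunks: %d; assembly round trip %s\n", length(x$chunks),
              if (x$roundtrip_ok) "exact" else "FAILED"))
  cat(sprintf("  SCRaMbLE: %d event(s); caller consistent: %s\n",
              length(x$scramble$events), x$sv_report$consistent))
  cat(sprintf("  copy number estimate: %.3f\n", x$copy_number))
  cat(sprintf("  BioLog: %d increased / %d decreased / %d excluded\n",
              sum(x$classification$status == "increased"),
              sum(x$classification$status == "decreased"),
              sum(x$classification$status == "excluded")))
  cat(sprintf("  retention: %s\n",
              paste(sprintf("%.1f%%@g%d", x$retention$per_generation$mean_pct,
                            x$retention$per_generation$generation),
                    collapse = ", ")))
  cat(sprintf("  loss rate: %.4f per generation; mu_max %.3f 1/h\n",
              x$loss_rate, x$mu_max))
  invisible(x)
}
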