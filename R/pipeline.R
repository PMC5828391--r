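#' Pipeline run configuration
#'
#' Builds a validated configuration for [run_pipeline()]. Every parameter has
#' a default; unknown keys are rejected. The defaults describe a small
#' multi-array experiment: arrays whose founder dimers carry increasingly
#' degraded CENP-B boxes (so per-contig motif score varies), small
#' within-array divergence, a specific antibody plus an IgG control, four
#' salt fractions, and spike-in reads in every sample.
#'
#' @param ... Named parameters overriding the defaults; see Details.
#' @details Parameters (defaults in parentheses):
#' * `seed` (1); `mode` (`"merged_250"`, or `"short_read_25"` where merging
#'   is impossible and R1 end-counts are used);
#' * array geometry: `n_arrays` (4), `units_per_array` (8), `periods`
#'   (340, recycled), `founder_divergence` (evenly spaced over 0-0.2),
#'   `array_divergence` (0.02);
#' * occupancy truth: `link` (`0.2 + score`), `noise_sd` (0.9),
#'   `jitter_sd` (20);
#' * sequencing: `antibodies` (`"CENP-A"`), `igg_name` (`"IgG"`),
#'   `n_fragments_per_antibody` (2000), `igg_fragments` (2000),
#'   `fragment_model` ([fragment_model()]), `read_length` (250),
#'   `per_base_error` (0.001), `spike_n` (500), `spike_genome_len` (4000);
#' * analysis: `min_quality`/`min_length`/`min_overlap` (25/25/15),
#'   `max_mismatch_frac` (0.1), `scale_const` (10000), `pseudocount` (1),
#'   `centered_tol` (25), `symmetry_ratio` (1.5), `dimers_antibody`
#'   (`"CENP-A"`), `dimers_fraction` (`"high_salt"`);
#' * control: `resume` (FALSE), `quiet` (FALSE).
#' @return Object of class `sat_config` (a named list).
#' @export
sat_config <- function(...) {
  cfg <- .sat_defaults()
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(names(dots) == ""))
      stop("all config entries must be named", call. = FALSE)
    unknown <- setdiff(names(dots), names(cfg))
    if (length(unknown))
      stop("unknown config key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    cfg[names(dots)] <- dots
  }
  if (is.null(cfg$founder_divergence))
    cfg$founder_divergence <- seq(0, 0.2, length.out = cfg$n_arrays)
  cfg$periods <- rep_len(cfg$periods, cfg$n_arrays)
  cfg$founder_divergence <- rep_len(cfg$founder_divergence, cfg$n_arrays)
  if (!cfg$mode %in% c("merged_250", "short_read_25"))
    stop("mode must be 'merged_250' or 'short_read_25'", call. = FALSE)
  structure(cfg, class = "sat_config")
}

.sat_defaults <- function() {
  list(seed = 1L, mode = "merged_250",
       n_arrays = 4L, units_per_array = 8L, periods = 340L,
       founder_divergence = NULL, array_divergence = 0.02,
       link = function(s) 0.2 + s, noise_sd = 0.9, jitter_sd = 20,
       antibodies = "CENP-A", igg_name = "IgG",
       n_fragments_per_antibody = 2000L, igg_fragments = 2000L,
       fragment_model = fragment_model(), read_length = 250L,
       per_base_error = 0.001, spike_n = 500L, spike_genome_len = 4000L,
       min_quality = 25L, min_length = 25L, min_overlap = 15L,
       max_mismatch_frac = 0.1, scale_const = 10000, pseudocount = 1,
       centered_tol = 25, symmetry_ratio = 1.5,
       dimers_antibody = "CENP-A", dimers_fraction = "high_salt",
       resume = FALSE, quiet = FALSE)
}

#' @export
print.sat_config <- function(x, ...) {
  cat("<sat_config> ", x$n_arrays, " arrays x ", x$units_per_array,
      " units; antibodies ", paste(x$antibodies, collapse = ","), " + ",
      x$igg_name, "; mode ", x$mode, "; seed ", x$seed, "\n", sep = "")
  invisible(x)
}

.log <- function(con, quiet, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
  if (!quiet) message(msg)
  if (!is.null(con)) writeLines(msg, con)
}

# deterministic random DNA string (for the synthetic spike-in genome)
.random_dna <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c(0.3, 0.2, 0.2, 0.3)), collapse = "")
}

# --- simulate stage -------------------------------------------------------

# builds arrays (specific + IgG occupancy variants), simulates fragments per
# antibody, emits per-sample FASTQ + truth; returns full in-memory state
.stage_simulate <- function(cfg, out, subseed) {
  arrays <- vector("list", cfg$n_arrays)
  for (i in seq_len(cfg$n_arrays)) {
    founder0 <- build_dimer(period = cfg$periods[i])
    founder_arr <- evolve_array(founder0, 1L, cfg$founder_divergence[i],
                                seed = subseed(), name = "founder")
    founder <- founder_arr$units[[1L]]
    arr <- evolve_array(founder, cfg$units_per_array, cfg$array_divergence,
                        seed = subseed(),
                        name = sprintf("array%02d", i))
    arr <- assign_truth_occupancy(arr, link = cfg$link,
                                  noise_sd = cfg$noise_sd, seed = subseed())
    arrays[[i]] <- list(array = arr, founder = founder)
  }
  names(arrays) <- vapply(arrays, function(a) a$array$name, character(1))

  seqs <- Biostrings::DNAStringSet(
    vapply(arrays, function(a) array_sequence(a$array), character(1)))
  Biostrings::writeXStringSet(seqs, file.path(out, "arrays.fasta"))
  founders <- Biostrings::DNAStringSet(
    vapply(arrays, function(a) a$founder$sequence, character(1)))
  names(founders) <- paste0(names(arrays), "_founder")
  Biostrings::writeXStringSet(founders, file.path(out, "founders.fasta"))

  spike_genome <- .random_dna(cfg$spike_genome_len, subseed())
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(c(spike_synthetic = spike_genome)),
    file.path(out, "spike_synthetic.fasta"))

  # fragments per antibody: specific antibodies follow the truth occupancy,
  # the IgG control is uniform over sequence with uniform fraction weights
  frag_by_ab <- list()
  for (ab in c(cfg$antibodies, cfg$igg_name)) {
    specific <- ab != cfg$igg_name
    n_total <- if (specific) cfg$n_fragments_per_antibody
               else cfg$igg_fragments
    wt <- vapply(arrays, function(a) {
      if (specific) sum(a$array$truth_occupancy)
      else a$array$n_units * a$array$period
    }, numeric(1))
    set.seed(subseed())
    n_per <- as.vector(rmultinom(1L, n_total, wt))
    parts <- list()
    for (i in seq_len(cfg$n_arrays)) {
      if (n_per[i] == 0L) next
      arr <- arrays[[i]]$array
      if (!specific) {
        arr$truth_occupancy <- rep(1, arr$n_units)
        arr$truth_fraction_weights <-
          matrix(0.25, arr$n_units, 4L, dimnames = list(NULL, SALT_FRACTIONS))
      }
      fr <- simulate_fragments(arr, cfg$fragment_model, n_per[i],
                               seed = subseed(), jitter_sd = cfg$jitter_sd)
      fr$array <- arr$name
      parts[[length(parts) + 1L]] <- fr
    }
    frag_by_ab[[ab]] <- do.call(rbind, parts)
  }

  # one sample (FASTQ pair + truth) per antibody x fraction
  fq_dir <- file.path(out, "fastq")
  dir.create(fq_dir, showWarnings = FALSE)
  samples <- list()
  for (ab in names(frag_by_ab)) {
    for (fr in SALT_FRACTIONS) {
      sel <- frag_by_ab[[ab]][frag_by_ab[[ab]]$fraction == fr, ,
                              drop = FALSE]
      if (!nrow(sel)) next
      set.seed(subseed())
      n_spike <- max(1L, rpois(1L, cfg$spike_n))
      sample_name <- paste(gsub("[^A-Za-z0-9-]", "", ab), fr, sep = "_")
      em <- emit_fastq(sel, read_length = cfg$read_length,
                       per_base_error = cfg$per_base_error,
                       spike_in = list(genome = spike_genome,
                                       n_reads = n_spike),
                       seed = subseed(), out_dir = fq_dir,
                       prefix = sample_name)
      samples[[length(samples) + 1L]] <- data.frame(
        sample = sample_name, antibody = ab, fraction = fr,
        r1 = em$r1, r2 = em$r2, truth = em$truth,
        n_pairs = em$n_pairs, n_spike_emitted = em$n_spike,
        stringsAsFactors = FALSE)
    }
  }
  sheet <- do.call(rbind, samples)
  # the written sheet uses paths relative to the run directory so that two
  # runs of one configuration are byte-identical wherever they land
  rel <- sheet
  for (col in c("r1", "r2", "truth"))
    rel[[col]] <- sub(paste0("^", normalizePath(out), "/?"), "",
                      normalizePath(rel[[col]]))
  write.table(rel, file.path(out, "samples.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  list(arrays = arrays, sheet = sheet, spike_genome = spike_genome)
}

# --- mapping helpers ------------------------------------------------------

# best hit of each fragment across several references: exact-match fast path
# on an N-spaced concatenation, then per-reference exhaustive Hamming scan
.map_to_arrays <- function(frags, refs, max_mismatch_frac = 0.1) {
  spacer <- strrep("N", 60L)
  concat <- paste(refs, collapse = spacer)
  offsets <- cumsum(c(0L, head(nchar(refs) + 60L, -1L)))
  names(offsets) <- names(refs)
  cdna <- Biostrings::DNAString(concat)
  ref_objs <- lapply(refs, .as_ref)
  rows <- vector("list", nrow(frags))
  for (k in seq_len(nrow(frags))) {
    frag <- toupper(frags$sequence[k])
    fdna <- Biostrings::DNAString(frag)
    nf <- nchar(frag)
    ex_p <- IRanges::start(Biostrings::matchPattern(fdna, cdna))
    ex_m <- IRanges::start(Biostrings::matchPattern(
      Biostrings::reverseComplement(fdna), cdna))
    if (length(ex_p) || length(ex_m)) {
      hit <- .pick_tie(ex_p, ex_m, 0L, "leftmost_plus")
      ai <- max(which(offsets <= hit$start0))
      local <- hit$start0 - offsets[ai]
      rows[[k]] <- data.frame(fragment_id = frags$fragment_id[k],
                              ref_name = names(refs)[ai],
                              start = as.integer(local),
                              end = as.integer(local + nf),
                              strand = hit$strand, n_mismatches = 0L,
                              stringsAsFactors = FALSE)
      next
    }
    best <- NULL
    for (ai in seq_along(refs)) {
      if (nf > ref_objs[[ai]]$len) next
      h <- .best_hit(frag, ref_objs[[ai]], max_mismatch_frac,
                     "leftmost_plus")
      if (!is.null(h) && (is.null(best) || h$mm < best$mm)) {
        best <- h
        best$ref <- names(refs)[ai]
      }
    }
    if (!is.null(best))
      rows[[k]] <- data.frame(fragment_id = frags$fragment_id[k],
                              ref_name = best$ref,
                              start = best$start0,
                              end = best$start0 + nf,
                              strand = best$strand, n_mismatches = best$mm,
                              stringsAsFactors = FALSE)
  }
  keep <- !vapply(rows, is.null, logical(1))
  df <- if (any(keep)) do.call(rbind, rows[keep])
        else data.frame(fragment_id = character(), ref_name = character(),
                        start = integer(), end = integer(),
                        strand = character(), n_mismatches = integer())
  rownames(df) <- NULL
  attr(df, "n_unmapped") <- sum(!keep)
  df
}

# --- run_pipeline ---------------------------------------------------------

#' Run the full simulate-merge-map-motifs-enrich-dimers pipeline
#'
#' Orchestrates one reproducible end-to-end run: synthetic arrays and reads
#' are generated (or reloaded when resuming), read pairs are merged into
#' fragments, fragments are mapped to the arrays, CENP-B boxes are scanned,
#' spike-in-calibrated enrichment / recovery / correlation tables are
#' computed, and per-dimer footprints are profiled and classified. All
#' tables are written as TSV, tracks as bedGraph, and every parameter and
#' output checksum is echoed into `manifest.json`. Given the same
#' configuration the TSV outputs are byte-identical.
#'
#' @param config A [sat_config()] (or plain named list of overrides).
#' @param out_dir Output directory, created if needed.
#' @return Invisible list with the main tables (`enrichment`,
#'   `correlations`, `recovery`, `dimers`, `sheet`, `motifs`) and
#'   `out_dir`.
#' @export
run_pipeline <- function(config = sat_config(), out_dir) {
  if (!inherits(config, "sat_config"))
    config <- do.call(sat_config, as.list(config))
  cfg <- config
  if (missing(out_dir)) stop("out_dir is required", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logcon <- file(file.path(out_dir, "run.log"), "w")
  on.exit(close(logcon), add = TRUE)

  set.seed(cfg$seed)
  pool <- sample.int(2147483646L, 4096L)
  counter <- new.env(parent = emptyenv()); counter$i <- 0L
  subseed <- function() {
    counter$i <- counter$i + 1L
    pool[counter$i]
  }

  t0 <- Sys.time()
  state_path <- file.path(out_dir, "state.rds")
  if (isTRUE(cfg$resume) && file.exists(state_path)) {
    .log(logcon, cfg$quiet, "simulate: resuming from existing outputs")
    sim <- readRDS(state_path)
  } else {
    .log(logcon, cfg$quiet, "simulate: generating arrays and reads")
    sim <- .stage_simulate(cfg, out_dir, subseed)
    saveRDS(sim, state_path)
  }
  arrays <- sim$arrays
  sheet <- sim$sheet
  .log(logcon, cfg$quiet, sprintf("simulate: %d samples, %d arrays (%.1fs)",
                                  nrow(sheet), length(arrays),
                                  as.numeric(Sys.time() - t0, units = "secs")))

  # ---- merge ----
  t0 <- Sys.time()
  merged_dir <- file.path(out_dir, "merged")
  dir.create(merged_dir, showWarnings = FALSE)
  per_sample <- list()
  for (si in seq_len(nrow(sheet))) {
    pr <- read_fastq_pairs(sheet$r1[si], sheet$r2[si])
    if (cfg$mode == "merged_250") {
      mg <- merge_pairs(pr, min_quality = cfg$min_quality,
                        min_length = cfg$min_length,
                        min_overlap = cfg$min_overlap)
    } else {
      # short-read mode: merging impossible; R1 end reads stand in as
      # mapping fragments and no fragment length is inferred
      mg <- data.frame(fragment_id = pr$id, sequence = pr$seq1,
                       length = NA_integer_, n_overlap = NA_integer_,
                       stringsAsFactors = FALSE)
      attr(mg, "n_pairs") <- length(pr$id)
      attr(mg, "n_merged") <- NA_integer_
    }
    spike <- grepl("^spike\\|", mg$fragment_id)
    per_sample[[sheet$sample[si]]] <- list(
      merged = mg[!spike, , drop = FALSE],
      spike_count = sum(spike))
    lt <- mg[!spike, c("fragment_id", "length", "n_overlap")]
    write.table(lt, file.path(merged_dir,
                              paste0(sheet$sample[si], "_lengths.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  .log(logcon, cfg$quiet, sprintf("merge: done (%.1fs)",
                                  as.numeric(Sys.time() - t0, units = "secs")))

  # ---- map ----
  t0 <- Sys.time()
  refs <- vapply(arrays, function(a) array_sequence(a$array), character(1))
  hits_dir <- file.path(out_dir, "hits")
  dir.create(hits_dir, showWarnings = FALSE)
  for (sn in names(per_sample)) {
    hits <- .map_to_arrays(per_sample[[sn]]$merged, refs,
                           cfg$max_mismatch_frac)
    per_sample[[sn]]$hits <- hits
    write.table(hits, file.path(hits_dir, paste0(sn, "_hits.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  .log(logcon, cfg$quiet, sprintf("map: done (%.1fs)",
                                  as.numeric(Sys.time() - t0, units = "secs")))

  # ---- motifs ----
  t0 <- Sys.time()
  motif_rows <- lapply(names(refs), function(an) {
    md <- motif_density(refs[[an]])
    data.frame(contig = an, n_hits = md$n_hits, best_score = md$best_score,
               density = md$density, length = md$length,
               stringsAsFactors = FALSE)
  })
  motifs <- do.call(rbind, motif_rows)
  write.table(motifs, file.path(out_dir, "motifs.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  .write_motif_bed(refs, file.path(out_dir, "motif_hits.bed"))
  .log(logcon, cfg$quiet, sprintf("motifs: done (%.1fs)",
                                  as.numeric(Sys.time() - t0, units = "secs")))

  # ---- enrich ----
  t0 <- Sys.time()
  enr <- .stage_enrich(cfg, sheet, per_sample, motifs, names(refs))
  write.table(enr$table, file.path(out_dir, "enrichment.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(enr$correlations, file.path(out_dir, "correlations.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(enr$recovery, file.path(out_dir, "recovery.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  .log(logcon, cfg$quiet, sprintf("enrich: done (%.1fs)",
                                  as.numeric(Sys.time() - t0, units = "secs")))

  # ---- dimers ----
  t0 <- Sys.time()
  dimers <- .stage_dimers(cfg, arrays, per_sample, sheet, out_dir)
  .log(logcon, cfg$quiet, sprintf("dimers: done (%.1fs)",
                                  as.numeric(Sys.time() - t0, units = "secs")))

  manifest <- list(
    package = "satfrag",
    version = as.character(packageVersion("satfrag")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    parameters = .manifest_params(cfg),
    inputs = list(arrays_fasta = unname(tools::md5sum(
      file.path(out_dir, "arrays.fasta")))),
    outputs = .md5_outputs(out_dir))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  .log(logcon, cfg$quiet, "pipeline complete")
  invisible(list(enrichment = enr$table, correlations = enr$correlations,
                 recovery = enr$recovery, dimers = dimers, sheet = sheet,
                 motifs = motifs, out_dir = out_dir))
}

.manifest_params <- function(cfg) {
  p <- unclass(cfg)
  p$link <- paste(deparse(p$link), collapse = " ")
  p$fragment_model <- unclass(p$fragment_model)
  p
}

.md5_outputs <- function(out) {
  files <- sort(c(list.files(out, pattern = "\\.(tsv|bed|bedgraph|fasta)$",
                             full.names = TRUE, recursive = TRUE)))
  md5 <- tools::md5sum(files)
  names(md5) <- sub(paste0("^", out, "/?"), "", files)
  as.list(md5)
}

.write_motif_bed <- function(refs, path) {
  tabs <- lapply(names(refs), function(an) {
    h <- scan_motifs(refs[[an]])
    if (!nrow(h)) return(NULL)
    cbind(contig = an, h)
  })
  tabs <- do.call(rbind, tabs)
  if (is.null(tabs) || !nrow(tabs)) return(invisible(path))
  gr <- GenomicRanges::GRanges(
    tabs$contig, IRanges::IRanges(tabs$start + 1L, tabs$start + 15L),
    strand = tabs$strand, score = tabs$score)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

.stage_enrich <- function(cfg, sheet, per_sample, motifs, contigs) {
  # per-sample calibrated per-contig counts
  count_tab <- list()
  for (si in seq_len(nrow(sheet))) {
    sn <- sheet$sample[si]
    ps <- per_sample[[sn]]
    raw <- table(factor(ps$hits$ref_name, levels = contigs))
    cal <- calibrate_counts(as.numeric(raw), max(1L, ps$spike_count),
                            cfg$scale_const)
    count_tab[[sn]] <- data.frame(
      contig = contigs, antibody = sheet$antibody[si],
      fraction = sheet$fraction[si], raw_count = as.integer(raw),
      spike_count = ps$spike_count, calibrated = cal,
      stringsAsFactors = FALSE)
  }
  counts <- do.call(rbind, count_tab)
  rownames(counts) <- NULL

  igg <- counts[counts$antibody == cfg$igg_name, ]
  spec <- counts[counts$antibody != cfg$igg_name, ]
  key <- function(d) paste(d$contig, d$fraction)
  igg_cal <- setNames(igg$calibrated, key(igg))
  spec$fold_enrichment <- fold_enrichment(
    spec$calibrated, igg_cal[key(spec)], cfg$pseudocount)
  spec$best_score <- motifs$best_score[match(spec$contig, motifs$contig)]
  spec$density <- motifs$density[match(spec$contig, motifs$contig)]

  cor_rows <- list()
  for (ab in unique(spec$antibody)) for (fr in unique(spec$fraction)) {
    sub <- spec[spec$antibody == ab & spec$fraction == fr, ]
    for (xv in c("best_score", "density")) {
      r <- tryCatch(correlate_motif_enrichment(sub, x = xv)$r,
                    error = function(e) NA_real_)
      cor_rows[[length(cor_rows) + 1L]] <- data.frame(
        antibody = ab, fraction = fr, x = xv, r = r, n = nrow(sub))
    }
  }

  rec_rows <- list()
  for (ab in unique(counts$antibody)) {
    sub <- counts[counts$antibody == ab, ]
    tot <- tapply(sub$calibrated, factor(sub$fraction,
                                         levels = SALT_FRACTIONS), sum,
                  default = 0)
    tot[is.na(tot)] <- 0
    pct <- percent_recovery(tot)
    rec_rows[[length(rec_rows) + 1L]] <- data.frame(
      antibody = ab, fraction = SALT_FRACTIONS,
      percent = as.numeric(pct), stringsAsFactors = FALSE)
  }

  list(table = spec,
       correlations = do.call(rbind, cor_rows),
       recovery = do.call(rbind, rec_rows))
}

.stage_dimers <- function(cfg, arrays, per_sample, sheet, out_dir) {
  sn <- paste(gsub("[^A-Za-z0-9-]", "", cfg$dimers_antibody),
              cfg$dimers_fraction, sep = "_")
  if (!sn %in% names(per_sample)) return(NULL)
  ps <- per_sample[[sn]]
  cal <- cfg$scale_const / max(1L, ps$spike_count)
  dim_dir <- file.path(out_dir, "dimers")
  trk_dir <- file.path(out_dir, "tracks")
  dir.create(dim_dir, showWarnings = FALSE)
  dir.create(trk_dir, showWarnings = FALSE)
  out_rows <- list()
  for (an in names(arrays)) {
    arr <- arrays[[an]]$array
    hits <- ps$hits[ps$hits$ref_name == an, , drop = FALSE]
    ref <- array_sequence(arr)
    track <- build_track(hits, ref, calibration_factor = cal, ref_name = an)
    write_bedgraph(track, file.path(trk_dir, paste0(an, "_", sn,
                                                    ".bedgraph")))
    prof <- per_dimer_occupancy(track, unit_intervals(arr), box_starts(arr))
    prof <- classify_dimers(prof, cfg$centered_tol, cfg$symmetry_ratio)
    prof$contig <- an
    prof$truth_occupancy <- arr$truth_occupancy
    out_rows[[an]] <- prof

    # folded middle-dimer profile on the triplicated founder consensus
    frs <- ps$merged[ps$merged$fragment_id %in% hits$fragment_id, ,
                     drop = FALSE]
    if (nrow(frs)) {
      tri <- triplicate_consensus(arrays[[an]]$founder)
      th <- align_fragments(frs, tri, cfg$max_mismatch_frac,
                            ref_name = paste0(an, "_tri3"))
      if (nrow(th)) {
        folded <- fold_to_middle_dimer(th, arr$period) * cal
        write_bedgraph(folded,
                       file.path(trk_dir, paste0(an, "_", sn,
                                                 "_folded.bedgraph")),
                       ref_name = paste0(an, "_dimer"))
      }
    }
  }
  dimers <- do.call(rbind, out_rows)
  rownames(dimers) <- NULL
  write.table(dimers, file.path(dim_dir, paste0(sn, "_profiles.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  dimers
}

#' Generate the packaged test/walkthrough fixture set
#'
#' Runs the simulation stage only, at a fixed small scale: two arrays (one
#' 340-bp and one 342-bp period, low and moderate divergence), two specific
#' antibodies plus IgG, four salt fractions each, roughly 20k read pairs in
#' total. Writes FASTQ pairs, truth TSVs, array/founder FASTA, the synthetic
#' spike-in genome and a sample sheet, plus a checksum manifest.
#'
#' @param out_dir Output directory.
#' @param seed Integer seed.
#' @return Invisible sample-sheet data.frame (attribute `out_dir`).
#' @export
make_fixtures <- function(out_dir, seed = 1L) {
  cfg <- sat_config(seed = seed, n_arrays = 2L, units_per_array = 10L,
                    periods = c(340L, 342L),
                    founder_divergence = c(0.02, 0.10),
                    array_divergence = 0.02,
                    antibodies = c("CENP-A", "CENP-B"),
                    n_fragments_per_antibody = 7000L,
                    igg_fragments = 5000L, spike_n = 400L)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  pool <- sample.int(2147483646L, 4096L)
  counter <- new.env(parent = emptyenv()); counter$i <- 0L
  subseed <- function() {
    counter$i <- counter$i + 1L
    pool[counter$i]
  }
  sim <- .stage_simulate(cfg, out_dir, subseed)
  manifest <- list(package = "satfrag",
                   version = as.character(packageVersion("satfrag")),
                   seed = seed,
                   outputs = .md5_outputs(out_dir))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  attr(sim$sheet, "out_dir") <- out_dir
  invisible(sim$sheet)
}
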