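#' Fragment-length model for CCAN-protected particles
#'
#' A three-regime Gaussian mixture for the lengths of antibody-released,
#' nuclease-protected fragments: subnucleosomal (~100 bp, nibbled or partial
#' particles), nucleosomal/CCAN (~160-185 bp major peak) and dimer-spanning
#' (~340 bp minor peak, one full repeat unit). Lengths are truncated to
#' [25, 500] bp, matching the merge filter's minimum and the observed
#' ~100-450 bp fragment range.
#'
#' @param regime_weights Named probabilities over
#'   `c(subnucleosomal, nucleosomal, dimeric)`; must sum to 1.
#' @param means,sds Per-regime Gaussian mean and sd in nt. The dimeric mean
#'   equals the dimer period by default.
#' @return Object of class `fragment_model`.
#' @export
fragment_model <- function(regime_weights = c(subnucleosomal = 0.15,
                                              nucleosomal = 0.60,
                                              dimeric = 0.25),
                           means = c(100, 172, 340),
                           sds = c(15, 12, 15)) {
  if (length(regime_weights) != 3L || any(regime_weights < 0))
    stop("regime_weights must be 3 non-negative values", call. = FALSE)
  if (abs(sum(regime_weights) - 1) > 1e-9)
    stop("regime_weights must sum to 1", call. = FALSE)
  if (length(means) != 3L || any(means <= 0)) stop("means must be positive")
  if (length(sds) != 3L || any(sds < 0)) stop("sds must be non-negative")
  structure(list(regime_weights = regime_weights, means = means, sds = sds,
                 range = c(25L, 500L)),
            class = "fragment_model")
}

#' @export
print.fragment_model <- function(x, ...) {
  cat("<fragment_model> weights", paste(x$regime_weights, collapse = "/"),
      "means", paste(x$means, collapse = "/"), "nt\n")
  invisible(x)
}

# truncated draw: resample until inside [lo, hi]
.rnorm_trunc <- function(n, mean, sd, lo, hi) {
  x <- rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad)) {
    x[bad] <- rnorm(length(bad), mean[bad], sd[bad])
    bad <- bad[x[bad] < lo | x[bad] > hi]
  }
  x
}

#' Simulate CCAN-protected fragments from an occupied array
#'
#' Draws fragments whose per-unit counts are proportional to the array's
#' ground-truth occupancy. Each fragment is centred on its unit (at
#' `center` nt into the unit, default the unit midpoint) with Gaussian
#' positional jitter, its length is drawn from the `fragment_model` mixture
#' truncated to [25, 500] nt, and its salt-fraction label is drawn from the
#' unit's truth weights.
#'
#' @param array A `satellite_array` with truth occupancy assigned.
#' @param model A [fragment_model()].
#' @param n_fragments Number of fragments (>= 1).
#' @param seed Integer seed.
#' @param jitter_sd Positional jitter sd in nt around the footprint centre.
#' @param center Footprint centre in unit-local nt, recycled over units.
#'   Default `period / 2` (symmetric dimer-centred footprint); e.g.
#'   `period / 4` places footprints on monomer A.
#' @return data.frame with `fragment_id`, `unit_index` (1-based),
#'   `fraction`, `start` (0-based array coordinate), `length`, `sequence`.
#' @export
simulate_fragments <- function(array, model = fragment_model(), n_fragments,
                               seed = 1L, jitter_sd = 20, center = NULL) {
  stopifnot(inherits(array, "satellite_array"),
            inherits(model, "fragment_model"))
  occ <- array$truth_occupancy
  if (is.null(occ) || all(occ == 0))
    stop("array has no positive truth occupancy; run assign_truth_occupancy",
         call. = FALSE)
  n_fragments <- as.integer(n_fragments)
  if (is.na(n_fragments) || n_fragments < 1L) stop("n_fragments must be >= 1")
  set.seed(seed)
  p <- array$period
  total_len <- p * array$n_units
  if (is.null(center)) center <- p / 2
  center <- rep_len(center, array$n_units)

  counts <- as.vector(rmultinom(1L, n_fragments, occ))
  u <- rep.int(seq_len(array$n_units), counts)
  u <- u[sample.int(length(u))]

  regime <- sample.int(3L, n_fragments, replace = TRUE,
                       prob = model$regime_weights)
  len <- round(.rnorm_trunc(n_fragments, model$means[regime],
                            model$sds[regime],
                            model$range[1], model$range[2]))
  mid <- (u - 1L) * p + center[u] + rnorm(n_fragments, 0, jitter_sd)
  start <- round(mid - len / 2)
  start <- pmax(0L, pmin(start, total_len - len))

  w <- array$truth_fraction_weights
  if (is.null(w))
    w <- matrix(0.25, array$n_units, 4L,
                dimnames = list(NULL, SALT_FRACTIONS))
  wcum <- t(apply(w, 1L, cumsum))
  fr_idx <- rowSums(runif(n_fragments) > wcum[u, , drop = FALSE]) + 1L
  fraction <- SALT_FRACTIONS[fr_idx]

  full <- array_sequence(array)
  data.frame(fragment_id = sprintf("%s_frag_%06d", array$name,
                                   seq_len(n_fragments)),
             unit_index = u, fraction = fraction,
             start = as.integer(start), length = as.integer(len),
             sequence = substring(full, start + 1L, start + len),
             stringsAsFactors = FALSE)
}

# substitution errors at rate e; errored bases get quality 11, others 37
.apply_read_errors <- function(seqs, per_base_error) {
  widths <- nchar(seqs)
  quals <- vapply(widths, function(w) strrep(rawToChar(as.raw(37L + 33L)), w),
                  character(1))
  if (per_base_error > 0) {
    n_err <- rbinom(length(seqs), widths, per_base_error)
    for (i in which(n_err > 0L)) {
      pos <- sample.int(widths[i], n_err[i])
      ch <- strsplit(seqs[i], "")[[1]]
      for (p2 in pos) {
        alt <- setdiff(c("A", "C", "G", "T"), ch[p2])
        ch[p2] <- alt[sample.int(3L, 1L)]
      }
      seqs[i] <- paste(ch, collapse = "")
      q <- strsplit(quals[i], "")[[1]]
      q[pos] <- rawToChar(as.raw(11L + 33L))
      quals[i] <- paste(q, collapse = "")
    }
  }
  list(seq = seqs, qual = quals)
}

.write_fastq <- function(seqs, quals, ids, path) {
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(seqs),
    Biostrings::PhredQuality(quals))
  names(x) <- ids
  Biostrings::writeQualityScaledXStringSet(x, path)
}

#' Emit paired-end FASTQ reads (plus spike-in) from simulated fragments
#'
#' R1 is the first `read_length` nt of each fragment and R2 the reverse
#' complement of the last `read_length` nt; reads are truncated at the
#' fragment end, so a 340-nt fragment read at 2 x 250 bp yields mates that
#' overlap by 160 nt. Base qualities are Phred 37, lowered to 11 at
#' substitution errors. Spike-in read pairs drawn from an exogenous genome
#' are appended with `spike|`-prefixed names so calibration can count them.
#'
#' @param fragments data.frame from [simulate_fragments()] (columns
#'   `fragment_id`, `unit_index`, `fraction`, `start`, `length`, `sequence`).
#' @param read_length Read length in nt (>= 20); 250 and 25 mirror the two
#'   sequencing modes.
#' @param per_base_error Per-base substitution error probability.
#' @param spike_in Optional `list(genome = <DNA string>, n_reads = <int>)`.
#' @param seed Integer seed.
#' @param out_dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Invisible list with paths `r1`, `r2`, `truth` and counts
#'   `n_pairs` (fragment pairs) and `n_spike`.
#' @export
emit_fastq <- function(fragments, read_length = 250L, per_base_error = 0.001,
                       spike_in = NULL, seed = 1L, out_dir = ".",
                       prefix = "sample") {
  read_length <- as.integer(read_length)
  if (is.na(read_length) || read_length < 20L)
    stop("read_length must be >= 20", call. = FALSE)
  stopifnot(is.data.frame(fragments), nrow(fragments) >= 1L)
  set.seed(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  seqs <- fragments$sequence
  lens <- nchar(seqs)
  ids <- fragments$fragment_id
  r1 <- substr(seqs, 1L, pmin(read_length, lens))
  r2 <- revcomp(substr(seqs, pmax(1L, lens - read_length + 1L), lens))

  n_spike <- 0L
  if (!is.null(spike_in)) {
    g <- .check_dna(spike_in$genome, "spike_in genome")
    n_spike <- as.integer(spike_in$n_reads)
    glen <- nchar(g)
    slen <- pmin(pmax(round(rnorm(n_spike, 167, 20)), 50L), min(300L, glen))
    sstart <- floor(runif(n_spike) * (glen - slen)) + 1L
    sseq <- substring(g, sstart, sstart + slen - 1L)
    sid <- sprintf("spike|read_%06d", seq_len(n_spike))
    r1 <- c(r1, substr(sseq, 1L, pmin(read_length, slen)))
    r2 <- c(r2, revcomp(substr(sseq, pmax(1L, slen - read_length + 1L), slen)))
    ids <- c(ids, sid)
  }

  e1 <- .apply_read_errors(r1, per_base_error)
  e2 <- .apply_read_errors(r2, per_base_error)

  paths <- list(r1 = file.path(out_dir, paste0(prefix, "_R1.fastq")),
                r2 = file.path(out_dir, paste0(prefix, "_R2.fastq")),
                truth = file.path(out_dir, paste0(prefix, "_truth.tsv")))
  .write_fastq(e1$seq, e1$qual, ids, paths$r1)
  .write_fastq(e2$seq, e2$qual, ids, paths$r2)
  truth <- fragments[, c("fragment_id", "unit_index", "fraction", "length",
                         "start")]
  write.table(truth, paths$truth, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(paths, list(n_pairs = nrow(fragments), n_spike = n_spike)))
}

#' Read a pair of FASTQ files into aligned character vectors
#'
#' @param r1,r2 FASTQ file paths (mates in the same order).
#' @return List with `id`, `seq1`, `qual1`, `seq2`, `qual2`.
#' @export
read_fastq_pairs <- function(r1, r2) {
  # Biostrings warns about dropping (empty) mcols when re-wrapping the reads
  x1 <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(r1))
  x2 <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(r2))
  if (length(x1) != length(x2))
    stop("R1 and R2 have different read counts", call. = FALSE)
  list(id = sub("[/ ].*$", "", names(x1)),
       seq1 = as.character(x1), qual1 = as.character(Biostrings::quality(x1)),
       seq2 = as.character(x2), qual2 = as.character(Biostrings::quality(x2)))
}
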