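#' Triplicate a dimer unit into an edge-free mapping reference
#'
#' Concatenates a repeat unit three times head-to-tail. Mapping to the
#' triplicated consensus and then folding coordinates onto one period (the
#' "middle dimer") lets fragments up to a full period long align without
#' running off the reference end, avoiding tandem-repeat edge effects.
#'
#' @param unit A `dimer_unit` (or a bare DNA string).
#' @return Character string of length `3 * period`.
#' @export
triplicate_consensus <- function(unit) {
  s <- if (inherits(unit, "dimer_unit")) unit$sequence
       else .check_dna(unit, "unit")
  strrep(s, 3L)
}

#' Exhaustive end-to-end ungapped alignment of one fragment
#'
#' Scans every start position on both strands of the reference, counting
#' mismatches (Hamming distance; no indels, no clipping — the hit span
#' always equals the fragment span). The best hit is the one with fewest
#' mismatches; ties are broken deterministically (leftmost start, then
#' `+` strand). Hits worse than `max_mismatch_frac * length` are rejected.
#'
#' @param fragment Fragment DNA string.
#' @param reference Reference DNA string (at least as long as the fragment).
#' @param max_mismatch_frac Maximum tolerated mismatch fraction.
#' @param tie_break `"leftmost_plus"` (default) or `"rightmost_minus"`;
#'   the alternative exists to let callers verify that folded profiles do
#'   not depend on how ties between tandem copies are resolved.
#' @param ref_name,fragment_id Labels copied into the hit.
#' @return One-row data.frame (`fragment_id`, `ref_name`, `start`, `end`
#'   0-based half-open, `strand`, `n_mismatches`), or `NULL` if unmapped.
#' @export
align_end_to_end <- function(fragment, reference, max_mismatch_frac = 0.1,
                             tie_break = c("leftmost_plus", "rightmost_minus"),
                             ref_name = "ref", fragment_id = NA_character_) {
  tie_break <- match.arg(tie_break)
  fragment <- toupper(fragment)
  ref <- .as_ref(reference)
  nf <- nchar(fragment)
  if (nf > ref$len)
    stop("fragment longer than reference", call. = FALSE)
  hit <- .best_hit(fragment, ref, max_mismatch_frac, tie_break)
  if (is.null(hit)) return(NULL)
  data.frame(fragment_id = fragment_id, ref_name = ref_name,
             start = hit$start0, end = hit$start0 + nf,
             strand = hit$strand, n_mismatches = hit$mm,
             stringsAsFactors = FALSE)
}

# precompute DNAString form of a reference once per batch
.as_ref <- function(reference) {
  if (is.list(reference) && !is.null(reference$dna)) return(reference)
  s <- toupper(reference)
  list(seq = s, dna = Biostrings::DNAString(s), len = nchar(s))
}

# best ungapped hit of one fragment; exact-match fast path, else full
# Hamming scan over all start positions on both strands
.best_hit <- function(fragment, ref, max_mismatch_frac, tie_break) {
  nf <- nchar(fragment)
  fdna <- Biostrings::DNAString(fragment)
  rdna <- Biostrings::reverseComplement(fdna)
  ex_p <- IRanges::start(Biostrings::matchPattern(fdna, ref$dna))
  ex_m <- IRanges::start(Biostrings::matchPattern(rdna, ref$dna))
  if (length(ex_p) || length(ex_m))
    return(.pick_tie(ex_p, ex_m, 0L, tie_break))
  allowed <- max_mismatch_frac * nf
  st <- seq_len(ref$len - nf + 1L)
  d_p <- Biostrings::neditStartingAt(fdna, ref$dna, starting.at = st,
                                     with.indels = FALSE)
  d_m <- Biostrings::neditStartingAt(rdna, ref$dna, starting.at = st,
                                     with.indels = FALSE)
  best <- min(d_p, d_m)
  if (best > allowed) return(NULL)
  .pick_tie(st[d_p == best], st[d_m == best], best, tie_break)
}

.pick_tie <- function(starts_plus, starts_minus, mm, tie_break) {
  if (tie_break == "leftmost_plus") {
    s <- min(c(starts_plus, starts_minus))
    strand <- if (s %in% starts_plus) "+" else "-"
  } else {
    s <- max(c(starts_plus, starts_minus))
    strand <- if (s %in% starts_minus) "-" else "+"
  }
  list(start0 = s - 1L, strand = strand, mm = as.integer(mm))
}

#' Map a batch of fragments to one reference
#'
#' @param fragments data.frame with `fragment_id` and `sequence` columns
#'   (e.g. merged fragments), or a (optionally named) character vector.
#' @inheritParams align_end_to_end
#' @return data.frame of hits (unmapped fragments dropped; their count is
#'   in attribute `n_unmapped`).
#' @export
align_fragments <- function(fragments, reference, max_mismatch_frac = 0.1,
                            tie_break = c("leftmost_plus", "rightmost_minus"),
                            ref_name = "ref") {
  tie_break <- match.arg(tie_break)
  if (is.data.frame(fragments)) {
    seqs <- fragments$sequence
    ids <- fragments$fragment_id
  } else {
    seqs <- as.character(fragments)
    ids <- if (!is.null(names(seqs))) names(seqs)
           else sprintf("frag_%06d", seq_along(seqs))
  }
  ref <- .as_ref(reference)
  rows <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    frag <- toupper(seqs[i])
    if (nchar(frag) > ref$len) next
    hit <- .best_hit(frag, ref, max_mismatch_frac, tie_break)
    if (is.null(hit)) next
    rows[[i]] <- data.frame(fragment_id = ids[i], ref_name = ref_name,
                            start = hit$start0,
                            end = hit$start0 + nchar(frag),
                            strand = hit$strand, n_mismatches = hit$mm,
                            stringsAsFactors = FALSE)
  }
  keep <- !vapply(rows, is.null, logical(1))
  df <- if (any(keep)) do.call(rbind, rows[keep])
        else data.frame(fragment_id = character(), ref_name = character(),
                        start = integer(), end = integer(),
                        strand = character(), n_mismatches = integer(),
                        stringsAsFactors = FALSE)
  attr(df, "n_unmapped") <- sum(!keep)
  df
}

# per-base coverage (numeric, length ref_len) from 0-based half-open hits
.coverage_from_hits <- function(hits, ref_len) {
  delta <- numeric(ref_len + 1L)
  if (nrow(hits)) {
    if (any(hits$start < 0L) || any(hits$end > ref_len))
      stop("hit coordinates outside reference bounds", call. = FALSE)
    add <- tabulate(hits$start + 1L, nbins = ref_len + 1L)
    sub <- tabulate(hits$end + 1L, nbins = ref_len + 1L)
    delta <- add - sub
  }
  cumsum(delta)[seq_len(ref_len)]
}

#' Fold triplicated-reference coverage onto one period (the middle dimer)
#'
#' Every covered base at position `p` of a triplicated reference contributes
#' to position `p mod period` of the folded profile, so the three tandem
#' copies are averaged into a single edge-free per-period occupancy profile.
#' Total coverage mass is conserved exactly.
#'
#' @param hits data.frame of hits against a `3 * period` reference.
#' @param period Repeat period in nt.
#' @return Numeric vector of length `period`.
#' @export
fold_to_middle_dimer <- function(hits, period) {
  period <- as.integer(period)
  cov <- .coverage_from_hits(hits, 3L * period)
  cov[seq_len(period)] + cov[seq_len(period) + period] +
    cov[seq_len(period) + 2L * period]
}

#' Build a calibrated per-base occupancy track
#'
#' @param hits data.frame of hits from [align_fragments()].
#' @param reference Reference DNA string the hits were made against.
#' @param calibration_factor Positive multiplier (spike-in scale) applied to
#'   raw depth.
#' @param ref_name Track name; defaults to the hits' `ref_name`.
#' @return Object of class `occupancy_track`: list with `ref_name`,
#'   `coverage` (numeric per base), `n_fragments`, `calibration_factor`.
#' @export
build_track <- function(hits, reference, calibration_factor = 1,
                        ref_name = NULL) {
  if (!is.numeric(calibration_factor) || calibration_factor <= 0)
    stop("calibration_factor must be > 0", call. = FALSE)
  ref <- .as_ref(reference)
  if (is.null(ref_name))
    ref_name <- if (nrow(hits)) hits$ref_name[1L] else "ref"
  structure(list(ref_name = ref_name,
                 coverage = .coverage_from_hits(hits, ref$len) *
                   calibration_factor,
                 n_fragments = nrow(hits),
                 calibration_factor = calibration_factor),
            class = "occupancy_track")
}

#' @export
print.occupancy_track <- function(x, ...) {
  cat("<occupancy_track> '", x$ref_name, "': ", length(x$coverage),
      " bp, ", x$n_fragments, " fragments, calibration ",
      format(x$calibration_factor), ", mean depth ",
      format(round(mean(x$coverage), 3)), "\n", sep = "")
  invisible(x)
}

#' @export
plot.occupancy_track <- function(x, ...) {
  plot(seq_along(x$coverage) - 1L, x$coverage, type = "l",
       xlab = paste0(x$ref_name, " position (bp)"),
       ylab = "calibrated depth", ...)
  invisible(x)
}

#' Export a track (or folded profile) as bedGraph
#'
#' @param track An `occupancy_track`, or a bare numeric coverage vector.
#' @param path Output file path.
#' @param ref_name Sequence name when `track` is a bare vector.
#' @return Invisibly, `path`.
#' @export
write_bedgraph <- function(track, path, ref_name = "ref") {
  if (inherits(track, "occupancy_track")) {
    cov <- track$coverage
    ref_name <- track$ref_name
  } else {
    cov <- as.numeric(track)
  }
  r <- S4Vectors::Rle(cov)
  rl <- S4Vectors::runLength(r)
  ends <- cumsum(rl)
  gr <- GenomicRanges::GRanges(
    seqnames = ref_name,
    ranges = IRanges::IRanges(start = ends - rl + 1L, end = ends),
    score = S4Vectors::runValue(r))
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}
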