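#' CENP-B box motif score
#'
#' Degree of identity of a 15-nt site to the ancestral CENP-B box core:
#' 15/15 matches scores 1, each mismatch subtracts 0.25, and more than three
#' mismatches scores 0, giving the four-point scale
#' \{0 mm: 1, 1: 0.75, 2: 0.5, 3: 0.25, >=4: 0\}.
#'
#' @param site 15-nt DNA string (ACGT only).
#' @param motif 15-nt reference motif (default [CENPB_BOX]).
#' @return Score in `[0, 1]`.
#' @examples
#' motif_score(CENPB_BOX)            # 1
#' motif_score("TTCGTTGGAAACGGA")    # 0.75
#' @export
motif_score <- function(site, motif = CENPB_BOX) {
  site <- .check_dna(site, "site")
  motif <- .check_dna(motif, "motif")
  if (nchar(site) != 15L || nchar(motif) != 15L)
    stop("site and motif must both be 15 nt", call. = FALSE)
  mm <- sum(utf8ToInt(site) != utf8ToInt(motif))
  max(0, 1 - 0.25 * mm)
}

#' Scan a sequence for CENP-B box occurrences
#'
#' Reports every 15-nt window on either strand within `max_mismatches` of
#' the motif — exactly the set of sites with nonzero motif score at the
#' default cutoff of 3. Overlapping hits on the same strand are collapsed to
#' the best-scoring one (leftmost on ties). The scan is case-insensitive.
#'
#' @param sequence DNA string (>= 15 nt).
#' @param motif 15-nt motif (default [CENPB_BOX]).
#' @param max_mismatches Maximum mismatches for a reported hit (default 3).
#' @return data.frame of hits sorted by `start` (0-based): `start`,
#'   `strand`, `n_mismatches`, `score`. Zero rows when nothing is found.
#' @export
scan_motifs <- function(sequence, motif = CENPB_BOX, max_mismatches = 3L) {
  sequence <- .check_dna(sequence, "sequence")
  motif <- .check_dna(motif, "motif")
  w <- nchar(motif)
  if (nchar(sequence) < w)
    stop("sequence shorter than the motif", call. = FALSE)
  subj <- Biostrings::DNAString(sequence)
  st <- seq_len(nchar(sequence) - w + 1L)
  mdna <- Biostrings::DNAString(motif)
  d_p <- Biostrings::neditStartingAt(mdna, subj, starting.at = st,
                                     with.indels = FALSE)
  d_m <- Biostrings::neditStartingAt(Biostrings::reverseComplement(mdna),
                                     subj, starting.at = st,
                                     with.indels = FALSE)
  hits <- rbind(
    .collapse_hits(st[d_p <= max_mismatches] - 1L,
                   d_p[d_p <= max_mismatches], "+", w),
    .collapse_hits(st[d_m <= max_mismatches] - 1L,
                   d_m[d_m <= max_mismatches], "-", w))
  hits <- hits[order(hits$start, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits$score <- pmax(0, 1 - 0.25 * hits$n_mismatches)
  hits
}

# greedy same-strand collapse: cluster mutually overlapping windows, keep
# the fewest-mismatch hit per cluster (leftmost on ties)
.collapse_hits <- function(starts0, mm, strand, w) {
  empty <- data.frame(start = integer(), strand = character(),
                      n_mismatches = integer(), stringsAsFactors = FALSE)
  if (!length(starts0)) return(empty)
  o <- order(starts0)
  starts0 <- starts0[o]; mm <- mm[o]
  cluster <- cumsum(c(1L, diff(starts0) >= w))
  keep <- vapply(split(seq_along(starts0), cluster), function(idx) {
    idx[which.min(mm[idx])]
  }, integer(1))
  data.frame(start = starts0[keep], strand = strand,
             n_mismatches = as.integer(mm[keep]), stringsAsFactors = FALSE)
}

#' CENP-B box density and best score of a sequence
#'
#' @inheritParams scan_motifs
#' @return List of class `motif_summary`: `n_hits`, `best_score`,
#'   `density` (collapsed hits per kb of sequence), `length`, and the hit
#'   table in `hits`.
#' @export
motif_density <- function(sequence, motif = CENPB_BOX, max_mismatches = 3L) {
  sequence <- .check_dna(sequence, "sequence")
  hits <- if (nchar(sequence) >= nchar(motif))
    scan_motifs(sequence, motif, max_mismatches)
  else
    data.frame(start = integer(), strand = character(),
               n_mismatches = integer(), score = numeric())
  structure(list(n_hits = nrow(hits),
                 best_score = if (nrow(hits)) max(hits$score) else 0,
                 density = nrow(hits) / (nchar(sequence) / 1000),
                 length = nchar(sequence),
                 hits = hits),
            class = "motif_summary")
}

#' @export
print.motif_summary <- function(x, ...) {
  cat("<motif_summary> ", x$n_hits, " hits in ", x$length, " nt; density ",
      format(round(x$density, 3)), "/kb; best score ",
      format(x$best_score), "\n", sep = "")
  invisible(x)
}
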