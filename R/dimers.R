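#' Per-dimer occupancy statistics from a coverage track
#'
#' Summarises a calibrated occupancy track over each repeat unit: mean
#' coverage over the unit and over each monomer half, and the signed offset
#' of the coverage centroid from the unit's CENP-B box start (in array
#' coordinates; negative = upstream of the box).
#'
#' @param track An `occupancy_track` (or bare numeric coverage vector).
#' @param units data.frame of 0-based half-open `start`/`end` unit intervals
#'   (e.g. [unit_intervals()]); must tile the track without exceeding its
#'   bounds.
#' @param box_starts Optional integer vector of 0-based box start positions,
#'   one per unit; required for `centroid_offset`.
#' @return data.frame of class `dimer_profiles`: `unit_index`, `occupancy`,
#'   `monomer_a_occ`, `monomer_b_occ`, `centroid_offset` (NA when the unit
#'   has no coverage or no box position was given).
#' @export
per_dimer_occupancy <- function(track, units, box_starts = NULL) {
  cov <- if (inherits(track, "occupancy_track")) track$coverage
         else as.numeric(track)
  stopifnot(is.data.frame(units), all(c("start", "end") %in% names(units)))
  if (any(units$start < 0L) || any(units$end > length(cov)))
    stop("unit intervals exceed track bounds", call. = FALSE)
  n <- nrow(units)
  if (!is.null(box_starts) && length(box_starts) != n)
    stop("box_starts must have one entry per unit", call. = FALSE)
  out <- data.frame(unit_index = if ("unit_index" %in% names(units))
                      units$unit_index else seq_len(n),
                    occupancy = NA_real_, monomer_a_occ = NA_real_,
                    monomer_b_occ = NA_real_, centroid_offset = NA_real_)
  for (i in seq_len(n)) {
    s <- units$start[i]; e <- units$end[i]
    v <- cov[(s + 1L):e]
    half <- (e - s) %/% 2L
    out$occupancy[i] <- mean(v)
    out$monomer_a_occ[i] <- mean(v[seq_len(half)])
    out$monomer_b_occ[i] <- mean(v[(half + 1L):(e - s)])
    if (!is.null(box_starts) && sum(v) > 0) {
      pos <- s:(e - 1L)               # 0-based base positions
      out$centroid_offset[i] <- sum(pos * v) / sum(v) - box_starts[i]
    }
  }
  class(out) <- c("dimer_profiles", "data.frame")
  out
}

#' Fold range of per-dimer occupancy within an array
#'
#' Ratio of the highest to the lowest per-unit occupancy. Zero-occupancy
#' units receive the pseudocount so the ratio stays finite.
#'
#' @param profiles A `dimer_profiles` data.frame (column `occupancy`) or a
#'   bare numeric vector of per-unit occupancies.
#' @param pseudocount Value substituted for zero occupancies.
#' @return `max / min` over units.
#' @export
occupancy_fold_range <- function(profiles, pseudocount = 1) {
  occ <- if (is.data.frame(profiles)) profiles$occupancy
         else as.numeric(profiles)
  if (length(occ) < 2L) stop("need at least 2 units", call. = FALSE)
  if (all(occ == 0)) stop("all units have zero occupancy", call. = FALSE)
  occ[occ == 0] <- pseudocount
  max(occ) / min(occ)
}

#' Classify dimer footprints by orientation and symmetry
#'
#' Labels each unit's footprint relative to its CENP-B box: `centered` when
#' the coverage centroid lies within `centered_tol` nt of the box start,
#' otherwise `upstream`/`downstream` by the sign of the offset; and
#' `symmetric` when the two monomer halves carry comparable coverage (ratio
#' below `symmetry_ratio`), otherwise `asymmetric_a`/`asymmetric_b` toward
#' the heavier monomer. Both labels are scale-invariant: multiplying the
#' track by any positive constant leaves them unchanged.
#'
#' @param profiles A `dimer_profiles` data.frame from
#'   [per_dimer_occupancy()].
#' @param centered_tol Centroid tolerance in nt (default 25, about half a
#'   nucleosome's DNA reach).
#' @param symmetry_ratio Monomer ratio above which a footprint is called
#'   asymmetric (default 1.5, chosen so flat sampling noise at ~50x coverage
#'   does not trigger asymmetry).
#' @return `profiles` with added `orientation` and `symmetry` columns
#'   (NA where the unit has no usable coverage).
#' @export
classify_dimers <- function(profiles, centered_tol = 25, symmetry_ratio = 1.5) {
  stopifnot(is.data.frame(profiles))
  off <- profiles$centroid_offset
  profiles$orientation <- ifelse(
    is.na(off), NA_character_,
    ifelse(abs(off) <= centered_tol, "centered",
           ifelse(off > 0, "downstream", "upstream")))
  a <- profiles$monomer_a_occ
  b <- profiles$monomer_b_occ
  ratio <- pmax(a, b) / pmin(a, b)        # Inf when one half is empty
  profiles$symmetry <- ifelse(
    !is.finite(a) | !is.finite(b) | (a == 0 & b == 0), NA_character_,
    ifelse(is.finite(ratio) & ratio < symmetry_ratio, "symmetric",
           ifelse(a >= b, "asymmetric_a", "asymmetric_b")))
  profiles
}

#' Pairwise percent identity of equal-length repeat units
#'
#' Percent of matching positions (100 minus the Hamming distance as a
#' percentage of length) for every pair of units. The substitution-only
#' mutation model guarantees equal lengths.
#'
#' @param units A `satellite_array`, a list of `dimer_unit`s, or a character
#'   vector of equal-length DNA strings.
#' @return Symmetric numeric matrix of percent identities, diagonal 100.
#' @export
pairwise_identity <- function(units) {
  seqs <- if (inherits(units, "satellite_array"))
    vapply(units$units, `[[`, character(1), "sequence")
  else if (is.list(units))
    vapply(units, `[[`, character(1), "sequence")
  else setNames(as.character(units), names(units))
  n <- length(seqs)
  if (n < 1L) stop("no units supplied", call. = FALSE)
  L <- unique(nchar(seqs))
  if (length(L) != 1L) stop("units must have equal length", call. = FALSE)
  m <- vapply(seqs, function(s) utf8ToInt(toupper(s)), integer(L))
  out <- matrix(100, n, n, dimnames = list(names(seqs), names(seqs)))
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        id <- 100 * sum(m[, i] == m[, j]) / L
        out[i, j] <- id
        out[j, i] <- id
      }
    }
  }
  out
}
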