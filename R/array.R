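#' Expand a dimer unit into a diverged tandem array
#'
#' Replicates a founder dimeric unit `n_units` times head-to-tail and applies
#' independent per-base substitutions at the given rate, emulating the
#' accumulation of random mutations that degrades (or abolishes) CENP-B boxes
#' in older, more divergent arrays. The mutation model is substitution-only
#' (uniform over the three alternative bases, no indels), so the dimer period
#' is preserved exactly and coordinate folding stays well defined.
#'
#' @param unit A [build_dimer()] `dimer_unit` founder.
#' @param n_units Number of tandem copies (>= 1).
#' @param divergence_rate Per-base substitution probability in `[0, 0.25]`.
#' @param seed Integer seed; the generator is fully determined by it.
#' @param name Array (contig) name.
#' @return A `satellite_array`: list with `name`, `period`, `n_units`,
#'   `units` (list of post-mutation `dimer_unit`s), `divergence_rate`,
#'   `box_mismatches` and `box_scores` (ground truth per unit), and
#'   `truth_occupancy` / `truth_fraction_weights` slots (filled by
#'   [assign_truth_occupancy()]).
#' @examples
#' arr <- evolve_array(build_dimer(), n_units = 10, divergence_rate = 0.05,
#'                     seed = 1)
#' arr$box_scores
#' @export
evolve_array <- function(unit, n_units, divergence_rate, seed = 1L,
                         name = "array") {
  stopifnot(inherits(unit, "dimer_unit"))
  n_units <- as.integer(n_units)
  if (is.na(n_units) || n_units < 1L) stop("n_units must be >= 1")
  if (!is.numeric(divergence_rate) || divergence_rate < 0 ||
      divergence_rate > 0.25)
    stop("divergence_rate must be in [0, 0.25]", call. = FALSE)
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  L <- unit$period
  anc <- strsplit(unit$sequence, "")[[1]]
  m <- matrix(rep(anc, n_units), nrow = L, ncol = n_units)
  hit <- which(runif(L * n_units) < divergence_rate)
  if (length(hit)) {
    shift <- sample.int(3L, length(hit), replace = TRUE)
    cur <- match(m[hit], bases)
    m[hit] <- bases[((cur - 1L + shift) %% 4L) + 1L]
  }
  seqs <- apply(m, 2L, paste, collapse = "")
  units <- lapply(seqs, function(s) {
    structure(list(sequence = s, cenpb_box_offset = unit$cenpb_box_offset,
                   box_strand = unit$box_strand, period = L),
              class = "dimer_unit")
  })
  box_chars <- strsplit(if (unit$box_strand == "+") CENPB_BOX
                        else revcomp(CENPB_BOX), "")[[1]]
  off <- unit$cenpb_box_offset
  box_mm <- vapply(seqs, function(s) {
    sum(strsplit(substr(s, off + 1L, off + 15L), "")[[1]] != box_chars)
  }, integer(1), USE.NAMES = FALSE)
  structure(list(name = name, period = L, n_units = n_units, units = units,
                 divergence_rate = divergence_rate,
                 box_mismatches = box_mm,
                 box_scores = pmax(0, 1 - 0.25 * box_mm),
                 truth_occupancy = NULL, truth_fraction_weights = NULL),
            class = "satellite_array")
}

#' @export
print.satellite_array <- function(x, ...) {
  cat("<satellite_array> '", x$name, "': ", x$n_units, " x ", x$period,
      "-nt units, divergence rate ", x$divergence_rate, "\n", sep = "")
  cat("  box scores: ", paste(format(x$box_scores), collapse = " "), "\n")
  if (!is.null(x$truth_occupancy))
    cat("  truth occupancy: ",
        paste(format(round(x$truth_occupancy, 2)), collapse = " "), "\n")
  invisible(x)
}

#' Full nucleotide sequence of an array
#' @param array A `satellite_array`.
#' @return Single character string, units concatenated head-to-tail.
#' @export
array_sequence <- function(array) {
  stopifnot(inherits(array, "satellite_array"))
  paste(vapply(array$units, `[[`, character(1), "sequence"), collapse = "")
}

#' Unit intervals of an array
#' @param array A `satellite_array`.
#' @return data.frame with 0-based half-open `start`/`end` per unit.
#' @export
unit_intervals <- function(array) {
  stopifnot(inherits(array, "satellite_array"))
  start <- (seq_len(array$n_units) - 1L) * array$period
  data.frame(unit_index = seq_len(array$n_units),
             start = start, end = start + array$period)
}

#' 0-based array coordinates of each unit's CENP-B box start
#' @param array A `satellite_array`.
#' @return Integer vector, one box start per unit.
#' @export
box_starts <- function(array) {
  stopifnot(inherits(array, "satellite_array"))
  (seq_len(array$n_units) - 1L) * array$period +
    array$units[[1L]]$cenpb_box_offset
}

# Fraction-weight endpoints: a perfect box shifts chromatin toward the
# stable, salt-resistant fractions; a dead box toward soluble ones. The
# perfect-box endpoint puts >80% of mass in high_salt + pellet.
.WEIGHTS_SCORE0 <- c(no_salt = 0.10, low_salt = 0.40, high_salt = 0.35,
                     pellet = 0.15)
.WEIGHTS_SCORE1 <- c(no_salt = 0.02, low_salt = 0.15, high_salt = 0.68,
                     pellet = 0.15)

#' Assign ground-truth CCAN occupancy and salt-fraction weights
#'
#' Ties each unit's true occupancy to the quality of its CENP-B box through a
#' monotone link function, with multiplicative lognormal unit-to-unit noise,
#' and sets per-unit salt-fraction weights that shift toward the high-salt
#' and pellet fractions as the box score increases (a strong CENP-B box is
#' associated with stabilization of the CENP-A/B/C particle). The link
#' function is a simulation choice: the occupancy-score relationship is not
#' an inference target, only its monotone trend is.
#'
#' @param array A `satellite_array`.
#' @param link Monotone non-decreasing function mapping box score in `[0,1]`
#'   to a positive expected occupancy. Default `0.2 + score`.
#' @param noise_sd Standard deviation (log scale) of the lognormal
#'   unit-level occupancy noise. Default 0.9.
#' @param seed Integer seed.
#' @return The array with `truth_occupancy` (positive numeric per unit) and
#'   `truth_fraction_weights` (units x 4 matrix, rows summing to 1) filled.
#' @export
assign_truth_occupancy <- function(array, link = function(s) 0.2 + s,
                                   noise_sd = 0.9, seed = 1L) {
  stopifnot(inherits(array, "satellite_array"))
  grid <- seq(0, 1, by = 0.05)
  fg <- vapply(grid, link, numeric(1))
  if (any(diff(fg) < -1e-12))
    stop("link must be monotone non-decreasing", call. = FALSE)
  if (any(!is.finite(fg)) || any(fg < 0) || fg[length(fg)] <= 0)
    stop("link must be non-negative with link(1) > 0", call. = FALSE)
  set.seed(seed)
  s <- array$box_scores
  noise <- if (noise_sd > 0) rlnorm(array$n_units, 0, noise_sd)
           else rep(1, array$n_units)
  array$truth_occupancy <- vapply(s, link, numeric(1)) * noise
  w <- outer(1 - s, .WEIGHTS_SCORE0) + outer(s, .WEIGHTS_SCORE1)
  w <- w / rowSums(w)
  dimnames(w) <- list(NULL, SALT_FRACTIONS)
  array$truth_fraction_weights <- w
  array
}
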