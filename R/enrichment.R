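#' Spike-in calibration of read counts
#'
#' Scales raw read counts by a constant over the sample's spike-in read
#' count, so occupancy is comparable across samples sequenced to different
#' depths. The scale constant is arbitrary (it cancels in all ratios) and
#' defaults to 10,000 for readable outputs.
#'
#' @param raw_count Raw read/fragment count(s), >= 0.
#' @param spike_count Spike-in read count(s), >= 1.
#' @param scale_const Positive scale constant.
#' @return Calibrated count(s): `raw_count * scale_const / spike_count`.
#' @export
calibrate_counts <- function(raw_count, spike_count, scale_const = 10000) {
  if (any(spike_count < 1)) stop("spike_count must be >= 1", call. = FALSE)
  if (any(raw_count < 0)) stop("raw_count must be >= 0", call. = FALSE)
  raw_count * scale_const / spike_count
}

#' Fold enrichment of a specific antibody over the IgG control
#'
#' @param target_calibrated,igg_calibrated Calibrated counts (>= 0).
#' @param pseudocount Added to both numerator and denominator (in calibrated
#'   units) to guard against division by zero on depleted contigs; set to 0
#'   for exact ratios.
#' @return `(target + pseudocount) / (igg + pseudocount)`.
#' @export
fold_enrichment <- function(target_calibrated, igg_calibrated,
                            pseudocount = 1) {
  if (any(target_calibrated < 0) || any(igg_calibrated < 0))
    stop("calibrated counts must be >= 0", call. = FALSE)
  if (pseudocount < 0) stop("pseudocount must be >= 0", call. = FALSE)
  (target_calibrated + pseudocount) / (igg_calibrated + pseudocount)
}

#' Percent recovery across salt fractions
#'
#' @param fraction_counts Named non-negative numeric vector of calibrated
#'   counts, one per fraction; at least one must be positive.
#' @return Named vector of percentages summing to 100.
#' @export
percent_recovery <- function(fraction_counts) {
  x <- as.numeric(fraction_counts)
  if (!length(x) || any(!is.finite(x)) || any(x < 0))
    stop("fraction_counts must be finite and >= 0", call. = FALSE)
  tot <- sum(x)
  if (tot <= 0) stop("all fraction counts are zero", call. = FALSE)
  setNames(100 * x / tot, names(fraction_counts))
}

#' Correlate CENP-B box motif statistics with fold enrichment
#'
#' Pearson product-moment correlation between a per-contig motif statistic
#' (best box score, or box density per kb) and the contig's antibody/IgG
#' fold enrichment. Computed on untransformed enrichment by default, with a
#' log10 option reported separately.
#'
#' @param table data.frame with a `fold_enrichment` column and the chosen
#'   `x` column (`best_score` or `density`); one row per contig (x fraction).
#' @param x Which motif statistic to correlate.
#' @param log10_enrichment If `TRUE`, correlate against
#'   `log10(fold_enrichment)`.
#' @return List with `r`, `n`, `x`, `log10_enrichment`.
#' @export
correlate_motif_enrichment <- function(table,
                                       x = c("best_score", "density"),
                                       log10_enrichment = FALSE) {
  x <- match.arg(x)
  stopifnot(is.data.frame(table))
  if (!all(c(x, "fold_enrichment") %in% names(table)))
    stop("table must have columns '", x, "' and 'fold_enrichment'",
         call. = FALSE)
  xv <- table[[x]]
  yv <- table$fold_enrichment
  if (log10_enrichment) yv <- log10(yv)
  ok <- is.finite(xv) & is.finite(yv)
  xv <- xv[ok]; yv <- yv[ok]
  if (length(xv) < 3L) stop("need at least 3 finite rows", call. = FALSE)
  if (sd(xv) == 0 || sd(yv) == 0)
    stop("zero variance in one of the variables", call. = FALSE)
  list(r = cor(xv, yv), n = length(xv), x = x,
       log10_enrichment = log10_enrichment)
}
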