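#' Merge one overlapping read pair into a full-length fragment
#'
#' Reconstructs the sequenced insert directly from an overlapping mate pair,
#' so fragment length is measured rather than inferred from mapped ends —
#' essential on tandem repeats where end-mapping is ambiguous. 3' bases below
#' `min_quality` are trimmed first; then the longest suffix(R1) /
#' prefix(revcomp(R2)) overlap of at least `min_overlap` nt with at most one
#' mismatch per 10 overlap nt is accepted. Disagreements take the
#' higher-quality base. Merged fragments shorter than `min_length` are
#' discarded.
#'
#' @param seq1,seq2 Read sequences (R2 on the opposite strand).
#' @param qual1,qual2 Phred+33 quality strings; `NULL` means constant Q37.
#' @param min_quality 3'-trim quality threshold (default 25).
#' @param min_length Minimum merged fragment length (default 25).
#' @param min_overlap Minimum overlap in nt (default 15).
#' @return List with `source` (`"merged"` or `"unmerged_pair"`), and for
#'   merged pairs `sequence`, `length`, `n_overlap`.
#' @export
merge_pair <- function(seq1, seq2, qual1 = NULL, qual2 = NULL,
                       min_quality = 25L, min_length = 25L,
                       min_overlap = 15L) {
  if (is.null(qual1)) qual1 <- strrep("F", nchar(seq1))
  if (is.null(qual2)) qual2 <- strrep("F", nchar(seq2))
  if (nchar(seq1) != nchar(qual1) || nchar(seq2) != nchar(qual2))
    stop("sequence and quality lengths differ", call. = FALSE)
  .merge_one(toupper(seq1), qual1, toupper(seq2), qual2,
             min_quality, min_length, min_overlap)
}

# core single-pair merge on character data; quality strings Phred+33
.merge_one <- function(s1, q1, s2, q2, min_quality, min_length, min_overlap) {
  unmerged <- list(source = "unmerged_pair", sequence = NA_character_,
                   length = NA_integer_, n_overlap = NA_integer_)
  # 3'-only quality trim
  t1 <- .trim3(s1, q1, min_quality)
  t2 <- .trim3(s2, q2, min_quality)
  n1 <- nchar(t1$s); n2 <- nchar(t2$s)
  if (n1 < min_overlap || n2 < min_overlap) return(unmerged)
  s2rc <- revcomp(t2$s)
  q2rc <- paste(rev(strsplit(t2$q, "")[[1]]), collapse = "")
  i1 <- utf8ToInt(t1$s); i2 <- utf8ToInt(s2rc)
  p1 <- utf8ToInt(t1$q); p2 <- utf8ToInt(q2rc)
  for (olap in seq.int(min(n1, n2), min_overlap)) {
    a <- i1[(n1 - olap + 1L):n1]
    b <- i2[1:olap]
    dif <- which(a != b)
    if (length(dif) <= olap %/% 10L) {
      cons <- a
      if (length(dif)) {
        qa <- p1[(n1 - olap + 1L):n1][dif]
        qb <- p2[dif]
        cons[dif] <- ifelse(qb > qa, b[dif], a[dif])
      }
      merged <- intToUtf8(c(i1[seq_len(n1 - olap)], cons,
                            i2[seq.int(olap + 1L, length.out = n2 - olap)]))
      if (nchar(merged) < min_length) return(unmerged)
      return(list(source = "merged", sequence = merged,
                  length = nchar(merged), n_overlap = olap))
    }
  }
  unmerged
}

.trim3 <- function(s, q, min_quality) {
  qi <- utf8ToInt(q) - 33L
  keep <- which(qi >= min_quality)
  if (!length(keep)) return(list(s = "", q = ""))
  k <- max(keep)
  list(s = substr(s, 1L, k), q = substr(q, 1L, k))
}

#' Merge all read pairs of a sample
#'
#' Vectorised driver over [merge_pair()]. Accepts either two FASTQ paths or
#' a list as returned by [read_fastq_pairs()].
#'
#' @param r1,r2 FASTQ file paths, or `r1` a list from [read_fastq_pairs()]
#'   (then `r2` is ignored).
#' @inheritParams merge_pair
#' @return data.frame of merged fragments with `fragment_id`, `sequence`,
#'   `length`, `n_overlap`. Attributes `n_pairs`, `n_merged`, `n_unmerged`
#'   and `unmerged_ids` record the pairs that did not merge (retained for
#'   short-read end-counting modes).
#' @export
merge_pairs <- function(r1, r2 = NULL, min_quality = 25L, min_length = 25L,
                        min_overlap = 15L) {
  pr <- if (is.list(r1)) r1 else read_fastq_pairs(r1, r2)
  n <- length(pr$seq1)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    out[[i]] <- .merge_one(pr$seq1[i], pr$qual1[i], pr$seq2[i], pr$qual2[i],
                           min_quality, min_length, min_overlap)
  }
  ok <- vapply(out, function(x) x$source == "merged", logical(1))
  df <- data.frame(
    fragment_id = pr$id[ok],
    sequence = vapply(out[ok], `[[`, character(1), "sequence"),
    length = vapply(out[ok], `[[`, integer(1), "length"),
    n_overlap = vapply(out[ok], `[[`, integer(1), "n_overlap"),
    stringsAsFactors = FALSE)
  attr(df, "n_pairs") <- n
  attr(df, "n_merged") <- sum(ok)
  attr(df, "n_unmerged") <- n - sum(ok)
  attr(df, "unmerged_ids") <- pr$id[!ok]
  df
}

#' Fragment-length histogram
#'
#' Bins merged-fragment lengths over the retained range (default 25-500 nt,
#' the merge filter's minimum to the maximum insert recoverable by
#' overlap merging of 250-nt mates).
#'
#' @param fragments data.frame with `fragment_id` and `length` columns
#'   (e.g. from [merge_pairs()]), or a bare numeric vector of lengths.
#' @param bin_width Bin width in nt.
#' @param range Two-element numeric, histogram range (closed).
#' @param restrict_to Optional character vector of fragment ids to keep
#'   (e.g. the ids mapped to one contig).
#' @return data.frame with `bin_start`, `bin_end`, `count`; counts sum to
#'   the number of (restricted) fragments inside `range`.
#' @export
length_histogram <- function(fragments, bin_width = 5L, range = c(25L, 500L),
                             restrict_to = NULL) {
  if (is.data.frame(fragments)) {
    if (!is.null(restrict_to))
      fragments <- fragments[fragments$fragment_id %in% restrict_to, ,
                             drop = FALSE]
    lens <- fragments$length
  } else {
    lens <- as.numeric(fragments)
  }
  if (!length(lens)) stop("no fragments left to histogram", call. = FALSE)
  inside <- lens >= range[1] & lens <= range[2]
  if (any(!inside))
    warning(sum(!inside), " fragment(s) outside [", range[1], ", ", range[2],
            "] dropped")
  lens <- lens[inside]
  breaks <- seq(range[1], range[2], by = bin_width)
  if (breaks[length(breaks)] < range[2]) breaks <- c(breaks, range[2])
  idx <- findInterval(lens, breaks, rightmost.closed = TRUE)
  nb <- length(breaks) - 1L
  data.frame(bin_start = breaks[-length(breaks)], bin_end = breaks[-1L],
             count = tabulate(idx, nbins = nb))
}
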