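#' The ancestral CENP-B box core motif
#'
#' The middle 15 bp of the 17-bp CENP-B box. This core is ancestral: it is
#' found at regular 340-bp intervals in the most homogeneous alpha-satellite
#' arrays of the major suprachromosomal families, and all motif scoring in
#' this package is relative to it.
#'
#' @format A length-one character vector, `"TTCGTTGGAAACGGG"`.
#' @export
CENPB_BOX <- "TTCGTTGGAAACGGG"

#' Salt-fraction labels
#'
#' The four fractions of a sequential-salt-extraction experiment, in
#' extraction order: no added salt, low salt, high salt (500 mM NaCl), and
#' the insoluble pellet.
#'
#' @format Character vector of length four.
#' @export
SALT_FRACTIONS <- c("no_salt", "low_salt", "high_salt", "pellet")

# Synthetic alpha-satellite-like monomers: fixed arbitrary AT-rich sequences,
# NOT derived from any real alphoid consensus. They carry no CENP-B box
# (checked at build time); build_dimer() writes the box in explicitly.
.MONOMER_A <- paste0(
  "GGAGCTCACCTCGATGGATTGAGGATTGTGCGTCAGAAGCTTAGTGGCGCTTTCACCAATCGCTGAAGCA",
  "AAATACATTATATCCTAAATCAAGGCTTCCCAATGGCCTACGCTTTATCGTTTTCTGGACGCCGGTGACC",
  "AATCCGAGAACTCTCCAAACGTCATATTAA")
.MONOMER_B_170 <- paste0(
  "CTTTTAGTCCGGTACCGCAAACAAAATACCGTGTATGTAATCTATGTTTGTATGTGTAAATATAGGAGTT",
  "ATAATTAATGTAATACATTCCATGTAGAGGACTAGTTTTTTAAGTATATAGCTTTACCAATTATGGTATT",
  "AGTAAGACGGTTAATGTGCCGAATCTTTGA")
.MONOMER_B_172 <- paste0(
  "TACTAAGTGGTTAACTCGTTTCAGCTCGTAATCACGAAAGTTTATGAGAAGTCACTGGTAATCTGAGAAT",
  "ATACAAACTAATGGTATTCTTTTAGATAATCGTGTTAGCATTCCTTACGGTAGAACTATGTAGGTTTGAC",
  "ATGAGTGAAAGTGTTACTAAAATGAGTAGAAC")

.check_dna <- function(x, what = "sequence") {
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop(what, " must be a single character string", call. = FALSE)
  if (grepl("[^ACGT]", toupper(x)))
    stop(what, " contains non-ACGT characters", call. = FALSE)
  toupper(x)
}

#' Default synthetic alpha-satellite monomers
#'
#' Returns a pair of fixed synthetic monomer sequences whose lengths sum to
#' the requested dimer period. The sequences are arbitrary AT-rich strings
#' (not a real alphoid consensus) and contain no CENP-B box, so the box
#' placed by [build_dimer()] is the only one in the unit.
#'
#' @param period Dimer period in bp, 340 (170 + 170) or 342 (170 + 172).
#' @return List with elements `monomer_a` and `monomer_b`.
#' @export
default_monomers <- function(period = 340L) {
  period <- as.integer(period)
  if (!period %in% c(340L, 342L))
    stop("period must be 340 or 342", call. = FALSE)
  list(monomer_a = .MONOMER_A,
       monomer_b = if (period == 340L) .MONOMER_B_170 else .MONOMER_B_172)
}

#' Build an alpha-satellite dimeric repeat unit
#'
#' Constructs the basic 340-bp (or 342-bp) head-to-tail dimeric unit of a
#' functional alpha-satellite array: two ~171-bp monomers joined end to end,
#' with the 15-bp ancestral CENP-B box core written in at a fixed offset so
#' that the unit carries exactly one perfect box.
#'
#' @param monomer_a,monomer_b Monomer DNA strings (ACGT). Defaults to the
#'   package's synthetic monomers for the requested `period`.
#' @param box_offset 0-based offset of the box start within the unit.
#'   Must satisfy `0 <= box_offset <= period - 15`.
#' @param period Dimer period used to pick default monomers; ignored when
#'   both monomers are supplied explicitly.
#' @param box Motif written into the unit (default [CENPB_BOX]).
#' @return An object of class `dimer_unit`: list with `sequence`,
#'   `cenpb_box_offset` (0-based), `box_strand` (`"+"`) and `period`.
#' @examples
#' u <- build_dimer()
#' nchar(u$sequence)                    # 340
#' substr(u$sequence, 61, 75)           # the CENP-B box
#' @export
build_dimer <- function(monomer_a = NULL, monomer_b = NULL, box_offset = 60L,
                        period = 340L, box = CENPB_BOX) {
  if (is.null(monomer_a) || is.null(monomer_b)) {
    mons <- default_monomers(period)
    if (is.null(monomer_a)) monomer_a <- mons$monomer_a
    if (is.null(monomer_b)) monomer_b <- mons$monomer_b
  }
  monomer_a <- .check_dna(monomer_a, "monomer_a")
  monomer_b <- .check_dna(monomer_b, "monomer_b")
  box <- .check_dna(box, "box")
  len <- nchar(monomer_a) + nchar(monomer_b)
  if (!len %in% c(340L, 342L))
    stop("monomer lengths must sum to 340 or 342 (got ", len, ")",
         call. = FALSE)
  box_offset <- as.integer(box_offset)
  if (box_offset < 0L || box_offset + nchar(box) > len)
    stop("box_offset out of range: box [", box_offset, ", ",
         box_offset + nchar(box), ") does not fit in a ", len, "-nt unit",
         call. = FALSE)
  seq <- paste0(monomer_a, monomer_b)
  substr(seq, box_offset + 1L, box_offset + nchar(box)) <- box
  n_box <- .count_perfect_box(seq, box)
  if (n_box != 1L)
    stop("unit contains ", n_box, " perfect boxes; monomers must not ",
         "already contain the motif", call. = FALSE)
  structure(list(sequence = seq, cenpb_box_offset = box_offset,
                 box_strand = "+", period = len),
            class = "dimer_unit")
}

.count_perfect_box <- function(seq, box = CENPB_BOX) {
  s <- Biostrings::DNAString(seq)
  b <- Biostrings::DNAString(box)
  length(Biostrings::matchPattern(b, s)) +
    length(Biostrings::matchPattern(Biostrings::reverseComplement(b), s))
}

#' @export
print.dimer_unit <- function(x, ...) {
  cat("<dimer_unit> ", x$period, " nt, CENP-B box at offset ",
      x$cenpb_box_offset, " (", x$box_strand, " strand)\n", sep = "")
  invisible(x)
}

#' Reverse-complement DNA strings
#'
#' @param x Character vector of DNA strings.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
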