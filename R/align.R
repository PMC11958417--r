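#' Global pairwise alignment of two nucleotide sequences
#'
#' Needleman-Wunsch alignment via [Biostrings::pairwiseAlignment()] with the
#' package-wide default scores (match 1, mismatch -1, gap open 2, gap extend 1,
#' penalties positive as in Biostrings).
#'
#' @param x,y Character scalars (nucleotide sequences).
#' @param match,mismatch Match/mismatch scores.
#' @param gap_open,gap_extend Gap penalties (positive).
#' @return List with aligned strings `x` and `y` (equal length, `-` for gaps)
#'   and the alignment `score`.
#' @export
global_align <- function(x, y, match = 1, mismatch = -1,
                         gap_open = 2, gap_extend = 1) {
  stopifnot(is.character(x), is.character(y), nzchar(x), nzchar(y))
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(toupper(x)), Biostrings::DNAString(toupper(y)),
    type = "global", substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_extend)
  list(x = as.character(Biostrings::alignedPattern(aln)),
       y = as.character(Biostrings::alignedSubject(aln)),
       score = Biostrings::score(aln))
}

#' Alignment identity between two sequences
#'
#' Identity is the proportion of identical columns over all aligned columns;
#' columns containing a gap count as mismatches.
#'
#' @inheritParams global_align
#' @return Proportion in `[0, 1]`.
#' @export
alignment_identity <- function(x, y, ...) {
  if (!nzchar(x) || !nzchar(y)) stop("empty sequence")
  aln <- global_align(x, y, ...)
  a <- strsplit(aln$x, "")[[1]]
  b <- strsplit(aln$y, "")[[1]]
  sum(a == b & a != "-") / length(a)
}

VALID_NT <- c("A", "C", "G", "T")
VALID_AA <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
              "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Uncorrected p-distance between two aligned sequences
#'
#' Proportion of differing sites among compared sites, with pairwise deletion:
#' columns where either sequence has a gap or an ambiguous/non-standard symbol
#' are excluded. Sequences of unequal length are globally aligned first.
#'
#' @param s1,s2 Character scalars.
#' @param mode `"nt"` (default) or `"aa"`.
#' @return Proportion in `[0, 1]`.
#' @export
p_distance <- function(s1, s2, mode = c("nt", "aa")) {
  mode <- match.arg(mode)
  s1 <- toupper(s1); s2 <- toupper(s2)
  if (nchar(s1) != nchar(s2)) {
    if (mode == "aa")
      stop("aa sequences must be pre-aligned to equal length")
    aln <- global_align(s1, s2)
    s1 <- aln$x; s2 <- aln$y
  }
  a <- strsplit(s1, "")[[1]]
  b <- strsplit(s2, "")[[1]]
  valid <- if (mode == "nt") VALID_NT else VALID_AA
  use <- a %in% valid & b %in% valid
  if (!any(use)) stop("no comparable sites between sequences")
  sum(a[use] != b[use]) / sum(use)
}

#' Translate a nucleotide sequence with a known reading-frame offset
#'
#' @param nt Nucleotide sequence (character scalar).
#' @param frame_offset Integer 0-2: bases to skip before the first codon.
#' @return Amino-acid string. A terminal stop is trimmed; an internal stop
#'   codon is an error (the amplicon is expected to be coding throughout).
#' @export
translate_seq <- function(nt, frame_offset = 0) {
  stopifnot(frame_offset %in% 0:2)
  s <- substr(toupper(nt), frame_offset + 1, nchar(nt))
  s <- substr(s, 1, nchar(s) - nchar(s) %% 3)
  if (nchar(s) < 3) stop("sequence too short to translate")
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(s),
                                           if.fuzzy.codon = "X"))
  if (endsWith(aa, "*")) aa <- substr(aa, 1, nchar(aa) - 1)
  if (grepl("*", aa, fixed = TRUE))
    stop("internal stop codon at frame offset ", frame_offset)
  aa
}

#' Pick the reading frame without internal stop codons
#'
#' Tries offsets 0, 1, 2 in order over all supplied sequences and returns the
#' first offset that yields stop-free translations for every sequence.
#'
#' @param seqs Character vector of nucleotide sequences.
#' @return Integer offset 0-2.
#' @export
auto_frame <- function(seqs) {
  for (off in 0:2) {
    ok <- all(vapply(seqs, function(s) {
      !inherits(try(translate_seq(s, off), silent = TRUE), "try-error")
    }, logical(1)))
    if (ok) return(off)
  }
  stop("no reading frame is stop-free for all sequences")
}
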