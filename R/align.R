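# Pairwise global alignment (Needleman-Wunsch with affine gaps) behind the
# marker identity scores and tree distances.  The dynamic program itself is
# delegated to Biostrings::pairwiseAlignment; this layer fixes the scoring
# convention: a gap of length L costs gap_open + L * gap_extend.

#' Alignment scoring parameters
#'
#' @param match Match score (default +1).
#' @param mismatch Mismatch score (default -1).
#' @param gap_open Gap-opening score (default -2; a gap of length L scores
#'   `gap_open + L * gap_extend`).
#' @param gap_extend Per-base gap-extension score (default -1).
#' @return A list of class `ardra_scoring`.
#' @export
align_scoring <- function(match = 1, mismatch = -1, gap_open = -2,
                          gap_extend = -1) {
  stopifnot(match > mismatch, gap_open <= 0, gap_extend <= 0)
  structure(list(match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "ardra_scoring")
}

# identity substitution matrix over the IUPAC alphabet: exact-letter match
# scores `match`, anything else `mismatch` (identity, not set overlap: the
# identity percentages reported by the marker screen count literal letters)
iupac_substitution_matrix <- function(scoring) {
  n <- length(IUPAC_LETTERS)
  m <- matrix(scoring$mismatch, n, n,
              dimnames = list(IUPAC_LETTERS, IUPAC_LETTERS))
  diag(m) <- scoring$match
  m
}

#' Global pairwise alignment
#'
#' Optimal Needleman-Wunsch global alignment with affine gap costs.
#'
#' @param a,b Non-empty DNA strings.
#' @param scoring An [align_scoring()].
#' @return A list of class `ardra_alignment`: `alignment1`, `alignment2`
#'   (equal-length gapped strings; de-gapping recovers the inputs), `score`,
#'   `scoring`.
#' @examples
#' global_align("ACGT", "ACT")
#' @export
global_align <- function(a, b, scoring = align_scoring()) {
  a <- normalize_residues(a)
  b <- normalize_residues(b)
  stopifnot(length(a) == 1L, length(b) == 1L, nchar(a) > 0L, nchar(b) > 0L)
  aln <- Biostrings::pairwiseAlignment(
    pattern = a, subject = b, type = "global",
    substitutionMatrix = iupac_substitution_matrix(scoring),
    gapOpening = -scoring$gap_open, gapExtension = -scoring$gap_extend
  )
  structure(
    list(
      alignment1 = as.character(Biostrings::alignedPattern(aln)),
      alignment2 = as.character(Biostrings::alignedSubject(aln)),
      score = Biostrings::score(aln),
      scoring = scoring
    ),
    class = "ardra_alignment"
  )
}

#' @export
print.ardra_alignment <- function(x, ...) {
  cat("<global alignment, score ", x$score, ">\n", sep = "")
  cat(" ", x$alignment1, "\n ", x$alignment2, "\n", sep = "")
  invisible(x)
}

# column-wise comparison of an alignment; used by percent_identity() and
# the tree distances
alignment_columns <- function(aln) {
  c1 <- strsplit(aln$alignment1, "", fixed = TRUE)[[1]]
  c2 <- strsplit(aln$alignment2, "", fixed = TRUE)[[1]]
  list(c1 = c1, c2 = c2, both = c1 != "-" & c2 != "-",
       identical = c1 == c2 & c1 != "-")
}

#' Percent identity of an alignment
#'
#' Identical columns over counted columns, times 100, rounded half-up to the
#' nearest integer so values print at the same precision as the published
#' screening table.
#'
#' @param aln An `ardra_alignment` from [global_align()].
#' @param mode `"excluding_gaps"` (default: only columns where both strings
#'   have a base are counted) or `"including_gaps"` (all columns counted).
#' @return Integer-valued percentage in `[0, 100]`.
#' @export
percent_identity <- function(aln, mode = c("excluding_gaps", "including_gaps")) {
  mode <- match.arg(mode)
  stopifnot(inherits(aln, "ardra_alignment"))
  cols <- alignment_columns(aln)
  denom <- if (mode == "excluding_gaps") sum(cols$both) else length(cols$c1)
  if (denom == 0L) return(0)
  round_half_up(100 * sum(cols$identical) / denom)
}
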