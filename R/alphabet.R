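# IUPAC nucleotide alphabet shared by every module. All coordinates in the
# package are 1-based and inclusive, on the stored (sense) strand.

IUPAC_LETTERS <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                   "B", "D", "H", "V", "N")

# concrete-base sets behind each code
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# complement map covers every IUPAC code (R<->Y, S<->S, W<->W, K<->M,
# B<->V, D<->H, N<->N)
IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", V = "B", D = "H", H = "D", N = "N"
)

# 15x15 lookup: does a subject base satisfy a pattern base?  A subject-side
# N (unknown base) never satisfies a concrete pattern base: low-quality
# records must not produce spurious cut or primer sites.
.build_match_table <- function() {
  m <- matrix(FALSE, 15L, 15L, dimnames = list(IUPAC_LETTERS, IUPAC_LETTERS))
  for (s in IUPAC_LETTERS) {
    for (p in IUPAC_LETTERS) {
      m[s, p] <- length(intersect(IUPAC_SETS[[s]], IUPAC_SETS[[p]])) > 0L
    }
  }
  m["N", ] <- FALSE
  m["N", "N"] <- TRUE
  m
}
IUPAC_MATCH_TABLE <- .build_match_table()

#' Do two IUPAC bases match?
#'
#' A subject base satisfies a pattern base when their concrete-base sets
#' intersect, with one conservative exception: `N` on the subject side matches
#' nothing unless the pattern base is itself `N`.  This keeps ambiguous
#' stretches of low-quality records from producing spurious restriction or
#' primer sites.
#'
#' @param seq_base,pattern_base Single IUPAC DNA letters (vectorised,
#'   recycled to common length).
#' @return Logical vector.
#' @examples
#' iupac_match("G", "S") # TRUE: {G} and {C,G} intersect
#' iupac_match("A", "S") # FALSE
#' iupac_match("N", "A") # FALSE: subject-side N is conservative
#' @export
iupac_match <- function(seq_base, pattern_base) {
  s <- match(toupper(seq_base), IUPAC_LETTERS)
  p <- match(toupper(pattern_base), IUPAC_LETTERS)
  if (anyNA(s) || anyNA(p)) {
    abort("non-IUPAC base passed to iupac_match()", class = "ardra_data_error")
  }
  IUPAC_MATCH_TABLE[cbind(s, p)]
}

# Normalize residues: uppercase, RNA U mapped to T.  Errors name the record
# and the 1-based position of the first offending character.
normalize_residues <- function(x, id = NULL) {
  x <- chartr("u", "t", x)
  x <- toupper(chartr("U", "T", x))
  chars <- strsplit(x, "", fixed = TRUE)
  for (i in seq_along(chars)) {
    bad <- which(!(chars[[i]] %in% IUPAC_LETTERS))
    if (length(bad) > 0L) {
      who <- if (is.null(id)) paste0("sequence ", i) else paste0("record '", id[[i]], "'")
      abort(
        sprintf("invalid character '%s' at position %d in %s",
                chars[[i]][bad[1L]], bad[1L], who),
        class = "ardra_data_error"
      )
    }
    if (length(chars[[i]]) == 0L) {
      who <- if (is.null(id)) paste0("sequence ", i) else paste0("record '", id[[i]], "'")
      abort(paste0("empty residues in ", who), class = "ardra_data_error")
    }
  }
  x
}

#' Reverse complement of IUPAC DNA strings
#'
#' IUPAC-aware: ambiguity codes are complemented by their base-set complement
#' (R to Y, S to S, W to W, K to M, B to V, D to H, N to N).
#'
#' @param residues Character vector of IUPAC DNA strings.
#' @return Character vector of the same length; each element reversed and
#'   complemented, always uppercase.
#' @examples
#' reverse_complement("AATACGTTCCCGGGCCTT")
#' @export
reverse_complement <- function(residues) {
  residues <- normalize_residues(residues)
  from <- paste(names(IUPAC_COMPLEMENT), collapse = "")
  to <- paste(IUPAC_COMPLEMENT, collapse = "")
  comp <- chartr(from, to, residues)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

# GC fraction helper used by the primer Tm formula
gc_count <- function(x) {
  vapply(strsplit(toupper(x), "", fixed = TRUE),
         function(ch) sum(ch %in% c("G", "C", "S")), integer(1))
}
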