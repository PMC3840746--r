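# Primer objects and the canonical 463F/463R constants.
#
# The published record of the 463F forward primer is internally inconsistent:
# the running text prints 5'-CTAAAACTCAAAGGAATTGACG-3' while the
# genus-by-genus specificity table lists CTGAAACTCAAAGGAATTGACG as the
# perfect-match form for the 100%-identity taxa.  Both constants ship; the
# "G" (CTG...) variant is the default because it is the form the specificity
# table treats as canonical.  The 463R reverse primer is recorded as the
# sense-strand segment it anneals to (AATACGTTCCCGGGCCTT, which contains the
# HaeIII site GGCC); the synthesized oligo is that segment's reverse
# complement.

PRIMER_463F_G <- "CTGAAACTCAAAGGAATTGACG"
PRIMER_463F_A <- "CTAAAACTCAAAGGAATTGACG"
SITE_463R <- "AATACGTTCCCGGGCCTT"

#' Construct a primer
#'
#' @param name Primer name.
#' @param oligo IUPAC DNA string, 5' to 3' as synthesized, length 15-35.
#' @param role `"forward"` or `"reverse"`.
#' @return An object of class `ardra_primer`.
#' @export
primer <- function(name, oligo, role = c("forward", "reverse")) {
  role <- match.arg(role)
  oligo <- normalize_residues(oligo)
  if (nchar(oligo) < 15L || nchar(oligo) > 35L) {
    abort("primer length must be 15-35 bases", class = "ardra_data_error")
  }
  structure(list(name = name, oligo = oligo, role = role),
            class = "ardra_primer")
}

#' @export
print.ardra_primer <- function(x, ...) {
  cat(sprintf("<primer %s (%s): 5'-%s-3'>\n", x$name, x$role, x$oligo))
  invisible(x)
}

#' Canonical 463F forward primer
#'
#' @param variant `"G"` for CTGAAACTCAAAGGAATTGACG (the perfect-match form of
#'   the published specificity table; default) or `"A"` for
#'   CTAAAACTCAAAGGAATTGACG (the form printed in the running text).  The
#'   two differ only at the third base; see the methods vignette.
#' @return An `ardra_primer`.
#' @export
primer_463f <- function(variant = c("G", "A")) {
  variant <- match.arg(variant)
  oligo <- if (variant == "G") PRIMER_463F_G else PRIMER_463F_A
  primer(paste0("463F-", variant), oligo, "forward")
}

#' Canonical 463R reverse primer
#'
#' The synthesized oligo is the reverse complement of the sense-strand
#' annealing site `AATACGTTCCCGGGCCTT` (see [site_463r()]).
#'
#' @return An `ardra_primer`.
#' @export
primer_463r <- function() {
  primer("463R", reverse_complement(SITE_463R), "reverse")
}

#' Sense-strand annealing site of 463R
#' @return The 18-base sense-strand site as a string.
#' @export
site_463r <- function() SITE_463R

#' Basic GC melting temperature
#'
#' `Tm = 64.9 + 41 * (GC - 16.4) / length`, the basic GC-content formula; a
#' deliberate simplification of thermodynamic (nearest-neighbor) predictors.
#'
#' @param oligo Character vector of DNA strings.
#' @return Tm in degrees Celsius.
#' @examples
#' primer_tm("CTGAAACTCAAAGGAATTGACG") # 51.1
#' @export
primer_tm <- function(oligo) {
  oligo <- normalize_residues(oligo)
  64.9 + 41 * (gc_count(oligo) - 16.4) / nchar(oligo)
}

#' Packaged panel of observed 463F/463R primer-site variants
#'
#' A curated subset of published primer-site variants across AEFB genera
#' (by NCBI accession): sense-strand forward and reverse annealing-site
#' sequences, the reported integer percent similarity of the marker region
#' to the *Bacillus subtilis*-type reference, the reported HaeIII-site flag,
#' and the reported marker span.  Used as a validation fixture for
#' [annotate_variant()] and the screening conventions.
#'
#' @return A tibble with columns `taxon`, `accession`, `fwd_site`,
#'   `rev_site`, `pct_similarity`, `site`, `span_start`, `span_end`.
#' @export
aefb_variant_panel <- function() {
  path <- system.file("extdata", "aefb_primer_variants.tsv", package = "ardra",
                      mustWork = TRUE)
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  col_types = readr::cols(
                    taxon = "c", accession = "c", fwd_site = "c",
                    rev_site = "c", pct_similarity = "i", site = "c",
                    span_start = "i", span_end = "i"))
}

#' Mark mismatches in an observed primer site
#'
#' Reproduces, in plain text, the convention of printing primer-site variants
#' with their substituted letters highlighted: every position of `observed`
#' that differs from `canonical` is wrapped in markers.
#'
#' @param observed,canonical Equal-length DNA strings (vectorised).
#' @param open,close Marker characters (default `[` and `]`).
#' @return Character vector of annotated site strings.
#' @examples
#' annotate_variant("AATACGTTCCCGGGTCTT", "AATACGTTCCCGGGCCTT")
#' @export
annotate_variant <- function(observed, canonical, open = "[", close = "]") {
  n <- max(length(observed), length(canonical))
  observed <- rep_len(toupper(observed), n)
  canonical <- rep_len(toupper(canonical), n)
  purrr::map2_chr(observed, canonical, function(o, c_) {
    if (nchar(o) != nchar(c_)) {
      abort("observed and canonical site lengths differ",
            class = "ardra_data_error")
    }
    oc <- strsplit(o, "", fixed = TRUE)[[1]]
    cc <- strsplit(c_, "", fixed = TRUE)[[1]]
    mm <- oc != cc
    oc[mm] <- paste0(open, oc[mm], close)
    paste(oc, collapse = "")
  })
}
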