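# In silico restriction digestion and gel-like (ARDRA) band patterns.
# Digestion is linear: inputs are PCR amplicons or gene regions, not
# plasmids.

# All start positions (1-based) where `recognition` matches `chars` under
# IUPAC semantics; overlapping occurrences are all reported.
match_starts <- function(chars, recognition) {
  m <- nchar(recognition)
  L <- length(chars)
  if (L < m) return(integer(0))
  sidx <- match(chars, IUPAC_LETTERS)
  pidx <- match(strsplit(recognition, "", fixed = TRUE)[[1]], IUPAC_LETTERS)
  ok <- rep(TRUE, L - m + 1L)
  for (k in seq_len(m)) {
    ok <- ok & IUPAC_MATCH_TABLE[cbind(sidx[k:(L - m + k)], pidx[k])]
  }
  which(ok)
}

#' Locate restriction sites
#'
#' Scans each sequence for recognition-site matches (IUPAC-aware, overlapping
#' occurrences all reported) and annotates the top-strand cut position.
#'
#' @param seqs A sequence-set tibble (or character vector of DNA strings).
#' @param enz An [enzyme()]; HaeIII by default.
#' @return A tibble with one row per site: `seq_id`, `site_start` (1-based
#'   start of the recognition site) and `cut_after` (the backbone is cut
#'   between `cut_after` and `cut_after + 1`; equals
#'   `site_start + cut_offset - 1`), sites in ascending order per sequence.
#' @examples
#' find_sites(c(x = "AAGGCCAA"))
#' @export
find_sites <- function(seqs, enz = enzyme()) {
  seqs <- as_sequence_set(seqs)
  stopifnot(inherits(enz, "ardra_enzyme"))
  out <- purrr::map2(seqs$id, seqs$residues, function(id, res) {
    st <- match_starts(strsplit(res, "", fixed = TRUE)[[1]], enz$recognition)
    tibble(seq_id = id, site_start = st, cut_after = st + enz$cut_offset - 1L)
  })
  bind_rows(out)
}

#' Digest sequences with a restriction enzyme
#'
#' Linear digestion: fragments are delimited by the enzyme's cut positions
#' plus the sequence ends, tile the sequence without gaps or overlaps, and
#' concatenate back to the input.
#'
#' @inheritParams find_sites
#' @return A tibble with one row per fragment: `seq_id`, `fragment` (index
#'   along the sequence), `start`, `end` (1-based inclusive), `length`,
#'   `residues`.
#' @examples
#' digest(c(x = "GGCC")) # two fragments "GG" and "CC"
#' @export
digest <- function(seqs, enz = enzyme()) {
  seqs <- as_sequence_set(seqs)
  sites <- find_sites(seqs, enz)
  out <- purrr::map2(seqs$id, seqs$residues, function(id, res) {
    L <- nchar(res)
    cuts <- sites$cut_after[sites$seq_id == id]
    cuts <- sort(unique(cuts[cuts >= 1L & cuts < L])) # end cuts are no-ops
    starts <- c(1L, cuts + 1L)
    ends <- c(cuts, L)
    tibble(
      seq_id = id, fragment = seq_along(starts),
      start = starts, end = ends, length = ends - starts + 1L,
      residues = substring(res, starts, ends)
    )
  })
  bind_rows(out)
}

# round-half-up (base round() is round-half-even)
round_half_up <- function(x) floor(x + 0.5)

# Single-linkage 1-D clustering: lengths closer than or equal to `tol` chain
# into one bin.  Returns integer bin index per element (bins ordered by
# increasing length).
bin_lengths <- function(lengths, tol) {
  stopifnot(tol >= 0)
  if (length(lengths) == 0L) return(integer(0))
  ord <- order(lengths)
  sorted <- lengths[ord]
  newbin <- c(TRUE, diff(sorted) > tol)
  bins_sorted <- cumsum(newbin)
  bins <- integer(length(lengths))
  bins[ord] <- bins_sorted
  bins
}

#' Gel-like band pattern of a digest
#'
#' Emulates what a 2% agarose gel with a 100 bp ladder resolves: fragments
#' shorter than `min_visible_length` run off and are discarded; remaining
#' fragment lengths are clustered by single linkage (a gap larger than
#' `bin_tolerance` separates bands) and each band is reported at the
#' round-half-up mean of its member lengths.
#'
#' @param fragments A fragment tibble from [digest()] (any data frame with a
#'   `length` column works; a `seq_id` column groups patterns per sequence
#'   unless `pool = TRUE`).
#' @param bin_tolerance Gel resolution in bp (default 10).
#' @param min_visible_length Fragments below this length are invisible
#'   (default 60 bp).
#' @param pool If `TRUE`, ignore `seq_id` and bin all fragments together
#'   (used when comparing cohorts).
#' @return A tibble of bands: `seq_id` (unless pooled), `bin_center`, `count`.
#' @export
band_pattern <- function(fragments, bin_tolerance = 10, min_visible_length = 60,
                         pool = FALSE) {
  stopifnot(is.data.frame(fragments), "length" %in% names(fragments))
  vis <- fragments[fragments$length >= min_visible_length, , drop = FALSE]
  per_group <- function(df) {
    if (nrow(df) == 0L) {
      return(tibble(bin_center = double(), count = integer()))
    }
    bins <- bin_lengths(df$length, bin_tolerance)
    tibble(length = df$length, bin = bins) |>
      group_by(.data$bin) |>
      summarise(bin_center = round_half_up(mean(.data$length)),
                count = n(), .groups = "drop") |>
      select("bin_center", "count")
  }
  if (!pool && "seq_id" %in% names(fragments)) {
    ids <- unique(fragments$seq_id)
    out <- purrr::map(ids, function(id) {
      b <- per_group(vis[vis$seq_id == id, , drop = FALSE])
      if (nrow(b)) b$seq_id <- id
      b
    })
    res <- bind_rows(out)
    if (nrow(res)) res <- select(res, "seq_id", "bin_center", "count")
    else res <- tibble(seq_id = character(), bin_center = double(),
                       count = integer())
  } else {
    res <- per_group(vis)
  }
  class(res) <- c("ardra_bands", class(res))
  res
}

#' Is the diagnostic band present?
#'
#' The marker system rests on a HaeIII fragment of around 460 bp found across
#' aerobic endospore-forming bacilli; this checks a band pattern for a band
#' center within `tolerance` of `target`.
#'
#' @param pattern A band tibble from [band_pattern()].
#' @param target Diagnostic band size in bp (default 460).
#' @param tolerance Acceptance half-width in bp (default 15).
#' @return A single logical for an ungrouped pattern, or a tibble
#'   (`seq_id`, `has_band`) when the pattern carries per-sequence bands.
#' @export
has_diagnostic_band <- function(pattern, target = 460, tolerance = 15) {
  stopifnot(is.data.frame(pattern), "bin_center" %in% names(pattern))
  hit <- abs(pattern$bin_center - target) <= tolerance
  if ("seq_id" %in% names(pattern)) {
    tibble(seq_id = unique(pattern$seq_id)) |>
      mutate(has_band = purrr::map_lgl(
        .data$seq_id, function(id) any(hit[pattern$seq_id == id])))
  } else {
    any(hit)
  }
}
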