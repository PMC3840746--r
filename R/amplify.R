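# Mismatch-tolerant primer-site search and in silico PCR.
#
# The mismatch model is Hamming-only (no indels): a hit needs at most
# `max_mismatches` substitutions overall and a perfect 3'-terminal anchor,
# mimicking the dominant mode of PCR failure.  Published primer-site
# variants in this system are substitution-only, so indel alignment would
# buy nothing.

# Mismatch profile of `pattern` against every window of `chars`.
# Returns list(total = int vector, by_pos = m x W logical matrix).
window_mismatches <- function(chars, pattern) {
  m <- nchar(pattern)
  L <- length(chars)
  if (L < m) {
    return(list(total = integer(0), by_pos = matrix(FALSE, m, 0)))
  }
  sidx <- match(chars, IUPAC_LETTERS)
  pidx <- match(strsplit(pattern, "", fixed = TRUE)[[1]], IUPAC_LETTERS)
  W <- L - m + 1L
  by_pos <- matrix(FALSE, m, W)
  for (k in seq_len(m)) {
    by_pos[k, ] <- !IUPAC_MATCH_TABLE[cbind(sidx[k:(W + k - 1L)], pidx[k])]
  }
  list(total = colSums(by_pos), by_pos = by_pos)
}

#' Find primer annealing sites
#'
#' Scans both strands of each sequence for sites within `max_mismatches`
#' substitutions of the primer, requiring zero mismatches in the primer's
#' 3'-terminal `anchor_3prime` bases (a mismatched 3' end blocks extension).
#' Comparison is IUPAC-aware ([iupac_match()]); indels are not modeled.
#' Minus-strand hits are reported in sense-strand coordinates.
#'
#' @param seqs A sequence-set tibble (or character vector).
#' @param prm An [primer()].
#' @param max_mismatches Maximum substitutions per site (default 2).
#' @param anchor_3prime Number of 3'-terminal primer bases that must match
#'   exactly (default 3).
#' @return A tibble with one row per hit: `seq_id`, `primer_name`, `strand`
#'   (`"+"`/`"-"`), `site_start`, `site_end` (1-based inclusive, sense
#'   strand), `mismatches`, `mismatch_positions` (list column of 1-based
#'   offsets within the site), `site_sequence` (sense-strand substring).
#' @export
find_primer_hits <- function(seqs, prm, max_mismatches = 2, anchor_3prime = 3) {
  seqs <- as_sequence_set(seqs)
  stopifnot(inherits(prm, "ardra_primer"))
  m <- nchar(prm$oligo)
  stopifnot(anchor_3prime >= 0, anchor_3prime <= m)

  scan_one <- function(id, res) {
    chars <- strsplit(res, "", fixed = TRUE)[[1]]
    rows <- list()

    # plus strand: oligo read 5'->3' along the sense strand; 3' anchor is
    # the last anchor_3prime site offsets
    mm <- window_mismatches(chars, prm$oligo)
    anchor_pos <- if (anchor_3prime > 0) (m - anchor_3prime + 1L):m else integer(0)
    keep <- which(mm$total <= max_mismatches &
                    colSums(mm$by_pos[anchor_pos, , drop = FALSE]) == 0L)
    if (length(keep)) {
      rows[[1]] <- tibble(
        seq_id = id, primer_name = prm$name, strand = "+",
        site_start = keep, site_end = keep + m - 1L,
        mismatches = mm$total[keep],
        mismatch_positions = purrr::map(keep, function(w) which(mm$by_pos[, w])),
        site_sequence = substring(res, keep, keep + m - 1L)
      )
    }

    # minus strand: scan with the reverse complement of the oligo; oligo
    # position p maps to site offset m - p + 1, so the 3' anchor is the
    # first anchor_3prime offsets of the sense-strand site
    rc <- reverse_complement(prm$oligo)
    mm2 <- window_mismatches(chars, rc)
    anchor_pos2 <- if (anchor_3prime > 0) seq_len(anchor_3prime) else integer(0)
    keep2 <- which(mm2$total <= max_mismatches &
                     colSums(mm2$by_pos[anchor_pos2, , drop = FALSE]) == 0L)
    if (length(keep2)) {
      rows[[2]] <- tibble(
        seq_id = id, primer_name = prm$name, strand = "-",
        site_start = keep2, site_end = keep2 + m - 1L,
        mismatches = mm2$total[keep2],
        mismatch_positions = purrr::map(keep2, function(w) which(mm2$by_pos[, w])),
        site_sequence = substring(res, keep2, keep2 + m - 1L)
      )
    }
    out <- bind_rows(rows)
    if (nrow(out)) arrange(out, .data$site_start, .data$strand) else out
  }

  out <- bind_rows(purrr::map2(seqs$id, seqs$residues, scan_one))
  if (nrow(out) == 0L) {
    out <- tibble(seq_id = character(), primer_name = character(),
                  strand = character(), site_start = integer(),
                  site_end = integer(), mismatches = integer(),
                  mismatch_positions = list(), site_sequence = character())
  }
  out
}

#' In silico PCR
#'
#' Pairs every plus-strand forward hit with every minus-strand reverse hit
#' downstream of it; each pair whose outer span (both primer sites included)
#' falls inside `product_window` yields one predicted amplicon.  Outer
#' coordinates include both primer sites: this is the convention under which
#' the published marker spans (e.g. 909-1371) have length 463.  Zero
#' amplicons is a valid result, not an error: that is exactly the behavior
#' of the system's negative controls.
#'
#' @inheritParams find_primer_hits
#' @param fwd Forward [primer()] (default [primer_463f()]).
#' @param rev Reverse [primer()] (default [primer_463r()]).
#' @param product_window Length-2 numeric `(min, max)` product size in bp
#'   (default `c(300, 700)`).
#' @return A tibble with one row per amplicon: `seq_id`, `orientation`
#'   (`"+"` when the forward primer sits on the stored strand, `"-"` for the
#'   mirrored configuration), `start`, `end` (1-based inclusive outer span
#'   on the stored strand), `length`, `residues` (stored-strand substring),
#'   `fwd_mismatches`, `rev_mismatches`, `fwd_site_sequence` (primer
#'   orientation), `rev_site_sequence` (reverse primer's sense-site
#'   orientation); sorted by input order, then start, then length.
#' @export
insilico_pcr <- function(seqs, fwd = primer_463f(), rev = primer_463r(),
                         max_mismatches = 2, product_window = c(300, 700),
                         anchor_3prime = 3) {
  seqs <- as_sequence_set(seqs)
  stopifnot(inherits(fwd, "ardra_primer"), inherits(rev, "ardra_primer"))
  if (fwd$role != "forward" || rev$role != "reverse") {
    abort("insilico_pcr() needs a forward and a reverse primer (in that order)",
          class = "ardra_data_error")
  }
  stopifnot(length(product_window) == 2L, product_window[1] <= product_window[2])

  fhits <- find_primer_hits(seqs, fwd, max_mismatches, anchor_3prime)
  rhits <- find_primer_hits(seqs, rev, max_mismatches, anchor_3prime)

  # orientation "+": forward primer on the plus strand upstream of the
  # reverse primer on the minus strand.  Orientation "-": the mirrored
  # configuration (the same physical product on a template stored in the
  # opposite sense; published screens record such hits as the primer pair
  # "in reverse order").  Site sequences are reported in primer
  # orientation: fwd comparable to the forward oligo, rev comparable to the
  # reverse primer's sense-strand annealing site.
  pair_up <- function(id, res, up, dn, orientation) {
    if (nrow(up) == 0L || nrow(dn) == 0L) return(NULL)
    pairs <- tidyr::expand_grid(ui = seq_len(nrow(up)), di = seq_len(nrow(dn)))
    starts <- up$site_start[pairs$ui]
    ends <- dn$site_end[pairs$di]
    len <- ends - starts + 1L
    ok <- up$site_start[pairs$ui] < dn$site_start[pairs$di] &
      len >= product_window[1] & len <= product_window[2]
    if (!any(ok)) return(NULL)
    ui <- pairs$ui[ok]
    di <- pairs$di[ok]
    f <- if (orientation == "+") up[ui, ] else dn[di, ]
    r <- if (orientation == "+") dn[di, ] else up[ui, ]
    fwd_site <- if (orientation == "+") f$site_sequence else
      reverse_complement(f$site_sequence)
    rev_site <- if (orientation == "+") r$site_sequence else
      reverse_complement(r$site_sequence)
    tibble(
      seq_id = id, orientation = orientation,
      start = starts[ok], end = ends[ok], length = len[ok],
      residues = substring(res, starts[ok], ends[ok]),
      fwd_mismatches = f$mismatches, rev_mismatches = r$mismatches,
      fwd_site_sequence = fwd_site, rev_site_sequence = rev_site
    )
  }

  one_seq <- function(id, res) {
    fh <- fhits[fhits$seq_id == id, , drop = FALSE]
    rh <- rhits[rhits$seq_id == id, , drop = FALSE]
    out <- bind_rows(
      pair_up(id, res, fh[fh$strand == "+", ], rh[rh$strand == "-", ], "+"),
      pair_up(id, res, rh[rh$strand == "+", ], fh[fh$strand == "-", ], "-")
    )
    if (nrow(out)) arrange(out, .data$start, .data$length, .data$orientation)
    else NULL
  }

  out <- bind_rows(purrr::map2(seqs$id, seqs$residues, one_seq))
  if (nrow(out) == 0L) {
    out <- tibble(seq_id = character(), orientation = character(),
                  start = integer(), end = integer(),
                  length = integer(), residues = character(),
                  fwd_mismatches = integer(), rev_mismatches = integer(),
                  fwd_site_sequence = character(),
                  rev_site_sequence = character())
  }
  out
}
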