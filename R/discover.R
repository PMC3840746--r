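# De novo diagnostic-fragment discovery: generalizes the observation that a
# single restriction-fragment size class separated one bacterial group from
# everything else into a procedure for arbitrary target/outgroup sets, with
# a simplified conserved-terminal-window primer designer standing in for an
# interactive primer-design program.

#' Discover diagnostic restriction fragments
#'
#' Digests every sequence in both sets, pools fragment lengths inside
#' `length_window`, clusters them into gel-like size bins (single linkage,
#' gap > `bin_tolerance` separates bins), and scores each bin by its
#' prevalence: the fraction of target (resp. outgroup) sequences carrying at
#' least one fragment in the bin.  Bins with
#' `target_prevalence >= min_target_prev`,
#' `outgroup_prevalence <= max_outgroup_prev` and a strictly positive
#' prevalence gap are reported, ranked by prevalence gap, then by number of
#' member fragments.  For each candidate, [design_primers()] is run on the
#' target-set member fragments.
#'
#' @param targets,outgroup Non-empty sequence-set tibbles.
#' @param enz An [enzyme()].
#' @param length_window Length-2 numeric: only fragment lengths inside this
#'   window are considered (default `c(200, 800)`).
#' @param min_target_prev Minimum fraction of target sequences with the band
#'   (default 0.9).
#' @param max_outgroup_prev Maximum fraction of outgroup sequences with the
#'   band (default 0.1).
#' @param bin_tolerance Size-bin resolution in bp (default 10).
#' @param design Run the primer designer on each candidate (default TRUE).
#' @param ... Passed to [design_primers()].
#' @return A tibble of class `ardra_candidates`, one row per candidate bin:
#'   `bin_center`, `n_fragments`, `target_prevalence`, `outgroup_prevalence`,
#'   `spans` (list column of per-sequence fragment spans), and when designed,
#'   `fwd_oligo`, `fwd_tm`, `rev_oligo`, `rev_tm`, `n_variable_columns`.
#'   Zero rows when nothing qualifies (not an error).
#' @export
discover_marker <- function(targets, outgroup, enz = enzyme(),
                            length_window = c(200, 800),
                            min_target_prev = 0.9, max_outgroup_prev = 0.1,
                            bin_tolerance = 10, design = TRUE, ...) {
  targets <- as_sequence_set(targets, "targets")
  outgroup <- as_sequence_set(outgroup, "outgroup")
  if (nrow(targets) == 0L || nrow(outgroup) == 0L) {
    abort("both target and outgroup sets must be non-empty",
          class = "ardra_data_error")
  }
  ft <- digest(targets, enz)
  fo <- digest(outgroup, enz)
  ft$set <- "target"
  fo$set <- "outgroup"
  pool <- bind_rows(ft, fo)
  pool <- pool[pool$length >= length_window[1] &
                 pool$length <= length_window[2], , drop = FALSE]
  empty <- tibble(bin_center = double(), n_fragments = integer(),
                  target_prevalence = double(), outgroup_prevalence = double(),
                  spans = list())
  if (nrow(pool) == 0L) {
    class(empty) <- c("ardra_candidates", class(empty))
    return(empty)
  }
  pool$bin <- bin_lengths(pool$length, bin_tolerance)
  n_t <- nrow(targets)
  n_o <- nrow(outgroup)
  cand <- pool |>
    group_by(.data$bin) |>
    summarise(
      bin_center = round_half_up(mean(.data$length)),
      n_fragments = n(),
      target_prevalence =
        length(unique(.data$seq_id[.data$set == "target"])) / n_t,
      outgroup_prevalence =
        length(unique(.data$seq_id[.data$set == "outgroup"])) / n_o,
      .groups = "drop"
    ) |>
    filter(.data$target_prevalence >= min_target_prev,
           .data$outgroup_prevalence <= max_outgroup_prev,
           .data$target_prevalence > .data$outgroup_prevalence) |>
    arrange(dplyr::desc(.data$target_prevalence - .data$outgroup_prevalence),
            dplyr::desc(.data$n_fragments), .data$bin_center)
  if (nrow(cand) == 0L) {
    class(empty) <- c("ardra_candidates", class(empty))
    return(empty)
  }
  cand$spans <- purrr::map(cand$bin, function(b) {
    mem <- pool[pool$bin == b & pool$set == "target", , drop = FALSE]
    select(mem, "seq_id", "start", "end", "length")
  })
  if (design) {
    proposals <- purrr::map(cand$bin, function(b) {
      mem <- pool[pool$bin == b & pool$set == "target", , drop = FALSE]
      design_primers(mem$residues, ...)
    })
    cand$fwd_oligo <- purrr::map_chr(proposals, function(p)
      if (nrow(p)) p$fwd_oligo[1] else NA_character_)
    cand$fwd_tm <- purrr::map_dbl(proposals, function(p)
      if (nrow(p)) p$fwd_tm[1] else NA_real_)
    cand$rev_oligo <- purrr::map_chr(proposals, function(p)
      if (nrow(p)) p$rev_oligo[1] else NA_character_)
    cand$rev_tm <- purrr::map_dbl(proposals, function(p)
      if (nrow(p)) p$rev_tm[1] else NA_real_)
    cand$n_variable_columns <- purrr::map_int(proposals, function(p)
      if (nrow(p)) p$n_variable_columns[1] else NA_integer_)
  }
  cand$bin <- NULL
  class(cand) <- c("ardra_candidates", class(cand))
  cand
}

# positional consensus of anchored columns; ties broken alphabetically so
# the designer is deterministic
consensus_base <- function(chars) {
  tab <- sort(table(chars), decreasing = TRUE)
  top <- names(tab)[tab == tab[1]]
  sort(top)[1]
}

#' Design a primer pair over conserved terminal windows
#'
#' A deliberately simple designer (a stand-in for interactive primer-design
#' software, documented as such): regions are anchored at their starts
#' (forward) and ends (reverse, emitted as the reverse-complement oligo); a
#' positional consensus is built over the terminal columns and candidate
#' windows slide within `max_offset` bases of each terminus.  A window is
#' kept when it has at most `max_degeneracy` non-unanimous columns and a
#' consensus Tm (basic GC formula, [primer_tm()]) inside `tm_window`.
#' Forward/reverse windows are then paired and ranked by total non-unanimous
#' columns, then by Tm balance `|Tm_f - Tm_r|`, then by smaller offsets,
#' then by longer windows.
#'
#' @param regions Character vector (>= 1) of DNA strings, e.g. the member
#'   fragments of a candidate bin.
#' @param primer_len Length-2 integer window of admissible primer lengths
#'   (default `c(18, 25)`).
#' @param max_degeneracy Maximum non-unanimous columns per window
#'   (default 1).
#' @param tm_window Admissible consensus Tm range in degrees Celsius
#'   (default `c(50, 65)`).
#' @param max_offset How far a window may slide in from the terminus
#'   (default 10).
#' @return A tibble with zero rows (no window satisfies the constraints) or
#'   one row: `fwd_oligo`, `fwd_tm`, `rev_oligo`, `rev_tm`,
#'   `n_variable_columns`.
#' @export
design_primers <- function(regions, primer_len = c(18, 25),
                           max_degeneracy = 1, tm_window = c(50, 65),
                           max_offset = 10) {
  stopifnot(length(regions) >= 1L)
  regions <- normalize_residues(regions)
  minlen <- min(nchar(regions))
  empty <- tibble(fwd_oligo = character(), fwd_tm = double(),
                  rev_oligo = character(), rev_tm = double(),
                  n_variable_columns = integer())
  lens <- seq(primer_len[1], primer_len[2])
  term <- min(minlen, max_offset + primer_len[2])
  if (term < primer_len[1]) return(empty)

  mats <- strsplit(regions, "", fixed = TRUE)
  # forward columns 1..term anchored at region starts; reverse columns
  # 1..term anchored at region ends (column j = j-th base from the 3' end)
  fcols <- lapply(seq_len(term), function(j)
    vapply(mats, function(ch) ch[j], character(1)))
  rcols <- lapply(seq_len(term), function(j)
    vapply(mats, function(ch) ch[length(ch) - j + 1L], character(1)))
  f_var <- vapply(fcols, function(cc) length(unique(cc)) > 1L, logical(1))
  r_var <- vapply(rcols, function(cc) length(unique(cc)) > 1L, logical(1))
  f_cons <- vapply(fcols, consensus_base, character(1))
  r_cons <- vapply(rcols, consensus_base, character(1))

  windows <- function(var, cons, reverse) {
    grid <- tidyr::expand_grid(offset = 0:max_offset, len = lens)
    grid <- grid[grid$offset + grid$len <= term, , drop = FALSE]
    if (nrow(grid) == 0L) return(NULL)
    rows <- purrr::pmap(grid, function(offset, len) {
      idx <- (offset + 1L):(offset + len)
      nv <- sum(var[idx])
      if (nv > max_degeneracy) return(NULL)
      sense <- paste(cons[idx], collapse = "")
      # reverse windows were collected 3'-to-5' along the sense strand:
      # re-reverse to sense orientation before complementing
      oligo <- if (reverse) {
        reverse_complement(paste(rev(cons[idx]), collapse = ""))
      } else sense
      tm <- primer_tm(oligo)
      if (tm < tm_window[1] || tm > tm_window[2]) return(NULL)
      tibble(offset = offset, len = len, n_var = nv, oligo = oligo, tm = tm)
    })
    bind_rows(rows)
  }

  fw <- windows(f_var, f_cons, reverse = FALSE)
  rw <- windows(r_var, r_cons, reverse = TRUE)
  if (is.null(fw) || is.null(rw) || nrow(fw) == 0L || nrow(rw) == 0L) {
    return(empty)
  }
  pairs <- tidyr::expand_grid(fi = seq_len(nrow(fw)), ri = seq_len(nrow(rw)))
  # windows must not collide on the shortest region
  ok <- (fw$offset[pairs$fi] + fw$len[pairs$fi] +
           rw$offset[pairs$ri] + rw$len[pairs$ri]) <= minlen
  pairs <- pairs[ok, , drop = FALSE]
  if (nrow(pairs) == 0L) return(empty)
  score <- tibble(
    n_var = fw$n_var[pairs$fi] + rw$n_var[pairs$ri],
    dtm = abs(fw$tm[pairs$fi] - rw$tm[pairs$ri]),
    off = fw$offset[pairs$fi] + rw$offset[pairs$ri],
    lf = fw$len[pairs$fi], lr = rw$len[pairs$ri]
  )
  best <- order(score$n_var, score$dtm, score$off, -score$lf, -score$lr)[1]
  fi <- pairs$fi[best]
  ri <- pairs$ri[best]
  tibble(
    fwd_oligo = fw$oligo[fi], fwd_tm = fw$tm[fi],
    rev_oligo = rw$oligo[ri], rev_tm = rw$tm[ri],
    n_variable_columns = as.integer(score$n_var[best])
  )
}

#' @rdname discover_marker
#' @param x An `ardra_candidates`.
#' @param ... Unused.
#' @export
glance.ardra_candidates <- function(x, ...) {
  tibble(
    n_candidates = nrow(x),
    best_bin = if (nrow(x)) x$bin_center[1] else NA_real_,
    best_gap = if (nrow(x)) x$target_prevalence[1] - x$outgroup_prevalence[1]
               else NA_real_
  )
}
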