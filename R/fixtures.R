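# Deterministic synthetic 16S-like sequences with planted primer sites,
# HaeIII sites and controlled mutations.  The generator is the package's
# ground truth: every planted coordinate is recorded, and the amplification
# and restriction modules must recover them exactly.
#
# Geometry of the default sequence (mirroring the published marker):
#   - full-length gene of 1550 bp;
#   - forward primer site at 909-930, reverse sense-strand site at
#     1354-1371, so the primer-delimited span is 909-1371, length 463;
#   - GGC planted at 906-908 so the forward primer's leading C completes a
#     HaeIII site cut after 907; the GGCC inside the reverse site is cut
#     after 1367; together they delimit a 460 bp digest fragment -- the
#     "around 460 bp" gel band sitting inside the 463 bp marker;
#   - background is ~55% GC (typical of 16S rRNA genes) with GGCC
#     suppressed everywhere except where planted, so site counts are
#     exactly controlled.

#' Specification for one synthetic 16S-like sequence
#'
#' @param seed Integer seed; generation is a pure function of the spec.
#' @param total_length Gene length in bp (default 1550, a full-length 16S).
#' @param fwd_site_start 1-based position of the forward primer site
#'   (default 909).
#' @param marker_length Outer primer-delimited span length (default 463).
#' @param fwd_variant `"G"` or `"A"`, the 463F form planted.
#' @param n_marker_substitutions Random substitutions planted strictly
#'   between the primer sites (default 0).
#' @param fwd_mismatches,rev_mismatches Substitutions planted inside the
#'   primer sites, never in the 3'-anchor bases and never destroying the
#'   HaeIII site inside the reverse site (default 0).
#' @param decoy_ggcc HaeIII sites planted outside the marker region
#'   (default 3), giving the gel pattern extra bands.
#' @param ablate_rev_site Leave the reverse site unplanted, so
#'   amplification fails (default FALSE).
#' @param extra_fwd_site Plant a second forward site inside the marker so
#'   that two in-window products arise (default FALSE).
#' @param gc Background GC fraction (default 0.55).
#' @param id Sequence id (default derived from the seed).
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1, total_length = 1550, fwd_site_start = 909,
                         marker_length = 463, fwd_variant = c("G", "A"),
                         n_marker_substitutions = 0, fwd_mismatches = 0,
                         rev_mismatches = 0, decoy_ggcc = 3,
                         ablate_rev_site = FALSE, extra_fwd_site = FALSE,
                         gc = 0.55, id = NULL) {
  fwd_variant <- match.arg(fwd_variant)
  s <- as.integer(fwd_site_start)
  L <- as.integer(total_length)
  ml <- as.integer(marker_length)
  if (s < 4L || s + ml - 1L > L) {
    abort("marker must fit inside the sequence (fwd_site_start >= 4 and span end <= total_length)",
          class = "ardra_data_error")
  }
  if (ml < 120L) {
    abort("marker_length must be at least 120 bp", class = "ardra_data_error")
  }
  structure(
    list(seed = as.integer(seed), total_length = L, fwd_site_start = s,
         marker_length = ml, fwd_variant = fwd_variant,
         n_marker_substitutions = as.integer(n_marker_substitutions),
         fwd_mismatches = as.integer(fwd_mismatches),
         rev_mismatches = as.integer(rev_mismatches),
         decoy_ggcc = as.integer(decoy_ggcc),
         ablate_rev_site = isTRUE(ablate_rev_site),
         extra_fwd_site = isTRUE(extra_fwd_site), gc = gc,
         id = if (is.null(id)) sprintf("aefb_s%d", as.integer(seed)) else id),
    class = "fixture_spec"
  )
}

random_dna_chars <- function(L, gc) {
  sample(c("A", "C", "G", "T"), L, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

# Replace the base at `pos` with one that differs and does not create a
# GGCC in the +/-3 window around it.
mutate_no_ggcc <- function(chars, pos) {
  for (b in sample(setdiff(c("A", "C", "G", "T"), chars[pos]))) {
    trial <- chars
    trial[pos] <- b
    lo <- max(1L, pos - 3L)
    hi <- min(length(chars), pos + 3L)
    if (length(match_starts(trial[lo:hi], "GGCC")) == 0L) return(trial)
  }
  chars # no safe base (cannot happen with a 4-letter alphabet)
}

# Remove every GGCC occurrence that is not fully inside a protected range
# by mutating one of its unprotected positions.
scrub_ggcc <- function(chars, protected_mask) {
  for (iter in 1:50) {
    occ <- match_starts(chars, "GGCC")
    bad <- occ[!vapply(occ, function(p) all(protected_mask[p:(p + 3L)]),
                       logical(1))]
    if (length(bad) == 0L) return(chars)
    for (p in bad) {
      free <- (p:(p + 3L))[!protected_mask[p:(p + 3L)]]
      pos <- free[1]
      chars[pos] <- if (chars[pos] == "A") "T" else "A"
    }
  }
  abort("failed to suppress background GGCC sites", class = "ardra_data_error")
}

# Core builder: assumes the RNG state is already set by the caller.
build_fixture <- function(spec) {
  L <- spec$total_length
  s <- spec$fwd_site_start
  e <- s + spec$marker_length - 1L
  fwd_oligo <- if (spec$fwd_variant == "G") PRIMER_463F_G else PRIMER_463F_A
  fchars <- strsplit(fwd_oligo, "", fixed = TRUE)[[1]]
  rchars <- strsplit(SITE_463R, "", fixed = TRUE)[[1]]
  flen <- length(fchars) # 22
  rlen <- length(rchars) # 18

  chars <- random_dna_chars(L, spec$gc)
  mask <- rep(FALSE, L)
  protect <- function(a, b) mask[a:b] <<- TRUE

  # flank GGC + forward primer site (the primer's first C completes GGCC)
  chars[(s - 3L):(s - 1L)] <- c("G", "G", "C")
  chars[s:(s + flen - 1L)] <- fchars
  protect(s - 3L, s + flen - 1L)
  cut_sites <- s - 3L

  rev_start <- e - rlen + 1L
  if (!spec$ablate_rev_site) {
    chars[rev_start:e] <- rchars
    protect(rev_start, e)
    cut_sites <- c(cut_sites, rev_start + 12L) # GGCC at site offsets 13-16
  }

  extra_start <- NA_integer_
  if (spec$extra_fwd_site) {
    extra_start <- s + 60L
    chars[extra_start:(extra_start + flen - 1L)] <- fchars
    protect(extra_start, extra_start + flen - 1L)
  }

  # decoy HaeIII sites outside the marker region; placed so that no
  # decoy-derived fragment lands near the diagnostic size class
  decoys <- integer(0)
  if (spec$decoy_ggcc > 0L) {
    lo_pool <- if (s - 53L >= 20L) 20L:(s - 53L) else integer(0)
    hi_pool <- if (L - 23L >= e + 20L) (e + 20L):(L - 23L) else integer(0)
    pool <- c(lo_pool, hi_pool)
    for (try in 1:100) {
      cand <- sort(sample(pool, spec$decoy_ggcc))
      if (length(cand) > 1L && min(diff(cand)) < 10L) next
      cuts <- sort(c(cand + 1L, s - 2L, if (!spec$ablate_rev_site) rev_start + 13L))
      lens <- diff(c(0L, cuts, L))
      diag_len <- spec$marker_length - 3L # the planted digest fragment
      extra_lens <- setdiff(lens, if (!spec$ablate_rev_site) diag_len else integer(0))
      if (!any(extra_lens >= 420L & extra_lens <= 520L)) { decoys <- cand; break }
    }
    if (length(decoys) == 0L && spec$decoy_ggcc > 0L) {
      abort("could not place decoy sites away from the diagnostic size class",
            class = "ardra_data_error")
    }
    for (p in decoys) {
      chars[p:(p + 3L)] <- c("G", "G", "C", "C")
      protect(p, p + 3L)
    }
    cut_sites <- c(cut_sites, decoys)
  }

  chars <- scrub_ggcc(chars, mask)

  # planted primer-site mismatches: never in the 3'-anchor bases; the
  # forward site's first base and the reverse site's internal GGCC are
  # also off-limits (they carry the restriction geometry)
  fwd_mm <- integer(0)
  if (spec$fwd_mismatches > 0L) {
    fwd_mm <- sort(sample(2:(flen - 3L), spec$fwd_mismatches))
    for (o in fwd_mm) chars <- mutate_no_ggcc(chars, s + o - 1L)
  }
  rev_mm <- integer(0)
  if (spec$rev_mismatches > 0L && !spec$ablate_rev_site) {
    rev_mm <- sort(sample(c(4:12, 17:18), spec$rev_mismatches))
    for (o in rev_mm) chars <- mutate_no_ggcc(chars, rev_start + o - 1L)
  }

  # free interior substitutions (marker divergence)
  interior <- (s + flen):(rev_start - 1L)
  subs <- integer(0)
  if (spec$n_marker_substitutions > 0L) {
    subs <- sort(sample(interior, spec$n_marker_substitutions))
    for (p in subs) chars <- mutate_no_ggcc(chars, p)
  }

  truth <- list(
    span = c(start = s, end = e),
    length = spec$marker_length,
    fwd_site = c(start = s, end = s + flen - 1L),
    rev_site = if (spec$ablate_rev_site) NULL else c(start = rev_start, end = e),
    digest_fragment = if (spec$ablate_rev_site) NULL else
      c(start = s - 1L, end = rev_start + 13L),
    digest_length = if (spec$ablate_rev_site) NA_integer_ else
      (rev_start + 13L) - (s - 1L) + 1L,
    cut_sites = sort(cut_sites),
    extra_fwd_site = extra_start,
    fwd_mismatch_offsets = fwd_mm,
    rev_mismatch_offsets = rev_mm,
    substitution_positions = subs
  )
  list(chars = chars, truth = truth)
}

#' Generate one synthetic 16S-like sequence
#'
#' Deterministic in the spec: the same [fixture_spec()] always yields the
#' identical sequence and truth record.
#'
#' @param spec A [fixture_spec()].
#' @return A list with `sequence` (a one-row sequence-set tibble) and
#'   `truth` (planted coordinates: span, primer sites, digest fragment,
#'   cut-site starts, mismatch offsets, substitution positions).
#' @examples
#' fx <- make_aefb_like(fixture_spec(seed = 42))
#' fx$truth$span
#' @export
make_aefb_like <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  built <- withr::with_seed(spec$seed, build_fixture(spec))
  list(
    sequence = sequence_set(spec$id, paste(built$chars, collapse = ""),
                            description = "synthetic 16S-like fixture"),
    truth = built$truth
  )
}

# outgroup sequence: GGCC-suppressed background plus planted cut sites whose
# fragment lengths avoid the diagnostic size class [430, 500]
build_outgroup_chars <- function(L, gc, n_sites) {
  for (try in 1:100) {
    chars <- random_dna_chars(L, gc)
    cand <- sort(sample(20:(L - 23L), n_sites))
    if (length(cand) > 1L && min(diff(cand)) < 10L) next
    lens <- diff(c(0L, cand + 1L, L))
    if (any(lens >= 430L & lens <= 500L)) next
    mask <- rep(FALSE, L)
    for (p in cand) {
      chars[p:(p + 3L)] <- c("G", "G", "C", "C")
      mask[p:(p + 3L)] <- TRUE
    }
    return(scrub_ggcc(chars, mask))
  }
  abort("could not build outgroup fixture", class = "ardra_data_error")
}

#' Generate a target/outgroup cohort
#'
#' Targets share a common ancestral sequence carrying the marker (built by
#' [make_aefb_like()] machinery, without decoy sites so the marker fragment
#' is the only one in the discovery window); each target receives
#' `divergence` random substitutions strictly between the primer sites, so
#' its amplification geometry is untouched.  Outgroup sequences lack both
#' primer sites and any fragment in the diagnostic size class.  With
#' `two_clade = TRUE`, targets descend from two ancestors 40 substitutions
#' apart, giving a planted bipartition for clustering checks.
#'
#' @param n_target,n_outgroup Cohort sizes (defaults 10/10).
#' @param divergence Substitutions per target sequence (default 5).
#' @param seed Integer seed for the whole cohort.
#' @param two_clade Split targets into two divergent clades (default FALSE).
#' @param spec Base [fixture_spec()] for the ancestor (its seed and
#'   mutation counts are ignored; decoys default off).
#' @return A list with `targets` and `outgroup` (sequence-set tibbles) and
#'   `truth` (ancestral marker geometry, per-target substitution positions,
#'   clade labels).
#' @export
make_cohort <- function(n_target = 10, n_outgroup = 10, divergence = 5,
                        seed = 1, two_clade = FALSE,
                        spec = fixture_spec(decoy_ggcc = 0)) {
  stopifnot(inherits(spec, "fixture_spec"), n_target >= 1, n_outgroup >= 0)
  base_spec <- spec
  base_spec$n_marker_substitutions <- 0L
  base_spec$fwd_mismatches <- 0L
  base_spec$rev_mismatches <- 0L
  base_spec$ablate_rev_site <- FALSE
  base_spec$extra_fwd_site <- FALSE

  withr::with_seed(as.integer(seed), {
    anc <- build_fixture(base_spec)
    s <- base_spec$fwd_site_start
    rev_start <- s + base_spec$marker_length - 18L
    interior <- (s + 22L):(rev_start - 1L)

    anc2 <- NULL
    if (two_clade) {
      ch <- anc$chars
      for (p in sample(interior, 40L)) ch <- mutate_no_ggcc(ch, p)
      anc2 <- ch
    }

    clade <- if (two_clade) sort(rep_len(c("A", "B"), n_target))
             else rep("A", n_target)

    subs_list <- vector("list", n_target)
    residues <- character(n_target)
    for (i in seq_len(n_target)) {
      ch <- if (clade[i] == "B") anc2 else anc$chars
      subs <- if (divergence > 0) sort(sample(interior, divergence)) else integer(0)
      for (p in subs) ch <- mutate_no_ggcc(ch, p)
      subs_list[[i]] <- subs
      residues[i] <- paste(ch, collapse = "")
    }
    targets <- sequence_set(sprintf("target_%02d", seq_len(n_target)), residues,
                            description = paste0("synthetic AEFB-like, clade ", clade))

    outgroup <- NULL
    if (n_outgroup > 0) {
      og <- vapply(seq_len(n_outgroup), function(j) {
        paste(build_outgroup_chars(base_spec$total_length, base_spec$gc,
                                   n_sites = sample(3:6, 1)), collapse = "")
      }, character(1))
      outgroup <- sequence_set(sprintf("outgroup_%02d", seq_len(n_outgroup)), og,
                               description = "synthetic non-AEFB control")
    }

    list(
      targets = targets,
      outgroup = outgroup,
      truth = c(anc$truth,
                list(clade = setNames(clade, targets$id),
                     target_substitutions = setNames(subs_list, targets$id)))
    )
  })
}
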