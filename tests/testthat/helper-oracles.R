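# Independent oracles used across the suite.  They deliberately avoid the
# package's own lookup tables and scanning code: IUPAC semantics come from
# Biostrings::IUPAC_CODE_MAP, site scanning is a naive window loop, and the
# alignment oracle enumerates all alignments recursively.

IUPAC15 <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
             "B", "D", "H", "V", "N")

oracle_sets <- strsplit(Biostrings::IUPAC_CODE_MAP[IUPAC15], "", fixed = TRUE)

# subject-side N matches nothing unless the pattern base is N
oracle_base_match <- function(s, p) {
  if (s == "N") return(p == "N")
  length(intersect(oracle_sets[[s]], oracle_sets[[p]])) > 0L
}

oracle_site_scan <- function(res, recognition) {
  chars <- strsplit(res, "", fixed = TRUE)[[1]]
  pat <- strsplit(recognition, "", fixed = TRUE)[[1]]
  m <- length(pat)
  L <- length(chars)
  if (L < m) return(integer(0))
  hits <- integer(0)
  for (i in seq_len(L - m + 1L)) {
    ok <- TRUE
    for (k in seq_len(m)) {
      if (!oracle_base_match(chars[i + k - 1L], pat[k])) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, i)
  }
  hits
}

oracle_hamming <- function(a, b) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  stopifnot(length(av) == length(bv))
  sum(av != bv)
}

# exhaustive global-alignment score under affine gaps
# (gap of length L costs gap_open + L * gap_extend)
oracle_align_score <- function(a, b, sc = ardra::align_scoring()) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(av)
  m <- length(bv)
  best <- -Inf
  rec <- function(i, j, score, last) {
    if (i > n && j > m) {
      best <<- max(best, score)
      return(invisible(NULL))
    }
    if (i <= n && j <= m) {
      s <- if (av[i] == bv[j]) sc$match else sc$mismatch
      rec(i + 1L, j + 1L, score + s, "d")
    }
    if (i <= n) {
      rec(i + 1L, j, score + sc$gap_extend + if (last != "u") sc$gap_open else 0, "u")
    }
    if (j <= m) {
      rec(i, j + 1L, score + sc$gap_extend + if (last != "l") sc$gap_open else 0, "l")
    }
  }
  rec(1L, 1L, 0, "start")
  best
}

random_dna <- function(L, letters = c("A", "C", "G", "T")) {
  paste(sample(letters, L, replace = TRUE), collapse = "")
}

random_iupac <- function(L) {
  paste(sample(IUPAC15, L, replace = TRUE), collapse = "")
}

# positionwise mismatch-mark oracle for the variant panel
oracle_mark <- function(observed, canonical) {
  oc <- strsplit(observed, "", fixed = TRUE)[[1]]
  cc <- strsplit(canonical, "", fixed = TRUE)[[1]]
  out <- character(length(oc))
  for (i in seq_along(oc)) {
    out[i] <- if (oc[i] == cc[i]) oc[i] else paste0("[", oc[i], "]")
  }
  paste(out, collapse = "")
}
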