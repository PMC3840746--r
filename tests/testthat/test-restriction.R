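test_that("find_sites locates HaeIII sites with correct cut positions", {
  s <- find_sites(c(x = "AAGGCCAA"))
  expect_equal(nrow(s), 1L)
  expect_equal(s$site_start, 3L)
  expect_equal(s$cut_after, 4L)
  expect_equal(nrow(find_sites(c(x = "ATATAT"))), 0L)
  # overlapping occurrences of a degenerate site are all reported
  gg <- find_sites(c(x = "GGGGCCCC"), enzyme("toy", "GGCC", 2))
  expect_equal(gg$site_start, 3L)
})

test_that("find_sites equals the naive window-scan oracle", {
  set.seed(21)
  enzymes <- list(enzyme(), enzyme("toy", "GGNCC", 2), enzyme("amb", "RGCY", 1))
  for (i in 1:120) {
    res <- random_dna(sample(4:50, 1))
    for (enz in enzymes) {
      expect_equal(find_sites(c(q = res), enz)$site_start,
                   oracle_site_scan(res, enz$recognition),
                   label = paste("scan", enz$name, res))
    }
  }
  # ambiguous subject bases: N must not satisfy concrete pattern bases
  expect_equal(find_sites(c(q = "GGNCCGGCC"))$site_start, 6L)
})

test_that("digest tiles the sequence and conserves residues", {
  fr <- digest(c(x = "GGCC"))
  expect_equal(fr$residues, c("GG", "CC"))
  expect_equal(fr$start, c(1L, 3L))
  expect_equal(fr$end, c(2L, 4L))
  one <- digest(c(x = "ATATATAT"))
  expect_equal(nrow(one), 1L)
  expect_equal(one$residues, "ATATATAT")
  set.seed(31)
  for (i in 1:100) {
    res <- random_dna(sample(10:400, 1))
    fr <- digest(c(q = res))
    expect_equal(sum(fr$length), nchar(res))
    expect_equal(paste(fr$residues, collapse = ""), res)
    expect_equal(fr$start[-1], fr$end[-nrow(fr)] + 1L)
  }
})

test_that("rejoining adjacent fragments never creates phantom sites", {
  set.seed(41)
  for (i in 1:20) {
    res <- random_dna(300, c("A", "C", "G", "T", "G", "C")) # GC-rich, many sites
    fr <- digest(c(q = res))
    if (nrow(fr) < 2L) next
    orig <- find_sites(c(q = res))$site_start
    for (j in seq_len(nrow(fr) - 1L)) {
      pair <- paste0(fr$residues[j], fr$residues[j + 1L])
      got <- find_sites(c(p = pair))$site_start + fr$start[j] - 1L
      expect_true(all(got %in% orig))
    }
  }
})

test_that("band_pattern clusters lengths at gel resolution", {
  fr <- tibble::tibble(length = c(463, 460, 120))
  b <- band_pattern(fr, bin_tolerance = 10)
  expect_equal(b$bin_center, c(120, 462)) # round-half-up mean of 463,460
  expect_equal(b$count, c(1L, 2L))
  expect_equal(nrow(band_pattern(tibble::tibble(length = 50))), 0L)
  b0 <- band_pattern(tibble::tibble(length = c(100, 101, 300)), bin_tolerance = 0)
  expect_equal(b0$bin_center, c(100, 101, 300))
  expect_equal(b0$count, rep(1L, 3))
})

test_that("diagnostic band detection is tolerance-aware", {
  expect_true(has_diagnostic_band(tibble::tibble(bin_center = 462)))
  expect_false(has_diagnostic_band(tibble::tibble(bin_center = 520)))
  fx <- make_aefb_like(fixture_spec(seed = 3))
  b <- band_pattern(digest(fx$sequence))
  expect_true(has_diagnostic_band(b)$has_band)
  # negative control: background with cut sites but no fragment in the
  # diagnostic size class, by construction
  co <- make_cohort(n_target = 1, n_outgroup = 2, seed = 3)
  bo <- band_pattern(digest(co$outgroup))
  expect_false(any(has_diagnostic_band(bo)$has_band))
})
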