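test_that("exact forward-primer site is found at the planted position", {
  fx <- make_aefb_like(fixture_spec(seed = 1))
  hits <- find_primer_hits(fx$sequence, primer_463f(), max_mismatches = 0)
  plus <- hits[hits$strand == "+", ]
  expect_equal(nrow(plus), 1L)
  expect_equal(plus$site_start, 909L)
  expect_equal(plus$site_end, 930L)
  expect_equal(plus$mismatches, 0)
})

test_that("a reverse-site variant yields a minus-strand hit with the right offset", {
  # observed sense site with a single substitution at site offset 15
  set.seed(61)
  subject <- paste0(random_dna(40), "AATACGTTCCCGGGTCTT", random_dna(40))
  hits <- find_primer_hits(c(s = subject), primer_463r())
  minus <- hits[hits$strand == "-", ]
  expect_equal(nrow(minus), 1L)
  expect_equal(minus$mismatches, 1)
  expect_equal(minus$mismatch_positions[[1]], 15L)
  expect_equal(minus$site_sequence, "AATACGTTCCCGGGTCTT")
})

test_that("no hits in sequences without the motif at zero mismatches", {
  set.seed(71)
  res <- random_dna(500)
  expect_equal(nrow(find_primer_hits(c(q = res), primer_463f(),
                                     max_mismatches = 0)), 0L)
})

test_that("planted primer-site mismatch counts are recovered exactly", {
  for (seed in c(2, 9, 17)) {
    fx <- make_aefb_like(fixture_spec(seed = seed, fwd_mismatches = 2,
                                      rev_mismatches = 1))
    fh <- find_primer_hits(fx$sequence, primer_463f())
    fh <- fh[fh$strand == "+" & fh$site_start == 909L, ]
    expect_equal(fh$mismatches, 2)
    expect_equal(fh$mismatch_positions[[1]], fx$truth$fwd_mismatch_offsets)
    rh <- find_primer_hits(fx$sequence, primer_463r())
    rh <- rh[rh$strand == "-" & rh$site_end == 1371L, ]
    expect_equal(rh$mismatches, 1)
    expect_equal(rh$mismatch_positions[[1]], fx$truth$rev_mismatch_offsets)
  }
})

test_that("3'-anchor mismatches veto a hit even within the budget", {
  fx <- make_aefb_like(fixture_spec(seed = 4))
  res <- fx$sequence$residues
  # break the last base of the forward site (oligo 3' end, position 930)
  ch <- strsplit(res, "")[[1]]
  ch[930] <- if (ch[930] == "G") "A" else "G"
  mut <- sequence_set("mut", paste(ch, collapse = ""))
  hits <- find_primer_hits(mut, primer_463f())
  expect_false(any(hits$strand == "+" & hits$site_start == 909L))
})

test_that("annotate_variant reproduces the bracketed-mismatch convention", {
  expect_equal(annotate_variant("AATACGTTCCCGGGTCTT", "AATACGTTCCCGGGCCTT"),
               "AATACGTTCCCGGG[T]CTT")
  expect_equal(annotate_variant("ACGT", "ACGT"), "ACGT")
  expect_equal(annotate_variant("AAAA", "TTTT"), "[A][A][A][A]")
  expect_error(annotate_variant("AAA", "AAAA"), class = "ardra_data_error")
})

test_that("in silico PCR reproduces the published span geometry on the fixture", {
  fx <- make_aefb_like(fixture_spec(seed = 1))
  amp <- insilico_pcr(fx$sequence)
  expect_equal(nrow(amp), 1L)
  expect_equal(amp$start, 909L)
  expect_equal(amp$end, 1371L)
  expect_equal(amp$length, 463L)
  # amplicon residues are bounded by near-primer sequences
  expect_lte(oracle_hamming(substr(amp$residues, 1, 22), primer_463f()$oligo), 2)
  expect_lte(oracle_hamming(substr(amp$residues, 446, 463),
                            reverse_complement(primer_463r()$oligo)), 2)
})

test_that("forward hit alone yields no product; extra site yields two", {
  abl <- make_aefb_like(fixture_spec(seed = 1, ablate_rev_site = TRUE))
  expect_equal(nrow(insilico_pcr(abl$sequence)), 0L)

  two <- make_aefb_like(fixture_spec(seed = 1, extra_fwd_site = TRUE))
  amp <- insilico_pcr(two$sequence)
  expect_equal(nrow(amp), 2L)
  # brute-force pairing oracle: every fwd/rev hit pair in the window
  fh <- find_primer_hits(two$sequence, primer_463f())
  rh <- find_primer_hits(two$sequence, primer_463r())
  fh <- fh[fh$strand == "+", ]
  rh <- rh[rh$strand == "-", ]
  expected <- 0L
  for (i in seq_len(nrow(fh))) {
    for (j in seq_len(nrow(rh))) {
      len <- rh$site_end[j] - fh$site_start[i] + 1L
      if (fh$site_start[i] < rh$site_start[j] && len >= 300 && len <= 700) {
        expected <- expected + 1L
      }
    }
  }
  expect_equal(nrow(amp), expected)
})

test_that("amplicon lengths are invariant under reverse-complementing the input", {
  for (seed in c(1, 8)) {
    fx <- make_aefb_like(fixture_spec(seed = seed, n_marker_substitutions = 4))
    rc <- sequence_set("rc", reverse_complement(fx$sequence$residues))
    a1 <- insilico_pcr(fx$sequence)
    a2 <- insilico_pcr(rc)
    expect_equal(sort(a1$length), sort(a2$length))
  }
})
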