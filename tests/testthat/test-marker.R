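test_that("extract_marker classifies positive / negative / indeterminate", {
  pos <- make_aefb_like(fixture_spec(seed = 1))
  call <- extract_marker(pos$sequence)
  expect_equal(call$classification, "positive")
  expect_equal(call$length, 463L)
  expect_equal(c(call$digest_start, call$digest_end), c(908L, 1367L))
  expect_equal(call$digest_length, 460L)
  expect_true(call$site_present)

  neg <- make_aefb_like(fixture_spec(seed = 1, ablate_rev_site = TRUE))
  expect_equal(extract_marker(neg$sequence)$classification, "negative")

  two <- make_aefb_like(fixture_spec(seed = 1, extra_fwd_site = TRUE))
  expect_equal(extract_marker(two$sequence)$classification, "indeterminate")
})

test_that("site rules diverge as documented", {
  fx <- make_aefb_like(fixture_spec(seed = 6))
  # default geometry: the only in-span HaeIII site sits inside the
  # reverse-primer region
  expect_true(extract_marker(fx$sequence, site_rule = "rev")$site_present)
  expect_true(extract_marker(fx$sequence, site_rule = "any")$site_present)
  expect_false(extract_marker(fx$sequence, site_rule = "interior")$site_present)
})

test_that("classification is invariant under reverse-complementing the input", {
  for (spec in list(fixture_spec(seed = 2),
                    fixture_spec(seed = 2, ablate_rev_site = TRUE))) {
    fx <- make_aefb_like(spec)
    rc <- sequence_set(fx$sequence$id, reverse_complement(fx$sequence$residues))
    expect_equal(extract_marker(rc)$classification,
                 extract_marker(fx$sequence)$classification)
  }
})

test_that("screen_panel reports one ordered row per sequence", {
  p1 <- make_aefb_like(fixture_spec(seed = 1, id = "s1"))
  # same seed as s1, so s2 is s1's marker plus 14 interior substitutions
  p2 <- make_aefb_like(fixture_spec(seed = 1, id = "s2",
                                    n_marker_substitutions = 14))
  p3 <- make_aefb_like(fixture_spec(seed = 3, id = "s3",
                                    ablate_rev_site = TRUE))
  panel <- dplyr::bind_rows(p1$sequence, p2$sequence, p3$sequence)
  ref <- extract_marker(p1$sequence)$residues
  scr <- screen_panel(panel, reference_marker = ref)
  expect_s3_class(scr, "ardra_screen")
  expect_equal(scr$seq_id, c("s1", "s2", "s3"))
  expect_equal(scr$classification, c("positive", "positive", "negative"))
  expect_equal(scr$start[1:2], c(909L, 909L))
  expect_equal(scr$percent_identity[1], 100)
  expect_equal(scr$percent_identity[2], 97) # 14 substitutions in 463 bp
  expect_true(is.na(scr$start[3]))
  g <- glance(scr)
  expect_equal(g$n_positive, 2L)
  expect_equal(g$n_negative, 1L)
})

test_that("screening an empty panel yields an empty table; re-screening is byte-identical", {
  empty <- sequence_set("a", "ACGT")[0, ]
  expect_equal(nrow(screen_panel(empty)), 0L)

  fx <- make_aefb_like(fixture_spec(seed = 5))
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::as_tibble(screen_panel(fx$sequence)), f1)
  readr::write_tsv(tibble::as_tibble(screen_panel(fx$sequence)), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("variant panel: bracket annotation equals the positionwise oracle", {
  panel <- aefb_variant_panel()
  expect_gte(nrow(panel), 30L)
  canon_f <- primer_463f("G")$oligo
  canon_r <- site_463r()
  for (i in seq_len(nrow(panel))) {
    expect_equal(annotate_variant(panel$fwd_site[i], canon_f),
                 oracle_mark(panel$fwd_site[i], canon_f),
                 label = panel$accession[i])
    expect_equal(annotate_variant(panel$rev_site[i], canon_r),
                 oracle_mark(panel$rev_site[i], canon_r),
                 label = panel$accession[i])
  }
  # hand-derived examples frozen from the published variants
  sed <- panel[panel$accession == "AB243866", ]
  expect_equal(annotate_variant(sed$fwd_site, canon_f),
               "CTGAAACTCAAA[A]GAATTGACG")
  expect_equal(annotate_variant(sed$rev_site, canon_r),
               "AATACGTTCCCGGG[T]CTT")
  mar <- panel[panel$accession == "AF483624", ]
  expect_equal(annotate_variant(mar$fwd_site, canon_f), canon_f)
  expect_equal(mar$span_end - mar$span_start + 1L, 463L)
})

test_that("variant destroying the reverse-site GGCC abolishes the site flag", {
  panel <- aefb_variant_panel()
  broken <- grepl("GGGTCTT", panel$rev_site)
  # the published +/- flag follows reverse-site integrity for these rows
  expect_true(all(panel$site[broken] == "-"))
  has_ggcc <- vapply(panel$rev_site, function(s)
    length(oracle_site_scan(s, "GGCC")) > 0, logical(1))
  expect_false(any(has_ggcc[broken]))
})
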