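test_that("p-distance and Jukes-Cantor match closed forms", {
  a <- strrep("ACGT", 25)
  expect_equal(unclass(distance_matrix(c(x = a, y = a)))["x", "y"], 0)

  set.seed(131)
  x <- strsplit(random_dna(100), "")[[1]]
  y <- x
  pos <- sample(100, 10)
  for (p in pos) y[p] <- setdiff(c("A", "C", "G", "T"), x[p])[1]
  pair <- c(x = paste(x, collapse = ""), y = paste(y, collapse = ""))
  expect_equal(unclass(distance_matrix(pair))["x", "y"], 0.10)
  jc <- unclass(distance_matrix(pair, model = "jukes_cantor"))["x", "y"]
  expect_equal(round(jc, 4), 0.1073)

  far <- c(a = strrep("A", 60), b = strrep("C", 60))
  expect_error(distance_matrix(far, model = "jukes_cantor"),
               class = "ardra_data_error")
})

test_that("distance_matrix is permutation-equivariant and tidy-able", {
  co <- make_cohort(5, 0, divergence = 4, seed = 23)
  mk <- extract_marker(co$targets)
  s <- sequence_set(mk$seq_id, mk$residues)
  d1 <- distance_matrix(s)
  perm <- c(3, 1, 5, 2, 4)
  d2 <- distance_matrix(s[perm, ])
  expect_equal(unclass(d2)[, ], unclass(d1)[perm, perm])
  td <- tidy(d1)
  expect_equal(nrow(td), choose(5, 2))
  expect_true(all(td$distance >= 0))
})

test_that("NJ recovers a known 4-taxon tree exactly", {
  # tree ((A:1,B:2):1,C:3,D:4) => additive distances
  d <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4,
              dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  tr <- nj_tree(d)
  expect_s3_class(tr, "phylo")
  expect_equal(max(abs(ape::cophenetic.phylo(tr)[rownames(d), colnames(d)] - d)), 0)
  tip_edge <- function(lbl) {
    tr$edge.length[tr$edge[, 2] == which(tr$tip.label == lbl)]
  }
  expect_equal(tip_edge("A"), 1)
  expect_equal(tip_edge("B"), 2)
  expect_equal(tip_edge("C"), 3)
  expect_equal(tip_edge("D"), 4)
  internal <- tr$edge.length[tr$edge[, 2] > 4]
  expect_equal(internal, 1)
})

test_that("three taxa resolve by the three-point formulas", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(d)
  lens <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(unname(lens[c("A", "B", "C")]), c(1, 2, 3))
})

test_that("NJ is exact on additive matrices and agrees with the reference NJ", {
  set.seed(141)
  for (i in 1:15) {
    n <- sample(4:6, 1)
    rt <- ape::rtree(n, br = function(k) stats::runif(k, 0.1, 2))
    d <- ape::cophenetic.phylo(rt)
    tr <- nj_tree(d)
    expect_lt(max(abs(ape::cophenetic.phylo(tr)[rownames(d), colnames(d)] - d)),
              1e-8)
    ref <- ape::nj(stats::as.dist(d))
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr), ape::unroot(ref))), 0)
  }
})

test_that("branch lengths are never negative, even on noisy matrices", {
  set.seed(151)
  for (i in 1:10) {
    n <- sample(4:8, 1)
    rt <- ape::rtree(n)
    d <- ape::cophenetic.phylo(rt)
    noise <- matrix(stats::runif(n * n, 0, 0.3), n)
    noise <- (noise + t(noise)) / 2
    diag(noise) <- 0
    tr <- nj_tree(d + noise)
    expect_true(all(tr$edge.length >= 0))
    expect_setequal(tr$tip.label, rownames(d))
  }
})

test_that("Newick round-trips preserve leaves and lengths", {
  d <- matrix(c(0, 2, 2, 2, 0, 2, 2, 2, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  f <- withr::local_tempfile(fileext = ".nwk")
  write_newick(nj_tree(d), f)
  expect_equal(readLines(f), "(A:1,B:1,C:1);")

  set.seed(161)
  for (i in 1:8) {
    rt <- ape::rtree(sample(4:12, 1))
    write_newick(rt, f)
    back <- read_newick(f)
    expect_setequal(back$tip.label, rt$tip.label)
    expect_equal(sort(back$edge.length), sort(rt$edge.length), tolerance = 1e-4)
  }
})

test_that("malformed Newick reports a position", {
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines("(A:1,(B:2,C:3);", f)
  expect_error(read_newick(f), "unclosed", class = "ardra_data_error")
  writeLines("A:1,B:2));", f)
  expect_error(read_newick(f), "position 8", class = "ardra_data_error")
})

test_that("cut_clusters splits at the longest internal edges", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(d)
  cl1 <- cut_clusters(tr, 1)
  expect_equal(unique(cl1$cluster), 1L)

  # caterpillar with one long internal edge
  cat_tree <- ape::read.tree(text = "((A:0.1,B:0.1):5,(C:0.1,D:0.1):0.1);")
  cl2 <- cut_clusters(cat_tree, 2)
  expect_equal(length(unique(cl2$cluster)), 2L)
  expect_equal(cl2$cluster[cl2$label %in% c("A", "B")][1],
               cl2$cluster[cl2$label == "B"])
  expect_true(all(cl2$cluster[cl2$label %in% c("C", "D")] !=
                    cl2$cluster[cl2$label == "A"]))
  expect_error(cut_clusters(cat_tree, 10), class = "ardra_data_error")
})

test_that("a two-clade cohort is recovered as its planted bipartition", {
  co <- make_cohort(10, 0, divergence = 3, seed = 11, two_clade = TRUE)
  mk <- extract_marker(co$targets)
  tr <- nj_tree(distance_matrix(sequence_set(mk$seq_id, mk$residues)))
  cl <- cut_clusters(tr, 2)
  tab <- table(cl$cluster, co$truth$clade[cl$label])
  # each recovered cluster maps to exactly one planted clade
  expect_equal(sort(as.vector(tab)), c(0, 0, 5, 5))
})
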