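# Marker-based distances and neighbor-joining trees.  Pairwise-alignment
# distances replace a multiple alignment: the published dendrograms are
# qualitative, and pairwise p-distances plus NJ are fully specifiable and
# testable.  Trees are ape "phylo" objects throughout.

#' Pairwise distance matrix over marker sequences
#'
#' Each pair is globally aligned ([global_align()]); the p-distance is the
#' proportion of mismatching columns among columns where both sequences have
#' a base (gap columns excluded).  The Jukes-Cantor model applies
#' `-(3/4) * log(1 - 4p/3)` to correct for multiple hits.
#'
#' @param markers A sequence-set tibble with at least two members.
#' @param model `"p_distance"` (default) or `"jukes_cantor"`.
#' @param scoring An [align_scoring()] for the pairwise alignments.
#' @return A symmetric matrix of class `marker_dist` with zero diagonal,
#'   labelled by sequence id; the model is kept in `attr(, "model")`.
#' @export
distance_matrix <- function(markers, model = c("p_distance", "jukes_cantor"),
                            scoring = align_scoring()) {
  markers <- as_sequence_set(markers, "markers")
  model <- match.arg(model)
  n <- nrow(markers)
  if (n < 2L) {
    abort("distance_matrix() needs at least two sequences",
          class = "ardra_data_error")
  }
  d <- matrix(0, n, n, dimnames = list(markers$id, markers$id))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      # canonical argument order (by content) so the distance is exactly
      # symmetric and permutation-equivariant even when co-optimal
      # alignments would place gaps differently
      pair <- sort(c(markers$residues[i], markers$residues[j]))
      aln <- global_align(pair[1], pair[2], scoring)
      cols <- alignment_columns(aln)
      compared <- sum(cols$both)
      p <- if (compared == 0L) 0 else
        sum(cols$both & cols$c1 != cols$c2) / compared
      if (model == "jukes_cantor") {
        if (p >= 0.75) {
          abort(sprintf(
            "p-distance %.3f between '%s' and '%s' is >= 0.75: Jukes-Cantor undefined",
            p, markers$id[i], markers$id[j]), class = "ardra_data_error")
        }
        p <- -0.75 * log(1 - 4 * p / 3)
      }
      d[i, j] <- d[j, i] <- p
    }
  }
  structure(d, model = model, class = c("marker_dist", "matrix", "array"))
}

#' @export
tidy.marker_dist <- function(x, ...) {
  m <- unclass(x)
  idx <- which(upper.tri(m), arr.ind = TRUE)
  tibble(
    item1 = rownames(m)[idx[, 1]],
    item2 = colnames(m)[idx[, 2]],
    distance = m[idx]
  )
}

as_dist_matrix <- function(d) {
  if (inherits(d, "marker_dist")) d <- unclass(d)
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d)) {
    abort("need a square distance matrix", class = "ardra_data_error")
  }
  if (is.null(rownames(d))) {
    rownames(d) <- colnames(d) <- paste0("t", seq_len(nrow(d)))
  }
  if (max(abs(d - t(d))) > 1e-8 || any(diag(d) != 0) || any(!is.finite(d))) {
    abort("distance matrix must be symmetric, finite, with zero diagonal",
          class = "ardra_data_error")
  }
  d
}

#' Neighbor-joining tree
#'
#' Canonical agglomerative neighbor joining: at each step the pair
#' minimizing the Q-criterion `(n-2) d(i,j) - r_i - r_j` is joined, with
#' deterministic tie-breaking by the smallest (row, column) index pair; limb
#' lengths come from the standard formulas, and negative limb estimates are
#' clamped to zero with the deficit transferred to the sister branch.  NJ is
#' exact on additive distance matrices: it recovers their topology and
#' branch lengths.
#'
#' @param d A `marker_dist`, `dist`, or symmetric labelled matrix with at
#'   least three taxa.
#' @return An unrooted `ape::phylo` tree (basal trifurcation, as
#'   conventional for NJ).
#' @export
nj_tree <- function(d) {
  d <- as_dist_matrix(d)
  n <- nrow(d)
  if (n < 3L) {
    abort("nj_tree() needs at least 3 taxa", class = "ardra_data_error")
  }
  labels <- rownames(d)
  active <- seq_len(n)            # node ids of current matrix rows
  next_id <- 2L * n - 2L          # internal ids count down so the final
                                  # (basal) node ends up as n + 1
  parent <- integer(0); child <- integer(0); elen <- double(0)
  add_edge <- function(p, c_, l) {
    parent <<- c(parent, p); child <<- c(child, c_); elen <<- c(elen, l)
  }
  clamp_pair <- function(li, lj) {
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    c(max(li, 0), max(lj, 0))
  }

  while (length(active) > 3L) {
    m <- length(active)
    r <- rowSums(d)
    q <- (m - 2) * d - outer(r, r, `+`)
    diag(q) <- Inf
    qmin <- min(q)
    hits <- which(q <= qmin + 1e-12 & upper.tri(q), arr.ind = TRUE)
    hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
    i <- hits[1, 1]; j <- hits[1, 2]
    li <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- d[i, j] - li
    ll <- clamp_pair(li, lj)
    u <- next_id; next_id <- next_id - 1L
    add_edge(u, active[i], ll[1])
    add_edge(u, active[j], ll[2])
    dn <- (d[i, ] + d[j, ] - d[i, j]) / 2
    d[i, ] <- dn; d[, i] <- dn; d[i, i] <- 0
    d <- d[-j, -j, drop = FALSE]
    active[i] <- u
    active <- active[-j]
  }

  # final three-node star: limb lengths from the three-point formulas
  la <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  lb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  lc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  limbs <- c(la, lb, lc)
  for (k in which(limbs < 0)) { # transfer deficit to the longest sister
    s <- setdiff(order(limbs, decreasing = TRUE), k)[1]
    limbs[s] <- limbs[s] + limbs[k]
    limbs[k] <- 0
  }
  limbs <- pmax(limbs, 0)
  root <- next_id
  stopifnot(root == n + 1L)
  for (k in 1:3) add_edge(root, active[k], limbs[k])

  tr <- structure(
    list(edge = cbind(parent, child, deparse.level = 0),
         edge.length = elen, tip.label = labels, Nnode = n - 2L),
    class = "phylo", order = NULL
  )
  ape::reorder.phylo(tr, "cladewise")
}

#' Write / read Newick trees
#'
#' Newick serialization with branch lengths at 6 significant digits;
#' round-trips are lossless up to that precision.  `read_newick()` validates
#' the text before parsing and reports the character position of unbalanced
#' parentheses.
#'
#' @param tree An `ape::phylo` tree.
#' @param path File path.
#' @return `write_newick()` returns `path` invisibly; `read_newick()`
#'   returns an `ape::phylo`.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path, digits = 6)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "ardra_data_error")
  }
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  depth <- 0L
  chars <- strsplit(txt, "", fixed = TRUE)[[1]]
  for (pos in seq_along(chars)) {
    if (chars[pos] == "(") depth <- depth + 1L
    if (chars[pos] == ")") depth <- depth - 1L
    if (depth < 0L) {
      abort(sprintf("Newick parse error: unbalanced ')' at position %d", pos),
            class = "ardra_data_error")
    }
  }
  if (depth != 0L) {
    abort(sprintf("Newick parse error: %d unclosed '(' at end of input", depth),
          class = "ardra_data_error")
  }
  if (!grepl(";", txt, fixed = TRUE)) {
    abort(sprintf("Newick parse error: missing ';' terminator at position %d",
                  nchar(txt) + 1L), class = "ardra_data_error")
  }
  tr <- tryCatch(ape::read.tree(text = txt), error = function(e) NULL,
                 warning = function(w) NULL)
  if (is.null(tr)) {
    abort("Newick parse error: unparsable tree text",
          class = "ardra_data_error")
  }
  tr
}

#' Cut a tree into k clusters
#'
#' Removes the `k - 1` longest internal edges (ties broken by edge order in
#' the tree) and reports the connected components of the remaining forest as
#' leaf clusters, numbered by first appearance in tip order.
#'
#' @param tree An `ape::phylo`.
#' @param k Number of clusters, `1 <= k <=` number of internal edges + 1.
#' @return A tibble with columns `label`, `cluster`.
#' @export
cut_clusters <- function(tree, k) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  internal <- which(tree$edge[, 2] > ntip)
  k <- as.integer(k)
  if (k < 1L || k > length(internal) + 1L) {
    abort(sprintf("k must be in [1, %d] for this tree", length(internal) + 1L),
          class = "ardra_data_error")
  }
  drop <- integer(0)
  if (k > 1L) {
    ord <- internal[order(-tree$edge.length[internal], seq_along(internal))]
    drop <- ord[seq_len(k - 1L)]
  }
  keep <- setdiff(seq_len(nrow(tree$edge)), drop)
  # union-find over remaining edges
  nodes <- ntip + tree$Nnode
  par <- seq_len(nodes)
  find <- function(x) { while (par[x] != x) { par[x] <<- par[par[x]]; x <- par[x] }; x }
  for (e in keep) {
    a <- find(tree$edge[e, 1]); b <- find(tree$edge[e, 2])
    if (a != b) par[a] <- b
  }
  comp <- vapply(seq_len(ntip), find, integer(1))
  cluster <- match(comp, unique(comp))
  tibble(label = tree$tip.label, cluster = cluster)
}
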