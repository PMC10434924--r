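#' @include AllClasses.R
#' @importFrom ape read.tree write.tree root getMRCA extract.clade is.rooted
NULL

.quoteLabel <- function(x) {
  ifelse(grepl("[^A-Za-z0-9_.-]", x), paste0("'", gsub("'", "''", x), "'"), x)
}

#' Neighbor-Joining tree from a distance matrix
#'
#' Standard agglomerative Neighbor-Joining (Saitou & Nei): at each step the
#' pair minimising Q(i, j) = (n-2) d(i, j) - r(i) - r(j) is joined; ties are
#' broken by the lowest (row, column) index pair so trees are
#' bit-reproducible. Negative branch lengths (a known NJ artefact) are
#' clamped to zero unless `clampNegative = FALSE`.
#'
#' @param dm a [DistanceMatrix-class] or square symmetric labelled matrix,
#'   n >= 3.
#' @param clampNegative clamp negative branch lengths to 0 (default TRUE).
#' @return an unrooted [ape::phylo] tree with branch lengths in the units of
#'   the input distances.
#' @export
neighborJoining <- function(dm, clampNegative = TRUE) {
  d <- if (is(dm, "DistanceMatrix")) as.matrix(dm) else dm
  n <- nrow(d)
  if (n < 3) stop("Neighbor-Joining needs at least 3 taxa")
  if (is.null(rownames(d))) stop("distance matrix must be labelled")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix must be symmetric")
  bl <- function(x) {
    if (clampNegative) max(x, 0) else x
  }
  nodes <- .quoteLabel(rownames(d)) # newick fragment per active node
  active <- seq_len(n)
  D <- d
  while (length(active) > 3) {
    m <- length(active)
    Dm <- D[active, active]
    r <- rowSums(Dm)
    Q <- (m - 2) * Dm - outer(r, r, "+")
    diag(Q) <- Inf
    # lowest (row, col) pair among the minima, i < j
    Qu <- Q
    Qu[lower.tri(Qu, diag = TRUE)] <- Inf
    best <- which(Qu == min(Qu), arr.ind = TRUE)
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
    i <- best[1]; j <- best[2]
    bi <- Dm[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    bj <- Dm[i, j] - bi
    ai <- active[i]; aj <- active[j]
    newick <- sprintf("(%s:%.12g,%s:%.12g)", nodes[ai], bl(bi),
                      nodes[aj], bl(bj))
    # distances from the new node u to every other active node
    ku <- (D[ai, active] + D[aj, active] - D[ai, aj]) / 2
    D[ai, active] <- ku
    D[active, ai] <- ku
    D[ai, ai] <- 0
    nodes[ai] <- newick
    active <- active[-j]
  }
  a <- active
  x <- (D[a[1], a[2]] + D[a[1], a[3]] - D[a[2], a[3]]) / 2
  y <- D[a[1], a[2]] - x
  z <- D[a[1], a[3]] - x
  newick <- sprintf("(%s:%.12g,%s:%.12g,%s:%.12g);",
                    nodes[a[1]], bl(x), nodes[a[2]], bl(y), nodes[a[3]], bl(z))
  ape::read.tree(text = newick)
}

#' Root a tree on an outgroup's pendant edge
#'
#' @param tree an [ape::phylo] tree.
#' @param outgroup a leaf label.
#' @return a rooted `phylo`; rooting an already correctly rooted tree is a
#'   no-op.
#' @export
rootWithOutgroup <- function(tree, outgroup) {
  if (!outgroup %in% tree$tip.label)
    stop("outgroup '", outgroup, "' is not a leaf of the tree")
  ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
}

#' Assign leaves to lineage groups anchored on known haplotypes
#'
#' Each group is defined by >= 1 anchor leaves; the group's clade is the
#' smallest rooted clade containing all of its anchors. A clade that
#' contains another group's anchors is rejected with a diagnostic. Leaves
#' falling in no anchor clade are `"ungrouped"`.
#'
#' @param tree a rooted [ape::phylo] tree.
#' @param anchors named list of character vectors of anchor leaf labels,
#'   e.g. `list(group1 = c("H1", "H2"), group2 = c("H8", "H9"))`.
#' @return named character vector over all leaves (minus any outgroup
#'   passed via `exclude`), values = group names or `"ungrouped"`.
#' @param exclude leaf labels to leave out of the assignment (outgroups).
#' @export
assignGroups <- function(tree, anchors, exclude = character()) {
  if (!ape::is.rooted(tree)) stop("tree must be rooted (see rootWithOutgroup)")
  if (is.null(names(anchors)) || any(names(anchors) == ""))
    stop("anchor sets must be named")
  tips <- tree$tip.label
  for (g in names(anchors)) {
    missing <- setdiff(anchors[[g]], tips)
    if (length(missing))
      stop("anchor leaves not in tree (", g, "): ",
           paste(missing, collapse = ", "))
  }
  cladeTips <- function(labels) {
    if (length(labels) == 1) return(labels)
    node <- ape::getMRCA(tree, labels)
    ape::extract.clade(tree, node)$tip.label
  }
  clades <- lapply(anchors, cladeTips)
  for (g in names(clades)) {
    others <- unlist(anchors[setdiff(names(anchors), g)])
    bad <- intersect(clades[[g]], others)
    if (length(bad))
      stop("anchor clades are not disjoint: clade of '", g,
           "' contains foreign anchor(s) ", paste(bad, collapse = ", "),
           "; choose anchors that span separate clades")
  }
  leaves <- setdiff(tips, exclude)
  out <- stats::setNames(rep("ungrouped", length(leaves)), leaves)
  for (g in names(clades))
    out[intersect(clades[[g]], leaves)] <- g
  out
}
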