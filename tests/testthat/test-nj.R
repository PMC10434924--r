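test_that("three taxa give the closed-form star branch lengths", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighborJoining(d)
  expect_setequal(tr$tip.label, c("a", "b", "c"))
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[["a"]], (3 + 4 - 5) / 2)
  expect_equal(bl[["b"]], (3 + 5 - 4) / 2)
  expect_equal(bl[["c"]], (4 + 5 - 3) / 2)
})

test_that("an additive four-taxon matrix is recovered exactly", {
  # hand-built tree: ((A:1,B:2):3,(C:4,D:5)) with internal edge 3
  d <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  d["A", "B"] <- d["B", "A"] <- 3
  d["A", "C"] <- d["C", "A"] <- 8
  d["A", "D"] <- d["D", "A"] <- 9
  d["B", "C"] <- d["C", "B"] <- 9
  d["B", "D"] <- d["D", "B"] <- 10
  d["C", "D"] <- d["D", "C"] <- 9
  tr <- neighborJoining(d)
  expect_equal(ape::cophenetic.phylo(tr)[rownames(d), colnames(d)], d,
               tolerance = 1e-12)
  # AB | CD split present
  rt <- rootWithOutgroup(tr, "D")
  ab <- ape::extract.clade(rt, ape::getMRCA(rt, c("A", "B")))$tip.label
  expect_setequal(ab, c("A", "B"))
})

test_that("NJ reproduces random additive trees (property)", {
  set.seed(30)
  for (rep in 1:15) {
    n <- sample(4:12, 1)
    tr0 <- ape::rtree(n, br = function(k) runif(k, 0.05, 1))
    D <- ape::cophenetic.phylo(tr0)
    tr <- neighborJoining(D, clampNegative = FALSE)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr), ape::unroot(tr0))), 0)
    expect_lt(max(abs(ape::cophenetic.phylo(tr)[rownames(D), colnames(D)] - D)),
              1e-9)
    expect_setequal(tr$tip.label, tr0$tip.label)
  }
})

test_that("NJ agrees with ape::nj on non-additive matrices", {
  set.seed(31)
  for (rep in 1:5) {
    n <- 8
    m <- matrix(runif(n * n, 0.1, 1), n)
    d <- (m + t(m)) / 2; diag(d) <- 0
    dimnames(d) <- list(paste0("t", 1:n), paste0("t", 1:n))
    mine <- neighborJoining(d, clampNegative = FALSE)
    ref <- ape::nj(as.dist(d))
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(mine), ape::unroot(ref))), 0)
  }
})

test_that("equal distances resolve deterministically with equal leaf depths", {
  d <- matrix(1, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  diag(d) <- 0
  t1 <- neighborJoining(d)
  t2 <- neighborJoining(d)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  tipEdges <- t1$edge.length[t1$edge[, 2] <= 4]
  expect_equal(tipEdges, rep(0.5, 4))
})

test_that("negative branch lengths are clamped unless retained", {
  d <- matrix(c(0, 0.249, 0.492, 0.183,
                0.249, 0, 0.627, 0.456,
                0.492, 0.627, 0, 0.692,
                0.183, 0.456, 0.692, 0), 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  clamped <- neighborJoining(d, clampNegative = TRUE)
  raw <- neighborJoining(d, clampNegative = FALSE)
  expect_true(all(clamped$edge.length >= 0))
  expect_true(any(raw$edge.length < 0))
})

test_that("NJ input validation", {
  d2 <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(neighborJoining(d2), "at least 3")
  d3 <- matrix(c(0, 1, 2, 3, 0, 1, 2, 1, 0), 3,
               dimnames = list(letters[1:3], letters[1:3]))
  expect_error(neighborJoining(d3), "symmetric")
})

test_that("outgroup rooting is placed on the pendant edge and idempotent", {
  set.seed(32)
  tr <- ape::rtree(6)
  rt <- rootWithOutgroup(ape::unroot(tr), "t1")
  expect_true(ape::is.rooted(rt))
  kids <- rt$edge[rt$edge[, 1] == ape::Ntip(rt) + 1, 2]
  childTips <- lapply(kids, function(k)
    if (k <= ape::Ntip(rt)) rt$tip.label[k]
    else ape::extract.clade(rt, k)$tip.label)
  expect_true(any(vapply(childTips, function(x) identical(x, "t1"), TRUE)))
  rt2 <- rootWithOutgroup(rt, "t1")
  expect_identical(ape::write.tree(rt2), ape::write.tree(rt))
  expect_error(rootWithOutgroup(tr, "nope"), "not a leaf")
})

test_that("anchored group assignment labels clades and leaves the rest", {
  tr <- ape::read.tree(text = "(((A1:1,A2:1):2,(B1:1,(B2:1,B3:1):1):2):1,OG:5);")
  rt <- rootWithOutgroup(tr, "OG")
  grp <- assignGroups(rt, list(group1 = c("A1", "A2"),
                               group2 = c("B1", "B3")), exclude = "OG")
  expect_identical(grp[["A1"]], "group1")
  expect_identical(grp[["B2"]], "group2")
  expect_setequal(names(grp), c("A1", "A2", "B1", "B2", "B3"))
  # overlapping anchor clades are rejected with a diagnostic
  expect_error(assignGroups(rt, list(g1 = c("A1", "B1"), g2 = c("B2", "B3"))),
               "not disjoint")
  expect_error(assignGroups(rt, list(g1 = c("A1", "ZZ"))), "not in tree")
  expect_error(assignGroups(ape::unroot(tr), list(g1 = c("A1", "A2"))),
               "rooted")
})

test_that("a tree with only one anchored group leaves others ungrouped", {
  tr <- ape::read.tree(text = "(((A1:1,A2:1):2,(B1:1,B2:1):2):1,OG:5);")
  rt <- rootWithOutgroup(tr, "OG")
  grp <- assignGroups(rt, list(group1 = c("A1", "A2")), exclude = "OG")
  expect_identical(unname(grp[c("A1", "A2")]), rep("group1", 2))
  expect_identical(unname(grp[c("B1", "B2")]), rep("ungrouped", 2))
})

test_that("fixture NJ tree: published group 2 is a clean clade, HU58 falls
           outside both groups", {
  fx <- studyFixture()
  seqs <- haplotypeSequences(fx$haplotypes)
  set.seed(33)
  og <- paste(sample(c("A", "C", "G", "T"), 434, TRUE), collapse = "")
  aln <- c(seqs, Biostrings::DNAStringSet(c(Foccidentalis = og)))
  tree <- neighborJoining(seqDistanceMatrix(aln, "p"))
  rt <- rootWithOutgroup(tree, "Foccidentalis")
  grp <- assignGroups(rt, list(group1 = c("H1", "H5"),
                               group2 = c("H8", "H15", "H28", "H30", "HU57")),
                      exclude = "Foccidentalis")
  g2pub <- names(fx$groups)[fx$groups == "group2"]
  expect_setequal(names(grp)[grp == "group2"], g2pub)
  expect_identical(grp[["H28"]], "group2")
  expect_identical(grp[["HU58"]], "ungrouped")
  expect_setequal(names(grp), haplotypeNames(fx$haplotypes))
})
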