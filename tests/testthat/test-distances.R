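test_that("pairwise distances match closed-form expectations", {
  a <- paste(rep("A", 434), collapse = "")
  b <- paste(c("C", rep("A", 433)), collapse = "")
  expect_equal(pairwiseDistance(a, b, "p"), 1 / 434)
  for (m in c("p", "JC69", "K2P", "MCL"))
    expect_identical(pairwiseDistance(a, a, m), 0)
  # all sites different
  x <- "ACACAC"; y <- "CACACA"
  expect_equal(pairwiseDistance(x, y, "p"), 1)
  expect_error(pairwiseDistance(x, y, "JC69"), "undefined")
  expect_error(pairwiseDistance("----", "AAAA", "p"), "resolved")
})

test_that("distance matrices equal an independent site-loop oracle", {
  set.seed(20)
  for (rep in 1:10) {
    seqs <- randomAlignment(6, 80, pDiff = 0.04, missingEnds = 3)
    dm <- as.matrix(seqDistanceMatrix(seqs, "p"))
    for (m in c("p", "JC69", "K2P", "MCL")) {
      dmm <- as.matrix(seqDistanceMatrix(seqs, m))
      for (i in 1:5) for (j in (i + 1):6)
        expect_equal(dmm[i, j], oracleDistance(seqs[i], seqs[j], m),
                     tolerance = 1e-12)
    }
    expect_true(isSymmetric(dm))
    expect_true(all(diag(dm) == 0))
  }
})

test_that("distances agree with ape::dist.dna under pairwise deletion", {
  set.seed(21)
  seqs <- randomAlignment(8, 120, pDiff = 0.05)
  bin <- ape::as.DNAbin(t(sapply(strsplit(tolower(seqs), ""), identity)))
  for (pair in list(c("p", "raw"), c("JC69", "JC69"), c("K2P", "K80"))) {
    mine <- as.matrix(seqDistanceMatrix(seqs, pair[1]))
    ref <- as.matrix(ape::dist.dna(bin, model = pair[2],
                                   pairwise.deletion = TRUE))
    expect_equal(mine, ref[rownames(mine), colnames(mine)],
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
  # MCL (pair-frequency TN93 form) vs ape TN93 on two-sequence alignments,
  # where both use the same empirical frequencies
  for (rep in 1:5) {
    two <- randomAlignment(2, 200, pDiff = 0.05)
    bin2 <- ape::as.DNAbin(t(sapply(strsplit(tolower(two), ""), identity)))
    expect_equal(pairwiseDistance(two[1], two[2], "MCL"),
                 as.numeric(ape::dist.dna(bin2, model = "TN93")),
                 tolerance = 1e-8)
  }
})

test_that("p-distance satisfies the triangle inequality on random triples", {
  set.seed(22)
  for (rep in 1:30) {
    tri <- randomAlignment(3, 60, pDiff = 0.2)
    d12 <- pairwiseDistance(tri[1], tri[2], "p")
    d13 <- pairwiseDistance(tri[1], tri[3], "p")
    d23 <- pairwiseDistance(tri[2], tri[3], "p")
    expect_lte(d12, d13 + d23 + 1e-12)
    expect_lte(d13, d12 + d23 + 1e-12)
    expect_lte(d23, d12 + d13 + 1e-12)
  }
})

test_that("all models converge at small divergences", {
  set.seed(23)
  seqs <- randomAlignment(6, 434, pDiff = 0.002)
  ds <- lapply(c("p", "JC69", "K2P", "MCL"), function(m)
    as.matrix(seqDistanceMatrix(seqs, m)))
  for (k in 2:4)
    expect_lt(max(abs(ds[[1]] - ds[[k]])), 5e-4)
  # MCL within 10% of JC69 at p <= 0.05
  seqs2 <- randomAlignment(4, 434, pDiff = 0.045)
  j <- as.matrix(seqDistanceMatrix(seqs2, "JC69"))
  m <- as.matrix(seqDistanceMatrix(seqs2, "MCL"))
  off <- upper.tri(j)
  expect_true(all(abs(m[off] - j[off]) <= 0.1 * j[off] + 1e-12))
})

test_that("pairwise deletion reproduces complete-sequence distances when
           the differing sites are resolved", {
  set.seed(24)
  full <- randomAlignment(2, 100, pDiff = 0) # identical pair
  s <- strsplit(full[2], "")[[1]]
  s[c(40, 60)] <- c("G", "C") # may coincide with original; force change
  s[40] <- setdiff(c("A", "C", "G", "T"), strsplit(full[1], "")[[1]][40])[1]
  s[60] <- setdiff(c("A", "C", "G", "T"), strsplit(full[1], "")[[1]][60])[1]
  complete <- c(full[1], paste(s, collapse = ""))
  dFull <- pairwiseDistance(complete[1], complete[2], "p")
  s[1:5] <- "-" # five leading missing on one sequence
  masked <- c(full[1], paste(s, collapse = ""))
  dMasked <- pairwiseDistance(masked[1], masked[2], "p")
  expect_equal(dMasked, 2 / 95)
  expect_equal(dFull, 2 / 100)
})

test_that("within-sample diversity is the mean over all unordered pairs", {
  two <- c(paste(rep("A", 434), collapse = ""),
           paste(c(rep("A", 433), "G"), collapse = ""))
  expect_equal(withinSampleDiversity(two, "p")$mean_pairwise_distance,
               1 / 434)
  expect_error(withinSampleDiversity(two[1]), "at least two")
  # duplicate-collapsed computation equals direct pair enumeration
  set.seed(25)
  samp <- sample(randomAlignment(4, 50, pDiff = 0.05), 12, replace = TRUE)
  got <- withinSampleDiversity(samp, "p")$mean_pairwise_distance
  dm <- as.matrix(seqDistanceMatrix(samp, "p"))
  expect_equal(got, mean(dm[upper.tri(dm)]), tolerance = 1e-12)
})

test_that("between-sample distance averages all cross pairs", {
  fx <- studyFixture()
  seqs <- as.character(haplotypeSequences(fx$haplotypes))
  expect_identical(betweenSampleDistance(seqs["H1"], seqs["H1"], "p"), 0)
  a <- rep(seqs["H1"], 10); b <- rep(seqs["HU40"], 10)
  expect_equal(betweenSampleDistance(a, b, "p"), 1 / 434)
  expect_error(betweenSampleDistance(character(), a), "non-empty")
  # dXY(A, A) >= within diversity relation, checked by direct enumeration
  samp <- rep(seqs[c("H1", "H7", "H8")], c(5, 3, 2))
  within <- withinSampleDiversity(samp, "p")$mean_pairwise_distance
  dAA <- betweenSampleDistance(samp, samp, "p")
  dm <- as.matrix(seqDistanceMatrix(samp, "p"))
  expect_equal(dAA, mean(dm), tolerance = 1e-12)
  expect_gte(within, dAA) # self pairs dilute the cross mean
})

test_that("mean haplotype distance is unweighted over haplotype pairs", {
  fx <- studyFixture()
  seqs <- haplotypeSequences(fx$haplotypes)
  ht2 <- HaplotypeTable(seqs[c("H1", "H7")], counts = c(100L, 1L))
  expect_equal(meanHaplotypeDistance(ht2, "p"), 12 / 434)
  same <- HaplotypeTable(
    setNames(Biostrings::DNAStringSet(rep("ACGTACGT", 2)), c("a", "b")),
    counts = c(3L, 2L))
  expect_identical(meanHaplotypeDistance(same, "p"), 0)
})

test_that("distance matrix writers produce readable output", {
  set.seed(26)
  dm <- seqDistanceMatrix(randomAlignment(4, 50), "p")
  f <- withr::local_tempfile(fileext = ".tsv")
  writeDistanceTSV(dm, f)
  back <- utils::read.delim(f, check.names = FALSE)
  expect_equal(as.matrix(back[, -1]), as.matrix(dm), ignore_attr = TRUE)
  fp <- withr::local_tempfile(fileext = ".phy")
  writePhylipLower(dm, fp)
  expect_identical(trimws(readLines(fp)[1]), "4")
})
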