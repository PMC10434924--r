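test_that("FASTA round-trip preserves ids, order and uppercases bases", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">ind1 some description", "acgtACGTnn-",
               ">ind2", "TTTTAAAACCCC", ">ind3", "GGG-TTTT"), f)
  x <- readCoiFasta(f)
  expect_length(x, 3)
  expect_identical(names(x), c("ind1", "ind2", "ind3"))
  expect_identical(as.character(x[["ind1"]]), "ACGTACGTNN-")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  writeCoiFasta(x, f2)
  expect_identical(as.character(readCoiFasta(f2)), as.character(x))
})

test_that("FASTA reader rejects duplicates and missing files, allows empty", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGT", ">a", "TTTT"), f)
  expect_error(readCoiFasta(f), "duplicate")
  expect_error(readCoiFasta(file.path(tempdir(), "nope.fa")), "no such file")
  fe <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(), fe)
  expect_length(readCoiFasta(fe), 0)
})

test_that("sample metadata round-trips and validates coordinates", {
  md <- data.frame(sample_id = c("a", "b"), location = c("X", "Y"),
                   latitude = c(10.5, -3), longitude = c(100, -55),
                   date = NA, host = "onion", extra_col = 1:2)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeSampleMetadata(md, f)
  md2 <- readSampleMetadata(f)
  expect_identical(md2$sample_id, md$sample_id)
  expect_true("extra_col" %in% colnames(md2))
  bad <- md; bad$latitude[1] <- 95
  fb <- withr::local_tempfile(fileext = ".tsv")
  writeSampleMetadata(bad, fb)
  expect_error(readSampleMetadata(fb), "latitude")
})

test_that("primer table reader validates the IUPAC alphabet", {
  pr <- readPrimerTable(system.file("extdata", "primers.tsv",
                                    package = "ThripsCOI"))
  expect_setequal(pr$name, c("MTD7.2F", "MTD9.2R", "TCOR", "TCOS", "TCOC"))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("name\tsequence\torientation", "bad\tACGTX\tF"), f)
  expect_error(readPrimerTable(f), "non-IUPAC")
})

test_that("trimPrimers excises both primer footprints", {
  pr <- thripsPrimers()
  fwd <- pr$sequence[pr$name == "MTD7.2F"]
  rev <- pr$sequence[pr$name == "MTD9.2R"]
  set.seed(1)
  core <- paste(sample(c("A", "C", "G", "T"), 434, TRUE), collapse = "")
  # H and Y in the forward primer are degenerate: instantiate one variant
  fwdConcrete <- chartr("HY", "AC", fwd)
  tmpl <- paste0(fwdConcrete, core, oracleRevComp(rev))
  out <- trimPrimers(setNames(tmpl, "t1"), fwd, rev, maxMismatch = 0)
  expect_identical(as.character(out[[1]]), core)
  expect_true(attr(out, "trimmed"))
})

test_that("templates lacking a primer are flagged and returned unchanged", {
  set.seed(2)
  tmpl <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  expect_warning(
    out <- trimPrimers(setNames(tmpl, "x"), "AAAAAAAAAACCCCCCCCCC",
                       "GGGGGGGGGGTTTTTTTTTT", maxMismatch = 0),
    "untrimmed")
  expect_identical(as.character(out[[1]]), tmpl)
  expect_false(attr(out, "trimmed"))
  expect_error(trimPrimers("ACGT", "AAAAAAAAAA", "CCCCCCCCCC"),
               "primer longer")
})

test_that("one-mismatch primers are found iff allowed (Hamming-scan oracle)", {
  set.seed(3)
  fwd <- "ACGTACGTACGTACG"
  rev <- "TTTTCCCCAAAAGGG"
  core <- paste(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = "")
  fwdMut <- paste0("T", substr(fwd, 2, nchar(fwd))) # 1 mismatch
  tmpl <- paste0(fwdMut, core, oracleRevComp(rev))
  expect_length(oracleMatchPrimer(tmpl, fwd, 0), 0)
  expect_identical(oracleMatchPrimer(tmpl, fwd, 1), 0L)
  expect_warning(out0 <- trimPrimers(setNames(tmpl, "x"), fwd, rev, 0))
  expect_false(attr(out0, "trimmed"))
  out1 <- trimPrimers(setNames(tmpl, "x"), fwd, rev, 1)
  expect_true(attr(out1, "trimmed"))
  expect_identical(as.character(out1[[1]]), core)
})

test_that("windowTrim implements the half-open barcode window", {
  set.seed(4)
  s <- paste(sample(c("A", "C", "G", "T"), 800, TRUE), collapse = "")
  w <- windowTrim(setNames(s, "x"), 341, 775)
  expect_identical(Biostrings::width(w), 434L)
  expect_identical(as.character(w[[1]]), substr(s, 341, 774))
  expect_identical(as.character(windowTrim(s, 1, 801)[[1]]), s)
  expect_error(windowTrim(s, 100, 100), "positive length")
  expect_error(windowTrim(s, 500, 900), "outside")
})

test_that("qcFilter drops >5 terminal missing and keeps boundary cases", {
  mk <- function(lead, trail) {
    paste(c(rep("-", lead),
            sample(c("A", "C", "G", "T"), 434 - lead - trail, TRUE),
            rep("-", trail)), collapse = "")
  }
  set.seed(5)
  seqs <- setNames(c(mk(6, 0), mk(0, 0), mk(0, 5), mk(5, 5), mk(0, 7)),
                   paste0("r", 1:5))
  res <- qcFilter(seqs)
  expect_setequal(names(res$kept), c("r2", "r3", "r4"))
  expect_setequal(names(res$discarded), c("r1", "r5"))
  # partition: kept and discarded are disjoint and cover the input
  expect_setequal(c(names(res$kept), names(res$discarded)), names(seqs))
  # idempotent
  res2 <- qcFilter(res$kept)
  expect_identical(as.character(res2$kept), as.character(res$kept))
  expect_length(res2$discarded, 0)
})

test_that("windowTrim then qcFilter commutes for fully covered sequences", {
  set.seed(6)
  full <- vapply(1:4, function(i)
    paste(sample(c("A", "C", "G", "T"), 800, TRUE), collapse = ""), "")
  names(full) <- paste0("s", 1:4)
  a <- qcFilter(windowTrim(full, 341, 775))$kept
  b <- windowTrim(qcFilter(full, windowLen = 800)$kept, 341, 775)
  expect_identical(as.character(a), as.character(b))
})
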