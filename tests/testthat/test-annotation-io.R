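test_that("an empty GFF3 file yields an empty annotation", {
  p <- withr::local_tempfile(fileext = ".gff3")
  writeLines("##gff-version 3", p)
  ann <- readGFF3(p)
  expect_s4_class(ann, "GeneAnnotation")
  expect_equal(nGenes(ann), 0L)
  expect_equal(nTranscripts(ann), 0L)
})

test_that("GFF3 coordinates and hierarchy survive a read", {
  p <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t101\t200\t.\t+\t.\tID=g1",
    "chr1\tsrc\tmRNA\t101\t200\t.\t+\t.\tID=g1.t1;Parent=g1",
    "chr1\tsrc\texon\t101\t150\t.\t+\t.\tParent=g1.t1",
    "chr1\tsrc\texon\t161\t200\t.\t+\t.\tParent=g1.t1",
    "chr1\tsrc\tCDS\t120\t150\t.\t+\t0\tParent=g1.t1"), p)
  ann <- readGFF3(p)
  expect_equal(nGenes(ann), 1L)
  g <- genes(ann)
  expect_equal(GenomicRanges::start(g), 101L)
  expect_equal(GenomicRanges::end(g), 200L)
  ex <- exonRanges(ann)[["g1.t1"]]
  expect_equal(GenomicRanges::start(ex), c(101L, 161L))
  cd <- cdsRanges(ann)[["g1.t1"]]
  expect_equal(GenomicRanges::end(cd), 150L)
})

test_that("malformed and structurally broken GFF3 raise located errors", {
  p <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t101\t200\t.\t+\t.\tID=g1",
               "chr1\tsrc\tgene\tnot_a_number"), p)
  expect_error(readGFF3(p), "line 3")

  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t101\t200\t.\t+\t.\tID=g1",
               "chr1\tsrc\tmRNA\t101\t200\t.\t+\t.\tID=t1;Parent=gX",
               "chr1\tsrc\texon\t101\t200\t.\t+\t.\tParent=t1"), p)
  expect_error(readGFF3(p), "t1")

  # transcripts disagreeing with their gene's strand are rejected at load
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t101\t400\t.\t+\t.\tID=g1",
               "chr1\tsrc\tmRNA\t101\t200\t.\t+\t.\tID=t1;Parent=g1",
               "chr1\tsrc\texon\t101\t200\t.\t+\t.\tParent=t1",
               "chr1\tsrc\tmRNA\t201\t400\t.\t-\t.\tID=t2;Parent=g1",
               "chr1\tsrc\texon\t201\t400\t.\t-\t.\tParent=t2"), p)
  expect_error(readGFF3(p), "strand")
})

test_that("write/read round-trip preserves a 50-gene simulated annotation", {
  fx <- simulateAnnotatedGenome(
    fixtureConfig(seed = 11, nGenes = 50L, nChromosomes = 4L))
  p <- withr::local_tempfile(fileext = ".gff3")
  writeGFF3(fx$annotation, p)
  back <- readGFF3(p)
  expect_equal(nGenes(back), nGenes(fx$annotation))
  expect_equal(nTranscripts(back), nTranscripts(fx$annotation))
  expect_setequal(geneIds(back), geneIds(fx$annotation))
  for (tid in txIds(fx$annotation)) {
    expect_equal(
      as.data.frame(exonRanges(back)[[tid]])[, 1:5],
      as.data.frame(exonRanges(fx$annotation)[[tid]])[, 1:5])
    expect_equal(
      as.data.frame(cdsRanges(back)[[tid]])[, 1:5],
      as.data.frame(cdsRanges(fx$annotation)[[tid]])[, 1:5])
  }
  # second write is byte-stable
  p2 <- withr::local_tempfile(fileext = ".gff3")
  writeGFF3(back, p2)
  p3 <- withr::local_tempfile(fileext = ".gff3")
  writeGFF3(back, p3)
  expect_identical(readLines(p2), readLines(p3))
})

test_that("non-core feature lines are carried verbatim through a round-trip", {
  p <- withr::local_tempfile(fileext = ".gff3")
  utr <- "chr1\tsrc\tfive_prime_UTR\t101\t119\t.\t+\t.\tParent=g1.t1"
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t101\t200\t.\t+\t.\tID=g1",
               "chr1\tsrc\tmRNA\t101\t200\t.\t+\t.\tID=g1.t1;Parent=g1",
               "chr1\tsrc\texon\t101\t200\t.\t+\t.\tParent=g1.t1",
               utr), p)
  ann <- readGFF3(p)
  p2 <- withr::local_tempfile(fileext = ".gff3")
  writeGFF3(ann, p2)
  expect_true(utr %in% readLines(p2))
})

test_that("mergeIntervals matches the per-base bitmap oracle", {
  # declared behavior on the trivial cases
  expect_equal(length(mergeIntervals(IRanges::IRanges())), 0L)
  m <- mergeIntervals(IRanges::IRanges(c(11, 16), c(20, 25)))
  expect_equal(IRanges::start(m), 11L)
  expect_equal(IRanges::end(m), 25L)
  expect_error(
    mergeIntervals(GenomicRanges::GRanges(c("a", "b"),
                                          IRanges::IRanges(1, 10))),
    "single seqname")

  set.seed(42)
  for (rep in 1:20) {
    iv <- randIntervals(200L, 2000L)
    m <- mergeIntervals(IRanges::IRanges(iv[, 1], iv[, 2]))
    expect_true(IRanges::isDisjoint(m))
    expect_false(is.unsorted(IRanges::start(m)))
    expect_equal(sum(IRanges::width(m)),
                 sum(bitmapCover(iv[, 1], iv[, 2], 2000L)))
    # idempotent and order-insensitive
    perm <- iv[sample.int(nrow(iv)), , drop = FALSE]
    m2 <- mergeIntervals(IRanges::IRanges(perm[, 1], perm[, 2]))
    expect_identical(as.data.frame(m), as.data.frame(m2))
    expect_identical(as.data.frame(mergeIntervals(m)), as.data.frame(m))
  }
})

test_that("overlapWidth matches the bitmap oracle and is symmetric", {
  expect_equal(overlapWidth(IRanges::IRanges(1, 10), IRanges::IRanges(11, 20)),
               0L)
  expect_equal(overlapWidth(IRanges::IRanges(1, 10), IRanges::IRanges(6, 8)),
               3L)
  set.seed(43)
  for (rep in 1:100) {
    a <- randIntervals(20L, 1000L)
    b <- randIntervals(20L, 1000L)
    ia <- IRanges::IRanges(a[, 1], a[, 2])
    ib <- IRanges::IRanges(b[, 1], b[, 2])
    ov <- overlapWidth(ia, ib)
    expect_equal(ov, bruteOverlapBp(a[, 1], a[, 2], b[, 1], b[, 2], 1000L))
    expect_equal(ov, overlapWidth(ib, ia))
    expect_lte(ov, min(sum(IRanges::width(IRanges::reduce(ia))),
                       sum(IRanges::width(IRanges::reduce(ib)))))
  }
})
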