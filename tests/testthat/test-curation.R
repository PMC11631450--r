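test_that("repeat overlap fraction agrees with the bitmap oracle", {
  # no repeats -> 0; CDS fully inside a repeat -> 1
  g <- makeAnn(list(simpleGene("g1", "c1", "+", 101L, 500L)))
  expect_equal(unname(repeatOverlapFraction(g, GenomicRanges::GRanges())), 0)
  rep1 <- GenomicRanges::GRanges("c1", IRanges::IRanges(1, 10000))
  expect_equal(unname(repeatOverlapFraction(g, rep1)), 1)

  set.seed(7)
  for (i in 1:100) {
    nCds <- sample(1:4, 1)
    cds <- randIntervals(nCds, 900L, maxLen = 80L)
    cds <- cds[order(cds[, 1]), , drop = FALSE]
    # keep CDS parts disjoint for a valid transcript
    keep <- c(TRUE, if (nCds > 1) cds[-1, 1] > cds[-nCds, 2])
    cds <- cds[keep, , drop = FALSE]
    ann <- makeAnn(list(list(id = "g", chr = "c1", strand = "+",
      tx = list("g.t1" = list(
        exons = rbind(c(1L, 1000L)), cds = cds)))))
    reps <- randIntervals(5L, 1000L, maxLen = 200L)
    repGr <- GenomicRanges::GRanges("c1",
      IRanges::IRanges(reps[, 1], reps[, 2]))
    got <- unname(repeatOverlapFraction(ann, repGr))
    cdsBit <- bitmapCover(cds[, 1], cds[, 2], 1000L)
    repBit <- bitmapCover(reps[, 1], reps[, 2], 1000L)
    expect_equal(got, sum(cdsBit & repBit) / sum(cdsBit))
  }
})

test_that("type-1 filter removes at and above the threshold, never below", {
  mk <- function(cdsLen, repLen) {
    ann <- makeAnn(list(list(id = "g", chr = "c1", strand = "+",
      tx = list("g.t1" = list(exons = rbind(c(1L, 1000L)),
                              cds = rbind(c(1L, cdsLen)))))))
    reps <- GenomicRanges::GRanges("c1", IRanges::IRanges(1, repLen))
    filterType1(ann, reps)
  }
  expect_equal(mk(100L, 95L)$removed, "g")   # fraction 0.95
  expect_equal(mk(100L, 90L)$removed, "g")   # fraction exactly 0.90
  expect_equal(mk(100L, 89L)$removed, character(0))  # fraction 0.89

  # planted-truth fixture: exactly the planted transposon-genes go,
  # near-misses at ~0.80 stay
  fx <- simulateAnnotatedGenome(fixtureConfig(seed = 5))
  res <- filterType1(fx$annotation, fx$repeats)
  expect_setequal(res$removed, fx$truth$type1)
  expect_true(all(fx$truth$nearMiss %in% geneIds(res$annotation)))
})

test_that("type-2 filter implements shortest-first removal on chains", {
  # pair: shorter of two same-strand overlappers is removed
  ann <- makeAnn(list(simpleGene("long", "c1", "+", 1L, 500L),
                      simpleGene("short", "c1", "+", 400L, 300L)))
  expect_equal(filterType2(ann)$removed, "short")

  # opposite strands: both kept
  ann2 <- makeAnn(list(simpleGene("a", "c1", "+", 1L, 500L),
                       simpleGene("b", "c1", "-", 400L, 300L)))
  expect_equal(filterType2(ann2)$removed, character(0))

  # chain A(100) ov B(200), B ov C(300), A and C disjoint:
  # remove A first (globally shortest), then B, keep C
  ann3 <- makeAnn(list(simpleGene("A", "c1", "+", 150L, 100L, inset = 5L),
                       simpleGene("B", "c1", "+", 100L, 200L, inset = 5L),
                       simpleGene("C", "c1", "+", 260L, 300L, inset = 5L)))
  res <- filterType2(ann3)
  expect_equal(res$removed, c("A", "B"))
  expect_equal(geneIds(res$annotation), "C")

  # post-condition: no retained same-strand span overlap, on random layouts
  set.seed(8)
  for (i in 1:30) {
    n <- sample(5:12, 1)
    genes <- lapply(seq_len(n), function(j) {
      simpleGene(sprintf("g%02d", j), "c1",
                 sample(c("+", "-"), 1),
                 sample.int(3000L, 1), sample(50:400, 1), inset = 5L)
    })
    res <- filterType2(makeAnn(genes))
    g <- genes(res$annotation)
    hits <- GenomicRanges::findOverlaps(g, drop.self = TRUE,
                                        ignore.strand = FALSE)
    expect_equal(length(hits), 0L)
  }
})

test_that("type-3 splitting matches a union-find oracle on random graphs", {
  # two isoforms far apart are split into two genes
  ann <- makeAnn(list(list(id = "g", chr = "c1", strand = "+", tx = list(
    "g.t1" = list(exons = rbind(c(1L, 500L)), cds = rbind(c(10L, 490L))),
    "g.t2" = list(exons = rbind(c(10001L, 10500L)),
                  cds = rbind(c(10010L, 10490L)))))))
  res <- splitType3(ann)
  expect_equal(res$splitIds, "g")
  expect_equal(res$nCreated, 2L)
  expect_setequal(geneIds(res$annotation), c("g_1", "g_2"))

  # overlap is transitive through components: t1-t2, t2-t3 keeps one gene
  ann2 <- makeAnn(list(list(id = "g", chr = "c1", strand = "+", tx = list(
    "g.t1" = list(exons = rbind(c(1L, 300L)), cds = NULL),
    "g.t2" = list(exons = rbind(c(250L, 600L)), cds = NULL),
    "g.t3" = list(exons = rbind(c(550L, 900L)), cds = NULL)))))
  expect_equal(splitType3(ann2)$splitIds, character(0))

  set.seed(9)
  for (i in 1:50) {
    nTx <- sample(2:8, 1)
    exStarts <- sample.int(5000L, nTx)
    exLen <- sample(100:800, nTx, replace = TRUE)
    tx <- lapply(seq_len(nTx), function(j)
      list(exons = rbind(c(exStarts[j], exStarts[j] + exLen[j])), cds = NULL))
    names(tx) <- paste0("g.t", seq_len(nTx))
    ann <- makeAnn(list(list(id = "g", chr = "c1", strand = "+", tx = tx)))
    res <- splitType3(ann)
    # oracle: union-find over pairwise exon-footprint overlaps
    edges <- which(outer(seq_len(nTx), seq_len(nTx), function(a, b) {
      exStarts[a] <= exStarts[b] + exLen[b] &
        exStarts[b] <= exStarts[a] + exLen[a]
    }), arr.ind = TRUE)
    comp <- bruteComponents(nTx, edges)
    expect_equal(nGenes(res$annotation), length(unique(comp)))
    # transcripts sharing an oracle component share the final gene
    got <- transcripts(res$annotation)$gene_id[
      match(names(tx), txIds(res$annotation))]
    expect_equal(length(unique(got)), length(unique(comp)))
    expect_true(all(tapply(got, comp, function(v) length(unique(v)) == 1L)))
    # transcript count conserved
    expect_equal(nTranscripts(res$annotation), nTx)
  }
})

test_that("the full curation pipeline recovers planted truth and is idempotent", {
  fx <- simulateAnnotatedGenome(fixtureConfig(seed = 1))
  res <- curateAnnotation(fx$annotation, fx$repeats)
  r <- res$report
  expect_equal(r@nRemovedType1, 3L)
  expect_equal(r@nRemovedType2, 2L)
  expect_equal(r@nGenesSplitType3, 1L)
  expect_equal(r@nGenesCreatedType3, 2L)
  expect_setequal(r@type1Ids, fx$truth$type1)
  expect_setequal(r@type2Ids, fx$truth$type2Removed)
  expect_setequal(r@type3Ids, fx$truth$type3)
  expect_equal(r@nOutput,
               r@nInput - r@nRemovedType1 - r@nRemovedType2 -
                 r@nGenesSplitType3 + r@nGenesCreatedType3)

  # idempotence: a second pass changes nothing
  res2 <- curateAnnotation(res$annotation, fx$repeats)
  expect_equal(res2$report@nRemovedType1, 0L)
  expect_equal(res2$report@nRemovedType2, 0L)
  expect_equal(res2$report@nGenesSplitType3, 0L)
  expect_identical(geneIds(res2$annotation), geneIds(res$annotation))
  expect_identical(txIds(res2$annotation), txIds(res$annotation))

  # empty annotation: all-zero report
  res3 <- curateAnnotation(makeAnn(list()), GenomicRanges::GRanges())
  expect_equal(res3$report@nInput, 0L)
  expect_equal(res3$report@nOutput, 0L)
  expect_equal(nGenes(res3$annotation), 0L)
})
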