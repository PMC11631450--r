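test_that("canonical k-mer enumeration matches the string oracle", {
  ks <- canonicalKmers("ACGT", k = 4)
  expect_equal(kmers(ks), "ACGT")  # self reverse complement
  expect_equal(length(canonicalKmers("ACG", k = 4)), 0L)
  # windows with ambiguity codes are skipped
  expect_equal(kmers(canonicalKmers("ACGNACGTT", k = 4)),
               bruteCanonicalKmers("ACGNACGTT", 4))

  set.seed(51)
  for (k in c(5L, 11L, 21L)) {
    s <- randomDna(2000L)
    expect_equal(kmers(canonicalKmers(s, k = k)), bruteCanonicalKmers(s, k))
  }
  # strand symmetry on random sequences
  for (i in 1:10) {
    s <- randomDna(500L)
    expect_equal(canonicalKmers(s, k = 9)@codes,
                 canonicalKmers(stringRevcomp(s), k = 9)@codes)
  }
})

test_that("containment matches brute-force set intersection", {
  set.seed(52)
  ref <- canonicalKmers(randomDna(3000L), k = 11)
  sub <- canonicalKmers(randomDna(200L), k = 11)
  expect_equal(containment(ref, ref), 1.0)
  for (i in 1:20) {
    q <- canonicalKmers(randomDna(300L), k = 11)
    got <- containment(q, ref)
    expect_equal(got,
                 length(intersect(kmers(q), kmers(ref))) / length(kmers(q)))
  }
  disjointA <- canonicalKmers(strrep("A", 50), k = 11)
  disjointC <- canonicalKmers(strrep("AC", 25), k = 11)
  expect_equal(containment(disjointA, disjointC), 0.0)
  expect_error(containment(canonicalKmers("ACGTACGTAC", k = 5),
                           canonicalKmers("ACGTACGTAC", k = 7)),
               "different k")
  empty <- canonicalKmers("", k = 11)
  expect_error(containment(empty, ref), "empty")
})

test_that("haplome calls behave as declared on verbatim and degenerate input", {
  set.seed(53)
  pa <- randomDna(20000L)
  pb <- randomDna(20000L)
  mA <- canonicalKmers(pa)
  mB <- canonicalKmers(pb)
  # scaffold copied verbatim from parent A: call A, margin = score_A = 1
  calls <- assignHaplomes(c(sc = substr(pa, 1001L, 15000L)), mA, mB,
                          minCount = 100L)
  expect_equal(calls$call, "A")
  expect_equal(calls$score_B, 0)  # disjoint marker sets, zero mutations
  expect_equal(calls$margin, calls$score_A)
  # identical scores: ambiguous
  half <- paste0(substr(pa, 1, 5000L), substr(pb, 1, 5000L))
  callsHalf <- assignHaplomes(c(sc = half), mA, mB, minCount = 100L)
  expect_equal(callsHalf$call, "ambiguous")
  expect_lt(callsHalf$margin, 0.02 + 0.05)
  # too few informative k-mers: ambiguous even with a clean margin
  tiny <- assignHaplomes(c(sc = substr(pa, 1, 200L)), mA, mB,
                         minCount = 100000L)
  expect_equal(tiny$call, "ambiguous")
  # empty scaffold: ambiguous with zero counts
  expect_message(
    emptyCall <- assignHaplomes(c(sc = ""), mA, mB),
    "no k-mers")
  expect_equal(emptyCall$informative, 0L)
  # single-reference mode: plain containment against parent A only
  single <- assignHaplomes(c(sc = substr(pa, 1001L, 15000L)), mA,
                           minCount = 100L)
  expect_equal(single$score_A, 1.0)
  expect_equal(single$call, "A")
})

test_that("simulated F1 chromosomes at 1.35% divergence are fully recovered", {
  cfg <- fixtureConfig(seed = 97, crossChromosomes = 4L,
                       crossLength = 60000L)
  cx <- simulateCross(cfg)
  mA <- canonicalKmers(cx$parentA)
  mB <- canonicalKmers(cx$parentB)
  calls <- assignHaplomes(c(cx$childA, cx$childB), mA, mB)
  truth <- cx$truth$origin[match(calls$scaffold, cx$truth$chromosome)]
  expect_equal(calls$call, truth)
  expect_gt(mean(calls$margin), 0.5)
  # zero divergence: indistinguishable parents, everything ambiguous
  cfg0 <- fixtureConfig(seed = 97, crossChromosomes = 2L,
                        crossLength = 30000L, divergence = 0,
                        childErrorRate = 0)
  cx0 <- simulateCross(cfg0)
  calls0 <- assignHaplomes(c(cx0$childA, cx0$childB),
                           canonicalKmers(cx0$parentA),
                           canonicalKmers(cx0$parentB))
  expect_true(all(calls0$call == "ambiguous"))
  expect_true(all(calls0$margin == 0))
})

test_that("PAF parsing and orientation decisions follow majority rules", {
  pafLine <- function(q, t, strand, len) {
    paste(q, 100000, 0, len, strand, t, 120000, 0, len, len - 5, len, 60,
          sep = "\t")
  }
  p <- withr::local_tempfile(fileext = ".paf")
  writeLines(c(
    pafLine("sc1", "chr10", "-", 70000),
    pafLine("sc1", "chr10", "-", 2000),
    pafLine("sc1", "chr10", "+", 8000),
    pafLine("sc1", "chr03", "+", 20000),
    pafLine("sc2", "chr05", "+", 30000),
    pafLine("sc3", "chr01", "+", 1000),
    pafLine("sc3", "chr02", "-", 1000),
    pafLine("sc3", "chr04", "+", 1000)), p)
  paf <- readPaf(p)
  res <- orientAndRename(paf, minAssignFraction = 0.5)
  d <- res$decisions
  expect_equal(d$chromosome[d$scaffold == "sc1"], "chr10")
  expect_equal(d$orientation[d$scaffold == "sc1"], "reverse")
  expect_equal(d$orientation[d$scaffold == "sc2"], "forward")
  expect_true(is.na(d$chromosome[d$scaffold == "sc3"]))  # no majority

  writeLines(c(pafLine("q", "t", "+", 100), "bad\tline"), p)
  expect_error(readPaf(p), "line 2")

  # constructed truth: shuffled and flipped chromosomes all recovered
  set.seed(54)
  ref <- setNames(lapply(1:4, function(i) randomDna(8000L)),
                  paste0("chr0", 1:4))
  perm <- sample(names(ref))
  flip <- setNames(sample(c(TRUE, FALSE), 4, replace = TRUE), perm)
  lines <- vapply(seq_along(perm), function(i) {
    pafLine(paste0("sc", i), perm[i], if (flip[[i]]) "-" else "+", 7500)
  }, character(1))
  writeLines(lines, p)
  res2 <- orientAndRename(readPaf(p))
  expect_equal(res2$decisions$chromosome, unname(perm))
  expect_equal(res2$decisions$orientation,
               unname(ifelse(flip, "reverse", "forward")))
  # applying the decisions renames and reverse-complements
  scaffolds <- Biostrings::DNAStringSet(setNames(
    vapply(seq_along(perm), function(i) {
      s <- ref[[perm[i]]]
      if (flip[[i]]) stringRevcomp(s) else s
    }, character(1)), paste0("sc", 1:4)))
  fixed <- applyOrientation(scaffolds, res2$decisions)
  expect_setequal(names(fixed), names(ref))
  for (nm in names(ref)) {
    expect_equal(as.character(fixed[[nm]]), ref[[nm]])
  }
})
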