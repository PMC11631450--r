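test_that("CROG count matrix counts genes per orthogroup and genome", {
  a <- c(g1 = "o1", g2 = "o1", g3 = "o2")
  m <- buildCrogMatrix(list(gnm = a), universe = c("o1", "o2", "o3"))
  expect_equal(m[, "gnm"], c(o1 = 2L, o2 = 1L, o3 = 0L))
  expect_error(buildCrogMatrix(setNames(list(a, a), c("x", "x"))), "unique")

  set.seed(41)
  for (i in 1:30) {
    nGenome <- sample(2:5, 1)
    asn <- lapply(seq_len(nGenome), function(g) {
      n <- sample(10:60, 1)
      setNames(sprintf("OG%02d", sample.int(15L, n, replace = TRUE)),
               sprintf("gnm%d_g%03d", g, seq_len(n)))
    })
    names(asn) <- paste0("gnm", seq_len(nGenome))
    m <- buildCrogMatrix(asn)
    expect_equal(unname(colSums(m)), unname(lengths(asn)))
    # spot-check one random cell against direct counting
    o <- sample(rownames(m), 1)
    g <- sample(colnames(m), 1)
    expect_equal(m[o, g], sum(unname(asn[[g]]) == o))
  }
})

test_that("z-score normalization drops zero-SD rows and standardizes the rest", {
  m <- rbind(a = c(2, 4, 6), b = c(5, 5, 5), c = c(0, 0, 0))
  z <- zscoreNormalize(m)
  expect_setequal(z$dropped, c("b", "c"))
  expect_equal(unname(z$z["a", ]), c(-1.224745, 0, 1.224745),
               tolerance = 1e-6)
  expect_error(zscoreNormalize(m[, 1, drop = FALSE]), "2 columns")

  set.seed(42)
  for (i in 1:30) {
    m <- matrix(rpois(60, 5), nrow = 10,
                dimnames = list(paste0("o", 1:10), paste0("g", 1:6)))
    z <- zscoreNormalize(m)$z
    if (nrow(z)) {
      expect_true(all(abs(rowMeans(z)) < 1e-9))
      expect_true(all(abs(sqrt(rowMeans(z^2)) - 1) < 1e-9))
    }
    # shift-invariance and positive-scale equivariance per row
    m2 <- m + 7
    m3 <- m * 3
    expect_equal(zscoreNormalize(m2)$z, z)
    expect_equal(zscoreNormalize(m3)$z, z)
  }
})

test_that("cluster order is deterministic and groups identical columns", {
  set.seed(43)
  z <- matrix(rnorm(40), nrow = 8)
  z <- cbind(z, z[, 2])  # duplicate a genome column
  colnames(z) <- paste0("g", seq_len(ncol(z)))
  ord <- clusterOrder(z)
  pos <- match(c("g2", "g6"), colnames(z)[ord$cols])
  expect_equal(abs(diff(pos)), 1L)  # zero-distance pair is adjacent
  expect_identical(clusterOrder(z), ord)
  expect_error(clusterOrder(z[1, , drop = FALSE]), "2 rows")
  zbad <- z
  zbad[1, 1] <- NA
  expect_error(clusterOrder(zbad), "finite")

  # two well-separated planted column groups stay contiguous in leaf order
  base <- matrix(rnorm(60), nrow = 12)
  grp <- cbind(base + 0.01 * matrix(rnorm(60), nrow = 12),
               base + 10 + 0.01 * matrix(rnorm(60), nrow = 12))
  colnames(grp) <- c(paste0("a", 1:5), paste0("b", 1:5))
  co <- clusterOrder(grp)$cols
  labs <- substr(colnames(grp)[co], 1, 1)
  expect_equal(length(rle(labs)$lengths), 2L)
})

test_that("z-score summaries reflect the row-mean-zero structure", {
  set.seed(44)
  m <- matrix(rpois(40, 8), nrow = 20, dimnames = list(NULL, c("gA", "gB")))
  z <- zscoreNormalize(m)$z
  s <- zscoreSummary(z)
  # with two genomes, column means are exact negatives
  expect_equal(s$mean[1], -s$mean[2])
  expect_equal(mean(z), 0, tolerance = 1e-9)
  # toy 3x3: direct arithmetic
  toy <- rbind(c(1, 2, 3), c(4, 6, 8), c(1, 1, 4))
  colnames(toy) <- c("x", "y", "z")
  zt <- zscoreNormalize(toy)$z
  st <- zscoreSummary(zt)
  expect_equal(st$mean, unname(colMeans(zt)))
  expect_equal(st$median, unname(apply(zt, 2, median)))
})

test_that("upset counts partition the union and match brute force", {
  up <- upsetCounts(list(A = c("o1", "o2"), B = c("o2", "o3")))
  counts <- setNames(up$count, up$category)
  expect_equal(counts[c("A", "B", "A&B")],
               c(A = 1L, B = 1L, "A&B" = 1L))
  expect_equal(sum(up$count), 3L)

  set.seed(45)
  for (i in 1:20) {
    sets <- lapply(1:6, function(j)
      sprintf("OG%03d", sample.int(500L, sample(50:300, 1))))
    names(sets) <- paste0("g", 1:6)
    up <- upsetCounts(sets)
    oracle <- bruteUpset(sets)
    expect_equal(sum(up$count), length(unique(unlist(sets))))
    expect_setequal(up$category, names(oracle))
    expect_equal(up$count[match(names(oracle), up$category)],
                 unname(as.integer(oracle)))
  }
})

test_that("focal-group unique orthogroups match the brute-force definition", {
  sets <- list(A = c("o1", "o2"), B = c("o2", "o3"), C = c("o2"))
  expect_equal(uniqueOrthogroups(sets, "A"), "o1")
  expect_equal(uniqueOrthogroups(sets, c("A", "B", "C")), "o2")
  expect_equal(uniqueOrthogroups(sets, "C"), character(0))
  expect_error(uniqueOrthogroups(sets, "Z"), "unknown")

  set.seed(46)
  for (i in 1:30) {
    sets <- lapply(1:5, function(j)
      sprintf("OG%02d", sample.int(40L, sample(5:30, 1))))
    names(sets) <- paste0("g", 1:5)
    focal <- sample(names(sets), sample(1:3, 1))
    got <- uniqueOrthogroups(sets, focal)
    all <- sort(unique(unlist(sets)))
    oracle <- all[vapply(all, function(o) {
      all(vapply(sets[focal], function(s) o %in% s, logical(1))) &&
        !any(vapply(sets[setdiff(names(sets), focal)],
                    function(s) o %in% s, logical(1)))
    }, logical(1))]
    expect_equal(got, unname(oracle))
  }
})
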