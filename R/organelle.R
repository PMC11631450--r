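#' Quadripartite length arithmetic
#'
#' Total plastome length implied by the canonical quadripartite layout:
#' `lsc + ssc + 2 * ir` (one long single copy region, one short single copy
#' region, and two inverted-repeat copies). When an independently measured
#' total is supplied, any discrepancy is reported as a warning.
#'
#' @param lsc,ssc,ir Region lengths in bp (all > 0).
#' @param expectedTotal Optional independently known total length.
#' @return Total length in bp.
#' @examples
#' quadripartiteTotal(88052, 19159, 26352)
#' @export
quadripartiteTotal <- function(lsc, ssc, ir, expectedTotal = NULL) {
  if (any(c(lsc, ssc, ir) <= 0)) stop("region lengths must be positive")
  total <- lsc + ssc + 2 * ir
  if (!is.null(expectedTotal) && total != expectedTotal) {
    warning("quadripartite total ", total,
            " differs from the expected total ", expectedTotal,
            " by ", total - expectedTotal, " bp")
  }
  total
}

.COMP <- c(A = "T", C = "G", G = "C", T = "A")

#' Detect the quadripartite structure of a circular plastome
#'
#' Finds the longest pair of exact reverse-complement repeats of at least
#' `minIr` bases with non-overlapping placements on the circle (seed k-mer
#' matching along anti-diagonals, followed by maximal character-level
#' extension), labels the longer inter-repeat arc LSC and the shorter SSC,
#' and returns the four region coordinates. Circularity is handled by
#' doubling the sequence and reducing coordinates modulo its length;
#' ambiguity symbols terminate repeat extension. Detection is
#' rotation-invariant: any rotation of the input yields the same region
#' lengths.
#'
#' @param sequence Circular sequence as a character scalar or
#'   [Biostrings::DNAString-class].
#' @param minIr Minimum inverted-repeat length in bp (default 1000).
#' @param seedLength Seed k-mer length used for matching (default 21).
#' @return `NULL` if no qualifying repeat pair exists, else a list with
#'   `ir_length`, `lsc_length`, `ssc_length`, `total`, and `regions`, a
#'   `data.frame` of 1-based inclusive `start`/`end` per region (`end` may
#'   wrap past the sequence length for regions spanning the origin; reduce
#'   modulo the total to map onto the circle).
#' @export
detectQuadripartite <- function(sequence, minIr = 1000L, seedLength = 21L) {
  if (methods::is(sequence, "DNAString")) sequence <- as.character(sequence)
  s <- toupper(sequence)
  n <- nchar(s)
  L <- as.integer(seedLength)
  if (n < 2L * minIr || n <= L) return(NULL)
  dd <- paste0(s, s)
  cc <- strsplit(dd, "", fixed = TRUE)[[1L]]
  code <- c(A = 0, C = 1, G = 2, T = 3)[cc]
  bad <- is.na(code)
  code[bad] <- 0
  nwin <- n  # circular: one window starting at every position 1..n
  valF <- numeric(nwin)
  valR <- numeric(nwin)
  nbad <- cumsum(c(0L, bad))
  broken <- (nbad[(L + 1L):(nwin + L)] - nbad[1:nwin]) > 0L
  for (j in 0:(L - 1L)) {
    cj <- code[(1L + j):(nwin + j)]
    valF <- valF + cj * 4^(L - 1L - j)
    valR <- valR + (3 - cj) * 4^j
  }
  valF[broken] <- NA
  valR[broken] <- NA
  # i (forward window) pairs with j (window whose revcomp equals it)
  oF <- order(valF, na.last = NA)
  oR <- order(valR, na.last = NA)
  vF <- valF[oF]
  vR <- valR[oR]
  # enumerate all (i, j) with valF[i] == valR[j] via merge of sorted runs
  common <- intersect(vF, vR)
  if (length(common) == 0L) return(NULL)
  pairI <- list()
  pairJ <- list()
  idxF <- split(oF, match(vF, common, nomatch = 0L))
  idxR <- split(oR, match(vR, common, nomatch = 0L))
  idxF <- idxF[names(idxF) != "0"]
  idxR <- idxR[names(idxR) != "0"]
  for (nm in names(idxF)) {
    ii <- idxF[[nm]]
    jj <- idxR[[nm]]
    if (length(ii) * length(jj) > 10000L) next  # hyper-repetitive seed
    grid <- expand.grid(i = ii, j = jj)
    pairI[[nm]] <- grid$i
    pairJ[[nm]] <- grid$j
  }
  i <- unlist(pairI, use.names = FALSE)
  j <- unlist(pairJ, use.names = FALSE)
  if (length(i) == 0L) return(NULL)
  keep <- i != j
  i <- i[keep]
  j <- j[keep]
  if (length(i) == 0L) return(NULL)
  d <- (i + j) %% n  # anti-diagonal index on the circle
  best <- NULL
  for (dv in unique(d)) {
    ii <- sort(unique(i[d == dv]))
    runs <- split(ii, cumsum(c(1L, diff(ii) != 1L)))
    for (r in runs) {
      m <- length(r) + L - 1L  # exact repeat length at seed resolution
      if (m < minIr) next
      a <- r[1L]
      jPaired <- j[d == dv & i == r[length(r)]][1L]
      b <- jPaired  # start of the partner arm
      # maximal character-level extension on the doubled sequence
      while (a > 1L && b + m <= 2L * n &&
             !is.na(.COMP[cc[a - 1L]]) && !is.na(.COMP[cc[b + m]]) &&
             .COMP[cc[a - 1L]] == cc[b + m]) {
        a <- a - 1L
        m <- m + 1L
      }
      while (a + m <= 2L * n && b > 1L &&
             !is.na(.COMP[cc[a + m]]) && !is.na(.COMP[cc[b - 1L]]) &&
             .COMP[cc[a + m]] == cc[b - 1L]) {
        b <- b - 1L
        m <- m + 1L
      }
      # arms must not overlap on the circle
      pos <- function(x) ((x - 1L) %% n) + 1L
      armA <- (pos(a) + 0:(m - 1L) - 1L) %% n
      armB <- (pos(b) + 0:(m - 1L) - 1L) %% n
      if (length(intersect(armA, armB))) next
      if (is.null(best) || m > best$m) best <- list(a = pos(a), b = pos(b), m = m)
    }
  }
  if (is.null(best)) return(NULL)
  a <- best$a; b <- best$b; m <- best$m
  # arcs between the arms (circular): from end of one arm to start of other
  gap <- function(from, to) (to - from - 1L) %% n  # bases strictly between
  arc1 <- gap(a + m - 1L, b)  # after arm at a, before arm at b
  arc2 <- gap(b + m - 1L, a)
  lsc <- max(arc1, arc2)
  ssc <- min(arc1, arc2)
  if (ssc == 0L) return(NULL)  # degenerate: arms adjacent, no quadripartite
  # order regions around the circle starting at the LSC
  if (arc1 >= arc2) {
    lscStart <- ((a + m - 1L) %% n) + 1L
    irbStart <- b
    sscStart <- ((b + m - 1L) %% n) + 1L
    iraStart <- a
  } else {
    lscStart <- ((b + m - 1L) %% n) + 1L
    irbStart <- a
    sscStart <- ((a + m - 1L) %% n) + 1L
    iraStart <- b
  }
  regions <- data.frame(
    region = c("LSC", "IRb", "SSC", "IRa"),
    start = c(lscStart, irbStart, sscStart, iraStart),
    length = c(lsc, m, ssc, m))
  regions$end <- regions$start + regions$length - 1L
  total <- lsc + ssc + 2L * m
  stopifnot(total == n)
  # invariant: IRa is the reverse complement of IRb
  arm <- function(st) paste(cc[st:(st + m - 1L)], collapse = "")
  ira <- arm(iraStart)
  irb <- arm(irbStart)
  stopifnot(identical(ira, paste(rev(.COMP[strsplit(irb, "")[[1L]]]),
                                 collapse = "")))
  list(ir_length = m, lsc_length = lsc, ssc_length = ssc, total = total,
       regions = regions[, c("region", "start", "end", "length")])
}

#' Tally organelle genes by category
#'
#' Counts annotated genes per category (protein-coding, tRNA, rRNA, ...)
#' and in total. With `dedup = "all"` (default) every gene copy is counted,
#' matching the usual organelle convention of listing multi-copy genes
#' individually; `dedup = "unique"` counts distinct gene names once.
#'
#' @param features `data.frame` with columns `gene` (name) and `category`.
#' @param dedup `"all"` or `"unique"`.
#' @return List with `counts` (named integer vector per category, sorted by
#'   name) and `total`.
#' @examples
#' tallyGenes(data.frame(gene = c("rrn5", "trnH", "atp1", "atp1"),
#'                       category = c("rRNA", "tRNA", "protein_coding",
#'                                    "protein_coding")))
#' @export
tallyGenes <- function(features, dedup = c("all", "unique")) {
  dedup <- match.arg(dedup)
  stopifnot(all(c("gene", "category") %in% names(features)))
  if (nrow(features) == 0L) {
    return(list(counts = integer(0), total = 0L))
  }
  if (dedup == "unique") {
    features <- features[!duplicated(features[, c("gene", "category")]), ,
                         drop = FALSE]
  }
  counts <- table(features$category)
  counts <- setNames(as.integer(counts), names(counts))
  counts <- counts[sort(names(counts))]
  list(counts = counts, total = sum(counts))
}
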