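#' Canonical k-mer set
#'
#' A set of canonical k-mers (each k-mer represented by the
#' lexicographically smaller of itself and its reverse complement, so the
#' set is strand-independent). Members are stored as exact base-4 numeric
#' codes (A=0, C=1, G=2, T=3, first base most significant), which preserves
#' lexicographic order and is collision-free for k <= 26.
#'
#' @slot k k-mer length.
#' @slot codes sorted unique numeric codes of the canonical members.
#' @seealso [canonicalKmers()], [containment()]
#' @export
setClass("KmerSet", slots = c(k = "integer", codes = "numeric"))

setValidity("KmerSet", function(object) {
  msg <- character()
  if (length(object@k) != 1L || object@k < 3L) msg <- c(msg, "k must be >= 3")
  if (object@k > 26L) msg <- c(msg, "k must be <= 26 for exact numeric codes")
  if (is.unsorted(object@codes, strictly = TRUE) && length(object@codes) > 1L) {
    msg <- c(msg, "codes must be sorted and unique")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "KmerSet", function(object) {
  cat("KmerSet: ", length(object@codes), " canonical ", object@k, "-mers\n",
      sep = "")
})

#' @describeIn KmerSet-class number of distinct canonical k-mers.
#' @param x A `KmerSet`.
#' @export
setMethod("length", "KmerSet", function(x) length(x@codes))

# numeric canonical codes for all valid k-windows of one sequence string
.kmerCodes <- function(s, k) {
  s <- toupper(s)
  n <- nchar(s)
  if (n < k) return(numeric(0))
  lut <- rep(NA_real_, 128L)
  lut[c(65L, 67L, 71L, 84L)] <- 0:3  # A C G T
  code <- lut[utf8ToInt(s)]
  bad <- is.na(code)
  code[bad] <- 0
  nwin <- n - k + 1L
  valF <- numeric(nwin)
  valR <- numeric(nwin)
  nbad <- cumsum(c(0L, bad))
  keep <- (nbad[(k + 1L):(n + 1L)] - nbad[1:nwin]) == 0L
  for (j in 0:(k - 1L)) {
    cj <- code[(1L + j):(nwin + j)]
    valF <- valF + cj * 4^(k - 1L - j)
    valR <- valR + (3 - cj) * 4^j
  }
  sort(unique(pmin(valF, valR)[keep]))
}

#' Enumerate canonical k-mers of a sequence
#'
#' All length-k windows over the A/C/G/T alphabet are canonicalized
#' (lexicographic minimum of the window and its reverse complement); windows
#' containing any other symbol are skipped. A sequence shorter than k yields
#' an empty set. The result is strand-symmetric:
#' `canonicalKmers(revcomp(s))` equals `canonicalKmers(s)`.
#'
#' @param x A character vector of sequences, a
#'   [Biostrings::DNAString-class] or a [Biostrings::DNAStringSet-class];
#'   k-mers are pooled over all sequences.
#' @param k k-mer length, 3-26 (default 21, the usual choice for genome
#'   k-mer analyses).
#' @return A [KmerSet-class].
#' @examples
#' kmers(canonicalKmers("ACGTA", k = 4))
#' @export
canonicalKmers <- function(x, k = 21L) {
  k <- as.integer(k)
  if (k < 3L || k > 26L) stop("k must be in [3, 26]")
  if (methods::is(x, "DNAString")) x <- as.character(x)
  if (methods::is(x, "DNAStringSet")) x <- as.character(x)
  codes <- sort(unique(unlist(lapply(x, .kmerCodes, k = k),
                              use.names = FALSE)))
  methods::new("KmerSet", k = k, codes = codes)
}

#' @describeIn KmerSet-class decode the members to character k-mers
#'   (sorted).
#' @export
kmers <- function(x) {
  stopifnot(methods::is(x, "KmerSet"))
  k <- x@k
  codes <- x@codes
  if (length(codes) == 0L) return(character(0))
  letters <- c("A", "C", "G", "T")
  out <- matrix("", nrow = length(codes), ncol = k)
  rem <- codes
  for (j in seq_len(k)) {
    pw <- 4^(k - j)
    digit <- floor(rem / pw)
    out[, j] <- letters[digit + 1L]
    rem <- rem - digit * pw
  }
  apply(out, 1L, paste, collapse = "")
}

#' @describeIn KmerSet-class members of `a` not in `b`.
#' @param a,b `KmerSet` objects with equal `k`.
#' @export
kmerDiff <- function(a, b) {
  stopifnot(methods::is(a, "KmerSet"), methods::is(b, "KmerSet"))
  if (a@k != b@k) stop("k-mer sets have different k")
  methods::new("KmerSet", k = a@k, codes = setdiff(a@codes, b@codes))
}

#' Containment of one k-mer set in another
#'
#' `|query ∩ reference| / |query|`: the fraction of the query's canonical
#' k-mers found in the reference set.
#'
#' @param query,reference [KmerSet-class] objects with equal `k`; the query
#'   must be non-empty.
#' @return Fraction in `[0, 1]`.
#' @export
containment <- function(query, reference) {
  stopifnot(methods::is(query, "KmerSet"), methods::is(reference, "KmerSet"))
  if (query@k != reference@k) stop("k-mer sets have different k")
  if (length(query@codes) == 0L) stop("containment of an empty query is undefined")
  sum(query@codes %in% reference@codes) / length(query@codes)
}

#' Assign scaffolds to parental haplomes by k-mer scoring
#'
#' Two operating modes:
#' \describe{
#'   \item{two-parent marker mode}{(both `markersA` and `markersB` given)
#'     scaffolds are scored against the parent-specific marker sets
#'     `A \\ B` and `B \\ A`. Scores are normalized by the *informative*
#'     k-mers of the scaffold (those found in either marker set):
#'     `score_A = |q ∩ (A\\B)| / |q ∩ ((A\\B) ∪ (B\\A))|`, so a scaffold
#'     inherited from parent A scores near 1 regardless of how diverged the
#'     parents are.}
#'   \item{single-reference mode}{(`markersB = NULL`) `score_A` is the plain
#'     containment of the scaffold's k-mers in the reference set, `score_B`
#'     is 0, and the informative count is the scaffold's k-mer count.}
#' }
#' A scaffold is called `A` or `B` by the larger score; it is `ambiguous`
#' exactly when the margin `|score_A - score_B|` falls below `minMargin` or
#' the informative k-mer count falls below `minCount`. Empty scaffolds are
#' ambiguous with zero counts.
#'
#' @param scaffolds Named character vector or
#'   [Biostrings::DNAStringSet-class] of scaffold sequences.
#' @param markersA,markersB [KmerSet-class] objects (parent k-mer sets).
#' @param minMargin Minimum score margin for a confident call (default
#'   0.02).
#' @param minCount Minimum informative k-mer count (default 1000).
#' @return `data.frame` with columns `scaffold`, `score_A`, `score_B`,
#'   `margin`, `informative`, `call`.
#' @export
assignHaplomes <- function(scaffolds, markersA, markersB = NULL,
                           minMargin = 0.02, minCount = 1000L) {
  if (methods::is(scaffolds, "DNAStringSet")) {
    scaffolds <- setNames(as.character(scaffolds), names(scaffolds))
  }
  if (is.null(names(scaffolds)) || any(!nzchar(names(scaffolds)))) {
    stop("scaffolds must be named")
  }
  k <- markersA@k
  twoSet <- !is.null(markersB) && length(markersB@codes) > 0L
  if (twoSet) {
    if (markersB@k != k) stop("marker sets have different k")
    aOnly <- setdiff(markersA@codes, markersB@codes)
    bOnly <- setdiff(markersB@codes, markersA@codes)
  }
  rows <- lapply(names(scaffolds), function(id) {
    q <- .kmerCodes(scaffolds[[id]], k)
    if (length(q) == 0L) {
      message("scaffold ", id, " yields no k-mers; called ambiguous")
      return(data.frame(scaffold = id, score_A = 0, score_B = 0, margin = 0,
                        informative = 0L, call = "ambiguous"))
    }
    if (twoSet) {
      nA <- sum(q %in% aOnly)
      nB <- sum(q %in% bOnly)
      informative <- nA + nB
      scoreA <- if (informative) nA / informative else 0
      scoreB <- if (informative) nB / informative else 0
    } else {
      scoreA <- sum(q %in% markersA@codes) / length(q)
      scoreB <- 0
      informative <- length(q)
    }
    margin <- abs(scoreA - scoreB)
    call <- if (margin < minMargin || informative < minCount) {
      "ambiguous"
    } else if (scoreA >= scoreB) "A" else "B"
    data.frame(scaffold = id, score_A = scoreA, score_B = scoreB,
               margin = margin, informative = as.integer(informative),
               call = call)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read pairwise alignments in PAF format
#'
#' Minimal reader for the first 12 standard PAF columns (query name/length/
#' start/end, strand, target name/length/start/end, residue matches,
#' alignment block length, mapping quality).
#'
#' @param path Path to a PAF file.
#' @return `data.frame` with the 12 standard columns.
#' @export
readPaf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 12L)
  if (length(bad)) {
    stop("malformed PAF at line ", bad[1L], ": fewer than 12 columns")
  }
  col <- function(i) vapply(fields, `[[`, "", i)
  num <- function(i, what) {
    v <- suppressWarnings(as.numeric(col(i)))
    if (anyNA(v)) {
      stop("malformed PAF at line ", which(is.na(v))[1L],
           ": non-numeric ", what)
    }
    v
  }
  strand <- col(5L)
  if (any(!strand %in% c("+", "-"))) {
    stop("malformed PAF at line ", which(!strand %in% c("+", "-"))[1L],
         ": strand must be + or -")
  }
  data.frame(
    qname = col(1L), qlen = num(2L, "query length"),
    qstart = num(3L, "query start"), qend = num(4L, "query end"),
    strand = strand,
    tname = col(6L), tlen = num(7L, "target length"),
    tstart = num(8L, "target start"), tend = num(9L, "target end"),
    nmatch = num(10L, "match count"), alnlen = num(11L, "block length"),
    mapq = num(12L, "mapping quality"))
}

#' Reference-guided chromosome renaming and orientation
#'
#' For each query scaffold, aligned bases (PAF block lengths) are summed per
#' reference chromosome. The scaffold is assigned to the chromosome with the
#' maximal total if that chromosome's share of the scaffold's aligned bases
#' reaches `minAssignFraction`, otherwise it is left unplaced. Orientation
#' is `reverse` when more aligned bases hit the assigned chromosome on the
#' minus strand than on the plus strand (ties are forward).
#'
#' @param paf `data.frame` from [readPaf()].
#' @param minAssignFraction Minimal share of a scaffold's aligned bases on
#'   its best reference chromosome (default 0.5).
#' @return List with `decisions` (`data.frame`: `scaffold`, `chromosome`
#'   (`NA` if unplaced), `orientation`, `fraction`) and `candidates`
#'   (long `data.frame` of per-chromosome aligned-base fractions).
#' @export
orientAndRename <- function(paf, minAssignFraction = 0.5) {
  cand <- stats::aggregate(alnlen ~ qname + tname, data = paf, FUN = sum)
  tot <- tapply(cand$alnlen, cand$qname, sum)
  cand$fraction <- cand$alnlen / as.numeric(tot[cand$qname])
  decisions <- do.call(rbind, lapply(unique(paf$qname), function(q) {
    sub <- cand[cand$qname == q, , drop = FALSE]
    best <- sub[order(-sub$fraction, sub$tname), ][1L, ]
    if (best$fraction < minAssignFraction) {
      return(data.frame(scaffold = q, chromosome = NA_character_,
                        orientation = "forward", fraction = best$fraction))
    }
    rows <- paf[paf$qname == q & paf$tname == best$tname, , drop = FALSE]
    minus <- sum(rows$alnlen[rows$strand == "-"])
    plus <- sum(rows$alnlen[rows$strand == "+"])
    data.frame(scaffold = q, chromosome = best$tname,
               orientation = if (minus > plus) "reverse" else "forward",
               fraction = best$fraction)
  }))
  rownames(decisions) <- NULL
  names(cand)[names(cand) == "qname"] <- "scaffold"
  names(cand)[names(cand) == "tname"] <- "chromosome"
  list(decisions = decisions, candidates = cand[, c("scaffold", "chromosome",
                                                    "alnlen", "fraction")])
}

#' Apply renaming/orientation decisions to sequences
#'
#' @param sequences Named [Biostrings::DNAStringSet-class].
#' @param decisions `decisions` element from [orientAndRename()]; unplaced
#'   scaffolds keep their name and orientation.
#' @return A renamed (and where decided, reverse-complemented)
#'   `DNAStringSet`.
#' @importFrom Biostrings reverseComplement
#' @export
applyOrientation <- function(sequences, decisions) {
  out <- sequences
  idx <- match(decisions$scaffold, names(sequences))
  if (anyNA(idx)) {
    stop("decisions refer to unknown scaffolds: ",
         paste(decisions$scaffold[is.na(idx)], collapse = ", "))
  }
  flip <- decisions$orientation == "reverse"
  out[idx[flip]] <- reverseComplement(out[idx[flip]])
  renamed <- !is.na(decisions$chromosome)
  names(out)[idx[renamed]] <- decisions$chromosome[renamed]
  out
}
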