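#' Assembly summary statistics
#'
#' N50 is the length L such that sequences of length >= L sum to at least
#' half the total assembly length; L50 is the number of (longest) sequences
#' needed to reach that half. GC fraction excludes ambiguous bases from the
#' denominator.
#'
#' @param sequences A [Biostrings::DNAStringSet-class] or named character
#'   vector of sequences; alternatively a numeric vector of sequence
#'   lengths (GC is then `NA`).
#' @return List with `n_sequences`, `total_length`, `n50`, `l50`,
#'   `gc_fraction`.
#' @examples
#' assemblyStats(c(a = "ACGTACGTAC", b = "GGCCAT", c = "ACGT", d = "AT"))
#' @export
assemblyStats <- function(sequences) {
  gc <- NA_real_
  if (is.numeric(sequences)) {
    len <- as.numeric(sequences)
  } else {
    if (is.character(sequences)) {
      sequences <- Biostrings::DNAStringSet(sequences)
    }
    len <- as.numeric(Biostrings::width(sequences))
    freq <- Biostrings::alphabetFrequency(sequences, baseOnly = TRUE)
    acgt <- colSums(freq[, c("A", "C", "G", "T"), drop = FALSE])
    gc <- unname((acgt["G"] + acgt["C"]) / sum(acgt))
  }
  if (length(len) == 0L) stop("at least one sequence is required")
  len <- sort(len, decreasing = TRUE)
  total <- sum(len)
  cum <- cumsum(len)
  l50 <- which(cum >= total / 2)[1L]
  list(n_sequences = length(len), total_length = total,
       n50 = len[l50], l50 = l50, gc_fraction = gc)
}

#' Sequencing coverage fold
#'
#' `fold = total_bases / genome_size`, with a nearest-integer form rounded
#' half away from zero (the form usually printed as "NNNx").
#'
#' @param totalBases Total sequenced bases.
#' @param genomeSize Haploid genome size in bases (> 0).
#' @return List with `fold` (numeric) and `fold_int` (integer).
#' @examples
#' coverageFold(261.3e9, 650e6)
#' @export
coverageFold <- function(totalBases, genomeSize) {
  if (genomeSize <= 0) stop("genome size must be positive")
  fold <- totalBases / genomeSize
  list(fold = fold, fold_int = as.integer(sign(fold) * floor(abs(fold) + 0.5)))
}

# canonical class of a tandem repeat unit: the lexicographically minimal
# string among all rotations of the unit and of its reverse complement
canonicalUnit <- function(unit) {
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(unit, "", fixed = TRUE)[[1L]]),
                                     collapse = ""))
  rots <- function(u) {
    n <- nchar(u)
    vapply(seq_len(n) - 1L, function(i)
      paste0(substr(u, i + 1L, n), substr(u, 1L, i)), character(1))
  }
  min(c(rots(unit), rots(rc)))
}

# best tandem run in a window: maximal number of identical consecutive
# non-overlapping unit-length words, over all unit lengths and phases
.bestTandem <- function(w, minUnit, maxUnit) {
  best <- list(copies = 0L, unit = NA_character_, unitLength = NA_integer_)
  n <- nchar(w)
  for (u in minUnit:min(maxUnit, floor(n / 2))) {
    for (phase in 0:(u - 1L)) {
      starts <- seq.int(phase + 1L, n - u + 1L, by = u)
      if (length(starts) < 2L) next
      words <- substring(w, starts, starts + u - 1L)
      r <- rle(words)
      i <- which.max(r$lengths)
      if (r$lengths[i] > best$copies) {
        best <- list(copies = r$lengths[i], unit = r$values[i],
                     unitLength = u)
      }
    }
  }
  best
}

#' Scan sequence ends for telomeric tandem repeats
#'
#' Each terminal window is scanned for tandem arrays of repeat units of
#' length `minUnit` to `maxUnit`: for every unit length and phase the
#' maximal run of identical consecutive non-overlapping words is counted,
#' and the best unit per end is reported. Units are reported as a canonical
#' rotation class (the lexicographically minimal rotation over the unit and
#' its reverse complement), so e.g. the plant telomere unit reported as
#' `AAACCCT` and its reverse complement `AGGGTTT` yield the same class.
#' Hits with fewer than `minCopies` tandem copies are suppressed.
#'
#' @param sequences Named character vector or
#'   [Biostrings::DNAStringSet-class].
#' @param minUnit,maxUnit Unit length bounds (defaults 2 and 20;
#'   `minUnit >= 2`).
#' @param window Terminal window size in bases (default 50000); the whole
#'   sequence is used when shorter.
#' @param minCopies Minimum tandem copy number to report (default 50).
#' @return `data.frame` with columns `seqid`, `end` (`"5p"`/`"3p"`),
#'   `unit_class`, `unit_length`, `copies` (zero rows if nothing found).
#' @export
telomereScan <- function(sequences, minUnit = 2L, maxUnit = 20L,
                         window = 50000L, minCopies = 50L) {
  if (minUnit < 2L || maxUnit < minUnit) {
    stop("need 2 <= minUnit <= maxUnit")
  }
  if (methods::is(sequences, "DNAStringSet")) {
    sequences <- setNames(as.character(sequences), names(sequences))
  }
  if (is.null(names(sequences))) {
    names(sequences) <- paste0("seq", seq_along(sequences))
  }
  rows <- list()
  for (id in names(sequences)) {
    s <- toupper(sequences[[id]])
    n <- nchar(s)
    w <- min(window, n)
    ends <- list("5p" = substr(s, 1L, w), "3p" = substr(s, n - w + 1L, n))
    for (e in names(ends)) {
      hit <- .bestTandem(ends[[e]], minUnit, maxUnit)
      if (hit$copies >= minCopies) {
        rows[[length(rows) + 1L]] <- data.frame(
          seqid = id, end = e, unit_class = canonicalUnit(hit$unit),
          unit_length = hit$unitLength, copies = hit$copies)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(seqid = character(), end = character(),
                      unit_class = character(), unit_length = integer(),
                      copies = integer()))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
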