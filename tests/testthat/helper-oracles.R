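# Independent brute-force oracles. These deliberately avoid the package's
# own code paths (GRanges algebra, numeric k-mer codes, rle scanning) and
# work by direct enumeration on small instances.

# per-base bitmap for 1-based closed intervals on [1, n]
bitmapCover <- function(starts, ends, n) {
  v <- logical(n)
  for (i in seq_along(starts)) v[starts[i]:ends[i]] <- TRUE
  v
}

bruteOverlapBp <- function(s1, e1, s2, e2, n) {
  sum(bitmapCover(s1, e1, n) & bitmapCover(s2, e2, n))
}

randIntervals <- function(m, n, maxLen = 50L) {
  st <- sample.int(n - maxLen, m, replace = TRUE)
  len <- sample.int(maxLen, m, replace = TRUE)
  cbind(start = st, end = pmin(st + len - 1L, n))
}

stringRevcomp <- function(x) {
  chartr("ACGT", "TGCA",
         paste(rev(strsplit(x, "", fixed = TRUE)[[1L]]), collapse = ""))
}

bruteCanonicalKmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  out <- character(0)
  for (i in 1:(n - k + 1)) {
    w <- substr(s, i, i + k - 1)
    if (grepl("[^ACGT]", w)) next
    out <- c(out, min(w, stringRevcomp(w)))
  }
  sort(unique(out))
}

bruteN50 <- function(lens) {
  lens <- sort(lens, decreasing = TRUE)
  tot <- sum(lens)
  cum <- 0
  for (i in seq_along(lens)) {
    cum <- cum + lens[i]
    if (cum >= tot / 2) return(list(n50 = lens[i], l50 = i))
  }
}

bruteUpset <- function(sets) {
  all <- sort(unique(unlist(sets, use.names = FALSE)))
  pat <- vapply(all, function(o) {
    paste(names(sets)[vapply(sets, function(s) o %in% s, logical(1))],
          collapse = "&")
  }, character(1))
  table(pat)
}

# connected components by union-find over an edge list on 1..n
bruteComponents <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  if (nrow(edges)) {
    for (r in seq_len(nrow(edges))) {
      a <- find(edges[r, 1L])
      b <- find(edges[r, 2L])
      if (a != b) parent[a] <- b
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

canonicalUnitOracle <- function(u) {
  rots <- function(x) {
    n <- nchar(x)
    vapply(seq_len(n) - 1L, function(i)
      paste0(substr(x, i + 1L, n), substr(x, 1L, i)), character(1))
  }
  min(c(rots(u), rots(stringRevcomp(u))))
}

randomDna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
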