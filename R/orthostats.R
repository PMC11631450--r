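#' Read a gene-to-orthogroup assignment table
#'
#' Two-column tab-separated text (gene id, orthogroup id), the classifier
#' output format; one orthogroup per gene.
#'
#' @param path File path.
#' @return Named character vector: names are gene ids, values orthogroup
#'   ids.
#' @export
readOrthogroupAssignment <- function(path) {
  tab <- read.table(path, header = FALSE, sep = "\t",
                    col.names = c("gene_id", "orthogroup"),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(tab$gene_id)) {
    stop("a gene may be assigned to only one orthogroup; duplicated: ",
         paste(unique(tab$gene_id[duplicated(tab$gene_id)]), collapse = ", "))
  }
  setNames(tab$orthogroup, tab$gene_id)
}

#' Orthogroup-by-genome gene count matrix
#'
#' Cell (o, g) counts the genes of genome g assigned to orthogroup o.
#' Orthogroups listed in `universe` but absent from a genome contribute
#' zero rows; column sums equal the number of assigned genes per genome.
#'
#' @param assignments Named list of assignment vectors (as returned by
#'   [readOrthogroupAssignment()]), one per genome; list names are the
#'   genome labels and must be unique.
#' @param universe Optional character vector of orthogroup ids to include
#'   even when unobserved (rows are its union with the observed ids).
#' @return Integer matrix, rows = orthogroups (sorted), columns = genomes.
#' @export
buildCrogMatrix <- function(assignments, universe = NULL) {
  if (length(assignments) == 0L) stop("at least one genome is required")
  labels <- names(assignments)
  if (is.null(labels) || anyDuplicated(labels) || any(!nzchar(labels))) {
    stop("assignments must be a named list with unique genome labels")
  }
  rows <- sort(unique(c(universe, unlist(lapply(assignments, unname),
                                         use.names = FALSE))))
  mat <- matrix(0L, nrow = length(rows), ncol = length(labels),
                dimnames = list(rows, labels))
  for (g in labels) {
    tab <- table(assignments[[g]])
    mat[names(tab), g] <- as.integer(tab)
  }
  mat
}

#' Row z-score normalization with zero-SD removal
#'
#' Rows with zero population standard deviation (including all-zero rows)
#' are uninformative for between-genome comparison and are removed; every
#' retained row is transformed to `(x - mean) / sd` with the population SD
#' (divide by n). Retained rows have mean 0 and SD 1 to within 1e-9.
#'
#' @param mat Numeric matrix with >= 2 columns.
#' @return List with `z` (the z-scored matrix) and `dropped` (row ids
#'   removed for zero SD).
#' @examples
#' zscoreNormalize(rbind(a = c(2, 4, 6), b = c(5, 5, 5)))
#' @export
zscoreNormalize <- function(mat) {
  if (ncol(mat) < 2L) stop("z-scores need at least 2 columns")
  mu <- rowMeans(mat)
  sdPop <- sqrt(rowMeans((mat - mu)^2))
  drop <- sdPop == 0
  z <- (mat[!drop, , drop = FALSE] - mu[!drop]) / sdPop[!drop]
  list(z = z, dropped = rownames(mat)[drop])
}

#' Hierarchical clustering order for a z-score matrix
#'
#' Average-linkage agglomerative clustering with Euclidean distance on rows
#' and on columns (the defaults of the common clustermap plotting tools).
#' Leaf order is deterministic for a fixed input order; zero-distance pairs
#' merge first.
#'
#' @param z Numeric matrix with >= 2 rows and >= 2 columns, finite entries.
#' @param method Linkage method passed to [stats::hclust()].
#' @return List with integer vectors `rows` and `cols` (leaf orders).
#' @export
clusterOrder <- function(z, method = "average") {
  if (nrow(z) < 2L || ncol(z) < 2L) {
    stop("clustering needs at least 2 rows and 2 columns")
  }
  if (!all(is.finite(z))) stop("non-finite entries in matrix")
  list(rows = hclust(dist(z), method = method)$order,
       cols = hclust(dist(t(z)), method = method)$order)
}

#' Per-genome z-score distribution summary
#'
#' Boxplot-style statistics per column of a z-scored matrix: mean, median,
#' quartiles, and Tukey whiskers (most extreme values within 1.5 IQR of the
#' quartiles). Because every row has mean zero, the grand mean over all
#' cells is zero.
#'
#' @param z A z-scored matrix (see [zscoreNormalize()]).
#' @return `data.frame` with one row per genome.
#' @export
zscoreSummary <- function(z) {
  out <- do.call(rbind, lapply(colnames(z), function(g) {
    v <- z[, g]
    q <- unname(quantile(v, c(0.25, 0.5, 0.75)))
    iqr <- q[3] - q[1]
    data.frame(genome = g, mean = mean(v), median = q[2],
               q1 = q[1], q3 = q[3],
               whisker_low = min(v[v >= q[1] - 1.5 * iqr]),
               whisker_high = max(v[v <= q[3] + 1.5 * iqr]))
  }))
  rownames(out) <- NULL
  out
}

#' UpSet-style exact intersection counts
#'
#' Counts orthogroups by their exact membership pattern over the genome
#' sets: each orthogroup falls into exactly one category (the subset of
#' genomes containing it), so the category counts partition the union.
#'
#' @param sets Named list of character vectors (orthogroup ids per genome).
#' @return `data.frame` with one row per non-empty observed category:
#'   `category` (genome labels joined with `"&"` in input order), one
#'   logical column per genome, and `count`.
#' @examples
#' upsetCounts(list(A = c("o1", "o2"), B = c("o2", "o3")))
#' @export
upsetCounts <- function(sets) {
  if (length(sets) == 0L) stop("at least one set is required")
  labels <- names(sets)
  sets <- lapply(sets, unique)
  all <- sort(unique(unlist(sets, use.names = FALSE)))
  member <- vapply(sets, function(s) all %in% s, logical(length(all)))
  if (length(all) == 1L) member <- matrix(member, nrow = 1L,
                                          dimnames = list(NULL, labels))
  pattern <- apply(member, 1L, function(r) paste(labels[r], collapse = "&"))
  counts <- table(pattern)
  cat <- names(counts)
  memb <- do.call(rbind, lapply(cat, function(p) {
    inSet <- labels %in% strsplit(p, "&", fixed = TRUE)[[1L]]
    setNames(as.data.frame(t(inSet)), labels)
  }))
  out <- cbind(data.frame(category = cat, stringsAsFactors = FALSE),
               memb, count = as.integer(counts))
  ord <- order(-out$count, out$category)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Orthogroups unique to a focal group of genomes
#'
#' Orthogroups present in every focal genome and absent from every
#' non-focal genome (e.g. present only in a cultivar's two haplomes).
#'
#' @param sets Named list of character vectors (orthogroup ids per genome).
#' @param focal Character vector of genome labels, a subset of
#'   `names(sets)`.
#' @return Character vector of orthogroup ids.
#' @export
uniqueOrthogroups <- function(sets, focal) {
  unknown <- setdiff(focal, names(sets))
  if (length(unknown)) {
    stop("unknown focal genome labels: ", paste(unknown, collapse = ", "))
  }
  inAll <- Reduce(intersect, sets[focal])
  others <- unlist(sets[setdiff(names(sets), focal)], use.names = FALSE)
  sort(setdiff(inAll, others))
}
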