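#' Standardized gene/transcript identifiers
#'
#' Identifiers follow the community convention for Rosaceae genome
#' databases: a tree-of-life prefix, a cultivar tag, a version tag
#' (`v<major>a<minor>`), a chromosome token (`ch` + two digits + optional
#' haplotype letter, or `chun` for unplaced sequence), a 5-digit zero-padded
#' gene ordinal and a transcript ordinal, joined with dots, e.g.
#' `drMalDome.wa38.v1a1.ch10A.g00001.t1`.
#'
#' @param tolPrefix Tree-of-life prefix, e.g. `"drMalDome"`.
#' @param cultivar Cultivar tag, e.g. `"wa38"`.
#' @param version Version tag, e.g. `"v1a1"`.
#' @param chromosome Chromosome token, e.g. `"ch10A"` or `"chun"`.
#' @param gene Gene ordinal (>= 1).
#' @param transcript Transcript ordinal (>= 1), or `NA` for a gene-level id.
#' @return An object of class `"geneIdentifier"` (a named list).
#' @examples
#' renderId(geneIdentifier("drMalDome", "wa38", "v1a1", "ch10A", 1, 1))
#' @export
geneIdentifier <- function(tolPrefix, cultivar, version, chromosome, gene,
                           transcript = NA_integer_) {
  stopifnot(grepl("^[A-Za-z][A-Za-z0-9]*$", tolPrefix),
            grepl("^[A-Za-z0-9]+$", cultivar),
            grepl("^v[0-9]+a[0-9]+$", version),
            grepl("^ch([0-9]{2}[A-Z]?|un)$", chromosome),
            is.numeric(gene), gene >= 1,
            is.na(transcript) || transcript >= 1)
  structure(list(tolPrefix = tolPrefix, cultivar = cultivar,
                 version = version, chromosome = chromosome,
                 gene = as.integer(gene),
                 transcript = as.integer(transcript)),
            class = "geneIdentifier")
}

#' @rdname geneIdentifier
#' @param x A `geneIdentifier`.
#' @export
renderId <- function(x) {
  stopifnot(inherits(x, "geneIdentifier"))
  base <- paste(x$tolPrefix, x$cultivar, x$version, x$chromosome,
                sprintf("g%05d", x$gene), sep = ".")
  if (is.na(x$transcript)) base else paste0(base, ".t", x$transcript)
}

#' @rdname geneIdentifier
#' @param string An identifier string to parse; `parseId` inverts
#'   `renderId` and raises a format error naming the failing token.
#' @export
parseId <- function(string) {
  parts <- strsplit(string, ".", fixed = TRUE)[[1L]]
  if (!length(parts) %in% c(5L, 6L)) {
    stop("malformed identifier (expected 5 or 6 dot-separated tokens): ",
         string)
  }
  chk <- function(i, re, what) {
    if (!grepl(re, parts[i])) {
      stop("malformed identifier token '", parts[i], "' (", what, ") in: ",
           string)
    }
  }
  chk(1L, "^[A-Za-z][A-Za-z0-9]*$", "tree-of-life prefix")
  chk(2L, "^[A-Za-z0-9]+$", "cultivar tag")
  chk(3L, "^v[0-9]+a[0-9]+$", "version tag")
  chk(4L, "^ch([0-9]{2}[A-Z]?|un)$", "chromosome token")
  chk(5L, "^g[0-9]{5}$", "gene ordinal, 5-digit zero-padded")
  tr <- NA_integer_
  if (length(parts) == 6L) {
    chk(6L, "^t[1-9][0-9]*$", "transcript ordinal")
    tr <- as.integer(sub("^t", "", parts[6L]))
  }
  geneIdentifier(parts[1L], parts[2L], parts[3L], parts[4L],
                 as.integer(sub("^g", "", parts[5L])), tr)
}

#' Rename an annotation to the standard convention
#'
#' Genes are numbered per chromosome token, step 1 starting at `g00001`, in
#' ascending span-start order (ties by id); transcripts are numbered `t1...`
#' within each gene in ascending start order (ties by old id). Renaming is
#' idempotent: applying it twice yields identical ids.
#'
#' @param annotation A [GeneAnnotation-class].
#' @param tolPrefix,cultivar,version Identifier fields, see
#'   [geneIdentifier()].
#' @param chromMap Named character vector mapping seqnames to chromosome
#'   tokens (e.g. `c(chr10 = "ch10A")`).
#' @param unplacedToken Token used for seqnames absent from `chromMap`
#'   (e.g. `"chun"`); if `NULL`, such seqnames raise an error.
#' @return List with `annotation` (renamed) and `map`, a `data.frame` with
#'   columns `type` (`"gene"`/`"mRNA"`), `old_id`, `new_id`.
#' @export
renameAnnotation <- function(annotation, tolPrefix, cultivar, version,
                             chromMap, unplacedToken = NULL) {
  g <- annotation@genes
  tx <- annotation@transcripts
  seqs <- as.character(GenomicRanges::seqnames(g))
  tok <- unname(chromMap[seqs])
  if (anyNA(tok)) {
    missing <- unique(seqs[is.na(tok)])
    if (is.null(unplacedToken)) {
      stop("no chromosome token for seqnames: ",
           paste(missing, collapse = ", "),
           " (provide unplacedToken to map them)")
    }
    tok[is.na(tok)] <- unplacedToken
  }
  ord <- order(tok, GenomicRanges::start(g), names(g))
  ordinal <- integer(length(g))
  counter <- list()
  for (i in ord) {
    t <- tok[i]
    counter[[t]] <- (if (is.null(counter[[t]])) 0L else counter[[t]]) + 1L
    ordinal[i] <- counter[[t]]
  }
  newGeneId <- vapply(seq_along(g), function(i)
    renderId(geneIdentifier(tolPrefix, cultivar, version, tok[i], ordinal[i])),
    character(1))
  names(newGeneId) <- names(g)

  newTxId <- character(length(tx))
  for (gid in names(g)) {
    sel <- which(tx$gene_id == gid)
    sel <- sel[order(GenomicRanges::start(tx)[sel], names(tx)[sel])]
    newTxId[sel] <- paste0(newGeneId[[gid]], ".t", seq_along(sel))
  }
  map <- data.frame(
    type = c(rep("gene", length(g)), rep("mRNA", length(tx))),
    old_id = c(names(g), names(tx)),
    new_id = c(unname(newGeneId), newTxId))
  tx2 <- tx
  names(tx2) <- newTxId
  tx2$gene_id <- unname(newGeneId[tx$gene_id])
  ex <- annotation@exons
  cd <- annotation@cds
  names(ex) <- newTxId
  names(cd) <- newTxId
  ann <- newGeneAnnotation(tx2, ex, cd, source = annotation@source)
  list(annotation = ann, map = map)
}

#' Keep only the longest isoform of each gene
#'
#' "Longest" is the spliced transcript length (summed exon widths); ties are
#' broken by the larger summed CDS length, then by the lexicographically
#' smaller transcript id. Gene count and every retained interval are
#' unchanged.
#'
#' @param annotation A [GeneAnnotation-class].
#' @return A [GeneAnnotation-class] with exactly one transcript per gene.
#' @export
longestIsoform <- function(annotation) {
  tx <- annotation@transcripts
  if (length(tx) == 0L) return(annotation)
  splicedLen <- vapply(seq_along(tx), function(i)
    sum(GenomicRanges::width(annotation@exons[[i]])), integer(1))
  cdsLen <- vapply(seq_along(tx), function(i)
    sum(GenomicRanges::width(annotation@cds[[i]])), integer(1))
  keep <- vapply(split(seq_along(tx), tx$gene_id), function(sel) {
    o <- order(-splicedLen[sel], -cdsLen[sel], names(tx)[sel])
    sel[o[1L]]
  }, integer(1))
  keep <- sort(unname(keep))
  newGeneAnnotation(tx[keep], annotation@exons[keep], annotation@cds[keep],
                    source = annotation@source)
}
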