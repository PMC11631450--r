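#' Read a GFF3 gene annotation
#'
#' Parses a GFF3 file (via rtracklayer) and reconstructs the
#' gene/mRNA/exon/CDS hierarchy into a [GeneAnnotation-class]. Both the
#' common `ID=`/`Parent=` attribute dialects emitted by BRAKER- and
#' PASA-style pipelines are accepted (`transcript` is treated as a synonym of
#' `mRNA`). Feature lines of any other type are carried verbatim and
#' re-emitted by [writeGFF3()].
#'
#' @param path Path to a GFF3 file.
#' @param source Label stored on the returned object (defaults to the file
#'   name).
#' @return A [GeneAnnotation-class].
#' @details Malformed lines (wrong column count, non-numeric or inverted
#'   coordinates) raise an error naming the line number. Features whose
#'   `Parent` does not resolve raise a structural error listing the orphan
#'   ids, as do genes whose transcripts disagree on strand or seqname.
#' @examples
#' path <- tempfile(fileext = ".gff3")
#' writeGFF3(exampleAnnotation(), path)
#' ann <- readGFF3(path)
#' nGenes(ann)
#' @export
readGFF3 <- function(path, source = basename(path)) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  lines <- readLines(path, warn = FALSE)
  body <- !startsWith(lines, "#") & nzchar(trimws(lines))
  fields <- strsplit(lines[body], "\t", fixed = TRUE)
  lineno <- which(body)
  nf <- lengths(fields)
  if (any(nf != 9L)) {
    bad <- lineno[which(nf != 9L)[1L]]
    stop("malformed GFF3 at line ", bad, ": expected 9 tab-separated columns")
  }
  if (length(fields)) {
    st <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 4L)))
    en <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 5L)))
    bad <- which(is.na(st) | is.na(en) | st < 1L | st > en)
    if (length(bad)) {
      stop("malformed GFF3 at line ", lineno[bad[1L]],
           ": invalid start/end coordinates")
    }
  }
  gr <- rtracklayer::import(path, format = "gff3")
  if (length(gr) == 0L) {
    tx0 <- GenomicRanges::GRanges()
    tx0$gene_id <- character(0)
    return(newGeneAnnotation(tx0, GenomicRanges::GRangesList(),
                             GenomicRanges::GRangesList(), source = source))
  }
  type <- as.character(gr$type)
  id <- if (is.null(gr$ID)) rep(NA_character_, length(gr)) else gr$ID
  parent <- if (is.null(gr$Parent)) {
    rep(NA_character_, length(gr))
  } else {
    p <- gr$Parent
    vapply(as.list(p), function(v) if (length(v)) v[[1L]] else NA_character_,
           character(1))
  }
  isGene <- type == "gene"
  isTx <- type %in% c("mRNA", "transcript")
  isExon <- type == "exon"
  isCds <- type == "CDS"

  geneIds <- id[isGene]
  if (anyNA(geneIds)) stop("gene feature without an ID attribute")
  if (anyDuplicated(geneIds)) {
    stop("duplicated gene ids: ",
         paste(unique(geneIds[duplicated(geneIds)]), collapse = ", "))
  }
  txId <- id[isTx]
  txParent <- parent[isTx]
  if (anyNA(txId)) stop("mRNA feature without an ID attribute")
  orphanTx <- txId[!txParent %in% geneIds | is.na(txParent)]
  if (length(orphanTx)) {
    stop("mRNA features with unresolvable Parent: ",
         paste(orphanTx, collapse = ", "))
  }
  partParent <- parent[isExon | isCds]
  orphanPart <- unique(partParent[!partParent %in% txId | is.na(partParent)])
  if (length(orphanPart)) {
    stop("exon/CDS features with unresolvable Parent: ",
         paste(orphanPart, collapse = ", "))
  }
  noTx <- setdiff(geneIds, txParent)
  if (length(noTx)) {
    stop("gene features without any mRNA child: ", paste(noTx, collapse = ", "))
  }

  tx <- GenomicRanges::granges(gr[isTx])
  names(tx) <- txId
  tx$gene_id <- txParent
  # strand/seqname consistency within each gene (design: reject at load)
  sq <- as.character(GenomicRanges::seqnames(tx))
  st <- as.character(GenomicRanges::strand(tx))
  gsq <- as.character(GenomicRanges::seqnames(gr[isGene]))[match(txParent, geneIds)]
  gst <- as.character(GenomicRanges::strand(gr[isGene]))[match(txParent, geneIds)]
  bad <- txParent[sq != gsq | st != gst]
  if (length(bad)) {
    stop("transcripts disagree with their gene on seqname/strand: ",
         paste(unique(bad), collapse = ", "))
  }

  splitParts <- function(sel) {
    parts <- GenomicRanges::granges(gr[sel])
    grl <- GenomicRanges::split(parts,
                                factor(parent[sel], levels = txId))
    grl <- GenomicRanges::sort(grl)
    grl
  }
  exons <- splitParts(isExon)
  cds <- splitParts(isCds)
  if (any(lengths(exons) == 0L)) {
    # tolerate mRNA lines without exon children by promoting the mRNA range
    empty <- which(lengths(exons) == 0L)
    for (i in empty) {
      exons[[i]] <- GenomicRanges::granges(tx[i])
    }
  }

  rawType <- vapply(fields, `[[`, "", 3L)
  keepExtra <- !(rawType %in% c("gene", "mRNA", "transcript", "exon", "CDS"))
  extra <- lines[body][keepExtra]
  extraParent <- vapply(fields[keepExtra], function(f) {
    m <- regmatches(f[9L], regexpr("Parent=[^;]+", f[9L]))
    if (length(m)) sub("Parent=", "", m) else NA_character_
  }, character(1))

  ann <- newGeneAnnotation(tx, exons, cds, source = source,
                           extra = extra, extraParent = extraParent)
  methods::validObject(ann)
  ann
}

#' Write a GFF3 gene annotation
#'
#' Emits a deterministic, spec-conformant GFF3 file: genes ordered by
#' (seqname, start, id), each followed by its transcripts (by start, then
#' id), exons and CDS parts in coordinate order. CDS phase is computed from
#' the cumulative coding length in transcription direction. Writing the same
#' annotation twice produces byte-identical files, and
#' `readGFF3(writeGFF3(x))` reconstructs a structurally identical object.
#'
#' @param annotation A [GeneAnnotation-class].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeGFF3 <- function(annotation, path) {
  stopifnot(methods::is(annotation, "GeneAnnotation"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  g <- annotation@genes
  src <- annotation@source
  if (length(g) == 0L) return(invisible(path))
  ord <- order(as.character(GenomicRanges::seqnames(g)),
               GenomicRanges::start(g), names(g))
  tx <- annotation@transcripts
  txByGene <- split(seq_along(tx), tx$gene_id)
  fmt <- function(seqid, type, start, end, strand, phase, attrs) {
    paste(seqid, src, type, start, end, ".", strand, phase, attrs, sep = "\t")
  }
  out <- character()
  for (i in ord) {
    gid <- names(g)[i]
    seqid <- as.character(GenomicRanges::seqnames(g))[i]
    strand <- as.character(GenomicRanges::strand(g))[i]
    if (strand == "*") strand <- "."
    out <- c(out, fmt(seqid, "gene", GenomicRanges::start(g)[i],
                      GenomicRanges::end(g)[i], strand, ".",
                      paste0("ID=", gid)))
    ti <- txByGene[[gid]]
    ti <- ti[order(GenomicRanges::start(tx)[ti], names(tx)[ti])]
    for (j in ti) {
      tid <- names(tx)[j]
      out <- c(out, fmt(seqid, "mRNA", GenomicRanges::start(tx)[j],
                        GenomicRanges::end(tx)[j], strand, ".",
                        paste0("ID=", tid, ";Parent=", gid)))
      ex <- annotation@exons[[j]]
      ex <- ex[order(GenomicRanges::start(ex))]
      for (e in seq_along(ex)) {
        out <- c(out, fmt(seqid, "exon", GenomicRanges::start(ex)[e],
                          GenomicRanges::end(ex)[e], strand, ".",
                          paste0("Parent=", tid)))
      }
      cd <- annotation@cds[[j]]
      if (length(cd)) {
        cd <- cd[order(GenomicRanges::start(cd))]
        w <- GenomicRanges::width(cd)
        if (strand == "-") {
          prior <- rev(cumsum(c(0L, rev(w)[-length(w)])))
        } else {
          prior <- cumsum(c(0L, w[-length(w)]))
        }
        phase <- (3L - prior %% 3L) %% 3L
        for (e in seq_along(cd)) {
          out <- c(out, fmt(seqid, "CDS", GenomicRanges::start(cd)[e],
                            GenomicRanges::end(cd)[e], strand, phase[e],
                            paste0("Parent=", tid)))
        }
      }
    }
  }
  # re-emit carried lines whose Parent (if any) still resolves
  if (length(annotation@extra)) {
    known <- c(names(g), names(tx))
    keep <- is.na(annotation@extraParent) | annotation@extraParent %in% known
    out <- c(out, annotation@extra[keep])
  }
  writeLines(out, con)
  invisible(path)
}

#' Merge intervals into a disjoint sorted set
#'
#' Union of a set of ranges on a single seqname: the result is sorted,
#' pairwise disjoint, and covers exactly the same bases (half-open-adjacent
#' ranges in 0-based terms, i.e. ranges that touch end-to-start in 1-based
#' closed coordinates, are joined).
#'
#' @param x A `GRanges` (all on one seqname) or an `IRanges`.
#' @return An object of the same class, reduced.
#' @examples
#' mergeIntervals(IRanges::IRanges(c(11, 16), c(20, 25)))
#' @export
mergeIntervals <- function(x) {
  if (methods::is(x, "GRanges")) {
    if (length(unique(as.character(GenomicRanges::seqnames(x)))) > 1L) {
      stop("mergeIntervals expects intervals on a single seqname")
    }
    return(GenomicRanges::reduce(x, ignore.strand = TRUE))
  }
  IRanges::reduce(x)
}

#' Overlap width between two interval sets
#'
#' Number of bases in the intersection of the unions of two interval sets:
#' `|union(a) ∩ union(b)|`. Symmetric in its arguments; strand is ignored.
#'
#' @param a,b `GRanges` objects (matched by seqname) or `IRanges`.
#' @return Integer base count.
#' @examples
#' overlapWidth(IRanges::IRanges(1, 10), IRanges::IRanges(6, 8))
#' @export
overlapWidth <- function(a, b) {
  if (methods::is(a, "GRanges")) {
    # suppress the benign seqlevel-union warning for disjoint seqname sets
    ov <- suppressWarnings(
      GenomicRanges::intersect(GenomicRanges::reduce(a, ignore.strand = TRUE),
                               GenomicRanges::reduce(b, ignore.strand = TRUE),
                               ignore.strand = TRUE))
    return(sum(GenomicRanges::width(ov)))
  }
  sum(IRanges::width(IRanges::intersect(IRanges::reduce(a), IRanges::reduce(b))))
}

#' Read a repeat annotation from BED
#'
#' BED intervals (0-based half-open on disk, converted to GRanges by
#' rtracklayer) with the repeat class carried in the BED name column.
#'
#' @param path Path to a BED3/BED6 file.
#' @return `GRanges` with a `class_label` metadata column (`NA` for BED3).
#' @export
readRepeatsBed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  gr$class_label <- if (!is.null(gr$name)) gr$name else NA_character_
  gr$name <- NULL
  gr
}

#' Read an evidence-coverage track from BED
#'
#' @param path Path to a BED file of evidence alignments (RNA or protein),
#'   produced upstream.
#' @return `GRanges` of covered intervals.
#' @export
readCoverageBed <- function(path) {
  GenomicRanges::granges(rtracklayer::import(path, format = "bed"))
}

#' Write intervals to BED
#'
#' @param gr A `GRanges`; a `class_label` or `name` metadata column becomes
#'   the BED name.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeBed <- function(gr, path) {
  if (!is.null(gr$class_label)) {
    gr$name <- gr$class_label
    gr$class_label <- NULL
  }
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' A small built-in example annotation
#'
#' Three genes on two sequences with one or two transcripts each; used in
#' documentation examples and round-trip tests.
#'
#' @return A [GeneAnnotation-class].
#' @export
exampleAnnotation <- function() {
  tx <- GenomicRanges::GRanges(
    c("chr1", "chr1", "chr1", "chr2"),
    IRanges::IRanges(c(101, 151, 1001, 501), c(400, 400, 1600, 900)),
    strand = c("+", "+", "-", "+"))
  names(tx) <- c("t1.1", "t1.2", "t2.1", "t3.1")
  tx$gene_id <- c("g1", "g1", "g2", "g3")
  exons <- GenomicRanges::GRangesList(
    "t1.1" = GenomicRanges::GRanges("chr1",
      IRanges::IRanges(c(101, 301), c(200, 400)), strand = "+"),
    "t1.2" = GenomicRanges::GRanges("chr1",
      IRanges::IRanges(c(151, 301), c(200, 400)), strand = "+"),
    "t2.1" = GenomicRanges::GRanges("chr1",
      IRanges::IRanges(c(1001, 1401), c(1200, 1600)), strand = "-"),
    "t3.1" = GenomicRanges::GRanges("chr2",
      IRanges::IRanges(501, 900), strand = "+"))
  cds <- GenomicRanges::GRangesList(
    "t1.1" = GenomicRanges::GRanges("chr1",
      IRanges::IRanges(c(131, 301), c(200, 340)), strand = "+"),
    "t1.2" = GenomicRanges::GRanges("chr1",
      IRanges::IRanges(c(161, 301), c(200, 340)), strand = "+"),
    "t2.1" = GenomicRanges::GRanges("chr1",
      IRanges::IRanges(1051, 1150), strand = "-"),
    "t3.1" = GenomicRanges::GRanges("chr2",
      IRanges::IRanges(551, 850), strand = "+"))
  newGeneAnnotation(tx, exons, cds, source = "example")
}
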