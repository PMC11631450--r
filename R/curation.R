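#' Curation parameters
#'
#' @param repeatFractionThreshold Fraction of a gene's merged coding region
#'   that must lie inside repeat regions for the gene to be removed by the
#'   type-1 filter. Genes at or above the threshold are removed (inclusive
#'   comparison). Default 0.90.
#' @return A named list of parameters, validated.
#' @export
curationConfig <- function(repeatFractionThreshold = 0.90) {
  stopifnot(is.numeric(repeatFractionThreshold),
            length(repeatFractionThreshold) == 1L,
            repeatFractionThreshold > 0, repeatFractionThreshold <= 1)
  list(repeatFractionThreshold = repeatFractionThreshold)
}

# Merged CDS footprint of one gene across all isoforms (strand-ignored union).
geneCdsFootprint <- function(ann, gid) {
  sel <- which(ann@transcripts$gene_id == gid)
  cd <- unlist(ann@cds[sel], use.names = FALSE)
  if (length(cd) == 0L) return(GenomicRanges::GRanges())
  GenomicRanges::reduce(cd, ignore.strand = TRUE)
}

# Merged exon footprint of one gene across all isoforms.
geneExonFootprint <- function(ann, gid) {
  sel <- which(ann@transcripts$gene_id == gid)
  ex <- unlist(ann@exons[sel], use.names = FALSE)
  GenomicRanges::reduce(ex, ignore.strand = TRUE)
}

#' Fraction of a gene's coding region overlapping repeats
#'
#' The coding region of a gene is the union of CDS intervals over all of its
#' isoforms; repeats are merged before intersection. Returns
#' `overlap / coding length` in `[0, 1]`. A gene with zero CDS bases has no
#' defined fraction: `NA` is returned (callers treat it as 0) with a warning
#' naming the gene.
#'
#' @param annotation A [GeneAnnotation-class].
#' @param repeats `GRanges` of repeat intervals (possibly empty).
#' @param geneId Gene id; if missing, fractions for all genes are returned.
#' @return Named numeric vector of fractions.
#' @export
repeatOverlapFraction <- function(annotation, repeats, geneId = geneIds(annotation)) {
  red <- GenomicRanges::reduce(repeats, ignore.strand = TRUE)
  out <- vapply(geneId, function(gid) {
    cds <- geneCdsFootprint(annotation, gid)
    tot <- sum(GenomicRanges::width(cds))
    if (tot == 0L) return(NA_real_)
    overlapWidth(cds, red) / tot
  }, numeric(1))
  if (anyNA(out)) {
    warning("genes with no coding region (fraction undefined, treated as 0): ",
            paste(names(out)[is.na(out)], collapse = ", "))
  }
  out
}

#' Remove repeat-derived gene models (type-1 filter)
#'
#' Removes genes whose merged coding region overlaps merged repeat regions
#' at or above the configured fraction (default 0.90) — the signature of a
#' transposable element mis-annotated as a gene.
#'
#' @inheritParams repeatOverlapFraction
#' @param config Output of [curationConfig()].
#' @return List with `annotation` (kept genes, untouched) and `removed`
#'   (character vector of removed gene ids).
#' @export
filterType1 <- function(annotation, repeats, config = curationConfig()) {
  if (nGenes(annotation) == 0L) {
    return(list(annotation = annotation, removed = character()))
  }
  fr <- suppressWarnings(repeatOverlapFraction(annotation, repeats))
  fr[is.na(fr)] <- 0
  removed <- names(fr)[fr >= config$repeatFractionThreshold]
  list(annotation = keepGenes(annotation, setdiff(geneIds(annotation), removed)),
       removed = removed)
}

#' Resolve same-strand overlapping gene models (type-2 filter)
#'
#' Two gene models overlapping on the same strand usually describe a single
#' gene annotated twice. Resolution repeatedly removes the globally shortest
#' (span length) gene that overlaps any other gene on the same seqname and
#' strand, until no same-strand span overlap (>= 1 bp) remains. Ties on span
#' length are broken by the larger start, then by the lexicographically
#' smaller id.
#'
#' @param annotation A [GeneAnnotation-class].
#' @param config Unused placeholder for interface symmetry.
#' @return List with `annotation` and `removed` (ids, in removal order).
#' @export
filterType2 <- function(annotation, config = curationConfig()) {
  g <- annotation@genes
  if (length(g) < 2L) return(list(annotation = annotation, removed = character()))
  alive <- setNames(rep(TRUE, length(g)), names(g))
  hits <- GenomicRanges::findOverlaps(g, ignore.strand = FALSE,
                                      drop.self = TRUE)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  w <- GenomicRanges::width(g)
  st <- GenomicRanges::start(g)
  ids <- names(g)
  removed <- character()
  repeat {
    deg <- tabulate(qh[alive[qh] & alive[sh]], nbins = length(g))
    cand <- which(deg > 0L & alive)
    if (length(cand) == 0L) break
    o <- order(w[cand], -st[cand], ids[cand])
    victim <- cand[o[1L]]
    alive[victim] <- FALSE
    removed <- c(removed, ids[victim])
  }
  list(annotation = keepGenes(annotation, ids[alive]), removed = removed)
}

#' Split genes whose isoforms do not overlap (type-3 filter)
#'
#' Splice variants of one gene must share transcribed sequence. Within each
#' gene, a graph is built on its transcripts with edges where merged exon
#' footprints overlap by >= 1 bp; each connected component becomes its own
#' gene. Genes with a single component are unchanged. New gene ids are the
#' original id plus an ordinal suffix (`_1`, `_2`, ...), with components
#' ordered by their leftmost start. Transcripts are moved, never dropped.
#'
#' @param annotation A [GeneAnnotation-class].
#' @return List with `annotation`, `splitIds` (ids of genes that were split)
#'   and `nCreated` (number of genes created from them).
#' @export
splitType3 <- function(annotation) {
  tx <- annotation@transcripts
  if (length(tx) == 0L) {
    return(list(annotation = annotation, splitIds = character(), nCreated = 0L))
  }
  newGid <- tx$gene_id
  splitIds <- character()
  nCreated <- 0L
  for (gid in unique(tx$gene_id)) {
    sel <- which(tx$gene_id == gid)
    if (length(sel) == 1L) next
    foot <- GenomicRanges::reduce(annotation@exons[sel], ignore.strand = TRUE)
    flat <- unlist(foot, use.names = FALSE)
    grp <- rep(seq_along(sel), lengths(foot))
    hits <- GenomicRanges::findOverlaps(flat, flat, ignore.strand = TRUE)
    ed <- cbind(grp[S4Vectors::queryHits(hits)], grp[S4Vectors::subjectHits(hits)])
    gph <- igraph::graph_from_edgelist(apply(ed, 2L, as.character),
                                       directed = FALSE)
    comp <- igraph::components(gph)
    if (comp$no == 1L) next
    member <- comp$membership[as.character(seq_along(sel))]
    # order components by leftmost start of their exon footprints
    lo <- vapply(split(seq_along(sel), member),
                 function(i) min(GenomicRanges::start(flat)[grp %in% i]),
                 integer(1))
    rank <- rank(lo, ties.method = "first")
    newGid[sel] <- paste0(gid, "_", rank[as.character(member)])
    splitIds <- c(splitIds, gid)
    nCreated <- nCreated + comp$no
  }
  tx$gene_id <- newGid
  ann <- newGeneAnnotation(tx, annotation@exons, annotation@cds,
                           source = annotation@source,
                           extra = annotation@extra,
                           extraParent = annotation@extraParent)
  list(annotation = ann, splitIds = splitIds, nCreated = as.integer(nCreated))
}

#' Sequential gene-model curation
#'
#' Applies the three error filters in order: type 1 (repeat-overlap
#' removal), type 2 (same-strand overlap removal), type 3 (disjoint-isoform
#' splitting). Splitting cannot create same-strand overlaps among its own
#' outputs (components are disjoint), so no re-iteration is needed, and the
#' whole pipeline is idempotent.
#'
#' @inheritParams filterType1
#' @return List with `annotation` (curated) and `report`
#'   ([CurationReport-class]).
#' @examples
#' fx <- simulateAnnotatedGenome(fixtureConfig(seed = 1))
#' res <- curateAnnotation(fx$annotation, fx$repeats)
#' res$report
#' @export
curateAnnotation <- function(annotation, repeats = GenomicRanges::GRanges(),
                             config = curationConfig()) {
  nIn <- nGenes(annotation)
  s1 <- filterType1(annotation, repeats, config)
  s2 <- filterType2(s1$annotation, config)
  s3 <- splitType3(s2$annotation)
  report <- methods::new("CurationReport",
    nInput = nIn,
    nRemovedType1 = length(s1$removed),
    nRemovedType2 = length(s2$removed),
    nGenesSplitType3 = length(s3$splitIds),
    nGenesCreatedType3 = s3$nCreated,
    nOutput = nGenes(s3$annotation),
    type1Ids = s1$removed, type2Ids = s2$removed, type3Ids = s3$splitIds)
  methods::validObject(report)
  list(annotation = s3$annotation, report = report)
}
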