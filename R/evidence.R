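#' Per-gene evidence support flags
#'
#' Screens every gene against RNA and protein evidence-coverage tracks and
#' against external annotation id lists, producing the six boolean flags used
#' for evidence-tier subsetting:
#' \describe{
#'   \item{full_rna}{RNA evidence covers 100% of the gene's merged exon
#'     footprint.}
#'   \item{any_rna}{RNA evidence overlaps the gene span by >= 1 bp.}
#'   \item{full_protein}{Protein evidence covers 100% of the gene's merged
#'     CDS footprint (genes with no CDS bases are never fully supported).}
#'   \item{any_protein}{Protein evidence overlaps the gene span by >= 1 bp.}
#'   \item{has_functional}{Gene id appears in the functional-annotation list.}
#'   \item{has_orthogroup}{Gene id appears in the orthogroup-assignment
#'     list.}
#' }
#' Full coverage is evaluated against the exonic/CDS footprint, not the
#' genomic span: spliced evidence cannot cover introns.
#'
#' @param annotation A [GeneAnnotation-class].
#' @param rna,protein `GRanges` coverage tracks (possibly empty).
#' @param functionalIds,orthogroupIds Character vectors of gene ids with a
#'   functional annotation / an orthogroup assignment.
#' @return `data.frame` with row names = gene ids and six logical columns.
#' @export
computeSupport <- function(annotation,
                           rna = GenomicRanges::GRanges(),
                           protein = GenomicRanges::GRanges(),
                           functionalIds = character(),
                           orthogroupIds = character()) {
  gids <- geneIds(annotation)
  g <- annotation@genes
  rnaRed <- GenomicRanges::reduce(rna, ignore.strand = TRUE)
  protRed <- GenomicRanges::reduce(protein, ignore.strand = TRUE)
  anyHit <- function(track) {
    suppressWarnings(
      GenomicRanges::countOverlaps(g, track, ignore.strand = TRUE) > 0L)
  }
  fullCover <- function(gid, track, footprint) {
    tot <- sum(GenomicRanges::width(footprint))
    if (tot == 0L) return(FALSE)
    overlapWidth(footprint, track) == tot
  }
  fullRna <- vapply(gids, function(gid)
    fullCover(gid, rnaRed, geneExonFootprint(annotation, gid)), logical(1))
  fullProt <- vapply(gids, function(gid)
    fullCover(gid, protRed, geneCdsFootprint(annotation, gid)), logical(1))
  out <- data.frame(
    full_rna = unname(fullRna),
    any_rna = unname(anyHit(rnaRed)),
    full_protein = unname(fullProt),
    any_protein = unname(anyHit(protRed)),
    has_functional = gids %in% functionalIds,
    has_orthogroup = gids %in% orthogroupIds,
    row.names = gids
  )
  # full support implies any support by construction (footprint within span)
  stopifnot(all(out$any_rna | !out$full_rna),
            all(out$any_protein | !out$full_protein))
  out
}

#' Evidence-tier gene subsets
#'
#' Extracts one of four stringency subsets from a support-flag table:
#' \describe{
#'   \item{1}{full RNA or full protein support,}
#'   \item{2}{any RNA or any protein support,}
#'   \item{3}{subset 1 plus genes with both a functional annotation and an
#'     orthogroup assignment,}
#'   \item{4}{subset 1 plus genes with either of the two.}
#' }
#' By construction subset 1 is contained in subsets 2, 3 and 4, and subset 3
#' in subset 4; no containment holds between subset 2 and subsets 3/4.
#'
#' @param flags `data.frame` from [computeSupport()] (row names = gene ids).
#' @param level Integer 1-4.
#' @param geneIds Optional gene id universe; every id must have flags.
#' @return Character vector of gene ids in the subset.
#' @export
selectSubset <- function(flags, level, geneIds = rownames(flags)) {
  if (!level %in% 1:4) stop("unknown subset level: ", level)
  missing <- setdiff(geneIds, rownames(flags))
  if (length(missing)) {
    stop("missing support flags for genes: ", paste(missing, collapse = ", "))
  }
  f <- flags[geneIds, , drop = FALSE]
  s1 <- f$full_rna | f$full_protein
  sel <- switch(as.character(level),
    "1" = s1,
    "2" = f$any_rna | f$any_protein,
    "3" = s1 | (f$has_functional & f$has_orthogroup),
    "4" = s1 | f$has_functional | f$has_orthogroup)
  geneIds[sel]
}

#' Write / read a support-flag table
#'
#' Tab-separated, one row per gene (`gene_id` first column, then the six
#' logical flag columns).
#'
#' @param flags `data.frame` from [computeSupport()].
#' @param path File path.
#' @return `path` (write) or the flags `data.frame` (read).
#' @export
writeSupportFlags <- function(flags, path) {
  out <- cbind(gene_id = rownames(flags), flags)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSupportFlags
#' @export
readSupportFlags <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  rownames(tab) <- tab$gene_id
  tab$gene_id <- NULL
  tab
}
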