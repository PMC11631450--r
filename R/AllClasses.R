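#' Hierarchical gene annotation container
#'
#' A `GeneAnnotation` holds a gene/mRNA/exon/CDS hierarchy on genomic
#' coordinates (1-based, closed, the GRanges convention). Gene ranges are
#' derived spans (min start to max end over the gene's transcripts); exon and
#' CDS parts are stored per transcript as `GRangesList` objects. Feature
#' lines of other types read from a GFF3 file (UTRs and the like) are carried
#' verbatim and re-emitted by [writeGFF3()]; they never participate in
#' filtering.
#'
#' Validity requires: unique gene and transcript ids, every transcript's
#' `gene_id` resolving, all parts of a transcript on the gene's seqname and
#' strand, exons sorted and pairwise disjoint, and the merged CDS footprint
#' contained in the merged exon footprint.
#'
#' @slot genes `GRanges` named by gene id.
#' @slot transcripts `GRanges` named by transcript id with a `gene_id`
#'   metadata column.
#' @slot exons `GRangesList` named by transcript id.
#' @slot cds `GRangesList` named by transcript id (elements may be empty).
#' @slot source single character label for the annotation source.
#' @slot extra character vector of verbatim non-core GFF3 lines.
#' @slot extraParent character vector parallel to `extra` holding the first
#'   `Parent` id of each line (`NA` when absent).
#'
#' @seealso [readGFF3()], [writeGFF3()], [curateAnnotation()]
#' @export
setClass("GeneAnnotation",
  slots = c(
    genes = "GRanges",
    transcripts = "GRanges",
    exons = "GRangesList",
    cds = "GRangesList",
    source = "character",
    extra = "character",
    extraParent = "character"
  )
)

setValidity("GeneAnnotation", function(object) {
  g <- object@genes
  tx <- object@transcripts
  msg <- character()
  if (anyDuplicated(names(g))) msg <- c(msg, "duplicated gene ids")
  if (anyDuplicated(names(tx))) msg <- c(msg, "duplicated transcript ids")
  if (length(tx)) {
    gid <- tx$gene_id
    if (is.null(gid) || anyNA(gid)) {
      msg <- c(msg, "transcripts lack gene_id")
    } else if (!all(gid %in% names(g))) {
      bad <- unique(gid[!gid %in% names(g)])
      msg <- c(msg, paste0("unresolved gene_id: ", paste(bad, collapse = ", ")))
    }
  }
  if (!identical(names(object@exons), names(tx)) ||
      !identical(names(object@cds), names(tx))) {
    msg <- c(msg, "exon/cds lists must be named by, and parallel to, transcripts")
  }
  if (length(tx)) {
    for (i in seq_along(tx)) {
      ex <- object@exons[[i]]
      if (length(ex) == 0L) {
        msg <- c(msg, paste0("transcript ", names(tx)[i], " has no exons"))
        next
      }
      if (is.unsorted(GenomicRanges::start(ex)) ||
          !GenomicRanges::isDisjoint(ex)) {
        msg <- c(msg, paste0("exons of ", names(tx)[i],
                             " must be sorted and pairwise disjoint"))
      }
      cd <- object@cds[[i]]
      if (length(cd)) {
        out <- GenomicRanges::setdiff(GenomicRanges::reduce(cd),
                                      GenomicRanges::reduce(ex))
        if (sum(GenomicRanges::width(out)) > 0L) {
          msg <- c(msg, paste0("CDS of ", names(tx)[i],
                               " extends outside its exons"))
        }
      }
      if (length(msg) > 6L) break  # keep messages bounded on badly broken input
    }
    seqOK <- as.character(GenomicRanges::seqnames(tx)) ==
      as.character(GenomicRanges::seqnames(g))[match(tx$gene_id, names(g))]
    strOK <- as.character(GenomicRanges::strand(tx)) ==
      as.character(GenomicRanges::strand(g))[match(tx$gene_id, names(g))]
    if (!all(seqOK & strOK)) {
      msg <- c(msg, "transcripts must share their gene's seqname and strand")
    }
  }
  if (length(object@source) != 1L) msg <- c(msg, "source must be length 1")
  if (length(msg)) msg else TRUE
})

# Internal constructor: derives gene spans from transcripts. `geneStrand` and
# `geneSeq` are taken from the transcripts; callers must have validated
# consistency (readGFF3 reports such problems with gene ids).
newGeneAnnotation <- function(tx, exons, cds, source = "orchardQC",
                              extra = character(), extraParent = character()) {
  stopifnot(identical(names(exons), names(tx)), identical(names(cds), names(tx)))
  if (length(tx)) {
    byGene <- split(seq_along(tx), tx$gene_id)
    gid <- names(byGene)
    gseq <- vapply(byGene, function(i)
      as.character(GenomicRanges::seqnames(tx))[i[1L]], character(1))
    gstr <- vapply(byGene, function(i)
      as.character(GenomicRanges::strand(tx))[i[1L]], character(1))
    gstart <- vapply(byGene, function(i)
      min(GenomicRanges::start(tx)[i]), integer(1))
    gend <- vapply(byGene, function(i)
      max(GenomicRanges::end(tx)[i]), integer(1))
    genes <- GenomicRanges::GRanges(gseq, IRanges::IRanges(gstart, gend),
                                    strand = gstr)
    names(genes) <- gid
  } else {
    genes <- GenomicRanges::GRanges()
  }
  methods::new("GeneAnnotation", genes = genes, transcripts = tx,
               exons = exons, cds = cds, source = source,
               extra = extra, extraParent = extraParent)
}

#' @rdname annotation-accessors
#' @export
setMethod("genes", "GeneAnnotation", function(x) x@genes)

#' @rdname annotation-accessors
#' @export
setMethod("transcripts", "GeneAnnotation", function(x) x@transcripts)

#' @rdname annotation-accessors
#' @export
setMethod("exonRanges", "GeneAnnotation", function(x) x@exons)

#' @rdname annotation-accessors
#' @export
setMethod("cdsRanges", "GeneAnnotation", function(x) x@cds)

#' @rdname annotation-accessors
#' @export
setMethod("geneIds", "GeneAnnotation", function(x) names(x@genes))

#' @rdname annotation-accessors
#' @export
setMethod("txIds", "GeneAnnotation", function(x) names(x@transcripts))

#' @rdname annotation-accessors
#' @export
setMethod("annotationSource", "GeneAnnotation", function(x) x@source)

#' @rdname annotation-accessors
#' @export
setMethod("nGenes", "GeneAnnotation", function(x) length(x@genes))

#' @rdname annotation-accessors
#' @export
setMethod("nTranscripts", "GeneAnnotation", function(x) length(x@transcripts))

setMethod("show", "GeneAnnotation", function(object) {
  cat("GeneAnnotation object\n")
  cat("  source:     ", object@source, "\n", sep = "")
  cat("  genes:      ", length(object@genes), "\n", sep = "")
  cat("  transcripts:", length(object@transcripts), "\n", sep = "")
  sq <- unique(as.character(GenomicRanges::seqnames(object@genes)))
  if (length(sq)) {
    shown <- paste(utils::head(sq, 5), collapse = ", ")
    if (length(sq) > 5) shown <- paste0(shown, ", ...")
    cat("  seqnames:   ", shown, "\n", sep = "")
  }
  if (length(object@extra)) {
    cat("  carried non-core feature lines: ", length(object@extra), "\n",
        sep = "")
  }
})

# Subset an annotation to the given gene ids (order of stored genes kept).
keepGenes <- function(ann, ids) {
  keepTx <- ann@transcripts$gene_id %in% ids
  tx <- ann@transcripts[keepTx]
  newGeneAnnotation(tx, ann@exons[keepTx], ann@cds[keepTx],
                    source = ann@source, extra = ann@extra,
                    extraParent = ann@extraParent)
}

#' Curation report
#'
#' Bookkeeping for [curateAnnotation()]: how many genes were removed by the
#' repeat-overlap filter (type 1) and the same-strand-overlap filter
#' (type 2), how many genes were split because their isoforms fell into
#' disjoint clusters (type 3), and the ids affected by each rule. The count
#' identity `nOutput = nInput - nRemovedType1 - nRemovedType2 -
#' nGenesSplitType3 + nGenesCreatedType3` is enforced by the class validity.
#'
#' @slot nInput,nRemovedType1,nRemovedType2,nGenesSplitType3,nGenesCreatedType3,nOutput
#'   integer counters.
#' @slot type1Ids,type2Ids,type3Ids character vectors of affected gene ids
#'   (for type 3, the ids of the genes that were split).
#' @export
setClass("CurationReport",
  slots = c(
    nInput = "integer", nRemovedType1 = "integer", nRemovedType2 = "integer",
    nGenesSplitType3 = "integer", nGenesCreatedType3 = "integer",
    nOutput = "integer",
    type1Ids = "character", type2Ids = "character", type3Ids = "character"
  )
)

setValidity("CurationReport", function(object) {
  msg <- character()
  expected <- object@nInput - object@nRemovedType1 - object@nRemovedType2 -
    object@nGenesSplitType3 + object@nGenesCreatedType3
  if (object@nOutput != expected) {
    msg <- c(msg, "output gene count inconsistent with per-type counts")
  }
  if (length(intersect(object@type1Ids, object@type2Ids))) {
    msg <- c(msg, "type 1 and type 2 id lists must be disjoint")
  }
  if (length(object@type1Ids) != object@nRemovedType1 ||
      length(object@type2Ids) != object@nRemovedType2 ||
      length(object@type3Ids) != object@nGenesSplitType3) {
    msg <- c(msg, "id list lengths must match the counters")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "CurationReport", function(object) {
  cat("CurationReport\n")
  cat("  input genes:            ", object@nInput, "\n")
  cat("  removed (repeat overlap):", object@nRemovedType1, "\n")
  cat("  removed (strand overlap):", object@nRemovedType2, "\n")
  cat("  split (disjoint isoforms):", object@nGenesSplitType3,
      "->", object@nGenesCreatedType3, "\n")
  cat("  output genes:           ", object@nOutput, "\n")
})

#' @describeIn CurationReport-class turn a report into a one-row data.frame.
#' @param report A `CurationReport`.
#' @export
curationSummary <- function(report) {
  data.frame(
    n_input = report@nInput,
    n_removed_type1 = report@nRemovedType1,
    n_removed_type2 = report@nRemovedType2,
    n_genes_split_type3 = report@nGenesSplitType3,
    n_genes_created_type3 = report@nGenesCreatedType3,
    n_output = report@nOutput
  )
}
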