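#' @import methods
#' @importFrom stats setNames hclust dist median quantile sd aggregate
#' @importFrom utils read.table write.table
#' @importClassesFrom GenomicRanges GRanges GRangesList
NULL

#' Accessors for annotation containers
#'
#' `genes()` returns the gene-level ranges (one range per gene, the span of
#' its transcripts), `transcripts()` the transcript-level ranges with a
#' `gene_id` metadata column, `exonRanges()`/`cdsRanges()` the per-transcript
#' exon and CDS parts as [GenomicRanges::GRangesList] objects named by
#' transcript id.
#'
#' @param x A [GeneAnnotation-class] object.
#' @return A `GRanges` (for `genes`, `transcripts`) or a `GRangesList`
#'   (for `exonRanges`, `cdsRanges`).
#' @name annotation-accessors
#' @aliases genes transcripts exonRanges cdsRanges
#' @examples
#' ann <- exampleAnnotation()
#' genes(ann)
#' exonRanges(ann)
NULL

#' @rdname annotation-accessors
#' @export
setGeneric("genes", function(x) standardGeneric("genes"))

#' @rdname annotation-accessors
#' @export
setGeneric("transcripts", function(x) standardGeneric("transcripts"))

#' @rdname annotation-accessors
#' @export
setGeneric("exonRanges", function(x) standardGeneric("exonRanges"))

#' @rdname annotation-accessors
#' @export
setGeneric("cdsRanges", function(x) standardGeneric("cdsRanges"))

#' @rdname annotation-accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname annotation-accessors
#' @export
setGeneric("txIds", function(x) standardGeneric("txIds"))

#' @rdname annotation-accessors
#' @export
setGeneric("annotationSource", function(x) standardGeneric("annotationSource"))

#' @rdname annotation-accessors
#' @export
setGeneric("nGenes", function(x) standardGeneric("nGenes"))

#' @rdname annotation-accessors
#' @export
setGeneric("nTranscripts", function(x) standardGeneric("nTranscripts"))
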