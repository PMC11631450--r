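# build a GeneAnnotation from a compact gene spec, bypassing GFF3 I/O:
# genes = list(list(id, chr, strand, tx = list(tid = list(exons = 2-col
# matrix, cds = 2-col matrix or NULL))))
makeAnn <- function(genes, source = "test") {
  txList <- list()
  exonsList <- list()
  cdsList <- list()
  for (g in genes) {
    for (tid in names(g$tx)) {
      t <- g$tx[[tid]]
      ex <- t$exons
      gr <- GenomicRanges::GRanges(g$chr,
        IRanges::IRanges(min(ex[, 1]), max(ex[, 2])), strand = g$strand)
      names(gr) <- tid
      gr$gene_id <- g$id
      txList[[tid]] <- gr
      exonsList[[tid]] <- GenomicRanges::GRanges(g$chr,
        IRanges::IRanges(ex[, 1], ex[, 2]), strand = g$strand)
      cd <- t$cds
      cdsList[[tid]] <- if (is.null(cd)) {
        GenomicRanges::GRanges()
      } else {
        GenomicRanges::GRanges(g$chr, IRanges::IRanges(cd[, 1], cd[, 2]),
                               strand = g$strand)
      }
    }
  }
  ids <- names(txList)
  if (length(txList) == 0L) {
    tx <- GenomicRanges::GRanges()
    tx$gene_id <- character(0)
    return(orchardQC:::newGeneAnnotation(tx, GenomicRanges::GRangesList(),
                                         GenomicRanges::GRangesList(),
                                         source = source))
  }
  tx <- suppressWarnings(unname(do.call(c, unname(txList))))
  names(tx) <- ids
  orchardQC:::newGeneAnnotation(tx,
    GenomicRanges::GRangesList(exonsList)[ids],
    GenomicRanges::GRangesList(cdsList)[ids], source = source)
}

# a simple single-transcript gene occupying [s, s+len) with one exon = span
# and cds inset by `inset` on both sides
simpleGene <- function(id, chr, strand, s, len, inset = 10L) {
  list(id = id, chr = chr, strand = strand,
       tx = setNames(list(list(
         exons = rbind(c(s, s + len - 1L)),
         cds = rbind(c(s + inset, s + len - 1L - inset)))),
         paste0(id, ".t1")))
}
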